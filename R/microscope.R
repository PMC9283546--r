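# Microscope emulation: configuration registry (pixel spacings and
# numerical apertures of six commercial systems at their available
# magnifications), parametric Gaussian PSFs, voxel rasterisation of marker
# fields, 3D PSF convolution and z-slice / z-stack extraction.

.microscope_table <- function() {
  # xy pixel spacing (um), z pixel spacing (um), numerical aperture.
  # Footnoted magnifications: gSTED x23 replaces x20, MultiPhoton x25
  # replaces x20; STED additionally has a x25 entry.
  df <- rbind(
    data.frame(microscope = "Airyscan", magnification = c(10, 20, 40, 63, 100),
               xy_um = c(0.13, 0.059, 0.035, 0.033, 0.028),
               z_um = c(1.14, 0.3, 0.15, 0.12, 0.1),
               na = c(0.45, 0.8, 1.3, 1.4, 1.46)),
    data.frame(microscope = "gSTED", magnification = c(23, 40, 63, 100),
               xy_um = c(0.065, 0.055, 0.042, 0.44),
               z_um = c(0.3, 0.20, 0.13, 0.13),
               na = c(0.95, 1.1, 1.4, 1.4)),
    data.frame(microscope = "Lowlight", magnification = c(20, 40, 100),
               xy_um = c(0.21, 0.11, 0.043),
               z_um = c(0.5, 0.3, 0.1),
               na = c(0.5, 0.75, 1.45)),
    data.frame(microscope = "MultiPhoton", magnification = c(10, 25, 40, 63),
               xy_um = c(0.20, 0.54, 0.058, 0.044),
               z_um = c(1.0, 0.25, 0.2, 0.15),
               na = c(0.3, 0.95, 0.85, 1.2)),
    data.frame(microscope = "Phenix", magnification = c(20, 40, 63),
               xy_um = c(0.3, 0.15, 0.095),
               z_um = c(0.8, 0.5, 0.4),
               na = c(1.0, 1.1, 1.15)),
    data.frame(microscope = "STED", magnification = c(20, 25, 40, 63, 100),
               xy_um = c(0.075, 0.06, 0.045, 0.034, 0.035),
               z_um = c(0.4, 0.25, 0.15, 0.1, 0.1),
               na = c(0.75, 0.95, 1.1, 1.4, 1.4))
  )
  rownames(df) <- NULL
  df
}

#' All microscope configurations
#'
#' The registry of 24 (microscope, magnification) configurations with
#' their XY and Z pixel spacings (um) and numerical apertures, including
#' the footnoted magnification substitutions (gSTED x23, MultiPhoton x25)
#' and the additional STED x25 entry.
#'
#' @return data.frame with columns `microscope`, `magnification`, `xy_um`,
#'   `z_um`, `na`.
#' @export
registry_all <- function() .microscope_table()

#' Look up one microscope configuration
#'
#' @param name microscope name (one of Airyscan, gSTED, Lowlight,
#'   MultiPhoton, Phenix, STED; case-insensitive).
#' @param magnification objective magnification.
#' @return an object of class `microscope_config`: a list with `name`,
#'   `magnification`, `xy_spacing_um`, `z_spacing_um`, `na`.
#' @export
registry_lookup <- function(name, magnification) {
  tab <- .microscope_table()
  hit <- tolower(tab$microscope) == tolower(name) &
    tab$magnification == magnification
  if (!any(hit)) {
    valid <- paste(sprintf("%s x%d", tab$microscope, tab$magnification),
                   collapse = ", ")
    stop(sprintf("unknown microscope configuration (%s, x%s); valid: %s",
                 name, magnification, valid))
  }
  row <- tab[which(hit)[1], ]
  structure(list(name = row$microscope, magnification = row$magnification,
                 xy_spacing_um = row$xy_um, z_spacing_um = row$z_um,
                 na = row$na),
            class = "microscope_config")
}

#' @export
print.microscope_config <- function(x, ...) {
  cat(sprintf("<microscope_config> %s x%d: xy %.3g um, z %.3g um, NA %.3g\n",
              x$name, x$magnification, x$xy_spacing_um, x$z_spacing_um,
              x$na))
  invisible(x)
}

new_psf_model <- function(kernel, spacing_um, sigma_um = NULL,
                          sigma_px = NULL) {
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, spacing_um = spacing_um,
                 sigma_um = sigma_um, sigma_px = sigma_px),
            class = "psf_model")
}

#' Parametric (Gaussian) synthetic PSF
#'
#' An anisotropic Gaussian approximation of a confocal PSF with
#' `sigma_xy = 0.21 lambda / NA` and `sigma_z = 0.66 lambda n / NA^2`
#' (scalar-diffraction widths, immersion index n), sampled on the
#' configuration's voxel grid out to `extent_sigmas` and normalised to sum
#' one.  The sampled width per axis is floored at `min_sigma_px` voxels: a
#' PSF distilled from bead images can never be narrower than its sampling
#' pitch, and a sub-voxel kernel would alias point sources onto single
#' voxels.
#'
#' @param config a `microscope_config`.
#' @param emission_wavelength_um emission wavelength (um; default GFP-like
#'   0.519).
#' @param extent_sigmas kernel half-extent in units of sigma.
#' @param n_immersion immersion refractive index (1.515, oil).
#' @param min_sigma_px sampling floor on the per-axis sigma, in voxels.
#' @return an object of class `psf_model`: `kernel` (3D array, odd extents,
#'   sum 1), `spacing_um` (xy, xy, z), `sigma_um` (optical widths before
#'   the sampling floor), `sigma_px` (sampled widths).
#' @export
synthetic_psf <- function(config, emission_wavelength_um = 0.519,
                          extent_sigmas = 4, n_immersion = 1.515,
                          min_sigma_px = 1) {
  stopifnot(emission_wavelength_um > 0, extent_sigmas > 0)
  sigma_xy_um <- 0.21 * emission_wavelength_um / config$na
  sigma_z_um <- 0.66 * emission_wavelength_um * n_immersion / config$na^2
  sx <- max(sigma_xy_um / config$xy_spacing_um, min_sigma_px)
  sz <- max(sigma_z_um / config$z_spacing_um, min_sigma_px)
  gx <- gauss1d(sx, ceiling(extent_sigmas * sx))
  gz <- gauss1d(sz, ceiling(extent_sigmas * sz))
  kernel <- outer(outer(gx, gx), gz)
  new_psf_model(kernel, c(config$xy_spacing_um, config$xy_spacing_um,
                          config$z_spacing_um),
                sigma_um = c(xy = sigma_xy_um, z = sigma_z_um),
                sigma_px = c(xy = sx, z = sz))
}

#' Write / read a PSF volume (plain-text)
#'
#' Stores the normalised 3D kernel with its voxel spacing: a commented
#' header (`spacing_um`, `dims`) followed by the kernel values in
#' column-major order.  On read the kernel is renormalised to sum one and
#' padded (trailing zero planes) to odd extents if needed.
#'
#' @param psf a `psf_model`.
#' @param path file path.
#' @return `read_psf` returns a `psf_model`.
#' @export
write_psf <- function(psf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# focisim psf v1",
               sprintf("# spacing_um: %s",
                       paste(format(psf$spacing_um, digits = 12),
                             collapse = " ")),
               sprintf("# dims: %s", paste(dim(psf$kernel), collapse = " "))),
             con)
  writeLines(format(as.numeric(psf$kernel), digits = 17), con)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) {
      stop("PSF format error: missing header field '", key, "'")
    }
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", m[1]), " +")[[1]])
  }
  spacing <- get("spacing_um")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("PSF format error: spacing_um must be three positive numbers")
  }
  dims <- as.integer(get("dims"))
  vals <- as.numeric(lines[!grepl("^#", lines)])
  if (length(vals) != prod(dims)) {
    stop("PSF format error: expected ", prod(dims), " values, got ",
         length(vals))
  }
  kernel <- array(vals, dims)
  for (d in 1:3) {                       # pad trailing plane to odd extent
    if (dim(kernel)[d] %% 2 == 0) {
      pad_dim <- dim(kernel)
      pad_dim[d] <- 1
      kernel <- abind_along(kernel, array(0, pad_dim), d)
    }
  }
  s <- sum(kernel)
  if (!is.finite(s) || s <= 0) {
    stop("PSF normalization error: kernel sum is ", s)
  }
  new_psf_model(kernel, spacing)
}

# minimal 3D abind (avoids an extra dependency)
abind_along <- function(a, b, d) {
  perm <- c(setdiff(1:3, d), d)
  ap <- aperm(a, perm)
  bp <- aperm(b, perm)
  out <- array(c(ap, bp), c(dim(ap)[1:2], dim(ap)[3] + dim(bp)[3]))
  aperm(out, order(perm))
}

# FFT-based "same" convolution (2D or 3D), zero-padded boundaries.
# Kernel extents must be odd.
fft_convolve_same <- function(vol, kernel) {
  dv <- dim(vol)
  dk <- dim(kernel)
  half <- (dk - 1) %/% 2
  dp <- vapply(dv + dk - 1, function(n) stats::nextn(n, c(2, 3, 5)),
               numeric(1))
  pad <- function(a, d) {
    out <- array(0, dp)
    idx <- lapply(seq_along(d), function(i) seq_len(d[i]))
    do.call(`[<-`, c(list(out), idx, list(a)))
  }
  conv <- Re(stats::fft(stats::fft(pad(vol, dv)) * stats::fft(pad(kernel, dk)),
                        inverse = TRUE)) / prod(dp)
  idx <- lapply(seq_along(dv), function(i) half[i] + seq_len(dv[i]))
  do.call(`[`, c(list(conv), idx))
}

# in-plane one-voxel Gaussian footprint used for deconvolved rendering;
# delta in z (ideal optical sectioning)
deconv_kernel <- function(sigma_px = 1, extent_sigmas = 4) {
  g <- gauss1d(sigma_px, ceiling(extent_sigmas * sigma_px))
  k <- outer(g, g)
  array(k, c(dim(k), 1L))
}

#' Render a marker field as a synthetic microscope image
#'
#' Sources are binned to their nearest voxel on a grid covering the nucleus
#' bounding box plus the kernel half-extent (so no intensity is lost at the
#' borders), then convolved in 3D.  With `deconvolved = FALSE` the kernel
#' is the microscope PSF, including out-of-plane fluorescence leaking
#' between z-planes.  With `deconvolved = TRUE` ("perfect deconvolution",
#' the image formed before the PSF applies) each source instead gets a
#' one-voxel-sigma in-plane Gaussian footprint in its nearest z-plane:
#' band-limited rendering at the grid's Nyquist limit, with no out-of-plane
#' contribution.  `mode = "slice"` returns the single z-plane nearest
#' `z_center_um`; `mode = "stack"` the full volume.
#'
#' @param field a `marker_field`.
#' @param geometry the `nuclear_geometry` (defines the rendered extent).
#' @param config a `microscope_config` (voxel spacing).
#' @param psf a `psf_model`; required unless `deconvolved = TRUE`.
#' @param mode `"slice"` or `"stack"`.
#' @param z_center_um z position of the extracted slice (default 0, the
#'   nuclear mid-plane).
#' @param deconvolved render without the microscope PSF.
#' @param noise_seed if non-`NULL`, apply seeded Poisson photon noise with
#'   `photons_per_unit` expected photons per intensity unit (off by
#'   default; no detector noise is modelled otherwise).
#' @param photons_per_unit photon scale for the optional noise model.
#' @return an object of class `synthetic_image`: `pixels` (2D matrix for a
#'   slice, 3D array for a stack, dimensions x, y\[, z\]), `spacing_um`,
#'   `z_offset_um` (z of the slice centre), and `provenance`.
#' @export
render_image <- function(field, geometry, config, psf = NULL,
                         mode = c("slice", "stack"), z_center_um = 0,
                         deconvolved = FALSE, noise_seed = NULL,
                         photons_per_unit = 100) {
  mode <- match.arg(mode)
  if (!deconvolved && is.null(psf)) {
    stop("psf is required unless deconvolved = TRUE")
  }
  kernel <- if (deconvolved) deconv_kernel() else psf$kernel
  dx <- config$xy_spacing_um
  dz <- config$z_spacing_um
  half <- (dim(kernel) - 1) %/% 2
  nhx <- ceiling(geometry$semi_axes[1] / dx) + half[1]
  nhy <- ceiling(geometry$semi_axes[2] / dx) + half[2]
  nhz <- ceiling(geometry$semi_axes[3] / dz) + half[3]
  dims <- c(2 * nhx + 1, 2 * nhy + 1, 2 * nhz + 1)
  ctr <- c(nhx, nhy, nhz) + 1
  iz_slice <- round(z_center_um / dz) + ctr[3]
  if (iz_slice < 1 || iz_slice > dims[3]) {
    stop("z_center is outside the rendered volume")
  }
  n_src <- nrow(field)
  if (n_src == 0) {
    vol <- array(0, dims)
  } else {
    ix <- round(field$x_um / dx) + ctr[1]
    iy <- round(field$y_um / dx) + ctr[2]
    iz <- round(field$z_um / dz) + ctr[3]
    if (any(ix < 1 + half[1] | ix > dims[1] - half[1] |
              iy < 1 + half[2] | iy > dims[2] - half[2] |
              iz < 1 + half[3] | iz > dims[3] - half[3])) {
      stop("marker source outside the nucleus bounding box")
    }
    occ <- rowsum(field$intensity, paste(ix, iy, iz))
    occ_idx <- do.call(rbind, lapply(strsplit(rownames(occ), " "),
                                     as.integer))
    # direct sparse placement for sparse fields, FFT otherwise
    if (nrow(occ_idx) * prod(dim(kernel)) <= 6 * prod(dims)) {
      vol <- array(0, dims)
      for (k in seq_len(nrow(occ_idx))) {
        xr <- (occ_idx[k, 1] - half[1]):(occ_idx[k, 1] + half[1])
        yr <- (occ_idx[k, 2] - half[2]):(occ_idx[k, 2] + half[2])
        zr <- (occ_idx[k, 3] - half[3]):(occ_idx[k, 3] + half[3])
        vol[xr, yr, zr] <- vol[xr, yr, zr] + occ[k] * as.vector(kernel)
      }
    } else {
      vol <- array(0, dims)
      vol[occ_idx] <- occ[, 1]
      vol <- fft_convolve_same(vol, kernel)
      vol[vol < 0] <- 0    # FFT round-off
    }
  }
  if (!is.null(noise_seed)) {
    set.seed(as.integer(noise_seed))
    vol[] <- stats::rpois(length(vol), vol * photons_per_unit) /
      photons_per_unit
  }
  pixels <- if (mode == "slice") vol[, , iz_slice] else vol
  structure(list(
    pixels = pixels,
    spacing_um = c(dx, dx, dz),
    z_offset_um = (iz_slice - ctr[3]) * dz,
    provenance = list(microscope = config$name,
                      magnification = config$magnification,
                      marker = attr(field, "marker_type"),
                      time_h = attr(field, "time_h"),
                      mode = mode, deconvolved = deconvolved,
                      n_sources = n_src)
  ), class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<synthetic_image> %s, %s x%s, %s marker%s, dims %s, total %.4g\n",
              p$mode, p$microscope, p$magnification, p$marker,
              if (isTRUE(p$deconvolved)) " (deconvolved)" else "",
              paste(dim(as.array(x$pixels)), collapse = "x"),
              sum(x$pixels)))
  invisible(x)
}

#' Write a synthetic image as 32-bit float TIFF
#'
#' Slices become single-page, stacks multi-page TIFFs.  The TIFF sample
#' range is \[0, 1\], so intensities are divided by the image maximum; the
#' scale factor, voxel spacing and provenance are stored in the TIFF
#' description tag.  Foci counting is invariant to this rescaling as long
#' as the threshold reference is taken from (or rescaled to) the same
#' units.
#'
#' @param image a `synthetic_image`.
#' @param path file path.
#' @return the path, invisibly; attribute `scale` carries the divisor.
#' @export
write_image_tiff <- function(image, path) {
  px <- image$pixels
  scale <- max(px, 1e-300)
  px <- px / scale
  desc <- sprintf("focisim: scale=%.9g; spacing_um=%s; %s",
                  scale, paste(format(image$spacing_um), collapse = ","),
                  paste(names(image$provenance),
                        vapply(image$provenance, format, character(1)),
                        sep = "=", collapse = "; "))
  pages <- if (length(dim(px)) == 2) list(px) else
    lapply(seq_len(dim(px)[3]), function(k) px[, , k])
  pages <- lapply(pages, function(pg) {
    attr(pg, "description") <- desc
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  invisible(structure(path, scale = scale))
}
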