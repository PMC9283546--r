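# Synthetic nuclear geometry: a reduced genome segmented into TADs, packed
# as hard spheres into a flattened ellipsoid (default 11.8 x 11.8 x 1.0 um
# radii, matching an IMR90-like flattened nucleus).

#' Default reduced genome
#'
#' A human-like genome scaled down to six chromosomes totalling 600 Mbp, so
#' that hundreds of nuclear geometries can be built in seconds.  Full-size
#' chromosome lengths can be passed to [build_genome()] instead.
#'
#' @return named numeric vector of chromosome lengths in bp.
#' @export
default_chromosomes <- function() {
  c(chr1 = 150e6, chr2 = 130e6, chr3 = 110e6,
    chr4 = 90e6, chr5 = 70e6, chr6 = 50e6)
}

#' Segment a genome into TADs
#'
#' Tiles each chromosome with contiguous TAD intervals whose sizes are drawn
#' from a normal distribution truncated at zero (the last TAD of each
#' chromosome is truncated to fit).  This is a synthetic stand-in for a
#' Hi-C-derived TAD segmentation: the downstream model only needs each TAD's
#' genomic interval.
#'
#' @param chromosome_lengths numeric vector of chromosome lengths (bp);
#'   names are used as chromosome ids (defaults to `chr1`, `chr2`, ...).
#' @param tad_size_mean,tad_size_sd mean and standard deviation of the TAD
#'   size distribution (bp).  `tad_size_sd = 0` gives exact tiling.
#' @param seed integer seed; the segmentation is deterministic per seed.
#' @return an object of class `genome_model`: a list with `chromosomes`
#'   (data.frame `chrom`, `length_bp`) and `tads` (data.frame `chrom`,
#'   `start_bp`, `end_bp`).
#' @export
build_genome <- function(chromosome_lengths = default_chromosomes(),
                         tad_size_mean = 1e6, tad_size_sd = 0.25e6,
                         seed = 1L) {
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (tad_size_mean <= 0) stop("tad_size_mean must be > 0")
  if (tad_size_sd < 0) stop("tad_size_sd must be >= 0")
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  }
  set.seed(as.integer(seed))
  tads <- list()
  for (ci in seq_along(chromosome_lengths)) {
    len <- chromosome_lengths[[ci]]
    pos <- 0
    starts <- ends <- numeric(0)
    while (pos < len) {
      size <- if (tad_size_sd == 0) tad_size_mean else {
        s <- -1
        while (s <= 0) s <- stats::rnorm(1, tad_size_mean, tad_size_sd)
        round(s)
      }
      end <- min(pos + size, len)
      starts <- c(starts, pos)
      ends <- c(ends, end)
      pos <- end
    }
    tads[[ci]] <- data.frame(chrom = names(chromosome_lengths)[ci],
                             start_bp = starts, end_bp = ends,
                             stringsAsFactors = FALSE)
  }
  structure(list(
    chromosomes = data.frame(chrom = names(chromosome_lengths),
                             length_bp = as.numeric(chromosome_lengths),
                             stringsAsFactors = FALSE),
    tads = do.call(rbind, tads)
  ), class = "genome_model")
}

#' Total genome length in bp
#' @param genome a `genome_model`.
#' @export
genome_length <- function(genome) sum(genome$chromosomes$length_bp)

#' Pack TAD beads into a nuclear ellipsoid
#'
#' Each TAD becomes a sphere whose volume is proportional to its genomic
#' content at the given packing density.  Centres are placed by rejection
#' sampling: beads must lie inside the ellipsoid (shrunk by the bead radius
#' so the whole sphere fits) and must not overlap previously placed beads;
#' beads of the same chromosome are placed within twice the summed radii of
#' their chromosomal predecessor to mimic polymer connectivity.  After a
#' bounded number of attempts the overlap constraint (and finally the
#' connectivity constraint) is relaxed with a warning, guaranteeing
#' termination.
#'
#' @param genome a `genome_model` from [build_genome()].
#' @param semi_axes ellipsoid semi-axes (a, b, c) in um; z is the optical
#'   axis.
#' @param bead_density_bp_per_um3 packing density converting genomic content
#'   to bead volume.  The default (1e7 bp/um^3) puts ~10% of the default
#'   nuclear volume into chromatin beads.
#' @param seed integer seed; geometries are byte-identical per seed.
#' @param geometry_id optional identifier stored with the geometry.
#' @param max_attempts rejection attempts per bead before relaxing the
#'   overlap constraint.
#' @return an object of class `nuclear_geometry`: a list with `semi_axes`,
#'   `beads` (data.frame `bead_id`, `chrom`, `start_bp`, `end_bp`, `x_um`,
#'   `y_um`, `z_um`, `radius_um`), `geometry_id` and `seed`.
#' @export
pack_geometry <- function(genome, semi_axes = c(11.8, 11.8, 1.0),
                          bead_density_bp_per_um3 = 1e7,
                          seed = 1L, geometry_id = 1L,
                          max_attempts = 1000L) {
  if (any(semi_axes <= 0)) stop("semi-axes must be > 0")
  if (bead_density_bp_per_um3 <= 0) stop("bead density must be > 0")
  tads <- genome$tads
  if (nrow(tads) == 0) stop("genome has no TADs")
  content <- tads$end_bp - tads$start_bp
  radius <- (3 * (content / bead_density_bp_per_um3) / (4 * pi))^(1 / 3)
  if (any(radius >= 0.95 * min(semi_axes))) {
    stop("packing infeasible: bead radius ", signif(max(radius), 3),
         " um does not fit semi-axes (", paste(semi_axes, collapse = ", "),
         "); lower tad_size_mean or raise bead_density_bp_per_um3")
  }
  set.seed(as.integer(seed))
  n <- nrow(tads)
  centers <- matrix(NA_real_, n, 3)
  n_relaxed <- 0L
  batch <- 64L
  for (i in seq_len(n)) {
    r <- radius[i]
    shrunk <- pmax(semi_axes - r, 0.05 * semi_axes)
    prev <- if (i > 1 && tads$chrom[i] == tads$chrom[i - 1]) i - 1L else NA
    placed <- centers[seq_len(i - 1), , drop = FALSE]
    placed_r <- radius[seq_len(i - 1)]
    candidate <- NULL
    attempts <- 0L
    while (is.null(candidate) && attempts < max_attempts) {
      cand <- if (is.na(prev)) {
        runif_in_ellipsoid(batch, shrunk)
      } else {
        runif_in_sphere(batch, centers[prev, ], 2 * (radius[prev] + r))
      }
      ok <- inside_ellipsoid(cand, shrunk)
      if (i > 1 && any(ok)) {
        idx <- which(ok)
        d2 <- outer(rowSums(cand[idx, , drop = FALSE]^2), rowSums(placed^2), "+") -
          2 * cand[idx, , drop = FALSE] %*% t(placed)
        min_gap <- sweep(sqrt(pmax(d2, 0)), 2, placed_r + r, "-")
        ok[idx] <- apply(min_gap, 1, min) >= 0
      }
      if (any(ok)) candidate <- cand[which(ok)[1], ]
      attempts <- attempts + batch
    }
    if (is.null(candidate)) {
      # relax overlap, keep connectivity + containment; then fully relax
      n_relaxed <- n_relaxed + 1L
      cand <- if (is.na(prev)) {
        runif_in_ellipsoid(batch, shrunk)
      } else {
        runif_in_sphere(4L * batch, centers[prev, ], 2 * (radius[prev] + r))
      }
      ok <- inside_ellipsoid(cand, shrunk)
      candidate <- if (any(ok)) cand[which(ok)[1], ] else
        runif_in_ellipsoid(1, shrunk)[1, ]
    }
    centers[i, ] <- candidate
  }
  if (n_relaxed > 0) {
    warning(sprintf("pack_geometry: overlap constraint relaxed for %d of %d beads",
                    n_relaxed, n), call. = FALSE)
  }
  structure(list(
    semi_axes = as.numeric(semi_axes),
    beads = data.frame(bead_id = seq_len(n), chrom = tads$chrom,
                       start_bp = tads$start_bp, end_bp = tads$end_bp,
                       x_um = centers[, 1], y_um = centers[, 2],
                       z_um = centers[, 3], radius_um = radius,
                       stringsAsFactors = FALSE),
    geometry_id = geometry_id, seed = as.integer(seed)
  ), class = "nuclear_geometry")
}

#' @export
print.nuclear_geometry <- function(x, ...) {
  cat(sprintf("<nuclear_geometry #%s> %d beads, semi-axes (%.3g, %.3g, %.3g) um, seed %d\n",
              x$geometry_id, nrow(x$beads), x$semi_axes[1], x$semi_axes[2],
              x$semi_axes[3], x$seed))
  invisible(x)
}

#' Serialize / read a nuclear geometry (plain-text)
#'
#' One file per geometry: a commented header carrying `semi_axes_um`,
#' `geometry_id` and `seed`, followed by a tab-separated bead table with the
#' bead centres (um), radii (um) and genomic intervals.
#'
#' @param geometry a `nuclear_geometry`.
#' @param path file path.
#' @return `read_geometry` returns a `nuclear_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# focisim geometry v1"),
    sprintf("# semi_axes_um: %s",
            paste(format(geometry$semi_axes, digits = 12), collapse = " ")),
    sprintf("# geometry_id: %s", geometry$geometry_id),
    sprintf("# seed: %d", geometry$seed)
  ), con)
  utils::write.table(geometry$beads, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) stop("geometry file missing header field: ", key)
    strsplit(sub(paste0("^# ", key, ": *"), "", m[1]), " +")[[1]]
  }
  semi <- as.numeric(get("semi_axes_um"))
  beads <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  structure(list(semi_axes = semi, beads = beads,
                 geometry_id = get("geometry_id"),
                 seed = as.integer(get("seed"))),
            class = "nuclear_geometry")
}
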