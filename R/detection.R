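# Scale-space Laplacian-of-Gaussian (LoG) blob detection for foci
# counting, identical machinery in 2D (single slice) and 3D (stack).

#' LoG detector parameters
#'
#' The two fixed parameter sets used for counting: direct marker
#' `(min 2, max 20, num 1, threshold 8%)` and gamma-H2AX marker
#' `(min 2, max 20, num 3, threshold 4%)`.  Sigmas are in pixels, so the
#' same numbers apply across magnifications and to both 2D and 3D
#' analyses.  `num_sigma = 1` means single-scale detection at `min_sigma`;
#' otherwise scales are log-spaced in `[min_sigma, max_sigma]`.
#'
#' @param min_sigma,max_sigma blob scale range in pixels.
#' @param num_sigma number of scales.
#' @param threshold_percent detection threshold as a percentage of the
#'   reference maximum intensity (see [reference_max()]).
#' @return a list of class `log_params`.
#' @export
log_params <- function(min_sigma = 2, max_sigma = 20, num_sigma = 1L,
                       threshold_percent = 8) {
  stopifnot(min_sigma > 0, max_sigma >= min_sigma, num_sigma >= 1,
            threshold_percent > 0, threshold_percent < 100)
  structure(list(min_sigma = min_sigma, max_sigma = max_sigma,
                 num_sigma = as.integer(num_sigma),
                 threshold_percent = threshold_percent),
            class = "log_params")
}

#' Preset detector parameters per marker
#' @param marker `"direct"` or `"gh2ax"`.
#' @export
log_params_for_marker <- function(marker = c("direct", "gh2ax")) {
  switch(match.arg(marker),
         direct = log_params(2, 20, 1L, 8),
         gh2ax = log_params(2, 20, 3L, 4))
}

log_scales <- function(params) {
  if (params$num_sigma == 1) return(params$min_sigma)
  exp(seq(log(params$min_sigma), log(params$max_sigma),
          length.out = params$num_sigma))
}

# sampled scale-normalised LoG kernel, -sigma^2 * laplacian(G_sigma),
# d = 2 or 3; zero-sum so constant backgrounds give zero response
log_kernel <- function(sigma, ndim) {
  h <- max(ceiling(4 * sigma), 2L)
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (ndim == 2) {
    G <- outer(g, g)
    F <- outer(rep(1, length(x)), rep(1, length(x))) *
      (2 - (outer(x^2, x^2, "+")) / sigma^2)
  } else {
    G <- outer(outer(g, g), g)
    s2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
    F <- 3 - s2 / sigma^2
  }
  K <- G * F
  K - mean(K)
}

#' Scale-normalised LoG response of an image
#'
#' Convolution with the sampled `-sigma^2 * Laplacian(Gaussian)` kernel
#' (zero-padded boundaries); bright blobs of radius ~ sigma*sqrt(d) give
#' positive peaks.
#'
#' @param pixels 2D matrix or 3D array.
#' @param sigma scale in pixels.
#' @export
log_response <- function(pixels, sigma) {
  nd <- length(dim(pixels))
  stopifnot(nd %in% c(2, 3))
  fft_convolve_same(pixels, log_kernel(sigma, nd))
}

#' Threshold anchor: maximum intensity of the 15-minute images
#'
#' The detection threshold for one simulation set-up is a percentage of
#' the maximum voxel intensity of that set-up's image(s) at the 15 min
#' time point; the same absolute threshold is reused for all other time
#' points, so later, dimmer images can never gain detections from a lower
#' anchor.
#'
#' @param setup_images_at_15min list of `synthetic_image` objects (or bare
#'   arrays) from one set-up at 15 min.
#' @return the maximum voxel intensity.
#' @export
reference_max <- function(setup_images_at_15min) {
  if (length(setup_images_at_15min) == 0) {
    stop("reference_max needs at least one image")
  }
  m <- max(vapply(setup_images_at_15min, function(im) {
    px <- if (inherits(im, "synthetic_image")) im$pixels else im
    max(px)
  }, numeric(1)))
  if (m <= 0) stop("threshold undefined: 15-min images are all zero")
  m
}

# local maxima of arr (strictly above threshold, >= all touching
# neighbours); returns index matrix
local_maxima <- function(arr, threshold) {
  d <- dim(arr)
  nd <- length(d)
  cand <- arr > threshold
  if (!any(cand)) {
    return(matrix(integer(0), ncol = nd))
  }
  padded <- array(-Inf, d + 2)
  idx_in <- lapply(d, function(n) 1 + seq_len(n))
  padded <- do.call(`[<-`, c(list(padded), idx_in, list(arr)))
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  is_max <- cand
  for (r in seq_len(nrow(offsets))) {
    if (all(offsets[r, ] == 0)) next
    shifted <- do.call(`[`, c(list(padded), lapply(seq_len(nd), function(i) {
      1 + offsets[r, i] + seq_len(d[i])
    })))
    is_max <- is_max & (arr >= shifted)
    if (!any(is_max)) break
  }
  which(is_max, arr.ind = TRUE)
}

# blob radius in pixels at detection scale
blob_radius <- function(sigma, ndim) sigma * sqrt(ndim)

# fraction of the smaller blob's area/volume shared with the larger
blob_overlap <- function(d, r1, r2, ndim) {
  lo <- min(r1, r2)
  hi <- max(r1, r2)
  if (d >= r1 + r2) return(0)
  if (d <= hi - lo) return(1)
  if (ndim == 2) {
    a1 <- lo^2 * acos(pmin(pmax((d^2 + lo^2 - hi^2) / (2 * d * lo), -1), 1))
    a2 <- hi^2 * acos(pmin(pmax((d^2 + hi^2 - lo^2) / (2 * d * hi), -1), 1))
    tri <- 0.5 * sqrt(pmax((-d + lo + hi) * (d + lo - hi) *
                             (d - lo + hi) * (d + lo + hi), 0))
    (a1 + a2 - tri) / (pi * lo^2)
  } else {
    inter <- pi * (r1 + r2 - d)^2 *
      (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
    inter / (4 / 3 * pi * lo^3)
  }
}

# drop the weaker of any two detections whose blobs overlap > 50%
prune_blobs <- function(det, ndim, overlap = 0.5) {
  if (nrow(det) <= 1) return(det)
  ord <- order(-det$response)
  det <- det[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  coords <- as.matrix(det[, seq_len(ndim), drop = FALSE])
  for (i in seq_len(nrow(det) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(det))) {
      if (!keep[j]) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      ri <- blob_radius(det$sigma_px[i], ndim)
      rj <- blob_radius(det$sigma_px[j], ndim)
      if (blob_overlap(d, ri, rj, ndim) > overlap) keep[j] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' Detect foci with scale-space LoG
#'
#' Computes scale-normalised LoG responses at the parameter scales, finds
#' local maxima in space (and, for multi-scale detection, across adjacent
#' scales) strictly above `threshold_percent/100 * reference`, and prunes
#' overlapping detections by the conventional >50%-overlap rule, keeping
#' the stronger response.  Identical machinery for 2D slices and 3D
#' stacks.
#'
#' @param image a `synthetic_image` or bare 2D/3D array.
#' @param params a [log_params()].
#' @param reference threshold anchor intensity, from [reference_max()]
#'   (> 0).
#' @return an object of class `foci_set`: `detections` (data.frame
#'   `x_px`, `y_px`\[, `z_px`\], `sigma_px`, `response`), `count`,
#'   `threshold_abs`.
#' @export
detect_foci <- function(image, params = log_params(), reference) {
  stopifnot(reference > 0)
  pixels <- if (inherits(image, "synthetic_image")) image$pixels else image
  nd <- length(dim(pixels))
  stopifnot(nd %in% c(2, 3))
  thr <- params$threshold_percent / 100 * reference
  scales <- log_scales(params)
  resp <- lapply(scales, function(s) log_response(pixels, s))
  det <- list()
  for (si in seq_along(scales)) {
    pk <- local_maxima(resp[[si]], thr)
    if (nrow(pk) == 0) next
    v <- resp[[si]][pk]
    keep <- rep(TRUE, nrow(pk))
    if (si > 1) keep <- keep & v >= resp[[si - 1]][pk]
    if (si < length(scales)) keep <- keep & v >= resp[[si + 1]][pk]
    if (!any(keep)) next
    pk <- pk[keep, , drop = FALSE]
    d <- data.frame(x_px = pk[, 1], y_px = pk[, 2])
    if (nd == 3) d$z_px <- pk[, 3]
    d$sigma_px <- scales[si]
    d$response <- v[keep]
    det[[length(det) + 1]] <- d
  }
  det <- if (length(det)) do.call(rbind, det) else {
    d <- data.frame(x_px = numeric(0), y_px = numeric(0))
    if (nd == 3) d$z_px <- numeric(0)
    d$sigma_px <- numeric(0)
    d$response <- numeric(0)
    d
  }
  det <- prune_blobs(det, nd)
  rownames(det) <- NULL
  structure(list(detections = det, count = nrow(det), threshold_abs = thr),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci (threshold %.4g)\n", x$count,
              x$threshold_abs))
  invisible(x)
}

#' Export detections as CSV
#'
#' One row per detection (`image_id,y_px,x_px[,z_px],sigma_px,response`)
#' plus the count and absolute threshold, for hand-off to external foci
#' counters.
#'
#' @param foci a `foci_set`.
#' @param path file path.
#' @param image_id identifier written with each row.
#' @param param_set label of the parameter set used.
#' @export
write_foci_csv <- function(foci, path, image_id = "image", param_set = "") {
  det <- foci$detections
  det$image_id <- image_id
  det$n_foci <- foci$count
  det$threshold_abs <- foci$threshold_abs
  det$param_set <- param_set
  utils::write.csv(det, path, row.names = FALSE)
  invisible(path)
}
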