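# Internal helpers: seeding, ellipsoid geometry, uniform sampling.

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one master seed into independent per-stage seeds via a small
#' deterministic integer recurrence, so any single pipeline stage can be
#' re-run in isolation.  All arithmetic stays below 2^53 so the result is
#' exact in doubles, and the returned value is always in \[1, 2^31 - 2\].
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... further integer-valued components (stage codes, indices).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  stopifnot(all(is.finite(parts)))
  h <- 104729
  for (p in parts) {
    h <- (h * 31 + (as.numeric(p) %% 2147483647) * 7919) %% 2147483629
  }
  as.integer(h %% 2147483561 + 1)
}

# quadratic form (x/a)^2 + (y/b)^2 + (z/c)^2 for points (n x 3)
ellipsoid_q <- function(xyz, semi_axes) {
  xyz <- matrix(xyz, ncol = 3)
  (xyz[, 1] / semi_axes[1])^2 + (xyz[, 2] / semi_axes[2])^2 +
    (xyz[, 3] / semi_axes[3])^2
}

inside_ellipsoid <- function(xyz, semi_axes, tol = 1e-9) {
  ellipsoid_q(xyz, semi_axes) <= 1 + tol
}

ellipsoid_volume_um3 <- function(semi_axes) {
  4 / 3 * pi * prod(semi_axes)
}

# n uniform points in the unit sphere, scaled by r, centred at center
runif_in_sphere <- function(n, center = c(0, 0, 0), r = 1) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  rad <- r * stats::runif(n)^(1 / 3)
  sweep(v * rad, 2, center, "+")
}

# n uniform points in the (possibly shrunken) ellipsoid, by rejection
runif_in_ellipsoid <- function(n, semi_axes) {
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, -semi_axes[1], semi_axes[1]),
                  stats::runif(m, -semi_axes[2], semi_axes[2]),
                  stats::runif(m, -semi_axes[3], semi_axes[3]))
    out <- rbind(out, cand[inside_ellipsoid(cand, semi_axes), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sampled, sum-normalised 1D Gaussian on -h:h
gauss1d <- function(sigma, h = ceiling(4 * sigma)) {
  h <- max(h, 1L)
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}
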