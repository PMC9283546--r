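# Shared fixtures and independent oracles used across the suite.

# small two-chromosome geometry (8 beads) inside a 3 x 3 x 1 um nucleus
small_geometry <- function(seed = 1L, semi_axes = c(3, 3, 1)) {
  gen <- build_genome(c(chrA = 4e6, chrB = 2e6), tad_size_mean = 1e6,
                      tad_size_sd = 0.2e6, seed = seed)
  pack_geometry(gen, semi_axes = semi_axes, seed = seed + 1000L)
}

# a bare marker field at given coordinates (unit intensity)
point_field <- function(x, y, z, intensity = rep(1, length(x)),
                        marker = "direct", time_h = 0.25) {
  structure(data.frame(x_um = x, y_um = y, z_um = z,
                       intensity = intensity),
            marker_type = marker, time_h = time_h,
            class = c("marker_field", "data.frame"))
}

# exhaustive maximum matching size for strand-break pairing (<= 12 breaks):
# recursion over all ways to pair compatible opposite-strand breaks
oracle_max_matching <- function(breaks, compatible) {
  n <- nrow(breaks)
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (compatible(breaks[i, ], breaks[j, ])) {
          pairs[[length(pairs) + 1]] <- c(i, j)
        }
      }
    }
  }
  best <- 0L
  recurse <- function(used, k, size) {
    best <<- max(best, size)
    if (k > length(pairs)) return(invisible())
    for (m in seq(k, length.out = length(pairs) - k + 1)) {
      p <- pairs[[m]]
      if (!used[p[1]] && !used[p[2]]) {
        used2 <- used
        used2[p] <- TRUE
        recurse(used2, m + 1, size + 1L)
      }
    }
  }
  recurse(rep(FALSE, n), 1L, 0L)
  best
}

# O(n^2) double-loop clustering oracle
oracle_clustering <- function(xyz, radius_um) {
  n <- nrow(xyz)
  if (n == 1) return(0)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= radius_um) total <- total + 1
    }
  }
  total / n
}

# exact two-sided Mann-Whitney p for tiny samples by full enumeration of
# all rank assignments
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  u_stat <- function(ix) {
    xs <- all_v[ix]
    ys <- all_v[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(all_v), n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}
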