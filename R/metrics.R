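# Miscount statistics, slice ground truth, the 200-nm clustering metric,
# kinetics normalisation and Mann-Whitney/Bonferroni comparisons.

#' Ground-truth DSBs inside one microscope slice
#'
#' Counts DSBs whose z lies in the half-open one-z-pixel window
#' `[z_center - z_spacing/2, z_center + z_spacing/2)` - the volume a
#' single voxel plane samples.
#'
#' @param dsbs_surviving DSB data.frame.
#' @param z_center_um slice centre (um).
#' @param z_spacing_um z pixel spacing (um), > 0.
#' @export
dsbs_in_slice <- function(dsbs_surviving, z_center_um = 0, z_spacing_um) {
  stopifnot(z_spacing_um > 0)
  sum(dsbs_surviving$z_um >= z_center_um - z_spacing_um / 2 &
        dsbs_surviving$z_um < z_center_um + z_spacing_um / 2)
}

#' Percentage foci miscount
#'
#' The symmetric percentage difference
#' `(counted - simulated) / ((counted + simulated) * 0.5) * 100`,
#' in (-200, 200]; positive for over-counting.
#'
#' @param counted detected foci.
#' @param simulated ground-truth DSBs in the evaluated region.
#' @return the percentage (vectorised); `NA` with a message where both
#'   inputs are zero (undefined, excluded from aggregates).
#' @export
percent_miscount <- function(counted, simulated) {
  out <- (counted - simulated) / ((counted + simulated) * 0.5) * 100
  und <- counted + simulated == 0
  if (any(und)) {
    message(sum(und), " percent-miscount value(s) undefined ",
            "(counted = simulated = 0); returned NA")
    out[und] <- NA_real_
  }
  out
}

#' DSB clustering metric
#'
#' The average number of other DSBs within `radius_nm` of each DSB
#' (Euclidean, whole nucleus).  Higher doses, higher LET and earlier time
#' points raise it, condensing those parameters into one spatial-density
#' metric.
#'
#' @param dsbs_surviving DSB data.frame with at least one row.
#' @param radius_nm proximity radius in nm (default 200).
#' @return a list of class `clustering_value`: `radius_nm`, `value`.
#' @export
clustering_metric <- function(dsbs_surviving, radius_nm = 200) {
  n <- nrow(dsbs_surviving)
  if (n == 0) stop("clustering metric undefined for an empty DSB set")
  value <- if (n == 1) 0 else {
    d <- stats::dist(dsbs_surviving[, c("x_um", "y_um", "z_um")])
    2 * sum(d <= radius_nm / 1000) / n
  }
  structure(list(radius_nm = radius_nm, value = value),
            class = "clustering_value")
}

#' Normalise a repair-kinetics series to a reference time point
#'
#' Divides each count by the count at `t_ref_h` (conventionally 15 min,
#' allowing the damage response to recruit observable proteins), so series
#' with different initial yields can be compared.
#'
#' @param counts numeric counts per time point.
#' @param time_h the matching time grid (hours).
#' @param t_ref_h reference time (must be on the grid, count > 0).
#' @return fractions, 1.0 at the reference.
#' @export
normalize_kinetics <- function(counts, time_h, t_ref_h = 0.25) {
  k <- match(t_ref_h, time_h)
  if (is.na(k)) stop("t_ref = ", t_ref_h, " h is not on the time grid")
  if (counts[k] == 0) stop("count at the reference time point is zero")
  counts / counts[k]
}

#' Significance category for an (adjusted) p value
#'
#' Nested bins: `ns` > 0.05 >= `*` > 0.01 >= `**` > 1e-3 >= `***` > 1e-4
#' >= `****`.
#'
#' @param p p values (vectorised).
#' @export
significance_category <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 0.01, 0.05, Inf),
                   labels = c("****", "***", "**", "*", "ns"), right = TRUE))
}

#' Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney U for each requested pair of groups (exact for
#' combined n <= 20 without ties, normal approximation with tie/continuity
#' correction otherwise), Bonferroni-adjusted over the number of
#' comparisons, with the significance category of the adjusted p.
#'
#' @param samples named list of numeric vectors (the labelled groups).
#' @param comparisons list of length-2 character vectors of group labels;
#'   default: all pairs.
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_raw`, `p_adj`, `category`.
#' @export
mann_whitney_bonferroni <- function(samples, comparisons = NULL) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(samples), 2, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% names(samples))) {
      stop("unknown group label(s): ",
           paste(setdiff(cmp, names(samples)), collapse = ", "))
    }
    x <- samples[[cmp[1]]]
    y <- samples[[cmp[2]]]
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided",
      exact = (length(x) + length(y)) <= 20))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1   # degenerate case: all values tied
    data.frame(group1 = cmp[1], group2 = cmp[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p_raw = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$category <- significance_category(out$p_adj)
  out
}
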