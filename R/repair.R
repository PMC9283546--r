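# Bi-exponential DSB repair kinetics, applied identically to every
# radiation quality so that only miscounting can alter perceived kinetics.

#' Bi-exponential repair parameters
#'
#' Remaining-fraction model `f(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)` with
#' a fast and a slow component; the defaults are the gamma-ray fit used
#' throughout (a1 = 0.711, a2 = 0.289, tau1 = 1.54 h, tau2 = 10 h).
#'
#' @param a1,a2 component amplitudes (a1 + a2 = 1 for a normalised model).
#' @param tau1_h,tau2_h component time constants in hours, > 0.
#' @return a list of class `repair_params`.
#' @export
repair_params <- function(a1 = 0.711, a2 = 0.289, tau1_h = 1.54,
                          tau2_h = 10) {
  stopifnot(tau1_h > 0, tau2_h > 0, a1 >= 0, a2 >= 0)
  structure(list(a1 = a1, a2 = a2, tau1_h = tau1_h, tau2_h = tau2_h),
            class = "repair_params")
}

#' Fraction of DSBs remaining at time t
#'
#' @param t_h time after irradiation in hours (vectorised, >= 0).
#' @param params a [repair_params()].
#' @return `a1 exp(-t/tau1) + a2 exp(-t/tau2)`, strictly decreasing in t.
#' @export
remaining_fraction <- function(t_h, params = repair_params()) {
  if (any(t_h < 0)) stop("t must be >= 0")
  params$a1 * exp(-t_h / params$tau1_h) + params$a2 * exp(-t_h / params$tau2_h)
}

#' Integer number of DSBs surviving at time t
#'
#' The ceiling of `n0 * remaining_fraction(t)`, so a nucleus keeps its last
#' break until the remaining fraction has fully decayed.
#'
#' @param n0 initial DSB count (>= 0).
#' @inheritParams remaining_fraction
#' @export
surviving_count <- function(n0, t_h, params = repair_params()) {
  if (any(n0 < 0)) stop("n0 must be >= 0")
  as.integer(ceiling(n0 * remaining_fraction(t_h, params)))
}

#' Schedule repair times over a time grid
#'
#' At each time point a uniformly random (seeded) subset of the previously
#' surviving DSBs is removed so that the survivor count equals
#' [surviving_count()].  Removal is nested: a repaired DSB never reappears.
#' Each DSB's `repair_time_h` is set to the first grid time at which it is
#' absent (`Inf` if it survives the whole grid).  Which DSBs are repaired
#' is exchangeable by construction, matching a single repair rate applied
#' uniformly to all breaks.
#'
#' @param dsbs DSB data.frame.
#' @param time_points_h sorted ascending time grid in hours, starting at 0.
#' @param params a [repair_params()].
#' @param seed integer seed.
#' @return a list of class `repair_timeline`: `time_h`, `surviving` (list
#'   of `dsb_id` vectors per time point), `dsbs` (input with
#'   `repair_time_h` filled in).
#' @export
schedule_repair <- function(dsbs, time_points_h = c(0, 0.25, 0.5, 2, 6, 24),
                            params = repair_params(), seed = 1L) {
  if (is.unsorted(time_points_h, strictly = TRUE)) {
    stop("time points must be sorted strictly ascending")
  }
  if (time_points_h[1] != 0) stop("first time point must be 0")
  n0 <- nrow(dsbs)
  set.seed(as.integer(seed))
  perm <- if (n0 > 0) sample(n0) else integer(0)   # repair order (last first)
  counts <- surviving_count(n0, time_points_h, params)
  surviving <- lapply(counts, function(k) sort(dsbs$dsb_id[perm[seq_len(k)]]))
  names(surviving) <- format(time_points_h)
  repair_time <- rep(Inf, n0)
  for (k in seq_along(time_points_h)[-1]) {
    gone <- perm[seq(counts[k] + 1, length.out = counts[k - 1] - counts[k])]
    repair_time[gone] <- pmin(repair_time[gone], time_points_h[k])
  }
  dsbs$repair_time_h <- repair_time
  structure(list(time_h = time_points_h, surviving = surviving, dsbs = dsbs,
                 seed = as.integer(seed)),
            class = "repair_timeline")
}

#' Surviving DSB records at one grid time
#'
#' @param timeline a `repair_timeline`.
#' @param t_h a time on the timeline's grid.
#' @export
surviving_dsbs <- function(timeline, t_h) {
  k <- match(t_h, timeline$time_h)
  if (is.na(k)) stop("t = ", t_h, " h is not on the timeline grid")
  timeline$dsbs[timeline$dsbs$dsb_id %in% timeline$surviving[[k]], ,
                drop = FALSE]
}

#' Export a repair timeline as CSV
#'
#' One row per time point with the comma-separated surviving `dsb_id`s.
#' @param timeline a `repair_timeline`.
#' @param path file path.
#' @export
write_timeline_csv <- function(timeline, path) {
  utils::write.csv(data.frame(
    time_h = timeline$time_h,
    dsb_ids_surviving = vapply(timeline$surviving, paste,
                               character(1), collapse = ";")
  ), path, row.names = FALSE)
  invisible(path)
}

#' Refit bi-exponential repair parameters from surviving counts
#'
#' Least-squares fit of `(a1, tau1, tau2)` (with `a2 = 1 - a1`) to
#' surviving counts observed over a time grid.  Because the scheduler takes
#' the ceiling of `n0 f(t)`, observed counts at t > 0 sit on average 1/2
#' above `n0 f(t)`; `bias_correct = TRUE` (default) subtracts that offset
#' before fitting, giving an unbiased moment estimator.
#'
#' @param counts data.frame with columns `time_h`, `count`, `n0`
#'   (per-nucleus initial count).
#' @param start starting values for the optimiser.
#' @param bias_correct subtract the ceiling offset of 1/2 at t > 0.
#' @return a [repair_params()] with the fitted values.
#' @export
fit_repair_params <- function(counts,
                              start = list(a1 = 0.5, tau1_h = 1, tau2_h = 8),
                              bias_correct = TRUE) {
  stopifnot(all(c("time_h", "count", "n0") %in% names(counts)))
  y <- counts$count - if (bias_correct) ifelse(counts$time_h > 0, 0.5, 0) else 0
  fit <- minpack.lm::nlsLM(
    y ~ n0 * (a1 * exp(-time_h / tau1_h) + (1 - a1) * exp(-time_h / tau2_h)),
    data = data.frame(y = y, time_h = counts$time_h, n0 = counts$n0),
    start = start,
    lower = c(a1 = 0, tau1_h = 1e-3, tau2_h = 1e-3),
    upper = c(a1 = 1, tau1_h = 100, tau2_h = 1000))
  cf <- stats::coef(fit)
  repair_params(a1 = unname(cf["a1"]), a2 = 1 - unname(cf["a1"]),
                tau1_h = unname(cf["tau1_h"]), tau2_h = unname(cf["tau2_h"]))
}
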