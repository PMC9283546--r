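# Fluorophore point-source fields for the two visualisation modes:
# direct repair-protein markers (Ku70/80, DNA-PKcs) with one source per
# surviving DSB, and indirect gamma-H2AX markers built from a histone model
# with TAD-restricted Cauchy-Lorentz activation.

#' gamma-H2AX histone-model parameters
#'
#' The number of H2AX histones per bead assumes 10% of H2A histones are the
#' H2AX variant, two H2A copies per nucleosome and 146 bp per nucleosome.
#' Activation as a function of genomic distance d (Mbp) from the break is a
#' Cauchy-Lorentz curve `baseline + amplitude / (1 + 4 (d / half_width)^2)`
#' fitted to ChIP-seq gamma-H2AX read counts.
#'
#' @param variant_fraction fraction of H2A histones that are H2AX (0.10).
#' @param copies_per_nucleosome H2A copies per nucleosome (2).
#' @param nucleosome_bp bp per nucleosome (146).
#' @param baseline,amplitude,half_width_mbp activation curve constants
#'   (0.23, 0.38, 0.45 Mbp).
#' @return a list of class `h2ax_params`.
#' @export
h2ax_params <- function(variant_fraction = 0.10, copies_per_nucleosome = 2L,
                        nucleosome_bp = 146L, baseline = 0.23,
                        amplitude = 0.38, half_width_mbp = 0.45) {
  stopifnot(variant_fraction > 0, variant_fraction <= 1,
            copies_per_nucleosome > 0, nucleosome_bp > 0,
            baseline > 0, amplitude > 0, half_width_mbp > 0)
  structure(as.list(environment()), class = "h2ax_params")
}

new_marker_field <- function(x, y, z, intensity, marker_type, time_h = NA) {
  structure(data.frame(x_um = x, y_um = y, z_um = z, intensity = intensity),
            marker_type = marker_type, time_h = time_h,
            class = c("marker_field", "data.frame"))
}

#' Direct (Ku/DNA-PKcs) marker field
#'
#' One unit-intensity point source at each surviving DSB position, each
#' retained with the labelling efficiency (1 models a perfectly efficient
#' fluorescent antibody).
#'
#' @param dsbs_surviving DSB data.frame (the survivors at one time point).
#' @param labelling_efficiency retention probability in (0, 1].
#' @param seed integer seed (only used when efficiency < 1).
#' @param time_h time point annotation carried on the field.
#' @return a `marker_field` data.frame (`x_um`, `y_um`, `z_um`,
#'   `intensity`) with attributes `marker_type = "direct"` and `time_h`.
#' @export
direct_marker_field <- function(dsbs_surviving, labelling_efficiency = 1,
                                seed = 1L, time_h = NA) {
  stopifnot(labelling_efficiency > 0, labelling_efficiency <= 1)
  keep <- rep(TRUE, nrow(dsbs_surviving))
  if (labelling_efficiency < 1) {
    set.seed(as.integer(seed))
    keep <- stats::runif(nrow(dsbs_surviving)) < labelling_efficiency
  }
  d <- dsbs_surviving[keep, , drop = FALSE]
  new_marker_field(d$x_um, d$y_um, d$z_um, rep(1, nrow(d)),
                   "direct", time_h)
}

#' Number of H2AX histones in a bead
#'
#' `round(variant_fraction * copies_per_nucleosome * bead_bp /
#' nucleosome_bp)`, rounding half away from zero.
#'
#' @param bead_bp genomic content of the bead (bp), > 0.
#' @param params an [h2ax_params()].
#' @export
count_histones <- function(bead_bp, params = h2ax_params()) {
  if (any(bead_bp <= 0)) stop("bead_bp must be > 0")
  as.integer(round_half_away(params$variant_fraction *
                               params$copies_per_nucleosome *
                               bead_bp / params$nucleosome_bp))
}

#' H2AX activation versus genomic distance
#'
#' Cauchy-Lorentz activation curve; 0.61 at the break, decaying to the
#' 0.23 baseline with half-width 0.45 Mbp.
#'
#' @param distance_mbp genomic distance from the DSB in Mbp (>= 0,
#'   vectorised).
#' @param params an [h2ax_params()].
#' @export
h2ax_activation <- function(distance_mbp, params = h2ax_params()) {
  if (any(distance_mbp < 0)) stop("distance must be >= 0")
  params$baseline + params$amplitude /
    (1 + 4 * (distance_mbp / params$half_width_mbp)^2)
}

#' Convert an intra-bead Euclidean distance to genomic distance
#'
#' Linear conversion based on the bead: genomic content (Mbp) divided by
#' bead diameter (um).
#'
#' @param bead one bead row (fields `start_bp`, `end_bp`, `radius_um`).
#' @param euclid_um Euclidean distance in um (>= 0, vectorised).
#' @return genomic distance in Mbp.
#' @export
euclidean_to_genomic <- function(bead, euclid_um) {
  if (any(euclid_um < 0)) stop("distance must be >= 0")
  diameter <- 2 * bead$radius_um
  if (diameter <= 0) stop("bead has zero diameter")
  euclid_um * ((bead$end_bp - bead$start_bp) / 1e6) / diameter
}

#' gamma-H2AX marker field
#'
#' H2AX histones are placed uniformly at random inside every bead that
#' contains at least one surviving DSB ([count_histones()] per bead).
#' Activation is restricted to the DSB's own TAD: each DSB adds
#' [h2ax_activation()] of its converted distance to every histone in the
#' same bead, additively for histones shared between nearby breaks.  The
#' histone placement for a bead is derived from `(seed, bead_id)` only, so
#' positions are identical across time points within a nucleus; activation
#' is recomputed from the surviving DSB set at each time point.
#'
#' @param dsbs_surviving DSB data.frame (survivors at one time point).
#' @param geometry the `nuclear_geometry` the DSBs live in.
#' @param params an [h2ax_params()].
#' @param seed per-nucleus histone seed (reused across time points).
#' @param time_h time point annotation.
#' @return a `marker_field` with one source per activated histone,
#'   intensity = accumulated activation.
#' @export
gh2ax_marker_field <- function(dsbs_surviving, geometry,
                               params = h2ax_params(), seed = 1L,
                               time_h = NA) {
  beads <- geometry$beads
  damaged <- unique(dsbs_surviving$bead_id)
  out <- vector("list", length(damaged))
  for (k in seq_along(damaged)) {
    b <- beads[beads$bead_id == damaged[k], , drop = FALSE]
    if (nrow(b) == 0) stop("DSB references unknown bead ", damaged[k])
    n_h <- count_histones(b$end_bp - b$start_bp, params)
    if (n_h == 0) next
    set.seed(derive_seed(seed, 7L, b$bead_id))
    pos <- runif_in_sphere(n_h, c(b$x_um, b$y_um, b$z_um), b$radius_um)
    d <- dsbs_surviving[dsbs_surviving$bead_id == damaged[k], , drop = FALSE]
    dist <- sqrt(outer(pos[, 1], d$x_um, "-")^2 +
                   outer(pos[, 2], d$y_um, "-")^2 +
                   outer(pos[, 3], d$z_um, "-")^2)
    act <- rowSums(h2ax_activation(euclidean_to_genomic(b, dist), params))
    keep <- act > 0
    out[[k]] <- data.frame(x = pos[keep, 1], y = pos[keep, 2],
                           z = pos[keep, 3], a = act[keep])
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(new_marker_field(numeric(0), numeric(0), numeric(0), numeric(0),
                            "gh2ax", time_h))
  }
  new_marker_field(out$x, out$y, out$z, out$a, "gh2ax", time_h)
}

#' Export a marker field as CSV
#'
#' Columns `x_um,y_um,z_um,intensity,marker_type,time_h`.
#' @param field a `marker_field`.
#' @param path file path.
#' @export
write_marker_csv <- function(field, path) {
  utils::write.csv(data.frame(field,
                              marker_type = attr(field, "marker_type"),
                              time_h = attr(field, "time_h")),
                   path, row.names = FALSE)
  invisible(path)
}
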