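# Ground-truth DSB induction: the photon Poisson model, the proton-style
# deposition -> strand-break -> DSB conversion, and SDD format I/O.

#' Damage model parameters
#'
#' @param photon_yield_per_gy mean DSB yield for photon irradiation
#'   (DSB/Gy); 30 for the reference gamma model.
#' @param sampling_fraction spatial sampling applied inside a bead to
#'   account for DNA sparsity within a TAD (0.141).
#' @param e_min_ev,e_max_ev anchors of the linear break-induction
#'   probability ramp: 0 at `e_min_ev`, 1 at `e_max_ev` (5 and 37.5 eV).
#' @param max_bp_separation maximum genomic separation for two
#'   opposite-strand breaks to pair into a DSB (10 bp).
#' @param max_um_separation the spatial equivalent of
#'   `max_bp_separation` (3.2 nm = 0.0032 um).
#' @return a list of class `damage_params`.
#' @export
damage_params <- function(photon_yield_per_gy = 30,
                          sampling_fraction = 0.141,
                          e_min_ev = 5, e_max_ev = 37.5,
                          max_bp_separation = 10,
                          max_um_separation = 0.0032) {
  stopifnot(photon_yield_per_gy > 0,
            sampling_fraction > 0, sampling_fraction <= 1,
            e_min_ev < e_max_ev,
            max_bp_separation > 0, max_um_separation > 0)
  structure(as.list(environment()), class = "damage_params")
}

#' Linear break-induction probability ramp
#'
#' Probability that an energy deposition of `energy_ev` induces a strand
#' break, given it hit genome-containing chromatin: 0 at `e_min_ev` rising
#' linearly to 1 at `e_max_ev`, clamped outside.
#'
#' @param energy_ev deposition energies (eV).
#' @param params a [damage_params()].
#' @export
break_probability <- function(energy_ev, params = damage_params()) {
  pmin(pmax((energy_ev - params$e_min_ev) /
              (params$e_max_ev - params$e_min_ev), 0), 1)
}

empty_dsbs <- function() {
  data.frame(dsb_id = integer(0), x_um = numeric(0), y_um = numeric(0),
             z_um = numeric(0), bead_id = integer(0), chrom = character(0),
             bp = numeric(0), source = character(0),
             repair_time_h = numeric(0), stringsAsFactors = FALSE)
}

#' Photon (gamma) DSB induction
#'
#' The number of DSBs per nucleus is Poisson with mean `dose *
#' photon_yield_per_gy`.  Each DSB picks a chromosome with probability
#' proportional to chromosome length, a bead within that chromosome with
#' probability proportional to its genomic content, a uniform position
#' inside the bead sphere (truncated to the nucleus for beads grazing the
#' envelope) and a uniform bp position within the bead's interval.
#'
#' @param geometry a `nuclear_geometry`.
#' @param dose_gy absorbed dose in Gy (>= 0).
#' @param params a [damage_params()].
#' @param seed integer seed.
#' @return a DSB data.frame (`dsb_id`, `x_um`, `y_um`, `z_um`, `bead_id`,
#'   `chrom`, `bp`, `source`, `repair_time_h`); `repair_time_h` is `Inf`
#'   until a repair timeline is scheduled.
#' @export
induce_photon_damage <- function(geometry, dose_gy, params = damage_params(),
                                 seed = 1L) {
  if (dose_gy < 0) stop("dose must be >= 0")
  beads <- geometry$beads
  if (is.null(beads) || nrow(beads) == 0) stop("geometry has no beads")
  set.seed(as.integer(seed))
  n <- stats::rpois(1, dose_gy * params$photon_yield_per_gy)
  if (n == 0) return(empty_dsbs())
  content <- beads$end_bp - beads$start_bp
  chrom_len <- tapply(content, beads$chrom, sum)
  chroms <- sample(names(chrom_len), n, replace = TRUE,
                   prob = as.numeric(chrom_len))
  bead_idx <- vapply(chroms, function(ch) {
    in_ch <- which(beads$chrom == ch)
    if (length(in_ch) == 1) in_ch else
      sample(in_ch, 1, prob = content[in_ch])
  }, integer(1))
  pos <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    b <- bead_idx[k]
    ctr <- c(beads$x_um[b], beads$y_um[b], beads$z_um[b])
    for (try in 1:100) {
      p <- runif_in_sphere(1, ctr, beads$radius_um[b])
      if (inside_ellipsoid(p, geometry$semi_axes)) break
    }
    if (!inside_ellipsoid(p, geometry$semi_axes)) p <- matrix(ctr, 1)
    pos[k, ] <- p
  }
  bp <- beads$start_bp[bead_idx] +
    floor(stats::runif(n) * (content[bead_idx]))
  data.frame(dsb_id = seq_len(n), x_um = pos[, 1], y_um = pos[, 2],
             z_um = pos[, 3], bead_id = beads$bead_id[bead_idx],
             chrom = beads$chrom[bead_idx], bp = bp, source = "photon",
             repair_time_h = Inf, stringsAsFactors = FALSE)
}

#' Synthetic charged-particle track depositions
#'
#' A desk-scale stand-in for track-structure simulation: straight tracks
#' parallel to the optical (z) axis cross the nucleus at uniformly random
#' (x, y).  The number of tracks follows from energy bookkeeping,
#' `n = round(dose * mass / (LET * mean chord))` with the nucleus mass from
#' its ellipsoid volume at 1 g/cm^3 and mean z-chord `4c/3`.  Depositions
#' are a Poisson process along each chord with linear density `LET /
#' mean_deposit_ev`, and deposition energies are exponential with mean
#' `mean_deposit_ev`.
#'
#' @param geometry a `nuclear_geometry`.
#' @param dose_gy absorbed dose (Gy).
#' @param let_kev_per_um linear energy transfer (keV/um), > 0.
#' @param mean_deposit_ev mean energy per deposition (eV), > 0.
#' @param seed integer seed.
#' @return data.frame `x_um`, `y_um`, `z_um`, `energy_ev`, `track_id`.
#' @export
generate_track_depositions <- function(geometry, dose_gy, let_kev_per_um,
                                       mean_deposit_ev = 60, seed = 1L) {
  stopifnot(let_kev_per_um > 0, mean_deposit_ev > 0, dose_gy >= 0)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), energy_ev = numeric(0),
                      track_id = integer(0))
  if (dose_gy == 0) return(empty)
  ax <- geometry$semi_axes
  mass_kg <- ellipsoid_volume_um3(ax) * 1e-15        # 1 g/cm^3
  energy_kev <- dose_gy * mass_kg / 1.602176634e-16  # Gy = J/kg
  mean_chord <- 4 * ax[3] / 3
  n_tracks <- round(energy_kev / (let_kev_per_um * mean_chord))
  if (n_tracks == 0) {
    warning("generate_track_depositions: parameters give 0 tracks",
            call. = FALSE)
    return(empty)
  }
  set.seed(as.integer(seed))
  # uniform (x, y) over the elliptical cross-section
  xy <- matrix(NA_real_, n_tracks, 2)
  filled <- 0
  while (filled < n_tracks) {
    m <- max(2 * (n_tracks - filled), 16)
    cand <- cbind(stats::runif(m, -ax[1], ax[1]),
                  stats::runif(m, -ax[2], ax[2]))
    keep <- (cand[, 1] / ax[1])^2 + (cand[, 2] / ax[2])^2 < 1
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n_tracks - filled)
    if (take > 0) xy[filled + seq_len(take), ] <- cand[seq_len(take), ]
    filled <- filled + take
  }
  half <- ax[3] * sqrt(1 - (xy[, 1] / ax[1])^2 - (xy[, 2] / ax[2])^2)
  density <- let_kev_per_um * 1000 / mean_deposit_ev   # deposits per um
  n_dep <- stats::rpois(n_tracks, density * 2 * half)
  track_id <- rep(seq_len(n_tracks), n_dep)
  z <- stats::runif(sum(n_dep), -half[track_id], half[track_id])
  data.frame(x_um = xy[track_id, 1], y_um = xy[track_id, 2], z_um = z,
             energy_ev = stats::rexp(sum(n_dep), 1 / mean_deposit_ev),
             track_id = track_id)
}

# assign each deposition to the bead sphere containing it (NA if none),
# using an xy-grid spatial index over beads
assign_beads <- function(deps, beads) {
  n <- nrow(deps)
  assignment <- rep(NA_integer_, n)
  if (n == 0 || nrow(beads) == 0) return(assignment)
  cell <- max(2 * max(beads$radius_um), 0.2)
  x0 <- min(beads$x_um - beads$radius_um)
  y0 <- min(beads$y_um - beads$radius_um)
  cx <- function(x) floor((x - x0) / cell)
  key <- function(ix, iy) paste(ix, iy)
  # beads may span up to 2x2 cells at this cell size
  bead_cells <- new.env(parent = emptyenv())
  for (b in seq_len(nrow(beads))) {
    for (ix in cx(beads$x_um[b] - beads$radius_um[b]):cx(beads$x_um[b] + beads$radius_um[b])) {
      for (iy in cx(beads$y_um[b] - beads$radius_um[b]):cx(beads$y_um[b] + beads$radius_um[b])) {
        k <- key(ix, iy)
        bead_cells[[k]] <- c(bead_cells[[k]], b)
      }
    }
  }
  dep_key <- key(cx(deps$x_um), cx(deps$y_um))
  groups <- split(seq_len(n), dep_key)
  for (k in names(groups)) {
    cand <- bead_cells[[k]]
    if (is.null(cand)) next
    idx <- groups[[k]]
    for (b in cand) {  # first containing bead wins, in bead-id order
      un <- idx[is.na(assignment[idx])]
      if (length(un) == 0) break
      d2 <- (deps$x_um[un] - beads$x_um[b])^2 +
        (deps$y_um[un] - beads$y_um[b])^2 +
        (deps$z_um[un] - beads$z_um[b])^2
      hit <- un[d2 <= beads$radius_um[b]^2]
      assignment[hit] <- b
    }
  }
  assignment
}

#' Convert energy depositions to strand breaks
#'
#' A deposition survives as a strand break iff (i) it lies inside a
#' chromatin bead, (ii) an independent Bernoulli draw with the spatial
#' sampling fraction (0.141) succeeds, and (iii) a Bernoulli draw with the
#' energy ramp [break_probability()] succeeds.  Survivors are assigned to
#' strand 1 or 2 with equal probability and get a uniform bp position
#' within the bead's genomic interval.
#'
#' @param deps deposition data.frame from [generate_track_depositions()]
#'   (or read from an external listing).
#' @param geometry a `nuclear_geometry`.
#' @param params a [damage_params()].
#' @param seed integer seed.
#' @return data.frame `x_um`, `y_um`, `z_um`, `bead_id`, `chrom`, `strand`,
#'   `bp`.
#' @export
depositions_to_strand_breaks <- function(deps, geometry,
                                         params = damage_params(),
                                         seed = 1L) {
  beads <- geometry$beads
  set.seed(as.integer(seed))
  bead_row <- assign_beads(deps, beads)
  inside <- !is.na(bead_row)
  keep <- inside
  keep[inside] <- stats::runif(sum(inside)) < params$sampling_fraction &
    stats::runif(sum(inside)) < break_probability(deps$energy_ev[inside], params)
  idx <- which(keep)
  b <- bead_row[idx]
  n <- length(idx)
  data.frame(x_um = deps$x_um[idx], y_um = deps$y_um[idx],
             z_um = deps$z_um[idx], bead_id = beads$bead_id[b],
             chrom = beads$chrom[b],
             strand = sample(1:2, n, replace = TRUE),
             bp = beads$start_bp[b] +
               floor(stats::runif(n) * (beads$end_bp[b] - beads$start_bp[b])))
}

#' Pair strand breaks into DSBs
#'
#' A DSB is one pair of opposite-strand breaks in the same bead whose
#' separation does not exceed the threshold.  By default the separation is
#' spatial (3.2 nm between deposition positions, the printed equivalent of
#' 10 bp); `by = "genomic"` uses the 10 bp genomic rule instead.  Pairing
#' is greedy in ascending order (z within bead for spatial, bp for
#' genomic), each break used at most once, which attains the maximum
#' matching for this 1D interval-compatibility structure.  The DSB position
#' is the midpoint of its two breaks and its bp the smaller of the pair.
#'
#' @param breaks strand-break data.frame from
#'   [depositions_to_strand_breaks()].
#' @param params a [damage_params()].
#' @param by `"spatial"` (default) or `"genomic"`.
#' @return a DSB data.frame as in [induce_photon_damage()], `source =
#'   "track"`.
#' @export
cluster_breaks_to_dsbs <- function(breaks, params = damage_params(),
                                   by = c("spatial", "genomic")) {
  by <- match.arg(by)
  if (is.null(breaks) || nrow(breaks) == 0) return(empty_dsbs())
  out <- list()
  for (bead in unique(breaks$bead_id)) {
    g <- breaks[breaks$bead_id == bead, , drop = FALSE]
    ord <- if (by == "genomic") order(g$bp, g$strand) else
      order(g$z_um, g$x_um, g$y_um)
    g <- g[ord, , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(g))) {
      if (used[i]) next
      j <- i + 1
      while (j <= nrow(g)) {
        if (!used[j] && g$strand[j] != g$strand[i]) {
          sep_ok <- if (by == "genomic") {
            abs(g$bp[j] - g$bp[i]) <= params$max_bp_separation
          } else {
            sqrt((g$x_um[j] - g$x_um[i])^2 + (g$y_um[j] - g$y_um[i])^2 +
                   (g$z_um[j] - g$z_um[i])^2) <= params$max_um_separation
          }
          # sorted scan: once past the window no later j can pair with i
          past <- if (by == "genomic") {
            g$bp[j] - g$bp[i] > params$max_bp_separation
          } else {
            g$z_um[j] - g$z_um[i] > params$max_um_separation
          }
          if (sep_ok) {
            used[i] <- used[j] <- TRUE
            out[[length(out) + 1]] <- data.frame(
              x_um = (g$x_um[i] + g$x_um[j]) / 2,
              y_um = (g$y_um[i] + g$y_um[j]) / 2,
              z_um = (g$z_um[i] + g$z_um[j]) / 2,
              bead_id = bead, chrom = g$chrom[i],
              bp = min(g$bp[i], g$bp[j]), stringsAsFactors = FALSE)
            break
          }
          if (past) break
        } else if (!used[j]) {
          past <- if (by == "genomic") {
            g$bp[j] - g$bp[i] > params$max_bp_separation
          } else {
            g$z_um[j] - g$z_um[i] > params$max_um_separation
          }
          if (past) break
        }
        j <- j + 1
      }
    }
  }
  if (length(out) == 0) return(empty_dsbs())
  dsbs <- do.call(rbind, out)
  data.frame(dsb_id = seq_len(nrow(dsbs)), dsbs[c("x_um", "y_um", "z_um",
                                                  "bead_id", "chrom", "bp")],
             source = "track", repair_time_h = Inf, stringsAsFactors = FALSE)
}

#' Full track-irradiation damage chain
#'
#' Convenience wrapper: depositions -> strand breaks -> DSBs.
#'
#' @inheritParams generate_track_depositions
#' @inheritParams cluster_breaks_to_dsbs
#' @export
induce_track_damage <- function(geometry, dose_gy, let_kev_per_um,
                                params = damage_params(),
                                mean_deposit_ev = 60, seed = 1L,
                                by = "spatial") {
  deps <- generate_track_depositions(geometry, dose_gy, let_kev_per_um,
                                     mean_deposit_ev, seed = seed)
  brk <- depositions_to_strand_breaks(deps, geometry, params,
                                      seed = derive_seed(seed, 2L))
  cluster_breaks_to_dsbs(brk, params, by = by)
}

sdd_fields <- c("dsb_id", "x_um", "y_um", "z_um", "chrom", "bead_id", "bp",
                "class")

#' Write / read DSB records in a minimal SDD dialect
#'
#' A minimal-field Standard DNA Damage (SDD) file: a header of `key, value;`
#' lines terminated by `***EndOfHeader***;`, then one comma-separated data
#' line per DSB carrying position (um), chromosome, bead, bp position and
#' the damage classification (`DSB`).  Unknown extra fields on data lines
#' are preserved verbatim on round trip.
#'
#' @param dsbs DSB data.frame.
#' @param geometry_ref free-text geometry reference stored in the header.
#' @param dose_gy dose recorded in the header.
#' @param path file path.
#' @return `read_sdd` returns the DSB data.frame (source `"external"`),
#'   with header metadata in attributes `dose_gy` and `geometry_ref`.
#' @export
write_sdd <- function(dsbs, geometry_ref = "synthetic", dose_gy = NA,
                      path) {
  extra <- setdiff(names(dsbs),
                   c(sdd_fields, "source", "repair_time_h"))
  fields <- c(sdd_fields, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "SDD version, 1.0;",
    sprintf("Software, focisim %s;",
            as.character(utils::packageVersion("focisim"))),
    sprintf("Dose or fluence, 1, %s;", format(dose_gy, digits = 10)),
    sprintf("Geometry description, %s;", geometry_ref),
    sprintf("Data entries, %s;", paste(fields, collapse = ", ")),
    "***EndOfHeader***;"
  ), con)
  if (nrow(dsbs) > 0) {
    m <- data.frame(dsbs$dsb_id,
                    format(dsbs$x_um, digits = 12),
                    format(dsbs$y_um, digits = 12),
                    format(dsbs$z_um, digits = 12),
                    dsbs$chrom, dsbs$bead_id,
                    format(dsbs$bp, scientific = FALSE), "DSB")
    for (e in extra) m[[e]] <- dsbs[[e]]
    writeLines(apply(m, 1, function(r) paste(trimws(r), collapse = ", ")),
               con)
  }
  invisible(path)
}

#' @rdname write_sdd
#' @export
read_sdd <- function(path) {
  lines <- readLines(path)
  end <- grep("^\\*\\*\\*EndOfHeader\\*\\*\\*;?$", lines)
  if (length(end) == 0) stop("malformed SDD file: no ***EndOfHeader*** line")
  header <- lines[seq_len(end[1] - 1)]
  hval <- function(key) {
    m <- grep(paste0("^", key, ","), header, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    trimws(sub(";\\s*$", "", sub(paste0("^", key, ",\\s*"), "", m[1])))
  }
  fields <- sdd_fields
  de <- hval("Data entries")
  if (!is.na(de)) fields <- trimws(strsplit(de, ",")[[1]])
  data_lines <- lines[seq(end[1] + 1, length.out = length(lines) - end[1])]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0) {
    out <- empty_dsbs()
  } else {
    rows <- strsplit(data_lines, ",")
    nf <- lengths(rows)
    if (any(nf != length(fields))) {
      bad <- which(nf != length(fields))[1]
      stop(sprintf("SDD parse error at line %d: %d fields, expected %d",
                   end[1] + bad, nf[bad], length(fields)))
    }
    m <- as.data.frame(do.call(rbind, lapply(rows, trimws)),
                       stringsAsFactors = FALSE)
    names(m) <- fields
    num <- function(col) {
      v <- suppressWarnings(as.numeric(m[[col]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(sprintf("SDD parse error at line %d: non-numeric %s '%s'",
                     end[1] + bad, col, m[[col]][bad]))
      }
      v
    }
    out <- data.frame(dsb_id = as.integer(num("dsb_id")),
                      x_um = num("x_um"), y_um = num("y_um"),
                      z_um = num("z_um"),
                      bead_id = as.integer(num("bead_id")),
                      chrom = m$chrom, bp = num("bp"),
                      source = "external", repair_time_h = Inf,
                      stringsAsFactors = FALSE)
    for (e in setdiff(fields, sdd_fields)) out[[e]] <- m[[e]]
  }
  dose <- suppressWarnings(as.numeric(
    sub("^1,\\s*", "", hval("Dose or fluence"))))
  attr(out, "dose_gy") <- dose
  attr(out, "geometry_ref") <- hval("Geometry description")
  out
}

#' Export ground-truth DSBs as CSV
#'
#' Columns `dsb_id,x_um,y_um,z_um,bead_id,chrom,bp,source,repair_time_h`.
#' @param dsbs DSB data.frame.
#' @param path file path.
#' @export
write_dsb_csv <- function(dsbs, path) {
  utils::write.csv(dsbs[c("dsb_id", "x_um", "y_um", "z_um", "bead_id",
                          "chrom", "bp", "source", "repair_time_h")],
                   path, row.names = FALSE)
  invisible(path)
}
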