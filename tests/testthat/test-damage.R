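test_that("photon damage follows the Poisson yield model", {
  geom <- small_geometry(seed = 1)
  expect_equal(nrow(induce_photon_damage(geom, 0, seed = 1)), 0)

  counts <- vapply(1:2000, function(s) {
    nrow(induce_photon_damage(geom, 2, seed = s))
  }, numeric(1))
  se <- sqrt(60 / 2000)              # Poisson SE of the mean
  expect_lt(abs(mean(counts) - 60), 3 * se)
  expect_gt(stats::var(counts) / mean(counts), 0.9)   # index of dispersion
  expect_lt(stats::var(counts) / mean(counts), 1.1)
})

test_that("photon DSBs land inside their bead and carry its genomic interval", {
  geom <- small_geometry(seed = 2)
  d <- induce_photon_damage(geom, 10, seed = 3)
  b <- geom$beads[match(d$bead_id, geom$beads$bead_id), ]
  dist <- sqrt((d$x_um - b$x_um)^2 + (d$y_um - b$y_um)^2 +
                 (d$z_um - b$z_um)^2)
  expect_true(all(dist <= b$radius_um + 1e-9))
  expect_true(all(d$bp >= b$start_bp & d$bp < b$end_bp))
  expect_true(all(inside_ellipsoid(
    as.matrix(d[, c("x_um", "y_um", "z_um")]), geom$semi_axes)))
})

test_that("chromosome assignment frequencies match length weights", {
  geom <- small_geometry(seed = 3)       # chrA 4 Mbp, chrB 2 Mbp
  pooled <- do.call(rbind, lapply(1:6, function(s) {
    induce_photon_damage(geom, 60, seed = s)
  }))
  expect_gt(nrow(pooled), 10000 * 0.9)
  obs <- table(factor(pooled$chrom, levels = c("chrA", "chrB")))
  p <- stats::chisq.test(obs, p = c(2 / 3, 1 / 3))$p.value
  expect_gt(p, 0.001)
})

test_that("break induction probability is a clamped linear ramp", {
  expect_equal(break_probability(5), 0)
  expect_equal(break_probability(37.5), 1)
  expect_equal(break_probability(21.25), 0.5)
  expect_equal(break_probability(c(0, 1000)), c(0, 1))
})

test_that("deposition survival combines containment, spatial sampling and the ramp", {
  geom <- small_geometry(seed = 4)
  b <- geom$beads[1, ]
  n <- 20000
  at_center <- data.frame(x_um = rep(b$x_um, n), y_um = rep(b$y_um, n),
                          z_um = rep(b$z_um, n), energy_ev = 37.5,
                          track_id = seq_len(n))
  brk <- depositions_to_strand_breaks(at_center, geom, seed = 5)
  # survival probability = 0.141 (ramp = 1 at 37.5 eV)
  expect_lt(abs(nrow(brk) / n - 0.141), 3 * sqrt(0.141 * 0.859 / n))
  expect_true(all(brk$bead_id == b$bead_id))
  expect_true(all(brk$strand %in% 1:2))
  expect_true(all(brk$bp >= b$start_bp & brk$bp < b$end_bp))

  # 5 eV never survives the ramp
  at_center$energy_ev <- 5
  expect_equal(nrow(depositions_to_strand_breaks(at_center, geom, seed = 6)),
               0)

  # outside every bead: never a break
  far <- data.frame(x_um = 0, y_um = 0, z_um = 100, energy_ev = 1000,
                    track_id = 1L)
  expect_equal(nrow(depositions_to_strand_breaks(far, geom, seed = 7)), 0)
})

test_that("strand-break pairing follows the opposite-strand separation rule", {
  mk <- function(strand, bp) {
    data.frame(x_um = bp * 1e-4, y_um = 0, z_um = 0, bead_id = 1L,
               chrom = "chrA", strand = strand, bp = bp)
  }
  p <- damage_params()
  two <- rbind(mk(1, 100), mk(2, 105))
  expect_equal(nrow(cluster_breaks_to_dsbs(two, p, by = "genomic")), 1)
  same <- rbind(mk(1, 100), mk(1, 105))
  expect_equal(nrow(cluster_breaks_to_dsbs(same, p, by = "genomic")), 0)
  far <- rbind(mk(1, 100), mk(2, 120))
  expect_equal(nrow(cluster_breaks_to_dsbs(far, p, by = "genomic")), 0)
  # greedy pairing uses each break once
  triple <- rbind(mk(1, 100), mk(2, 105), mk(2, 108))
  expect_equal(nrow(cluster_breaks_to_dsbs(triple, p, by = "genomic")), 1)
  # DSB position and bp conventions
  d <- cluster_breaks_to_dsbs(two, p, by = "genomic")
  expect_equal(d$x_um, (100 + 105) / 2 * 1e-4)
  expect_equal(d$bp, 100)
})

test_that("greedy pairing attains the exhaustive maximum matching (<= 12 breaks)", {
  p <- damage_params()
  for (s in 1:40) {
    set.seed(s)
    n <- sample(2:12, 1)
    brk <- data.frame(x_um = 0, y_um = 0, z_um = sort(runif(n, 0, 0.02)),
                      bead_id = 1L, chrom = "chrA",
                      strand = sample(1:2, n, replace = TRUE),
                      bp = sort(sample(1:60, n)))
    got_gen <- nrow(cluster_breaks_to_dsbs(brk, p, by = "genomic"))
    want_gen <- oracle_max_matching(brk, function(a, b) {
      a$strand != b$strand & abs(a$bp - b$bp) <= p$max_bp_separation
    })
    expect_equal(got_gen, want_gen)
    got_sp <- nrow(cluster_breaks_to_dsbs(brk, p, by = "spatial"))
    want_sp <- oracle_max_matching(brk, function(a, b) {
      a$strand != b$strand &
        abs(a$z_um - b$z_um) <= p$max_um_separation
    })
    expect_equal(got_sp, want_sp)
  }
})

test_that("track depositions respect dose-energy bookkeeping", {
  geom <- small_geometry(seed = 5)
  expect_equal(nrow(generate_track_depositions(geom, 0, 5)), 0)

  mass_kg <- focisim:::ellipsoid_volume_um3(geom$semi_axes) * 1e-15
  target_ev <- 1 * mass_kg / 1.602176634e-19
  sums <- vapply(1:30, function(s) {
    sum(generate_track_depositions(geom, 1, 5, seed = s)$energy_ev)
  }, numeric(1))
  expect_lt(abs(mean(sums) - target_ev) / target_ev, 0.05)

  # higher LET at fixed dose -> fewer tracks
  n_tracks <- vapply(c(1.7, 7.15, 27.95), function(let) {
    max(generate_track_depositions(geom, 1, let, seed = 1)$track_id)
  }, numeric(1))
  expect_true(all(diff(n_tracks) < 0))
})

test_that("track DSB positions lie between their two strand breaks", {
  geom <- small_geometry(seed = 6)
  deps <- generate_track_depositions(geom, 5, 27.95, seed = 7)
  brk <- depositions_to_strand_breaks(deps, geom, seed = 8)
  dsb <- cluster_breaks_to_dsbs(brk)
  expect_gt(nrow(dsb), 0)
  # each DSB is a midpoint of two breaks <= 3.2 nm apart, so it must lie
  # within 1.6 nm of some break
  for (k in seq_len(min(nrow(dsb), 20))) {
    d <- sqrt((brk$x_um - dsb$x_um[k])^2 + (brk$y_um - dsb$y_um[k])^2 +
                (brk$z_um - dsb$z_um[k])^2)
    expect_lte(min(d), 0.0032 / 2 + 1e-12)
  }
})

test_that("SDD files round-trip, preserve extra fields and report parse errors", {
  geom <- small_geometry(seed = 7)
  d <- induce_photon_damage(geom, 2, seed = 9)[1:10, ]
  path <- withr::local_tempfile(fileext = ".sdd")
  write_sdd(d, geometry_ref = "geom-7", dose_gy = 2, path = path)
  back <- read_sdd(path)
  expect_equal(back$dsb_id, d$dsb_id)
  expect_equal(back$x_um, d$x_um, tolerance = 1e-9)
  expect_equal(back$bp, d$bp)
  expect_equal(back$chrom, d$chrom)
  expect_equal(attr(back, "dose_gy"), 2)
  expect_equal(attr(back, "geometry_ref"), "geom-7")

  # extra fields survive the round trip verbatim
  d$lesion_note <- paste0("n", seq_len(nrow(d)))
  write_sdd(d, "geom-7", 2, path)
  back2 <- read_sdd(path)
  expect_equal(back2$lesion_note, d$lesion_note)

  # empty damage set: header-only file is valid
  write_sdd(d[0, ], "geom-7", 0, path)
  expect_equal(nrow(read_sdd(path)), 0)

  # malformed content errors name the line
  lines <- readLines({write_sdd(d[1:2, 1:9], "g", 1, path); path})
  lines[8] <- sub("^2, [-0-9.e]+", "2, not_a_number", lines[8])
  writeLines(lines, path)
  expect_error(read_sdd(path), "line 8")
  writeLines(lines[-6], path)   # drop ***EndOfHeader***;
  expect_error(read_sdd(path), "EndOfHeader")
})
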