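# direct spatial-domain LoG response + exhaustive maxima scan, used as an
# independent oracle for the FFT-based detector on small images
oracle_log_count <- function(img, sigma, threshold) {
  k <- focisim:::log_kernel(sigma, 2)
  h <- (dim(k)[1] - 1) / 2
  d <- dim(img)
  resp <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- 0
      for (a in -h:h) {
        ii <- i + a
        if (ii < 1 || ii > d[1]) next
        for (b in -h:h) {
          jj <- j + b
          if (jj < 1 || jj > d[2]) next
          acc <- acc + img[ii, jj] * k[a + h + 1, b + h + 1]
        }
      }
      resp[i, j] <- acc
    }
  }
  count <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (resp[i, j] <= threshold) next
      nb <- resp[max(1, i - 1):min(d[1], i + 1),
                 max(1, j - 1):min(d[2], j + 1)]
      if (resp[i, j] >= max(nb)) count <- count + 1
    }
  }
  count
}

gauss_blob <- function(n, cx, cy, s, amp = 1) {
  x <- matrix(rep(seq_len(n), n), n)
  y <- t(x)
  amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
}

test_that("an isolated Gaussian blob gives exactly one focus; blank images none", {
  img <- gauss_blob(61, 31, 31, 3)
  f <- detect_foci(img, log_params(2, 20, 1, 8), reference = max(img))
  expect_equal(f$count, 1)
  expect_equal(unname(unlist(f$detections[1, c("x_px", "y_px")])), c(31, 31))

  blank <- matrix(0, 41, 41)
  expect_equal(detect_foci(blank, log_params(), reference = 1)$count, 0)
})

test_that("blob separation controls merging, matching the exhaustive oracle", {
  s <- 3
  near <- gauss_blob(61, 31, 31, s) + gauss_blob(61, 31, 31 + 0.1 * s, s)
  far <- gauss_blob(91, 46, 25, s) + gauss_blob(91, 46, 25 + 10 * s, s)
  p <- log_params(2, 20, 1, 8)
  f_near <- detect_foci(near, p, reference = max(near))
  f_far <- detect_foci(far, p, reference = max(far))
  expect_equal(f_near$count, 1)
  expect_equal(f_far$count, 2)
  expect_equal(f_near$count,
               oracle_log_count(near, 2, 0.08 * max(near)))
  expect_equal(f_far$count,
               oracle_log_count(far, 2, 0.08 * max(far)))
})

test_that("counts are invariant to joint intensity rescaling", {
  img <- gauss_blob(61, 31, 31, 3) + gauss_blob(61, 15, 45, 2.5, amp = 0.6)
  p <- log_params(2, 20, 3, 4)
  base <- detect_foci(img, p, reference = max(img))$count
  for (c in c(1e-3, 0.5, 7, 1e4)) {
    expect_equal(detect_foci(c * img, p, reference = c * max(img))$count,
                 base)
  }
})

test_that("raising the threshold never increases the count", {
  set.seed(9)
  img <- matrix(0, 81, 81)
  for (k in 1:6) {
    img <- img + gauss_blob(81, runif(1, 15, 67), runif(1, 15, 67),
                            runif(1, 2, 4), amp = runif(1, 0.3, 1))
  }
  counts <- vapply(c(1, 2, 4, 8, 16, 32, 64), function(thr) {
    detect_foci(img, log_params(2, 20, 1, thr), reference = max(img))$count
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single in-slice point source counts once in both 2D and 3D", {
  geom <- small_geometry(seed = 1)
  cfg <- registry_lookup("Airyscan", 40)
  psf <- synthetic_psf(cfg)
  fld <- point_field(0.4, -0.3, 0)
  sl <- render_image(fld, geom, cfg, psf, mode = "slice")
  st <- render_image(fld, geom, cfg, psf, mode = "stack")
  p <- log_params_for_marker("direct")
  expect_equal(detect_foci(sl, p, reference_max(list(sl)))$count, 1)
  expect_equal(detect_foci(st, p, reference_max(list(st)))$count, 1)
})

test_that("the threshold anchor is the 15-min set-up maximum", {
  expect_equal(reference_max(list(matrix(12.5, 2, 2))), 12.5)
  expect_equal(reference_max(list(matrix(3, 2, 2), matrix(7, 2, 2))), 7)
  expect_error(reference_max(list()), "at least one")
  expect_error(reference_max(list(matrix(0, 3, 3))), "all zero")
  # a dimmer late image measured against the brighter 15-min anchor can
  # only lose detections relative to its own maximum
  late <- 0.4 * (gauss_blob(61, 31, 31, 3) +
                   gauss_blob(61, 15, 45, 2.5, amp = 0.12))
  p <- log_params(2, 20, 1, 8)
  anchored <- detect_foci(late, p, reference = 1)$count    # 15-min max = 1
  own <- detect_foci(late, p, reference = max(late))$count
  expect_lte(anchored, own)
})

test_that("marker presets carry the printed detector parameters", {
  pd <- log_params_for_marker("direct")
  expect_equal(c(pd$min_sigma, pd$max_sigma, pd$num_sigma,
                 pd$threshold_percent), c(2, 20, 1, 8))
  pg <- log_params_for_marker("gh2ax")
  expect_equal(c(pg$min_sigma, pg$max_sigma, pg$num_sigma,
                 pg$threshold_percent), c(2, 20, 3, 4))
})

test_that("detection output is well-formed and exports as CSV", {
  img <- gauss_blob(61, 31, 31, 3)
  f <- detect_foci(img, log_params(), reference = max(img))
  expect_s3_class(f, "foci_set")
  expect_equal(f$count, nrow(f$detections))
  expect_true(all(f$detections$x_px >= 1 & f$detections$x_px <= 61))
  path <- withr::local_tempfile(fileext = ".csv")
  write_foci_csv(f, path, image_id = "img1", param_set = "direct")
  got <- utils::read.csv(path)
  expect_equal(nrow(got), f$count)
  expect_equal(got$n_foci[1], f$count)
})
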