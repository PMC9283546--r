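test_that("the registry holds 24 unique configurations with transcribed values", {
  tab <- registry_all()
  expect_equal(nrow(tab), 24)
  expect_false(any(duplicated(tab[, c("microscope", "magnification")])))

  a63 <- registry_lookup("Airyscan", 63)
  expect_equal(a63$xy_spacing_um, 0.033)
  expect_equal(a63$z_spacing_um, 0.12)
  expect_equal(a63$na, 1.4)

  # footnoted magnification substitutions and the extra STED x25 entry
  expect_silent(registry_lookup("gSTED", 23))
  expect_error(registry_lookup("gSTED", 20), "unknown")
  expect_silent(registry_lookup("MultiPhoton", 25))
  expect_error(registry_lookup("MultiPhoton", 20), "unknown")
  s25 <- registry_lookup("STED", 25)
  expect_equal(c(s25$xy_spacing_um, s25$z_spacing_um, s25$na),
               c(0.06, 0.25, 0.95))

  expect_error(registry_lookup("Phenix", 100), "valid")
  expect_true(all(tab$na > 0 & tab$na <= 1.6))
  expect_true(all(tab$xy_um > 0 & tab$z_um > 0))
})

test_that("synthetic PSFs use scalar-diffraction widths, odd extents, sum one", {
  psf <- synthetic_psf(registry_lookup("Airyscan", 63))
  expect_equal(unname(psf$sigma_um["xy"]), 0.21 * 0.519 / 1.4,
               tolerance = 1e-12)  # 0.0778 um
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-9)
  expect_true(all(dim(psf$kernel) %% 2 == 1))

  # higher NA -> smaller optical sigma_xy
  tab <- registry_all()
  sig <- vapply(seq_len(nrow(tab)), function(i) {
    synthetic_psf(registry_lookup(tab$microscope[i],
                                  tab$magnification[i]))$sigma_um[["xy"]]
  }, numeric(1))
  expect_true(all(diff(sig[order(tab$na)]) <= 1e-12))

  # sampled width never drops below one voxel
  px <- vapply(seq_len(nrow(tab)), function(i) {
    min(synthetic_psf(registry_lookup(tab$microscope[i],
                                      tab$magnification[i]))$sigma_px)
  }, numeric(1))
  expect_true(all(px >= 1))
})

test_that("PSF files round-trip and malformed files are rejected", {
  psf <- synthetic_psf(registry_lookup("Phenix", 20))
  path <- withr::local_tempfile(fileext = ".psf")
  write_psf(psf, path)
  back <- read_psf(path)
  expect_lt(max(abs(back$kernel - psf$kernel)), 1e-12)
  expect_equal(back$spacing_um, psf$spacing_um)

  lines <- readLines(path)
  writeLines(lines[!grepl("spacing_um", lines)], path)
  expect_error(read_psf(path), "spacing_um")

  # all-zero kernel cannot be normalised
  writeLines(c("# focisim psf v1", "# spacing_um: 0.1 0.1 0.3",
               "# dims: 1 1 1", "0"), path)
  expect_error(read_psf(path), "normalization")

  # even extents are padded back to odd
  k <- array(1, c(2, 2, 2))
  writeLines(c("# focisim psf v1", "# spacing_um: 0.1 0.1 0.3",
               "# dims: 2 2 2", format(as.numeric(k))), path)
  expect_true(all(dim(read_psf(path)$kernel) %% 2 == 1))
})

test_that("rendering conserves intensity and a slice picks the nearest plane", {
  geom <- small_geometry(seed = 1)
  cfg <- registry_lookup("Phenix", 40)
  psf <- synthetic_psf(cfg)

  f1 <- point_field(0.2, -0.4, 0.1)
  stack <- render_image(f1, geom, cfg, psf, mode = "stack")
  expect_equal(sum(stack$pixels), 1, tolerance = 1e-6)

  # total intensity conserved for a dense gamma-H2AX field too
  d <- induce_photon_damage(geom, 2, seed = 2)
  gf <- gh2ax_marker_field(d, geom, seed = 3)
  gstack <- render_image(gf, geom, cfg, psf, mode = "stack")
  expect_equal(sum(gstack$pixels), sum(gf$intensity), tolerance = 1e-6)

  sl <- render_image(f1, geom, cfg, psf, mode = "slice", z_center_um = 0.1)
  expect_equal(sl$z_offset_um, round(0.1 / cfg$z_spacing_um) *
                 cfg$z_spacing_um)
  expect_error(render_image(f1, geom, cfg, psf, z_center_um = 50),
               "outside")

  empty <- point_field(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(sum(render_image(empty, geom, cfg, psf,
                                mode = "stack")$pixels), 0)
})

test_that("rendering is linear and shift-covariant on the voxel lattice", {
  geom <- small_geometry(seed = 2)
  cfg <- registry_lookup("Phenix", 40)
  psf <- synthetic_psf(cfg)
  fa <- point_field(0.5, 0.5, 0)
  fb <- point_field(-1, 0.2, 0.4, intensity = 2.5)
  fab <- point_field(c(0.5, -1), c(0.5, 0.2), c(0, 0.4),
                     intensity = c(1, 2.5))
  ia <- render_image(fa, geom, cfg, psf, mode = "stack")$pixels
  ib <- render_image(fb, geom, cfg, psf, mode = "stack")$pixels
  iab <- render_image(fab, geom, cfg, psf, mode = "stack")$pixels
  expect_equal(iab, ia + ib, tolerance = 1e-12)

  # translating a source by whole voxels translates the image
  sh <- render_image(point_field(0.5 + 3 * cfg$xy_spacing_um, 0.5,
                                 cfg$z_spacing_um),
                     geom, cfg, psf, mode = "stack")$pixels
  d <- dim(ia)
  expect_equal(sh[4:d[1], , 2:d[3]], ia[1:(d[1] - 3), , 1:(d[3] - 1)],
               tolerance = 1e-12)
})

test_that("out-of-plane sources contribute monotonically less to the slice", {
  geom <- small_geometry(seed = 3)
  cfg <- registry_lookup("Airyscan", 63)
  psf <- synthetic_psf(cfg)
  dz_grid <- cfg$z_spacing_um * (0:5)
  peak <- vapply(dz_grid, function(dz) {
    max(render_image(point_field(0, 0, dz), geom, cfg, psf,
                     mode = "slice", z_center_um = 0)$pixels)
  }, numeric(1))
  expect_true(all(diff(peak) < 0))
})

test_that("deconvolved rendering is band-limited in-plane and z-sectioned", {
  geom <- small_geometry(seed = 4)
  cfg <- registry_lookup("Airyscan", 63)
  img <- render_image(point_field(0.3, -0.2, 0), geom, cfg,
                      mode = "stack", deconvolved = TRUE)
  expect_equal(sum(img$pixels), 1, tolerance = 1e-9)
  # all light stays in the source's z-plane (ideal optical sectioning)
  per_plane <- apply(img$pixels, 3, sum)
  expect_equal(sum(per_plane > 0), 1)
  # and spreads over a compact in-plane Gaussian footprint
  plane <- img$pixels[, , which(per_plane > 0)]
  expect_gt(sum(plane > 0), 1)
  expect_lt(max(plane), 0.2)   # one-voxel-sigma Gaussian peak ~ 0.16
  expect_error(render_image(point_field(0, 0, 0), geom, cfg,
                            mode = "stack"), "psf is required")
})

test_that("synthetic images export as normalised float TIFF", {
  geom <- small_geometry(seed = 5)
  cfg <- registry_lookup("Phenix", 20)
  psf <- synthetic_psf(cfg)
  d <- induce_photon_damage(geom, 2, seed = 6)
  img <- render_image(gh2ax_marker_field(d, geom, seed = 7), geom, cfg,
                      psf, mode = "stack")
  path <- withr::local_tempfile(fileext = ".tiff")
  out <- write_image_tiff(img, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(pages), dim(img$pixels)[3])
  back <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  # pages are y-x transposed relative to the internal x-y-z array
  expect_equal(max(back) * attr(out, "scale"), max(img$pixels),
               tolerance = 1e-6)
})
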