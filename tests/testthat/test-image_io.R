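# Calibrated stack reading/writing and result serialization.

test_that("integer stacks round-trip bit-exactly with their calibration", {
  vox <- array(sample(0:65535, 3 * 3 * 32 * 32, TRUE), dim = c(3, 3, 32, 32))
  st <- calibrated_stack(vox, 0.3, 0.5, list(dextran = 1, gfp = 2, dapi = 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_identical(back$voxels, vox + 0)
  expect_equal(back$pixel_size, 0.3, tolerance = 1e-6)
  expect_equal(back$z_spacing, 0.5)  # constant 0.5 um slice spacing survives
  expect_identical(back$channel_roles, st$channel_roles)
})

test_that("single-plane reads normalize axes and accept calibration overrides", {
  path <- withr::local_tempfile(fileext = ".tif")
  pg <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  write_tiff(path, list(pg), bits = 8)  # no resolution metadata at all
  expect_error(read_stack(path), class = "mq_config_error")
  st <- read_stack(path, calibration_override = list(pixel_size = 0.3))
  expect_identical(dim(st$voxels), c(1L, 1L, 64L, 64L))
  expect_equal(st$pixel_size, 0.3)
  expect_identical(st$voxels[1, 1, , ], pg + 0)
})

test_that("explicit calibration override beats file metadata", {
  st <- calibrated_stack(array(0:99, c(1, 1, 10, 10)), 0.25)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  expect_equal(read_stack(path)$pixel_size, 0.25, tolerance = 1e-6)
  ov <- read_stack(path, calibration_override = list(pixel_size = 0.30))
  expect_equal(ov$pixel_size, 0.30)
})

test_that("RGB pages map red/green/blue to dextran/gfp/dapi", {
  arr <- array(0L, dim = c(16, 16, 3))
  arr[, , 1] <- 11L; arr[, , 2] <- 22L; arr[, , 3] <- 33L
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(path, list(arr), bits = 8, pixel_size = 0.3)
  st <- read_stack(path)
  expect_identical(unlist(st$channel_roles),
                   c(dextran = 1L, gfp = 2L, dapi = 3L))
  expect_true(all(st$voxels[1, st$channel_roles$gfp, , ] == 22))
})

test_that("split_channel is a pure slicing operation", {
  vox <- array(stats::runif(2 * 2 * 8 * 8, 0, 100), dim = c(2, 2, 8, 8))
  st <- calibrated_stack(vox, 0.3, 0.5, list(dextran = 1, dapi = 2))
  sl <- split_channel(st, "dextran")
  expect_length(sl, 2)
  for (z in 1:2) expect_identical(sl[[z]]$pixels, vox[z, 1, , ])
  expect_equal(sl[[1]]$pixel_size, 0.3)
  expect_error(split_channel(st, "gfp"), class = "mq_config_error")
  one <- calibrated_stack(array(1, c(1, 1, 4, 4)), 0.3)
  expect_length(split_channel(one, "dextran"), 1)
})

test_that("stack constructor enforces its invariants", {
  expect_error(calibrated_stack(array(0, c(1, 1, 4, 4)), -1),
               class = "mq_config_error")
  expect_error(calibrated_stack(array(0, c(2, 1, 4, 4)), 0.3, NA),
               class = "mq_config_error")
  expect_error(calibrated_stack(array(0, c(1, 2, 4, 4)), 0.3, NA,
                                list(dextran = 3)),
               class = "mq_config_error")
  expect_error(read_stack(file.path(tempdir(), "no-such-file.tif")),
               class = "mq_input_error")
})

test_that("write_results produces the full file set and survives re-reading", {
  out <- withr::local_tempdir()
  paths <- write_results(list(), list(), out, manifest = list(a = 1))
  expect_true(all(file.exists(paths)))
  expect_identical(nrow(utils::read.csv(paths["per_field"])), 0L)
  expect_identical(nrow(utils::read.csv(paths["per_particle"])), 0L)

  particles <- data.frame(
    particle_id = 1:3, n_px = c(4L, 5L, 6L),
    area_um2 = c(0.36, 0.45, 0.54), equiv_diameter_um = 2 * sqrt(c(0.36, 0.45, 0.54) / pi),
    centroid_y_px = c(1.5, 10.2, 20.8), centroid_x_px = c(2.5, 11.1, 21.9),
    bbox_y0 = 0L, bbox_x0 = 0L, bbox_y1 = 3L, bbox_x1 = 3L,
    integrated_density = c(400, 512.5, 620.25), mean_intensity = 100,
    touches_border = FALSE, in_gfp_mask = NA)
  fr <- normalize_per_cell(particles, 10L, "img1", "ctrl", "r1")
  sm <- summarize_condition(list(fr), "ctrl")
  paths <- write_results(list(fr), sm, out, manifest = list(seed = 1))
  pp <- utils::read.csv(paths["per_particle"])
  expect_identical(nrow(pp), 3L)
  pf <- utils::read.csv(paths["per_field"])
  expect_equal(pf$mp_total_area_um2, fr$mp_total_area_um2, tolerance = 1e-6)
  expect_equal(pf$mp_intden, fr$mp_intden_total, tolerance = 1e-6)
  expect_equal(pf$mp_per_100_cells, 30, tolerance = 1e-6)
})
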