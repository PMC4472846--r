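# Scene generation, rendering, ground truth and detection scoring.

test_that("scenes are deterministic and honour their bookkeeping contracts", {
  p <- scene_params(field_px = 128L, n_mp_total = 20L)
  s1 <- generate_scene(p, 77)
  s2 <- generate_scene(p, 77)
  expect_identical(s1, s2)
  expect_identical(sum(s1$structures$class == "macropinosome"), 20L)
  s3 <- generate_scene(p, 78)
  expect_false(identical(s1$structures, s3$structures))

  truth <- scene_truth(s1)
  expect_setequal(unique(truth$class),
                  c("macropinosome", "vesicle", "nucleus", "cell"))
  expect_identical(sum(truth$class == "nucleus"), nrow(s1$cells))
  mp <- truth[truth$class == "macropinosome", ]
  expect_true(all(mp$diameter_um >= 0.5 & mp$diameter_um <= 5.0))
  W <- 128 * p$pixel_size
  expect_true(all(truth$x_um >= 0 & truth$x_um <= W &
                  truth$y_um >= 0 & truth$y_um <= W))
  expect_error(generate_scene(scene_params(confluency = 0.95), 1),
               class = "mq_config_error")
})

test_that("macropinosomes never inter-penetrate in 3-D", {
  sc <- generate_scene(scene_params(field_px = 160L, mean_mp_per_cell = 8), 13)
  mp <- sc$structures[sc$structures$class == "macropinosome", ]
  d3 <- as.matrix(dist(mp[, c("x_um", "y_um", "z_um")]))
  diag(d3) <- Inf
  minsep <- outer(mp$diameter_um / 2, mp$diameter_um / 2, `+`)
  expect_true(all(d3 >= minsep - 1e-9))
})

test_that("the requested confluency is realized on the rendered footprint", {
  p <- scene_params(confluency = 0.75)
  sc <- generate_scene(p, 3)
  frac <- mean(macroquant:::.render_footprint(sc$cells, p$field_px, p$pixel_size))
  expect_gte(frac, 0.70)
  expect_lte(frac, 0.80)
})

test_that("rendering respects z geometry and the empty-world case", {
  p <- scene_params(field_px = 64L, mean_mp_per_cell = 0,
                    confounders_per_cell = 0, background_photons = 0,
                    background_gradient = 0, noise = FALSE)
  rend <- render_stack(generate_scene(p, 2))
  expect_true(all(rend$stack$voxels[, 1, , ] == 0))

  # a 0.8-um macropinosome centred at z = 2.0 um appears only in slice 5
  # (its 0.4-um axial radius cannot reach the neighbouring slices)
  p2 <- scene_params(field_px = 64L, mean_mp_per_cell = 0,
                     confounders_per_cell = 0, noise = FALSE)
  sc <- generate_scene(p2, 2)
  sc$structures <- data.frame(class = "macropinosome", x_um = 9.6, y_um = 9.6,
                              z_um = 2.0, diameter_um = 0.8, cell_id = 1L)
  rend <- render_stack(sc)
  slice_max <- apply(rend$stack$voxels[, 1, , ], 1, max)
  expect_identical(which.max(slice_max), 5L)
})

test_that("rendered stacks carry calibration readable by the pipeline", {
  p <- scene_params(field_px = 96L)
  rend <- render_stack(generate_scene(p, 8))
  expect_s3_class(rend$stack, "CalibratedStack")
  expect_equal(rend$stack$z_spacing, 0.5)
  expect_identical(dim(rend$stack$voxels)[1:2], c(11L, 3L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(rend$stack, path)
  expect_identical(read_stack(path)$voxels, rend$stack$voxels)
})

test_that("ground truth files round-trip through JSON", {
  sc <- generate_scene(scene_params(field_px = 96L), 4)
  truth <- scene_truth(sc)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path, field_id = "f9", pixel_size = 0.3)
  back <- read_truth(path)
  expect_identical(attr(back, "field_id"), "f9")
  expect_equal(back$x_um, truth$x_um, tolerance = 1e-12)
  expect_identical(back$class, truth$class)
})

test_that("greedy one-to-one scoring behaves on constructed cases", {
  truth <- data.frame(class = "macropinosome",
                      x_um = c(5, 10, 15), y_um = c(5, 5, 5),
                      z_um = 2, diameter_um = 1)
  det_exact <- data.frame(centroid_x_px = truth$x_um / 0.3 - 0.5,
                          centroid_y_px = truth$y_um / 0.3 - 0.5)
  s <- score_detections(truth, det_exact, pixel_size = 0.3)
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 1)
  expect_equal(s$f1, 1)

  s0 <- score_detections(truth[rep(1:3, length.out = 10), ], det_exact[0, ],
                         pixel_size = 0.3)
  expect_equal(s0$recall, 0)
  expect_identical(s0$false_negatives, 10L)

  # 10 truths, 9 matched, 1 spurious detection
  t10 <- data.frame(class = "macropinosome", x_um = seq(3, 30, 3), y_um = 10,
                    z_um = 2, diameter_um = 1)
  d10 <- data.frame(centroid_x_px = c(seq(3, 27, 3), 60) / 0.3 - 0.5,
                    centroid_y_px = c(rep(10, 9), 60) / 0.3 - 0.5)
  s9 <- score_detections(t10, d10, pixel_size = 0.3)
  expect_equal(s9$precision, 0.9)
  expect_equal(s9$recall, 0.9)
  expect_equal(s9$count_error_fraction, 0)
  expect_identical(s9$true_positives + s9$false_negatives, s9$n_truth)
  expect_identical(s9$true_positives + s9$false_positives, s9$n_detected)

  # one detection cannot match two truths: two truths 0.6 um apart, one det
  t2 <- data.frame(class = "macropinosome", x_um = c(10, 10.6), y_um = 10,
                   z_um = 2, diameter_um = 1)
  d1 <- data.frame(centroid_x_px = 10.3 / 0.3 - 0.5, centroid_y_px = 10 / 0.3 - 0.5)
  s2 <- score_detections(t2, d1, pixel_size = 0.3)
  expect_identical(s2$true_positives, 1L)
  expect_identical(s2$false_negatives, 1L)

  expect_error(score_detections(structure(truth, field_id = "a"),
                                cbind(det_exact, image_id = "b"),
                                pixel_size = 0.3),
               class = "mq_input_error")
  expect_error(score_detections(truth, det_exact, match_radius_um = 0,
                                pixel_size = 0.3),
               class = "mq_config_error")
})

test_that("detection quality degrades monotonically as SNR falls", {
  p0 <- scene_params(field_px = 128L)
  f1_at <- function(snr) {
    f1s <- vapply(c(61, 62, 63), function(seed) {
      p <- p0; p$snr <- snr
      sc <- generate_scene(p, seed)   # same scenes: seed fixes geometry
      rend <- render_stack(sc)
      res <- run_field(rend$stack, image_id = "f")
      score_detections(rend$truth, res$particles, pixel_size = 0.3)$f1
    }, 0)
    median(f1s)
  }
  hi <- f1_at(20); mid <- f1_at(8); lo <- f1_at(3.5)
  expect_gte(hi, mid - 0.02)
  expect_gte(mid, lo - 0.02)
  expect_gt(hi, lo)
})
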