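# Particle analysis, size filtering, nucleus counting, per-cell readouts.

test_that("component labelling and areas match a flood-fill oracle", {
  set.seed(101)
  for (i in 1:100) {
    mask <- matrix(stats::runif(64 * 64) < 0.18, 64, 64)
    mine <- cpp_label(mask, 8L)
    ref <- oracle_label(mask, 8)
    expect_identical(max(mine), max(ref))
    if (max(ref) > 0) {
      # same partition: component pixel counts agree as multisets
      expect_identical(sort(tabulate(mine[mine > 0])),
                       sort(tabulate(ref[ref > 0])))
      # and pixel-for-pixel: each of my labels maps to exactly one oracle label
      expect_true(all(rowSums(table(mine[mask], ref[mask]) > 0) == 1))
    }
  }
})

test_that("the calibrated size filter excludes by area, bounds inclusive", {
  ps <- 0.3  # 0.09 um^2 per pixel
  m <- matrix(FALSE, 64, 64)
  m[10, 10:11] <- TRUE                 # 2 px = 0.18 um^2 -> below 0.2
  m[30, 30:32] <- TRUE                 # 3 px = 0.27 um^2 -> kept
  m[50:62, 40:57] <- TRUE              # 13 x 18 = 234 px = 21.06 -> above 20
  got <- analyze_particles(binary_mask(m, ps), matrix(100, 64, 64))
  expect_identical(nrow(got), 1L)
  expect_equal(got$area_um2, 0.27)
  rej <- attr(got, "rejected")
  expect_identical(nrow(rej), 2L)
  # conservation: kept + rejected pixels account for all foreground
  expect_equal(sum(got$area_um2) + sum(rej$area_um2), sum(m) * ps^2)

  # a 5.0-um disk (area ~19.63 um^2) passes, a 5.3-um one (~22.06) does not
  a5 <- matrix(FALSE, 40, 40); a5[which(disk_mask(40, 40, 20, 20, 8.31))[1:218]] <- TRUE
  a53 <- matrix(FALSE, 40, 40); a53[which(disk_mask(40, 40, 20, 20, 8.9))[1:245]] <- TRUE
  expect_identical(nrow(analyze_particles(binary_mask(a5, ps), matrix(0, 40, 40))), 1L)
  expect_identical(nrow(analyze_particles(binary_mask(a53, ps), matrix(0, 40, 40))), 0L)

  empty <- analyze_particles(binary_mask(matrix(FALSE, 8, 8), ps), matrix(0, 8, 8))
  expect_identical(nrow(empty), 0L)
  expect_error(analyze_particles(binary_mask(m, ps), matrix(0, 8, 8)),
               class = "mq_input_error")
  expect_error(size_filter(2, 1), class = "mq_config_error")
})

test_that("measurements: integrated density, centroid, diameter consistency", {
  ps <- 0.5
  m <- matrix(FALSE, 16, 16)
  m[4:5, 4:5] <- TRUE  # 4-px square
  inten <- matrix(0, 16, 16); inten[m] <- 100
  p <- analyze_particles(binary_mask(m, ps), inten)
  expect_equal(p$integrated_density, 400)
  expect_equal(p$mean_intensity, 100)
  expect_equal(p$area_um2, 4 * ps^2)
  expect_equal(p$equiv_diameter_um, 2 * sqrt(p$area_um2 / pi), tolerance = 1e-9)
  expect_equal(p$centroid_y_px, 3.5)  # 0-based centres of rows 4:5
  expect_equal(p$centroid_x_px, 3.5)
  expect_identical(c(p$bbox_y0, p$bbox_x0, p$bbox_y1, p$bbox_x1),
                   c(3L, 3L, 5L, 5L))  # half-open, 0-based
  expect_false(p$touches_border)
})

test_that("border particles are kept by default, excluded on request", {
  ps <- 0.3
  m <- matrix(FALSE, 20, 20)
  m[1:2, 1:3] <- TRUE       # touches the border
  m[10:11, 10:12] <- TRUE
  keep <- analyze_particles(binary_mask(m, ps), matrix(0, 20, 20))
  expect_identical(nrow(keep), 2L)
  expect_identical(sum(keep$touches_border), 1L)
  excl <- analyze_particles(binary_mask(m, ps), matrix(0, 20, 20),
                            exclude_border_particles = TRUE)
  expect_identical(nrow(excl), 1L)
})

test_that("nucleus counting applies an inclusive area floor", {
  ps <- 0.5
  m <- matrix(FALSE, 128, 128)
  centres <- cbind(c(20, 20, 64, 100, 100), c(20, 100, 64, 20, 100))
  for (i in 1:5) m[disk_mask(128, 128, centres[i, 1], centres[i, 2], 10)] <- TRUE
  set.seed(5)  # 40 speckles well under the floor
  for (i in 1:40) {
    cy <- sample(30:50, 1); cx <- sample(40:124, 1)
    m[cy, cx] <- TRUE
  }
  expect_identical(count_nuclei(binary_mask(m, ps), 30), 5L)
  expect_identical(count_nuclei(binary_mask(matrix(FALSE, 8, 8), ps), 30), 0L)

  # exactly at the floor: counted
  one <- matrix(FALSE, 20, 20); one[1:12, 1:10] <- TRUE  # 120 px * 0.25 = 30
  expect_identical(count_nuclei(binary_mask(one, ps), 30), 1L)
})

test_that("per-cell normalization handles its degenerate cases", {
  p45 <- data.frame(area_um2 = rep(1, 45), integrated_density = rep(10, 45))
  r <- normalize_per_cell(p45, 30L, "i1", "ctrl", "1")
  expect_equal(r$mp_per_cell, 1.5)
  expect_equal(r$mp_per_100_cells, 150)
  expect_true(r$valid)

  r0 <- normalize_per_cell(p45[0, ], 10L, "i2", "ctrl", "1")
  expect_identical(r0$mp_count, 0L)
  expect_equal(r0$mp_avg_size_um2, 0)
  expect_true(r0$valid)

  rz <- normalize_per_cell(p45[1:7, ], 0L, "i3", "ctrl", "1")
  expect_false(rz$valid)
  expect_true(is.na(rz$mp_per_cell))
})

test_that("condition summaries pool within replicates and report SEM", {
  mk <- function(id, rep, mp, nuc)
    normalize_per_cell(data.frame(area_um2 = rep(1, mp),
                                  integrated_density = rep(1, mp)),
                       nuc, id, "ctrl", rep)
  # one field per replicate with mp per 100 cells = 10, 12, 14
  res <- list(mk("a", "1", 10, 100), mk("b", "2", 12, 100), mk("c", "3", 14, 100))
  s <- summarize_condition(res)
  expect_equal(s$mean_mp_per_100_cells, 12)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-12)
  expect_identical(s$n_replicates, 3L)
  expect_identical(s$n_cells_total, 300L)
  expect_true(s$under_sampled)  # 100 cells per replicate < 200

  # replicate pooling: two fields pool counts before dividing
  res2 <- list(mk("a", "1", 10, 100), mk("b", "1", 50, 300),
               mk("c", "2", 30, 200))
  s2 <- summarize_condition(res2)
  expect_equal(s2$mean_mp_per_100_cells, mean(c(100 * 60 / 400, 15)))

  expect_true(is.na(summarize_condition(list(mk("a", "1", 5, 250)))$sem))
  expect_false(summarize_condition(list(mk("a", "1", 5, 250)))$under_sampled)
  bad <- list(normalize_per_cell(data.frame(area_um2 = 1, integrated_density = 1),
                                 0L, "x", "eipa", "1"))
  expect_error(summarize_condition(bad), "eipa", class = "mq_input_error")
})
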