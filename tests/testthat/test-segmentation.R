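# Thresholding, watershed splitting, cell masks, nucleus segmentation.

test_that("Otsu matches exhaustive search of the between-class criterion", {
  img <- matrix(c(rep(10L, 900), rep(200L, 100)), 50, 20)
  counts <- tabulate(as.vector(img) + 1L, 256L)
  expect_identical(otsu_level(counts), oracle_otsu(counts))
  bm <- threshold_binary(img, "otsu")
  expect_identical(sum(bm$pixels), 100L)          # exactly the bright pixels
  expect_true(all(img[bm$pixels] == 200))

  set.seed(3)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 400, TRUE, prob = stats::dexp(0:255, 0.03)), 20, 20)
    counts <- tabulate(as.vector(px) + 1L, 256L)
    expect_identical(otsu_level(counts), oracle_otsu(counts))
  }
  expect_error(threshold_binary(matrix(7L, 4, 4), "otsu"),
               class = "mq_input_error")
})

test_that("fixed thresholding is an inclusive >= comparison", {
  bm <- threshold_binary(matrix(c(127, 129, 128, 0), 2, 2), "fixed", 128)
  expect_identical(bm$pixels, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_identical(bm$threshold_used, 128)
  expect_true(all(threshold_binary(matrix(0:255, 16, 16), "fixed", 0)$pixels))
  expect_error(threshold_binary(matrix(1, 2, 2), "fixed", 300),
               class = "mq_config_error")
  # monotone: foreground never grows as t increases
  set.seed(4)
  px <- matrix(sample(0:255, 900, TRUE), 30, 30)
  counts <- vapply(seq(0, 250, by = 25),
                   function(t) sum(threshold_binary(px, "fixed", t)$pixels), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("robust background cutoff agrees with median + k*mad on pixels", {
  set.seed(9)
  px <- matrix(pmax(0, pmin(255, round(stats::rnorm(4096, 20, 8)))), 64, 64)
  px[1:5, 1:5] <- 240
  h <- tabulate(as.vector(px) + 1L, 256L)
  expect_equal(robust_background_level(h, 2.4),
               stats::median(px) + 2.4 * stats::mad(px), tolerance = 1e-9)
  bm <- threshold_binary(px, "robust_background", k = 2.4)
  expect_true(all(px[bm$pixels] >= bm$threshold_used))
})

test_that("watershed separates tangent structures and never merges", {
  # single isolated disk: untouched
  d1 <- disk_mask(32, 32, 16, 16, 7)
  expect_identical(watershed_split(d1, 2)$pixels, d1)

  # two tangent disks (r = 8 px, centres 16 px apart) come apart
  m <- disk_mask(48, 64, 24, 24, 8) | disk_mask(48, 64, 24, 40, 8)
  split <- watershed_split(m, 2)
  expect_identical(max(oracle_label(split$pixels, 8)), 2L)
  expect_true(all(split$pixels | !split$pixels))  # logical
  expect_true(all(!split$pixels[!m]))             # subset of input

  # empty passes through
  e <- watershed_split(matrix(FALSE, 8, 8), 2)
  expect_false(any(e$pixels))
  expect_true(e$watershed_applied)

  # never merges: component count non-decreasing on random blobs
  set.seed(21)
  for (i in 1:8) {
    mm <- matrix(FALSE, 40, 40)
    for (j in 1:5)
      mm <- mm | disk_mask(40, 40, sample(8:32, 1), sample(8:32, 1), sample(2:6, 1))
    ws <- watershed_split(mm, 2)
    expect_gte(max(oracle_label(ws$pixels, 8)), max(oracle_label(mm, 8)))
    expect_true(all(!ws$pixels[!mm]))
  }
})

test_that("cell masks fill nucleus holes and drop debris", {
  # dark field: no GFP-positive cells
  dark <- projected_image(matrix(3, 64, 64) + diag(64), 0.3, "gfp")
  expect_false(any(make_cell_mask(dark, "fixed", 100)$pixels))

  # 30-um cell with a dark nucleus hole: footprint covers the hole
  ps <- 0.3
  cell_r_px <- (15 / ps)
  img <- matrix(0, 128, 128)
  img[disk_mask(128, 128, 64, 64, cell_r_px)] <- 200
  img[disk_mask(128, 128, 64, 64, 12)] <- 0    # nucleus hole
  cm <- make_cell_mask(projected_image(img, ps, "gfp"), "fixed", 100,
                       min_cell_area_um2 = 50)
  measured <- sum(cm$pixels) * ps^2
  expect_lt(abs(measured - pi * 15^2) / (pi * 15^2), 0.02)

  # 5-um^2 speck below the 50-um^2 floor disappears
  img2 <- matrix(0, 128, 128)
  img2[disk_mask(128, 128, 40, 40, cell_r_px)] <- 200
  img2[disk_mask(128, 128, 110, 110, 4)] <- 200   # ~4.5 um^2
  cm2 <- make_cell_mask(projected_image(img2, ps, "gfp"), "fixed", 100, 50)
  expect_identical(max(oracle_label(cm2$pixels, 8)), 1L)
})

test_that("mask superimposition clips or keeps whole particles", {
  s <- matrix(FALSE, 10, 10); s[2:4, 2:4] <- TRUE          # 9-px particle
  cells <- matrix(FALSE, 10, 10); cells[1:10, 1:3] <- TRUE # covers 6 px of it
  sm <- binary_mask(s, 0.3); cmask <- binary_mask(cells, 0.3)

  all_true <- binary_mask(matrix(TRUE, 10, 10), 0.3)
  expect_identical(apply_mask(sm, all_true, "pixel_and")$pixels, s)
  all_false <- binary_mask(matrix(FALSE, 10, 10), 0.3)
  expect_false(any(apply_mask(sm, all_false, "pixel_and")$pixels))

  clipped <- apply_mask(sm, cmask, "pixel_and")
  expect_identical(sum(clipped$pixels), 6L)
  whole <- apply_mask(sm, cmask, "whole_particle", overlap_fraction = 0.5)
  expect_identical(sum(whole$pixels), 9L)   # 6/9 >= 0.5: kept intact
  gone <- apply_mask(sm, cmask, "whole_particle", overlap_fraction = 0.7)
  expect_identical(sum(gone$pixels), 0L)    # 6/9 < 0.7: dropped entirely

  expect_true(all(clipped$pixels <= s) && all(clipped$pixels <= cells))
  expect_true(all(whole$pixels <= s))
  expect_error(apply_mask(sm, binary_mask(matrix(TRUE, 5, 5), 0.3)),
               class = "mq_input_error")
})

test_that("nucleus segmentation separates touching nuclei", {
  ps <- 0.3
  img <- matrix(5, 128, 128)
  centres <- cbind(c(20, 20, 64, 108, 108), c(20, 108, 64, 20, 108))
  for (i in 1:5) img[disk_mask(128, 128, centres[i, 1], centres[i, 2], 14)] <- 220
  nm <- segment_nuclei(projected_image(img, ps, "dapi"), "fixed", 100)
  expect_identical(max(oracle_label(nm$pixels, 8)), 5L)

  # two tangent ellipses come apart
  img2 <- matrix(5, 90, 140)
  yy <- matrix(seq_len(90), 90, 140); xx <- matrix(seq_len(140), 90, 140, byrow = TRUE)
  e1 <- ((yy - 45) / 12)^2 + ((xx - 45) / 18)^2 <= 1
  e2 <- ((yy - 45) / 12)^2 + ((xx - 81) / 18)^2 <= 1
  img2[e1 | e2] <- 220
  nm2 <- segment_nuclei(projected_image(img2, ps, "dapi"), "fixed", 100)
  expect_identical(max(oracle_label(nm2$pixels, 8)), 2L)

  empty <- segment_nuclei(projected_image(matrix(c(2, 3), 64, 64), ps, "dapi"),
                          "fixed", 100)
  expect_false(any(empty$pixels))
})
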