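test_that("blank or low-contrast images yield zero detections", {
  blank <- list(cyt = matrix(0.05, 200, 200), nuc = matrix(0.05, 200, 200),
                pixel_scale = 0.25)
  seg <- segment_cells(blank)
  expect_equal(nrow(seg$cells), 0L)
  set.seed(1)
  noisy <- list(cyt = matrix(abs(rnorm(4e4, 0.05, 0.02)), 200, 200),
                nuc = matrix(abs(rnorm(4e4, 0.05, 0.02)), 200, 200),
                pixel_scale = 0.25)
  expect_equal(nrow(segment_cells(noisy)$cells), 0L)
})

test_that("detection recovers counts within 2% with high recall and precision", {
  img <- render_density_field(4000, 450, 450,
                              render = render_params(pixel_scale = 0.25),
                              seed = 11L)
  seg <- segment_cells(img)
  n_true <- nrow(img$ground_truth)
  expect_lt(abs(nrow(seg$cells) / n_true - 1), 0.02)
  # match detections to ground truth centres
  det <- seg$cells
  gt <- img$ground_truth
  ps <- img$pixel_scale
  hit <- vapply(seq_len(nrow(gt)), function(i) {
    any((det$x_px * ps - gt$x_um[i])^2 +
          (det$y_px * ps - gt$y_um[i])^2 < 4^2)
  }, TRUE)
  recall <- mean(hit)
  precision <- min(1, sum(hit) / nrow(det))
  expect_gte(recall, 0.98)
  expect_gte(precision, 0.98)
})

test_that("density estimates follow replicate-field arithmetic", {
  de <- estimate_density(c(980, 1000, 1020), 0.25)
  expect_equal(de$density, 4000)
  expect_equal(de$relative_sd_pct, 2.0, tolerance = 1e-9)
  one <- estimate_density(1000L, 0.25)
  expect_true(is.na(one$relative_sd_pct))
  expect_error(estimate_density(c(10, 20), 0), "positive")
  expect_error(estimate_density(integer(0), 0.25), "at least one")
})

test_that("counts are invariant to translation and 90-degree rotation", {
  img <- render_density_field(3000, 300, 300,
                              render = render_params(pixel_scale = 0.25),
                              seed = 21L)
  n0 <- nrow(segment_cells(img)$cells)
  rot <- list(cyt = t(img$cyt)[ncol(img$cyt):1, ],
              nuc = t(img$nuc)[ncol(img$nuc):1, ],
              pixel_scale = img$pixel_scale)
  expect_equal(nrow(segment_cells(rot)$cells), n0)
  # translation by whole pixels: pad on one side, crop the other
  shift <- function(m, k) rbind(matrix(0.05, k, ncol(m)),
                                m[seq_len(nrow(m) - k), ])
  tra <- list(cyt = shift(img$cyt, 8L), nuc = shift(img$nuc, 8L),
              pixel_scale = img$pixel_scale)
  expect_lte(abs(nrow(segment_cells(tra)$cells) - n0), 2L)
})

test_that("radial profiles quantify uniformity and the donut artifact", {
  # large synthetic point sets: the profile statistic itself
  set.seed(33)
  n <- 20000
  rho <- sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  seg_u <- list(cells = data.frame(x_px = 1000 + 900 * rho * cos(ang),
                                   y_px = 1000 + 900 * rho * sin(ang)))
  rp <- radial_profile(seg_u, c(1000, 1000), 900)
  expect_equal(rp$uniformity_ratio, 1, tolerance = 0.15)
  expect_false(rp$donut)
  expect_true(rp$reliable)

  # rendered donut image through the full detection path
  img <- render_spot(simple_roster(500, "small"),
                     list(type = "disc", diameter_um = 600),
                     render_params(pixel_scale = 0.25, mode = "donut"),
                     seed = 5L)
  seg <- segment_cells(img)
  ctr <- nrow(img$cyt) / 2
  rp2 <- radial_profile(seg, c(ctr, ctr), 300 / img$pixel_scale)
  expect_gt(rp2$uniformity_ratio, 1.5)
  expect_true(rp2$donut)

  few <- list(cells = data.frame(x_px = 1000 + rnorm(20, 0, 50),
                                 y_px = 1000 + rnorm(20, 0, 50)))
  expect_false(radial_profile(few, c(1000, 1000), 900)$reliable)
  outside <- list(cells = data.frame(x_px = 5000, y_px = 5000))
  expect_error(radial_profile(outside, c(1000, 1000), 900), "no detections")
})
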