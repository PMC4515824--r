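test_that("circle and ellipse contours match closed-form geometry", {
  disk <- synthesize_nucleus("ellipse", r0 = 3, ratio = 1)
  expect_equal(disk$area, pi * 9, tolerance = 1e-6)
  expect_equal(disk$perimeter, 2 * pi * 3, tolerance = 1e-6)
  expect_equal(disk$nci, 2 * sqrt(pi), tolerance = 1e-6)

  # independent oracle: exact elliptic-integral perimeter
  for (q in c(1.3, 1.7, 2.2)) {
    a <- sqrt(q); b <- 1 / sqrt(q)
    ek <- pracma::ellipke(1 - (b / a)^2)
    p_exact <- 4 * a * ek$e
    s <- synthesize_nucleus("ellipse", r0 = 1, ratio = q)
    expect_equal(s$perimeter, p_exact, tolerance = 1e-4)
    expect_equal(s$area, pi, tolerance = 1e-6)
  }
  # axis ratio 1.3 stays well below the lobed band
  s13 <- synthesize_nucleus("ellipse", r0 = 1, ratio = 1.3)
  expect_equal(s13$nci, 3.5907, tolerance = 1e-3)
  expect_lt(s13$nci, 4.1)
})

test_that("degenerate lobed specifications are rejected", {
  expect_error(synthesize_nucleus("lobed", k = 1L, depth = 0.6), "k >= 2")
  expect_error(synthesize_nucleus("lobed", k = 3L, depth = 1.2), "depth")
  expect_error(synthesize_nucleus("ellipse", ratio = 0.8), ">= 1")
})

test_that("lobed nuclei invert NCI and relative depth accurately", {
  for (target in c(4.2, 4.4, 4.7, 5.0)) {
    set.seed(1)
    s <- nucleus_from_nci(target, "lobed")
    expect_equal(s$nci, target, tolerance = 1e-4)
    expect_gte(s$k, 2L)
    expect_gte(s$rel_depth, 0.5)
  }
  for (target in c(3.56, 3.75, 4.05)) {
    s <- nucleus_from_nci(target, "ellipse")
    expect_equal(s$nci, target, tolerance = 1e-4)
  }
  expect_error(nucleus_from_nci(3.0, "ellipse"), "disk minimum")

  s <- lobed_nucleus(4, rel_depth = 0.6)
  expect_equal(s$rel_depth, 0.6, tolerance = 1e-4)
  expect_gte(s$nci, 2 * sqrt(pi))
})

test_that("NCI population sampler has the stated medians and supports", {
  set.seed(5)
  lob <- sample_nci(40000, "lobed")
  non <- sample_nci(40000, "nonlobed")
  expect_true(all(lob >= 4.2 & lob <= 5.0))
  expect_true(all(non >= 3.56 & non <= 4.05))
  expect_equal(median(lob), 4.4, tolerance = 0.01)
  expect_equal(median(non), 3.75, tolerance = 0.01)
})

test_that("rasterized pixel area agrees with analytic area within 1%", {
  set.seed(8)
  shapes <- list(
    synthesize_nucleus("ellipse", r0 = 3, ratio = 1.4),
    nucleus_from_nci(4.6, "lobed", r0 = 4),
    synthesize_nucleus("kidney", r0 = 3.5, depth = 0.4)
  )
  for (s in shapes) {
    m <- measure_nucleus_shape(s, pixel_scale = 0.1)
    expect_lt(abs(m$area_px / s$area - 1), 0.01)
    expect_lt(abs(m$perimeter / s$perimeter - 1), 0.02)
  }
})

test_that("rendering is deterministic and cells never overlap", {
  ros <- simple_roster(60, c(rep("small", 40), rep("monocyte", 20)))
  reg <- list(type = "rect", w = 220, h = 220)
  a <- render_spot(ros, reg, render_params(pixel_scale = 0.25), seed = 10L)
  b <- render_spot(ros, reg, render_params(pixel_scale = 0.25), seed = 10L)
  expect_identical(a$cyt, b$cyt)
  expect_identical(a$nuc, b$nuc)
  expect_identical(a$ground_truth, b$ground_truth)

  gt <- a$ground_truth
  if (nrow(gt) > 1) {
    dmat <- as.matrix(dist(gt[, c("x_um", "y_um")]))
    rads <- gt$diameter_um / 2
    lim <- 0.95 * outer(rads, rads, `+`)
    diag(dmat) <- Inf
    expect_true(all(dmat >= lim - 1e-9))
  }
})

test_that("empty rosters render blank images and capacity is enforced", {
  img <- render_spot(simple_roster(0), list(type = "rect", w = 50, h = 50),
                     render_params(pixel_scale = 0.25, noise_sd = 0),
                     seed = 1L)
  expect_equal(nrow(img$ground_truth), 0L)
  expect_true(all(img$cyt <= 0.051))
  set.seed(3)
  dense <- simple_roster(5000, "monocyte")
  expect_error(
    render_spot(dense, list(type = "rect", w = 100, h = 100),
                render_params(pixel_scale = 0.25), seed = 1L),
    "packing capacity")
})

test_that("uniform placement realizes the requested density within 3%", {
  img <- render_density_field(7500, 400, 400, morphotype = "small",
                              render = render_params(pixel_scale = 0.25),
                              seed = 42L)
  expect_gt(nrow(img$ground_truth), 0.97 * 7500 * 0.16)
  expect_lte(nrow(img$ground_truth), 7500 * 0.16)
})

test_that("donut mode places cells edge-heavy in the ground truth", {
  img <- render_spot(simple_roster(500, "small"),
                     list(type = "disc", diameter_um = 600),
                     render_params(pixel_scale = 0.25, mode = "donut"),
                     seed = 5L)
  gt <- img$ground_truth
  rho <- sqrt((gt$x_um - 300)^2 + (gt$y_um - 300)^2) / 300
  outer_d <- sum(rho >= 0.8) / (pi * (1 - 0.8^2))
  inner_d <- sum(rho <= 0.45) / (pi * 0.45^2)
  expect_gt(outer_d / inner_d, 1.5)
})
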