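test_that("packing limit reproduces the lattice bound endpoints", {
  expect_identical(packing_limit(12), 6945)
  expect_identical(packing_limit(11), 8265)
  expect_identical(packing_limit(1000), 1)
  expect_error(packing_limit(0), "positive")
})

test_that("expected density follows the shared-x0 saturation curve", {
  sat <- saturation_params(x0 = 2.4)
  expect_equal(expected_density(1, 1e9, sat, d_sat = 6400), 6400,
               tolerance = 1e-6)
  expect_equal(expected_density(0.5, 0, sat), 0)
  # direct evaluation at the saturating concentration
  expect_equal(expected_density(1, 7, sat, d_sat = 6400),
               6400 * (1 - exp(-7 / 2.4)), tolerance = 1e-12)
  expect_equal(round(expected_density(1, 7, sat, d_sat = 6400)), 6054)
  # monotone non-decreasing in x
  xs <- seq(0, 12, by = 0.5)
  d <- vapply(xs, function(x) expected_density(0.7, x, sat), 0)
  expect_true(all(diff(d) >= 0))
})

test_that("expected-density ratios between spots are concentration-invariant", {
  sat <- saturation_params()
  for (x in c(0.5, 2, 5, 8, 12)) {
    r <- expected_density(0.56, x, sat) / expected_density(0.05, x, sat)
    expect_equal(r, 0.56 / 0.05, tolerance = 1e-12)
  }
})

test_that("simulated capture respects capacity, background and temperature", {
  cap <- healthy_capture()
  bound <- 0.9 * packing_limit(11)
  expect_true(all(cap$spots$density <= bound))
  expect_lt(cap$off_spot_density, 20)
  # 4 degrees: no nonspecific monocyte binding anywhere
  origins <- unlist(lapply(cap$rosters, function(r) r$origin))
  expect_false("mono_nonspecific" %in% origins)
  # no monocytes at all on the lymphoid-lineage spots
  for (cd in c("CD3", "CD8", "CD19")) {
    sid <- as.character(cap$spots$spot_id[cap$spots$cd == cd])
    expect_equal(sum(cap$rosters[[sid]]$morphotype == "monocyte"), 0L)
  }
})

test_that("room-temperature incubation adds on-spot monocyte binding", {
  warm <- simulate_capture(healthy_donor(),
                           params = capture_params(temperature = 22),
                           seed = 101L)
  origins <- unlist(lapply(warm$rosters, function(r) r$origin))
  expect_true("mono_nonspecific" %in% origins)
  # step function: just below the threshold nothing is added
  cool <- simulate_capture(healthy_donor(),
                           params = capture_params(temperature = 17.5),
                           seed = 101L)
  expect_false("mono_nonspecific" %in%
                 unlist(lapply(cool$rosters, function(r) r$origin)))
})

test_that("a target with no positive cells binds at the cross-binding level", {
  pr <- default_cohort_params(
    fraction_mean = c(cd4_t = 0.62, cd8_t = 0.18, nk = 0.06, b = 0,
                      mono = 0.14),
    fraction_sd = c(cd4_t = 0, cd8_t = 0, nk = 0, b = 0, mono = 0))
  tr <- build_healthy_profile(pr, seed = 12L)
  cap <- simulate_capture(tr, seed = 12L)
  d19 <- cap$spots$density[cap$spots$cd == "CD19"]
  expect_lt(d19, 20)  # residual floor only (~5 cells/mm^2)
})

test_that("capture without a positive-control spot is refused", {
  panel <- default_panel()
  panel$role[panel$role == "positive"] <- "capture"
  expect_error(simulate_capture(healthy_donor(), panel, seed = 1L),
               "positive-control")
})

test_that("matched-spot purities are recovered from the stained-specificity parameterization", {
  tr <- healthy_donor()
  cap <- simulate_capture(tr, params = table1_capture_params(), seed = 9L)
  got <- matched_positive_fraction(cap, tr,
                                   cds = c("CD3", "CD4", "CD8", "CD19"))
  want <- c(CD3 = 97, CD4 = 97, CD8 = 98, CD19 = 93)
  # binomial error at >=2000 captured cells stays within 2pp
  sid <- as.character(cap$spots$spot_id[cap$spots$cd == "CD19"])
  expect_gte(nrow(cap$rosters[[sid]]), 2000L)
  expect_true(all(abs(got[names(want)] - want) < 2))
})
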