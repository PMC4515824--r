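test_that("class fractions and morphotype mixtures are simplex-valued", {
  for (s in 1:8) {
    tr <- build_healthy_profile(seed = s)
    expect_equal(sum(tr$class_fractions), 1, tolerance = 1e-9)
    expect_true(all(tr$class_fractions >= 0))
  }
  for (cl in default_cell_classes()) {
    expect_equal(sum(cl$morphotypes), 1, tolerance = 1e-9)
    expect_true(all(cl$markers >= 0 & cl$markers <= 1))
  }
})

test_that("the generator is deterministic given a seed", {
  a <- build_healthy_profile(seed = 7L)
  b <- build_healthy_profile(seed = 7L)
  expect_identical(a$cells, b$cells)
  expect_identical(a$markers, b$markers)
  expect_false(identical(build_healthy_profile(seed = 8L)$cells, a$cells))
})

test_that("no cell is both B-class and granular, and B cells carry CD19", {
  tr <- healthy_donor()
  b_cells <- tr$cells$class == "b"
  expect_equal(sum(b_cells &
                     tr$cells$morphotype %in% c("granular", "granular_lobed",
                                                "lobed")), 0L)
  expect_true(all(tr$markers[b_cells, "CD19"]))
  expect_false(any(tr$markers[!b_cells, "CD19"]))
})

test_that("granular share among CD8-expressing cells matches the captured-composition target", {
  shares <- vapply(1:20, function(s) {
    tr <- build_healthy_profile(default_cohort_params(n_cells = 8000L),
                                seed = 400L + s)
    cd8 <- tr$markers[, "CD8"]
    100 * mean(tr$cells$morphotype[cd8] %in% c("granular", "granular_lobed"))
  }, 0)
  # CD8 T cells carry 23/99 granular morphotypes by construction
  expect_equal(mean(shares), 23.2, tolerance = 0.05)
})

test_that("disease profiles carry their marker signatures", {
  hcl <- build_disease_profile("HCL", 0.3, seed = 5L)
  clone <- hcl$cells$class == "clone_hcl"
  expect_gt(mean(clone), 0.25)
  for (mk in c("CD19", "CD11c", "CD25", "CD103")) {
    expect_true(all(hcl$markers[clone, mk]), label = mk)
  }
  expect_true(all(hcl$cells$trap[clone]))
  expect_true(all(hcl$cells$morphotype[clone] == "hairy"))

  cll <- build_disease_profile("CLL", 0.5, seed = 5L)
  clone <- cll$cells$class == "clone_cll"
  for (mk in c("CD5", "CD23", "CD19")) {
    expect_true(all(cll$markers[clone, mk]), label = mk)
  }
  # weak CD20/CD22 expression strength reduces capture weight
  expect_equal(cll$classes$clone_cll$strength[["CD20"]], 0.35)
})

test_that("clone_fraction zero reproduces the healthy donor exactly", {
  h <- build_healthy_profile(seed = 31L)
  d0 <- build_disease_profile("CLL", 0, seed = 31L)
  expect_identical(h$cells, d0$cells)
  expect_identical(h$markers, d0$markers)
  expect_error(build_disease_profile("ALL", 0.2, seed = 1L), "allowed")
})

test_that("simulated flow is a calibrated binomial sample", {
  tr <- healthy_donor()
  fl <- simulate_flow(tr, n_events = 1e6L, seed = 2L)
  truth <- true_percent_positive(tr)
  # 1e6 events: binomial SE ~0.05pp, allow 4 SE
  expect_lt(max(abs(fl$percent_positive - truth)), 0.2)
  expect_true(all(fl$percent_positive >= 0 & fl$percent_positive <= 100))

  # no B cells -> CD19 exactly zero
  pr <- default_cohort_params(
    fraction_mean = c(cd4_t = 0.6, cd8_t = 0.2, nk = 0.06, b = 0,
                      mono = 0.14),
    fraction_sd = c(cd4_t = 0, cd8_t = 0, nk = 0, b = 0, mono = 0),
    n_cells = 4000L)
  tr0 <- build_healthy_profile(pr, seed = 3L)
  expect_identical(simulate_flow(tr0, 1e4L, seed = 4L)$percent_positive[["CD19"]], 0)

  expect_error(simulate_flow(tr, n_events = 50L), "at least 100")
})

test_that("flow estimates are unbiased over replicates", {
  tr <- build_healthy_profile(default_cohort_params(n_cells = 5000L),
                              seed = 77L)
  p <- true_percent_positive(tr)[["CD3"]] / 100
  reps <- vapply(1:120, function(i) {
    simulate_flow(tr, 2000L, seed = i)$percent_positive[["CD3"]]
  }, 0) / 100
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(reps) - p), 3 * se)
})
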