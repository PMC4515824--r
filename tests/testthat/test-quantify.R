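test_that("normalization divides by the anti-CD45 reference", {
  prof <- normalize_densities(c(CD45 = 6400, CD3 = 3580, CD19 = 330))
  expect_equal(prof$normalized_pct[prof$cd == "CD45"], 100)
  expect_equal(prof$normalized_pct[prof$cd == "CD3"], 55.9, tolerance = 1e-3)
  expect_equal(prof$normalized_pct[prof$cd == "CD19"], 5.2, tolerance = 1e-2)
  expect_error(normalize_densities(c(CD45 = 0, CD3 = 100)), "undefined")
  expect_error(normalize_densities(c(CD3 = 100)), "CD45")
  over <- normalize_densities(c(CD45 = 1000, CD16 = 1200))
  expect_true(over$flag_over_100[over$cd == "CD16"])
})

test_that("the global saturation fit recovers noiseless parameters exactly", {
  x <- c(0.5, 1, 2, 3, 5, 7, 10)
  a <- c(CD45 = 6400, CD3 = 3580, CD19 = 330)
  tit <- expand.grid(spot = names(a), x = x, KEEP.OUT.ATTRS = FALSE)
  tit$y <- a[as.character(tit$spot)] * (1 - exp(-tit$x / 2.4))
  fit <- fit_saturation(tit)
  expect_equal(fit$x0, 2.4, tolerance = 1e-6)
  expect_equal(unname(fit$a[names(a)]), unname(a), tolerance = 1e-6)
  expect_lt(sum(residuals(fit$fit)^2), 1e-6)

  expect_error(fit_saturation(data.frame(spot = "CD45", x = 5, y = 6000)),
               "3 distinct")
  flat <- expand.grid(spot = c("A", "B"), x = x)
  flat$y <- ifelse(flat$spot == "A", 100, 200)
  expect_error(fit_saturation(flat), "unidentifiable")
})

test_that("cross-tab rows are compositions and degenerate inputs are handled", {
  classified <- data.frame(
    donor = rep(1:3, each = 400),
    cd = rep(rep(c("CD3", "CD19"), each = 200), 3),
    morphotype = "small")
  xt <- crosstab(classified)
  expect_equal(unname(xt$mean[, "small"]), c(100, 100))
  expect_true(all(abs(rowSums(xt$mean) - 100) < 0.5))

  set.seed(4)
  classified$morphotype <- sample(c("small", "large", "granular"),
                                  nrow(classified), replace = TRUE)
  xt2 <- crosstab(classified)
  expect_true(all(abs(rowSums(xt2$mean) - 100) < 0.5))
  expect_equal(xt2$n_donors, 3L)
  expect_warning(crosstab(classified[1:150, ]), "fewer than")
})

test_that("immunophenotype calls follow the nonspecific-bound logic", {
  cds <- c("CD3", "CD4", "CD8", "CD16", "CD19", "CD56")
  mean_mat <- matrix(0, length(cds), 2,
                     dimnames = list(cds, c("granular", "small")))
  mean_mat[, "granular"] <- c(4.5, 0.1, 23, 54, 0, 65)
  sem_mat <- mean_mat * 0 + 0.7
  xtab <- structure(list(mean = mean_mat, sem = sem_mat, n_donors = 40L),
                    class = "morphotype_by_antibody")
  call <- call_immunophenotype(xtab, "granular")
  got <- setNames(call$call, call$cd)
  expect_equal(got[["CD3"]], "positive")
  expect_equal(got[["CD8"]], "positive")
  expect_equal(got[["CD16"]], "positive")
  expect_equal(got[["CD56"]], "positive")
  expect_equal(got[["CD4"]], "negative")
  expect_equal(got[["CD19"]], "negative")

  # uniform share at the bound: nothing can be called positive
  mean_mat[, "granular"] <- 2
  xtab$mean <- mean_mat
  flat <- call_immunophenotype(xtab, "granular")
  expect_false(any(flat$call == "positive"))
  expect_error(call_immunophenotype(xtab, "plasma"), "absent")
})

test_that("mann_whitney matches frozen values and handles edge cases", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  big <- mann_whitney(rnorm(30), rnorm(30))
  expect_equal(big$method, "normal")
  expect_true(big$p > 0 && big$p <= 1)
  expect_true(big$U >= 0 && big$U <= 900)
})

test_that("exact mann_whitney equals the exhaustive permutation oracle", {
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:6, n1, replace = TRUE)  # replace=TRUE forces ties
    b <- sample(1:6, n2, replace = TRUE)
    mw <- mann_whitney(a, b)
    expect_equal(mw$p, mw_oracle_p(a, b), tolerance = 1e-12,
                 label = paste("ties case", i))
  }
  # tie-free cases also agree with the classical exact distribution
  for (i in 1:10) {
    pool <- sample(1:1000, 11)
    a <- pool[1:5]; b <- pool[6:11]
    mw <- mann_whitney(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
    expect_equal(mw$U, unname(wt$statistic))
  }
})

test_that("reference ranges cover the cohort and reject tiny cohorts", {
  set.seed(9)
  profiles <- do.call(rbind, lapply(1:55, function(d) {
    data.frame(donor = d, cd = c("CD3", "CD19"),
               normalized_pct = c(rnorm(1, 60, 5), rnorm(1, 12, 3)))
  }))
  rr <- reference_ranges(profiles)
  cd3 <- rr[rr$cd == "CD3", ]
  expect_true(cd3$lower < 60 && 60 < cd3$upper)
  expect_true(rr[rr$cd == "CD19", "lower"] < 12)

  const <- profiles
  const$normalized_pct <- rep(c(50, 10), 55)
  rc <- reference_ranges(const)
  expect_equal(rc$lower, rc$upper)
  expect_error(reference_ranges(profiles[profiles$donor <= 2, ]),
               "at least 3")
  expect_warning(reference_ranges(profiles[profiles$donor <= 10, ]),
                 "fewer than 20")
})

test_that("diagnosis flags and scores behave at the boundaries", {
  ranges <- data.frame(cd = c("CD3", "CD19", "CD23", "CD5", "CD25"),
                       median = c(60, 12, 5, 62, 2),
                       lower = c(45, 5, 1, 50, 0.5),
                       upper = c(75, 20, 9, 75, 4), n_donors = 30L)
  sig <- disease_signatures()
  # a profile exactly at the medians: normal, no flags raised
  prof <- normalize_densities(
    c(CD45 = 6000, CD3 = 3600, CD19 = 720, CD23 = 300, CD5 = 3720,
      CD25 = 120))
  dx <- suggest_diagnosis(prof, ranges, sig)
  expect_true(all(dx$flags$flag == "within"))
  expect_equal(dx$ranking$disease[1], "normal")
  expect_equal(dx$ranking$score[dx$ranking$disease == "normal"], 1)
  # unknown CD in the profile: panel mismatch
  bad <- normalize_densities(c(CD45 = 6000, CD99 = 50))
  expect_error(suggest_diagnosis(bad, ranges, sig), "mismatch")
})

test_that("concordance statistics have their closed-form degenerate values", {
  paired <- data.frame(donor = rep(1:5, 2),
                       cd = rep(c("CD3", "CD19"), each = 5),
                       array_pct = c(55, 60, 65, 58, 62, 8, 10, 12, 9, 11))
  paired$flow_pct <- paired$array_pct
  cr <- fc_concordance(paired)
  expect_equal(unname(cr$R), c(1, 1))
  expect_equal(cr$k, 1)
  paired$array_pct[paired$cd == "CD19"] <- 10
  cr2 <- fc_concordance(paired)
  expect_true(is.na(cr2$R[["CD19"]]))
  expect_equal(cr2$zero_variance, "CD19")
  expect_error(fc_concordance(paired[c(1, 6), ]), "fewer than")
})
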