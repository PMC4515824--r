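test_that("sub-pixel measurement recovers disk and square geometry", {
  disk <- synthesize_nucleus("ellipse", r0 = 3, ratio = 1)
  m <- measure_nucleus_shape(disk, pixel_scale = 0.1)  # radius 30 px
  expect_lt(abs(m$nci / (2 * sqrt(pi)) - 1), 0.01)

  sq <- matrix(FALSE, 140, 140)
  sq[21:120, 21:120] <- TRUE
  ct <- subpixel_contour(sq)
  nci_sq <- ct$perimeter_px / sqrt(sum(sq))
  expect_lt(abs(nci_sq / 4 - 1), 0.015)
})

test_that("cleft detection reads lobed, kidney and smooth contours correctly", {
  rast_contour <- function(s, ps = 0.1) subpixel_contour(rasterize_nucleus(s, ps))
  # circle: no clefts
  expect_length(detect_clefts(rast_contour(
    synthesize_nucleus("ellipse", r0 = 3, ratio = 1))), 0L)
  # four-lobe nucleus with generative relative depth 0.6
  s4 <- lobed_nucleus(4, rel_depth = 0.6, r0 = 4)
  cl <- detect_clefts(rast_contour(s4))
  expect_length(cl, 4L)
  expect_true(all(abs(cl - 0.6) < 0.08))
  # kidney indentation: one cleft, below the lobed threshold
  kd <- synthesize_nucleus("kidney", r0 = 4, depth = 0.38)
  clk <- detect_clefts(rast_contour(kd))
  expect_lte(sum(clk >= 0.18), 1L)
  expect_true(all(clk < 0.5))
  expect_gte(sum(clk >= 0.18), 1L)
})

test_that("measure computes areas, NC ratio and NCI from masks", {
  # synthetic concentric masks with known pixel counts
  n <- 200
  ix <- matrix(seq_len(n), n, n); iy <- t(ix)
  rr <- sqrt((ix - 100.5)^2 + (iy - 100.5)^2)
  cell <- rr <= 80
  nuc <- rr <= 60
  rec <- measure(cell, nuc, pixel_scale = 0.1)
  expect_equal(rec$cell_area_um2, sum(cell) * 0.01)
  expect_equal(rec$nuclear_area_um2, sum(nuc) * 0.01)
  expect_equal(rec$nc_ratio, sum(nuc) / (sum(cell) - sum(nuc)),
               tolerance = 1e-9)
  expect_equal(rec$nci, 2 * sqrt(pi), tolerance = 0.03)
  expect_equal(rec$nuclei, 1L)
  # a nucleus outside the cell is an error
  nuc_bad <- rr <= 90
  expect_error(measure(cell, nuc_bad, 0.1), "beyond the cell")
})

test_that("classification rules fire in the documented order", {
  rec <- function(d, nc, gran = 0L, clefts = numeric(0), nuclei = 1L) {
    list(equiv_diameter_um = d, nc_ratio = nc, granules = gran,
         cleft_depths = list(clefts), nuclei = nuclei)
  }
  expect_equal(classify(rec(10, 4))$label, "small")
  expect_equal(classify(rec(14, 2.5, gran = 5L))$label, "granular")
  expect_equal(classify(rec(13, 2.5, gran = 4L,
                            clefts = c(0.6, 0.6, 0.6)))$label,
               "granular_lobed")
  expect_equal(classify(rec(14, 2.5, clefts = c(0.62, 0.55)))$label, "lobed")
  expect_equal(classify(rec(17, 1.3, clefts = 0.3))$label, "monocyte")
  expect_equal(classify(rec(17, 1.3))$label, "reactive")
  expect_equal(classify(rec(14, 2.5, nuclei = 2L))$label, "binuclear")
  # the 12-13 um gap is assigned by NC ratio
  expect_equal(classify(rec(12.5, 3.4))$label, "small")
  expect_equal(classify(rec(12.5, 2.4))$label, "large")
  expect_equal(classify(rec(14, 2.2))$label, "large")
  expect_equal(classify(rec(22, 0.5))$label, "other")
  expect_true(length(classify(rec(10, 4))$trace) > 0)
})

test_that("rendered cells are classified to their generative morphotype", {
  mf <- mixed_field()
  mm <- mf$matched
  expect_gte(nrow(mm), 0.95 * nrow(mf$img$ground_truth))
  acc <- mean(mm$label == mm$true_morphotype)
  expect_gte(acc, 0.95)
})

test_that("measured cell areas are indistinguishable from generative areas", {
  mm <- mixed_field()$matched
  lym <- mm[mm$true_morphotype %in% c("small", "large", "granular"), ]
  mono <- mm[mm$true_morphotype == "monocyte", ]
  gen_area <- function(d) pi * d^2 / 4
  p_l <- mann_whitney(lym$cell_area_um2, gen_area(lym$true_diameter_um))$p
  p_m <- mann_whitney(mono$cell_area_um2, gen_area(mono$true_diameter_um))$p
  expect_gt(p_l, 0.01)
  expect_gt(p_m, 0.01)
  # monocytes are larger than lymphocytes, as in the size comparison
  expect_gt(median(mono$cell_area_um2), median(lym$cell_area_um2))
})

test_that("measured NCI medians recover the two nuclear populations", {
  lob <- nci_population_study(40, "lobed", seed = 9L)
  non <- nci_population_study(80, "nonlobed", seed = 9L)
  expect_lt(max(abs(lob$measured_nci / lob$analytic_nci - 1)), 0.02)
  expect_lt(max(abs(non$measured_nci / non$analytic_nci - 1)), 0.02)
  expect_equal(median(lob$measured_nci), 4.4, tolerance = 0.035)
  expect_equal(median(non$measured_nci), 3.75, tolerance = 0.022)
  expect_true(all(lob$measured_nci > 4.1))
})
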