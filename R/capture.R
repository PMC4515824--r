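#' Geometric packing limit for bound round cells
#'
#' One cell per d x d square-lattice site: `ceiling(1 / d^2)` with the
#' diameter in mm, i.e. `ceiling(1e6 / d_um^2)` cells/mm^2. For 11-12 um
#' cells this gives 8265-6945 cells/mm^2.
#'
#' @param diameter_um cell diameter in micrometres.
#' @return Density bound in cells/mm^2.
#' @export
packing_limit <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  ceiling(1e6 / diameter_um^2)
}

#' Saturation-binding parameters
#'
#' The bound density on every spot follows `y = a * (1 - exp(-x / x0))` in
#' the suspension concentration x (1e6 cells/ml), with the characteristic
#' concentration `x0` shared across spots. Defaults are the global-fit
#' values for the anti-CD45/CD3/CD19 titration.
#'
#' @param x0 shared characteristic concentration (1e6 cells/ml).
#' @param a named asymptotic densities (cells/mm^2) per spot.
#' @return A `saturation_params` list.
#' @export
saturation_params <- function(x0 = 2.4,
                              a = c(CD45 = 6400, CD3 = 3580, CD19 = 330)) {
  if (x0 <= 0) stop("x0 must be positive")
  if (any(a < 0)) stop("asymptotic densities must be non-negative")
  structure(list(x0 = x0, a = a), class = "saturation_params")
}

#' Expected bound density on one spot
#'
#' `d_sat * f * (1 - exp(-x / x0))`: the saturated pan-leukocyte density
#' scaled by the fraction of suspension cells positive for the spot's
#' target. Ratios between spots are independent of x (shared x0), which is
#' what makes CD45-normalized densities concentration-invariant.
#'
#' @param fraction_positive fraction of cells positive for the target.
#' @param x suspension concentration (1e6 cells/ml).
#' @param sat [saturation_params()].
#' @param d_sat saturated reference density (cells/mm^2).
#' @return Expected density, cells/mm^2.
#' @export
expected_density <- function(fraction_positive, x, sat = saturation_params(),
                             d_sat = 6400) {
  stopifnot(fraction_positive >= 0, fraction_positive <= 1, x >= 0)
  d_sat * fraction_positive * (1 - exp(-x / sat$x0))
}

#' Capture-model parameters
#'
#' @param purity optional named per-spot matched-capture purity (fraction of
#'   captured cells positive for the spot's target). When `NULL` the purity
#'   is `1 - cross_binding`.
#' @param cross_binding nonspecific residual captured on every antibody
#'   spot, expressed as a fraction of the saturated reference density (an
#'   absolute density floor of about cross_binding * d_sat cells/mm^2).
#'   The default 0.0008 (~5 cells/mm^2) reproduces the healthy anti-CD14
#'   captured composition (99.4% monocytes, 0.6% small lymphocytes) and
#'   keeps the nonspecific share of every spot inside the reported
#'   0-2 +/- 2% band.
#' @param background_density off-spot binding, cells/mm^2 (reported below
#'   20 cells/mm^2).
#' @param monocyte_nonspecific_level on-spot monocyte binding added when the
#'   incubation temperature is at or above the 18 degree phagocytosis
#'   threshold, cells/mm^2.
#' @param temperature incubation temperature, degrees C (default 4).
#' @param packing_efficiency attainable fraction of the geometric packing
#'   limit.
#' @param d_sat saturated reference (anti-CD45) density, cells/mm^2.
#' @return A `capture_params` list.
#' @export
capture_params <- function(purity = NULL, cross_binding = 8e-4,
                           background_density = 12,
                           monocyte_nonspecific_level = 100,
                           temperature = 4, packing_efficiency = 0.9,
                           d_sat = 6400) {
  stopifnot(cross_binding >= 0, cross_binding < 1, background_density >= 0,
            packing_efficiency > 0, packing_efficiency <= 1, d_sat > 0)
  if (!is.null(purity) && any(purity <= 0 | purity > 1)) {
    stop("purities must lie in (0, 1]")
  }
  structure(list(purity = purity, cross_binding = cross_binding,
                 background_density = background_density,
                 monocyte_nonspecific_level = monocyte_nonspecific_level,
                 temperature = temperature,
                 packing_efficiency = packing_efficiency, d_sat = d_sat),
            class = "capture_params")
}

#' Capture parameters of the fluorescent specificity experiment
#'
#' Matched-capture purities set to the stained-positive diagonal of the
#' published specificity matrix (93-98%).
#'
#' @inheritParams capture_params
#' @return A `capture_params` list with per-spot purities.
#' @export
table1_capture_params <- function(...) {
  capture_params(purity = c(CD3 = 0.97, CD4 = 0.97, CD8 = 0.98, CD19 = 0.93),
                 ...)
}

# internal: per-cell capture weight for one CD (marker x class strength)
.capture_weights <- function(truth, cd) {
  if (!cd %in% colnames(truth$markers)) return(numeric(nrow(truth$cells)))
  w <- as.numeric(truth$markers[, cd])
  for (nm in names(truth$classes)) {
    s <- truth$classes[[nm]]$strength
    if (length(s) && cd %in% names(s)) {
      w[truth$cells$class == nm] <- w[truth$cells$class == nm] * s[[cd]]
    }
  }
  w
}

# internal: sample n cell indices with weights, without replacement while
# possible
.sample_cells <- function(weights, n) {
  pos <- which(weights > 0)
  if (!length(pos) || n == 0L) return(integer(0))
  if (length(pos) >= n) {
    sample(pos, n, prob = weights[pos])
  } else {
    sample(pos, n, replace = TRUE, prob = weights[pos])
  }
}

#' Simulate cell capture on an antibody panel
#'
#' Per-spot counts are Poisson at the expected density times the spot area,
#' capped at the attainable packing capacity. Captured rosters mix matched
#' cells (drawn with marker-times-strength weights) with a nonspecific
#' residual drawn from agranular, non-lobed lymphocytes - the captured-cell
#' data show structural zeros for granular/lobed cells on non-matching
#' spots - plus on-spot monocyte binding when the temperature reaches the
#' 18 degree phagocytosis threshold.
#'
#' @param truth a `donor_truth`.
#' @param panel a panel map, see [default_panel()].
#' @param params [capture_params()].
#' @param sat [saturation_params()].
#' @param seed integer seed.
#' @return A `capture_result`: `spots` (spot_id, cd, area, n, density),
#'   `rosters` (list of captured-cell data frames with an `origin` column),
#'   `off_spot_density`, and the parameters used.
#' @export
simulate_capture <- function(truth, panel = default_panel(),
                             params = capture_params(),
                             sat = saturation_params(), seed = 1L) {
  if (!nrow(truth$cells)) stop("empty donor roster")
  if (!any(panel$role == "positive")) {
    stop("panel lacks an anti-CD45 positive-control spot; ",
         "normalization is undefined downstream")
  }
  set.seed(child_seed(seed, 4L, salt = 19L))
  satfrac <- 1 - exp(-truth$x / sat$x0)
  cap_density <- params$packing_efficiency * packing_limit(11)
  is_mono <- truth$cells$class == "mono" |
    truth$cells$morphotype == "monocyte"
  cross_pool <- which(truth$cells$morphotype %in% c("small", "large") &
                        !is_mono)
  spots <- panel
  spots$area_mm2 <- pi * (spots$diameter_mm / 2)^2
  spots$n <- 0L
  spots$density <- 0
  rosters <- vector("list", nrow(spots))
  names(rosters) <- spots$spot_id
  for (i in seq_len(nrow(spots))) {
    cd <- spots$cd[i]
    area <- spots$area_mm2[i]
    if (spots$role[i] == "negative") {
      n <- stats::rpois(1L, params$background_density * area)
      idx <- if (n > 0) .sample_cells(rep(1, nrow(truth$cells)), n) else integer(0)
      origin <- rep("background", length(idx))
    } else {
      w <- .capture_weights(truth, cd)
      f_eff <- mean(w)
      matched_d <- params$d_sat * satfrac * f_eff
      cross_d <- params$d_sat * satfrac * params$cross_binding
      mono_d <- if (params$temperature >= 18) {
        params$monocyte_nonspecific_level
      } else 0
      pur <- if (!is.null(params$purity) && cd %in% names(params$purity)) {
        params$purity[[cd]]
      } else NULL
      if (!is.null(pur) && matched_d > 0) {
        total_d <- matched_d / pur
        shares <- c(matched = pur, cross = 1 - pur, mono = 0)
      } else {
        total_d <- matched_d + cross_d + mono_d
        shares <- c(matched = matched_d, cross = cross_d, mono = mono_d)
        shares <- if (total_d > 0) shares / total_d else c(0, 0, 0)
      }
      n <- stats::rpois(1L, total_d * area)
      n <- min(n, floor(cap_density * area))
      parts <- if (n > 0) {
        stats::rmultinom(1L, n, shares)[, 1]
      } else c(matched = 0L, cross = 0L, mono = 0L)
      idx_m <- .sample_cells(w, parts[["matched"]])
      cross_w <- rep(0, nrow(truth$cells))
      cross_w[cross_pool] <- 1
      if (cd %in% colnames(truth$markers)) cross_w[truth$markers[, cd]] <- 0
      idx_c <- .sample_cells(cross_w, parts[["cross"]])
      mono_w <- as.numeric(is_mono)
      idx_n <- .sample_cells(mono_w, parts[["mono"]])
      idx <- c(idx_m, idx_c, idx_n)
      origin <- rep(c("matched", "cross", "mono_nonspecific"),
                    c(length(idx_m), length(idx_c), length(idx_n)))
      n <- length(idx)
    }
    spots$n[i] <- n
    spots$density[i] <- n / area
    ros <- truth$cells[idx, , drop = FALSE]
    ros$origin <- origin
    ros$spot_id <- spots$spot_id[i]
    ros$cd <- cd
    rownames(ros) <- NULL
    rosters[[i]] <- ros
  }
  off_area <- 50
  off_n <- stats::rpois(1L, params$background_density * off_area)
  structure(list(spots = spots, rosters = rosters,
                 off_spot_density = off_n / off_area,
                 params = params, sat = sat, x = truth$x, seed = seed),
            class = "capture_result")
}

#' Fraction of captured cells positive for the spot's own target
#'
#' @param capture a `capture_result`.
#' @param truth the `donor_truth` it was generated from.
#' @param cds CDs to evaluate (default: all non-control spots).
#' @return Named numeric, percent of captured cells carrying the matching
#'   marker.
#' @export
matched_positive_fraction <- function(capture, truth, cds = NULL) {
  sp <- capture$spots[capture$spots$role == "capture", ]
  if (!is.null(cds)) sp <- sp[sp$cd %in% cds, ]
  out <- vapply(seq_len(nrow(sp)), function(i) {
    ros <- capture$rosters[[as.character(sp$spot_id[i])]]
    if (!nrow(ros)) return(NA_real_)
    100 * mean(truth$markers[ros$cell_id, sp$cd[i]])
  }, 0)
  stats::setNames(out, sp$cd)
}
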