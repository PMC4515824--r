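#' Sub-pixel contour of a binary mask
#'
#' Gaussian-smooths the mask (sigma = 1 px) and traces the 0.5 iso-contour,
#' yielding a sub-pixel polygon whose length estimates the true perimeter
#' to within 2% for shapes of radius >= 10 px. Raw pixel-edge counting
#' overestimates smooth perimeters by ~8-12% and would distort the nuclear
#' contour index.
#'
#' @param mask logical or 0/1 matrix (a single object).
#' @param sigma smoothing sigma in pixels.
#' @return List with `x`, `y` (polygon vertices, px), `perimeter_px`,
#'   `area_px` (shoelace).
#' @export
subpixel_contour <- function(mask, sigma = 1) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  pad <- 3L
  mp <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(mp), sigma = sigma))
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = sm, levels = 0.5)
  if (!length(cl)) stop("no contour found (object too small or empty)")
  lens <- vapply(cl, function(cc) length(cc$x), 0L)
  cc <- cl[[which.max(lens)]]
  x <- cc$x - pad; y <- cc$y - pad
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  per <- sum(sqrt(dx^2 + dy^2))
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(x = x, y = y, perimeter_px = per, area_px = area)
}

#' Detect nuclear clefts on a closed contour
#'
#' Resamples the radial function r(theta) about the centroid on a uniform
#' angular grid, smooths it circularly, and reports local minima as clefts.
#' Cleft depth is (local baseline - minimum) / nominal radius, with the
#' baseline taken as the mean of the two flanking local maxima and the
#' nominal radius sqrt(A/pi). Distinct minima closer than 15 degrees are
#' merged (the deeper one is kept); dips shallower than `min_depth` are
#' treated as contour noise.
#'
#' @param contour list with `x`, `y` polygon vertices (any unit).
#' @param n_theta angular grid size.
#' @param min_depth noise floor for reported depths.
#' @return Numeric vector of relative cleft depths, deepest first.
#' @export
detect_clefts <- function(contour, n_theta = 720L, min_depth = 0.12) {
  x <- contour$x; y <- contour$y
  cx <- mean(x); cy <- mean(y)
  # polygon-area centroid is more stable than the vertex mean
  xs <- c(x, x[1]); ys <- c(y, y[1])
  cr <- xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]
  A2 <- sum(cr)
  if (abs(A2) > 1e-9) {
    cx <- sum((xs[-length(xs)] + xs[-1]) * cr) / (3 * A2)
    cy <- sum((ys[-length(ys)] + ys[-1]) * cr) / (3 * A2)
  }
  th <- atan2(y - cy, x - cx)
  rr <- sqrt((x - cx)^2 + (y - cy)^2)
  ord <- order(th)
  th <- th[ord]; rr <- rr[ord]
  grid <- seq(-pi, pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rg <- stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(rr, 3L),
                      xout = grid, rule = 2, ties = mean)$y
  # circular Gaussian smoothing at two scales: a heavy pass to localize
  # one minimum per notch (wide kidney indentations are flat-bottomed and
  # would otherwise fragment), a light pass to read depths
  csmooth <- function(v, sd_deg) {
    sd <- sd_deg / 360 * n_theta
    half <- ceiling(3 * sd)
    k <- stats::dnorm(-half:half, 0, sd); k <- k / sum(k)
    vv <- c(v[(n_theta - half + 1L):n_theta], v, v[1:half])
    as.numeric(stats::filter(vv, k, sides = 2))[(half + 1L):(half + n_theta)]
  }
  heavy <- csmooth(rg, 5)
  light <- csmooth(rg, 1.5)
  r_nom <- sqrt(abs(A2) / 2 / pi)
  d1 <- diff(c(heavy, heavy[1]))
  sign_prev <- c(d1[n_theta], d1[-n_theta])
  mins <- which(sign_prev < 0 & d1 >= 0)
  if (!length(mins)) return(numeric(0))
  # prominence-style baseline: highest radius within a quarter turn on
  # each side; depth read from the light-smoothed signal near the minimum
  w90 <- round(n_theta / 4); w7 <- round(n_theta * 7 / 360)
  win <- function(i, a, b) light[((i + a):(i + b) - 1L) %% n_theta + 1L]
  depths <- vapply(mins, function(i) {
    rmin <- min(win(i, -w7, w7))
    (min(max(win(i, -w90, 0)), max(win(i, 0, w90))) - rmin) / r_nom
  }, 0)
  keep <- depths >= min_depth
  mins <- mins[keep]; depths <- depths[keep]
  if (!length(mins)) return(numeric(0))
  # merge minima closer than 15 degrees, keeping the deeper one
  min_sep <- n_theta * 15 / 360
  ord <- order(depths, decreasing = TRUE)
  chosen <- integer(0); kept <- numeric(0)
  for (j in ord) {
    ang_dist <- abs(mins[j] - chosen)
    ang_dist <- pmin(ang_dist, n_theta - ang_dist)
    if (!length(chosen) || all(ang_dist >= min_sep)) {
      chosen <- c(chosen, mins[j]); kept <- c(kept, depths[j])
    }
  }
  sort(kept, decreasing = TRUE)
}

#' Measure one cell
#'
#' Areas are pixel sums times the squared pixel scale; the nuclear
#' perimeter comes from the sub-pixel smoothed contour of the largest
#' nucleus; the nuclear contour index NCI = P/sqrt(A) is computed last
#' from the single-nucleus contour measurements. The NC ratio follows the
#' smear-morphology convention nuclear : cytoplasmic (= cell - nuclear)
#' area.
#'
#' @param cell_mask logical/0-1 matrix for the cell.
#' @param nucleus_mask matrix for its nuclei (may contain several
#'   components).
#' @param pixel_scale um per pixel.
#' @param cyt_image optional cytoplasm-channel crop for granule counting.
#' @param granule_threshold intensity above which a pixel is granule.
#' @return A one-row data frame (`morphometry_record`): cell and nuclear
#'   areas (um^2), equivalent diameter (um), nuclear perimeter (um), NC
#'   ratio, granule count, nuclei count, cleft depths (list column), NCI.
#' @export
measure <- function(cell_mask, nucleus_mask, pixel_scale,
                    cyt_image = NULL, granule_threshold = 0.75) {
  cell_px <- sum(cell_mask > 0)
  nuc_px_total <- sum(nucleus_mask > 0)
  if (!cell_px || !nuc_px_total) stop("empty cell or nucleus mask")
  if (any(nucleus_mask > 0 & !(cell_mask > 0))) {
    ol <- sum(nucleus_mask > 0 & !(cell_mask > 0))
    if (ol > 0.05 * nuc_px_total) {
      stop("nucleus mask extends beyond the cell mask")
    }
  }
  nlab <- EBImage::imageData(EBImage::bwlabel(
    EBImage::Image((nucleus_mask > 0) * 1)))
  n_nuclei <- max(nlab)
  # largest nucleus carries the contour measurements
  areas <- tabulate(nlab[nlab > 0])
  main <- which.max(areas)
  cont <- subpixel_contour(nlab == main)
  clefts <- detect_clefts(cont)
  cell_area <- cell_px * pixel_scale^2
  nuc_area_main <- cont$area_px * pixel_scale^2
  nuc_area_total <- nuc_px_total * pixel_scale^2
  nuc_per <- cont$perimeter_px * pixel_scale
  granules <- 0L
  if (!is.null(cyt_image)) {
    gmask <- (cyt_image > granule_threshold) & (cell_mask > 0)
    if (any(gmask)) {
      glab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(gmask * 1)))
      gareas <- tabulate(glab[glab > 0])
      min_gr_px <- max(3, 0.3 * pi * (0.3 / pixel_scale)^2)
      granules <- sum(gareas >= min_gr_px)
    }
  }
  nc <- nuc_area_total / max(cell_area - nuc_area_total, 1e-9)
  rec <- data.frame(
    cell_area_um2 = cell_area,
    equiv_diameter_um = 2 * sqrt(cell_area / pi),
    nuclear_area_um2 = nuc_area_total,
    nuclear_area_main_um2 = areas[main] * pixel_scale^2,
    nuclear_perimeter_um = nuc_per,
    nc_ratio = nc,
    granules = granules,
    nuclei = n_nuclei,
    nci = nuc_per / sqrt(nuc_area_main),
    stringsAsFactors = FALSE)
  rec$cleft_depths <- list(clefts)
  class(rec) <- c("morphometry_record", "data.frame")
  rec
}

#' Rule-based morphotype classification
#'
#' Decision order: (1) two nuclei - binuclear lymphocyte; (2) at least two
#' clefts deeper than half the nominal nuclear radius - lobed (granular
#' variant if granules present); (3) >= `granule_min` granules - granular
#' lymphocyte; (4) monocyte: diameter above 15 um, NC below 2:1 and a
#' kidney nucleus (exactly one indentation, shallower than the lobed
#' threshold); (5) reactive: 15-20 um with NC 2:1-1:1; (6) size rule -
#' small (<= 12 um) vs large (13-15 um), with the 12-13 um gap assigned by
#' NC ratio (> 3:1 small, else large). Anything else is `other`.
#'
#' @param record a `morphometry_record` row (or list with the same
#'   fields).
#' @param granule_min granules required to call a cell granular.
#' @return A `morphotype_call`: `label` and `trace` (thresholds fired).
#' @export
classify <- function(record, granule_min = 3L) {
  d <- record$equiv_diameter_um
  nc <- record$nc_ratio
  clefts <- if (is.list(record$cleft_depths)) {
    record$cleft_depths[[1]]
  } else record$cleft_depths
  gran <- record$granules
  trace <- character(0)
  lab <- NULL
  if (record$nuclei >= 2L) {
    lab <- "binuclear"; trace <- "nuclei >= 2"
  } else if (sum(clefts >= 0.5) >= 2L) {
    trace <- sprintf("%d clefts >= 0.5 R", sum(clefts >= 0.5))
    if (gran >= granule_min) {
      lab <- "granular_lobed"
      trace <- c(trace, sprintf("%d granules", gran))
    } else lab <- "lobed"
  } else if (gran >= granule_min) {
    lab <- "granular"; trace <- sprintf("%d granules", gran)
  } else if (d > 15 && nc < 2 && sum(clefts >= 0.18) == 1L &&
             max(c(clefts, 0)) < 0.5) {
    lab <- "monocyte"
    trace <- c("d > 15", "NC < 2:1", "single shallow indentation")
  } else if (d >= 15 && d <= 20 && nc >= 1 && nc <= 2) {
    lab <- "reactive"; trace <- c("15 <= d <= 20", "1:1 <= NC <= 2:1")
  } else if (d <= 12) {
    lab <- "small"; trace <- "d <= 12"
  } else if (d < 13) {
    if (nc > 3) {
      lab <- "small"; trace <- c("12 < d < 13", "NC > 3:1")
    } else {
      lab <- "large"; trace <- c("12 < d < 13", "NC <= 3:1")
    }
  } else if (d <= 15) {
    lab <- "large"; trace <- "13 <= d <= 15"
  } else {
    lab <- "other"; trace <- "no rule matched"
  }
  structure(list(label = lab, trace = trace), class = "morphotype_call")
}

#' Measure and classify every segmented cell of a spot image
#'
#' @param img a `spot_image`.
#' @param seg its `segmentation_result`.
#' @param granule_min granules required for a granular call.
#' @param border_margin_px cells whose centroid lies within this margin of
#'   the image border are skipped (truncated geometry).
#' @return Data frame: one row per measured cell with the morphometry
#'   record fields, `label`, and centroid coordinates in um.
#' @export
morphometry_table <- function(img, seg, granule_min = 3L,
                              border_margin_px = 5L) {
  cells <- seg$cells
  out <- vector("list", nrow(cells))
  nx <- nrow(seg$cell_labels); ny <- ncol(seg$cell_labels)
  # one pass over the label matrix: pixel lists per cell id
  nz <- which(seg$cell_labels > 0L)
  px_by_cell <- split(nz, seg$cell_labels[nz])
  for (i in seq_len(nrow(cells))) {
    id <- cells$id[i]
    sel <- px_by_cell[[as.character(id)]]
    xi <- ((sel - 1L) %% nx) + 1L
    yi <- ((sel - 1L) %/% nx) + 1L
    x0 <- max(1L, min(xi) - 4L); x1 <- min(nx, max(xi) + 4L)
    y0 <- max(1L, min(yi) - 4L); y1 <- min(ny, max(yi) + 4L)
    cmask <- seg$cell_labels[x0:x1, y0:y1] == id
    # only nuclei assigned to this cell (majority overlap), so fragments
    # of a touching neighbour's nucleus are not miscounted as extra nuclei
    own <- seg$nuclei$id[seg$nuclei$cell == id]
    ncrop <- seg$nucleus_labels[x0:x1, y0:y1]
    nmask <- matrix(ncrop %in% own, nrow(ncrop), ncol(ncrop)) & cmask
    if (!any(nmask)) next
    rec <- tryCatch(
      measure(cmask, nmask, seg$pixel_scale,
              cyt_image = img$cyt[x0:x1, y0:y1]),
      error = function(e) NULL)
    if (is.null(rec)) next
    call <- classify(rec, granule_min)
    rec$label <- call$label
    rec$x_um <- cells$x_px[i] * seg$pixel_scale
    rec$y_um <- cells$y_px[i] * seg$pixel_scale
    rec$cell <- id
    out[[i]] <- rec
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  out
}

#' Match measured cells to rendered ground truth by nearest centroid
#'
#' @param measured output of [morphometry_table()].
#' @param ground_truth `ground_truth` of the rendered image.
#' @param max_dist_um maximal centroid distance for a match.
#' @return `measured` with ground-truth columns appended (prefix `true_`);
#'   unmatched rows dropped.
#' @export
match_ground_truth <- function(measured, ground_truth, max_dist_um = 4) {
  if (is.null(measured) || !nrow(measured) || !nrow(ground_truth)) {
    return(NULL)
  }
  gm <- as.matrix(ground_truth[, c("x_um", "y_um")])
  idx <- vapply(seq_len(nrow(measured)), function(i) {
    d2 <- (gm[, 1] - measured$x_um[i])^2 + (gm[, 2] - measured$y_um[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist_um^2) j else NA_integer_
  }, 0L)
  ok <- !is.na(idx)
  gt <- ground_truth[idx[ok], , drop = FALSE]
  names(gt) <- paste0("true_", names(gt))
  cbind(measured[ok, , drop = FALSE], gt)
}
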