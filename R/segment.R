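#' Segmentation parameters
#'
#' @param cyt_threshold,nuc_threshold intensity thresholds for the cell and
#'   nucleus channels (the renderer puts cytoplasm at 0.45 and nuclei at
#'   0.8 over a 0.05 background).
#' @param min_cell_area_um2 minimum object area; 30% of the smallest
#'   expected cell (8 um diameter) is ~15 um^2.
#' @param watershed_tolerance depth (in distance-map pixels) a local
#'   maximum must have to seed its own cell; splits touching cells without
#'   fragmenting lobed or kidney nuclei owners.
#' @return A `segment_params` list.
#' @export
segment_params <- function(cyt_threshold = 0.25, nuc_threshold = 0.55,
                           min_cell_area_um2 = 15,
                           watershed_tolerance = 3) {
  structure(list(cyt_threshold = cyt_threshold,
                 nuc_threshold = nuc_threshold,
                 min_cell_area_um2 = min_cell_area_um2,
                 watershed_tolerance = watershed_tolerance),
            class = "segment_params")
}

# internal: centroids and areas per label of a label matrix
.label_stats <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0)))
  }
  l <- lab[idx]
  nx <- nrow(lab)
  xi <- ((idx - 1L) %% nx) + 1L
  yi <- ((idx - 1L) %/% nx) + 1L
  ids <- sort(unique(l))
  area <- tabulate(l)[ids]
  sx <- rowsum(as.numeric(xi), l)[, 1]
  sy <- rowsum(as.numeric(yi), l)[, 1]
  data.frame(id = ids, x_px = sx / area, y_px = sy / area, area_px = area)
}

#' Detect and label cells on a rendered spot image
#'
#' Threshold on the combined channels, distance-transform watershed to
#' split touching cells, small-object removal, then nucleus labelling
#' within each cell. Blank or low-contrast images yield zero detections
#' rather than an error.
#'
#' @param img a `spot_image` (or a list with `cyt`, `nuc`, `pixel_scale`).
#' @param params [segment_params()].
#' @return A `segmentation_result`: `cell_labels` and `nucleus_labels`
#'   matrices, `cells` (id, x_px, y_px, area_px, n_nuclei), `nuclei`
#'   (id, cell, x_px, y_px, area_px), `pixel_scale`.
#' @export
segment_cells <- function(img, params = segment_params()) {
  ps <- img$pixel_scale
  mask <- img$cyt > params$cyt_threshold | img$nuc > params$nuc_threshold
  min_px <- params$min_cell_area_um2 / ps^2
  out_empty <- function() {
    structure(list(cell_labels = matrix(0L, nrow(img$cyt), ncol(img$cyt)),
                   nucleus_labels = matrix(0L, nrow(img$cyt), ncol(img$cyt)),
                   cells = data.frame(id = integer(0), x_px = numeric(0),
                                      y_px = numeric(0), area_px = integer(0),
                                      n_nuclei = integer(0)),
                   nuclei = data.frame(id = integer(0), cell = integer(0),
                                       x_px = numeric(0), y_px = numeric(0),
                                       area_px = integer(0)),
                   pixel_scale = ps),
              class = "segmentation_result")
  }
  if (!any(mask)) return(out_empty())
  m <- EBImage::Image(mask * 1)
  m <- EBImage::opening(m, EBImage::makeBrush(5L, shape = "disc"))
  if (!any(m > 0)) return(out_empty())
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = 1L)
  lab <- EBImage::imageData(lab)
  stats_all <- .label_stats(lab)
  keep <- stats_all$id[stats_all$area_px >= min_px]
  if (!length(keep)) return(out_empty())
  relab <- integer(max(stats_all$id) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  lab <- matrix(relab[lab + 1L], nrow(lab), ncol(lab))
  cells <- .label_stats(lab)
  # nuclei: threshold the nucleus channel, label, assign to owning cell
  nmask <- img$nuc > params$nuc_threshold
  nlab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(nmask * 1)))
  nstats <- .label_stats(nlab)
  min_nuc_px <- 0.25 * min_px
  nstats <- nstats[nstats$area_px >= min_nuc_px, , drop = FALSE]
  if (nrow(nstats)) {
    nnz <- which(nlab > 0L)
    px_by_nuc <- split(nnz, nlab[nnz])
    owner <- vapply(as.character(nstats$id), function(id) {
      o <- lab[px_by_nuc[[id]]]
      o <- o[o > 0]
      if (length(o)) as.integer(names(which.max(table(o)))) else 0L
    }, 0L, USE.NAMES = FALSE)
    nstats$cell <- owner
    nstats <- nstats[nstats$cell > 0, , drop = FALSE]
  } else {
    nstats$cell <- integer(0)
  }
  nn <- tabulate(nstats$cell, nbins = nrow(cells))
  cells$n_nuclei <- nn
  structure(list(cell_labels = lab, nucleus_labels = nlab, cells = cells,
                 nuclei = nstats[, c("id", "cell", "x_px", "y_px", "area_px")],
                 pixel_scale = ps),
            class = "segmentation_result")
}

#' Replicate-field density estimate
#'
#' Mirrors the laboratory practice of counting all cells in three x200
#' fields: density is the mean of count/area over fields, and the
#' relative standard deviation across fields is reported when at least two
#' fields are available (the bench protocol keeps it under 5%).
#'
#' @param counts integer vector of per-field cell counts (e.g.
#'   `nrow(seg$cells)` per field).
#' @param field_area_mm2 area of one field, mm^2 (x200 default 0.25).
#' @return A `density_estimate`: `density` (cells/mm^2), `n_fields`,
#'   `relative_sd_pct` (NA with one field).
#' @export
estimate_density <- function(counts, field_area_mm2 = 0.25) {
  if (!length(counts)) stop("at least one field is required")
  if (field_area_mm2 <= 0) stop("field area must be positive")
  dens <- counts / field_area_mm2
  rel_sd <- if (length(counts) >= 2L) {
    100 * stats::sd(dens) / mean(dens)
  } else NA_real_
  structure(list(density = mean(dens), n_fields = length(counts),
                 relative_sd_pct = rel_sd),
            class = "density_estimate")
}

#' Edge-to-edge radial density profile of a spot
#'
#' Bins detections by normalized radial position and reports the
#' uniformity ratio (mean density of the outer 20% of bins over the inner
#' 20%); a ratio above the donut threshold flags the drying artifact of
#' non-uniform antibody immobilization.
#'
#' @param seg a `segmentation_result` from a disc-region image.
#' @param center_px spot centre (x, y) in pixels.
#' @param radius_px spot radius in pixels.
#' @param n_bins number of radial bins.
#' @param donut_ratio flag threshold for the uniformity ratio.
#' @return A `radial_profile`: `profile` (bin mid radius, density),
#'   `uniformity_ratio`, `donut`, `reliable`.
#' @export
radial_profile <- function(seg, center_px, radius_px, n_bins = 10L,
                           donut_ratio = 1.5) {
  rho <- sqrt((seg$cells$x_px - center_px[1])^2 +
                (seg$cells$y_px - center_px[2])^2) / radius_px
  inside <- rho <= 1
  if (!any(inside)) stop("no detections inside the spot boundary")
  rho <- rho[inside]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(rho, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  # annulus areas in spot-radius units
  ann <- pi * (breaks[-1]^2 - breaks[-(n_bins + 1L)]^2)
  dens <- counts / ann
  k <- max(1L, round(0.2 * n_bins))
  ratio <- mean(dens[(n_bins - k + 1L):n_bins]) / mean(dens[seq_len(k)])
  structure(list(profile = data.frame(
    r_mid = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2, density = dens),
    uniformity_ratio = ratio, donut = is.finite(ratio) && ratio > donut_ratio,
    reliable = sum(counts) >= 50L, n_detections = sum(counts)),
    class = "radial_profile")
}
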