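#' Rendering parameters for synthetic spot images
#'
#' Two-channel output (cytoplasm, nucleus) rather than a stain simulation:
#' the downstream measurements need masks, not color fidelity. The default
#' pixel scale of 0.1 um/px matches x1000 oil-immersion sampling and keeps
#' the smallest nuclear radius above the 10 px floor that the sub-pixel
#' perimeter estimator needs.
#'
#' @param pixel_scale um per pixel.
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @param background background intensity.
#' @param cyt_intensity,nuc_intensity,granule_intensity channel intensities.
#' @param granule_radius_um rendered granule radius; granules are small
#'   high-contrast discs in the cytoplasm.
#' @param mode `"uniform"` or `"donut"` (edge-heavy radial density bias,
#'   emulating the drying artifact of room-temperature antibody
#'   immobilization).
#' @param donut_strength weight of the radial bias (placement density
#'   proportional to 1 + s*rho^5).
#' @return A `render_params` list.
#' @export
render_params <- function(pixel_scale = 0.1, noise_sd = 0.02,
                          background = 0.05, cyt_intensity = 0.45,
                          nuc_intensity = 0.8, granule_intensity = 1,
                          granule_radius_um = 0.3,
                          mode = c("uniform", "donut"),
                          donut_strength = 9) {
  mode <- match.arg(mode)
  stopifnot(pixel_scale > 0, noise_sd >= 0)
  structure(list(pixel_scale = pixel_scale, noise_sd = noise_sd,
                 background = background, cyt_intensity = cyt_intensity,
                 nuc_intensity = nuc_intensity,
                 granule_intensity = granule_intensity,
                 granule_radius_um = granule_radius_um, mode = mode,
                 donut_strength = donut_strength),
            class = "render_params")
}

#' Build a minimal roster for rendering tests
#'
#' @param n number of cells.
#' @param morphotype morphotype id(s), recycled.
#' @return Data frame with `cell_id`, `class`, `morphotype`, `diameter_um`.
#' @export
simple_roster <- function(n, morphotype = "small") {
  m <- rep_len(morphotype, n)
  data.frame(cell_id = seq_len(n), class = rep(NA_character_, n),
             morphotype = m, diameter_um = sample_diameters(m),
             stringsAsFactors = FALSE)
}

# internal: greedy non-overlapping placement with grid hashing.
# Returns data frame x_um/y_um (NA rows dropped) in region coordinates.
.place_cells <- function(radii, region, mode, donut_strength,
                         max_tries = 200L) {
  n <- length(radii)
  if (!n) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  hmax <- 2 * max(radii)
  if (region$type == "rect") {
    w <- region$w; h <- region$h
  } else {
    w <- h <- region$diameter_um
    R <- region$diameter_um / 2
  }
  nxb <- max(1L, ceiling(w / hmax)); nyb <- max(1L, ceiling(h / hmax))
  buckets <- vector("list", nxb * nyb)
  xs <- ys <- rep(NA_real_, n)
  bucket_of <- function(x, y) {
    bx <- min(nxb, max(1L, ceiling(x / hmax)))
    by <- min(nyb, max(1L, ceiling(y / hmax)))
    (by - 1L) * nxb + bx
  }
  # place large cells first so they are not squeezed out
  ord <- order(radii, decreasing = TRUE)
  for (i in ord) {
    r <- radii[i]
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      if (region$type == "rect") {
        x <- stats::runif(1, r, w - r); y <- stats::runif(1, r, h - r)
      } else {
        repeat {
          x <- stats::runif(1, -R, R); y <- stats::runif(1, -R, R)
          rho2 <- x^2 + y^2
          # cells may overhang the spot edge slightly; only the centre
          # must sit on the antibody-coated area
          if (rho2 > (R - 0.3 * r)^2) next
          if (mode == "donut") {
            rho <- sqrt(rho2) / R
            wgt <- (1 + donut_strength * rho^5) / (1 + donut_strength)
            if (stats::runif(1) > wgt) next
          }
          x <- x + R; y <- y + R
          break
        }
      }
      bx <- min(nxb, max(1L, ceiling(x / hmax)))
      by <- min(nyb, max(1L, ceiling(y / hmax)))
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        jx <- bx + dx; jy <- by + dy
        if (jx < 1L || jx > nxb || jy < 1L || jy > nyb) next
        for (j in buckets[[(jy - 1L) * nxb + jx]]) {
          if ((xs[j] - x)^2 + (ys[j] - y)^2 <
              (0.95 * (radii[j] + r))^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        xs[i] <- x; ys[i] <- y
        b <- bucket_of(x, y)
        buckets[[b]] <- c(buckets[[b]], i)
        placed <- TRUE
        break
      }
    }
  }
  data.frame(x_um = xs, y_um = ys)
}

# internal: draw per-cell nucleus specification from morphotype geometry
.draw_nucleus_spec <- function(morphotype, geom = morphotype_geometry()) {
  g <- geom[[morphotype]] %||% geom[["other"]]
  nc <- stats::runif(1, g$nc[1], g$nc[2])
  nuc <- g$nucleus
  spec <- list(nc = nc, nuclei = g$nuclei,
               eccentric = isTRUE(nuc$eccentric), type = nuc$type)
  if (nuc$type == "ellipse") {
    # two nuclei stay circular so both fit inside the cell with a gap
    spec$ratio <- if (g$nuclei == 2L) 1 else
      stats::runif(1, nuc$ratio[1], nuc$ratio[2])
  } else if (nuc$type == "lobed") {
    spec$k <- if (length(nuc$k) > 1L) sample(nuc$k, 1L) else nuc$k
    spec$rel_depth <- stats::runif(1, nuc$depth[1], nuc$depth[2])
  } else {
    spec$depth <- stats::runif(1, nuc$depth[1], nuc$depth[2])
    spec$width <- nuc$width
  }
  if (!is.null(g$granules)) {
    spec$granules <- g$granules$min + stats::rpois(1L, g$granules$lambda)
  } else spec$granules <- 0L
  spec
}

#' Render a spot (or field) image with analytic ground truth
#'
#' Places the roster's cells without overlap (rejection sampling up to the
#' packing capacity), synthesizes each nucleus from its morphotype
#' geometry, and rasterizes two channels plus additive Gaussian noise. The
#' ground-truth table records the analytic geometry actually rendered.
#' Deterministic given `seed`.
#'
#' @param roster data frame with at least `morphotype` and `diameter_um`
#'   (e.g. a captured-spot roster or [simple_roster()]).
#' @param region `list(type = "rect", w = , h = )` in um, or
#'   `list(type = "disc", diameter_um = )`.
#' @param render [render_params()].
#' @param seed integer seed.
#' @return A `spot_image`: channel matrices `cyt` and `nuc` (x by y),
#'   `pixel_scale`, `region`, and `ground_truth`.
#' @export
render_spot <- function(roster, region, render = render_params(), seed = 1L) {
  ps <- render$pixel_scale
  area_mm2 <- if (region$type == "rect") {
    region$w * region$h / 1e6
  } else pi * (region$diameter_um / 2)^2 / 1e6
  if (nrow(roster)) {
    dmin <- min(roster$diameter_um)
    if (nrow(roster) / area_mm2 > packing_limit(dmin)) {
      stop("requested density exceeds the packing capacity for ",
           round(dmin, 1), " um cells")
    }
  }
  set.seed(child_seed(seed, 5L, salt = 23L))
  nx <- as.integer(ceiling((if (region$type == "rect") region$w
                            else region$diameter_um) / ps))
  ny <- as.integer(ceiling((if (region$type == "rect") region$h
                            else region$diameter_um) / ps))
  cyt <- matrix(0, nx, ny)
  nuc <- matrix(0, nx, ny)
  gt <- NULL
  if (nrow(roster)) {
    radii <- roster$diameter_um / 2
    pos <- .place_cells(radii, region, render$mode, render$donut_strength)
    keep <- which(!is.na(pos$x_um))
    geom <- morphotype_geometry()
    rows <- vector("list", length(keep))
    for (jj in seq_along(keep)) {
      i <- keep[jj]
      rc <- radii[i]
      morph <- roster$morphotype[i]
      spec <- .draw_nucleus_spec(morph, geom)
      # nominal nuclear radius from the NC ratio (total over all nuclei)
      an_frac <- spec$nc / (1 + spec$nc)
      rn <- rc * sqrt(an_frac)
      if (rn / spec$nuclei^0.5 < 10 * ps) {
        stop("pixel scale too coarse: nuclear radius below 10 px")
      }
      phi <- stats::runif(1, 0, 2 * pi)
      shape <- switch(spec$type,
        ellipse = synthesize_nucleus("ellipse", r0 = rn /
            sqrt(spec$nuclei), ratio = spec$ratio),
        lobed = {
          s1 <- lobed_nucleus(spec$k, spec$rel_depth, r0 = 1)
          synthesize_nucleus("lobed", r0 = rn / sqrt(s1$area / pi),
                             k = spec$k, depth = s1$depth)
        },
        kidney = {
          s1 <- synthesize_nucleus("kidney", r0 = 1, depth = spec$depth,
                                   width = spec$width)
          synthesize_nucleus("kidney", r0 = rn / sqrt(s1$area / pi),
                             depth = spec$depth, width = spec$width)
        })
      # nucleus centre offsets within the cell
      offs <- if (spec$nuclei == 2L) {
        d_off <- min(shape$r0 + 0.45, rc - shape$r0 - 0.05)
        rbind(c(d_off * cos(phi), d_off * sin(phi)),
              c(-d_off * cos(phi), -d_off * sin(phi)))
      } else if (spec$eccentric) {
        rbind(0.25 * rc * c(cos(phi), sin(phi)))
      } else rbind(c(0, 0))
      cx <- pos$x_um[i]; cy <- pos$y_um[i]
      ruffle <- morph %in% c("hairy", "villous")
      # rasterize into the bounding box
      pad <- rc + 3 * ps
      ix <- max(1L, floor((cx - pad) / ps)):min(nx, ceiling((cx + pad) / ps))
      iy <- max(1L, floor((cy - pad) / ps)):min(ny, ceiling((cy + pad) / ps))
      px <- (ix - 0.5) * ps - cx
      py <- (iy - 0.5) * ps - cy
      dxm <- matrix(px, length(ix), length(iy))
      dym <- matrix(py, length(ix), length(iy), byrow = TRUE)
      rr <- sqrt(dxm^2 + dym^2)
      rcell <- if (ruffle) {
        th <- atan2(dym, dxm)
        rc * (1 + 0.07 * sin(9 * th + phi))
      } else rc
      inside <- rr <= rcell
      cyt[ix, iy][inside] <- pmax(cyt[ix, iy][inside], render$cyt_intensity)
      nmask_any <- matrix(FALSE, length(ix), length(iy))
      for (nn in seq_len(nrow(offs))) {
        ndx <- dxm - offs[nn, 1]; ndy <- dym - offs[nn, 2]
        nth <- atan2(ndy, ndx) - phi
        nrr <- sqrt(ndx^2 + ndy^2)
        nin <- nrr <= shape$r0 * shape$rfun(nth)
        nmask_any <- nmask_any | nin
      }
      nuc[ix, iy][nmask_any] <- pmax(nuc[ix, iy][nmask_any],
                                     render$nuc_intensity)
      # granules: uniform in the cytoplasm outside the nucleus
      ngr <- spec$granules
      placed <- 0L
      if (ngr > 0L) {
        gr <- render$granule_radius_um
        placed <- 0L; tries <- 0L
        gpos <- matrix(numeric(0), 0, 2)
        while (placed < ngr && tries < 120L * ngr) {
          tries <- tries + 1L
          gx <- stats::runif(1, -rc + gr, rc - gr)
          gy <- stats::runif(1, -rc + gr, rc - gr)
          grr <- sqrt(gx^2 + gy^2)
          if (grr > rc - 1.5 * gr) next
          gth <- atan2(gy - offs[1, 2], gx - offs[1, 1]) - phi
          gdist <- sqrt((gx - offs[1, 1])^2 + (gy - offs[1, 2])^2)
          # prefer free cytoplasm; when the ring is too thin (high-NC
          # granular cells) allow granules over the nuclear projection,
          # as in a flattened smear
          if (tries <= 40L * ngr &&
              gdist < shape$r0 * shape$rfun(gth) + 1.2 * gr) next
          # granules stay separated so the count survives segmentation
          if (nrow(gpos) &&
              any((gpos[, 1] - gx)^2 + (gpos[, 2] - gy)^2 <
                    (3 * gr)^2)) next
          gin <- (dxm - gx)^2 + (dym - gy)^2 <= gr^2
          cyt[ix, iy][gin] <- render$granule_intensity
          gpos <- rbind(gpos, c(gx, gy))
          placed <- placed + 1L
        }
      }
      rows[[jj]] <- data.frame(
        cell_id = roster$cell_id[i], x_um = cx, y_um = cy,
        class = if ("class" %in% names(roster)) roster$class[i]
                else NA_character_,
        morphotype = morph, diameter_um = roster$diameter_um[i],
        nc_ratio = spec$nc, nuclei = spec$nuclei,
        nuclear_area_um2 = spec$nuclei * shape$area,
        nuclear_perimeter_um = spec$nuclei * shape$perimeter,
        nci = shape$nci, n_clefts = shape$k,
        rel_depth = shape$rel_depth, granules = placed,
        stringsAsFactors = FALSE)
    }
    gt <- do.call(rbind, rows)
  }
  if (is.null(gt)) {
    gt <- data.frame(cell_id = integer(0), x_um = numeric(0),
                     y_um = numeric(0), class = character(0),
                     morphotype = character(0), diameter_um = numeric(0),
                     nc_ratio = numeric(0), nuclei = integer(0),
                     nuclear_area_um2 = numeric(0),
                     nuclear_perimeter_um = numeric(0), nci = numeric(0),
                     n_clefts = integer(0), rel_depth = numeric(0),
                     granules = integer(0), stringsAsFactors = FALSE)
  }
  if (render$noise_sd > 0 || render$background > 0) {
    cyt <- cyt + render$background +
      matrix(stats::rnorm(nx * ny, 0, render$noise_sd), nx, ny)
    nuc <- nuc + render$background +
      matrix(stats::rnorm(nx * ny, 0, render$noise_sd), nx, ny)
    cyt <- pmin(pmax(cyt, 0), 1)
    nuc <- pmin(pmax(nuc, 0), 1)
  }
  structure(list(cyt = cyt, nuc = nuc, pixel_scale = ps, region = region,
                 area_mm2 = area_mm2, ground_truth = gt, seed = seed),
            class = "spot_image")
}

#' Render a rectangular counting field at a requested density
#'
#' Places `round(density * area)` cells of the given morphotype mix in a
#' rectangular field; used to emulate the x200 counting fields.
#'
#' @param density target density, cells/mm^2.
#' @param width_um,height_um field dimensions.
#' @param morphotype morphotype mix, recycled over cells.
#' @param render [render_params()].
#' @param seed integer seed.
#' @return A `spot_image`.
#' @export
render_density_field <- function(density, width_um = 500, height_um = 500,
                                 morphotype = "small",
                                 render = render_params(pixel_scale = 0.25),
                                 seed = 1L) {
  n <- round(density * width_um * height_um / 1e6)
  set.seed(child_seed(seed, 6L, salt = 29L))
  roster <- simple_roster(n, morphotype)
  render_spot(roster, list(type = "rect", w = width_um, h = height_um),
              render, seed = seed)
}

#' Write a spot image to TIFF (and optional PNG preview)
#'
#' @param img a `spot_image`.
#' @param path output TIFF path (two-channel, 16-bit).
#' @param png_path optional PNG preview path (channels merged).
#' @return `path`, invisibly.
#' @export
write_spot_image <- function(img, path, png_path = NULL) {
  arr <- EBImage::Image(c(img$cyt, img$nuc),
                        dim = c(nrow(img$cyt), ncol(img$cyt), 2))
  EBImage::writeImage(arr, path, type = "tiff", bits.per.sample = 16L)
  if (!is.null(png_path)) {
    EBImage::writeImage(EBImage::rgbImage(red = EBImage::Image(img$cyt),
                                          green = EBImage::Image(img$nuc)),
                        png_path, type = "png")
  }
  invisible(path)
}
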