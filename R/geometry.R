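#' Morphotype identifiers used throughout the package
#'
#' Internal snake_case ids for the peripheral-blood mononuclear cell (PBMC)
#' morphotypes handled by the generator and the classifier. `hairy` and
#' `villous` are generator-only labels for neoplastic cells; the measurement
#' classifier has no rule for them and reports such cells as `other` or
#' `reactive` depending on their realized geometry.
#'
#' @return Character vector of morphotype ids.
#' @export
morphotype_ids <- function() {
  c("small", "large", "lobed", "granular", "granular_lobed",
    "monocyte", "reactive", "binuclear", "plasma", "hairy", "villous", "other")
}

#' Human-readable morphotype labels
#' @return Named character vector mapping ids to smear-morphology names.
#' @export
morphotype_labels <- function() {
  c(small = "small lymphocyte",
    large = "large lymphocyte",
    lobed = "lymphocyte with lobed nucleus",
    granular = "granular lymphocyte",
    granular_lobed = "granular lymphocyte with lobed nucleus",
    monocyte = "monocyte",
    reactive = "reactive lymphocyte",
    binuclear = "binuclear lymphocyte",
    plasma = "plasma cell",
    hairy = "hairy cell",
    villous = "villous lymphocyte",
    other = "other")
}

#' Geometric parameters per morphotype
#'
#' Each entry gives the sampling ranges used both when drawing cells for a
#' donor roster and when rendering them: cell diameter (um), nuclear to
#' cytoplasmic area ratio NC = A_nucleus / (A_cell - A_nucleus), the granule
#' count model, the nucleus contour model and the number of nuclei.
#'
#' Diameter bands follow the smear-morphology convention (small lymphocyte
#' up to 12 um; large 13-15 um; reactive 15-20 um; monocyte above 15 um) with
#' a small safety margin inside each band so that sub-pixel measurement
#' noise cannot carry a cell across a classification threshold. Cleft depths
#' are expressed relative to the nominal nuclear radius sqrt(A/pi). A lobed
#' nucleus has k >= 2 clefts of relative depth >= 0.5; the monocyte kidney
#' indentation is a single wide notch of relative depth about 0.3, below the
#' lobed threshold.
#'
#' The granule count model and the monocyte contour are package choices: the
#' source morphology convention shows but does not parameterize them. A cell
#' is "granular" when it carries at least 3 granules.
#'
#' @return Named list of geometry specifications.
#' @export
morphotype_geometry <- function() {
  lymph_nuc <- list(type = "ellipse", ratio = c(1, 1.45))
  list(
    small = list(diameter = c(8, 11.6), nc = c(3.2, 5), granules = NULL,
                 nucleus = lymph_nuc, nuclei = 1L),
    large = list(diameter = c(13, 14.7), nc = c(2.1, 2.9), granules = NULL,
                 nucleus = lymph_nuc, nuclei = 1L),
    lobed = list(diameter = c(13, 14.7), nc = c(2.1, 2.9), granules = NULL,
                 nucleus = list(type = "lobed", k = 2:3, depth = c(0.58, 0.78)),
                 nuclei = 1L),
    granular = list(diameter = c(10, 14.7), nc = c(2.1, 3.5),
                    granules = list(min = 3L, lambda = 5),
                    nucleus = lymph_nuc, nuclei = 1L),
    granular_lobed = list(diameter = c(13, 14.7), nc = c(2.1, 2.9),
                          granules = list(min = 3L, lambda = 5),
                          nucleus = list(type = "lobed", k = 2:3,
                                         depth = c(0.58, 0.78)),
                          nuclei = 1L),
    monocyte = list(diameter = c(15.4, 20), nc = c(0.8, 1.8), granules = NULL,
                    nucleus = list(type = "kidney", depth = c(0.34, 0.44),
                                   width = 0.7),
                    nuclei = 1L),
    reactive = list(diameter = c(15.4, 19.5), nc = c(1.05, 1.95),
                    granules = NULL,
                    nucleus = list(type = "ellipse", ratio = c(1, 1.12)),
                    nuclei = 1L),
    binuclear = list(diameter = c(13, 14.7), nc = c(0.55, 0.72),
                     granules = NULL,
                     nucleus = list(type = "ellipse", ratio = c(1, 1.2)),
                     nuclei = 2L),
    plasma = list(diameter = c(14, 17), nc = c(1.2, 2.2), granules = NULL,
                  nucleus = list(type = "ellipse", ratio = c(1, 1.3),
                                 eccentric = TRUE),
                  nuclei = 1L),
    hairy = list(diameter = c(15.4, 18), nc = c(1.0, 1.8), granules = NULL,
                 nucleus = list(type = "ellipse", ratio = c(1, 1.5)),
                 nuclei = 1L),
    villous = list(diameter = c(13, 15.5), nc = c(1.5, 2.5), granules = NULL,
                   nucleus = list(type = "ellipse", ratio = c(1, 1.5)),
                   nuclei = 1L),
    other = list(diameter = c(10, 16), nc = c(1.5, 3), granules = NULL,
                 nucleus = lymph_nuc, nuclei = 1L)
  )
}

# internal: draw cell diameters for a vector of morphotype ids
sample_diameters <- function(morphotypes, geom = morphotype_geometry()) {
  lo <- vapply(morphotypes, function(m) geom[[m]]$diameter[1], 0)
  hi <- vapply(morphotypes, function(m) geom[[m]]$diameter[2], 0)
  stats::runif(length(morphotypes), lo, hi)
}
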