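#' Define a cell class for the synthetic cohort generator
#'
#' A cell class couples a lineage (via per-CD marker expression
#' probabilities) to a smear-morphology mixture. Marker expression is
#' Bernoulli per cell; `strength` scales the capture probability of an
#' expressed marker below 1 to model weakly expressed antigens (e.g. CD20
#' and CD22 on CLL cells) whose cells wash off the spot more easily.
#'
#' @param name class id.
#' @param markers named numeric vector of expression probabilities in `[0,1]`.
#' @param morphotypes named numeric vector over [morphotype_ids()] summing to 1.
#' @param size_mean,size_sd fallback cell diameter (um) used only for
#'   morphotypes without a geometry entry.
#' @param strength named numeric vector of capture strengths in `(0,1]`;
#'   markers not listed default to 1.
#' @param trap,anae cytochemistry flags inherited by every cell of the class
#'   (tartrate-resistant acid phosphatase; alpha-naphtyl acetate esterase).
#' @return A `cell_class` object.
#' @export
cell_class <- function(name, markers, morphotypes, size_mean = 10,
                       size_sd = 1, strength = NULL, trap = FALSE,
                       anae = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (any(markers < 0 | markers > 1)) {
    stop("marker expression probabilities must lie in [0, 1]")
  }
  if (size_mean <= 0) stop("size_mean must be positive")
  bad <- setdiff(names(morphotypes), morphotype_ids())
  if (length(bad)) stop("unknown morphotypes: ", paste(bad, collapse = ", "))
  morphotypes <- morphotypes / sum(morphotypes)
  assert_simplex(morphotypes, paste0("morphotype mixture of ", name))
  if (!is.null(strength) && any(strength <= 0 | strength > 1)) {
    stop("capture strengths must lie in (0, 1]")
  }
  structure(list(name = name, markers = markers, morphotypes = morphotypes,
                 size_mean = size_mean, size_sd = size_sd,
                 strength = strength %||% numeric(0),
                 trap = trap, anae = anae),
            class = "cell_class")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Morphotype mixtures are back-calculated from the captured-cell composition
# of healthy donors: each antibody row of the published cross-tab is read as
# six disjoint categories (small; large non-lobed; lobed; granular
# non-lobed; granular lobed; monocyte), clamped at zero and renormalized.
# Rows captured by a single class give that class's mixture directly; the
# anti-CD4 row is first stripped of its 8% monocyte component.
.row_mixture <- function(small, large_total, lobed, gl_total, gl_lobed,
                         monocyte = 0, extra = NULL) {
  v <- c(small = small,
         large = max(large_total - lobed, 0),
         lobed = lobed,
         granular = max(gl_total - gl_lobed, 0),
         granular_lobed = gl_lobed,
         monocyte = monocyte)
  v <- c(v[v > 0], extra)
  v / sum(v)
}

#' Default healthy PBMC cell classes
#'
#' Five classes: CD4 T cells, CD8 T cells, NK cells, B cells and monocytes.
#' Marker maps follow standard lineage immunophenotypes; morphotype mixtures
#' are back-calculated from the captured-cell composition observed for
#' healthy donors (see the methods vignette). NK cells are modelled
#' CD8-negative so that the anti-CD8 captured composition equals the CD8 T
#' mixture; the dim NK CD8 binding is folded into the CD8 T class.
#'
#' @return Named list of [cell_class()] objects.
#' @export
default_cell_classes <- function() {
  list(
    cd4_t = cell_class(
      "cd4_t",
      markers = c(CD45 = 1, CD2 = 1, CD3 = 1, CD4 = 1, CD5 = 1, CD7 = 1,
                  CD43 = 1, CD45RA = 0.5, CD45RO = 0.55, CD38 = 0.35),
      morphotypes = .row_mixture(90, 1.9, 0.3, 0.1, 0.3) ),
    cd8_t = cell_class(
      "cd8_t",
      markers = c(CD45 = 1, CD2 = 1, CD3 = 1, CD8 = 1, CD5 = 1, CD7 = 1,
                  CD43 = 1, CD45RA = 0.6, CD45RO = 0.45, CD38 = 0.35),
      morphotypes = .row_mixture(74, 2, 1.5, 23, 1.4) ),
    nk = cell_class(
      "nk",
      markers = c(CD45 = 1, CD16 = 1, CD56 = 1, CD2 = 0.8, CD7 = 0.9,
                  CD38 = 0.6, CD43 = 0.8, CD45RA = 0.85),
      morphotypes = .row_mixture(33, 2, 3.5, 65, 4.7) ),
    b = cell_class(
      "b",
      markers = c(CD45 = 1, CD19 = 1, CD20 = 1, CD21 = 0.85, CD22 = 0.95,
                  CD23 = 0.3, CD5 = 0.15, `HLA-DR` = 1, CD38 = 0.15,
                  CD45RA = 0.9, IgM = 0.8, IgGk = 0.6, IgGl = 0.35),
      morphotypes = .row_mixture(95.3, 4.7, 0, 0, 0,
                                 extra = c(binuclear = 0.07)) ),
    mono = cell_class(
      "mono",
      markers = c(CD45 = 1, CD14 = 1, CD4 = 0.30, CD16 = 0.094, CD33 = 1,
                  CD64 = 1, CD15 = 0.3, CD43 = 1, `HLA-DR` = 1,
                  CD45RO = 0.8),
      morphotypes = c(monocyte = 1), size_mean = 17, size_sd = 1.2,
      anae = TRUE)
  )
}

#' Default cohort parameters
#'
#' Suspension class-fraction means back-calculated so that capture under the
#' default model reproduces the healthy captured-cell composition in
#' expectation, with the CD3-positive fraction centred at 60% of PBMC.
#' Donor-to-donor variation is truncated normal per class followed by
#' renormalization.
#'
#' @param fraction_mean,fraction_sd optional named overrides.
#' @param x suspension concentration, 1e6 cells/ml.
#' @param n_cells roster size per donor.
#' @return List of cohort parameters.
#' @export
default_cohort_params <- function(fraction_mean = NULL, fraction_sd = NULL,
                                  x = 8, n_cells = 20000L) {
  fm <- c(cd4_t = 0.485, cd8_t = 0.115, nk = 0.051, b = 0.219, mono = 0.130)
  fs <- c(cd4_t = 0.060, cd8_t = 0.022, nk = 0.015, b = 0.045, mono = 0.028)
  if (!is.null(fraction_mean)) fm[names(fraction_mean)] <- fraction_mean
  if (!is.null(fraction_sd)) fs[names(fraction_sd)] <- fraction_sd
  list(classes = default_cell_classes(), fraction_mean = fm,
       fraction_sd = fs, x = x, n_cells = as.integer(n_cells))
}

# internal: realize one roster from class fractions
.build_roster <- function(classes, fractions, n_cells, geom) {
  marker_names <- sort(unique(unlist(lapply(classes, function(cl) names(cl$markers)))))
  cls <- sample(names(fractions), n_cells, replace = TRUE, prob = fractions)
  morph <- character(n_cells)
  markers <- matrix(FALSE, n_cells, length(marker_names),
                    dimnames = list(NULL, marker_names))
  trap <- logical(n_cells); anae <- logical(n_cells)
  for (nm in names(classes)) {
    idx <- which(cls == nm)
    if (!length(idx)) next
    cl <- classes[[nm]]
    morph[idx] <- sample(names(cl$morphotypes), length(idx), replace = TRUE,
                         prob = cl$morphotypes)
    for (mk in names(cl$markers)) {
      markers[idx, mk] <- stats::runif(length(idx)) < cl$markers[[mk]]
    }
    trap[idx] <- cl$trap; anae[idx] <- cl$anae
  }
  diam <- sample_diameters(morph, geom)
  cells <- data.frame(cell_id = seq_len(n_cells), class = cls,
                      morphotype = morph, diameter_um = diam,
                      trap = trap, anae = anae, stringsAsFactors = FALSE)
  list(cells = cells, markers = markers)
}

#' Generate one healthy donor
#'
#' Draws class fractions from truncated normals (renormalized to the
#' simplex), then realizes a roster of cells with Bernoulli marker sets,
#' class-specific morphotypes and morphotype-specific diameters.
#' Deterministic given `seed`.
#'
#' @param params see [default_cohort_params()].
#' @param seed integer seed.
#' @return A `donor_truth` object: `class_fractions`, `cells` (one row per
#'   cell), `markers` (logical cell x CD matrix), `classes`, suspension
#'   concentration `x`.
#' @export
build_healthy_profile <- function(params = default_cohort_params(), seed = 1L) {
  set.seed(child_seed(seed, 1L, salt = 11L))
  fm <- params$fraction_mean; fs <- params$fraction_sd
  draws <- vapply(names(fm), function(nm) {
    if (fs[[nm]] <= 0) return(fm[[nm]])
    rtrunc_norm(1L, fm[[nm]], fs[[nm]],
                lower = max(0.002, fm[[nm]] - 4 * fs[[nm]]),
                upper = min(0.97, fm[[nm]] + 4 * fs[[nm]]))
  }, 0)
  fractions <- draws / sum(draws)
  assert_simplex(fractions, "class fractions")
  ros <- .build_roster(params$classes, fractions, params$n_cells,
                       morphotype_geometry())
  structure(list(class_fractions = fractions, cells = ros$cells,
                 markers = ros$markers, classes = params$classes,
                 x = params$x, seed = seed),
            class = "donor_truth")
}

#' Leukemic clone class definitions
#'
#' Marker profiles of the circulating B-cell neoplasms handled by the
#' signature library: CLL coexpresses CD5 and CD23 (with weak CD20/CD22,
#' modelled as reduced capture strength); HCL expresses CD11c, CD25 and
#' CD103 and is TRAP-positive with hairy morphology; SMZL is CD25-positive
#' with villous morphology but lacks CD23, CD10, CD11c and CD103; MCL
#' coexpresses CD5; FL expresses CD10.
#'
#' @param disease one of `"CLL"`, `"HCL"`, `"SMZL"`, `"MCL"`, `"FL"`.
#' @return A [cell_class()] for the clone.
#' @export
disease_clone_class <- function(disease) {
  base <- c(CD45 = 1, CD19 = 1, CD20 = 1, CD22 = 1, `HLA-DR` = 1)
  switch(disease,
    CLL = cell_class("clone_cll",
      markers = c(base, CD5 = 1, CD23 = 1, CD21 = 0.5, IgM = 0.6),
      morphotypes = c(small = 1),
      strength = c(CD20 = 0.35, CD22 = 0.35)),
    HCL = cell_class("clone_hcl",
      markers = c(base, CD11c = 1, CD25 = 1, CD103 = 1, IgM = 0.7),
      morphotypes = c(hairy = 1), trap = TRUE),
    SMZL = cell_class("clone_smzl",
      markers = c(base, CD25 = 1, IgM = 0.8),
      morphotypes = c(villous = 1)),
    MCL = cell_class("clone_mcl",
      markers = c(base, CD5 = 1, IgM = 0.7),
      morphotypes = c(small = 1)),
    FL = cell_class("clone_fl",
      markers = c(base, CD10 = 1, IgM = 0.7),
      morphotypes = c(small = 1)),
    stop("unknown disease '", disease,
         "'; allowed: CLL, HCL, SMZL, MCL, FL, normal")
  )
}

#' Generate a patient with a leukemic clone
#'
#' Builds the healthy background for `seed`, then replaces a
#' `clone_fraction` share of the roster (chosen at random) by clone cells
#' with the disease's marker profile and morphotype. With
#' `clone_fraction = 0` the result is identical to
#' [build_healthy_profile()] for the same seed.
#'
#' @param disease disease label (`"normal"` returns the healthy donor).
#' @param clone_fraction proportion of PBMC belonging to the clone.
#' @param seed integer seed.
#' @param params cohort parameters.
#' @return A `donor_truth` object.
#' @export
build_disease_profile <- function(disease, clone_fraction, seed = 1L,
                                  params = default_cohort_params()) {
  if (!disease %in% c("CLL", "HCL", "SMZL", "MCL", "FL", "normal")) {
    stop("unknown disease '", disease,
         "'; allowed: CLL, HCL, SMZL, MCL, FL, normal")
  }
  stopifnot(clone_fraction >= 0, clone_fraction <= 1)
  truth <- build_healthy_profile(params, seed)
  if (disease == "normal" || clone_fraction == 0) return(truth)
  clone <- disease_clone_class(disease)
  n <- nrow(truth$cells)
  n_clone <- round(clone_fraction * n)
  if (n_clone == 0L) return(truth)
  set.seed(child_seed(seed, 2L, salt = 13L))
  idx <- sample.int(n, n_clone)
  truth$cells$class[idx] <- clone$name
  truth$cells$morphotype[idx] <- sample(names(clone$morphotypes), n_clone,
                                        replace = TRUE,
                                        prob = clone$morphotypes)
  truth$cells$diameter_um[idx] <- sample_diameters(truth$cells$morphotype[idx])
  truth$cells$trap[idx] <- clone$trap
  truth$cells$anae[idx] <- clone$anae
  truth$markers[idx, ] <- FALSE
  for (mk in names(clone$markers)) {
    if (!mk %in% colnames(truth$markers)) {
      truth$markers <- cbind(truth$markers,
                             matrix(FALSE, n, 1, dimnames = list(NULL, mk)))
    }
    truth$markers[idx, mk] <- stats::runif(n_clone) < clone$markers[[mk]]
  }
  truth$classes[[clone$name]] <- clone
  truth$class_fractions <- c(truth$class_fractions * (1 - clone_fraction),
                             stats::setNames(clone_fraction, clone$name))
  truth
}

#' Simulate a flow-cytometry measurement of percent-positive fractions
#'
#' Flow cytometry is the gold-standard comparator; it is emulated as a
#' binomial sample of `n_events` CD45-positive events at the roster's true
#' marker frequencies.
#'
#' @param truth a `donor_truth`.
#' @param n_events number of acquired events (>= 100).
#' @param seed integer seed.
#' @param cds CD antigens to report.
#' @return A `flow_result`: `percent_positive` (% of CD45+ events) and
#'   `n_events`.
#' @export
simulate_flow <- function(truth, n_events = 10000L, seed = 1L,
                          cds = c("CD3", "CD4", "CD8", "CD19")) {
  if (!nrow(truth$cells)) stop("empty donor roster")
  if (n_events < 100) stop("n_events must be at least 100")
  set.seed(child_seed(seed, 3L, salt = 17L))
  gate <- truth$markers[, "CD45"]
  pp <- vapply(cds, function(cd) {
    p <- if (cd %in% colnames(truth$markers)) {
      mean(truth$markers[gate, cd])
    } else 0
    if (p == 0) return(0)
    100 * stats::rbinom(1L, n_events, p) / n_events
  }, 0)
  structure(list(percent_positive = pp, n_events = as.integer(n_events)),
            class = "flow_result")
}

#' True percent-positive fractions of a roster
#'
#' @param truth a `donor_truth`.
#' @param cds CD antigens to report.
#' @return Named numeric, % of CD45+ cells expressing each CD.
#' @export
true_percent_positive <- function(truth, cds = c("CD3", "CD4", "CD8", "CD19")) {
  gate <- truth$markers[, "CD45"]
  vapply(cds, function(cd) {
    if (!cd %in% colnames(truth$markers)) return(0)
    100 * mean(truth$markers[gate, cd])
  }, 0)
}

#' Export a donor roster as a data frame (one row per cell)
#'
#' @param truth a `donor_truth`.
#' @return `cells` joined with the realized marker set (logical columns).
#' @export
roster_table <- function(truth) {
  cbind(truth$cells, as.data.frame(truth$markers))
}
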