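#' End-to-end captured-cell classification over a cohort
#'
#' For each donor: build the truth, simulate capture on the requested
#' spots, render the captured cells as a microscopy-like field, segment,
#' measure and classify them. Returns the classified roster (one row per
#' measured cell) together with the rendered ground truth, so both the
#' cross-tab and the classifier accuracy can be computed from the same
#' run.
#'
#' @param n_donors number of donors.
#' @param cds antibody spots to image.
#' @param cells_per_spot captured cells rendered per spot (subsampled from
#'   the captured roster).
#' @param seed master seed.
#' @param params cohort parameters.
#' @param cap_params capture parameters.
#' @param pixel_scale render scale (um/px).
#' @param pack_fraction target cell-area fraction of the rendered field;
#'   sizes the field from the roster's total cell area so that large-cell
#'   (monocyte) compositions place as reliably as small-lymphocyte ones
#'   while touching cells stay separable.
#' @return List: `classified` (donor, cd, morphotype = measured label),
#'   `matched` (measured vs ground truth per cell), `accuracy` (fraction
#'   of matched cells whose label equals the generative morphotype).
#' @export
run_morpho_crosstab <- function(n_donors = 5L,
                                cds = c("CD14", "CD8", "CD19"),
                                cells_per_spot = 500L, seed = 1L,
                                params = default_cohort_params(),
                                cap_params = capture_params(),
                                pixel_scale = 0.15,
                                pack_fraction = 0.4) {
  panel <- default_panel()
  rows <- list(); gmatch <- list()
  for (d in seq_len(n_donors)) {
    dseed <- child_seed(seed, d, salt = 37L)
    truth <- build_healthy_profile(params, seed = dseed)
    cap <- simulate_capture(truth, panel, cap_params, seed = dseed)
    for (cd in cds) {
      sid <- as.character(panel$spot_id[panel$cd == cd])
      ros <- cap$rosters[[sid]]
      if (!nrow(ros)) next
      set.seed(child_seed(dseed, match(cd, cds), salt = 41L))
      if (nrow(ros) > cells_per_spot) {
        ros <- ros[sample.int(nrow(ros), cells_per_spot), ]
      }
      cell_area_mm2 <- sum(pi * (ros$diameter_um / 2)^2) / 1e6
      side_um <- sqrt(cell_area_mm2 / pack_fraction) * 1000
      img <- render_spot(ros, list(type = "rect", w = side_um, h = side_um),
                         render_params(pixel_scale = pixel_scale),
                         seed = child_seed(dseed, match(cd, cds), salt = 43L))
      seg <- segment_cells(img)
      mt <- morphometry_table(img, seg)
      if (is.null(mt) || !nrow(mt)) next
      mm <- match_ground_truth(mt, img$ground_truth)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, cd = cd, morphotype = mt$label,
        stringsAsFactors = FALSE)
      if (!is.null(mm)) gmatch[[length(gmatch) + 1L]] <- mm
    }
  }
  classified <- do.call(rbind, rows)
  matched <- do.call(rbind, gmatch)
  accuracy <- if (!is.null(matched) && nrow(matched)) {
    mean(matched$label == matched$true_morphotype)
  } else NA_real_
  list(classified = classified, matched = matched, accuracy = accuracy)
}

#' Simulate normalized profiles for a cohort (tables-only mode)
#'
#' Capture simulation plus counting-noise profile measurement for
#' `n_donors` healthy donors; no imaging stages.
#'
#' @param n_donors cohort size.
#' @param seed master seed.
#' @param params cohort parameters.
#' @param cap_params capture parameters.
#' @param counting_cv per-spot counting error.
#' @return Data frame stack of per-donor profile tables with a `donor`
#'   column.
#' @export
cohort_profiles <- function(n_donors, seed = 1L,
                            params = default_cohort_params(),
                            cap_params = capture_params(),
                            counting_cv = 0.05) {
  panel <- default_panel()
  out <- lapply(seq_len(n_donors), function(d) {
    dseed <- child_seed(seed, d, salt = 47L)
    truth <- build_healthy_profile(params, seed = dseed)
    cap <- simulate_capture(truth, panel, cap_params, seed = dseed)
    prof <- measure_profile(cap, counting_cv, seed = dseed)
    cbind(donor = d, prof)
  })
  do.call(rbind, out)
}

# internal: tiny FNV-1a hash for the run manifest
.config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run configuration for the full pipeline
#'
#' @param seed master seed (required for reproducibility).
#' @param disease disease label (`"normal"` for a healthy subject).
#' @param clone_fraction clone share of PBMC for disease runs.
#' @param n_reference healthy donors simulated for the reference ranges.
#' @param stages pipeline stages to execute, a prefix-closed subset of
#'   `simulate`, `capture`, `quantify`, `diagnose` plus the optional
#'   `imaging` block.
#' @param imaging run the render/segment/classify block (slow).
#' @param output_dir where CSV/JSON artifacts are written (`NULL` keeps
#'   everything in memory).
#' @param x suspension concentration, 1e6 cells/ml.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, disease = "normal", clone_fraction = 0,
                       n_reference = 25L,
                       stages = c("simulate", "capture", "quantify",
                                  "diagnose"),
                       imaging = FALSE, output_dir = NULL, x = 8) {
  if (missing(seed)) stop("a seed is required")
  allowed <- c("simulate", "capture", "quantify", "diagnose")
  if (!all(stages %in% allowed)) {
    stop("unknown stages: ", paste(setdiff(stages, allowed), collapse = ", "))
  }
  need <- match(stages, allowed)
  if (!identical(sort(need), seq_len(max(need)))) {
    stop("stages must form a prefix of the pipeline: ",
         paste(allowed, collapse = " -> "))
  }
  structure(list(seed = as.integer(seed), disease = disease,
                 clone_fraction = clone_fraction,
                 n_reference = as.integer(n_reference), stages = stages,
                 imaging = imaging, output_dir = output_dir, x = x),
            class = "run_config")
}

#' Execute the simulate -> capture -> quantify -> diagnose pipeline
#'
#' Runs the requested stages for one subject, writes tabular artifacts and
#' a manifest when `output_dir` is set, and returns everything invisibly.
#' Identical config and seed give identical tabular outputs.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list with the per-stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list(config = config)
  params <- default_cohort_params(x = config$x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if ("simulate" %in% config$stages) {
    res$truth <- stage("simulate",
      build_disease_profile(config$disease, config$clone_fraction,
                            seed = config$seed, params = params))
  }
  if ("capture" %in% config$stages) {
    res$capture <- stage("capture",
      simulate_capture(res$truth, default_panel(), capture_params(),
                       seed = config$seed))
  }
  if ("quantify" %in% config$stages) {
    res$profile <- stage("quantify",
      measure_profile(res$capture, seed = config$seed))
    if (config$imaging) {
      res$morpho <- stage("quantify", run_morpho_crosstab(
        n_donors = 1L, seed = config$seed))
      res$crosstab <- stage("quantify", crosstab(res$morpho$classified,
                                                 min_cells = 1L))
    }
  }
  if ("diagnose" %in% config$stages) {
    ref <- stage("diagnose", cohort_profiles(
      config$n_reference, seed = child_seed(config$seed, 999L, salt = 53L),
      params = default_cohort_params(x = config$x)))
    res$ranges <- stage("diagnose", reference_ranges(ref))
    evid <- if (config$disease == "HCL") {
      list(trap = TRUE, morphotype = "hairy")
    } else NULL
    res$diagnosis <- stage("diagnose",
      suggest_diagnosis(res$profile, res$ranges,
                        morph_evidence = evid))
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wr <- function(obj, name) {
      p <- file.path(config$output_dir, name)
      utils::write.csv(obj, p, row.names = FALSE)
      files <<- c(files, name)
    }
    if (!is.null(res$profile)) wr(res$profile, "profile.csv")
    if (!is.null(res$capture)) {
      wr(res$capture$spots, "spot_densities.csv")
    }
    if (!is.null(res$truth)) wr(roster_table(res$truth), "roster.csv")
    if (!is.null(res$ranges)) wr(res$ranges, "reference_ranges.csv")
    if (!is.null(res$diagnosis)) {
      wr(res$diagnosis$flags, "flags.csv")
      jsonlite::write_json(
        list(ranking = res$diagnosis$ranking,
             flags = res$diagnosis$flags),
        file.path(config$output_dir, "report.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
      files <- c(files, "report.json")
    }
    manifest <- list(seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("leukarray")),
                     r_version = as.character(getRversion()),
                     config_hash = .config_hash(
                       config[setdiff(names(config), "output_dir")]),
                     files = files)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

#' Microarray vs flow-cytometry concordance study
#'
#' Simulates a cohort of healthy donors with donor-level variation in the
#' CD3-positive fraction (truncated Normal, mean 60%, SD 8%, bounds
#' 30-85%) and in the CD4:CD8 split, measures each donor's normalized
#' profile (5% counting noise) and flow percentages (binomial at 10^4
#' events), and computes the per-CD Pearson correlations plus the pooled
#' through-origin slope.
#'
#' @param n_donors cohort size (the reference comparison used 14).
#' @param seed master seed.
#' @param n_events flow events per donor.
#' @param counting_cv microarray counting error.
#' @param x suspension concentration, 1e6 cells/ml.
#' @return List: `paired` (donor, cd, array_pct, flow_pct) and
#'   `concordance` ([fc_concordance()] result).
#' @export
concordance_study <- function(n_donors = 14L, seed = 1L, n_events = 10000L,
                              counting_cv = 0.05, x = 8) {
  panel <- default_panel()
  rows <- list()
  for (d in seq_len(n_donors)) {
    ds <- child_seed(seed, d, salt = 61L)
    set.seed(ds)
    cd3 <- rtrunc_norm(1L, 60, 8, 30, 85) / 100
    # CD4:CD8 split and B share vary between donors on the scale of
    # published flow reference ranges (CD4 31-60%, CD8 13-41%, CD19 6-25%)
    split <- rtrunc_norm(1L, 0.81, 0.09, 0.55, 0.95)
    bshare <- rtrunc_norm(1L, 0.5475, 0.10, 0.25, 0.75)
    rest <- 1 - cd3
    oshare <- (1 - bshare) / (0.1275 + 0.325)
    fm <- c(cd4_t = cd3 * split, cd8_t = cd3 * (1 - split),
            nk = rest * 0.1275 * oshare, b = rest * bshare,
            mono = rest * 0.325 * oshare)
    pr <- default_cohort_params(
      fraction_mean = fm,
      fraction_sd = c(cd4_t = 0, cd8_t = 0, nk = 0, b = 0, mono = 0),
      x = x)
    tr <- build_healthy_profile(pr, seed = ds)
    cap <- simulate_capture(tr, panel, seed = ds)
    # counting error applies to the normalized density estimate (the
    # replicate-field counts of the two spots are averaged into one ratio)
    prof <- measure_profile(cap, counting_cv = 0, seed = ds)
    fl <- simulate_flow(tr, n_events, seed = ds)
    set.seed(child_seed(ds, 2L, salt = 67L))
    for (cd in c("CD3", "CD4", "CD8", "CD19")) {
      est <- prof$normalized_pct[prof$cd == cd] *
        max(1 + stats::rnorm(1L, 0, counting_cv), 0.01)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, cd = cd, array_pct = est,
        flow_pct = fl$percent_positive[[cd]])
    }
  }
  paired <- do.call(rbind, rows)
  list(paired = paired, concordance = fc_concordance(paired))
}
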