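#' Normalize per-spot densities to the anti-CD45 reference
#'
#' The percent of cells positive for a CD is estimated as the density of
#' cells captured by the corresponding antibody divided by the density on
#' the anti-CD45 positive-control spot, times 100. Values above 100% are
#' allowed but flagged.
#'
#' @param densities named numeric vector (cells/mm^2) or a data frame with
#'   `cd` and `density` columns.
#' @param reference name of the reference spot.
#' @return A `profile_table` data frame: `cd`, `density`,
#'   `normalized_pct`, `flag_over_100`.
#' @export
normalize_densities <- function(densities, reference = "CD45") {
  if (is.data.frame(densities)) {
    cd <- densities$cd; dens <- densities$density
  } else {
    cd <- names(densities); dens <- as.numeric(densities)
  }
  if (!reference %in% cd) stop("no ", reference, " density supplied")
  ref <- dens[match(reference, cd)]
  if (is.na(ref) || ref <= 0) {
    stop("normalization undefined: ", reference, " density is zero")
  }
  if (any(dens < 0)) stop("densities must be non-negative")
  out <- data.frame(cd = cd, density = dens,
                    normalized_pct = 100 * dens / ref,
                    stringsAsFactors = FALSE)
  out$flag_over_100 <- out$normalized_pct > 100 & out$cd != reference
  class(out) <- c("profile_table", "data.frame")
  out
}

#' Normalized profile of a simulated capture, with counting noise
#'
#' Emulates the bench measurement of each spot's density from replicate
#' counting fields as a multiplicative Gaussian error (default CV 5%)
#' applied to the simulated density, then normalizes to anti-CD45.
#'
#' @param capture a `capture_result`.
#' @param counting_cv relative counting error per spot.
#' @param seed integer seed.
#' @return A `profile_table` (capture spots only, plus the reference).
#' @export
measure_profile <- function(capture, counting_cv = 0.05, seed = 1L) {
  sp <- capture$spots[capture$spots$role %in% c("capture", "positive"), ]
  set.seed(child_seed(seed, 7L, salt = 31L))
  noisy <- sp$density * pmax(1 + stats::rnorm(nrow(sp), 0, counting_cv), 0.01)
  normalize_densities(stats::setNames(noisy, sp$cd))
}

#' Global saturation-binding fit with a shared characteristic concentration
#'
#' Least-squares fit of `y_i = a_i * (1 - exp(-x / x0))` over all titration
#' series simultaneously, with one asymptote per spot and a single shared
#' x0 (Levenberg-Marquardt). Standard errors come from the fit covariance.
#'
#' @param titration data frame with `spot`, `x`, `y`.
#' @return A `saturation_fit`: `x0`, `x0_se`, `a` and `a_se` (named per
#'   spot), `fit` (the `nls` object).
#' @export
fit_saturation <- function(titration) {
  stopifnot(all(c("spot", "x", "y") %in% names(titration)))
  titration$spot <- factor(titration$spot)
  if (length(unique(titration$x)) < 3L) {
    stop("at least 3 distinct concentrations are required")
  }
  flat <- tapply(titration$y, titration$spot, function(y) {
    diff(range(y)) < 1e-9 * max(1, abs(mean(y)))
  })
  if (all(flat)) {
    stop("x0 is unidentifiable: every series is flat across x")
  }
  spots <- levels(titration$spot)
  a_start <- tapply(titration$y, titration$spot, max)
  start <- c(list(x0 = stats::median(titration$x) / 2),
             stats::setNames(as.list(as.numeric(a_start)),
                             paste0("a", seq_along(spots))))
  amat <- stats::model.matrix(~ 0 + spot, titration)
  colnames(amat) <- paste0("a", seq_along(spots))
  form <- stats::as.formula(paste0(
    "y ~ (", paste(sprintf("%s * amat[, %d]", colnames(amat),
                           seq_along(spots)), collapse = " + "),
    ") * (1 - exp(-x / x0))"))
  fit <- minpack.lm::nlsLM(form, data = titration, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(
    x0 = unname(est["x0"]), x0_se = unname(se["x0"]),
    a = stats::setNames(unname(est[paste0("a", seq_along(spots))]), spots),
    a_se = stats::setNames(unname(se[paste0("a", seq_along(spots))]), spots),
    fit = fit), class = "saturation_fit")
}

#' Morphotype x antibody cross-tabulation across donors
#'
#' Per-antibody morphotype percentages computed per donor, then averaged
#' (mean +/- s.e.m.). Antibodies with no captured cells in a donor are
#' excluded from that donor's average and flagged. A warning is issued
#' when a donor contributes fewer than `min_cells` classified cells for an
#' antibody, mirroring the bench rule of analysing at least 200 captured
#' cells per antibody.
#'
#' @param classified data frame with `donor`, `cd`, `morphotype`.
#' @param morphotypes category set for the columns.
#' @param min_cells per-donor per-antibody count below which a warning is
#'   raised.
#' @return A `morphotype_by_antibody`: `mean` and `sem` matrices
#'   (antibody x morphotype, percent), `n_donors`, `flagged` antibodies.
#' @export
crosstab <- function(classified, morphotypes = morphotype_ids(),
                     min_cells = 200L) {
  stopifnot(all(c("donor", "cd", "morphotype") %in% names(classified)))
  donors <- unique(classified$donor)
  cds <- unique(classified$cd)
  low <- character(0)
  per_donor <- array(NA_real_, c(length(cds), length(morphotypes),
                                 length(donors)),
                     dimnames = list(cds, morphotypes, donors))
  for (d in seq_along(donors)) {
    sub <- classified[classified$donor == donors[d], ]
    for (a in seq_along(cds)) {
      mm <- sub$morphotype[sub$cd == cds[a]]
      if (!length(mm)) next
      if (length(mm) < min_cells) {
        low <- union(low, paste0(donors[d], ":", cds[a]))
      }
      tab <- table(factor(mm, levels = morphotypes))
      per_donor[a, , d] <- 100 * as.numeric(tab) / length(mm)
    }
  }
  if (length(low)) {
    warning("fewer than ", min_cells, " classified cells for ",
            paste(utils::head(low, 5), collapse = ", "),
            if (length(low) > 5) " ..." else "")
  }
  mean_mat <- apply(per_donor, c(1, 2), mean, na.rm = TRUE)
  n_eff <- apply(!is.na(per_donor[, 1, , drop = FALSE]), 1, sum)
  sem_mat <- apply(per_donor, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  flagged <- cds[apply(is.na(per_donor[, 1, , drop = FALSE]), 1, all)]
  structure(list(mean = mean_mat, sem = sem_mat,
                 n_donors = length(donors), n_per_antibody = n_eff,
                 flagged = flagged),
            class = "morphotype_by_antibody")
}

#' Infer the immunophenotype of a morphotype from the cross-tab
#'
#' For each antibody, the morphotype's mean share among captured cells is
#' compared with the nonspecific bound: negative when the mean share is at
#' or below it, positive when mean - 2 s.e.m. exceeds it, indeterminate
#' otherwise. This is the logic by which the absence of granular
#' lymphocytes on anti-CD19 shows that none of them is a B cell.
#'
#' @param xtab a `morphotype_by_antibody`.
#' @param morphotype column to interrogate.
#' @param nonspecific_bound percent share attributable to nonspecific
#'   binding (default 2, the reported upper bound).
#' @return An `immunophenotype_call` data frame: `cd`, `share_pct`,
#'   `sem`, `call`.
#' @export
call_immunophenotype <- function(xtab, morphotype, nonspecific_bound = 2) {
  if (!morphotype %in% colnames(xtab$mean)) {
    stop("morphotype '", morphotype, "' absent from the cross-tab")
  }
  share <- xtab$mean[, morphotype]
  sem <- xtab$sem[, morphotype]
  call <- ifelse(share <= nonspecific_bound, "negative",
                 ifelse(share - 2 * ifelse(is.na(sem), 0, sem) >
                          nonspecific_bound, "positive", "indeterminate"))
  out <- data.frame(cd = rownames(xtab$mean), share_pct = share, sem = sem,
                    call = call, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("immunophenotype_call", "data.frame")
  out
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' U from midrank sums; for n1 + n2 <= 12 the two-sided p-value is exact
#' (enumeration of all group assignments of the pooled midranks, doubling
#' the smaller tail and capping at 1); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples.
#' @return A `mw_test`: `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= 12L) {
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
    method <- "exact"
  } else {
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "mw_test")
}

#' Percentile reference intervals from a healthy cohort
#'
#' @param profiles data frame with `donor`, `cd`, `normalized_pct` (stack
#'   of per-donor profile tables).
#' @param probs interval probabilities (default 2.5-97.5 percentile).
#' @return Data frame: `cd`, `median`, `lower`, `upper`, `n_donors`.
#' @export
reference_ranges <- function(profiles, probs = c(0.025, 0.975)) {
  stopifnot(all(c("donor", "cd", "normalized_pct") %in% names(profiles)))
  n_donors <- length(unique(profiles$donor))
  if (n_donors < 3L) stop("at least 3 donors are required")
  if (n_donors < 20L) {
    warning("reference ranges from fewer than 20 donors are unstable")
  }
  sp <- split(profiles$normalized_pct, profiles$cd)
  out <- data.frame(
    cd = names(sp),
    median = vapply(sp, stats::median, 0),
    lower = vapply(sp, function(v) stats::quantile(v, probs[1], names = FALSE), 0),
    upper = vapply(sp, function(v) stats::quantile(v, probs[2], names = FALSE), 0),
    n_donors = n_donors, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("reference_ranges", "data.frame")
  out
}

#' Built-in disease signature library
#'
#' Expected direction of the CD45-normalized binding density per CD for
#' the circulating B-cell neoplasms, relative to healthy reference
#' intervals. `variable` marks antigens whose magnitude is reported as
#' highly variable (weak CD20/CD22 in CLL); they do not score.
#'
#' @param path optional YAML/JSON file overriding the built-ins.
#' @return Named list of signatures (`disease`, `expect`, `evidence`).
#' @export
disease_signatures <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    return(lapply(raw, function(s) {
      list(disease = s$disease, expect = unlist(s$expect),
           evidence = s$evidence %||% NULL)
    }))
  }
  t_down <- c(CD2 = "down", CD3 = "down", CD4 = "down", CD7 = "down",
              CD8 = "down")
  b_up <- c(CD19 = "up", CD20 = "up", CD22 = "up")
  list(
    CLL = list(disease = "CLL",
               expect = c(CD19 = "up", CD20 = "variable", CD22 = "variable",
                          CD23 = "up", CD5 = "up", t_down),
               evidence = NULL),
    HCL = list(disease = "HCL",
               expect = c(b_up, CD25 = "up", CD11c = "up", CD103 = "up",
                          CD5 = "down", CD23 = "normal", t_down),
               evidence = list(trap = TRUE, morphotype = "hairy")),
    SMZL = list(disease = "SMZL",
                expect = c(b_up, CD25 = "up", CD5 = "down", CD23 = "normal",
                           CD11c = "normal", CD103 = "normal", t_down),
                evidence = NULL),
    MCL = list(disease = "MCL",
               expect = c(b_up, CD5 = "up", CD23 = "normal", t_down),
               evidence = NULL),
    FL = list(disease = "FL",
              expect = c(b_up, CD10 = "up", CD5 = "down", t_down),
              evidence = NULL),
    normal = list(disease = "normal", expect = character(0), evidence = NULL)
  )
}

#' Flag a profile against reference ranges and rank disease signatures
#'
#' Each CD is flagged `above`, `below` or `within` its healthy reference
#' interval. A signature's score is the fraction of its scorable
#' expectations (everything but `variable`) matched by the flags;
#' `normal` scores the fraction of panel CDs within range. Optional
#' morphotype evidence (e.g. TRAP-positive hairy cells) adds one matched
#' criterion to signatures that require it.
#'
#' @param profile a `profile_table` for the patient.
#' @param ranges [reference_ranges()] from a healthy cohort on the same
#'   panel.
#' @param signatures [disease_signatures()].
#' @param morph_evidence optional list, e.g.
#'   `list(trap = TRUE, morphotype = "hairy")`.
#' @return A `diagnosis_suggestion`: `flags` data frame and `ranking`
#'   (disease, score, matched, applicable), ordered by score.
#' @export
suggest_diagnosis <- function(profile, ranges,
                              signatures = disease_signatures(),
                              morph_evidence = NULL) {
  prof <- profile[profile$cd != "CD45", ]
  missing_cd <- setdiff(prof$cd, ranges$cd)
  if (length(missing_cd)) {
    stop("panel mismatch: no reference range for ",
         paste(missing_cd, collapse = ", "))
  }
  m <- match(prof$cd, ranges$cd)
  flag <- ifelse(prof$normalized_pct > ranges$upper[m], "above",
                 ifelse(prof$normalized_pct < ranges$lower[m], "below",
                        "within"))
  flags <- data.frame(cd = prof$cd, normalized_pct = prof$normalized_pct,
                      lower = ranges$lower[m], upper = ranges$upper[m],
                      flag = flag, stringsAsFactors = FALSE)
  score_one <- function(sig) {
    if (!length(sig$expect)) {
      applicable <- nrow(flags)
      matched <- sum(flags$flag == "within")
    } else {
      exp_cds <- intersect(names(sig$expect), flags$cd)
      exp_use <- sig$expect[exp_cds]
      exp_use <- exp_use[exp_use != "variable"]
      applicable <- length(exp_use)
      fl <- flags$flag[match(names(exp_use), flags$cd)]
      matched <- sum((exp_use == "up" & fl == "above") |
                       (exp_use == "down" & fl == "below") |
                       (exp_use == "normal" & fl == "within"))
    }
    if (!is.null(sig$evidence) && !is.null(morph_evidence)) {
      applicable <- applicable + 1L
      hit <- all(vapply(names(sig$evidence), function(k) {
        identical(morph_evidence[[k]], sig$evidence[[k]])
      }, TRUE))
      matched <- matched + as.integer(hit)
    }
    c(matched = matched, applicable = applicable)
  }
  sc <- t(vapply(signatures, score_one, c(matched = 0, applicable = 0)))
  ranking <- data.frame(disease = vapply(signatures, `[[`, "", "disease"),
                        matched = sc[, "matched"],
                        applicable = sc[, "applicable"],
                        score = sc[, "matched"] / pmax(sc[, "applicable"], 1),
                        row.names = NULL, stringsAsFactors = FALSE)
  if (all(flags$flag == "within")) {
    ranking$score[ranking$disease == "normal"] <- 1
  }
  ranking <- ranking[order(-ranking$score, ranking$disease), ]
  structure(list(flags = flags, ranking = ranking),
            class = "diagnosis_suggestion")
}

#' Concordance between microarray and flow-cytometry percent-positive
#'
#' Per-CD Pearson correlation across donors plus the pooled
#' through-origin regression slope `k = sum(x*y) / sum(x^2)` of the flow
#' percentage on the microarray percentage.
#'
#' @param paired data frame with `donor`, `cd`, `array_pct`, `flow_pct`.
#' @param min_donors minimum paired donors per CD.
#' @return A `concordance_result`: `R` (named per CD), `k`, `n_donors`.
#' @export
fc_concordance <- function(paired, min_donors = 3L) {
  stopifnot(all(c("donor", "cd", "array_pct", "flow_pct") %in% names(paired)))
  sp <- split(paired, paired$cd)
  R <- vapply(sp, function(d) {
    if (nrow(d) < min_donors) {
      stop("fewer than ", min_donors, " paired donors for ", d$cd[1])
    }
    if (stats::sd(d$array_pct) == 0 || stats::sd(d$flow_pct) == 0) {
      return(NA_real_)
    }
    stats::cor(d$array_pct, d$flow_pct)
  }, 0)
  k <- sum(paired$array_pct * paired$flow_pct) / sum(paired$array_pct^2)
  structure(list(R = R, k = k,
                 n_donors = length(unique(paired$donor)),
                 zero_variance = names(R)[is.na(R)]),
            class = "concordance_result")
}
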