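#' Default 35-spot antibody panel map
#'
#' A 5 x 7 grid covering the standard leukocyte lineage panel, with
#' anti-CD45 as the pan-leukocyte positive control and mouse IgG (mIgG) as
#' the negative control mapped to the background-binding check.
#'
#' @param diameter_mm spot diameter (1 ul hand-spotted drops).
#' @return A `panel_config` data frame: spot_id, row, col, cd, diameter_mm,
#'   role (`capture`, `positive`, `negative`).
#' @export
default_panel <- function(diameter_mm = 1.5) {
  cds <- c("CD1a", "CD2", "CD3", "CD4", "CD5", "CD7", "CD8",
           "CD10", "CD11c", "CD14", "CD15", "CD16", "CD19", "CD20",
           "CD21", "CD22", "CD23", "CD25", "CD33", "CD38", "CD41a",
           "CD43", "CD45", "CD45RA", "CD45RO", "CD56", "CD61", "CD64",
           "CD103", "HLA-DR", "IgGk", "IgGl", "IgM", "CD117", "mIgG")
  n <- length(cds)
  panel <- data.frame(
    spot_id = seq_len(n),
    row = rep(seq_len(5), each = 7),
    col = rep(seq_len(7), times = 5),
    cd = cds,
    diameter_mm = diameter_mm,
    role = ifelse(cds == "CD45", "positive",
                  ifelse(cds == "mIgG", "negative", "capture")),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("panel_config", "data.frame")
  panel
}

#' Load and validate a panel map from YAML or JSON
#'
#' The file holds a list of spots with `row`, `col`, `cd` and optionally
#' `diameter_mm` and `role`; roles default to `capture` except CD45
#' (`positive`) and mIgG (`negative`).
#'
#' @param path file path (.yaml/.yml or .json).
#' @return A validated `panel_config`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spots <- raw$spots
  if (is.null(spots)) stop("panel file has no 'spots' entry")
  if (!is.data.frame(spots)) {
    spots <- do.call(rbind, lapply(spots, function(s) {
      data.frame(row = s$row, col = s$col, cd = s$cd,
                 diameter_mm = s$diameter_mm %||%
                   raw$spot_diameter_mm %||% 1.5,
                 role = s$role %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  } else if (is.null(spots$diameter_mm)) {
    spots$diameter_mm <- raw$spot_diameter_mm %||% 1.5
  }
  if (is.null(spots$role)) spots$role <- NA_character_
  spots$role[is.na(spots$role)] <-
    ifelse(spots$cd[is.na(spots$role)] == "CD45", "positive",
           ifelse(spots$cd[is.na(spots$role)] == "mIgG", "negative",
                  "capture"))
  panel <- data.frame(spot_id = seq_len(nrow(spots)), spots,
                      stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Validate a panel map
#'
#' @param panel a panel data frame.
#' @return The panel, invisibly classed as `panel_config`.
#' @export
validate_panel <- function(panel) {
  if (sum(panel$role == "positive") != 1L) {
    stop("panel must contain exactly one anti-CD45 positive-control spot")
  }
  pos <- paste(panel$row, panel$col)
  if (anyDuplicated(pos)) {
    stop("duplicate grid position: ", pos[duplicated(pos)][1])
  }
  dup_cd <- panel$cd[duplicated(panel$cd)]
  if (length(dup_cd)) {
    message("panel duplicates CD targets: ", paste(unique(dup_cd), collapse = ", "))
  }
  class(panel) <- c("panel_config", "data.frame")
  panel
}
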