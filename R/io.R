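REQUIRED_COHORT_COLUMNS <- c("animal_id", "age_weeks", "WBC", "LY", "LY%",
                             "RBC", "HB", "HCT%", "MCV", "MCH", "MCHC", "PLT")

SEX_LABELS <- c("m" = "M", "male" = "M", "M" = "M",
                "f" = "F", "female" = "F", "F" = "F")

#' Read a cohort CSV table
#'
#' Validates the required columns, normalizes sex labels to `{M, F}`,
#' parses ages as numeric weeks (unparseable rows are rejected with their
#' line numbers), and reports row counts and per-column missingness.
#' An optional column map renames dialect columns to the canonical names
#' (e.g. MPD export headers).
#'
#' @param path CSV file path.
#' @param column_map optional named character vector `canonical = source`
#'   or a path to a two-column CSV (`canonical`, `source`).
#' @return a CohortTable data frame with attribute `missingness`.
#' @export
read_cohort_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map)) {
    mp <- utils::read.csv(column_map, stringsAsFactors = FALSE)
    column_map <- stats::setNames(mp$source, mp$canonical)
  }
  if (!is.null(column_map))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (src %in% names(tab)) names(tab)[names(tab) == src] <- canon
    }
  missing_cols <- setdiff(REQUIRED_COHORT_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  age <- suppressWarnings(as.numeric(tab$age_weeks))
  bad <- is.na(age) & !is.na(tab$age_weeks)
  if (any(bad)) {
    warning(sprintf("rejecting %d row(s) with unparseable age (lines %s)",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
    age <- age[!bad]
  }
  tab$age_weeks <- age
  if ("sex" %in% names(tab)) {
    key <- tolower(trimws(as.character(tab$sex)))
    norm <- SEX_LABELS[key]
    unknown <- is.na(norm) & !is.na(tab$sex)
    if (any(unknown))
      warning("unrecognized sex label(s): ",
              paste(unique(tab$sex[unknown]), collapse = ", "))
    tab$sex <- unname(norm)
  }
  num_cols <- intersect(c(CBC_FEATURES, "MO", "MO%"), names(tab))
  for (cc in num_cols) tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
  attr(tab, "missingness") <-
    vapply(tab[num_cols], function(x) mean(is.na(x)), numeric(1L))
  message(sprintf("read %d records from %s", nrow(tab), path))
  tab
}

#' Read a survival CSV table
#'
#' Enforces one row per animal and `observed` in `{0, 1}`.
#'
#' @param path CSV file path.
#' @return a SurvivalTable data frame.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty survival table: ", path)
    return(data.frame(animal_id = character(), event_age_weeks = numeric(),
                      observed = integer()))
  }
  need <- c("animal_id", "event_age_weeks", "observed")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  dup <- unique(tab$animal_id[duplicated(tab$animal_id)])
  if (length(dup))
    stop("duplicate animal_id(s): ", paste(utils::head(dup, 10), collapse = ", "))
  if (!all(tab$observed %in% c(0L, 1L)))
    stop("`observed` must be 0 (censored) or 1 (death)")
  tab$event_age_weeks <- as.numeric(tab$event_age_weeks)
  tab
}

#' Write cohort / survival tables with canonical headers
#'
#' @param table data frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_table_csv <- function(table, path) {
  drop <- intersect(".invalid", names(table))
  if (length(drop)) table[[drop]] <- NULL
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
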