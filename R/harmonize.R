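#' Derive granulocyte columns from the white-cell balance
#'
#' Some CBC table dialects omit granulocytes.  They are recovered from the
#' exact identities of the differential count:
#' `GR = WBC - LY - MO` and `GR% = 100 - LY% - MO%`.
#' Records already carrying granulocytes are left untouched.  Derived values
#' outside their physical range (GR < 0 or GR% outside \[0, 100\]) mark the
#' record invalid; [assemble_matrix()] drops flagged records.
#'
#' @param table a CohortTable data frame.
#' @return the table with `GR`/`GR%` columns present and a logical
#'   `.invalid` column flagging out-of-range derivations.
#' @export
derive_granulocytes <- function(table) {
  stopifnot(is.data.frame(table))
  has_gr <- c("GR", "GR%") %in% names(table)
  if (!all(has_gr)) {
    need_cnt <- c("WBC", "LY", "MO")
    need_pct <- c("LY%", "MO%")
    if (!all(need_cnt %in% names(table)) || !all(need_pct %in% names(table)))
      stop("cannot derive granulocytes: need WBC, LY, MO and LY%, MO%")
    if (!("GR" %in% names(table)))
      table[["GR"]] <- table[["WBC"]] - table[["LY"]] - table[["MO"]]
    if (!("GR%" %in% names(table)))
      table[["GR%"]] <- 100 - table[["LY%"]] - table[["MO%"]]
  }
  invalid <- (!is.na(table[["GR"]]) & table[["GR"]] < 0) |
    (!is.na(table[["GR%"]]) & (table[["GR%"]] < 0 | table[["GR%"]] > 100))
  if (".invalid" %in% names(table)) invalid <- invalid | table[[".invalid"]]
  table[[".invalid"]] <- invalid
  table
}

#' Remove between-strain baseline differences
#'
#' Subtracts, from every record of a strain, the per-feature mean of that
#' strain's earliest-age group ("earliest" = the minimal age present for
#' that strain in the table).  This centers each strain at its youthful
#' state so that pooled analyses see aging displacement, not strain
#' identity.  Sexes are pooled within a strain.
#'
#' @param table a CohortTable data frame with `strain` and `age_weeks`.
#' @param features columns to center (default: all canonical CBC columns
#'   present, plus MO/MO% when present).
#' @return the centered table.
#' @export
strain_center <- function(table, features = NULL) {
  stopifnot(is.data.frame(table), "strain" %in% names(table),
            "age_weeks" %in% names(table))
  if (is.null(features))
    features <- intersect(c(CBC_FEATURES, "MO", "MO%"), names(table))
  for (st in unique(table$strain)) {
    idx <- table$strain == st
    if (sum(idx) == 1L)
      warning(sprintf("strain '%s' has a single record: centering collapses it to zero", st))
    age0 <- min(table$age_weeks[idx])
    ref <- idx & table$age_weeks == age0
    mu <- colMeans(table[ref, features, drop = FALSE], na.rm = TRUE)
    table[idx, features] <- sweep(table[idx, features, drop = FALSE], 2L, mu)
  }
  table
}

#' Keep fully-grown animals only
#'
#' Early development and aging are distinct phenotypes; analyses use records
#' strictly older than the threshold (default 25 weeks).
#'
#' @param table a CohortTable data frame.
#' @param threshold age threshold in weeks; rows with
#'   `age_weeks > threshold` are kept.
#' @return the filtered table.
#' @export
filter_adult <- function(table, threshold = 25) {
  stopifnot(is.data.frame(table), "age_weeks" %in% names(table))
  out <- table[table$age_weeks > threshold, , drop = FALSE]
  if (nrow(out) == 0L)
    stop(sprintf("no records older than %g weeks", threshold))
  rownames(out) <- NULL
  out
}

#' Assemble the harmonized 12-feature matrix
#'
#' Drops records with any of the 12 canonical features missing or flagged
#' invalid (by [derive_granulocytes()]); no imputation.  The drop fraction
#' is reported (and a warning raised above 20%, far beyond the <2% expected
#' of a clean export).
#'
#' @param table a CohortTable passed through [derive_granulocytes()].
#' @return a `feature_matrix` object: list with `values` (n x 12 matrix in
#'   original units, columns in the fixed [CBC_FEATURES] order), `row_keys`
#'   (animal_id, age_weeks data frame) and `dropped_fraction`.
#' @export
assemble_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(CBC_FEATURES, names(table))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         " (run derive_granulocytes first?)")
  vals <- as.matrix(table[, CBC_FEATURES, drop = FALSE])
  bad <- rowSums(is.na(vals)) > 0
  if (".invalid" %in% names(table)) bad <- bad | table[[".invalid"]]
  frac <- mean(bad)
  if (frac > 0.2)
    warning(sprintf("dropping %.1f%% of records (expected <2%% on clean data)",
                    100 * frac))
  keep <- !bad
  keys <- data.frame(animal_id = table$animal_id[keep],
                     age_weeks = table$age_weeks[keep])
  structure(list(values = vals[keep, , drop = FALSE], row_keys = keys,
                 dropped_fraction = frac),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d records x %d features (%.2f%% dropped)\n",
              nrow(x$values), ncol(x$values), 100 * x$dropped_fraction))
  invisible(x)
}
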