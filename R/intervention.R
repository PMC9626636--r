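#' Stratified randomization on baseline dFI
#'
#' Animals are sorted by baseline dFI and divided into consecutive blocks;
#' within each block, group labels are allocated proportionally to the
#' requested sizes and shuffled.  The resulting groups have nearly
#' indistinguishable baseline dFI distributions -- far better balanced than
#' simple randomization.
#'
#' @param baseline data frame with `animal_id` and `dfi` (baseline scores).
#' @param group_sizes named integer vector of group sizes (must sum to the
#'   number of animals; all sizes > 0).
#' @param seed integer seed; identical seeds give identical assignments.
#' @return data frame: `animal_id`, `group`.
#' @export
stratified_randomize <- function(baseline, group_sizes, seed = 1L) {
  stopifnot(is.data.frame(baseline),
            all(c("animal_id", "dfi") %in% names(baseline)))
  if (any(group_sizes <= 0)) stop("all group sizes must be > 0")
  n <- nrow(baseline)
  if (sum(group_sizes) != n)
    stop(sprintf("group sizes sum to %d but there are %d animals",
                 sum(group_sizes), n))
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  g <- gcd_vec(group_sizes)
  block_sizes <- group_sizes / g       # composition of one block
  block_n <- sum(block_sizes)
  labels_one <- rep(names(group_sizes), times = block_sizes)
  ord <- order(baseline$dfi, baseline$animal_id)
  assignment <- character(n)
  with_seed(seed, {
    for (b in seq_len(g)) {
      idx <- ord[((b - 1L) * block_n + 1L):(b * block_n)]
      assignment[idx] <- sample(labels_one)
    }
  })
  data.frame(animal_id = baseline$animal_id, group = assignment)
}

gcd_vec <- function(x) Reduce(function(a, b) {
  while (b) { t <- b; b <- a %% b; a <- t }
  a
}, as.integer(x))

#' Per-interval dFI increments along individual trajectories
#'
#' One increment per consecutive same-animal visit pair:
#' `delta = dfi(t_end) - dfi(t_start)`.  An interval is flagged treated when
#' it overlaps any treatment range of that animal.  Because visit intervals
#' are short on the aging scale (`alpha * dt << 1`), the autoregression
#' coefficient is effectively 1 and the raw increment directly estimates the
#' drift plus any accumulated drug force `J`; increments are therefore not
#' age-detrended by default (an optional cohort-mean detrend is available).
#'
#' @param scores longitudinal DFIScore data frame (`animal_id`, `age_weeks`,
#'   `dfi`).
#' @param treatment_intervals `NULL`, or a data frame `animal_id`,
#'   `start_week`, `end_week` (one row per treatment range).
#' @param detrend subtract the mean increment of each `(t_start, t_end)`
#'   visit-pair cell before returning (off by default).
#' @return an IncrementRecord data frame: `animal_id`, `t_start`, `t_end`,
#'   `delta_dfi`, `treated_interval`.
#' @export
dfi_increments <- function(scores, treatment_intervals = NULL,
                           detrend = FALSE) {
  stopifnot(is.data.frame(scores),
            all(c("animal_id", "age_weeks", "dfi") %in% names(scores)))
  if (anyDuplicated(scores[, c("animal_id", "age_weeks")]))
    stop("duplicate visits (same animal and age) are not allowed")
  scores <- scores[order(scores$animal_id, scores$age_weeks), ]
  out <- list()
  for (id in unique(scores$animal_id)) {
    sub <- scores[scores$animal_id == id, ]
    if (nrow(sub) < 2) next
    i <- seq_len(nrow(sub) - 1L)
    rec <- data.frame(animal_id = id, t_start = sub$age_weeks[i],
                      t_end = sub$age_weeks[i + 1L],
                      delta_dfi = sub$dfi[i + 1L] - sub$dfi[i],
                      treated_interval = FALSE)
    if (!is.null(treatment_intervals)) {
      tr <- treatment_intervals[treatment_intervals$animal_id == id, ,
                                drop = FALSE]
      if (nrow(tr))
        rec$treated_interval <- vapply(seq_len(nrow(rec)), function(k) {
          any(rec$t_start[k] < tr$end_week & rec$t_end[k] > tr$start_week)
        }, logical(1L))
    }
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out))
    return(data.frame(animal_id = character(), t_start = numeric(),
                      t_end = numeric(), delta_dfi = numeric(),
                      treated_interval = logical()))
  res <- do.call(rbind, out)
  if (detrend) {
    key <- interaction(res$t_start, res$t_end, drop = TRUE)
    res$delta_dfi <- res$delta_dfi - stats::ave(res$delta_dfi, key)
  }
  rownames(res) <- NULL
  res
}

#' Two-sample test of treated vs untreated dFI increments
#'
#' Student's two-tailed t test (pooled variance) of the increments of
#' treated intervals against the untreated pool.  Following the pooling
#' rule of the rapamycin analysis, the untreated pool contains control
#' animals' intervals *and* treated animals' intervals after cessation.
#' Repeated increments from one animal are treated as independent (as the
#' published t test implies); `cluster_robust = TRUE` aggregates per animal
#' first as a sensitivity analysis.
#'
#' @param records an IncrementRecord data frame from [dfi_increments()].
#' @param cluster_robust average increments within each
#'   (animal, treated-flag) cell before testing.
#' @return list: `t`, `p`, `mean_treated`, `mean_untreated`, `n_treated`,
#'   `n_untreated`, `effect` (treated minus untreated mean).
#' @export
increment_test <- function(records, cluster_robust = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("delta_dfi", "treated_interval") %in% names(records)))
  if (cluster_robust) {
    key <- interaction(records$animal_id, records$treated_interval,
                       drop = TRUE)
    records <- data.frame(
      delta_dfi = as.numeric(tapply(records$delta_dfi, key, mean)),
      treated_interval = as.logical(tapply(records$treated_interval, key,
                                           unique)))
  }
  x <- records$delta_dfi[records$treated_interval]
  y <- records$delta_dfi[!records$treated_interval]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 increments")
  tt <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_treated = mean(x), mean_untreated = mean(y),
       n_treated = length(x), n_untreated = length(y),
       effect = mean(x) - mean(y))
}
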