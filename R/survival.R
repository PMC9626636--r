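#' Build censoring records from a cohort and partial death records
#'
#' Animals with a recorded death become observed events.  Animals without a
#' death record but with at least two CBC measurements are treated as lost
#' to follow-up at their last measurement (censored there); animals with a
#' single measurement and no death record were most likely sacrificed at
#' blood collection and are excluded.  Class counts are reported as an
#' attribute.
#'
#' @param cohort a CohortTable data frame (`animal_id`, `age_weeks`).
#' @param deaths a partial SurvivalTable with observed deaths
#'   (`animal_id`, `event_age_weeks`; an `observed` column, when present,
#'   selects the death rows).
#' @return a SurvivalTable data frame (`animal_id`, `event_age_weeks`,
#'   `observed`), with attribute `counts`.
#' @export
build_censoring <- function(cohort, deaths) {
  stopifnot(is.data.frame(cohort),
            all(c("animal_id", "age_weeks") %in% names(cohort)))
  if (!is.null(deaths) && nrow(deaths) > 0 && "observed" %in% names(deaths))
    deaths <- deaths[deaths$observed == 1, , drop = FALSE]
  n_visits <- table(cohort$animal_id)
  last_age <- tapply(cohort$age_weeks, cohort$animal_id, max)
  ids <- names(n_visits)
  dead <- ids %in% deaths$animal_id
  multi <- as.integer(n_visits) >= 2L
  keep_dead <- ids[dead]
  keep_cens <- ids[!dead & multi]
  excluded <- ids[!dead & !multi]
  out <- rbind(
    if (length(keep_dead))
      data.frame(animal_id = keep_dead,
                 event_age_weeks = deaths$event_age_weeks[
                   match(keep_dead, deaths$animal_id)],
                 observed = 1L),
    if (length(keep_cens))
      data.frame(animal_id = keep_cens,
                 event_age_weeks = as.numeric(last_age[keep_cens]),
                 observed = 0L))
  if (is.null(out))
    out <- data.frame(animal_id = character(), event_age_weeks = numeric(),
                      observed = integer())
  out <- out[order(out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(observed = length(keep_dead),
                           censored = length(keep_cens),
                           excluded = length(excluded))
  out
}

#' Gompertz mortality fit by censored maximum likelihood
#'
#' Hazard `M(t) = M0 * exp(alpha_g * t)` with right censoring.  The
#' log-likelihood is maximized over `(log M0, alpha_g)` (so `alpha_g` may be
#' negative: the exponential/constant-hazard limit is inside the parameter
#' space), standard errors come from the observed information, and the mean
#' lifespan is the mean of the fitted death-time distribution
#' (`integral of S(t) dt`).
#'
#' @param surv a SurvivalTable data frame (`event_age_weeks`, `observed`).
#' @param min_events minimum number of observed deaths required.
#' @return a `gompertz_params` list: `M0`, `alpha_g`, `mean_lifespan`, `se`
#'   (named, for M0 and alpha_g), `loglik`, `n_events`.
#' @export
fit_gompertz <- function(surv, min_events = 30L) {
  stopifnot(is.data.frame(surv),
            all(c("event_age_weeks", "observed") %in% names(surv)))
  t <- surv$event_age_weeks
  d <- surv$observed
  if (sum(d) < min_events)
    stop(sprintf("need >= %d observed events (have %d)", min_events, sum(d)))
  # cumulative hazard: M0/a (e^{at} - 1); a -> 0 limit M0 * t
  cumhaz <- function(lM0, a, t) {
    if (abs(a) < 1e-10) exp(lM0) * t else exp(lM0) * (exp(a * t) - 1) / a
  }
  negll <- function(par) {
    lM0 <- par[1L]; a <- par[2L]
    h <- sum(d * (lM0 + a * t))
    -(h - sum(cumhaz(lM0, a, t)))
  }
  # moment start: crude event rate; small positive acceleration
  start <- c(log(sum(d) / sum(t)), 0.01)
  fit <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("Gompertz MLE did not converge: ", fit$message,
         " (neg loglik ", signif(fit$value, 6), ")")
  lM0 <- fit$par[1L]; a <- fit$par[2L]
  cov <- tryCatch(solve(fit$hessian), error = function(e) matrix(NA, 2, 2))
  se_lM0 <- sqrt(cov[1L, 1L]); se_a <- sqrt(cov[2L, 2L])
  M0 <- exp(lM0)
  S <- function(u) exp(-cumhaz(lM0, a, u))
  upper <- if (a > 0) (log(1 + a * 700 / M0)) / a else 700 / M0
  tbar <- tryCatch(stats::integrate(S, 0, upper, rel.tol = 1e-8)$value,
                   error = function(e) NA_real_)
  structure(list(M0 = M0, alpha_g = a, mean_lifespan = tbar,
                 se = c(M0 = M0 * se_lM0, alpha_g = se_a),
                 loglik = -fit$value, n_events = sum(d)),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz fit: M0 = %.3g /wk (se %.2g), alpha = %.4g /wk (se %.2g)\n",
              x$M0, x$se[["M0"]], x$alpha_g, x$se[["alpha_g"]]))
  cat(sprintf("  mean lifespan %.1f wk, %d events\n", x$mean_lifespan,
              x$n_events))
  invisible(x)
}

#' Kaplan--Meier survival curve with Greenwood confidence bands
#'
#' Product-limit estimator (via the `survival` package), plain Greenwood
#' 95% intervals clipped to `[0, 1]`.
#'
#' @param surv a SurvivalTable data frame.
#' @return a `survival_curve` data frame: `time`, `survival`, `ci_low`,
#'   `ci_high`, `n_risk`, `n_event`.
#' @export
kaplan_meier <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("event_age_weeks", "observed") %in% names(surv)))
  sf <- survival::survfit(
    survival::Surv(surv$event_age_weeks, surv$observed) ~ 1,
    conf.type = "plain", conf.int = 0.95)
  out <- data.frame(time = sf$time, survival = sf$surv,
                    ci_low = pmax(sf$lower, 0, na.rm = FALSE),
                    ci_high = pmin(sf$upper, 1, na.rm = FALSE),
                    n_risk = sf$n.risk, n_event = sf$n.event)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Nelson--Aalen cumulative hazard and kernel-smoothed hazard
#'
#' Cumulative hazard `H(t) = sum(d_i/n_i)` over event times with
#' variance-based 95% intervals (`Var H = sum(d_i/n_i^2)`).  The hazard
#' itself is the Epanechnikov-kernel derivative of `H`, with boundary
#' correction by renormalizing the kernel mass inside the observed range.
#'
#' @param surv a SurvivalTable data frame.
#' @param bandwidth kernel bandwidth, weeks (> 0).
#' @param grid evaluation grid for the smoothed hazard (default: uniform,
#'   bandwidth/4 spacing across the event range).
#' @return a `hazard_curve` list: `events` data frame (time, cumhaz,
#'   ci_low, ci_high, n_risk, n_event, var_cumhaz) and `smooth` data frame
#'   (time, hazard).
#' @export
nelson_aalen_hazard <- function(surv, bandwidth = 10, grid = NULL) {
  stopifnot(is.data.frame(surv), bandwidth > 0)
  t <- surv$event_age_weeks; d <- surv$observed
  ord <- order(t)
  t <- t[ord]; d <- d[ord]
  ut <- unique(t[d == 1])
  if (!length(ut)) {
    ev <- data.frame(time = numeric(), cumhaz = numeric(),
                     ci_low = numeric(), ci_high = numeric(),
                     n_risk = integer(), n_event = integer(),
                     var_cumhaz = numeric())
    return(structure(list(events = ev,
                          smooth = data.frame(time = numeric(),
                                              hazard = numeric())),
                     class = "hazard_curve"))
  }
  n_risk <- vapply(ut, function(u) sum(t >= u), numeric(1L))
  n_event <- vapply(ut, function(u) sum(t == u & d == 1), numeric(1L))
  dH <- n_event / n_risk
  H <- cumsum(dH)
  V <- cumsum(n_event / n_risk^2)
  ev <- data.frame(time = ut, cumhaz = H,
                   ci_low = pmax(H - 1.96 * sqrt(V), 0),
                   ci_high = H + 1.96 * sqrt(V),
                   n_risk = n_risk, n_event = n_event, var_cumhaz = V)
  if (is.null(grid))
    grid <- seq(min(ut), max(ut), by = bandwidth / 4)
  lo <- min(ut); hi <- max(ut)
  epan <- function(u) ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)
  hz <- vapply(grid, function(g) {
    k <- epan((g - ut) / bandwidth) / bandwidth
    # boundary renormalization: divide by kernel mass inside [lo, hi]
    a <- max((g - hi) / bandwidth, -1); b <- min((g - lo) / bandwidth, 1)
    mass <- 0.75 * ((b - b^3 / 3) - (a - a^3 / 3))
    sum(k * dH) / max(mass, 1e-12)
  }, numeric(1L))
  structure(list(events = ev, smooth = data.frame(time = grid, hazard = hz),
                 bandwidth = bandwidth),
            class = "hazard_curve")
}

#' Late-life mortality plateau check
#'
#' The critical-dynamics model predicts the hazard saturates at the Gompertz
#' exponent: `M(t >> t_bar) ~ alpha`.  This compares the mean smoothed
#' hazard over a late-life window (default `[t_bar + 2/alpha_g, last
#' event]`) against `alpha_g`, with a propagated confidence interval (the
#' window-mean hazard is `(H(b) - H(a))/(b - a)`, its variance from the
#' Nelson--Aalen increments; the ratio CI folds in the `alpha_g` standard
#' error by the delta method).
#'
#' @param hazard a `hazard_curve` from [nelson_aalen_hazard()].
#' @param gompertz a `gompertz_params` fit with `alpha_g > 0`.
#' @param window optional `c(start, end)` in weeks; default as above.
#' @param min_at_risk warn when fewer animals remain at the window start.
#' @return list: `ratio`, `ci` (95%), `window`, `mean_hazard`, `n_at_risk`.
#' @export
plateau_check <- function(hazard, gompertz, window = NULL, min_at_risk = 20L) {
  stopifnot(inherits(hazard, "hazard_curve"),
            inherits(gompertz, "gompertz_params"))
  a <- gompertz$alpha_g
  if (!is.finite(a) || a <= 1e-8)
    stop("plateau undefined: fitted Gompertz exponent is not positive")
  ev <- hazard$events
  if (is.null(window))
    window <- c(gompertz$mean_lifespan + 2 / a, max(ev$time))
  if (window[2] <= window[1])
    stop("hazard not estimated beyond the window start")
  inw <- ev$time > window[1] & ev$time <= window[2]
  if (!any(inw)) stop("no events inside the plateau window")
  n_at_risk <- max(ev$n_risk[inw])
  if (n_at_risk < min_at_risk)
    warning(sprintf("only %d animals at risk in the window: CI is wide",
                    n_at_risk))
  dH <- sum(ev$n_event[inw] / ev$n_risk[inw])
  vH <- sum(ev$n_event[inw] / ev$n_risk[inw]^2)
  span <- window[2] - window[1]
  m <- dH / span
  vm <- vH / span^2
  se_a <- gompertz$se[["alpha_g"]]
  ratio <- m / a
  var_ratio <- vm / a^2 + m^2 * se_a^2 / a^4
  list(ratio = ratio,
       ci = c(ratio - 1.96 * sqrt(var_ratio), ratio + 1.96 * sqrt(var_ratio)),
       window = window, mean_hazard = m, n_at_risk = n_at_risk)
}

#' Cox proportional-hazards benchmark
#'
#' Multivariate Cox-PH (partial likelihood, Efron ties) over the given
#' covariates; the per-animal linear predictor (the log-hazard ratio,
#' `HR_CBC` when fed CBC features) is exported for downstream rank tests.
#'
#' @param covariates numeric matrix or data frame (one row per animal; no
#'   constant column).
#' @param surv a SurvivalTable aligned with the covariate rows.
#' @param ridge optional ridge penalty (theta) to rescue monotone
#'   likelihoods.
#' @return a `cox_model` list: `coefficients`, `linear_predictor`, `se`,
#'   `fit` (the underlying coxph object).
#' @export
cox_ph <- function(covariates, surv, ridge = 0) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == nrow(surv))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant covariate(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  df <- data.frame(time = surv$event_age_weeks, status = surv$observed, X,
                   check.names = TRUE)
  covnames <- colnames(df)[-(1:2)]
  rhs <- if (ridge > 0)
    sprintf("survival::ridge(%s, theta = %g)",
            paste(covnames, collapse = ", "), ridge)
  else paste(covnames, collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("monotone likelihood (perfect separation?): retry with ridge > 0",
             call. = FALSE)
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  beta <- stats::coef(fit)
  lp <- as.numeric(scale(X, center = TRUE, scale = FALSE) %*% beta)
  structure(list(coefficients = beta, linear_predictor = lp,
                 se = sqrt(diag(stats::vcov(fit))), fit = fit),
            class = "cox_model")
}

#' Rank correlation between a predictor and lifespan, by cohort
#'
#' Spearman correlation (two-sided test) between a per-animal predictor
#' (age-adjusted dFI, a Cox log-hazard ratio, body weight, ...) and the
#' death age, within each sex-by-measurement-age cohort.  Only observed
#' deaths enter; ties get midranks.
#'
#' @param scores data frame with `animal_id`, the predictor column, and the
#'   cohort columns (`sex`, `age_weeks`) when present.
#' @param surv a SurvivalTable data frame.
#' @param predictor name of the predictor column.
#' @param min_n cohorts below this size are skipped (reported via message).
#' @return data frame: cohort keys, `n`, `rho`, `p`.
#' @export
lifespan_rank_correlation <- function(scores, surv,
                                      predictor = "dfi_age_adjusted",
                                      min_n = 10L) {
  stopifnot(is.data.frame(scores), predictor %in% names(scores))
  dead <- surv[surv$observed == 1, ]
  m <- match(scores$animal_id, dead$animal_id)
  scores$death_age <- dead$event_age_weeks[m]
  scores <- scores[!is.na(scores$death_age), , drop = FALSE]
  keys <- intersect(c("sex", "age_weeks"), names(scores))
  grp <- if (length(keys))
    interaction(scores[, keys, drop = FALSE], drop = TRUE)
  else factor(rep("all", nrow(scores)))
  out <- list()
  skipped <- 0L
  for (g in levels(grp)) {
    sub <- scores[grp == g, ]
    if (nrow(sub) < min_n) { skipped <- skipped + 1L; next }
    ct <- suppressWarnings(
      stats::cor.test(sub[[predictor]], sub$death_age, method = "spearman"))
    row <- sub[1L, keys, drop = FALSE]
    row$n <- nrow(sub); row$rho <- unname(ct$estimate); row$p <- ct$p.value
    out[[length(out) + 1L]] <- row
  }
  if (skipped) message(sprintf("%d cohort(s) below n = %d skipped",
                               skipped, min_n))
  if (!length(out)) return(data.frame(n = integer(), rho = numeric(),
                                      p = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a survival or hazard curve as CSV
#'
#' @param curve a `survival_curve` or `hazard_curve`.
#' @param path output CSV path.
#' @return invisibly, the data frame written.
#' @export
curve_to_csv <- function(curve, path) {
  df <- if (inherits(curve, "hazard_curve")) curve$events else as.data.frame(curve)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
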