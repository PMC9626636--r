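test_that("censoring rules follow the measurement-count heuristic", {
  cohort <- data.frame(
    animal_id = c("one", "multi", "multi", "multi", "dead"),
    age_weeks = c(30, 26, 52, 78, 40))
  deaths <- data.frame(animal_id = "dead", event_age_weeks = 110,
                       observed = 1L)
  out <- build_censoring(cohort, deaths)
  expect_equal(nrow(out), 2L)  # "one" excluded
  expect_equal(out$event_age_weeks[out$animal_id == "multi"], 78)
  expect_equal(out$observed[out$animal_id == "multi"], 0L)
  expect_equal(out$event_age_weeks[out$animal_id == "dead"], 110)
  expect_equal(out$observed[out$animal_id == "dead"], 1L)
  expect_equal(attr(out, "counts"),
               c(observed = 1L, censored = 1L, excluded = 1L))
})

test_that("Gompertz MLE handles the exponential limit", {
  set.seed(10)
  t <- rexp(5000, rate = 0.01)
  surv <- data.frame(event_age_weeks = t, observed = 1L)
  fit <- fit_gompertz(surv)
  expect_lt(abs(fit$alpha_g), 3 * fit$se[["alpha_g"]])  # CI covers 0
  expect_equal(fit$M0, 0.01, tolerance = 0.05)
  expect_error(fit_gompertz(surv[1:10, ]), "observed events")
})

test_that("Gompertz MLE recovers simulated parameters under censoring", {
  M0 <- 4.1e-4; a <- 0.0385; n <- 3000
  set.seed(20)
  u <- runif(n)
  t <- log(1 - a * log(u) / M0) / a  # inverse CDF of the Gompertz law
  cens <- runif(n, 0, 500)
  obs <- as.integer(t <= cens)
  surv <- data.frame(event_age_weeks = pmin(t, cens), observed = obs)
  expect_gt(mean(obs), 0.7)
  fit <- fit_gompertz(surv)
  expect_lt(abs(fit$M0 - M0), 3 * fit$se[["M0"]])
  expect_lt(abs(fit$alpha_g - a), 3 * fit$se[["alpha_g"]])
  expect_equal(fit$alpha_g, a, tolerance = 0.08)
  # mean lifespan of this law is ~100 wk
  expect_equal(fit$mean_lifespan, 100.5, tolerance = 0.05)
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  s1 <- data.frame(event_age_weeks = c(1, 2), observed = c(1L, 1L))
  km1 <- kaplan_meier(s1)
  expect_equal(km1$survival, c(0.5, 0))

  s2 <- data.frame(event_age_weeks = c(1, 2, 3, 4),
                   observed = c(1L, 0L, 1L, 0L))
  km2 <- kaplan_meier(s2)
  expect_equal(km2$survival[km2$time == 1], 3 / 4)
  expect_equal(km2$survival[km2$time == 3], 3 / 8)

  s3 <- data.frame(event_age_weeks = c(5, 6), observed = c(0L, 0L))
  km3 <- kaplan_meier(s3)
  expect_true(all(km3$survival == 1))
  # bounds bracket the estimate
  expect_true(all(km2$ci_low <= km2$survival + 1e-12, na.rm = TRUE))
  expect_true(all(km2$ci_high >= km2$survival - 1e-12, na.rm = TRUE))
})

test_that("Nelson-Aalen cumulative hazard and smoothed hazard", {
  s1 <- data.frame(event_age_weeks = c(1, 2), observed = c(1L, 1L))
  na1 <- nelson_aalen_hazard(s1, bandwidth = 1)
  expect_equal(na1$events$cumhaz, c(0.5, 1.5))  # 1/2 then + 1/1
  expect_true(all(diff(na1$events$cumhaz) >= 0))

  s0 <- data.frame(event_age_weeks = c(3, 4), observed = c(0L, 0L))
  na0 <- nelson_aalen_hazard(s0, bandwidth = 1)
  expect_equal(nrow(na0$events), 0L)

  # constant-hazard simulation: smoothed hazard flat at the rate over the
  # well-populated interior (risk sets in the thousands)
  set.seed(30)
  t <- rexp(15000, 0.02)
  na2 <- nelson_aalen_hazard(data.frame(event_age_weeks = t, observed = 1L),
                             bandwidth = 10)
  interior <- na2$smooth$time > 20 & na2$smooth$time < 80
  expect_lt(max(abs(na2$smooth$hazard[interior] - 0.02)) / 0.02, 0.1)

  # agreement with Kaplan-Meier: S ~ exp(-H) where risk sets are large
  # (join on event time; survfit may collapse near-tied float times)
  km <- kaplan_meier(data.frame(event_age_weeks = t, observed = 1L))
  j <- merge(data.frame(time = km$time, s = km$survival, n_risk = km$n_risk),
             data.frame(time = na2$events$time, H = na2$events$cumhaz))
  big <- j$n_risk > 50
  expect_lt(max(abs(j$s[big] - exp(-j$H[big]))), 0.02)
})

test_that("plateau check compares late-life hazard to the Gompertz exponent", {
  # cohort from the critical-dynamics model: hazard must plateau at alpha
  alpha <- 0.05
  p <- mortal_langevin(alpha = alpha, z_bar = 0.1, log_ratio = 2,
                       z_init = 0)
  sim <- simulate_latent_cohort(p, 6000, horizon = 150, step = 0.01,
                                seed = 17)
  dead <- !is.na(sim$death_time)
  surv <- data.frame(
    event_age_weeks = ifelse(dead, sim$death_time, 150),
    observed = as.integer(dead))
  gfit <- fit_gompertz(surv)
  hz <- nelson_aalen_hazard(surv, bandwidth = 8)
  pl <- plateau_check(hz, gfit,
                      window = c(mean_lifespan(p, exp(2)) + 2 / alpha, 145))
  expect_gt(pl$ci[2], pl$ratio)
  expect_equal(pl$mean_hazard, alpha, tolerance = 0.15)

  # guard: no positive exponent, no plateau
  flat <- structure(list(M0 = 0.01, alpha_g = 0, mean_lifespan = 100,
                         se = c(M0 = 1e-3, alpha_g = 1e-3)),
                    class = "gompertz_params")
  expect_error(plateau_check(hz, flat), "not positive")
})

test_that("Cox benchmark agrees with a brute-force partial likelihood", {
  # 4 subjects, one binary covariate, no ties: grid-search oracle
  surv <- data.frame(event_age_weeks = c(2, 5, 7, 9),
                     observed = c(1L, 1L, 1L, 1L))
  x <- c(1, 0, 1, 0)
  fit <- cox_ph(matrix(x, ncol = 1, dimnames = list(NULL, "trt")), surv)
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, function(b) {
    risk <- exp(b * x)
    ord <- order(surv$event_age_weeks)
    ll <- 0
    at_risk <- rep(TRUE, 4)
    for (i in ord) {
      ll <- ll + b * x[i] - log(sum(risk[at_risk]))
      at_risk[i] <- FALSE
    }
    ll
  }, numeric(1))
  expect_equal(unname(fit$coefficients), grid[which.max(pl)],
               tolerance = 1e-3)
  # linear predictor is the centered dot product
  expect_equal(fit$linear_predictor,
               as.numeric((x - mean(x)) * fit$coefficients))

  # null covariate: CI covers zero
  set.seed(40)
  survn <- data.frame(event_age_weeks = rexp(300, 0.02) + 1,
                      observed = rbinom(300, 1, 0.8))
  xn <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "noise"))
  fn <- cox_ph(xn, survn)
  expect_lt(abs(fn$coefficients[1]), 2.5 * fn$se[1])
  expect_error(cox_ph(matrix(1, 300, 1), survn), "constant")
})

test_that("proportional-hazards simulation is recovered", {
  set.seed(50)
  n <- 800
  x <- rnorm(n)
  t <- rexp(n, rate = 0.02 * exp(1 * x))
  surv <- data.frame(event_age_weeks = t, observed = 1L)
  fit <- cox_ph(matrix(x, ncol = 1, dimnames = list(NULL, "z")), surv)
  expect_lt(abs(fit$coefficients[1] - 1), 1.96 * fit$se[1] + 0.05)
})

test_that("lifespan rank correlation per cohort, with midrank ties", {
  # perfect inverse ordering
  sc <- data.frame(animal_id = letters[1:10],
                   dfi_age_adjusted = 1:10)
  sv <- data.frame(animal_id = letters[1:10], event_age_weeks = 10:1,
                   observed = 1L)
  res <- lifespan_rank_correlation(sc, sv, min_n = 5)
  expect_equal(res$rho, -1)

  # hand-built 5-animal ranking with one tie (midranks)
  sc2 <- data.frame(animal_id = letters[1:5],
                    dfi_age_adjusted = c(1, 2, 2, 4, 5))
  sv2 <- data.frame(animal_id = letters[1:5],
                    event_age_weeks = c(9, 8, 7, 6, 5), observed = 1L)
  res2 <- lifespan_rank_correlation(sc2, sv2, min_n = 5)
  manual <- cor(rank(c(1, 2, 2, 4, 5)), rank(c(9, 8, 7, 6, 5)))
  expect_equal(res2$rho, manual)

  # cohorts below the size floor are skipped
  sc3 <- rbind(cbind(sc, sex = "M", age_weeks = 26),
               data.frame(animal_id = "zz", dfi_age_adjusted = 1,
                          sex = "F", age_weeks = 26))
  expect_message(res3 <- lifespan_rank_correlation(
    sc3, rbind(sv, data.frame(animal_id = "zz", event_age_weeks = 4,
                              observed = 1L)), min_n = 5), "skipped")
  expect_equal(nrow(res3), 1L)
})
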