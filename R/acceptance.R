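# Internal drivers for the acceptance surface: each function rebuilds its
# scenario from scratch (generator -> method -> measurement) so that the
# test suite and scripts/acceptance.R exercise identical code paths.

# criterion 1: dialect harmonization round trip
acc_harmonize_roundtrip <- function(seed) {
  full <- generate_cohort(cohort_config(n_per_strain_sex = 40, seed = seed))
  nog <- generate_cohort(cohort_config(n_per_strain_sex = 40, seed = seed,
                                       emit_granulocytes = FALSE))
  m_full <- assemble_matrix(derive_granulocytes(full$cohort))
  m_nog <- assemble_matrix(derive_granulocytes(nog$cohort))
  list(n_features = ncol(m_nog$values),
       max_abs_diff = max(abs(m_nog$values - m_full$values)))
}

# criterion 2: SDE cohort vs the closed-form survival and hazard plateau
acc_sde_selfconsistency <- function(seed, n = 20000, alpha = 0.05,
                                    z_bar = 0.1, log_ratio = 3,
                                    step = 0.01, horizon = 220,
                                    bandwidth = 10) {
  ratio <- exp(log_ratio)
  p <- langevin_params(alpha, g = alpha / (z_bar * ratio),
                       noise_power = 2 * alpha * z_bar^2, z_init = 0)
  sim <- simulate_latent_cohort(p, n, horizon = horizon, step = step,
                                seed = seed)
  dead <- sort(sim$death_time[!is.na(sim$death_time)])
  m <- length(dead)
  ks_at <- function(r) {
    Fth <- 1 - analytic_survival(p, r, dead)
    max(pmax(abs(Fth - seq_len(m) / m), abs(Fth - (seq_len(m) - 1) / m)))
  }
  opt <- stats::optimize(ks_at, c(2, 400))
  surv <- data.frame(
    event_age_weeks = ifelse(is.na(sim$death_time), horizon, sim$death_time),
    observed = as.integer(!is.na(sim$death_time)))
  hz <- nelson_aalen_hazard(surv, bandwidth = bandwidth)
  t_bar <- mean_lifespan(p, ratio)
  n_risk <- stats::approx(hz$events$time, hz$events$n_risk,
                          hz$smooth$time, rule = 2)$y
  sel <- hz$smooth$time > t_bar + 2 / alpha & n_risk >= 500
  h <- hz$smooth$hazard[sel]
  list(n_deaths = m, fitted_ratio = opt$minimum, ks = opt$objective,
       hazard_max_rel_dev = max(abs(h - alpha)) / alpha,
       hazard_window_mean_ratio = mean(h) / alpha)
}

# criterion 3: AE-AR parameter recovery over several seeds
acc_aear_recovery <- function(seed, n_seeds = 5, n_per_strain_sex = 500,
                              alpha = 0.03, epochs = 600,
                              steps_per_epoch = 16L, holdout = 0.2) {
  seeds <- derive_seeds(seed, 2L * n_seeds)
  lp <- langevin_params(alpha = alpha, g = 0,
                        noise_power = 2 * alpha * 0.1^2, z_init = 0)
  per_seed <- lapply(seq_len(n_seeds), function(i) {
    coh <- generate_cohort(cohort_config(n_per_strain_sex = n_per_strain_sex,
                                         langevin = lp, seed = seeds[i]))
    fm <- assemble_matrix(derive_granulocytes(coh$cohort))
    ids <- unique(fm$row_keys$animal_id)
    test_ids <- with_seed(seeds[n_seeds + i],
                          sample(ids, round(holdout * length(ids))))
    is_test <- fm$row_keys$animal_id %in% test_ids
    fm_train <- structure(list(values = fm$values[!is_test, , drop = FALSE],
                               row_keys = fm$row_keys[!is_test, ],
                               dropped_fraction = 0),
                          class = "feature_matrix")
    fm_test <- structure(list(values = fm$values[is_test, , drop = FALSE],
                              row_keys = fm$row_keys[is_test, ],
                              dropped_fraction = 0),
                         class = "feature_matrix")
    cfg <- aear_config(seed = seeds[n_seeds + i], epochs = epochs,
                       steps_per_epoch = steps_per_epoch)
    pairs <- make_pairs(fm_train, interval = cfg$pair_interval,
                        tolerance = cfg$pair_tolerance)
    model <- train_aear(build_model(cfg), fm_train, pairs,
                        ages = fm_train$row_keys$age_weeks)
    truth <- merge(cbind(fm_test$row_keys, dfi = score_dfi(model, fm_test)$dfi),
                   coh$latent, by = c("animal_id", "age_weeks"))
    c(alpha_hat = ar_exponent(model),
      corr = abs(stats::cor(truth$dfi, truth$z_true)),
      ab = sum(model$params$A %*% model$params$B))
  })
  res <- do.call(rbind, per_seed)
  list(per_seed = res,
       median_alpha_rel_err = stats::median(abs(res[, "alpha_hat"] - alpha) / alpha),
       median_corr = stats::median(res[, "corr"]))
}

# criterion 4: PCA recovery against the linearised generator truth
acc_pca_recovery <- function(seed, n_per_sex = 2500, alpha = 0.03,
                             z_bar = 0.1) {
  lp <- langevin_params(alpha = alpha, g = 0,
                        noise_power = 2 * alpha * z_bar^2, z_init = 0)
  cc <- cohort_config(strains = list(S1 = c()), n_per_strain_sex = n_per_sex,
                      langevin = lp, censor_rate = 0,
                      sex_offset = c("RBC" = 0), seed = seed)
  coh <- generate_cohort(cc)
  fm <- assemble_matrix(strain_center(derive_granulocytes(coh$cohort)))
  pc <- fit_pca(fm, standardize = FALSE)
  b_eff <- effective_loadings(cc)
  cosine <- abs(sum(pc$loadings[, 1] * b_eff)) /
    sqrt(sum(b_eff^2) * sum(pc$loadings[, 1]^2))
  # parametric oracle: top eigenvalue share of J b b' J' var(z) + J S J'
  J <- feature_jacobian(cc)
  var_z <- mean(z_bar^2 * (exp(2 * alpha * cc$visit_ages) - 1))
  S <- tcrossprod(J %*% cc$loadings[GEN_CHANNELS]) * var_z +
    J %*% diag(cc$feature_noise_sd[GEN_CHANNELS]^2) %*% t(J)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  list(cosine = cosine, pc1_fraction = pc$variance_fraction[1],
       pc1_fraction_expected = ev[1] / sum(ev))
}

# criterion 5: Gompertz MLE recovery at the published parameter scale
acc_gompertz_recovery <- function(seed, n = 5000, M0 = 4.1e-4,
                                  alpha_g = 0.0385) {
  t <- with_seed(seed, {
    u <- stats::runif(n)
    log(1 - alpha_g * log(u) / M0) / alpha_g
  })
  fit <- fit_gompertz(data.frame(event_age_weeks = t, observed = 1L))
  list(M0_hat = fit$M0, alpha_hat = fit$alpha_g,
       M0_rel_err = abs(fit$M0 - M0) / M0,
       alpha_rel_err = abs(fit$alpha_g - alpha_g) / alpha_g)
}

# criterion 6: increment-test calibration and effect recovery
acc_increment_calibration <- function(seed, null_reps = 2000,
                                      effect_reps = 500, J = -0.5,
                                      n_treated = 36, n_untreated = 204) {
  flag <- rep(c(TRUE, FALSE), c(n_treated, n_untreated))
  one <- function(shift) {
    d <- stats::rnorm(n_treated + n_untreated)
    d[flag] <- d[flag] + shift
    rec <- data.frame(animal_id = "x", t_start = 1, t_end = 2,
                      delta_dfi = d, treated_interval = flag)
    increment_test(rec)
  }
  with_seed(seed, {
    pvals <- replicate(null_reps, one(0)$p)
    effects <- replicate(effect_reps, one(J)$effect)
    list(type1_rate = mean(pvals < 0.05),
         J_hat = mean(effects),
         J_rel_bias = abs(mean(effects) - J) / abs(J))
  })
}
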