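# Canonical harmonized CBC feature set (fixed column order of FeatureMatrix)
# Units: counts in 10^3/uL (WBC, LY, GR, PLT), RBC in 10^6/uL, HB/MCHC in
# g/dL, MCV in fL, MCH in pg, differentials in %.
CBC_FEATURES <- c("GR%", "GR", "HB", "HCT%", "LY%", "LY",
                  "MCHC", "MCH", "MCV", "PLT", "RBC", "WBC")

# Channels generated directly from the latent state (everything else --
# WBC and the differentials -- is derived from these for consistency).
GEN_CHANNELS <- c("LY", "GR", "MO", "RBC", "HB", "HCT%", "MCV", "MCH",
                  "MCHC", "PLT")

default_baseline <- function() {
  c("LY" = 5.5, "GR" = 1.8, "MO" = 0.35, "RBC" = 9.3, "HB" = 14.5,
    "HCT%" = 45, "MCV" = 48.5, "MCH" = 15.5, "MCHC" = 32, "PLT" = 900)
}

# aging directions per dFI-unit: lymphopenia and myeloid skew of the white
# lineage, mild anemia with rising cell volume, thrombocytosis
default_loadings <- function() {
  c("LY" = -0.9, "GR" = 0.5, "MO" = 0.1, "RBC" = -0.35, "HB" = -0.5,
    "HCT%" = -1.5, "MCV" = 1.2, "MCH" = 0.35, "MCHC" = -0.3, "PLT" = 80)
}

# per-visit measurement noise, roughly 5-8% of baseline (analyzer-scale CVs)
default_noise_sd <- function() {
  c("LY" = 0.8, "GR" = 0.4, "MO" = 0.05, "RBC" = 0.3, "HB" = 0.45,
    "HCT%" = 1.4, "MCV" = 1.0, "MCH" = 0.3, "MCHC" = 0.35, "PLT" = 70)
}

#' Configuration of the synthetic CBC cohort generator
#'
#' Describes the stated world the generator emulates: multi-strain cohorts
#' with strain-specific CBC baselines, one shared latent order parameter per
#' animal following the critical-dynamics Langevin model, linear feature
#' loadings plus independent per-channel measurement noise, a fixed visit
#' schedule, deaths from finite-time blow-up of the latent state, and an
#' independent exponential censoring clock.
#'
#' Ten channels are generated directly (`LY`, `GR`, `MO`, `RBC`, `HB`,
#' `HCT%`, `MCV`, `MCH`, `MCHC`, `PLT`); `WBC = LY + GR + MO` and the
#' differentials (`LY%`, `GR%`, `MO%` as shares of WBC) are derived, so the
#' granulocyte-derivation identities hold exactly in the noiseless limit.
#'
#' @param strains named list of per-strain baseline offsets added to the
#'   default baseline (each a named vector over a subset of [GEN_CHANNELS]);
#'   the names are the strain labels.
#' @param n_per_strain_sex animals per strain and sex.
#' @param loadings named vector b over the generated channels, CBC units per
#'   dFI-unit.
#' @param feature_noise_sd named non-negative vector of per-channel noise SDs.
#' @param langevin a [langevin_params()] object for the shared latent
#'   dynamics (default: alpha = 0.02/wk, lifespan scale 100 wk,
#'   z_bar = 0.1, starting at z(0) = z_bar).
#' @param visit_ages strictly increasing vector of scheduled visit ages (wk).
#' @param pair_interval nominal longitudinal sampling interval, weeks.
#' @param emit_granulocytes,emit_monocytes emit the GR/GR% (MO/MO%) columns;
#'   suppressing granulocytes produces the table dialect that exercises the
#'   derivation formulas downstream.
#' @param warp optional monotone per-feature distortion: a list with
#'   `strength` (>= 0) and optionally `features` (channel names); each warped
#'   channel x is mapped through x + strength * d^3 / (3 c^2), d = x - mu,
#'   c = |b| + sigma. Identity when `NULL`.
#' @param sex_offset named vector added to male baselines (default: slightly
#'   higher RBC and HB in males).
#' @param censor_rate rate (1/week) of the independent exponential censoring
#'   clock; 0 disables random censoring.
#' @param step Euler-Maruyama step, weeks.
#' @param seed integer master seed.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(strains = list(B6 = c("RBC" = 0.2),
                                         SWR = c("LY" = -0.4, "PLT" = 40),
                                         D2 = c("HB" = -0.4, "MCV" = 1.0)),
                          n_per_strain_sex = 25,
                          loadings = default_loadings(),
                          feature_noise_sd = default_noise_sd(),
                          langevin = langevin_params(alpha = 0.02,
                                                     g = 0.02 / (0.1 * exp(2)),
                                                     noise_power = 4e-4,
                                                     z_init = 0.1),
                          visit_ages = c(26, 52, 78, 104),
                          pair_interval = 26,
                          emit_granulocytes = TRUE,
                          emit_monocytes = TRUE,
                          warp = NULL,
                          sex_offset = c("RBC" = 0.15, "HB" = 0.3),
                          censor_rate = 0.001,
                          step = 0.01,
                          seed = 1L) {
  b <- default_loadings(); b[names(loadings)] <- loadings
  s <- default_noise_sd(); s[names(feature_noise_sd)] <- feature_noise_sd
  if (any(s < 0)) stop("feature noise SDs must be >= 0")
  if (length(visit_ages) > 1 && is.unsorted(visit_ages, strictly = TRUE))
    stop("`visit_ages` must be strictly increasing")
  stopifnot(inherits(langevin, "langevin_params"))
  base <- default_baseline()
  z_bar <- langevin_scales(langevin)$z_bar
  if (!is.finite(z_bar)) z_bar <- 0
  for (nm in names(strains)) {
    mu <- base; off <- strains[[nm]]; mu[names(off)] <- mu[names(off)] + off
    bad <- mu - 5 * abs(b) * z_bar < 0
    if (any(bad))
      stop(sprintf("strain '%s': baseline of %s goes negative at 5 latent SDs",
                   nm, paste(names(mu)[bad], collapse = ", ")))
  }
  if (!is.null(warp)) {
    if (is.null(warp$strength) || warp$strength < 0)
      stop("warp$strength must be >= 0")
    if (is.null(warp$features)) warp$features <- GEN_CHANNELS
  }
  structure(list(strains = strains, n_per_strain_sex = n_per_strain_sex,
                 loadings = b, feature_noise_sd = s, langevin = langevin,
                 visit_ages = visit_ages, pair_interval = pair_interval,
                 emit_granulocytes = emit_granulocytes,
                 emit_monocytes = emit_monocytes, warp = warp,
                 sex_offset = sex_offset, censor_rate = censor_rate,
                 step = step, seed = as.integer(seed)),
            class = "cohort_config")
}

strain_baseline <- function(config, strain, sex) {
  mu <- default_baseline()
  off <- config$strains[[strain]]
  mu[names(off)] <- mu[names(off)] + off
  if (sex == "M") mu[names(config$sex_offset)] <-
      mu[names(config$sex_offset)] + config$sex_offset
  mu
}

#' Linearised loadings of the 12 harmonized features
#'
#' The generator is linear in the latent state for the ten generated
#' channels; `WBC` and the differentials are smooth functions of them.  This
#' returns the exact first-order (at z = 0, averaged over strains and sexes)
#' loading vector of the canonical 12-feature set -- the ground truth against
#' which PCA/AE loading recovery is judged.
#'
#' @param config a [cohort_config()] object.
#' @return named numeric vector over [CBC_FEATURES].
#' @export
effective_loadings <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  J <- feature_jacobian(config)
  drop(J %*% config$loadings[GEN_CHANNELS])
}

# Jacobian of the 12 canonical features with respect to the ten generated
# channels, at the pooled baseline (z = 0).  Derived rows: WBC is the sum of
# the white counts; the differentials are 100 * count / WBC.
feature_jacobian <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  combos <- expand.grid(strain = names(config$strains), sex = c("F", "M"),
                        stringsAsFactors = FALSE)
  mus <- t(mapply(function(st, sx) strain_baseline(config, st, sx),
                  combos$strain, combos$sex))
  mu <- colMeans(mus); names(mu) <- GEN_CHANNELS
  W <- mu[["LY"]] + mu[["GR"]] + mu[["MO"]]
  J <- matrix(0, length(CBC_FEATURES), length(GEN_CHANNELS),
              dimnames = list(CBC_FEATURES, GEN_CHANNELS))
  for (ch in c("GR", "HB", "HCT%", "LY", "MCHC", "MCH", "MCV", "PLT", "RBC"))
    J[ch, ch] <- 1
  J["WBC", c("LY", "GR", "MO")] <- 1
  for (ch in c("LY", "GR")) {
    row <- paste0(ch, "%")
    J[row, c("LY", "GR", "MO")] <- -100 * mu[[ch]] / W^2
    J[row, ch] <- 100 * (W - mu[[ch]]) / W^2
  }
  J
}

apply_warp <- function(x, mu, scale, strength) {
  d <- x - mu
  x + strength * d^3 / (3 * scale^2)
}

#' Generate a synthetic CBC cohort
#'
#' Per animal: one latent order-parameter trajectory (shared Langevin
#' parameters), CBC records at the scheduled visit ages while the animal is
#' alive and on study, built as strain/sex baseline + loadings * z + noise
#' (optionally warped, with the differentials then recomputed from the
#' warped counts), and a death/censoring record.  The true latent value per
#' visit is returned for oracle testing only.
#'
#' @param config a [cohort_config()] object.
#' @param horizon optional simulation horizon (weeks); defaults to the
#'   lifespan scale plus six e-folding times when deaths are possible,
#'   otherwise just past the last visit.
#' @return a `dfi_cohort` list: `cohort` (CohortTable data frame),
#'   `survival` (SurvivalTable data frame: animal_id, event_age_weeks,
#'   observed), `latent` (animal_id, age_weeks, z_true), and the config.
#' @examples
#' cc <- cohort_config(n_per_strain_sex = 5, seed = 42)
#' coh <- generate_cohort(cc)
#' head(coh$cohort)
#' @export
generate_cohort <- function(config, horizon = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  lp <- config$langevin
  sc <- langevin_scales(lp)
  if (is.null(horizon)) {
    horizon <- if (is.finite(sc$t_bar) && lp$alpha > 0)
      sc$t_bar + 6 / lp$alpha else max(config$visit_ages) + 1
    horizon <- max(horizon, max(config$visit_ages) + 1)
  }
  combos <- expand.grid(sex = c("F", "M"), strain = names(config$strains),
                        stringsAsFactors = FALSE)[, c("strain", "sex")]
  n_group <- config$n_per_strain_sex
  n_total <- nrow(combos) * n_group
  seeds <- derive_seeds(config$seed, 3L)

  lat <- simulate_latent_cohort(lp, n_total, visit_ages = config$visit_ages,
                                horizon = horizon, step = config$step,
                                seed = seeds[1L])
  censor <- if (config$censor_rate > 0)
    with_seed(seeds[2L], stats::rexp(n_total, rate = config$censor_rate))
  else rep(Inf, n_total)
  end_of_study <- max(config$visit_ages) + config$pair_interval

  ids <- sprintf("A%05d", seq_len(n_total))
  strain <- rep(combos$strain, each = n_group)
  sex <- rep(combos$sex, each = n_group)
  death <- lat$death_time
  end <- pmin(ifelse(is.na(death), Inf, death), censor, end_of_study)
  observed <- as.integer(!is.na(death) & death <= pmin(censor, end_of_study))

  # long-format visit rows for animals alive and on study at the visit
  nv <- length(config$visit_ages)
  on_study <- outer(end, config$visit_ages, ">") & !is.na(lat$z)
  row_animal <- rep(seq_len(n_total), times = nv)[as.vector(on_study)]
  row_visit <- rep(seq_len(nv), each = n_total)[as.vector(on_study)]
  z_vis <- lat$z[cbind(row_animal, row_visit)]
  n_rows <- length(row_animal)

  mu_mat <- t(mapply(function(st, sx) strain_baseline(config, st, sx),
                     strain[row_animal], sex[row_animal]))
  noise <- with_seed(seeds[3L],
                     matrix(stats::rnorm(n_rows * length(GEN_CHANNELS)),
                            n_rows, length(GEN_CHANNELS)))
  noise <- sweep(noise, 2L, config$feature_noise_sd[GEN_CHANNELS], "*")
  X <- mu_mat + outer(z_vis, config$loadings[GEN_CHANNELS]) + noise
  colnames(X) <- GEN_CHANNELS

  if (!is.null(config$warp)) {
    sc_w <- abs(config$loadings) + config$feature_noise_sd
    for (ch in intersect(config$warp$features, GEN_CHANNELS))
      X[, ch] <- apply_warp(X[, ch], mu_mat[, ch], sc_w[[ch]],
                            config$warp$strength)
  }

  wbc <- X[, "LY"] + X[, "GR"] + X[, "MO"]
  tab <- data.frame(animal_id = ids[row_animal], strain = strain[row_animal],
                    sex = sex[row_animal],
                    age_weeks = config$visit_ages[row_visit],
                    check.names = FALSE)
  tab[["WBC"]] <- wbc
  tab[["LY"]] <- X[, "LY"]; tab[["LY%"]] <- 100 * X[, "LY"] / wbc
  tab[["GR"]] <- X[, "GR"]; tab[["GR%"]] <- 100 * X[, "GR"] / wbc
  tab[["MO"]] <- X[, "MO"]; tab[["MO%"]] <- 100 * X[, "MO"] / wbc
  tab[["RBC"]] <- X[, "RBC"]; tab[["HB"]] <- X[, "HB"]
  tab[["HCT%"]] <- X[, "HCT%"]; tab[["MCV"]] <- X[, "MCV"]
  tab[["MCH"]] <- X[, "MCH"]; tab[["MCHC"]] <- X[, "MCHC"]
  tab[["PLT"]] <- X[, "PLT"]
  if (!config$emit_granulocytes) tab[["GR"]] <- tab[["GR%"]] <- NULL
  if (!config$emit_monocytes) tab[["MO"]] <- tab[["MO%"]] <- NULL
  tab <- tab[order(tab$animal_id, tab$age_weeks), , drop = FALSE]
  rownames(tab) <- NULL

  surv <- data.frame(animal_id = ids,
                     event_age_weeks = ifelse(is.finite(end), end,
                                              end_of_study),
                     observed = observed)
  latent <- data.frame(animal_id = ids[row_animal],
                       age_weeks = config$visit_ages[row_visit],
                       z_true = z_vis)
  latent <- latent[order(latent$animal_id, latent$age_weeks), , drop = FALSE]
  rownames(latent) <- NULL
  structure(list(cohort = tab, survival = surv, latent = latent,
                 config = config),
            class = "dfi_cohort")
}

#' Write a generated cohort to CSV files plus a sidecar config JSON
#'
#' @param cohort a `dfi_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             survival = file.path(dir, "survival.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(cohort$cohort, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(cohort$survival, paths[["survival"]], row.names = FALSE)
  cfg <- cohort$config
  cfg$langevin <- unclass(cfg$langevin)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
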