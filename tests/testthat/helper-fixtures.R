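# Shared fixtures: small cohorts built in code (no stored data).

linear_langevin <- function(alpha = 0.03, z_bar = 0.1, z_init = 0) {
  langevin_params(alpha = alpha, g = 0, noise_power = 2 * alpha * z_bar^2,
                  z_init = z_init)
}

# cohort with finite lifespans: alpha * t_bar = 2 by default
mortal_langevin <- function(alpha = 0.02, z_bar = 0.1, log_ratio = 2,
                            z_init = z_bar) {
  Z <- z_bar * exp(log_ratio)
  langevin_params(alpha = alpha, g = alpha / Z,
                  noise_power = 2 * alpha * z_bar^2, z_init = z_init)
}

small_cohort <- function(n_per_strain_sex = 30, seed = 101, ...) {
  generate_cohort(cohort_config(n_per_strain_sex = n_per_strain_sex,
                                seed = seed, ...))
}

harmonized <- function(cohort) assemble_matrix(derive_granulocytes(cohort$cohort))

# merge scored dFI with the generator's latent truth
dfi_vs_truth <- function(model, fm, cohort) {
  sc <- score_dfi(model, fm)
  merge(cbind(fm$row_keys, dfi = sc$dfi), cohort$latent,
        by = c("animal_id", "age_weeks"))
}
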