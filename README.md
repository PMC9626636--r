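# dfiage

Quantitative aging analysis for longitudinal complete-blood-count (CBC)
panels, built on a critical-dynamics model of the organism state.  The
package is aimed at researchers analysing rodent aging cohorts (phenome
databases, lifespan experiments, intervention studies) who want a single
dynamic frailty score with an explicit equation of motion behind it.

## The model in one paragraph

The organism state is summarized by a scalar order parameter $z$ obeying the
Langevin equation

$$\dot z = \alpha z + g z^2 + f, \qquad \langle f(t)f(t')\rangle = B\,\delta(t-t'),$$

with stiffness $\alpha > 0$ (the system sits past a tipping point, so small
deviations grow exponentially) and a quadratic term that drives a
finite-time blow-up — death — once $z \gtrsim Z = \alpha/g$.  The model
yields closed forms: survival
$S(t) = \operatorname{Erf}(Z/\bar z\; e^{-\alpha t})$ with
$\bar z = \sqrt{B/2\alpha}$, a hazard that saturates at the late-life
plateau $M(t \gg \bar t) \approx \alpha$, and a mean-lifespan scale
$\bar t = \log(Z/\bar z)/\alpha$.  CBC features track the latent state
linearly, $x_i \approx b_i z + \xi_i$.  The **dynamic frailty indicator
(dFI)** estimates $z$ from the 12-feature CBC panel with a coupled
autoencoder–autoregression network: an autoencoder compresses the panel to
a 4-dimensional bottleneck, a linear projector reads off the scalar dFI,
and a linear autoregression $z_{n+1} = r z_n + z'$ ties same-animal visits
$\Delta t = 26$ weeks apart, so that $\log(\hat r)/\Delta t$ recovers
$\alpha$.

What the package provides, per module:

* `langevin_params()`, `simulate_trajectory()`, `simulate_latent_cohort()`,
  `analytic_survival()`, `analytic_hazard()`, `mean_lifespan()`,
  `predicted_covariance()` — the stochastic model, its closed forms, and a
  vectorised Euler–Maruyama simulator with blow-up deaths.
* `cohort_config()`, `generate_cohort()` — a synthetic multi-strain CBC
  cohort generator (the validation harness: latent trajectories, strain
  baselines, visit schedules, deaths, censoring, dialect flags, optional
  monotone warp).
* `derive_granulocytes()`, `strain_center()`, `filter_adult()`,
  `assemble_matrix()` — CBC harmonization across table dialects.
* `fit_pca()`, `pc_age_stats()`, `cluster_features()` — PCA diagnostics.
* `aear_config()`, `build_model()`, `train_aear()`, `score_dfi()`,
  `age_adjust_dfi()`, `fit_growth_exponent()`, `dfi_autocorrelation()`,
  `evaluate_reconstruction()`, `save_model()`/`load_model()` — the AE–AR
  network (hand-written backprop, C++ kernels, no deep-learning framework).
* `build_censoring()`, `fit_gompertz()`, `kaplan_meier()`,
  `nelson_aalen_hazard()`, `plateau_check()`, `cox_ph()`,
  `lifespan_rank_correlation()` — mortality analytics.
* `stratified_randomize()`, `dfi_increments()`, `increment_test()` —
  longitudinal intervention analysis on dFI increments.
* `dfi_cli()` (plus `inst/scripts/dfiage`) — a command-line surface:
  `simulate-cohort`, `harmonize`, `pca`, `train`, `score`, `fit-gompertz`,
  `hazard`, `lifespan-corr`, `intervention`.

## Worked example

Simulate a cohort, train the dFI, and recover the latent dynamics:

```r
library(dfiage)

# a linear-regime world: alpha = 0.03/wk, no deaths, visits every 26 wk
lp  <- langevin_params(alpha = 0.03, g = 0, noise_power = 2 * 0.03 * 0.1^2)
coh <- generate_cohort(cohort_config(n_per_strain_sex = 500, langevin = lp,
                                     censor_rate = 0, seed = 11))
fm  <- assemble_matrix(derive_granulocytes(coh$cohort))

pairs <- make_pairs(fm, interval = 26, tolerance = 4)
model <- train_aear(build_model(aear_config(seed = 21)), fm, pairs,
                    ages = fm$row_keys$age_weeks)
model
#> AE-AR model: 12 -> 4 latent, width 32, 2 ResNet blocks/arm (trained)
#>   r = 1.9765 (ln r / dt = 0.0262 /wk), z' = 0.1739, A.B = 1.0001

scores <- score_dfi(model, fm)
truth  <- merge(cbind(fm$row_keys, dfi = scores$dfi), coh$latent,
                by = c("animal_id", "age_weeks"))
cor(truth$dfi, truth$z_true)
#> [1] 0.9738047
```

The autoregression coefficient `r = 1.98` over $\Delta t = 26$ weeks gives
`ln(r)/26 = 0.026` per week against the generator's true stiffness 0.030
(least-squares AR fits on noisy scores are attenuated; the bias stays well
inside the 20% recovery tolerance), and the scored dFI correlates at 0.97
with the latent state it never saw.

Mortality side, at the published parameter scale:

```r
set.seed(1)
M0 <- 4.1e-4; a <- 0.0385                    # per week
t  <- log(1 - a * log(runif(5000)) / M0) / a  # Gompertz death ages
fit_gompertz(data.frame(event_age_weeks = t, observed = 1L))
#> Gompertz fit: M0 = 0.00044 /wk (se 2.2e-05), alpha = 0.03762 /wk (se 0.00046)
#>   mean lifespan 104.4 wk, 5000 events
```

Both parameters land within two standard errors of the truth (the baseline
hazard `M0` and the exponent are strongly anti-correlated in the
likelihood, so `M0`'s marginal error is the larger of the two).

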