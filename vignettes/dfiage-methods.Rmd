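---
title: "Modelling aging as critical dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aging as critical dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dfiage` treats aging as the dynamics of a complex regulatory network poised
just past a tipping point.  Near such a (saddle-node) instability a single
collective mode dominates the slow dynamics, and the organism state can be
summarized by one scalar order parameter $z$ obeying the Langevin equation

$$\dot z = \alpha z + g z^2 + f, \qquad
  \langle f(t) f(t') \rangle = B\,\delta(t - t'),$$

with stiffness $\alpha$ (1/week), lowest-order nonlinearity $g$, and white
noise of power $B$.  For $\alpha > 0$ there is no equilibrium: deviations
from the youthful state are amplified exponentially, and once
$z \gtrsim Z = \alpha/g$ the quadratic term drives a finite-time blow-up,
which the model identifies with death.  Three derived scales organise
everything:

* $Z = \alpha/g$ — where the nonlinearity takes over;
* $\bar z = \sqrt{B/2\alpha}$ — the amplitude the noise builds up before
  exponential growth dominates (from
  $\langle z^2 \rangle \approx (B/2\alpha) e^{2\alpha t}$);
* $\bar t = \log(Z/\bar z)/\alpha$ — the mean-lifespan scale.

Closed forms implemented in `analytic_survival()`, `analytic_hazard()` and
`mean_lifespan()`: survival is
$S(t) = \operatorname{Erf}\!\big(\rho\,e^{-\alpha t}\big)$ with the single
dimensionless scale $\rho = Z/\bar z$, and the hazard $M = -\dot S/S$ rises
monotonically to the plateau $M(t \gg \bar t) \to \alpha$ — late-life
mortality *deceleration*, the model's sharpest departure from the Gompertz
law $M = M_0 e^{\alpha_g t}$.  Because the theory fixes only the order of
magnitude of $\bar z$, $\rho$ is treated as a free scale when matching
empirical survival; we fix the constant as $\bar z = \sqrt{B/2\alpha}$
internally so that the derived scales are reproducible numbers.

Feature panels enter through a linear observation model
$x_i \approx b_i z + \xi_i$: every complete-blood-count (CBC) feature tracks
the same latent mode with loading $b_i$ plus channel noise.  The implied
covariance $b_i b_j (B/2\alpha) e^{2\alpha t}$ is rank-1 and grows
exponentially with age (`predicted_covariance()`), which is why the first
principal component approximates the order parameter and why PC-score
variance growing with age is the signature of a stochastic latent process.

## The estimator: a coupled autoencoder–autoregression network

PCA is linear and noisy panels need regularization, so the package estimates
$z$ with a small network (`build_model()`, `train_aear()`): an autoencoder
(12 CBC features $\to$ 4-dimensional bottleneck $y$, mirrored decoder, dense
layers plus residual blocks of two leaky-ReLU dense layers with a skip
connection), a linear projector $z = A y$ whose output is the **dynamic
frailty indicator (dFI)**, scalar linear dynamics
$z_{n+1} = r z_n + z'$ tying same-animal visits one sampling interval
$\Delta t$ apart, and a lift $y = B z$ feeding the shared decoder.  The loss
is the weighted sum

$$\mathcal L = \alpha_1(\mathcal L_{AE} + \mathcal L_{pred})
  + \alpha_2 \mathcal L_{AR} + \alpha_3 \mathcal L_C
  + \alpha_4 \lVert W \rVert_2^2,$$

with reconstruction, future-state reconstruction, autoregression and
constraint terms; $\mathcal L_C$ enforces $A B = 1$ and unit column norm of
$B$, making $A$ and $B$ left/right eigenvectors of the latent dynamics and
pinning the dFI scale.  Defaults follow the published recipe:
$\alpha_1 = 1$, $\alpha_3 = 100$, $\alpha_4 = 0.01$, $\alpha_2$ ramped
linearly from 0 to 1 (the ramp lets the autoencoder organise its latent
space before the dynamics constraint bites), 600 epochs of Adam at learning
rate $10^{-3}$ dropping to $10^{-4}$ at epoch 400.  The trained $r$
estimates the stiffness through $\hat\alpha = \log(\hat r)/\Delta t$
(`ar_exponent()`), and the dFI sign is fixed by requiring non-negative
correlation with age.

Choices the source recipe leaves open, decided here and recorded in the
configuration:

* **Hidden width 32, 2 residual blocks per arm, leaky slope 0.2.**  The
  block structure is prescribed but not the sizes.  With 12 inputs and a
  4-dimensional bottleneck, 32 units are ample (the parameter-recovery
  suite confirms full recovery), and desk-scale runtime stays in minutes on
  one CPU.
* **Batching.**  Each optimizer step draws one cross-sectional and one
  longitudinal-pair batch of 256 (or the full data if smaller); an epoch is
  capped at `steps_per_epoch = 8` such steps by default.  On the cohort
  sizes used here Adam reaches the same solution as full passes for the
  autoencoder, while the autoregression coefficient converges more slowly —
  the acceptance configuration therefore raises the cap (see
  `scripts/acceptance.R`).  Gradients are clipped at global norm 10.
* **Warm start of the dynamics.**  `(r, z')` are seeded from a regression
  of paired first-PC scores before optimization (`ar_warm_start`).  When
  $\alpha\,\Delta t$ is not small the solution $r = e^{\alpha\Delta t}$ is
  far from the cold start $r = 1$ and converges slowly within the fixed
  600-epoch budget; seeding the linear dynamics from a PCA/DMD-style fit
  is standard practice for Koopman-type models.
* **Denoising.**  The corruption process of the "denoising" autoencoder is
  unspecified in the source; corruption is off by default and available as
  Gaussian noise in scaled units (`corruption_sd`).
* **$R^2$ convention.**  Reconstruction quality reports the standard
  (unbounded-below) $R^2 = 1 - SS_{res}/SS_{tot}$ per feature in original
  units; negative values flag features reconstructed worse than their mean.
* **Gradients.**  Backpropagation is hand-written (dense/ResNet kernels in
  C++ via Rcpp/Armadillo) and unit-tested against finite differences to
  $10^{-5}$; no deep-learning framework is involved.

## Harmonization

CBC table dialects differ; the pipeline (`derive_granulocytes()`,
`strain_center()`, `filter_adult()`, `assemble_matrix()`) reproduces the
preprocessing the estimator expects: granulocytes recovered from the exact
white-cell balance ($GR = WBC - LY - MO$, $GR\% = 100 - LY\% - MO\%$),
strain baselines removed by subtracting each strain's earliest-age mean
(pooling sexes — the centering is indexed by strain only; a sex-specific
variant would be a straightforward extension), records at or below 25 weeks
discarded (early growth is a different phenotype from aging; the threshold
is strictly `> 25`), and records missing any of the 12 canonical features
dropped rather than imputed.  "Earliest age" is the minimal age present per
strain in the data at hand, not a global constant.

## The synthetic cohort generator as a stated world

`generate_cohort()` is first-class, tested code: the harness on which every
downstream module is validated.  It emulates what the method assumes about
real multi-strain phenome-database cohorts:

* one latent trajectory per animal from the Langevin model — defaults
  $\alpha = 0.02$/wk, $\bar z = 0.1$, $\bar t = 100$ wk (so
  $\alpha\bar t = 2$, deterministic drift dominating noise severalfold,
  and lifespans near 100 weeks as in laboratory mice), trajectories started
  at $z(0) = \bar z$;
* strain- and sex-specific CBC baselines at typical murine values (e.g.
  WBC $\approx 7.7\times10^3/\mu L$, RBC $\approx 9.3\times10^6/\mu L$,
  PLT $\approx 900\times10^3/\mu L$; males slightly higher RBC/HB);
* linear loadings encoding known aging directions (lymphopenia with myeloid
  skew, mild anemia with rising corpuscular volume, thrombocytosis) and
  per-channel Gaussian measurement noise at roughly analyzer-scale CVs
  (5–8% of baseline), sized so that one dFI-unit of signal is comparable to
  one visit's noise per channel;
* visits at 26, 52, 78, 104 weeks while alive ($\Delta t = 26$ wk), deaths
  from latent blow-up, and an independent exponential censoring clock
  (default rate 0.001/wk, $\approx$10% lost over a lifespan — a stand-in
  for administrative censoring);
* ten channels are generated directly; WBC and the differentials are
  derived as sums/shares, so the granulocyte identities hold exactly in the
  noiseless limit.  A consequence: the *derived* columns carry noise
  correlated with their parents, so the "rank-1 plus diagonal noise"
  covariance statement holds exactly only on the directly generated
  channels, and loading-recovery oracles use the linearised truth
  `effective_loadings()`.
* an optional monotone cubic warp per feature emulates the nonlinear
  feature–state relations that motivate the autoencoder over PCA.

What a green test does **not** establish: the generator does not reproduce
real MPD marginal distributions feature by feature, batch effects,
assay drift, or non-administrative informative censoring — only the latent
structure the method assumes.  Recovery on this world validates the
estimator's correctness, not its adequacy on any particular real dataset.

## Survival analytics

Gompertz fitting is censored maximum likelihood over
$(\log M_0, \alpha_g)$ with observed-information standard errors — the
exponential limit $\alpha_g \to 0$ lies inside the parameter space, so
constant-hazard data yield a confidence interval covering zero rather than
a boundary failure.  The mean lifespan is the integral of the fitted
survival.  Kaplan–Meier (Greenwood intervals) and Cox proportional hazards
(Efron ties; the per-animal linear predictor is exported as the
`HR_CBC`-style benchmark) are delegated to the `survival` package behind
the module's interfaces, each checked against hand or brute-force oracles
in the tests.  The Nelson–Aalen estimator and its Epanechnikov-kernel
smoothed hazard (default bandwidth 10 wk, boundary-renormalised) are
implemented directly, and `plateau_check()` compares the mean smoothed
hazard over $[\,\bar t + 2/\alpha_g,\ \text{last event}\,]$ to $\alpha_g$
with a delta-method interval — the quantitative form of the
mortality-plateau prediction.

Censoring-record construction follows the measurement-count heuristic:
animals with a recorded death are events; animals with $\ge 2$ CBC
measurements and no death record are censored at the last measurement;
single-measurement animals without a death record are presumed sacrificed
at collection and excluded.

## Intervention analysis

Over one short interval the autoregression coefficient is
$r \approx 1$ ($\alpha\,\Delta t \ll 1$), so a treatment acting as a force
$J$ shifts the per-interval dFI increments
$\Delta\mathrm{dFI} = z(t + \Delta t) - z(t)$ additively.
`increment_test()` compares treated against untreated increments with
Student's pooled-variance two-tailed t test; the untreated pool includes
control animals *and* treated animals after cessation.  Increments are not
age-detrended by default (justified by $r \approx 1$); a cohort-mean
detrend and a per-animal cluster-robust aggregation are available as
sensitivity analyses.  `stratified_randomize()` reproduces the design used
for such experiments: animals sorted by baseline dFI, allocated within
consecutive blocks proportionally to group sizes, shuffled within block.

## Numerical choices and degenerate inputs

* SDE integration is Euler–Maruyama at 0.01 wk by default; a warning fires
  when $\alpha \cdot \text{step} > 0.1$.  Blow-up is detected at the guard
  $z \ge 10Z$: the residual time to the true divergence is below
  $1/(10\alpha)$, negligible on the lifespan scale, and the guard avoids
  floating-point overflow.
* **Negative excursions.**  The quadratic term makes $-Z$ a *stable* fixed
  point, so under an upper-only death rule trajectories that diffuse
  negative park there forever and the simulated hazard collapses instead of
  plateauing — whereas the Erf survival law equals
  $P(|z_{lin}| < Z)$ and counts negative macroscopic deviations as dead.
  The simulator therefore uses a lower *absorbing* (not reflecting:
  early-life negative excursions remain free) level, default $-Z/2$ — the
  point of maximal downward drift, past which the state is committed to the
  degenerate attractor.  This choice reproduces the analytic survival
  (Kolmogorov–Smirnov distance $\approx 0.01$ at $n = 2\times10^4$ after
  fitting the free scale) and the hazard plateau at $\alpha$; absorbing at
  $-Z$ itself would add a large noise-driven first-passage lag because the
  drift vanishes at the fixed point.
* All randomness flows through a saved-and-restored Mersenne-Twister state
  keyed by explicit seeds; derived child seeds stay below $2^{31}$.
* PCA standardizes features to unit variance by default (CBC units are
  incommensurable); the flag is exposed because covariance-PCA is what the
  rank-1 theory addresses.  Component signs are fixed by making the
  largest-magnitude loading positive.  Feature clustering uses
  $1 - |r|$ distance with average linkage; ties resolve deterministically
  by column order.
* The growth-exponent fit profiles the two linear parameters out of
  $\bar z e^{\alpha t} + z_0$, leaving a 1-D search over $\alpha$ — flat
  data then return $\hat\alpha \approx 0$ with an honest (huge) interval
  instead of a convergence failure.  Groups older than the lifespan cutoff
  are excluded because the exponential regime ends near $\bar t$.
* Checkpoints are a JSON manifest plus a CSV of weights at 17 significant
  digits — a text-only, bit-exact round trip.

## Known limitations

* The acceptance surface is property-based on synthetic worlds; headline
  numbers tied to external databases (MPD slices, large published lifespan
  cohorts) require those exports and are not reproduced offline.
* The linear AR model is first-order and scalar by design; when
  $\alpha \bar t \sim 3$ the nonlinearity is only borderline negligible,
  and the latent saturation near death is outside the linear fit's domain
  (hence the lifespan cutoff in the growth fit).
* The increment t test treats repeated increments from one animal as
  independent, mirroring the published analysis; the cluster-robust option
  exists precisely because that assumption is optimistic.
* The advertised advantage of the nonlinear autoencoder over PCA under
  monotone feature warps did **not** reproduce at desk scale: with the
  generator's cubic warp (strengths 2–5, $\le 600$ epochs, $\sim$2,000
  animals) held-out latent correlation of the dFI was comparable to or
  slightly below the first PC score's.  A mild monotone warp hurts both
  estimators about equally, and this small network does not learn the
  inverse warp from these sample sizes.  The comparison is therefore not
  asserted as a test invariant; on linear worlds the two agree, and the
  AE's autoregressive coupling — not nonlinearity — is what improves
  longitudinal persistence.
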