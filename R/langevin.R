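#' Parameters of the one-dimensional critical-dynamics model of aging
#'
#' The organism state is summarised by a scalar order parameter \eqn{z}
#' obeying the Langevin equation \eqn{\dot z = \alpha z + g z^2 + f}, where
#' \eqn{f} is white noise of power \eqn{B}
#' (\eqn{\langle f(t) f(t')\rangle = B\,\delta(t - t')}).  For \eqn{\alpha > 0}
#' the linear term amplifies deviations exponentially; once
#' \eqn{z \gtrsim Z = \alpha/g} the quadratic term drives a finite-time
#' blow-up, interpreted as death.
#'
#' Derived scales (available through [langevin_scales()]):
#' \describe{
#'   \item{Z}{\eqn{\alpha/g}, the nonlinearity scale where blow-up begins.}
#'   \item{z_bar}{\eqn{\sqrt{B/2\alpha}}, the amplitude accumulated by the
#'     noise-driven early phase (from \eqn{\langle z^2\rangle \approx
#'     B e^{2\alpha t}/2\alpha}).}
#'   \item{t_bar}{\eqn{\log(Z/\bar z)/\alpha}, the mean-lifespan scale.}
#' }
#'
#' @param alpha stiffness, 1/week.  Positive values describe an aging
#'   (dynamically unstable) organism.
#' @param g quadratic coupling, 1/(week * dFI-unit); must be >= 0.
#' @param noise_power noise power B, dFI-unit^2/week; must be >= 0.
#' @param z_init initial order parameter, dFI-unit.
#' @return an object of class `langevin_params`.
#' @examples
#' p <- langevin_params(alpha = 0.02, g = 0.027, noise_power = 4e-4)
#' langevin_scales(p)
#' @export
langevin_params <- function(alpha, g = 0, noise_power = 0, z_init = 0) {
  stop_if_not_finite(c(alpha, g, noise_power, z_init), "langevin parameters")
  if (g < 0) stop("`g` must be >= 0")
  if (noise_power < 0) stop("`noise_power` must be >= 0")
  structure(list(alpha = alpha, g = g, noise_power = noise_power,
                 z_init = z_init),
            class = "langevin_params")
}

#' @rdname langevin_params
#' @param params a `langevin_params` object.
#' @export
langevin_scales <- function(params) {
  stopifnot(inherits(params, "langevin_params"))
  Z <- if (params$alpha > 0 && params$g > 0) params$alpha / params$g else NA_real_
  z_bar <- if (params$alpha > 0) sqrt(params$noise_power / (2 * params$alpha)) else NA_real_
  t_bar <- if (is.finite(Z) && is.finite(z_bar) && z_bar > 0 && Z > z_bar)
    log(Z / z_bar) / params$alpha else NA_real_
  list(Z = Z, z_bar = z_bar, t_bar = t_bar)
}

#' @export
print.langevin_params <- function(x, ...) {
  s <- langevin_scales(x)
  cat("Langevin aging model parameters\n")
  cat(sprintf("  alpha = %g /wk, g = %g, B = %g, z(0) = %g\n",
              x$alpha, x$g, x$noise_power, x$z_init))
  cat(sprintf("  Z = %g, z_bar = %g, t_bar = %g wk\n", s$Z, s$z_bar, s$t_bar))
  invisible(x)
}

#' Simulate one order-parameter trajectory
#'
#' Euler--Maruyama integration of \eqn{dz = (\alpha z + g z^2)\,dt +
#' \sqrt{B}\,dW}.  Death is recorded when \eqn{z} crosses the blow-up guard
#' `10 * Z` (a finite proxy for the divergence of the Riccati flow; the
#' remaining time to the true blow-up at that point is below
#' \eqn{1/(10\alpha)}, negligible on the lifespan scale), or an explicit
#' `death_threshold` when supplied.
#'
#' @param params a [langevin_params()] object.
#' @param horizon simulation horizon, weeks (> 0).
#' @param step integration step, weeks (> 0).  A warning is raised when
#'   `step * alpha > 0.1` (accuracy degrades).
#' @param seed integer seed; identical seeds reproduce the trajectory.
#' @param record_every record every k-th step (thins the output grid only).
#' @param death_threshold optional explicit death level overriding the
#'   blow-up guard.
#' @param lower_death lower absorbing level; defaults to `-Z/2` when `Z`
#'   is defined.  Negative excursions past `-Z/2` are committed to the
#'   stable degenerate state at `-Z` (the downward drift peaks at `-Z/2`),
#'   a deviation from the youthful state as macroscopic as the tipping
#'   scale itself, which the closed-form Erf survival counts as death.
#'   Set to `-Inf` to disable.
#' @return a `dfi_trajectory` list: `times`, `z` (recorded while alive),
#'   `death_time` (weeks or `NA`), `death_cause`
#'   (`"blow-up"`, `"threshold"` or `"none"`).
#' @examples
#' p <- langevin_params(alpha = 0.02, g = 0.002, noise_power = 0, z_init = 1)
#' tr <- simulate_trajectory(p, horizon = 150, step = 0.01, seed = 1)
#' tr$death_time # ~ 50 * log(11)
#' @export
simulate_trajectory <- function(params, horizon, step = 0.01, seed = 1L,
                                record_every = 1L, death_threshold = NULL,
                                lower_death = NULL) {
  stopifnot(inherits(params, "langevin_params"))
  if (!is.finite(horizon) || horizon <= 0) stop("`horizon` must be > 0")
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0")
  if (step * abs(params$alpha) > 0.1)
    warning("integration step too large for stability: step * alpha > 0.1")
  guard <- death_guard(params, death_threshold, lower_death)
  n_steps <- ceiling(horizon / step)
  keep <- seq(0L, n_steps, by = as.integer(record_every))
  z <- numeric(length(keep)); z[1L] <- params$z_init
  with_seed(seed, {
    cur <- params$z_init
    sqBdt <- sqrt(params$noise_power * step)
    death_time <- NA_real_
    ki <- 2L
    noise <- params$noise_power > 0
    for (i in seq_len(n_steps)) {
      cur <- cur + step * (params$alpha * cur + params$g * cur^2)
      if (noise) cur <- cur + sqBdt * rnorm(1L)
      if (cur >= guard$level || cur <= guard$lower) {
        death_time <- i * step
        break
      }
      if (ki <= length(keep) && i == keep[ki]) { z[ki] <- cur; ki <- ki + 1L }
    }
    times <- keep[seq_len(ki - 1L)] * step
    structure(list(times = times, z = z[seq_len(ki - 1L)],
                   death_time = death_time,
                   death_cause = if (is.na(death_time)) "none" else guard$cause),
              class = "dfi_trajectory")
  })
}

# Death levels.  Upper: the blow-up guard 10 Z.  Lower: -Z/2 by default.
# The quadratic term creates a *stable* fixed point at -Z, so trajectories
# that diffuse negative would settle there and never die under an
# upper-only rule -- while the closed-form Erf survival counts |z| ~ Z as
# dead on either side (the deviation from the youthful state is equally
# macroscopic).  -Z/2 is where the downward drift peaks; past it the state
# is committed to the degenerate attractor, and absorbing there reproduces
# the analytic survival (KS ~ 0.01) and its hazard plateau at alpha,
# whereas absorbing at -Z itself adds a large noise-driven first-passage
# lag (the flow vanishes at the fixed point) and distorts both.
death_guard <- function(params, death_threshold, lower_death = NULL) {
  Z <- langevin_scales(params)$Z
  lower <- if (!is.null(lower_death)) lower_death
  else if (is.finite(Z)) -Z / 2 else -Inf
  if (!is.null(death_threshold)) {
    if (!is.finite(death_threshold)) stop("`death_threshold` must be finite")
    return(list(level = death_threshold, lower = lower, cause = "threshold"))
  }
  list(level = if (is.finite(Z)) 10 * Z else Inf, lower = lower,
       cause = "blow-up")
}

#' Simulate the latent order parameter for a whole cohort (vectorised)
#'
#' Runs `n` independent Euler--Maruyama trajectories simultaneously,
#' recording the latent state at the requested visit ages and each animal's
#' death time (blow-up guard as in [simulate_trajectory()]).
#'
#' @inheritParams simulate_trajectory
#' @param n number of animals.
#' @param visit_ages ages (weeks) at which to record z; may be empty.
#' @param horizon simulation horizon; defaults to beyond the last visit.
#' @return list with `z` (n x length(visit_ages) matrix, NA after death) and
#'   `death_time` (length-n vector, NA when alive at the horizon).
#' @export
simulate_latent_cohort <- function(params, n, visit_ages = numeric(),
                                   horizon = NULL, step = 0.01, seed = 1L,
                                   death_threshold = NULL,
                                   lower_death = NULL) {
  stopifnot(inherits(params, "langevin_params"), n >= 1)
  if (is.unsorted(visit_ages, strictly = TRUE) && length(visit_ages) > 1)
    stop("`visit_ages` must be strictly increasing")
  if (is.null(horizon))
    horizon <- max(c(visit_ages, 0)) + 1
  if (step * abs(params$alpha) > 0.1)
    warning("integration step too large for stability: step * alpha > 0.1")
  guard <- death_guard(params, death_threshold, lower_death)
  n_steps <- ceiling(horizon / step)
  visit_steps <- as.integer(round(visit_ages / step))
  zmat <- matrix(NA_real_, n, length(visit_ages))
  death <- rep(NA_real_, n)
  with_seed(seed, {
    z <- rep(params$z_init, n)
    alive <- rep(TRUE, n)
    sqBdt <- sqrt(params$noise_power * step)
    vi <- 1L
    if (vi <= length(visit_steps) && visit_steps[vi] == 0L) {
      zmat[alive, vi] <- z[alive]; vi <- vi + 1L
    }
    for (i in seq_len(n_steps)) {
      idx <- which(alive)
      if (!length(idx)) break
      zi <- z[idx]
      zi <- zi + step * (params$alpha * zi + params$g * zi * zi)
      if (sqBdt > 0) zi <- zi + sqBdt * rnorm(length(idx))
      dead <- zi >= guard$level | zi <= guard$lower
      if (any(dead)) {
        death[idx[dead]] <- i * step
        alive[idx[dead]] <- FALSE
      }
      z[idx] <- zi
      if (vi <= length(visit_steps) && i == visit_steps[vi]) {
        zmat[alive, vi] <- z[alive]
        vi <- vi + 1L
      }
    }
    list(z = zmat, death_time = death)
  })
}

#' Analytic mean trajectory of the order parameter
#'
#' In the linear regime the ensemble-averaged deviation from the youthful
#' state grows exponentially: \eqn{z(t) \approx \bar z\,e^{\alpha t} + z_0},
#' where \eqn{\bar z} and \eqn{z_0} summarise the accumulated early random
#' and deterministic effects.
#'
#' @param params a [langevin_params()] object (only `alpha` is used).
#' @param z_bar_fit amplitude scale (a fit parameter), dFI-unit.
#' @param z0 constant offset, dFI-unit.
#' @param t age(s), weeks (>= 0).
#' @return mean order parameter at `t` (vectorised over `t`).
#' @export
analytic_mean_z <- function(params, z_bar_fit, z0, t) {
  stopifnot(inherits(params, "langevin_params"))
  stop_if_not_finite(c(z_bar_fit, z0, t), "arguments")
  if (any(t < 0)) stop("`t` must be >= 0")
  z_bar_fit * exp(params$alpha * t) + z0
}

#' Closed-form survival of the critical-dynamics model
#'
#' The fraction of animals surviving to age \eqn{t} is
#' \eqn{S(t) = \mathrm{Erf}(\rho\, e^{-\alpha t})} with the single
#' dimensionless scale \eqn{\rho = Z/\bar z}.  Because the model fixes only
#' the order of magnitude of \eqn{\bar z}, \eqn{\rho} is treated as a free
#' scale when matching empirical survival.
#'
#' @inheritParams analytic_mean_z
#' @param ratio dimensionless scale \eqn{Z/\bar z} (> 0).
#' @return survival fraction(s) in `[0, 1]`, non-increasing in `t`.
#' @export
analytic_survival <- function(params, ratio, t) {
  stopifnot(inherits(params, "langevin_params"))
  if (!is.finite(ratio) || ratio <= 0) stop("`ratio` must be > 0")
  if (any(t < 0)) stop("`t` must be >= 0")
  erf(ratio * exp(-params$alpha * t))
}

# error function via pnorm
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Hazard (all-cause mortality) of the closed-form survival law
#'
#' \eqn{M(t) = -\dot S/S} for \eqn{S(t) = \mathrm{Erf}(u)},
#' \eqn{u = \rho e^{-\alpha t}}:
#' \deqn{M(t) = \frac{2}{\sqrt\pi}\,\alpha\,u\,e^{-u^2} / \mathrm{Erf}(u).}
#' The hazard is non-decreasing and saturates at the plateau
#' \eqn{M(t \gg \bar t) \to \alpha}: late-life mortality deceleration.
#'
#' @inheritParams analytic_survival
#' @return hazard in 1/week (vectorised over `t`).
#' @export
analytic_hazard <- function(params, ratio, t) {
  stopifnot(inherits(params, "langevin_params"))
  if (!is.finite(ratio) || ratio <= 0) stop("`ratio` must be > 0")
  if (any(t < 0)) stop("`t` must be >= 0")
  u <- ratio * exp(-params$alpha * t)
  h <- params$alpha * (2 / sqrt(pi)) * u * exp(-u^2) / erf(u)
  # u -> 0: M -> alpha (expansion of Erf); avoids 0/0
  h[u < 1e-8] <- params$alpha * (1 - u[u < 1e-8]^2 / 3)
  h
}

#' Mean-lifespan scale of the model
#'
#' \eqn{\bar t = \log(Z/\bar z)/\alpha}: the age at which the exponential
#' amplification of the initial noise-born amplitude \eqn{\bar z} reaches the
#' nonlinearity scale \eqn{Z}, after which death follows quickly.
#'
#' @inheritParams analytic_survival
#' @param ratio dimensionless \eqn{Z/\bar z} (> 1).
#' @return lifespan scale in weeks.
#' @export
mean_lifespan <- function(params, ratio) {
  stopifnot(inherits(params, "langevin_params"))
  if (params$alpha <= 0) stop("`alpha` must be > 0")
  if (!is.finite(ratio) || ratio <= 1) stop("`ratio` must be > 1")
  log(ratio) / params$alpha
}

#' Predicted feature covariance under a single unstable mode
#'
#' When every feature tracks the order parameter linearly,
#' \eqn{x_i \approx b_i z + \xi_i}, the signal part of the sample covariance
#' at age \eqn{t} is the rank-1 matrix
#' \eqn{\langle x_i x_j \rangle \approx b_i b_j\,(B/2\alpha)\,e^{2\alpha t}}.
#'
#' @param loadings numeric vector of feature loadings \eqn{b}.
#' @param params a [langevin_params()] object with `alpha > 0`.
#' @param t age, weeks.
#' @return a symmetric positive-semidefinite rank-<=1 matrix.
#' @export
predicted_covariance <- function(loadings, params, t) {
  stopifnot(inherits(params, "langevin_params"))
  if (params$alpha <= 0) stop("`alpha` must be > 0")
  stop_if_not_finite(loadings, "loadings")
  amp <- params$noise_power / (2 * params$alpha) * exp(2 * params$alpha * t)
  amp * tcrossprod(loadings)
}

#' Export a trajectory as a tidy data frame / CSV
#'
#' @param trajectory a `dfi_trajectory`.
#' @param animal_id id stamped on every row.
#' @param path optional CSV path; when given the frame is also written.
#' @return data.frame with columns `animal_id`, `time_weeks`, `z` (invisibly
#'   when `path` is given).
#' @export
trajectory_to_csv <- function(trajectory, animal_id = "a1", path = NULL) {
  stopifnot(inherits(trajectory, "dfi_trajectory"))
  df <- data.frame(animal_id = animal_id, time_weeks = trajectory$times,
                   z = trajectory$z)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
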