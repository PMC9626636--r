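test_that("parameter container validates inputs and exposes derived scales", {
  p <- langevin_params(alpha = 0.02, g = 0.02 / (0.1 * exp(2)),
                       noise_power = 2 * 0.02 * 0.01)
  s <- langevin_scales(p)
  expect_equal(s$Z, 0.1 * exp(2))
  expect_equal(s$z_bar, 0.1)
  expect_equal(s$t_bar, 100)
  expect_error(langevin_params(0.02, g = -1), "g")
  expect_error(langevin_params(0.02, noise_power = -1), "noise_power")
  expect_error(langevin_params(NaN), "finite")
  # scales undefined outside their domain
  expect_true(is.na(langevin_scales(langevin_params(0.02, g = 0))$Z))
  expect_true(is.na(langevin_scales(langevin_params(-0.01))$z_bar))
})

test_that("noiseless simulation matches the closed forms", {
  # linear ODE: z(50) = e at alpha = 0.02, z0 = 1
  p <- langevin_params(alpha = 0.02, g = 0, noise_power = 0, z_init = 1)
  tr <- simulate_trajectory(p, horizon = 50, step = 0.01, seed = 1)
  expect_equal(tail(tr$z, 1), exp(1), tolerance = 1e-3)
  expect_identical(tr$death_cause, "none")

  # all-zero fixed point
  p0 <- langevin_params(alpha = 0, g = 0, noise_power = 0, z_init = 0)
  tr0 <- simulate_trajectory(p0, horizon = 10, step = 0.1, seed = 1)
  expect_true(all(tr0$z == 0))

  # Riccati blow-up: guard at 10 Z fires within 1/(10 alpha) of the true
  # divergence time (1/alpha) * log(1 + Z/z0)
  pr <- langevin_params(alpha = 0.02, g = 0.002, noise_power = 0, z_init = 1)
  trr <- simulate_trajectory(pr, horizon = 150, step = 0.01, seed = 1)
  t_true <- log(1 + 10 / 1) / 0.02
  expect_identical(trr$death_cause, "blow-up")
  expect_lt(trr$death_time, t_true)
  expect_gt(trr$death_time, t_true - 1 / (10 * 0.02))
  # trajectory agrees with the closed-form Riccati solution en route
  z_exact <- function(t) 0.02 * exp(0.02 * t) / (0.02 + 0.002 * (1 - exp(0.02 * t)))
  at <- trr$times > 0 & trr$times <= 100
  expect_equal(trr$z[at], z_exact(trr$times[at]), tolerance = 1e-3)
})

test_that("simulation guards reject bad input and warn on coarse steps", {
  p <- langevin_params(alpha = 0.5, g = 0, noise_power = 0, z_init = 1)
  expect_warning(simulate_trajectory(p, horizon = 1, step = 0.3, seed = 1),
                 "step")
  expect_error(simulate_trajectory(p, horizon = -1, step = 0.01, seed = 1))
  expect_error(simulate_trajectory(p, horizon = 1, step = 0, seed = 1))
})

test_that("linear-regime ensemble moments match theory (g = 0)", {
  alpha <- 0.03; B <- 6e-4; z0 <- 1; t <- 50; n <- 4000
  p <- langevin_params(alpha = alpha, g = 0, noise_power = B, z_init = z0)
  sim <- simulate_latent_cohort(p, n, visit_ages = t, step = 0.01, seed = 42)
  z <- sim$z[, 1]
  m_th <- z0 * exp(alpha * t)
  v_th <- B / (2 * alpha) * (exp(2 * alpha * t) - 1)
  expect_equal(mean(z), m_th, tolerance = 3 * sqrt(v_th / n) / m_th)
  expect_lt(abs(var(z) - v_th), 3 * v_th * sqrt(2 / (n - 1)))
})

test_that("analytic mean trajectory and its identities", {
  p <- langevin_params(alpha = 0.02)
  expect_equal(analytic_mean_z(p, z_bar_fit = 0.5, z0 = 0.1, t = 0), 0.6)
  expect_equal(analytic_mean_z(p, 0.5, 0.1, 100), 0.5 * exp(2) + 0.1)
  # doubling time log(2)/alpha
  t <- 37
  v1 <- analytic_mean_z(p, 0.5, 0.1, t) - 0.1
  v2 <- analytic_mean_z(p, 0.5, 0.1, t + log(2) / 0.02) - 0.1
  expect_equal(v2, 2 * v1)
  expect_error(analytic_mean_z(p, 0.5, 0.1, -1), "t")
})

test_that("closed-form survival behaves like an Erf survival law", {
  p <- langevin_params(alpha = 0.02)
  expect_equal(analytic_survival(p, ratio = exp(2), t = 100),
               2 * pnorm(sqrt(2)) - 1)  # Erf(1)
  expect_equal(analytic_survival(p, 10, 0), 1, tolerance = 1e-15)
  expect_equal(analytic_survival(p, 10, 1e5), 0)
  ts <- seq(0, 300, by = 1)
  s <- analytic_survival(p, exp(2), ts)
  expect_true(all(diff(s) <= 0))
  expect_error(analytic_survival(p, -1, 0), "ratio")
})

test_that("hazard saturates at alpha and matches numeric differentiation", {
  p <- langevin_params(alpha = 0.05)
  expect_equal(analytic_hazard(p, exp(3), 1e4), 0.05, tolerance = 1e-6)
  expect_lt(analytic_hazard(p, 20, 0), 1e-100)
  # spot value at u = 1
  p2 <- langevin_params(alpha = 0.02)
  t_u1 <- log(exp(2)) / 0.02  # ratio = e^2 -> u = 1 at t = 100
  expect_equal(analytic_hazard(p2, exp(2), t_u1),
               0.02 * (2 / sqrt(pi)) * exp(-1) / (2 * pnorm(sqrt(2)) - 1),
               tolerance = 1e-12)
  # independent oracle: -S'/S by central differences
  ts <- seq(10, 250, by = 10)
  h <- analytic_hazard(p2, exp(2), ts)
  eps <- 1e-4
  num <- -(analytic_survival(p2, exp(2), ts + eps) -
             analytic_survival(p2, exp(2), ts - eps)) /
    (2 * eps * analytic_survival(p2, exp(2), ts))
  expect_equal(h, num, tolerance = 1e-6)
  # monotone, bounded by alpha
  grid <- analytic_hazard(p2, exp(2), seq(0, 500, by = 0.5))
  expect_true(all(diff(grid) >= -1e-12))
  expect_true(all(grid <= 0.02 * (1 + 1e-9)))
})

test_that("mean lifespan scale", {
  p <- langevin_params(alpha = 0.02)
  expect_equal(mean_lifespan(p, exp(2)), 100)
  expect_lt(mean_lifespan(p, 1 + 1e-9), 1e-6)
  expect_error(mean_lifespan(p, 1), "ratio")
  expect_error(mean_lifespan(langevin_params(0), 2), "alpha")
})

test_that("median simulated death age tracks the lifespan scale", {
  # trajectories started at z_bar are dominated by deterministic growth,
  # so the median blow-up age sits near t_bar = log(ratio)/alpha
  alpha <- 0.05; z_bar <- 0.1; ratio <- exp(2)
  p <- mortal_langevin(alpha = alpha, z_bar = z_bar, log_ratio = 2)
  sim <- simulate_latent_cohort(p, 3000, horizon = 150, step = 0.01, seed = 7)
  med <- median(sim$death_time, na.rm = TRUE)
  expect_equal(med, mean_lifespan(p, ratio), tolerance = 0.10)
})

test_that("predicted covariance is rank-1 and grows exponentially", {
  p <- langevin_params(alpha = 0.02, noise_power = 4e-4)
  b <- c(1, rep(0, 11))
  C <- predicted_covariance(b, p, t = 50)
  expect_equal(C[1, 1], 4e-4 / 0.04 * exp(2 * 0.02 * 50))
  expect_equal(sum(abs(C)) - abs(C[1, 1]), 0)
  b2 <- rnorm(12)
  C1 <- predicted_covariance(b2, p, t = 40)
  C2 <- predicted_covariance(b2, p, t = 40 + log(2) / (2 * 0.02))
  expect_equal(C2, 2 * C1)
  expect_equal(qr(C1)$rank, 1L)
  expect_true(isSymmetric(C1))
  # ensemble oracle: mapped linear trajectories
  sim <- simulate_latent_cohort(langevin_params(0.02, 0, 4e-4, 0), 8000,
                                visit_ages = 100, step = 0.02, seed = 3)
  X <- outer(sim$z[, 1], b2)
  emp <- cov(X)
  th <- predicted_covariance(b2, p, 100) * (1 - exp(-2 * 0.02 * 100))
  expect_equal(emp, th, tolerance = 0.1)
})

test_that("identical seeds reproduce trajectories; CSV export is tidy", {
  p <- mortal_langevin()
  t1 <- simulate_trajectory(p, 120, step = 0.05, seed = 9)
  t2 <- simulate_trajectory(p, 120, step = 0.05, seed = 9)
  expect_identical(t1, t2)
  df <- trajectory_to_csv(t1, animal_id = "m1")
  expect_named(df, c("animal_id", "time_weeks", "z"))
  expect_true(all(diff(df$time_weeks) > 0))
  expect_true(all(is.finite(df$z)))
})
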