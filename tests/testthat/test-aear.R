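test_that("configuration and construction contracts", {
  cfg <- aear_config(seed = 2)
  expect_error(aear_config(latent_dim = 12L), "latent_dim")
  expect_warning(aear_config(latent_dim = 3L), "published")
  expect_error(aear_config(alpha3 = 0.001, alpha4 = 0.01), "alpha3")

  m <- build_model(cfg)
  X <- matrix(rnorm(7 * 12), 7)
  Y <- dfiage:::encode(m, X)
  expect_equal(dim(Y), c(7L, 4L))
  expect_equal(dim(dfiage:::decode(m, Y)), c(7L, 12L))
  # bit-identical initialization under one seed
  m2 <- build_model(aear_config(seed = 2))
  expect_identical(m$params, m2$params)
  m3 <- build_model(aear_config(seed = 3))
  expect_false(identical(m$params, m3$params))
  expect_equal(sqrt(sum(m$params$B^2)), 1)
})

test_that("a ResNet block with zeroed inner weights is the identity", {
  arch <- dfiage:::nn_arch(4, 4, 4, n_blocks = 1, slope = 0.2)[2]
  p <- list(list(W1 = matrix(0, 4, 4), b1 = rep(0, 4),
                 W2 = matrix(0, 4, 4), b2 = rep(0, 4)))
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(dfiage:::nn_forward(arch, p, X)$out, X)
})

test_that("backpropagation matches finite differences", {
  set.seed(71)
  cfg <- suppressWarnings(
    aear_config(input_dim = 5L, latent_dim = 2L, hidden_width = 6L,
                n_resnet_blocks = 1L, seed = 7))
  m <- suppressWarnings(build_model(cfg))
  Xc <- matrix(rnorm(15 * 5), 15)
  X1 <- matrix(rnorm(6 * 5), 6)
  X2 <- matrix(rnorm(6 * 5), 6)
  w <- list(a1 = 1, a2 = 0.7, a3 = 100, a4 = 0.01)
  lg <- dfiage:::aear_loss_grad(m$arch, m$params, Xc, X1, X2, w)
  g <- dfiage:::flatten_params(lg$grads)
  th <- dfiage:::flatten_params(m$params)
  idx <- sample(length(th), 50)
  num <- vapply(idx, function(i) {
    e <- 1e-6
    tp <- th; tp[i] <- tp[i] + e
    tm <- th; tm[i] <- tm[i] - e
    up <- dfiage:::aear_loss_grad(
      m$arch, dfiage:::unflatten_params(tp, m$params), Xc, X1, X2, w,
      want_grads = FALSE)$losses$total
    dn <- dfiage:::aear_loss_grad(
      m$arch, dfiage:::unflatten_params(tm, m$params), Xc, X1, X2, w,
      want_grads = FALSE)$losses$total
    (up - dn) / (2 * e)
  }, numeric(1))
  expect_equal(g[idx], num, tolerance = 1e-5)
})

test_that("training pairs respect animal identity, gap and window", {
  tab <- data.frame(
    animal_id = c("a", "a", "b", "b", "c", "c", "d", "d"),
    age_weeks = c(26, 52, 26, 60, 30, 120, 40, 66))
  prs <- make_pairs(tab, interval = 26, tolerance = 4)
  # a: gap 26 ok; b: gap 34 out; c: 120 outside window; d: gap 26 ok
  expect_setequal(prs$animal_id, c("a", "d"))
  expect_true(all(prs$age_next - prs$age_now == 26))
  suppressMessages(
    expect_equal(nrow(make_pairs(tab, interval = 10, tolerance = 1)), 0L))
})

test_that("loss components evaluate Eq-by-Eq on constructed systems", {
  # exact linear system on a 1-D manifold: all data losses vanish
  cfg <- suppressWarnings(
    aear_config(input_dim = 2L, latent_dim = 1L, hidden_width = 2L,
                n_resnet_blocks = 0L, seed = 1))
  m <- suppressWarnings(build_model(cfg))
  # encoder: y = x1; decoder: x = (y, 2y); A = 1, B = 1, r = 1, z' = 0.3
  m$params$enc <- list(list(W = diag(2), b = c(0, 0)),
                       list(W = matrix(c(1, 0), 2, 1), b = 0))
  m$params$dec <- list(list(W = matrix(c(1, 2), 1, 2), b = c(0, 0)),
                       list(W = diag(2), b = c(0, 0)))
  m$params$A <- matrix(1, 1, 1)
  m$params$B <- matrix(1, 1, 1)
  m$params$r <- 1; m$params$zprime <- 0.3
  t0 <- c(0.2, 0.9, 1.4)
  Xn <- cbind(t0, 2 * t0)
  Xn1 <- cbind(t0 + 0.3, 2 * (t0 + 0.3))
  L <- compute_losses(m, rbind(Xn, Xn1),
                      list(x_now = Xn, x_next = Xn1))
  expect_equal(L$L_AE, 0)
  expect_equal(L$L_pred, 0)
  expect_equal(L$L_AR, 0)
  expect_equal(L$L_C, 0)

  # constraint loss directly: A.B = 0 gives L_C = 1 (with unit-norm B)
  m$params$A <- matrix(0, 1, 1)
  expect_equal(compute_losses(m, Xn)$L_C, 1)

  # hand-computed single-sample residuals
  m$params$A <- matrix(1, 1, 1)
  x <- matrix(c(0.5, 1.2), 1)          # off the manifold
  # phi(x) = 0.5; recon = (0.5, 1.0); residual (0, -0.2)
  expect_equal(compute_losses(m, x)$L_AE, 0.04)
  pair <- list(x_now = matrix(c(0.1, 0.2), 1),
               x_next = matrix(c(0.6, 1.2), 1))
  # z1 = 0.1, zp = 0.4, pred = (0.4, 0.8): residual (0.2, 0.4)
  # z2 = 0.6, AR residual 0.2
  L2 <- compute_losses(m, x, pair)
  expect_equal(L2$L_pred, 0.2)
  expect_equal(L2$L_AR, 0.04)
  expect_equal(L2$total, 1 * (0.04 + 0.2) + 1 * 0.04 + 0 + 0.01 * L2$L2)
})

test_that("reconstruction metrics follow their definitions", {
  rm <- dfiage:::recon_metrics(matrix(c(1, 2, 3), dimnames = list(NULL, "f")),
                               matrix(c(1, 2, 4)))
  expect_equal(rm$rmse, sqrt(1 / 3), ignore_attr = TRUE)
  expect_equal(rm$r2, 0.5, ignore_attr = TRUE)   # SS_res 1, SS_tot 2
  rm0 <- dfiage:::recon_metrics(matrix(c(1, 2, 3)), matrix(c(2, 2, 2)))
  expect_equal(rm0$r2, 0, ignore_attr = TRUE)    # predicting the mean
  rmc <- dfiage:::recon_metrics(matrix(c(1, 1, 1)), matrix(c(1, 1, 1)))
  expect_true(is.na(rmc$r2))                     # zero-variance feature
  expect_equal(rmc$rmse, 0, ignore_attr = TRUE)
})

test_that("age adjustment removes group means exactly", {
  sc <- data.frame(animal_id = letters[1:4],
                   sex = c("M", "M", "F", "F"),
                   age_weeks = c(26, 26, 52, 52),
                   dfi = c(1, 3, 10, 20))
  out <- age_adjust_dfi(sc)
  expect_equal(out$dfi_age_adjusted, c(-1, 1, -5, 5))
  expect_equal(as.numeric(tapply(out$dfi_age_adjusted,
                                 interaction(out$sex, out$age_weeks,
                                             drop = TRUE),
                                 sum)), c(0, 0))
  same <- data.frame(animal_id = 1:5, dfi = rep(2, 5))
  expect_equal(age_adjust_dfi(same)$dfi_age_adjusted, rep(0, 5))
  single <- data.frame(animal_id = 1:2, sex = c("M", "F"),
                       age_weeks = 26, dfi = c(1, 2))
  expect_warning(out2 <- age_adjust_dfi(single), "singleton")
  expect_equal(out2$dfi_age_adjusted, c(0, 0))
})

test_that("scoring is deterministic and absorbs affine input rescaling", {
  coh <- small_cohort(15, seed = 91)
  fm <- harmonized(coh)
  m <- build_model(aear_config(seed = 4))
  m$scaler <- list(center = colMeans(fm$values),
                   scale = apply(fm$values, 2, sd))
  s1 <- score_dfi(m, fm)
  s2 <- score_dfi(m, fm)
  expect_identical(s1, s2)

  # rescale one feature affinely and refit the scaler: dFI unchanged
  fm2 <- fm
  fm2$values[, "PLT"] <- 3.7 * fm2$values[, "PLT"] + 100
  m2 <- m
  m2$scaler <- list(center = colMeans(fm2$values),
                    scale = apply(fm2$values, 2, sd))
  s3 <- score_dfi(m2, fm2)
  expect_equal(s3$dfi, s1$dfi, tolerance = 1e-6)

  # missing features: rows skipped with a report
  tab <- derive_granulocytes(coh$cohort)
  tab$HB[2] <- NA
  expect_message(s4 <- score_dfi(m, tab), "skipping 1")
  expect_equal(nrow(s4), nrow(tab) - 1L)
  expect_error(score_dfi(m, tab[, 1:5]), "lack feature")
})

test_that("growth-exponent fit recovers exact and degenerate inputs", {
  ages <- seq(26, 104, by = 13)
  exact <- data.frame(age = ages, mean = 0.5 * exp(0.02 * ages) + 0.1,
                      sem = 0.01)
  fit <- fit_growth_exponent(exact)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-6)
  expect_equal(fit$z_bar, 0.5, tolerance = 1e-5)
  expect_equal(fit$z0, 0.1, tolerance = 1e-4)

  flat <- data.frame(age = ages, mean = 1, sem = 0.01)
  ffit <- fit_growth_exponent(flat)
  expect_true(ffit$ci[1] <= 0 && ffit$ci[2] >= 0)

  # lifespan cutoff excludes old groups
  bent <- exact
  bent$mean[bent$age > 90] <- max(exact$mean)
  fit2 <- fit_growth_exponent(bent, lifespan_cutoff = 90)
  expect_equal(fit2$alpha, 0.02, tolerance = 1e-6)
  expect_error(fit_growth_exponent(exact[1:3, ]), "4 age groups")
})

test_that("growth-exponent confidence intervals are calibrated", {
  # Monte-Carlo calibration at known alpha = 0.025 with sem-weighted noise
  ages <- seq(26, 104, by = 13)
  sem <- 0.05 * exp(0.012 * ages)
  set.seed(72)
  cover <- replicate(60, {
    mu <- 0.4 * exp(0.025 * ages) + 0.2 + rnorm(length(ages), sd = sem)
    f <- fit_growth_exponent(data.frame(age = ages, mean = mu, sem = sem))
    f$ci[1] <= 0.025 && 0.025 <= f$ci[2]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("autocorrelation separates persistent signal from noise", {
  ids <- sprintf("p%03d", 1:60)
  per_animal <- rnorm(60)
  sc <- data.frame(animal_id = rep(ids, 2),
                   age_weeks = rep(c(52, 78), each = 60),
                   dfi = rep(per_animal, 2),
                   dfi_age_adjusted = rep(per_animal, 2))
  ac <- dfi_autocorrelation(sc, lags = 26)
  expect_equal(ac$r, 1)
  expect_equal(ac$n_pairs, 60L)

  set.seed(73)
  noise <- sc
  noise$dfi_age_adjusted <- rnorm(120)
  acn <- dfi_autocorrelation(noise, lags = 26)
  expect_lt(abs(acn$r), 0.3)
  expect_warning(dfi_autocorrelation(sc[c(1, 61), ], lags = 26), "fewer")
})

test_that("checkpoints reload bit-exactly", {
  m <- build_model(aear_config(seed = 14))
  m$scaler <- list(center = rnorm(12), scale = abs(rnorm(12)) + 0.5)
  m$sign <- -1
  m$trained <- TRUE
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- suppressWarnings(load_model(dir))
  expect_identical(m2$params, m$params)
  expect_equal(m2$scaler$center, m$scaler$center)
  expect_identical(m2$sign, m$sign)
  X <- matrix(rnorm(60), 5, 12, dimnames = list(NULL, CBC_FEATURES))
  fmX <- structure(list(values = X,
                        row_keys = data.frame(animal_id = as.character(1:5),
                                              age_weeks = 52)),
                   class = "feature_matrix")
  expect_identical(score_dfi(m, fmX)$dfi, score_dfi(m2, fmX)$dfi)
})

test_that("a short training run learns the latent order parameter", {
  lp <- linear_langevin(alpha = 0.03)
  cc <- cohort_config(n_per_strain_sex = 60, langevin = lp,
                      censor_rate = 0, seed = 81)
  coh <- generate_cohort(cc)
  fm <- harmonized(coh)
  prs <- make_pairs(fm)
  cfg <- aear_config(seed = 82, epochs = 120, ramp_epochs = 60,
                     lr_switch_epoch = 80)
  m <- train_aear(build_model(cfg), fm, prs, ages = fm$row_keys$age_weeks)
  expect_true(m$trained)
  expect_lt(abs(sum(m$params$A %*% m$params$B) - 1), 1e-2)
  expect_lt(abs(sqrt(sum(m$params$B^2)) - 1), 1e-2)
  # loss decreased and stayed finite
  expect_lt(tail(m$history, 1), m$history[1])
  truth <- dfi_vs_truth(m, fm, coh)
  expect_gt(abs(cor(truth$dfi, truth$z_true)), 0.8)
  # sign convention: dFI grows with age
  expect_gte(cor(truth$dfi, truth$age_weeks), 0)
  # mean dFI strictly increasing across age groups 26 -> 78
  mu <- tapply(truth$dfi, truth$age_weeks, mean)
  expect_true(all(diff(mu[c("26", "52", "78")]) > 0))
})
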