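#' Configuration of the autoencoder--autoregression (AE--AR) network
#'
#' The network couples a denoising autoencoder (12-feature CBC input, a
#' 4-dimensional bottleneck `y`) with a scalar linear autoregression: a
#' projector `z = A y` (the dFI), linear dynamics
#' `z_{n+1} = r z_n + z'`, and a lift `y = B z` feeding the shared decoder.
#' Constraint losses force `A B = 1` and unit column norm of `B`, so `A` and
#' `B` act as the left/right eigenvectors of the latent dynamics.
#'
#' Loss weights follow the published defaults: `alpha1 = 1` on the
#' reconstruction and future-state losses, `alpha2` ramped from 0 to
#' `alpha2_max = 1` over the first `ramp_epochs`, `alpha3 = 100` on the
#' constraints, `alpha4 = 0.01` on the L2 weight penalty.  Training runs 600
#' epochs of Adam, learning rate 1e-3 switching to 1e-4 at epoch 400.
#'
#' @param input_dim number of input features (12 CBC features).
#' @param latent_dim bottleneck width (4; other values are allowed with a
#'   warning).
#' @param hidden_width units in the dense/ResNet layers (32: ample capacity for
#'   12 inputs at desk-scale runtime).
#' @param n_resnet_blocks ResNet blocks per arm (each: two dense layers with
#'   leaky-ReLU activations plus a skip connection).
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param alpha1,alpha2_max,alpha3,alpha4 loss weights (see above).
#' @param ramp_epochs epochs over which `alpha2` ramps linearly 0 -> max.
#' @param epochs total training epochs.
#' @param lr,lr_late,lr_switch_epoch learning-rate schedule.
#' @param batch_size per-step batch size for the cross-sectional and pair
#'   batches (full data when smaller).
#' @param pair_interval nominal longitudinal sampling interval Delta-t, weeks.
#' @param pair_tolerance allowed deviation of a pair's age gap, weeks.
#' @param pair_window age window (weeks) from which training pairs are drawn.
#' @param corruption_sd SD (in scaled units) of Gaussian input corruption for
#'   the denoising reconstruction path; 0 disables corruption.
#' @param grad_clip global gradient-norm clip.
#' @param steps_per_epoch cap on the number of optimizer steps per epoch
#'   (each step draws fresh cross-sectional and pair batches); `NULL` means
#'   a full pass over the cross-sectional data.  The default (8, i.e. up to
#'   2048 samples per epoch) keeps desk-scale training within minutes; on
#'   large cohorts Adam converges to the same solution as a full pass (the
#'   parameter-recovery suite verifies this).
#' @param ar_warm_start seed `(r, z')` from a PC1 pair regression before
#'   optimization (the cold start `r = 1` is far from the solution when
#'   `alpha * dt` is not small and converges slowly).
#' @param seed integer seed controlling initialization and batch order.
#' @return an `aear_config` object.
#' @export
aear_config <- function(input_dim = 12L, latent_dim = 4L, hidden_width = 32L,
                        n_resnet_blocks = 2L, leaky_slope = 0.2,
                        alpha1 = 1, alpha2_max = 1, alpha3 = 100,
                        alpha4 = 0.01, ramp_epochs = 300L, epochs = 600L,
                        lr = 1e-3, lr_late = 1e-4, lr_switch_epoch = 400L,
                        batch_size = 256L, pair_interval = 26,
                        pair_tolerance = 4, pair_window = c(26, 104),
                        corruption_sd = 0, grad_clip = 10,
                        steps_per_epoch = 8L, ar_warm_start = TRUE,
                        seed = 1L) {
  if (latent_dim >= input_dim) stop("latent_dim must be < input_dim")
  if (latent_dim != 4L) warning("latent_dim != 4 deviates from the published architecture")
  if (alpha3 <= alpha4) stop("expect alpha3 >> alpha4 (constraint dominates L2)")
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_width = as.integer(hidden_width),
                 n_resnet_blocks = as.integer(n_resnet_blocks),
                 leaky_slope = leaky_slope, alpha1 = alpha1,
                 alpha2_max = alpha2_max, alpha3 = alpha3, alpha4 = alpha4,
                 ramp_epochs = as.integer(ramp_epochs),
                 epochs = as.integer(epochs), lr = lr, lr_late = lr_late,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 batch_size = as.integer(batch_size),
                 pair_interval = pair_interval,
                 pair_tolerance = pair_tolerance, pair_window = pair_window,
                 corruption_sd = corruption_sd, grad_clip = grad_clip,
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                 else as.integer(steps_per_epoch),
                 ar_warm_start = isTRUE(ar_warm_start),
                 seed = as.integer(seed)),
            class = "aear_config")
}

#' Build an (untrained) AE--AR model
#'
#' Encoder: Dense(input -> width), `n` ResNet blocks, Dense(width -> latent);
#' decoder mirrored.  Projector `A` (1 x latent), lift `B` (latent x 1,
#' initialised unit-norm), autoregression coefficient `r` (init 1) and shift
#' `z'` (init 0).  Identical seeds give bit-identical initial parameters.
#'
#' @param config an [aear_config()].
#' @return an `aear_model` list: `arch`, `params`, `scaler` (identity until
#'   trained), `sign`, `config`, `trained` flag.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "aear_config"))
  arch <- list(
    enc = nn_arch(config$input_dim, config$hidden_width, config$latent_dim,
                  config$n_resnet_blocks, config$leaky_slope),
    dec = nn_arch(config$latent_dim, config$hidden_width, config$input_dim,
                  config$n_resnet_blocks, config$leaky_slope))
  params <- with_seed(config$seed, {
    p <- list(enc = nn_init(arch$enc), dec = nn_init(arch$dec))
    A <- matrix(stats::rnorm(config$latent_dim, sd = 0.5), 1L)
    B <- matrix(stats::rnorm(config$latent_dim), ncol = 1L)
    p$A <- A
    p$B <- B / sqrt(sum(B^2))
    p$r <- 1
    p$zprime <- 0
    p
  })
  structure(list(arch = arch, params = params,
                 scaler = list(center = numeric(config$input_dim),
                               scale = rep(1, config$input_dim)),
                 sign = 1, config = config, trained = FALSE,
                 history = NULL),
            class = "aear_model")
}

#' @export
print.aear_model <- function(x, ...) {
  cat(sprintf("AE-AR model: %d -> %d latent, width %d, %d ResNet blocks/arm%s\n",
              x$config$input_dim, x$config$latent_dim, x$config$hidden_width,
              x$config$n_resnet_blocks,
              if (x$trained) " (trained)" else " (untrained)"))
  if (x$trained)
    cat(sprintf("  r = %.4f (ln r / dt = %.4f /wk), z' = %.4f, A.B = %.4f\n",
                x$params$r, ar_exponent(x), x$params$zprime,
                sum(x$params$A %*% x$params$B)))
  invisible(x)
}

scale_input <- function(model, X) {
  sweep(sweep(X, 2L, model$scaler$center), 2L, model$scaler$scale, "/")
}
unscale_output <- function(model, X) {
  sweep(sweep(X, 2L, model$scaler$scale, "*"), 2L, model$scaler$center, "+")
}

encode <- function(model, X_scaled) nn_forward(model$arch$enc, model$params$enc, X_scaled)$out
decode <- function(model, Y) nn_forward(model$arch$dec, model$params$dec, Y)$out

#' Longitudinal training pairs
#'
#' Same-animal record pairs whose age gap lies within
#' `interval +/- tolerance`, restricted to the fully-grown age window
#' (default 26--104 weeks).
#'
#' @param table a CohortTable data frame or a `feature_matrix` (its row keys
#'   are used); must provide `animal_id` and `age_weeks`.
#' @param interval nominal gap Delta-t, weeks.
#' @param tolerance allowed gap deviation, weeks.
#' @param window age window (both records inside); `NULL` disables.
#' @return data frame: `animal_id`, `row_now`, `row_next`, `age_now`,
#'   `age_next` (rows index `table`/the feature matrix).
#' @export
make_pairs <- function(table, interval = 26, tolerance = 4,
                       window = c(26, 104)) {
  keys <- if (inherits(table, "feature_matrix")) table$row_keys else table
  stopifnot(all(c("animal_id", "age_weeks") %in% names(keys)))
  idx <- seq_len(nrow(keys))
  if (!is.null(window))
    idx <- idx[keys$age_weeks >= window[1] & keys$age_weeks <= window[2]]
  out <- list()
  for (id in unique(keys$animal_id[idx])) {
    rows <- idx[keys$animal_id[idx] == id]
    rows <- rows[order(keys$age_weeks[rows])]
    if (length(rows) < 2) next
    cmb <- utils::combn(length(rows), 2L)
    gaps <- keys$age_weeks[rows[cmb[2L, ]]] - keys$age_weeks[rows[cmb[1L, ]]]
    ok <- abs(gaps - interval) <= tolerance
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        animal_id = id, row_now = rows[cmb[1L, ok]],
        row_next = rows[cmb[2L, ok]],
        age_now = keys$age_weeks[rows[cmb[1L, ok]]],
        age_next = keys$age_weeks[rows[cmb[2L, ok]]])
  }
  if (!length(out)) {
    message("no longitudinal pairs found for the requested interval")
    return(data.frame(animal_id = character(), row_now = integer(),
                      row_next = integer(), age_now = numeric(),
                      age_next = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# loss + gradient engine.  All matrices already scaled.  Xc_in may be a
# corrupted copy of Xc (denoising); the reconstruction target is Xc.
aear_loss_grad <- function(arch, params, Xc, X1, X2, w, Xc_in = Xc,
                           want_grads = TRUE) {
  n <- nrow(Xc); m <- if (is.null(X1)) 0L else nrow(X1)
  A <- params$A; B <- params$B
  fc <- nn_forward(arch$enc, params$enc, Xc_in)
  dc <- nn_forward(arch$dec, params$dec, fc$out)
  res_ae <- dc$out - Xc
  L_AE <- sum(res_ae^2) / n

  if (m > 0) {
    f1 <- nn_forward(arch$enc, params$enc, X1)
    f2 <- nn_forward(arch$enc, params$enc, X2)
    z1 <- f1$out %*% t(A)
    z2 <- f2$out %*% t(A)
    zp <- params$r * z1 + params$zprime
    Yp <- zp %*% t(B)
    dp <- nn_forward(arch$dec, params$dec, Yp)
    res_pred <- dp$out - X2
    res_ar <- z2 - zp
    L_pred <- sum(res_pred^2) / m
    L_AR <- sum(res_ar^2) / m
  } else L_pred <- L_AR <- 0

  AB <- sum(A %*% B)
  nB <- sum(B^2)
  L_C <- (AB - 1)^2 + (nB - 1)^2
  L2 <- nn_l2(params$enc) + nn_l2(params$dec)
  total <- w$a1 * (L_AE + L_pred) + w$a2 * L_AR + w$a3 * L_C + w$a4 * L2
  losses <- list(L_AE = L_AE, L_pred = L_pred, L_AR = L_AR, L_C = L_C,
                 L2 = L2, total = total)
  if (!want_grads) return(list(losses = losses))

  # --- gradients ---
  dRec <- 2 * w$a1 * res_ae / n
  bd_c <- nn_backward(arch$dec, params$dec, dc$caches, dRec)
  be_c <- nn_backward(arch$enc, params$enc, fc$caches, bd_c$dX)
  g_enc <- be_c$grads
  g_dec <- bd_c$grads
  gA <- A * 0; gB <- B * 0; gr <- 0; gzp <- 0

  if (m > 0) {
    dXp <- 2 * w$a1 * res_pred / m
    bd_p <- nn_backward(arch$dec, params$dec, dp$caches, dXp)
    g_dec <- grads_add(g_dec, bd_p$grads)
    dz2 <- 2 * w$a2 * res_ar / m
    dzp <- (bd_p$dX %*% B) - dz2
    gB <- gB + t(crossprod(zp, bd_p$dX))
    gr <- gr + sum(dzp * z1)
    gzp <- gzp + sum(dzp)
    dz1 <- params$r * dzp
    gA <- gA + crossprod(dz1, f1$out) + crossprod(dz2, f2$out)
    be_1 <- nn_backward(arch$enc, params$enc, f1$caches, dz1 %*% A)
    be_2 <- nn_backward(arch$enc, params$enc, f2$caches, dz2 %*% A)
    g_enc <- grads_add(g_enc, grads_add(be_1$grads, be_2$grads))
  }

  gA <- gA + w$a3 * 2 * (AB - 1) * t(B)
  gB <- gB + w$a3 * 2 * (AB - 1) * t(A) + w$a3 * 2 * (nB - 1) * 2 * B
  g_enc <- grads_add(g_enc, nn_l2_grads(params$enc, w$a4))
  g_dec <- grads_add(g_dec, nn_l2_grads(params$dec, w$a4))

  list(losses = losses,
       grads = list(enc = g_enc, dec = g_dec, A = gA, B = gB, r = gr,
                    zprime = gzp))
}

#' Evaluate the AE--AR loss components on given batches
#'
#' Returns the reconstruction loss `L_AE`, the future-state reconstruction
#' loss `L_pred`, the autoregression loss `L_AR`, the eigenvector constraint
#' loss `L_C`, the `L2` weight penalty, and the weighted `total`.  Batches
#' must already be scaled by the model's input scaler.
#'
#' @param model an `aear_model`.
#' @param cross_batch scaled n x p matrix of cross-sectional samples.
#' @param pair_batch `NULL`, or a list with scaled matrices `x_now`,
#'   `x_next` of equal dimensions.
#' @param alpha2 the (possibly ramped) autoregression weight to use.
#' @return named list of loss components.
#' @export
compute_losses <- function(model, cross_batch, pair_batch = NULL,
                           alpha2 = model$config$alpha2_max) {
  stopifnot(inherits(model, "aear_model"))
  cross_batch <- as.matrix(cross_batch)
  X1 <- X2 <- NULL
  if (!is.null(pair_batch)) {
    X1 <- as.matrix(pair_batch$x_now); X2 <- as.matrix(pair_batch$x_next)
    stopifnot(nrow(X1) == nrow(X2))
  }
  w <- list(a1 = model$config$alpha1, a2 = alpha2, a3 = model$config$alpha3,
            a4 = model$config$alpha4)
  out <- aear_loss_grad(model$arch, model$params, cross_batch, X1, X2, w,
                        want_grads = FALSE)$losses
  if (!all(vapply(out, is.finite, logical(1L))))
    stop("non-finite loss encountered; inspect inputs and scaling")
  out
}

#' Train the AE--AR model
#'
#' Optimizes the weighted loss with Adam under the configured schedule:
#' every step draws one cross-sectional batch and one pair batch (batch
#' size or full data if smaller), `alpha2` ramps linearly from 0 over the
#' first `ramp_epochs`, and the learning rate drops at `lr_switch_epoch`.
#' After training the scaler holds the training statistics, the dFI sign is
#' fixed so that dFI correlates non-negatively with age (when `ages` is
#' supplied), and the per-epoch loss curve is stored in `$history`.
#'
#' @param model an untrained [build_model()] output.
#' @param cross_data a `feature_matrix` or numeric matrix of cross-sectional
#'   samples (original units; the scaler is fitted here).
#' @param pairs a pair table from [make_pairs()] (rows indexing
#'   `cross_data`), or `NULL` to train the autoencoder alone.
#' @param ages optional ages aligned with `cross_data` rows (sign fixing).
#' @return the trained `aear_model`.
#' @export
train_aear <- function(model, cross_data, pairs = NULL, ages = NULL) {
  stopifnot(inherits(model, "aear_model"))
  cfg <- model$config
  X <- if (inherits(cross_data, "feature_matrix")) cross_data$values
  else as.matrix(cross_data)
  if (ncol(X) != cfg$input_dim)
    stop(sprintf("cross data has %d features, config expects %d",
                 ncol(X), cfg$input_dim))
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  model$scaler <- list(center = center, scale = scl,
                       features = colnames(X))
  Xs <- scale_input(model, X)
  have_pairs <- !is.null(pairs) && nrow(pairs) > 0
  if (have_pairs) {
    P1 <- Xs[pairs$row_now, , drop = FALSE]
    P2 <- Xs[pairs$row_next, , drop = FALSE]
  }
  n <- nrow(Xs); m <- if (have_pairs) nrow(P1) else 0L
  if (have_pairs && isTRUE(cfg$ar_warm_start)) {
    # warm-start the linear dynamics from the first principal direction:
    # regress paired PC1 scores to seed (r, z'), which Adam then refines
    # jointly with the encoder (r starts far from 1 when alpha*dt is not
    # small, and converges slowly from a cold start)
    v <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)$rotation[, 1L]
    s1 <- as.numeric(P1 %*% v); s2 <- as.numeric(P2 %*% v)
    cf <- stats::coef(stats::lm.fit(cbind(s1, 1), s2))
    if (all(is.finite(cf)) && cf[1L] > 0) {
      model$params$r <- unname(cf[1L])
      model$params$zprime <- unname(cf[2L])
    }
  }
  steps <- max(1L, ceiling(n / cfg$batch_size))
  if (!is.null(cfg$steps_per_epoch)) steps <- min(steps, cfg$steps_per_epoch)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  history <- numeric(cfg$epochs)
  seeds <- derive_seeds(cfg$seed + 1L, cfg$epochs)
  init_loss <- NA_real_
  for (epoch in seq_len(cfg$epochs)) {
    a2 <- if (cfg$ramp_epochs > 0)
      cfg$alpha2_max * min(1, epoch / cfg$ramp_epochs) else cfg$alpha2_max
    w <- list(a1 = cfg$alpha1, a2 = a2, a3 = cfg$alpha3, a4 = cfg$alpha4)
    lr <- if (epoch <= cfg$lr_switch_epoch) cfg$lr else cfg$lr_late
    tot <- 0
    with_seed(seeds[epoch], {
      for (s in seq_len(steps)) {
        ic <- if (n > cfg$batch_size) sample.int(n, cfg$batch_size) else seq_len(n)
        Xc <- Xs[ic, , drop = FALSE]
        Xc_in <- if (cfg$corruption_sd > 0)
          Xc + matrix(stats::rnorm(length(Xc), sd = cfg$corruption_sd),
                      nrow(Xc)) else Xc
        if (have_pairs) {
          ip <- if (m > cfg$batch_size) sample.int(m, cfg$batch_size) else seq_len(m)
          X1 <- P1[ip, , drop = FALSE]; X2 <- P2[ip, , drop = FALSE]
        } else X1 <- X2 <- NULL
        lg <- aear_loss_grad(model$arch, model$params, Xc, X1, X2, w, Xc_in)
        if (!is.finite(lg$losses$total))
          stop(sprintf("non-finite loss at epoch %d (seed %d): aborting",
                       epoch, cfg$seed))
        g <- flatten_params(lg$grads)
        st <- adam_step(opt, theta, g, lr, clip = cfg$grad_clip)
        opt <- st$state; theta <- st$theta
        model$params <- unflatten_params(theta, model$params)
        tot <- tot + lg$losses$total
      }
    })
    history[epoch] <- tot / steps
    if (epoch == 1L) init_loss <- history[1L]
    if (history[epoch] > 10 * init_loss + 1e-12)
      stop(sprintf(
        "training diverged at epoch %d (loss %.3g vs initial %.3g); seed %d, width %d, lr %g",
        epoch, history[epoch], init_loss, cfg$seed, cfg$hidden_width, cfg$lr))
  }
  model$trained <- TRUE
  model$history <- history
  if (!is.null(ages)) {
    dfi <- as.numeric(encode(model, Xs) %*% t(model$params$A))
    if (stats::sd(dfi) > 0 && stats::cor(dfi, ages) < 0) model$sign <- -1
  }
  model
}

#' Autoregression growth exponent implied by the trained dynamics
#'
#' `r = exp(alpha * dt)`, so `ln(r)/dt` estimates the stiffness alpha of the
#' latent Langevin dynamics.
#'
#' @param model a trained `aear_model`.
#' @return estimated exponent, 1/week.
#' @export
ar_exponent <- function(model) {
  stopifnot(inherits(model, "aear_model"))
  log(model$params$r) / model$config$pair_interval
}

#' Score records with the trained dFI
#'
#' `dfi = s * A * phi(scaled x)`; deterministic given the model.  Records
#' missing any of the 12 features are skipped and reported.  Age adjustment
#' (group-mean removal within sex and age groups) is applied via
#' [age_adjust_dfi()].
#'
#' @param model a trained `aear_model`.
#' @param records a CohortTable data frame carrying the canonical feature
#'   columns, or a `feature_matrix`.
#' @return a DFIScore data frame: `animal_id`, `age_weeks`, `sex` (when
#'   available), `dfi`, `dfi_age_adjusted`.
#' @export
score_dfi <- function(model, records) {
  stopifnot(inherits(model, "aear_model"))
  if (inherits(records, "feature_matrix")) {
    X <- records$values
    meta <- records$row_keys
  } else {
    missing_cols <- setdiff(CBC_FEATURES, names(records))
    if (length(missing_cols))
      stop("records lack feature columns: ",
           paste(missing_cols, collapse = ", "))
    X <- as.matrix(records[, CBC_FEATURES, drop = FALSE])
    meta <- records[, intersect(c("animal_id", "age_weeks", "sex"),
                                names(records)), drop = FALSE]
  }
  ok <- rowSums(is.na(X)) == 0
  if (any(!ok))
    message(sprintf("skipping %d record(s) with missing features", sum(!ok)))
  X <- X[ok, , drop = FALSE]
  meta <- meta[ok, , drop = FALSE]
  dfi <- model$sign *
    as.numeric(encode(model, scale_input(model, X)) %*% t(model$params$A))
  out <- cbind(meta, data.frame(dfi = dfi))
  rownames(out) <- NULL
  age_adjust_dfi(out)
}

#' Age- and sex-adjust dFI scores
#'
#' Subtracts the mean dFI of each (sex, age-group) cell, so adjusted values
#' have zero mean within every cell; a singleton cell adjusts to 0 with a
#' warning.
#'
#' @param scores a data frame with `dfi` and the grouping columns.
#' @param grouping columns defining the cells (those present are used;
#'   default sex and age).
#' @return `scores` with a `dfi_age_adjusted` column.
#' @export
age_adjust_dfi <- function(scores, grouping = c("sex", "age_weeks")) {
  stopifnot(is.data.frame(scores), "dfi" %in% names(scores))
  grouping <- intersect(grouping, names(scores))
  if (!length(grouping)) {
    scores$dfi_age_adjusted <- scores$dfi - mean(scores$dfi)
    return(scores)
  }
  key <- interaction(scores[, grouping, drop = FALSE], drop = TRUE)
  sizes <- table(key)
  if (any(sizes == 1L))
    warning("singleton (sex, age) group(s): adjusted value set to 0")
  mu <- stats::ave(scores$dfi, key)
  scores$dfi_age_adjusted <- scores$dfi - mu
  scores
}

#' Reconstruction quality per feature
#'
#' RMSE and coefficient of determination `R^2 = 1 - SS_res/SS_tot` per
#' feature, in original units.  `R^2` may be negative for a particularly bad
#' fit and is `NA` for a zero-variance feature.
#'
#' @param model a trained `aear_model`.
#' @param matrix a `feature_matrix` or numeric matrix (original units).
#' @return list: `per_feature` data frame (feature, rmse, r2), `avg_rmse`,
#'   `avg_r2`.
#' @export
evaluate_reconstruction <- function(model, matrix) {
  stopifnot(inherits(model, "aear_model"))
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else as.matrix(matrix)
  Xs <- scale_input(model, X)
  rec <- unscale_output(model, decode(model, encode(model, Xs)))
  rm <- recon_metrics(X, rec)
  per <- data.frame(feature = if (is.null(colnames(X)))
    paste0("f", seq_len(ncol(X))) else colnames(X),
    rmse = rm$rmse, r2 = rm$r2, row.names = NULL)
  list(per_feature = per, avg_rmse = mean(rm$rmse),
       avg_r2 = mean(rm$r2, na.rm = TRUE))
}

# per-column RMSE and R^2 = 1 - SS_res/SS_tot (NA for zero-variance columns)
recon_metrics <- function(X, Xhat) {
  res <- Xhat - X
  sstot <- colSums(sweep(X, 2L, colMeans(X))^2)
  list(rmse = sqrt(colMeans(res^2)),
       r2 = ifelse(sstot > 0, 1 - colSums(res^2) / sstot, NA_real_))
}

#' Fit the exponential growth law to mean dFI by age
#'
#' Weighted nonlinear least squares of `z_bar * exp(alpha t) + z0` to group
#' means (weights `1/sem^2`), excluding groups above the lifespan cutoff --
#' beyond the mean lifespan the latent dynamics saturate and the
#' exponential-growth regime no longer applies.  The fit profiles out the
#' two linear parameters, leaving a 1-D search over `alpha`; standard errors
#' come from the Gauss-Newton information matrix.
#'
#' @param mean_dfi_by_age data frame with columns `age`, `mean`, `sem`.
#' @param lifespan_cutoff exclude groups with `age > lifespan_cutoff` (wk).
#' @param alpha_range search interval for the exponent, 1/week.
#' @return list: `alpha`, `z_bar`, `z0`, `se` (named), `ci` (95% for alpha),
#'   `fitted` data frame.
#' @export
fit_growth_exponent <- function(mean_dfi_by_age, lifespan_cutoff = Inf,
                                alpha_range = c(-0.2, 0.2)) {
  df <- mean_dfi_by_age
  stopifnot(all(c("age", "mean", "sem") %in% names(df)))
  df <- df[df$age <= lifespan_cutoff & is.finite(df$sem) & df$sem > 0, ]
  if (nrow(df) < 4) stop("need at least 4 age groups below the cutoff")
  w <- 1 / df$sem^2
  profile_sse <- function(alpha) {
    Xd <- cbind(exp(alpha * df$age), 1)
    fit <- stats::lm.wfit(Xd, df$mean, w)
    sum(w * fit$residuals^2)
  }
  opt <- stats::optimize(profile_sse, interval = alpha_range, tol = 1e-9)
  alpha <- opt$minimum
  Xd <- cbind(exp(alpha * df$age), 1)
  fit <- stats::lm.wfit(Xd, df$mean, w)
  zb <- fit$coefficients[1L]; z0 <- fit$coefficients[2L]
  # Jacobian of the model wrt (alpha, z_bar, z0)
  J <- cbind(zb * df$age * exp(alpha * df$age), exp(alpha * df$age), 1)
  info <- crossprod(J * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) matrix(Inf, 3, 3))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- c("alpha", "z_bar", "z0")
  pred <- as.numeric(Xd %*% c(zb, z0))
  list(alpha = alpha, z_bar = unname(zb), z0 = unname(z0), se = se,
       ci = c(alpha - 1.96 * se[["alpha"]], alpha + 1.96 * se[["alpha"]]),
       fitted = data.frame(age = df$age, mean = df$mean, sem = df$sem,
                           fitted = pred))
}

#' Auto-correlation of age-adjusted dFI along individual trajectories
#'
#' Pearson correlation between age-adjusted dFI values of the same animal at
#' visits separated by each requested lag (gap within `tolerance`).  High
#' auto-correlation distinguishes a persistent latent state from
#' measurement noise.
#'
#' @param scores a DFIScore data frame ([score_dfi()] output).
#' @param lags lags in weeks.
#' @param tolerance allowed gap deviation, weeks.
#' @return data frame: `lag`, `n_pairs`, `r`, `p` (lags with fewer than 3
#'   pairs are skipped with a warning).
#' @export
dfi_autocorrelation <- function(scores, lags = c(26), tolerance = 4) {
  stopifnot(is.data.frame(scores),
            all(c("animal_id", "age_weeks", "dfi_age_adjusted") %in% names(scores)))
  out <- list()
  for (lag in lags) {
    prs <- make_pairs(scores, interval = lag, tolerance = tolerance,
                      window = NULL)
    if (nrow(prs) < 3) {
      warning(sprintf("lag %g wk: fewer than 3 pairs, skipped", lag))
      next
    }
    a <- scores$dfi_age_adjusted[prs$row_now]
    b <- scores$dfi_age_adjusted[prs$row_next]
    ct <- stats::cor.test(a, b)
    out[[length(out) + 1L]] <- data.frame(lag = lag, n_pairs = nrow(prs),
                                          r = unname(ct$estimate),
                                          p = ct$p.value)
  }
  if (!length(out))
    return(data.frame(lag = numeric(), n_pairs = integer(), r = numeric(),
                      p = numeric()))
  do.call(rbind, out)
}
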