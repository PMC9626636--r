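# Minimal dense / residual-block neural network with hand-written
# backpropagation.  The whole AE-AR model is small (tens of thousands of
# parameters) and trains in seconds-to-minutes with BLAS matrix products,
# so no external deep-learning framework is needed -- and the gradients are
# unit-tested against finite differences.

lrelu <- function(x, slope) {
  pos <- x > 0
  x * pos + (slope * x) * !pos
}
lrelu_grad <- function(x, slope) {
  slope + (1 - slope) * (x > 0)
}

# architecture description: list of layer specs
# dense: list(type = "dense", d_in, d_out)
# resblock: list(type = "resblock", d, slope)
nn_arch <- function(d_in, d_hidden, d_out, n_blocks, slope) {
  layers <- list(list(type = "dense", d_in = d_in, d_out = d_hidden))
  for (i in seq_len(n_blocks))
    layers <- c(layers, list(list(type = "resblock", d = d_hidden,
                                  slope = slope)))
  c(layers, list(list(type = "dense", d_in = d_hidden, d_out = d_out)))
}

nn_init <- function(arch, scale = NULL) {
  lapply(arch, function(l) {
    if (l$type == "dense") {
      sd <- if (is.null(scale)) sqrt(2 / l$d_in) else scale
      list(W = matrix(stats::rnorm(l$d_in * l$d_out, sd = sd), l$d_in, l$d_out),
           b = numeric(l$d_out))
    } else {
      sd <- if (is.null(scale)) sqrt(2 / l$d) else scale
      list(W1 = matrix(stats::rnorm(l$d^2, sd = sd), l$d, l$d),
           b1 = numeric(l$d),
           W2 = matrix(stats::rnorm(l$d^2, sd = sd), l$d, l$d),
           b2 = numeric(l$d))
    }
  })
}

nn_forward <- function(arch, params, X) {
  caches <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    l <- arch[[i]]; p <- params[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- .dense_fwd(X, p$W, p$b)
    } else {
      fw <- .resblock_fwd(X, p$W1, p$b1, p$W2, p$b2, l$slope)
      caches[[i]] <- list(X = X, G1 = fw$G1, T1 = fw$T1, G2 = fw$G2)
      X <- fw$out
    }
  }
  list(out = X, caches = caches)
}

nn_backward <- function(arch, params, caches, dOut) {
  grads <- vector("list", length(arch))
  for (i in rev(seq_along(arch))) {
    l <- arch[[i]]; p <- params[[i]]; cc <- caches[[i]]
    if (l$type == "dense") {
      bw <- .dense_bwd(cc$X, p$W, dOut)
      grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
      dOut <- bw$dX
    } else {
      bw <- .resblock_bwd(cc$X, cc$G1, cc$T1, cc$G2, p$W1, p$W2, dOut)
      grads[[i]] <- list(W1 = bw$dW1, b1 = as.numeric(bw$db1),
                         W2 = bw$dW2, b2 = as.numeric(bw$db2))
      dOut <- bw$dX
    }
  }
  list(grads = grads, dX = dOut)
}

# sum of squared dense weights (L2 term; biases excluded) and its gradient
nn_l2 <- function(params) {
  s <- 0
  for (p in params)
    for (nm in intersect(names(p), c("W", "W1", "W2"))) s <- s + sum(p[[nm]]^2)
  s
}

nn_l2_grads <- function(params, coef) {
  lapply(params, function(p) {
    g <- lapply(p, function(x) x * 0)
    for (nm in intersect(names(p), c("W", "W1", "W2"))) g[[nm]] <- coef * 2 * p[[nm]]
    g
  })
}

# elementwise sum of two identically-shaped nested lists of numerics
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

# fast flatten/unflatten for nested parameter lists (utils::relist builds
# names recursively and is far too slow for a per-step hot path)
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(theta, template) {
  pos <- 0L
  rec <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, rec))
    n <- length(tpl)
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    d <- dim(tpl)
    if (!is.null(d)) dim(out) <- d
    out
  }
  rec(template)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(grad^2))
  if (is.finite(gn) && gn > clip) grad <- grad * (clip / gn)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}
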