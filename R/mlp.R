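# Feed-forward neural network for binary classification.
#
# A compact multi-layer perceptron supporting the hyperparameters the model
# grid declares: arbitrary hidden-layer architectures, identity / logistic /
# tanh / relu activations, and three solvers (full-batch adam, sgd with
# momentum, and l-bfgs via stats::optim). The output neuron is logistic and
# the loss is mean binary cross-entropy with an L2 weight penalty. Training
# is deterministic given the seed (initialization is the only stochastic
# element; both gradient solvers run full-batch).

.mlp_act <- function(name) {
  switch(name,
    identity = list(f = function(z) z,            df = function(a) 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)), df = function(a) a * (1 - a)),
    tanh     = list(f = tanh,                     df = function(a) 1 - a^2),
    relu     = list(f = function(z) pmax(z, 0),   df = function(a) (a > 0) + 0),
    .stopf("unknown activation '%s'", name))
}

.mlp_init <- function(sizes, seed) {
  .with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

.mlp_forward <- function(W, b, act, X) {
  L <- length(W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
    A[[l + 1L]] <- if (l < L) act$f(Z) else 1 / (1 + exp(-Z))
  }
  A
}

# Loss and exact gradients by backpropagation (cross-entropy + logistic
# output makes the output delta linear in the residual).
.mlp_grad <- function(W, b, act, X, y, l2) {
  n <- nrow(X)
  L <- length(W)
  A <- .mlp_forward(W, b, act, X)
  p <- A[[L + 1L]]
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
    l2 / 2 * sum(vapply(W, function(w) sum(w^2), 0))
  delta <- (p - y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta) + l2 * W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(W[[l]])) * act$df(A[[l]])
  }
  list(loss = loss, gW = gW, gb = gb)
}

.mlp_flatten <- function(W, b) unlist(c(lapply(W, as.numeric), b))

.mlp_unflatten <- function(theta, sizes) {
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(W)) {
    k <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(theta[pos + seq_len(k)], sizes[l], sizes[l + 1L])
    pos <- pos + k
  }
  for (l in seq_along(b)) {
    k <- sizes[l + 1L]
    b[[l]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  list(W = W, b = b)
}

.mlp_fit <- function(X, y, hidden = c(100L), activation = "relu",
                     solver = "adam", learning_rate_init = 0.001,
                     max_iter = 200L, l2 = 1e-4, seed = 1L) {
  stopifnot(is.matrix(X), all(y %in% c(0, 1)))
  act <- .mlp_act(activation)
  sizes <- c(ncol(X), hidden, 1L)
  par <- .mlp_init(sizes, seed)
  W <- par$W; b <- par$b

  if (solver == "lbfgs") {
    fn <- function(theta) {
      p <- .mlp_unflatten(theta, sizes)
      .mlp_grad(p$W, p$b, act, X, y, l2)$loss
    }
    gr <- function(theta) {
      p <- .mlp_unflatten(theta, sizes)
      g <- .mlp_grad(p$W, p$b, act, X, y, l2)
      .mlp_flatten(g$gW, g$gb)
    }
    opt <- stats::optim(.mlp_flatten(W, b), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter))
    par <- .mlp_unflatten(opt$par, sizes)
    W <- par$W; b <- par$b
  } else if (solver %in% c("adam", "sgd")) {
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; momentum <- 0.9
    for (it in seq_len(max_iter)) {
      g <- .mlp_grad(W, b, act, X, y, l2)
      for (l in seq_along(W)) {
        if (solver == "adam") {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$gW[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$gb[[l]]^2
          mhW <- mW[[l]] / (1 - beta1^it); vhW <- vW[[l]] / (1 - beta2^it)
          mhb <- mb[[l]] / (1 - beta1^it); vhb <- vb[[l]] / (1 - beta2^it)
          W[[l]] <- W[[l]] - learning_rate_init * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - learning_rate_init * mhb / (sqrt(vhb) + eps)
        } else {
          mW[[l]] <- momentum * mW[[l]] - learning_rate_init * g$gW[[l]]
          mb[[l]] <- momentum * mb[[l]] - learning_rate_init * g$gb[[l]]
          W[[l]] <- W[[l]] + mW[[l]]
          b[[l]] <- b[[l]] + mb[[l]]
        }
      }
    }
  } else {
    .stopf("unknown solver '%s'", solver)
  }
  list(W = W, b = b, activation = activation, hidden = hidden)
}

.mlp_ps <- function(fit, X) {
  if (nrow(X) == 0) return(numeric(0))
  act <- .mlp_act(fit$activation)
  A <- .mlp_forward(fit$W, fit$b, act, X)
  as.numeric(A[[length(A)]])
}
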