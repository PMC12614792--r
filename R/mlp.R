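# Small fully connected regression networks, trained with Adam on mean
# squared error. Plain matrix algebra keeps training deterministic under a
# seed and fast at the problem sizes used here (tens to hundreds of
# materials, feature widths 28-1341).

mlp_architectures <- list(
  T = c(1341L, 256L, 64L, 32L, 16L),
  S = c(28L, 16L, 16L, 16L),
  C = c(1024L, 512L, 512L, 16L)
)

mlp_init <- function(dims) {
  L <- length(dims) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1]), dims[l], dims[l + 1]) *
      sqrt(2 / dims[l])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, keep_hidden = FALSE) {
  L <- length(par$W)
  H <- vector("list", L + 1)
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    H[[l + 1]] <- if (l < L) pmax(Z, 0) else Z # rectifier on hidden, identity out
  }
  if (keep_hidden) H else H[[L + 1]]
}

mlp_grad <- function(par, X, Y) {
  L <- length(par$W)
  H <- mlp_forward(par, X, keep_hidden = TRUE)
  n <- nrow(X)
  delta <- 2 * (H[[L + 1]] - Y) / (n * ncol(Y)) # d(MSE)/d(out)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (H[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

mlp_loss <- function(par, X, Y) mean((mlp_forward(par, X) - Y)^2)

# Adam minimisation of the MSE with optional early stopping on a validation
# slice; everything (init, shuffling, split) is driven by the caller's seed
mlp_fit <- function(X, Y, dims, lr = 1e-3, epochs = 4000, batch_size = 32,
                    val_frac = 0.1, patience = 300, weight_decay = 1,
                    seed = 1) {
  with_local_seed(seed, {
    n <- nrow(X)
    par <- mlp_init(dims)
    n_val <- floor(val_frac * n)
    use_val <- n_val >= 1 && n - n_val >= 2
    if (use_val) {
      vi <- sample.int(n, n_val)
      Xv <- X[vi, , drop = FALSE]; Yv <- Y[vi, , drop = FALSE]
      Xt <- X[-vi, , drop = FALSE]; Yt <- Y[-vi, , drop = FALSE]
    } else {
      Xt <- X; Yt <- Y
    }
    m <- lapply(par$W, function(w) w * 0)
    v <- m
    mb <- lapply(par$b, function(bb) bb * 0)
    vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t <- 0
    best <- list(par = par, loss = Inf, epoch = 0)
    history <- numeric(0)
    nt <- nrow(Xt)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nt)
      for (start in seq(1, nt, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nt)]
        g <- mlp_grad(par, Xt[idx, , drop = FALSE], Yt[idx, , drop = FALSE])
        t <- t + 1
        for (l in seq_along(par$W)) {
          m[[l]] <- b1 * m[[l]] + (1 - b1) * g$W[[l]]
          v[[l]] <- b2 * v[[l]] + (1 - b2) * g$W[[l]]^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
          mh <- m[[l]] / (1 - b1^t); vh <- v[[l]] / (1 - b2^t)
          # decoupled weight decay on the weights (not the biases)
          par$W[[l]] <- par$W[[l]] -
            lr * (mh / (sqrt(vh) + eps) + weight_decay * par$W[[l]])
          mbh <- mb[[l]] / (1 - b1^t); vbh <- vb[[l]] / (1 - b2^t)
          par$b[[l]] <- par$b[[l]] - lr * mbh / (sqrt(vbh) + eps)
        }
      }
      monitor <- if (use_val) mlp_loss(par, Xv, Yv) else mlp_loss(par, Xt, Yt)
      history <- c(history, monitor)
      if (monitor < best$loss - 1e-12) {
        best <- list(par = par, loss = monitor, epoch = ep)
      } else if (use_val && ep - best$epoch >= patience) {
        break
      }
    }
    final <- if (use_val) best$par else par
    list(par = final, history = history,
         train_loss = mlp_loss(final, Xt, Yt),
         val_loss = if (use_val) best$loss else NA_real_,
         epochs_run = length(history))
  })
}

mlp_n_params <- function(par) {
  sum(vapply(par$W, length, numeric(1))) + sum(vapply(par$b, length, numeric(1)))
}
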