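# Minimal feed-forward network used only as a benchmark baseline: two
# hidden ReLU layers trained with full-batch Adam on squared error, early
# stopping on a 10% validation split. Not the product model.

mlp_fit <- function(X, y, hidden = c(32L, 16L), lr = 0.01, max_epochs = 300L,
                    patience = 25L, val_frac = 0.1, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  with_seed(seed, {
    n_val <- max(1L, floor(val_frac * n))
    idx <- sample.int(n)
    val <- idx[seq_len(n_val)]
    tr <- idx[-seq_len(n_val)]
    sizes <- c(ncol(X), hidden, 1L)
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    forward <- function(W, b, X) {
      a <- list(X)
      L <- length(W)
      for (l in seq_len(L)) {
        z <- a[[l]] %*% W[[l]] + matrix(b[[l]], nrow(X), length(b[[l]]),
                                        byrow = TRUE)
        a[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      a
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- list(W = W, b = b, loss = Inf); wait <- 0L; t_adam <- 0L
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xval <- X[val, , drop = FALSE]; yval <- y[val]
    L <- length(W)
    for (epoch in seq_len(max_epochs)) {
      a <- forward(W, b, Xtr)
      pred <- a[[L + 1]][, 1]
      delta <- matrix(2 * (pred - ytr) / length(ytr), ncol = 1)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(a[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
      t_adam <- t_adam + 1L
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        corr1 <- 1 - beta1^t_adam; corr2 <- 1 - beta2^t_adam
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
      vp <- forward(W, b, Xval)[[L + 1]][, 1]
      vloss <- mean((vp - yval)^2)
      if (vloss < best$loss - 1e-9) {
        best <- list(W = W, b = b, loss = vloss); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(W = best$W, b = best$b, feature_names = colnames(X)),
              class = "mlp")
  })
}

#' @export
predict.mlp <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  a <- newdata
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- a %*% object$W[[l]] +
      matrix(object$b[[l]], nrow(a), length(object$b[[l]]), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
  }
  as.numeric(a[, 1])
}
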