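# Independent SIMPLS implementation (de Jong 1993), used only as a test
# oracle for the package's NIPALS engine. Kept deliberately separate from
# the implementation under test.

simpls_pls1 <- function(X, y, n_lv) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  X0 <- sweep(X, 2, x_mean)
  y0 <- y - y_mean
  p <- ncol(X0)
  S <- crossprod(X0, y0)
  R <- V <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    r <- S
    t_ <- X0 %*% r
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt
    r <- r / nt
    p_ <- crossprod(X0, t_)
    q <- sum(y0 * t_)
    v <- p_
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    Q[a] <- q
  }
  b <- as.vector(R %*% Q)
  list(coefficients = b, x_mean = x_mean, y_mean = y_mean)
}

predict_simpls <- function(fit, X_new) {
  fit$y_mean + as.vector(sweep(as.matrix(X_new), 2, fit$x_mean) %*%
                           fit$coefficients)
}
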