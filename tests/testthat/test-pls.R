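rand_problem <- function(n, p, seed, informative = min(3, p)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rnorm(informative), rep(0, p - informative))
  y <- as.vector(X %*% beta) + rnorm(n, sd = 0.3)
  list(X = X, y = y)
}

test_that("one latent variable on a single column equals simple least squares", {
  pr <- rand_problem(25, 1, 1)
  fit <- fit_pls(pr$X, pr$y, 1)
  ols <- lm(pr$y ~ pr$X[, 1])
  expect_equal(unname(fit$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-10)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares predictions", {
  pr <- rand_problem(20, 10, 2)
  fit <- fit_pls(pr$X, pr$y, 10)
  ols <- lm(pr$y ~ pr$X)
  expect_lt(max(abs(fit$fitted - unname(fitted(ols)))), 1e-8)
})

test_that("a response orthogonal to X yields no explained variance", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Xc <- scale(X, scale = FALSE)
  e <- rnorm(30)
  ## project the noise out of the column space of [1, Xc]
  y <- e - cbind(1, Xc) %*% qr.solve(cbind(1, Xc), e)
  y <- as.vector(y) + 5
  fit <- fit_pls(X, y, 2, strict = FALSE)
  expect_lt(max(abs(fit$y_loadings)), 1e-8)
  expect_equal(fit$fitted, rep(mean(y), 30), tolerance = 1e-6)
})

test_that("score orthogonality, deflation monotonicity and prediction-path equivalence", {
  pr <- rand_problem(30, 12, 4)
  A <- 6
  fit <- fit_pls(pr$X, pr$y, A)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  ## sequential score-space predictions equal regression-vector predictions
  Xc <- sweep(pr$X, 2, fit$x_center)
  Tn <- Xc %*% fit$weights %*%
    solve(crossprod(fit$loadings, fit$weights))
  expect_lt(max(abs(fit$y_center + Tn %*% fit$y_loadings - fit$fitted)),
            1e-8)

  ## frobenius norm of the deflated X decreases per component
  X <- sweep(pr$X, 2, colMeans(pr$X))
  yc <- pr$y - mean(pr$y)
  norms <- numeric(A)
  for (a in seq_len(A)) {
    w <- fit$weights[, a]
    t_ <- X %*% w
    p_ <- crossprod(X, t_) / sum(t_^2)
    X <- X - t_ %*% t(p_)
    norms[a] <- norm(X, "F")
  }
  expect_true(all(diff(c(norm(sweep(pr$X, 2, colMeans(pr$X)), "F"), norms))
                  < 1e-10))
})

test_that("training error is non-increasing in the component count", {
  pr <- rand_problem(25, 10, 5)
  rmsec <- vapply(1:8, function(a) {
    sqrt(mean(fit_pls(pr$X, pr$y, a)$residuals^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) < 1e-12))
})

test_that("NIPALS matches the independent SIMPLS oracle on random problems", {
  for (seed in 1:25) {
    n <- sample(8:30, 1)
    p <- sample(2:15, 1)
    pr <- rand_problem(n, p, seed + 100)
    for (a in unique(c(1, min(3, p), min(n - 1, p)))) {
      fit <- fit_pls(pr$X, pr$y, a, strict = FALSE)
      oracle <- simpls_pls1(pr$X, pr$y, fit$n_lv)
      expect_lt(max(abs(predict(fit, pr$X) - predict_simpls(oracle, pr$X))),
                1e-6)
    }
  }
})

test_that("degenerate fits are rejected with informative errors", {
  pr <- rand_problem(10, 4, 6)
  expect_error(fit_pls(pr$X, rep(2, 10), 2), "zero variance")
  expect_error(fit_pls(pr$X, pr$y, 9), "1..min")
  ## rank-1 X cannot support 3 components
  X1 <- outer(rnorm(12), rnorm(5))
  y <- X1[, 1] + 1
  expect_error(fit_pls(X1, y, 3), "rank")
  expect_warning(f <- fit_pls(X1, y, 3, strict = FALSE), "truncated")
  expect_equal(f$n_lv, 1L)
})

test_that("prediction validates the wavenumber grid and honors the centroid", {
  pr <- rand_problem(15, 6, 7)
  colnames(pr$X) <- as.character(1000:1005)
  fit <- fit_pls(pr$X, pr$y, 3)
  expect_equal(predict(fit, pr$X), fit$fitted)
  centroid <- matrix(fit$x_center, 1,
                     dimnames = list(NULL, colnames(pr$X)))
  expect_equal(predict(fit, centroid), fit$y_center, tolerance = 1e-10)
  wrong <- pr$X
  colnames(wrong) <- as.character(2000:2005)
  expect_error(predict(fit, wrong), "mismatch")
})

test_that("VIP scores satisfy their defining identities", {
  ## p = 1: normalization forces VIP = 1
  pr1 <- rand_problem(20, 1, 8)
  expect_equal(vip_scores(fit_pls(pr1$X, pr1$y, 1))$vip, 1)

  ## y tied to column 1 only: VIP_1 > 1 > VIP_2
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + rnorm(20, sd = 0.05)
  v <- vip_scores(fit_pls(X, y, 2))$vip
  expect_gt(v[1], 1)
  expect_lt(v[2], 1)

  ## mean of squared VIP is exactly 1 for any fitted model
  for (seed in 10:14) {
    pr <- rand_problem(18, 9, seed)
    v <- vip_scores(fit_pls(pr$X, pr$y, 4))$vip
    expect_lt(abs(mean(v^2) - 1), 1e-10)
    expect_true(all(v >= 0))
  }
})

test_that("leverage and standardized residuals follow their definitions", {
  pr <- rand_problem(24, 8, 15)
  A <- 4
  fit <- fit_pls(pr$X, pr$y, A)
  d <- pls_diagnostics(fit)
  n <- 24
  expect_true(all(d$leverage >= 1 / n - 1e-12))
  expect_true(all(d$leverage <= 1 + 1e-12))
  expect_equal(sum(d$leverage), A + 1, tolerance = 1e-8)
  expect_equal(sum(d$std_residual^2), n - A - 1, tolerance = 1e-8)

  ## a sample sitting at the centroid has minimal leverage 1/n
  X2 <- rbind(pr$X, colMeans(pr$X))
  y2 <- c(pr$y, mean(pr$y))
  fit2 <- fit_pls(X2, y2, A)
  d2 <- pls_diagnostics(fit2)
  expect_equal(d2$leverage[25], 1 / 25, tolerance = 1e-8)

  ## duplicating a calibration row lowers that row's leverage when the
  ## score matrix is recomputed on the augmented data
  T3 <- rbind(fit$scores, fit$scores[3, ])
  h3 <- 1 / 25 + as.numeric(T3[3, ] %*% solve(crossprod(T3), T3[3, ]))
  expect_lt(h3, d$leverage[3])

  expect_error(pls_diagnostics(fit_pls(pr$X[1:5, ], pr$y[1:5], 4)),
               "degrees of freedom")
})

test_that("models persist to JSON and reload with identical predictions", {
  pr <- rand_problem(20, 7, 16)
  colnames(pr$X) <- as.character(800:806)
  fit <- fit_pls(pr$X, pr$y, 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_pls_model(fit, path)
  fit2 <- load_pls_model(path)
  expect_identical(predict(fit2, pr$X), predict(fit, pr$X))
  expect_identical(fit2$coefficients, fit$coefficients)
})

test_that("tidy and glance summarize a fitted model", {
  pr <- rand_problem(20, 5, 17)
  colnames(pr$X) <- as.character(1101:1105)
  fit <- fit_pls(pr$X, pr$y, 2)
  td <- tidy(fit)
  expect_equal(names(td), c("wavenumber", "coefficient", "vip"))
  expect_equal(nrow(td), 5L)
  gl <- glance(fit)
  expect_equal(gl$n_lv, 2L)
  expect_equal(gl$rmsec, sqrt(mean(fit$residuals^2)))
})
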