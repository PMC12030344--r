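#' Fit a PLS1 regression model (NIPALS)
#'
#' Single-response partial least squares by the classical NIPALS algorithm.
#' Per component `a`: the weight `w_a` is proportional to `X'y` (unit norm),
#' scores `t_a = X w_a`, X-loading `p_a = X't_a / t_a't_a`, y-loading
#' `q_a = y't_a / t_a't_a`, after which both `X` and `y` are deflated. The
#' regression vector is assembled as `b = W (P'W)^-1 q`, so predictions are
#' `y_center + (x - x_center) b`. The explained y-variance per component,
#' `SSY_a = q_a^2 t_a't_a`, is recorded for VIP scoring.
#'
#' @param x Predictor matrix, a data frame/tibble with wavenumber columns,
#'   or a plain numeric matrix (rows = samples).
#' @param y Numeric response, one value per row.
#' @param n_lv Number of latent variables, at most `min(n - 1, p)`.
#' @param center Learn column/response means from the data (default)? Set
#'   to `FALSE` when `x` and `y` are already centered.
#' @param strict If the deflated `X` collapses before `n_lv` components,
#'   fail (`TRUE`) or truncate with a warning (`FALSE`).
#' @return A `raman_pls` object with elements `n_lv`, `weights` (p x A),
#'   `loadings` (p x A), `y_loadings` (A), `coefficients` (p), `x_center`,
#'   `y_center`, `scores` (n x A), `ssy` (per-component explained
#'   y-variance), `fitted`, `residuals`, `wavenumbers`.
#' @seealso [predict.raman_pls()], [vip_scores()], [pls_diagnostics()]
#' @export
fit_pls <- function(x, y, n_lv, center = TRUE, strict = TRUE) {
  xm <- as_pls_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm); p <- ncol(xm)
  if (length(y) != n) abort("`x` and `y` must have matching rows.")
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    abort("`n_lv` must lie in 1..min(n - 1, p).")
  }
  if (sd(y) == 0) abort("`y` has zero variance; nothing to model.")

  x_center <- if (center) colMeans(xm) else numeric(p)
  y_center <- if (center) mean(y) else 0
  X <- sweep(xm, 2, x_center)
  yc <- y - y_center

  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- ssy <- numeric(n_lv)
  tol <- 1e-12 * sqrt(sum(crossprod(X, yc)^2))

  a <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(X, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= tol || !is.finite(nw)) break
    w <- w / nw
    t_ <- X %*% w
    tt <- sum(t_^2)
    if (tt <= .Machine$double.eps) break
    p_ <- crossprod(X, t_) / tt
    q_ <- sum(yc * t_) / tt
    X <- X - t_ %*% t(p_)
    yc <- yc - t_ * q_
    a <- k
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- t_
    q[k] <- q_; ssy[k] <- q_^2 * tt
  }
  if (a < n_lv) {
    msg <- paste0("X is numerically exhausted after ", a,
                  " components (", n_lv, " requested).")
    if (strict) abort(paste(msg, "Achievable rank:", a))
    warn(paste(msg, "Model truncated."))
    if (a == 0L) abort("No PLS component could be extracted.")
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]; ssy <- ssy[seq_len(a)]
  }
  b <- as.vector(W %*% solve(crossprod(P, W), q))
  fitted <- y_center + as.vector(sweep(xm, 2, x_center) %*% b)
  structure(
    list(n_lv = a, weights = W, loadings = P, y_loadings = q,
         coefficients = b, x_center = x_center, y_center = y_center,
         scores = Tm, ssy = ssy, fitted = fitted, residuals = y - fitted,
         wavenumbers = colnames(xm)),
    class = "raman_pls"
  )
}

as_pls_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (length(wn_cols(x))) return(spectra_matrix(x))
    x <- as.matrix(x)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

#' @export
print.raman_pls <- function(x, ...) {
  cat("<raman_pls> ", x$n_lv, " latent variable(s), ",
      length(x$coefficients), " variables, ", nrow(x$scores),
      " calibration samples\n", sep = "")
  cat("  RMSEC: ", signif(sqrt(mean(x$residuals^2)), 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' `y_hat = y_center + (x_new - x_center) b`. The new data must carry
#' exactly the model's retained wavenumbers (extra tibble metadata columns
#' are ignored); any discrepancy is reported.
#'
#' @param object A `raman_pls` model.
#' @param newdata Tibble with wavenumber columns, or numeric matrix with
#'   matching columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.raman_pls <- function(object, newdata, ...) {
  m <- as_pls_matrix(newdata)
  if (!identical(colnames(m), object$wavenumbers)) {
    missing <- setdiff(object$wavenumbers, colnames(m))
    extra <- setdiff(colnames(m), object$wavenumbers)
    abort(paste0(
      "Wavenumber mismatch between model and new data.",
      if (length(missing)) paste0(" Missing: ",
        paste(head(missing, 5), collapse = ", "),
        if (length(missing) > 5) ", ..."),
      if (length(extra)) paste0(" Unexpected: ",
        paste(head(extra, 5), collapse = ", "),
        if (length(extra) > 5) ", ...")))
  }
  object$y_center + as.vector(sweep(m, 2, object$x_center) %*%
                                object$coefficients)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)`: each
#' variable's contribution to the model weighted by the y-variance each
#' component explains. By construction the mean of `VIP^2` over variables
#' is 1, so scores above 1 flag variables contributing more than average —
#' the usual significance rule.
#'
#' @param model A fitted `raman_pls` model.
#' @return A tibble with columns `wavenumber` (numeric where the model was
#'   fitted on wavenumber columns) and `vip`, of class `vip_profile`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "raman_pls"))
  if (all(model$ssy == 0)) {
    abort("Model explains no y-variance; VIP undefined.")
  }
  W <- model$weights
  wnorm2 <- colSums(W^2)
  contrib <- sweep(W^2, 2, wnorm2, "/")
  p <- nrow(W)
  vip <- sqrt(p * as.vector(contrib %*% model$ssy) / sum(model$ssy))
  wn <- suppressWarnings(as.numeric(model$wavenumbers))
  out <- tibble::tibble(
    wavenumber = if (all(is.finite(wn))) wn else model$wavenumbers,
    vip = vip
  )
  class(out) <- c("vip_profile", class(out))
  out
}

#' Leverage and standardized-residual diagnostics
#'
#' Leverage `h_i = 1/n + t_i' (T'T)^-1 t_i` (the 1/n term accounts for
#' centering) and standardized residuals `e_i / s` with
#' `s^2 = sum(e^2) / (n - A - 1)`. Points with high leverage but small
#' residuals are influential yet well fitted; large standardized residuals
#' flag candidate outliers.
#'
#' @param model A fitted `raman_pls` model.
#' @param x,y Optional data to diagnose; defaults to the calibration fit
#'   stored in the model.
#' @return A tibble `sample`, `fitted`, `residual`, `leverage`,
#'   `std_residual`, of class `pls_diagnostics`.
#' @export
pls_diagnostics <- function(model, x = NULL, y = NULL) {
  stopifnot(inherits(model, "raman_pls"))
  Tm <- model$scores
  n <- nrow(Tm)
  if (is.null(x) != is.null(y)) abort("Supply both `x` and `y` or neither.")
  if (!is.null(x)) {
    m <- sweep(as_pls_matrix(x), 2, model$x_center)
    ## project on the model's score space: T_new = X W (P'W)^-1
    Tnew <- m %*% model$weights %*%
      solve(crossprod(model$loadings, model$weights))
    pred <- predict(model, x)
    resid <- as.numeric(y) - pred
  } else {
    Tnew <- Tm
    pred <- model$fitted
    resid <- model$residuals
  }
  dof <- n - model$n_lv - 1
  if (dof <= 0) {
    abort("No residual degrees of freedom (n <= n_lv + 1).")
  }
  s <- sqrt(sum(model$residuals^2) / dof)
  lev <- 1 / n + rowSums((Tnew %*% solve(crossprod(Tm))) * Tnew)
  out <- tibble::tibble(sample = seq_len(nrow(Tnew)),
                        fitted = pred,
                        residual = resid,
                        leverage = lev,
                        std_residual = resid / s)
  class(out) <- c("pls_diagnostics", class(out))
  out
}

# ---------------------------------------------------------------------------
# broom-style accessors and persistence
# ---------------------------------------------------------------------------

#' Tidy a fitted PLS model
#'
#' One row per retained variable: regression coefficient and VIP score.
#'
#' @param x A `raman_pls` model.
#' @param ... Unused.
#' @return A tibble with `wavenumber`, `coefficient`, `vip`.
#' @export
tidy.raman_pls <- function(x, ...) {
  v <- vip_scores(x)
  tibble::tibble(wavenumber = v$wavenumber,
                 coefficient = x$coefficients,
                 vip = v$vip)
}

#' Glance at a fitted PLS model
#'
#' @param x A `raman_pls` model.
#' @param ... Unused.
#' @return A one-row tibble: `n_lv`, `n_obs`, `n_vars`, `rmsec`, `r2_cal`.
#' @export
glance.raman_pls <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble::tibble(
    n_lv = x$n_lv,
    n_obs = nrow(x$scores),
    n_vars = length(x$coefficients),
    rmsec = sqrt(mean(x$residuals^2)),
    r2_cal = 1 - sum(x$residuals^2) / sum((y - mean(y))^2)
  )
}

#' Save / load a PLS model as JSON
#'
#' Flat JSON with full floating-point precision; a reloaded model
#' reproduces predictions exactly.
#'
#' @param model A `raman_pls` model.
#' @param path File path.
#' @return `load_pls_model()` returns the `raman_pls` object.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "raman_pls"))
  payload <- list(
    n_lv = model$n_lv,
    wavenumbers = model$wavenumbers,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, coefficients = model$coefficients,
    x_center = model$x_center, y_center = model$y_center,
    scores = model$scores, ssy = model$ssy,
    fitted = model$fitted, residuals = model$residuals
  )
  ## I(17) significant digits: lossless IEEE double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pls_model
#' @export
load_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "loadings", "scores")) {
    p[[nm]] <- matrix(as.numeric(p[[nm]]), ncol = max(1, p$n_lv))
  }
  p$wavenumbers <- as.character(p$wavenumbers)
  structure(p[c("n_lv", "weights", "loadings", "y_loadings", "coefficients",
                "x_center", "y_center", "scores", "ssy", "fitted",
                "residuals", "wavenumbers")],
            class = "raman_pls")
}
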