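#' Root mean square error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`, in the analyte's units.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) abort("Empty input.")
  if (length(y_true) != length(y_pred)) abort("Lengths differ.")
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` between reference values and predictions.
#' On external test data this can be negative; it is reported as-is.
#'
#' @param y_true Reference values (must not be constant).
#' @param y_pred Predictions.
#' @return Unitless scalar.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Lengths differ.")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("`y_true` is constant; R^2 undefined.")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Relative prediction error, RMSEP(%)
#'
#' Expresses an RMSEP as a percentage of either the mean or the upper limit
#' of the validation range — the two conventions used when reporting
#' bioprocess calibration models (low-concentration analytes are usually
#' reported against the maximum).
#'
#' @param rmsep Prediction error in analyte units.
#' @param y_val Validation reference values (defines the denominator).
#' @param mode `"average"` or `"max"`.
#' @return Percent (0-100 scale).
#' @examples
#' rmsep_percent(0.5, c(2, 5, 8), mode = "average")
#' @export
rmsep_percent <- function(rmsep, y_val, mode = c("average", "max")) {
  mode <- match.arg(mode)
  denom <- switch(mode, average = mean(y_val), max = max(y_val))
  if (!is.finite(denom) || denom <= 0) {
    abort("The validation-range denominator must be positive.")
  }
  100 * rmsep / denom
}

#' Pearson cross-correlation between two analyte time courses
#'
#' Cross-correlation between analyte concentration series drives model
#' specificity: two analytes whose courses are strongly correlated cannot
#' be distinguished by a regression on spectra alone, which is why a batch
#' with induced cell death (decoupling viable from total cell density) is
#' valuable in calibration.
#'
#' @param a,b Equal-length numeric series (length >= 3, non-constant).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("Series lengths differ.")
  if (length(a) < 3) abort("Series must have at least 3 points.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Cross-correlation undefined for constant series.")
  }
  cor(a, b)
}

#' Pairwise cross-correlation table for a batch
#'
#' Computes [cross_correlation()] between analyte series measured on a
#' common time base (the off-line sampling times of one batch).
#'
#' @param offline Off-line reference tibble of one batch (`timestamp_h`,
#'   `analyte`, `value`).
#' @param analytes Which analytes to cross (default: all present).
#' @return A tibble `analyte_a`, `analyte_b`, `cc`.
#' @export
cross_correlation_table <- function(offline,
                                    analytes = unique(offline$analyte)) {
  wide <- offline |>
    dplyr::filter(.data$analyte %in% analytes) |>
    dplyr::select(dplyr::all_of(c("timestamp_h", "analyte", "value"))) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  pairs <- utils::combn(analytes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    tibble::tibble(analyte_a = pairs[1, i], analyte_b = pairs[2, i],
                   cc = cross_correlation(wide[[pairs[1, i]]],
                                          wide[[pairs[2, i]]]))
  })
}

#' k-fold cross-validation for latent-variable selection
#'
#' Splits the calibration samples into `k` folds, refits the PLS model on
#' the training folds for every candidate component count and accumulates
#' the held-out squared errors into RMSECV(A). Centering (the only
#' statistics-bearing part of the default preprocessing chain) is
#' re-learned on the training folds of each split, so the held-out fold
#' never leaks into the transformation. The selected component count
#' minimizes RMSECV, with ties resolved toward the smaller model.
#'
#' Fold assignment is contiguous in time within each batch by default —
#' conservative for autocorrelated bioprocess trajectories — or random
#' under a fixed seed.
#'
#' @param x Predictors (tibble with wavenumber columns, or matrix).
#' @param y Response vector.
#' @param k Number of folds (>= 2); `k = n` is leave-one-out.
#' @param max_lv Largest candidate component count (truncated with a
#'   warning if a training split cannot support it).
#' @param scheme `"contiguous"` or `"random"`.
#' @param groups Optional batch ids (fold blocks are contiguous within each
#'   group under the contiguous scheme).
#' @param seed Seed for the random scheme.
#' @param center Passed to [fit_pls()]; `FALSE` only when `x`/`y` are
#'   pre-centered externally (used to demonstrate centering leakage).
#' @return A `cv_result`: tibble `summary` (`n_lv`, `rmsecv`, `r2_cv`),
#'   `n_lv` (chosen), `folds`, `k`.
#' @export
kfold_cv <- function(x, y, k = 3, max_lv = 12,
                     scheme = c("contiguous", "random"), groups = NULL,
                     seed = 1L, center = TRUE) {
  scheme <- match.arg(scheme)
  xm <- as_pls_matrix(x)
  y <- as.numeric(y)
  n <- nrow(xm)
  if (k < 2 || k > n) abort("`k` must lie in 2..n.")
  folds <- assign_folds(n, k, scheme, groups, seed)

  max_train_lv <- min(purrr::map_int(seq_len(k), function(f) {
    nt <- sum(folds != f)
    as.integer(min(nt - 1, ncol(xm)))
  }))
  if (max_lv > max_train_lv) {
    warn(paste0("`max_lv` reduced from ", max_lv, " to ", max_train_lv,
                " (training-fold size)."))
    max_lv <- max_train_lv
  }

  press <- matrix(NA_real_, n, max_lv)
  achievable <- max_lv
  for (f in seq_len(k)) {
    tr <- folds != f
    fit_max <- tryCatch(
      fit_pls(xm[tr, , drop = FALSE], y[tr], n_lv = max_lv,
              center = center, strict = FALSE),
      error = function(e) abort(paste0("Cross-validation fold ", f,
                                       " failed: ", conditionMessage(e))))
    if (fit_max$n_lv < achievable) achievable <- fit_max$n_lv
    for (a in seq_len(fit_max$n_lv)) {
      ## re-fit at each candidate A: deflation makes the A-component
      ## coefficients differ from truncating the max_lv fit
      fit_a <- if (a == fit_max$n_lv) fit_max else
        fit_pls(xm[tr, , drop = FALSE], y[tr], n_lv = a, center = center)
      press[!tr, a] <- (y[!tr] - predict(fit_a, xm[!tr, , drop = FALSE]))^2
    }
  }
  if (achievable < max_lv) {
    warn(paste0("Candidate components truncated to ", achievable,
                " (rank of the training splits)."))
  }
  rmsecv <- sqrt(colMeans(press[, seq_len(achievable), drop = FALSE]))
  ss_tot <- sum((y - mean(y))^2)
  r2_cv <- 1 - colSums(press[, seq_len(achievable), drop = FALSE]) / ss_tot
  chosen <- which.min(rmsecv)  # which.min takes the first = smallest A
  structure(
    list(summary = tibble::tibble(n_lv = seq_len(achievable),
                                  rmsecv = rmsecv, r2_cv = r2_cv),
         n_lv = as.integer(chosen), folds = folds, k = k),
    class = "cv_result"
  )
}

assign_folds <- function(n, k, scheme, groups, seed) {
  if (scheme == "random") {
    return(local({
      set.seed(seed)
      sample(rep_len(seq_len(k), n))
    }))
  }
  if (is.null(groups)) groups <- rep(1L, n)
  folds <- integer(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ## contiguous blocks in (time) order within the group
    folds[idx] <- as.integer(cut(seq_along(idx), breaks = k, labels = FALSE))
  }
  folds
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold; chosen n_lv = ", x$n_lv,
      " (RMSECV ", signif(x$summary$rmsecv[x$n_lv], 4), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(k = x$k, n_lv = x$n_lv,
                 rmsecv = x$summary$rmsecv[x$n_lv],
                 r2_cv = x$summary$r2_cv[x$n_lv])
}

#' @export
tidy.cv_result <- function(x, ...) x$summary
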