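#' Normalize spectra by total acquisition time
#'
#' Divides raw counts by `integration_time_s * n_scans`, bringing every
#' spectrum to an equivalent 1 s acquisition (counts/s) so that batches
#' recorded with different integration times and scan counts are
#' comparable. Guarded against double application through the `normalized`
#' flag column.
#'
#' @param data A spectra tibble with `normalized = FALSE`.
#' @return The spectra tibble in counts/s with `normalized = TRUE`.
#' @export
normalize_by_integration_time <- function(data) {
  if (!all(c("integration_time_s", "n_scans") %in% names(data))) {
    abort("`data` must carry `integration_time_s` and `n_scans` columns.")
  }
  if (isTRUE(any(data$normalized))) {
    abort("Spectra are already acquisition-time normalized.")
  }
  total <- data$integration_time_s * data$n_scans
  if (any(!is.finite(total)) || any(total <= 0)) {
    abort("`integration_time_s * n_scans` must be positive.")
  }
  m <- spectra_matrix(data) / total
  out <- spectra_replace(data, m)
  out$normalized <- TRUE
  out
}

#' Average consecutive spectra in non-overlapping blocks
#'
#' Averages blocks of `n` consecutive spectra (per batch, in time order) to
#' improve signal-to-noise ratio; the block timestamp is the mean of the
#' member timestamps and a trailing incomplete block is dropped.
#' Non-overlapping blocks ensure no spectrum contributes to two averaged
#' samples.
#'
#' @param data A spectra tibble (single grid).
#' @param n Block size (>= 1); `n = 1` is the identity.
#' @return The averaged spectra tibble.
#' @export
average_consecutive <- function(data, n = 3) {
  if (n < 1) abort("`n` must be at least 1.")
  if (n == 1) return(data)
  data |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$timestamp_h)
      block <- (seq_len(nrow(d)) - 1L) %/% n
      keep <- block < nrow(d) %/% n
      d <- d[keep, , drop = FALSE]
      block <- block[keep]
      m <- spectra_matrix(d)
      avg <- rowsum(m, block) / as.vector(table(block))
      meta <- d |>
        dplyr::mutate(.block = block) |>
        dplyr::group_by(.data$.block) |>
        dplyr::summarise(
          timestamp_h = mean(.data$timestamp_h),
          integration_time_s = .data$integration_time_s[1],
          n_scans = .data$n_scans[1],
          normalized = .data$normalized[1],
          .groups = "drop") |>
        dplyr::select(-dplyr::all_of(".block"))
      dplyr::bind_cols(meta, tibble::as_tibble(avg, .name_repair = "minimal"))
    }) |>
    dplyr::ungroup()
}

#' Pair averaged spectra with their nearest off-line reference values
#'
#' Each off-line sample of the requested analyte is matched to the
#' temporally nearest spectrum (ties broken toward the earlier spectrum).
#' Samples with no spectrum within `max_lag_h` are skipped with a warning.
#'
#' @param data Averaged spectra tibble.
#' @param offline Off-line reference tibble (`timestamp_h`, `analyte`,
#'   `value`, ...).
#' @param analyte One of the ids in [analyte_info()].
#' @param max_lag_h Maximum allowed |spectrum time - sample time| (h).
#' @return A paired tibble: metadata columns `batch_id`, `timestamp_h`
#'   (spectrum), `ref_time_h`, `lag_h`, `analyte`, `value`, followed by the
#'   wavenumber columns.
#' @export
pair_with_reference <- function(data, offline, analyte, max_lag_h = 1) {
  stopifnot(length(analyte) == 1L)
  if (nrow(data) == 0L || nrow(offline) == 0L) {
    abort("Both spectra and off-line references must be non-empty.")
  }
  refs <- offline[offline$analyte == analyte, , drop = FALSE]
  pairs <- purrr::map_dfr(split(refs, refs$batch_id), function(rb) {
    sb <- data[data$batch_id == rb$batch_id[1], , drop = FALSE]
    if (nrow(sb) == 0L) return(NULL)
    purrr::map_dfr(seq_len(nrow(rb)), function(i) {
      lag <- abs(sb$timestamp_h - rb$timestamp_h[i])
      j <- which.min(lag)  # which.min takes the first (earlier) on ties
      if (lag[j] > max_lag_h) {
        warn(paste0("No spectrum within ", max_lag_h, " h of the ",
                    analyte, " sample at t = ", rb$timestamp_h[i],
                    " h (", rb$batch_id[1], "); sample skipped."))
        return(NULL)
      }
      meta <- tibble::tibble(batch_id = rb$batch_id[i],
                             timestamp_h = sb$timestamp_h[j],
                             ref_time_h = rb$timestamp_h[i],
                             lag_h = lag[j],
                             analyte = analyte,
                             value = rb$value[i])
      dplyr::bind_cols(meta, sb[j, wn_cols(sb), drop = FALSE])
    })
  })
  pairs
}

# ---------------------------------------------------------------------------
# Row-wise spectral operators
# ---------------------------------------------------------------------------

#' Savitzky-Golay smoothing and derivatives
#'
#' Filters each spectrum with a local least-squares polynomial of degree
#' `order` over a `width`-point window; `deriv > 0` returns the analytical
#' derivative of the local fit (per cm^-1). Terminal points are handled by
#' evaluating the first/last window's polynomial, which preserves the grid
#' length without padding artifacts.
#'
#' @param data A tibble with wavenumber columns.
#' @param width Odd window width >= 3.
#' @param order Polynomial degree, `order < width` and `>= deriv`.
#' @param deriv Derivative order: 0 (smoothing), 1 or 2.
#' @return The filtered tibble (same shape).
#' @export
savitzky_golay <- function(data, width, order, deriv = 0) {
  if (width %% 2 == 0 || width < 3) abort("`width` must be odd and >= 3.")
  if (order >= width) abort("`order` must be smaller than `width`.")
  if (deriv > order) abort("`deriv` must not exceed `order`.")
  m <- spectra_matrix(data)
  if (width > ncol(m)) abort("`width` exceeds the number of wavenumbers.")
  ts <- stats::median(diff(wn_values(data)))
  filt <- t(apply(m, 1, signal::sgolayfilt, p = order, n = width, m = deriv,
                  ts = ts))
  colnames(filt) <- colnames(m)
  spectra_replace(data, filt)
}

#' Standard normal variate (SNV) transformation
#'
#' Standardizes each spectrum to mean 0 and sample standard deviation 1
#' (n - 1 denominator), removing per-spectrum multiplicative scatter and
#' additive offset. Idempotent.
#'
#' @param data A tibble with wavenumber columns.
#' @return The transformed tibble.
#' @export
snv <- function(data) {
  m <- spectra_matrix(data)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    abort(paste0("SNV undefined for constant spectra (rows ",
                 paste(bad, collapse = ", "), ")."))
  }
  spectra_replace(data, (m - mu) / s)
}

#' Linear detrending
#'
#' Subtracts, per spectrum, the least-squares straight line in wavenumber;
#' the residual is orthogonal to both the constant and the wavenumber axis.
#'
#' @param data A tibble with >= 3 wavenumber columns.
#' @return The detrended tibble.
#' @export
detrend_linear <- function(data) {
  m <- spectra_matrix(data)
  if (ncol(m) < 3) abort("Detrending needs at least 3 wavenumbers.")
  v <- wn_values(data)
  basis <- cbind(1, v)
  fit <- basis %*% qr.solve(basis, t(m))  # p x n fitted lines
  spectra_replace(data, m - t(fit))
}

#' Area (1-norm) normalization
#'
#' Divides each spectrum by the sum of its absolute intensities so the
#' resulting 1-norm is exactly 1.
#'
#' @param data A tibble with wavenumber columns.
#' @return The normalized tibble.
#' @export
area_normalize <- function(data) {
  m <- spectra_matrix(data)
  a <- rowSums(abs(m))
  bad <- which(a == 0 | !is.finite(a))
  if (length(bad)) {
    abort(paste0("Area normalization undefined for all-zero spectra (rows ",
                 paste(bad, collapse = ", "), ")."))
  }
  spectra_replace(data, m / a)
}

#' Select a wavenumber range
#'
#' Retains wavenumber columns with `lo <= v <= hi` (inclusive), preserving
#' order and all metadata columns.
#'
#' @param data A tibble with wavenumber columns.
#' @param lo,hi Range bounds (cm^-1), `lo < hi`.
#' @return The restricted tibble.
#' @export
select_range <- function(data, lo, hi) {
  if (lo >= hi) abort("`lo` must be smaller than `hi`.")
  v <- wn_values(data)
  keep <- wn_cols(data)[v >= lo & v <= hi]
  if (length(keep) == 0L) {
    abort("The requested range contains no wavenumbers of the grid.")
  }
  meta <- setdiff(names(data), wn_cols(data))
  data[c(meta, keep)]
}

# ---------------------------------------------------------------------------
# Preprocessing specifications
# ---------------------------------------------------------------------------

#' Preprocessing specification
#'
#' An ordered recipe of spectral operators plus a model wavenumber range,
#' written in the compact notation used in chemometric model tables:
#' `"D1(23,2)+SNV"` means first derivative (Savitzky-Golay window 23,
#' polynomial order 2) followed by SNV. Supported steps: `SG(w,o)`
#' (smoothing), `D1(w,o)`, `D2(w,o)` (derivatives), `SNV`, `Detrend`,
#' `AreaNorm`. Steps are applied in listed order on the working region,
#' then the model range is selected, then (optionally) columns are
#' mean-centered with means learned from calibration rows only.
#'
#' @param steps Character notation (e.g. `"D1(23,2)+SNV"`, `""` for none)
#'   or a list of step descriptors.
#' @param range Model range `c(lo, hi)` in cm^-1 (inclusive).
#' @param working_range Region on which the operators run before the model
#'   range is cut out (the informative fingerprint region by default).
#' @param mean_center Centre columns after range selection?
#' @return A `preprocess_spec` object.
#' @examples
#' preprocess_spec("D1(23,2)+SNV", range = c(1000, 1500))
#' @export
preprocess_spec <- function(steps = "", range = c(700, 1700),
                            working_range = c(700, 1700),
                            mean_center = TRUE) {
  if (is.character(steps)) steps <- parse_steps(steps)
  for (st in steps) {
    if (!st$op %in% c("SG", "D1", "D2", "SNV", "Detrend", "AreaNorm")) {
      abort(paste0("Unknown preprocessing step `", st$op, "`."))
    }
    if (st$op %in% c("SG", "D1", "D2")) {
      if (st$width %% 2 == 0 || st$width < 3 || st$order >= st$width) {
        abort("Savitzky-Golay width must be odd >= 3 and order < width.")
      }
      d <- switch(st$op, SG = 0, D1 = 1, D2 = 2)
      if (d > st$order) abort("Derivative order must not exceed `order`.")
    }
  }
  if (length(range) != 2L || range[1] >= range[2]) {
    abort("`range` must be c(lo, hi) with lo < hi.")
  }
  structure(list(steps = steps, range = as.numeric(range),
                 working_range = as.numeric(working_range),
                 mean_center = isTRUE(mean_center)),
            class = "preprocess_spec")
}

parse_steps <- function(text) {
  text <- gsub("\\s+", "", text)
  if (identical(text, "")) return(list())
  purrr::map(strsplit(text, "+", fixed = TRUE)[[1]], function(tok) {
    m <- regmatches(tok,
                    regexec("^([A-Za-z]+[0-9]*)(\\(([0-9]+),([0-9]+)\\))?$",
                            tok))[[1]]
    if (length(m) == 0L) abort(paste0("Cannot parse step `", tok, "`."))
    op <- m[2]
    if (m[3] != "") {
      list(op = op, width = as.integer(m[4]), order = as.integer(m[5]))
    } else {
      list(op = op)
    }
  })
}

#' @export
format.preprocess_spec <- function(x, ...) {
  steps <- purrr::map_chr(x$steps, function(st) {
    if (!is.null(st$width)) {
      paste0(st$op, "(", st$width, ",", st$order, ")")
    } else st$op
  })
  paste0(if (length(steps)) paste(steps, collapse = "+") else "none",
         " | ", x$range[1], ":", x$range[2])
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec> ", format(x),
      if (x$mean_center) " | mean-centered" else "", "\n", sep = "")
  invisible(x)
}

apply_steps <- function(data, steps) {
  for (st in steps) {
    data <- switch(st$op,
      SG = savitzky_golay(data, st$width, st$order, deriv = 0),
      D1 = savitzky_golay(data, st$width, st$order, deriv = 1),
      D2 = savitzky_golay(data, st$width, st$order, deriv = 2),
      SNV = snv(data),
      Detrend = detrend_linear(data),
      AreaNorm = area_normalize(data))
  }
  data
}

#' Apply a preprocessing specification to calibration (and test) spectra
#'
#' Runs the operator chain on the working region, selects the model range,
#' and mean-centers with column means learned from the calibration rows
#' only — the fitted center is returned and applied unchanged to the test
#' rows, so no test information leaks into the transformation.
#'
#' @param cal Calibration tibble (wavenumber columns + metadata).
#' @param test Optional test tibble on the same grid.
#' @param spec A [preprocess_spec()].
#' @param center Optional previously fitted center (named numeric vector);
#'   when supplied, it is used instead of refitting, so a stored model can
#'   reproduce its transformation exactly.
#' @return A list with `cal`, `test` (or `NULL`) and `center`.
#' @export
apply_spec <- function(cal, test = NULL, spec = preprocess_spec(),
                       center = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  prep <- function(d) {
    d <- select_range(d, spec$working_range[1], spec$working_range[2])
    d <- apply_steps(d, spec$steps)
    select_range(d, spec$range[1], spec$range[2])
  }
  cal <- prep(cal)
  if (!is.null(test)) {
    test <- prep(test)
    check_same_grid(cal, test)
  }
  if (spec$mean_center) {
    if (is.null(center)) {
      center <- colMeans(spectra_matrix(cal))
    }
    shift <- function(d) {
      m <- spectra_matrix(d)
      if (!identical(colnames(m), names(center))) {
        abort("Stored center does not match the wavenumber grid.")
      }
      spectra_replace(d, sweep(m, 2, center))
    }
    cal <- shift(cal)
    if (!is.null(test)) test <- shift(test)
  } else {
    center <- setNames(numeric(length(wn_cols(cal))), wn_cols(cal))
  }
  list(cal = cal, test = test, center = center)
}
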