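#' In-line acquisition settings for the spectral forward model
#'
#' @param cadence_min Minutes between consecutive spectra (20-30 min is
#'   typical for in-line probes).
#' @param integration_time_s Integration time per scan (s).
#' @param n_scans Co-added scans per spectrum.
#' @param noise_sd Detector noise standard deviation, counts/s (i.i.d.
#'   Gaussian per grid point; raw counts receive sd `noise_sd * Ti * Nscan`).
#' @param fluor_amp Fluorescence baseline amplitude, counts/s.
#' @param fluor_drift Fractional growth of the fluorescence baseline per day
#'   of culture.
#' @param turbidity_coupling Attenuation constant k in
#'   `atten(tcd) = 1 / (1 + k * tcd)` (per 1e6 cells/mL); 0 disables the
#'   turbidity effect.
#' @return An `acquisition_settings` object.
#' @export
acquisition_settings <- function(cadence_min = 20,
                                 integration_time_s = 60,
                                 n_scans = 9,
                                 noise_sd = 0.133,
                                 fluor_amp = 4,
                                 fluor_drift = 0.08,
                                 turbidity_coupling = 0.04) {
  if (cadence_min <= 0) abort("`cadence_min` must be positive.")
  if (integration_time_s <= 0) abort("`integration_time_s` must be positive.")
  if (n_scans < 1) abort("`n_scans` must be at least 1.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (turbidity_coupling < 0) abort("`turbidity_coupling` must be >= 0.")
  structure(as.list(environment()), class = "acquisition_settings")
}

#' Default wavenumber grid
#'
#' The spectrometer grid: 250 to 3200 cm^-1 at 1 cm^-1 spacing.
#' @return Integer vector of wavenumbers.
#' @export
default_wavenumbers <- function() seq(250, 3200)

## Turbidity attenuation: strictly decreasing in tcd, atten(0) = 1.
attenuation <- function(tcd, k) 1 / (1 + k * tcd)

## Fluorescence background: broad low-order polynomial in the reduced
## wavenumber, growing linearly with culture time.
fluor_baseline <- function(wavenumbers, time_h, acq) {
  if (acq$fluor_amp == 0) {
    return(matrix(0, length(time_h), length(wavenumbers)))
  }
  x <- (wavenumbers - min(wavenumbers)) /
    max(1, diff(range(wavenumbers)))
  shape <- 1.5 - 1.2 * x + 0.4 * x^2
  amp <- acq$fluor_amp * (1 + acq$fluor_drift * time_h / 24)
  outer(amp, shape)
}

## Forward model shared by generate_spectrum()/generate_batch().
## state: tibble of kinetics values (one row per acquisition time).
forward_spectra <- function(state, library, acq, wavenumbers, noise = TRUE) {
  validate_band_library(library, min(wavenumbers), max(wavenumbers))
  bm <- band_matrix(library, wavenumbers)          # p x drivers
  drivers <- colnames(bm)
  cmat <- sapply(drivers, function(d) {
    switch(d,
           water = rep(1, nrow(state)),
           dead  = pmax(0, state$tcd - state$vcd),
           state[[d]])
  })
  cmat <- matrix(cmat, nrow = nrow(state), dimnames = list(NULL, drivers))
  if (any(cmat < 0)) abort("Kinetics state values must be non-negative.")
  signal <- cmat %*% t(bm)                          # n x p, counts/s
  att <- attenuation(state$tcd, acq$turbidity_coupling)
  base <- fluor_baseline(wavenumbers, state$time_h, acq)
  total_s <- acq$integration_time_s * acq$n_scans
  raw <- total_s * (signal * att + base)
  if (noise && acq$noise_sd > 0) {
    raw <- raw + matrix(rnorm(length(raw), sd = acq$noise_sd * total_s),
                        nrow(raw))
  }
  colnames(raw) <- as.character(wavenumbers)
  raw
}

#' Generate a single Raman spectrum from a culture state
#'
#' Forward model: raw counts are
#' `Ti*Nscan * (atten(tcd) * (sum_a c_a s_a(v) + water(v)) + baseline(v, t))`
#' plus i.i.d. Gaussian detector noise. `atten` is strictly decreasing in
#' total cell density with `atten(0) = 1`, so growing turbidity dims both
#' the analyte and the water bands; the fluorescence baseline drifts up
#' slowly over culture time.
#'
#' @param state One-row tibble (or named list) with `time_h` and the seven
#'   kinetics quantities.
#' @param library Band library, see [raman_band_library()].
#' @param acq [acquisition_settings()].
#' @param wavenumbers Wavenumber grid (cm^-1).
#' @param noise Draw detector noise? Uses the current RNG state.
#' @param batch_id Batch label.
#' @return A one-row spectra tibble (raw counts, `normalized = FALSE`).
#' @export
generate_spectrum <- function(state, library = raman_band_library(),
                              acq = acquisition_settings(),
                              wavenumbers = default_wavenumbers(),
                              noise = TRUE, batch_id = "B1") {
  state <- tibble::as_tibble(as.list(state))
  raw <- forward_spectra(state, library, acq, wavenumbers, noise = noise)
  meta <- tibble::tibble(batch_id = batch_id,
                         timestamp_h = state$time_h,
                         integration_time_s = acq$integration_time_s,
                         n_scans = acq$n_scans,
                         normalized = FALSE)
  new_spectra(meta, raw)
}

#' Generate a complete synthetic fed-batch dataset
#'
#' Simulates culture kinetics, forward-models the in-line Raman time series
#' at the acquisition cadence over the full culture, and draws the noisy
#' off-line reference samples. Fully reproducible given `seed`.
#'
#' @param params [kinetics_params()]; set `feed_stop_day` for the
#'   induced-death scenario.
#' @param library Band library.
#' @param acq [acquisition_settings()].
#' @param assay_cv Relative standard deviation of the off-line assays.
#' @param seed Integer seed controlling all randomness in the batch.
#' @param batch_id Batch label.
#' @param wavenumbers Wavenumber grid.
#' @return A `batch_dataset` list: `batch_id`, `scenario` (`"normal"` or
#'   `"induced_death"`), `kinetics`, `spectra` (raw counts), `offline`,
#'   `acq`, `seed`.
#' @examples
#' b <- generate_batch(kinetics_params(duration_days = 3), seed = 7)
#' nrow(b$spectra)
#' @export
generate_batch <- function(params = kinetics_params(),
                           library = raman_band_library(),
                           acq = acquisition_settings(),
                           assay_cv = 0.12,
                           seed = 1L,
                           batch_id = "B1",
                           wavenumbers = default_wavenumbers()) {
  duration_h <- params$duration_days * 24
  if (acq$cadence_min / 60 > duration_h) {
    abort("Acquisition cadence is longer than the culture duration.")
  }
  kin <- simulate_batch_kinetics(params, seed = seed)
  times <- seq(0, duration_h, by = acq$cadence_min / 60)
  state <- kinetics_at(kin, times)
  set.seed(seed + 1L)
  raw <- forward_spectra(state, library, acq, wavenumbers, noise = TRUE)
  spectra <- new_spectra(
    tibble::tibble(batch_id = batch_id, timestamp_h = times,
                   integration_time_s = acq$integration_time_s,
                   n_scans = acq$n_scans, normalized = FALSE),
    raw
  )
  offline <- schedule_offline_samples(kin, assay_cv = assay_cv,
                                      seed = seed + 2L,
                                      batch_id = batch_id)
  structure(
    list(batch_id = batch_id,
         scenario = if (is.na(params$feed_stop_day)) "normal"
                    else "induced_death",
         kinetics = kin, spectra = spectra, offline = offline,
         acq = acq, seed = seed),
    class = "batch_dataset"
  )
}

#' @export
print.batch_dataset <- function(x, ...) {
  cat("<batch_dataset> ", x$batch_id, " (", x$scenario, "): ",
      nrow(x$spectra), " spectra, ",
      length(unique(x$offline$timestamp_h)), " off-line sampling times\n",
      sep = "")
  invisible(x)
}

#' Simulate the five-batch monitoring study
#'
#' The study preset mirrors a five-batch 10 L campaign: four batches under
#' normal operation and one with feeding stopped on day 10 to induce cell
#' death and decouple the otherwise strongly correlated analytes. Batch
#' roles follow the calibrate-then-blind-test design: B1, B3, B4 and the
#' induced-death B5 calibrate the models; B2 is held out for blind
#' validation. Batch durations (14-16 days) and acquisition settings
#' (20-30 min cadence, varying integration time and scan counts) differ
#' across batches, which exercises the acquisition-time normalization.
#'
#' `preset = "noise_free"` is the exact-recovery diagnostic limit: no
#' detector noise, no assay noise, no fluorescence baseline, no turbidity
#' attenuation, no block averaging, and off-line sampling aligned to the
#' acquisition grid — spectra are then exactly linear in the seven
#' monitored quantities.
#'
#' @param seed Integer seed; each batch derives its own sub-seed.
#' @param preset `"default"` (study conditions) or `"noise_free"`.
#' @param assay_cv Assay relative SD for the default preset.
#' @return A `raman_study_data` list with `batches` (named list of
#'   [generate_batch()] results), `roles` (`calibration` ids, `test` id),
#'   `preset` and `seed`.
#' @export
simulate_study <- function(seed = 1L, preset = c("default", "noise_free"),
                           assay_cv = 0.12) {
  preset <- match.arg(preset)
  noise_free <- preset == "noise_free"
  if (noise_free) assay_cv <- 0

  acq_of <- function(cadence, ti, scans) {
    acquisition_settings(
      cadence_min = cadence, integration_time_s = ti, n_scans = scans,
      noise_sd = if (noise_free) 0 else 0.133,
      fluor_amp = if (noise_free) 0 else 4,
      turbidity_coupling = if (noise_free) 0 else 0.04
    )
  }
  ## durations chosen so the calibration set (B1, B3, B4, B5) holds 112
  ## off-line samples and the blind batch (B2) 31, a realistic campaign size
  plan <- list(
    B1 = list(duration = 15, stop = NA, acq = acq_of(30, 60, 9)),
    B2 = list(duration = 16, stop = NA, acq = acq_of(20, 90, 10)),
    B3 = list(duration = 15, stop = NA, acq = acq_of(20, 90, 10)),
    B4 = list(duration = 14, stop = NA, acq = acq_of(20, 45, 16)),
    B5 = list(duration = 14, stop = 10, acq = acq_of(20, 45, 16))
  )
  batches <- purrr::imap(plan, function(p, id) {
    params <- kinetics_params(duration_days = p$duration,
                              feed_stop_day = p$stop)
    generate_batch(params, acq = p$acq, assay_cv = assay_cv,
                   seed = seed * 100L + match(id, names(plan)),
                   batch_id = id)
  })
  structure(
    list(batches = batches,
         roles = list(calibration = c("B1", "B3", "B4", "B5"), test = "B2"),
         preset = preset, seed = seed),
    class = "raman_study_data"
  )
}

#' @export
print.raman_study_data <- function(x, ...) {
  cat("<raman_study_data> preset '", x$preset, "', seed ", x$seed, "\n",
      sep = "")
  for (b in x$batches) print(b)
  cat("calibration: ", paste(x$roles$calibration, collapse = ", "),
      "; blind test: ", x$roles$test, "\n", sep = "")
  invisible(x)
}
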