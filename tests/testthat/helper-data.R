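# Shared small fixtures, built in code at test time.

# A spectra tibble from a plain matrix on an integer grid.
toy_spectra <- function(m, wavenumbers = seq_len(ncol(m)) + 999,
                        batch_id = "B1", normalized = TRUE) {
  colnames(m) <- as.character(wavenumbers)
  dplyr::bind_cols(
    tibble::tibble(batch_id = batch_id,
                   timestamp_h = seq_len(nrow(m)),
                   integration_time_s = 1, n_scans = 1L,
                   normalized = normalized),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

toy_matrix <- function(data) ramanpls:::spectra_matrix(data)

# A small, fast synthetic study: three short batches (one induced-death in
# calibration), coarse cadence. Used by pipeline unit tests; the acceptance
# tests run the full five-batch presets.
small_study <- function(seed = 11, noise_free = FALSE, duration = 6) {
  acq <- acquisition_settings(
    cadence_min = 60,
    noise_sd = if (noise_free) 0 else 0.133,
    fluor_amp = if (noise_free) 0 else 4,
    turbidity_coupling = if (noise_free) 0 else 0.04
  )
  assay_cv <- if (noise_free) 0 else 0.12
  mk <- function(id, stop_day, s) {
    generate_batch(kinetics_params(duration_days = duration,
                                   feed_stop_day = stop_day),
                   acq = acq, assay_cv = assay_cv, seed = s, batch_id = id)
  }
  list(
    batches = list(C1 = mk("C1", NA, seed),
                   C2 = mk("C2", 4, seed + 1L),
                   T1 = mk("T1", NA, seed + 2L)),
    roles = list(calibration = c("C1", "C2"), test = "T1")
  )
}
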