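#' Plot in-line spectra
#'
#' Overlays spectra colored by acquisition time, the standard view of how
#' the Raman signal evolves over a culture.
#'
#' @param data A spectra tibble.
#' @param every Plot every `every`-th spectrum (thins dense series).
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, every = 25) {
  sel <- data[seq(1, nrow(data), by = every), , drop = FALSE]
  long <- tidyr::pivot_longer(sel, dplyr::all_of(wn_cols(sel)),
                              names_to = "wavenumber",
                              values_to = "intensity") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$timestamp_h,
                                     colour = .data$timestamp_h)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::scale_colour_viridis_c(name = "time (h)") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot simulated culture kinetics
#'
#' @param kinetics Output of [simulate_batch_kinetics()].
#' @return A ggplot object, one facet per monitored quantity.
#' @export
plot_kinetics <- function(kinetics) {
  long <- tidyr::pivot_longer(tibble::as_tibble(kinetics),
                              -dplyr::all_of("time_h"),
                              names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "culture day", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn vip_scores Plot a VIP profile with the significance line at 1.
#' @param object,x A `vip_profile`.
#' @param ... Unused.
#' @export
autoplot.vip_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$vip)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "VIP score") +
    ggplot2::theme_minimal()
}

#' @describeIn kfold_cv Plot RMSECV against the candidate component count.
#' @param object A `cv_result`.
#' @param ... Unused.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$n_lv, .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_lv, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "latent variables", y = "RMSECV") +
    ggplot2::theme_minimal()
}

#' @describeIn pls_diagnostics Standardized residuals vs leverage plot.
#' @param object A `pls_diagnostics` tibble.
#' @param ... Unused.
#' @export
autoplot.pls_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$leverage,
                                       .data$std_residual)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "leverage", y = "standardized residual") +
    ggplot2::theme_minimal()
}

#' Plot back-predicted time courses against off-line references
#'
#' @param predictions Output of [back_predict()].
#' @return A ggplot object, one facet per analyte.
#' @export
plot_back_prediction <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(.data$timestamp_h / 24, .data$predicted)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(y = .data$reference),
                        data = ~dplyr::filter(.x, !is.na(.data$reference)),
                        colour = "steelblue", size = 1) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "culture day", y = "predicted (line) / reference (dots)") +
    ggplot2::theme_minimal()
}
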