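#' Raman band library for the culture matrix
#'
#' Gaussian band sets used by the spectral forward model. Each row is one
#' band: `component` names the signal source, `driver` the kinetics quantity
#' that scales it, `center`/`fwhm` are in cm^-1 and `amplitude` in counts/s
#' per driver unit (per g/L, per mM, or per 1e6 cells/mL).
#'
#' Band positions follow the standard assignments for this matrix: glucose
#' ring C-O stretches at 1033/1060 cm^-1 and COH bending at 1117 cm^-1 plus
#' the weaker CH2 modes (1318, 1370, 1455 cm^-1); lactate carboxylate and
#' C-C stretches in 830-872 cm^-1 with C-H bending near 911 cm^-1 and CH3
#' rocking near 932 cm^-1; glutamine CH3 rocking at 934 cm^-1, C-CH3 at
#' 1021 cm^-1, C-O at 1044 cm^-1 and the 1088-1100 cm^-1 NH2/C-O region;
#' glutamate NH2 rocking near 1075 cm^-1, CH2 deformation near 1298 cm^-1
#' and the COO-/NH3+ cluster near 1413 cm^-1; IgG tryptophan/tyrosine bands
#' (1554, 1563, 1595 cm^-1) and the amide I band near 1648 cm^-1. Cellular
#' material contributes through two distinct sets: live-biomass
#' lipid/cholesterol bands (702, 717, 1450 cm^-1) scaling with viable cell
#' density, and debris nucleic-acid bands (783, 811, 1100 cm^-1) scaling
#' with the accumulated dead-cell density (TCD - VCD), emulating material
#' released on cell death. Water contributes broad bands at 1640 and
#' 3150 cm^-1 whose apparent decline with culture progress arises from
#' turbidity attenuation, not from a concentration change.
#'
#' Amplitudes are chosen so that mid-culture peak signal-to-noise ratios sit
#' in the 10-50 range at the default acquisition settings (glucose ~20).
#'
#' @return A tibble with columns `component`, `driver`, `center`, `fwhm`,
#'   `amplitude`.
#' @export
raman_band_library <- function() {
  tribble_band <- function(component, driver, center, fwhm, amplitude) {
    tibble::tibble(component = component, driver = driver, center = center,
                   fwhm = fwhm, amplitude = amplitude)
  }
  dplyr::bind_rows(
    tribble_band("glc", "glc",
                 c(1033, 1060, 1117, 1318, 1370, 1455),
                 c(14, 14, 16, 18, 18, 18),
                 c(1.00, 0.75, 0.55, 0.28, 0.22, 0.32)),
    tribble_band("lac", "lac",
                 c(840, 865, 911, 932),
                 c(14, 12, 12, 10),
                 c(1.20, 0.70, 0.45, 0.40)),
    tribble_band("gln", "gln",
                 c(934, 1021, 1044, 1094),
                 c(10, 12, 12, 14),
                 c(0.22, 0.12, 0.12, 0.10)),
    tribble_band("glu", "glu",
                 c(1075, 1298, 1413),
                 c(14, 20, 16),
                 c(0.18, 0.08, 0.12)),
    tribble_band("igg", "igg",
                 c(1554, 1563, 1595, 1648),
                 c(12, 12, 14, 24),
                 c(0.45, 0.35, 0.45, 0.90)),
    tribble_band("biomass", "vcd",
                 c(702, 717, 1450),
                 c(12, 12, 20),
                 c(0.040, 0.040, 0.060)),
    tribble_band("debris", "dead",
                 c(783, 811, 1100),
                 c(12, 12, 16),
                 c(0.080, 0.050, 0.050)),
    tribble_band("water", "water",
                 c(1640, 3150),
                 c(90, 180),
                 c(60, 100))
  )
}

validate_band_library <- function(library, wn_min = 250, wn_max = 3200) {
  stopifnot(all(c("component", "driver", "center", "fwhm", "amplitude") %in%
                  names(library)))
  if (any(library$center < wn_min | library$center > wn_max)) {
    abort("Band centers must lie within the wavenumber grid.")
  }
  if (any(library$fwhm <= 0) || any(library$amplitude <= 0)) {
    abort("Band fwhm and amplitude must be positive.")
  }
  invisible(library)
}

## Band-shape matrix: one column per driver, evaluated on the grid.
## Gaussian profile amp * exp(-4 ln2 (v - c)^2 / fwhm^2), summed per driver.
band_matrix <- function(library, wavenumbers) {
  drivers <- unique(library$driver)
  m <- matrix(0, length(wavenumbers), length(drivers),
              dimnames = list(NULL, drivers))
  k <- 4 * log(2)
  for (i in seq_len(nrow(library))) {
    b <- library[i, ]
    m[, b$driver] <- m[, b$driver] +
      b$amplitude * exp(-k * (wavenumbers - b$center)^2 / b$fwhm^2)
  }
  m
}
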