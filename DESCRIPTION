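Package: ramanpls
Title: Raman Spectroscopy Chemometrics for Fed-Batch Bioprocess Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating and validating in-line Raman spectroscopy
    models of fed-batch mammalian cell cultures. Provides a synthetic
    fed-batch CHO bioreactor generator (culture kinetics, forward-modelled
    Raman spectra with turbidity attenuation and fluorescence drift, noisy
    off-line reference assays), the standard chemometric preprocessing menu
    (Savitzky-Golay smoothing and derivatives, standard normal variate,
    linear detrending, area normalization, wavenumber-range selection),
    a NIPALS PLS1 regression engine with variable-importance-in-projection
    (VIP) scores and leverage/residual diagnostics, cross-validated
    latent-variable selection, RMSEC/RMSECV/RMSEP figures of merit, and a
    batch-wise calibrate-then-blind-test study pipeline for glucose,
    lactate, glutamine, glutamate, IgG titer and cell densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
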