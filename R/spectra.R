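## Spectra live in wide tibbles: a handful of metadata columns followed by
## one numeric column per wavenumber, named by the wavenumber itself
## ("250" ... "3200"). All preprocessing operators work on this layout and
## on any tibble that carries wavenumber columns (e.g. paired datasets).

.spectra_meta_cols <- c("batch_id", "timestamp_h", "integration_time_s",
                        "n_scans", "normalized")

#' Identify wavenumber columns of a spectra tibble
#'
#' Wavenumber columns are those whose name parses as a number (the Raman
#' shift in cm^-1). All other columns are treated as per-spectrum metadata.
#'
#' @param data A tibble with wavenumber-named intensity columns.
#' @return `wn_cols()` returns the column names; `wn_values()` the numeric
#'   wavenumbers in column order.
#' @examples
#' s <- tibble::tibble(batch_id = "B1", `1000` = 1, `1001` = 2)
#' wn_cols(s)
#' wn_values(s)
#' @export
wn_cols <- function(data) {
  nm <- names(data)
  nm[grepl("^[0-9]+(\\.[0-9]+)?$", nm)]
}

#' @rdname wn_cols
#' @export
wn_values <- function(data) {
  as.numeric(wn_cols(data))
}

## Extract the intensity block as a plain matrix (rows = spectra).
spectra_matrix <- function(data) {
  cols <- wn_cols(data)
  if (length(cols) == 0L) {
    abort("`data` has no wavenumber columns.")
  }
  m <- as.matrix(data[cols])
  colnames(m) <- cols
  m
}

## Replace the intensity block, keeping metadata columns untouched.
spectra_replace <- function(data, m) {
  stopifnot(nrow(m) == nrow(data))
  cols <- colnames(m)
  meta <- data[setdiff(names(data), wn_cols(data))]
  dplyr::bind_cols(meta, tibble::as_tibble(m, .name_repair = "minimal"))
}

## Assemble a spectra tibble from metadata and an intensity matrix whose
## columns are named by wavenumber.
new_spectra <- function(meta, m) {
  colnames(m) <- as.character(colnames(m))
  dplyr::bind_cols(tibble::as_tibble(meta),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

check_same_grid <- function(a, b, what = "spectra") {
  if (!identical(wn_cols(a), wn_cols(b))) {
    abort(paste0("The two ", what, " sets are not on the same wavenumber grid."))
  }
  invisible(TRUE)
}

#' Read and write spectra CSV files
#'
#' The on-disk format has one header row whose trailing entries are the
#' integer wavenumbers (cm^-1) and one row per spectrum, with leading columns
#' `batch_id`, `timestamp_h`, `integration_time_s`, `n_scans` (and, if
#' present, `normalized`).
#'
#' @param data A spectra tibble.
#' @param path File path.
#' @return `read_spectra_csv()` returns a spectra tibble; a missing
#'   `normalized` column is filled with `FALSE` (raw counts).
#' @export
write_spectra_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"normalized" %in% names(data)) {
    data <- dplyr::mutate(data, normalized = FALSE,
                          .after = dplyr::all_of("n_scans"))
  }
  data
}

#' Read and write off-line reference CSV files
#'
#' Long format with columns `batch_id`, `timestamp_h`, `analyte`, `value`,
#' `units`.
#'
#' @param data A reference tibble.
#' @param path File path.
#' @export
write_reference_csv <- function(data, path) {
  cols <- c("batch_id", "timestamp_h", "analyte", "value", "units")
  readr::write_csv(data[intersect(c(cols, names(data)), names(data))], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
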