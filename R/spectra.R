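#' Validate and normalize a table of MS2 spectra
#'
#' Spectra live in a tibble with one row per scan and peak arrays in
#' list-columns. `as_spectra()` enforces the container invariants: peak
#' arrays of equal positive length, m/z strictly increasing (peaks are
#' re-sorted if needed), non-negative intensities normalized to the base
#' peak (maximum intensity 1), and a neutral `precursor_mass` derived from
#' `precursor_mz` and `precursor_charge` when absent.
#'
#' @param x A data frame with columns `spectrum_id`, `mz` (list of numeric),
#'   `intensity` (list of numeric), `precursor_mz`, `precursor_charge`, and
#'   optionally `precursor_mass`, `retention_time`, `peptide`.
#' @param normalize Normalize intensities to the base peak (default `TRUE`).
#' @return A tibble of spectra satisfying the invariants.
#' @export
as_spectra <- function(x, normalize = TRUE) {
  x <- as_tibble(x)
  need <- c("spectrum_id", "mz", "intensity", "precursor_mz",
            "precursor_charge")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste("missing spectrum column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  x$spectrum_id <- as.character(x$spectrum_id)
  if (anyDuplicated(x$spectrum_id)) abort("duplicate spectrum_id values")
  x$precursor_charge <- as.integer(x$precursor_charge)
  if (any(x$precursor_charge < 1)) abort("precursor charge must be >= 1")
  cleaned <- purrr::map2(x$mz, x$intensity, function(m, i) {
    m <- as.numeric(m); i <- as.numeric(i)
    if (length(m) != length(i)) abort("mz and intensity lengths differ")
    if (length(m) < 1) abort("spectrum must contain at least one peak")
    if (any(i < 0)) abort("negative intensity")
    o <- order(m)
    m <- m[o]; i <- i[o]
    if (anyDuplicated(m)) {
      # merge exact duplicate m/z by summing intensity (keeps ordering strict)
      i <- as.numeric(tapply(i, match(m, unique(m)), sum))
      m <- unique(m)
    }
    if (normalize && max(i) > 0) i <- i / max(i)
    list(m = m, i = i)
  })
  x$mz <- purrr::map(cleaned, "m")
  x$intensity <- purrr::map(cleaned, "i")
  if (!"precursor_mass" %in% names(x) || anyNA(x$precursor_mass)) {
    x$precursor_mass <- mass_from_mz(x$precursor_mz, x$precursor_charge)
  }
  x
}

#' Number of peaks per spectrum
#' @param spectra A spectra tibble (see [as_spectra()]).
#' @return Integer vector.
#' @export
n_peaks <- function(spectra) lengths(spectra$mz)

#' Keep only the most intense peaks of each spectrum
#'
#' Inference-time alternative to dropping large spectra: retains the
#' `max_peaks` most intense peaks (ties broken by m/z), re-sorted by m/z.
#'
#' @param spectra A spectra tibble.
#' @param max_peaks Maximum retained peak count (default 800).
#' @return The spectra tibble with truncated peak arrays.
#' @export
truncate_peaks <- function(spectra, max_peaks = 800) {
  keep <- purrr::map2(spectra$mz, spectra$intensity, function(m, i) {
    if (length(m) <= max_peaks) return(seq_along(m))
    sort(order(-i, m)[seq_len(max_peaks)])
  })
  spectra$mz <- purrr::map2(spectra$mz, keep, `[`)
  spectra$intensity <- purrr::map2(spectra$intensity, keep, `[`)
  spectra
}
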