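#' Read tandem MS spectra from MGF or mzML
#'
#' `read_spectra()` dispatches on the file extension (or an explicit
#' `format`). Scans without a precursor charge are skipped and counted; the
#' skip count is attached as attribute `n_skipped` and reported as a message.
#' Peaks are re-sorted ascending and intensities normalized to the base peak
#' at ingestion (see [as_spectra()]).
#'
#' @param path Path to an `.mgf` or `.mzML` file.
#' @param format One of `"auto"`, `"mgf"`, `"mzml"`.
#' @return A spectra tibble. MGF `SEQ=` annotations, when present, populate a
#'   `peptide` column.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     abort(paste("cannot infer spectrum format from:", path)))
  }
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    abort(paste0("malformed MGF (unbalanced BEGIN/END IONS blocks): ", path))
  }
  n_skipped <- 0L
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    fields <- setNames(vals, keys)
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    if ("CHARGE" %in% keys) {
      ch_str <- fields[["CHARGE"]]
      charge <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch_str)))
      if (grepl("-", ch_str, fixed = TRUE)) charge <- NA_integer_
    } else {
      charge <- NA_integer_
    }
    if (is.na(charge) || charge < 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!"PEPMASS" %in% keys) {
      abort(sprintf("malformed MGF: scan %d (line %d) lacks PEPMASS",
                    k, starts[k]))
    }
    pepmass <- as.numeric(strsplit(trimws(fields[["PEPMASS"]]), "\\s+")[[1]][1])
    if (length(peak_lines) == 0) {
      abort(sprintf("malformed MGF: scan %d (line %d) has no peaks",
                    k, starts[k]))
    }
    pk <- do.call(rbind, lapply(peak_lines, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])
    }))
    if (anyNA(pk)) {
      abort(sprintf("malformed MGF: unparseable peak in scan %d (line %d)",
                    k, starts[k]))
    }
    rows[[k]] <- tibble(
      spectrum_id = if ("TITLE" %in% keys) fields[["TITLE"]] else
        sprintf("scan=%d", k),
      mz = list(pk[, 1]),
      intensity = list(pk[, 2]),
      precursor_mz = pepmass,
      precursor_charge = charge,
      retention_time = if ("RTINSECONDS" %in% keys)
        as.numeric(fields[["RTINSECONDS"]]) else NA_real_,
      peptide = if ("SEQ" %in% keys) fields[["SEQ"]] else NA_character_
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_skipped > 0) {
    inform(sprintf("skipped %d scan(s) lacking a precursor charge", n_skipped))
  }
  out <- if (length(rows) == 0) {
    tibble(spectrum_id = character(), mz = list(), intensity = list(),
           precursor_mz = numeric(), precursor_charge = integer(),
           retention_time = numeric(), peptide = character())
  } else {
    as_spectra(bind_rows(rows))
  }
  if (all(is.na(out$peptide))) out$peptide <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  hdr <- hdr[hdr$msLevel == 2, , drop = FALSE]
  n_skipped <- sum(is.na(hdr$precursorCharge) | hdr$precursorCharge < 1)
  hdr <- hdr[!is.na(hdr$precursorCharge) & hdr$precursorCharge >= 1, ,
             drop = FALSE]
  if (n_skipped > 0) {
    inform(sprintf("skipped %d scan(s) lacking a precursor charge", n_skipped))
  }
  pk <- mzR::peaks(handle, hdr$seqNum)
  if (is.matrix(pk)) pk <- list(pk)
  out <- as_spectra(tibble(
    spectrum_id = sprintf("scan=%d", hdr$acquisitionNum),
    mz = purrr::map(pk, ~ .x[, 1]),
    intensity = purrr::map(pk, ~ .x[, 2]),
    precursor_mz = hdr$precursorMZ,
    precursor_charge = as.integer(hdr$precursorCharge),
    retention_time = hdr$retentionTime
  ))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write spectra (and optional annotations) to MGF
#'
#' Writes one `BEGIN IONS` block per spectrum with `TITLE`, `PEPMASS`,
#' `CHARGE`, optional `RTINSECONDS` and, when a `peptide` column is present,
#' a `SEQ=` line, so annotated synthetic datasets round-trip through
#' [read_mgf()]. Numeric formatting is fixed-width, making output
#' byte-stable for identical inputs.
#'
#' @param spectra A spectra tibble.
#' @param path Output file path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(spectra))) {
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[k]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[k]),
      sprintf("CHARGE=%d+", spectra$precursor_charge[k])
    )
    if ("retention_time" %in% names(spectra) &&
        !is.na(spectra$retention_time[k])) {
      lines <- c(lines, sprintf("RTINSECONDS=%.3f", spectra$retention_time[k]))
    }
    if ("peptide" %in% names(spectra) && !is.na(spectra$peptide[k])) {
      lines <- c(lines, paste0("SEQ=", spectra$peptide[k]))
    }
    lines <- c(lines,
               sprintf("%.6f %.6g", spectra$mz[[k]], spectra$intensity[[k]]),
               "END IONS")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Apply the training-set filters to annotated PSMs
#'
#' Retains exactly the peptide-spectrum matches with peptide length at most
#' `max_length` residues and at most `max_peaks` peaks, and reports how many
#' records each rule removed (attributes `n_removed_length`,
#' `n_removed_peaks`). The filter is idempotent.
#'
#' @param psms A spectra tibble with a `peptide` column.
#' @param max_length Maximum peptide length in residues (default 30).
#' @param max_peaks Maximum number of peaks (default 800).
#' @param vocab A [residue_vocabulary()] used to count residues in bracket
#'   notation.
#' @return The filtered tibble.
#' @export
filter_psms <- function(psms, max_length = 30, max_peaks = 800,
                        vocab = residue_vocabulary()) {
  len <- lengths(tokenize_peptide(psms$peptide, vocab))
  npk <- n_peaks(psms)
  keep_len <- len <= max_length
  keep_pk <- npk <= max_peaks
  out <- psms[keep_len & keep_pk, , drop = FALSE]
  attr(out, "n_removed_length") <- sum(!keep_len)
  attr(out, "n_removed_peaks") <- sum(!keep_pk & keep_len)
  out
}

#' Split annotated PSMs by unique peptide sequence
#'
#' Partitions the set of unique peptide sequences into train/validation/test
#' fractions with a seeded permutation, then assigns every PSM to the split
#' of its peptide, so no peptide sequence leaks across splits. Split sizes
#' match the fractions up to rounding and are identical for a fixed seed.
#'
#' @param psms A spectra tibble with a `peptide` column.
#' @param fractions Named numeric vector summing to 1
#'   (default `c(train = 0.8, validation = 0.1, test = 0.1)`).
#' @param seed Integer seed.
#' @return A named list of tibbles, one per fraction.
#' @export
split_psms <- function(psms,
                       fractions = c(train = 0.8, validation = 0.1,
                                     test = 0.1),
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("split", seq_along(fractions))
  }
  peps <- unique(psms$peptide)
  n <- length(peps)
  perm <- with_seed(seed, sample.int(n))
  bounds <- round(cumsum(fractions) * n)
  sizes <- diff(c(0L, bounds))
  assignment <- rep(names(fractions), times = sizes)
  bucket <- setNames(assignment, peps[perm])
  split_of <- bucket[psms$peptide]
  out <- lapply(names(fractions), function(s) {
    psms[which(split_of == s), , drop = FALSE]
  })
  names(out) <- names(fractions)
  out
}

#' Assert that no peptide sequence is shared between PSM sets
#'
#' Leakage check between dataset splits (within one dataset or across
#' datasets, e.g. a high-confidence and an all-candidate variant of the same
#' corpus).
#'
#' @param ... Two or more PSM tibbles with `peptide` columns.
#' @return Invisibly `TRUE`; aborts with the offending peptides otherwise.
#' @export
assert_no_peptide_overlap <- function(...) {
  sets <- lapply(list(...), function(x) unique(x$peptide))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (j <= i) next
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov) > 0) {
        abort(sprintf("peptide leakage between sets %d and %d (e.g. %s)",
                      i, j, ov[1]))
      }
    }
  }
  invisible(TRUE)
}

#' Write and read prediction tables
#'
#' Predictions are exchanged as CSV with columns `spectrum_id`, `peptide`,
#' `log_prob`, `confidence`, `model`, `precursor_ppm_error`.
#'
#' @param predictions A predictions tibble.
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("spectrum_id", "peptide", "log_prob", "confidence", "model",
            "precursor_ppm_error")
  write.csv(as.data.frame(predictions[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
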