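#' Build a knapsack reachability table over residue-sum masses
#'
#' Dynamic-programming closure over discretized masses: a bin is reachable
#' iff it is zero or can be written as a reachable bin plus one residue
#' mass. The table lives in residue-sum mass space (neutral peptide mass
#' minus water), avoiding the classic water/proton off-by-one. Build it once
#' and reuse; [save_knapsack()] caches it to disk keyed by the vocabulary.
#'
#' @param vocab A [residue_vocabulary()].
#' @param max_mass Largest residue-sum mass covered (Da); must exceed the
#'   largest residue mass.
#' @param resolution Bin width in Da (default 0.0005). Continuation queries
#'   widen their window by one bin on each side so discretization is
#'   conservative (no false "unreachable").
#' @return A `knapsack_table` object.
#' @examples
#' vocab <- residue_vocabulary(residues = c("G", "A"), variable_mods = FALSE)
#' tab <- build_knapsack(vocab, max_mass = 200)
#' is_continuable(114.04292, tab, tol_ppm = 50, precursor_mass = 200)
#' @export
build_knapsack <- function(vocab, max_mass = 4000, resolution = 5e-4) {
  masses <- vocab$masses[!vocab$special]
  if (resolution <= 0) abort("resolution must be > 0")
  if (max_mass <= max(masses)) {
    abort("max_mass must exceed the largest residue mass")
  }
  reachable <- knapsack_build_cpp(masses, max_mass, resolution)
  structure(
    list(
      reachable = reachable,
      cum = c(0, cumsum(as.numeric(reachable))),
      resolution = resolution,
      max_mass = max_mass,
      tokens = residue_tokens(vocab)
    ),
    class = "knapsack_table"
  )
}

#' @export
print.knapsack_table <- function(x, ...) {
  cat(sprintf(
    "<knapsack_table: %d tokens, %.0f Da at %.4g Da resolution, %.1f%% reachable>\n",
    length(x$tokens), x$max_mass, x$resolution,
    100 * mean(x$reachable)
  ))
  invisible(x)
}

#' Can a remaining mass budget still be completed?
#'
#' `TRUE` iff some reachable residue-sum bin lies within the tolerance
#' window around `remaining_mass`. The window is `tol_ppm` relative to the
#' precursor residue mass, widened by one discretization bin on each side.
#' Negative remaining mass beyond the window is never continuable.
#' Vectorized over `remaining_mass`.
#'
#' @param remaining_mass Remaining residue-sum mass budget (Da); may be
#'   negative (overshoot).
#' @param table A [build_knapsack()] table.
#' @param tol_ppm Relative tolerance in ppm (default 50).
#' @param precursor_mass Precursor residue-sum mass (Da) that the tolerance
#'   is relative to.
#' @return Logical vector.
#' @export
is_continuable <- function(remaining_mass, table, tol_ppm = 50,
                           precursor_mass) {
  tol <- tol_ppm * 1e-6 * precursor_mass
  res <- table$resolution
  nb <- length(table$reachable)
  lo <- pmax(0L, as.integer(floor((remaining_mass - tol) / res)) - 1L)
  hi <- as.integer(ceiling((remaining_mass + tol) / res)) + 1L
  out <- logical(length(remaining_mass))
  ok <- hi >= 0L & lo <= nb - 1L
  hi <- pmin(hi, nb - 1L)
  out[ok] <- (table$cum[hi[ok] + 2L] - table$cum[lo[ok] + 1L]) > 0
  out
}

#' Cache a knapsack table to disk
#'
#' Stored as a flat binary file keyed by the vocabulary tokens, resolution
#' and mass range; [load_knapsack()] refuses a cache built under different
#' settings.
#'
#' @param table A `knapsack_table`.
#' @param path File path.
#' @export
save_knapsack <- function(table, path) {
  saveRDS(table, path)
  invisible(path)
}

#' @rdname save_knapsack
#' @param vocab Vocabulary the cache must match.
#' @param max_mass,resolution Expected table settings.
#' @export
load_knapsack <- function(path, vocab, max_mass = NULL, resolution = NULL) {
  table <- readRDS(path)
  if (!inherits(table, "knapsack_table")) abort("not a knapsack_table cache")
  if (!identical(table$tokens, residue_tokens(vocab)) ||
      (!is.null(max_mass) && table$max_mass != max_mass) ||
      (!is.null(resolution) && table$resolution != resolution)) {
    abort("knapsack cache does not match the requested vocabulary/settings")
  }
  table
}

# lexicographic key over token ids, used for deterministic tie-breaking
lexico_key <- function(ids) paste(sprintf("%03d", ids), collapse = "")

# Beam search over decoder logits with knapsack masking for one spectrum.
# Tokens are decoded C-terminal-first; the returned peptide is reversed to
# N->C order. Returns NULL when no vocabulary composition fits the window.
decode_one <- function(model, cfg, mz, intensity, prec_mass, charge,
                       table, beam_width, tol_ppm, max_len) {
  vocab <- model$vocab
  res_ids <- which(!vocab$special)
  res_mass <- vocab$masses[res_ids]
  m_res <- prec_mass - mass_constants[["water"]]
  if (m_res <= 0) return(NULL)
  tol_abs <- tol_ppm * 1e-6 * m_res
  memory <- tf_encode_cpp(model$params, cfg, mz, intensity, prec_mass,
                          as.integer(charge))

  beams <- list(list(ids = integer(0), score = 0, rem = m_res,
                     steps = numeric(0)))
  best <- NULL
  repeat {
    logits <- tf_next_logits_cpp(model$params, cfg, memory, prec_mass, mz,
                                 lapply(beams, function(b)
                                   as.integer(b$ids - 1L)))
    # column-wise log softmax
    logp <- apply(logits, 2, function(z) {
      z <- z - max(z)
      z - log(sum(exp(z)))
    })
    logp <- matrix(logp, nrow = nrow(logits))

    cand <- list()
    for (b in seq_along(beams)) {
      bm <- beams[[b]]
      # terminal: end-of-sequence admissible only inside the mass window
      if (abs(bm$rem) <= tol_abs && length(bm$ids) > 0) {
        sc <- bm$score + logp[vocab$eos_id, b]
        if (is.null(best) || sc > best$score ||
            (sc == best$score &&
             lexico_key(bm$ids) < lexico_key(best$ids))) {
          best <- list(ids = bm$ids, score = sc,
                       steps = c(bm$steps, logp[vocab$eos_id, b]))
        }
      }
      if (length(bm$ids) >= max_len) next
      rem2 <- bm$rem - res_mass
      ok <- is_continuable(rem2, table, tol_ppm, m_res)
      for (k in which(ok)) {
        cand[[length(cand) + 1]] <- list(
          ids = c(bm$ids, res_ids[k]),
          score = bm$score + logp[res_ids[k], b],
          rem = rem2[k],
          steps = c(bm$steps, logp[res_ids[k], b])
        )
      }
    }
    if (length(cand) == 0) break
    scores <- vapply(cand, `[[`, numeric(1), "score")
    keys <- vapply(cand, function(x) lexico_key(x$ids), character(1))
    ord <- order(-scores, keys)
    beams <- cand[ord[seq_len(min(beam_width, length(cand)))]]
    # extensions only lower the cumulative log-probability, so once the best
    # completed sequence outscores every live beam the search is done
    if (!is.null(best) && best$score >= beams[[1]]$score) break
  }
  if (is.null(best)) return(NULL)
  ids_nc <- rev(best$ids)                       # back to N->C order
  pep_mass <- sum(vocab$masses[ids_nc])
  list(
    ids = ids_nc,
    peptide = paste(vocab$tokens[ids_nc], collapse = ""),
    log_prob = best$score,
    per_residue = c(rev(utils::head(best$steps, -1)),
                    utils::tail(best$steps, 1)),
    ppm = ppm_diff(pep_mass, m_res)
  )
}

#' Knapsack-filtered beam search decoding
#'
#' Beam search over the autoregressive decoder where every expansion whose
#' remaining mass budget cannot be completed by any residue multiset is
#' masked out, and the end-of-sequence token is admissible only when the
#' residue-sum mass lies within `tol_ppm` of the precursor residue mass.
#' Every returned peptide therefore matches the precursor mass within the
#' window; a spectrum yields no prediction only when no vocabulary
#' composition fits (a data condition, not an error). Beam pruning ties are
#' broken by lexicographic token order.
#'
#' @param spectra A spectra tibble (any number of rows).
#' @param model A trained `denovo_model`.
#' @param beam_width Beam width B (default 5).
#' @param tol_ppm Precursor mass window in ppm (default 50).
#' @param knapsack Optional prebuilt [build_knapsack()] table (built on the
#'   fly to cover the largest precursor otherwise).
#' @param max_len Maximum peptide length (defaults to the model
#'   configuration).
#' @return A predictions tibble with one row per decoded spectrum: columns
#'   `spectrum_id`, `peptide`, `tokens` (list), `per_residue_log_probs`
#'   (list; the final entry is the stop decision), `log_prob` (their sum),
#'   `confidence` (`exp(log_prob)`), `model` = `"ar"`, and
#'   `precursor_ppm_error`. Spectra with no mass-valid sequence are omitted
#'   (count in attribute `n_no_prediction`).
#' @export
knapsack_beam_search <- function(spectra, model, beam_width = 5,
                                 tol_ppm = 50, knapsack = NULL,
                                 max_len = NULL) {
  stopifnot(beam_width >= 1)
  if (isTRUE(model$config$refiner)) {
    abort("beam search needs the autoregressive model, not a refiner")
  }
  max_len <- max_len %||% model$config$max_peptide_len
  cfg <- cpp_config(model$config)
  m_res_all <- spectra$precursor_mass - mass_constants[["water"]]
  if (is.null(knapsack)) {
    knapsack <- build_knapsack(model$vocab,
                               max_mass = max(m_res_all) * 1.001 + 1)
  }
  rows <- vector("list", nrow(spectra))
  for (k in seq_len(nrow(spectra))) {
    hit <- decode_one(model, cfg, spectra$mz[[k]], spectra$intensity[[k]],
                      spectra$precursor_mass[k], spectra$precursor_charge[k],
                      knapsack, beam_width, tol_ppm, max_len)
    if (is.null(hit)) next
    rows[[k]] <- tibble(
      spectrum_id = spectra$spectrum_id[k],
      peptide = hit$peptide,
      tokens = list(model$vocab$tokens[hit$ids]),
      per_residue_log_probs = list(hit$per_residue),
      log_prob = hit$log_prob,
      confidence = exp(hit$log_prob),
      model = "ar",
      precursor_ppm_error = hit$ppm
    )
  }
  n_missing <- sum(vapply(rows, is.null, logical(1)))
  out <- bind_rows(rows)
  attr(out, "n_no_prediction") <- n_missing
  out
}
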