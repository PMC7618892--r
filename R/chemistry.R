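#' Monoisotopic mass constants
#'
#' Fixed monoisotopic masses (Da) used by every m/z formula in the package:
#' the proton mass and the mass of one water molecule (added to the residue
#' sum to obtain a neutral peptide mass). Compiled in as constants; never
#' recomputed at runtime.
#'
#' @format A named numeric vector with elements `proton` and `water`.
#' @export
mass_constants <- c(proton = 1.007276, water = 18.010565)

# Monoisotopic residue masses (Da), standard 6-decimal values.
.residue_masses <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Variable/fixed modification mass shifts (Da).
.mod_deltas <- c(
  carbamidomethyl = 57.021464,
  oxidation = 15.994915,
  deamidation = 0.984016
)

#' Build the residue token vocabulary
#'
#' The vocabulary maps residue tokens to monoisotopic masses and carries the
#' special start/end/padding tokens used by the sequence models. Modified
#' residues are distinct tokens in ProForma-like bracket notation (for
#' example `"M[+15.99491]"`), not mass offsets applied after decoding, so the
#' decoder predicts them like any other residue. The modification set is
#' carbamidomethylation of cysteine, oxidation of methionine and deamidation
#' of asparagine and glutamine.
#'
#' @param fixed_cys If `TRUE` (default) cysteine always carries the
#'   carbamidomethyl group: the token `C[+57.02146]` replaces unmodified `C`
#'   in the alphabet. If `FALSE`, both `C` and `C[+57.02146]` are available.
#' @param residues Optional character vector restricting the canonical
#'   residue alphabet (useful for small test vocabularies).
#' @param variable_mods If `TRUE` (default) include the variable-modification
#'   tokens `M[+15.99491]`, `N[+0.98402]`, `Q[+0.98402]`.
#'
#' @return An object of class `residue_vocabulary`: a list with `tokens`
#'   (character), `masses` (numeric, 0 for specials), `special` (logical),
#'   and the indices `pad_id`, `sos_id`, `eos_id`.
#' @examples
#' vocab <- residue_vocabulary()
#' peptide_mass("AG", vocab)
#' @export
residue_vocabulary <- function(fixed_cys = TRUE, residues = NULL,
                               variable_mods = TRUE) {
  base <- .residue_masses
  if (!is.null(residues)) {
    bad <- setdiff(residues, names(base))
    if (length(bad) > 0) {
      stop("unknown residue(s): ", paste(bad, collapse = ", "))
    }
    base <- base[names(base) %in% residues]
  }
  tokens <- names(base)
  masses <- unname(base)
  if (fixed_cys && "C" %in% tokens) {
    masses <- masses[tokens != "C"]
    tokens <- tokens[tokens != "C"]
  }
  # token labels follow the field's 5-decimal convention (truncated, not
  # rounded, for the oxidation delta: +15.99491)
  add_mod <- function(res, label, delta) {
    if (res %in% names(base)) {
      tokens <<- c(tokens, paste0(res, "[", label, "]"))
      masses <<- c(masses, unname(base[res]) + delta)
    }
  }
  if ("C" %in% names(base)) {
    add_mod("C", "+57.02146", .mod_deltas[["carbamidomethyl"]])
  }
  if (variable_mods) {
    add_mod("M", "+15.99491", .mod_deltas[["oxidation"]])
    add_mod("N", "+0.98402", .mod_deltas[["deamidation"]])
    add_mod("Q", "+0.98402", .mod_deltas[["deamidation"]])
  }
  specials <- c("<pad>", "<s>", "</s>")
  vocab <- list(
    tokens = c(specials, tokens),
    masses = c(0, 0, 0, masses),
    special = c(TRUE, TRUE, TRUE, rep(FALSE, length(tokens))),
    pad_id = 1L, sos_id = 2L, eos_id = 3L
  )
  stopifnot(!anyDuplicated(vocab$tokens), all(masses > 0))
  class(vocab) <- "residue_vocabulary"
  vocab
}

#' @export
print.residue_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<residue_vocabulary: %d residue tokens + %d specials>\n",
    sum(!x$special), sum(x$special)
  ))
  invisible(x)
}

#' @rdname residue_vocabulary
#' @param vocab A `residue_vocabulary`.
#' @export
residue_tokens <- function(vocab) vocab$tokens[!vocab$special]

#' @rdname residue_vocabulary
#' @export
residue_token_masses <- function(vocab) {
  stats::setNames(vocab$masses[!vocab$special], residue_tokens(vocab))
}

#' Split a peptide string into vocabulary tokens
#'
#' Parses ProForma-like bracket notation, e.g. `"AGC[+57.02146]K"` splits
#' into `A`, `G`, `C[+57.02146]`, `K`. Every token must be a non-special
#' member of the vocabulary.
#'
#' @param peptide A peptide string (or character vector of them).
#' @param vocab A [residue_vocabulary()].
#' @return A list of character vectors (one per input string).
#' @export
tokenize_peptide <- function(peptide, vocab) {
  lapply(peptide, function(p) {
    if (is.na(p) || !nzchar(p)) return(character(0))
    toks <- regmatches(p, gregexpr("[A-Z](\\[[+-][0-9.]+\\])?", p))[[1]]
    if (nchar(paste(toks, collapse = "")) != nchar(p)) {
      stop("cannot tokenize peptide string: '", p, "'")
    }
    bad <- setdiff(toks, residue_tokens(vocab))
    if (length(bad) > 0) {
      stop("unknown residue token(s): ", paste(unique(bad), collapse = ", "))
    }
    toks
  })
}

# token character vector -> 1-based vocabulary indices
token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab$tokens)
  if (anyNA(ids)) {
    stop(
      "unknown residue token(s): ",
      paste(unique(tokens[is.na(ids)]), collapse = ", ")
    )
  }
  ids
}

as_token_vector <- function(seq, vocab) {
  if (is.character(seq) && length(seq) == 1 && !seq %in% vocab$tokens) {
    tokenize_peptide(seq, vocab)[[1]]
  } else {
    as.character(seq)
  }
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water. The empty sequence has the mass of
#' water alone.
#'
#' @param seq A peptide string in bracket notation, or a character vector of
#'   residue tokens.
#' @param vocab A [residue_vocabulary()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' vocab <- residue_vocabulary()
#' peptide_mass("G", vocab) # 75.03203
#' @export
peptide_mass <- function(seq, vocab) {
  tokens <- as_token_vector(seq, vocab)
  if (length(tokens) == 0) return(mass_constants[["water"]])
  ids <- token_ids(tokens, vocab)
  if (any(vocab$special[ids])) {
    stop(
      "special token(s) not allowed in a peptide body: ",
      paste(unique(tokens[vocab$special[ids]]), collapse = ", ")
    )
  }
  sum(vocab$masses[ids]) + mass_constants[["water"]]
}

# residue-sum mass (no water) for token id vectors; vectorized over a list
residue_mass_of_ids <- function(ids, vocab) {
  if (length(ids) == 0) return(0)
  sum(vocab$masses[ids])
}

#' Convert between neutral mass and m/z
#'
#' `mz_from_mass()` computes `(mass + charge * proton) / charge`;
#' `mass_from_mz()` is its exact inverse.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param mz Observed m/z in Th.
#' @param charge Positive integer charge state (vectorized).
#' @return m/z in Th, or neutral mass in Da.
#' @examples
#' mz_from_mass(1000, 2) # 501.00728
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (neutral_mass + charge * mass_constants[["proton"]]) / charge
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * mass_constants[["proton"]]
}

#' Relative mass difference in parts per million
#'
#' @param observed,expected Masses in Da; `expected` must be positive.
#' @return `|observed - expected| / expected * 1e6`, vectorized.
#' @examples
#' ppm_diff(500.025, 500) # 50
#' @export
ppm_diff <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected mass must be > 0")
  abs(observed - expected) / expected * 1e6
}

#' Read or write a vocabulary as a two-column table
#'
#' Plain-text tab-separated serialization with columns `token` and `mass`.
#' Special tokens are stored with mass 0.
#'
#' @param vocab A [residue_vocabulary()].
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(token = vocab$tokens, mass = vocab$masses),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric"))
  special <- tab$token %in% c("<pad>", "<s>", "</s>")
  if (!identical(tab$token[special], c("<pad>", "<s>", "</s>"))) {
    stop("vocabulary table must start with <pad>, <s>, </s>")
  }
  if (any(tab$mass[!special] <= 0)) stop("non-special tokens need mass > 0")
  vocab <- list(
    tokens = tab$token, masses = tab$mass, special = special,
    pad_id = 1L, sos_id = 2L, eos_id = 3L
  )
  class(vocab) <- "residue_vocabulary"
  vocab
}
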