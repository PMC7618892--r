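#' Theoretical b/y fragment ladder of a peptide
#'
#' Singly and multiply protonated b and y ions from backbone cleavage:
#' `b_i = (sum of the first i residue masses) + z * proton` (divided by z),
#' `y_i = (sum of the last i residue masses) + water + z * proton` (divided
#' by z), for `i = 1 .. length - 1`. These are the dominant ion series under
#' HCD fragmentation.
#'
#' @param peptide Peptide string or token vector of length >= 2.
#' @param vocab A [residue_vocabulary()].
#' @param max_charge Highest fragment charge (default 2).
#' @return A tibble with columns `ion` ("b"/"y"), `index`, `charge`, `mz`.
#' @examples
#' theoretical_fragments("AG", residue_vocabulary(), max_charge = 1)
#' @export
theoretical_fragments <- function(peptide, vocab = residue_vocabulary(),
                                  max_charge = 2) {
  toks <- as_token_vector(peptide, vocab)
  n <- length(toks)
  if (n < 2) abort("peptide must have at least 2 residues")
  m <- vocab$masses[token_ids(toks, vocab)]
  proton <- mass_constants[["proton"]]
  water <- mass_constants[["water"]]
  b_res <- cumsum(m)[-n]
  y_res <- rev(cumsum(rev(m)))[-1]      # suffix sums, i = 1..n-1 from C-term
  y_res <- rev(y_res)
  grid <- expand.grid(index = seq_len(n - 1), charge = seq_len(max_charge))
  bind_rows(
    tibble(ion = "b", index = grid$index, charge = grid$charge,
           mz = (b_res[grid$index] + grid$charge * proton) / grid$charge),
    tibble(ion = "y", index = grid$index, charge = grid$charge,
           mz = (y_res[grid$index] + water + grid$charge * proton) /
             grid$charge)
  )
}

#' Simulation settings for HCD-style synthetic spectra
#'
#' The generator emulates tryptic HCD fragmentation data: b/y ladders at
#' charges 1-2 with log-normal intensity variation (y ions boosted, as they
#' read out better for tryptic peptides), fragment m/z jitter within a ppm
#' tolerance, per-peak dropout, and uniform-random noise peaks whose
#' intensities come from the lowest quartile of the signal distribution.
#' Defaults describe a modern Orbitrap-style acquisition at desk scale.
#'
#' @param n_peptides Number of unique peptides.
#' @param length_range Peptide length bounds (max 30).
#' @param tryptic Peptides end in K/R with no internal K/R.
#' @param ptm_rates Named per-residue modification probabilities for
#'   oxidation of M and deamidation of N/Q (cysteine is always
#'   carbamidomethylated via the vocabulary).
#' @param charge_probs Named precursor-charge distribution.
#' @param fragment_ppm_jitter Uniform m/z jitter half-width in ppm.
#' @param noise_peaks Mean of the Poisson noise-peak count.
#' @param peak_dropout Per-fragment dropout probability.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   parameters.
#' @param y_boost Multiplicative intensity boost for y ions.
#' @param spectra_per_peptide Replicate spectra per peptide.
#' @param max_fragment_charge Highest fragment charge simulated.
#' @param seed Integer seed; all outputs are reproducible per seed.
#' @param vocab A [residue_vocabulary()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_peptides = 1000,
                              length_range = c(7, 16),
                              tryptic = TRUE,
                              ptm_rates = c("M" = 0.1, "N" = 0.02,
                                            "Q" = 0.02),
                              charge_probs = c("2" = 0.6, "3" = 0.4),
                              fragment_ppm_jitter = 10,
                              noise_peaks = 10,
                              peak_dropout = 0.1,
                              intensity_meanlog = 0,
                              intensity_sdlog = 0.6,
                              y_boost = 2,
                              spectra_per_peptide = 1,
                              max_fragment_charge = 2,
                              seed = 1L,
                              vocab = residue_vocabulary()) {
  stopifnot(length(length_range) == 2, length_range[1] >= 2,
            length_range[2] <= 30, length_range[1] <= length_range[2])
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# sample one peptide (token vector) under the config
sample_peptide <- function(config) {
  vocab <- config$vocab
  toks <- residue_tokens(vocab)
  lens <- seq(config$length_range[1], config$length_range[2])
  n <- lens[sample.int(length(lens), 1)]
  if (config$tryptic) {
    internal <- setdiff(toks, c("K", "R",
                                grep("^[MNQ]\\[", toks, value = TRUE)))
    term <- intersect(c("K", "R"), toks)
    if (length(term) == 0) abort("tryptic peptides need K or R in the vocabulary")
    pep <- c(sample(internal, n - 1, replace = TRUE), sample(term, 1))
  } else {
    plain <- setdiff(toks, grep("^[MNQ]\\[", toks, value = TRUE))
    pep <- sample(plain, n, replace = TRUE)
  }
  # variable modifications applied per occurrence
  for (res in names(config$ptm_rates)) {
    mod_tok <- grep(paste0("^", res, "\\["), vocab$tokens, value = TRUE)
    if (length(mod_tok) == 0) next
    hit <- which(pep == res & runif(length(pep)) < config$ptm_rates[[res]])
    pep[hit] <- mod_tok[1]
  }
  pep
}

#' Simulate one annotated spectrum for a peptide
#'
#' Fragment peaks are placed at the theoretical b/y ladder, jittered
#' uniformly within `fragment_ppm_jitter`, given log-normal intensities
#' (y ions boosted by `y_boost`), thinned by `peak_dropout` (at least one
#' peak always survives), and mixed with Poisson-many uniform noise peaks.
#' The precursor fields are exact: in the noise-free limit the spectrum's
#' precursor ppm error is 0 and the peaks equal the theoretical ladder.
#'
#' @param peptide Peptide string or token vector.
#' @param config A [simulation_config()].
#' @param seed Optional seed for this spectrum.
#' @param id Spectrum identifier.
#' @return A one-row annotated spectra tibble (with `peptide`).
#' @export
simulate_spectrum <- function(peptide, config = simulation_config(),
                              seed = NULL, id = "sim_000001") {
  vocab <- config$vocab
  toks <- as_token_vector(peptide, vocab)
  with_seed(seed, {
    charge <- as.integer(names(config$charge_probs)[
      sample.int(length(config$charge_probs), 1,
                 prob = config$charge_probs)])
    frags <- theoretical_fragments(toks, vocab,
                                   max_charge = config$max_fragment_charge)
    mz <- frags$mz
    if (config$fragment_ppm_jitter > 0) {
      mz <- mz * (1 + runif(length(mz), -1, 1) *
                    config$fragment_ppm_jitter * 1e-6)
    }
    inten <- rlnorm(length(mz), config$intensity_meanlog,
                    config$intensity_sdlog)
    inten[frags$ion == "y"] <- inten[frags$ion == "y"] * config$y_boost
    if (config$peak_dropout > 0) {
      keep <- runif(length(mz)) >= config$peak_dropout
      if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
      mz <- mz[keep]; inten <- inten[keep]
    }
    n_noise <- if (config$noise_peaks > 0) rpois(1, config$noise_peaks) else 0L
    if (n_noise > 0) {
      lo <- 100
      hi <- max(mz) + 50
      nmz <- runif(n_noise, lo, hi)
      ni <- runif(n_noise, 0, quantile(inten, 0.25))
      mz <- c(mz, nmz); inten <- c(inten, ni)
    }
    pep_mass <- peptide_mass(toks, vocab)
    as_spectra(tibble(
      spectrum_id = id,
      mz = list(mz),
      intensity = list(inten),
      precursor_mz = mz_from_mass(pep_mass, charge),
      precursor_charge = charge,
      precursor_mass = pep_mass,
      retention_time = NA_real_,
      peptide = paste(toks, collapse = "")
    ))
  })
}

#' Generate an annotated synthetic dataset
#'
#' Draws `n_peptides` unique peptides (rejection-sampled for uniqueness)
#' and simulates `spectra_per_peptide` spectra for each. Fully reproducible
#' per seed.
#'
#' @param config A [simulation_config()].
#' @return An annotated spectra tibble (PSMs).
#' @export
generate_psms <- function(config = simulation_config()) {
  vocab <- config$vocab
  with_seed(config$seed, {
    peptides <- character(0)
    seen <- new.env(hash = TRUE)
    tries <- 0
    while (length(peptides) < config$n_peptides) {
      tries <- tries + 1
      if (tries > 50 * config$n_peptides + 1000) {
        abort(paste(
          "cannot draw", config$n_peptides, "unique peptides under this",
          "configuration; enlarge the vocabulary or length range"))
      }
      pep <- paste(sample_peptide(config), collapse = "")
      if (!is.null(seen[[pep]])) next
      seen[[pep]] <- TRUE
      peptides <- c(peptides, pep)
    }
    rows <- vector("list", config$n_peptides * config$spectra_per_peptide)
    k <- 0
    for (i in seq_along(peptides)) {
      for (r in seq_len(config$spectra_per_peptide)) {
        k <- k + 1
        rows[[k]] <- simulate_spectrum(
          peptides[i], config,
          id = sprintf("sim_%06d_%d", i, r)
        )
      }
    }
    bind_rows(rows)
  })
}

#' @rdname generate_psms
#' @param mgf_path,csv_path Output files: an annotated MGF and a CSV
#'   annotation table (`spectrum_id`, `peptide`). Both round-trip through
#'   [read_mgf()]/[read.csv()] and are byte-stable per seed.
#' @export
generate_dataset <- function(config = simulation_config(), mgf_path,
                             csv_path) {
  psms <- generate_psms(config)
  write_mgf(psms, mgf_path)
  write.csv(
    data.frame(spectrum_id = psms$spectrum_id, peptide = psms$peptide),
    csv_path,
    row.names = FALSE
  )
  invisible(psms)
}

#' Matching-based oracle sequencer for clean spectra
#'
#' A dynamic search over the y-ion ladder used to validate the simulator
#' independently of any learned model: residues are appended C-terminal
#' first, each step requiring either a peak at the new suffix's singly
#' charged y m/z (within `tol_da`) or completion of the precursor residue
#' mass. Complete candidates are ranked by the fraction of their own
#' theoretical ladder present in the spectrum. In the noise-free limit this
#' recovers the generating peptide exactly up to isobaric residues.
#'
#' @param spectrum A one-row spectra tibble.
#' @param vocab A [residue_vocabulary()].
#' @param tol_da Peak-match tolerance in Da (default 0.005).
#' @param max_len Maximum peptide length searched.
#' @param max_solutions Cap on complete candidates collected.
#' @return The best peptide string, or `NA_character_` when no candidate
#'   completes.
#' @export
oracle_sequence <- function(spectrum, vocab = residue_vocabulary(),
                            tol_da = 0.005, max_len = 30,
                            max_solutions = 50) {
  mz <- spectrum$mz[[1]]
  m_res <- spectrum$precursor_mass[1] - mass_constants[["water"]]
  res_toks <- residue_tokens(vocab)
  res_mass <- unname(residue_token_masses(vocab))
  proton <- mass_constants[["proton"]]
  water <- mass_constants[["water"]]
  has_peak <- function(x) {
    i <- findInterval(x, mz)
    (i >= 1 && abs(mz[i] - x) <= tol_da) ||
      (i < length(mz) && abs(mz[i + 1] - x) <= tol_da)
  }
  solutions <- list()
  dfs <- function(suffix_ids, s) {
    if (length(solutions) >= max_solutions) return()
    if (length(suffix_ids) >= max_len) return()
    for (k in order(res_mass)) {
      s2 <- s + res_mass[k]
      if (s2 > m_res + tol_da) next
      if (abs(s2 - m_res) <= tol_da && length(suffix_ids) + 1 >= 2) {
        solutions[[length(solutions) + 1]] <<- c(k, suffix_ids)
        next
      }
      if (has_peak(s2 + water + proton)) {
        dfs(c(k, suffix_ids), s2)
      }
    }
  }
  dfs(integer(0), 0)
  if (length(solutions) == 0) return(NA_character_)
  score <- vapply(solutions, function(ids) {
    pep <- res_toks[ids]
    fr <- theoretical_fragments(pep, vocab, max_charge = 2)
    mean(vapply(fr$mz, has_peak, logical(1)))
  }, numeric(1))
  paste(res_toks[solutions[[which.max(score)]]], collapse = "")
}
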