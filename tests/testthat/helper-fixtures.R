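# shared fixtures: small vocabularies, clean synthetic PSM sets, and tiny
# transformer presets used across test files

small_vocab <- function(residues = c("G", "A", "S", "K")) {
  residue_vocabulary(residues = residues, variable_mods = FALSE)
}

clean_sim_config <- function(n_peptides, length_range = c(5, 8), seed = 1L,
                             ...) {
  simulation_config(
    n_peptides = n_peptides, length_range = length_range,
    fragment_ppm_jitter = 0, noise_peaks = 0, peak_dropout = 0,
    seed = seed, ...
  )
}

tiny_config <- function(vocab = residue_vocabulary(), ...) {
  model_config(vocab, hidden_dim = 16, heads = 2, encoder_layers = 1,
               decoder_layers = 1, ff_dim = 32, ...)
}

toy_config <- function(vocab = residue_vocabulary(), ...) {
  model_config(vocab, hidden_dim = 64, heads = 8, encoder_layers = 2,
               decoder_layers = 2, ff_dim = 256, ...)
}

# enumerate all residue multisets with total mass <= max_mass (brute force
# oracle for the knapsack table)
enumerate_reachable_masses <- function(masses, max_mass) {
  out <- 0
  frontier <- 0
  repeat {
    nxt <- unique(round(as.numeric(outer(frontier, masses, "+")), 6))
    nxt <- nxt[nxt <= max_mass]
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# exhaustive enumeration of mass-valid sequences scored by the same model:
# the independent oracle for knapsack beam search
enumerate_best_sequence <- function(model, spectrum, tol_ppm = 50,
                                    max_len = 6) {
  vocab <- model$vocab
  res_ids <- which(!vocab$special)
  res_mass <- vocab$masses[res_ids]
  m_res <- spectrum$precursor_mass[1] - mass_constants[["water"]]
  tol <- tol_ppm * 1e-6 * m_res
  seqs <- list()
  recurse <- function(ids, total) {
    if (length(ids) > 0 && abs(total - m_res) <= tol) {
      seqs[[length(seqs) + 1]] <<- ids
    }
    if (length(ids) >= max_len) return()
    for (k in seq_along(res_ids)) {
      if (total + res_mass[k] <= m_res + tol) {
        recurse(c(ids, res_ids[k]), total + res_mass[k])
      }
    }
  }
  recurse(integer(0), 0)
  if (length(seqs) == 0) return(NULL)
  memory <- encode_spectrum(spectrum, model)
  score_one <- function(ids) {
    # ids in decoding (C-terminal-first) order; score residues then stop
    lp <- 0
    for (i in seq_along(ids)) {
      z <- next_token_logits(model, memory,
                             prefix = vocab$tokens[ids[seq_len(i - 1)]])
      z <- z - max(z)
      lp <- lp + (z[ids[i]] - log(sum(exp(z))))
    }
    z <- next_token_logits(model, memory, prefix = vocab$tokens[ids])
    z <- z - max(z)
    lp + (z[vocab$eos_id] - log(sum(exp(z))))
  }
  scores <- vapply(seqs, score_one, numeric(1))
  keys <- vapply(seqs, function(ids) paste(sprintf("%03d", ids),
                                           collapse = ""), character(1))
  ord <- order(-scores, keys)
  best <- seqs[[ord[1]]]
  # sequences are enumerated in decoding order; report N->C
  list(ids = rev(best), peptide = paste(vocab$tokens[rev(best)],
                                        collapse = ""),
       score = scores[ord[1]], n_candidates = length(seqs))
}
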