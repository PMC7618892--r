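test_that("reachability table equals brute-force multiset enumeration", {
  vocab <- small_vocab(c("G", "A"))
  tab <- build_knapsack(vocab, max_mass = 200, resolution = 5e-4)
  masses <- vocab$masses[!vocab$special]
  truth <- enumerate_reachable_masses(masses, 200)
  expect_true(all(c(0, 57.02, 71.04, 114.04, 128.06, 142.07) %in%
                    round(truth, 2)))
  # every brute-force mass maps to a reachable bin
  bins <- round(truth / tab$resolution) + 1
  expect_true(all(tab$reachable[bins]))
  # reachable bins are exactly the brute-force ones (within 1 bin slack)
  reach_idx <- which(tab$reachable) - 1
  near <- vapply(reach_idx * tab$resolution, function(x)
    min(abs(truth - x)), numeric(1))
  expect_true(all(near <= 2 * tab$resolution))
  # 100.00 Da is unreachable with {G, A}
  expect_false(is_continuable(100, tab, tol_ppm = 50, precursor_mass = 1000))
  expect_false(tab$reachable[round(100 / tab$resolution) + 1])
})

test_that("table closure: reachable + residue stays reachable", {
  vocab <- small_vocab()
  tab <- build_knapsack(vocab, max_mass = 600, resolution = 5e-4)
  masses <- vocab$masses[!vocab$special]
  reach <- which(tab$reachable) - 1
  set.seed(3)
  for (b in sample(reach, 200, replace = TRUE)) {
    for (rm in masses) {
      b2 <- round(b + rm / tab$resolution)
      if (b2 < length(tab$reachable)) {
        expect_true(tab$reachable[b2 + 1])
      }
    }
  }
  expect_true(tab$reachable[1])   # empty suffix
})

test_that("is_continuable window arithmetic handles boundary cases", {
  vocab <- small_vocab(c("G", "A"))
  tab <- build_knapsack(vocab, max_mass = 2000)
  # remaining 0 within tolerance
  expect_true(is_continuable(0, tab, 50, 1000))
  expect_true(is_continuable(0.04, tab, 50, 1000))
  # -1 Da at precursor 1000 (window +-0.05) is dead
  expect_false(is_continuable(-1, tab, 50, 1000))
  # single-residue reachability
  expect_true(is_continuable(57.0215, tab, 50, 1000))
  # beyond the table bound nothing is reachable
  expect_false(is_continuable(3000, tab, 50, 1000))
})

test_that("knapsack cache round-trips and validates its key", {
  vocab <- small_vocab()
  tab <- build_knapsack(vocab, max_mass = 500)
  path <- withr::local_tempfile(fileext = ".bin")
  save_knapsack(tab, path)
  back <- load_knapsack(path, vocab, max_mass = 500)
  expect_equal(back$reachable, tab$reachable)
  expect_error(load_knapsack(path, small_vocab(c("G", "A"))), "match")
})

test_that("beam search equals exhaustive enumeration on toy instances", {
  vocab <- small_vocab(c("G", "A", "S", "K"))
  tab <- build_knapsack(vocab, max_mass = 800)
  n_agree <- 0
  for (inst in 1:8) {
    cfg <- model_config(vocab, hidden_dim = 16, heads = 2,
                        encoder_layers = 1, decoder_layers = 1, ff_dim = 32,
                        max_peptide_len = 6)
    m <- new_model(cfg, seed = 100 + inst)
    pep <- with_seed(inst, paste(
      sample(residue_tokens(vocab), sample(2:4, 1), replace = TRUE),
      collapse = ""))
    sp <- simulate_spectrum(pep, clean_sim_config(1, vocab = vocab),
                            seed = inst)
    oracle <- enumerate_best_sequence(m, sp[1, ], max_len = 6)
    pred <- knapsack_beam_search(sp, m, beam_width = 64, knapsack = tab,
                                 max_len = 6)
    expect_equal(nrow(pred), 1)
    expect_equal(pred$peptide, oracle$peptide)
    expect_equal(pred$log_prob, oracle$score, tolerance = 1e-8)
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 8)
})

test_that("every decoded peptide satisfies the precursor ppm window", {
  psms <- generate_psms(clean_sim_config(25, length_range = c(4, 6),
                                         seed = 51))
  m <- train_model(psms, config = tiny_config(), epochs = 2, seed = 1)
  preds <- knapsack_beam_search(psms, m, beam_width = 5, tol_ppm = 50)
  expect_gt(nrow(preds), 0)
  vocab <- m$vocab
  for (k in seq_len(nrow(preds))) {
    m_res <- psms$precursor_mass[match(preds$spectrum_id[k],
                                       psms$spectrum_id)] -
      mass_constants[["water"]]
    res_mass <- sum(vocab$masses[denovoms:::token_ids(preds$tokens[[k]],
                                                      vocab)])
    expect_lte(ppm_diff(res_mass, m_res), 50)
  }
  expect_equal(preds$precursor_ppm_error,
               purrr::map_dbl(seq_len(nrow(preds)), function(k) {
                 m_res <- psms$precursor_mass[match(preds$spectrum_id[k],
                                                    psms$spectrum_id)] -
                   mass_constants[["water"]]
                 ppm_diff(sum(vocab$masses[denovoms:::token_ids(
                   preds$tokens[[k]], vocab)]), m_res)
               }))
})

test_that("log_prob equals the sum of per-residue terms; B=1 is greedy", {
  vocab <- small_vocab()
  psms <- generate_psms(clean_sim_config(5, length_range = c(3, 4),
                                         seed = 61, vocab = vocab))
  m <- new_model(tiny_config(vocab), seed = 9)
  tab <- build_knapsack(vocab, max_mass = 1000)
  preds <- knapsack_beam_search(psms, m, beam_width = 3, knapsack = tab)
  for (k in seq_len(nrow(preds))) {
    expect_equal(preds$log_prob[k], sum(preds$per_residue_log_probs[[k]]))
    expect_equal(preds$confidence[k], exp(preds$log_prob[k]))
  }
  # B = 1: greedy decoding under knapsack masking
  g <- knapsack_beam_search(psms[1, ], m, beam_width = 1, knapsack = tab)
  expect_equal(nrow(g), 1)
  mem <- encode_spectrum(psms[1, ], m)
  m_res <- psms$precursor_mass[1] - mass_constants[["water"]]
  res_ids <- which(!vocab$special)
  out <- integer(0); rem <- m_res; score <- 0; best <- NULL
  repeat {
    z <- next_token_logits(m, mem, prefix = vocab$tokens[out])
    z <- z - max(z); z <- z - log(sum(exp(z)))
    if (abs(rem) <= 50e-6 * m_res && length(out) > 0) {
      sc <- score + z[vocab$eos_id]
      if (is.null(best) || sc > best$score) best <- list(ids = out,
                                                         score = sc)
    }
    cand <- res_ids[is_continuable(rem - vocab$masses[res_ids], tab, 50,
                                   m_res)]
    if (length(cand) == 0) break
    pick <- cand[which.max(z[cand])]
    if (!is.null(best) && best$score >= score + z[pick]) break
    out <- c(out, pick); rem <- rem - vocab$masses[pick]
    score <- score + z[pick]
  }
  expect_equal(g$tokens[[1]], rev(vocab$tokens[best$ids]))
  expect_equal(g$log_prob, unname(best$score), tolerance = 1e-10)
})

test_that("increasing the beam width never lowers the returned score", {
  vocab <- small_vocab()
  tab <- build_knapsack(vocab, max_mass = 1000)
  for (inst in 1:6) {
    m <- new_model(tiny_config(vocab), seed = 300 + inst)
    pep <- with_seed(inst * 7, paste(
      sample(residue_tokens(vocab), 3, replace = TRUE), collapse = ""))
    sp <- simulate_spectrum(pep, clean_sim_config(1, vocab = vocab),
                            seed = inst)
    scores <- vapply(c(1, 2, 4, 8), function(B) {
      knapsack_beam_search(sp, m, beam_width = B, knapsack = tab,
                           max_len = 5)$log_prob
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-12))
  }
})
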