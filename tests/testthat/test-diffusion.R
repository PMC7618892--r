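test_that("noise schedule satisfies the corruption invariants", {
  sch <- noise_schedule(20)
  expect_equal(sch$alpha_bar[1], 1)
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_lte(sch$alpha_bar[21], 0.05)
  expect_true(all(sch$beta > 0 & sch$beta < 1))
  expect_equal(sch$alpha_bar[-1], cumprod(1 - sch$beta), tolerance = 1e-12)
})

test_that("q_sample keeps tokens with probability alpha_bar + (1-alpha_bar)/K", {
  # single step with beta = 0.4 and K = 4: keep probability 0.7
  sch <- structure(list(n_steps = 1L, beta = 0.4, alpha_bar = c(1, 0.6)),
                   class = "noise_schedule")
  x0 <- rep(1L, 40000)
  xt <- q_sample(x0, 1, sch, k = 4, seed = 11)
  expect_equal(mean(xt == 1L), 0.7, tolerance = 0.02)
  # t = 0 is the identity
  expect_identical(q_sample(x0, 0, sch, 4), x0)
  expect_error(q_sample(x0, 2, sch, 4), "range")
  # alpha_bar -> 0 gives the uniform distribution
  sch0 <- structure(list(n_steps = 1L, beta = 0.999,
                         alpha_bar = c(1, 0.001)),
                    class = "noise_schedule")
  xt0 <- q_sample(x0, 1, sch0, k = 4, seed = 12)
  expect_equal(unname(as.numeric(table(xt0)) / length(xt0)),
               rep(0.25, 4), tolerance = 0.02)
})

test_that("closed-form marginal matches the composed single-step chain", {
  sch <- noise_schedule(6)
  K <- 4
  n <- 10000
  t_target <- 4
  x0 <- rep(2L, n)
  # compose single steps 1..t
  xt <- x0
  set.seed(99)
  for (t in seq_len(t_target)) xt <- q_step(xt, t, sch, K)
  direct <- q_sample(x0, t_target, sch, K, seed = 123)
  tab_c <- tabulate(xt, K)
  tab_d <- tabulate(direct, K)
  expect_gt(stats::chisq.test(rbind(tab_c, tab_d))$p.value, 1e-4)
  # and against the analytic marginal
  ab <- sch$alpha_bar[t_target + 1]
  p_exp <- rep((1 - ab) / K, K)
  p_exp[2] <- p_exp[2] + ab
  expect_gt(stats::chisq.test(tab_c, p = p_exp)$p.value, 1e-4)
})

test_that("posterior rows normalize and collapse correctly", {
  sch <- noise_schedule(10)
  K <- 6
  set.seed(5)
  x_t <- sample.int(K, 30, replace = TRUE)
  x0 <- sample.int(K, 30, replace = TRUE)
  for (t in c(1, 5, 10)) {
    post <- posterior_distribution(x_t, x0, t, sch, K)
    expect_equal(rowSums(post), rep(1, 30), tolerance = 1e-10)
    expect_true(all(post >= 0))
  }
  # beta_t = 0 (no corruption at step t): posterior is a point mass on x_t
  sch0 <- structure(list(n_steps = 2L, beta = c(0.3, 1e-12),
                         alpha_bar = c(1, 0.7, 0.7 * (1 - 1e-12))),
                    class = "noise_schedule")
  post <- posterior_distribution(x_t, x0, 2, sch0, K)
  expect_equal(post[cbind(seq_along(x_t), x_t)], rep(1, 30),
               tolerance = 1e-6)
  # at t = 1 the posterior collapses onto the clean sequence x_0
  post1 <- posterior_distribution(x_t, x0, 1, sch, K)
  expect_equal(post1[cbind(seq_along(x0), x0)], rep(1, 30),
               tolerance = 1e-10)
})

test_that("posterior matches brute-force Bayes for K = 2", {
  sch <- noise_schedule(5)
  K <- 2
  t <- 3
  beta <- sch$beta[t]
  ab_prev <- sch$alpha_bar[t]
  q_step_prob <- function(to, from) (1 - beta) * (to == from) + beta / K
  q_marg_prob <- function(v, x0) ab_prev * (v == x0) + (1 - ab_prev) / K
  for (x_t in 1:2) for (x0 in 1:2) {
    un <- vapply(1:2, function(v) q_step_prob(x_t, v) * q_marg_prob(v, x0),
                 numeric(1))
    expected <- un / sum(un)
    got <- posterior_distribution(x_t, x0, t, sch, K)
    expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  }
})

test_that("refiner training decreases loss and conditions on the timestep", {
  vocab <- residue_vocabulary()
  psms <- generate_psms(clean_sim_config(60, length_range = c(4, 6),
                                         seed = 71))
  sch <- noise_schedule(8)
  ref <- train_refiner(psms, config = tiny_config(vocab), schedule = sch,
                       epochs = 3, seed = 2)
  expect_lt(utils::tail(ref$loss_trace, 1), ref$loss_trace[1])
  expect_gt(max(abs(ref$params$time_emb[, 2] - ref$params$time_emb[, 8])), 0)
  # timestep changes the x0 prediction
  cfg <- denovoms:::cpp_config(ref$config, alpha_bar = sch$alpha_bar)
  mem <- denovoms:::tf_encode_cpp(ref$params, cfg, psms$mz[[1]],
                                  psms$intensity[[1]],
                                  psms$precursor_mass[1],
                                  psms$precursor_charge[1])
  ids <- denovoms:::token_ids(
    denovoms:::tokenize_peptide(psms$peptide[1], vocab)[[1]], vocab)
  z1 <- denovoms:::tf_refiner_logits_cpp(ref$params, cfg, mem,
                                         psms$precursor_mass[1],
                                         psms$mz[[1]],
                                         as.integer(ids - 1L), 1L)
  z7 <- denovoms:::tf_refiner_logits_cpp(ref$params, cfg, mem,
                                         psms$precursor_mass[1],
                                         psms$mz[[1]],
                                         as.integer(ids - 1L), 7L)
  expect_gt(max(abs(z1 - z7)), 1e-6)
  expect_error(train_refiner(psms[0, ], config = tiny_config(vocab)),
               "empty")
})

test_that("refine contracts: start_t = 0 identity, full chain, determinism", {
  vocab <- residue_vocabulary()
  psms <- generate_psms(clean_sim_config(20, length_range = c(4, 5),
                                         seed = 81))
  ref <- train_refiner(psms, config = tiny_config(vocab),
                       schedule = noise_schedule(20), epochs = 1, seed = 3)
  sp <- psms[1, ]
  r0 <- refine(sp, ref, init = sp$peptide, start_t = 0)
  expect_equal(r0$peptide, sp$peptide)
  expect_equal(r0$n_steps_run, 0L)
  # from uniform noise the chain executes exactly T = 20 reverse steps
  rn <- refine(sp, ref, init = NULL, seed = 4)
  expect_equal(rn$n_steps_run, 20L)
  rn2 <- refine(sp, ref, init = NULL, seed = 4)
  expect_identical(rn$peptide, rn2$peptide)
  r15 <- refine(sp, ref, init = sp$peptide, start_t = 15, seed = 5)
  expect_equal(r15$n_steps_run, 15L)
})

test_that("selection decoding picks the best mass-valid sample or falls back", {
  vocab <- residue_vocabulary()
  psms <- generate_psms(clean_sim_config(30, length_range = c(4, 5),
                                         seed = 91))
  ref <- train_refiner(psms, config = tiny_config(vocab),
                       schedule = noise_schedule(20), epochs = 2, seed = 3)
  sp <- psms[1, ]
  out <- decode_with_selection(sp, ref, in_prediction = sp$peptide,
                               n_samples = 5, seed = 7)
  expect_true(out$source %in% c("refined", "fallback"))
  # selection safety: with an initialization the result is mass-valid
  expect_true(out$mass_valid)
  expect_lte(out$precursor_ppm_error, 50)
  if (out$source == "fallback") expect_equal(out$peptide, sp$peptide)
  # n_samples = 1 degenerate case still returns a row
  one <- decode_with_selection(sp, ref, in_prediction = sp$peptide,
                               n_samples = 1, seed = 8)
  expect_equal(nrow(one), 1)
  expect_true(one$mass_valid)
})

test_that("a refiner overfitted on toy data repairs single-residue errors", {
  vocab <- residue_vocabulary()
  psms <- generate_psms(clean_sim_config(40, length_range = c(5, 6),
                                         seed = 111))
  ref <- train_refiner(psms, config = toy_config(vocab),
                       schedule = noise_schedule(20), epochs = 60, seed = 5,
                       learning_rate = 2e-3)
  res_toks <- residue_tokens(vocab)
  set.seed(17)
  fixed <- 0; total <- 20
  for (k in seq_len(total)) {
    toks <- tokenize_peptide(psms$peptide[k], vocab)[[1]]
    pos <- sample(seq_along(toks), 1)
    wrong <- toks
    wrong[pos] <- sample(setdiff(res_toks, toks[pos]), 1)
    out <- decode_with_selection(psms[k, ], ref,
                                 in_prediction = paste(wrong, collapse = ""),
                                 n_samples = 5, seed = 1000 + k)
    if (aa_matches(out$peptide, psms$peptide[k], vocab)$peptide_match) {
      fixed <- fixed + 1
    }
  }
  expect_gt(fixed / total, 0.5)
})
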