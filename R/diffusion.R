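#' Multinomial-diffusion noise schedule
#'
#' Per-step corruption probabilities `beta_t` and their cumulative survival
#' products `alpha_bar_t = prod_{s<=t}(1 - beta_s)` over `n_steps` discrete
#' timesteps (default 20, the refinement depth used at decode time). The
#' default is a cosine schedule mapped onto the discrete steps, which
#' satisfies the schedule invariants: `alpha_bar_0 = 1`, strictly
#' decreasing, and nearly zero at the final step.
#'
#' @param n_steps Number of diffusion steps T (default 20).
#' @param s Cosine-schedule offset (default 0.008).
#' @return A `noise_schedule` object with fields `n_steps`, `beta` (length
#'   T) and `alpha_bar` (length T + 1; `alpha_bar[1]` is `alpha_bar_0 = 1`).
#' @export
noise_schedule <- function(n_steps = 20L, s = 0.008) {
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1)
  f <- function(t) cos((t / n_steps + s) / (1 + s) * pi / 2)^2
  ab <- f(0:n_steps) / f(0)
  beta <- pmin(1 - ab[-1] / ab[-length(ab)], 0.999)
  alpha_bar <- c(1, cumprod(1 - beta))
  stopifnot(all(beta > 0 & beta < 1), all(diff(alpha_bar) < 0),
            alpha_bar[n_steps + 1] <= 0.05)
  structure(list(n_steps = n_steps, beta = beta, alpha_bar = alpha_bar),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule: T = %d, beta in [%.4f, %.4f], alpha_bar_T = %.4g>\n",
    x$n_steps, min(x$beta), max(x$beta), x$alpha_bar[x$n_steps + 1]
  ))
  invisible(x)
}

#' Forward corruption: sample x_t given x_0
#'
#' Each position independently keeps its token with probability
#' `alpha_bar_t + (1 - alpha_bar_t) / K` and is otherwise uniform over the K
#' categories; this closed-form marginal equals the composition of the
#' single-step transitions `q(x_t | x_{t-1})`.
#'
#' @param x0 Integer vector of categories in `1..k`.
#' @param t Timestep in `0..n_steps` (`t = 0` returns `x0` unchanged).
#' @param schedule A [noise_schedule()].
#' @param k Number of categories.
#' @param seed Optional seed for a reproducible draw.
#' @return Integer vector `x_t`.
#' @export
q_sample <- function(x0, t, schedule, k, seed = NULL) {
  if (t < 0 || t > schedule$n_steps) abort("t out of range")
  if (t == 0) return(x0)
  ab <- schedule$alpha_bar[t + 1]
  with_seed(seed, {
    keep <- runif(length(x0)) < ab
    out <- ifelse(keep, x0, sample.int(k, length(x0), replace = TRUE))
    as.integer(out)
  })
}

#' Single-step corruption kernel (for composition tests)
#'
#' One application of `q(x_t | x_{t-1})`: keep with probability
#' `1 - beta_t`, otherwise resample uniformly over the K categories.
#'
#' @inheritParams q_sample
#' @param x Integer vector `x_{t-1}`.
#' @export
q_step <- function(x, t, schedule, k, seed = NULL) {
  if (t < 1 || t > schedule$n_steps) abort("t out of range")
  b <- schedule$beta[t]
  with_seed(seed, {
    keep <- runif(length(x)) >= b
    as.integer(ifelse(keep, x, sample.int(k, length(x), replace = TRUE)))
  })
}

#' Multinomial-diffusion posterior q(x_{t-1} | x_t, x_0)
#'
#' Per-position categorical posterior over the K categories. `x0_estimate`
#' may be a point estimate (integer vector) or a per-position probability
#' matrix (`length(x_t)` rows, K columns), in which case the exact Bayes
#' posteriors under each candidate `x_0` are mixed by its probability.
#' Every returned row sums to 1.
#'
#' @param x_t Integer vector of categories at step t.
#' @param x0_estimate Integer vector or `L x K` probability matrix.
#' @param t Timestep in `1..n_steps`.
#' @param schedule A [noise_schedule()].
#' @param k Number of categories.
#' @return An `L x K` matrix of posterior probabilities.
#' @export
posterior_distribution <- function(x_t, x0_estimate, t, schedule, k) {
  if (t < 1 || t > schedule$n_steps) abort("t out of range")
  L <- length(x_t)
  beta <- schedule$beta[t]
  ab_prev <- schedule$alpha_bar[t]        # alpha_bar_{t-1}
  p0 <- if (is.matrix(x0_estimate)) {
    stopifnot(nrow(x0_estimate) == L, ncol(x0_estimate) == k)
    x0_estimate
  } else {
    m <- matrix(0, L, k)
    m[cbind(seq_len(L), x0_estimate)] <- 1
    m
  }
  # a(v) = q(x_t | x_{t-1} = v); b_u(v) = q(x_{t-1} = v | x0 = u)
  # Z(u) = ab_prev * a(u) + (1 - ab_prev) / k
  a <- matrix(beta / k, L, k)
  a[cbind(seq_len(L), x_t)] <- a[cbind(seq_len(L), x_t)] + (1 - beta)
  Z <- ab_prev * a + (1 - ab_prev) / k    # L x k, Z[, u]
  w <- p0 / Z
  theta <- a * (ab_prev * w + (1 - ab_prev) / k * rowSums(w))
  theta / rowSums(theta)
}

#' Train the diffusion refiner
#'
#' Fits the iterative-refinement model: a spectrum encoder identical to the
#' base model's plus a bidirectional decoder that cross-attends to an
#' embedding of the current timestep and predicts the clean sequence `x_0`
#' from a corrupted `x_t`. Each example draws `t` uniformly from `1..T` and
#' corrupts the ground truth with the closed-form marginal; the loss is the
#' per-position cross-entropy to `x_0` (the stable surrogate for the full
#' variational bound).
#'
#' @param psms Training PSMs (spectra tibble with `peptide`).
#' @param model An existing refiner to continue training, or `NULL`.
#' @param config A [model_config()] with `refiner = TRUE` (when `model` is
#'   `NULL`; `refiner` is forced on).
#' @param schedule A [noise_schedule()].
#' @inheritParams train_model
#' @return A trained refiner `denovo_model` (carries the schedule and the
#'   training length distribution, used when refining from pure noise).
#' @export
train_refiner <- function(psms, model = NULL, config = model_config(),
                          schedule = noise_schedule(), epochs = 10,
                          seed = 1L, learning_rate = 1e-3, batch_size = 32,
                          clip = 1, dropout = 0.1, augment_ppm = 5,
                          augment_intensity = 0.4, verbose = FALSE) {
  if (nrow(psms) == 0) abort("empty training set")
  if (is.null(model)) {
    config$refiner <- TRUE
    config$n_steps <- schedule$n_steps
    model <- new_model(config, seed = seed)
    model$schedule <- schedule
  }
  if (!isTRUE(model$config$refiner)) {
    abort("model is not a refiner; use train_model()")
  }
  vocab <- model$vocab
  data <- training_examples(psms, vocab, reverse = FALSE, append_eos = FALSE)
  lens <- lengths(tokenize_peptide(psms$peptide, vocab))
  cfg <- cpp_config(model$config, alpha_bar = model$schedule$alpha_bar)
  fit <- tf_train_cpp(model$params, cfg, data, model$opt %||% list(),
                      as.integer(epochs), learning_rate,
                      as.integer(batch_size), clip, as.integer(seed),
                      isTRUE(verbose), dropout, augment_ppm,
                      augment_intensity)
  model$params <- fit$params
  model$opt <- fit$opt
  model$loss_trace <- c(model$loss_trace, as.numeric(fit$loss))
  model$token_accuracy <- c(model$token_accuracy,
                            as.numeric(fit$token_accuracy))
  model$epochs_trained <- model$epochs_trained + as.integer(epochs)
  dist <- table(lens) / length(lens)
  model$length_distribution <- setNames(as.numeric(dist),
                                        names(dist))
  model
}

# x0-prediction distribution over residue categories (L x K), masking the
# special tokens out of the softmax; `enc` carries memory + precursor mass
refiner_x0_probs <- function(refiner, cfg, enc, ids, t) {
  logits <- tf_refiner_logits_cpp(refiner$params, cfg, enc$memory,
                                  enc$precursor_mass, enc$mz,
                                  as.integer(ids - 1L), as.integer(t))
  res_ids <- which(!refiner$vocab$special)
  z <- logits[res_ids, , drop = FALSE]              # K x L
  z <- sweep(z, 2, apply(z, 2, max))
  p <- exp(z)
  t(sweep(p, 2, colSums(p), "/"))                   # L x K
}

# model log-probability of a final sequence: the x0 head evaluated at t = 1
# with the sequence itself as input
refiner_log_prob <- function(refiner, cfg, enc, ids) {
  p <- refiner_x0_probs(refiner, cfg, enc, ids, 1L)
  res_ids <- which(!refiner$vocab$special)
  sum(log(p[cbind(seq_along(ids), match(ids, res_ids))]))
}

#' Iteratively refine a sequence with the diffusion model
#'
#' Runs the reverse chain from `start_t` down to 0. At each step the model
#' predicts the clean sequence and `x_{t-1}` is sampled from the
#' multinomial-diffusion posterior; the final step takes the argmax of the
#' predicted `x_0` distribution. With `init = NULL` the chain starts from
#' uniform noise at `start_t = T` with a length drawn from the refiner's
#' training length distribution. The initialization is injected uncorrupted
#' at `start_t` (set `noise_init = TRUE` to corrupt it to the `start_t`
#' marginal first).
#'
#' @param spectrum A one-row spectra tibble.
#' @param refiner A trained [train_refiner()] model.
#' @param init Initial peptide (string or token vector), or `NULL` for pure
#'   noise.
#' @param start_t Step to start from (defaults to T for noise, and must be
#'   `<= T`).
#' @param seed Optional seed.
#' @param noise_init Corrupt the initialization to the `start_t` marginal
#'   before refining (default `FALSE`).
#' @return A list with `tokens` (character), `peptide`, `log_prob`,
#'   `n_steps_run`.
#' @export
refine <- function(spectrum, refiner, init = NULL, start_t = NULL,
                   seed = NULL, noise_init = FALSE) {
  schedule <- refiner$schedule
  vocab <- refiner$vocab
  res_ids <- which(!vocab$special)
  K <- length(res_ids)
  if (is.null(init)) {
    start_t <- start_t %||% schedule$n_steps
    if (start_t != schedule$n_steps) {
      abort("refining from noise must start at t = n_steps")
    }
  } else {
    start_t <- start_t %||% schedule$n_steps
    if (start_t > schedule$n_steps) abort("start_t exceeds n_steps")
  }
  cfg <- cpp_config(refiner$config, alpha_bar = schedule$alpha_bar)
  memory <- list(
    memory = tf_encode_cpp(refiner$params, cfg, spectrum$mz[[1]],
                           spectrum$intensity[[1]],
                           spectrum$precursor_mass[1],
                           as.integer(spectrum$precursor_charge[1])),
    precursor_mass = spectrum$precursor_mass[1],
    mz = spectrum$mz[[1]]
  )
  if (!is.null(init) && start_t == 0) {
    toks <- as_token_vector(init, vocab)
    ids <- token_ids(toks, vocab)
    return(list(tokens = toks, peptide = paste(toks, collapse = ""),
                log_prob = refiner_log_prob(refiner, cfg, memory, ids),
                n_steps_run = 0L))
  }
  with_seed(seed, {
    if (is.null(init)) {
      ld <- refiner$length_distribution
      if (is.null(ld)) abort("refiner lacks a training length distribution")
      L <- as.integer(names(ld)[sample.int(length(ld), 1, prob = ld)])
      x <- res_ids[sample.int(K, L, replace = TRUE)]
    } else {
      toks <- as_token_vector(init, vocab)
      x <- token_ids(toks, vocab)
      if (noise_init) {
        xk <- q_sample(match(x, res_ids), start_t, schedule, K)
        x <- res_ids[xk]
      }
    }
    n_run <- 0L
    for (t in seq(start_t, 1)) {
      p0 <- refiner_x0_probs(refiner, cfg, memory, x, t)   # L x K
      if (t > 1) {
        post <- posterior_distribution(match(x, res_ids), p0, t, schedule, K)
        xk <- vapply(seq_len(nrow(post)), function(i)
          sample.int(K, 1, prob = post[i, ]), integer(1))
      } else {
        xk <- max.col(p0, ties.method = "first")
      }
      x <- res_ids[xk]
      n_run <- n_run + 1L
    }
    list(
      tokens = vocab$tokens[x],
      peptide = paste(vocab$tokens[x], collapse = ""),
      log_prob = refiner_log_prob(refiner, cfg, memory, x),
      n_steps_run = n_run
    )
  })
}

#' Multi-sample diffusion decoding with precursor-mass selection
#'
#' Draws `n_samples` refined sequences (initialized from the base-model
#' prediction at `start_t` when provided, else from uniform noise at T).
#' Among samples whose residue mass lies within `tol_ppm` of the precursor
#' residue mass, the one with the highest model log-probability is
#' selected. If none qualifies and an initialization exists, the
#' initialization is returned unchanged (`source = "fallback"`); without an
#' initialization the highest-scoring sample is returned flagged as
#' mass-violating.
#'
#' @param spectrum A one-row spectra tibble.
#' @param refiner A trained refiner.
#' @param in_prediction Initial peptide string (e.g. the base model's
#'   prediction) or `NULL`.
#' @param n_samples Number of refined samples (default 5).
#' @param tol_ppm Precursor window in ppm (default 50).
#' @param start_t Injection step for the initialization (default 15).
#' @param seed Optional seed.
#' @return One-row tibble: `spectrum_id`, `peptide`, `log_prob`,
#'   `n_steps_run`, `source` (`"refined"` or `"fallback"`), `mass_valid`,
#'   `precursor_ppm_error`.
#' @export
decode_with_selection <- function(spectrum, refiner, in_prediction = NULL,
                                  n_samples = 5, tol_ppm = 50, start_t = 15,
                                  seed = NULL) {
  stopifnot(n_samples >= 1)
  vocab <- refiner$vocab
  m_res <- spectrum$precursor_mass[1] - mass_constants[["water"]]
  samples <- lapply(seq_len(n_samples), function(i) {
    refine(spectrum, refiner, init = in_prediction,
           start_t = if (is.null(in_prediction)) refiner$schedule$n_steps
                     else start_t,
           seed = if (is.null(seed)) NULL else seed + i)
  })
  mass_of <- function(s) sum(vocab$masses[token_ids(s$tokens, vocab)])
  ppm <- vapply(samples, function(s) ppm_diff(mass_of(s), m_res), numeric(1))
  lp <- vapply(samples, `[[`, numeric(1), "log_prob")
  valid <- ppm <= tol_ppm
  if (any(valid)) {
    pick <- which(valid)[which.max(lp[valid])]
    s <- samples[[pick]]
    out_source <- "refined"
    out_valid <- TRUE
    out_ppm <- ppm[pick]
  } else if (!is.null(in_prediction)) {
    toks <- as_token_vector(in_prediction, vocab)
    cfg <- cpp_config(refiner$config, alpha_bar = refiner$schedule$alpha_bar)
    memory <- list(
      memory = tf_encode_cpp(refiner$params, cfg, spectrum$mz[[1]],
                             spectrum$intensity[[1]],
                             spectrum$precursor_mass[1],
                             as.integer(spectrum$precursor_charge[1])),
      precursor_mass = spectrum$precursor_mass[1],
      mz = spectrum$mz[[1]]
    )
    ids <- token_ids(toks, vocab)
    s <- list(tokens = toks, peptide = paste(toks, collapse = ""),
              log_prob = refiner_log_prob(refiner, cfg, memory, ids),
              n_steps_run = samples[[1]]$n_steps_run)
    out_source <- "fallback"
    m <- sum(vocab$masses[ids])
    out_ppm <- ppm_diff(m, m_res)
    out_valid <- out_ppm <= tol_ppm
  } else {
    pick <- which.max(lp)
    s <- samples[[pick]]
    out_source <- "refined"
    out_valid <- FALSE
    out_ppm <- ppm[pick]
  }
  tibble(
    spectrum_id = spectrum$spectrum_id[1],
    peptide = s$peptide,
    log_prob = s$log_prob,
    n_steps_run = s$n_steps_run,
    source = out_source,
    mass_valid = out_valid,
    precursor_ppm_error = out_ppm
  )
}

#' Refine a table of base-model predictions
#'
#' Applies [decode_with_selection()] to every spectrum, initializing from
#' the matching base-model prediction when one exists (spectra without a
#' prediction start from noise). Returns a predictions tibble with
#' `model = "diffusion"`.
#'
#' @param spectra A spectra tibble.
#' @param refiner A trained refiner.
#' @param predictions Base-model predictions tibble (may omit spectra).
#' @inheritParams decode_with_selection
#' @param seed Seed; each spectrum uses an offset substream.
#' @return Predictions tibble (`spectrum_id`, `peptide`, `log_prob`,
#'   `confidence`, `model`, `source`, `mass_valid`, `precursor_ppm_error`).
#' @export
refine_predictions <- function(spectra, refiner, predictions,
                               n_samples = 5, tol_ppm = 50, start_t = 15,
                               seed = 1L) {
  idx <- match(spectra$spectrum_id, predictions$spectrum_id)
  rows <- lapply(seq_len(nrow(spectra)), function(k) {
    init <- if (is.na(idx[k])) NULL else predictions$peptide[idx[k]]
    decode_with_selection(spectra[k, ], refiner, in_prediction = init,
                          n_samples = n_samples, tol_ppm = tol_ppm,
                          start_t = start_t,
                          seed = seed + (k - 1L) * (n_samples + 1L))
  })
  out <- bind_rows(rows)
  out$confidence <- exp(out$log_prob)
  out$model <- "diffusion"
  out
}
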