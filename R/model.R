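#' Model configuration
#'
#' Geometry and encoding hyper-parameters of the sequence models. The
#' published full-scale geometry is 9 encoder and 9 decoder layers with 16
#' heads, a hidden dimension of 768 and a feed-forward dimension of 1024;
#' the defaults here are a desk-scale preset that trains on a CPU in
#' minutes. Peak m/z values (and precursor/prefix masses) are embedded with
#' multi-scale sinusoidal encodings over geometrically spaced wavelengths in
#' `[wavelength_min, wavelength_max]` Da.
#'
#' @param vocab A [residue_vocabulary()].
#' @param hidden_dim Hidden dimension (divisible by `heads`).
#' @param heads Attention heads.
#' @param encoder_layers,decoder_layers Transformer depth.
#' @param ff_dim Feed-forward dimension.
#' @param max_peptide_len Maximum decodable peptide length (residues).
#' @param wavelength_min,wavelength_max Sinusoidal embedding wavelength
#'   bounds in Da.
#' @param max_charge Largest precursor charge with its own learned
#'   embedding; higher charges map to an "unknown charge" row (with a
#'   warning at encoding time).
#' @param refiner Build the diffusion-refiner variant (bidirectional decoder
#'   with a timestep embedding).
#' @param n_steps Number of diffusion steps (refiner only; default 20).
#' @return A `model_config` object.
#' @export
model_config <- function(vocab = residue_vocabulary(),
                         hidden_dim = 64, heads = 8,
                         encoder_layers = 2, decoder_layers = 2,
                         ff_dim = 256, max_peptide_len = 30,
                         wavelength_min = 0.001, wavelength_max = 10000,
                         max_charge = 6, refiner = FALSE, n_steps = 20L) {
  if (hidden_dim %% heads != 0) abort("hidden_dim must be divisible by heads")
  if (hidden_dim %% 2 != 0) abort("hidden_dim must be even")
  cfg <- list(
    vocab = vocab, hidden_dim = hidden_dim, heads = heads,
    encoder_layers = encoder_layers, decoder_layers = decoder_layers,
    ff_dim = ff_dim, max_peptide_len = max_peptide_len,
    wavelength_min = wavelength_min, wavelength_max = wavelength_max,
    max_charge = max_charge, refiner = refiner, n_steps = as.integer(n_steps)
  )
  class(cfg) <- "model_config"
  cfg
}

# config in the form the C++ core expects (0-based ids)
cpp_config <- function(config, alpha_bar = NULL) {
  vocab <- config$vocab
  list(
    d = config$hidden_dim, H = config$heads, ff = config$ff_dim,
    n_enc = config$encoder_layers, n_dec = config$decoder_layers,
    V = length(vocab$tokens), max_len = config$max_peptide_len,
    n_charges = config$max_charge,
    lmin = config$wavelength_min, lmax = config$wavelength_max,
    pad = vocab$pad_id - 1L, sos = vocab$sos_id - 1L, eos = vocab$eos_id - 1L,
    masses = vocab$masses,
    residue_ids = which(!vocab$special) - 1L,
    refiner = isTRUE(config$refiner),
    T = config$n_steps,
    alpha_bar = alpha_bar
  )
}

#' Construct an untrained sequencing model
#'
#' Initializes transformer parameters for the given configuration. Use
#' [train_model()] to fit it.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `denovo_model` object.
#' @export
new_model <- function(config = model_config(), seed = 1L) {
  cfg <- cpp_config(config)
  params <- tf_init_params_cpp(cfg, as.integer(seed))
  structure(
    list(
      config = config, vocab = config$vocab, params = params, opt = NULL,
      loss_trace = numeric(0), token_accuracy = numeric(0),
      epochs_trained = 0L, schedule = NULL, length_distribution = NULL
    ),
    class = "denovo_model"
  )
}

#' @export
print.denovo_model <- function(x, ...) {
  cat(sprintf(
    "<denovo_model (%s): %d+%d layers, %d heads, dim %d/%d, %s parameters>\n",
    if (isTRUE(x$config$refiner)) "diffusion refiner" else "autoregressive",
    x$config$encoder_layers, x$config$decoder_layers, x$config$heads,
    x$config$hidden_dim, x$config$ff_dim,
    format(n_parameters(x), big.mark = ",")
  ))
  if (x$epochs_trained > 0) {
    cat(sprintf("  trained %d epoch(s), final loss %.4f\n",
                x$epochs_trained, utils::tail(x$loss_trace, 1)))
  }
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `denovo_model`.
#' @return Numeric scalar.
#' @export
n_parameters <- function(model) tf_param_count_cpp(model$params)

# PSM tibble -> the per-example list structure the C++ trainer consumes.
# Targets are token ids in DECODING order: right-to-left (C-terminal first),
# with the end-of-sequence token appended (autoregressive model only).
training_examples <- function(psms, vocab, reverse = TRUE,
                              append_eos = TRUE) {
  toks <- tokenize_peptide(psms$peptide, vocab)
  purrr::map(seq_len(nrow(psms)), function(k) {
    ids <- token_ids(toks[[k]], vocab)
    if (reverse) ids <- rev(ids)
    if (append_eos) ids <- c(ids, vocab$eos_id)
    list(
      mz = psms$mz[[k]], intensity = psms$intensity[[k]],
      precursor_mass = psms$precursor_mass[k],
      precursor_charge = psms$precursor_charge[k],
      target = as.integer(ids - 1L)
    )
  })
}

#' Train the autoregressive sequencing model
#'
#' Minimizes token-level cross-entropy between the decoder logits and the
#' ground-truth peptide, presented right-to-left (C-terminal first, matching
#' the y-ion ladder that dominates tryptic HCD spectra). Optimization is
#' Adam with global-norm gradient clipping; all randomness (initialization
#' aside) flows from `seed`, so a fixed seed reproduces the loss trace
#' exactly on one machine.
#'
#' @param psms A spectra tibble with a `peptide` column (training PSMs).
#' @param model A `denovo_model` from [new_model()] (continues training), or
#'   `NULL` to build one from `config`.
#' @param config A [model_config()] used when `model` is `NULL`.
#' @param epochs Number of passes over the data.
#' @param seed Integer seed (data order and initialization).
#' @param learning_rate,batch_size,clip Optimizer settings; the defaults are
#'   the package's documented desk-scale values.
#' @param dropout Dropout probability on every residual branch during
#'   training (default 0.1).
#' @param augment_ppm Training-time uniform m/z jitter half-width in ppm
#'   applied to each presented spectrum (default 5). This regularizes the
#'   finest sinusoidal channels, which on noise-free spectra would otherwise
#'   let the model memorize exact peak masses instead of learning fragment
#'   structure.
#' @param augment_intensity Log-normal sd of training-time multiplicative
#'   intensity jitter (default 0.4); a spectrum's fixed intensity pattern
#'   would otherwise fingerprint its peptide.
#' @param verbose Print per-epoch loss.
#' @return The trained `denovo_model`, with `loss_trace` and
#'   `token_accuracy` per epoch.
#' @export
train_model <- function(psms, model = NULL, config = model_config(),
                        epochs = 10, seed = 1L, learning_rate = 1e-3,
                        batch_size = 32, clip = 1, dropout = 0.1,
                        augment_ppm = 5, augment_intensity = 0.4,
                        verbose = FALSE) {
  if (nrow(psms) == 0) abort("empty training set")
  if (is.null(model)) model <- new_model(config, seed = seed)
  if (isTRUE(model$config$refiner)) {
    abort("model is a diffusion refiner; use train_refiner()")
  }
  vocab <- model$vocab
  len <- lengths(tokenize_peptide(psms$peptide, vocab))
  if (any(len > model$config$max_peptide_len)) {
    abort("training peptides exceed max_peptide_len; filter first")
  }
  data <- training_examples(psms, vocab)
  cfg <- cpp_config(model$config)
  fit <- tf_train_cpp(model$params, cfg, data,
                      model$opt %||% list(),
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
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-scale sinusoidal encoding
#'
#' Encodes scalar masses (or m/z values) as interleaved sine/cosine pairs
#' over `dim/2` geometrically spaced wavelengths between `wavelength_min`
#' and `wavelength_max` Da, spanning isotope-scale to precursor-scale
#' structure. All components lie in `[-1, 1]`; at `x = 0` the sine
#' components are 0 and the cosine components 1.
#'
#' @param x Numeric vector of masses (Da) or m/z (Th).
#' @param dim Even embedding dimension.
#' @param wavelength_min,wavelength_max Wavelength bounds in Da.
#' @return A `length(x)` x `dim` matrix.
#' @export
multiscale_encoding <- function(x, dim, wavelength_min = 0.001,
                                wavelength_max = 10000) {
  half <- dim / 2
  k <- seq_len(half) - 1
  frac <- if (half == 1) 0 else k / (half - 1)
  lambda <- wavelength_min * (wavelength_max / wavelength_min)^frac
  w <- 2 * pi / lambda
  ang <- outer(x, w)
  out <- matrix(0, length(x), dim)
  out[, 2 * k + 1] <- sin(ang)
  out[, 2 * k + 2] <- cos(ang)
  out
}

#' Per-peak embeddings of a spectrum
#'
#' The peak representation summed into the encoder input: a multi-scale
#' sinusoidal encoding of m/z plus a learned linear lift of
#' `log(1 + intensity)` (intensities are base-peak normalized), keeping the
#' peak a single vector that is monotone in intensity.
#'
#' @param spectrum A one-row spectra tibble (or a list with `mz` and
#'   `intensity` vectors).
#' @param model A `denovo_model` (supplies the learned intensity lift).
#' @return An `N x hidden_dim` matrix, one row per peak.
#' @export
embed_peaks <- function(spectrum, model) {
  mz <- if (is.data.frame(spectrum)) spectrum$mz[[1]] else spectrum$mz
  inten <- if (is.data.frame(spectrum)) spectrum$intensity[[1]] else
    spectrum$intensity
  cfg <- model$config
  E <- multiscale_encoding(mz, cfg$hidden_dim, cfg$wavelength_min,
                           cfg$wavelength_max)
  E + log1p(inten) %o% as.numeric(model$params$w_int)
}

#' Precursor embedding
#'
#' Sinusoidal encoding of the neutral precursor mass summed with a learned
#' per-charge vector. Charges outside `1..max_charge` fall back to an
#' "unknown charge" embedding with a warning.
#'
#' @param model A `denovo_model`.
#' @param mass Neutral precursor mass (Da).
#' @param charge Integer charge.
#' @return A numeric vector of length `hidden_dim`.
#' @export
encode_precursor <- function(model, mass, charge) {
  cfg <- model$config
  col <- if (charge >= 1 && charge <= cfg$max_charge) charge else {
    warn(sprintf("charge %d outside 1..%d; using unknown-charge embedding",
                 charge, cfg$max_charge))
    cfg$max_charge + 1
  }
  as.numeric(multiscale_encoding(mass, cfg$hidden_dim, cfg$wavelength_min,
                                 cfg$wavelength_max)) +
    as.numeric(model$params$charge_emb[, col])
}

#' Encode a spectrum into decoder memory
#'
#' Runs the peak embeddings (plus a learned latent-spectrum token and the
#' precursor token) through the transformer encoder self-attention stack.
#' The memory has one column per peak plus two: the latent-spectrum and
#' precursor positions.
#'
#' @param spectrum A one-row spectra tibble.
#' @param model A `denovo_model`.
#' @param peak_valid Optional 0/1 vector flagging valid peaks; invalid
#'   (padding) positions are masked out of every attention step.
#' @return An `encoded_spectrum` object: the `hidden_dim x (N + 2)` memory
#'   matrix plus the precursor fields the decoder conditions on.
#' @export
encode_spectrum <- function(spectrum, model, peak_valid = NULL) {
  cfg <- cpp_config(model$config)
  if (!is.null(spectrum$precursor_charge) &&
      (spectrum$precursor_charge[1] < 1 ||
       spectrum$precursor_charge[1] > model$config$max_charge)) {
    warn(sprintf("charge %d outside 1..%d; using unknown-charge embedding",
                 spectrum$precursor_charge[1], model$config$max_charge))
  }
  memory <- tf_encode_cpp(
    model$params, cfg, spectrum$mz[[1]], spectrum$intensity[[1]],
    spectrum$precursor_mass[1], as.integer(spectrum$precursor_charge[1]),
    if (is.null(peak_valid)) NULL else as.integer(peak_valid))
  structure(
    list(memory = memory,
         precursor_mass = spectrum$precursor_mass[1],
         precursor_charge = spectrum$precursor_charge[1],
         mz = spectrum$mz[[1]],
         n_peaks = length(spectrum$mz[[1]])),
    class = "encoded_spectrum"
  )
}

#' Next-token scores given a decoded prefix
#'
#' Causal decoder logits for the position following `prefix` (tokens in
#' decoding order, i.e. C-terminal first). Softmax of the returned vector is
#' the model's next-residue distribution.
#'
#' @param model A `denovo_model`.
#' @param memory Encoder memory from [encode_spectrum()].
#' @param prefix Character vector of residue tokens already decoded (may be
#'   empty).
#' @return Named numeric vector of scores, one per vocabulary token.
#' @export
next_token_logits <- function(model, memory, prefix = character(0)) {
  if (length(prefix) >= model$config$max_peptide_len + 1) {
    abort("prefix length exceeds max_peptide_len")
  }
  ids <- if (length(prefix)) token_ids(prefix, model$vocab) else integer(0)
  cfg <- cpp_config(model$config)
  out <- tf_next_logits_cpp(model$params, cfg, memory$memory,
                            memory$precursor_mass, memory$mz,
                            list(as.integer(ids - 1L)))
  setNames(as.numeric(out[, 1]), model$vocab$tokens)
}

#' @rdname tidy.denovo_model
#' @export
glance.denovo_model <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x),
    epochs = x$epochs_trained,
    final_loss = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1) else
      NA_real_,
    final_token_accuracy = if (length(x$token_accuracy))
      utils::tail(x$token_accuracy, 1) else NA_real_,
    hidden_dim = x$config$hidden_dim,
    heads = x$config$heads,
    encoder_layers = x$config$encoder_layers,
    decoder_layers = x$config$decoder_layers,
    refiner = isTRUE(x$config$refiner)
  )
}

#' Tidy the training trace of a model
#'
#' `tidy()` returns the per-epoch loss and teacher-forced token accuracy;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `denovo_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.denovo_model <- function(x, ...) {
  tibble(
    epoch = seq_along(x$loss_trace),
    loss = x$loss_trace,
    token_accuracy = x$token_accuracy
  )
}

#' @export
autoplot.denovo_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$loss)) +
    geom_line() + geom_point() +
    labs(x = "epoch", y = "mean token cross-entropy",
         title = "training loss") +
    theme_minimal()
}

#' Save or load a model checkpoint
#'
#' Checkpoints embed the full configuration (and, for refiners, the noise
#' schedule), so a loaded model is immediately usable.
#'
#' @param model A `denovo_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "denovo_model")) abort("not a denovo_model checkpoint")
  model
}

#' Write or read a model configuration as YAML
#'
#' @param config A [model_config()].
#' @param path YAML file path.
#' @param vocab Vocabulary to attach on read.
#' @export
write_model_config <- function(config, path) {
  fields <- config[setdiff(names(config), "vocab")]
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path, vocab = residue_vocabulary()) {
  fields <- yaml::read_yaml(path)
  do.call(model_config, c(list(vocab = vocab), fields))
}
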