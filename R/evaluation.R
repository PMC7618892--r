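#' Mass-based residue matching between a prediction and the ground truth
#'
#' Follows the matching convention of the de novo benchmarking lineage: the
#' two sequences are walked from the N-terminus with two pointers advancing
#' the side whose cumulative (prefix) mass is smaller; an aligned pair of
#' residues matches when the residue masses differ by less than
#' `tol_residue` Da and the prefix masses differ by at most `tol_prefix`
#' Da. The same pass is run from the C-terminus and the union of the two
#' match sets is taken, so isobaric substitutions (I/L; deamidated N vs D)
#' count as matches and a single internal error does not poison the
#' remainder of the peptide.
#'
#' @param pred,truth Peptide strings or token vectors (non-empty).
#' @param vocab A [residue_vocabulary()].
#' @param tol_residue Residue-mass tolerance in Da (default 0.1).
#' @param tol_prefix Prefix-mass tolerance in Da (default 0.5).
#' @return A list: `pred_flags` (logical per predicted residue),
#'   `truth_flags` (per true residue), `n_match`, `peptide_match` (all
#'   residues of both sequences matched and lengths equal).
#' @export
aa_matches <- function(pred, truth, vocab, tol_residue = 0.1,
                       tol_prefix = 0.5) {
  pt <- as_token_vector(pred, vocab)
  tt <- as_token_vector(truth, vocab)
  if (length(pt) == 0 || length(tt) == 0) abort("sequences must be non-empty")
  pm <- vocab$masses[token_ids(pt, vocab)]
  tm <- vocab$masses[token_ids(tt, vocab)]
  pass <- function(pm, tm) {
    fp <- logical(length(pm))
    ft <- logical(length(tm))
    i <- 1L; j <- 1L
    cp <- pm[1]; ct <- tm[1]
    while (i <= length(pm) && j <= length(tm)) {
      if (abs(cp - ct) <= tol_prefix) {
        if (abs(pm[i] - tm[j]) < tol_residue) {
          fp[i] <- TRUE; ft[j] <- TRUE
        }
        i <- i + 1L; j <- j + 1L
        cp <- cp + if (i <= length(pm)) pm[i] else 0
        ct <- ct + if (j <= length(tm)) tm[j] else 0
      } else if (cp < ct) {
        i <- i + 1L
        cp <- cp + if (i <= length(pm)) pm[i] else 0
      } else {
        j <- j + 1L
        ct <- ct + if (j <= length(tm)) tm[j] else 0
      }
    }
    list(fp = fp, ft = ft)
  }
  fwd <- pass(pm, tm)
  bwd <- pass(rev(pm), rev(tm))
  pred_flags <- fwd$fp | rev(bwd$fp)
  truth_flags <- fwd$ft | rev(bwd$ft)
  n_match <- sum(pred_flags)
  list(
    pred_flags = pred_flags,
    truth_flags = truth_flags,
    n_match = n_match,
    peptide_match = n_match == length(pt) && length(pt) == length(tt)
  )
}

# join predictions to truths; errors on duplicate prediction ids
join_predictions <- function(predictions, truths) {
  if (anyDuplicated(predictions$spectrum_id)) {
    abort("duplicate spectrum_id among predictions")
  }
  truths <- truths[, c("spectrum_id", "peptide")]
  names(truths)[2] <- "truth_peptide"
  left_join(truths, predictions[, c("spectrum_id", "peptide", "confidence")],
            by = "spectrum_id")
}

#' Peptide and amino-acid level metrics
#'
#' Peptide recall is the fraction of ground-truth PSMs whose prediction
#' matches at every residue under the mass rule of [aa_matches()]; peptide
#' precision uses the number of predictions made as denominator, and
#' peptide accuracy the number of evaluated (spectrum, prediction) pairs.
#' Amino-acid precision/recall aggregate matched residues over predicted and
#' true residue totals respectively (spectra without predictions still count
#' in the recall denominator), and the amino-acid error rate is
#' `1 - aa_precision`.
#'
#' @param predictions Predictions tibble (unique `spectrum_id`).
#' @param truths Annotated PSMs tibble (`spectrum_id`, `peptide`).
#' @param vocab A [residue_vocabulary()].
#' @return A one-row tibble (`aa_precision`, `aa_recall`, `aa_error_rate`,
#'   `peptide_precision`, `peptide_recall`, `peptide_accuracy`, `n_psms`,
#'   `n_predictions`, `precision_defined`). With no predictions, precisions
#'   are reported as 0 and flagged via `precision_defined = FALSE`.
#' @export
compute_metrics <- function(predictions, truths,
                            vocab = residue_vocabulary()) {
  j <- join_predictions(predictions, truths)
  n_truth <- nrow(j)
  has_pred <- !is.na(j$peptide)
  n_pred <- sum(has_pred)
  truth_len <- lengths(tokenize_peptide(j$truth_peptide, vocab))
  n_match <- 0
  pred_len_total <- 0
  pep_correct <- 0
  for (k in which(has_pred)) {
    m <- aa_matches(j$peptide[k], j$truth_peptide[k], vocab)
    n_match <- n_match + m$n_match
    pred_len_total <- pred_len_total + length(m$pred_flags)
    pep_correct <- pep_correct + m$peptide_match
  }
  tibble(
    aa_precision = if (pred_len_total > 0) n_match / pred_len_total else 0,
    aa_recall = n_match / sum(truth_len),
    aa_error_rate = if (pred_len_total > 0)
      1 - n_match / pred_len_total else 0,
    peptide_precision = if (n_pred > 0) pep_correct / n_pred else 0,
    peptide_recall = pep_correct / n_truth,
    peptide_accuracy = if (n_pred > 0) pep_correct / n_pred else 0,
    n_psms = n_truth,
    n_predictions = n_pred,
    precision_defined = n_pred > 0
  )
}

#' Precision-recall curve over a confidence sweep
#'
#' Sweeps the confidence threshold from the highest to the lowest value in
#' the prediction set; at each threshold, precision and recall are computed
#' over the retained predictions (peptide level by default, or residue
#' level). The area under the curve is the trapezoid over recall.
#'
#' @inheritParams compute_metrics
#' @param level `"peptide"` or `"aa"`.
#' @return A `pr_curve` tibble (`threshold`, `precision`, `recall`) with
#'   attribute `auc`.
#' @export
pr_curve <- function(predictions, truths, vocab = residue_vocabulary(),
                     level = c("peptide", "aa")) {
  level <- match.arg(level)
  j <- join_predictions(predictions, truths)
  j <- j[!is.na(j$peptide), ]
  if (nrow(j) == 0) abort("no predictions to sweep")
  n_truth_pep <- nrow(truths)
  truth_len_total <- sum(lengths(tokenize_peptide(truths$peptide, vocab)))
  stats <- purrr::map(seq_len(nrow(j)), function(k) {
    m <- aa_matches(j$peptide[k], j$truth_peptide[k], vocab)
    list(correct = m$peptide_match, n_match = m$n_match,
         n_pred_res = length(m$pred_flags))
  })
  d <- tibble(
    confidence = j$confidence,
    correct = purrr::map_lgl(stats, "correct"),
    n_match = purrr::map_dbl(stats, "n_match"),
    n_pred_res = purrr::map_dbl(stats, "n_pred_res")
  ) %>% arrange(desc(.data$confidence))
  thresholds <- unique(d$confidence)
  rows <- purrr::map(thresholds, function(th) {
    keep <- d$confidence >= th
    if (level == "peptide") {
      tibble(threshold = th,
             precision = mean(d$correct[keep]),
             recall = sum(d$correct[keep]) / n_truth_pep)
    } else {
      tibble(threshold = th,
             precision = sum(d$n_match[keep]) / sum(d$n_pred_res[keep]),
             recall = sum(d$n_match[keep]) / truth_len_total)
    }
  })
  curve <- bind_rows(rows)
  auc <- 0
  if (nrow(curve) > 1) {
    r <- curve$recall; p <- curve$precision
    auc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  }
  structure(curve, auc = auc, level = level, class = c("pr_curve",
                                                       class(curve)))
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$recall, y = .data$precision)) +
    geom_step() +
    labs(
      x = paste(attr(object, "level"), "recall"),
      y = paste(attr(object, "level"), "precision"),
      title = sprintf("precision-recall (AUC = %.3f)", attr(object, "auc"))
    ) +
    theme_minimal()
}

#' Surrogate FDR confidence threshold
#'
#' Given predictions and database-search-style reference peptides, returns
#' the lowest confidence cutoff such that the fraction of retained
#' predictions disagreeing with the reference is at most `target_fdr`. This
#' is the surrogate FDR used to compare de novo models against a grounded
#' search, not a target-decoy FDR. The empirical FDR above the returned
#' cutoff is checked on every invocation.
#'
#' @inheritParams compute_metrics
#' @param target_fdr Target false discovery rate (default 0.05).
#' @return A list: `cutoff` (confidence, or `NA` if unattainable with
#'   `diagnostics`), `n_above`, `fdr_above`, and `retained` — the retained
#'   predictions flagged `overlap` (agree with reference) or novel.
#' @export
fdr_threshold <- function(predictions, truths, vocab = residue_vocabulary(),
                          target_fdr = 0.05) {
  j <- join_predictions(predictions, truths)
  j <- j[!is.na(j$peptide), ]
  if (nrow(j) == 0) abort("no predictions to threshold")
  j$correct <- purrr::map2_lgl(j$peptide, j$truth_peptide, function(p, t) {
    aa_matches(p, t, vocab)$peptide_match
  })
  j <- arrange(j, desc(.data$confidence))
  cum_fdr <- cumsum(!j$correct) / seq_len(nrow(j))
  # candidate cutoffs are the observed confidences; FDR at a cutoff is the
  # cumulative error fraction at the LAST prediction with that confidence
  last_at <- !duplicated(j$confidence, fromLast = TRUE)
  cand <- which(last_at & cum_fdr <= target_fdr)
  if (length(cand) == 0) {
    return(list(
      cutoff = NA_real_, n_above = 0L, fdr_above = NA_real_,
      retained = j[0, ],
      diagnostics = sprintf(
        "no confidence cutoff reaches FDR <= %.3f (best attainable %.3f)",
        target_fdr, min(cum_fdr))
    ))
  }
  pick <- max(cand)
  cutoff <- j$confidence[pick]
  keep <- j$confidence >= cutoff
  fdr_above <- mean(!j$correct[keep])
  stopifnot(fdr_above <= target_fdr)
  retained <- j[keep, ]
  retained$overlap <- retained$correct
  retained$novel <- !retained$correct
  list(cutoff = cutoff, n_above = sum(keep), fdr_above = fdr_above,
       retained = retained)
}

#' Count prediction overlap between models
#'
#' For predictions of several models over the same spectra, counts per-model
#' correct predictions and the size of every intersection pattern (the
#' numbers behind an UpSet/Venn display).
#'
#' @param ... Named prediction tibbles.
#' @param truths Annotated PSMs.
#' @param vocab A [residue_vocabulary()].
#' @return A tibble of intersection patterns and counts.
#' @export
model_overlap <- function(..., truths, vocab = residue_vocabulary()) {
  preds <- list(...)
  if (is.null(names(preds)) || any(!nzchar(names(preds)))) {
    abort("prediction sets must be named")
  }
  correct_ids <- lapply(preds, function(p) {
    j <- join_predictions(p, truths)
    j <- j[!is.na(j$peptide), ]
    ok <- purrr::map2_lgl(j$peptide, j$truth_peptide, function(a, b) {
      aa_matches(a, b, vocab)$peptide_match
    })
    j$spectrum_id[ok]
  })
  all_ids <- unique(unlist(correct_ids))
  member <- vapply(correct_ids, function(ids) all_ids %in% ids,
                   logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(NULL, names(preds)))
  pattern <- apply(member, 1, function(r)
    paste(names(preds)[r], collapse = "&"))
  out <- as_tibble(as.data.frame(table(pattern = pattern),
                                 stringsAsFactors = FALSE))
  names(out) <- c("pattern", "n_correct")
  out
}

#' Classify a wrong prediction into an error taxonomy
#'
#' Mutually exclusive classes evaluated in order: equal-length predictions
#' are classed by the number of mismatched residues under the mass rule
#' (`"1 AA substitution"`, `"2 AA errors"`, `"more than 2 AA errors"`);
#' length differences with a peptide mass still inside the ppm window are
#' `"length mismatch"` (mass-conserving rearrangements, e.g. two glycines
#' vs one asparagine), and remaining length differences are
#' `"precursor-mass mismatch"`.
#'
#' @inheritParams aa_matches
#' @param tol_ppm Mass window for the final class split (default 50).
#' @return A single class string.
#' @export
classify_errors <- function(pred, truth, vocab = residue_vocabulary(),
                            tol_ppm = 50) {
  m <- aa_matches(pred, truth, vocab)
  if (m$peptide_match) abort("prediction matches the truth; nothing to classify")
  np <- length(m$pred_flags)
  nt <- length(m$truth_flags)
  if (np == nt) {
    n_err <- sum(!m$pred_flags)
    return(if (n_err <= 1) "1 AA substitution"
           else if (n_err == 2) "2 AA errors"
           else "more than 2 AA errors")
  }
  pm <- peptide_mass(pred, vocab)
  tm <- peptide_mass(truth, vocab)
  if (ppm_diff(pm, tm) <= tol_ppm) "length mismatch"
  else "precursor-mass mismatch"
}

#' @rdname classify_errors
#' @param predictions,truths Prediction and annotation tibbles.
#' @return For `count_error_classes()`: a tibble of class counts over all
#'   wrong predictions (classes partition the wrong predictions).
#' @export
count_error_classes <- function(predictions, truths,
                                vocab = residue_vocabulary(),
                                tol_ppm = 50) {
  j <- join_predictions(predictions, truths)
  j <- j[!is.na(j$peptide), ]
  cls <- character(0)
  for (k in seq_len(nrow(j))) {
    if (aa_matches(j$peptide[k], j$truth_peptide[k], vocab)$peptide_match) {
      next
    }
    cls <- c(cls, classify_errors(j$peptide[k], j$truth_peptide[k], vocab,
                                  tol_ppm))
  }
  lv <- c("1 AA substitution", "2 AA errors", "more than 2 AA errors",
          "length mismatch", "precursor-mass mismatch")
  out <- as_tibble(as.data.frame(table(class = factor(cls, levels = lv)),
                                 stringsAsFactors = FALSE))
  names(out) <- c("class", "n")
  out
}

#' Write a metric report as JSON
#'
#' @param metrics One-row tibble from [compute_metrics()].
#' @param path Output JSON path.
#' @export
write_metric_report <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
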