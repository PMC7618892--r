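vocab <- residue_vocabulary()

test_that("mass-based residue matching handles the canonical cases", {
  m <- aa_matches("AGKR", "AGKR", vocab)
  expect_true(all(m$pred_flags))
  expect_true(m$peptide_match)
  # C-terminal alignment rescues K; A vs G differ by 14.016 Da
  m2 <- aa_matches("AK", "GK", vocab)
  expect_equal(m2$n_match, 1)
  expect_false(m2$peptide_match)
  # N vs G fails both residue and prefix tests in "GG" vs "NG"
  m3 <- aa_matches("GG", "NG", vocab)
  expect_false(m3$pred_flags[1])
  expect_lte(m3$n_match, 1)
  # isobaric pairs match: L/I and deamidated N vs D
  expect_true(aa_matches("ALK", "AIK", vocab)$peptide_match)
  expect_true(aa_matches("AN[+0.98402]K", "ADK", vocab)$peptide_match)
  expect_error(aa_matches("", "AK", vocab), "non-empty")
})

make_preds <- function(ids, peptides, conf) {
  tibble::tibble(spectrum_id = ids, peptide = peptides,
                 log_prob = log(conf), confidence = conf, model = "ar",
                 precursor_ppm_error = 0)
}

make_truths <- function(ids, peptides) {
  tibble::tibble(spectrum_id = ids, peptide = peptides)
}

test_that("metric counting matches direct enumeration", {
  truths <- make_truths(paste0("s", 1:5),
                        c("AGK", "GGK", "ASK", "AAK", "GSK"))
  preds <- make_preds(paste0("s", 1:4),
                      c("AGK", "GGK", "ASK", "ASK"),
                      c(0.9, 0.8, 0.7, 0.6))
  met <- compute_metrics(preds, truths, vocab)
  expect_equal(met$peptide_precision, 0.75)
  expect_equal(met$peptide_recall, 0.6)
  expect_equal(met$n_psms, 5)
  expect_equal(met$n_predictions, 4)
  # perfect predictions give all ones
  perfect <- compute_metrics(
    make_preds(truths$spectrum_id, truths$peptide, rep(0.9, 5)),
    truths, vocab)
  expect_equal(perfect$aa_precision, 1)
  expect_equal(perfect$peptide_recall, 1)
  expect_equal(perfect$aa_error_rate, 0)
  # no predictions: recall 0, precision reported 0 and flagged
  none <- compute_metrics(preds[0, ], truths, vocab)
  expect_equal(none$peptide_recall, 0)
  expect_equal(none$peptide_precision, 0)
  expect_false(none$precision_defined)
  # aa_error_rate complements aa_precision; peptide <= aa recall
  expect_equal(met$aa_error_rate, 1 - met$aa_precision)
  expect_lte(met$peptide_recall, met$aa_recall)
  dup <- make_preds(c("s1", "s1"), c("AGK", "AGK"), c(0.9, 0.8))
  expect_error(compute_metrics(dup, truths, vocab), "duplicate")
})

test_that("peptide recall never exceeds amino-acid recall", {
  set.seed(23)
  toks <- residue_tokens(vocab)
  for (i in 1:10) {
    truths <- make_truths(paste0("t", 1:8), vapply(1:8, function(j)
      paste(sample(toks, 5, replace = TRUE), collapse = ""), character(1)))
    preds <- make_preds(truths$spectrum_id, vapply(1:8, function(j) {
      p <- tokenize_peptide(truths$peptide[j], vocab)[[1]]
      if (runif(1) < 0.5) p[sample(5, 1)] <- sample(toks, 1)
      paste(p, collapse = "")
    }, character(1)), runif(8))
    met <- compute_metrics(preds, truths, vocab)
    expect_lte(met$peptide_recall, met$aa_recall + 1e-12)
  }
})

test_that("PR curve sweep matches a hand-enumerated table", {
  truths <- make_truths(paste0("s", 1:5),
                        c("AGK", "GGK", "ASK", "AAK", "GSK"))
  preds <- make_preds(paste0("s", 1:4),
                      c("AGK", "GGK", "AAK", "AAK"),
                      c(0.9, 0.8, 0.7, 0.6))
  curve <- pr_curve(preds, truths, vocab)
  # thresholds descend; correctness flags are T T F T
  expect_equal(curve$threshold, c(0.9, 0.8, 0.7, 0.6))
  expect_equal(curve$precision, c(1, 1, 2 / 3, 3 / 4))
  expect_equal(curve$recall, c(1 / 5, 2 / 5, 2 / 5, 3 / 5))
  expect_equal(curve$recall, cummax(curve$recall))   # non-decreasing
  # all-correct predictions: precision identically 1, AUC = max recall
  allc <- make_preds(paste0("s", 1:4),
                     c("AGK", "GGK", "ASK", "AAK"), c(0.9, 0.8, 0.7, 0.6))
  cv <- pr_curve(allc, truths, vocab)
  expect_true(all(cv$precision == 1))
  expect_equal(attr(cv, "auc"), max(cv$recall) - min(cv$recall))
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})

test_that("FDR cutoff matches hand enumeration and bounds empirical FDR", {
  truths <- make_truths(paste0("s", 1:4), c("AGK", "GGK", "ASK", "AAK"))
  preds <- make_preds(paste0("s", 1:4),
                      c("AGK", "GGK", "AAK", "AAK"),
                      c(0.9, 0.8, 0.7, 0.6))
  fdr <- fdr_threshold(preds, truths, vocab, target_fdr = 0.05)
  expect_equal(fdr$cutoff, 0.8)
  expect_equal(fdr$n_above, 2)
  expect_lte(fdr$fdr_above, 0.05)
  expect_true(all(fdr$retained$overlap))
  # all correct: cutoff is the minimum confidence
  allc <- make_preds(paste0("s", 1:4),
                     c("AGK", "GGK", "ASK", "AAK"), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(fdr_threshold(allc, truths, vocab)$cutoff, 0.6)
  # all wrong: unattainable, reported with diagnostics
  wrong <- make_preds(paste0("s", 1:4),
                      c("GGK", "AGK", "GAK", "GGK"), c(0.9, 0.8, 0.7, 0.6))
  res <- fdr_threshold(wrong, truths, vocab)
  expect_true(is.na(res$cutoff))
  expect_match(res$diagnostics, "no confidence cutoff")
})

test_that("empirical FDR above the cutoff is bounded on random sets", {
  set.seed(31)
  toks <- residue_tokens(vocab)
  for (i in 1:10) {
    n <- 40
    truths <- make_truths(paste0("r", 1:n), vapply(1:n, function(j)
      paste(sample(toks, 4, replace = TRUE), collapse = ""), character(1)))
    correct <- runif(n) < 0.7
    pep <- vapply(1:n, function(j) {
      if (correct[j]) return(truths$peptide[j])
      p <- tokenize_peptide(truths$peptide[j], vocab)[[1]]
      p[1] <- sample(setdiff(toks, p[1]), 1)
      paste(p, collapse = "")
    }, character(1))
    conf <- plogis(rnorm(n, ifelse(correct, 1.5, -0.5)))
    fdr <- fdr_threshold(make_preds(truths$spectrum_id, pep, conf),
                         truths, vocab, target_fdr = 0.1)
    if (!is.na(fdr$cutoff)) expect_lte(fdr$fdr_above, 0.1)
  }
})

test_that("error taxonomy is a partition evaluated in order", {
  expect_equal(classify_errors("AAKR", "AGKR", vocab), "1 AA substitution")
  expect_equal(classify_errors("AASR", "AGKR", vocab), "2 AA errors")
  expect_equal(classify_errors("SSSR", "AGKR", vocab),
               "more than 2 AA errors")
  # two glycines vs one asparagine conserves mass: length mismatch
  expect_equal(classify_errors("AGGK", "ANK", vocab), "length mismatch")
  expect_equal(classify_errors("AAAK", "AK", vocab),
               "precursor-mass mismatch")
  expect_error(classify_errors("AGK", "AGK", vocab), "matches")
  # counts over a toy set partition the wrong predictions
  truths <- make_truths(paste0("s", 1:5),
                        c("AGKR", "AGKR", "AGKR", "ANK", "AK"))
  preds <- make_preds(paste0("s", 1:5),
                      c("AGKR", "AAKR", "AASR", "AGGK", "AAAK"),
                      seq(0.9, 0.5, by = -0.1))
  counts <- count_error_classes(preds, truths, vocab)
  expect_equal(sum(counts$n), 4)
  expect_equal(counts$n[counts$class == "1 AA substitution"], 1)
})

test_that("model overlap counting finds intersection patterns", {
  truths <- make_truths(paste0("s", 1:3), c("AGK", "GGK", "ASK"))
  a <- make_preds(paste0("s", 1:3), c("AGK", "GGK", "AAK"), c(.9, .8, .7))
  b <- make_preds(paste0("s", 1:3), c("AGK", "GAK", "ASK"), c(.9, .8, .7))
  ov <- model_overlap(ar = a, diffusion = b, truths = truths)
  expect_setequal(ov$pattern, c("ar&diffusion", "ar", "diffusion"))
  expect_equal(ov$n_correct[ov$pattern == "ar&diffusion"], 1)
})

test_that("metric reports serialize to JSON", {
  truths <- make_truths(c("s1", "s2"), c("AGK", "GGK"))
  preds <- make_preds(c("s1", "s2"), c("AGK", "GGK"), c(0.9, 0.8))
  met <- compute_metrics(preds, truths, vocab)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(met, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$peptide_recall, 1)
})
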