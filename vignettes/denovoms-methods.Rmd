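---
title: "De novo peptide sequencing with denovoms: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo peptide sequencing with denovoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bottom-up proteomics identifies peptides by matching tandem (MS2) spectra
against a protein database. When no database is available — unsequenced
organisms, antibodies, immunopeptides — the peptide must be read directly
from the fragment-ion ladder: de novo sequencing. Under HCD fragmentation
the dominant ions are the b series (N-terminal prefixes, `b_i = sum of the
first i residue masses + proton`) and the y series (C-terminal suffixes,
`y_i = suffix mass + water + proton`), observed at charges 1–2 with noisy
intensities, jittered m/z and missing peaks. The sequencing task is to
recover the residue sequence whose theoretical ladder explains the observed
peaks and whose total residue mass matches the precursor.

`denovoms` implements this as a desk-scale, fully tested stack: a
transformer encoder over peaks, an autoregressive decoder with
knapsack-constrained beam search, a multinomial-diffusion refiner that
iteratively corrects a candidate sequence, the field's evaluation metrics
(amino-acid/peptide precision and recall, confidence-sweep PR curves, a
surrogate-FDR confidence threshold, an error taxonomy), and a synthetic
spectrum generator so that everything trains and validates without any
external download.

## Token chemistry

Residues are vocabulary tokens carrying monoisotopic masses; modified
residues are *distinct tokens* in bracket notation (`C[+57.02146]`,
`M[+15.99491]`, `N[+0.98402]`, `Q[+0.98402]`), because the decoder must
predict them like any other residue. By default cysteine is always
carbamidomethylated (the alkylation applied in virtually all modern sample
preparation); `residue_vocabulary(fixed_cys = FALSE)` provides the
unmodified token as well. Neutral peptide mass is the residue sum plus one
water; all m/z arithmetic uses fixed monoisotopic constants compiled into
the package.

## The autoregressive model

Each peak is embedded as a multi-scale sinusoidal encoding of its m/z over
`hidden_dim/2` geometrically spaced wavelengths (defaults 0.001 Da to
10,000 Da, spanning isotope-scale to precursor-scale structure), plus a
learned linear lift of `log(1 + intensity)` (intensities are base-peak
normalized at ingestion, making inputs scale-free), plus a learned lift of
the sinusoidal encoding of the peak's *complement mass*
(`precursor + 2 protons − m/z`): the m/z at which the singly charged b/y
partner of the peak would appear. The peak embeddings, a learned
latent-spectrum token and a precursor token (sinusoidal mass encoding plus
a learned per-charge vector) pass through the encoder self-attention stack
together, so peaks can contextualize against the precursor; the memory has
one position per peak plus two. Including the two extra tokens in
self-attention (rather than appending them after encoding) lets the
encoder pool evidence into them; the memory-length contract is unchanged.

The decoder is a pre-norm causal transformer. Decoding runs
right-to-left (C-terminal first): y ions of tryptic peptides read out best,
so the suffix ladder is the strongest signal, and the C-terminal K/R of a
tryptic peptide anchors the first prediction. Decoder inputs combine four
features per position: the token embedding, the index positional encoding,
the sinusoidal encoding of the *cumulative residue mass* of the decoded
prefix, and a learned lift of the *remaining* residue mass (precursor
residue mass minus the prefix). The two mass channels give the network the
quantities a human sequencer tracks — "where am I in the ladder" and "how
much mass is left" — as input features rather than quantities it must
compute internally; they are deterministic functions of the prefix and the
precursor, so causality is untouched.

The decoder's cross-attention additionally carries a *relative-mass bias*,
the package's adaptation of relative positional attention to mass space.
For decoder position `i` (suffix mass `s_i`) and peak `j`, each head adds
to its attention score a learned scalar function — a linear readout of
sinusoid features — of three mass differences: `mz_j − s_i` (a singly
charged y ion continuing the suffix sits at a residue-mass offset),
`2·mz_j − s_i` (its doubly charged counterpart) and
`complement(mz_j) − s_i` (a singly charged b ion, through the precursor
complement). This is the spectrum-graph edge structure of classical de
novo sequencing expressed as an attention prior: heads learn bumps at
residue-mass offsets and thereby attend sharply to the peaks that extend
the current suffix. The bias weights initialize at zero, so the model
starts as a vanilla transformer and learns how much of the prior to use.
At desk scale this component matters more than any other design choice:
during development, removing it left the 2-layer model far below the
unseen-peptide recall that the end-to-end check in the test suite
demonstrates. The same features back the refiner's decoder.

Training minimizes token-level cross-entropy against the ground-truth
peptide (teacher forcing) with Adam, global-norm gradient clipping, and
dropout on every residual branch. Two training-time augmentations matter
disproportionately at desk scale, where the training set is small enough to
memorize: every presented spectrum receives (i) uniform m/z jitter (default
±5 ppm) and (ii) multiplicative log-normal intensity jitter (default sd
0.4). Without them, the finest sinusoid wavelengths turn exact peak masses
into a hash of the training peptide, and a spectrum's fixed intensity
pattern fingerprints it; both routes let the network memorize the training
answers instead of learning ladder arithmetic, which we observed directly
as a large train/held-out gap. Both augmentations are model-training
choices and leave the dataset itself untouched.

The full published geometry (9+9 layers, 16 heads, 768/1024 dims) is
constructible and its parameter count is reported by `glance()`; the
package does not assert agreement with the published 95M total because the
embedding and vocabulary details that fix the count are not public. All
experiments here use the desk preset (2+2 layers, 8 heads, 64/256 dims).

## Knapsack-constrained beam search

Greedy or beam decoding alone may emit sequences whose mass cannot match
the precursor. The knapsack table marks which discretized residue-sum
masses are reachable by *some* residue multiset (dynamic-programming
closure over bins; default resolution 0.0005 Da). During beam search every
expansion whose remaining mass budget is unreachable within the tolerance
window (50 ppm of the precursor residue mass, widened by one bin per side
so discretization can never produce a false "unreachable") is masked; the
end-of-sequence token is admissible only when the remaining budget is
within the window under the *exact* ppm test, so any returned peptide is
mathematically guaranteed to match the precursor mass. The search works in
residue-sum mass space (neutral mass minus water) to avoid the classic
water/proton off-by-one. Ties in pruning are broken lexicographically for
determinism. Because extensions only lower a sequence's cumulative
log-probability, the search terminates as soon as the best completed
sequence outscores every live beam; with a beam at least as wide as the
number of continuable prefixes this returns the exact argmax over
mass-valid sequences, which the test suite verifies against exhaustive
enumeration on small vocabularies.

A prediction's `log_prob` is the sum of its per-residue log-probabilities
plus the stop decision (stored as the final entry of the per-residue
vector), and `confidence = exp(log_prob)`.

## The diffusion refiner

The refiner shares the encoder architecture and replaces the causal
decoder with a bidirectional one that predicts the clean sequence `x_0`
from a corrupted `x_t`, conditioning on the timestep by cross-attending to
a learned timestep embedding appended to the memory. The forward process
is multinomial diffusion: at step `t` each position keeps its token with
probability `alpha_bar_t + (1 - alpha_bar_t)/K` and is otherwise uniform
over the K residue tokens. The schedule is a cosine schedule mapped onto
T = 20 discrete steps (`alpha_bar` strictly decreasing from 1 to below
0.05); T = 20 is also the refinement depth used at decode time. Training
uses the simple x0-prediction cross-entropy surrogate rather than the full
variational bound — the standard, stable choice for discrete diffusion.

Reverse decoding samples `x_{t-1}` from the exact Bayes posterior
`q(x_{t-1} | x_t, x_0)` with the model's x0 distribution mixed over
candidate clean tokens (each candidate's posterior normalized before
mixing, so rows sum to one by construction); the final step takes the
argmax of the predicted x0 distribution. Refinement operates at the
initialization's length; starting from pure noise, the length is drawn
from the training length distribution (length handling under discrete
diffusion is genuinely open; this is the package's choice and is flagged
here).

Selection decoding draws five samples per spectrum. When initialized from
a base-model prediction, the sequence is injected *uncorrupted* at t = 15
(a config switch corrupts it to the t = 15 marginal instead; the
uncorrupted variant is the default reading of "the prediction used at
t = 15") and refined for 15 steps. Among samples whose residue mass falls
within the ppm window, the one with the highest model log-probability wins;
if none qualifies and an initialization exists, the initialization is
returned unchanged (`source = "fallback"`), so an initialized call always
returns a mass-valid peptide. The refiner's confidence is its x0 head
evaluated at t = 1 on the final sequence; it is a model-internal score and
is *not calibrated against* the autoregressive model's confidences.

## Evaluation

Residue matching follows the de novo benchmarking convention: walk both
sequences from each terminus with two pointers, advancing the side with
the smaller cumulative mass; an aligned residue pair matches when residue
masses differ by under 0.1 Da and prefix masses by at most 0.5 Da; the
union over the two passes is taken. Isobaric substitutions (I/L,
deamidated N vs D) therefore count as matches — standard field practice —
and one internal error cannot poison the rest of the peptide. The exact
tolerance constants vary between published variants of this convention, so
they are configuration values here.

Peptide recall (fraction of ground-truth PSMs predicted fully correctly)
is the primary metric; precision uses predictions made as denominator.
PR curves sweep the confidence threshold from highest to lowest, with AUC
by trapezoid over recall. The FDR utility returns the lowest confidence
cutoff at which the fraction of retained predictions disagreeing with the
reference is at most the target (default 5%); this is a *surrogate* FDR
against database-search-style ground truth, not a target-decoy FDR, and
the empirical FDR above the cutoff is asserted on every invocation. The
error taxonomy classifies wrong predictions, in order, as 1 / 2 / more
than 2 residue errors (equal lengths), length mismatch (lengths differ,
mass within tolerance — e.g. two glycines for one asparagine), or
precursor-mass mismatch (the remainder); equal-length errors are always
consumed by the first three classes, which is why the mass split applies
to the length classes.

## The simulator

`simulation_config()` emulates HCD spectra of tryptic peptides: b/y
ladders at charges 1–2; log-normal intensities with y ions boosted 2x
(their better readout is the reason the decoder runs right-to-left);
uniform fragment m/z jitter within a ppm tolerance (default 10 ppm,
Orbitrap-scale); per-peak dropout (default 0.1); Poisson-many uniform
noise peaks (default mean 10) with intensities from the lowest quartile of
the signal; charges 2:3 at 60:40; lengths 7–16; variable modifications at
rates 0.1 (M oxidation) and 0.02 (N/Q deamidation). Precursor fields are
exact, so in the noise-free limit the generated peaks equal the
theoretical ladder and the precursor ppm error is zero — the limit in
which a dynamic-programming ladder oracle (`oracle_sequence()`) recovers
peptides without any learned model, validating the generator
independently.

What the simulator does *not* emulate: isotope envelopes, neutral losses,
a/c/x/z ions, co-isolation chimeras, retention-time structure, FAIMS
effects, and realistic intensity models (no learned fragmentation
intensities). Passing tests on synthetic data therefore demonstrates that
the algorithms are implemented correctly and can learn ladder structure,
not that the desk-scale models match published performance on real
instruments.

## Numerical and scale choices

Problem sizes in the test suite are chosen to keep the full run in tens of
minutes on one CPU: toy transformers (1–2 layers, dims 16–64) on dozens to
a few thousand synthetic spectra; the end-to-end learning check trains the
desk preset on 5,000 clean spectra of length 5–8 and evaluates on 500
held-out spectra of unseen peptides. Knapsack tables default to 0.0005 Da
bins; beam width defaults to 5. Degenerate inputs are handled explicitly:
empty peptides are water-only masses, spectra must contain at least one
peak, duplicate m/z values are merged at ingestion, beam search returns
nothing (a data condition, not an error) when no composition fits the
window, and charges outside 1–6 map to an unknown-charge embedding with a
warning.

Determinism: every stochastic step (initialization, batch order,
augmentation, diffusion corruption and sampling, simulation) flows from an
explicit integer seed; training twice with one seed reproduces the loss
trace bit for bit on one machine.

## Known limitations

- Desk-scale training reaches useful but far-from-published accuracy; no
  claim about real-data performance is made or tested.
- The refiner's confidence scale is not comparable to the autoregressive
  confidence without calibration.
- The knapsack table does not track the number of residues needed to
  complete a mass, so a continuation can in principle dead-end at the
  length cap; with tryptic desk-scale peptides this was never observed.
- mzML reading requires the optional mzR package; MGF is the native
  interchange format.
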