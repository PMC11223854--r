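---
title: "Methods: sequence-based APR prediction with an LSTM ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based APR prediction with an LSTM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aprscan)
```

## The problem and the model

Aggregation of proteins — and amyloid formation in particular — is
nucleated by short sequence stretches, and the best available training
signal comes from libraries of experimentally characterized
**hexapeptides** labelled amyloid-prone or not. `aprscan` therefore models
aggregation propensity at the hexapeptide level and lifts those
predictions to whole proteins by sliding-window aggregation.

A hexapeptide is encoded residue-by-residue with a 20 × 36 **feature
table**: each canonical amino acid maps to 36 numeric descriptors, giving
a 6 × 36 input window (216 values). The classifier is a small recurrent
network whose sequence axis is the six residue positions:

| layer | input | output | role |
|---|---|---|---|
| 1 | 36 × 6 | 64 × 6 | per-residue linear projection (time-distributed) |
| 2 | 64 × 6 | 64 × 6 | bidirectional LSTM, returns sequences (32 units/direction) |
| 3 | 64 × 6 | 96 | bidirectional LSTM, returns final states (48 units/direction) |
| 4–5 | 96 | 32 | dense + ReLU, dropout |
| 6–7 | 32 | 32 | dense + ReLU, dropout |
| 8 | 32 | 1 | dense, sigmoid |

Eight layers in total; the sigmoid guarantees the score contract
`[0, 1]` that profiling and thresholding assume. The published width
descriptions give layer output sizes but not the wiring of the recurrent
reduction; we adopt the standard bidirectional contract — concatenate the
two directions; intermediate recurrent layers return per-step sequences
and the last one returns the concatenation of each direction's final
state. This choice is recorded in every saved model manifest, so models
are auditable.

The predictor proper is an **ensemble of five** such networks, one per
split of a stratified 5-fold cross-validation; the consensus score is the
arithmetic mean of the member scores (hence order-invariant and still in
`[0, 1]`).

### Feature table

The shipped default combines 5 atomic-composition counts (C, H, N, O, S
atoms of the free amino acid, authored from molecular formulas) with 31
published AAindex physicochemical scales (hydrophobicity, volume and
surface, polarity and charge, secondary-structure propensity,
flexibility, burial; see `data-raw/make_feature_table.R` for the exact
accessions). The table is deliberately pluggable
(`load_feature_table()`): any 20 × 36 numeric table over the canonical
alphabet works, and models record an identifier of the table they were
trained with. Non-canonical residues (X, B, U, gaps) are **rejected, not
imputed** — there is no defensible imputation rule, and silently guessing
would corrupt downstream profiles.

### Feature scaling

Descriptor magnitudes span three orders of magnitude (net charge ±1,
molecular weight ≈ 75–204). Feeding raw values to tanh/sigmoid LSTM gates
under Glorot initialization saturates them and stalls learning, so
`fit_network()`/`train_crossval()` default to per-feature z-score
standardization **fitted on the training split only** and stored with
each member (applied automatically at inference). Encoding functions
always return the table values exactly as stored; pass
`standardize = FALSE` to train on raw values.

## Training

* **Loss / optimizer**: binary cross-entropy, Adam (β₁ = 0.9,
  β₂ = 0.999) at the configured learning rate; mini-batches of the
  configured size. Unweighted loss by default (the hexapeptide classes
  are only mildly imbalanced); `class_weight = "balanced"` upweights the
  minority class inversely to prevalence.
* **Early stopping**: the guiding criterion is the epoch where the
  training and validation ROC curves *diverge*. Operationally we record
  AuROCC on both sets each epoch and stop once validation AuROCC has not
  improved by at least `min_delta` for `patience` consecutive epochs,
  returning the weights of the best-validation epoch (earliest on ties).
  Defaults: `patience = 5`, `min_delta = 0.001`, `max_epochs = 200`.
  `select_stopping_epoch()` exposes the rule as a pure function of a
  history so it can be tested by brute force.
* **Splitting**: the 90/10 train/test split is stratified per class with
  `round(fraction × n_class)` (round-half-even — R's `round()`) items in
  train, remainder to test; 5-fold plans are stratified with per-class
  fold sizes differing by at most one. Both are deterministic under a
  single integer seed, as is the whole training loop (initialization,
  shuffling, dropout masks), which runs single-threaded.
* **Hyperparameter search**: the optimization grid covers 1–2
  bidirectional layers, 1–3 dense layers, dropout `{0, .2, .4, .6, .8}`,
  power-of-two widths in `[8, 512]`, batch size `{16, 32}` and
  learning-rate decades `1e-4 … 1e-1`. The full product is far larger
  than any practical budget, so `hyperparameter_search()` takes an
  explicit budget with either a deterministic grid walk or seeded random
  sampling, ranking configurations by cross-validated mean validation
  AuROCC. It makes no claim of reproducing any particular historical
  search trajectory. Note the published architecture itself (width 96) is
  not on the power-of-two grid; configuration validation therefore
  enforces the range `[8, 512]` (plus evenness for bidirectional widths),
  while grid *candidates* stay on powers of two.

## Profiling and APR calling

Coordinates are 1-based inclusive in all user-facing output (internal
indexing is 0-based half-open only in the BED adapter, which states its
convention in the file header). A length-L sequence yields L − 5 windows;
residue *i* is covered by windows `max(1, i−5) … min(i, L−5)` and its
score is the **unweighted mean** over that coverage set (1–6 windows).
Terminal residues are averaged over their reduced coverage — padding
would invent scores. Positional weighting of windows is a conceivable
alternative; uniform averaging is the natural reading of "mirroring the
windowing" and is what we adopt.

APR calls are maximal runs of residues with score ≥ threshold, kept only
when at least `min_length = 6` residues long — a shorter peak, however
high, is not an APR. The default threshold is the Youden-J optimum
computed at train time on the out-of-fold predictions and stored in the
model manifest; both threshold and `min_length` are overridable per run.
Auxiliary per-residue channels (transmembrane propensity, relative
solvent accessibility) are ingestion-only: the package attaches
user-supplied vectors to profiles but never computes them.

## Evaluation metrics

* Precision, recall and specificity are the three tally ratios; a metric
  with zero denominator is returned as a **flagged `NA`** (with a
  warning), never silently 0 or 1, and macro-averages exclude it.
* The ROC curve sweeps every distinct score (plus infinite sentinels) as
  a threshold under `score ≥ threshold ⇒ positive`; tied scores share a
  threshold; the AUC is trapezoidal and equals the pairwise-ordering
  (Mann–Whitney) statistic with ties counted ½ — the test suite asserts
  this equivalence to 1e-12.
* The PR AUC uses **non-interpolated step summation** (average-precision
  style); trapezoidal interpolation in PR space is biased and is not
  offered.
* Youden's J is maximized over the ROC thresholds with ties broken toward
  the smallest threshold.
* The SOV score follows the **refined (1999) definition**: per
  overlapping reference/predicted segment pair,
  `(minov + δ)/maxov` weighted by the reference segment length, with the
  allowance δ capped by `maxov − minov`, `minov`, and half of either
  segment length; reference segments with no overlapping prediction count
  only in the normalizer. Reported per class (APR and non-APR) on a
  0–100 scale. The earlier 1994 normalization is not implemented; the
  refined variant is the one in contemporary use. Degenerate edge: if the
  reference has no segment of the class, the score is 100 when the
  prediction also has none, else 0.
* Whole-protein benchmarking (`evaluate_proteins()`) compares per-residue
  scores against the union of annotated intervals, computes the four
  statistics per protein, and macro-averages across proteins.

## The synthetic world

`gen_hexapeptides()` emulates a labelled hexapeptide collection with a
**composition** rule: positives sample residues with weights concentrated
on hydrophobic/β-prone amino acids (I, V, F, L, Y, W, M …), negatives on
charged/proline-rich ones (D, E, K, R, P, G, S …); exactly
`round(fraction × n)` positives pre-noise; optional label-flip noise;
sequences distinct; everything deterministic under seed. Because the rule
is compositional rather than motif-exact, a classifier must generalize,
not memorize, and the rule is recoverable without training: mean
Kyte–Doolittle hydropathy (`hydropathy_score()`) reaches AuROCC ≥ 0.9 at
noise 0. `gen_annotated_proteins()` embeds positive-composition segments
(length 8–20 by default, never above the 50-residue cap, never touching
the first or last six residues, mutually separated) into
negative-composition backgrounds and records them as true intervals.

What passing on this world shows — and does not show: it validates the
**machinery** (encoding, training dynamics, consensus, windowing,
aggregation, calling, metrics) end to end. It does not certify accuracy
on real amyloid data: real hexapeptide labels encode structure-dependent
effects far subtler than composition, real APR annotations are noisy and
boundary-uncertain, and real proteins contain low-complexity regions the
generator does not imitate. Retraining on a real database export is
supported via `inst/scripts/reproduce_waltzdb.R`.

### Problem sizes

The test suite and `scripts/acceptance.R` use 500 hexapeptides
(positive fraction 0.36, mirroring the ~36% amyloid share of real
hexapeptide collections), 90/10 split, 5 folds, and 6–10 annotated
proteins of length 90–160 — sizes at which a full
train → profile → evaluate round takes seconds while leaving every class,
fold and segment type populated. Oracle-equivalence checks run on
hundreds to a thousand random instances each.

## Numerical choices and degenerate inputs

* Scores are compared with thresholds using `≥`, everywhere.
* Batch and single-window prediction agree to ≤ 1e-12 (BLAS summation
  order may differ); determinism contracts (same seed, same data ⇒
  identical models) are exact because execution is single-threaded.
* Empty datasets encode to 0 × 6 × 36 arrays; empty call sets and empty
  BED files round-trip as empty tibbles.
* `stratified_split()` refuses single-class input; `make_folds()` refuses
  `k` above the minority class count; ROC construction refuses
  single-class truth and PR curves refuse truth without positives.
* Model persistence uses a JSON manifest plus binary per-member weight
  files so that reloaded models score **bit-identically**; manifests
  carry a format version, and mismatches or truncated files fail loudly.

## Known limitations

* Sequence-only: no structural context (solvent accessibility,
  transmembrane topology) is computed, so exposed and buried hydrophobic
  stretches are indistinguishable to the score itself.
* Hexapeptide-centred training limits sensitivity to long
  aggregation-relevant elements such as low-complexity or prion-like
  domains.
* The hand-rolled optimizer is CPU-only and single-threaded; it is sized
  for thousands of hexapeptides, not millions.
* The default feature table is a documented, reasonable 36-descriptor
  set, not a transcription of any specific prior tool's table; results
  with other tables will differ (which is why the table is pluggable and
  fingerprinted in the manifest).
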