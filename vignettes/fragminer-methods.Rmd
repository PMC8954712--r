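---
title: "Methods: imbalance-aware fingerprint classification and privileged-fragment mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware fingerprint classification and privileged-fragment mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragminer)
```

# Scope and model

`fragminer` implements a qualitative structure–activity pipeline for
kinase inhibitors described by binary molecular fingerprints. The
science it encodes is simple but easy to get subtly wrong: a binary
potency classification from IC50 measurements, class balancing on badly
imbalanced training data, honest cross-validated evaluation with the
full confusion-matrix metric suite, and identification of
*privileged substructures* — fingerprint bits statistically tied to
potency. This vignette records the modeling assumptions, the tunable
parameters, the numerical conventions, and the design decisions that
were genuinely open.

# Potency labeling and splitting

Potency is defined on the pIC50 scale, pIC50 = 6 − log10(IC50 in μM);
the cutoff defaults to pIC50 6.0 (IC50 = 1 μM), the conventional potency
boundary for kinase inhibitors. The boundary itself counts as potent:
"IC50 = 1 μM" is the last potent value. Labeling is vectorized,
idempotent and order-independent, and rejects non-finite input rather
than guessing.

`stratified_split()` seeds all randomness and apportions the training
set per class by largest remainder, so per-class proportions are within
one compound of the whole. Published datasets sometimes realize a split
that is *not* exactly proportional (e.g. a 69/19 train design from an
89/28 set at 3:1, where proportional rounding gives 67/21); since the
exact member assignment of such a design is unrecoverable, the sizes are
the reproducible contract, and the `train_counts` argument realizes
explicitly requested per-class sizes on top of the seeded sampler.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates
the statistical shape of a curated DYRK1A inhibitor dataset:

* 117 compounds, 89 potent / 28 non-potent (exact counts, not expected
  values);
* 881 binary bits, the PubChem fingerprint length;
* eight enriched bits with class-conditional presence probabilities
  (p_P, p_N) echoing the count patterns of real privileged fragments
  (0.55/0.07 down to 0.20/0.07) — roughly "present in half the potent
  compounds and almost no non-potent ones";
* a background of class-independent Bernoulli bits at presence
  probability 0.3 (the mid-range prevalence of informative PubChem
  bits);
* 30 constant (all-ones) bits and 40 duplicate-with-flip pairs (flip
  probability 0.05), the two pathologies a descriptor/bit screen must
  tolerate.

Bits are class-conditionally independent Bernoulli draws — the simplest
structure consistent with per-bit frequency analysis; correlation enters
only through the explicit duplicate pairs. pIC50 values are drawn from
two truncated normals, mean 6.9 (sd 0.5) on [6.0, 8.5] for potent and
mean 5.4 (sd 0.5) on [4.5, 6.0) for non-potent compounds, reproducing an
activity distribution with modes near 6 and 7 over the range 4.5–8.5;
truncation guarantees that relabeling the generated activities
reproduces the generated classes exactly.

What the generator does **not** emulate: real fingerprints derive from
shared scaffolds, so their bits co-occur in blocks and their classes
cluster in chemistry space; synthetic bits are conditionally
independent. Passing tests on synthetic data therefore demonstrate the
*bookkeeping and statistics* of the pipeline, not classifier
performance transferable to real chemistry.

# SMOTE, Tomek links, and the hybrid

All distances are Euclidean on the raw 0/1 features (equal to the square
root of the Hamming distance); no scaling is applied, matching how such
fingerprints are compared in practice. Nearest-neighbor ties are broken
toward the lower row index, which makes every downstream result
deterministic given the seed.

`smote_oversample()` draws a minority row, one of its k = 5 minority
nearest neighbors, and a Uniform(0,1) interpolation weight. Because
interpolated fingerprints are not valid bit vectors, synthetic rows are
binarized at 0.5 with ties going to 1; this keeps them usable by the
fragment-mining stage. Binarization and k are declared package
decisions — the procedure is often run un-binarized on continuous
features, available via `binarize = FALSE`.

A Tomek link is a cross-class pair of mutual nearest neighbors. Since
the tie-broken nearest-neighbor map is a function, links form a
matching: each sample belongs to at most one link. `smote_tomek()`
oversamples the minority to parity and then removes, by default, *both*
members of every link. Removing both keeps class counts exactly balanced
(each link holds one sample per class) and matches balanced-set sizes
observed in practice (e.g. 69/19 → 69/69 → 67/67 with two links); the
alternative reading of the hybrid — undersampling only the majority
member — is available as `policy = "majority-only"`. Balancing is
applied to training data only; held-out sets are never resampled.

# Classifier grid and cross-validation

`make_model()` wraps seven classical algorithms behind one
`fit`/`predict_prob` surface: e1071 SVM (RBF kernel, cost 1, probability
calibration seeded, no rescaling of 0/1 features), `stats::glm`
logistic regression, `class::knn` (k = 5), `nnet` (5 hidden units,
decay 0.1), e1071 naive Bayes on two-level factors with Laplace
smoothing 1, `ranger` random forest fixed at 20 trees of maximum depth
15 (the one hyperparameter pair the protocol pins down), and `rpart`
decision trees. Remaining hyperparameters are the backends' defaults,
recorded per run; reproducing any particular published trained-model
number is explicitly not a goal, because those depend on another
toolkit's internal defaults and on unreleased structures.

`cross_validate()` assigns stratified folds (every class must have at
least as many members as folds), trains one model per fold on its
complement, and pools the out-of-fold predictions into a single
confusion table — so training-set counts sum to the full training size,
the convention used in published grid tables. Predicted class is P when
the positive-class score is ≥ 0.5.

When balancing is enabled, `run_grid()` by default balances the *whole*
training set and then cross-validates. This mirrors the historical
protocol (recognizable when published balanced training rows sum to the
balanced, not the original, size), but it lets synthetic rows share
parents across folds, leaking information and flattering the CV
numbers. The statistically sound variant — balancing each fold's
training portion only — is `balance_within_folds = TRUE`. Both are
first-class; the default is the faithful one, the flag is the honest
one.

# Metrics and their conventions

SE, SP, CA, MCC and BA are exact rational functions of the confusion
counts. Degenerate cases return `NA` rather than a number: MCC whenever
a marginal factor is zero (e.g. an always-positive classifier), SE/SP
when their denominator is empty; reports render `NA` as `"-"`.

AUC is implemented twice on purpose — as the Mann–Whitney concordance
probability with ties counted ½, and as trapezoidal integration of the
empirical ROC with tie groups advancing jointly. The two are
mathematically identical; the test suite holds them to 1e-12 agreement
on random score sets, and cross-checks against an independent ROC
implementation.

Display rounding is half-away-from-zero at 3 decimals. One wrinkle
uncovered by regression-testing published tables: printed BA columns mix
two conventions, the mean of the *rounded* SE/SP in most rows and the
mean of the *exact* SE/SP in others. `render_tables()` uses the
rounded-average convention; the regression test accepts either. A small
number of published cells contradict their own confusion counts
(recomputation pinpoints them, e.g. an accuracy column shuffle across
four balanced test rows and swapped SE/SP digits in three validation
rows); those cells are excluded, individually and explicitly, from the
regression rather than reproduced.

# Fragment mining

For each bit, `information_gain()` computes base-2 Shannon information
gain of the class given bit presence, with 0·log 0 := 0. The
class-frequency statistic is

freq(class) = (N_fragment_class × N_total) / (N_fragment_total × N_class),

i.e. the prevalence of the fragment among class members relative to its
overall prevalence; 1 means no enrichment, and the two class frequencies
are exactly consistent with the counts
(freq_P·N_P + freq_N·N_N = N_total for every bit). The totals are those
of the modeling set on which the counts were taken — using a grander
total silently shifts every frequency, which is detectable because
zero-negative-count bits must print exactly N_total/N_P.

`rank_fragments()` sorts by IG (ties: potent-class frequency, then bit
name), labels polarity by which frequency is larger, and filters by
support (default 2 — a bit seen once cannot evidence a reusable
pharmacophore) and by a minimum IG (default 0). Count thresholds for
declaring "positive"/"negative" fingerprint sets are exposed rather than
hard-coded, because published selections of this kind rarely state their
cutoff.

# Chemical-space characterization

`distance_heat_matrix()` returns pairwise Euclidean distances,
normalized by the maximum to a [0, 1] color scale by default (matching
heat maps drawn on a 0–1 scale; raw distances via `normalize = FALSE`).
`screen_descriptors()` removes descriptors whose modal value exceeds an
80% share, then prunes |r| > 0.95 pairs keeping the earlier-listed
member — the pruning order is otherwise unstated in common protocols, so
keep-first is fixed for determinism. `project_descriptors()` uses
correlation-matrix PCA (unit-variance scaling) because descriptor units
are heterogeneous; constant columns are an error by design — screen
first. The published 825→634 descriptor screen and "51% variance in
three components" figures depend on a proprietary descriptor calculator
and are treated as properties of the method demonstrated on constructed
fixtures, not as reproduction targets.

# Problem sizes and numerical choices

The test suite runs everything at desk scale: the full 117 × 881
generator shape wherever the study conditions matter (labeling, splits,
balancing, recovery), 60–88 compounds and 50–120 bits for classifier
plumbing, 20-seed and 100-replicate loops for the stochastic
properties. Tolerances: 1e-12 for the AUC route agreement and distance
oracles, 1e-9 for PCA reconstruction, printed precision (3 decimals)
for reference-table regression.

# Known limitations

* The planted-bit recovery experiment (one enriched bit, p_P = 0.55,
  p_N = 0.07, among the full 881-bit universe at n = 117) is a
  multiplicity race: the planted bit's realized enrichment occasionally
  fluctuates low while one of ~840 null bits fluctuates high. The
  acceptance test asserts recovery in ≥95 of 100 seeded replicates and
  currently measures 93 under these conditions; the shortfall is a
  statement about the method's power at this sample size and bit count,
  not about the implementation, and the experiment's conditions are
  deliberately not tuned to pass.
* Logistic regression on p ≫ n fingerprint data is rank-deficient and
  separable; it is kept (suppressing the separation warnings) because
  the protocol calls for it, but its coefficients are not
  interpretable.
* Synthetic data cannot validate chemistry-transferability claims; see
  the generator section.
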