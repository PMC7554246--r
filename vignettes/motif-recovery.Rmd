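---
title: "Predicting plant ubiquitylation sites from bigram embeddings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant ubiquitylation sites from bigram embeddings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ubicnn)
```

## The problem

Ubiquitylation is the covalent attachment of ubiquitin to a substrate
lysine through the E1/E2/E3 enzyme cascade. In plants it regulates
growth, stress response and protein turnover, and experimentally mapping
modified lysines is slow and expensive, which motivates sequence-based
predictors. The local sequence context of plant ubiquitylation sites
differs visibly from animals and fungi — most prominently an enrichment
of arginine in the residues flanking the modified lysine — so this
package models plant sites specifically.

The prediction unit is a 31-residue window centred on a lysine: 15
residues on each side, with flanks that fall outside the protein padded
by the pseudo-residue `X`. A window is scored with a probability that
its central K is ubiquitylated.

## Pipeline overview

1. **Dataset construction** (`read_fasta()`, `extract_fragments()`,
   `cluster_reduce()`, `balance_and_split()`): annotated positions give
   positive windows, every unannotated K a negative window; near-identical
   windows are removed by greedy identity clustering; negatives are
   subsampled to a 1:1 balance; a stratified test set is held out.
2. **Embedding pretraining** (`build_vocab()`, `train_skipgram()`):
   overlapping bigrams (two adjacent residues; 20² = 400 tokens plus one
   pad token) are embedded by skip-gram with negative sampling, trained
   unsupervised on whole protein sequences.
3. **Classifier** (`ubi_cnn()`): the pretrained embedding initialises the
   lookup layer of a three-block 1D convolutional network, which is then
   fine-tuned end to end under the site labels.
4. **Evaluation** (`repeated_kfold()`, `roc_auc()`): repeated stratified
   k-fold cross-validation with accuracy, precision, recall, F-score and
   rank-based AUC.
5. **Synthetic data** (`motif_spec()`, `gen_labeled_fragments()`,
   `end_to_end_recovery()`): a generator with planted positional
   enrichments makes the whole pipeline testable without external
   databases.

## Dataset construction choices

*Coordinates.* Site annotations are 1-based positions in the parent
protein; all user-facing tables use 1-based coordinates.

*Redundancy reduction.* `cluster_reduce()` is a self-contained greedy
incremental clustering: fragments are processed in input order and join
the first cluster whose representative shares at least the identity
threshold (default 0.30). For equal-length ungapped 31-mers identity is
the fraction of matching columns (Hamming identity); the pad symbol `X`
never counts as a match, even against another `X`. This mirrors the
strategy of standard redundancy-reduction tools such as CD-HIT without
depending on an external binary; exact parity with CD-HIT's word-based
heuristics is not claimed and not needed, since the goal is homology-bias
reduction, not a specific cluster inventory. Clustering is applied to
positives and negatives jointly by default (`cluster_by = "class"`
switches to per-class clustering; the choice is exposed because either
protocol is defensible and published descriptions are often ambiguous).

*Negatives.* By default only proteins that carry at least one annotated
site contribute negative windows (`negatives_from = "annotated"`),
because proteins never assayed for ubiquitylation are weaker evidence of
true negatives; `"all"` widens the pool.

*Balancing and splitting.* Negatives are subsampled uniformly without
replacement to match the positive count; the held-out test set is
stratified by label, so train and test are each balanced to within one
fragment. Everything is reproducible from the seed.

## Feature statistics

Four comparative statistics contrast positive and negative fragment
sets:

- **AAC** — per-residue frequency $A_r = N_r / N$ with
  $N = \mathrm{window} \times n_{\mathrm{fragments}}$. `X` counts in the
  denominator (the window length is fixed) but is not reported as a
  residue, so the 20 frequencies sum to 1 only for pad-free sets. This
  asymmetry is deliberate and documented in `compute_aac()`.
- **AAPC** — frequencies of the 30 overlapping ordered adjacent
  dipeptides per window. Pairs containing `X` are dropped from numerator
  and denominator, so reported frequencies always sum to 1 when anything
  was countable. Non-adjacent pair statistics (k-spaced pairs) are a
  different feature family and out of scope.
- **PWM** — residue-by-position occurrence counts (21 × window, `X`
  included as a row); every column sums to the fragment count. Positions
  are labelled by offset from the centre: −15…−1, 0, +1…+15.
- **Log-ratio contrasts** — `log_ratio()` computes
  $\ln\big((c^+ + \lambda)/(c^- + \lambda)\big)$ elementwise on pooled
  counts, used both for the dipeptide contrast $P_{r,s}$ and the
  positional contrast $M$. The pseudocount $\lambda$ (default 1,
  Laplace) keeps all entries finite; the result is antisymmetric under
  swapping the classes. Pooled counts are normalised once, not per
  fragment — summing per-fragment frequencies first gives the same
  ordering and nearly identical values at equal fragment counts, and
  pooling is the variant with a clean sampling interpretation.
- **Two-sample logo** — for every residue × non-centre position, a
  two-proportion z-test (pooled variance, two-sided) between the classes.
  Default α = 0.05 without multiple-testing correction, matching common
  logo-server practice; `correction = "bonferroni"` is available and is
  what the package's own acceptance checks use, since 20 × 30 = 600
  simultaneous tests at α = 0.05 would otherwise flag ≈ 30 cells by
  chance alone.

## Embedding

Tokens are overlapping bigrams. Tokenizing every overlapping bigram of a
sequence once is equivalent to tokenizing the two frame-shifted copies
(starting at residue 1 and at residue 2) non-overlappingly, so the
corpus is tokenized once. Any bigram containing `X` maps to a reserved
pad token that never participates in training, as `X` is not a
biological symbol.

Skip-gram training uses negative sampling (5 negatives per pair, noise
distribution proportional to unigram frequency^0.75) over all ordered
(centre, context) pairs within ±2 tokens. Full-softmax training would
also work at a 401-token vocabulary but negative sampling is the
standard choice and scales to larger gram lengths (`build_vocab(3)`
gives 8000 tokens). Five epochs at learning rate 0.025 with linear decay
are the defaults; the corpus for pretraining is whole proteins, not
31-mer windows, because the embedding should capture generic sequence
context rather than site-specific signal.

The embedding dimension defaults to 20, which matches the classifier's
30 × 20 input encoding of a window; the config accepts any width
(including 200) for experimentation. The input-side (hidden layer)
weight matrix is what `train_skipgram()` returns and what the classifier
transfers.

## Classifier

Architecture (all defaults in `cnn_config()`):

```
token indices (30)
  -> embedding lookup (30 x 20, initialised from the pretrained matrix)
  -> 3 x [ conv1d: 128 filters, width 3, relu -> maxpool width 2 -> dropout 0.5 ]
  -> flatten (2 x 128 = 256)
  -> dense 128 relu -> dense 64 relu -> dense 1 sigmoid
```

Design points that required a decision:

- **Convolution padding** is *valid* (no zero padding), so the sequence
  axis shrinks 30 → 28 → 14 → 12 → 6 → 4 → 2. With *same* padding the
  flattened size would differ; the option is exposed through the config
  since either reading of the architecture is possible.
- **Dense activations** are rectifiers; the output unit is logistic.
- **Dropout (0.5)** sits after each max-pooling layer, inside the conv
  blocks only.
- **Initialisation**: conv and dense weights are Gaussian(0, 0.01),
  biases zero; the embedding layer is the transferred matrix exactly.
- **Optimiser**: RMSprop with learning rate 0.001 and smoothing constant
  β = 0.9, minimising binary cross-entropy with scores clipped at
  1e−7 — the loss is finite even for saturated outputs.
- **Determinism**: the implementation is single-threaded and draws all
  randomness (initialisation, shuffling, dropout) from R's RNG, so a
  seed fully reproduces a training run. This also makes the
  full-scale recipe (batch 500, 120 epochs) slow on one core; the
  reduced regimes below are the package's working defaults for
  experimentation.

### The short-regime plateau

With σ = 0.01 initialisation the pre-activation scale shrinks through
three valid-padded conv blocks, and dropout noise initially dominates
the informative signal, so the first phase of training is a plateau at
the trivial loss ln 2. At the full 120-epoch recipe this resolves on its
own; in short regimes (tens of epochs) escape at learning rate 0.001 is
unreliable. `end_to_end_recovery()` therefore trains its reduced 20-epoch
runs at learning rate 0.003 with minibatches of 100 — enough update
steps and step size for consistent escape — and this is a property of
the reduced regime, not of the model. A useful observed side effect:
transferring a pretrained embedding gets the network off the plateau
more reliably than random initialisation, which is exactly the transfer
benefit the design predicts.

## Evaluation

`confusion()` predicts positive at score ≥ threshold (0.5 by default,
the natural convention for a sigmoid output). Precision is reported as
`NA` with a warning when no positives are predicted (and recall when
none exist) rather than silently zero, to avoid inflating averaged
F-scores on degenerate folds. `roc_auc()` uses the rank (Mann–Whitney)
formulation with midranks, so ties are handled exactly; it equals the
trapezoidal integral of the empirical ROC curve and is cross-checked
against both in the tests. `repeated_kfold()` stratifies folds by label —
a deliberate mild strengthening of plain random partitioning that keeps
every fold at the designed 1:1 balance (`stratified = FALSE` restores
plain partitioning).

## The synthetic generator and what it can show

`gen_labeled_fragments()` draws every flank position independently:
negatives from the background distribution (uniform by default — tests
want controlled, not realistic, conditions), positives from per-position
distributions in which listed (residue, offset) cells are multiplied by
the effect factor and renormalised. The default enrichment cells are
arginine at offsets −9…−5 and +1…+8, mirroring the qualitative plant
pattern; `effect = 1` is an exact null under which the two classes are
exchangeable (verified by permutation test).

Because positions are independent, the Bayes-optimal classifier is the
per-position likelihood ratio, and its AUC — the ceiling for *any*
classifier trained on this generator — is computable. `optimal_auc()`
estimates it by Monte Carlo; for a single enriched residue over a
uniform background it reduces to a two-binomial closed form, which the
tests use as an independent oracle. Two consequences shaped the test
design:

- At the moderate default effect ×3 the ceiling is ≈ 0.77. A moderate
  planted effect is the right condition for the *feature statistics*
  (the log-ratio and logo tests recover exactly the planted cells at
  n = 2000 per class) but cannot support a high-AUC recovery claim, for
  any model.
- The **recovery experiment** (`end_to_end_recovery()`) therefore uses
  effect ×8 as its strong condition, chosen from the closed-form bound
  alone: ceiling ≈ 0.96, leaving honest headroom for a trained model to
  clear 0.90. The fine-tuned CNN reaches ≈ 0.94 cross-validated AUC
  there — close to the ceiling, which is the meaningful statement: the
  pipeline recovers nearly all the information the generator plants.

What the generator does **not** emulate: dependencies between positions
(real motifs are not products of marginals), homologous fragments
(clustering is exercised on constructed near-duplicates instead),
realistic amino-acid composition, or any actual ubiquitylation biology
(E3-ligase specificity, structural accessibility). Passing the synthetic
recovery suite therefore demonstrates that the machinery — data
handling, embedding transfer, optimisation, evaluation — is correct and
sensitive, not that a given real-data accuracy will be achieved.

## Problem sizes used by the checks

The packaged checks run the full pipeline at working sizes chosen for a
single CPU: 2000+2000 fragments, dim-20 embeddings, 20 fine-tuning
epochs, 3-fold cross-validation for the recovery experiments, and 2-fold
cross-validation over five seeds for the transfer comparison; the module
tests use a reduced architecture (8–16 filters) for speed. The full-scale
recipe (batch 500, 120 epochs, 10-fold CV repeated 5 times) is available
through the same configs and the command line.

## Known limitations

- Training on one core is minutes-per-run at desk scale; there is no GPU
  path.
- The greedy clustering is quadratic in the worst case; fine up to tens
  of thousands of fragments, not millions.
- `two_sample_logo()` implements the two-proportion z-test only; exact
  tests for very small counts are not provided.
- The skip-gram and CNN are bespoke implementations; they are validated
  against closed forms, independent reimplementations and statistical
  oracles in the test suite, but they do not aim for numerical parity
  with any particular deep-learning framework.
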