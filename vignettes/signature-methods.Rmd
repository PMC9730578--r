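---
title: "Signature methods for event-sequence classification: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature methods for event-sequence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigehr)
```

## The problem and the model

A patient's coded history is an ordered sequence of categorical events with
integer-day timestamps, and the task is binary: will this patient receive a
target diagnosis within a short horizon after the prediction date? Sequences
are short, irregular, heavily imbalanced between classes (1:9
case:control), and order can matter clinically even when event counts do
not.

`sigehr` treats a sequence as a piecewise-linear path. Each event token is
one-hot encoded; by default the one-hot rows are accumulated into a
*running-count stream*, so the path's increments are exactly the events.
The depth-`N` signature of a path — the graded family of iterated
integrals — is a canonical, basis-independent summary: level 1 is the total
increment (the bag-of-words count vector on the cumulative stream), level 2
contains ordered co-occurrence structure (its antisymmetric part is the
pairwise Lévy area, which flips sign when two events swap order), and
higher levels capture higher-order sequencing.

The classifier composes, in fixed order:

1. a trainable token embedding (the learnt projection, `a × V`), which makes
   the signature tractable for realistic vocabularies;
2. the augmentation chain: optional time channel, optional lead-lag,
   mandatory basepoint;
3. the signature or log-signature pooling layer at depth 2 or 3;
4. a small fully connected head with a sigmoid output.

Everything is trained end-to-end by Adam on binary cross-entropy: the
signature layer is a polynomial in the path increments, and the package
ships hand-written reverse-mode gradients through the Chen-product
recursion, the tensor logarithm and the Lyndon-basis projection
(finite-difference-verified in the test suite to 1e-4 relative error).

## Algebraic conventions

* **Level 0.** The truncated tensor container stores the constant level-0
  scalar (it is 1 for every signature, and the term-count formula
  `(d^(N+1)-1)/(d-1)` includes it), but feature vectors exposed to models
  exclude it: a constant feature is uninformative.
* **Ordering.** Within a level, coefficients are stored in lexicographic
  multi-index order with the first index most significant; levels are
  concatenated in increasing order. Fixed once so serialised features are
  reproducible.
* **Log-signature basis.** The compact coordinates live on Lyndon words
  (aperiodic words smaller than all their rotations), whose per-level count
  is Witt's necklace formula `W(d,k) = (1/k) Σ_{m|k} μ(m) d^{k/m}`. The
  bracketed expansion of a Lyndon word equals the word itself plus
  lexicographically larger words, so expressing the tensor logarithm in this
  basis is a unit-triangular solve per level, in lexicographic Lyndon order.
  A verbose full-tensor basis is kept for testing.
* **Computation strategy.** Signatures are computed by left-to-right Chen
  products over segments — linear in sequence length. Direct numerical
  quadrature of the iterated integrals exists only as an independent test
  oracle. At depth 2 the training path uses an equivalent closed form
  (one cumulative sum and two crossproducts per sequence), which is what
  makes pure-R training practical; depth 3 uses the stepwise recursion with
  saved states. The differentiable engine covers depths 2 and 3 — the
  depths the model variants use; the generic algebra has no depth limit.
* **Tolerances.** All algebra is double precision. Tests assert algebraic
  identities (Chen splitting, exp/log inversion) at 1e-10 and quadrature
  agreement at 1e-6.

## Augmentations

Applied in the fixed order *projection → time channel → lead-lag →
basepoint*. The order is a design choice: the embedding is a property of
tokens (time is not embedded), and the basepoint must anchor the final
path, whatever came before. The time channel is appended as the last
coordinate.

* **Time index** appends 0, 1, …, n−1; **time delta** appends
  `min(T_scale · log(ΔT), T_max)` with `ΔT` the days from event to
  prediction date (defaults `T_scale = 0.25`, `T_max = 2`, chosen so a
  10-year lookback maps into roughly the unit scale of the embeddings; both
  are exposed as hyperparameters). `ΔT` is floored at one day so the
  logarithm is defined even for events on the prediction date, which a
  pre-index buffer normally excludes. Either channel removes
  reparameterisation invariance; they are mutually exclusive.
* **Basepoint** prepends the origin, removing translation invariance and
  making single-event sequences signaturable.
* **Lead-lag** interleaves the path with a one-step lagged copy:
  `(x1,x1), (x2,x1), (x2,x2), …, (xn,xn)` — `2n−1` points in `2d`
  channels, lead block first. (Summaries elsewhere sometimes quote `2n`
  points; the explicit interleaving above is what is implemented.) The
  cross-block antisymmetric signature terms recover quadratic
  (co-)variation. Inside the model pipeline a single-point path maps to the
  single duplicated point `(x1, x1)` — consistent with the `2n−1` count —
  because the basepoint is applied after lead-lag; the standalone
  `lead_lag()` keeps its two-point precondition.

## The synthetic cohort generator

The generator emulates the *structure* of an inpatient EHR cohort, not its
content: an exact case/control split (default 1:9); controls matched to
cases and inheriting the matched case's index date; integer-day event times
uniform over a 10-year lookback ending at the 90-day pre-index buffer
(events exactly at 90 days are kept — the boundary convention is closed on
the allowed side); a Zipf-skewed background vocabulary (exponent 1.1,
mimicking clinical code frequency skew); sequence lengths with a point mass
at one event (default 20%) plus a shifted Poisson calibrated so the mean
matches the configured target (default 4.15 background events; ~14 emulates
a corpus with secondary diagnoses and procedures); and tied timestamps
randomly ordered once, at cohort construction — re-randomising ties every
training epoch was considered and rejected, since it forces path
reconstruction each epoch and changes nothing statistically at this scale.

Three plantable class signals, all carried with probability
`signal_strength` by cases *and* controls symmetrically where counts are
concerned:

* **order** (default): a reserved token pair appears *a-then-b* in carrier
  cases and *b-then-a* in carrier controls, at two distinct random days.
  Marginal token counts are identically distributed across classes, so the
  signal is invisible to any order-blind model by construction.
* **cooccurrence**: carrier cases receive the pair; carrier controls
  receive one of the two tokens twice, balancing expected marginal counts
  while the pair co-occurs only in cases.
* **frequency**: carrier cases receive one extra marker token — a
  deliberately bag-of-words-solvable control condition.

Signal tokens are excluded from the background distribution so the planted
orientation is never diluted. Note the planted pair adds two events to
carriers of both classes on top of the background length distribution, so
with full signal strength the realised mean exceeds the background target
by two and single-event carriers become three-event patients; background
statistics should be validated on signal-free cohorts.

What the generator does **not** emulate: real code semantics and hierarchy,
comorbidity correlation structure, age/sex matching, inter-event dependence
within a patient, and non-stationary event rates. Passing tests on these
cohorts demonstrate that order-sensitive models recover a planted ordering
signal that count models provably cannot — they do not certify performance
on real EHR data.

## Training

Defaults: embedding 30, one hidden layer of 64 ReLU units, dropout 0.1,
Adam at 1e-3, batch 64, up to 50 epochs with early stopping (patience 5) on
the AUROC of a stratified 15% validation split. The final linear layer is
zero-initialised, so an untrained model scores exactly 0.5 — a useful
smoke-test invariant — while hidden and embedding layers use Glorot/normal
initialisation. Class imbalance is handled only through the evaluation
metrics, not through loss reweighting. Fits are deterministic given the
seed under single-threaded numerics.

For the simulation experiments shipped with the package (cohorts of 2000
patients, 50 tokens), smaller settings are ample and keep runtimes in
seconds-to-minutes on one CPU: embedding 8, hidden 16, GRU hidden 16,
learning rate 3e-3, 25 epochs. These were chosen once on validation curves
— every order-sensitive variant reaches validation AUROC ≈ 1.0 well within
the epoch budget — and then frozen.

The GRU baseline embeds tokens with the same trainable-projection role,
optionally appends the scaled time-delta channel to the embedded vector,
and reads out the final hidden state — the most common convention.

## Evaluation choices

* **AUROC** is the Mann-Whitney probability with midrank ties; **AUPRC** is
  step-wise average precision with tied scores handled as blocks, so a
  constant scorer gets exactly the prevalence. Step (not trapezoidal)
  integration avoids optimistic interpolation.
* Under random scores, average precision has a positive finite-sample bias
  of order `1/n_pos` — at 200 positives it is ≈ 0.002 — so null-concentration
  checks compare the mean over repeats against three standard deviations of
  a *single* estimate; three standard errors of the mean over 100 repeats
  would sit below the bias itself for any sample size tested.
* **Cross-validation** is stratified k-fold (folds preserve the 1:9 ratio
  to within one patient), each fold serving once as the held-out test set;
  reported as mean ± sd across folds, matching the usual reporting
  convention for this design.
* The **ablation study** holds out one fixed stratified test set (20%),
  subsamples the remaining pool at each fraction (default grid 0.05–1.0),
  refits, and evaluates on the unchanged test set.
* The order-signal experiment in `scripts/acceptance.R` uses a stratified
  80/20 train/test split per replicate: bag-of-words must be scored out of
  sample, since a 50-feature logistic regression visibly overfits count
  noise in sample (≈ 0.65 in-sample vs ≈ 0.5 held out).

## Known limitations

* Depth-2 signatures on an order-signal cohort capture the planted pairwise
  order directly through Lévy areas, so the log-signature model *without*
  lead-lag performs essentially as well as with it on these synthetic
  cohorts; the two differ by noise at saturation. Observing a lead-lag
  advantage requires signals living in quadratic variation rather than
  pairwise order.
* The Lyndon projection is cached per (dimension, depth); depth-3
  log-signatures are practical up to path dimension ≈ 20 (the triangular
  factor is dense in the Lyndon block). Large-vocabulary paths must pass
  through the learnt projection first, which is also the modelling intent.
* Pure-R training is single-threaded and per-sample; it is sized for
  cohorts of thousands, not millions.
* `simulate()` draws labels from fitted scores; it does not simulate event
  sequences.
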