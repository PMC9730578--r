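# sigehr — path-signature models for clinical event sequences

Coded electronic health records are irregular, variable-length sequences of
categorical events (diagnoses, procedures) with day-resolution timestamps.
Predicting a near-term diagnosis from such a history needs features that are
sensitive to the *order* of events, not just their counts. `sigehr`
implements the path-signature approach to this problem for biostatisticians
and ML researchers working with longitudinal event data:

* an exact **truncated signature / log-signature engine** for
  piecewise-linear paths, built on Chen's identity, the tensor logarithm and
  the Lyndon-word basis of the free Lie algebra;
* the standard **path augmentations** (time index, capped-log time delta,
  basepoint, lead-lag, learnt projection);
* a **neural-signature classifier** in which the signature acts as a
  differentiable, non-parametric pooling layer between a trainable token
  embedding and a small fully connected head;
* **GRU** and **bag-of-words logistic regression** baselines;
* a **synthetic cohort generator** that emulates the structure of inpatient
  EHR cohorts (1:9 case:control matching, Zipf-skewed vocabularies, tied
  timestamps, a 90-day pre-index buffer) with a plantable order-dependent
  disease signal that is invisible to bag-of-words models by construction;
* stratified cross-validation, data-ablation studies, and AUROC / average
  precision metrics for imbalanced cohorts.

## The model

A patient history is a path `x` in `R^d` (one-hot token channels, by default
accumulated into a running-count stream so that path increments are the
events themselves). The depth-`N` signature is the collection of iterated
integrals

    Sig(x)^{i1..ik} = ∫···∫_{0<t1<..<tk<T}  dx^{i1}_{t1} ··· dx^{ik}_{tk},  k ≤ N,

computed segment-by-segment: a linear segment's level-`k` coefficients are
`(Δx^{i1}···Δx^{ik})/k!` and segments combine by Chen's identity
`Sig(x*y) = Sig(x) ⊗ Sig(y)`. The log-signature `log Sig(x)` lives in the
free Lie algebra and is coordinatised on Lyndon words — `Σ_k W(d,k)` terms
by Witt's formula instead of `Σ_k d^k`. The classifier is

    f(x; θ) = σ( g_fc( Sig^N( φ_aug( θ_A · x ) ) ) ),

trained end-to-end with hand-written reverse-mode gradients through the
Chen recursion, tensor logarithm and Lyndon projection. Lead-lag
augmentation pairs the path with a one-step lagged copy, exposing quadratic
variation; basepoint anchors translation; time channels break
reparameterisation invariance. Variants follow the usual naming: `S2`,
`LS2`, `LS2+LL`, `LS2+LL+ATI`, `LS2+LL+ATD`, `LS3+LL+ATD`, `BOW`, `GRU`,
`GRU+ATD`.

## Worked example

```r
library(sigehr)

co  <- generate_cohort(cohort_config(n_patients = 1000, vocab_size = 40, seed = 42))
summary(co)
#> Cohort of 1000 patients: 100 cases (10.0%), mean 6.09 events/patient,
#> 0.0% single-event, vocabulary 40

fit <- sigfit(co, "LS2+LL", embedding_dim = 8, hidden = 16,
              learning_rate = 3e-3, epochs = 15, seed = 1)
summary(fit)
#> Sequence classifier LS2+LL (neural_signature)
#>   vocabulary: 40 tokens; trainable parameters: 2529
#>   pooled feature width: 136
#>   training-set AUROC 1.000, AUPRC 1.000
#>   final training loss 0.0717 after 15 epochs

bow <- sigfit(co, "BOW")
auroc(predict(bow), vapply(co$sequences, function(s) s$label, 0L))
#> [1] 0.645
```

The generated cohort carries a pure order signal: a designated token pair
occurs as *a-then-b* in cases and *b-then-a* in controls, so per-patient
token counts are identically distributed across classes. The signature
model separates the classes essentially perfectly (the pair's Lévy area
flips sign with the order), while the bag-of-words baseline sees only
count noise (its in-sample 0.645 is overfitting; held out, it scores ≈ 0.5).
Note the default `mean_events = 4.15` is a background-event target — the
planted signal pair adds two events to carriers of both classes, and with
`signal_strength = 1` no single-event background sequence stays single.

The algebra is exposed directly:

```r
p <- rbind(c(0, 0), c(1, 0), c(1, 1))   # unit "L" path
log_signature(p, 2)
#> <log_signature d=2 N=2 basis=lyndon (3 terms)>
#>   [1] 1
#>   [2] 1
#>   [12] 0.5      # the Lévy area of the L-path
```

A YAML-driven pipeline (`run_simulate()`, `run_train()`, `run_evaluate()`,
`run_ablate()`, or `inst/cli/sigehr.R` from a shell) writes cohorts,
checkpoints, per-patient predictions and formatted evaluation tables with a
full audit trail (resolved config + seed + config hash).

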