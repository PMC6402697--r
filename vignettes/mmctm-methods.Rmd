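---
title: "Mutation-signature inference with correlated topic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The generative models

A *modality* is one mutation data type with its own category space: SNVs in
the 96 pyrimidine-centric trinucleotide categories, SVs in 63 (or 48 without
foldback inversions) categories of rearrangement type × breakpoint-homology
bin (0–1, 2–5, >5 bp) × breakpoint-distance bin (<10kbp, 10–100kbp,
100kbp–1Mbp, 1–10Mbp, >10Mbp; translocations carry no distance). Counts per
sample and category are the sufficient data; tokens within a category are
exchangeable, so variational responsibilities are aggregated per category,
which is exact.

Every model draws, for each mutation of sample *d* in modality *m*, a
signature `z ~ Cat(θ_d^(m))` and a category `x ~ Cat(φ_z^(m))`, with
`φ_k^(m) ~ Dirichlet(β)`:

* **LDA** (single modality): `θ_d ~ Dirichlet(α)`.
* **CTM / MMCTM**: `θ_d^(m) = softmax(η_d[block m])`,
  `η_d ~ N(μ, Σ)` over the `Ktot = Σ_m K^(m)` concatenated signature
  dimensions. Correlations within and across modality blocks of `Σ` are what
  the correlated models add; the CTM is exactly the single-modality MMCTM
  and is implemented as such.
* **Independent-feature variants** (ILDA/ICTM/IMMCTM): the same machinery on
  catalogs whose features (substitution type, 5′ base, 3′ base) are separate
  categorical emissions sharing the modality's `θ` block. A signature's
  probability of a full category is the product of its per-feature
  probabilities; the per-feature matrices and the product each row-normalize
  to 1.

## Inference

Mean-field variational EM (variational Bayes for LDA). The variational
family is fully factorized: Dirichlet `q(φ_k)`, diagonal Gaussian
`q(η_d) = N(λ_d, diag(ν_d²))`, and one categorical responsibility vector per
(sample, category), aggregated by count. The intractable
`E[log Σ_k exp η_k]` term uses the standard first-order auxiliary-normalizer
upper bound, one normalizer per sample and modality block; the normalizer is
profiled out at its optimum, so the bound term reduces to
`N_d^(m) · logsumexp(λ + ν²/2)` over the block. The bound choice is recorded
in each fit's metadata.

Per iteration: responsibilities and Dirichlet statistics are recomputed (in
compiled code), `q(φ)` is updated in closed form, all samples' `(λ, log ν²)`
are updated jointly by one bounded L-BFGS-B pass on the exact coordinate
objective with analytic gradients (inner projected-gradient tolerance 1e-6,
bounds |λ| ≤ 30, log ν² ∈ [−20, 5] to keep exponentials finite), and the
M-step sets `μ` to the mean of `λ_d` and `Σ` to the empirical second moment
of the variational means plus the mean variational variances, with a 1e-6
diagonal ridge to keep small-cohort fits invertible (unless the covariance
is fixed to the identity). Every step is coordinate ascent, so the recorded
ELBO trace is non-decreasing (the test suite enforces a 1e-8 relative
tolerance).

Iterations stop when the relative change in the training average
per-mutation log-likelihood (under the current point estimates) drops below
the tolerance. Point estimates are variational posterior means for `φ` and
LDA's `θ`; for the correlated models `θ` is the softmax of the posterior
mean of `η` — an approximation to the mean of the logistic-normal, which
has no closed form; the choice is deliberate and documented here.

**Initialization and determinism.** Signature Dirichlet parameters start as
random positive integers in 1..100; `λ = 0`, `ν² = 1`, `μ = 0`, `Σ = I`.
All randomness flows from the supplied seed, so identical data, settings and
seed reproduce a fit bit-for-bit on the same platform.

**Restart protocol.** `fitWithRestarts()` runs `nRestarts` short fits
(tolerance 1e-4, at most 100 iterations each — the iteration cap is a
package choice, recorded in the fit config, since only "a limited number of
iterations" is inherent to the protocol), ranks restarts per modality by
training predictive log-likelihood, selects the best mean rank, and
continues that fit at tolerance 1e-5. Desk-scale defaults use 50 restarts;
the protocol scales to thousands unchanged.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `K` (per modality) | — | number of signatures; choose via `selectSignatureNumber()` and judgement |
| `beta` | 1.0 | symmetric Dirichlet on signatures (flat; counts dominate) |
| `alpha` | 0.1 | LDA's Dirichlet on `θ` (sparse); *not* used by the correlated models, whose `θ` prior is the fitted Gaussian — both knobs are exposed because either convention appears in practice |
| `tol` / `tolRestart` | 1e-5 / 1e-4 | relative training log-likelihood convergence |
| `fixCovarianceIdentity` | FALSE | ablation switch: keep `Σ = I` |
| `ridge` | 1e-6 | covariance M-step ridge |
| observed `fraction` | 0.5 | document-completion split; symmetric convention, configurable |

## Evaluation machinery

The predictive log-likelihood is the average per-hidden-mutation log
probability `Σ_dv X_dv log(θφ)_dv / ΣX`; a probability floor (1e-16) is
available for comparator methods whose renormalized outputs can be exactly
zero (NMF-style solutions); the topic models never need it. Cross-validation
is stratified (e.g. by histotype) with repeats; observed/hidden splits are
per-token binomial. Downsampling is per-category binomial thinning, which
removes mutations in proportion to their type frequencies in expectation; an
exact without-replacement mode is available behind `method = "exact"`. The
classifier benchmark balances classes by subsampling, then scores an
L2-regularized logistic regression (glmnet ridge with λ = 1/n, mirroring a
unit-C solver, up to 10,000 iterations) by plain accuracy over stratified
folds.

`selectSignatureNumber()` produces the likelihood-vs-K curve by half-split
(fit on ~half of each sample's mutations, score the other half — all samples
participate) or by sample-level CV. The suggested K — smallest K whose
successor gains less than one standard error — is advisory and logged, never
silently binding: the curve is the deliverable.

## The synthetic-data generator

`simulateCounts()` draws `counts[d,v] ~ Poisson(N_d · (θ_d φ)_v)`, the
count model the methods assume, seeded and reproducible.
`syntheticSignatures()` draws reference signatures from a sparse Dirichlet
(concentration 0.1) and redraws until all pairwise cosine similarities are
below 0.5 — "qualitatively distinct" made operational.
`drawCorrelatedProbs()` draws logistic-normal sample probabilities with a
user-specified covariance, giving corpora the correlation structure the
MMCTM models. A user-supplied signature TSV can replace the synthetic
references for exact replication against published signature sets.

What the generator emulates: Poisson sampling noise, signature mixing,
cross-modality correlation, sparse-count regimes (via small `N_d` or
`downsampleCounts()`). What it does not: clustered breakpoints (deliberately
out of scope), sequencing error, tumor purity, copy-number-driven count
inflation, or inter-sample differences in mutability per category. Passing
recovery tests therefore demonstrates correctness of inference under the
model's own assumptions, not robustness to real-data violations of them.

**Study conditions.** The package's signature-recovery study
(`signatureRecoveryStudy()`, also run by `scripts/acceptance.R` and the
acceptance tests) uses 10 replicate datasets, 200 samples, 4 SNV signatures,
Dirichlet(1) sample probabilities, ~5000 mutations per sample and 50
restarts — a desk-scale analogue of a 560-sample, 500-restart design, sized
so the whole study completes in minutes on one CPU. The sparse-data
comparison fits a rich modality (~2000 mutations/sample) alongside a sparse
one (~30/sample, about 1% of SNV scale) with strongly correlated
probabilities, 60 samples (40 train / 20 test), K = 3, 3 restarts, 20
seeds, and compares MMCTM to per-modality LDA by held-out per-mutation
log-likelihood with a one-sided sign test.

## Stratification

Signature probabilities are z-scored per signature across samples (SD with
the n−1 denominator — a documented convention choice) so low-prevalence
signatures contribute comparably; zero-variance columns become zeros and
are flagged. Clustering is Ward (`ward.D2`) on Euclidean distances. The
default cut picks the largest number of clusters for which every cluster
has ≥ 3 members — a deterministic, parameter-recorded stand-in for dynamic
hybrid tree cutting, which this package intentionally does not re-implement;
`fixed_k` and `fixed_height` cuts are available and the biological result
should always be read from the recorded parameters.

Cluster-signature enrichment uses one-sided (greater) Welch t-tests of
in-cluster versus out-of-cluster probabilities; annotation associations use
two-tailed Fisher exact tests (binary), Welch t-tests (numeric) or Welch on
midranks (robust to hypermutators); confounded annotations use the blocked
permutation test, whose permutations redraw the cluster without replacement
preserving per-block (e.g. receptor-status or histotype) composition, with
`p = (1 + #{|s′| ≥ |s|}) / (1 + N)`. The exhaustive mode enumerates all
distinct draws and reports the plain proportion — exact, so no +1
smoothing. Benjamini–Hochberg correction is applied separately to the
signature tests and the annotation tests. Reported confidence intervals are
Welch-based for t-tests and omitted for permutation tests, since the
permutation scheme defines no canonical interval.

## Numerical choices and degenerate inputs

* Bin edges: homology 0–1/2–5/>5 inclusive as written; distances half-open
  `[0,10k) … [10M,∞)` so every distance maps to exactly one bin. The labels
  fix the bins only up to edge convention; this is the package's documented
  choice.
* Greedy signature matching breaks MAE ties by (estimated, reference) index
  order — determinism over optimality; matching is otherwise row-order
  invariant.
* Zero-count samples are retained everywhere, flagged, and given
  prior-mean-induced probabilities by `inferSampleProbs()`.
* All-zero count matrices, mismatched sample orders across modalities,
  category-space mismatches at inference time, clusters covering every
  sample, and non-PSD simulation covariances are rejected with errors.
* Reference-base mismatches against the FASTA are errors (they indicate a
  build mismatch); indels, multi-allelic records and N-flanked contexts are
  skipped and logged, never silent.

## Known limitations

* The logistic-normal bound is first-order; tighter (e.g. quadratic) bounds
  could speed convergence but the contract here is only monotone ascent.
* `θ` point estimates for correlated models are softmax-of-mean, which
  slightly sharpens relative to the true posterior-mean composition.
* Signature probabilities are probabilities of generating a mutation, not
  activities (expected counts); thresholding small probabilities for
  presence/absence calls is left to the analyst.
* The independent-feature variants discard within-mutation feature
  coupling; their factorization is only weakly identifiable when sample
  compositions stay far from the simplex corners (the test suite's
  factorizable-recovery case uses sparse Dirichlet compositions for this
  reason).
* Survival analysis and NMF internals are intentionally out of scope; NMF
  solutions can be scored through `predictiveLogLik(..., floor = 1e-16)`
  after external normalization.
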