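# mmctm — multi-modal correlated topic models for mutation signatures

`mmctm` infers **mutation signatures** — probability distributions over
mutation categories attributed to mutational processes — jointly from several
mutation data types ("modalities"), typically single-nucleotide variants
(SNVs, 96 trinucleotide categories) and structural variants (SVs, categories
of rearrangement type × breakpoint homology × breakpoint distance). It is
aimed at cancer-genomics analysts who want signature probabilities per
sample, signature correlations within and across mutation types, and
signature-based patient stratification — especially when some mutation type
is sparse (tens of events per genome, as is typical for SVs).

## The models

All models are topic models on per-sample category counts. Each modality
`m` has `K^(m)` signatures `φ_k^(m)` (rows of a K × V stochastic matrix,
Dirichlet(β) priors) and each sample `d` a signature-probability vector
`θ_d^(m)`. Each mutation draws a signature `z ~ Cat(θ_d^(m))`, then a
category `x ~ Cat(φ_z^(m))`.

* **LDA**: `θ_d ~ Dirichlet(α)` (single modality).
* **CTM**: `θ_d = softmax(η_d)` with `η_d ~ N(μ, Σ)` — the logistic-normal
  lets signature probabilities correlate across samples.
* **MMCTM**: one Gaussian `η_d ∈ R^{ΣK^(m)}` is shared by *all* modalities;
  `θ_d^(m)` is the softmax of the modality's block. Off-diagonal blocks of
  `Σ` capture cross-modality signature correlations (e.g. an HRD SNV
  signature co-occurring with small-deletion SV signatures). With a single
  modality the MMCTM *is* the CTM.
* **ILDA / ICTM / IMMCTM**: the same models on "independent" encodings that
  treat each mutation feature (substitution type, 5′ base, 3′ base) as a
  separate categorical emission, shrinking 6·4·4 = 96 category values to
  6 + 4 + 4 = 14 feature values.

Inference is mean-field variational EM (variational Bayes for LDA): Dirichlet
posteriors for signatures, diagonal-Gaussian posteriors `q(η_d)=N(λ_d, ν_d²)`
with the logistic-normal normalizer handled by the standard first-order
auxiliary bound, and `(μ, Σ)` re-estimated each M-step. The ELBO is
non-decreasing across iterations; fits are reproducible from a seed.

Held-out evaluation uses the average per-mutation predictive log-likelihood

```
l = Σ_d Σ_n log( Σ_k p(x_nd | φ_k) p(z_nd = k | θ_d) ) / Σ_d N_d
```

with θ for test samples estimated from an "observed" half of their mutations
and `l` computed on the "hidden" half. Patient stratification z-scores the
joint signature probabilities, clusters with Ward linkage, and tests cluster
associations with Welch/Fisher tests and a blocked permutation test whose
two-tailed p-value is `(1 + #{|s′| ≥ |s|}) / (1 + N)`, permuting cluster
membership while preserving confounder-block composition.

## Worked example

Simulate a 60-sample corpus from three well-separated synthetic SNV
signatures, fit the model with the restart protocol, and score recovery:

```r
library(mmctm)

phi <- syntheticSignatures(3, snvCategories(), seed = 11)
th  <- drawCorrelatedProbs(rep(0, 3), diag(3), D = 60, blockSizes = 3,
                           seed = 12)
sim <- simulateCounts(list(SNV = phi), th, totals = 2000, seed = 13)

fit <- fitWithRestarts(sim, K = 3, nRestarts = 10, seed = 1)
fit
#> MmctmFit (MMCTM)
#>   modalities: SNV [K=3]
#>   samples: 60
#>   iterations: 34, final ELBO: -402950.4
#>   training log-lik per mutation: SNV=-3.34316

m <- matchSignatures(signatures(fit, "SNV"), phi,
                     sampleProbs(fit, "SNV"), th[[1]])
round(m$signatureMAE, 4)
#> [1] 0.0011 0.0013 0.0017

round(signatureCorrelations(fit), 2)
#>       SNV1  SNV2  SNV3
#> SNV1  1.00 -0.40 -0.58
#> SNV2 -0.40  1.00 -0.51
#> SNV3 -0.58 -0.51  1.00
```

`fitWithRestarts` ran 10 short random-restart fits, picked the restart with
the best mean rank of per-modality training log-likelihoods, and continued it
to convergence. Each recovered signature matches its reference with mean
absolute error ≈ 0.001–0.002 per category probability. The correlation
matrix is the Pearson correlation of per-sample signature probabilities
(negative here because a 3-component composition is anti-correlated by
construction when probabilities are independent).

Raw calls are encoded with `buildSnvCatalog()` (VCF + indexed FASTA, via
`readSnvVcf()`) and `buildSvCatalog()`; `inferSampleProbs()` scores new
samples under a fitted model; `standardizeProbs()`, `clusterSamples()`,
`clusterSignatureEnrichment()`, `blockedPermutationTest()` and
`annotationAssociation()` drive the stratification step. A thin command-line
wrapper with `encode`, `fit`, `infer`, `simulate`, `benchmark` and
`stratify` subcommands is installed at `inst/cli/mmctm`.

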