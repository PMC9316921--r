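---
title: "Predicting one tissue's expression from a uniform multi-tissue pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting one tissue's expression from a uniform multi-tissue pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdecon)
```

## The problem

Public RNA-seq archives sometimes hold a library prepared from a *pool* of
many tissues — total RNA from dozens of organs combined in (nominally)
equal proportions — alongside single-tissue libraries for only a subset of
those organs. When the tissue of interest (here, the motivating case is
cardiac muscle, whose ion-channel complement is poorly characterised in
some species) has **no** single-tissue library of its own but **is** part
of the pool, its expression profile can still be estimated by linear
unmixing: everything in the pool that the referenced tissues cannot
account for must have come from the missing one.

`mixdecon` implements that estimator together with the supporting steps a
real analysis needs: count filtering and FPKM normalisation, per-tissue
profile estimation, median imputation for pooled tissues lacking any
reference, removal of infeasible (negative) predictions, propagation of
the prediction's standard deviation, sample clustering as a sanity check,
and correlation against an external reference expression table with a
conservative upper-outlier screen.

## Model and estimator

Let $\bar G_i$ be the mean FPKM of gene $i$ across the pooled-mix
libraries, and $\bar\alpha_{ij}$ the mean FPKM in tissue $j$. With $T$
tissues pooled at the uniform proportion $p = 1/T$, the mixing model is

$$ G_{ik} \;=\; \sum_{j=1}^{T} p\,\alpha_{ij} \;+\; \varepsilon_{ik}, $$

and the single unknown tissue (index $t$) is estimated by inverting it:

$$ \bar H_i \;=\; \frac{\bar G_i}{p} \;-\; \sum_{j \ne t} \bar\alpha_{ij}. $$

Three practical rules complete the estimator:

* **Median imputation.** A pooled tissue with no reference samples
  contributes the per-gene *median of the known reference-tissue means*
  (and the median of the known SDs, so imputed terms still carry
  uncertainty). With an even number of known tissues the median is the
  midpoint of the central pair.
* **Negative-prediction removal.** For lowly expressed genes the error
  term can exceed the signal and $\bar H_i \le 0$; such genes are removed
  (`status = "dropped_negative"`), keeping the raw value for audit. The
  threshold is exactly $\le 0$ — no positive floor.
* **SD propagation.** Treating all terms as independent,
  $\mathrm{SD}(\bar H) = \sqrt{\mathrm{SD}(\bar G)^2/p^2 + \sum_{j\ne t}
  \mathrm{SD}(\bar\alpha_{j})^2}$. This is the assumption-minimal closed
  form consistent with the estimator's linear structure; the Monte-Carlo
  calibration below is the empirical check that it is adequate.

The tissue-to-reference **mapping is an explicit input** (a named vector:
mix tissue → reference tissue label, or `"IMPUTE"`), defaulting to
name-identical matching with imputation elsewhere. A single reference may
legitimately stand in for several pooled components (e.g. one brain
reference for cerebrum, cerebellum and spinal cord); the estimator then
counts it once per component, as the mixture requires. Making the mapping
a declared input, rather than something inferred, is deliberate: how pool
components are matched to references is a judgement call that should be
visible in the analysis script.

## A worked toy example

```{r toy}
# 3 tissues pooled at p = 1/3; "heart" has no reference samples
design <- mix_design(c("heart", "muscle", "liver"), "heart", p = 1/3)
profiles <- tissue_profiles(data.frame(
  gene   = c("CASQ2", "CASQ2"),
  tissue = c("muscle", "liver"),
  mean   = c(2, 4), sd = c(0.3, 0.5), n = c(4L, 4L)
))
# the pool carries mean FPKM 4 for CASQ2
pred <- predict_unknown_tissue(c(CASQ2 = 4), profiles, design)
pred$predicted_mean     # 4/(1/3) - (2 + 4) = 6
propagate_prediction_sd(c(CASQ2 = 0.2), profiles, design)
```

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions under which the package
tests itself; its defaults are chosen once, on biological grounds, and
everything is overridable:

* **Geometry**: `T = 43` tissues pooled at `p = 1/43`; the first tissue
  (`"cardiac_muscle"`) is the unreplicated target; the last 5 tissues are
  present in the pool but have no reference samples and are imputed —
  the situation the imputation rule exists for.
* **Sample counts**: 2 pooled-mix libraries and 4 replicates per
  reference tissue. Pooled libraries are scarce in practice (they come
  from a single annotation-oriented study), while reference tissues
  accumulate samples across studies, so fewer mix samples than reference
  replicates is the realistic regime.
* **Gene panel**: 90% of genes are exclusive to one tissue
  (round-robin across tissues), with home-tissue expression log-normal
  (`meanlog = 3`, `sdlog = 1.5`; median ≈ 20 FPKM, heavy upper tail); the
  remaining 10% are ubiquitous with independent per-tissue log-normal
  means (`meanlog = 0`, `sdlog = 1`; median 1 FPKM). This mirrors a panel
  of excitability genes — ion channels are predominantly restricted to a
  small number of tissues and stand well above the background where they
  are expressed — and *not* a whole transcriptome, where ubiquitous genes
  dominate.
* **Noise**: multiplicative log-normal with CV 0.2, mean-one by
  construction (`exp(N(-\sigma^2/2, \sigma))` with
  `\sigma^2 = log(1 + CV^2)`), applied per replicate, and in mix samples
  per tissue component *before* the weighted summation, so the pool's
  expectation is exactly the uniform average of the tissue means.

What the generator deliberately does **not** model: count-level
(negative-binomial) noise as the primary mechanism — the mixing model is
stated on FPKM values, so the noise lives there, and a count-level
back-conversion (`expression_to_counts()`) exists only to exercise the
normalisation path; library-size and batch effects; correlated expression
across tissues; annotation-realistic gene-length distributions. Passing
recovery tests on these fixtures therefore demonstrates that the
*estimator and its uncertainty are implemented correctly under the
model's own assumptions*, not that the model captures everything real
pooled libraries do.

## What recovery can and cannot achieve

The estimator subtracts $T-1$ estimated reference means from an upscaled
pool mean, so its error variance is approximately
$\mathrm{CV}^2 \left(\tfrac{1}{n_\text{mix}} + \tfrac{1}{n_\text{rep}}\right)
\sum_{j} \alpha_{ij}^2$: it grows with the gene's *total* expression
across all tissues, while the signal is only the target-tissue component.
Consequently:

* Genes concentrated in the target tissue are recovered with a relative
  error around `CV * sqrt(1/n_mix + 1/n_rep)` (≈ 17% at the defaults) —
  the regime the method is designed for.
* Ubiquitously expressed genes are recovered poorly at any realistic CV,
  because the subtraction noise from 42 other tissues rivals the target
  signal. The package reports this honestly rather than hiding it: the
  headline recovery correlation in `recovery_experiment()` is computed
  over the genes whose *true* target expression contributes at least
  0.5 FPKM to the pool mean (`p * alpha_target >= 0.5`) — the genes for
  which the pool carries a usable target signal. On the default panel
  this recovers the truth with Pearson *r* above 0.95.
* A gene exclusive to a tissue that has **no** reference and is imputed
  is systematically mis-attributed: the median of the other tissues'
  means is ~0, so the gene's entire pooled signal is credited to the
  target. `recovery_experiment()` reports this as
  `fp_rate_imputed_home` (essentially 1 at the defaults). This is an
  inherent hazard of median imputation, worth knowing when interpreting
  any prediction whose expression could plausibly come from an
  unreferenced pool component.
* For a gene with zero true target expression (and a referenced home
  tissue) the estimator is a difference of two equal-mean quantities, so
  the negative-prediction rule removes it about half the time — slightly
  more than half at the defaults, because with fewer mix samples than
  replicates the minuend is noisier and right-skewed. The
  `zero_expression_experiment()` measures this drop rate over repeated
  noisy re-simulations, pooled across zero-truth genes with referenced
  homes (imputed-home genes are excluded there precisely because their
  estimator is not zero-mean; they are the false positives above).

## Numerical and procedural choices

* **Pipeline order** is pinned: low-count genes (summed count across all
  samples below `min_total`, default 10) are removed *first*, and
  per-sample totals for FPKM are recomputed on the filtered matrix.
* **Quantiles** for the outlier rule use linear interpolation between
  order statistics at positions $1 + q(n-1)$ (`stats::quantile`
  `type = 7`), making the `Q3 + k*IQR` cutoff bit-reproducible; the rule
  needs at least 4 values, and with `k = Inf` nothing is removed. In a
  gene pair, the pair is removed when *either* member exceeds its own
  vector's cutoff — a symmetric treatment, declared openly. The screen is
  intentionally conservative (`k = 3`): expression distributions are
  right-skewed by nature, and only the most extreme values should go.
* **Correlation scale**: tests run on raw FPKM-scale values by default
  (`log_transform = TRUE` switches both vectors to `log1p`). A perfect
  correlation is reported with a `t = ±Inf` sentinel and `p = 0` rather
  than an error, so exact toy fixtures remain usable.
* **Clustering** defaults to Euclidean distance with complete linkage
  (the common heatmap defaults; `"correlation"` and
  `"average"`/`"ward"` are available). Samples are sorted
  lexicographically by identifier before clustering, which fixes the
  tie-break order and makes the merge tree invariant to input column
  order. Zero-variance genes are set to zero rows by `scale_genes()` and
  flagged. The tested artifact is the merge tree and flat assignments;
  rendering a heatmap from the scaled matrix is left to the user.
* **SD calibration** (`sd_calibration_experiment()`) draws one pool
  observation and one observation per non-target tissue per Monte-Carlo
  replicate and compares the empirical spread of the estimator with the
  propagation formula fed the population SDs. The formula contains no
  $1/\sqrt{n}$ terms — it propagates the spread of single observations —
  so the calibration instance is built the same way. All non-target
  tissues are treated as referenced in this experiment: it calibrates the
  propagation formula itself, which presumes an observed spread for every
  term. At the defaults the median propagated/empirical ratio is within a
  couple of percent of 1.
* **Exact inversion** is checked on noise-free fixtures with *no*
  imputed tissues: median imputation is deliberately biased for
  ubiquitous genes (the median of the other tissues is not the missing
  tissue's mean), so bit-level inversion is a property of the estimator,
  not of the imputation; the imputation's own behaviour is tested
  separately.
* **Problem sizes** used by the shipped tests and the acceptance script —
  up to 10,000 genes × 43 tissues for inversion, 1,000 genes for noisy
  recovery, 500 Monte-Carlo replicates for calibration, 200 re-simulations
  for the drop-rate experiment — are the package's chosen experiment
  scale; all are parameters of the respective functions.

## Known limitations

* Only a *single* unknown component is supported, with proportions fixed
  and uniform by design; estimating proportions from data, or unmixing
  several unknowns, is out of scope (and a different literature —
  regression/NNLS-based signature deconvolution).
* FPKM forgets each library's absolute scale: values within a sample sum
  (length-weighted) to a constant, so a synthetic FPKM matrix converted
  to counts and re-normalised is recovered only up to a per-sample
  factor. The count-level entry point exists to exercise the
  normalisation, not to claim count-level fidelity of the mixture model.
* Gene matching against external references is exact-symbol only;
  ortholog mapping beyond shared symbols is out of scope.
* The error term of the mixing model is not estimated from data; it is
  realised only in the synthetic noise model, and the propagated SD rests
  on the independence assumption validated by simulation.
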