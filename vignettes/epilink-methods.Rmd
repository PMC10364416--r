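---
title: "epilink: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epilink: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`epilink` reconstructs enhancer–promoter interactions (EPIs) from CAGE
activity alone. The underlying assumption is that a regulating enhancer's
eRNA transcription co-varies with its target promoter's transcription
across cell and tissue states, and that this co-variation is positive,
cis-restricted (same chromosome, within 1 Mb of the TSS), and strong enough
to stand out against the genome-wide background of coincidental
co-activity.

The pipeline factorizes this into five steps per promoter:

1. *Candidate enumeration.* All enhancers whose midpoint lies within 1 Mb of
   the TSS on the same chromosome. Distance is |midpoint − TSS| throughout;
   the midpoint is used because CAGE enhancers are short (hundreds of bp)
   and bidirectionally transcribed from their center.
2. *LASSO selection.* Promoter activity is regressed on all candidate
   activities jointly with an L1 penalty; candidates with β > 0 are kept.
   The joint fit matters: a bystander enhancer that merely co-occurs with a
   true regulator is absorbed by the regulator's coefficient. All variables
   are z-scored before fitting so the penalty treats candidates
   symmetrically; the penalty is chosen by seeded k-fold cross-validation
   (k = 5, reduced so that every fold keeps at least 3 observations) at
   `lambda.min`.
3. *Empirical-FDR correlation filter.* For each promoter, 10,000 enhancers
   are drawn from the other chromosomes and their Spearman correlations
   with the promoter form a null for "co-activity without cis regulation"
   — trans pairs share the global state structure (cell-type programs,
   batch-like sample effects) but cannot be direct cis partners. A
   candidate survives iff its ρ strictly exceeds the empirical 95% quantile
   (FDR 5%) of its promoter's null.
4. *Per-sample activation.* Usage calls (TPM strictly > 1) gate each
   retained pair per sample: an EPI is active iff both endpoints are in
   usage.
5. *ABC scoring and aggregation.* Active EPIs are scored with an
   Activity-By-Contact form and aggregated per state as the union over
   replicates with the maximal score.

## The ABC score used here

The classical ABC model combines element activity with Hi-C contact
frequency. With CAGE-only inputs there is no measured contact, so the
contact term is a power-law distance decay:

$$\mathrm{ABC}(e) \;=\; \frac{\sqrt{A_e A_p}\,(d_e + d_0)^{-\gamma}}
{\sum_{e'\,\text{active}}\sqrt{A_{e'} A_p}\,(d_{e'} + d_0)^{-\gamma} + B_p}$$

* `gamma` (default 1.0) — decay exponent; 1.0 matches the near-hyperbolic
  decay of average chromatin contact with genomic distance.
* `d0` (default 5,000 bp) — pseudo-distance flattening the decay below the
  scale at which contact frequency saturates; it also removes the
  singularity at d = 0. Setting `d0 = 0` is accepted and meaningful when
  all distances are positive.
* `B_p` (default 0) — a promoter "background" share entering the
  denominator; with B_p > 0 the scores of a promoter's active enhancers
  plus the background share sum to exactly 1, with B_p = 0 the scores
  themselves sum to 1.

The Activity term is the geometric mean of enhancer and promoter TPM, which
keeps the score symmetric in scale between the two element classes and
reduces the leverage of a single very hot element. This exact functional
form is this package's documented choice; the normalization per promoter
per sample (scores in [0, 1], conserving total regulatory input) is the
property downstream analyses rely on.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `usage_threshold` | 1 TPM (strict >) | element "in usage" per sample |
| `max_dist` | 1 Mb | cis candidate window (midpoint to TSS) |
| `n_null` | 10,000 | trans pairs per promoter null |
| `fdr` | 0.05 | empirical FDR of the correlation filter |
| `abc_gamma`, `abc_d0`, `abc_background` | 1.0, 5000, 0 | ABC contact/background |
| `lasso_nfolds` | 5 | CV folds for the penalty |
| `linkage` | "average" | agglomeration for state clustering |
| `flank` | 2,000 bp | proximal SNP-to-gene window around gene bodies |
| `alpha` | 0.05 | BH FDR for gene calls |

# Numerical choices

* **Quantiles.** The null threshold is the linear-interpolation quantile
  (R type 7) of the null correlations, so thresholds are reproducible and
  continuous in `fdr`.
* **Spearman at scale.** Rows are midrank-transformed once and
  standardized; Spearman correlations are then inner products, which makes
  the 10,000-pair nulls cheap (a matrix–vector product per promoter).
  Constant rows get correlation 0.
* **Ties and ordering.** All rankings (AUPR, aggregation keys, outputs) are
  broken lexicographically by (gene_id, enhancer_id); every stochastic step
  takes an explicit seed, and per-promoter sub-seeds are derived by fixed
  offsets, so a single seed reproduces a run byte-for-byte.
* **Degenerate inputs.** A zero-variance promoter yields an empty retained
  set (logged, not an error). A trans pool smaller than `n_null` is sampled
  with replacement (warning). If cross-validation encounters a fold with
  constant response — possible for promoters active in almost no samples —
  `lasso_select` falls back to marginal correlation signs rather than
  failing the whole run. An all-zero activity row has undefined entropy
  specificity and reports `NA`; two all-zero networks have undefined
  similarity, treated as distance 1 with a warning in clustering.
* **AUPR.** Computed as average precision (step-wise PR integration) over a
  restricted universe; universe pairs missing from the predictions rank
  last with score 0. Average precision of a random ranker equals the truth
  prevalence in expectation, which is the natural chance floor to quote
  next to it.
* **Empirical FDR reading.** "Correlation higher than random pairs at FDR
  5%" is implemented as a null-quantile cutoff (retain above the 95%
  quantile), not as a ratio-based false/total FDR at a data-driven
  threshold; the quantile reading is the one that makes the per-promoter
  threshold well-defined without reference to the candidate set.

# The synthetic-data generator

`simulate_dataset()` is a first-class module, not a test fixture. It
emulates the structure the pipeline assumes:

* **States and replicates.** `n_states` cell/tissue types with
  `replicates_per_state` samples each (defaults 10 × 2).
* **Cell-type-restricted usage.** Each element is active in a
  `usage_specificity` fraction of states (default 0.2). Active elements
  draw log-normal TPM (median 5, so the > 1 TPM usage rule separates
  cleanly); inactive elements draw a near-zero floor (uniform on
  [0, 0.1] TPM), matching the near-silent baseline of real CAGE enhancers.
* **Planted regulation.** Each promoter receives 2–4 planted enhancers
  within 1 Mb with positive effects β ~ U(0.5, 1.5); planted enhancers
  inherit their target's active states. In a promoter's active samples its
  activity is Σβ·(enhancer activity) plus Gaussian noise (floored at 0);
  in its inactive samples it shows *leaky basal transcription*: a damped
  (×0.2), noisy, saturating transform of the same enhancer signal, kept
  strictly below 1 TPM by a rank-preserving squash. The leak term reflects
  that regulatory coupling does not switch off discontinuously below the
  usage threshold, and it is what makes the planted correlation observable
  across all samples rather than only within the few active ones.
* **Noise level.** `noise_sd` defaults to 0.25 TPM. With 2–4 enhancers
  competing per promoter, each planted pair's Spearman correlation is
  bounded near 0.70 even at zero noise (the other regulators act as
  structured noise); the default lands the mean planted ρ at ≈ 0.66,
  i.e. the intended "strong but not trivial" regime.
* **Validation sets and GWAS.** `make_validation()` keeps each planted link
  with probability `sensitivity` and adds non-linked within-1-Mb pairs at
  `false_link_rate`, standing in for pcHi-C/eQTL truth sets.
  `make_gwas()` places SNPs uniformly, draws background p-values from
  U(0, 1) and p-values inside causal genes' bodies ±2 kb or their planted
  enhancers from Beta(1/(1 + effect_shift), 1).

What the generator does **not** emulate: read-level counts and their
overdispersion, linkage disequilibrium among SNPs, correlated enhancer
modules (super-enhancers), unbalanced replicate numbers, batch effects
beyond the shared state structure, and measured chromatin contact. Passing
tests on this generator therefore demonstrate the pipeline's correctness
and calibration under its stated assumptions — not performance on real
FANTOM-scale data.

## Specificity of synthetic elements

The Gini index of per-state mean activity is the generator's specificity
diagnostic. It is structurally capped near 1 − (fraction of active
states): with elements active in 2 of 10 states the cap is 0.8 exactly, so
the "highly specific" regime (Gini > 0.8) is demonstrated at
`usage_specificity = 0.1` and the index degrades smoothly as specificity
is broadened.

# Design choices that were genuinely open

* **Aggregation across replicates** is the union of per-replicate active
  EPIs (an EPI active in any replicate enters the state network), with the
  maximal ABC score. The conservative alternative (intersection) is easy to
  express downstream by filtering on `n_samples_active`.
* **Correlation across all samples jointly**, not per state: the filter
  asks whether the pair co-varies over the whole body map, which is where
  the contrast between states carries the signal.
* **SNP routing uses binary edge presence**, not ABC weights: a SNP in an
  enhancer linked to a gene in the state's network is assigned to that
  gene regardless of the edge weight. Weighted p-value combination would
  require a model for how ABC share scales association strength, which the
  data here do not constrain.
* **Gene-level combination** is Fisher's method with SNPs treated as
  independent. This is exact for the synthetic generator (independent
  p-values) and anti-conservative under real LD; the combiner is a single
  pluggable function (`gene_pvalue`) so an LD-aware statistic can be
  swapped in.
* **BH per state**, not global: each state's gene list is its own multiple
  testing family, mirroring the per-state reporting of the results.
* **"Higher than 50% of the remaining genes"** is read as strictly above
  the median of all *other* genes in that sample (exposed as a percentile
  parameter); qualified sets are union-aggregated over replicates.
* **Validation pair semantics**: one shared variant (or ≥ 1 bp overlap)
  suffices to support an enhancer–gene truth pair.

# Calibration and its limits

Under a no-signal simulation, the per-promoter null threshold is well
calibrated: fresh independent pairs exceed it at the nominal 5% ± 1%. The
retention rate *among LASSO-surviving candidates*, however, is higher
(~15% at the default settings) — and must be, by construction: step 1
selects candidates for positive association on the same samples the filter
then tests, so the survivors' correlations are not draws from the null.
Even if step 1 only fixed the sign, exceedance of a two-sided 95% null
quantile among positively-signed pairs would be ~10%. The filter's FDR
parameter therefore describes the null quantile it cuts at, not the
false-discovery rate of the two-step cascade; the cascade's end-to-end
error is what the planted-recovery evaluation measures.

# Problem sizes

The shipped tests and the reproduction script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which the statistical
properties are stable: recovery studies use 1,000 enhancers × 200
promoters × 10 states × 2 replicates (≈ 600 planted links); null
calibration uses 100 promoters × 1,000 enhancers × 20 samples with no
planted links; prioritization uses the recovery dataset with 20 planted
causal genes and ≈ 50 SNPs expected per gene body. A full run of the test
suite takes well under a minute per study on a single core.

# Known limitations

* CAGE cannot separate active from poised enhancers; an EPI here asserts
  co-activity-supported regulation, not a validated chromatin loop.
* Trans (inter-chromosomal) regulation is out of scope by construction.
* The ABC adaptation uses distance decay as a contact surrogate; where
  measured contact matters (e.g. CTCF-anchored skipping of nearby genes),
  the score will misrank.
* Fisher's combination over LD-correlated SNPs overstates significance on
  real GWAS input; treat real-data gene calls as a screening list.
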