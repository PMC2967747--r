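---
title: "Multiplex meta-analysis of differential expression with metamux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex meta-analysis of differential expression with metamux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamux)
```

## The problem

Expression studies of the same biological contrast — here the motivating
setting is acute rejection (AR) versus stable acceptance (STA) of solid
organ transplants — accumulate across laboratories and platforms, but no
single study is large, and platforms disagree about which genes they
measure and how many probes interrogate each gene. *Multiplex*
meta-analysis combines tens of thousands of genes at once across such
studies, tolerating genes that are missing from some platforms and
measured redundantly on others.

`metamux` implements the two classical combination routes side by side and
the machinery to compare them:

* a **non-parametric significance route**: per probe and study, two
  one-sided Welch t-tests (increased and decreased expression in cases);
  per gene and direction, Fisher's omnibus combination of all probe
  p-values across all studies; the directional minimum as the gene's meta
  p-value, Benjamini–Hochberg adjusted across genes;
* a **parametric effect-size route**: per probe and study, the log2
  fold-change `f = mean(case) − mean(control)` (the log ratio of
  geometric means on the raw scale) with sampling variance
  `v = s²_case/n_case + s²_control/n_control`; per gene, the
  inverse-variance fixed-effects pool `meta_fc = Σ wᵢfᵢ / Σ wᵢ` with
  `wᵢ = 1/vᵢ` and standard error `sqrt(1/Σ wᵢ)`.

Rankings by either criterion are scored against signature gene sets with
ROC curves whose AUC equals the Mann–Whitney probability that a random
signature gene outranks a random non-signature gene (ties count one half).

## Statistical model and assumptions

Fisher's statistic `X = −2 Σ ln pᵢ` over `k` pooled p-values is referred
to a χ² distribution with `2k` degrees of freedom. Its validity assumes
the pooled p-values are independent and uniform under the null; probes of
one gene within a study are treated as independent evidence, which
overstates `k` slightly when probes of a gene are correlated. `k` counts
pooled p-values (probes × studies); the number of distinct contributing
studies is reported separately as `n_studies`, and genes measured in only
a subset of studies are retained with their own `k`.

The fixed-effects pool assumes one shared true effect per gene across
studies. Two pooling policies are available: by default every mapped probe
of every study contributes one `(f, v)` pair (probe-as-unit); with
`within_study_first = TRUE` a gene's probes are first pooled within each
study and the per-study summaries then pooled across studies. The two
coincide when each study has one probe per gene.

Taking the minimum of the two directional Fisher p-values introduces a
slight anti-conservative bias; it is deliberately left uncorrected because
the meta p-value is used for *ranking*, and the BH adjustment is applied
to the minima, after the minimum is taken.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `var_floor` | 1e-8 | log2² | keeps inverse-variance weights finite on constant probes |
| `p_clip` | 1e-300 | — | keeps `ln p` and `−log10 p` finite |
| `alpha` | 0.01 | — | conventional reporting cutoff for the run log |
| `within_study_first` | `FALSE` | — | probe-as-unit pooling is the symmetric default |
| log base | 2 | — | the transcriptomics convention; the base cancels in weights |

Welch (unequal-variance) t-tests are used rather than pooled-variance
tests: the groups being compared are clinical classes with no reason to
share a variance, and Welch is the robust two-group default. Quantile
normalization (per study, never across studies — studies touch each other
only through statistics) uses the per-rank-means construction with ties
receiving the mean of the rank means they span.

## The synthetic data generator

`sim_config()` / `simulate_studies()` emulate the multi-study design the
analysis assumes, with ground truth for every planted effect:

* five studies by default, with case/control sizes 7/27, 3/6, 18/14,
  7/10, 18/8 — the sample layout of a published five-study
  transplant-rejection compendium (two kidney, two lung, one heart);
* expression simulated **directly on the log2 scale** as Gaussian:
  gene baseline ~ N(8, 1.5), probe affinity offset ~ N(0, 0.25),
  residual noise sd 0.7 — typical magnitudes for log2 single-color
  array intensities;
* planted effects drawn once per gene (mean 1 log2 unit, spread 0.25,
  random sign by default) and shared across studies: a fixed-effects
  world matching the downstream model;
* per-study platform structure: 1–3 probes per gene, each gene missing
  from a platform with probability 0.1 (never from all platforms);
* one master seed; per-study substreams derived deterministically from
  (seed, study index), so identical configurations are bit-identical.

What the generator does **not** emulate: probe-level intensity physics,
spatial artifacts, batch effects, between-study heterogeneity
(random-effects worlds), or heavy-tailed/noisily-dependent real
distributions. Passing tests therefore demonstrate correctness of the
statistical machinery under its own assumptions, not performance on real
GEO data.

## Numerical choices and degenerate inputs

* p-values are clipped to `[1e-300, 1]` before any logarithm;
* a probe whose two groups are constant and equal is a perfect null
  observation (`p_up = p_down = 0.5`, `f = 0`); constant groups with
  unequal means give a degenerate extreme tail, clipped;
* the fold-change variance is floored at `var_floor`;
* probes with fewer than two finite values in either group are dropped
  with a message, never imputed;
* results are sorted by `gene_id` and ranking ties break by `gene_id`,
  so all outputs are byte-identical across reruns;
* the ROC universe is the set of ranked (i.e. measured) genes; signature
  members outside it are dropped with a message, since an unmeasured gene
  cannot be prioritized.

## Design decisions that were genuinely open

* **Fisher statistic form.** The log form `−2 Σ ln p` against χ²(2k) is
  the only form consistent with the χ² reference distribution; it is used
  throughout.
* **Effect pooling unit.** Published descriptions of probe pooling cover
  the p-value route explicitly; for the effect route both defensible
  policies are implemented (probe-as-unit default, `within_study_first`
  option).
* **Single-study baselines.** Single-study rankings reduce a gene's
  probes by within-study Fisher combination per direction and rank by the
  directional minimum — the closest single-study analogue of the meta
  p-value route.
* **alpha domain.** `null_calibration()` accepts `alpha` in `(0, 1]`; at
  `alpha = 1` both fractions saturate at 1.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which the binomial/Monte-Carlo error bands are informative: null
calibration at 5,000 genes (99% binomial band ≈ [0.65%, 1.40%] around the
1% nominal level), Fisher-vs-Monte-Carlo agreement at 2×10⁵ null draws,
fixed-effects recovery at 500 replicate gene-level combinations, and the
ranking comparison (meta fold-change versus meta p and versus every
single-study baseline) over 20 simulation seeds at 400 genes with 10% of
genes planted at exactly 1 log2 unit inside a designated signature.

## Known limitations

* The fixed-effects standard error `sqrt(1/Σ ŵ)` uses weights built from
  *sample* variances. At very small group sizes (the 3/6 study) `1/v̂` is
  biased upward (roughly `df/(df−2)`), so the reported SE understates the
  true sampling SD of `meta_fc` — by about 15–20% under the default
  five-study design. The point estimate remains unbiased (sample means
  and variances are independent under normality); rankings by `|meta_fc|`
  are unaffected, but per-gene confidence intervals built from
  `meta_fc_se` would be anti-conservative.
* Welch p-values at tiny group sizes are approximate; the Fisher
  combination inherits (and slightly amplifies) any miscalibration,
  though the null fraction below 0.01 stays inside its binomial band
  under the default design.
* Fisher's method treats a gene's probes as independent; correlated
  probes inflate `k`.
* No random-effects model, heterogeneity statistics or Storey q-values
  are provided; these are out of scope by design.
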