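---
title: "Stochastic epigenetic mutations, mutation load, and epigenetic aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic epigenetic mutations, mutation load, and epigenetic aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semload)
```

## The model

DNA methylation at a CpG is summarised by a beta value in [0, 1], the
fraction of methylated cells at that site. Across a cohort, most CpGs have
a tight, unimodal beta distribution; a failing epigenetic maintenance
system shows up as rare, person-specific excursions far outside that
distribution. `semload` operationalises this as an interquartile-range
fence rule: with per-probe quartiles Q1 and Q3 estimated across all
samples of the cohort and IQR = Q3 - Q1, sample i carries a stochastic
epigenetic mutation (SEM) at probe j when

\[
\beta_{ij} < Q1_j - k \cdot IQR_j
\quad\text{or}\quad
\beta_{ij} > Q3_j + k \cdot IQR_j,
\]

hypo- and hypermethylated respectively. The inequalities are strict: a
value exactly on a fence is not a mutation, and a constant probe (IQR = 0,
fences collapsed onto the constant) can never produce a call. The fence
multiplier k defaults to 3; k = 2 ("loose") and k = 4 ("stringent") exist
for sensitivity analysis, and calls are nested by construction:
calls(k = 4) ⊆ calls(k = 3) ⊆ calls(k = 2).

The per-person epigenetic mutation load (EML) is the SEM count, used on
the natural-log scale because loads are strongly right-skewed. Region-,
regulatory-feature-, island-context- and clock-specific loads count only
calls on probes carrying the corresponding annotation; a probe annotated
to several gene-region groups increments each of them once, so region
loads deliberately do not partition the total (directions do).

Two companion measures probe the same biology from different angles.
Methylome Shannon entropy,

\[
H = \frac{1}{N \log_2(1/2)} \sum_{j=1}^{N}
  \big[\beta_j \log_2 \beta_j + (1-\beta_j)\log_2(1-\beta_j)\big],
\]

with \(0 \log 0 = 0\), is 1 when every site is half-methylated and 0 when
the methylome is fully polarized: SEMs capture rare extreme excursions,
entropy captures a diffuse drift of beta values toward 50%. Epigenetic age
acceleration is the residual of DNAm age — a linear clock
\(\mathrm{intercept} + \sum_j w_j \beta_j\) over a CpG subset — regressed
on chronological age; by construction it has mean zero and exactly zero
correlation with chronological age, so it isolates "older than expected"
from "old".

## The association layer

Within a cohort, the outcome (log EML or entropy) is first residualized by
ordinary least squares on confounders — age, sex, race/ethnicity and five
estimated blood-cell fractions — and the residuals are correlated with
each target by biweight midcorrelation (bicor), a median/MAD-based
correlation with Tukey biweights \(w = (1-u^2)^2\,\mathbf 1(|u|<1)\),
\(u = (x - \mathrm{med})/(9\,\mathrm{mad})\), robust to exactly the kind of
outlying observations SEM analysis traffics in. The raw MAD (no 1.4826
consistency factor) is used, matching the definition the field's reference
implementation adopts. Only the outcome is residualized; targets (age,
accelerations, cell fractions) enter untouched. When a target is itself
one of the covariates (age, a cell fraction), it is excluded from its own
residualization — regressing age out of the outcome and then correlating
with age would be self-defeating — as is the stratifying factor in
sex-stratified runs. Two-sided p-values use the Student-t transform
\(t = r\sqrt{(n-2)/(1-r^2)}\) with n − 2 degrees of freedom.

Cohorts are analysed separately and pooled with a Stouffer-style
combination: the meta correlation is the sample-size-weighted mean of
Fisher-z transforms, \(\sum n_i \operatorname{atanh}(r_i) / \sum n_i\),
reported on the z scale. For the weak correlations this method targets,
z and r differ only in the third decimal, and the z-scale report is what
reproduces published three-decimal meta correlations exactly in our
validation suite; `backtransform = TRUE` applies tanh for users who want a
strict correlation scale. The meta p combines signed normal deviates of
the per-cohort two-sided p-values with \(\sqrt{n_i}\) weights. Weighting
by \(n_i\) instead of \(n_i - 3\) in the meta r is immaterial at three
decimals; \(n_i\) is the default.

Per-participant enrichment uses the upper tail of the hypergeometric
distribution: with N the probe universe (all probes surviving filtering,
not just annotated ones — fences and draws are defined on the analysis
matrix), K the probe-set size, n the participant's SEM count and k the
overlap, \(p = P(X \ge k)\). The test is one-sided by design: the
question is over-representation. The significance indicator uses a
nominal α = 0.05 with no per-participant multiplicity correction, because
prevalence across participants is interpreted descriptively. The
follow-up regression per probe set,
\(\mathrm{AgeAccel}_i = \beta_0 + \beta_1\,\mathrm{Enrich}_{ij} +
\beta_2 \log(\mathrm{EML}_i) + \varepsilon_i\), asks whether enrichment in
a set predicts faster aging beyond total mutational burden.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 3 | fence multiplier, IQR units; 2 = loose, 4 = stringent |
| `p_threshold`, `frac_threshold` | 0.05, 0.05 | detection-p filter: remove probes failing p > 0.05 in ≥ 5% of samples |
| `min_beads` | 3 | bead-count filter threshold |
| `min_participants` | 10 | recurrent-SEM carrier threshold (strict >) |
| `alpha` | 0.05 | per-participant enrichment significance |
| `missing_policy` | `"error"` | clock probes absent/missing: error or mean-impute (> 20% absent always errors) |
| `pseudocount` | unset | only if set, log(EML + pseudocount) for zero loads |

Zero-count samples get a missing log load rather than a fabricated
pseudocount: real loads are in the thousands, so a zero is a signal about
the data (tiny probe universe, broken sample), not a value to smooth over.

## Numerical choices

- **Quantiles.** Linear interpolation at position p(n−1)
  (`stats::quantile` type 7). Call counts are sensitive to the quantile
  rule, so fences are computed by one exact, tested routine
  (a partial-sort implementation cross-checked against `stats::quantile`
  in the tests). Missing betas are excluded per probe; probes with fewer
  than 4 non-missing values are flagged unusable and never called.
- **No minimum-IQR floor.** Probes with tiny IQR have tight fences and
  call easily; a floor would silently redefine the measure. The strict
  inequality already protects the degenerate IQR = 0 case.
- **Fences include the evaluated sample.** Quartiles are population
  estimates over all samples; no leave-one-out variant is attempted.
- **Entropy guard.** Betas strictly inside (0, 1) are clipped to
  [1e-12, 1 − 1e-12] before logs; exact 0/1 values take the 0·log 0 = 0
  convention first, so the guard never changes a well-defined term.
- **bicor degeneracy.** A vector whose MAD is zero falls back to
  mean-centering with unit weights (Pearson-style) with a warning; a zero
  weighted sum of squares yields a missing correlation with a diagnostic.
- **Meta p under extreme inputs.** Per-cohort p-values are floored at the
  smallest positive double before the normal quantile, keeping the
  combined Z finite.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` draws per-probe baseline betas by island context
(island probes mostly unmethylated, Beta(2, 18); open-sea probes mostly
methylated, Beta(18, 2); shore/shelf intermediate), then per-cell values
from a Beta distribution around each baseline (precision 100). Expected
SEM counts follow
\(\lambda_i = \exp(\alpha + \gamma_{age}\,\mathrm{age}_i +
\gamma_{acc}\,\mathrm{acc}_i)\) with \(\alpha\) solved so that a mid-range
age with zero acceleration expects `mean_eml` mutations — by default 0.5%
of probes, the per-probe rate cohort arrays show, and \(\gamma_{age}\)
doubling the load across the age range. The latent acceleration is
Normal(0, 5 years). Counts are Poisson; hypermethylated outliers land
preferentially in islands (where low baselines leave headroom above the
upper fence) and hypomethylated ones in open sea, mirroring the direction
asymmetry real data show. Injected values are placed beyond the k = 3
fence by a margin of `delta` = 0.5 IQRs and verified against fences
recomputed *after* injection — injection shifts the quantiles, and
placement against pre-injection fences under-calls at small n; an
injection whose target would leave [0, 1] is re-placed on another feasible
probe. Thirty clock CpGs encode DNAm age = age + acc + Normal(0, 2) years
exactly up to a small per-cell beta noise, so `apply_linear_clock()`
recovers the generator's DNAm age to a few tenths of a year. Metadata
(sex, ethnicity, batch labels, bisulfite-control intensities) carry no
planted effect, and the five reported cell fractions are a Dirichlet
subset of a larger composition so they remain jointly usable as
regression covariates.

The generator deliberately omits probe-probe co-methylation structure,
array-level technical artifacts (dye bias, batch-correlated intensity
drift) and any nonlinearity in the clock. Passing tests therefore
demonstrate that the pipeline's statistics recover the effects they are
defined to measure under the model's own assumptions — not that those
assumptions hold in any particular real cohort.

## Problem sizes used in the validation suite

The test suite exercises the full pipeline at desk scale: the
parameter-recovery study runs 100 seeds of four cohorts with 500 samples
and 5,000 probes each, checking that the meta correlation of log EML with
age and with acceleration is positive at meta p < 0.01 in at least 95% of
seeds and that every injected mutation is recovered (sensitivity ≥ 0.99
per seed, and in practice exactly 1 by construction). Null calibration
uses 200 replicates of two 150-sample cohorts with all effects set to
zero, checking by Kolmogorov-Smirnov that meta p and batch-ANOVA p are
uniform. Array-scale generation (hundreds of thousands of probes) works
through the same code path; these sizes were chosen as the smallest at
which the stochastic criteria are stable.

## Design decisions on open points

- **Published clock coefficients are not bundled** (licensing and array
  versioning); the module applies any user-supplied linear clock and also
  accepts precomputed DNAm-age columns, which is how real analyses mirror
  the online calculators. "Intrinsic" acceleration is obtained by passing
  cell fractions as additional covariates to the residualization step, not
  by a separate code path.
- **Exclusion lists are user-supplied files**, not bundled: the lists are
  array-version-specific and bundling one version would silently pin it.
  A probe removed by several rules is counted once in the unique removal
  total while the report attributes it to every rule, so both the
  per-rule and de-duplicated views are available.
- **Probes with missing betas are retained** through filtering; fence
  computation simply ignores missing values per probe. Dropping them
  would shrink the probe universe as a side effect of missingness.
- **Entropy is computed on the filtered probe set** by default (the same
  universe the fences see); callers can pass any matrix.
- **Acceleration residuals are fit per cohort**, matching the
  cohort-by-cohort analysis model; pooling before residualization would
  let cohort age composition leak into the acceleration measure.
- **Pathway draws are probe-level** after expanding gene sets through the
  manifest's probe-gene map; gene-level draws would discard the fact that
  genes carry very different probe counts.

## Known limitations

Within-person longitudinal SEM accumulation is out of scope (the measures
are cross-sectional); family or repeated-measures correlation structure is
not modelled in the association layer; and detection p-values, bead
counts, normalized betas and cell fractions are inputs, not computed here
— upstream array preprocessing belongs to the tools that own it.
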