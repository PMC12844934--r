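---
title: "soil2leaf: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soil2leaf: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soil2leaf)
```

## The analysis problem

A monitoring survey of orchard sites pairs a composite soil sample per
site with leaves from several trees per site. From those paired
measurements the package computes, in order: descriptive site summaries,
per-tree bioaccumulation factors, inferential comparisons between sites,
multivariate structure (PCA, Ward clustering, stepwise LDA), a
soil-to-leaf predictive model (PLSR), and a probabilistic exceedance
assessment against food-safety thresholds. The motivating design is 20
sites × 4 trees with Cd, Pb, Ni, Zn, Cu, Fe and Mn in both compartments.

## Data model

Everything flows through one long-format table — one row per
(site, tree, compartment, analyte) with value and units. Keys must be
unique, units consistent within an analyte–compartment pair, values
non-negative and finite; missing data are explicit `NA`s. CSV export
writes 17 significant digits so a write/read round-trip is bit-exact.

Site summaries report the mean and SEM over trees, with the sample
standard deviation (divisor n−1); for a single tree the SEM is undefined
and reported `NA` rather than 0. Grand summaries are unweighted means of
site means — for a balanced design this equals the tree-level mean, and
only site means are published for the motivating survey, so that is the
level the package aggregates at. Ties for the extreme site are broken
lexicographically by site id purely for determinism.

### The packaged fixtures

The survey's published site-summary tables ship as plain CSVs,
transcribed cell-for-cell (including one SEM cell that prints larger
than its mean, almost certainly a typo — kept as printed, excluded from
assertions). A handful of "overall mean" values quoted in the survey's
text do not equal the mean of its own printed site means (they were
presumably computed on unpublished tree-level data); the package sides
with the tables, and nothing is asserted against the conflicting text
values. Presentation rounding is half-away-from-zero
(`round_half_up()`), applied only when rendering.

## Pigments

Chlorophyll a and b follow the linear two-wavelength equations for
methanol extracts (coefficients 16.82/−9.28 and 36.92/−16.54 on A665.2
and A652.4, µg/g FW). Negative computed pigments are physically
implausible readings: they are returned and flagged, never clamped,
because the equations are linear and clamping would hide bad readings.
The a/b ratio is undefined (`NA`) when chlorophyll b ≤ 0. The inverse
map (`generate_absorbance_readings()`) solves the 2×2 system; because
the inverse matrix has positive entries, every strictly positive pigment
pair yields positive absorbances.

SPAD values are treated as direct field measurements, never derived from
pigments.

## Bioaccumulation

`BAF = C_leaf / C_soil` per tree, dimensionless, computed on matched
units without moisture correction (both compartments are reported on a
dry-mass basis). Default pairing is site-level soil (each orchard's
composite soil sample serves all its trees), matching how such surveys
sample; tree-level soil is supported for synthetic studies. A BAF
strictly above 1 classifies the element as actively accumulated.

## Inference

**Welch ANOVA.** Group weights `w_i = n_i/s_i²`; the statistic is the
weighted between-group mean square over `1 + 2(k−2)/(k²−1)·Λ` with
`Λ = Σ(1−w_i/W)²/(n_i−1)`, and `df2 = (k²−1)/(3Λ)`. Any zero-variance
group makes the statistic undefined and is an error, not a silent drop.
The survey's significance rows are read as Welch ANOVA per analyte
across sites — the only dimension with replication (4 trees per site).
Since tree-level data are unpublished, the packaged fixtures carry the
printed star codes as metadata; tests assert the star-code mapping
(strict boundaries: p = 0.05 is `ns`), not the printed stars.

**Games–Howell.** For each pair,
`t = |x̄_i − x̄_j| / sqrt(s_i²/n_i + s_j²/n_j)` with Welch–Satterthwaite
degrees of freedom, and the p-value from the studentized range at
`q = t√2` with k groups. Tail probabilities come from base R's
`ptukey`, which is always available in the target environment; tests
nonetheless keep two independent cross-checks (the exact k = 2
reduction to the Welch t-test, and a direct Monte Carlo simulation of
the studentized range), so the implementation is never validated only
against itself. `ptukey`'s numerical accuracy is about 1e−5 in relative
terms, which is the tolerance those equivalence tests use. No
multiplicity correction is applied beyond the procedure's built-in
family-wise control.

**Correlations.** Pearson by default (Spearman is Pearson on midranks,
available via `method`), pairwise-complete deletion, two-tailed p from
`t = r·sqrt((n−2)/(1−r²))`. Strength labels: |r| < 0.2 none, 0.2–0.4
weak, 0.4–0.6 moderate, > 0.6 strong. Constant variables yield `NA`
correlations rather than errors.

## Multivariate stages

**PCA.** Eigendecomposition of the covariance matrix of (by default)
z-scored data. The survey's methods specify a covariance-matrix PCA,
but its variables span four orders of magnitude (Fe in hundreds of
mg/kg next to percent-scale nutrients); raw covariance would be
dominated by Fe alone, which cannot produce the biologically mixed
leading axes the survey reports. Standardization is therefore the
default, with raw covariance retained behind `standardize = FALSE`.
Loadings are eigenvectors scaled by √eigenvalue, each column oriented
so its largest-magnitude entry is positive (a determinism convention,
not a statistical choice). Two components are retained by default.

**Varimax.** Classical iterative pairwise-angle algorithm, Kaiser row
normalization by default, relative tolerance 1e−6, at most 1000 sweeps.
The rotation matrix is orthogonal to 1e−9 and row communalities are
invariant. Note that Kaiser normalization maximizes the criterion of
the row-normalized matrix; the raw-criterion optimum (what a grid
search over angles finds) is attained with `normalize = FALSE`, and
that is the configuration the grid-search oracle test uses. After
rotation, explained variance is reported as rotated sums of squared
loadings; scores are regression scores.

**Ward HCA.** Lance–Williams agglomeration on squared Euclidean
distances with heights reported on the distance scale (the "ward.D2"
convention, verified against both a naive O(n³) recomputation and
`stats::hclust`). Ward's criterion is reducible, so heights are
non-decreasing; ties are broken by smallest pair index for
reproducibility. The default cut is k = 4 clusters, the structure the
motivating survey describes.

**Stepwise LDA.** Forward-only selection (no removal step — only an
entry criterion is specified in the motivating analysis): at each step
the candidate minimizing Wilks' Λ enters if its partial F-to-enter has
p < 0.05. Axes are eigenvectors of `W⁻¹B` scaled to identity pooled
within-group score covariance; reported loadings are pooled
within-group correlations between variables and scores (structure
coefficients). Whether the survey fit LDA on trees or sites is
ambiguous; the pipeline fits it on sites labeled by their HCA cluster,
which is the reading consistent with "validating the clusters".

## PLSR

NIPALS with both blocks autoscaled, convergence tolerance 1e−10, at
most 500 iterations per component, deflation of X and Y; coefficients
`W(PᵀW)⁻¹Cᵀ` back-transformed to original units. NIPALS was chosen over
SIMPLS for transparency and testability (the motivating analysis names
only a software product, not an algorithm). Two latent components by
default. The pipeline's default predictors are soil Cd, Pb, Zn and Ni;
default responses are leaf N, P, K, Ca, Mg, Cd, Pb, SPAD and
chlorophyll a. Reported R² is in-sample calibration R² (what the survey
reports); no cross-validation is performed because the component count
is fixed, not selected.

## Monte Carlo exceedance

A log-normal is fitted by `μ_ln` = mean of logs and `σ_ln` = SD of logs
with divisor n−1 (ML location, bias-adjusted scale). Simulation draws
`exp(N(μ_ln, σ_ln))` with R's Mersenne-Twister and an explicit recorded
seed; summaries are the mean, SD, 5/25/50/75/95th percentiles and
`P(draw > limit)` per threshold. The closed form
`1 − Φ((ln limit − μ_ln)/σ_ln)` is exposed as the analytic oracle; a
degenerate fit (σ_ln = 0) yields a step function. Each variable is
simulated independently — no copula — matching the per-variable
description of the motivating analysis.

Defaults: 10,000 iterations; fits on site means (the only level
published; tree-level mode exists for synthetic or complete data);
thresholds for leaf tissue Cd 0.1 and Pb 0.3 mg/kg DW ("strict" set),
with Cd 0.2 / Pb 2.0 mg/kg DW available as the "general" set. The
default simulated battery is BAF-Cd, BAF-Pb, leaf Cd, leaf Pb, SPAD and
chlorophyll a.

## The synthetic generator

`generate_orchard_dataset()` draws from the world the analysis assumes:

- soil element concentration per site ~ log-normal(geometric mean,
  geometric SD) — multiplicative noise keeps concentrations positive
  and matches the distributional family used for risk simulation;
- leaf metal per tree = true BAF × soil × log-normal tree noise;
- macronutrients ~ normal site effect + normal tree residual, truncated
  at zero;
- SPAD and chlorophyll a = baseline + linear (negative) response to
  leaf Cd and Pb + noise, truncated at zero; chlorophyll b follows
  chlorophyll a through a target a/b ratio.

Defaults are calibrated once to the published summaries and then left
alone: true BAFs are the published element grand means (Cd 3.52,
Pb 0.021, Ni 0.09, Zn 0.51, Cu 0.52, Fe 36.26, Mn 11.71); soil
geometric means are back-solved as published leaf grand mean ÷ BAF
grand mean; nutrient means are the table-derived grand means; site GSD
1.4 and tree-noise GSD 1.15 reproduce the order of between-site and
within-site spread visible in the published SEMs; stress slopes
(SPAD: −60 per mg/kg Cd, −8 per mg/kg Pb; chlorophyll a: −100, −10
from baselines 58 and 75) span the published SPAD and pigment ranges
across the published leaf Cd/Pb ranges.

For cluster-recovery testing the generator can plant group structure:
`cluster_profiles` multiplies soil geometric means per cluster, with
sites assigned round-robin. The test world uses four contamination
signatures (baseline; Cd/Pb/Ni-enriched; Fe/Mn/Zn-enriched; Cu/Zn-rich
with depressed Cd/Pb) and a within-cluster site GSD of 1.1 — sites in
a cluster share a contamination source, so their spread is tighter than
the survey-wide default.

What a green synthetic test establishes: that the estimators recover
the parameters of *this* generative model (unbiasedness up to the known
log-normal mean factor `exp(log(gsd)²/2)`, correct coupling signs,
cluster recovery under planted separation). What it does not establish:
behaviour under spatial autocorrelation, temporal drift, censored
detection limits, or correlated multi-element contamination — none of
which the generator emulates.

## Reproducibility

One global pipeline seed fans out to per-stage seeds through a fixed
string-hash (`derive_seed`), each kept below 2³¹. Manifests record a
canonical config dump and the md5 of every CSV/JSON artifact; reruns
with the same config and seed are byte-identical. PDF figures embed
creation timestamps and are therefore excluded from the hashed set.

## Known limitations

- The motivating survey's multivariate outputs (PCA variance shares,
  specific soil–leaf correlations, PLSR R² values, the simulated BAF-Cd
  95th percentile) depend on unpublished tree-level and soil appendix
  data and cannot be recomputed from the published tables; the package
  reproduces the procedures and validates them against independent
  oracles and synthetic recovery instead.
- Site-mean log-normal fits are the default for risk simulation because
  site means are what is published; fitting on tree-level values (when
  available) widens the simulated distribution and is the more
  conservative choice for risk.
- No mixed models, FDR control, factor-analysis estimation, k-means,
  cross-validated LDA error rates, hazard-quotient dose modeling, or
  root-to-fruit translocation modeling.
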