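---
title: "Pan-epigenetic aging clocks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-epigenetic aging clocks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`panepiclock` implements a cross-species, cross-layer analysis of
epigenetic aging. Its premise is that age-related change in gene-body
chromatin signal is coordinated across epigenetic layers — several
histone modifications and DNA methylation — well enough that (a) the
most age-associated genes largely coincide between layers and species,
and (b) a single regression model trained on profiles from all layers
can predict a donor's age from any one of them. This vignette documents
the models, the tunable parameters and the choices made where the
design was genuinely open.

## From raw profiles to a gene-level matrix

Histone-mark profiles arrive as narrowPeak peak calls, methylomes as
per-CpG tables (chrom, 0-based position, methylated fraction,
coverage). Both are reduced to one value per gene per profile:

* **ChIP-seq**: the arithmetic mean of the narrowPeak *score* (column 5)
  of all peaks overlapping the gene body by at least one base pair.
  Peaks are not length-weighted, strand is ignored, and a peak spanning
  two genes contributes to both means. Genes with no overlapping peak
  are assigned 0. Column 7 (`signalValue`) can be aggregated instead via
  `score_col = "signal"`.
* **WGBS**: the mean methylated fraction of the CpGs contained in the
  gene body (half-open coordinates: a CpG at the gene's end coordinate
  is outside). Genes without CpGs are assigned 0.

All internal coordinates are 0-based half-open; GTF/GFF3 input is
converted on read, and only autosomal genes are retained. Mouse gene
ids are mapped to their one-to-one human orthologs (mouse genes without
an ortholog are dropped), so every profile lives in a common human gene
coordinate system. Genes that are zero or absent in every sample of
some dataset-by-layer stratum are discarded; a gene absent from a
particular sample is recorded as missing, which is distinct from an
observed zero.

## Normalization and batch correction

Within each `{dataset x layer}` stratum, values are min–max normalized
to [0, 1] using the stratum-wide minimum and maximum (not per gene —
per-gene location and scale are removed by the inverse normal transform
that follows; methylation fractions are already natural in [0, 1]).
Applied values are clipped into [0, 1]; a constant stratum maps to 0.

Missing DNA-methylation values are imputed with the per-gene training
mean of their stratum. Missingness in histone strata is treated as an
error, because peak aggregation always produces an explicit value.

Batch correction is a per-dataset, per-gene **inverse normal transform
(INT)**: values are ranked across the dataset's samples (average ranks
for ties), ranks become percentiles `r / (n + 1)` — a convention that
avoids infinite quantiles at the extremes — and percentiles are mapped
through the standard normal quantile. The INT "parameter" is the table
of sorted training values. Held-out data are mapped to percentiles by
linear interpolation of the training empirical CDF, clipped to
`[1/(n+1), n/(n+1)]`, with values strictly outside the training range
pinned to the boundary percentiles. This fit/apply split is used inside
every cross-validation fold so that no information from held-out donors
reaches the fitted transforms; tests verify that applying the transform
to arbitrary test rows leaves the fitted parameters bit-identical.

## Age associations and cross-layer statistics

Within each `{species x layer}` stratum, each gene's harmonized signal
is Spearman-correlated with chronological age. Two-sided p-values use
the Student-t model `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
degrees of freedom; q-values are Benjamini–Hochberg within the stratum.
Constant gene columns are reported as rho = 0, p = 1 and flagged.

* **Top-k overlap**: genes are ranked by unsigned |rho| in two strata;
  the overlap of the two top-k sets is compared with the expectation
  `k^2 / G` for independent k-sets drawn from the shared universe of G
  genes. Fold enrichment is observed/expected. Significance is a
  two-sided exact binomial with success probability `k / G` over k
  trials (the expectation above is the binomial mean); a flag switches
  to the exact hypergeometric null, which models sampling without
  replacement. Ties at the k-th rank are broken by ascending gene id so
  results are reproducible.
* **Crosstalk**: for layers A and B, take A's k most positively and k
  most negatively age-associated genes (signed rho), extract B's rho
  over each set, and report the median difference with a two-sided
  Mann–Whitney U p-value, Bonferroni-corrected over the `choose(7, 2) =
  21` unordered layer pairs.
* **Direction gene sets**: genes "epigenetically repressed with age"
  are the intersection, within and then across species, of the top-k
  most positively age-associated genes under each repressive mark
  (H3K27me3, H3K9me3, DNAm) and the top-k most negatively associated
  under each activating mark (H3K27ac, H3K36me3, H3K4me1, H3K4me3);
  "activated" is the converse. Functional enrichment of these sets is a
  local one-sided hypergeometric test against user-supplied GMT
  libraries within the quantified-gene universe, keeping terms with at
  least two overlapping genes and BH-adjusted p < 0.05.

## The age representation

Chronological age is expressed as a fraction of the species' maximum
lifespan (human 120 years, mouse 4 years; the registry is extensible)
and transformed with the negative log–log map
`scaled = -log(-log(age / lifespan))` using natural logarithms (the
transform is only defined up to an affine rescaling under a change of
base; the natural log is fixed and documented). The transform is
strictly increasing, aligns equal relative ages across species, and
stretches both early development and late life relative to mid-life.
Its exact inverse, `lifespan * exp(-exp(-scaled))`, converts
predictions back to years. Ages at the domain boundary are clamped
inward by one day and flagged, since real sample sheets contain age-0
newborns.

## Clocks

The clock dataset excludes cell lines, sex-specific tissues and
placenta (a configurable list), tissues with fewer than 50 libraries,
and the sparse marks H3K36me3/H3K9me3; calorically restricted samples
are withheld from fitting but predicted afterwards by the average of
all fold models.

Cross-validation is 10-fold and donor-grouped: donors are binned into
quintiles of scaled age, ordered within quintile by profile count
(descending, with a seeded shuffle breaking ties), and assigned
greedily to the currently lightest fold, so every profile of a donor
shares one fold and age strata stay balanced. The greedy construction
is this package's choice; only the grouping and balance constraints are
inherent to the design.

Within each training fold: harmonization (imputation + INT) is fitted
on the fold's training rows; features are the genes whose Spearman
age-association exceeds |rho| > 0.2 in both species *with the same
sign* (computed on the profiles being trained on — for single-layer
clocks, only that layer's profiles; for the pan clock, all pooled
training profiles); and a gradient-boosted decision-tree regressor
(squared-error loss, 100 rounds, depth 6, learning rate 0.3 — the
reference library defaults, frozen as explicit contract values) is fit
on the selected features with lifespan-scaled age as the target. The
scaled value is used as the regression target because the age
representation above is the cross-species common scale; predictions
are reported in years through the exact inverse.

The **pan-epigenetic clock** is architecturally identical but trains a
single model over profiles from all five clock layers. The
**leave-one-layer-out** analysis retrains the pan clock five times
under 5-fold CV, each time without one layer, and evaluates both on the
left-out layer (each fold model predicts all of its samples; results
averaged) and on held-out samples of the training layers, reporting
percent change against the full pan clock under the same fold
assignment. The **scaling rate** of a layer is the slope of a
zero-intercept least-squares fit of held-out Spearman accuracy on
log10(training donors), over repeated subsampled training cohorts.

Evaluation first averages predictions per donor within the evaluated
group (e.g., over tissues within a layer), then Spearman-correlates
with actual age on the scaled basis — rank-identical to years within a
species and the only meaningful common scale when species are pooled.

## Residual analyses

A donor's residual in a layer is predicted minus actual age in years,
averaged over tissues; positive residuals mean the epigenome reads
older than the calendar age. Cross-layer synchronization is the
pairwise Spearman correlation of residuals over shared donors. Because
residuals of rank-based clocks retain a dependence on age itself, the
default correlates *age-adjusted* residuals — the residual of a linear
fit on the rank of chronological age — making each cell a partial
correlation controlling for age; age is the natural (and only
available) conditioning variable. Binned curves group donors by one
layer's residual rounded to the nearest year (±1-year half-width,
bins with fewer than two donors dropped). Caloric-restriction effects
are two-sided Mann–Whitney comparisons of residuals between diet
groups, reported in months for mice.

## The synthetic cohort generator

`simulate_cohort()` realizes, as raw on-disk files, the latent model

```
signal(d, g, l) = sign(l) * loading(g) * (scaled_age(d) + rate(d))
                  + shift(dataset(d), l) + noise
```

with per-gene loadings shared across layers (zero outside the
informative set), a per-donor aging-rate factor common to all of the
donor's layers, dataset-by-layer batch shifts, and a reduction of
effective relative age for calorically restricted mice. Latent values
become narrowPeak scores (`1000 * plogis(latent / 2)`, one
gene-spanning peak per gene, peaks under a floor omitted) or CpG
fractions (`plogis(latent / 2)`, ten CpGs per gene body sharing the
gene's fraction), so the readers' aggregation recovers the realized
value exactly and every rank-based statistic sees the latent structure
undistorted. Ages are drawn uniformly on a configurable band of
relative lifespan (default 5–90%) and converted to years per species.
One RNG is seeded per cohort for loadings, ages, batch shifts and CR
assignment, with per-sample and per-donor substreams derived by stable
hashing of ids, so enlarging a cohort never redraws existing samples.

Default conditions (the cohort used by the recovery tests): two
species, 200 donors each, the five clock layers, 2000 genes with 300
informative, two datasets per species, unit loading and noise scales
(noise matched to the informative-signal scale), aging-rate sd 0.1,
batch-shift sd 0.5, and a 10% caloric-restriction arm in mice with a
0.15 relative-lifespan offset.

**Layer signs.** The generator accepts an arbitrary per-layer sign map,
and `mark_direction_map()` encodes the empirically observed directions
(repressive marks, DNAm, H3K27ac and H3K4me3 one way; H3K4me1 and
H3K36me3 opposite). The *default* map, however, is +1 for every layer.
The reason is identifiability: with perfectly shared loadings, a layer
whose signs are strictly mirrored is feature-by-feature
indistinguishable from an aligned layer observed at a mirrored age, so
no covariate-free pooled regressor can predict it — whereas in real
data each layer retains enough layer-specific structure for the pan
clock to transfer across all layers. The aligned default encodes the
transferable component that the clock analyses probe; the mixed-sign
map is used where the opposing-direction structure itself is under
study (crosstalk, direction gene sets).

What the generator deliberately does *not* emulate: read-level noise,
peak-calling artifacts, chromatin-domain spatial correlation along the
genome, tissue-specific aging trajectories, and genes whose cross-layer
coupling deviates from the global sign map. Passing recovery tests
therefore demonstrates correctness of the pipeline's statistics and
leakage-safety of its training procedure on data satisfying the model
above — not clock accuracy on real consortium data.

## Numerical choices and degenerate inputs

* Spearman everywhere uses average ranks for ties; top-k ranking ties
  are broken by ascending gene id.
* Constant gene columns: association rho recorded as 0 with p = 1 and a
  flag; constant predictions evaluate to rho 0 with a flag; constant
  min–max strata map to 0.
* The Mann–Whitney U test is exact for small tie-free groups and a
  normal approximation with continuity correction otherwise.
* Groups with fewer than 4 donors are excluded from evaluation with a
  warning; layer pairs sharing fewer than 10 donors are an error in
  synchronization analysis.
* Empty feature selection aborts with advice to lower the threshold
  rather than silently training on nothing.

## Problem sizes used by the test-suite studies

Chosen as the smallest sizes at which the studied effects are stable:
the clock-recovery cohort uses the default conditions above (400
donors, 2000 genes); the noise-free recovery check uses 160 donors and
150 genes; the leave-one-layer-out study uses 160 donors and 800 genes
(the transfer property does not require the full gene count); null
calibrations use 500 independent pairs at G = 2000, k = 200; residual
synchronization uses 109 donors with five layers at an aging-rate to
noise ratio of 1; the caloric-restriction power study uses 160 control
and 40 CR mice with a 0.6-year planted offset against 0.4-year
prediction noise.

## Known limitations

Real multi-consortium data add protocol heterogeneity, uneven layer
coverage per donor, and non-monotone age trajectories that this package
does not model; its published-scale headline numbers are therefore not
reproduction targets for the synthetic studies. The ortholog map is
strictly one-to-one; multi-mapping orthologs are out of scope. The
binomial overlap null treats the two top-k sets as independent draws
with replacement — the hypergeometric switch is provided where the
exactness matters.
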