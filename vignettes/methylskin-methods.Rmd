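---
title: "Methods: bead-level methylation analysis in methylskin"
author: "methylskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-level methylation analysis in methylskin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`methylskin` implements a complete analysis chain for two-channel
bead-array DNA methylation data of the 27k CpG promoter-array generation,
motivated by studies of human skin aging and chronic sun exposure. The
pipeline runs from raw per-bead fluorescence intensities to differential
methylation calls, global shift statistics, and orthogonal validation by
deep bisulfite amplicon sequencing. Because raw bead-level data of this
array generation are rarely redistributable, the package ships a
synthetic-data generator that reproduces the statistical structure such a
study assumes, so every stage is testable end to end.

## The measurement model

Each CpG probe is interrogated by two bead populations: a methylated
allele read in the green channel and an unmethylated allele read in the
red channel. For sample $j$ and probe $i$ the methylation level is
summarized as a beta value

$$\beta_{ij} = \frac{M_{ij}}{M_{ij} + U_{ij} + \alpha},$$

where $M$ and $U$ are the mean intensities over the probe's beads
(negatives floored at zero) and $\alpha \ge 0$ is a regularization offset.
The default $\alpha = 100$ is the platform convention for this array
generation: it shrinks low-intensity, high-variance probes towards zero at
the cost of a mild multiplicative compression (with total intensity
$T \approx 2000$ in simulated data, $\hat\beta \approx \beta\,T/(T+\alpha)
\approx 0.95\,\beta$). `compute_beta(..., offset = 0)` disables it. A
degenerate total of zero returns $\beta = 0$ rather than `NaN`.

## Quantile normalization

The green and red channels have genuinely different intensity
distributions, so each channel is quantile-normalized separately across
samples at the bead level, probe and negative-control beads together.
After normalization every sample's sorted intensity vector equals the
rank-wise cross-sample mean (exact to floating tolerance); within-sample
rank order is untouched, so rank-based statistics (the detection test
below) are invariant to this step. Ties map to the reference quantile at
their mid-rank; samples with unequal bead counts are mapped through
linear interpolation of the mean quantile function, which reduces to the
classical equal-count algorithm when counts agree.

Normalization scope is the whole manifest by default. When the cohort
mixes genuinely different methylomes (dermis vs epidermis, male vs
female X dosage), joint normalization transfers a small amount of
distributional difference between groups — in simulations this moves the
island-unmethylated fraction of an epidermis profile by one to two
percentage points. Staged analyses (e.g. a pilot subset) can therefore be
preprocessed as their own experiment by passing the corresponding
manifest subset, which is what `scripts/acceptance.R` does for the
suction-blister pilot set.

## Detection P-values

A probe is "detected" in a sample if its beads are brighter than the
sample's negative-control beads. Per channel this is a one-sided
Mann-Whitney test of the probe's beads against the channel's negative
pool. The two per-channel P-values are Benjamini-Hochberg adjusted
across all probes within the channel — two variables are measured per
probe, and genome-wide adjustment within a channel is the only scope
that yields an interpretable FDR — and the per-probe detection P-value
is the minimum of the two adjusted values. Probes with detection
P > 0.05 in any analyzed sample are excluded; with realistic signal
levels this removes well under 0.1% of probes.

The one-sided alternative is deliberate: signal detection is inherently
directional, and the choice only matters for probes comparable to
background. Calibration is a marginal property: with probe beads drawn
from the negative distribution and a fresh negative pool per replicate,
detection P-values are uniform (Kolmogorov-Smirnov distance below 0.05
at 10,000 replicates). Conditional on a single shared pool of $n$
negatives, all P-values shift coherently by $O(1/\sqrt{n})$; this is a
property of every rank test against a finite reference, not an
implementation artifact.

## Exact rank-sum machinery

All Mann-Whitney/Wilcoxon tests run on the U statistic computed from
mid-ranks, with three evaluation strategies chosen per input:

* tie-free inputs of moderate size use the closed-form exact null
  distribution (`pwilcox`, cached per group-size pair);
* tied inputs with both groups small are evaluated by full enumeration
  of all $\binom{m+n}{m}$ group assignments;
* everything else uses a normal approximation with mid-rank tie
  correction and continuity correction.

Two-sided P-values use the symmetric-deviation convention
$P(|U - mn/2| \ge |u_{obs} - mn/2|)$, which equals the doubled smaller
tail for the symmetric tie-free null. Group comparisons with up to 10
samples per side — the regime of this study design — are always exact.
The bead-level detection test uses a batched implementation
(`findInterval` against the sorted negative pool) that routes any set
tying with the pool, or internally (e.g. floored zero intensities),
through the general scalar test.

Exactness has a visible consequence: with 5 samples per group the
smallest attainable two-sided P-value is $2/\binom{10}{5} \approx
0.0079$, and the attainable null mass below 0.05 is $2 P(U \le 2) =
8/252 \approx 0.032$. Null rejection rates must be compared against the
attainable mass, not the nominal level, and no probe in a 5v5 comparison
can survive a Benjamini-Hochberg threshold of 0.01 at array scale. The
P(BH)-filtered analyses in this package's worked examples therefore use
the punch-biopsy comparisons, where each age group contributes two
samples per donor (10 vs 10) and the minimum adjusted P-value with
roughly 100 true signals is about 0.003.

## Differential methylation calling

For a comparison of groups $A$ and $B$, the effect size is
$\Delta\beta_i = \bar\beta_{iA} - \bar\beta_{iB}$ (missing values
excluded pairwise; probes with fewer than two values per group are
dropped and reported). Significance comes from the two-sided exact
rank-sum test on per-sample beta values — not bead-level data, which
would overstate the effective sample size. Raw P-values are BH-adjusted
across all retained probes within the comparison; separate comparisons
(age, sun, tissue, sex) are adjusted independently, mirroring
per-comparison reporting.

Markers are called hypermethylated when $\Delta\beta \ge 0.2$ and
hypomethylated when $\Delta\beta \le -0.2$; with `require_p = TRUE` the
call additionally demands $P_{BH} < 0.01$ ("substantial" markers). The
delta-only rule (`require_p = FALSE`) reproduces threshold-only marker
counts. The 0.2 threshold for "variable" markers in the sex comparison
is configurable; 0.2 is the package default by analogy with the other
comparisons. Calls are stratified by CpG-island association and
chromosome (X localization for sex-variable markers), and marker sets
from independent sample sets are intersected with
`overlap_markers()`.

## RS curves and the global shift test

To visualize a global methylation trend, probes are sorted by
$|\Delta\beta|$ in decreasing order (ties broken lexicographically by
probe id, making the curve deterministic) and the ratio-over-sum curve
is accumulated:

$$y_N = \frac{\sum_{i \le N} \Delta\beta_i}
             {\sum_{i \le N} (\beta_{iA} + \beta_{iB})},
  \qquad x_N = N/M.$$

This cumulative reconstruction is this package's documented reading of
the ratio-over-sum construction (a cumulative relative of the MA-plot);
it is isolated in `rs_curve()` so an alternative formula can be swapped
without touching callers. Two properties anchor it: the final point
$y_M$ is the global shift ratio (total delta over total beta sum),
invariant to the sort order, and $|y_N| \le 1$ whenever all betas are in
$[0,1]$.

The significance of a global shift is assessed on the significant,
low-variance probes: those with $P_{BH} < 0.01$ and pooled within-group
standard deviation of beta below 0.1 (the package uses the pooled
within-group sd; a per-group variant only tightens the filter). Their
$\Delta\beta$ values are compared by Welch's t-test against a seeded
sample of 10,000 draws from a reference Gaussian of randomly generated
methylation differences, $\mathcal{N}(0, 0.1)$. The null sample is
standardized to exactly the nominal moments, which removes Monte Carlo
error in the reference and makes the test antisymmetric under
$\Delta\beta \to -\Delta\beta$; a one-sample variant against $\mu = 0$
is available (`null_sample = FALSE`). Whether the null sd of 0.1 was
matched to data or fixed a priori cannot be recovered from the source
analysis; it is a configurable parameter here. Fewer than three
surviving probes is an error naming the failed filter, not a silent
degenerate test.

## The synthetic study generator

The generator's defaults are the study conditions the package emulates:
a 27,578-probe promoter-biased array (73% CpG-island probes, 4% on
chromosome X) measured over a 50-sample design — 10 male suction-blister
epidermis samples (5 young, 5 old; sun-protected) and 10 female
punch-biopsy donors (5 young, 5 old) each contributing epidermis and
dermis from a sun-exposed and a sun-protected site.

Baseline beta values are drawn per probe from a three-component mixture:
Beta(1, 20) (unmethylated), Beta(20, 1) (methylated) and
Uniform(0.2, 0.8) (intermediate). Because the Beta components leak ~1.2%
of their mass past the 0.2/0.8 boundaries, the component weights are
calibrated by inverting the tail masses so that the realized fractions
equal the targets exactly: 86% of island probes at $\beta \le 0.2$, 5%
at $\beta \ge 0.8$, and 29% of non-island probes methylated (the
unmethylated share outside islands, 55%, is not pinned by the emulated
study and is a fixed package choice). The baseline represents the
epidermis state.

Planted effects occupy disjoint, autosomal probe subsets:

* **age**: 0.4% of probes (110 at full scale) gain +0.3 in old samples;
  90% are drawn from island probes, matching the observed island
  enrichment of age-hypermethylated markers;
* **sun**: 0.05% (14 probes) lose 0.3 in sun-exposed samples;
* **tissue**: 6.4% split 58/42 into dermis-high (+0.3 in dermis) and
  epidermis-high (−0.3 in dermis), leaving epidermis columns at
  baseline;
* **sex**: every X probe gains +0.3 in female samples.

Hyper-effects are planted on probes with baseline headroom
($\beta \le 1-\delta$) and hypo-effects on probes with
$\beta \ge \delta$: hypermethylation of an already-methylated locus is
not biologically meaningful, and without the headroom rule clamping to
$[0,1]$ silently truncates about a tenth of planted effects below the
call threshold, making recovery metrics ambiguous. Effects are excluded
from chromosome X because the female shift already occupies those
probes and stacked effects would clamp.

Bead-level intensities follow the two-channel model: methylated-allele
beads have mean $T\beta$, unmethylated beads $T(1-\beta)$, with
$T = 2000$ arbitrary fluorescence units, 15 beads per allele (about one
million beads per 27k-probe sample), and multiplicative lognormal noise
at a coefficient of variation of 0.15 — a typical fluorescence-array
noise level; the emulated study states none, so this is a tuning
parameter, not a claim. Negative-control beads (500 per channel) are
lognormal with mean $0.02\,T$ and CV 0.5. A single integer seed is split
deterministically per sub-generator, so identical seeds give
byte-identical outputs.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: the two Infinium chemistries and their
different beta distributions, dye bias, batch and position effects,
probe cross-hybridization, SNPs under probes, bisulfite-conversion
failure on the array itself, cellular-composition drift with age, and
correlated noise between neighboring probes. Parameter-recovery results
on synthetic data are a check of the pipeline's statistics, not of
array chemistry.

## Bisulfite amplicon validation

Amplicons are modeled on the bisulfite top strand only, matching
single-strand primer design; coordinates are 0-based internally and
1-based in reports. Simulated reads are full-length and error-free apart
from conversion: methylated CpG cytosines are retained as C with the
site's probability, unmethylated ones read T, and non-CpG cytosines
convert with the deamination efficiency (default 0.995). Sequencing
error and indels (the homopolymer errors of long-read pyrosequencing)
are out of scope; reads shorter than the amplicon are supported through
a best ungapped offset search under bisulfite-aware matching (read T
matches reference C), with reads below 90% identity rejected rather
than miscalled.

Per-site methylation is the methylated fraction of non-gap calls;
zero-coverage sites are reported missing, never 0%. Deamination
efficiency is tallied at non-CpG cytosines, pooled and per read, with a
QC flag below 99%. Reads with partial conversion failure are retained
(and visible in the per-read efficiencies) rather than filtered — the
choice is configurable downstream by the caller. Array concordance
pairs a linked site's sequencing percentage with 100× the group-mean
beta, flagging absolute differences above 20 percentage points — the
sequencing-scale mirror of the 0.2 delta-beta convention.

## Problem sizes and numerical choices

The test suite exercises full-scale components where the statistics
demand it and small fixtures elsewhere: the parameter-recovery check
runs the complete 27,578-probe universe over the 30 epidermis samples
that enter the age and sun comparisons, with all bead-level defaults;
rank-test oracle equivalence enumerates 1,000 random inputs at group
sizes up to 6; detection calibration uses 50 independent negative pools
of 200 beads with 200 probes each; shift-test type-I control uses 1,000
seeded replicates. The acceptance script simulates the full 50-sample
study. Exact equalities are asserted to 1e-12, quantile-normalization
equality across samples to 1e-9, and stochastic recoveries to binomial
99% bounds at their respective sample sizes.

Degenerate inputs have defined behavior throughout: constant groups give
P = 1, zero-variance profiles an `NA` correlation with a warning,
zero-coverage sites are missing, empty negative pools are configuration
errors, and an all-probes-excluded detection filter is a hard error.

## Known limitations

* The ratio-over-sum reconstruction is an interpretation; if the
  original construction differed (e.g. non-cumulative per-point ratios),
  absolute curve shapes — though not the endpoint, which any
  ratio-over-sum variant shares — would change.
* Exact 5v5 rank tests cannot produce adjusted P-values below 1 at
  array scale; P(BH)-filtered statements need larger (or paired-site)
  designs, as discussed above.
* Joint quantile normalization across heterogeneous cohorts transfers
  small distributional differences between groups; staged preprocessing
  is available but changes the normalization scope.
* The beta offset compresses measured betas by $T/(T+\alpha)$; marker
  calls at the 0.2 threshold therefore correspond to slightly larger
  true differences.
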