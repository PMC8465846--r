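---
title: "Methods: canopy phenology, trial statistics and heterosis in wheatphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy phenology, trial statistics and heterosis in wheatphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatphen)
```

`wheatphen` analyzes multi-location hybrid-vs-parent wheat trials: it
extracts stay-green statistics from canopy NDVI dynamics, computes
adjusted genotype means and broad-sense heritability from augmented
designs, quantifies mid-parent and best-parent heterosis, and tests the
trait associations that explain it. This vignette is the package's own
account of the models, the choices behind them, and what the synthetic
validation does and does not show.

## 1. The three-phase canopy model

A winter wheat canopy seen through NDVI rises roughly linearly from
emergence to a maximum around heading, holds an almost flat plateau
through flowering and early grain filling, then collapses in a sigmoid
senescence. We model the three phases on a thermal-time axis:

- **Thermal time.** `TT(d)` is the cumulative daily mean temperature
  `(tmin + tmax)/2`, truncated at a base of 0 °C, accumulated from
  sowing, and centered so the heading date maps to 0 °C days
  (`build_thermal_axis()`). Centering on heading makes senescence
  statistics comparable across genotypes whose development differs in
  calendar time.
- **Growing phase** `f(TT) = a1·TT + b1` and **flowering plateau**
  `g(TT) = a2·TT + b2`, ordinary least squares.
- **Senescence**
  `h(TT) = NDVI_final + NDVI_amplitude / (1 + exp(a3·TT + b3))`,
  with `a3 > 0` (decreasing curve). `NDVI_final` is anchored at the
  lowest observed post-peak NDVI and `NDVI_amplitude` at the flowering
  line evaluated at the phase boundary minus `NDVI_final`; both stay
  fixed while (`a3`, `b3`) are estimated by Levenberg–Marquardt
  nonlinear least squares (`minpack.lm`), started at
  `a3 = 4/span(TT)`, `b3 = −a3·median(TT)` with up to 5 deterministic
  ±50 % restarts and an SSE tolerance of 1e-12.

From the fitted logistic, the thermal times at which 90/50/10/1 % of the
amplitude remains follow in closed form (`tfn()`):
`TFN90 = (−ln 9 − b3)/a3`, `TFN50 = −b3/a3`, `TFN10 = (ln 9 − b3)/a3`,
`TFN1 = (ln 99 − b3)/a3`. Two structural identities follow and are
enforced by tests: the quantiles are symmetric
(`TFN50 − TFN90 = TFN10 − TFN50`) and all spacings are fixed multiples
of `1/a3`, so any TFN statistic is an affine function of
(`TFN50`, `TFN10 − TFN50`) — which also means averaging commutes with
the formulas, the property `senescence_from_quantiles()` exploits to
reconstruct mean-level statistics from published summary means.

Phase areas integrate the fitted curves: GPA from sowing to the NDVI
maximum, FPA from the maximum to the phase boundary, SPA from the
boundary to TFN1 using the exact antiderivative
`H(t) = NDVI_final·t + NDVI_amplitude·(t − ln(1 + e^{a3 t + b3})/a3)`
(evaluated with a softplus guard against overflow), and DPA = FPA + SPA
by definition. TA is, by default, the trapezoid area under the measured
points (`ta_mode = "measured"`); `"modelled"` gives GPA + DPA. We emit
both because the two conventions disagree in published summary tables,
and neither is treated as a validation surface.

### Phase boundaries

Where flowering ends and senescence begins is not observable directly.
`segment_phases()` assigns points up to the NDVI maximum to the growing
phase — taking as "maximum" the first observation within one measurement
noise standard deviation (default 0.02) of the series maximum, so a
noisy late plateau reading cannot swallow the flowering phase — and then
chooses the flowering/senescence split by exhaustive search over
post-peak split indices, minimizing the joint SSE of (line left,
logistic right), each side keeping at least 3 points (2 on the flowering
side as a fallback when the peak sits close to the boundary). The
alternative rule `boundary = "logistic_all"` fits the logistic to all
post-peak points and cuts at the 99 %-amplitude time. The search is
deterministic; no seed is involved.

Fits are refused, with a reason recorded per plot, when a series has
fewer than 8 observations, fewer than 3 post-peak points, a non-positive
amplitude, a non-converged optimizer, or an unidentifiable timing (the
implied senescence width exceeding the post-peak span, or the implied
mid-senescence time falling more than one width outside the observed
senescence window). `phenology_pipeline()` lists failures rather than
dropping them, and reports the mean and SD of the per-phase correlation
between fitted and observed values (the "R" of each phase; for a simple
regression this equals √R², so the distinction between the two readings
is moot).

### Accuracy limits

Because `NDVI_final` is anchored at the *minimum observed* post-peak
NDVI, the anchor carries the residual logistic tail at the last
measurement date (and, under noise, the negative bias of a minimum).
Even on noiseless data this bounds pipeline-level recovery of `a3` at
roughly the 0.1–1 % relative level — the tests assert exactly that — while
`fit_senescence()` given exact anchors recovers parameters to 1e-6.
Under realistic noise (SD 0.02, 13–14 campaigns) the median absolute
error on TFN50 is a few degree days, with occasional poorly covered
plots failing identifiability and being flagged.

## 2. Adjusted means and heritability

Augmented designs replicate only check varieties (here: 4 checks in each
of 8 blocks, all other entries once per location), so genotype means
must be adjusted for block effects estimated from the checks. Per
location, `fit_blues()` fits the fixed-effects model
`value ~ genotype + block` under sum-to-zero contrasts and reports the
estimated marginal means over blocks (via `emmeans`). Across locations
it fits the additive model `value ~ genotype + location-block`: the
genotype × location interaction is saturated for unreplicated entries
and is therefore left out of the mean model (it is instead estimated as
a random component below). Genotypes missing from some locations are
averaged over their observed cells. Non-estimable (aliased) genotypes
raise an error naming them.

`estimate_variance_components()` treats genotype (and genotype ×
location) as random and design effects as fixed, estimated by REML
(`lme4`). Broad-sense heritability is
`h² = σ²G / (σ²G + σ²GxL/l + σ²r/(n·l))`, reducing to
`h² = σ²G / (σ²G + σ²r/n)` at `l = 1`. We define `n` as the number of
plots divided by the number of observed genotype × location cells —
about 1.21 for this design — so that `n·l` is the total replicate count
per genotype; defining `n` as plots per genotype across all locations
would make the combined formula divide by the location count twice.
Two numerical corners are handled explicitly: with (near) zero residual
variance the REML likelihood is flat and the optimizer unreliable, so a
saturated-fit pre-check returns expected-mean-squares estimates at the
boundary; REML cannot produce negative components, and estimates at the
zero boundary are flagged. A method-of-moments estimator
(`method = "mom"`, single-location) is kept as an independent
cross-check for tests.

## 3. Heterosis

`compute_heterosis()` forms, per hybrid and trait, the mid-parent value
`(F + M)/2` and best parent `max(F, M)` from genotype-level BLUEs and
the pedigree, and reports percent deviations. A record exists only when
the hybrid and *both* parents have values; incomplete trios are listed
as skipped. Records with a zero mid-parent are flagged undefined and
excluded from summaries. Best-parent heterosis never exceeds mid-parent
heterosis for positive-valued traits (the best parent is at least the
average), and percentages are invariant to rescaling but not to shifting
the trait — both properties are tested.

`summarize_heterosis()` reports mean, range, σ/μ, the share of positive
records, and the p-value of a two-sided one-sample Student t-test of the
per-hybrid heterosis values against zero. We read the published "Student
test between hybrids and parent lines" as this one-sample test, because
the accompanying figures plot the mean ± SD of per-hybrid heterosis; a
Welch two-sample hybrids-vs-parents variant is available behind
`test = "two_sample"`. P-values are reported raw (α = 0.05, no
multiple-testing correction, matching the source analysis).
`top_k_subset()` restricts the summaries to the k highest-yielding
hybrids, ties broken by id.

## 4. Trait associations

`correlation_matrix()` computes pairwise-complete Pearson correlations
with two-sided p-values, traits ordered measured → estimated → modelled.
`grain_protein_deviation()` regresses protein content on yield over the
whole panel (hybrids and lines jointly — GPD is defined against the
panel-wide trade-off) and reports the residuals plus the hybrid-vs-line
offset from the joint model `GPC ~ YLD + group`. `group_ancova()` fits
`response ~ covariate + group` (offset test) and
`response ~ covariate × group` (slope-difference test) for TKW given
grains/m², senescence onset given heading date, and yield given heading
date. Check varieties are excluded from the hybrid-vs-line contrasts by
default (they are neither parents nor hybrids); `include_checks = TRUE`
folds them into the line group.

## 5. What the synthetic generator emulates

`sim_config()` fixes the study conditions: 19 CMS females × 16 restorer
males; 92 F1s selected so every male sires ≥ 3 and every female ≥ 2
crosses; 160 entries × 8 blocks × 3 locations with 4 replicated checks
and 1 unreplicated check; sowing late October, harvest mid-July.

Trait architecture: parent values are multivariate normal with means and
additive SDs at the published trait means and genetic variances (yield
8.5 t/ha, protein 11.9 %, heading day-of-year 132.6, TKW 41.1 g, …). A
hybrid's true value is its mid-parent times `1 + het/100`, with `het`
drawn per trait around the published mean mid-parent heterosis (+5.0 %
yield, +7.7 % TKW, −0.7 % protein, −2.3 % heading date, …) with the
published between-hybrid spread. Trait trade-offs are induced by shared
latent factors at the genotype level — for both additive values and
dominance deviations, so the trade-offs survive in the hybrid fraction
of the panel. The latent loadings (0.87/−0.87 for yield/protein, −0.9
for the heading→senescence coupling) are the *genetic-level*
correlations obtained by disattenuating the published adjusted-mean
correlations (−0.57 and −0.76 to −0.80) with the published
heritabilities: simulating the observed correlation at the genetic level
and then adding design noise would underestimate the observed one.
Grain number per m² is derived as `YLD·1e5/TKW`, so its ≈ −3 % hybrid
deficit emerges from the yield and TKW heterosis rather than being
injected (a configurable extra penalty defaults to 0); hybrids are noted
as sown at 85 % density in the trial metadata.

Senescence timing: genotype mid-senescence time TFN50 averages 688.5
°C days with genetic SD 25 °C days — set from the published genotype
range rather than the published genetic variance, which is inconsistent
with that range — coupled to heading date with loading −0.9; senescence
width (TFN10 − TFN50) averages 121.3 °C days. Per plot, the true curve
adds G×L and residual timing noise (SD ≈ 4 °C days each), anchors the
flowering line at the true boundary (60 °C days before the 90 % point),
and caps the NDVI maximum at 0.98 (sensor saturation). Measurement
dates follow per-location campaign schedules shared by all plots — 13–14
visits: three winter passes, ten-day passes through May, then roughly
weekly passes to harvest — because per-plot random dates leave some
senescence drops unsampled and produce unidentifiable fits at rates far
above what field campaigns show. Gaussian noise (SD 0.02) is added and
values clipped to [0, 1].

Weather is a sinusoidal annual cycle (mean 11.8 °C, amplitude 7.8 °C,
peak mid-July, daily noise SD 2.5 °C) calibrated so the three cycles
accumulate ≈ 2700–3000 °C days, matching the reference sites.

Determinism: each stage derives its seed from the master seed by a fixed
offset, so a fixed seed yields a byte-identical CSV bundle; the
simulation truth is written alongside the data and is never read by the
analysis pipeline.

**What passing tests show — and not.** Parameter recovery on this
generator demonstrates that the estimators are consistent under the
generating model: correctly specified variance components, Gaussian
noise, a logistic senescence truth, no spatial trends, no missing data,
heading dates known without error. Real trials violate several of these
(spatial fertility gradients, scanner drift, non-logistic late-season
regreening, missing plots), so recovery here validates the *code and the
mathematics*, not the field robustness of the method.

## 6. Validation surfaces and problem sizes

The suite (≈ 2.5 minutes on one CPU) checks, among others: the logistic
quantile identities on the published combined-environment means
(reconstructed TFN1 = 942.2 and TFN90 = 567.2 °C days, and
DPA = FPA + SPA, each to one decimal); design bookkeeping (cycle
durations 260/274/281 days, 5.8 hybrids per male, 30 % of the factorial
selected); agreement of closed forms with numerical oracles (1000
bisection inversions and 200 quadratures at 1e-6); noiseless refit of
(`a3`, `b3`) to 1e-6 given exact anchors; heritability recovery (200
paper-shaped trials, mean ĥ² within ±0.05 of truth); heterosis recovery
(100 panels, mean within 2 SE of the configured dominance, and
best-parent ≤ mid-parent in every record); exact group offsets on
noiseless constructions with uniform null p-values (KS over 1000
replicates); and byte-identical end-to-end reruns under a fixed seed.
The same acceptance script that readers can run
(`scripts/acceptance.R`) recomputes the quantile-identity statistics
from the shipped published means at run time.

## 7. Known limitations

- The senescence anchors (`NDVI_final`, amplitude) are plug-in
  estimates; their sampling error propagates into (`a3`, `b3`) and is
  the dominant error source at realistic noise levels.
- The flowering/senescence breakpoint is selected per plot by SSE; on
  sparse post-peak sampling the selected boundary can shift by one
  observation, which moves FPA/SPA (but not their sum's endpoints'
  definition, DPA = FPA + SPA always).
- Combined-environment BLUEs come from the additive model; with strong
  genotype × location crossover the adjusted means average over a real
  interaction (reported separately as a variance component).
- The generator's dominance is multiplicative on the mid-parent and its
  trade-offs single-factor; it reproduces the published summary
  structure, not wheat physiology.
- GPD attenuates on noisy BLUEs: the hybrid offset is +0.2 protein
  points at the genetic level but shrinks toward +0.05–0.1 in the
  estimated regression because design noise flattens the yield–protein
  slope. The sign is stable; its magnitude is reliability-dependent.
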