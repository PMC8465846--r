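# wheatphen

Canopy phenology, multi-environment trial statistics and heterosis for
hybrid wheat phenomics.

## The problem

Hybrid wheat programs need to know *where* hybrid vigor comes from. Plot
yields alone cannot separate a longer grain-filling phase from a denser
canopy or an earlier heading date. `wheatphen` implements the analysis
chain used to dissect heterosis in multi-location hybrid-vs-parent trials:

1. **Canopy phenology in thermal time.** Per-plot NDVI time series are
   placed on a thermal-time axis (base 0 °C, cumulative daily mean
   temperature, centered so heading date = 0 °C days) and fitted with a
   three-phase development model

   - growing phase: `f(TT) = a1·TT + b1`
   - flowering plateau: `g(TT) = a2·TT + b2`
   - senescence: `h(TT) = NDVI_final + NDVI_amplitude / (1 + e^(a3·TT + b3))`

   with `NDVI_final` the lowest post-peak NDVI and `NDVI_amplitude` the
   drop from the flowering line at the phase boundary, both held fixed
   while (`a3`, `b3`) are fitted by nonlinear least squares. Stay-green
   statistics follow in closed form: `TFN90 = (−ln 9 − b3)/a3`,
   `TFN50 = −b3/a3`, `TFN10 = (ln 9 − b3)/a3`, `TFN1 = (ln 99 − b3)/a3`,
   plus phase areas (GPA, FPA, SPA, DPA = FPA + SPA, TA) from the exact
   antiderivatives.

2. **Adjusted means and heritability.** Genotype BLUEs from fixed-effects
   models of the augmented design (replicated checks in every block),
   per location (`y = μ + α_i + β_j + ε`) and across locations
   (additive genotype + location-block model); REML variance components
   (genotype and genotype×location random) and broad-sense heritability
   `h² = σ²G / (σ²G + σ²GxL/l + σ²r/(n·l))` with `n` the mean replicate
   count per genotype per location and `l` the number of locations.

3. **Heterosis.** Per hybrid and trait, mid-parent heterosis
   `100·(HYB − (F+M)/2) / ((F+M)/2)` and best-parent heterosis
   `100·(HYB − max(F,M)) / max(F,M)`, with per-trait summaries (mean,
   range, σ/μ, share positive, one-sample t-test against 0) and a
   top-k-yield subset view.

4. **Trait associations.** Pairwise-complete Pearson correlations on the
   BLUEs; grain protein deviation (GPD — the residual of protein content
   regressed on yield, plus the hybrid-vs-line offset at equal yield);
   hybrid-vs-line ANCOVAs for TKW given grains/m², and senescence onset
   or yield given heading date.

A first-class synthetic-data module (`sim_config()`, `simulate_study()`)
emulates the study design end to end — 19 CMS females × 16 restorer
males, 92 selected F1s, 160 entries in 8 blocks with 4 replicated checks
at 3 locations, sinusoidal weather, trait architecture with dominance and
latent-factor trade-offs, campaign-sampled three-phase NDVI — and emits
the generating truth alongside, so every stage can be validated by
parameter recovery.

## Worked example

```r
library(wheatphen)
run_pipeline("all", out = "run1", seed = 1)

read.csv("run1/phenology_fit_report.csv")
#>        phase    mean_r        sd_r
#> 1    growing 0.9965847 0.003555077
#> 2  flowering 0.9096191 0.128496507
#> 3 senescence 0.9981445 0.003766715

s <- read.csv("run1/heterosis_summary.csv")
s[s$kind == "mid_parent" & s$trait %in% c("YLD", "TKW", "HD"),
  c("trait", "mean_pct", "frac_positive", "p_value")]
#>   trait  mean_pct frac_positive      p_value
#> 1   YLD  5.569168    0.69565217 1.046977e-07
#> 6   TKW  8.550588    0.96739130 4.034497e-28
#> 4    HD -2.419496    0.03260870 1.356110e-33
```

Reading: the three phase fits average R = 0.997 / 0.910 / 0.998 across
the 480 plots; hybrids out-yield their mid-parent by +5.6 % on average
(70 % of hybrids positive), driven by +8.6 % thousand-kernel weight,
while heading 2.4 % earlier — the qualitative signature of stay-green
yield heterosis. Correlations on the combined BLUEs in the same run:
YLD–GPC r = −0.41, TKW–GPSM r = −0.47, HD–TFN90 r = −0.56 (all
p < 1e-5), i.e. the yield–protein and kernel-weight–kernel-number
trade-offs and the heading-date dependence of senescence timing.
`run1/heritability.csv` holds the variance components behind each trait
(e.g. combined-environment h² = 0.73 for yield, 0.91 for heading date in
this run). Two runs with the same seed produce byte-identical files.

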