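---
title: "Branch-level drought response: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-level drought response: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinonbranch)
```

## The scientific problem

Pinyon pines (*Pinus edulis*) in the southwestern USA experience combined
soil drought and atmospheric drought (high vapour pressure deficit, VPD).
A branch responds structurally on an annual rhythm: each year it adds a new
cohort of needles (evaporative surface), a new ring of xylem on every twig
section (water-supply area), and a new elongation segment. This package
analyses how those annual additions shift under different watering regimes —
an irrigated plot, an ambient plot, and a rainfall-exclusion ("droughted")
plot — over a seven-year experiment, and whether the shifts mitigate or
aggravate the drop of water potential along the branch.

Under steady state the xylem water-potential gradient is
$d\Psi_X/dx = E / k_L$ with $k_L = k_S \cdot A_S{:}A_L$
(`potential_gradient()`); a larger sapwood-to-leaf-area ratio therefore
flattens the gradient at fixed transpiration. Because total sapwood and
total leaf area cannot be reconstructed retrospectively, the analysis works
with *annual* increments: the ratio of the ring area added in year $y$
(measured on the section whose innermost ring dates to year $\Gamma$) to the
leaf area of the year-$y$ needle cohort distal to that section,

$$\mathrm{SA{:}LA}_{y,\Gamma} = \frac{\mathrm{SA}_{y,\Gamma}}{\mathrm{LA}_{y,\Gamma}}
\quad [\mathrm{cm^2/m^2}],$$

and its length-corrected companion $\mathrm{SA{:}LA}_{y,\Gamma}/d_{y,\Gamma}$
with $d$ the distance from the section to the tip as of year $y$.

## Pipeline stages

### Climate predictors

The hydrological year runs November–October and is labelled by the calendar
year of its October endpoint. Precipitation is split at June 30 into
premonsoon (Nov–Jun) and monsoon (Jul–Oct) windows; atmospheric-drought
predictors are counts of days whose daily-maximum VPD strictly exceeds a
threshold (default 4.5 kPa, the value found most explanatory in the source
experiment and exposed as a parameter) over the dry-season (MAMJ) and
monsoon (JASO) windows. When VPD is not recorded directly it is derived
from daily maximum temperature and minimum relative humidity with the
Tetens saturation curve, $e_s = 0.6108\,e^{17.27T/(T+237.3)}$ kPa.

Missing days are excluded from sums and counts with a logged coverage
fraction; a year below 95% coverage is excluded from the period statistics
(`period_stats()`, sample SD with $n-1$). Mixed-model covariates are
standardized by the experimental-period mean and SD (`standardize_series()`),
which are retained so the transform is invertible.

### Needle traits

Needle adaxial area is measured on a subset (~20% in the source campaign)
and filled for the remainder with the allometry
$A_{ad} = \gamma + \alpha\, l\, w$ (`fit_area_model()`); measured values
always take precedence. The abaxial face is taken equal to the adaxial one,
so total needle area is $2A_{ad}$. Stomatal density per needle is

$$D_s = \frac{\bar{D}_{lin}\; l\;(R_{ad}+R_{ab})}{2 A_{ad}},$$

with $\bar D_{lin}$ the linear density of stomata within rows and
$R_{ad}, R_{ab}$ the row counts per face, recorded to the nearest half row
and propagated without rounding. Stomata are near-circular in this species,
so the pore is idealized as a half-sphere of maximal diameter $d_S$:
pore depth $p = d_S/2$, maximal pore area $a_{max} = \pi (d_S/2)^2$. The
maximal anatomical stomatal conductance is

$$g_{smax} = \frac{d}{v}\cdot
  \frac{a_{max} D_s}{p + \frac{\pi}{2}\sqrt{a_{max}/\pi}},$$

with $d = 2.49\times10^{-5}\,\mathrm{m^2/s}$ (water-vapour diffusivity) and
$v = 2.446\times10^{-2}\,\mathrm{m^3/mol}$ (molar volume of air), both at
25&nbsp;°C. These constants are not part of the data and are exposed as
parameters of `stomatal_geometry()`. One $g_{smax}$ is derived per
branch-year from the *cohort means* of $D_s$ and $d_S$ — not by averaging
per-needle conductances — matching how a yearly anatomical conductance is
defined for a branch.

### Functional ratios

Ring areas arrive in mm² per (branch, section $\Gamma$, year $y$) cell.
The pipeline discards the apical cells ($y = \Gamma$, primary xylem),
propagates missing rings as absent cells (a missing ring is absent data,
never a zero area), excludes cells whose year has no needle cohort, and
averages arithmetically across sections within each branch-year. For
$\mathrm{SA{:}LA}/d$ the *per-section quotients* are averaged (mean of
quotients, not quotient of means). On the primary axis every year-$y$
needle is distal to any older section, so the cohort leaf area depends only
on the year; lateral shoots are outside the data model.

Where along the genesis-year segment a section was cut is not recoverable
from the tables, so the section is placed at that segment's proximal end by
default ($d_{y,\Gamma} = \sum_{t=\Gamma}^{y} \mathrm{seg}_t$); a midpoint
convention is available (`distance_to_tip(position = "midpoint")`).

### Inference

Cross-treatment comparisons within a year use the two-sided Wilcoxon
rank-sum test (the design is unpaired: different trees per plot); a year's
distribution is compared with the pooled years by the two-sample
Kolmogorov–Smirnov test. SA-on-LA relationships are zero-intercept
regressions (slope $\sum xy / \sum x^2$); slopes are compared with a
pairs-resampling bootstrap whose two-sided p-value is the percentile
position of zero in the difference distribution (the percentile interval
was chosen over the basic interval; the source analysis does not specify
which was used).

The climate mixed models are
$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2$ with random intercept and slopes
grouped by treatment, fitted by maximum likelihood (so AIC is comparable
across fixed-effect structures) via `lme4`. With only three groups the
random-effect covariance is kept diagonal, boundary (singular) estimates
are tolerated, and a random-intercept-only fallback is used on hard
failures. Coefficient p-values are Wald normal approximations. Marginal
and conditional $R^2$ follow the variance-partition formulation, with the
random-slope contribution computed as the observation-averaged
$z_i^\top \Sigma z_i$. `model_search()` ranks all candidate predictor pairs
by AIC, adds nested likelihood-ratio comparisons, and flags collinear
pairs ($|r| > 0.8$ — at this site monsoon precipitation and monsoon high-VPD
days are strongly anti-correlated, which is why the search cannot cleanly
separate them). Cross-treatment coefficient comparisons resample *branches*
within treatment, the exchangeable unit.

## The synthetic experiment

The generator (`sim_config()`, `generate_dataset()`) defines the study
conditions under which everything is verified; it is not a tuning surface.

* **Cohort**: 10 irrigated, 10 ambient, 4 droughted trees; three branches
  collected per tree of which one is measured (three on droughted trees),
  matching the dissection campaign and yielding ~170 measured branch-years.
  Needle-year cohorts span 4–7 years (mean 5.5), with 1–15 needles per
  cohort (mean 13.2, SD 3.1).
* **Climate**: the default "anchored" mode reproduces the experimental
  period — per-year premonsoon/monsoon totals, seasonal mean VPD, and
  high-VPD-day counts follow the site's published yearly record (2007–2013),
  with ±15 mm seasonal noise — because the experiment's identifiability
  rests on that particular sequence (one extreme year, 2011). A
  "climatology" mode draws stationary years around the long-term record
  (annual mean 355.3 mm, SD 83.4; 18% winter share, 52% July–September
  share) for long-run checks. Rain falls in discrete events; VPD exceedance
  days are placed explicitly inside each window and the remaining days are
  kept below the threshold, so the exceedance predictors are exact by
  construction. Real VPD series have smoother tails; this is a deliberate
  stylization for verifiability, and the VPD-day anchors themselves are
  stylized choices (daily VPD is not published).
* **Treatments**: the droughted plot loses 45% of every event from
  August 2007; the irrigated plot receives ~19 mm events April–October
  summing to 57/69.5/112/107/95/95 mm in 2008–2013. VPD is shared across
  plots — treatments differ only in water input.
* **Responses**: yearly mean needle length is linear in the treatment's own
  premonsoon and monsoon water input with treatment-specific coefficients
  (irrigated 18/0.051/0.05, ambient 0.4/0.126/0.096, droughted 2/0.236/0.171
  mm per mm), plus a branch-level intercept (SD 1.5 mm) and needle-level
  noise (SD 3 mm; non-positive draws are resampled and counted). Segment
  elongation scales with needle length. Ring areas are set so the implied
  SA:LA tracks a treatment-specific linear response (irrigated
  0.11/4.2e-3/3.8e-3, ambient −0.09/6.5e-3/4.1e-3, droughted
  −0.21/6.5e-3/8.0e-3 cm²/m² per mm) against the leaf area actually
  generated, with equal expected ring area across sections (no within-branch
  taper is reported for this material) and 20% lognormal noise. Stomatal
  inputs are truncated normals with modest treatment shifts: linear density
  higher and stomatal diameter slightly lower under drier treatments, so
  density and pore size partly offset in $g_{smax}$ — the compensation seen
  in the field data.
* **Extreme-year collapse**: a year with ≥10 monsoon days above 4.5 kPa and
  a site total below 200 mm is a collapse year for every plot whose own
  water input is also below 200 mm (irrigation lifts a plot out of the
  collapse). The rule is evaluated on the site series *and* the plot's
  input because the droughted plot's mean input (~173 mm) sits permanently
  below the 200 mm cut — a plot-input-only rule would fire in every
  high-VPD year. In collapse years rings go missing with probability 0.25.
  The collapse multipliers on needle length and ring area default to 1
  (no extra attenuation): the anchored 2011 climate already drives the
  linear responses to roughly half their prior-year values — the observed
  magnitude — and the treatment-specific coefficients were estimated
  through the extreme year, so stacking a further ×0.5 would double-count
  the collapse. The multipliers remain configurable for sensitivity work.
  With multipliers at 1 and missing rings the only non-linearity, disabling
  the rule makes every response exactly affine in the seasonal predictors,
  which the test suite exploits.

### What passing tests do and do not show

The generator's data are affine in the seasonal predictors with Gaussian
(or lognormal) noise — exactly the regime the mixed models assume. Passing
parameter recovery therefore demonstrates that the pipeline is
*self-consistent* (no unit slips, no aggregation bias, correct estimators),
not that real branch data satisfy those assumptions. Features of real data
the generator does not emulate: within-year phenology, carry-over (lagged)
climate effects, needle abscission, within-branch ring-area gradients,
spatial correlation between neighbouring trees, and measurement error in
ring dating.

## Numerical choices

* Strict inequality for VPD exceedance; calendar-month season windows.
* Ratios with zero cohort leaf area are undefined and excluded (flagged),
  never zero; the same for missing rings.
* Negative area predictions are clamped to zero with a warning.
* Zero-variance series refuse to standardize (error), and a degenerate
  bootstrap resample (all-zero abscissa) is redrawn and counted.
* Bootstrap p-values use the $(\#\{\cdot\}+1)/(B+1)$ continuity adjustment;
  all bootstrap routines require a seed for reproducibility.
* Problem sizes of the verification experiments: 200 simulated replicates
  for mixed-model recovery, 50 for the bootstrap ordering rate (400
  resamples each), 1,000 replicates per test for type-I calibration, 20 for
  the SA:LA ordering check — sizes at which the Monte-Carlo error is well
  inside the assertion margins. Calibration sample sizes (rank-sum 20 per
  group, KS 60 vs 300, slope bootstrap 120 pairs per group with 999
  resamples) are chosen so the discreteness of exact small-sample tests and
  the small-sample anticonservatism of the percentile bootstrap do not
  distort the nominal 5% level being checked.

## Known limitations

* Treatment-specific behaviour is modelled from the start of 2007 although
  treatments ramped up during that year; 2007 usually falls outside the
  4–7-year needle cohorts, so this mainly affects the deepest sections.
* The weighting of branches in treatment summaries is equal per branch;
  weighting per tree (droughted trees contribute three branches) is a
  defensible alternative not implemented.
* With three grouping levels the random-effect variances are weakly
  identified; fixed effects remain well-behaved (the recovery experiment
  checks exactly this), but the random-effect SDs themselves should be read
  qualitatively.
* `vpd_from_trh()` pairs daily maximum temperature with daily minimum
  humidity, a standard but approximate proxy for the daily maximum VPD.
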