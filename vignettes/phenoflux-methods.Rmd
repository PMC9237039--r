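---
title: "Methods: from seasonal curves to attribution of spring phenology"
author: "phenoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from seasonal curves to attribution of spring phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoflux)
```

## The scientific question

In temperate and boreal forests the timing of spring leaf-out (start of
season, SOS) is classically explained by winter chilling and spring
forcing temperatures. A complementary hypothesis is that conditions of
the *previous* growing season matter too: a warm, productive summer lets
trees assimilate and store more carbohydrate, and that stored carbon
supports an earlier budburst the following spring. Testing this requires
(i) extracting SOS from several independent observation systems, (ii)
summarising the previous season's climate and carbon uptake, and (iii) a
statistical chain that separates direct climate effects on SOS from
indirect effects routed through photosynthesis.

`phenoflux` implements that chain end to end and—because the
observational archives involved are large, access-restricted and
heterogeneous—pairs it with a synthetic multi-site generator whose
ground truth (true SOS/EOS, true temperature sensitivity, true causal
path coefficients) is known exactly. Every claim the test suite makes is
therefore a claim about recovering known truth, not about any particular
archive.

## The seasonal curve model

All three observation families are modelled with the same
double-logistic seasonal curve,

$$y(t) = b + a\left[\frac{1}{1+e^{-k(t-m)}} - \frac{1}{1+e^{-r(t-n)}}\right],$$

which rises from the winter background $b$ to a summer plateau near
$a + b$ and returns to $b$; $k$ and $r$ are the spring and autumn rates
(day$^{-1}$), $m$ and $n$ the spring and autumn inflection days. The
form is algebraically identical to the familiar
$b + a\,[L_\text{rise} + L_\text{fall} - 1]$ parameterisation. We treat
the autumn rate as a fourth free rate parameter, fitted independently of
the spring rate, since spring green-up and autumn senescence have no
reason to share kinetics.

A note on conventions: published variants of this equation differ in the
signs of the exponents and in which symbol denotes background versus
amplitude, and some printed forms (two same-sign logistics summed)
cannot produce a seasonal peak at all. The convention above is the one
under which "background" and "amplitude" mean what they say, and it is
used consistently by the generator, the fitter and the extractors.

## Phenology extraction

**Camera greenness (Gcc).** The green chromatic coordinate
$G_{cc} = G/(R+G+B)$ is composited to its 90th percentile over
non-overlapping 3-day windows (suppressing weather- and exposure-induced
low outliers), assigned to the last day of each window (where the upper
quantile of a rising segment sits), and smoothed with a 3-point running
median — chosen over a linear smoother because it preserves step-like
transitions exactly. The year's baseline and peak are the 10th and 90th
percentiles of that composite; SOS is the first day of the spring
segment at which the curve reaches half amplitude, linearly interpolated
between bracketing observations. At the half-amplitude level a logistic
is exactly at its inflection, so this extractor is unbiased for the
spring inflection.

**Satellite NDVI.** 15-day composites are Savitzky–Golay smoothed, the
double logistic is fitted by bounded nonlinear least squares, and SOS /
EOS are the first and second local maxima of the fitted curve's analytic
second derivative on a 0.1-day grid. For a single logistic that maximum
sits at $m - \ln(2+\sqrt3)/k$, i.e. the SOS *leads* the inflection by
13.2 days at $k = 0.1$; the suite checks the numeric extractor against
this closed form to ≤ 0.2 day. Savitzky–Golay defaults are window 7,
polynomial order 4: with 15-day composites a window spans 105 days, and
a quadratic over that span measurably flattens the green-up (it biases
the fitted rate low and pushes the second-derivative date a further ~4
days early, beyond one composite interval); a quartic preserves the
logistic shape and, in our Monte-Carlo checks at noise SD 0.02, roughly
halves the SOS error. Fit initialisation: background = 5th percentile,
amplitude = 95th − 5th, inflections at the first/last half-amplitude
crossings, both rates 0.1 day⁻¹; bounds keep amplitude and rates
positive and $1 \le m < n \le 365$; up to five deterministically
jittered restarts on non-convergence.

**Flux GPP.** Daily gross primary productivity is smoothed by singular
spectrum analysis (trajectory-matrix SVD with diagonal averaging;
window 60 days, 4 leading components — at these settings the zero-noise
reconstruction error of a seasonal curve of amplitude 10 is < 0.05, so
the smoother does not move threshold crossings). SOS is the first day in
the year's first half at which smoothed GPP exceeds 15% of the
multi-year smoothed maximum and stays above it for 5 consecutive days;
the persistence rule operationalises "turning point", which is otherwise
undefined for noisy upcrossings. GPPmax is the year's smoothed maximum
and mean growing-season GPP the May–September mean.

**Truth conventions in the generator.** Each extractor estimates a
different geometric feature of the curve. The generator therefore
anchors each curve so that the feature its extractor measures coincides
with the recorded `true_sos`: for NDVI and Gcc the spring inflection is
placed at `true_sos` (the Gcc extractor targets the inflection exactly;
the NDVI second-derivative date leads it by the known 13-day offset,
within its 15-day sampling interval), while for GPP the rising limb is
positioned so the noise-free curve crosses the 15% threshold exactly at
`true_sos` — with an inflection-anchored curve the threshold crossing
would lead truth by $\ln((0.85M - b)/(0.15M - b))/k \approx 21$ days by
construction and no threshold extractor could ever "recover" the
inflection to daily precision.

## Screening rules

Phenology records are screened with an unscaled median-absolute-
deviation fence: keep $|v - \text{median}|\le 2.5\,\text{MAD}$, applied
per site(-species) across years. No 1.4826 normality constant is used —
the rule is a fixed multiple of the raw MAD — and values exactly at the
fence are kept. When MAD = 0 (more than half the record tied at the
median) only values equal to the median are kept. NDVI sites whose
across-record mean of annual mean NDVI is below 0.1 are excluded as
bare land (boundary inclusive). Record-length filters retain a site
only with at least `min_years` valid years, dropping years below a
daily-observation count first. Every filter emits a report whose counts
reconcile exactly (`n_input = n_retained + removals`), and the pipeline
asserts that reconciliation on every run.

## Climate metrics

T\_GS is the May–September mean of daily mean temperature; the package
uses a fixed 365-day calendar (leap days dropped on ingest) and the
half-open DOY window [121, 274). Chilling units count days with daily
mean temperature in [0, 5] °C (bounds inclusive: "from 0 to 5");
forcing units accumulate degree-days strictly above a 5 °C base. Both
run from November 1 of the previous year to the site's mean SOS across
years, a window that deliberately crosses the calendar boundary. Windows
with under 90% daily coverage yield missing values — partial sums are
never rescaled, because a prorated degree-day sum is biased whenever
missingness correlates with season. Gridded climate is brought to sites
by bilinear interpolation of the four surrounding nodes, with no
extrapolation outside the grid hull.

## The statistical chain

**Temperature sensitivity.** Anomalies are z-scores per site record
("normalized" is read as divide-by-SD, not merely centred: only then is
the anomaly regression unit-free, and the slope in days/°C is recovered
by the back-transform $S_T = \beta_z\,\mathrm{SD(SOS)}/\mathrm{SD(T)}$,
which the code maintains as an exact identity). Each site is regressed
separately — current-year SOS anomaly on previous-season T\_GS anomaly —
and site-level slopes are pooled with a t-based 95% CI; significance
means the CI excludes zero. On z-scored inputs the slope equals the
Pearson correlation of the raw series, which the suite uses as an
oracle.

**Partial correlations.** Computed from the inverse of the joint
correlation matrix (identical to correlating the two residual vectors,
and cross-checked against that brute force to 10⁻¹⁰), with two-sided
p-values from $t$ with $df = n - 2 - (\#\text{controls})$. Controls in
the pipeline are the chilling and forcing accumulations aligned to the
window ending at the focal spring.

**Group comparisons.** One-way ANOVA with Tukey HSD p-values from the
studentized range, and a compact letter display built by the
insert-and-absorb algorithm over the pairwise significance matrix (ties
broken by input group order).

**Piecewise SEM.** The causal model — five growing-season climate
drivers each pointing at GPPmax and at SOS, plus GPPmax → SOS — is
estimated locally: one linear regression per endogenous variable,
coefficients standardized by the SD ratio. Consistency of graph and data
is judged by Shipley's d-separation test: each non-adjacent pair
(excluding pairs of exogenous drivers, whose association the model
leaves free) is tested by regressing the topologically later variable on
the earlier plus the union of both parent sets, and Fisher's
$C = -2\sum \ln p_i \sim \chi^2_{2k}$. The full default graph is
saturated, so its basis set is empty and $C = 0$ with $df = 0$ is
reported with an explicit flag rather than a meaningless p-value; the
validation suite calibrates the test on pruned graphs, where its
empirical size matches the nominal 5% within ±3 points over 1000
simulations. Effects are decomposed by path tracing: indirect = (driver
→ GPPmax) × (GPPmax → SOS), total = direct + indirect; decomposed totals
are checked against marginal regression slopes on generated data. The
SEM is fitted once on the pooled panel after z-scoring every variable
within site, mirroring the anomaly construction used elsewhere.

**Random-forest importance.** A regression forest (ntree = 1000,
mtry = 4) with permutation importance on out-of-bag samples —
preferred to impurity importance, which is inflated for high-variance
or high-cardinality predictors. Percentage shares are regularized:
clamped scores are augmented by the across-variable mean absolute
importance before normalizing. The reason is statistical: under a null
response every permutation importance is zero in expectation, and a
ratio of clamped noise terms makes one variable "dominate" in about
half of replicates; the mean-|importance| floor represents the
measurement noise common to all variables, keeps null shares
near-uniform, and provably never changes the ranking. A planted
dominant predictor still takes the majority share and first rank in
essentially every replicate.

## The synthetic generator: what it does and does not emulate

Daily temperature is a cosine seasonal cycle (peak DOY 200) plus a
linear decadal trend and iid Gaussian daily noise. The default daily
noise SD is 5 °C: because the noise is independent day to day, the
interannual SD of a 153-day seasonal mean is `noise_sd/√153`, and 5 °C
puts the interannual T\_GS SD at ≈ 0.40 °C, the magnitude observed at
temperate sites. (Real daily weather is autocorrelated, which is *why*
real seasonal means vary this much; the generator reproduces the
variance through the noise scale rather than the autocorrelation.)

True SOS responds linearly to the previous season's T\_GS anomaly with
an imposed sensitivity (default −2 days/°C, interannual noise SD 3
days, truncated so 1 ≤ SOS < EOS ≤ 365); EOS follows at a fixed
160-day season. Observation noise defaults — NDVI σ = 0.02 (unitless),
Gcc σ = 0.005, GPP σ = 5% of a 10 gC m⁻² d⁻¹ amplitude — are realistic
fixture choices, stated once here; no archive prescribes them. The flux
panel draws the five climate drivers as independent standard normals
and builds GPPmax and SOS as linear combinations plus noise, with noise
variances chosen so both endogenous variables have unit population
variance — under that construction the generating coefficients *are*
the true standardized path coefficients (for user-supplied noise the
attribute still reports the correct population paths).

Not emulated: satellite compositing artifacts, cloud flags, camera
exposure drift (only additive Gaussian noise), spatial correlation
between sites, autocorrelated weather, and any dependence of the
seasonal amplitude on climate. Passing tests therefore demonstrate that
the *methods* recover truth under clean stochastic conditions; they do
not certify performance on any real archive.

## Validation design and problem sizes

The suite validates each stage against an independent oracle: exact
hand-computed values for the combinatorial rules; the closed-form
curvature offset for the transition-date extractor; brute-force
residual correlations for the partial correlation; χ² calibration for
Fisher's C; and Monte-Carlo truth-recovery for the regression chain.
Problem sizes were chosen to make each check sharp at desk scale:
zero-noise round trips on 4-year sites; 200 Monte-Carlo double-logistic
fits (24 points/year, σ = 0.02); temperature-sensitivity recovery on
100 sites × 30 years with the null calibration on 1000 site-fits; SEM
recovery at n = 2000 over 100 replicates with 1000 calibration draws;
50 + 50 random-forest replicates at n = 300; and the 20-site × 15-year
demo pipeline run twice to verify byte-identical reproduction. One
statistical note: a single n = 2000 SEM draw has path standard errors
near 0.02, so individual estimates sit within ±0.05 of truth only with
~70% probability per draw; the suite therefore asserts the
replicate-median within ±0.05 (a bias check) together with ≥95% sign
recovery, which is the stable form of the same claim.

## Known limitations

- The NDVI extractor estimates the curvature maximum, which leads the
  inflection by $\ln(2+\sqrt3)/k$; comparisons across extraction
  methods must account for that systematic offset.
- SSA smoothing assumes an (almost) gap-free daily series; gaps up to
  30 days are linearly interpolated before embedding, longer gaps
  reject the series.
- The piecewise SEM assumes linear relations and residual independence
  across site-years; no spatial or temporal autocorrelation correction
  is applied, matching the per-site / pooled-panel design it mirrors.
- With the saturated default graph Fisher's C is degenerate (df = 0);
  model evaluation there rests on the component regressions, not on a
  d-separation p-value.
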