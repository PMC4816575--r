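---
title: "From daily cloud flags to cloud-driven species distributions: models and choices"
author: "cloudclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From daily cloud flags to cloud-driven species distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudclim)
```

## What this package computes

Twice-daily satellite overpasses yield, per ~1 km pixel and day, a binary
cloud flag and a validity mask. `cloudclim` turns stacks of such flags into
a monthly cloud-frequency (CF) climatology and its derived seasonal and
stability metrics, corrects two systematic artifacts (orbital stripes and
albedo contamination), validates the gridded product against ground-station
cloud-amount records, and feeds the result into two biodiversity models: a
presence-only point-process model of cloud-forest habitat and a Bayesian
zero-inflated binomial (ZIB) occupancy model with imperfect detection.
Every stage can be exercised on synthetic data with known ground truth; the
`analysis/` scripts at the repository root run the whole chain.

## The climatology model

For sensor $s$, month $m$ and year $y$, the cloud frequency at a pixel is

$$\mathrm{CF}_{s,m,y} = 100 \cdot
  \frac{\#\{\text{valid days with positive flag}\}}
       {\#\{\text{valid days}\}},$$

masked where no valid observation exists. Climatological summaries are
$\mu_m = \mathrm{mean}_y(\mathrm{CF}_{m,y})$ and
$\sigma_m = \mathrm{SD}_y(\mathrm{CF}_{m,y})$; sensors are merged by
equal-weight averaging where both report, falling back to the surviving
sensor. Derived metrics:

* **mean annual CF** — mean of the available $\mu_m$;
* **intra-annual variability** — SD of the $\mu_m$ (seasonality);
* **inter-annual variability** — mean of the $\sigma_m$ (year-to-year
  stability);
* **spatial variability** — circular moving-window SD of mean annual CF;
* **seasonal concentration** — see below;
* **stability hotspots** — cells in the top decile of mean annual CF,
  classed by whether they also sit in the bottom decile of intra- and/or
  inter-annual variability.

All SDs in this module are sample SDs ($n-1$); whether the original maps
used sample or population SD is not stated anywhere we could anchor to, so
one convention is chosen and exposed (`circular_window_stat()` takes
`sd_type`). High-latitude winter months can be absent; every summary uses
the available months and publishes a `months_available` count, requiring at
least two months for SD-type and concentration metrics.

### Seasonal concentration

Monthly means are placed on a polar "month clock", month $m$ at angle
$\phi_m = 2\pi(m-1)/12$, and summed as vectors
$S = \sum_m \mu_m(\cos\phi_m, \sin\phi_m)$. We report

$$\text{concentration} = 100\,\frac{|S|}{\sum_m \mu_m},$$

which is 0 when all months are equally cloudy and 100 when all cloudiness
falls in a single month. Note that normalizing by the mean **annual** CF
(the verbal definition common in the literature) would give a 0–12 range;
dividing by the *total* $\sum\mu_m$ — equivalently, dividing by the mean and
rescaling by $100/12$ — is the normalization that actually makes the stated
0 and 100 endpoints true, and is what this package implements. The
resultant direction gives the peak month; an angular tie between two months
resolves to the earlier calendar month, and resultants below $10^{-9}$
(perfectly balanced regimes, e.g. two equal opposite months) are snapped to
index 0 with an undefined peak. Scale invariance
($\mathrm{index}(c\mu) = \mathrm{index}(\mu)$) and rotation equivariance
(shifting all months by $k$ shifts the peak by $k$) are tested properties.

```{r concentration}
seasonal_concentration(rep(50, 12))$index          # aseasonal
seasonal_concentration(c(60, rep(0, 11)))$index    # one cloudy month
seasonal_concentration(c(60, rep(20, 11)))$index   # 100 * 40/280
```

## Stripe removal

Orbital geometry leaves near-longitudinal artifacts (about +15 degrees from
vertical for the morning sensor, -15 for the afternoon one) in long-term
frequencies. We model the artifact as translates of a single oriented
pattern $\psi$ and estimate its coefficient field $w$ by the quadratic
special case of variational stationary noise removal:

$$\hat w = \arg\min_w\; \lambda\|w\|^2 + \|\nabla(u - \psi * w)\|^2,$$

solved in closed form in the frequency domain. Properties that follow:
the domain mean is preserved exactly (the gradient annihilates DC), large
$\lambda$ recovers the identity, and the per-frequency gain is
$G = |\Psi|^2|D|^2 / (|\Psi|^2|D|^2 + \lambda)$.

Choices that needed deciding:

* **Pattern.** `gabor_pattern()` builds a zero-mean, unit-norm anisotropic
  Gaussian envelope (long axis along the stripe). When the artifact is a
  band of known width — as overpass-gap stripes are — the `"boxcar"`
  cross-profile (flat over the band width) captures the band's full
  harmonic series and removes substantially more stripe energy than a
  Gaussian cross-section of similar width.
* **Regularization.** $\lambda$ trades stripe suppression against damage
  to genuine smooth signal. A sensitivity study on synthetic stripes
  (matched-orientation versus orthogonal-orientation controls) put the
  usable range at roughly $\lambda \in [3, 10]$; the default is 5. At
  $\lambda = 1$ the filter noticeably degrades an image whose stripes it
  cannot match, which is why the default is not smaller.
* **Gain mode.** The closed-form shrinkage filter is a Wiener-type linear
  operator and therefore *not* idempotent: re-applying it keeps shrinking
  partially attenuated frequencies (second-pass change is ~25% of the first
  correction on realistic fields; this is intrinsic, not a bug). Where
  idempotence matters, `gain = "projection"` thresholds the gain at 1/2,
  giving an exact projection — idempotent by construction — at the cost of
  some stripe-band residual. The default remains `"shrinkage"`, which wins
  on RMSE-to-truth.
* **Mean bias.** A one-sided (e.g. multiplicative) stripe artifact has a
  nonzero domain-mean component. Exact mean preservation deliberately
  leaves that component in place; destriping therefore reduces, but cannot
  zero, the RMSE to truth.

Albedo-contaminated cells (bright *and* seasonally varying surfaces such as
salt flats) are flagged where maximum monthly albedo exceeds 0.5 and the
intra-annual albedo SD exceeds 0.15 — both configurable, since no canonical
thresholds exist — and gap-filled by inverse-distance-weighted (power 2)
donors within 10 cells.

## Station validation

A ground observer reports the fraction of visible sky that is cloudy — an
area far wider than one pixel — so gridded CF is averaged over a 16-km
circular footprint (spherical Earth, radius 6371 km) before comparison; no
calibration transfer beyond that averaging is applied. Two archive filters
mirror standard completeness rules: the satellite-era rule keeps stations
with at least 20 observations in *every* month of the 2000–2009 window;
the long-record rule keeps stations with at least 20 qualifying years (a
year qualifies when all 12 months have at least 20 observations).
Validation is unweighted OLS of station amount on footprint CF per month
and per season (DJF/MAM/JJA/SON, December with the following winter),
reporting $R^2$, RMSE, slope and intercept. Residuals — defined as station
amount minus footprint value — are summarized by latitude band and by the
modal land-cover class within the footprint (ties to the lower class id).

## Presence-only model (IWLR)

Presence-only records are modelled as an inhomogeneous Poisson point
process with log-linear intensity. The fit is an *infinitely weighted
logistic regression*: presences get weight 1, the 10,000 uniform background
points get a large weight $W$, and as $W \to \infty$ the slope estimates
converge to the point-process maximum likelihood (the MaxEnt-equivalent
estimator). Decisions:

* $W = 10^3$ by default; slope stability under $W \in [10^3, 10^6]$ is a
  tested invariant (relative change below 1%), and an independent
  brute-force maximization of the discretized Poisson likelihood is the
  equivalence oracle.
* The IRLS loop is this package's own Newton solver with an explicit
  gradient-norm stopping rule and two separation guards (coefficient cap
  during iteration; perfect-classification check at convergence), because
  separation makes the weighted-logistic gradient vanish at drifting
  coefficients.
* Model scores: AIC $= -2\ell + 2k$ and BIC $= -2\ell + k\ln n_p$ on the
  weighted log-likelihood, with the presence count $n_p$ as the effective
  sample size — the information-bearing unit of a point process. AUC
  treats background as pseudo-absence and the reported COR is the
  point-biserial correlation. These conventions are stated because no
  canonical choice exists for weighted presence-only likelihoods.
* Predictions are *relative occurrence rates*: the exponentiated linear
  predictor rescaled to a maximum of 1, which cancels the intercept (an
  artifact of $W$) while preserving ratios between cells.

## Occupancy model (ZIB)

Cell-level detections are modelled as
$z_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(x_i'\beta))$ (latent
suitability) and $y_i \sim \mathrm{Binomial}(n_i, z_i\,\delta)$ with an
intercept-only detection probability $\delta$ — detection covariates are
deliberately out of scope. Checklists qualify as trials when they are
complete and satisfy duration < 4 h and (distance ≤ 5 km or area ≤ 500 ha).
The sampler is Metropolis-within-Gibbs (implemented in C++ for speed, using
R's RNG for reproducibility):

* $z_i$ is drawn from its exact full conditional — for a never-detected
  cell the odds are $\theta_i(1-\delta)^{n_i} : (1-\theta_i)$ — verified
  in tests against brute-force enumeration over all latent configurations;
* $\beta$ and $\gamma = \mathrm{logit}(\delta)$ move by componentwise
  random-walk Metropolis with proposal scales adapted only during burn-in
  (every 50 iterations, targeting 20–45% acceptance), frozen afterwards to
  preserve the Markov property;
* priors are independent Normal(0, $10^6$), configurable (the toy
  enumeration test pins parameters with a tight prior);
* covariates are standardized internally; coefficients are reported on
  both scales.

Reported alongside the posterior: DIC ($\bar D + p_D$ on the
$z$-marginalized likelihood $L_i = \theta_i\,\mathrm{Binom}(y_i|n_i,\delta)
+ (1-\theta_i)\,[y_i = 0]$; a negative $p_D$ is flagged, not fatal — a
known DIC pathology), the Brooks–Gelman multivariate potential scale
reduction factor across chains, AUC of detected-versus-never-detected
cells, the Pearson correlation between $y_i/n_i$ and $\hat\theta_i$, and
the probabilistic range size $\sum_i \hat\theta_i$ — two cells at 50%
probability contribute one cell, no thresholding. Default iteration
settings are 3 chains, 10,000 burn-in, 50,000 iterations thinned by 50;
tests and the analysis scripts run scaled-down chains (e.g.
2 × (2000 + 8000)/10) purely for runtime, and the convergence diagnostic is
always checked.

## Spatial statistics

Moran's I and Geary's C use a symmetric pair-list weight representation;
the default for reporting on model predictions is binary queen contiguity
on the prediction lattice, and the choice is recorded in the output
metadata because the statistics are meaningless without it. Correlograms compute Moran's I per
great-circle distance bin (default: 10 equal-width bins to half the domain
diameter). Both statistics are affine-invariant in the values, match a
dense double-loop oracle to $10^{-12}$, and reproduce the permutation-null
expectation $E[I] = -1/(N-1)$.

## The synthetic world

`generate_truth_climatology()` builds smooth probability surfaces
(Gaussian-filtered white noise rescaled to a stated range) with uniform,
single-peak, or bimodal seasonal structure; `generate_cloud_stack()` draws
daily flags as independent Bernoulli trials per pixel and day, with two
artifact switches — validity-gap stripes (missingness every
`overpass_gap_period` days along the stripe bands) and a multiplicative CF
bias along those bands (the destriping stages' target, amplitude 0.15 in
the analysis world). Stations average the truth within their footprint plus
Gaussian noise (SD 5% of sky); regular reporters log ~90 observations per
month (several synoptic reports daily) and a 20% minority logs ~10,
exercising the completeness filters in both directions. Presence points
are a thinned Poisson realization of a log-linear intensity; occupancy data
follow the ZIB law exactly. Every generator records its parameters, and
all randomness flows from one root seed through named substreams.

What a green test does *not* establish: flags here are independent across
days and pixels (no weather persistence, no spatially correlated
missingness beyond the stripes), stations have no reporting biases beyond
additive noise, and presences carry no observation bias — so recovery
results certify the estimators, not the real-world product accuracy. In
the analysis world two realism choices matter: the truth field's
correlation length (8 cells) is set above the 16-km footprint so that
footprint averaging preserves spatial signal, and the occupancy covariates
are fields on the survey grid (mean annual cloud truth plus an independent
smooth habitat axis), so prediction-surface autocorrelation is a real
signal rather than noise.

## Numerical choices and degenerate inputs

* Raster I/O uses plain-text ASCII grids with a JSON sidecar (CRS, band
  labels); read-after-write is the identity on values, mask and
  georeference. Files without georeferencing or CRS are hard errors; a
  missing nodata declaration warns and yields an empty mask.
* Cell registration: cell centers, row 1 = northernmost, half-open cell
  intervals for point lookups.
* Masked cells propagate: any derived metric is masked wherever a required
  input is masked; the moving-window SD needs at least two contributing
  cells; inter-annual SD needs at least two years.
* The moving window is a radius in cells with no great-circle correction —
  a stated simplification appropriate for abstract synthetic grids.
* Whether biome summaries should weight cells by area is undecidable from
  available anchors; `zonal_stats()` reports unweighted cell statistics
  and exposes `n` so area weighting can be applied downstream.
* Hotspot deciles are computed over the whole unmasked domain (not per
  region); degenerate (constant) variability surfaces are an error rather
  than an arbitrary all-or-nothing classification.

## Known limitations

* The destriping filter assumes the stripe orientation and cross-profile
  are known; estimating them from data is out of scope.
* The quadratic noise model cannot remove the mean component of a biased
  artifact (see above) and under-removes amplitude-modulated stripe
  energy relative to the full sparse-prior estimator it stands in for.
* DIC on mixture-type likelihoods can misbehave ($p_D < 0$); it is
  reported with a warning when it does.
* AUC for presence-only fits depends on the background sample; the seed is
  recorded in the fit so numbers are reproducible.
* Station validation compares sky-fraction amounts to overpass-time
  frequencies directly; any diurnal-sampling bias in a real product would
  appear as a slope/intercept offset, which the residual summaries are
  designed to localize.
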