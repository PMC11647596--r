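---
title: "Models and methods behind leafheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafheat)
```

`leafheat` analyses whether trees acclimate to the elevated temperatures
of an urban heat island: it contrasts paired-site microclimates, predicts
leaf temperature from traits and environment, and estimates two
physiological acclimation axes — the photosynthetic thermal optimum and
photosynthetic heat tolerance — on a nested species × site × tree design.
This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generator
can and cannot stand in for.

## Leaf energy balance

The leaf temperature of a horizontal sun leaf is modeled with the
linearized energy balance

$$T_l = T_a + \frac{\gamma^*}{s + \gamma^*}\left[\frac{R_{ni}}{g_{HR}\,c_p}
 - \frac{\mathrm{VPD}}{\rho\,\gamma^*}\right]$$

which balances absorbed isothermal net radiation $R_{ni}$ against
sensible heat, thermal re-radiation (linearized into the radiative
conductance $g_r$) and latent heat loss. The model is algebraic, not
iterative: it linearizes the saturation curve at air temperature, which
is accurate for moderate leaf-to-air differences and keeps every step
auditable. Assumptions: a flat horizontal leaf in steady state,
forced-convection boundary layer, no heat storage, no canopy radiation
transfer.

Component formulas and constants
($c_p = 29.3$ J mol⁻¹ °C⁻¹, $\gamma = 6.66\times10^{-4}$ °C⁻¹,
$\sigma = 5.67\times10^{-8}$ W m⁻² K⁻⁴):

* $\rho = 101.3\,e^{-\mathrm{altitude}/8200}$ kPa. The decaying exponent
  is used; a positive exponent would make pressure grow with altitude,
  which is unphysical.
* Saturation vapor pressure uses the Tetens form
  $e_s(T) = 0.611\,\exp(17.502\,T/(T+240.97))$ kPa. Field protocols in
  this area name VPD without defining it; Tetens with these coefficients
  is the standard micrometeorological choice, and the slope term
  $s = (de_s/dT)/\rho$ follows analytically.
* $g_{Ha} = 1.4\cdot0.135\sqrt{u/d}$ and $g_{va} = 1.4\cdot0.147\sqrt{u/d}$
  mol m⁻² s⁻¹, with $u$ wind speed (m s⁻¹) and $d$ the effective leaf
  width (m). A wind floor of 0.1 m s⁻¹ is applied before the square root:
  free convection takes over in near-still air and the forced-convection
  formula would otherwise collapse to zero conductance.
* $g_r = 4\sigma T_{a,K}^3/c_p$ with $T_{a,K}$ in Kelvin — the standard
  linearized radiative conductance and the only dimensionally consistent
  form (protocol write-ups sometimes print it without the cube).
  $g_{HR} = g_{Ha} + g_r$ throughout.
* Whole-path vapor conductance $g_{wv}$: the default, `as_printed`,
  follows the field protocol's printed expression
  $0.5\,(g_s/2)\,g_{va} / ((g_s/2) + g_{va})$, which halves the stomatal
  conductance (one-sided stomata) and then halves the series result
  again; the factor of 0.5 has no stated physical justification, so the
  textbook hypostomatous series form $g_s g_{va}/(g_s + g_{va})$ is
  selectable via `gwv_mode = "series_hypostomatous"`. Neither is
  endorsed; results record which was used, and the printed form yields
  substantially warmer leaves because it throttles latent heat loss.
* $R_{ni}$ defaults to absorbed shortwave, $a \times$ irradiance, with a
  configurable net-longwave term defaulting to zero; a measured $R_{ni}$
  can be passed through unchanged. With the default, predicted
  leaf-minus-air differences are upper-bound-ish for clear days, since
  net longwave loss from a sunlit leaf is typically negative.

Units: °C at the interface, Kelvin inside the radiation law,
conductances in mol m⁻² s⁻¹, pressures kPa, radiation W m⁻².

## Photosynthesis–temperature response

Net photosynthesis follows the Gaussian response
$P(T) = P_{opt}\exp(-((T - T_{opt})/\Omega)^2)$: $T_{opt}$ is the thermal
optimum (°C), $P_{opt}$ the rate there, and $\Omega$ (°C) the offset at
which the rate falls to $e^{-1}$ (≈37%) of the optimum. Fits are per
tree by default (configurable), by Levenberg–Marquardt least squares
with:

* $\Omega$ parameterized as $\log\Omega$, enforcing positivity;
* deterministic initialization — $T_{opt}$ at the maximum of a 3-point
  moving average of $A_{net}$, $P_{opt}$ at the maximum $A_{net}$ — and a
  multistart over $\Omega \in \{5, 10, 20\}$ °C keeping the
  lowest-residual fit, so refits are reproducible and order-invariant;
* convergence tolerances of $10^{-12}$ on relative parameter and
  objective change, 500 iterations maximum;
* SEs from the estimator covariance, delta-method transformed for
  $\Omega$; fits with $T_{opt}$ more than 5 °C outside the sampled range
  are flagged extrapolated.

Species-level site contrasts pool tree fits by inverse-variance
weighting (the protocol literature is silent on pooling; weighting by
$1/SE^2$ is the minimum-variance choice) and apply the SE-overlap rule
$|x_1 - x_2| - 2.99\sqrt{SE_1^2 + SE_2^2} > 0$. The multiplier 2.99 is
used exactly as the field protocol states it (an adjusted t-score for
multiple comparisons); it is not recomputed from degrees of freedom.

## Photosynthetic heat tolerance

Dark-adapted Fv/Fm declines with 15-minute water-bath treatment
temperature as the three-parameter logistic
$\theta_1/(1+\exp(-(\theta_2+\theta_3 T)))$, $\theta_3 < 0$. Trees whose
control-temperature disks average below 0.75 (healthy leaves sit near
0.8) are excluded whole. Thresholds are closed-form damage temperatures
relative to the fitted asymptote $\theta_1$ — not to the nominal 0.8 —
at 15% (T_crit), 50% (T50 $= -\theta_2/\theta_3$) and 95% (T95) loss.
T_crit is deliberately the 15%-damage point of the same logistic rather
than a segmented-regression breakpoint, keeping all three thresholds on
one fitted curve.

Initialization is deterministic: $\theta_1$ from the control mean,
$\theta_3$ from the steepest adjacent drop of the temperature-mean curve
scaled by $4/\theta_1$ (the logistic's slope–derivative relation at
midpoint), $\theta_2 = -\theta_3 T_{1/2}$ with $T_{1/2}$ the first
temperature whose mean falls below half the control. Fits whose
$\theta_3 \ge 0$ (no decline) are flagged invalid and excluded
downstream.

**Bootstrap.** Confidence intervals are percentile (2.5/97.5) over
refits of resampled disks, 1000 replicates by default (100 is available
for lighter protocols). Resampling is *unstratified* by default: with
only three disks per bath temperature, resampling within strata deflates
each stratum's bootstrap variance by $(n-1)/n = 2/3$, and simulation at
the design scale shows the stratified intervals undercover badly
(roughly 83% instead of 95% for true T50), while plain resampling
reaches ~92%. Stratified resampling remains available
(`stratified = TRUE`) for designs with many disks per temperature, where
its guarantee of full curve support matters more than the small-stratum
deflation. Failed refits are dropped and counted; more than 50% failures
flags the interval unreliable.

## Microclimate contrast

Daily summaries (whole-day mean, daytime mean, daytime maximum, night
mean) split day from night by measured irradiance above 5 W m⁻², not by
clock hours — the loggers record irradiance, and a fixed clock rule
would misclassify twilight. Days with under 80% of the expected 48
records are dropped to avoid biased maxima.

Because daily temperature series are serially correlated, each site's
daily series is prewhitened before the location test: AR(p) by
Yule–Walker, order 0–5 selected by BIC (AIC too often picks spurious
orders on white series), with $d = q = 0$ — the aim is only
serial-correlation removal before a rank test, for which AR prewhitening
is sufficient and fully specifiable. The fitted mean is added back to the
innovations so the residuals keep the site's temperature level;
otherwise the rank test would compare mean-zero innovations and be blind
to the very offset under study. A constant series degenerates to order 0
with all-zero (demeaned) residuals.

The rank-sum test enumerates all rank assignments exactly (midranks
under ties) for pooled samples of 12 or fewer, and uses the
tie-corrected, continuity-corrected normal approximation otherwise. The
two-sided p is the doubled smaller tail, capped at 1.

## Leaf traits

SLA = area/dry mass (mm² mg⁻¹); LDMC = 1000·dry/fresh (mg g⁻¹ — some
trait tables print g g⁻¹; the conversion is exactly the factor 1000);
absorptance $a = 1 - R - T$ from band-averaged reflectance and
transmittance. Leaf area is the silhouette's foreground pixel count over
the squared resolution. Effective leaf width — the diameter of the
largest circle fitting within the leaf margin, which sets the
boundary-layer dimension — is twice the maximum of the exact Euclidean
distance transform: deterministic, $O(\text{pixels})$, and exact for
convex shapes up to discretization. At ≥10 px/mm the width error is
below 2% for smooth margins; masks are padded so the image border counts
as background, and disconnected masks are reduced to their largest
component with a warning. Traits are computed per leaf and then averaged
per tree (the alternative, pooling leaves before computing, is not
offered; per-leaf-then-mean keeps leaf-level QC possible). Leaf
thickness is a pass-through of the micrometer measurement.

## The synthetic-data generator

The generator emulates the study's design so every stage is testable
without field data: 7 species × 2 sites × 10 trees; 9 bath temperatures
(22.0–56.5 °C, the lowest being the control) × 3 disks per tree — 3780
disks; A–T curves on 20–40 °C in 2 °C steps; 5 leaves per tree for
traits; and paired 30-min microclimate series.

Defaults are the study conditions: the microclimate sites are sinusoidal
diurnal cycles (peak 14:00, clear-sky half-sine irradiance 06:00–18:00)
with hot-site mean 23.3 °C/max 37.8 °C and cold-site mean 22.0 °C/max
34.4 °C — encoding the 1.3 °C mean and 3.4 °C maximum offsets by
construction — plus stationary AR(1) noise (marginal SD 1 °C, lag-1
correlation 0.7). Heat-tolerance truth is $\theta = (0.8, 30, -0.6)$,
i.e. T50 = 50 °C, the regime observed for temperate urban trees, with a
tree-level Gaussian shift on $\theta_2$ (SD 0.3, moving each tree's T50
by ~0.5 °C without changing slope — the simplest nesting consistent with
per-tree fits) and disk noise SD 0.03 clipped to [0, 1]; clipping
slightly biases the most extreme treatments toward the interior, which
matters only for noise SDs several times the default. Gas-exchange truth
is $P_{opt} = 15$ µmol m⁻² s⁻¹, $T_{opt} = 28$ °C, $\Omega = 12$ °C with
noise SD 1.0; gs and E are positive temperature-correlated companions
(gs tracks a broadened response curve, E scales with gs and evaporative
demand). The study never reported within- versus between-tree variance
components, so these noise levels are realistic placeholders for power
exploration, not estimates of the study's variances.

All randomness flows from one root seed through fixed sub-streams; the
same seed and configuration reproduce every table byte for byte.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: weather systems (fronts, clouds, heat waves)
beyond AR(1) noise; humidity and wind time series; species-realistic
allometry or trait covariance beyond configured means; leaf-level
non-logistic damage kinetics; spatial arrangement of trees and soil
water.

## Problem sizes and test design

The suite verifies fits exactly on noiseless fixtures (the model classes
contain the truth, so recovery must be ≤10⁻⁶ relative), against
brute-force lattice searches on noisy fixtures, and by simulation for
calibration claims. Two calibration studies deserve a note:

* 2-SE parameter coverage. With 11-point (Gaussian) and 27-point
  (logistic) fits, standardized estimation errors are t-distributed with
  8 and 24 df, so a ±2 SE band truly covers ~92–94%, not the normal
  95.4%. The suite estimates coverage from 1000 seeded replicates per
  model so the binomial error (~0.9 points) is small against the 90%
  pass threshold; at 100 replicates the estimate itself wobbles by ~±3
  points and fails sporadically under a correct implementation.
* Bootstrap coverage uses 100 simulated trees × 1000 resamples each,
  checking that the 95% T50 interval covers the known truth in 90–99 of
  100 trees.

The end-to-end pipeline test runs a reduced demo design (3 species × 3
trees, 10 days, 30 bootstrap replicates), chosen so a full run completes
in seconds while still exercising every stage.

## Known limitations

* The energy balance is linearized; for ΔT beyond ~10 °C the
  linearization of the saturation curve at air temperature
  overestimates the latent-heat response slope.
* The printed vapor-path rule (`as_printed`) is kept as the default for
  protocol fidelity despite its unexplained extra factor of 0.5; compare
  both modes before interpreting absolute ΔT.
* Percentile bootstrap intervals undercover slightly (~92% for a
  nominal 95%) at three disks per temperature; BCa or more disks would
  tighten this.
* The overlap test with the fixed 2.99 multiplier is conservative for
  two-group comparisons and is applied per species without further
  multiplicity control across species.
* T_opt fits assume the Gaussian response; strongly skewed responses
  (e.g. sharp high-temperature cutoffs) will bias $\Omega$.
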