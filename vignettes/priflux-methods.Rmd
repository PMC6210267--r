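---
title: "From paired PRI radiometers to canopy light use efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paired PRI radiometers to canopy light use efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priflux)
library(dplyr)
```

# The problem

Autonomous two-band PRI radiometers log radiance (downward-looking, restricted
field of view) and irradiance (upward-looking, cosine diffuser) at 532 nm — the
waveband sensitive to xanthophyll-cycle pigment conversion — and at 570 nm, a
reference band. The photochemical reflectance index
$\mathrm{PRI} = (\rho_{532} - \rho_{570})/(\rho_{532} + \rho_{570})$, and its
scaled form $\mathrm{sPRI} = (1 + \mathrm{PRI})/2$, track short-term
(facultative) changes in photosynthetic light use efficiency and slower
(constitutive) pigment-pool and canopy-structure changes.

The two fore-optics of a sensor pair respond differently to the diffuse
fraction of skylight: under overcast skies the restricted-view radiance optic
and the hemispherical irradiance optic see similar light fields; under direct
sun they do not, and the mismatch varies with solar elevation. Left
uncorrected, this imprints a spurious diurnal and weather signal on PRI that
swamps the physiology. `priflux` implements the offline cross-calibration that
removes it, and the downstream validation of corrected sPRI as a proxy of
canopy light use efficiency (LUE) against eddy-covariance carbon fluxes.

# The cross-calibration model

During a multi-week campaign the sensor pair stares at a 99% reflective white
standard panel. For an ideal Lambertian reflector the radiance/irradiance
ratio is $1/\pi \approx 0.318$ sr$^{-1}$ (`lambertian_ratio()`); measured
panel ratios scatter around $0.99/\pi$, with deviations that depend on sky
state. Two covariates capture that state:

* **solar elevation**, from the NOAA solar-calculator equations
  (`solar_position()`), discretised into half-open 3° bins
  (`elevation_bin()`): 3° corresponds to roughly 30 min of solar motion at
  morning and evening, when elevation changes fastest;
* **percent illumination**, the ratio of measured global radiation to the
  Ryan–Stolzenbach clear-sky model
  $I = I_0\,E\,a^{m}\sin h$ with altitude-corrected air mass $m$
  (`modeled_clear_sky()`, `percent_illumination()`).

Within each (waveband, elevation bin) cell, `fit_calibration()` regresses the
panel ratio on percent illumination by ordinary least squares. The fitted
lines have negative slopes — ratios are higher under diffuse light — and are
steeper at low elevations, flattening toward solar noon. `correction_ratio()`
evaluates them for field data, and corrected reflectance is
$\rho_\mathrm{corr} = \rho_\mathrm{uncorr} / \text{ratio}$
(`correct_reflectance()`), i.e. a reflectance factor relative to the white
standard; the panel's 0.99 is deliberately not divided out, since all
downstream quantities are ratio-based.

Two correction modes exist (`apply_calibration()`): **diurnal**, which keys
each observation on the bin containing its own solar elevation, and
**midday**, which uses the day's solar-noon elevation bin for all of that
day's observations. The midday mode mis-states the fore-optic mismatch away
from noon, which is exactly the morning/evening error the diurnal mode
removes — the package's synthetic experiments reproduce that ordering.

Numerical choices: illumination is capped at 120% (cloud-edge enhancement
retained without extrapolating far beyond the fitted 15–100% range) and
clamped to each bin's fitted span, never extrapolated — fitted slopes are
negative, so extrapolation could drive a ratio through zero. Elevations above
the campaign's maximum fall back to the nearest retained bin and are flagged.
Bins with fewer than 20 points or degenerate illumination spread are omitted.
Calibration functions are step functions across bins, mirroring the binned
procedure; no cross-bin interpolation is applied. No atmospheric refraction
correction is applied to solar elevations: refraction matters only below
~1°, inside near-night bins that never satisfy the minimum-n rule.

On the choice of solar algorithm: the declination and equation of time come
from the Meeus-style series behind NOAA's online solar calculator (accurate to
a few hundredths of a degree) rather than the simpler fractional-year Fourier
series. The Fourier form drifts by up to ~0.5° near the equinoxes in the
2010s — material against a 0.2° verification target, and needless given the
closed-form alternative. The test suite checks elevations against an
independent Astronomical-Almanac implementation on 1000 random site/time
pairs.

# Canopy structure: fAPAR, broadband NDVI, phenology

A wireless sensor network of quantum-sensor pairs above and below the canopy
yields the fraction of absorbed PAR,
$f\mathrm{APAR} = 1 - t - r + t\,r_s$ (`fapar()`), from the transmitted
fraction $t$, canopy-reflected fraction $r$ and soil reflectance $r_s$.
Broadband NDVI comes from pyranometer and quantum-sensor reflectance pairs,
$(\rho_\mathrm{PYR} - \rho_\mathrm{PPFD})/(\rho_\mathrm{PYR} +
\rho_\mathrm{PPFD})$ (`broadband_ndvi()`). Daily values are means of the
10:00–14:00 local window (`daily_canopy_indices()`), avoiding low-sun
artifacts; the sub-daily sampling window is a package choice, as is using the
network mean.

The NDVI–fAPAR relation is saturating, so `ndvi_fapar_fit()` fits a
degree-two polynomial of fAPAR on NDVI. The maturity-to-senescence
transition is detected by `phenology_transition()`: 7-day moving-average
smoothing, discrete second derivative by central differences, transition at
the most negative curvature in the post-peak part of the season. The smoother
and the post-peak restriction are package choices; a series without a
post-peak decline returns no transition rather than a spurious date.

# Flux partitioning and the light response

Half-hourly eddy-covariance NEE uses the meteorological sign convention
(negative = uptake; `covariance_nee()` demonstrates the block covariance;
raw 20-Hz corrections are out of scope). Records with friction velocity
strictly below 0.21 m s$^{-1}$ are discarded (`ustar_filter()`) as poorly
mixed.

Ecosystem respiration uses a single-window nighttime regression
$R_\mathrm{eco} = R_{10}\,Q_{10}^{(T-10)/10}$ (`nighttime_reco()`) — a
deliberate simplification of moving-window partitioning algorithms, chosen
to reuse the same respiration term as the light-response model and keep the
pipeline self-contained. GPP follows as $R_\mathrm{eco} - \mathrm{NEE}$,
clipped at zero (`partition_gpp()`).

The light response is the rectangular hyperbola

$$\mathrm{NEE} = -\frac{A_\mathrm{max}\,\alpha\,Q}{A_\mathrm{max} +
\alpha\,Q} + R_{10}\,Q_{10}^{(T_\mathrm{air}-10)/10}$$

with PPFD $Q$, fitted per consecutive 2-day window by Gauss–Newton with
step halving and an analytic Jacobian (`light_response_fit()`;
Levenberg–Marquardt through minpack.lm as fallback). Initial values:
$A_\mathrm{max}$ = 95th percentile of $-\mathrm{NEE}$, $\alpha = 0.02$,
$R_{10}$ = mean nighttime NEE, $Q_{10} = 2$. By default each window's raw
half-hours are fitted rather than a time-of-day composite: averaging NEE
across days at the same clock time mixes different sky states on a curved
response (the mean of the hyperbola is not the hyperbola of the mean) and
measurably degrades $\alpha$ recovery on cloudy synthetic seasons; the
composite variant remains available (`bin_two_day()`,
`fit_light_response_windows(composite = TRUE)`).

Fits are screened, not clipped: a fit is out of bounds if $\alpha > 0.125$
(the theoretical quantum-yield ceiling), $Q_{10} \notin [1, 4]$,
$A_\mathrm{max} > 100\ \mu$mol m$^{-2}$ s$^{-1}$, or the half-saturation
PPFD $A_\mathrm{max}/\alpha < 100\ \mu$mol m$^{-2}$ s$^{-1}$ — the last two
are the degenerate corners (hyperbola collapsed to a line; curve saturating
inside the noise) that flat, low-signal windows produce. A linearised
standard error of $\alpha$ from the Jacobian at the optimum is reported, and
`reliable` flags windows with $SE(\alpha) < 0.5\,\alpha$. The pipeline's
seasonal $\alpha$ trajectory keeps every converged in-bounds window —
low-signal shoulder-season windows are individually imprecise but anchor the
seasonal envelope — and removes isolated fit jumps with a 5-point running
median.

# LUE and the proxy models

$\mathrm{LUE} = \mathrm{GPP}/\mathrm{APAR}$ with
$\mathrm{APAR} = f\mathrm{APAR} \times \mathrm{PPFD}$ (`lue()`), reported
only where APAR exceeds 50 µmol m$^{-2}$ s$^{-1}$ to avoid dawn/dusk ratio
blow-up. Proxy models are linear season-wide calibrations
$\mathrm{LUE} = a\,x + b$ for $x \in \{\mathrm{sPRI}, \alpha\}$
(`fit_lue_model()`; a maturity-only scope is available), and modeled GPP is
$(a\,x + b)\,\mathrm{APAR}$ with negative predictions clipped
(`predict_gpp()`), preserving the identity GPP$_\mathrm{model}$/APAR =
modeled LUE wherever nothing was clipped. Pearson correlations, stratified
by phenological stage, quantify the facultative/constitutive split
(`stratified_correlation()`).

Comparisons involving $\alpha$ are made at its native 2-day resolution:
window LUE is flux-weighted ($\sum \mathrm{GPP}/\sum \mathrm{APAR}$, the
standard period definition, far less noise-prone than averaging half-hourly
ratios), and the piecewise-constant $\alpha$ series is correlated against
it. All other comparisons are at 30 min. Whether such regressions are better
run on 30-min or daily aggregates is genuinely open; 30 min is implemented
as the default with aggregation left to the caller.

# The synthetic study conditions

`generator_config()` fixes a complete synthetic measurement system at a
boreal aspen site (56.7439° N, 118.3439° W, 867 m): a 23-day white-panel
campaign around the solstice spanning 0–56° solar elevations and 15–100%+
illumination, and a May–October canopy/flux season. Its components:

* **Sky.** Clear-sky radiation times an AR(1) cloudiness process in logit
  space, producing persistent mixed-sky days, occasional deep overcast
  (< 15%) and cloud-edge enhancement (> 100%). PPFD = global × 0.45 × 4.6
  (PAR fraction times quantum conversion, both configurable).
* **Fore-optic bias.** A multiplicative gain per band,
  $1 + s_b\,w(h)\,(100 - \mathrm{illum})/100$ with elevation weight
  $w(h) = \max(0.15,\, 1 - h/60)$ — linear in illumination at fixed
  elevation, so the binned linear calibration functions are well specified.
  The 0.15 floor reflects residual diffuse-fraction sensitivity at high sun
  and keeps every bin's slope statistically identifiable; panel noise is
  elevation-weighted (larger specular scatter at low sun).
* **Canopy.** Double-logistic NDVI phenology whose fall inflection (most
  negative curvature) is placed on the configured day (default day-of-year
  233); fAPAR follows the saturating quadratic of NDVI; WSN channels encode
  both with 2% multiplicative noise.
* **Fluxes.** GPP from the rectangular hyperbola with $A_\mathrm{max}$
  scaled by canopy phenology and $\alpha$ = peak × phenology × a lognormal
  AR(1) day-to-day factor (quantum yield collapses outside the green
  season and varies with meteorology within it); NEE = −GPP + $R_{10}
  Q_{10}^{(T-10)/10}$ + Gaussian noise (default sd 1 µmol m$^{-2}$
  s$^{-1}$, a typical random flux error).
* **sPRI.** Coupled to instantaneous true LUE with slope 12 and intercept
  0.30, weighted by canopy state (the facultative xanthophyll signal
  requires functional leaves); plus an fAPAR-proportional constitutive
  drift and extra decoupling noise during senescence; plus a persistent
  AR(1) canopy nuisance (sunfleck/background scatter, sd 0.06 scaled by
  canopy state) and a band-differential solar-azimuth BRDF modulation of
  the measured radiance. The azimuth artifact is deliberately
  uncorrectable — the cross-calibration does not model azimuth — and is
  absent over the flat panel. These scales were set so the seasonal sPRI
  standard deviation and its stage-wise efficiency correlations land in
  the range canopy PRI studies report (σ ≈ 0.06–0.1, r² ≈ 0.3–0.5), not
  an implausibly clean proxy.

Every realisation writes a truth table holding the exact reflectances, LUE,
GPP, respiration, fAPAR and parameter trajectories, and
`true_calibration()` gives the closed-form calibration truth per bin. For
scoring a binned fit, the truth is evaluated at each bin's mean visited
elevation: binned OLS estimates the visit-weighted average of the truth
function, which matters for the top bin truncated by the site's maximum
elevation.

What the generator does **not** emulate: radiative-transfer realism (no
BRDF beyond the single azimuth harmonic, no sunfleck geometry, no spectral
variation within bands), instrument drift and temperature sensitivity,
gap patterns and sensor outages, footprint mismatch between the optical
field of view and the flux footprint, and advection or storage terms in
NEE. Passing tests therefore demonstrate the pipeline's correctness and
its statistical behaviour under a controlled, documented noise model — not
field performance.

# Problem sizes and verification design

The test-suite and acceptance computations use: one 23-day 1-min panel
campaign (~46,000 paired observations); full May–October seasons at 1-min
optical / 15-min WSN / 30-min flux resolution (~242,000 optical rows);
100 seeded replicates for quantum-yield recovery at 0.5 µmol noise;
20 seeded seasons for transition detection (the daily canopy layer is
generated directly, which makes this cheap); and four replicate seasons,
pooled, for the stage-stratified correlation orderings. Pooling replicates
is a deliberate design choice: a single season's stage-wise r² carries
sampling error of ±0.05–0.08, large enough that orderings with a true
margin of ~0.1 can tie by chance, while the pooled estimate is stable.
The transition criterion is likewise summarised as the mean absolute error
across the 20 seasons.

The light-response fitter is verified along two independent routes: a
brute-force refined grid search over the four parameters, and `stats::nls`
on the same windows; the solar-position implementation against a separately
coded Astronomical-Almanac algorithm; the calibration and correction
algebra against the generator's closed-form truth.

# Known limitations

* The calibration does not model solar azimuth; residual
  directional-reflectance error remains in corrected field PRI (and is
  present, by design, in the synthetic canopy data).
* The simplified single-window respiration regression ignores seasonal
  variation in temperature sensitivity; it is adequate for the synthetic
  conditions (constant true $R_{10}, Q_{10}$) but is not a substitute for
  full partitioning algorithms on real data.
* The proxy→LUE mapping is a season-wide linear calibration; the stage
  analysis itself shows the coupling differs between maturity and
  senescence, so stage-specific calibrations (supported via `scope`) may be
  preferable in application.
* Half-hour binning uses a 50% coverage rule; sites with systematic
  sub-window gap patterns may need a stricter rule.
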