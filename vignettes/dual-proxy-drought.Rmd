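---
title: "Dual-proxy reconstruction of atmospheric and soil drought from tree rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-proxy reconstruction of atmospheric and soil drought from tree rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodrought)
```

## The problem

Trees in semi-arid mountain woodlands experience two distinct kinds of
drought.  *Soil drought* — a deficit in the accumulated water balance —
limits water uptake, turgor and cambial activity, and is commonly indexed by
standardized multi-month precipitation-minus-evapotranspiration anomalies
(the SPEI family).  *Atmospheric drought* — high vapor pressure deficit
(VPD) — drives evaporative demand at the leaf irrespective of soil water.
Ring width (TRW) responds mainly to the former; the oxygen-isotope ratio of
ring cellulose (δ¹⁸O) records leaf-water evaporative enrichment and hence
the latter.  Used together, the two proxies can separate the drought types
over centuries where instrumental records cover only decades.

`dendrodrought` implements that dual-proxy workflow end to end for
long-lived junipers of the kind found between roughly 2000 and 2700 m
a.s.l.: chronology building with signal-free detrending, isotope elevation
normalization, climate-index targets, transfer-function calibration with
leave-one-out validation, full-period reconstruction, k-means drought
typology, and superposed epoch analysis (SEA) of growth responses.  A
seeded synthetic-data module generates climate and proxy series with known
transfer functions so every stage can be tested against ground truth.

## Chronology construction

Raw ring widths mix a biological age trend with the common climate signal.
Each series is divided by a fitted growth curve to give ring-width indices
(RWI ≈ 1), which are averaged across series per year with Tukey's biweight
robust mean (tuning constant 9 on the MAD scale, iterated to relative
change < 10⁻⁶, median fallback when the MAD collapses, arithmetic mean for
n ≤ 2).

Detrending is *signal-free*: the chronology is divided back out of the
measurements before the growth curves are refit, and the loop repeats until
the maximum absolute chronology change falls below `tol` (default 10⁻⁴,
at most `max_iter = 20` iterations).  This reduces the trend distortion of
one-pass detrending, at the price of a weakly identified decomposition: the
product of per-series growth curves and the chronology admits a smooth
near-null direction.  Two numerical choices follow from that:

* **Growth-curve fitter.**  The default is the modified negative
  exponential `a·exp(−b·age) + k` (parameters kept positive by optimizing
  on the log scale with a deterministic Nelder–Mead search, polished by
  Gauss–Newton where it converges cleanly, with non-increasing-line and
  horizontal-mean fallbacks).  Its rigidity makes the signal-free iteration
  contractive.  Flexible smoothing splines — an age-dependent spline whose
  50% frequency cutoff grows with cambial age (`"ads"`, cutoff = age +
  `stiffness`), and a fixed 67%-of-length spline (`"spline"`) — are
  available, but with a smoother this flexible the iteration can drift
  slowly along the near-null direction instead of contracting, so a stall
  guard stops it (flagged, with a warning) when the chronology change stops
  shrinking while still well above tolerance.  On zero-noise synthetic data
  the default fitter recovers a shared multiplicative signal with
  correlation above 0.99 (see `test-chronology.R`).
* **Branch freezing.**  Within the loop each series keeps the fitting
  family chosen on the first pass and warm-starts from its previous
  parameters; letting series flip between the exponential and its
  fallbacks destabilizes the fixed point.

Chronology quality is summarized by the classical statistics: mean
inter-series correlation (rbar, pairwise Pearson over ≥ 10 common years),
expressed population signal EPS = n·r̄/(1+(n−1)·r̄), signal-to-noise ratio
SNR = n·r̄/(1−r̄) (so EPS = SNR/(1+SNR) identically), per-year subsample
signal strength, and the lag-1 autocorrelation of the chronology.  The
replication n entering EPS/SNR is the time-averaged sample depth, since a
single whole-period value is reported.  Gleichläufigkeit (`glk()`) uses the
convention that a pair with exactly one zero first-difference scores ½.
Missing rings encoded as width 0 are set to 0.001 mm (the measurement
precision) and flagged.

## Isotope elevation normalization

δ¹⁸O in precipitation, and downstream in cellulose, decreases with
elevation.  With trees sampled across several hundred meters of relief this
lapse inflates between-tree spread and can bias the chronology when sample
composition changes over time.  The package fits per-tree period-mean δ¹⁸O
against elevation by OLS (≥ 3 trees, distinct elevations required;
two-elevation designs succeed with a leverage warning) and shifts every
series by `β₁·(reference − elevation)` to a common reference elevation
(default 2000 m).  The shift is constant per tree, so all interannual
anomalies and temporal correlations are preserved exactly — a property the
tests assert.  The gradient is assumed stable in time; no time-varying
correction is attempted.

The isotope chronology is the annual arithmetic mean across trees (robust
weighting is not worthwhile at replication ~5–8; a biweight switch exists),
with a Student-t 95% band and a minimum replication rule (default 5 trees;
deficient years are excluded and reported, never interpolated).

## Climate indices

* **VPD** is `es(T)·(1 − RH/100)` with the Magnus saturation curve
  `es(T) = 0.6108·exp(17.27·T/(T + 237.3))` kPa — the FAO-56-compatible
  constants, configurable since other constant sets circulate.  Monthly
  maximum temperature is the default demand-side temperature, with a flag
  for the monthly mean.  The seasonal target is the March–September mean.
* **Moisture index.**  The soil-drought target has the structure of the
  SPEI family: the monthly climatic water balance D = P − PET
  (Thornthwaite PET with the daylength correction at latitude 37° N;
  PET = 0 at or below 0 °C) is accumulated over k months ending in a target
  month (defaults k = 7, September — the full March–September growing
  season), then standardized.  Instead of the log-logistic fit of the full
  SPEI, an empirical normal-score transform (average ranks for ties,
  rescaled to mean 0/SD 1 over the reference years) is used: the pipeline
  needs a standardized index with SPEI's structure, not a parametric
  distribution, and the transform is invariant under any rank-preserving
  change of D.  A constant accumulation series maps to all-zero by
  convention.  Accumulation windows are taken over the continuous monthly
  sequence, so early years whose window reaches before the record start are
  undefined and dropped, not zero-filled.  One numerical point worth
  recording: window sums are computed per window rather than as differences
  of a running cumulative sum, so exactly tied water balances remain exactly
  tied through the rank transform.

## Calibration, validation, reconstruction

Proxy–climate screening uses Spearman rank correlations over a
month × accumulation grid with a pairwise-bootstrap significance (1000
resamples of year pairs; the two-sided p is twice the smaller tail fraction
of the resampled correlation around zero — the construction is declared in
the output rather than assumed identical to any particular screening tool).

Transfer models are OLS with one or two predictors — deliberately no more,
mirroring the scientific model space (δ¹⁸O → VPD; δ¹⁸O + RWI → moisture
index).  Reported diagnostics: R², adjusted R², residual SE, Durbin–Watson
Σ(eₜ−eₜ₋₁)²/Σeₜ², variance inflation factors (1 exactly for a single
predictor, 1/(1−r²) for two), and a Shapiro–Wilk residual-normality p.
Diagnostics never refuse a fit; only perfect collinearity does.

Validation is leave-one-out: each year is withheld, the model refit, the
year predicted.  From the assembled predictions: RMSE, MAE, cross-validated
R² (reported both as the squared Pearson correlation of predicted versus
observed, the common dendro convention, and as the 1 − SSE/SST skill form,
since the two differ and conventions vary), and the reduction of error
RE = 1 − SSE(pred)/SSE(calibration-mean null).  The RE null is the
calibration-period mean (the classical dendro choice), stated in every
report.  Degenerate folds are skipped and counted.

Reconstruction applies the fitted coefficients over the full proxy period;
the error band is the constant calibration residual SE (no time-varying
interval, no propagation of proxy replication).  The 10-year low-pass view
uses an FFT filter: mean removal, full reflection padding on both sides
(edge handling is otherwise the dominant artifact), a one-bin cosine taper
at the cutoff frequency, and exact restoration of the series mean.

## Drought typology and growth response

Reconstructed years are classified by k-means with k = 3 (severe
drought D, moderate M, non-drought ND) on reconstructed VPD, on the
reconstructed moisture index, and on the combined two-column matrix.  The
combined matrix is z-scored per variable first — unscaled kPa against
SPEI-like units would let one variable dominate the distances.  Labels
come from a fixed severity ordering (lowest moisture mean = D; highest VPD
mean = D; combined: highest mean z(VPD) − z(SPEI) = D, ties broken toward
the lower moisture mean), which makes them invariant to the arbitrary
cluster numbering of any particular k-means run.  Defaults: 25 restarts,
300 iterations, seeded.  Fixed index thresholds are deliberately avoided;
the clusters adapt to the site's own hydroclimatic regime.  Summaries
report per-cluster means, the drought-year fraction (D+M)/total, the
composition of each combined cluster by its (VPD label, SPEI label) pairs,
and 50-year-block trends in the severe share of drought years,
n_D/(n_D+n_M).

SEA composites the ring-width chronology at lags −w..+w (default w = 3;
a ±2 view is contained in it) around the severe years of each scheme.
Anomalies are standardized by the *whole-record* mean and SD of the
chronology — the normalization is stated in the output because conventions
differ.  Significance comes from a Monte-Carlo null: 1000 random event sets
of the same size drawn without replacement from all eligible years (events
included, the common convention; a switch excludes them), with percentile
confidence bands per lag.  The tests verify that the lag-0 significance
rate under a no-signal null sits near the nominal 5%, and the acceptance
suite re-runs that calibration at full size.

## The synthetic-data module

The generator produces the study conditions the pipeline assumes: 47 trees
(two cores each) on elevations uniform in 2000–2656 m over 1821–2020, with
a 1984–2020 calibration window, built so that the known transfer functions
are exactly recoverable at zero noise.

Causal order matters.  Monthly climate comes first: fixed monthly normals
(January mean 3.8 °C to August mean 28.4 °C; March precipitation maximum
48.7 mm, August minimum 0.19 mm; ~213 mm yr⁻¹) plus a latent AR(1)
(φ = 0.3) wet-year factor that raises relative humidity and (lognormally,
mean-corrected) precipitation together — the single source of the negative
VPD/moisture-index dependence.  The latent drivers are then *computed from
that table with the pipeline's own operators*: latent VPD is the
March–September table VPD, and the latent moisture index is the package's
standardized moisture index (k = 7, September).  δ¹⁸O follows the inverse
atmospheric transfer (VPD − a)/b (defaults a = −4.643 kPa, b = 0.218
kPa ‰⁻¹) plus the elevation term (−0.339 ‰/100 m), a between-tree offset
(SD 0.56 ‰), and per-year noise; the latent ring index follows the inverse
soil-moisture transfer given the moisture index and δ¹⁸O (defaults
14.371, −0.491, 2.537), rescaled to a mean-1 RWI baseline with the scale
kept in the truth object.  Raw widths are a modified negative exponential
growth curve (0.8·e^(−0.02·age) + 0.25 mm) times per-core noisy indices
(additive Gaussian, truncated at 0.05 to keep widths positive), rounded to
the 0.001 mm measurement precision.

Germination dates are drawn over a 150-year window before the span plus
its first 20%: the stand is multi-century, as sites with 200-year common
periods require, and a pure within-window cohort would confound cambial
age with calendar year and leave the growth-curve/chronology decomposition
unidentifiable.  Isotope series cover the whole span (the sampling
protocol demands full-period replication).  All randomness flows from one
integer seed; identical configs give bit-identical output.

Noise defaults were set once, from the variance budget, to emulate the
coherence structure of real multi-tree networks (per-year isotope noise
1.6 ‰ and ring-index noise 0.6 give rbar near 0.49 and 0.32 respectively);
transfer residual SDs are 0.22 kPa and 0.78 index units.  Problem sizes in
the test and acceptance suites (1000 forests for the elevation recovery,
2000 calibration windows, 1000 SEA null simulations) were chosen as the
smallest giving Monte-Carlo error comfortably below the assertion bands.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no mechanistic leaf-water enrichment (the
isotope–climate link is linear by construction), no missing or false
rings, no time-varying elevation gradient, no spatial structure among
trees, and no low-frequency climate trend beyond AR(1) persistence.  One
structural artifact is worth knowing: because the latent ring index is
defined through the inverse soil-moisture transfer given δ¹⁸O, RWI is
mildly positively tied to δ¹⁸O at fixed moisture, so the default generator
does not reproduce a negative growth anomaly in atmospheric-drought-only
years; growth-response ordering across drought types is therefore tested
on constructed event data with planted suppressions.

Calibrating proxy against climate on the default (noisy) synthetic data
shows the classical errors-in-variables attenuation of the fitted slope —
the proxy records the target imperfectly, so the regression slope is
biased toward zero relative to the generating value.  The recovery
simulations therefore follow the exogenous-predictor design (predictor
drawn first, target generated from it with residual noise), where OLS is
unbiased; at zero noise the full pipeline reproduces the atmospheric
transfer coefficients to better than six significant digits, and the
soil-moisture triple is exactly recoverable from the stored latents.

## Degenerate inputs and edge conventions

Rejected with informative errors: non-overlapping ring series; constant
series where a statistic is undefined (SEA on a flat chronology, Spearman
on a constant — reported `NA`, not zero); relative humidity outside
(0, 100]; temperatures at the Magnus pole; identical values offered to the
clusterer; mismatched years across classifications; perfectly collinear
predictors.  Years failing a completeness rule (a missing window month, a
replication shortfall, an event too close to the record edge) are dropped
and reported, never silently filled.  Tucson files auto-detect the 0.01 mm
(stop marker 999) and 0.001 mm (stop marker −9999) dialects from the
terminal marker, so an interior 999 in a 0.001 mm file reads as a 0.999 mm
ring.

## Known limitations

The elevation correction assumes a temporally stable gradient.  The
moisture index is an empirical stand-in for database SPEI — structurally
faithful, not numerically identical, so absolute correlation levels
against published values are not reproducible, only their structure.  The
signal-free decomposition is weakly identified at low frequency; the
chronology object reports `converged`, `n_iter` and `final_delta` so users
can see when the iteration stopped on the stall guard rather than the
tolerance.  Cluster means and SEA anomaly magnitudes are data products of
whatever series are supplied; only their orderings and invariants are
portable claims.
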