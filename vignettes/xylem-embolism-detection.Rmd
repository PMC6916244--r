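---
title: "Methods: weakly supervised detection of xylem embolism from acoustic emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised detection of xylem embolism from acoustic emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemAE)
```

## Scope and data model

`xylemAE` analyses a combined acoustic-emission (AE) and microCT drydown of
a woody stem. The observable units are:

* **AE hits** — one row per ultrasonic hit with a timestamp (`TIME_S`,
  seconds from experiment start) and the 18 waveform parameters exported by
  standard AE acquisition software: RISE (µs), COUN (–), ENER
  (10⁻¹⁴ V²s), DURATION (µs), AMP (dB), AFRQ (kHz), RMS (µV), ASL (dB),
  RFRQ (kHz), IFRQ (kHz), SIGSTRNGTH (10⁻⁹ Vs), ABSENERGY (aJ), the four
  partial spectral powers FREQPP1–FREQPP4 (%, summing to 100), FRQC (kHz)
  and PFRQ (kHz). The raw digitized waveforms are out of scope; parameters
  are taken as given.
* **Labelled windows** — spans of the scan timeline (4-min tomogram
  rotations grouped in 24-min runs, separated by 6-min day or 30-min night
  breaks), each carrying the number of new embolisms that microCT detected
  in it. This count is the *only* supervision: per-hit labels are never
  observed.
* **A dendrometer strain trace and point measurements of xylem water
  potential** ψ~x~ (MPa), used to convert time to a water-potential axis.

Six of the 18 parameters carry the discrimination: AMP, COUN, DURATION,
SIGSTRNGTH, ABSENERGY and FREQPP2 (the 100–200 kHz partial power), in that
fixed order. The remaining twelve exist so that ingest, PCA and the
correlogram handle the full schema.

## The count-weighted discriminant model

The generative assumption is classical LDA: background hits have feature
distribution N(μ₀, Σ), embolism hits N(μ₁, Σ), with one shared covariance.
With only window counts available, the class means are estimated as
count-weighted averages of the window mean vectors,

$$\hat\mu_1 = \frac{\sum_d n_{1,d}\,\bar x_d}{\sum_d n_{1,d}}, \qquad
  \hat\mu_0 = \frac{\sum_d n_{0,d}\,\bar x_d}{\sum_d n_{0,d}},$$

where $n_{1,d}$ is window $d$'s microCT count and $n_{0,d}$ its complement
(window size minus count — non-embolism events are not separately
detected, so the complement is the only available weight). The prior is
the global count ratio, and posteriors follow from Bayes' rule evaluated
through the linear discriminant score (a log-density difference), which is
numerically stable for any feature magnitude.

**Covariance centring.** The pooled covariance averages each window's
scatter, weighted by window size. The window scatter must be taken about
*some* centre; the package centres each window at its model-implied
mixture mean $(n_{1,d}\hat\mu_1 + n_{0,d}\hat\mu_0)/m_d$
(`cov_center = "model"`, the default). This choice has a sharp
justification: when every window is pure (count zero or count equal to
size), the estimator collapses *exactly* to supervised LDA — pooled class
means and within-class ML covariance — which the test suite asserts at
machine precision. Centring at the window's own mean
(`cov_center = "window"`) is available; on pure windows it under-counts
the between-window spread within a class and the degenerate equivalence
holds only approximately.

**Attenuation, and the moment-corrected variant.** When windows mix
classes, each $\bar x_d$ blends both class means, so the weighted
estimator is *attenuated*: $\hat\mu_1 - \hat\mu_0$ shrinks toward zero by
roughly the spread in within-window event proportions. This is a property
of the estimator, not a bug — it reproduces the characteristic behaviour
of count-supervised AE classification, where per-signal posteriors stay
far below 1 even though their *sums* per window track the observed counts
well (the fitted model is calibrated in aggregate). `method = "moment"`
instead solves the mixture moment equations
$E[\bar x_d] = \mu_0 + p_d(\mu_1-\mu_0)$ by weighted regression of window
means on the count proportion $p_d$; it is unbiased under the generative
model and is the right tool for parameter-recovery studies. The default
stays `"weighted"`: it is the estimator the analysis chain is defined
around. Identifiability of either estimator requires *contrast* — windows
must differ in their event proportions; if all windows share one
proportion, the direction μ₁ − μ₀ is not identified and the fit degrades
to the prior (predictions then equal prior × window size, which is still
count-calibrated).

**Validation.** `loo_crossvalidate()` refits on all windows but one (by
downdating the per-window sufficient statistics, so the full pass is
O(W²p²) rather than O(W·N)) and predicts the held-out window's expected
count. Folds left without any positive count fall back to the full-data
model and are flagged.

## Window construction

Hits are assigned to windows half-open, `[start_s, end_s)`, so a boundary
hit belongs to the window that starts there; hits in schedule gaps (e.g.
during instrument holds) are reported as orphans and excluded. Consecutive
windows in which microCT saw no embolism are merged into single
non-embolism datasets (`merge_nonevent_windows()`), while every event
window keeps its identity. This mirrors how combined AE–microCT timelines
are condensed into "embolism and non-embolism datasets" and concentrates
supervision contrast in the short event windows.

## Screening: thresholds and ROC curves

Because per-hit truth is unavailable, the parameter-wise ROC sweep counts
true positives *capped per window*: at threshold $t$, window $d$
contributes $\min(\#\{x > t\}, n_{1,d})$ true positives, the excess being
false positives. The sweep starts at the global parameter maximum (the
(0, 0) point) and ends below the minimum ((1, 1)). Two caveats are
documented and tested:

* Capped counting is **optimistic for uninformative parameters**: the
  first retained hits of an event window are credited as true positives
  regardless of truth, so a label-independent parameter's capped ROC lies
  well above the diagonal. The uncapped variant (`cap = FALSE`, which
  treats every hit of an event window as a potential positive) is the
  construction for which the diagonal null holds, and is what the test
  suite uses for that property.
* The histogram threshold for a single window is defined to retain
  *exactly* the window's count of hits, ties broken toward earlier
  timestamps; the reported threshold is the largest non-retained value.

## microCT event detection

Per scan, the 50 mid-centred slices are collapsed by per-pixel median
(robust to single-slice artefacts; mean available). Pairs of consecutive
projections are cropped with a *common* box (computed from the earlier
image, margin 2 px), median-filtered 3×3, and registered by rigid
translation plus isotropic scale about the image centre, minimizing mean
squared intensity difference — an integer grid search (±6 px) followed by
Nelder–Mead refinement on (dx, dy, log s). The registration contract
guarantees the reported residual never exceeds the identity residual; if
the optimizer cannot improve on doing nothing, the identity is returned
with a warning flag. Elastic contour matching used interactively on real
stacks is intentionally replaced by this rigid+scale model — the drift a
mounted sample exhibits between scans — and is a documented fidelity
reduction.

The difference image `before − after` makes grey→black vessel transitions
positive. One event is reported per 8-connected region of difference at
least the maxima threshold (default 30 grey values) above the zero
baseline, at the region's intensity-weighted centroid; for a difference
image the zero baseline makes height and prominence coincide. Events
closer than `min_separation` (default 3 px) are suppressed greedily,
strongest first, to avoid double-counting one vessel. On noise-free
planted data with transition depth above threshold, precision and recall
are exactly 1 (tested), and sub-threshold transitions are never reported.

## Vulnerability curves

* **Cumulation**: events (weight 1) or posteriors (their values) are
  cumulated and averaged within 10-min bins; the bin average is taken over
  a one-minute evaluation grid, which makes the "bin mean of the running
  cumulative" reading explicit. (Whether the field's "10-min averaging"
  means bin means or resampling at bin ends is not standardized; bin means
  are implemented, and the convention is logged by `run_full()`.)
* **Derivatives**: the order-k derivative is computed by k passes of
  centred windowed least-squares slopes, each pass using a window of
  `window_minutes / k`. For a cubic this construction is exact away from
  the edges (the h² bias of the first pass is constant and vanishes under
  the later passes), which the tests verify to well under 2%. A pass
  window narrower than 3 bins falls back to the 3 nearest bins — needed
  because the conventional first-derivative window (15 min) is narrower
  than two 10-min bins.
* **Endpoint rule**: the acoustic curve's endpoint is the first local
  maximum of the third derivative after the time of maximum AE activity
  (the first-derivative peak). If the third derivative is still rising at
  the end of the record — embolism unfinished — the endpoint is undefined
  and `NA` is returned; `run_full()` also reports `NA` when the record is
  shorter than the derivative window.
* **Rescaling**: the percentage ceiling is
  $100\,( \text{native} + \text{detected})/\text{total}$ — e.g. 541 native
  plus 457 detected of 1100 vessels gives 90.7, reported 91. The printed
  formula is read as a ceiling on the whole fraction (the only reading that
  produces the reported percentages), and the native count raises only the
  ceiling, never the starting value; the alternative convention (curves
  starting at the native percentage) is available behind
  `start_at_native = TRUE` and off by default.
* **Stress–strain mapping**: ψ~x~ is regressed on strain with a continuous
  three-segment linear model; the two breakpoints are found by exhaustive
  search over a grid of observed strain quantiles (default 5–95% in 2.5%
  steps), skipping candidates that leave a segment with fewer than two
  points. Breakpoint precision is therefore grid resolution, which the
  planted-model tests assert. Strain outside the fitted range is
  extrapolated linearly with a warning.
* **Vulnerability values**: the percentage-vs-ψ curve is isotonically
  corrected, smoothed with a GCV-tuned smoothing spline, clamped monotone
  on a 2000-point grid, and inverted at *absolute* levels 12/50/88/100% —
  absolute, not fractions of the ceiling, so that an 88% crossing can
  exist on a 91%-ceiling curve while 100% correctly does not (`NA`).
  Curves with fewer than four distinct ψ values fall back to linear
  interpolation. Curve comparison interpolates both curves onto a common
  ψ grid and reports the absolute-difference series, its mean and maximum,
  and the relative v50 difference $100\,|v_{50}^{ref} - v_{50}|/|v_{50}^{ref}|$.

## The synthetic generator

`simulate_experiment()` draws a complete experiment whose defaults are the
study conditions the package is designed around: a 96-h drydown of a stem
with 1100 vessels, 541 natively embolized, an expected 457 new embolism
events, a 28 dB-floored AE stream of roughly 25,000 background hits
(4.4 hits/min on average), 4-min rotations in 24-min runs with 6/30-min
day/night breaks, and a three-segment stress–strain relation reaching
about −6 MPa (breakpoints at strain 0.5 and 1.2 µm mm⁻¹, segment slopes
−1.2/−2.0/−3.5 MPa per unit strain).

Specific modelling choices, and why:

* **Embolism arrivals** are an inhomogeneous Poisson process whose
  cumulative intensity is logistic in the strain-mapped ψ~x~ (midpoint
  −2.3 MPa, scale 0.45 MPa), normalized so the expected total is exact —
  which makes the generator analytically checkable (the tests verify the
  457-event expectation over 200 replicates against the Poisson standard
  error). Counts are truncated at the available vessel budget.
* **Background AE is not uniform in time**: its intensity is a 30% uniform
  floor plus 70% proportional to the embolism hazard density. Dehydration-
  related AE sources (shrinking tissue, leaves) wax and wane with the
  drydown itself — AE activity peaks mid-experiment — and this coupling is
  precisely why even an *unfiltered* acoustic vulnerability curve can agree
  closely with the microCT reference. With a uniform background that
  agreement is structurally impossible, so uniformity would misrepresent
  the experiment the package emulates. The fraction is exposed
  (`background_uniform_frac`) and a fully uniform background is used in
  tests that need time-varying class contrast.
* **Class features** are drawn from the LDA generative model itself: six-
  dimensional normals with a shared covariance in which the five energetic
  parameters are positively inter-correlated (0.4–0.7) and FREQPP2 mildly
  anti-correlated with AMP and COUN, with class separations of about 2–2.5
  within-class standard deviations per feature. A configurable fraction
  (default 2%) of background hits is replaced by heavy-tailed outliers
  (deviations inflated 4×) to emulate sporadic non-Gaussian sources.
  Features are floored at physical zero; the defaults keep the floor
  essentially inactive (≲0.1% of draws) so the distributional convergence
  tests remain valid.
* **Partial powers** honour the 100% simplex: FREQPP2 comes from the class
  model and the remaining mass is split FREQPP1/3/4 by a Dirichlet draw.
  The other nine nuisance parameters are independent log-normals in
  plausible instrument ranges.
* **Images** are a disc-packed cross-section (default 300 vessels of
  radius 2–6 px in a 256² frame; water-filled grey 140, gas-filled 30,
  matrix 180) with anti-aliased edges, per-slice Gaussian noise (σ = 3)
  and a per-stack rigid drift (±1.5 px). Anti-aliasing matters: aliased
  edges make subpixel registration residuals spike above the detection
  threshold. All image levels are arbitrary fixture values, not
  measurements.
* **Seeding**: one master seed; each component (counts, arrival times,
  features, nuisance, images) consumes a deterministically derived child
  seed, so experiments are bitwise reproducible and components are
  independently stable.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no physical acoustics (attenuation, sensor
coupling, waveform shape), no spatial correlation of embolism within the
stem, no drift in the feature distributions over the drydown, no
registration deformations beyond rigid+scale, and class-conditional
normality is true by construction rather than an empirical fact. Results
on real experiments depend on how far those assumptions bend.

## Degenerate inputs and numerical choices

Covariances are factorized by Cholesky; near-singular fits receive a
relative ridge of 10⁻⁸ × trace/p, doubled until factorization succeeds.
A zero-embolism experiment is handled end to end: the LDA stage reports
its documented "all window counts are zero" error, the pipeline completes
with the unfiltered acoustic curve only, and the ROC stage refuses to run
without positives. Posterior evaluation never forms raw densities, only
log-density differences. All pipeline stages after the generator are
deterministic, so a full run is reproducible from its inputs alone.

## Problem sizes

The test suite and acceptance script run the default configuration
(~25,000 hits, ~375 windows) for end-to-end checks, 128²-pixel stacks of
9 slices for image tests, and n ∈ {10³, 10⁴, 10⁵} with 20 replicates for
estimator-recovery curves; these sizes give stable statistics while
keeping a full run in minutes on one core.

## Known limitations

The weighted estimator's attenuation means per-signal posteriors are not
calibrated class probabilities (only their window sums are); the capped
ROC is optimistic near the origin for weak parameters; breakpoint
estimates inherit grid resolution; and the registration family is rigid +
isotropic scale only. The acoustic endpoint rule requires the record to
extend past peak activity by at least the derivative window, otherwise the
endpoint is (correctly) undefined.
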