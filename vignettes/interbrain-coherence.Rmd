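---
title: "Interbrain wavelet coherence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interbrain wavelet coherence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadcoh)
library(dplyr)
```

## The problem

In a dual-fMRI hyperscanning experiment, two interacting participants (a
*dyad*) are scanned simultaneously on two synchronized scanners while they
perform a joint button-press task in five conditions per run: cooperation
(press simultaneously), communication (cooperation with voice chat during the
planning phase), competition (press faster than the partner), and a
solo/watch control pair in which one member performs alone while the other
only observes. The scientific question is whether and where the two brains'
BOLD signals become *coherent* — phase-locked at some frequency — beyond what
the shared task structure alone induces.

`dyadcoh` implements that analysis end to end on extracted ROI time series
(one eigenvariate-like signal per region, sampled at the TR): wavelet
transform coherence, empirical selection of a frequency band of interest,
per-block coherence extraction, a surrogate-dyad baseline correction, and
per-ROI repeated-measures inference. A synthetic-cohort generator with known
ground truth makes every stage testable without any scanner data.

## Wavelet transform coherence

The time-frequency decomposition uses the analytic Morlet wavelet with
centre frequency $\omega_0 = 6$ rad. Scales are geometric — `voices` scales
per frequency octave — and map to frequencies through the standard Fourier
factor $\lambda = 4\pi/(\omega_0 + \sqrt{2+\omega_0^2})$, $f = 1/(\lambda
s)$. The default grid spans 3.9–289.4 mHz at 12 voices per octave, which
yields 75 scales at TR = 1.5 s; the count follows
$\lfloor v \log_2(f_{max}/f_{min})\rfloor + 1$.

The CWT is computed by frequency-domain multiplication with L2-normalised
daughter wavelets, zero-padded to the next power of two beyond the wavelet
support so no periodic wrap-around reaches the record. A direct time-domain
convolution oracle in the test suite confirms agreement to better than
$10^{-8}$ relative error on short records.

Coherence of signals $x, y$ is the magnitude-squared quantity

$$ r^2(s, t) \;=\; \frac{\left|S\!\left(s^{-1} W_x \overline{W_y}\right)\right|^2}
{S\!\left(s^{-1}|W_x|^2\right)\, S\!\left(s^{-1}|W_y|^2\right)} $$

where $S$ smooths in time with a Gaussian kernel of standard deviation equal
to the scale (matching the Morlet envelope) and across scales with a centred
boxcar of 12 scales — the conventional smoothing pair for this estimator.
Both kernels are renormalised at record edges, so a constant field passes
through unchanged and, because one positive-weight operator smooths
numerator and denominator alike, $r^2 \in [0,1]$ holds exactly
(Cauchy–Schwarz), with self-coherence identically 1. Cross-phase is the
argument of the smoothed cross-spectrum, signed so that a pure delay
$y(t) = x(t-\tau)$ at frequency $f$ yields $+2\pi f\tau$. Points closer to a
record edge than $\sqrt{2}s$ (the envelope's e-folding time) fall outside
the cone of influence; they are flagged but, matching the block-extraction
procedure below, not excluded from averages unless requested.

Signals are mean-removed but not variance-normalised before transforming —
coherence is invariant under affine rescaling of either input, which the
test suite asserts directly.

## Band selection

Per ROI and scale, $r^2$ is averaged over all dyads, runs and in-block
volumes; the grand mean over ROIs gives one coherence curve across
frequency. Frequencies above 220 mHz and below 9.6 mHz are trimmed first, as
sampling and the coherence computation distort the extremes. The band of
interest is then defined empirically by the curve's *peak differentials*:
the peak frequency plus, on each side, the frequency of steepest slope.
Slopes are central differences on the scale index — the grid is geometric,
so index differences are derivatives in $\log f$ up to a constant, which
avoids unequal-step artifacts; the endpoints use one-sided differences and
slope ties resolve away from the peak (the inclusive reading of a linear
flank). Band edges are inclusive. The selection is invariant to shifting or
positively rescaling the curve. A monotone curve has no interior peak and
raises an error rather than inventing a band; for null-calibration
experiments, where no coherence peak exists by construction, the band is
supplied explicitly instead.

On synthetic cohorts with coupling injected at 80–150 mHz the procedure
recovers a band overlapping the injected one, with the peak within one voice
of the injected centre (see the test suite); on real data of this design the
analogous curve peaks near 137 mHz with edges near 81 and 153 mHz — periods
of 6.5–12.3 s, the time scale of the task's trial structure.

## Block extraction

One scalar coherence term per dyad, condition and ROI is obtained by
averaging $r^2$ over the band's scales and each block's volumes, where a
block window runs from the first trial's onset *plus 5 s* — the peak latency
of the canonical hemodynamic response — to the last trial's offset (end of
feedback). Windows convert to volume indices with `ceil` at the start and
`floor` at the end, half-open, so no out-of-block sample contributes. Block
terms are averaged over the two runs; the solo and watch blocks are averaged
into a single overarching "solo" condition, since while one member performs
solo the other necessarily watches — the two cannot be attributed uniquely.
ROIs unusable in more than a third of dyads are excluded entirely.

## The surrogate-dyad baseline

All dyads perform the identical, non-randomised block schedule, so a
substantial part of any interbrain coherence is driven by shared task
structure, not by the interaction. The correction pairs each subject with
every other-scanner subject except the true partner ("fake dyads"; never two
subjects from the same scanner, avoiding scanner-specific bias), runs the
identical extraction on each surrogate pair using the per-block intersection
of the two members' windows, and averages per subject — with $n$ dyads this
is an exhaustive $n-1$ permutations per subject and therefore
seed-independent. The dyad-level baseline is the arithmetic mean of its two
members' baselines (the symmetric choice; either single member's baseline is
available as an alternative strategy), and is subtracted from the raw term.

This is the pipeline's key calibration property: for uncoupled synthetic
cohorts the corrected values centre on zero cell by cell, while injected
dyad-specific coupling survives subtraction. Both are asserted in the
acceptance tests at the study's native geometry.

## Group statistics

Corrected terms are Fisher z-transformed (`atanh`, applied to the corrected
values as the procedure defines; a signed square-root variant is available
behind a flag since magnitude-squared and magnitude conventions both appear
in this literature). Outliers are screened per ROI and condition: first a
1.5 IQR fence, then iterative removal of the single most extreme value
(largest deviation from the running median) until |skewness| < 1 and
|excess kurtosis| < 2 — the moment thresholds this design treats as
acceptable normality — with a floor of 70% of values retained. Classical
g1/g2 moment estimators are used, with kurtosis on the excess (normal = 0)
convention. Removal affects only the offending cell; the ANOVA then uses
complete cases per ROI, the conservative choice for a within-dyad design.

Per ROI, a one-way repeated-measures ANOVA compares the four conditions
(cooperation, communication, competition, solo). Sphericity is tested with
Mauchly's W (chi-square approximation); when its p falls below 0.05 both
degrees of freedom are multiplied by the Greenhouse–Geisser $\varepsilon$
estimated from the covariance of orthonormal condition contrasts
($\varepsilon \in [1/(k-1), 1]$). The implementation is validated term by
term against a hand-computed fixture, against `stats::aov`, and against
`car::Anova`'s sphericity routines, and its null p-values are uniform by
construction (KS-checked in the tests).

Omnibus p-values are controlled across ROIs by Benjamini–Hochberg FDR at
q = 0.05. Post hoc paired t-tests are limited to contrasts containing
cooperation — cooperation−solo, cooperation−communication,
cooperation−competition — the only contrasts with a clean interpretation in
this design; their FDR family is all post hoc tests jointly (contrasts ×
significant ROIs), with a per-contrast family available behind a flag since
the reporting convention does not pin the family down.

## The synthetic cohort

The generator reproduces the design's geometry: TR 1.5 s, two runs of 775
volumes, five blocks per run in fixed order with the solo/watch pair swapped
in the second run, 18 trials per block, a 5 s planning phase, a uniform
stimulus delay averaging 1.05 s, and feedback averaging 2.55 s with the
feedback duration absorbing the delay jitter so trial durations stay
constant. Trial response times come from a per-condition bivariate normal
model (cooperative conditions slow and correlated, competition fast —
below the 1.6 s breakpoint, exercising the margin-shrinking response-time
adjustment of the scoring rules). Eighteen trials per block keeps the
five-block schedule plus rests inside a 775-volume run for typical response
times, mirroring the roughly 19-minute runs of this design.

Background noise per subject and ROI is AR(1) with coefficient 0.3 at unit
SD — a realistic one-lag autocorrelation for denoised BOLD eigenvariates at
this TR; an optional 1/f spectral shaping is available but off by default,
as extracted eigenvariates are already high-pass filtered in this design.
Interbrain coupling is injected additively at the extracted-series level:
in the configured (ROI, condition) cells, both members of every dyad receive
the same band-limited Gaussian component (default 80–150 mHz) over that
condition's block span, scaled to a multiple of the noise SD, with an
optional phase lag applied to the second member by rotating the component's
positive frequencies. There is no per-voxel hemodynamic forward model, no
motion or physiological artifacts, and no inter-dyad variability in coupling
strength — so passing tests demonstrate the machinery's calibration and
sensitivity under this idealised signal model, not performance on real
scanner data.

Every random stream derives from `(seed, subject or dyad index)`, so
cohorts are bit-reproducible and adding dyads never perturbs existing ones.

## Task scoring

The behavioral rules are implemented for simulation realism and for
analysing the simulated behaviour. Response times at or above 1.6 s are used
as-is; faster ones are mapped through $(e^{rt}-1)/2.5$. The published
formula's typography is ambiguous; this reading is the unique one that meets
the identity branch near-continuously at the breakpoint
($(e^{1.6}-1)/2.5 = 1.581 \approx 1.6$, within 1.2%) while shrinking the
margin sharply for fast presses, and the adjustment is exposed as a
pluggable function so alternative readings can be explored. The synchrony
margin is $E = \sum RT_{adj} / 8$; cooperation succeeds when
$|RT_a - RT_b| \le E$ (non-strict by default — "within a margin" — with a
strict flag, as the two descriptions of the rule differ on the boundary
case). Success earns both members +1, failure −1. Invalid trials (time-out
past 6 s, or a premature press) deduct 2 from the offender — "additional"
deduction is read as one point beyond the ordinary failure, with the
magnitude configurable since the exact value is not printed. Competition
awards the faster valid responder +1 and the slower −1; exact ties (a
probability-zero event for continuous response times) score 0/0 by default.
Block accuracy is the fraction of successful trials.

## Numerical choices and problem sizes

* FFT padding: next power of two past the record plus twice the widest
  kernel half-width (kernels truncated at 5 SD), so circular convolution
  never wraps record into record. The surrogate engine transforms only the
  band's scales plus the smoothing margin, *pinned to the full grid's padded
  length*: near-Nyquist scales are sensitive to padding, and pinning makes
  the restricted computation reproduce a full-grid `wtc()` exactly.
* The surrogate stage computes each subject's transform and smoothed
  auto-spectrum once per ROI and run and reuses them across all of that
  subject's pairings, which is what makes the exhaustive baseline
  affordable: terms for 900 pairings of a 30-dyad cohort cost roughly the
  transforms of 60 subjects plus one smoothed cross-spectrum per pairing.
* Degenerate inputs: zero-variance series raise an error before the
  transform; zero smoothed denominators yield $r^2 = 0$ rather than NaN; a
  degenerate ANOVA (zero error variance) is flagged rather than reported as
  an ordinary F.
* Test problem sizes: unit tests use shortened runs (260–500 volumes, 4–8
  trials per block, 2–6 dyads) and complete in seconds; the two
  calibration/recovery acceptance tests run the native geometry (775
  volumes, 20 dyads × 50 ROIs and 30 dyads × 12 ROIs) and take minutes
  each. The ROI counts there are deliberate scale-downs of a full-cortex
  parcellation — statistical behaviour per ROI is what is under test, and
  ROIs enter the pipeline independently until the FDR step.

## Known limitations

* The pipeline starts at extracted ROI series; volumetric preprocessing,
  GLM nuisance removal and eigenvariate extraction are upstream and out of
  scope, as are behavioral mixed models, clustering of communication
  styles, and questionnaire analyses.
* The generator's noise model is stationary AR(1); real BOLD noise is
  heteroscedastic and spatially correlated across ROIs, so real-data error
  rates can differ from the calibrated synthetic ones.
* Corrected values are not fully independent across dyads: every dyad's
  baseline is built from the same pool of surrogate partners, and the merged
  solo condition averages four block terms against two for the others. On
  null cohorts this leaves the per-ROI *uncorrected* omnibus p-values mildly
  anticonservative (a p < 0.05 fraction of about 0.14 at 20 dyads in the
  calibration run), while the FDR-controlled decisions the pipeline actually
  reports remain clean (no ROI declared significant under the null).
  Interpret uncorrected per-ROI p-values with this in mind.
* Coherence maps are kept in memory per dyad; cohorts far beyond a few
  hundred ROI × dyad combinations would need the streaming pattern the
  pipeline uses internally.
* HDF5 containers are not read or written; all artifacts are TSV.
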