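---
title: "kymoflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kymoflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoflux)
```

# What the package analyzes

Dual-trap optical tweezers stretch a single lambda-DNA molecule (48.5 kbp,
about 16 um at ~5 pN) between two beads while a confocal line scan repeatedly
images fluorescently labeled proteins bound to it. Each scan line takes
42.4 ms; stacking the lines gives a kymograph in which every DNA-bound
particle appears as a line of position versus time. Particle-tracking software
turns those lines into tracks: time in seconds, position along the tether in
micrometers, one color channel per label. `kymoflux` starts from those track
tables and quantifies four behaviors of ATP-dependent chromatin remodelers
(RSC and ISW2 are the motivating systems):

1. **1D diffusion** along the DNA, classified frame-by-frame into
   non-diffusive, low-diffusive and high-diffusive states;
2. **dwell times** (bound lifetimes, pause durations, colocalization
   lifetimes) fit by exponential maximum likelihood with AIC model selection;
3. **two-color encounters** between molecules (short colocalization with
   recoil, long colocalization with brief co-diffusion, or bypass) and
   remodeler-nucleosome colocalization;
4. **processive translocation**: sustained directional movement of a
   nucleosome-remodeler pair at tens of bp/s, segmented into constant-speed
   pieces and classified as pushing or pulling relative to the remodeler's
   1D approach direction.

A fifth, separate input type is the force-clamp unwrapping record used to
count nucleosomes on an array: at a 15-20 pN clamp each nucleosome's inner
DNA turn releases ~25 nm of extension as a discrete step.

Because the headline numbers in this field are fits to proprietary
kymographs, every stage here is validated instead by *parameter recovery*:
the `simulate_*` generators produce ground-truth-labeled synthetic data with
the statistical structure the analysis assumes, and the test suite checks
that the pipeline recovers the generating parameters.

# Units and physical constants

All positions are carried internally in micrometers; base pairs enter and
leave through a single conversion constant, `um_per_bp = 0.072/225`
(3.2e-4 um/bp), which encodes the equivalence of 72 nm and 225 bp for DNA
under this tension. The frame (line) time defaults to 0.0424 s. The
kymograph pixel size is not a quantity the analysis depends on directly, but
the synthetic studies use "one pixel" of localization noise; we fix
`pixel_to_um = 0.05` (50 nm, a standard confocal line-scan pixel setting,
comparable to but slightly below the ~72 nm localization precision typical
of these measurements). All of these live in `sim_config()` and are
overridable.

# Rolling-window diffusion analysis

For each track, 20-frame sub-trajectories are taken with stride one frame
from the beginning to the end. In each window the mean squared displacement
(MSD) over the first five lags is fit by ordinary least squares with an
intercept (the intercept absorbs the static localization-noise offset,
`2 sigma0^2`), and the apparent diffusion coefficient is `D = slope/(2d)`
with `d = 1` dimension. Negative fitted slopes, which occur under noise, are
floored at `D = 0` so that every window is classified. Windows in which any
of the first five lags has no observed pair (dark excitation pulses, linked
gaps) are left unclassified and excluded from state fractions.

Windows are classified by two thresholds: `D < 0.01` um^2/s is
*non-diffusive* (the band occupied by a truly immobile dCas9 control),
`0.01 <= D < 0.04` is *low-diffusive*, and `D >= 0.04` is *high-diffusive*.
The boundary value 0.04 is assigned upward (the threshold statement leaves
equality open; we fix it and make it configurable). Two filters then reduce
spurious state transitions when durations and fractions are quantified: the
position vector is smoothed by a centered 5-frame moving average (with
shrinking windows at the ends) before classification, and maximal runs of
equal labels shorter than 10 windows are dissolved into the flanking segment
with the longer duration (ties go to the earlier segment). Smoothing is used
*only* for state classification, never for estimating the reported `D`
values: a 5-point moving average attenuates the lag-1 MSD of free diffusion
five-fold, so smoothed positions systematically understate `D`.

Two quantitative consequences of this design are worth knowing. First,
directed motion at `v` produces a quadratic MSD whose 5-lag linear fit gives
an apparent `D ~ 3 v^2 dt`; at 300 bp/s this is ~0.0012 um^2/s, far below
the 0.01 threshold, so slow translocation is *invisible* to the
rolling-window method and lands in the non-diffusive class. That detection
limit is a feature of the windowed estimator, not a bug, and the
translocation module exists precisely to capture what it misses. Second, the
window-`D` sampling distribution at a true `D = 0.05` um^2/s has its median
essentially at the 0.04 threshold, so individual windows split roughly
50/40 between high and low; the per-track *modal* state is nonetheless
recovered reliably for 5000-frame tracks because the high fraction exceeds
the low fraction on average by ~0.1 (the recovery study in the test suite
runs 50 tracks per generative `D` in {0.005, 0.02, 0.05} and requires >= 90%
modal accuracy).

Localization precision follows the standard Gaussian-fit relation
`sigma0 = s/sqrt(N)` for a fitted PSF standard deviation `s` and photon
count `N`. (Some sources print this relation without the square root; the
square-root form is the standard estimator and is what
`localization_precision()` computes.)

# Dwell-time likelihoods

Event durations are modeled as exponential or two-component exponential
mixtures. The one-component MLE is closed form (the sample mean; with right
censoring, total observed time over the number of uncensored events). The
two-component fit runs EM from five deterministic starts (a median split
plus log-spaced pairs around the mean) to a 1e-8 log-likelihood tolerance;
censored events contribute their expected residual life inside the M step.
Model choice is by AIC with `k = 2 n_components - 1` parameters; ties go to
the smaller model. Fits are reported slow-component first.

Reporting convention: the field frequently labels the fitted exponential
time constant tau a "half-life". We report tau as the primary lifetime
(matching that convention) and additionally emit `ln 2 * tau` as
`half_life_ln2`, clearly labeled. All recovery validation is
convention-independent because we simulate at tau and recover tau.

Censoring is off by default: bound lifetimes in these experiments are
typically reported without bleaching corrections, and the synthetic studies
quantify the resulting bias instead (a Kaplan-Meier survival mode and the
censored MLE are available and tested). Durations below one frame time can
be excluded with `min_duration`; the default keeps everything, since the
instrument already cannot produce sub-frame durations.

# Two-color colocalization

The distance threshold below which two molecules count as colocalized comes
from their mobility: with mean diffusion coefficients `mu1`, `mu2` and frame
time `dt`, each molecule's RMS one-frame displacement is
`x_i = sqrt(2 mu_i dt)` and the pair threshold is `d = x1 + x2`
(~0.117 um for two molecules at 0.04 um^2/s and 42.4 ms). Empirically
determined constant thresholds can be imposed directly via `fixed_d` when
reproducing a specific dataset's operating point (values around 0.3 um are
typical for remodeler pairs).

Both tracks are smoothed with a Gaussian kernel before thresholding. The
smoothing scale is specified as a *time window of 5 exposure points*; we
interpret the 5-point window as the kernel support and use `sigma =
span/4 = 1.25` frames. A sigma of five full frames (support ~40 frames)
would raise the apparent minimum separation of a fast graze by several
hundred nanometers and make the most common event class — sub-frame
collisions with recoil — undetectable at the mobility-derived threshold, so
we treat the window, not sigma, as the stated quantity.

Maximal sub-threshold runs become candidate events and are classified:

* **bypass** (checked first): the sign of `x1 - x2`, averaged over 5
  smoothed frames on each side of the interval, flips, and both tracks
  persist at least 5 frames on each side;
* **long colocalization**: the interval exceeds 5 frames; or the raw
  separation change across the interval exceeds the threshold `d`; or the
  interval has at least 4 frames and its *interior* separation increments
  are far smaller than two independent diffusers could sustain (median
  interior step below `0.15 sqrt(2 mean_D dt)`), indicating co-movement;
* **short colocalization** otherwise.

The co-movement test is our reading of the "local diffusion coefficient"
validation: comparing a local relative-motion `D` directly against the mean
single-molecule `D` fails near contact, because the measured separation is a
*folded* (absolute-value) coordinate whose increments are compressed when
two molecules are close — even a genuine graze shows a local relative `D`
below the molecules' mean. Testing whether the interior of the interval is
essentially static separates grazes from brief co-diffusion much more
sharply. One limit is fundamental: a co-diffusion event whose realized dwell
is under ~2 frames is observationally identical to a graze and will be
classified short; at a 0.70 s mean dwell this bounds the long-event recall
near 91%, which is what the recovery study measures.

For remodeler-nucleosome analysis, nucleosome positions observed under
pulsed excitation are extended piecewise-constant across dark gaps using the
last visible signal (and back-filled before the first observation). Signals
whose positional SD while observed exceeds twice the localization precision
(default bound `2 x 0.072` um) are excluded as unstable — these typically
reflect non-specifically adsorbed labeled histones — and exclusion
propagates through linking: a stable signal linked to an excluded one is
excluded too. A remodeler within 500 bp (converted via `um_per_bp`) of a
mapped nucleosome is colocalized with it; maximal runs become events tagged
with the nucleosome identity.

# Translocation segmentation and push/pull

Processive translocation appears as a constant-slope stretch of the
position-time trace. Since the trace is continuous in position, changepoints
are located by recursive continuous piecewise-linear (hinge) fitting: within
a segment, the best single hinge is found by exhaustive search, and the
split is accepted when it improves the residual sum of squares by more than
`penalty_mult * log(n)` noise variances (the noise variance is estimated
robustly from first differences; `penalty_mult = 1.5` was calibrated on
synthetic speed-change recovery and gives no spurious splits on static or
single-speed traces). A continuous fit spends one extra parameter per
changepoint instead of three, which is what makes a subtle 20 -> 40 bp/s
slope change detectable at pixel-scale noise. Manual segment boundaries can
be supplied instead (`manual_breaks`), mirroring how such traces are often
segmented by eye.

Each segment is then fit by ordinary least squares. Segments adjacent to an
internal changepoint are fit with 1 s trimmed from the changepoint side:
changepoint-location error and the selection effect at the kink otherwise
bias the two slopes apart by up to ~10%. Speeds are reported in bp/s via
`um_per_bp`; a segment is *admitted* when it lasts at least 5 s, spans at
least 300 bp, and has R^2 >= 0.5. Static control traces (no ATP, or with a
non-hydrolyzable analog) processed identically yield no admitted segments —
flat noise fails the R^2 and distance filters. Note the admission filters
are deliberately strict: a genuine 20 bp/s segment lasting 10 s spans only
200 bp and is excluded by design.

Trace fragmentation labels every frame `search_1D` (diffusive), `engaged_static`
(colocalized with a nucleosome, not translocating) or `translocating`
(inside an admitted segment), with precedence translocating > engaged >
search. The push/pull call takes the longest translocating fragment (the
dominant event), finds the 1D search segment adjacent to it (directly or
across one engaged segment), and measures the approach direction as the sign
of the net smoothed displacement over the final 5 observed frames of that
search segment. When only a search segment *after* the translocation exists
(translocation ending in 1D disengagement), the first 5 frames of that
segment are used with the sign inverted. Translocation parallel to the
approach is a *push* (RSC-like, widening a nucleosome-depleted region);
antiparallel is a *pull* (ISW2-like); the call is undefined when either
direction is unavailable. The 5-frame window matches the smoothing span used
elsewhere; it is a design choice, not a measured constant.

# Nucleosome counting from force-clamp records

Unwrapping steps are detected by recursive binary segmentation on the
distance signal: the best mean-shift split of each segment is computed from
cumulative sums, and a split is retained when the local jump — difference of
plateau means over up to `noise_window` samples on each side, truncated at
the neighboring changepoints — is at least `min_step` (default half the
expected 25 nm). Truncating the size windows at neighboring changepoints
matters: with exponential waiting times, ~20% of steps are closer than the
window, and untruncated means inflate their sizes. Two nucleosomes
unwrapping within the detector's resolution merge into one near-double step;
`count_nucleosomes()` counts any step of at least 1.75x the expected size as
two, with a flag. A linear drift check on long plateaus warns when the
baseline moves by more than half a step within a plateau.

# The synthetic generators

The generators produce the study conditions under which every recovery test
runs; their defaults encode the measured operating points of the system:

* `simulate_switching_track()`: state-switching 1D Brownian motion with
  reflecting tether ends. Default three states at `D` = 0.001, 0.02, 0.06
  um^2/s (one per classification band) with mean lifetimes 3.8 s
  (non-diffusive, the measured pause lifetime on naked DNA) and 2 s for the
  two mobile states (unconstrained by a printed value; chosen as a plausible
  scanning timescale).
* `simulate_encounter_pair()`: labeled recoil / co-diffusion / bypass
  scenarios with exponential dwells (defaults 0.033 s and 0.70 s, the
  measured short and long colocalization lifetimes). The approach and
  retreat are stylized linear ramps moving at the RMS relative Brownian
  displacement per frame (the physical closing speed of two independent
  0.04 um^2/s diffusers), with small per-frame jitter. During a recoil
  contact the relative coordinate keeps moving at the full relative
  Brownian scale (no binding); during co-diffusion both particles share one
  Brownian displacement and the separation collapses to the noise floor.
* `simulate_translocation_track()`: piecewise-linear mean paths at
  configurable bp/s with Gaussian localization noise and an optional
  co-moving nucleosome channel.
* `simulate_force_clamp_trace()`: monotone stepped extension, 25 nm steps at
  exponential waiting times, Gaussian noise.
* `apply_observation_model()`: dark pulse schedules mark frames unobserved;
  single-step exponential photobleaching truncates the track. Fluorophore
  blinking is not modeled by default.

What these generators deliberately do **not** emulate: photon-level image
formation (no point-spread function or shot-noise model — tracks are
sampled directly), tracking failures and misconnections, spectral
crosstalk, tether drift, and any force dependence of motor speed. Passing
the recovery suite therefore demonstrates that the *analysis* is correct and
well-calibrated under the stated stochastic model; it does not certify
performance on raw images, where tracking quality dominates.

# Validation scales and numerical choices

The packaged studies (`run_validation_suite()` and the acceptance tests)
use: 50 tracks x 5000 frames per diffusion level; 1000 dwell draws per
lifetime (bias assessed as a mean over replicates, so the Monte Carlo error
of the bias estimate is ~1%); 500 encounters per scenario class; 100
translocation traces of 33 s (the median constant-speed segment duration)
at 29 bp/s (the measured mean speed) with one pixel of noise, plus 100
static controls; 200 push/pull traces; and 100 force-clamp traces at 10 or
30 nucleosomes with 2 nm noise. These sizes put every Monte Carlo standard
error well inside the acceptance margins while keeping the full suite at
about two minutes on one core.

Degenerate inputs are handled explicitly: empty track lists produce valid
empty reports with a warning; tracks shorter than one analysis window are
skipped; label sequences in which every run is below the minimum run length
collapse to the modal label with a warning; all-censored dwell samples give
a flat survival curve with a warning; EM restarts that fail to converge
report the best restart with a flag, and mixture components with weight
below 0.01 are flagged as degenerate.

# Known limitations

* The threshold-based three-state classification is reproduced as published;
  no hidden-Markov or Bayesian state inference is attempted.
* Sub-frame co-diffusion events are indistinguishable from grazes (see
  above); event-type proportions for the short class are correspondingly
  conservative.
* Mixtures with more than two exponential components are not fit.
* The rolling-window `D` at the high/low boundary is intrinsically noisy for
  single windows; only windowed aggregates (fractions, modal states,
  segment durations) should be interpreted.
* Speeds below the admission filters (short, slow, or low-R^2 segments) are
  reported but flagged inadmissible rather than silently dropped, so users
  can audit the filter's effect.
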