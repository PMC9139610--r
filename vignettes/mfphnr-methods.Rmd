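---
title: "Methods: simulating and analysing multifocal PhNR recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing multifocal PhNR recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfphnr)
```

## The measurement problem

The photopic negative response (PhNR) is a slow negative wave that follows
the b-wave of the cone-driven electroretinogram and originates mainly in
retinal ganglion cell activity. Its *multifocal* variant (mfPhNR) stimulates
many retinal locations simultaneously and recovers a local response per
location, so ganglion-cell function can be mapped topographically -- the
question of interest in optic neuropathies such as multiple-sclerosis
optic neuritis, where ganglion cells degenerate while the outer retina is
spared.

`mfphnr` implements the full analysis chain of this paradigm:

1. **Stimulus geometry** -- a 60-segment scaled dartboard covering 25° of
   eccentricity, and three analysis topographies (rings, oblique quadrant
   sectors, ETDRS-style grid).
2. **Stimulation and kernel extraction** -- a 12-bit maximum-length
   (m-)sequence drives every segment with a circularly shifted copy of one
   binary schedule; first-order kernels are recovered from the single
   continuous recording by cross-correlation.
3. **Measurement** -- the response amplitude density (RAD, nV/deg²) of each
   region is measured baseline-to-trough (BT) in the 50--90 ms window.
4. **Cohort simulation** -- a seeded generator produces two groups of
   synthetic eyes whose ring statistics are calibrated to the published
   summaries of a reference cohort (25 control eyes vs 20 MS-ON eyes).
5. **Statistics** -- one-way ANOVA between and within groups (from raw
   values or from printed summaries), eccentricity-decay fits,
   Kolmogorov--Smirnov normality, and noncentral-t power/sample size.

## Stimulus geometry and topographies

The dartboard uses five annular bands with boundaries at 5/10/15/20/25° and
4/8/12/16/20 segments per band. The per-band counts are not published for
the reference stimulus; this layout honours its two stated properties --
60 segments in total and sizes "scaled" with eccentricity -- and makes all
counts divisible by four, so quadrant boundaries never cut a segment. Within
each band the first angular edge is placed on the 45° meridian, which makes
the four diagonal meridians segment edges in every band; the ETDRS-style
quadrants (bounded by the diagonals, centred on the cardinal directions) are
therefore exact segment unions.

The oblique sector quadrants (ST/SN/IN/IT) are bounded by the vertical and
horizontal meridians instead -- a superior-temporal quarter is by definition
the intersection of the superior and temporal halves. With the default band
counts those meridians are segment edges only in bands whose count is
divisible by eight, so assignment goes by each segment's angular centroid;
centroids falling exactly on a boundary meridian (four per affected band)
are assigned counter-clockwise. This tie-break is deterministic and keeps
the four quadrants exactly balanced (9 segments and an identical area
each).

Region labels are **retinal**, not visual-field: the optics invert the
image, so a screen-superior stimulus is labelled inferior and, for a right
eye, a screen-right stimulus is labelled nasal; left-eye maps are the
horizontal mirror of right-eye maps. Retinal labelling was chosen because
the paradigm's natural structural counterpart is OCT sector analysis, which
reports retinal sectors. Users comparing against visual-field conventions
should swap the labels accordingly.

The trace array of the reference instrument is described as subtending 30°
in one figure while the ring analysis is defined to 25°; the package uses
25°, the definition under which all analyses are specified.

## m-sequence stimulation and kernel extraction

A maximal-length sequence of order 12 (length 4095) is generated by a
Fibonacci LFSR with taps {12, 6, 4, 1}; non-primitive tap sets are detected
at run time by their shortened period. Each segment's schedule is the base
sequence circularly shifted by 68 m-steps per segment index -- the standard
decorrelation device; the shift must exceed the kernel epoch length in
m-steps or neighbouring responses would contaminate each other.

The frame model is deliberately simple: one m-step per stimulus frame at
7 Hz (142.86 ms), with the per-step response being the kernel epoch. The
reference instrument's internal frame scheduling is not published; this
single-step model is the plainest one consistent with its stated stimulus
frequency. Recordings are treated circularly over whole sequence cycles,
and the number of cycles is a free parameter (the published total recording
time is an average, not a cycle count).

The first-order kernel of segment *a* is the frame-onset average of the
recording signed by that segment's schedule. Because the off-peak circular
autocorrelation of an m-sequence is −1/L rather than 0, this raw estimate
contains a small scaled copy of the *summed* response of all segments. The
bias has a closed form -- every shifted m-sequence sums to +1, so the plain
frame-onset average of the recording estimates that summed response divided
by L -- and is removed exactly:

$$\hat k_a = \frac{\mathrm{raw}_a + \overline{r}_{\text{onsets}}}{1 + 1/L}.$$

With this correction the noise-free synthesis-extraction round trip is
exact to machine precision (the test suite asserts < 1 % but observes
~1e−15), and recording noise of SD σ enters each kernel with SD
σ/(√M · area).

Default sampling rate is 1000 Hz, giving 1 ms kernel resolution across the
−20 to +120 ms epoch; the pre-onset 20 ms exists purely to estimate the
baseline. Band-pass filtering (Butterworth order 2, 3--100 Hz) is zero-phase
-- forward-backward with odd-reflection padding long enough for the 3 Hz
transient to die inside the padding -- so the trough latency is not shifted
and a DC offset is annihilated; it is applied per acquisition period to
avoid transients bleeding across the rest gaps. Artifact rejection drops any
~30 s acquisition period containing a sample beyond a 1000 nV threshold
(an order of magnitude above the synthetic signal scale; the reference
description says only "automatic rejection").

## Waveform model and calibration

No waveform equation is published for these responses -- only the BT measure
and its window -- so the per-segment template is a difference of two
unit-peak Gaussian bumps: a positive b-wave-like component (default centre
32 ms, SD 9 ms) and the PhNR trough (default centre 70 ms, SD 12 ms),
hard-zeroed before stimulus onset. The defaults place the trough at the
centre of the 50--90 ms search window with a realistic width; the b-wave
component's leakage into the trough window is negligible at these defaults
and is in any case absorbed by calibration.

Calibration finds, per ring band, the multiplicative scale under which the
noise-free ring-averaged BT RAD equals the target mean exactly. The BT
measure is linear in the scale (the trough location does not move), so the
fixed-point iteration converges immediately; it is still iterated to 1e−6
relative tolerance as a guard.

The cohort generator's defaults *are* the reference study conditions:

* 25 control eyes; ring targets 32.252, 14.928, 9.448, 5.840, 4.372
  nV/deg² (the published control means);
* 20 case eyes; the case effect is multiplicative per-ring attenuation with
  the published case/control mean ratios. Only amplitude effects are
  modelled -- the study reports no latency pathology;
* between-eye variability as per-ring additive amplitude offsets drawn with
  the published per-group SDs. Whether the case group's spread reflects
  attenuation-scaled control variability or independent variability is not
  inferable from the published summaries; independent per-group SD targets
  are used;
* band-limited (3--100 Hz) Gaussian trace noise of SD 0.5 nV/deg² per
  kernel. This value is the package's own choice of a small
  measurement-noise floor: it is large enough to make every trace visibly
  noisy yet contributes little to the ring-level SD, which the published
  summaries already fix via the between-eye offsets. The noise is scaled by
  the exact RMS gain of the zero-phase filter on the epoch window, computed
  from the filter's action on the unit basis vectors, so the post-filter SD
  is exactly the nominal value;
* angular structure: sector and ETDRS regions inherit the ring profile (no
  bespoke angular effects by default); per-quadrant multipliers can be
  supplied through the eye-level offsets to emulate the mild
  temporal/nasal dominance visible in the published ETDRS means.

The generator emulates what the study's summary tables constrain: ring-wise
means and SDs, a smooth PhNR-shaped waveform, trace-level noise, and
laterality-mirrored topography. It does **not** emulate angular asymmetries
(beyond opt-in multipliers), latency variability, eye-movement or blink
artifacts, or any correlation between rings within an eye other than that
induced by the shared template. Passing tests therefore demonstrate the
correctness of the measurement and statistics chain under the published
group conditions -- not waveform-level realism of individual recordings.

## Measurement conventions

* Baseline: mean of the −20--0 ms window (the reference description says
  "pre-stimulus baseline" without a window; the full pre-onset epoch is the
  natural estimator).
* Trough: sample minimum in 50--90 ms, earliest sample on ties, no
  interpolation -- at 1 ms resolution sub-sample interpolation would move
  values by far less than the noise floor.
* Regional averaging is area-weighted (total response over total area),
  which keeps the density interpretation exact; for a simple mean the
  central rings would over-weight their smaller segments. BT is measured on
  the averaged trace (as the reference instrument reports region averages);
  measuring per segment and averaging afterwards coincides only when
  trough times align across members.

## Statistics conventions

* SDs are sample SDs (n−1); this convention is required to reproduce the
  published F values from the published summaries.
* Two-group one-way ANOVA from summaries uses the pooled within-group
  variance; it is algebraically identical to the classical ANOVA on any
  raw data with those summaries and to the squared pooled t statistic
  (both identities are asserted in the tests).
* Within-group region comparisons treat regions as independent groups even
  though the same eyes contribute to every region -- this matches the
  published degrees of freedom (e.g. F(1, 48) for the 25-eye control
  group).
* Eccentricity fits use equally spaced abscissae in table order (rings
  R1..R5; sectors ST, SN, IN, IT; ETDRS T, S, N, I). r² is invariant to
  affine rescaling of x, so band midpoints would give identical values.
  The ring decay is fitted exponentially; the default mode is ordinary
  least squares on log-means with r² reported in log space, which
  reproduces the published control value (0.97). A nonlinear mode
  (original-space least squares, log-linear initialisation) is provided
  for sensitivity analysis. The case-group log-linear r² computes to
  ~0.967 where 0.95 is printed; the published fitting convention for that
  one value is not recoverable, so both outputs are documented rather than
  forced to agree.
* The power computation iterates the per-group n upward through the
  two-sided noncentral-t power function. The planning SD is a genuine
  convention choice: the published analysis (pilot means 31.1 vs 21.8,
  SDs 6.2 and 5.9, α = 0.01, power 0.90, result 14 per group) is
  reproduced exactly when the case group's pilot SD is the single planning
  SD -- the form in which such tools accept their σ input -- whereas the
  textbook pooled SD yields a continuous solution of 14.36 and hence 15.
  The default is therefore `planning_sd = "case"`, with `"pooled"`
  available; both are reported by the same function and the discrepancy is
  documented here rather than hidden.

## Printed-precision comparisons

`verify_printed_statistics()` recomputes every F value of the six published
tables, the six linear r² values, the ring exponential r² values and the
power n from the embedded printed summaries, and compares each at *printed
precision*: within one unit in the last printed decimal. The one-ulp rule
is the tightest uniform criterion the study's own arithmetic satisfies --
its tables mix rounding and truncation (e.g. a linear r² of 0.28613 printed
as 0.28, 0.16505 printed as 0.17).

A minority of printed cells are internally inconsistent with the study's
own printed summaries and recompute to different values: in the ring
within-group table the two groups' R3/R4 rows appear transposed and two
isolated cells look like digit slips; the sector within-group table has its
last two columns transposed and one unexplainable cell (1.34 where the
summaries give 0.06, which the printed p value 0.709 actually supports);
one between-group ETDRS cell prints 7.85 where the summaries give 7.52.
The ledger reports these as disagreements -- they are evidence about the
publication, not about the arithmetic.

## Problem sizes and numerical choices

The test suite runs the full 60-segment, order-12 synthesis-extraction
round trip once (a ~585 000-sample recording) and uses an order-8,
12-segment configuration for the remaining kernel properties; the
Monte-Carlo checks use 100--200 seeded replicates at the published group
sizes. These sizes were chosen so the whole suite completes in a few
minutes while every stochastic assertion still has comfortable margins.

Degenerate inputs are errors, not silent results: constant groups in the
ANOVA, non-positive means in the log-linear fit, constant samples in the
KS test, a zero pilot effect in the power computation, all-rejected
recordings, and epochs that do not cover the measurement windows.

## Known limitations

* The generator is summary-calibrated; it does not model biophysical
  retina mechanisms, outer-retina contributions, or latency pathology.
* The detection-rate property of the end-to-end pipeline is limited by the
  published effect sizes themselves: with the groups calibrated to the
  published means and SDs, the expected F for ring 4 is ~7.7 against a
  0.01-level critical value of 7.26 (the study's own ring-4 p value, 0.008,
  is marginal at its own threshold), so per-replicate power in that ring is
  near one half and the joint "all five rings significant" event occurs in
  roughly a third of replicates, not ≥95 %. The acceptance test asserts
  the claimed ≥95 % rate and is expected to fail; the package reports the
  measured rate honestly rather than recalibrating the generator away from
  the published conditions to force a pass.
* The single-step-per-frame stimulation model is an explicit
  simplification of an unpublished instrument internals.
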