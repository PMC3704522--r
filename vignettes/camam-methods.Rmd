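---
title: "CaMAM methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CaMAM methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaMAM)
```

CaMAM quantifies three things about myotubes with altered mitochondrial
plasticity: how they release and clear calcium after caffeine, what their
mitochondria look like and how often those mitochondria touch the
sarcoplasmic reticulum (SR), and how strongly mitochondrial and SR/ER
markers colocalize along a line scan. This vignette is the package's own
account of the models behind each stage, the tunable parameters, and the
places where a genuinely open design choice was made.

## The calcium-transient model

Caffeine opens ryanodine receptors and empties the SR store; cytosolic
Fluo-4 fluorescence rises and then recovers as calcium is cleared. The
package idealizes one transient as four phases:

* a flat baseline $F_0$ (fau, fluorescence arbitrary units) until
  $t_{on} = t_{app} + \text{latency}$;
* a linear rise of slope $s$ (fau/s) lasting $\text{riseDuration}$ seconds;
* a peak of amplitude $A = s \cdot \text{riseDuration}$ above baseline;
* a single-exponential recovery $F_0 + A e^{-(t - t_{peak})/\tau}$.

The shape was chosen because it makes every reported metric analytic:
latency, time to peak, amplitude, $\Delta F/\Delta T = s$, and clearance
times $t_q = \tau \ln\!\frac{1}{1-q}$, i.e. $t_{50} = \tau \ln 2$,
$t_{90} = \tau \ln 10$. Noise is additive, Gaussian and homoscedastic —
the simplest model consistent with fluorescence traces at this intensity
scale. `simulateTrace()` attaches all of these as ground truth, which the
estimators never see.

**Assumptions and what they exclude.** The model assumes a single global
release event (no wave trains or repetitive sparks), a monophasic recovery,
no dye saturation and no bleaching. Real recoveries in this preparation are
visibly multiphasic: published group means for early/mid/late clearance do
not keep the $\ln$-ratio spacing a single exponential enforces
($t_{90}/t_{50} = \ln 10 / \ln 2 \approx 3.3$, whereas measured triplets
are often much flatter). The generator therefore matches amplitude, latency,
slope and *one* clearance anchor (we use $\tau = t_{50}/\ln 2$) rather than
all three clearance times at once. Passing recovery tests on these traces
shows the estimators are correct for the stated shape; it does not certify
them on multiphasic or saturating recoveries.

**Sampling defaults.** dt = 0.5 s and a 400 s record are package
configuration, chosen so that a slow recovery ($\tau \sim 165$ s) still
uncensors $t_{90}$; they are not claims about any particular rig.

## Kinetic estimators

All knobs live in `kineticsConfig()`:

| parameter | default | units | role |
|---|---|---|---|
| `baselineWindow` | 20 | s | pre-stimulus window for $F_0$ and its SD |
| `onsetK` | 3 | SD multiples | onset threshold above baseline |
| `onsetMinSamples` | 3 | samples | consecutive samples required above threshold |
| `onsetAbsFloor` | 1 | fau | threshold floor when baseline SD is 0 |
| `smoothWindow` | 9 | samples (odd) | moving-average width for dF/dT and clearance |

*Baseline* is the mean and sample SD over
$[t_{app} - \text{baselineWindow},\ t_{app})$; at least 5 samples are
required.

*Onset* ("caffeine response time") is a threshold rule: the first run of
`onsetMinSamples` consecutive samples exceeding
$F_0 + \max(k \cdot SD,\ \text{floor})$. The reported time is the linear
interpolation of the threshold crossing between the last sub-threshold
sample and the first sample of the run. Interpolation matters: reporting
the run's first sample time carries an up-to-one-sample grid bias on top of
the $\sim k \cdot SD / s$ bias inherent to any threshold rule, and at
realistic noise that combination can push latency errors past two sample
intervals for unlucky sub-sample onset phases. Published studies rarely
state how response time was scored; this rule is this package's explicit
operationalization.

*Amplitude and time to peak* use the raw (unsmoothed) trace: amplitude is
the post-onset maximum minus $F_0$; ties at the maximum resolve to the
earliest sample. Time to peak is measured **from onset**, not from caffeine
application — the two latencies are separate legs, which is the only way
group means for "response time" and "time to peak" of similar magnitude
can coexist. No $\Delta F/F_0$ normalization is applied; amplitudes stay
in fau.

*Maximal dF/dT* smooths with a centered moving average and takes central
finite differences over the onset-to-peak window. A 9-sample window is the
default: the difference of two moving averages two samples apart has noise
SD $\sigma/(w\,dt)$, and at trace noise of 2 % of amplitude a 5-sample
window leaves the max-of-noisy-differences estimator with ~13 % mean error
against a true linear slope, while 9 samples brings it under 7 % and is
still exact on the interior of any linear rise longer than about 5 s at
dt = 0.5 s. Shorter windows remain available for very fast transients.

*Clearance* finds, on the smoothed trace, the first time after the peak at
which fluorescence falls to $F_0 + (1-q)A$, with linear interpolation
between the bracketing samples. Smoothing is deliberate: on the raw trace a
single noise dip triggers the crossing, biasing every $t_q$ early; the
smoothing bias on a noiseless exponential is second-order
($\sim dt^2 (w^2-1)/24 \cdot |F''|$, well under dt/2 here). If the record
ends before a level is reached, the value is censored: the flag is set and
the value carries the remaining record length, mirroring experiments where
complete recovery could not be observed. Group summaries exclude censored
values and report how many were excluded.

`analyzeTransient()` runs the chain baseline → onset → peak → dF/dT →
clearance and emits a fully flagged "no response" row instead of an error
when the threshold is never met.

## Morphometry

**2-D size.** Per mitochondrion, size is length × width (µm²). On EM-style
tables the two are given; on images they are the side lengths of the
minimum-area enclosing rectangle of the segmented object, the digital
analogue of calipering an EM profile (ellipse axes were rejected: they
underestimate rod width). The rectangle is fitted to pixel centers and
widened by the 1-px pixel extent per dimension — exact for axis-aligned
pixel blocks, and unlike a rectangle over pixel corners it is not inflated
by the rasterization staircase of rotated rods. A genuine limit remains:
any convention carries ~1 px of uncertainty per dimension, so thin rods
(a few pixels wide) cannot be sized to a few percent at arbitrary angles;
the rotation-invariance tests use rods thick enough that 1 px sits inside
a 5 % band.

**Segmentation.** Otsu threshold by default (a fixed threshold is available
for reproducibility), 8-connected components (diagonal contact joins
objects), components under `minAreaPx` (default 4) discarded.

**Fused classification.** A cell is fused when the largest object holds at
least half the total mitochondrial area **or** any object reaches 5 µm;
both thresholds are configurable, and ties for "largest" break to the
lowest id. Published fused/not-fused scoring is usually human judgment;
this rule is the package's reproducible operationalization of it.

**Contact sites.** A mitochondrion is a contact when its SR distance is at
most `dMaxNm`, default 30 nm — a typical mitochondria-associated-membrane
gap in the ultrastructure literature. Published EM scoring criteria are
rarely stated, so this is a prominent knob; contact frequency is
nonincreasing as it tightens. On images, per-object SR distance is the
minimum Euclidean distance from the object's boundary pixels to SR
foreground, computed on a distance transform of the SR mask (an empty mask
yields infinite distances plus a flag). Counts are per mitochondrion, so a
group of n = 50 means 50 mitochondria — the reading consistent with using
Fisher's exact test on contact yes/no tables.

## Line-scan colocalization

`lineScan()` samples both channels along a segment at unit-pixel spacing by
bilinear interpolation, averaging over an odd number of integer
perpendicular offsets; positions are reported in µm. `profileCorrelation()`
reduces a profile to the Pearson correlation of the two channels — adopted
as the single quantitative readout because it is affine-invariant and
threshold-free (Manders coefficients were rejected as
threshold-dependent). Zero variance in either channel flags the correlation
undefined. Full-image colocalization statistics are out of scope.

## Group statistics

* Two numeric groups: unpaired two-tailed **Student's t** with pooled
  variance and df $= n_a + n_b - 2$ (Welch available behind a flag, but the
  pooled form is the stated convention of the studies this mirrors).
* Three or more: **one-way ANOVA**, $F = MS_{between}/MS_{within}$.
* Boolean metrics (fused, contact): **two-sided Fisher's exact test** by
  the probability-mass rule — the sum of hypergeometric probabilities, over
  tables with the observed margins, no larger than the observed table's
  (ties at relative tolerance 1e-7). Other two-sided conventions exist;
  this one matches standard statistical software.
* Summaries are mean ± SE (sample SD/√n); no multiple-testing correction is
  applied and reports carry raw p-values, stated as such.

Degenerate inputs (zero pooled variance, all-identical ANOVA input,
negative counts) raise errors rather than returning p-values; p-values are
clamped at 1 against floating-point tail sums.

## Synthetic generators: scope and honesty

`simulateEMObjects()` draws length and width independently from uniform
ranges and places a rounded fraction of objects within a near SR-distance
range (the rest far), so contact frequency and mean 2-D size have known
expectations (e.g. lengths U(0.8, 1.0) × widths U(0.6, 0.8) µm give
E[LW] = 0.63 µm²). `simulateCellImage()` renders non-overlapping binary
rods (no anti-aliasing, so ground-truth geometry is exact) plus a soft-blob
SR texture; channel 2 on mitochondrial pixels mixes channel 1 with an
independent texture by `colocLevel`. The generators emulate the
*statistical structure* the pipeline assumes — not point-spread functions,
shot noise, out-of-focus light, organelle curvature or 3-D structure. Tests
passing on them certify the estimators, not the microscope.

## Conventions and numerics

* Units ride in column names: `time_s`, `length_um`, `sr_distance_nm`,
  `amplitude_fau`. CSVs are comma-separated UTF-8 with a header row and
  '.' decimal.
* Pixel coordinates are R-native 1-based (row, col).
* Pixel size comes from an explicit argument or a JSON sidecar next to the
  TIFF; the explicit argument wins.
* Configuration round-trips through YAML at 15 significant digits; traces
  and images carry JSON sidecars for stimulus time, ground truth and pixel
  size.
* All generators accept a seed and are bit-reproducible under it without
  disturbing the caller's RNG stream.
* Trace validity requires ≥ 20 samples on a uniform grid (relative jitter
  < 1e-6) with the stimulus inside the record.

## Problem sizes used by the test suite

Monte-Carlo checks use 200 traces (801 samples each) at noise 2 % of
amplitude for parameter recovery, 2 000 replicates for t-test type-I
calibration, an exhaustive sweep of all 2×2 tables with total ≤ 40 against
a hypergeometric enumeration oracle, 100 random ≤ 32×32 grids against a
brute-force distance oracle, and 160–256 px synthetic images for
segmentation, colocalization and monotonicity suites. These sizes give
stable verdicts for the properties tested while keeping the suite quick to
run.

## Known limitations

* The monophasic recovery model cannot reproduce clearance-time triplets
  whose ratios deviate from $\ln$-spacing; fitted multiphasic recovery is
  future work.
* Kinetics are per-trace; wave trains, spark analysis and ratiometric
  calibration to [Ca²⁺] are out of scope.
* Morphometry is strictly 2-D (no skeleton/branch topology, no 3-D), and
  EM images themselves are not segmented — EM mode consumes measurement
  tables.
* Whether published per-field amplitudes were background-subtracted per
  cell or per field is generally unstated; the pipeline exposes baseline
  subtraction only.
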