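---
title: "Quantifying the vestibulospinal reflex: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the vestibulospinal reflex: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsrquant)
```

## The assay

A 5-6 dpf zebrafish larva is mounted head-fixed on a rotary platform that
rocks sinusoidally about the yaw axis (default ±75° at 0.53 Hz) while an
infrared camera records the freed tail at 30 fps. Rotation of the head
excites the utricular hair cells and drives compensatory trunk movements —
the vestibulospinal reflex (VSR), carried by a conserved three-neuron arc
(vestibular afferents → vestibulospinal neurons → spinal motor neurons).
Once per stimulus cycle the illumination pauses for ~16 ms, so an all-black
marker frame delimits every cycle: at 30 fps / 0.53 Hz one cycle spans
`floor(30 / 0.53) = 56` frames. The nominal per-cycle duration of 1.84 s
quoted for this hardware is mutually inconsistent with 56 frames at 30 fps
(56/30 ≈ 1.867 s); since all segmentation is frame-based, the frame count
is treated as authoritative throughout and durations are derived from it.

The per-frame signal is the signed **tail angle** α: the angle between the
body axis and the chord from the swim-bladder center to the tail tip.
Because the platform itself sways the agarose and bath, α contains a slow
passive component; the **rolling median** over 5 frames tracks that sway,
and all activity metrics are computed from the **difference signal**
|α − rollmed(α)|.

## Per-cycle metrics and exclusion rules

Cycles are half-open frame intervals `[b_i, b_{i+1})` between consecutive
black frames; the delimiting black frame belongs to the cycle it starts and
is excluded from metrics as an invalid frame. A trailing segment after the
final marker is kept as a partial final cycle. The first cycle and the
final (complete or partial) cycle of each recording epoch are excluded as
edge artifacts, which is why the standard 1280-frame recording yields
exactly 21 analyzable cycles (23 segments − 2). Retained cycles whose
difference signal exceeds 45° anywhere are excluded as startles — normal
evoked movements stay within 0-45°, escape responses can exceed 100°. The
45° rule automates what is usually a manual exclusion.

Per retained cycle, over valid frames:

* `max_tail_angle` — maximum of the difference signal (movement amplitude);
* `normalized_integral` — mean difference per valid frame. "Normalized
  integral" is not given a formula in the assay literature; defining it as
  the per-frame mean makes it duration-invariant and therefore comparable
  across partial cycles;
* `pct_above_threshold` — percentage of valid frames with difference
  strictly above the threshold (default 5°). A frame exactly at 5.000° is
  *not* above threshold;
* `active` — `max_tail_angle > threshold`. (Equivalently
  `pct_above_threshold > 0` under these definitions.)

Whether the original analysis computed the rolling median within or across
cycle boundaries is not documented; here the difference signal is computed
once over the whole trace and then windowed into cycles, which avoids
5-frame edge effects at every cycle boundary.

## Temporal statistics

**Half-time.** The baseline `B` is the mean normalized integral of the
first 3 retained cycles (the normalization used for the published half-time
is not stated; the first-3 mean is robust to a single weak opening cycle).
Per-cycle integrals are bursty — a bout lands somewhere in the cycle or not
at all — so the series is smoothed with a centered 3-cycle moving average
before thresholding; a raw first crossing would be noise-dominated. The
half-time is the linearly interpolated time between cycle midpoints at
which the smoothed series first reaches ≤ B/2 *and stays there for the next
cycle*; a transient dip does not count. Trials that never halve report
`NA`; a zero baseline is an error (no initial response to halve).

**Pauses.** A pause is a maximal run of ≥ 2 consecutive inactive retained
cycles (a single skipped cycle is not a pause), with duration = run length ×
cycle duration. Rest periods between epochs neither break nor extend a run.

**Minimal recovery interval.** The defined-interval protocol delivers six
42-s stimuli separated by rests of 20, 15, 10, 5 and 0 s. The published
description gives only the range ("0-20 s") and the 302-s total; equal 5-s
steps are the only uniform sequence consistent with both
(6 × 42 + 20 + 15 + 10 + 5 + 0 = 302). An epoch *resumes* when it contains an
active cycle after the preceding epoch ended with its final 3 retained
cycles inactive; the minimal recovery interval is the shortest rest
preceding any resumed epoch. Requiring prior loss of activity makes
sustained responders report 0 ("no additional recovery time needed") rather
than the longest rest they happened to follow. Animals that lose activity
and never resume report `NA` (censored above the longest offered rest; the
analysis scripts and acceptance checks rank such animals above all
recovered ones when correlating with the simulated recovery constant).

## The synthetic generator

No recordings are distributed with this package, so a seeded generator
stands in for the animals. It emulates exactly the structure the analysis
assumes: a slow sinusoidal sway baseline phase-locked to the stimulus
(default 8°, so the rolling median tracks it almost perfectly — its
5-frame curvature is ≈ 0.1°), Gaussian frame noise (0.8°), black markers
every 56 frames, rare startles (> 45°), and stimulus-evoked bouts drawn
from a phenomenological resource model:

* each stimulated cycle consumes δ (`depletion_per_cycle`) of a releasable
  resource `R ∈ [0, 1]`;
* a bout fires with probability `bout_prob` when `R ≥ response_threshold`,
  with peak amplitude `bout_amplitude_deg · R · (1 − adaptation_rate)^k`;
* during rests `R` relaxes toward 1 with time constant τ_rec
  (`recovery_tau_s`): `R ← 1 − (1 − R)·e^(−Δt/τ_rec)`.

Depletion is applied per *stimulated* cycle, not per fired bout. This is
the "stimulation is continuously depleting" reading: if depletion were
gated on firing, resource would silently accumulate across sub-threshold
epochs of the interval protocol and the estimated minimal recovery
interval would collapse to the shortest rest regardless of τ_rec. The two
readings coincide when `bout_prob = 1`. Recovery runs only during rests.

A bout is a half-sine envelope of 6-12 frames on a ~10 Hz alternating
carrier. The carrier matters: tail beats are fast relative to the 30 fps
camera, and an unmodulated smooth envelope of that length would be tracked
by the 5-frame rolling median itself, erasing the difference signal the
metrics are built on. Only cycle-level metrics depend on the bout
micro-shape.

Default phenotypes (each one set of `phenotype_params()`):

| preset | key values | emulates |
|---|---|---|
| `phenotype_wildtype()` | δ = 0, adaptation 1.5 %/cycle, bout 30°, p = 0.9 | sustained response, mild adaptation |
| `phenotype_null()` | bout amplitude 0 | mechanotransduction loss (*pcdh15a*, *lhfpl5a*-like): sway and noise only |
| `phenotype_synj1()` | δ = 0.25/cycle, τ_rec = 15 s | normal initial cycles, rapid rundown, long pauses, tens of seconds to recover |

These defaults were chosen once to place the three phenotypes in the
qualitative regimes the assay distinguishes (wild-type ≈ 90 % active
cycles; null ≈ 0 %; depletion ≈ 15-25 % with ≥ 3-cycle pauses and a
10-15 s estimated recovery interval at τ_rec = 15 s) and are not tuned
further. The generator ignores pectoral-fin motion — whether fins
contaminate the real tail signal is unknown — and does not model eye
movements, free swimming, calcium dynamics or vesicle pools: the resource
model is phenomenological, so passing tests demonstrate that the *pipeline*
recovers the statistical structure it assumes, not that real larvae follow
the model.

## Rendering and tracking

`render_frames()` draws each frame as a bright tapered body on black: a
head/swim-bladder blob at a fixed position and a circular-arc tail whose
curvature is set so the bladder-to-tip chord makes exactly the requested
angle with the body axis. `track_video()` inverts it: black frames are
detected at < 10 % of the median frame intensity; the body is segmented as
the largest connected component above intensity 0.2; the bladder is
located at the maximum of the distance transform (the widest point); the
tail tip is the geodesically farthest body pixel; centroids of
geodesic-distance bins give the midline, resampled by arc length to 10
points from bladder to tip. Equal arc-length spacing is used where the
assay description says only "regular intervals". The tail angle uses the
bladder→tip chord only; the intermediate points are retained for QC.

The reference axis is fixed once from the trunk direction of the first
trackable frame — the "body axis" definition is stimulus-independent,
whereas measuring against the image X axis would coincide with it only for
an axis-aligned mount. Tracking failures are carried as invalid frames
with angles linearly interpolated from the nearest tracked neighbors, so
cycle frame counts stay fixed; a recording with > 20 % failures errors
out. Round-tripping rendered fixtures recovers angles within 2° RMS
(typically ≈ 0.6°) and the exact marker schedule. AVI decoding is not
provided — input is a directory of numbered PNG frames or a trace CSV.

## Group statistics

The published analysis style is "two-way ANOVA with Benjamini-Hochberg
correction" with per-cycle significance stars. That is interpreted here as
an omnibus fixed-effects two-way ANOVA (genotype × cycle) *plus* per-cycle
two-group Welch contrasts, BH-adjusted across the 21 cycles within each
metric; metric families are not pooled, since each metric panel is starred
independently. BH is implemented from the step-up formula (and checked
against brute force and `p.adjust`); the ANOVA is `stats::aov`. The
repeated-measures structure — every larva contributes all cycles — is
deliberately ignored to match the published fixed-effects analysis; this
is anticonservative for the cycle effect and is flagged as a known
limitation (a mixed model is out of scope). Welch rather than pooled
t-tests keep the near-zero-variance cycles of null mutants from inflating
the remaining contrasts; two groups with literally identical values yield
no significant contrast.

The normality screen reports Anderson-Darling, D'Agostino-Pearson,
Shapiro-Wilk and Lilliefors-corrected Kolmogorov-Smirnov p-values without
gating any downstream analysis. Lilliefors is the appropriate KS variant
because the normal parameters are estimated from the data.
D'Agostino-Pearson K² is implemented from the standard formulas (verified
against an independent implementation to 10 decimals).

## Numerical choices and degenerate inputs

* Rolling-median edges shrink symmetrically (window 1, 3, ... at the
  borders); `stats::runmed` supplies the interior.
* Modal cycle length (for partial-cycle detection) uses the most frequent
  inter-marker spacing; ties resolve to the shortest.
* Ties at thresholds: difference = threshold is not "above"; smoothed
  activity exactly at B/2 counts as halved.
* The half-time is well defined only while the first three retained cycles
  carry evoked signal; at depletion rates high enough that fewer than
  three initial cycles fire (δ ≳ (1 − threshold)/3 in the generator), the
  baseline approaches the noise floor and the crossing time becomes
  arbitrary, so analyses of half-time vs δ stay below that range.
* Degenerate inputs error loudly rather than guess: < 2 markers, cycles
  with no valid frames, zero half-time baseline, empty genotype × cycle
  cells, p-values outside [0, 1], zero-length chords.
* Seeds: every simulation consumes a fixed number of uniforms per cycle,
  whether or not the corresponding event fires, so traces under different
  parameter values are coupled (common random numbers) and monotonicity
  properties (e.g. more depletion ⇒ never more active cycles) hold
  pathwise.

## Problem sizes

The bundled analyses and checks use cohorts of 8 larvae per genotype on the
1280-frame standard recording, 200 replicate pairs for the null-calibration
estimate, 5 τ_rec levels × 20 seeds on the full 302-s interval protocol for
parameter recovery, and a 168-frame rendered recording for the tracking
round trip — sizes chosen to make every statistical property measurable in
minutes on a laptop while matching the study's per-group n of 7-10.
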