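---
title: "Validating a chest-patch accelerometer against a hip reference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a chest-patch accelerometer against a hip reference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madpair)
```

## The problem

Ambulatory ECG patches increasingly carry a small MEMS accelerometer, which
raises a practical question for epidemiology: can the patch's accelerometer —
sampled at only ~1.56 Hz per axis, stored as 8-bit codes over ±2 g — stand in
for a research-grade hip accelerometer (40 Hz, 12-bit, ±8 g) when measuring
free-living physical activity? `madpair` implements the complete analysis
needed to answer that question on paired recordings: format decoding, epoch
summaries, device-specific non-wear detection, wear-validity filtering, and
multi-level agreement statistics. Because real paired cohort recordings of
this kind are access-restricted, the package also ships a synthetic
paired-device generator with known ground truth, so every stage of the
pipeline is exercised and scored offline.

## Activity metric

Raw tri-axial samples are collapsed to the vector magnitude
$r(t) = \sqrt{x^2(t) + y^2(t) + z^2(t)}$ and summarised per epoch by the mean
amplitude deviation

$$\mathrm{MAD}(t, H) = \frac{1}{H} \sum_{h=0}^{H-1} \left| r(t+h) -
\bar r(t; H) \right|,$$

where $H$ is the number of samples the device actually delivered in the
epoch. Subtracting the epoch mean removes the static gravity component, so
MAD measures movement intensity regardless of sensor orientation — the
property that makes chest and hip placements comparable at all. Six epoch
lengths are analysed (1, 5, 10, 30 min, 1 h, 2 h). MAD is computed per
device at its native rate; for a 5-min epoch that means roughly 468 patch
samples versus 12,000 hip samples. No resampling is done.

Epochs live on a grid anchored at local midnight (so 5-min epochs begin at
:00, :05, ...), with half-open intervals $[t, t+L)$ so no sample is counted
twice. Midnight anchoring makes diurnal averaging across days and
participants well defined. An epoch is scored only if it contains at least
90% of its nominal $L \cdot f_s$ samples (`min_fraction`, configurable);
this is how the ragged partial epochs at recording edges are dropped.

## Device models and quantization

A `device_spec` records the per-axis sampling rate, bit depth, dynamic
range and placement. The code grid is offset-binary: code $2^{b-1}$
represents 0 g and one level spans $2R / 2^b$ g — 0.00390625 g for the
12-bit ±8 g hip monitor, 0.015625 g for the 8-bit ±2 g patch. The patch's
binary dialect stores 8-bit codes interleaved in x, y, z trifectas; the
zero-g code is not documented by the vendor, so the conventional
offset-binary choice (code 128, giving the slightly asymmetric range
[−2, +1.984375] g typical of two's-complement MEMS converters) is made
once, in one function, and would be a one-line change. The hip device's
native binary container is proprietary; the supported interface is the raw
CSV export dialect documented in `read_actigraph_csv()`.

## Non-wear detection

*Chest patch*: the patch records ECG whenever attached, so wear is read off
the ECG. The signal is smoothed with a centred 2-s rectangular moving
average (edges truncated); timepoints whose absolute deviation from the
smoothed signal is below 0.1 mV are non-wear. Pointwise labels must be
consolidated to analysis epochs, and the consolidation rule is a package
convention: a minute is worn iff at least 2% of its samples deviate by
0.1 mV or more. The margin is deliberately wide — QRS complexes occupy
roughly 10% of samples at 60 bpm, while a detached flat lead yields
essentially 0% — so the rule is insensitive to the exact cut, and the
fraction is configurable.

*Hip monitor*: the conventional rule flags runs of ≥ 90 consecutive
zero-activity minutes as non-wear. Vendor activity counts are proprietary,
so the package defines a documented, deterministic proxy for a
"zero-activity minute": minute-level MAD of the hip vector magnitude below
one quantization step (0.00390625 g). A worn device at rest shows sensor
noise above one code step; an off-body device does not. A consequence worth
knowing: an off-body block shorter than 90 minutes (for instance a trailing
23:00–24:00 block on the final recording day) is invisible to the rule by
construction.

*Joint wear and inclusion*: a minute is jointly worn iff worn on both
devices; epochs containing any non-jointly-worn minute are excluded
entirely (a conservative union — non-wear must never leak into MAD). A
calendar day is valid iff jointly worn minutes within the daytime window
[07:00, 23:00) total at least 10 h, and a participant is included iff at
least 3 calendar days are valid ("at least" boundaries are inclusive).
Agreement analyses use jointly worn epochs on valid days of included
participants only; the same restriction is applied at every epoch length
and to the pooled Bland–Altman analysis, which keeps all levels of the
analysis consistent with the cohort flow.

## Agreement statistics

Per participant and epoch length: the sample Pearson correlation and mean
squared error between the time-synchronised MAD pairs (hip reference vs
chest test). A correlation is reported missing when fewer than 10 pairs
exist or either series is constant; such participants are excluded from
correlation summaries with a logged count. Cohort summaries report mean,
SD, median, quartiles (type-7 linear interpolation), range, and the count
of participants with r strictly below 0.8. MSE is reported in g² and,
mirroring the conventional presentation, scaled by 10⁶ in the CSV tables.

Bland–Altman analyses are computed at two levels: one pair per participant
(participant mean MADs) and pooled over all epoch pairs. Differences are
taken reference-minus-test (hip − chest), the direction in which placement
gain differences produce a positive bias; limits of agreement are
bias ± 1.96 × SD with the sample (n−1) SD, and "outside the limits" is
strict, so ties on a limit count as inside. The diurnal profile averages
each device's MAD in midnight-anchored clock bins (5-min by default) over
all jointly worn participant-day epochs.

## The synthetic cohort generator

The generator emulates the measurement chain that the validation design
implies, with every parameter configurable and defaults fixed at the
package's reference study conditions:

* **Latent intensity** λ(t): minute-resolution motion amplitude shared by
  both devices — a Gaussian diurnal envelope (peak ~11:00, SD 3 h, so
  8:00–14:00 is the active period) modulating Poisson-seeded activity bouts
  (4/h at peak, geometric durations with 10-min mean, amplitudes 50–100% of
  0.15 g) on a 0.01 g sedentary floor. These levels put mean epoch MAD near
  0.02 g, the sedentary-dominated free-living range for older adults.
* **Rendering**: per axis, gravity (a unit vector fixed by placement) +
  a band-limited walking-like oscillation — three sinusoidal components
  with frequencies drawn from 1–3 Hz, unit-RMS weights and per-axis
  phases, one waveform per participant shared by both devices — with
  per-sample amplitude gain × λ(t) (split evenly across axes) + white
  noise (SD 0.01 g per axis while worn), sampled at the device's nominal
  rate under a per-device clock model — quartz drift (uniform ±50 ppm)
  plus an initialization offset (uniform ±10 s, emulating devices set up
  from computers whose system times disagree) — then snapped to the
  device's code grid. The 1–3 Hz band is genuinely
  undersampled (and aliased) by the 1.56 Hz patch, which is the mechanism
  behind short-epoch disagreement, while epoch MAD remains comparable.
  While off-body the signal is the gravity constant plus noise at 10% of
  one code step, which the zero-activity proxy detects.
* **Placement** is a scalar gain: hip 1, chest drawn from U(0.85, 0.95),
  reproducing a positive hip-minus-chest bias. Richer biomechanics (arm
  swing, breathing, posture changes) are deliberately out of scope.
* **ECG**: a train of 1 mV half-sine R-waves (~0.1 s wide) at a constant
  per-participant heart rate (U(55, 80) bpm) on a near-zero baseline while
  worn; flat baseline with noise < 0.01 mV while off-body.
* **Schedules**: the chest patch is worn continuously; the hip monitor is
  removed 23:00–07:00, emulating the instruction to remove the hip device
  for sleep. Default cohort: 20 participants × 5 days.

All randomness flows from one master seed through a named stream per
participant (with separate render seeds per device), so cohorts and their
serialised files are byte-identical across runs.

What passing tests on this generator do *not* show: agreement under real
biomechanics (different movement axes at chest vs hip, breathing
artefacts), real ECG morphology and noise, irregular wear behaviour, or
vendor signal conditioning (anti-alias filtering is unknown and not
modelled). The synthetic results validate the *pipeline* — that every rule
computes what it claims on signals with known truth — and reproduce the
qualitative structure of the real validation (correlation rising with
epoch length, error falling, strong 5-min agreement), not its numeric
table values.

## Numerical and design choices

* Timestamps are timezone-naive local clock times (internally POSIXct in a
  fixed zone so arithmetic is linear and the 7 a.m.–11 p.m. window means
  wall-clock time).
* Epoch grouping, rendering, the moving average and vector magnitude are
  compiled kernels (they touch every raw sample; 17–86 million per
  participant at native rates); all thresholds and analysis logic stay in
  R. The moving average uses a sliding sum whose accumulated rounding error
  over an 86-million-sample series is ~10⁻⁶ mV, far below the 0.1 mV rule.
* Quantization rounds half-to-even in both the R and compiled paths, so
  encode/decode round trips agree bit-for-bit.
* `simulate_cohort()` is lazy by default: raw signals are rendered per
  participant on demand and reduced to epoch series before the next
  participant is touched, so peak memory is bounded by one participant's
  raw signals regardless of cohort size. Writing dialect files is an explicit opt-in (`dir=`)
  intended for small fixtures and interchange, since a native-rate cohort
  is tens of GB as text.
* Unit tests run the same study design at reduced sampling rates (e.g.
  8 Hz hip, 40 Hz ECG, 2–3 days); the full-rate 20 × 5-day default cohort
  is exercised in the acceptance suite and by `scripts/acceptance.R`.
* Whether "three days" means calendar days or rolling 24-h spans is
  ambiguous in the protocol; calendar days are used, consistent with the
  clock-window definition of a valid day.

## Known limitations

* The zero-activity proxy stands in for proprietary vendor activity
  counts; both flag extended motionless periods, but counts-based and
  MAD-based zero minutes need not coincide on real data near the noise
  floor.
* The ECG minute-consolidation fraction (2%) is a stated convention, not a
  vendor rule.
* Off-body blocks shorter than 90 min on the hip device are undetectable
  by design of the run-length rule.
* The patch's exact rational sampling rate is unspecified ("about
  1.56 Hz"); a header-declared rate always overrides the nominal default.
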