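---
title: "Methods: auditory EEG biomarkers from synthetic gap-ASSR cohorts"
author: "gapassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory EEG biomarkers from synthetic gap-ASSR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`gapassr` implements the measurement chain used to phenotype auditory
processing in developing mice from two-channel epidural EEG (auditory
cortex, AC; frontal cortex, FC): noise-burst event-related potentials (ERP)
with P1/N1/P2 peak amplitudes, single-trial power (STP) maps with a
cluster-based permutation test for group differences, and 40 Hz gap-in-noise
auditory steady-state response (gap-ASSR) temporal processing quantified as
inter-trial phase clustering (ITPC). Because no public recordings exist for
this paradigm at these ages, the package pairs the analysis chain with a
forward simulator whose planted effect structure (elevated |N1| and gamma
background in knockouts, phase jitter reduced by treatment) lets every stage
be validated against known ground truth.

## Stimuli and session

A session is 58 minutes: 8 min rest, a 30 min gap-ASSR block and a 20 min
noise-burst block, the two stimulus blocks counterbalanced in order across
animals. Noise bursts are 1–12 kHz band-limited noise, 100 ms long with 5 ms
cosine-squared ramps, presented at 0.25 Hz (the burst count per session is
therefore duration-driven: 300 onsets in 20 min; the conventional figure of
120 repetitions would occupy 8 min and both parameters are exposed, with the
block duration taken as authoritative). The gap-ASSR block alternates 250 ms
segments of plain noise and gap-interrupted noise. Within a gap segment, gap
onsets are spaced 25 ms apart — a 40 Hz presentation rate — and all gaps in
a segment share one width, drawn uniformly at random from 3–9 ms in 1 ms
steps. At the default 75% modulation depth the noise envelope inside a gap
drops to 25% of its background value.

Three geometric choices were genuinely open and are fixed as follows. Gap
edges are instantaneous amplitude steps: ramps are specified only for the
noise bursts, and sharp edges maximize the 40 Hz drive. Gap widths are drawn
per segment (not per gap), which is what makes "mean ITPC per gap width" a
well-defined per-trial label. The first gap onset sits one full inter-gap
interval (25 ms) into the segment, giving ten whole 40 Hz cycles per
segment; the tenth onset coincides with the segment boundary, so in the
continuous stimulus its gap opens into the following plain-noise segment and
a standalone segment waveform carries nine attenuated spans. Sound level is
symbolic in silico: 75 dB SPL maps to waveform RMS 1 through a fixed
calibration constant.

## Synthetic EEG

Each virtual animal's AC signal is the sum of:

* **1/f^α background** — spectrally synthesized Gaussian noise, default
  α = 1.3 and 40 µV RMS, flattened below 0.5 Hz;
* **gamma background** — band-limited (30–100 Hz) noise, default 15 µV RMS,
  multiplied by the animal's `gamma_bg_scale`;
* **ERP template** — three Gaussians (P1 +10 µV at 25 ms, N1 −20 µV at
  50 ms, P2 +12 µV at 110 ms; widths 8/12/30 ms) injected at every burst
  onset with 10% amplitude and 2 ms latency jitter;
* **40 Hz gap-locked response** — per gap segment, a Bernoulli draw with
  probability `plogis(0.9 · (width − 2 ms))` decides whether the generator
  locks to that segment's gap train; if it does, every gap onset receives a
  40 µV Gaussian-windowed burst (SD 5 ms, 15 ms latency) riding a 40 Hz
  carrier whose segment phase is drawn wrapped-normal with the animal's
  jitter SD.

FC shares the neural signal (ERP + ASSR) attenuated to 0.8 and lagged 5 ms,
with independent background noise of the same spectrum — enough to produce
the qualitative AC/FC similarity without claiming a connectivity model.
Simulation is done directly at the 1024 Hz analysis rate; the
acquisition-rate decimation contract (24414 Hz → 1024 Hz) is tested
separately in the i/o layer.

The wrapped-normal phase mechanism is the deliberate core of the design: the
population mean resultant length of wrapped-normal phases is exp(−σ²/2), so
the mean 40 Hz ITPC the analysis chain should recover is
exp(−σ²/2)·P(respond), an analytic oracle the tests check across a σ × width
grid. The Bernoulli response draw is made once per segment (all ten gaps
lock coherently, or none) precisely so this closed form holds; a per-gap
draw would make the trial phase a mixture with no clean oracle.

Effect magnitudes are configuration defaults, not empirical estimates — the
source literature reports significance, not effect sizes. Defaults: knockout
multiplies |N1| by 1.5, the gamma background by 1.6 and phase jitter by 1.4;
treatment multiplies jitter by 0.7 in both genotypes and, at P30 only,
returns the knockout gamma background to the wild-type level (the "rescue").
Between-animal variability is a 10% multiplicative log-normal draw on each
scale parameter. Sex is carried as metadata with no planted effect, so the
supplementary sex-by-gap-width ANOVA machinery can be exercised under a true
null. The single-trial ERP template is deliberately modest relative to the
low-frequency background (as in real epidural recordings, where the evoked
response emerges only after averaging): this keeps the knockout's larger N1
from masquerading as a low-frequency STP difference, matching the observed
specificity of the gamma-band effect.

What the simulator does *not* emulate: biophysical cortical dynamics, volume
conduction, movement or electrode artifacts (the emulated protocol rejected
no data), non-stationarity across the session, and any real animal-to-animal
covariance structure. Passing tests therefore demonstrate that the analysis
chain measures what it claims on data with known structure — not that the
effect sizes or variances are those of real cohorts.

## Time-frequency analysis

The transform is a dynamic complex Morlet wavelet bank. The cycle count
follows a sigmoid in frequency: n(f) = 3 + 26·S(f), with S a logistic of
slope 0.05 per Hz and inflection 70 Hz, affinely rescaled so S(1 Hz) = 0 and
S(∞) = 1. The raw logistic with these constants gives n(1) ≈ 3.8; anchoring
is the only reading that honors all four printed constants (3 cycles at
1 Hz, asymptote 29, inflection 70 Hz, scale 0.05) simultaneously, and the
package adopts it.

"Gabor normalization" is implemented as amplitude normalization of the Gabor
atoms: each wavelet (Gaussian envelope of SD n/(2πf), truncated at ±3 SD) is
scaled so a unit-amplitude sinusoid at a grid frequency yields
|coefficient| ≈ 1 in steady state. This makes STP directly interpretable in
µV² and gives the acceptance tests an analytic target. STP is the mean over
trials of |coefficient|², with no baseline normalization. ITPC is the
modulus of the across-trial mean of unit phase vectors; points where any
trial has an exactly zero coefficient are set to 0 and counted. Samples
within one wavelet half-length of an epoch edge are flagged per frequency
and excluded from summary windows; full maps retain them (both groups share
the same edges, so group contrasts there are attenuated, not biased).

Grids: ERP/STP maps use 5–100 Hz in 1 Hz steps — 5 Hz is the lowest
frequency whose wavelet fits the 750 ms ERP epoch (−250 to +500 ms; the
post-onset extent is unstated in the emulated protocol and 500 ms covers the
P1–P2 latencies). Gap segments are analyzed over their full 250 ms at the
40 Hz row (the whole-map heatmaps use 15–100 Hz, the lowest frequency whose
wavelet fits 250 ms). The mean 40 Hz ITPC per gap width averages the
edge-trimmed interior of the 40 Hz row, ≈84–166 ms post segment onset.

## Cluster-based permutation test

Group STP maps are compared with a Welch two-sample t-test at every
time-frequency point (Welch, because group sizes are typically unequal);
points with two-sided p < 0.025 form clusters under 4-neighbour connectivity
(the most conservative common choice; 8-neighbour is available), separately
for positive and negative t. Cluster area is the member point count. The
null distribution is built from random relabelings of the animals: per
permutation the whole t/p/cluster pipeline is re-run and the **maximum**
cluster area recorded; an observed cluster is significant when its area
exceeds the 95th percentile of that null. The max-statistic null is the
standard FWER-controlling reading of "a distribution of cluster sizes"; a
pooled null (all surrogate areas) is available behind a flag. When the
number of distinct relabelings is at most 100 the null is enumerated
exhaustively, which the tests exploit to compare against a brute-force
oracle. Maps entering the cluster test are averaged into 15.6 ms time bins
(16 samples), which keeps the permutation loop fast without moving the
gamma-band effects the test is meant to find.

## Group statistics

ERP peaks are compared with Mann-Whitney tests — exact enumeration when the
combined n ≤ 12 without ties (the variant used originally is unstated; exact
is the defensible default at these group sizes), normal approximation with
tie correction otherwise — adjusted with the Holm-Sidak step-down
(1 − (1 − p₍ᵢ₎)^(m−i+1), monotonicity enforced). The gap-ASSR ITPC table is
analyzed with a mixed repeated-measures ANOVA: genotype × treatment between
animals, gap width within, the classical univariate partition (between
effects over the between-animal error; within and interaction effects over
the animal × width error). The Greenhouse-Geisser epsilon is estimated from
the pooled within-cell covariance of the width responses and applied to the
within-factor degrees of freedom; following common practice the corrected p
is the one to read when ε < 0.75 (the threshold is configurable, as "applied
as needed" admits several conventions). Sidak post hoc contrasts
(1 − (1 − p)^m) compare treatment levels within genotype on per-animal means.
Regions and ages are always analyzed separately, never entered as factors.
With unbalanced designs the partition is sequential (Type I) in the order
the factors are given; the synthetic cohorts are balanced, where all types
coincide.

## Numerical choices and degenerate inputs

* Epoch windows are half-open [t_min, t_max) with onset at t = 0; an epoch
  sample index is the rounded onset sample plus the rounded offset.
* Peak search windows: P1 10–40 ms, N1 25–100 ms, P2 60–250 ms post onset
  (unstated in the emulated protocol; brackets standard mouse latencies and
  the simulator's template). Amplitudes are baseline-to-peak against the
  corrected 0 µV baseline, N1 signed negative; ties break to the earliest
  latency; identically zero waveforms are flagged low-SNR rather than
  treated as peaks.
* Downsampling applies a frequency-domain anti-alias filter (flat to
  0.4·target, cosine roll-off to zero at 0.5·target) and then decimates
  exactly for integer rate ratios or linearly interpolates the band-limited
  signal otherwise.
* Constant ANOVA responses are reported as F = 0, p = 1 (the raw ratio is
  0/0); ε is clamped to [1/(k−1), 1].
* ITPC is clamped at 1 against floating-point overshoot; a single trial is a
  degenerate-input error, as is a zero-length averaging window.
* All randomness derives from one master seed split into per-module,
  per-animal streams, so any stage can be re-run in isolation bit-exactly.

## Problem sizes used in the shipped analyses

The default end-to-end run (`run_config()`) simulates one P30 cohort of 8
animals per genotype × treatment group (4 + 4 across sexes), each with a full
58-minute session at 1024 Hz, and uses 2000 permutations for the cluster
tests; it completes in a few minutes on one CPU. The test suite exercises
the same chain at these sizes once, and uses reduced permutation counts
(500) and smaller map grids for the repeated null-calibration suites
(point-wise rate, family-wise error, planted-effect power), sizes at which
the binomial error of the estimated rates is already well below the margins
being asserted.

## Known limitations

The simulator's effect magnitudes are self-chosen; group-level significance
on synthetic cohorts says nothing quantitative about real animals. STP maps
retain edge-contaminated samples. The FC channel is a caricature of
cortico-cortical similarity. EDF+ input and WAV stimulus export are not
implemented; recordings move through the package's plain-text container. The
exact sigmoid form, normalization constant and ITPC averaging window of the
original analysis are not printed anywhere; the package's readings are
documented above and all downstream numbers are reproducible from them.
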