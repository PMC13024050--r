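---
title: "Decoding environmentally defined affect from plant signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding environmentally defined affect from plant signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the shape of the analysis

A plant in a controlled chamber is exposed to sustained environmental regimes
— heat pulses, diurnal light, humidity swings — while two kinds of internal
signals are recorded: an extracellular bioelectric potential and gas-emission
proxies (eCO2, TVOC) from a metal-oxide sensor. The analysis asks whether
those internal signals alone carry decodable information about an
*environmentally defined* affective state: a valence coordinate (how
favourable the regime is) and an arousal coordinate (how physiologically
demanding it is), both constructed purely from chamber variables. The
decoders never see any environmental channel; successful decoding therefore
means the plant's internal dynamics reflect the regime, not that the model
peeked at the thermometer.

`phytoaffect` implements that analysis as a reusable, fully tested pipeline:
a chamber/plant simulator that serves as ground truth, the label
construction, windowed feature extraction, a windowed linear decoder and an
echo state network (ESN), forward-chaining cross-validation, and
circular-shift permutation nulls. The numbered scripts under `analysis/` are
thin narrative drivers over the package functions.

## Label construction

Environmental variables are z-scored over the labelled trace using the
population (divide-by-*n*) standard deviation — a convention fixed throughout
the package, including window features. Light is then regressed on
temperature and humidity by ordinary least squares with an intercept,

$$L = \beta_0 + \beta_T T + \beta_H H + \varepsilon,$$

and the residual $L_{res}$ is kept: the component of light statistically
independent of temperature and humidity (zero mean, zero sample correlation
with both regressors, checked to 1e-8 in the tests). The affect coordinates
are fixed linear combinations

$$V = L_{res} - T + H, \qquad A = L_{res} + T - H,$$

so that valence rises with residual light and humidity and falls with
temperature, and arousal does the reverse. Two identities follow and are
asserted to 1e-12: $V + A = 2L_{res}$ and $V - A = 2(H - T)$.

Both coordinates are smoothed with a centered rolling median (default 15 min,
odd-sized, shrinking symmetrically at the series edges) to suppress
transients on the scale of chamber interventions. Binarisation is strict
($v = \mathbb{1}[V_{smooth} > 0]$, likewise for $a$), with a dead-zone of
half-width 0.1 z-units around each axis: samples inside the band carry no
class. The quadrant code is $q = 2v + a$ (0: −−, 1: −+, 2: +−, 3: ++).
Samples with infrared below 1 sensor unit are excluded jointly from traces
and labels; in the emulated chamber these correspond to sensor write
failures, not to night-time.

A consequence worth keeping in mind: because $V - A = 2(H - T)$, any fast
environmental driver that moves temperature (and, through anti-coupling,
humidity) enters both coordinates with equal magnitude and opposite sign.
With humidity anti-coupled to temperature the correlation of $V$ and $A$ is
bounded above by $-1/3$, so the two axes are never close to independent, the
off-diagonal quadrants dominate occupancy, and a decoder for one axis always
receives some information about the other through shared channels. This is a
structural property of the label construction, not of the simulator.

## What the simulator emulates

`simulate_environment()` reproduces the chamber protocol: 0.5 Hz sampling;
ambient near 25 °C; heater onsets as a homogeneous Poisson process
(memoryless, the minimal reading of "random intervals"), refractory while an
episode is active, each episode lasting Uniform(15, 45) minutes; a thermostat
that engages fans at 36 °C on the very sample the trigger is crossed and
holds the chamber at or above 35 °C while the episode persists; fresh-air
flushes every 24 h; a half-rectified sinusoidal diurnal light waveform plus a
heater-correlated component; humidity anti-coupled to temperature
(−1.5 %RH/°C) with slow independent wander, clipped to [0, 100]; infrared
tracking daylight and warmth with occasional sub-threshold dips. Temperature
noise enters the dynamics rather than the measurement so the thermostat
invariant ("never above 36 °C with fans off") holds exactly on recorded
samples.

The default heater rate is 24 onsets/day. That choice makes arousal regimes
flip on the 20–60 min scale, which is what gives arousal decoding its
short-window character (below); it also yields occupancy of all four
quadrants over 72 h, with the −− quadrant rare (a few percent), matching the
qualitative picture of extended regime residence with occasional deep-night
calm.

`simulate_plant()` generates the three channels the decoders may see, on the
environmental timebase (the physical 100 Hz bioelectric stream is represented
after aggregation, since all decoding operates on window summaries):

* **bioelectric** = `fast_gain` × (leaky filter of the arousal drive, response
  time `tau_fast` = 60 s) + white noise. The channel *tracks the arousal
  level* with a lag of about a minute, like a sustained depolarisation
  following stress onset. An alternative, purely derivative (high-pass)
  coupling was considered and rejected: a high-passed drive encodes only
  transitions, so sustained regimes become invisible at short windows, the
  coupling gain stops influencing decodability, and the fast/slow
  dissociation the generator exists to express disappears. Level-tracking
  with a short time constant is also the physiologically natural reading of
  variation-potential-like responses.
* **eCO2 / TVOC** = `slow_gain` × (leaky integration of the valence drive,
  time constant `tau_slow` = 30 min) + random-walk drift + white noise. The
  drift (0.1 drive units per √hour) models the notorious baseline wander of
  metal-oxide gas sensors.

Both drives are computed from the *true* environmental variables via the same
residual-light construction used for labelling; labelling downstream re-fits
everything from the observed trace, so label construction remains an honest
estimation step. All randomness flows from one seeded generator per trace:
identical (config, seed) pairs give bitwise-identical traces.

Default gains are `fast_gain = slow_gain = 3` with channel noise 0.3 drive
units — a strong-but-noisy coupling. Because window averaging crushes white
sensor noise, decoding on these synthetic recordings runs cleaner than on
real tissue (valence balanced accuracy near 0.9, arousal near ceiling at
1 min windows); what the generator is built to reproduce is the *pattern* of
results — valence decodable at long windows, arousal requiring short ones,
quadrants well above the 0.25 chance level, and total collapse under label
misalignment — not the headline numbers of any particular recording, which a
single-plant experiment could not pin down anyway.

What the simulator does **not** emulate: mechanistic physiology (stomatal or
photosynthetic dynamics), sensor dropout, watering/lid-removal artefacts,
action-potential waveforms, or any feedback from plant to chamber. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
couplings of the assumed statistical form; they cannot certify performance on
real recordings.

## Windowing and features

Windows are half-open `[start, start + length)`, anchored at the first
sample, tiled at the configured stride, with one end-anchored window appended
if the strided grid leaves an uncovered tail. Features are the mean and
population standard deviation of each plant channel over the *unmasked*
in-window samples — six numbers per window. Window labels aggregate the
per-sample binary labels by majority vote over unmasked samples (exact ties
dropped); a `mean-sign` rule on the smoothed coordinates is available as an
alternative. Windows with fewer than 50% valid samples are dropped. The task
windowings follow the protocol: valence at 20 min windows / 15 min stride,
arousal at 1 min, the trajectory table at non-overlapping 7 min windows, and
the ESN on the 1 min table (the finer windowing that gives the reservoir a
long, temporally continuous input sequence).

## Decoders

The **windowed linear decoder** is a closed-form ridge regression on the
standardised window features with binary targets encoded ±1, an unpenalised
bias, penalty 1.0; the continuous score is mapped through a logistic sigmoid
and thresholded at 0.5 (equivalently, score at 0, strictly). Quadrants come
from combining the two independent binary decoders, $q = 2v + a$ — quadrant
structure is never learned directly.

The **echo state network** expands the same standardised feature sequence
through a fixed random reservoir before the identical ridge readout:

$$x(t+1) = (1 - \alpha)\,x(t) + \alpha \tanh(W_{in} u(t) + W x(t)),$$

with 300 units, spectral radius 0.9 (rescaled exactly, to 1e-6), leak rate
α = 0.2, input scaling 0.5, recurrent density 0.1, one reservoir step per
window, a 50-step washout before readout training, and tanh chosen as the
activation (the reservoir-computing default; it gives state containment in
[−1, 1]). The reservoir weights are drawn once from a seed and never
trained; one reservoir instance is shared across folds and only the readout
is refit. The leak rate and the ridge penalty are deliberately distinct
parameters (both default notations collide on α in the literature). Because
the two decoders differ *only* by the reservoir expansion, the
windowed-versus-ESN comparison is internally controlled.

Design notes: the readout's probability map is a plain sigmoid with no
calibration fitting; recurrent weights are Uniform(−1, 1) before rescaling
(the distribution is immaterial after spectral normalisation, only density
matters); the leak rate sets the reservoir timescale, so the temporal-capacity
benchmark in the tests (decoding a one-step-delayed white ±1 stream above
95%) runs at leak 0.5 — the slow default of 0.2 is matched to biosignal
windows, not to white sequences.

## Evaluation protocol

Forward-chaining time-series cross-validation with five contiguous splits and
no shuffling: the tail of the window sequence is partitioned into five
equal-sized test blocks (remainder to the earlier folds) and fold *k* trains
on everything strictly before its test block — asserted before any fit.
Feature standardisation is computed on each training fold and applied to its
test fold; constant columns pass through centred with a warning. Metrics —
accuracy, balanced accuracy (mean per-class recall), F1 and macro-F1,
confusion matrices, majority baseline — are computed on test segments only.
Fold-mean ± sd is the headline view; pooled-confusion metrics are reported
alongside, because the two legitimately differ and quoting only one invites
ambiguity. Folds whose training labels are single-class are skipped and
recorded, never silently scored.

## The circular-shift null

The null control rotates the label sequence relative to the signals by a
random offset of at least a minimum lag (arousal tiers: ≥60 and ≥360 min;
valence tiers: ≥360 and ≥720 min), respecting the minimum in both circular
directions, and re-runs the *identical* fold plan and decoder. Shifting
happens at the window level, in units of the window stride, so the feature
matrix is bit-identical across null runs and label alignment is the only
difference; sample-level shifting before windowing is available via
`shift_affect_labels()`. A shift is discarded and resampled (bounded retries,
logged) exactly when some training fold would contain a single class.
Alignment-dependent decoding collapses to the vicinity of 0.5 under the null
while the unshifted run stays far above it; a rotation by one full circular
period restores the unshifted metrics exactly, which the tests assert as an
identity. On the synthetic recordings the arousal nulls settle slightly above
0.5 (≈0.53–0.58): the gas channels carry diurnal structure that retains some
alignment under day-scale shifts — a useful reminder that "near-chance" under
circular shifting is an empirical distribution, not an exact 0.5.

## Numerical choices and degenerate inputs

* Population standard deviation everywhere (z-scores, window features,
  per-fold standardisation); re-standardising standardised data is an
  identity.
* Strict `> 0` binarisation; exact zeros fall to class 0 and are dead-zone
  masked whenever the half-width is positive.
* Rolling-median edges: symmetric shrinking odd windows (medians of 1, 3,
  5, ... points), implemented explicitly so the documented semantics match
  the code.
* Constant series refuse to z-score; collinear light regressions fail naming
  the offending regressor; single-class folds raise a classed degenerate
  error; an all-masked analysis set (e.g. everything below the IR threshold)
  fails loudly rather than emitting an empty table.
* Errors are classed (`phyto_config_error`, `phyto_data_error`,
  `phyto_degenerate_error`) so callers and the drivers can dispatch on the
  failure mode.
* A hard guard refuses environmental channels in any decoder feature set, at
  configuration time and again inside `evaluate_pipeline()`.

## Problem sizes

The package's own test suite and acceptance script run entirely on synthetic
data: 72 h chamber traces at 0.5 Hz (129,600 samples) for the main analyses —
five replicate seeds for the parameter-recovery checks and twenty
permutations per null tier over three to five seeds — with shorter traces
(24–36 h) and reduced reservoirs for the structural and orchestration tests.
These sizes keep the full suite under a minute of simulation-bound work per
replicate while leaving every fold with enough windows (about 280 at
20 min/15 min, about 4,100 at 1 min over 72 h) for stable fold-mean metrics.

## Known limitations

The simulator is a statistical stand-in, so every decoding result here is an
internal-consistency statement about the pipeline, not evidence about plants.
The label algebra's built-in V–A anti-correlation means arousal information
leaks into valence channels (and vice versa) at all window lengths; on real
recordings with richer independent variation this coupling would be weaker.
Logistic and multinomial readouts are deliberately out of scope — ridge is
retained for consistency with reservoir-computing practice — and the ESN path
feeds on window summaries, not raw samples, so sub-window temporal structure
is invisible to it by construction.
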