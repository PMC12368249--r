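---
title: "Models and methods behind optophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

optophys analyses light-evoked activity in neuronal cultures and brain
organoids interfaced with photoactive (graphene-type) substrates, where brief
light pulses depolarise nearby neurons without genetic modification. The
package covers the four computational strands such experiments need — calcium
imaging, microelectrode arrays (MEA), a closed-loop activity trigger, and
pipette thermometry — together with a ground-truthed synthetic-data generator
that every stage is tested against. This vignette explains the models, the
parameters that matter, the numerical conventions, and what the synthetic
benchmarks do and do not establish about real data.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture: it defines the
study conditions under which every claim in the test suite is evaluated.

**Calcium movies.** `generate_network()` places non-overlapping circular
somata uniformly in the field of view and wires them as an Erdős–Rényi graph
with independent per-edge conduction delays (default 0.2–0.8 s). A single
light pulse activates one designated cell and activation propagates along
shortest-delay paths, so cell *j* activates at `pulse + d(stim, j)`; this is
deliberately the simplest propagation structure satisfying the analyses'
assumptions (no synaptic failure — an optional activation probability would
only be needed for negative-control fixtures). Each activated cell emits a
calcium transient, rendered as a difference of exponentials with rise 0.1 s
and decay 1.5 s — the slow kinetics typical of hiPSC-derived neurons — at
amplitude 10 fluorescence units over a baseline of 100, with i.i.d. Gaussian
pixel noise. Cell placement enforces a minimum separation of one soma
diameter so each pixel belongs to at most one cell, which makes the
per-pixel ground truth unambiguous. Movies are 30 fps by default (wide-field
acquisition range 30–50 fps; confocal up to 100 fps is supported).

**MEA recordings.** Ground-truth spikes are drawn from an inhomogeneous
Poisson process at `baseline_rate` per electrode (default 1 Hz), multiplied
by `evoked_multiplier` inside evoked windows on responding electrodes, with
an absolute refractory period of 2.5 ms. The evoked window for each pulse
opens after a uniformly jittered latency (default 5–20 ms) and spans the
pulse plus a `response_span` of 0.9 s of after-discharge. The span is a
modelling decision worth spelling out: organoid responses to 1-Hz, 10-ms
pulse trains are not confined to the 10-ms pulse — lag-time distributions
extend to hundreds of milliseconds and population firing stays elevated
between pulses. A 3-fold multiplier confined to the pulse itself would raise
mean rates by only ~6%, which contradicts the premise of the closed-loop
experiments (a ≥2-fold mean-rate elevation); with the 0.9-s after-discharge
the realised elevation on a responding electrode is ~2.8-fold per stimulation
cycle. Traces are white Gaussian noise (default 5 µV SD) plus a biphasic
template (negative lobe −50 µV, positive lobe 40%, 1 ms wide) summed at the
spike times, sampled at 20 kHz.

What the generator does **not** emulate: LFP/volume-conductor structure,
electrode cross-talk, spike-amplitude variability and drift, bursting
point-process structure beyond rate modulation, photostimulation artefacts,
bleaching, motion, or shot noise. Detector performance numbers on these
synthetic recordings are therefore upper bounds for real data, not claims
about it; the oracle-equivalence and analytic-identity tests, by contrast,
hold for any input.

All generators derive independent random streams from one integer seed, so
identical calls are bit-identical.

## Calcium pipeline

**SVD denoising.** The movie (frames × pixels) is truncated to its dominant
singular modes; `rank = "auto"` keeps every mode above the Gavish–Donoho
optimal hard threshold, ω(β)·median of the spectrum with β the matrix
aspect ratio, which separates signal modes from the Marchenko–Pastur noise
bulk without assuming the noise level. A largest-ratio-drop ("elbow") rule
was considered and abandoned after it proved degenerate on fluorescence
movies, where the static-baseline mode dwarfs many comparable dynamic modes
and the largest drop lands at rank 1–2, flattening all latency structure.
The full spectrum is attached to the result so the cut can be inspected and
overridden, and the residual obeys the Eckart–Young identity, which the
tests assert to 1e-6.

**Active pixels.** A pixel participates when its fluorescence range
(max − min over time) exceeds a threshold; `"auto"` uses Otsu's split of the
range image. The statistic is the one the experimental pipelines use; only
the automatic cutoff is our choice.

**Phase-based event detection.** Each trace is smoothed with a centered
5-frame moving average (edges shrink), centred on its median, and the
instantaneous phase of its analytic signal is computed as
`atan2(H(x), x_centred + pedestal)` with a pedestal of `pedestal_k = 20`
robust noise SDs (MAD, floored at 2% of the signal range for noiseless
input). The pedestal is the package's key convention and deserves
justification: for transient-dominated traces the analytic-signal phase of a
plainly mean-subtracted trace rests near ±π, where the branch cut turns
baseline noise into spurious near-2π phase excursions. Anchoring the real
part at a positive pedestal moves the resting phase to zero; each calcium
rise then produces exactly one prominent local minimum of the phase near the
rising mid-point, and the depth of that minimum grows with transient
amplitude, so the global phase minimum marks the stimulus-evoked (largest)
event — the property the evoked-spike rule relies on. Minima are gated by
topographic prominence (`min_prominence = 0.4` rad); both constants were
calibrated once on synthetic fixtures spanning noiseless to 5%-noise
regimes, where they give recall and precision 1.0 at 10× noise amplitude and
zero events on flat noise, and they are exposed as arguments. Event times
are refined from the phase-minimum frame to the 20%-rise crossing of the
smoothed trace (interpolated between frames), which compensates the
smoothing lead and lands within about one frame of the true onset.

**Maps.** `activation_map()` subtracts the stimulation time from each masked
pixel's evoked event; pixels without a clear event are `NA`. Events more
than half a frame before the pulse are rejected (and counted in a report
attribute); sub-half-frame negatives are timing quantisation and clamp to
zero. `spike_count_map()` counts all detected events per pixel and flags
multi-spike sites.

**Connectivity and mixtures.** ROI traces are compared by Spearman rank
correlation (average ranks for ties; constant traces yield `NA`, not 0).
Activation-time histograms are decomposed into univariate Gaussian mixtures
fitted by EM for each candidate component count, with BIC selecting the
count (`mclust`, equal- and unequal-variance families). mclust initialises
EM from deterministic model-based hierarchical agglomeration rather than the
random multi-restart scheme one might write by hand; this is at least as
robust, and because the input is sorted first the fit is invariant to input
order. Means are returned ascending with their SDs and weights.

## MEA pipeline

Conventions: all windows are half-open `[start, end)`, times are in seconds,
electrode ids are opaque strings.

* **Filtering** — zero-phase Butterworth band-pass 200–3000 Hz, order 4 (the
  order stated for the LFP filter; the acquisition software's own order is
  not published). Two equivalent implementations are provided: classic
  forward–backward `filtfilt`, and an FFT application of the identical
  squared-magnitude response, which agrees to 1e-6 away from the edges and
  is an order of magnitude faster on multi-minute traces. LFP extraction
  low-passes at 500 Hz (order 4) and resamples to 1 kHz.
* **Spike detection** — negative peaks crossing −5.5 robust noise SDs
  (`median(|x|)/0.6745`, re-estimated in rolling 10-s windows so the
  threshold adapts), with a 2.16-ms dead time. The detector enforces a
  refractory-violation-free output by construction.
* **Bursts** — ≥5 spikes with every ISI ≤100 ms; **network bursts** — ≥10
  pooled spikes under the same 100-ms ISI rule with ≥25% of active
  electrodes (≥5 spikes/min) contributing. Both are property-tested against
  exhaustive brute-force scanners.
* **STTC** — the standard tiling formula with merged, duration-clipped
  ±dt windows, dt defaulting to the 20-ms synchrony window; empty trains and
  vanishing denominators return `NA`.
* **Synchrony index** — the acquisition vendor's exact definition is
  proprietary, so the package documents its own: the fraction of
  spike-time differences within ±20 ms of a ±1-s correlogram support, with
  the chance level (window/support) reported alongside so values can be
  read as multiples of chance.
* **LZC** — binary sequences (1-ms presence/absence bins by default; the
  binarisation is always recorded in the result) parsed by the
  exhaustive-history LZ76 rule, normalised as `c(n)/n·log2(n)`. Printed
  complexity differences from organoid experiments depend on an unstated
  binarisation and are not reproduction targets.
* **Lag times** — first peak strictly after each pulse and before the next;
  both spike-event and analog-peak inputs are accepted.
* **MFR metrics** — per-electrode rates in before/during/after windows,
  during/before fold change (`NA` for silent-before electrodes), and
  before-normalised rates.
* **Spike sorting** — PCA on the waveform matrix, k-means on the first five
  scores for k = 1…10, the count chosen by the gap statistic with 20
  uniform reference draws over the score bounding box and Tibshirani's
  one-SE rule. Waveforms are cut 0.6 ms before to 1.4 ms after the peak.

## Closed-loop controller

The trigger rule encodes the decision criterion of closed-loop
organoid-to-robot experiments: an avoidance command
when the mean firing rate over the active electrodes — at least 8 of 16,
i.e. ≥50% of a well — reaches at least twice its baseline. Around that rule
the package had to fix several unstated details:

* **Evaluation cadence** 1 s, matching the 1-Hz stimulation.
* **Active set.** Electrodes are classified once, from the pre-stimulation
  baseline epoch, by the 5-spikes/min rule, and the trigger averages over
  that fixed set. Re-selecting "active" electrodes within each 1-s window
  (e.g. requiring a spike in the window) conditions the mean on firing and
  inflates it by a factor `1/(1 − e^{−λ})` (~1.6 at 1 Hz) — a selection bias
  that would make the controller fire on quiescent wells; the fixed-set
  reading avoids it and matches how array software reports active
  electrodes. The twofold criterion is read as comparing means over the
  active set (not per-electrode), the natural reading of a well-level rule.
* **Confirmation.** With 16 electrodes and 1-s windows a single-window rate
  estimate has ~25% coefficient of variation, so the condition must hold on
  two consecutive evaluations before the command is emitted; this debounce
  suppresses chance triggers by several orders of magnitude at the cost of
  one second of latency. One command is emitted per episode (hysteresis);
  the controller returns to forward navigation after the stimulation ends
  and a full evaluation window passes without the trigger.
* **Control-path detection.** The control software's stated threshold is 3
  noise SDs — far more permissive than the 5.5-SD analysis path. On
  band-limited Gaussian noise a bare 3-SD crossing detector fires at ~16 Hz
  per electrode (the Rice rate, bandwidth × e^{−9/2} — a property of the
  threshold in SD units, independent of the noise amplitude), which would
  swamp a 1-Hz baseline and pin every fold change near 1; no closed-loop
  system could operate that way. The control path therefore validates the
  biphasic spike shape: a positive rebound of ≥4 noise SDs within 1 ms of
  the negative peak. This cuts chance events to ~0.05 Hz while passing
  simulated spikes (whose positive lobe is ~8 filtered-noise SDs) with
  recall ≥0.95, and both thresholds are explicit configuration fields.
  Uniform thinning of true spikes would not bias the trigger in any case,
  since the rule compares rate ratios.

End-to-end latency from window close to command is reported in the log but
never compared against the published 50-ms hardware figure, which includes
transport and actuation outside this package's scope.

## Thermometry

Electrolyte conductivity follows an Arrhenius law, so `ln R` is linear in
`1/T`; the calibration fit recovers the activation energy `E_a` from the
slope (gas constant fixed at 8.314 J mol⁻¹ K⁻¹) and evaluates the reference
resistance `R_0` at the reference temperature `T_0` (room temperature by
default). Conversion uses
`T_i = [1/T_0 − R/E_a · ln(R_0/R_i)]⁻¹`, whose fixed point `T(R_0) = T_0`
and strict monotonicity are asserted in the tests. Kelvin is used
internally; the analysis scripts write Celsius at the interface.

## Problem sizes and test design

The test and acceptance workloads were sized for a single CPU: 10 + 10
closed-loop trials of 120 s × 16 electrodes at 20 kHz; 1500 random instances
per brute-force oracle family; 100-seed Monte Carlo for the detectors;
600-s ground-truth-only simulations (traces unrendered) for long-run rate
statistics. Mixture recovery uses n = 1500 with component means 2.853,
6.361 and 19.764 s — the three-component activation-time regime of an
impaired-network model — as the planted truth.

## Known limitations

The phase detector assumes positive-going transients on a slowly varying
baseline; bleaching or strongly oscillatory baselines would need detrending
upstream (out of scope here, as are motion correction and ROI segmentation).
Overlapping somata make per-pixel evoked attribution ambiguous; the
generator avoids them, real data may not. The MEA noise model is Gaussian
and stationary, so the 3-SD control path's false-positive rate on real
electrodes — with artefacts and non-stationary noise — will be higher than
the synthetic figure; the rebound validation level is the knob to retune in
that case. Network-burst semantics ("the same ISI rule on the pooled
train") follow one reading of the array vendor's description; counts from
other tools may differ at the margins.
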