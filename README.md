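# optophys

Analysis pipelines for light-evoked neuronal activity on photoactive
(graphene-type) interfaces, where brief light pulses depolarise adjacent
neurons without genetic modification. The package serves experimenters who
record such stimulation with **calcium imaging** (does a single-cell light
pulse launch a network-wide activation wave? how coherent is the network?)
or **microelectrode arrays** (how strongly and how fast does population
firing follow the light?), and who may close the loop by translating evoked
organoid activity into robot commands.

## What it computes

**Calcium pipeline.** Movies are denoised by truncated SVD (automatic rank
from the eigenspectrum via the Gavish–Donoho optimal hard threshold,
Eckart–Young-checked) and reduced to pixels with
significant fluorescence range (Otsu threshold). Spikes are detected from
the instantaneous phase of the analytic signal of each smoothed trace:
every calcium rise produces one prominent local minimum of the phase, and
the global minimum marks the stimulus-evoked transient. From these the
package builds per-pixel activation-time maps `T(x, y)` (latency from the
light pulse, `NA` where no clear event), spike-count maps flagging
multi-spike sites, Spearman connectivity matrices, and a Gaussian-mixture
decomposition (EM, BIC-selected k) of activation-time histograms whose
means t₁ … t_k summarise the propagation stages of the wave.

**MEA pipeline.** Zero-phase 200–3000 Hz Butterworth filtering; adaptive
5.5-SD spike detection (robust rolling noise estimate, 2.16-ms dead time);
active electrodes (≥5 spikes/min); bursts (≥5 spikes, ISI ≤100 ms); network
bursts (≥10 pooled spikes, ≥25% of active electrodes); the spike-time
tiling coefficient

  STTC = ½ [(P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A)]

with ±20-ms windows; a cross-correlogram synchrony index reported against
its chance level; Lempel–Ziv complexity LZC = c(n)/n · log₂(n) of binarised
trains (exhaustive LZ76 parsing); stimulation lag times (first peak after
each pulse); before/during/after mean-firing-rate fold changes; LFP
extraction (500 Hz → 1 kHz); and PCA + k-means spike sorting with the gap
statistic (5 PCs, k ≤ 10).

**Closed-loop controller.** The trigger rule — avoidance when the
mean firing rate over ≥8 active electrodes (≥50% of a well) rises ≥2-fold
over its pre-stimulation baseline, with 3-SD spike detection on the control
path — implemented as a 1-Hz-evaluated state machine with two-window
confirmation and one command per episode.

**Thermometry.** Arrhenius calibration of pipette resistance
(ln R linear in 1/T, slope E_a/R) and the conversion
T_i = [1/T₀ − R/E_a · ln(R₀/R_i)]⁻¹.

**Synthetic data.** Ground-truthed generators for both modalities — a 2-D
cell network in which one stimulated cell launches a wave with
shortest-path conduction delays, and multichannel recordings with biphasic
spike waveforms whose Poisson rate is multiplicatively elevated, with
latency jitter, during light pulses. Every analysis stage is tested against
these ground truths; no experimental download is needed.

## Worked example

```r
library(optophys)

net  <- generate_network(40, field_shape = c(64, 64), mean_degree = 3, seed = 1)
stim <- stim_schedule(1.0, 0.01)                      # one pulse at t = 1 s
sim  <- simulate_calcium_movie(net, stim, frame_rate = 30, duration = 20,
                               noise_sd = 0.5, seed = 1)

mask <- active_pixel_mask(sim$movie)                  # Otsu on the range image
am   <- activation_map(sim$movie, mask)               # T(x, y) in seconds
fit  <- fit_activation_mixture(am$T[!is.na(am$T)], 1:6, seed = 1)
print(fit)
```

```
<mixture_fit> k = 5 components (BIC-selected), n = 747
  t1 = 0.329 s (sd 0.254, weight 0.095)
  t2 = 1.026 s (sd 0.212, weight 0.412)
  t3 = 1.379 s (sd 0.043, weight 0.126)
  t4 = 1.701 s (sd 0.086, weight 0.212)
  t5 = 2.173 s (sd 0.291, weight 0.155)
```

747 pixels (38 of 40 cells) showed a clear stimulus-evoked event; their
latencies decompose into five stages spanning 0.3–2.2 s — the stimulated
cell and its first activation ring, then successively deeper neighbours,
as expected for a wave with 0.2–0.8-s edge delays.

The `analysis/` directory chains the full workflow as numbered scripts
(simulate → calcium connectivity → MEA metrics → closed-loop trials →
thermometry), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_datasets.R
Rscript analysis/02_calcium_connectivity.R
# ...
```

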