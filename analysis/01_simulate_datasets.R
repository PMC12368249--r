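#!/usr/bin/env Rscript
# Generates the synthetic datasets the downstream analyses run on:
# a calcium movie of a light-triggered activation wave, and a multichannel
# MEA recording with light-locked rate elevation. Both are written with
# their ground truth so every later step can be checked.

suppressPackageStartupMessages(library(optophys))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260925L

## Calcium movie: 40 cells, single pulse at 1 s, wave propagates outward.
net <- generate_network(40, field_shape = c(64, 64), mean_degree = 3,
                        delay_range = c(0.2, 0.8), seed = seed)
stim <- stim_schedule(1.0, 0.01, "561 nm single-cell pulse")
cal <- simulate_calcium_movie(net, stim, frame_rate = 30, duration = 20,
                              kernel = c(0.1, 1.5, 10), noise_sd = 0.5,
                              seed = seed)
write_movie(cal$movie, "results/data/calcium_wave.tif", seed = seed)
gt <- cal$ground_truth
utils::write.csv(
  data.frame(cell = seq_along(gt$activation_time),
             activation_time_s = gt$activation_time,
             n_spikes = lengths(gt$spike_times)),
  "results/data/calcium_ground_truth.csv", row.names = FALSE)
message(sprintf("calcium movie: %d frames, %d/%d cells activated",
                dim(cal$movie)[1], sum(!is.na(gt$activation_time)),
                length(gt$activation_time)))

## MEA recording: 16 electrodes, 60 s, 1-Hz pulses over [20, 50) s.
mst <- make_stim_schedule(1, 0.010, 20, 50, "475 nm, 3.9 mW/mm2")
mea <- simulate_mea_recording(16, 20000, 60, baseline_rate = 1,
                              evoked_multiplier = 3, stim = mst,
                              responding_electrodes = 1:12, seed = seed)
write_mea_recording(mea$recording, "results/data/mea_recording")
write_spike_table(spike_train_set(mea$ground_truth$spike_times, 60),
                  "results/data/mea_ground_truth_spikes.csv")
message(sprintf("MEA recording: %d ground-truth spikes on 16 electrodes",
                sum(lengths(mea$ground_truth$spike_times))))
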