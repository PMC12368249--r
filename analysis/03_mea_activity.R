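#!/usr/bin/env Rscript
# MEA activity analysis of the simulated light-stimulated recording:
# 5.5-SD spike detection, active electrodes, bursts and network bursts,
# STTC and cross-correlogram synchrony, Lempel-Ziv complexity, lag times,
# MFR fold changes, and PCA/k-means spike sorting on one electrode.

suppressPackageStartupMessages(library(optophys))
dir.create("results/mea", recursive = TRUE, showWarnings = FALSE)

rec <- read_mea_recording("results/data/mea_recording")
trains <- detect_spikes_all(rec, k_sd = 5.5)
write_spike_table(trains, "results/mea/detected_spikes.csv")
act <- active_electrodes(trains)
message(sprintf("%d spikes detected; %d of %d electrodes active",
                sum(lengths(trains$trains)), length(act),
                length(trains$trains)))

bursts <- do.call(rbind, lapply(act, function(e) {
  b <- detect_bursts(trains$trains[[e]])
  if (nrow(b)) cbind(electrode = e, b) else NULL
}))
if (!is.null(bursts))
  utils::write.csv(bursts, "results/mea/bursts.csv", row.names = FALSE)
nb <- detect_network_bursts(trains)
message(sprintf("%d single-electrode bursts, %d network bursts",
                if (is.null(bursts)) 0L else nrow(bursts), nrow(nb)))

sm <- sttc_matrix(trains)
utils::write.csv(sm$sttc, "results/mea/sttc_matrix.csv")
si <- synchrony_index(trains)
message(sprintf("mean STTC %.3f; synchrony index %.3f (chance %.3f)",
                mean(sm$sttc[upper.tri(sm$sttc)], na.rm = TRUE),
                si$well_raw, si$expected_raw))

lz <- lzc_per_electrode(trains)
utils::write.csv(lz, "results/mea/lzc.csv", row.names = FALSE)

lag <- lag_times(sort(unlist(trains$trains, use.names = FALSE)),
                 rec$stim_times)
utils::write.csv(lag, "results/mea/lag_times.csv", row.names = FALSE)
message(sprintf("median stimulation lag %.1f ms over %d pulses",
                1000 * stats::median(lag$lag, na.rm = TRUE), nrow(lag)))

mfr <- mfr_metrics(trains, list(before = c(0, 20), during = c(20, 50),
                                after = c(50, 60)))
utils::write.csv(mfr$rates, "results/mea/mfr.csv", row.names = FALSE)
message(sprintf("median MFR fold change during stimulation: %.2f",
                stats::median(mfr$rates$fold_change, na.rm = TRUE)))

## spike sorting on the busiest electrode
e <- names(which.max(lengths(trains$trains)))
xf <- bandpass_filter(rec$raw[match(e, rec$layout$electrode), ], rec$fs)
wf <- extract_waveforms(xf, rec$fs, trains$trains[[e]])
if (nrow(wf$waveforms) >= 20) {
  sr <- sort_spikes(wf$waveforms, seed = 1)
  message(sprintf("electrode %s: %d spikes sorted into %d unit(s)",
                  e, length(sr$labels), sr$n_units))
  utils::write.csv(data.frame(time_s = wf$times, unit = sr$labels),
                   "results/mea/sorted_units.csv", row.names = FALSE)
}
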