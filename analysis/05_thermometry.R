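#!/usr/bin/env Rscript
# Pipette-resistance thermometry: fit the Arrhenius calibration from a
# synthetic cooling curve and convert a series of resistance readings back
# to temperature.

suppressPackageStartupMessages(library(optophys))
dir.create("results/thermometry", recursive = TRUE, showWarnings = FALSE)
set.seed(5)

## synthetic cooling-curve calibration: 50 C down to room temperature,
## E_a = 15 kJ/mol, 5-MOhm pipette at room temperature, 0.5% read noise
T_cal <- seq(296.15, 323.15, length.out = 25)
R_cal <- 5e6 * exp(15000 / 8.314 * (1 / T_cal - 1 / 296.15)) *
  exp(rnorm(25, 0, 0.005))
utils::write.csv(data.frame(resistance_ohm = R_cal,
                            temperature_c = T_cal - 273.15),
                 "results/thermometry/calibration_table.csv", row.names = FALSE)

cal <- fit_arrhenius(data.frame(R_cal, T_cal), T0 = 296.15)
print(cal)

## convert a mock illumination time series (resistance dips = warming)
R_series <- cal$R_0 * exp(cumsum(rnorm(60, 0, 0.0005)) -
                          0.002 * pmin(1:60, 30) / 30)
Ti <- resistance_to_temperature(R_series, cal)
utils::write.csv(data.frame(t_s = 1:60, resistance_ohm = R_series,
                            temperature_c = Ti - 273.15),
                 "results/thermometry/illumination_series.csv",
                 row.names = FALSE)
message(sprintf("temperature change over the series: %+.3f C",
                Ti[60] - Ti[1]))
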