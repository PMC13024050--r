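#!/usr/bin/env Rscript
# Simulate the study conditions: 72 h of chamber environment (heater pulses,
# thermostat fans, diurnal light, anti-coupled humidity, 24 h flushes) and the
# coupled internal plant channels. Writes both traces as tidy CSV.

suppressPackageStartupMessages(library(phytoaffect))
dir.create("results", showWarnings = FALSE)

seed <- 1L
env <- simulate_environment(chamber_config(seed = seed))
plant <- simulate_plant(env, coupling_config(seed = seed + 1))

write_trace_csv(env, "results/environment_trace.csv")
write_trace_csv(plant, "results/plant_trace.csv")

cat(sprintf("simulated %d samples (%.0f h at %.1f Hz)\n",
            nrow(env), max(env$timestamp) / 3600, 0.5))
cat(sprintf("heater duty cycle: %.1f%%; fan duty cycle: %.1f%%\n",
            100 * mean(env$heater), 100 * mean(env$fan)))
cat(sprintf("temperature: %.1f-%.1f degC; humidity: %.0f-%.0f %%RH\n",
            min(env$temperature), max(env$temperature),
            min(env$humidity), max(env$humidity)))
cat(sprintf("samples above the 36 degC trigger with fans off: %d (must be 0)\n",
            sum(env$temperature > 36 & env$fan == 0)))
cat("wrote results/environment_trace.csv and results/plant_trace.csv\n")
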