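#!/usr/bin/env Rscript
# Caged-substrate enzyme kinetics: the two-step uncaging experiment for
# the light-gated enzyme (120 s dark, UV uncaging, 85 s dark, 300 s green
# light, 364 s dark), constant-slope quantification of the product marker
# trace, full turnover-model fitting, and the onset comparison between
# the M-state (1630) and product (1087) marker bands.

suppressMessages(library(rhodokin))
dir.create("results", showWarnings = FALSE)
seed <- 1L

protocol <- protocol_rgc_turnover()
times <- seq(0, 869, by = 1)
truth <- turnover_params(v_dark = 2e-4, bound_amplitude = 0.5, k_burst = 1,
                         v_light = 8e-4, v_post = 3e-4,
                         substrate_total = 1.5)
ds <- simulate_enzyme_dataset(truth, protocol, axis_ftir(), times,
                              noise = noise_model(sigma = 0.005,
                                                  seed = seed))
write_dataset(ds, "results/enzyme_dataset_rgc.tsv")

trace <- extract_trace(ds, 1087, window = 3)
cat("Constant-slope sections of the 1087 (product) marker trace:\n")
pf <- fit_phases(trace, breakpoints = c(120, 205, 505))
print(pf$phases, row.names = FALSE, digits = 3)
cat("The pre-uncaging and pre-illumination slopes expose the dark\n")
cat("activity; the green-light phase is dominated by the burst of\n")
cat("pre-bound substrate followed by binding-limited turnover.\n")

fit <- fit_turnover(trace$times, trace$values, protocol, seed = seed)
# the trace reports product through the 1087 band gain (the generator
# normalizes the product trace by the substrate pool), so amplitude-like
# parameters are compared on that scale
gain <- mean(ds$metadata$species_matrix["cGMP",
             abs(ds$axis - 1087) <= 1]) / truth$substrate_total
comp <- data.frame(
  parameter = c("v_dark", "bound_amplitude", "k_burst", "v_light", "v_post"),
  truth = c(2e-4, 0.5, 1, 8e-4, 3e-4) * c(gain, gain, 1, gain, gain))
comp$fitted <- unlist(fit$params[comp$parameter])
write.csv(comp, "results/enzyme_fit.csv", row.names = FALSE)
cat("\nTurnover-model fit to the 1087 trace (trace-scale units):\n")
print(comp, row.names = FALSE, digits = 3)

onset <- onset_similarity(extract_trace(ds, 1630), extract_trace(ds, 1087),
                          onset_window = c(205, 235),
                          pre_window = c(130, 204))
cat(sprintf("\nM-state (1630) vs product (1087) at illumination onset:\n"))
cat(sprintf("  normalized RMS difference %.3f, best lag %d samples\n",
            onset$rms, onset$lag))
cat("The two marker kinetics are nearly identical at onset: product\n")
cat("formation tracks the formation of the catalytically active M state.\n")
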