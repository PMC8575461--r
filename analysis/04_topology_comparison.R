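#!/usr/bin/env Rscript
# Sequential vs branched photocycle: joint target analysis of a
# flash-excited single-turnover dataset and a post-illumination decay
# with shared species spectra. A single dataset cannot distinguish the
# two schemes (any remixing of the concentration profiles is absorbed by
# the freely fitted spectra); the two-protocol design can.

suppressMessages(library(rhodokin))
dir.create("results", showWarnings = FALSE)
seed <- 1L

axis <- axis_ftir(1180, 1700, by = 4)
times <- seq(0.029, 120, by = 0.25)
species <- default_species("ftir-rgc")

make_pair <- function(branch_fraction) {
  sch <- scheme_c259s_m10C(k_ex = 1, branch_fraction = branch_fraction)
  flash <- simulate_dataset(sch, protocol_single_turnover(130, 1), species,
                            times, axis,
                            noise = noise_model(0.005, seed = seed))
  decay <- simulate_ftir_decay_m10(sch, sigma_rel = 0, seed = seed,
                                   times = times, axis = axis)
  set.seed(seed + 1000L)
  decay$values <- decay$values +
    matrix(rnorm(length(decay$values), 0, 0.005), nrow(decay$values))
  list(flash, decay)
}

rows <- list()
for (bf in c(1, 0.5)) {
  ct <- compare_topologies(make_pair(bf), seed = seed)
  cat(sprintf("\nGenerator branch fraction %.1f -> preferred topology: %s\n",
              bf, ct$winner))
  print(ct$report, row.names = FALSE, digits = 6)
  rows[[length(rows) + 1L]] <- cbind(generator_branch = bf, ct$report)
}
out <- do.call(rbind, rows)
write.csv(out, "results/topology_comparison.csv", row.names = FALSE)

cat("\nWith no branch the two candidates tie on residuals and the\n")
cat("information criterion picks the thriftier sequential scheme; with a\n")
cat("50% L -> D branch the sequential fit pays a clear residual penalty\n")
cat("and the branched scheme wins.\n")
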