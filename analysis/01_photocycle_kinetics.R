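#!/usr/bin/env Rscript
# Photocycle kinetics of the rhodopsin guanylyl cyclase: preset schemes,
# their eigen-decay lifetimes, photostationary mixtures, and example
# population trajectories under flash and continuous illumination.

suppressMessages(library(rhodokin))
dir.create("results", showWarnings = FALSE)

schemes <- list("C259S 20C" = scheme_c259s_20C(),
                "WT 20C" = scheme_wt_20C(),
                "C259S -10C" = scheme_c259s_m10C())

rows <- lapply(names(schemes), function(nm) {
  tc <- eigen_time_constants(schemes[[nm]])
  data.frame(scheme = nm,
             tau_L_s = sort(tc)[2],   # fastest is the unresolved K decay
             tau_M_s = max(tc))
})
constants <- do.call(rbind, rows)
write.csv(constants, "results/photocycle_constants.csv", row.names = FALSE)
cat("Eigen-decay lifetimes (s):\n")
print(constants, row.names = FALSE)
cat(sprintf("M-decay ratio C259S / WT: %.1f-fold\n",
            constants$tau_M_s[1] / constants$tau_M_s[2]))

cat("\nPhotostationary states under continuous illumination (k_ex = 1/s):\n")
ps <- t(vapply(list(scheme_c259s_20C(k_ex = 1), scheme_c259s_m10C(k_ex = 1)),
               photostationary, numeric(4)))
rownames(ps) <- c("C259S 20C", "C259S -10C")
print(round(ps, 4))
cat("At 20 C the long-lived M state accumulates almost exclusively; at\n")
cat("-10 C the 50-fold slower L decay raises the stationary L population\n")
cat("tenfold. M still dominates in this closed four-state scheme because\n")
cat("its lifetime exceeds L's; see the methods vignette for why measured\n")
cat("photostationary mixtures can be more L-rich than the scheme predicts.\n")

# single-turnover trajectory at 20 C: L precedes M, M decays in seconds
tr <- propagate(scheme_c259s_20C(), protocol_single_turnover(20, 0.3),
                times_uvvis_flash())
write_trajectory(tr, "results/trajectory_c259s_20C_flash.tsv")
i_L <- which.max(tr$populations[, "L"])
i_M <- which.max(tr$populations[, "M"])
cat(sprintf("\nAfter a flash at 20 C, L peaks at %.3g s and M at %.3g s.\n",
            tr$times[i_L], tr$times[i_M]))
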