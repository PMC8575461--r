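# Shared fixtures: small grids keep the suite fast while resolving both
# photocycle lifetimes.

fix_times_uvvis <- times_uvvis_flash(n = 120)
fix_axis_uvvis <- axis_uvvis(by = 5)
fix_axis_ftir <- axis_ftir(by = 2)

# coarse FTIR decay grid: still ~40 frames per fast lifetime at -10 C
fix_times_ftir <- times_ftir_frames(to = 120, by = 0.058)

random_scheme <- function() {
  kinetic_scheme(k_KL = stats::runif(1, 10, 1e3),
                 k_LM = stats::runif(1, 0.5, 50),
                 k_LD = stats::runif(1, 0, 5),
                 k_MD = stats::runif(1, 0.01, 1),
                 k_ex = stats::runif(1, 0, 2))
}

expect_rows_sum_to_one <- function(traj, tol = 1e-9) {
  expect_lt(max(abs(rowSums(traj$populations) - 1)), tol)
}
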