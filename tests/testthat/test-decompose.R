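test_that("SVD is exact, deterministic in sign, and rank-revealing", {
  set.seed(31)
  u <- exp(-seq(0, 5, length.out = 40))
  v <- render_spectrum(default_species("uvvis-rgc")$L, fix_axis_uvvis)
  ds <- spectral_dataset(seq_len(40), fix_axis_uvvis, u %o% v)
  sv <- svd_decompose(ds)
  d <- sv$singular_values
  expect_equal(sum(d > 1e-10 * d[1]), 1)
  # sign convention: dominant element of each spectral component positive
  expect_gt(sv$spectral_components[which.max(abs(sv$spectral_components[, 1])), 1], 0)

  m <- matrix(stats::rnorm(600), 30)
  svm <- svd_decompose(m)
  rec <- svm$temporal_components %*% diag(svm$singular_values) %*%
    t(svm$spectral_components)
  expect_lt(norm(m - rec, "F") / norm(m, "F"), 1e-10)
  m[3, 4] <- NaN
  expect_error(svd_decompose(m), "NA")
})

test_that("rank selection counts signal components, not noise", {
  set.seed(77)
  noise <- matrix(stats::rnorm(120 * 60, 0, 0.01), 120)
  expect_equal(svd_decompose(noise)$selected_rank, 0L)

  u <- exp(-seq(0, 4, length.out = 120))
  v <- stats::dnorm(seq(-3, 3, length.out = 60))
  r1 <- svd_decompose(u %o% v + 1e-5 * noise)
  expect_equal(r1$selected_rank, 1L)

  ds <- simulate_uvvis_single_turnover(seed = 3, sigma_rel = 0.01,
                                       times = fix_times_uvvis,
                                       axis = fix_axis_uvvis)
  expect_equal(svd_decompose(ds)$selected_rank, 2L)
})

test_that("a single noiseless exponential is fitted to optimizer precision", {
  times <- seq(0, 10, length.out = 60)
  y <- matrix(exp(-times / 2.0), ncol = 1)
  fit <- global_exponential_fit(y, 1, times = times, fit_offset = TRUE,
                                use_svd = FALSE)
  expect_equal(fit$time_constants, 2.0, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
})

test_that("the variable-projection optimum matches a dense grid oracle", {
  ds <- simulate_uvvis_single_turnover(seed = 9, sigma_rel = 0.01,
                                       times = fix_times_uvvis,
                                       axis = fix_axis_uvvis)
  sv <- svd_decompose(ds)
  fit <- global_exponential_fit(sv, 2, seed = 9)
  # brute-force search over a dense log-spaced (tau1, tau2) grid never
  # beats the optimizer
  Y <- sv$temporal_components[, 1:2] %*% diag(sv$singular_values[1:2])
  ts <- ds$times - ds$times[1]
  grid <- exp(seq(log(1e-4), log(80), length.out = 60))
  best_grid <- Inf
  for (i in seq_along(grid)) {
    for (j in seq_len(i - 1)) {
      X <- cbind(exp(-ts / grid[j]), exp(-ts / grid[i]), 1)
      rss <- sum(stats::lm.fit(X, Y)$residuals^2)
      if (rss < best_grid) best_grid <- rss
    }
  }
  expect_lte(fit$rss, best_grid + 1e-12)
  expect_equal(fit$time_constants, c(0.040, 3.13), tolerance = 0.05)
})

test_that("noiseless recovery is exact and components never hurt", {
  ds <- simulate_uvvis_single_turnover(seed = 1, sigma_rel = 0,
                                       times = fix_times_uvvis,
                                       axis = fix_axis_uvvis)
  fit2 <- global_exponential_fit(ds, 2, seed = 1)
  expect_equal(fit2$time_constants, c(0.040, 3.13), tolerance = 1e-5)
  rss <- vapply(1:3, function(nc) {
    global_exponential_fit(ds, nc, seed = 1, rank = 3)$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("time constants are recovered within 5% median error at 1% noise", {
  rc <- recover_time_constants(scheme_c259s_20C(), n_seeds = 8,
                               sigma_rel = 0.01, times = fix_times_uvvis,
                               axis = fix_axis_uvvis)
  expect_lt(abs(stats::median(rc$tau_fast) / 0.040 - 1), 0.05)
  expect_lt(abs(stats::median(rc$tau_slow) / 3.13 - 1), 0.05)
})

test_that("single-component rotation is the identity", {
  times <- seq(0, 10, length.out = 40)
  y <- exp(-times / 1.5) %o% render_spectrum(default_species("uvvis-rgc")$M,
                                             fix_axis_uvvis)
  fit <- global_exponential_fit(
    spectral_dataset(times, fix_axis_uvvis, y), 1, fit_offset = FALSE)
  sp <- dads_to_sads(fit, "sequential")
  expect_equal(unname(sp$sads[1, ]), unname(fit$dads[1, ]))
})

test_that("sequential target analysis recovers the generator spectra", {
  sp_true <- default_species("uvvis-rgc")
  res <- recover_uvvis_species(seed = 4, sigma_rel = 0.01,
                               times = fix_times_uvvis, axis = fix_axis_uvvis)
  for (s in c("L", "M")) {
    expect_gt(stats::cor(res$species$sads[s, ],
                         render_spectrum(sp_true[[s]], fix_axis_uvvis)),
              0.99)
  }
  # the DADS -> SADS map is invertible and reproduces the fitted surface
  sf <- res$species
  C <- species_populations(sf)
  surf <- C %*% sf$sads
  if (!is.null(res$fit$offset)) {
    surf <- surf + rep(1, nrow(C)) %o% res$fit$offset
  }
  expect_lt(max(abs(surf - fitted_surface(res$fit))), 1e-10)
})

test_that("branched target analysis finds the amide-I marker bands", {
  res <- recover_ftir_species_m10(seed = 2, times = fix_times_ftir,
                                  axis = fix_axis_ftir)
  expect_equal(res$rank, 2L)
  expect_lt(abs(res$L_peak_cm - 1647), 2 + 1e-9)
  expect_lt(abs(res$M_peak_cm - 1630), 2 + 1e-9)
  expect_error(dads_to_sads(res$fit, "branched", init_fraction = 0.1,
                            branch_fraction = 0.5), NA)
})

test_that("topology comparison prefers the generating scheme", {
  ax <- axis_ftir(1180, 1700, by = 4)
  tms <- seq(0.029, 120, by = 0.25)
  sp <- default_species("ftir-rgc")
  mk_pair <- function(bf, seed) {
    sch <- scheme_c259s_m10C(k_ex = 1, branch_fraction = bf)
    d1 <- simulate_dataset(sch, protocol_single_turnover(130, 1), sp,
                           tms, ax, noise = noise_model(0.005, seed = seed))
    d2 <- simulate_ftir_decay_m10(sch, sigma_rel = 0, seed = seed,
                                  times = tms, axis = ax)
    with_seed <- function(s, v) { set.seed(s); v() }
    d2$values <- d2$values + with_seed(seed + 1000, function() {
      matrix(stats::rnorm(length(d2$values), 0, 0.005), nrow(d2$values))
    })
    list(d1, d2)
  }
  winners <- function(bf) {
    vapply(1:3, function(seed) {
      compare_topologies(mk_pair(bf, seed), seed = seed)$winner
    }, character(1))
  }
  w_seq <- winners(1)       # sequential generator (no branch)
  w_br <- winners(0.5)      # strong branch
  expect_gte(sum(w_seq == "sequential"), 2)
  expect_gte(sum(w_br == "branched"), 2)
  # the loser is always reported alongside the winner
  ct <- compare_topologies(mk_pair(0.5, 1), seed = 1)
  expect_setequal(ct$report$topology, c("sequential", "branched"))
  expect_true(all(is.finite(ct$report$aicc)))
})
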