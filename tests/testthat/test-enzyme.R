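test_that("the turnover model honors its limiting cases", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 1)
  # inert enzyme
  expect_equal(simulate_turnover(turnover_params(), pr, times),
               rep(0, length(times)))
  # burst-only: the asymptote is the pre-bound amplitude
  burst <- simulate_turnover(
    turnover_params(bound_amplitude = 0.7, k_burst = 0.5), pr, times)
  expect_equal(burst[length(burst)], 0.7, tolerance = 1e-8)
  # and follows 1 - exp(-k t) during illumination
  sel <- times >= 205 & times <= 505
  expect_equal(burst[sel], 0.7 * (1 - exp(-0.5 * (times[sel] - 205))),
               tolerance = 1e-9)
  expect_error(simulate_turnover(turnover_params(), protocol_cw(10),
                                 seq(0, 10)), "uv")
})

test_that("dark activity gives a strictly positive pre-illumination slope", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 1)
  tr <- simulate_turnover(turnover_params(v_dark = 2e-4, bound_amplitude = 0.5,
                                          k_burst = 1, v_light = 8e-4),
                          pr, times)
  pre_green <- times >= 125 & times <= 204
  slopes <- diff(tr[pre_green]) / diff(times[pre_green])
  expect_true(all(slopes > 0))
  expect_equal(stats::median(slopes), 2e-4, tolerance = 1e-6)
})

test_that("mass balance and light gating hold", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 0.5)
  tp <- turnover_params(v_dark = 5e-4, bound_amplitude = 0.4, k_burst = 2,
                        v_light = 3e-3, v_post = 1e-3, substrate_total = 0.8)
  tr <- simulate_turnover(tp, pr, times)
  expect_true(all(diff(tr) >= -1e-10))
  expect_true(all(tr <= 0.8 + 1e-12))
  expect_equal(max(tr), 0.8, tolerance = 1e-6)  # the cap binds here
  # gating: without dark or post activity the trace is flat outside the
  # green window once the burst has completed
  tg <- simulate_turnover(turnover_params(bound_amplitude = 0.5, k_burst = 1),
                          pr, times)
  expect_true(all(tg[times <= 205] == 0))
  expect_lt(diff(range(tg[times >= 520])), 1e-9)
})

test_that("hyperbolic product inhibition slows and reorders saturation", {
  pr <- protocol_gc_turnover()
  times <- seq(0, 489, by = 0.5)
  base <- list(v_dark = 0, bound_amplitude = 0.3, k_burst = 0.3,
               v_light = 2e-3)
  free <- simulate_turnover(do.call(turnover_params, base), pr, times)
  inhib <- simulate_turnover(
    do.call(turnover_params, c(base, list(K_inhib = 0.1))), pr, times)
  expect_true(all(inhib <= free + 1e-12))
  # a 10-fold larger substrate pool saturates at a higher product level
  # and reaches a given relative completion earlier than predicted by
  # linear scaling (rates fall off as product accumulates)
  s1 <- simulate_turnover(turnover_params(bound_amplitude = 0.3,
                                          k_burst = 0.3, v_light = 2e-3,
                                          K_inhib = 0.1,
                                          substrate_total = 0.5), pr, times)
  s10 <- simulate_turnover(turnover_params(bound_amplitude = 3,
                                           k_burst = 0.3, v_light = 2e-2,
                                           K_inhib = 0.1,
                                           substrate_total = 5), pr, times)
  expect_gt(max(s10), max(s1))
})

test_that("phase fitting recovers piecewise slopes", {
  times <- seq(0, 300, by = 0.5)
  slopes <- c(0.1, 1.0, 0.3)
  bp <- c(100, 200)
  truth <- ifelse(times < 100, 0.1 * times,
                  ifelse(times < 200, 10 + (times - 100),
                         110 + 0.3 * (times - 200)))
  # globally linear input: every phase gets the global slope
  lin <- fit_phases(times, 2 + 0.05 * times, bp)
  expect_equal(lin$phases$slope, rep(0.05, 3), tolerance = 1e-10)
  set.seed(12)
  noisy <- truth + stats::rnorm(length(truth), 0, 0.01 * diff(range(truth)))
  pf <- fit_phases(times, noisy, bp)
  expect_equal(pf$phases$slope, slopes, tolerance = 0.05)
  # published protocol breakpoints are accepted on the full-length trace
  long <- seq(0, 869, by = 1)
  expect_silent(fit_phases(long, 0.001 * long, c(120, 205, 505, 869)))
  expect_error(fit_phases(times, truth, c(0.2, 0.6)), "phase 1 .* need >= 3")
})

test_that("turnover fitting is self-consistent on noiseless data", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 2)
  truth <- turnover_params(v_dark = 2e-4, bound_amplitude = 0.5, k_burst = 1,
                           v_light = 8e-4, v_post = 3e-4)
  trace <- simulate_turnover(truth, pr, times)
  fit <- fit_turnover(times, trace, pr, seed = 1)
  for (nm in c("v_dark", "bound_amplitude", "k_burst", "v_light", "v_post")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-4)
  }
})

test_that("turnover parameters are recovered within 10% median error at 2% noise", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 2)
  truth <- turnover_params(v_dark = 2e-4, bound_amplitude = 0.5, k_burst = 1,
                           v_light = 8e-4, v_post = 3e-4)
  trace <- simulate_turnover(truth, pr, times)
  sig <- 0.02 * diff(range(trace))
  nm_names <- c("v_dark", "bound_amplitude", "k_burst", "v_light", "v_post")
  errs <- t(vapply(1:8, function(seed) {
    set.seed(seed)
    noisy <- trace + stats::rnorm(length(trace), 0, sig)
    fit <- fit_turnover(times, noisy, pr, seed = seed, n_starts = 2)
    vapply(nm_names, function(nm) {
      abs(fit$params[[nm]] / truth[[nm]] - 1)
    }, numeric(1))
  }, numeric(5)))
  med <- apply(errs, 2, stats::median)
  expect_true(all(med < 0.10))
})

test_that("feedback inhibition is recovered when fitted", {
  pr <- protocol_gc_turnover()
  times <- seq(0, 489, by = 8)
  truth <- turnover_params(v_dark = 0, bound_amplitude = 0.3, k_burst = 0.3,
                           v_light = 2e-3, K_inhib = 0.15,
                           substrate_total = 0.6)
  trace <- simulate_turnover(truth, pr, times)
  fit <- fit_turnover(times, trace, pr, with_inhibition = TRUE,
                      substrate_total = 0.6, seed = 1, n_starts = 3)
  expect_equal(fit$params$K_inhib, 0.15, tolerance = 1e-3)
  expect_equal(fit$params$k_burst, 0.3, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
})

test_that("phase slopes of a simulated trace follow the activity ordering", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 1)
  tp <- turnover_params(v_dark = 2e-4, bound_amplitude = 0.5, k_burst = 0.05,
                        v_light = 1.5e-3, v_post = 4e-4)
  trace <- simulate_turnover(tp, pr, times)
  pf <- fit_phases(times, trace, c(120, 205, 505))
  sl <- pf$phases$slope
  # dark activity < post-illumination < illuminated (burst + turnover)
  expect_lt(sl[1], sl[4])
  expect_lt(sl[4], sl[3])
  expect_gt(sl[3], sl[2])
})
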