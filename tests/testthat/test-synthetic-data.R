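test_that("species presets carry the published band positions", {
  uv <- default_species("uvvis-rgc")
  ax <- fix_axis_uvvis
  expect_equal(ax[which.max(render_spectrum(uv$L, ax))], 450)
  expect_equal(ax[which.max(render_spectrum(uv$M, ax))], 350)
  ir <- default_species("ftir-rgc")
  axf <- fix_axis_ftir
  m <- render_spectrum(ir$M, axf)
  pk <- detect_signed_peaks(m, axf, "positive", min_prominence = 0)
  expect_equal(pk$position[1], 1630)
  expect_error(default_species("nope"), "uvvis-rgc, ftir-rgc, ftir-enzyme")
  # axis excluding every band center: nothing to render
  far <- seq(2500, 2600, by = 2)
  expect_equal(render_spectrum(ir$L, far), rep(0, length(far)),
               tolerance = 1e-12)
})

test_that("Gaussian band rendering is exact and linear", {
  b <- spectral_band(500, 0.8, 30)
  expect_equal(render_spectrum(list(b), 500), 0.8)
  # cancellation
  b2 <- spectral_band(500, -0.8, 30)
  ax <- seq(400, 600, by = 1)
  expect_equal(render_spectrum(list(b, b2), ax), rep(0, length(ax)))
  # area against the closed-form Gaussian integral
  fine <- seq(200, 800, by = 0.05)
  y <- render_spectrum(list(b), fine)
  area <- sum(y) * 0.05
  expect_equal(area, 0.8 * 30 * sqrt(pi / (4 * log(2))), tolerance = 1e-6)
  expect_error(spectral_band(500, 1, 0), "fwhm")
})

test_that("noiseless datasets follow the bilinear model exactly", {
  sch <- scheme_c259s_20C()
  pr <- protocol_single_turnover(t_end = 20, flash_conversion = 0.3)
  sp <- default_species("uvvis-rgc")
  ds <- simulate_dataset(sch, pr, sp, fix_times_uvvis, fix_axis_uvvis,
                         noise = NULL)
  md <- ds$metadata
  expect_identical(ds$values,
                   md$trajectory$populations %*% md$species_matrix)
  # bilinearity: doubling every band amplitude doubles the dataset
  sp2 <- lapply(sp, function(s) {
    s$bands <- lapply(s$bands, function(b) { b$amplitude <- 2 * b$amplitude; b })
    s
  })
  ds2 <- simulate_dataset(sch, pr, sp2, fix_times_uvvis, fix_axis_uvvis,
                          noise = NULL)
  expect_equal(ds2$values, 2 * ds$values, tolerance = 1e-14)
})

test_that("nothing happens without excitation", {
  ds <- simulate_dataset(kinetic_scheme(0, 0, 0, 0),
                         protocol_single_turnover(10, flash_conversion = 0),
                         default_species("uvvis-rgc"),
                         seq(0.1, 10, length.out = 20), fix_axis_uvvis,
                         noise = noise_model(sigma = 0, seed = 1))
  expect_true(all(ds$values == 0))
})

test_that("numeric rank equals the number of populated intermediates", {
  sch <- scheme_c259s_20C()
  pr <- illumination_protocol(
    data.frame(start = 0, duration = 20, mode = "dark"))
  # start in an L/M mixture: two spectrally distinct decaying species
  ds <- simulate_dataset(sch, pr, default_species("uvvis-rgc"),
                         seq(0.01, 20, length.out = 100), fix_axis_uvvis,
                         noise = NULL,
                         init = c(D = 0.4, K = 0, L = 0.3, M = 0.3))
  d <- svd(ds$values)$d
  expect_equal(sum(d / d[1] > 1e-8), 2)
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  args <- list(scheme_c259s_20C(), protocol_single_turnover(20),
               default_species("uvvis-rgc"),
               fix_times_uvvis, fix_axis_uvvis)
  nm <- noise_model(sigma = 0.01, drift_amplitude = 0.005, seed = 7)
  d1 <- do.call(simulate_dataset, c(args, list(noise = nm)))
  d2 <- do.call(simulate_dataset, c(args, list(noise = nm)))
  expect_identical(d1$values, d2$values)
  d3 <- do.call(simulate_dataset,
                c(args, list(noise = noise_model(sigma = 0.01,
                                                 drift_amplitude = 0.005,
                                                 seed = 8))))
  expect_false(identical(d1$values, d3$values))
})

test_that("late continuous-illumination spectra are nearly pure M", {
  sch <- scheme_c259s_20C(k_ex = 1)
  pr <- protocol_cw(t_on = 60)
  sp <- default_species("ftir-rgc")
  ds <- simulate_dataset(sch, pr, sp, seq(0, 60, by = 0.5), fix_axis_ftir,
                         noise = noise_model(sigma = 1e-3, seed = 2))
  late <- ds$values[nrow(ds$values), ]
  pure_m <- render_spectrum(sp$M, ds$axis)
  expect_gt(stats::cor(late, pure_m), 0.999)
  pk <- detect_signed_peaks(late, ds$axis, "positive", min_prominence = 0.05)
  expect_equal(pk$position[1], 1630)
})

test_that("a missing species spectrum is reported by state name", {
  sp <- default_species("uvvis-rgc")
  sp$M <- NULL
  expect_error(
    simulate_dataset(scheme_c259s_20C(), protocol_single_turnover(20),
                     sp, fix_times_uvvis, fix_axis_uvvis, noise = NULL),
    "M")
})

test_that("enzyme datasets expose their generator traces", {
  pr <- protocol_rgc_turnover()
  times <- seq(0, 869, by = 2)
  tp <- turnover_params(v_dark = 2e-4, bound_amplitude = 0.5, k_burst = 1,
                        v_light = 8e-4, v_post = 3e-4, substrate_total = 1.5)
  ds <- simulate_enzyme_dataset(tp, pr, fix_axis_ftir, times, noise = NULL)
  md <- ds$metadata
  # the 1087 channel is the cGMP trace scaled by the band gain, on top of
  # the (constant after uncaging) contributions of the other species
  j <- which.min(abs(ds$axis - 1087))
  others <- md$traces[, colnames(md$traces) != "cGMP", drop = FALSE] %*%
    md$species_matrix[rownames(md$species_matrix) != "cGMP", j, drop = FALSE]
  got <- extract_trace(ds, 1087)$values - as.numeric(others)
  want <- md$traces[, "cGMP"] * md$species_matrix["cGMP", j]
  expect_lt(max(abs(got - want)), 1e-9)

  # M marker responds only during/after the green segment
  tr1630 <- extract_trace(ds, 1630)$values
  expect_true(all(abs(tr1630[times < 205]) < 1e-9))
  expect_gt(max(abs(tr1630[times >= 205 & times < 505])), 0.1)
})

test_that("an inert enzyme shows only the uncaging steps", {
  pr <- protocol_gc_turnover()
  times <- seq(0, 489, by = 2)
  ds <- simulate_enzyme_dataset(turnover_params(), pr, fix_axis_ftir, times,
                                noise = NULL,
                                scheme = scheme_c259s_20C(k_ex = 0))
  pre <- ds$values[times < 120, ]
  post <- ds$values[times >= 125, ]
  expect_true(all(pre == 0))
  # every post-uncaging spectrum is the same step spectrum
  expect_lt(max(abs(sweep(post, 2, post[1, ]))), 1e-12)
  expect_gt(max(abs(post)), 0.5)
  expect_error(
    simulate_enzyme_dataset(turnover_params(),
                            protocol_cw(10), fix_axis_ftir, seq(0, 10)),
    "uv")
})
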