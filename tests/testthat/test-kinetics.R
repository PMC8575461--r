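test_that("rate matrix is a probability-conserving generator", {
  s <- kinetic_scheme(k_KL = 100, k_LM = 25, k_LD = 3, k_MD = 0.3, k_ex = 2)
  for (light in c(TRUE, FALSE)) {
    A <- rate_matrix(s, light_on = light)
    expect_equal(colSums(A), c(D = 0, K = 0, L = 0, M = 0))
    offdiag <- A[row(A) != col(A)]
    expect_true(all(offdiag >= 0))
    expect_equal(A["K", "D"], if (light) 2 else 0)
  }
  # no transitions at all
  expect_equal(rate_matrix(kinetic_scheme(0, 0, 0, 0, 0)),
               matrix(0, 4, 4, dimnames = list(c("D", "K", "L", "M"),
                                               c("D", "K", "L", "M"))))
  expect_error(kinetic_scheme(k_LM = -1), "k_LM")
})

test_that("eigen-decay constants match a brute-force eigenvalue oracle", {
  # sequential scheme: the generator is triangular up to state ordering,
  # so its eigenvalues are exactly {0, -k_KL, -k_LM, -k_MD}
  s <- kinetic_scheme(k_KL = 50, k_LM = 10, k_LD = 0, k_MD = 0.5)
  st <- c("D", "K", "L", "M")
  A <- matrix(0, 4, 4, dimnames = list(st, st))
  A["L", "K"] <- 50; A["K", "K"] <- -50
  A["M", "L"] <- 10; A["L", "L"] <- -10
  A["D", "M"] <- 0.5; A["M", "M"] <- -0.5
  ev <- sort(Re(eigen(A, only.values = TRUE)$values))
  expect_equal(sort(-c(50, 10, 0.5, 0)), ev)
  expect_equal(eigen_time_constants(s), sort(1 / c(50, 10, 0.5)))

  # single decaying edge
  expect_equal(eigen_time_constants(kinetic_scheme(0, 0, 0, k_MD = 2)), 0.5)

  # branched L decays through the sum of its channels
  sb <- kinetic_scheme(k_KL = 1e4, k_LM = 7, k_LD = 3, k_MD = 0.2)
  expect_true(any(abs(eigen_time_constants(sb) - 1 / 10) < 1e-12))
})

test_that("preset schemes carry the published lifetimes", {
  tc <- eigen_time_constants(scheme_c259s_20C())
  expect_equal(max(tc), 3.13)
  expect_equal(sort(tc)[2], 0.040)
  tw <- eigen_time_constants(scheme_wt_20C())
  expect_equal(rev(sort(tw))[1:2], c(0.570, 0.030))
  # temperature scaling: L decay x50, M decay x10
  tm <- scheme_c259s_m10C()
  expect_equal(tm$k$k_LM + tm$k$k_LD, (1 / 0.040) / 50)
  expect_equal(tm$k$k_MD, (1 / 3.13) / 10)
})

test_that("propagation conserves populations and matches the ODE oracle", {
  set.seed(421)
  protocol <- protocol_cw(t_on = 2, t_end = 5)
  times <- seq(0, 5, length.out = 40)
  for (i in 1:25) {
    s <- random_scheme()
    tr_e <- propagate(s, protocol, times, method = "eigen")
    tr_o <- propagate(s, protocol, times, method = "ode")
    expect_rows_sum_to_one(tr_e)
    expect_true(all(tr_e$populations >= -1e-12))
    expect_lt(max(abs(tr_e$populations - tr_o$populations)), 1e-8)
  }
})

test_that("a frozen system stays put and a flash transfers D to K", {
  s0 <- kinetic_scheme(0, 0, 0, 0)
  pr <- protocol_single_turnover(t_end = 10, flash_conversion = 0.4)
  tr <- propagate(s0, pr, seq(0.1, 10, length.out = 20))
  expect_true(all(tr$populations[, "D"] == 0.6))
  expect_true(all(tr$populations[, "K"] == 0.4))
})

test_that("flash relaxation follows the closed-form linear-chain solution", {
  # Bateman cascade K -> L -> M -> D starting in pure K
  s <- kinetic_scheme(k_KL = 200, k_LM = 25, k_LD = 0, k_MD = 1 / 3.13)
  pr <- protocol_single_turnover(t_end = 20, flash_conversion = 1)
  times <- times_uvvis_flash(from = 1e-4, to = 20, n = 200)
  tr <- propagate(s, pr, times)
  k <- c(200, 25, 1 / 3.13)
  bate <- function(t, ks) {
    # concentration of the last species of a chain fed from species 1
    n <- length(ks)
    sapply(t, function(tt) {
      sum(vapply(seq_len(n), function(j) {
        num <- prod(ks[seq_len(n - 1)])
        den <- prod(ks[setdiff(seq_len(n), j)] - ks[j])
        num / den * exp(-ks[j] * tt)
      }, numeric(1)))
    })
  }
  expect_lt(max(abs(tr$populations[, "K"] - exp(-k[1] * times))), 1e-8)
  expect_lt(max(abs(tr$populations[, "L"] - bate(times, k[1:2]))), 1e-8)
  expect_lt(max(abs(tr$populations[, "M"] - bate(times, k))), 1e-8)

  # the slow tail of M is mono-exponential with the M lifetime
  late <- times > 6
  slope <- stats::coef(stats::lm(log(tr$populations[late, "M"]) ~ times[late]))[2]
  expect_equal(unname(-1 / slope), 3.13, tolerance = 1e-3)
})

test_that("the sequential limit of the branched scheme is exact", {
  sb <- kinetic_scheme(k_KL = 500, k_LM = 20, k_LD = 0, k_MD = 0.4)
  ss <- kinetic_scheme(k_KL = 500, k_LM = 20, k_MD = 0.4)
  pr <- protocol_single_turnover(t_end = 10, flash_conversion = 0.7)
  times <- seq(0.01, 10, length.out = 50)
  expect_identical(propagate(sb, pr, times)$populations,
                   propagate(ss, pr, times)$populations)
})

test_that("branching ratio equals k_LM / (k_LM + k_LD)", {
  # the total flux through M equals the branch fraction: integrate the
  # L -> M flux analytically-free on a fine grid and compare
  s <- kinetic_scheme(k_KL = 1e4, k_LM = 6, k_LD = 4, k_MD = 1e9)
  pr <- protocol_single_turnover(t_end = 10, flash_conversion = 1)
  times <- exp(seq(log(1e-5), log(10), length.out = 4000))
  tr <- propagate(s, pr, times)
  flux_LM <- 6 * tr$populations[, "L"]
  through_M <- sum(diff(times) * (flux_LM[-1] + flux_LM[-length(times)]) / 2)
  expect_equal(through_M, 0.6, tolerance = 1e-3)
})

test_that("photostationary state is the generator null space and favors M at 20 C", {
  s <- scheme_c259s_20C(k_ex = 1)
  p <- photostationary(s)
  expect_equal(sum(p), 1)
  expect_lt(max(abs(rate_matrix(s, TRUE) %*% p)), 1e-12)
  # long-time ODE integration reaches the same distribution
  pr <- protocol_cw(t_on = 400)
  tr <- propagate(s, pr, c(0, 400), method = "ode")
  expect_equal(unname(tr$populations[2, ]), unname(p), tolerance = 1e-6)
  # under continuous light the slow M state accumulates
  expect_gt(p["M"], p["K"])
  expect_gt(p["M"], p["L"])
  # degenerate limit: no excitation
  expect_warning(p0 <- photostationary(scheme_c259s_20C(k_ex = 0)), "k_ex")
  expect_equal(unname(p0[]), c(1, 0, 0, 0), ignore_attr = TRUE)
})

test_that("propagation validates its inputs", {
  s <- scheme_c259s_20C()
  pr <- protocol_single_turnover(t_end = 5)
  expect_error(propagate(s, pr, c(0.1, 1), init = c(0.5, 0, 0, 0)), "sum to 1")
  expect_error(propagate(s, pr, c(0.1, 10)), "protocol span")
  expect_error(illumination_protocol(
    data.frame(start = 0, duration = 1, mode = "flash")), "duration 0")
  expect_error(illumination_protocol(
    data.frame(start = c(0, 0.5), duration = c(1, 1),
               mode = c("cw", "dark"))), "overlap")
})
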