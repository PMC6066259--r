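test_that("spike counting matches a brute-force crossing scan", {
  expect_identical(count_spikes(rep(-53.5, 100)), 0L)
  # one full sine of amplitude 60 about -10 crosses zero upward once
  t <- seq(0, 2 * pi, length.out = 2000)
  expect_identical(count_spikes(-10 + 60 * sin(t)), 1L)
  # tie-break: a sample exactly at 0 followed by a positive one counts once
  expect_identical(count_spikes(c(-1, 0, 1, -1)), 1L)
  expect_identical(count_spikes(c(-1, 0, -1)), 0L)
  # oracle equivalence on random traces
  set.seed(42)
  brute <- function(v) {
    n <- 0; armed <- FALSE
    for (x in v) {
      if (x < 0) armed <- TRUE
      if (armed && x > 0) { n <- n + 1; armed <- FALSE }
    }
    n
  }
  for (k in 1:20) {
    v <- cumsum(stats::rnorm(500, sd = 5)) - 20
    expect_identical(count_spikes(v), as.integer(brute(v)))
  }
})

test_that("AP features are exact on an analytic triangular spike", {
  # symmetric triangle from -60 to +40 over 4 ms on a flat baseline
  dt <- 0.001
  t <- seq(0, 30, by = dt)
  v <- rep(-60, length(t))
  up <- t >= 10 & t <= 12
  dn <- t > 12 & t <= 14
  v[up] <- -60 + (t[up] - 10) / 2 * 100
  v[dn] <- 40 - (t[dn] - 12) / 2 * 100
  tr <- tibble::tibble(time_ms = t, vm_mv = v)
  ft <- extract_ap_features(tr, stim_window = c(10, 14))
  expect_equal(ft$rmp_mv, -60)
  expect_equal(ft$peak_mv, 40, tolerance = 1e-3)
  expect_equal(ft$amplitude_mv, 100, tolerance = 1e-3)
  # half level at -10 mV: crossings at t = 11 and t = 13 exactly
  expect_equal(ft$duration_ms, 2, tolerance = 1e-3)
  # sampling invariance between 10 and 100 kHz
  tr10 <- tr[seq(1, nrow(tr), by = 100), ]  # 10 kHz
  ft10 <- extract_ap_features(tr10, stim_window = c(10, 14))
  expect_lt(abs(ft10$duration_ms - ft$duration_ms) / ft$duration_ms, 0.005)
  expect_lt(abs(ft10$amplitude_mv - ft$amplitude_mv) / ft$amplitude_mv, 0.005)
})

test_that("subthreshold traces report the RMP only", {
  t <- seq(0, 100, by = 0.05)
  tr <- tibble::tibble(time_ms = t, vm_mv = -53.5 + 3 * (t > 20 & t < 70))
  ft <- extract_ap_features(tr, stim_window = c(20, 70))
  expect_identical(ft$n_spikes, 0L)
  expect_equal(ft$rmp_mv, -53.5)
  expect_true(is.na(ft$peak_mv) && is.na(ft$duration_ms))
})

test_that("I-V extraction distinguishes peak and steady modes", {
  t <- seq(0, 100, by = 0.1)
  mk <- function(tp, i_peak, i_ss) {
    tibble::tibble(time_ms = t,
                   i_test = ifelse(t < 10, 0,
                                   i_ss + (i_peak - i_ss) * exp(-(t - 10) / 5)),
                   test_mv = tp)
  }
  traces <- dplyr::bind_rows(mk(-20, -2, -0.5), mk(0, -5, -1.5))
  pk <- extract_iv(traces, "i_test", "peak", window = c(10, 100))
  ss <- extract_iv(traces, "i_test", "steady", window = c(10, 100))
  expect_equal(pk$current, c(-2, -5), tolerance = 0.02)
  expect_equal(ss$current, c(-0.5, -1.5), tolerance = 1e-2)
  expect_true(all(abs(pk$current) > abs(ss$current)))
  # constant trace: peak equals steady
  const <- tibble::tibble(time_ms = t, i_test = -1, test_mv = 0)
  expect_equal(extract_iv(const, "i_test", "peak", window = c(10, 100))$current,
               extract_iv(const, "i_test", "steady", window = c(10, 100))$current)
  expect_error(extract_iv(const, "i_test", "peak", window = c(200, 300)),
               class = "drgsoma_invalid_input")
})

test_that("the S statistic is a dof-corrected RMS residual", {
  y <- stats::rnorm(10)
  expect_equal(s_statistic(y, y), 0)
  expect_equal(s_statistic(rep(1, 10), rep(0, 10), n_params = 1),
               sqrt(10 / 9))
  # refused when residual dof < 4
  expect_warning(out <- s_statistic(rep(1, 4), rep(0, 4), n_params = 2))
  expect_true(is.na(out))
  # scale equivariance
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  expect_equal(s_statistic(3 * a, 3 * b), 3 * s_statistic(a, b))
  expect_error(s_statistic(1:3, 1:4), class = "drgsoma_invalid_input")
})

test_that("transient features recover closed-form decay times", {
  t <- seq(0, 5000, by = 1)
  base <- 136e-6
  tau <- 400
  y <- base + ifelse(t < 100, 0, 50e-6 * exp(-(t - 100) / tau))
  tr <- tibble::tibble(time_ms = t, cai_mM = y)
  tf <- transient_features(tr, baseline_window = c(0, 99))
  expect_equal(tf$baseline, base)
  expect_equal(tf$delta, 50e-6, tolerance = 1e-6)
  # 80% recovery of an exponential takes tau * ln(5)
  expect_equal(tf$decay_ms, tau * log(5), tolerance = 0.01)
  flat <- tibble::tibble(time_ms = t, cai_mM = rep(base, length(t)))
  expect_equal(transient_features(flat, c(0, 99))$delta, 0)
})
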