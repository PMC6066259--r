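test_that("steady-state curves pass their half-activation points exactly", {
  expect_equal(ttxs_kinetics(-25.8)$m_inf, 0.5)
  expect_equal(ttxs_kinetics(-55.8)$h_inf, 0.5)
  expect_equal(nav18_kinetics(-11.4)$m_inf, 0.5)
  expect_equal(nav18_kinetics(-24.2)$h_inf, 0.5)
  expect_equal(ka_kinetics(-40.8)$n_inf, 0.5)
  expect_equal(ka_kinetics(-74.2)$h_inf, 0.5)
  expect_equal(kdr_kinetics(-35)$n_inf, 0.5)
  expect_equal(ca_l_kinetics(8.46)$m_inf, 0.5)
  expect_equal(ca_n_kinetics(-6.5)$m_inf, 0.5)
  expect_equal(ca_n_kinetics(-70)$h_inf, 0.5)
  expect_equal(skca_evaluate(0, 0.42e-3)$o, 0.5)
})

test_that("printed time-constant landmarks are reproduced", {
  expect_equal(ka_kinetics(0)$tau_h_slow, 787.4)
  expect_equal(ka_kinetics(-50)$tau_h_fast, 92.87)
  expect_equal(kdr_kinetics(-20)$tau_n, 36.88)
  expect_equal(ca_l_kinetics(0)$tau_h, 1463.71)
  # Nav1.8 inactivation opening rate at its sigmoid midpoint
  kk <- nav18_kinetics(-68.5)
  a_h <- 0.003 + 1.63 / 2
  b_h <- 0.81 - 0.81 / (1 + exp((-68.5 - 11.44) / 13.12))
  expect_equal(kk$tau_h, 1 / (a_h + b_h), tolerance = 1e-12)
  # TTX-S activation tau equals 1/(alpha+beta) evaluated directly
  a_m <- 15.5 / (1 + exp((-5 - 5) / -12.08))
  b_m <- 35.2 / (1 + exp((-5 + 72.7) / 16.7))
  expect_equal(ttxs_kinetics(-5)$tau_m, 1 / (a_m + b_m), tolerance = 1e-12)
})

test_that("all time constants are strictly positive on the working range", {
  v <- seq(-120, 80, by = 1)
  expect_true(all(ttxs_kinetics(v)$tau_m > 0) && all(ttxs_kinetics(v)$tau_h > 0))
  expect_true(all(nav18_kinetics(v)$tau_m > 0) && all(nav18_kinetics(v)$tau_h > 0))
  ka <- ka_kinetics(v)
  expect_true(all(ka$tau_n > 0) && all(ka$tau_h_fast > 0) && all(ka$tau_h_slow > 0))
  expect_true(all(kdr_kinetics(v)$tau_n > 0))
  expect_true(all(bkca_kinetics(v, 1.36e-4)$tau_n > 0))
  expect_true(all(ca_l_kinetics(v)$tau_m > 0) && all(ca_l_kinetics(v)$tau_h > 0))
  expect_true(all(ca_n_kinetics(v)$tau_m > 0) && all(ca_n_kinetics(v)$tau_h > 0))
})

test_that("passive current is ohmic with the stated leak parameters", {
  expect_equal(passive_current(-41.583, 1e-4, -41.583), 0)
  expect_equal(passive_current(-53.5, 1e-4, -41.583), -1.1917e-3,
               tolerance = 1e-6)
  expect_equal(passive_current(-30, 2e-4, -41.583),
               2 * passive_current(-30, 1e-4, -41.583))
})

test_that("BK activation shifts with calcium as a Boltzmann in pCa", {
  kk <- bkca_kinetics(0, 1e-3)   # 1 uM -> pCa = -6
  expect_equal(kk$v_half, 57.4, tolerance = 1e-10)
  expect_equal(bkca_kinetics(kk$v_half, 1e-3)$n_inf, 0.5)
  # higher [Ca]i opens the channel at fixed potential
  n_lo <- bkca_kinetics(0, 1e-4)$n_inf
  n_hi <- bkca_kinetics(0, 1e-2)$n_inf
  expect_gt(n_hi, n_lo)
  expect_error(bkca_kinetics(0, 0), class = "drgsoma_invalid_input")
})

test_that("SK channel combines Hill calcium activation with rectification", {
  ek <- -84.7
  # zero current at the K+ reversal for either variant
  expect_equal(skca_evaluate(ek, 1e-3, e_k = ek, rectify = TRUE)$current, 0)
  expect_equal(skca_evaluate(ek, 1e-3, e_k = ek, rectify = FALSE)$current, 0)
  # the IR gate is half open at E_K + V1/2([Ca])
  tab <- skca_ir_table_default()
  ca <- tab$ca_i[3]
  expect_equal(skca_evaluate(ek + tab$v_half[3], ca, e_k = ek)$m_ir, 0.5)
  # without rectification, g is gbar * o, independent of Vm
  v <- seq(-80, 80, by = 20)
  out <- skca_evaluate(v, 1e-3, e_k = ek, g_bar = 9e-4, rectify = FALSE)
  expect_equal(out$g, rep(9e-4 * out$o[1], length(v)))
  # with rectification g declines at depolarized potentials
  out_ir <- skca_evaluate(v, 1e-3, e_k = ek, g_bar = 9e-4, rectify = TRUE)
  expect_true(all(diff(out_ir$g) < 0))
  expect_error(
    skca_evaluate(0, 1e-3, ir_table = tibble::tibble(ca_i = numeric(),
                                                     v_half = numeric(),
                                                     sf = numeric())),
    class = "drgsoma_config_error")
})

test_that("Ca channel inactivation includes the CDI Hill gate", {
  expect_equal(ca_l_kinetics(0, ca_i = 1e-3)$h_ca, 0.5)
  expect_equal(ca_n_kinetics(0, ca_i = 1e-3)$h_ca, 0.5)
  # N-type residual conduction: as h -> 0 the voltage-inactivation factor
  # tends to 1 - a
  a <- 0.7326
  expect_equal(a * 0 + (1 - a), 0.2674)
  # deep-depolarization steady state of N keeps a nonzero gate product
  kk <- ca_n_kinetics(40, ca_i = 1.36e-4)
  gate <- kk$m_inf * (a * kk$h_inf + (1 - a)) * kk$h_ca
  expect_gt(gate, 0.2)
  expect_error(ca_n_kinetics(0, tauh_table = tibble::tibble(vm = numeric(),
                                                            tau_h = numeric())),
               class = "drgsoma_config_error")
})

test_that("gates relax exponentially under a step clamp in the integrator", {
  # constant-coefficient case: the compiled trajectory must match the
  # closed-form relaxation of the Nav1.8 activation gate
  vm <- validation_model("nav18")
  tr <- voltage_clamp_step(vm$model, -70, 0, hold_ms = 30, test_ms = 10,
                           record_dt = 0.05, ca_on = FALSE,
                           ca_fixed = vm$ca_fixed)
  kin0 <- nav18_kinetics(0)
  kinh <- nav18_kinetics(-70)
  # skip the first millisecond (one-step phase offset at the clamp edge)
  seg <- tr[tr$time_ms > 31, ]
  t_rel <- seg$time_ms - 30
  m_t <- kin0$m_inf + (kinh$m_inf - kin0$m_inf) * exp(-t_rel / kin0$tau_m)
  h_t <- kin0$h_inf + (kinh$h_inf - kin0$h_inf) * exp(-t_rel / kin0$tau_h)
  pred <- 0.0086 * m_t^3 * h_t *
    (0 - vm$model$config$conditions$e_rev$na)
  expect_equal(seg$i_nav18, pred, tolerance = 0.01)
})

test_that("peak I-V curves of the Na channels are biphasic", {
  trough_window <- list(ttxs = c(-20, 20), nav18 = c(-10, 10))
  for (ch in c("ttxs", "nav18")) {
    vmd <- validation_model(ch)
    tests <- seq(-80, 45, by = 10)
    iv <- voltage_clamp_step(vmd$model, -60, tests, hold_ms = 5,
                             test_ms = 25, ca_on = FALSE,
                             ca_fixed = vmd$ca_fixed)
    pk <- extract_iv(iv, paste0("i_", ch), "peak")
    imin <- which.min(pk$current)
    # single inward minimum near the activation range
    w <- trough_window[[ch]]
    expect_true(pk$test_mv[imin] >= w[1] && pk$test_mv[imin] <= w[2])
    # biphasic: inward limb grows then shrinks (tiny numerical slack on the
    # near-zero hyperpolarized tail)
    expect_true(all(diff(pk$current[seq_len(imin)]) < 1e-9))
    expect_true(all(diff(pk$current[imin:nrow(pk)]) > -1e-9))
    # reverses near the fixed validation E_Na (+38 mV)
    expect_lt(pk$current[pk$test_mv == 30], 0)
    expect_gt(pk$current[pk$test_mv == 40], 0)
  }
})
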