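test_that("the mechanism registry enforces the plug-in contract", {
  reg <- default_mechanisms()
  expect_length(reg, 22)
  expect_setequal(names(reg), mechanism_names())
  expect_error(register_mechanism(reg, mechanism_spec("pas", "ns", 1e-4)),
               class = "drgsoma_duplicate_mechanism")
  expect_error(default_mechanisms(list(not_a_channel = 1)),
               class = "drgsoma_unknown_mechanism")
  # a registry reduced to the passive channel carries only leak current
  m <- default_mechanisms()
  for (nm in setdiff(names(m), "pas")) m[[nm]]$density <- 0
  model <- assemble(soma_config(mechanisms = m))
  model <- calibrate_rest(model, target_rmp = -53.5)
  # passive-only calibration pins E_pas at the target RMP
  expect_equal(model$e_pas, -53.5, tolerance = 1e-9)
})

test_that("supplementary mechanisms obey their gating limits", {
  cond <- ionic_conditions()
  # ohmic mechanisms vanish at their reversal potentials
  expect_equal(supplementary_current("kcnq", cond$e_rev$k, 1e-4, cond)$total, 0)
  expect_equal(supplementary_current("kna", cond$e_rev$k, 1e-4, cond)$total, 0)
  expect_equal(supplementary_current("hcn", -30, 1e-4, cond)$total, 0)
  expect_equal(supplementary_current("cacc", cond$e_rev$cl, 1e-4, cond)$total, 0)
  # K_Na closes as cytosolic Na+ vanishes
  lo <- update_conditions(cond, na_i = 1e-3)
  expect_equal(supplementary_current("kna", 0, 1e-4, lo)$total, 0,
               tolerance = 1e-12)
  expect_gt(supplementary_current("kna", 0, 1e-4, cond)$total, 0)
  # SOCC grows monotonically as the ER store depletes
  ers <- c(0.4, 0.2, 0.1, 0.05)
  cur <- vapply(ers, function(er) {
    supplementary_current("socc", -53.5, 1e-6, cond,
                          state = list(ca_er = er))$total
  }, numeric(1))
  expect_true(all(diff(cur) < 0))  # more negative = larger Ca2+ influx
  expect_error(supplementary_current("nope", 0, 1, cond),
               class = "drgsoma_unknown_mechanism")
})

test_that("pump and exchanger stoichiometries balance their ion fluxes", {
  cond <- ionic_conditions()
  nak <- supplementary_current("nak", -53.5, 2e-3, cond)
  expect_gt(nak$total, 0)                       # net outward at rest
  expect_equal(nak$na + nak$k, nak$total)       # 3 Na out : 2 K in
  expect_equal(nak$na / nak$total, 3)
  expect_equal(nak$k / nak$total, -2)
  ncx <- supplementary_current("ncx", -53.5, 1e-3, cond)
  expect_lt(ncx$total, 0)                       # forward mode at rest
  expect_gt(ncx$ca, 0)                          # ... extrudes Ca2+
  expect_equal(ncx$na + ncx$ca, ncx$total)
  # reversal near 3 E_Na - 2 E_Ca
  v_rev <- 3 * cond$e_rev$na - 2 * cond$e_rev$ca
  above <- supplementary_current("ncx", v_rev + 20, 1e-3, cond)$total
  below <- supplementary_current("ncx", v_rev - 20, 1e-3, cond)$total
  expect_gt(above, 0)
  expect_lt(below, 0)
})

test_that("a zero block multiplier silences a mechanism in the full model", {
  m <- control_model()
  tr <- current_clamp(m, 0.16, 50, delay_ms = 5, post_ms = 5,
                      blocks = list(bk = 0, kcnq = 0))
  expect_true(all(tr$i_bk == 0))
  expect_true(all(tr$i_kcnq == 0))
  expect_true(any(tr$i_kdr != 0))
})

test_that("per-ion mechanism currents sum to the recorded totals", {
  # bookkeeping identity on a live trace: membrane charge balance
  # C dV/dt = I_stim - sum(I_mech) within integrator tolerance
  m <- control_model()
  tr <- current_clamp(m, 0.16, 50, delay_ms = 10, post_ms = 20,
                      record_dt = m$config$dt)
  imech <- rowSums(as.matrix(tr[paste0("i_", drgsoma:::.MECH_RECORD_ORDER)]))
  istim <- tr$i_stim_nA * 1e-6 / m$area_cm2
  dv <- c(NA, diff(tr$vm_mv)) / m$config$dt              # mV/ms
  icap <- m$cm_spec * dv / 1e3                           # mA/cm2
  resid <- icap - (istim - imech)
  # exclude the stimulus onset/offset discontinuities
  ok <- !is.na(resid) & abs(c(NA, diff(istim))) < 1e-12
  expect_lt(stats::quantile(abs(resid[ok]), 0.99, names = FALSE),
            0.02 * max(abs(imech)))
})
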