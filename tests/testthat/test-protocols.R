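test_that("current clamp produces the expected qualitative responses", {
  m <- control_model()
  flat <- current_clamp(m, 0, 50, delay_ms = 10, post_ms = 10)
  expect_lt(diff(range(flat$vm_mv)), 1e-4)
  # hyperpolarizing clamp deflects downward without a sag or spike
  hyp <- current_clamp(m, -0.01, 300, delay_ms = 20, post_ms = 50)
  expect_identical(count_spikes(hyp), 0L)
  expect_lt(min(hyp$vm_mv), -53.5)
})

test_that("input resistance is linear and matches the passive analytic value", {
  m <- control_model()
  r1 <- input_resistance(m, -0.01)
  r2 <- input_resistance(m, -0.005)
  # near-linear regime: the rest slope conductance (chiefly the n^4 delayed
  # rectifier) varies slightly over a 3 mV deflection
  expect_lt(abs(r2 - r1) / r1, 0.05)
  # passive-only sphere: R_in = R_m / area exactly
  mech <- default_mechanisms()
  for (nm in setdiff(names(mech), "pas")) mech[[nm]]$density <- 0
  mp <- calibrate_rest(assemble(soma_config(mechanisms = mech)))
  rin_pas <- input_resistance(mp)
  expect_equal(rin_pas, 1e4 / mp$area_cm2 / 1e6, tolerance = 1e-3)
  expect_equal(rin_pas, 552.6, tolerance = 1e-3)
})

test_that("voltage clamps are ideal and respect channel reversals", {
  vk <- validation_model("kdr")
  ek <- vk$model$config$conditions$e_rev$k
  tr <- voltage_clamp_step(vk$model, ek, ek, hold_ms = 10, test_ms = 100,
                           ca_on = FALSE, ca_fixed = vk$ca_fixed)
  expect_lt(max(abs(tr$i_kdr)), 1e-12)
  expect_equal(unique(round(tr$vm_mv, 9)), round(ek, 9))
  # N-type keeps a nonzero steady current under strong depolarization
  vn <- validation_model("can")
  trn <- voltage_clamp_step(vn$model, -60, 10, hold_ms = 100, test_ms = 400,
                            ca_on = FALSE, ca_fixed = vn$ca_fixed)
  late <- trn[trn$time_ms > 450, ]
  expect_lt(max(late$i_can), 0)   # still inward, not fully inactivated
  pk <- min(trn$i_can)
  expect_gt(min(late$i_can) / pk, 0.15)  # residual plateau fraction
  expect_lt(min(late$i_can) / pk, 0.9)
})

test_that("the SK ramp clamp shows inward rectification", {
  vs <- validation_model("sk")
  tr <- voltage_clamp_ramp(vs$model, 0, -80, 80, 200, hold_ms = 50,
                           ca_on = FALSE, ca_fixed = 3e-4)
  ramp <- tr[tr$time_ms > 50, ]
  # IR gate closes with depolarization
  expect_gt(ramp$sk_m[which.min(abs(ramp$vm_mv + 60))], 0.9)
  expect_lt(ramp$sk_m[which.min(abs(ramp$vm_mv - 70))], 0.6)
  # outward limb lies below the ohmic extrapolation from the reversal
  ek <- vs$model$config$conditions$e_rev$k
  g0 <- ramp$g_sk_S_cm2[which.min(abs(ramp$vm_mv - ek))]
  i60 <- ramp$i_sk[which.min(abs(ramp$vm_mv - 60))]
  expect_lt(i60, 0.8 * g0 * (60 - ek))
  # without rectification the conductance is flat along the ramp
  vs2 <- validation_model("sk", rectify = FALSE)
  tr2 <- voltage_clamp_ramp(vs2$model, 0, -80, 80, 200, hold_ms = 50,
                            ca_on = FALSE, ca_fixed = 3e-4)
  expect_lt(diff(range(tr2$g_sk_S_cm2)), 1e-12)
  expect_error(voltage_clamp_ramp(vs$model, 0, -80, 80, 0),
               class = "drgsoma_invalid_protocol")
})

test_that("high-K challenge raises [Ca]i monotonically with [K]o", {
  m <- control_model()
  deltas <- vapply(c(5, 15, 30), function(ko) {
    tr <- high_k_challenge(m, k_out = ko, duration_s = 3, pre_s = 1,
                           post_s = 2, dye = NULL)
    transient_features(tr, baseline_window = c(200, 900))$delta
  }, numeric(1))
  expect_lt(abs(deltas[1]), 1e-9)        # resting [K]o: no transient
  expect_true(all(diff(deltas) > 0))     # monotone in [K]o
  # recovery after washout: end of record below the peak
  tr30 <- high_k_challenge(m, k_out = 30, duration_s = 3, pre_s = 1,
                           post_s = 3, dye = NULL)
  expect_lt(tr30$cai_mM[nrow(tr30)], max(tr30$cai_mM))
})

test_that("the inflammation preset converts phasic to tonic firing", {
  m <- control_model()
  mi <- inflamed_model()
  expect_equal(mi$config$mechanisms$nav18$density, 0.06)
  expect_equal(mi$config$mechanisms$ka$density, 1e-4)
  expect_equal(mi$config$mechanisms$kdr$density, 1e-3)
  ctrl <- current_clamp(m, 0.12, 600, delay_ms = 20, post_ms = 50)
  expect_lte(count_spikes(ctrl), 1L)
  infl <- current_clamp(mi, 0.12, 600, delay_ms = 20, post_ms = 50)
  expect_gt(count_spikes(infl), 5L)
})

test_that("a conductance sweep of length 1 reproduces the single run", {
  m <- control_model()
  pr <- protocol_current_clamp(0.18, 15, delay_ms = 110, post_ms = 400)
  single <- extract_ap_features(simulate_soma(m, pr))
  sw <- conductance_sweep(m, "sk", 9e-4, pr)
  expect_equal(sw$peak_mv, single$peak_mv)
  expect_equal(sw$ahp80_ms, single$ahp80_ms)
  expect_error(conductance_sweep(m, "bogus", 1e-3, pr),
               class = "drgsoma_unknown_mechanism")
})

test_that("figure protocol presets are well formed", {
  pr <- figure_protocols()
  expect_true(all(c("fig9a", "fig9b", "fig11b", "fig12", "fig14",
                    "fig17", "fig18") %in% names(pr)))
  for (p in pr) expect_s3_class(p, "soma_protocol")
  expect_equal(pr$fig9a$stim_window, c(20, 70))
  expect_error(soma_protocol(list(list(segments = matrix(c(0, 0, 0, 0),
                                                         nrow = 1)))),
               class = "drgsoma_invalid_protocol")
})
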