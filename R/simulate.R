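# Bridge between the R model object and the compiled integrator: parameter
# packing, state vectors, and the user-facing simulate/step functions.

.MECH_RECORD_ORDER <- c("pas", "ttxs", "nav18", "nav19", "ka", "kdr", "kcnq",
                        "kna", "bk", "sk", "cal", "can", "capq", "car",
                        "cat", "socc", "trpm8", "cacc", "nak", "ncx",
                        "pmca", "hcn")

.TRACE_COLS <- c("time_ms", "vm_mv",
                 paste0("i_", .MECH_RECORD_ORDER),
                 "cai_mM", "caer_mM", "camt_mM", "ip3_mM",
                 "g_sk_S_cm2", "sk_o", "sk_m", "i_stim_nA")

# Build the flat parameter list consumed by the compiled core.
.build_pack <- function(model, conditions = model$config$conditions,
                        dye = NULL, enable = list(), ca_on = TRUE,
                        ca_fixed = NULL, blocks = list()) {
  cfg <- model$config
  mech <- cfg$mechanisms
  for (nm in names(blocks)) {
    if (!nm %in% names(mech)) {
      abort(paste0("Unknown mechanism in block directive: ", nm),
            class = "drgsoma_unknown_mechanism")
    }
    mech[[nm]]$block <- blocks[[nm]]
  }
  dens <- function(nm) mech[[nm]]$density * mech[[nm]]$block
  cap <- cfg$calcium
  en <- utils::modifyList(
    list(pmca = TRUE, serca = TRUE, ip3r = TRUE, cicr = TRUE, leak = TRUE,
         mcu = TRUE, mncx = TRUE, diffusion = TRUE, membrane = TRUE), enable)
  if (mech$pmca$block == 0) en$pmca <- FALSE
  tabs <- .gating_tables(mech)
  geo <- model$geometry
  skp <- mech$sk$params
  sup <- function(nm) mech[[nm]]$params
  t_k <- conditions$temp_c + 273.15
  l_er <- cap$l_er
  if (is.na(l_er)) l_er <- 0
  list(
    area_cm2 = model$area_cm2, cm_spec = model$cm_spec,
    rtf_mV = 1e3 * .GAS_CONSTANT * t_k / .FARADAY,
    e_na = conditions$e_rev$na, e_k = conditions$e_rev$k,
    e_cl = conditions$e_rev$cl,
    e_pas = if (is.na(model$e_pas)) -41.583 else model$e_pas,
    e_hcn = sup("hcn")$e_rev, e_trpm8 = sup("trpm8")$e_rev,
    g_pas = dens("pas"), g_ttxs = dens("ttxs"), g_nav18 = dens("nav18"),
    g_nav19 = dens("nav19"), g_ka = dens("ka"), g_kdr = dens("kdr"),
    g_kcnq = dens("kcnq"), g_kna = dens("kna"), g_bk = dens("bk"),
    g_sk = dens("sk"), g_hcn = dens("hcn"),
    p_cal = dens("cal"), p_can = dens("can"), p_capq = dens("capq"),
    p_car = dens("car"), p_cat = dens("cat"), p_socc = dens("socc"),
    g_trpm8 = dens("trpm8"), g_cacc = dens("cacc"),
    i_nak = dens("nak"), k_ncx = dens("ncx"),
    na_i = conditions$na_i, na_o = conditions$na_o,
    ca_o = conditions$ca_o, k_o = conditions$k_o,
    kna_ec50 = sup("kna")$ec50_na, kna_hill = sup("kna")$hill,
    nak_km_na = sup("nak")$km_na, nak_km_k = sup("nak")$km_k,
    ncx_eta = sup("ncx")$eta, ncx_ksat = sup("ncx")$ksat,
    ncx_kmna = sup("ncx")$km_na, ncx_kmca = sup("ncx")$km_ca,
    trpm8_vhalf = sup("trpm8")$m_vhalf, trpm8_vslope = sup("trpm8")$m_slope,
    trpm8_fca = sup("trpm8")$f_ca,
    cacc_ec50 = sup("cacc")$ec50, cacc_hill = sup("cacc")$hill,
    cacc_vhalf = sup("cacc")$v_vhalf, cacc_vslope = sup("cacc")$v_slope,
    cacc_wip3 = sup("cacc")$w_ip3,
    socc_k = sup("socc")$k_er, socc_hill = sup("socc")$hill,
    can_a = .CAN_A, cdi_k = .CDI_K, cdi_n = .CDI_N,
    sk_ec50 = .SK_EC50, sk_hill = .SK_HILL,
    sk_rectify = as.integer(isTRUE(skp$rectify)),
    sk_ca = skp$ir_table$ca_i, sk_v12 = skp$ir_table$v_half,
    sk_sf = skp$ir_table$sf,
    v_min = tabs$v_min, v_step = tabs$v_step,
    tab_inf = tabs$tab_inf, tab_tau = tabs$tab_tau,
    ca_on = as.integer(ca_on), ns = geo$n_shells,
    v_cyt = geo$v_cyt, v_er = geo$v_er,
    cs_area = geo$area, cs_dr = geo$dr,
    d_ca = cap$d_ca, beta_cyt = cap$beta_cyt, d_ip3 = cap$d_ip3,
    k_degr_ip3 = cap$k_degr_ip3, ip3_rest = cap$ip3_rest,
    k_ip3 = cap$k_ip3, k_act_ip3 = cap$k_act_ip3,
    k_on_ip3 = cap$k_on_ip3, k_inh_ip3 = cap$k_inh_ip3,
    j_ip3r_bar = cap$j_ip3r_bar,
    v_serca = cap$v_serca, k_psr = cap$k_psr, n_serca = cap$n_serca,
    v_cicr = cap$v_cicr, k_cicr = cap$k_cicr, k_t_cicr = cap$k_t_cicr,
    kb_er = cap$kb_er, btot_er = cap$btot_er,
    kb_mt = cap$kb_mt, btot_mt = cap$btot_mt,
    v_mcu = cap$v_mcu, k_mcu = cap$k_mcu, n_mcu = cap$n_mcu,
    v_mncx = cap$v_mncx, k_na_mncx = cap$k_na_mncx,
    k_ca_mncx = cap$k_ca_mncx, mcu_scale = cap$mcu_scale,
    l_er = l_er,
    pk1 = cap$pmca_k1, pk2 = cap$pmca_k2, pk3 = cap$pmca_k3,
    pk4 = cap$pmca_k4,
    dye_on = as.integer(!is.null(dye)),
    dye_cyt = as.integer(is.null(dye) || dye$compartment == "cyt"),
    dye_kb = if (is.null(dye)) 1 else dye$kb,
    dye_btot = if (is.null(dye)) 0 else dye$btot,
    dye_d = if (is.null(dye)) 0 else dye$d_dye,
    en_pmca = as.integer(en$pmca), en_serca = as.integer(en$serca),
    en_ip3r = as.integer(en$ip3r), en_cicr = as.integer(en$cicr),
    en_leak = as.integer(en$leak), en_mcu = as.integer(en$mcu),
    en_mncx = as.integer(en$mncx), en_diff = as.integer(en$diffusion),
    en_mem = as.integer(en$membrane),
    ca_fixed = if (is.null(ca_fixed)) cap$ca_rest else ca_fixed,
    caer_fixed = cap$ca_er_rest
  )
}

# Full state vector at rest (or at an arbitrary holding potential).
.initial_state <- function(model, vm = model$config$target_rmp,
                           ca_on = TRUE, ca0 = NULL) {
  cfg <- model$config
  cap <- cfg$calcium
  if (is.null(ca0)) ca0 <- cap$ca_rest
  gates <- .gate_steady(vm, ca0, cfg$mechanisms)
  if (!ca_on) return(c(vm, unname(gates)))
  n <- model$geometry$n_shells
  h0 <- cap$k_inh_ip3 / (cap$ca_rest + cap$k_inh_ip3)
  pump0 <- cap$pmca_pump0
  bound0 <- if (!is.null(model$calibration)) {
    model$calibration$pump_bound0
  } else {
    cap$ca_rest * pump0 * cap$pmca_k1 / cap$pmca_k2
  }
  c(vm, unname(gates), rep(cap$ca_rest, n), rep(cap$ca_er_rest, n),
    rep(cap$ca_mt_rest, n), rep(cap$ip3_rest, n), rep(h0, n), pump0, bound0)
}

.trace_tibble <- function(mat, model) {
  colnames(mat) <- .TRACE_COLS
  out <- as_tibble(as.data.frame(mat))
  class(out) <- c("drg_trace", class(out))
  attr(out, "area_cm2") <- model$area_cm2
  out
}

#' Run the model through a sequence of clamp segments (low level)
#'
#' Most users should use [simulate_soma()] with a protocol object; this is
#' the raw engine entry point.
#'
#' @param model A calibrated `soma_model`.
#' @param segments A matrix with columns `mode` (0 current clamp, 1 voltage
#'   clamp), `dur_ms`, `a0`, `a1` (level at segment start/end; nA for current
#'   clamp, mV for voltage clamp; a linear ramp when a0 != a1).
#' @param state Initial state vector (default: calibrated rest).
#' @param dt Step (ms).
#' @param record_dt Sampling interval (ms).
#' @param conditions Ionic conditions override.
#' @param dye Optional [dye_preset()].
#' @param enable Calcium-flux switches (see [advance_calcium()]).
#' @param blocks Named list of block multipliers applied to mechanisms.
#' @param ca_on Run the shell Ca2+ system (TRUE) or hold \[Ca\]i fixed.
#' @param ca_fixed Fixed near-membrane \[Ca\]i when `ca_on = FALSE`.
#' @return A list with `trace` (tibble) and `state` (final state vector).
#' @export
soma_run <- function(model, segments, state = NULL, dt = model$config$dt,
                     record_dt = 0.05, conditions = model$config$conditions,
                     dye = NULL, enable = list(), blocks = list(),
                     ca_on = TRUE, ca_fixed = NULL) {
  stopifnot(inherits(model, "soma_model"))
  if (is.null(dim(segments))) segments <- matrix(segments, nrow = 1)
  if (any(segments[, 2] <= 0)) {
    abort("Segment durations must be positive.", class = "drgsoma_invalid_protocol")
  }
  pack <- .build_pack(model, conditions = conditions, dye = dye,
                      enable = enable, ca_on = ca_on, ca_fixed = ca_fixed,
                      blocks = blocks)
  if (is.null(state)) state <- .initial_state(model, ca_on = ca_on)
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  res <- soma_run_cpp(pack, segments, dt, record_every, state)
  list(trace = .trace_tibble(res$trace, model), state = res$state)
}

#' Advance the model state by a single step
#'
#' One integrator step under a constant stimulus current: the voltage is
#' advanced by a linearized implicit update, gates by their exact exponential
#' solutions, and the shell Ca2+ system by one (sub-stepped) explicit step.
#'
#' @param model A calibrated `soma_model`.
#' @param state State vector (see [soma_run()]); default calibrated rest.
#' @param i_stim Stimulus current (nA), positive depolarizing.
#' @param dt Step (ms), > 0.
#' @return A list with `state` (updated) and `trace` (one-row sample).
#' @export
soma_step <- function(model, state = NULL, i_stim = 0, dt = model$config$dt) {
  if (dt <= 0) abort("dt must be > 0.", class = "drgsoma_invalid_input")
  res <- soma_run(model, matrix(c(0, dt, i_stim, i_stim), nrow = 1),
                  state = state, dt = dt, record_dt = dt)
  res
}
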