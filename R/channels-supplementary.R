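# Plug-in mechanisms beyond the nine main-text channels: persistent TTX-R Na+
# (Nav1.9), KCNQ/M, Na+-activated K+, HCN, T-/P/Q-/R-type Ca2+, store-operated
# Ca2+ entry, TRPM8, Ca2+-activated Cl-, the Na+/K+ pump and the plasma
# membrane Na+/Ca2+ exchanger. Their kinetic parameterizations follow the
# model families of the source recordings they were adapted from; every
# constant is exposed through the mechanism configuration so alternative
# parameter sets can be dropped in without code changes.

#' Default parameter sets for the supplementary mechanisms
#'
#' Returns the full parameter list for one of the plug-in mechanisms. All
#' voltage parameters in mV, time constants in ms, concentrations in mM.
#'
#' @param name One of `"nav19"`, `"kcnq"`, `"kna"`, `"hcn"`, `"cat"`,
#'   `"capq"`, `"car"`, `"socc"`, `"trpm8"`, `"cacc"`, `"nak"`, `"ncx"`.
#' @return A named list of parameters.
#' @export
supplementary_params <- function(name) {
  defaults <- list(
    # persistent TTX-R Na+: hyperpolarized activation, very slow inactivation
    nav19 = list(m_vhalf = -54, m_slope = 7, h_vhalf = -60, h_slope = 8,
                 taum_base = 1, taum_amp = 15, taum_mid = -55, taum_w = 20,
                 tauh_base = 300, tauh_amp = 1200, tauh_mid = -60, tauh_w = 25),
    # KCNQ/M: slow non-inactivating K+ current active near rest
    kcnq = list(n_vhalf = -30, n_slope = 9,
                taun_base = 4, taun_amp = 250, taun_mid = -30, taun_w = 35),
    # Na+-activated K+: instantaneous ligand gate on cytosolic Na+
    kna = list(ec50_na = 40, hill = 2.8),
    # HCN: hyperpolarization-activated nonspecific cation current
    hcn = list(m_vhalf = -80, m_slope = 7, e_rev = -30,
               taum_base = 50, taum_amp = 1500, taum_mid = -80, taum_w = 20),
    # T-type Ca2+: low-voltage activated, transient
    cat = list(m_vhalf = -40, m_slope = 6, h_vhalf = -70, h_slope = 6.5,
               taum_base = 2, taum_amp = 8, taum_mid = -45, taum_w = 20,
               tauh_base = 10, tauh_amp = 40, tauh_mid = -65, tauh_w = 20),
    # P/Q-type Ca2+: high-voltage activated, non-inactivating here
    capq = list(m_vhalf = -5, m_slope = 5,
                taum_base = 0.5, taum_amp = 2, taum_mid = -10, taum_w = 20),
    # R-type Ca2+: high-voltage activated with moderate inactivation
    car = list(m_vhalf = -10, m_slope = 6, h_vhalf = -60, h_slope = 10,
               taum_base = 0.8, taum_amp = 3, taum_mid = -15, taum_w = 20,
               tauh_base = 30, tauh_amp = 80, tauh_mid = -60, tauh_w = 25),
    # store-operated Ca2+ entry: instantaneous gate on ER depletion
    socc = list(k_er = 0.25, hill = 4),
    # TRPM8 at fixed 22 degC: weak depolarization-activated nonspecific
    # current with a Ca2+-carrying fraction
    trpm8 = list(m_vhalf = 90, m_slope = 25, e_rev = 0, f_ca = 0.2),
    # Ca2+-activated Cl-: gated by Vm and by near-membrane Ca2+, with extra
    # sensitivity to IP3R release in the outermost shell (coupling
    # coefficient in ms-equivalent units of local accumulation)
    cacc = list(ec50 = 1.8e-3, hill = 2, v_vhalf = -10, v_slope = 15,
                w_ip3 = 50),
    # Na+/K+-ATPase: 3:2 stoichiometry, saturating in [Na]i and [K]o
    nak = list(km_na = 10, km_k = 1.5),
    # plasma membrane Na+/Ca2+ exchanger (3 Na+ : 1 Ca2+), cardiac-type
    # exponential voltage dependence
    ncx = list(eta = 0.35, ksat = 0.1, km_na = 87.5, km_ca = 1.38)
  )
  if (!name %in% names(defaults)) {
    abort(paste0("Unknown supplementary mechanism: ", name),
          class = "drgsoma_unknown_mechanism")
  }
  defaults[[name]]
}

.gauss_tau <- function(vm, base, amp, mid, w) base + amp * exp(-((vm - mid) / w)^2)

#' Gating curves of a supplementary voltage-gated mechanism
#'
#' @param name Mechanism name (see [supplementary_params()]); must be one of
#'   the voltage-gated ones (`nav19`, `kcnq`, `hcn`, `cat`, `capq`, `car`).
#' @param vm Membrane potential(s), mV.
#' @param params Parameter list (default [supplementary_params()]).
#' @return Tibble of steady states and time constants present for that
#'   mechanism.
#' @export
supplementary_kinetics <- function(name, vm, params = supplementary_params(name)) {
  p <- params
  out <- tibble(vm = vm)
  has_m <- !is.null(p$m_vhalf) || !is.null(p$n_vhalf)
  if (!has_m) {
    abort(paste0("Mechanism '", name, "' has no voltage gate."),
          class = "drgsoma_unknown_mechanism")
  }
  if (!is.null(p$n_vhalf)) {
    out$n_inf <- boltzmann(vm, p$n_vhalf, p$n_slope, 1)
    out$tau_n <- .gauss_tau(vm, p$taun_base, p$taun_amp, p$taun_mid, p$taun_w)
  } else {
    sgn <- if (name == "hcn") -1 else 1   # HCN opens on hyperpolarization
    out$m_inf <- boltzmann(vm, p$m_vhalf, p$m_slope, sgn)
    out$tau_m <- .gauss_tau(vm, p$taum_base, p$taum_amp, p$taum_mid, p$taum_w)
    if (!is.null(p$h_vhalf)) {
      out$h_inf <- boltzmann(vm, p$h_vhalf, p$h_slope, -1)
      out$tau_h <- .gauss_tau(vm, p$tauh_base, p$tauh_amp, p$tauh_mid, p$tauh_w)
    }
  }
  out
}

#' Current through a supplementary mechanism
#'
#' Evaluates one plug-in mechanism at given state. Gates default to their
#' steady-state values at `vm` (the relevant case for rest calibration and
#' instantaneous-gate mechanisms).
#'
#' @param name Mechanism name.
#' @param vm Membrane potential (mV).
#' @param density Maximum conductance (S/cm2), permeability (cm/s) or, for
#'   `nak`/`ncx`, the pump/exchanger scale (mA/cm2).
#' @param cond An [ionic_conditions()] object.
#' @param state Optional named list of gate values / auxiliary state
#'   (`m`, `h`, `n`, `ca_er`, `j_ip3r`).
#' @param params Mechanism parameters.
#' @return Named list: `total` current (mA/cm2, positive outward) and the
#'   per-ion components `na`, `k`, `ca`, `cl`, `ns` (nonspecific).
#' @export
supplementary_current <- function(name, vm, density, cond,
                                  state = list(), params = supplementary_params(name)) {
  p <- params
  zero <- list(total = 0, na = 0, k = 0, ca = 0, cl = 0, ns = 0)
  gate_or <- function(g, def) if (!is.null(state[[g]])) state[[g]] else def
  cur <- switch(
    name,
    nav19 = {
      kk <- supplementary_kinetics("nav19", vm, p)
      i <- density * gate_or("m", kk$m_inf) * gate_or("h", kk$h_inf) *
        (vm - cond$e_rev$na)
      utils::modifyList(zero, list(total = i, na = i))
    },
    kcnq = {
      kk <- supplementary_kinetics("kcnq", vm, p)
      i <- density * gate_or("n", kk$n_inf) * (vm - cond$e_rev$k)
      utils::modifyList(zero, list(total = i, k = i))
    },
    kna = {
      w <- 1 / (1 + (p$ec50_na / cond$na_i)^p$hill)
      i <- density * w * (vm - cond$e_rev$k)
      utils::modifyList(zero, list(total = i, k = i))
    },
    hcn = {
      kk <- supplementary_kinetics("hcn", vm, p)
      i <- density * gate_or("m", kk$m_inf) * (vm - p$e_rev)
      utils::modifyList(zero, list(total = i, ns = i))
    },
    cat = {
      kk <- supplementary_kinetics("cat", vm, p)
      i <- ghk_flux(density, gate_or("m", kk$m_inf) * gate_or("h", kk$h_inf),
                    vm, cond$ca_i, cond$ca_o, 2, cond$temp_c)
      utils::modifyList(zero, list(total = i, ca = i))
    },
    capq = {
      kk <- supplementary_kinetics("capq", vm, p)
      i <- ghk_flux(density, gate_or("m", kk$m_inf), vm, cond$ca_i, cond$ca_o,
                    2, cond$temp_c)
      utils::modifyList(zero, list(total = i, ca = i))
    },
    car = {
      kk <- supplementary_kinetics("car", vm, p)
      i <- ghk_flux(density, gate_or("m", kk$m_inf) * gate_or("h", kk$h_inf),
                    vm, cond$ca_i, cond$ca_o, 2, cond$temp_c)
      utils::modifyList(zero, list(total = i, ca = i))
    },
    socc = {
      ca_er <- gate_or("ca_er", 0.4)
      s <- 1 / (1 + (ca_er / p$k_er)^p$hill)
      i <- ghk_flux(density, s, vm, cond$ca_i, cond$ca_o, 2, cond$temp_c)
      utils::modifyList(zero, list(total = i, ca = i))
    },
    trpm8 = {
      m <- boltzmann(vm, p$m_vhalf, p$m_slope, 1)
      i <- density * m * (vm - p$e_rev)
      utils::modifyList(zero, list(total = i, ca = p$f_ca * i, ns = (1 - p$f_ca) * i))
    },
    cacc = {
      ca_eff <- cond$ca_i + p$w_ip3 * gate_or("j_ip3r", 0)
      oc <- ca_eff^p$hill / (ca_eff^p$hill + p$ec50^p$hill)
      ov <- boltzmann(vm, p$v_vhalf, p$v_slope, 1)
      i <- density * oc * ov * (vm - cond$e_rev$cl)
      utils::modifyList(zero, list(total = i, cl = i))
    },
    nak = {
      r <- density * (cond$na_i / (cond$na_i + p$km_na))^3 *
        (cond$k_o / (cond$k_o + p$km_k))^2
      utils::modifyList(zero, list(total = r, na = 3 * r, k = -2 * r))
    },
    ncx = {
      t_k <- cond$temp_c + 273.15
      u <- .FARADAY * (vm * 1e-3) / (.GAS_CONSTANT * t_k)
      xf <- cond$na_i^3 * cond$ca_o * exp(p$eta * u)
      xr <- cond$na_o^3 * cond$ca_i * exp((p$eta - 1) * u)
      den <- (p$km_na^3 + cond$na_o^3) * (p$km_ca + cond$ca_o) *
        (1 + p$ksat * exp((p$eta - 1) * u))
      i <- density * (xf - xr) / den   # net current, positive outward
      # forward mode (Ca2+ extrusion; 3 Na+ in per Ca2+ out) carries net
      # inward charge: i < 0. Per-ion split: 3 units Na+, -2 units Ca2+.
      utils::modifyList(zero, list(total = i, na = 3 * i, ca = -2 * i))
    },
    abort(paste0("Unknown supplementary mechanism: ", name),
          class = "drgsoma_unknown_mechanism")
  )
  cur
}
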