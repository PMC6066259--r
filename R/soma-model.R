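# Assembly of the single-compartment soma model: geometry, mechanism
# registry, calcium system and resting-state calibration.

#' Soma model configuration
#'
#' @param diameter_um Soma diameter (um, default 24).
#' @param capacitance_pF Total membrane capacitance (pF, default 28); the
#'   specific capacitance is derived from the sphere area.
#' @param r_m Specific membrane resistance (Ohm cm2, default 10000); sets the
#'   passive leak density 1/R_m.
#' @param conditions An [ionic_conditions()] object.
#' @param mechanisms A mechanism registry (default [default_mechanisms()]).
#' @param calcium Ca2+ dynamics parameters (default [calcium_params()]).
#' @param dt Integrator step (ms, default 0.005).
#' @param target_rmp Resting membrane potential the calibration aims for (mV).
#' @return A `soma_config` list.
#' @export
soma_config <- function(diameter_um = 24, capacitance_pF = 28, r_m = 10000,
                        conditions = ionic_conditions(),
                        mechanisms = default_mechanisms(),
                        calcium = calcium_params(),
                        dt = 0.005, target_rmp = -53.5) {
  if (diameter_um <= 0 || capacitance_pF <= 0) {
    abort("Geometry and capacitance must be positive.",
          class = "drgsoma_config_error")
  }
  structure(list(diameter_um = diameter_um, capacitance_pF = capacitance_pF,
                 r_m = r_m, conditions = conditions, mechanisms = mechanisms,
                 calcium = calcium, dt = dt, target_rmp = target_rmp),
            class = "soma_config")
}

#' Assemble the soma model
#'
#' Builds the membrane geometry (area, specific capacitance), shell
#' discretization and mechanism registry into a simulatable model object.
#' Call [calibrate_rest()] before simulating.
#'
#' @param config A [soma_config()].
#' @return A `soma_model` object.
#' @export
assemble <- function(config = soma_config()) {
  stopifnot(inherits(config, "soma_config"))
  r_cm <- config$diameter_um / 2 * 1e-4
  area_cm2 <- 4 * pi * r_cm^2
  model <- structure(list(
    config = config,
    area_cm2 = area_cm2,
    cm_spec = config$capacitance_pF * 1e-6 / area_cm2,  # uF/cm2
    geometry = build_shells(config$diameter_um, config$calcium$n_shells),
    e_pas = NA_real_,
    calibrated = FALSE,
    calibration = NULL
  ), class = "soma_model")
  model
}

#' @export
print.soma_model <- function(x, ...) {
  cat("Bladder small DRG neuron soma model\n")
  cat(sprintf("  diameter %g um, area %.4g cm2, Cm %.3f uF/cm2\n",
              x$config$diameter_um, x$area_cm2, x$cm_spec))
  cat(sprintf("  %d mechanisms, %d Ca2+ shells, dt = %g ms\n",
              length(x$config$mechanisms), x$geometry$n_shells, x$config$dt))
  if (x$calibrated) {
    cat(sprintf("  calibrated: E_pas %.3f mV, RMP target %.2f mV\n",
                x$e_pas, x$config$target_rmp))
  } else {
    cat("  not yet calibrated (run calibrate_rest())\n")
  }
  invisible(x)
}

# Steady-state values of the 22 ODE gates at (vm, ca), in the integrator's
# column order.
.gate_order <- c("ttxs_m", "ttxs_h", "nav18_m", "nav18_h", "ka_n", "ka_hf",
                 "ka_hs", "kdr_n", "bk_n", "cal_m", "cal_h", "can_m",
                 "can_h", "nav19_m", "nav19_h", "kcnq_n", "hcn_m", "cat_m",
                 "cat_h", "capq_m", "car_m", "car_h")

.gate_steady <- function(vm, ca, mech) {
  tx <- ttxs_kinetics(vm); n18 <- nav18_kinetics(vm); ka <- ka_kinetics(vm)
  kd <- kdr_kinetics(vm); bk <- bkca_kinetics(vm, ca)
  cl <- ca_l_kinetics(vm, ca); cn <- ca_n_kinetics(vm, ca)
  n19 <- supplementary_kinetics("nav19", vm, mech$nav19$params)
  kq <- supplementary_kinetics("kcnq", vm, mech$kcnq$params)
  hc <- supplementary_kinetics("hcn", vm, mech$hcn$params)
  ct <- supplementary_kinetics("cat", vm, mech$cat$params)
  pq <- supplementary_kinetics("capq", vm, mech$capq$params)
  cr <- supplementary_kinetics("car", vm, mech$car$params)
  setNames(c(tx$m_inf, tx$h_inf, n18$m_inf, n18$h_inf, ka$n_inf, ka$h_inf,
             ka$h_inf, kd$n_inf, bk$n_inf, cl$m_inf, cl$h_inf, cn$m_inf,
             cn$h_inf, n19$m_inf, n19$h_inf, kq$n_inf, hc$m_inf, ct$m_inf,
             ct$h_inf, pq$m_inf, cr$m_inf, cr$h_inf), .gate_order)
}

# Voltage-indexed inf/tau lookup tables for the integrator (the single source
# of truth is the R kinetics functions evaluated on a fine uniform grid).
.gating_tables <- function(mech, v_min = -150, v_max = 100, v_step = 0.05) {
  v <- seq(v_min, v_max, by = v_step)
  tx <- ttxs_kinetics(v); n18 <- nav18_kinetics(v); ka <- ka_kinetics(v)
  kd <- kdr_kinetics(v); bk_tau <- 5.55 * exp(v / 42.91) + 0.75 - 0.12 * v
  cl <- ca_l_kinetics(v); cn <- ca_n_kinetics(v)
  n19 <- supplementary_kinetics("nav19", v, mech$nav19$params)
  kq <- supplementary_kinetics("kcnq", v, mech$kcnq$params)
  hc <- supplementary_kinetics("hcn", v, mech$hcn$params)
  ct <- supplementary_kinetics("cat", v, mech$cat$params)
  pq <- supplementary_kinetics("capq", v, mech$capq$params)
  cr <- supplementary_kinetics("car", v, mech$car$params)
  tab_inf <- cbind(tx$m_inf, tx$h_inf, n18$m_inf, n18$h_inf, ka$n_inf,
                   ka$h_inf, ka$h_inf, kd$n_inf, 0.5, cl$m_inf, cl$h_inf,
                   cn$m_inf, cn$h_inf, n19$m_inf, n19$h_inf, kq$n_inf,
                   hc$m_inf, ct$m_inf, ct$h_inf, pq$m_inf, cr$m_inf,
                   cr$h_inf)
  tab_tau <- cbind(tx$tau_m, tx$tau_h, n18$tau_m, n18$tau_h, ka$tau_n,
                   ka$tau_h_fast, ka$tau_h_slow, kd$tau_n, bk_tau, cl$tau_m,
                   cl$tau_h, cn$tau_m, cn$tau_h, n19$tau_m, n19$tau_h,
                   kq$tau_n, hc$tau_m, ct$tau_m, ct$tau_h, pq$tau_m,
                   cr$tau_m, cr$tau_h)
  colnames(tab_inf) <- colnames(tab_tau) <- .gate_order
  list(v_min = v_min, v_step = v_step, tab_inf = tab_inf, tab_tau = tab_tau)
}

#' Total membrane current with gates at steady state
#'
#' Evaluates every mechanism's current at a clamped potential with all gates
#' relaxed to steady state and the Ca2+ system at its resting configuration.
#' This is the balance equation the resting-state calibration solves.
#'
#' @param model A `soma_model`.
#' @param vm Membrane potential (mV).
#' @param e_pas Leak reversal (mV); defaults to the model's calibrated value.
#' @param pmca_rest PMCA extrusion current to include (mA/cm2, outward).
#' @return A tibble of per-mechanism currents (mA/cm2) with a `total` column
#'   attached as an attribute-free final row ordering; use
#'   `sum(out$current)` for the total.
#' @export
membrane_current_rest <- function(model, vm, e_pas = model$e_pas,
                                  pmca_rest = 0) {
  cfg <- model$config
  mech <- cfg$mechanisms
  cond <- cfg$conditions
  cap <- cfg$calcium
  ca0 <- cap$ca_rest
  dens <- function(nm) mech[[nm]]$density * mech[[nm]]$block
  g <- .gate_steady(vm, ca0, mech)
  ek <- cond$e_rev$k; ena <- cond$e_rev$na
  cur <- c(
    pas = dens("pas") * (vm - e_pas),
    ttxs = dens("ttxs") * g[["ttxs_m"]]^3 * g[["ttxs_h"]] * (vm - ena),
    nav18 = dens("nav18") * g[["nav18_m"]]^3 * g[["nav18_h"]] * (vm - ena),
    nav19 = supplementary_current("nav19", vm, dens("nav19"), cond,
                                  params = mech$nav19$params)$total,
    ka = dens("ka") * g[["ka_n"]] *
      (.KA_W_FAST * g[["ka_hf"]] + .KA_W_SLOW * g[["ka_hs"]]) * (vm - ek),
    kdr = dens("kdr") * g[["kdr_n"]]^4 * (vm - ek),
    kcnq = supplementary_current("kcnq", vm, dens("kcnq"), cond,
                                 params = mech$kcnq$params)$total,
    kna = supplementary_current("kna", vm, dens("kna"), cond,
                                params = mech$kna$params)$total,
    bk = dens("bk") * g[["bk_n"]] * (vm - ek),
    sk = skca_evaluate(vm, ca0, e_k = ek, g_bar = dens("sk"),
                       rectify = isTRUE(mech$sk$params$rectify),
                       ir_table = mech$sk$params$ir_table)$current,
    cal = ca_l_kinetics(vm, ca0, cond$ca_o, p_max = dens("cal"))$current,
    can = ca_n_kinetics(vm, ca0, cond$ca_o, p_max = dens("can"),
                        tauh_table = mech$can$params$tauh_table)$current,
    capq = supplementary_current("capq", vm, dens("capq"), cond,
                                 params = mech$capq$params)$total,
    car = supplementary_current("car", vm, dens("car"), cond,
                                params = mech$car$params)$total,
    cat = supplementary_current("cat", vm, dens("cat"), cond,
                                params = mech$cat$params)$total,
    socc = supplementary_current("socc", vm, dens("socc"), cond,
                                 state = list(ca_er = cap$ca_er_rest),
                                 params = mech$socc$params)$total,
    trpm8 = supplementary_current("trpm8", vm, dens("trpm8"), cond,
                                  params = mech$trpm8$params)$total,
    cacc = supplementary_current("cacc", vm, dens("cacc"), cond,
                                 params = mech$cacc$params)$total,
    nak = supplementary_current("nak", vm, dens("nak"), cond,
                                params = mech$nak$params)$total,
    ncx = supplementary_current("ncx", vm, dens("ncx"), cond,
                                params = mech$ncx$params)$total,
    pmca = pmca_rest,
    hcn = supplementary_current("hcn", vm, dens("hcn"), cond,
                                params = mech$hcn$params)$total
  )
  tibble(mechanism = names(cur), current = unname(cur))
}

# Ca2+-carried current density at rest (mA/cm2), channels only (no NCX).
.resting_ca_channel_current <- function(model, vm) {
  cur <- membrane_current_rest(model, vm, e_pas = 0)
  sum(cur$current[cur$mechanism %in%
                    c("cal", "can", "capq", "car", "cat", "socc")]) +
    model$config$mechanisms$trpm8$params$f_ca *
      cur$current[cur$mechanism == "trpm8"]
}

#' Calibrate the resting state of the assembled model
#'
#' Four-stage deterministic calibration: (1) the ER leak factor is solved so
#' the four ER fluxes cancel at rest; (2) the mitochondrial MNCX rate is
#' rescaled so MCU uptake and MNCX release cancel at rest; (3) the plasma
#' membrane Ca2+ budget is closed: the NCX scale is bounded so the exchanger
#' extrudes at most half the resting channel influx and the PMCA pump
#' densities are solved so the pump removes the remainder (steady two-reaction
#' fluxes); (4) the leak reversal E_pas is solved so the total membrane
#' current vanishes at the target resting potential with all gates at steady
#' state.
#'
#' @param model An [assemble()]d `soma_model`.
#' @param target_rmp Target resting potential (mV); defaults to the config's.
#' @param dye Optional [dye_preset()] the model will be run with (the pump
#'   solution then stabilizes the dye-loaded resting state).
#' @return The calibrated model, with a `calibration` report list
#'   (`e_pas`, `l_er`, `mcu_scale`, `pump0`, `pump_bound0`, `ncx_scale`,
#'   `i_ca_rest`).
#' @export
calibrate_rest <- function(model, target_rmp = model$config$target_rmp,
                           dye = NULL) {
  stopifnot(inherits(model, "soma_model"))
  cfg <- model$config
  if (is.null(cfg$mechanisms$pas)) {
    abort("Calibration requires the passive mechanism.",
          class = "drgsoma_calibration_failure")
  }
  cap <- calibrate_er_leak(cfg$calcium)
  cap <- calibrate_mito_rest(cap, na_i = cfg$conditions$na_i)

  # plasma-membrane Ca2+ budget at rest
  i_ca_chan <- .resting_ca_channel_current(model, target_rmp)  # < 0 influx
  ncx <- supplementary_current("ncx", target_rmp,
                               cfg$mechanisms$ncx$density, cfg$conditions,
                               params = cfg$mechanisms$ncx$params)
  ncx_scale <- 1
  if (i_ca_chan < 0 && ncx$ca > 0) {
    max_ncx <- 0.5 * (-i_ca_chan)
    if (ncx$ca > max_ncx) ncx_scale <- max_ncx / ncx$ca
  }
  model$config$mechanisms$ncx$density <- cfg$mechanisms$ncx$density * ncx_scale
  i_ca_rest <- i_ca_chan + ncx_scale * ncx$ca
  # PMCA: steady two-reaction fluxes equal the needed extrusion
  j_need <- max(-i_ca_rest, 0) / (2 * .FARADAY * 1e6)  # mol/cm2/ms
  p1 <- cap$pmca_k1 * cap$ca_rest; p2 <- cap$pmca_k2
  p3 <- cap$pmca_k3; p4 <- cap$pmca_k4 * cfg$conditions$ca_o
  det <- p1 * p3 - p2 * p4
  if (det <= 0) {
    abort("PMCA rate constants do not admit a steady extruding state.",
          class = "drgsoma_calibration_failure")
  }
  pump0 <- j_need * (p2 + p3) / det
  bound0 <- j_need * (p1 + p4) / det
  cap$pmca_pump0 <- pump0
  model$config$calcium <- cap

  # leak reversal from the full current balance (PMCA current included)
  i_pmca_rest <- j_need * 2 * .FARADAY * 1e6  # mA/cm2 outward
  cur <- membrane_current_rest(model, target_rmp, e_pas = 0,
                               pmca_rest = i_pmca_rest)
  other <- sum(cur$current[cur$mechanism != "pas"])
  g_pas <- model$config$mechanisms$pas$density *
    model$config$mechanisms$pas$block
  if (g_pas <= 0) {
    abort("Passive conductance must be positive for calibration.",
          class = "drgsoma_calibration_failure")
  }
  e_pas <- target_rmp + other / g_pas
  if (e_pas < -150 || e_pas > 50) {
    abort("E_pas calibration left the physiological range; check densities.",
          class = "drgsoma_calibration_failure")
  }
  model$e_pas <- e_pas
  model$calibrated <- TRUE
  model$config$target_rmp <- target_rmp
  model$calibration <- list(
    e_pas = e_pas, l_er = cap$l_er, mcu_scale = cap$mcu_scale,
    pump0 = pump0, pump_bound0 = bound0, ncx_scale = ncx_scale,
    i_ca_rest = i_ca_rest, dye = if (is.null(dye)) NA_character_ else dye$name
  )
  model
}

#' Broom-style one-row summary of a calibrated model
#'
#' @param x A `soma_model`.
#' @param ... Unused.
#' @return A one-row tibble with the headline calibration quantities.
#' @export
glance.soma_model <- function(x, ...) {
  if (!x$calibrated) {
    return(tibble(calibrated = FALSE))
  }
  tibble(calibrated = TRUE, e_pas_mv = x$e_pas,
         rmp_mv = x$config$target_rmp,
         area_cm2 = x$area_cm2, cm_uF_cm2 = x$cm_spec,
         l_er = x$calibration$l_er, pump0_mol_cm2 = x$calibration$pump0,
         n_mechanisms = length(x$config$mechanisms))
}

#' Tidy the mechanism table of a model
#'
#' @param x A `soma_model`.
#' @param ... Unused.
#' @return A tibble with one row per mechanism: name, ion, density, block.
#' @export
tidy.soma_model <- function(x, ...) {
  m <- x$config$mechanisms
  tibble(mechanism = names(m),
         ion = purrr::map_chr(m, "ion"),
         density = purrr::map_dbl(m, "density"),
         block = purrr::map_dbl(m, "block"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
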