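# Stimulus/recording programs: current clamps, step and ramp voltage clamps,
# high-K challenge, pulse trains, mechanism blocks and conductance sweeps,
# plus the named presets reproducing the study protocols.

.seg <- function(mode, dur, a0, a1 = a0) c(mode, dur, a0, a1)

#' Construct a protocol object
#'
#' @param stages List of stages; each stage is a list with `segments` (matrix
#'   of rows `(mode, dur_ms, a0, a1)`) and optional `conditions` (an
#'   [ionic_conditions()] object in force during that stage).
#' @param dye Optional dye preset name (see [dye_preset()]).
#' @param record_dt Sampling interval (ms).
#' @param stim_window Two-element numeric `(on, off)` in ms, used by feature
#'   extraction; NULL if not applicable.
#' @param name Optional protocol name.
#' @return A `soma_protocol` object.
#' @export
soma_protocol <- function(stages, dye = NULL, record_dt = 0.05,
                          stim_window = NULL, name = NULL) {
  for (st in stages) {
    seg <- st$segments
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    if (any(seg[, 2] <= 0)) {
      abort("Protocol segment durations must be positive.",
            class = "drgsoma_invalid_protocol")
    }
  }
  structure(list(stages = stages, dye = dye, record_dt = record_dt,
                 stim_window = stim_window, name = name),
            class = "soma_protocol")
}

#' Simulate the model under a protocol
#'
#' Runs every stage in sequence (state carried across stages, so ionic
#' overrides such as a high-K application integrate seamlessly) and returns
#' the recorded trace as a tibble.
#'
#' @param model A calibrated `soma_model`.
#' @param protocol A [soma_protocol()] (or segment matrix for convenience).
#' @param blocks Named list of block multipliers (0 = fully blocked).
#' @param dt Integrator step (ms).
#' @param v_init Optional initial potential (mV) at which all gates start at
#'   steady state (default: the calibrated resting potential).
#' @param ... Passed to [soma_run()] (e.g. `enable`, `ca_on`, `ca_fixed`).
#' @return A `drg_trace` tibble (`time_ms`, `vm_mv`, per-mechanism currents,
#'   outer-shell `cai_mM`/`caer_mM`/`camt_mM`, instantaneous SK conductance
#'   `g_sk_S_cm2`, `i_stim_nA`), with the stimulus window as an attribute.
#' @export
simulate_soma <- function(model, protocol, blocks = list(),
                          dt = model$config$dt, v_init = NULL, ...) {
  if (!inherits(protocol, "soma_protocol")) {
    protocol <- soma_protocol(list(list(segments = protocol)))
  }
  dye <- if (is.null(protocol$dye)) NULL else dye_preset(protocol$dye)
  if (!is.null(dye) && !is.null(model$calibration)) {
    # restabilize the dye-loaded resting state
    model <- calibrate_rest(model, dye = dye)
  }
  dots <- list(...)
  ca_on_flag <- if (!is.null(dots$ca_on)) dots$ca_on else TRUE
  state <- if (is.null(v_init)) NULL else {
    .initial_state(model, vm = v_init, ca_on = ca_on_flag,
                   ca0 = dots$ca_fixed)
  }
  traces <- vector("list", length(protocol$stages))
  t_off <- 0
  for (k in seq_along(protocol$stages)) {
    st <- protocol$stages[[k]]
    cond <- if (is.null(st$conditions)) model$config$conditions else st$conditions
    res <- soma_run(model, st$segments, state = state, dt = dt,
                    record_dt = protocol$record_dt, conditions = cond,
                    dye = dye, blocks = blocks, ...)
    tr <- res$trace
    tr$time_ms <- tr$time_ms + t_off
    t_off <- max(tr$time_ms)
    if (k > 1) tr <- tr[-1, ]   # drop duplicated boundary sample
    traces[[k]] <- tr
    state <- res$state
  }
  out <- dplyr::bind_rows(traces)
  class(out) <- c("drg_trace", class(out))
  attr(out, "area_cm2") <- model$area_cm2
  attr(out, "stim_window") <- protocol$stim_window
  attr(out, "protocol") <- protocol$name
  out
}

#' Rectangular current-clamp protocol
#'
#' @param amplitude_nA Stimulus amplitude (nA), positive depolarizing.
#' @param duration_ms Stimulus duration (ms).
#' @param delay_ms Pre-stimulus baseline (ms).
#' @param post_ms Post-stimulus recording (ms).
#' @param record_dt Sampling interval (ms).
#' @return A `soma_protocol`.
#' @export
protocol_current_clamp <- function(amplitude_nA, duration_ms, delay_ms = 20,
                                   post_ms = 100, record_dt = 0.05) {
  segs <- rbind(.seg(0, delay_ms, 0), .seg(0, duration_ms, amplitude_nA))
  if (post_ms > 0) segs <- rbind(segs, .seg(0, post_ms, 0))
  soma_protocol(list(list(segments = segs)), record_dt = record_dt,
                stim_window = c(delay_ms, delay_ms + duration_ms))
}

#' Run a rectangular current clamp and return the trace
#'
#' @param model A calibrated `soma_model`.
#' @param amplitude_nA,duration_ms,delay_ms,post_ms,record_dt See
#'   [protocol_current_clamp()].
#' @param ... Passed to [simulate_soma()].
#' @return A `drg_trace` tibble.
#' @export
current_clamp <- function(model, amplitude_nA, duration_ms, delay_ms = 20,
                          post_ms = 100, record_dt = 0.05, ...) {
  simulate_soma(model, protocol_current_clamp(amplitude_nA, duration_ms,
                                              delay_ms, post_ms, record_dt),
                ...)
}

#' Train of brief current pulses
#'
#' @param amplitude_nA Pulse amplitude (nA).
#' @param pulse_ms Pulse width (ms).
#' @param n_pulses Number of pulses.
#' @param period_ms Inter-pulse period (ms); 100 ms = 10 Hz.
#' @param delay_ms Pre-train baseline (ms).
#' @param post_ms Post-train recording (ms).
#' @param record_dt Sampling interval (ms).
#' @return A `soma_protocol`.
#' @export
protocol_pulse_train <- function(amplitude_nA = 1.25, pulse_ms = 1,
                                 n_pulses = 20, period_ms = 100,
                                 delay_ms = 50, post_ms = 3000,
                                 record_dt = 0.2) {
  segs <- .seg(0, delay_ms, 0)
  for (k in seq_len(n_pulses)) {
    segs <- rbind(segs, .seg(0, pulse_ms, amplitude_nA),
                  .seg(0, period_ms - pulse_ms, 0))
  }
  segs <- rbind(segs, .seg(0, post_ms, 0))
  soma_protocol(list(list(segments = segs)), record_dt = record_dt,
                stim_window = c(delay_ms, delay_ms + n_pulses * period_ms))
}

#' Input resistance from a small hyperpolarizing clamp
#'
#' Applies a long weak hyperpolarizing current clamp and returns
#' (RMP - steady-state Vm) / |I| in megaohms.
#'
#' @param model A calibrated `soma_model`.
#' @param amplitude_nA Clamp amplitude (nA, default -0.01).
#' @param duration_ms Clamp length (ms); must reach steady state.
#' @param ... Passed to [simulate_soma()].
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(model, amplitude_nA = -0.01,
                             duration_ms = 1000, ...) {
  tr <- current_clamp(model, amplitude_nA, duration_ms, delay_ms = 50,
                      post_ms = 0, ...)
  on <- 50
  rmp <- mean(tr$vm_mv[tr$time_ms >= on - 10 & tr$time_ms < on])
  tail_win <- tr$vm_mv[tr$time_ms > on + 0.9 * duration_ms]
  drift <- abs(tail_win[length(tail_win)] - tail_win[1])
  if (drift > 0.05) {
    abort("Vm still drifting at clamp end; lengthen the protocol.",
          class = "drgsoma_protocol_too_short")
  }
  v_ss <- mean(tail_win)
  (rmp - v_ss) / abs(amplitude_nA)   # mV / nA = MOhm
}

#' Step voltage clamp over a family of test potentials
#'
#' Ideal clamp (no series resistance): Vm is forced. For single-mechanism
#' validation build the model with [validation_model()]. Gates start at their
#' steady state for the holding potential.
#'
#' @param model A `soma_model`.
#' @param holding_mV Holding potential (mV).
#' @param tests_mV Vector of test potentials (mV).
#' @param hold_ms Pre-step holding duration (ms).
#' @param test_ms Test-step duration (ms).
#' @param record_dt Sampling interval (ms).
#' @param ... Passed to [simulate_soma()] (e.g. `ca_on = FALSE`,
#'   `ca_fixed =` for a fixed-\[Ca\] clamp context).
#' @return A long tibble: the per-test traces stacked with a `test_mv`
#'   column. Current columns are in mA/cm2.
#' @export
voltage_clamp_step <- function(model, holding_mV, tests_mV, hold_ms = 10,
                               test_ms = 50, record_dt = 0.05, ...) {
  out <- purrr::map_dfr(tests_mV, function(tp) {
    pr <- soma_protocol(list(list(segments = rbind(
      .seg(1, hold_ms, holding_mV), .seg(1, test_ms, tp)))),
      record_dt = record_dt, stim_window = c(hold_ms, hold_ms + test_ms))
    tr <- simulate_soma(model, pr, v_init = holding_mV, ...)
    tr$test_mv <- tp
    tr
  })
  attr(out, "stim_window") <- c(hold_ms, hold_ms + test_ms)
  out
}

#' Ramp voltage clamp
#'
#' @param model A `soma_model`.
#' @param holding_mV Holding potential (mV).
#' @param from_mV,to_mV Ramp start/end (mV).
#' @param ramp_ms Ramp duration (ms), > 0.
#' @param hold_ms Pre-ramp holding (ms).
#' @param ... Passed to [simulate_soma()].
#' @return A `drg_trace` tibble (instantaneous currents against `vm_mv`).
#' @export
voltage_clamp_ramp <- function(model, holding_mV, from_mV, to_mV, ramp_ms,
                               hold_ms = 50, ...) {
  if (ramp_ms <= 0) {
    abort("Ramp duration must be positive.", class = "drgsoma_invalid_protocol")
  }
  pr <- soma_protocol(list(list(segments = rbind(
    .seg(1, hold_ms, holding_mV), .seg(1, ramp_ms, from_mV, to_mV)))),
    record_dt = min(0.05, ramp_ms / 400))
  simulate_soma(model, pr, v_init = holding_mV, ...)
}

#' High-extracellular-potassium challenge
#'
#' Overrides \[K\]o for a stated window, recomputing E_K everywhere it
#' appears (including the SK rectification shift), and records the
#' outer-shell Ca2+ transient through the application and washout.
#'
#' @param model A calibrated `soma_model`.
#' @param k_out High \[K\]o (mM, default 30).
#' @param duration_s Application window (s, default 50).
#' @param pre_s,post_s Baseline and washout windows (s).
#' @param dye Dye preset name for the imaging context (default `"fura2"`;
#'   NULL for dye-free).
#' @param dt Integrator step (ms); the slow dynamics tolerate a coarser step
#'   than the default.
#' @param ... Passed to [simulate_soma()].
#' @return A `drg_trace` tibble.
#' @export
high_k_challenge <- function(model, k_out = 30, duration_s = 50, pre_s = 5,
                             post_s = 20, dye = "fura2", dt = 0.02, ...) {
  cond_hi <- update_conditions(model$config$conditions, k_o = k_out)
  pr <- soma_protocol(list(
    list(segments = .seg(0, pre_s * 1e3, 0)),
    list(segments = .seg(0, duration_s * 1e3, 0), conditions = cond_hi),
    list(segments = .seg(0, post_s * 1e3, 0))
  ), dye = dye, record_dt = 5,
  stim_window = c(pre_s * 1e3, (pre_s + duration_s) * 1e3))
  simulate_soma(model, pr, dt = dt, ...)
}

#' Inflammation density preset
#'
#' Applies the channel-density changes of the inflamed-bladder state
#' (Nav1.8 0.06, slow KA 1e-4, KDR 1e-3 S/cm2), which convert the control
#' model's phasic firing to ~20 Hz tonic firing; all other densities and the
#' calibrated E_pas are left at control.
#'
#' @param model A calibrated `soma_model`.
#' @return The modified model.
#' @export
inflammation_preset <- function(model) {
  stopifnot(inherits(model, "soma_model"))
  model$config$mechanisms$nav18$density <- 0.06
  model$config$mechanisms$ka$density <- 1e-4
  model$config$mechanisms$kdr$density <- 1e-3
  model
}

#' Sweep a mechanism's maximum density and tabulate excitability features
#'
#' Re-runs a protocol for each density value and extracts AP/AHP features,
#' spike count and peak outer-shell \[Ca\]i.
#'
#' @param model A calibrated `soma_model`.
#' @param mechanism Mechanism name (e.g. `"sk"`, `"bk"`).
#' @param values Densities to test (S/cm2).
#' @param protocol A [soma_protocol()].
#' @param ... Passed to [simulate_soma()].
#' @return A tibble: one row per density with the feature columns of
#'   [extract_ap_features()], plus `g_bar`, `n_spikes`, `peak_cai_mM`.
#' @export
conductance_sweep <- function(model, mechanism, values, protocol, ...) {
  if (!mechanism %in% names(model$config$mechanisms)) {
    abort(paste0("Unknown mechanism: ", mechanism),
          class = "drgsoma_unknown_mechanism")
  }
  purrr::map_dfr(values, function(gb) {
    m <- model
    m$config$mechanisms[[mechanism]]$density <- gb
    tr <- simulate_soma(m, protocol, ...)
    ft <- extract_ap_features(tr, stim_window = protocol$stim_window)
    ft$g_bar <- gb
    ft$peak_cai_mM <- max(tr$cai_mM)
    ft
  })
}

#' Named presets for the study's figure protocols
#'
#' @return A named list of [soma_protocol()] objects (`fig9a`, `fig9b`,
#'   `fig11b`, `fig12`, `fig14`, `fig17`, `fig18`); the high-K imaging
#'   challenge (`fig11a`) is exposed through [high_k_challenge()] because it
#'   carries an ionic override.
#' @export
figure_protocols <- function() {
  list(
    # single AP, 0.16 nA x 50 ms
    fig9a = protocol_current_clamp(0.16, 50, delay_ms = 20, post_ms = 250),
    # phasic response to a long 0.24 nA x 800 ms clamp
    fig9b = protocol_current_clamp(0.24, 800, delay_ms = 20, post_ms = 100),
    # single-AP Ca2+ transient: hold -80 mV 50 ms, then 2 nA x 1 ms
    fig11b = soma_protocol(list(list(segments = rbind(
      .seg(1, 50, -80), .seg(0, 1, 2), .seg(0, 1500, 0)))),
      dye = "indo1", record_dt = 0.2, stim_window = c(50, 51)),
    # 20 APs at 10 Hz (1.25 nA, 1 ms pulses)
    fig12 = protocol_pulse_train(1.25, 1, 20, 100, delay_ms = 50,
                                 post_ms = 3000),
    # single AP for AHP analysis: 0.18 nA x 15 ms at 110 ms
    fig14 = protocol_current_clamp(0.18, 15, delay_ms = 110, post_ms = 900),
    # inflammation firing, 0.12 nA x 600 ms
    fig17 = protocol_current_clamp(0.12, 600, delay_ms = 20, post_ms = 100),
    # inflammation firing, 0.12 nA x 1000 ms
    fig18 = protocol_current_clamp(0.12, 1000, delay_ms = 20, post_ms = 100)
  )
}
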