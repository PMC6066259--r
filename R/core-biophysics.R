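#' @useDynLib drgsoma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats approx uniroot setNames
NULL

# Physical constants (SI). Unit system throughout the package is the
# compartmental-modelling convention: mV, ms, mM, mA/cm2, S/cm2, cm/s, um.
.GAS_CONSTANT <- 8.314462618   # J / (mol K)
.FARADAY      <- 96485.33212   # C / mol

#' Nernst equilibrium potential
#'
#' Computes the equilibrium (reversal) potential of an ion from its
#' intracellular and extracellular concentrations,
#' \eqn{E = (RT / zF) \log(c_{out}/c_{in})}.
#'
#' @param z Integer valence of the ion (e.g. +1 for K+, +2 for Ca2+, -1 for Cl-).
#' @param c_in,c_out Intracellular / extracellular concentration (mM), > 0.
#' @param temp_c Temperature in degrees Celsius (default 22, the modelling
#'   temperature for dissociated DRG neuron recordings).
#' @return Reversal potential in mV.
#' @examples
#' nernst_potential(1, 140, 5)    # K+ : about -84.7 mV
#' nernst_potential(1, 10, 150)   # Na+: about +68.9 mV
#' @export
nernst_potential <- function(z, c_in, c_out, temp_c = 22) {
  if (any(c_in <= 0) || any(c_out <= 0)) {
    abort("Concentrations must be strictly positive.", class = "drgsoma_invalid_input")
  }
  if (any(z == 0)) {
    abort("Ion valence must be non-zero.", class = "drgsoma_invalid_input")
  }
  t_k <- temp_c + 273.15
  1e3 * (.GAS_CONSTANT * t_k / (z * .FARADAY)) * log(c_out / c_in)
}

#' Goldman-Hodgkin-Katz flux current density
#'
#' Open-channel current density through a permeability-parameterized channel,
#' using the GHK flux equation. The removable singularity at Vm = 0 is handled
#' by a series branch for |zFV/RT| < 1e-4, whose leading term is
#' \eqn{P z F (c_{in} - c_{out})}.
#'
#' @param p_max Maximum permeability (cm/s), >= 0.
#' @param gate_product Product of open gate probabilities in \[0, 1\].
#' @param vm Membrane potential (mV).
#' @param c_in,c_out Intracellular / extracellular concentration (mM).
#' @param z Ion valence.
#' @param temp_c Temperature (deg C).
#' @return Current density in mA/cm2, positive outward.
#' @export
ghk_flux <- function(p_max, gate_product, vm, c_in, c_out, z = 2, temp_c = 22) {
  if (any(p_max < 0)) abort("p_max must be >= 0.", class = "drgsoma_invalid_input")
  if (any(gate_product < -1e-12) || any(gate_product > 1 + 1e-12)) {
    abort("gate_product must lie in [0, 1].", class = "drgsoma_invalid_input")
  }
  t_k <- temp_c + 273.15
  u <- z * .FARADAY * (vm * 1e-3) / (.GAS_CONSTANT * t_k)  # dimensionless
  # concentrations mM -> mol/cm3 carries 1e-6; A/cm2 -> mA/cm2 carries 1e3
  scale <- p_max * gate_product * z * .FARADAY * 1e-3
  small <- abs(u) < 1e-4
  out <- numeric(length(u + vm + c_in + c_out))  # broadcast length
  ue <- rep_len(u, length(out))
  ci <- rep_len(c_in, length(out)); co <- rep_len(c_out, length(out))
  sc <- rep_len(scale, length(out))
  sm <- rep_len(small, length(out))
  if (any(!sm)) {
    uu <- ue[!sm]
    out[!sm] <- sc[!sm] * uu * (ci[!sm] - co[!sm] * exp(-uu)) / (1 - exp(-uu))
  }
  if (any(sm)) {
    # limit: u/(1-e^-u) -> 1 + u/2 + u^2/12 ; times (ci - co e^-u)
    uu <- ue[sm]
    out[sm] <- sc[sm] * (1 + uu / 2 + uu^2 / 12) *
      (ci[sm] - co[sm] * exp(-uu))
  }
  out
}

#' Boltzmann sigmoid for steady-state gating
#'
#' \eqn{1 / (1 + \exp(sign (v_{1/2} - V_m)/k)}. With `sign = +1` this is an
#' activation curve (increasing in Vm); with `sign = -1` an inactivation curve.
#' The value at `vm = v_half` is exactly 0.5.
#'
#' @param vm Membrane potential (mV).
#' @param v_half Half-activation potential (mV).
#' @param slope Slope factor (mV), non-zero.
#' @param sign +1 (activation) or -1 (inactivation).
#' @return Open probability in (0, 1).
#' @export
boltzmann <- function(vm, v_half, slope, sign = 1) {
  if (any(slope == 0)) abort("slope must be non-zero.", class = "drgsoma_invalid_input")
  1 / (1 + exp(sign * (v_half - vm) / slope))
}

#' Advance a first-order gate by its exact exponential solution
#'
#' For constant steady state and time constant over a step,
#' \eqn{x(t + dt) = x_\infty + (x - x_\infty) e^{-dt/\tau}} solves
#' \eqn{dx/dt = (x_\infty - x)/\tau} exactly.
#'
#' @param gate Current gate value (probability).
#' @param steady Steady-state value at the present potential.
#' @param tau Time constant (ms), > 0.
#' @param dt Step (ms), > 0.
#' @return Updated gate value.
#' @export
gate_step <- function(gate, steady, tau, dt) {
  if (any(tau <= 0)) abort("tau must be > 0.", class = "drgsoma_invalid_kinetics")
  if (any(dt <= 0)) abort("dt must be > 0.", class = "drgsoma_invalid_input")
  steady + (gate - steady) * exp(-dt / tau)
}

#' Piecewise-linear interpolation table
#'
#' A one-dimensional lookup table evaluated by linear interpolation, clamping
#' to the end values outside the abscissa range (the convention of table-driven
#' gating parameters in compartmental simulators).
#'
#' @param x Strictly increasing abscissa values.
#' @param y Ordinate values, same length as `x`.
#' @return A function of one numeric argument.
#' @export
interp_table <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Interpolation table must be non-empty.", class = "drgsoma_config_error")
  }
  if (length(x) != length(y)) abort("x and y lengths differ.", class = "drgsoma_config_error")
  if (length(x) > 1 && any(diff(x) <= 0)) {
    abort("Table abscissae must be strictly increasing.", class = "drgsoma_config_error")
  }
  force(x); force(y)
  if (length(x) == 1) return(function(q) rep_len(y, length(q)))
  function(q) approx(x, y, xout = q, rule = 2)$y
}

#' Ionic conditions of the bath and cytosol
#'
#' Bundles the intracellular/extracellular concentrations of Na+, K+, Ca2+ and
#' Cl- with temperature, and derives the Nernst reversal potentials. Updating a
#' concentration with [update_conditions()] recomputes the potentials.
#'
#' Defaults are the physiological set for dissociated bladder small DRG
#' neurons: \[K\]i 140 / \[K\]o 5, \[Na\]i 10 / \[Na\]o 150, resting \[Ca\]i
#' 136 nM / \[Ca\]o 2 mM, \[Cl\]i 40 / \[Cl\]o 145 (mM), 22 deg C, which give
#' E_K -84.7, E_Na +68.9, E_Ca +122 and E_Cl -32.7 mV.
#'
#' @param na_i,na_o,k_i,k_o,ca_i,ca_o,cl_i,cl_o Concentrations (mM), > 0.
#' @param temp_c Temperature (deg C).
#' @return An object of class `ionic_conditions`: a list with the
#'   concentrations, the temperature and an element `e_rev` holding the derived
#'   potentials (mV) named `na`, `k`, `ca`, `cl`.
#' @export
ionic_conditions <- function(na_i = 10, na_o = 150, k_i = 140, k_o = 5,
                             ca_i = 1.36e-4, ca_o = 2, cl_i = 40, cl_o = 145,
                             temp_c = 22) {
  conc <- c(na_i = na_i, na_o = na_o, k_i = k_i, k_o = k_o,
            ca_i = ca_i, ca_o = ca_o, cl_i = cl_i, cl_o = cl_o)
  if (any(conc <= 0)) {
    abort("All ionic concentrations must be > 0.", class = "drgsoma_invalid_input")
  }
  x <- list(na_i = na_i, na_o = na_o, k_i = k_i, k_o = k_o,
            ca_i = ca_i, ca_o = ca_o, cl_i = cl_i, cl_o = cl_o,
            temp_c = temp_c)
  x$e_rev <- list(
    na = nernst_potential(1, na_i, na_o, temp_c),
    k  = nernst_potential(1, k_i, k_o, temp_c),
    ca = nernst_potential(2, ca_i, ca_o, temp_c),
    cl = nernst_potential(-1, cl_i, cl_o, temp_c)
  )
  structure(x, class = "ionic_conditions")
}

#' Modify ionic conditions, recomputing reversal potentials
#'
#' @param cond An [ionic_conditions()] object.
#' @param ... Named concentration or temperature overrides (e.g. `k_o = 30`).
#' @return A new `ionic_conditions` object.
#' @export
update_conditions <- function(cond, ...) {
  stopifnot(inherits(cond, "ionic_conditions"))
  ov <- list(...)
  allowed <- c("na_i", "na_o", "k_i", "k_o", "ca_i", "ca_o", "cl_i", "cl_o", "temp_c")
  bad <- setdiff(names(ov), allowed)
  if (length(bad)) {
    abort(paste0("Unknown ionic condition field(s): ", paste(bad, collapse = ", ")),
          class = "drgsoma_config_error")
  }
  args <- utils::modifyList(cond[allowed], ov)
  do.call(ionic_conditions, args)
}

#' @export
print.ionic_conditions <- function(x, ...) {
  cat("Ionic conditions (", x$temp_c, " degC)\n", sep = "")
  cat(sprintf("  Na %g/%g  K %g/%g  Ca %g/%g  Cl %g/%g mM (in/out)\n",
              x$na_i, x$na_o, x$k_i, x$k_o, x$ca_i, x$ca_o, x$cl_i, x$cl_o))
  cat(sprintf("  E_Na %.1f  E_K %.1f  E_Ca %.1f  E_Cl %.1f mV\n",
              x$e_rev$na, x$e_rev$k, x$e_rev$ca, x$e_rev$cl))
  invisible(x)
}
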