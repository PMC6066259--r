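# Twelve-shell intracellular Ca2+/IP3 system: rapid-buffer approximation,
# radial diffusion, PMCA kinetic scheme, ER fluxes (SERCA, IP3R, RYR/CICR,
# leak), mitochondrial fluxes (MCU, MNCX) and indicator-dye corrections.
# These R-level operators define the fluxes used throughout; the compiled
# integrator applies the same expressions inside the full-model time loop.

#' Default Ca2+ dynamics parameter set
#'
#' All rates and dissociation constants of the shell Ca2+ system. Units:
#' concentrations mM, rates per ms (pump kinetic rates per mM-ms / per ms),
#' diffusion coefficients um2/ms, pump densities mol/cm2.
#'
#' @return A named list.
#' @export
calcium_params <- function() {
  list(
    n_shells = 12,
    d_ca = 0.6,              # um2/ms, cytosolic Ca2+ diffusion
    beta_cyt = 370,          # fixed endogenous cytosolic binding ratio
    ca_rest = 1.36e-4,       # mM
    ca_er_rest = 0.4,        # mM
    ca_mt_rest = 2e-4,       # mM
    ip3_rest = 1.6e-4,       # mM
    # PMCA two-reaction scheme (rates converted to per-ms)
    pmca_k1 = 3.74e7 * 1e-3, # /mM-ms
    pmca_k2 = 2.5e5 * 1e-3,  # /ms
    pmca_k3 = 500 * 1e-3,    # /ms
    pmca_k4 = 5 * 1e-3,      # /mM-ms
    pmca_pump0 = 4.232e-13,  # mol/cm2 initial free density
    # SERCA
    v_serca = 3.75e-6,       # mM/ms
    k_psr = 2.7e-4,          # mM
    n_serca = 2,
    # IP3 / IP3R
    k_degr_ip3 = 1.4e-4,     # /ms
    d_ip3 = 0.283,           # um2/ms
    k_ip3 = 8e-4,            # mM
    k_act_ip3 = 3e-4,        # mM
    k_on_ip3 = 2.7,          # /mM-ms
    k_inh_ip3 = 2e-4,        # mM
    j_ip3r_bar = 3.5e-6,     # mM/ms
    # CICR via RYR
    v_cicr = 5e-7,           # /ms
    k_cicr = 1.98e-3,        # mM
    k_t_cicr = 6e-4,         # mM activation threshold
    # ER buffer
    kb_er = 0.5, btot_er = 10,
    # mitochondria
    v_mcu = 1.4468e-6,       # mM/ms
    k_mcu = 6.06e-4,         # mM
    n_mcu = 2.3,
    v_mncx = 6e-5,           # mM/ms
    k_na_mncx = 8,           # mM
    k_ca_mncx = 0.035,       # mM
    kb_mt = 1e-5, btot_mt = 0.065,
    # derived at calibration
    l_er = NA_real_,         # ER leak factor (rest zero-sum)
    mcu_scale = 1            # rest balance factor applied to v_mcu
  )
}

#' Indicator-dye presets
#'
#' Buffering parameters of the Ca2+ indicator dyes used when comparing
#' simulated transients with imaging data. `kb`/`btot` in mM, `d_dye` in
#' um2/ms; `compartment` says which pool the dye loads. `pump0` is the
#' retuned initial PMCA free-pump density that restabilizes the resting
#' \[Ca\]i in the dye's presence (recomputed exactly at calibration).
#'
#' @param name `"fura2"`, `"indo1"`, `"furaff"` or `"mtpericam"`.
#' @return A named list of dye parameters.
#' @export
dye_preset <- function(name) {
  presets <- list(
    fura2     = list(kb = 224e-6, btot = 5e-3, d_dye = 0.1e-3,
                     compartment = "cyt", pump0 = 4.08e-13),
    indo1     = list(kb = 250e-6, btot = 0.1, d_dye = 0.1e-3,
                     compartment = "cyt", pump0 = 4.0815e-13),
    furaff    = list(kb = 5500e-6, btot = 0.2, d_dye = 0.075e-3,
                     compartment = "cyt", pump0 = NA_real_),
    mtpericam = list(kb = 1700e-6, btot = 15e-3, d_dye = 0,
                     compartment = "mt", pump0 = NA_real_)
  )
  if (!name %in% names(presets)) {
    abort(paste0("Unknown dye preset: ", name, ". Valid: ",
                 paste(names(presets), collapse = ", ")),
          class = "drgsoma_config_error")
  }
  c(presets[[name]], list(name = name))
}

#' Rapid-buffer-approximation binding ratio
#'
#' Incremental Ca2+ binding ratio \eqn{\beta = K_B B_{tot}/(K_B + [Ca])^2}
#' of a single buffer species under the rapid buffer approximation.
#'
#' @param k_b Buffer dissociation constant (mM), > 0.
#' @param b_tot Total buffer concentration (mM), >= 0.
#' @param ca Free Ca2+ concentration (mM), > 0.
#' @return Dimensionless binding ratio.
#' @export
binding_ratio <- function(k_b, b_tot, ca) {
  if (any(k_b <= 0) || any(ca <= 0) || any(b_tot < 0)) {
    abort("k_b and ca must be > 0, b_tot >= 0.", class = "drgsoma_invalid_input")
  }
  k_b * b_tot / (k_b + ca)^2
}

#' Concentric-shell discretization of the soma
#'
#' Divides a sphere into `n_shells` concentric shells of equal radial
#' thickness, except the outermost shell at half thickness (the
#' near-membrane compartment of reference compartmental simulators). Shell 1
#' is the outermost. Each shell's total volume splits 81% cytosol, 12% ER,
#' 7% mitochondria.
#'
#' @param diameter_um Soma diameter (um), > 0.
#' @param n_shells Number of shells, >= 2 (default 12).
#' @return A `shell_geometry` list: `r_outer`, `r_inner`, `v_total`, `v_cyt`,
#'   `v_er`, `v_mt` (um3), `area` (um2, interface between shell i and i+1),
#'   `dr` (um, center-to-center), `frac = c(cyt = .81, er = .12, mt = .07)`.
#' @export
build_shells <- function(diameter_um = 24, n_shells = 12) {
  if (diameter_um <= 0) abort("diameter must be > 0.", class = "drgsoma_invalid_input")
  if (n_shells < 2) abort("need at least 2 shells.", class = "drgsoma_invalid_input")
  r_tot <- diameter_um / 2
  delta <- r_tot / (n_shells - 0.5)
  r_outer <- c(r_tot, r_tot - delta / 2 - delta * (seq_len(n_shells - 1) - 1))
  r_inner <- c(r_outer[-1], 0)
  v_total <- 4 / 3 * pi * (r_outer^3 - r_inner^3)
  centers <- (r_outer + r_inner) / 2
  frac <- c(cyt = 0.81, er = 0.12, mt = 0.07)
  structure(list(
    n_shells = n_shells,
    r_outer = r_outer, r_inner = r_inner,
    v_total = v_total,
    v_cyt = frac[["cyt"]] * v_total,
    v_er = frac[["er"]] * v_total,
    v_mt = frac[["mt"]] * v_total,
    area = 4 * pi * r_inner[-n_shells]^2,
    dr = centers[-n_shells] - centers[-1],
    frac = frac
  ), class = "shell_geometry")
}

#' Membrane Ca2+ current to concentration rate
#'
#' Converts the total membrane Ca2+ current into a rate of free-Ca2+ change
#' of the outermost shell, \eqn{J = -I_{Ca}/(zFv)}: an inward (negative)
#' current raises \[Ca\]i. Buffering is applied by the caller.
#'
#' @param i_ca_nA Total membrane Ca2+ current (nA, positive outward).
#' @param volume_um3 Volume of the outermost-shell cytosol (um3), > 0.
#' @return Rate in mM/ms.
#' @export
membrane_ca_flux <- function(i_ca_nA, volume_um3) {
  if (any(volume_um3 <= 0)) abort("volume must be > 0.", class = "drgsoma_invalid_input")
  v_l <- volume_um3 * 1e-15            # um3 -> L
  -(i_ca_nA * 1e-9) / (2 * .FARADAY * v_l)  # A/(C/mol)/L = M/s == mM/ms
}

#' Buffered Fickian exchange between two adjacent shells
#'
#' Flux per Fick's first law scaled by the buffered diffusivity
#' \eqn{D/(1+\beta)}; mass conservative (the amount leaving one shell enters
#' the other).
#'
#' @param ca_a,ca_b Concentrations in the two shells (mM).
#' @param area_um2 Interface area (um2).
#' @param dr_um Center-to-center distance (um).
#' @param v_a_um3,v_b_um3 (Cytosolic) volumes of the two shells (um3).
#' @param beta Buffer binding ratio applied to diffusion.
#' @param d Free diffusion coefficient (um2/ms), > 0.
#' @return Named list `rate_a`, `rate_b` (mM/ms in each shell).
#' @export
diffusion_flux <- function(ca_a, ca_b, area_um2, dr_um, v_a_um3, v_b_um3,
                           beta = 370, d = 0.6) {
  if (d <= 0) abort("d must be > 0.", class = "drgsoma_invalid_input")
  amt <- d / (1 + beta) * area_um2 * (ca_b - ca_a) / dr_um  # mM um3 / ms
  list(rate_a = amt / v_a_um3, rate_b = -amt / v_b_um3)
}

#' One step of the PMCA two-reaction pump scheme
#'
#' Cytosolic Ca2+ binds the free pump (rates K1/K2) and the bound pump
#' releases Ca2+ to the exterior (rates K3/K4). The reported `j_pmca` is the
#' net forward flux of the second (release) reaction; the cytosol-facing flux
#' is the net of the first. Total pump density is conserved. Densities are
#' advanced by an implicit (backward Euler) step, stable for the stiff
#' binding reaction.
#'
#' @param ca Outer-shell cytosolic Ca2+ (mM).
#' @param ca_o Extracellular Ca2+ (mM).
#' @param pump_free,pump_bound Pump densities (mol/cm2), >= 0.
#' @param rates Named list `k1` (/mM-ms), `k2` (/ms), `k3` (/ms), `k4`
#'   (/mM-ms).
#' @param dt Step (ms).
#' @return List `pump_free`, `pump_bound`, `j_pmca` (mol/cm2/ms, the
#'   release-reaction net flux), `j_cyt` (mol/cm2/ms removed from cytosol via
#'   the binding reaction).
#' @export
pmca_step <- function(ca, ca_o, pump_free, pump_bound, rates, dt) {
  if (pump_free < 0 || pump_bound < 0) {
    abort("pump densities must be >= 0.", class = "drgsoma_invalid_input")
  }
  k1 <- rates$k1; k2 <- rates$k2; k3 <- rates$k3; k4 <- rates$k4
  # backward Euler on (free, bound): d free = -a*free + b*bound,
  # d bound = a*free - b*bound with a = k1 ca + k4 ca_o, b = k2 + k3
  a <- k1 * ca + k4 * ca_o
  b <- k2 + k3
  tot <- pump_free + pump_bound
  # solve (I - dt A) x_new = x_old for the 2x2 linear system
  den <- 1 + dt * (a + b)
  free_new <- (pump_free * (1 + dt * b) + dt * b * pump_bound) / den
  bound_new <- tot - free_new
  if (free_new < 0 || bound_new < 0) {
    abort("PMCA step produced a negative density; reduce dt.",
          class = "drgsoma_step_size_error")
  }
  list(pump_free = free_new, pump_bound = bound_new,
       j_pmca = k3 * bound_new - k4 * ca_o * free_new,
       j_cyt = k1 * ca * free_new - k2 * bound_new)
}

#' ER flux quartet (SERCA, IP3R, CICR, leak)
#'
#' @param ca Cytosolic Ca2+ in the shell (mM), > 0.
#' @param ca_er ER Ca2+ in the shell (mM), > 0.
#' @param ip3 IP3 concentration (mM).
#' @param h IP3R inhibition-gate value in \[0,1\].
#' @param params Ca2+ parameter list (see [calcium_params()]); `l_er` must be
#'   set (see [calibrate_er_leak()]).
#' @return Named list `j_serca`, `j_ip3r`, `j_cicr`, `j_leak` (mM/ms). All
#'   are defined positive in their physiological direction; the cytosol gains
#'   `j_ip3r + j_cicr + j_leak - j_serca`.
#' @export
er_fluxes <- function(ca, ca_er, ip3, h, params = calcium_params()) {
  if (any(ca_er <= 0)) abort("ca_er must be > 0.", class = "drgsoma_invalid_state")
  p <- params
  j_serca <- p$v_serca * ca^p$n_serca / (ca^p$n_serca + p$k_psr^p$n_serca)
  po <- (ip3 / (ip3 + p$k_ip3)) * (ca / (ca + p$k_act_ip3)) * h
  j_ip3r <- p$j_ip3r_bar * po^3 * (1 - ca / ca_er)
  j_cicr <- ifelse(ca > p$k_t_cicr,
                   p$v_cicr * ca / (ca + p$k_cicr) * (ca_er - ca), 0)
  l_er <- if (is.na(p$l_er)) 0 else p$l_er
  j_leak <- l_er * (1 - ca / ca_er)
  list(j_serca = j_serca, j_ip3r = j_ip3r, j_cicr = j_cicr, j_leak = j_leak)
}

#' Solve the ER leak factor for zero net resting ER flux
#'
#' Sets \eqn{L_{ER}} so that SERCA uptake exactly balances IP3R + CICR + leak
#' release at the resting state (with the IP3R gate at its steady state).
#'
#' @param params Ca2+ parameter list.
#' @return The parameter list with `l_er` filled in.
#' @export
calibrate_er_leak <- function(params = calcium_params()) {
  p <- params
  h0 <- p$k_inh_ip3 / (p$ca_rest + p$k_inh_ip3)
  p$l_er <- 0
  fl <- er_fluxes(p$ca_rest, p$ca_er_rest, p$ip3_rest, h0, p)
  drive <- 1 - p$ca_rest / p$ca_er_rest
  p$l_er <- (fl$j_serca - fl$j_ip3r - fl$j_cicr) / drive
  p
}

#' IP3R inhibition-gate update
#'
#' \eqn{dh/dt = k_{on}(k_{inh} - ([Ca] + k_{inh})h)}; advanced by the exact
#' exponential solution with \eqn{h_\infty = k_{inh}/([Ca]+k_{inh})} and
#' \eqn{\tau = 1/(k_{on}([Ca]+k_{inh}))}.
#'
#' @param h Current gate value.
#' @param ca Cytosolic Ca2+ (mM).
#' @param dt Step (ms).
#' @param params Ca2+ parameter list.
#' @return Updated gate value.
#' @export
ip3r_gate_step <- function(h, ca, dt, params = calcium_params()) {
  p <- params
  h_inf <- p$k_inh_ip3 / (ca + p$k_inh_ip3)
  tau <- 1 / (p$k_on_ip3 * (ca + p$k_inh_ip3))
  gate_step(h, h_inf, tau, dt)
}

#' Advance the per-shell IP3 field
#'
#' Radial diffusion plus first-order degradation toward the resting
#' concentration.
#'
#' @param ip3 Vector of per-shell IP3 (mM), outermost first.
#' @param geometry A [build_shells()] object.
#' @param dt Step (ms).
#' @param params Ca2+ parameter list.
#' @return Updated IP3 vector.
#' @export
ip3_step <- function(ip3, geometry, dt, params = calcium_params()) {
  p <- params
  n <- geometry$n_shells
  stopifnot(length(ip3) == n)
  amt <- p$d_ip3 * geometry$area * (ip3[-1] - ip3[-n]) / geometry$dr
  rate <- numeric(n)
  rate[-n] <- rate[-n] + amt / geometry$v_cyt[-n]
  rate[-1] <- rate[-1] - amt / geometry$v_cyt[-1]
  rate <- rate - p$k_degr_ip3 * (ip3 - p$ip3_rest)
  ip3 + dt * rate
}

#' Mitochondrial uptake and release fluxes
#'
#' MCU uptake is a Hill function of cytosolic Ca2+ (coefficient 2.3); MNCX
#' release depends on cytosolic Na+ (Hill 3) and mitochondrial Ca2+. The two
#' cancel at the calibrated resting state.
#'
#' @param ca Cytosolic Ca2+ (mM).
#' @param ca_mt Mitochondrial Ca2+ (mM).
#' @param na_i Cytosolic Na+ (mM).
#' @param params Ca2+ parameter list.
#' @return List `j_mcu`, `j_mncx` (mM/ms).
#' @export
mito_fluxes <- function(ca, ca_mt, na_i = 10, params = calcium_params()) {
  p <- params
  j_mcu <- p$mcu_scale * p$v_mcu * ca^p$n_mcu / (ca^p$n_mcu + p$k_mcu^p$n_mcu)
  j_mncx <- p$v_mncx * na_i^3 / (na_i^3 + p$k_na_mncx^3) *
    ca_mt / (ca_mt + p$k_ca_mncx)
  list(j_mcu = j_mcu, j_mncx = j_mncx)
}

#' Balance mitochondrial fluxes at rest
#'
#' Rescales the MCU uptake rate so that MCU uptake and MNCX release cancel
#' exactly at the resting state (the stated maximal rates, both tuned
#' quantities, do not balance there on their own).
#'
#' @param params Ca2+ parameter list.
#' @param na_i Resting cytosolic Na+ (mM).
#' @return The parameter list with `mcu_scale` set.
#' @export
calibrate_mito_rest <- function(params = calcium_params(), na_i = 10) {
  p <- params
  p$mcu_scale <- 1
  fl <- mito_fluxes(p$ca_rest, p$ca_mt_rest, na_i, p)
  p$mcu_scale <- fl$j_mncx / fl$j_mcu
  p
}

#' Effective diffusion coefficient in the presence of an indicator dye
#'
#' \eqn{D_{eff} = (D_{Ca} + \beta_{dye} D_{dye}) / (1 + \beta + \beta_{dye})}.
#' The dye also adds its binding ratio to the rate divisor of the shell ODEs.
#'
#' @param ca Free Ca2+ (mM) at which the dye ratio is evaluated.
#' @param dye A [dye_preset()] list (or NULL for no dye).
#' @param params Ca2+ parameter list.
#' @return List `beta_dye`, `d_eff` (um2/ms), `divisor` (1 + beta + beta_dye).
#' @export
apply_dye <- function(ca, dye, params = calcium_params()) {
  p <- params
  if (is.null(dye)) {
    return(list(beta_dye = 0, d_eff = p$d_ca / (1 + p$beta_cyt),
                divisor = 1 + p$beta_cyt))
  }
  beta_dye <- binding_ratio(dye$kb, dye$btot, ca)
  list(beta_dye = beta_dye,
       d_eff = (p$d_ca + beta_dye * dye$d_dye) / (1 + p$beta_cyt + beta_dye),
       divisor = 1 + p$beta_cyt + beta_dye)
}

#' Construct the resting calcium state
#'
#' @param geometry A [build_shells()] object.
#' @param params Ca2+ parameter list (calibrated).
#' @return A `calcium_state` list of per-shell vectors `ca`, `ca_er`, `ca_mt`,
#'   `ip3`, `h`, plus scalars `pump_free`, `pump_bound`.
#' @export
calcium_rest_state <- function(geometry, params = calcium_params()) {
  p <- params
  n <- geometry$n_shells
  h0 <- p$k_inh_ip3 / (p$ca_rest + p$k_inh_ip3)
  bound0 <- p$ca_rest * p$pmca_pump0 * p$pmca_k1 / p$pmca_k2
  structure(list(
    ca = rep(p$ca_rest, n), ca_er = rep(p$ca_er_rest, n),
    ca_mt = rep(p$ca_mt_rest, n), ip3 = rep(p$ip3_rest, n),
    h = rep(h0, n), pump_free = p$pmca_pump0, pump_bound = bound0
  ), class = "calcium_state")
}

#' Advance the full shell Ca2+ system one step (R reference implementation)
#'
#' Updates all shells' cytosolic, ER and mitochondrial Ca2+, IP3, IP3R gate
#' and PMCA densities. Membrane and PMCA terms apply only to the outermost
#' shell. This is the reference operator mirrored by the compiled integrator;
#' it substeps automatically if a concentration would go non-positive.
#'
#' @param state A `calcium_state`.
#' @param i_ca_nA Total membrane Ca2+ current (nA, positive outward).
#' @param geometry A [build_shells()] object.
#' @param dt Step (ms).
#' @param params Calibrated Ca2+ parameter list.
#' @param dye Optional [dye_preset()].
#' @param na_i Cytosolic Na+ (mM).
#' @param area_cm2 Membrane area (cm2) for the PMCA surface flux.
#' @param enable Named logical switches: `pmca`, `serca`, `ip3r`, `cicr`,
#'   `leak`, `mcu`, `mncx`, `diffusion`, `membrane` (all TRUE by default).
#' @return Updated `calcium_state`.
#' @export
advance_calcium <- function(state, i_ca_nA, geometry, dt,
                            params = calcium_params(), dye = NULL,
                            na_i = 10, area_cm2 = 1.809557e-5,
                            ca_o = 2, enable = list()) {
  en <- utils::modifyList(
    list(pmca = TRUE, serca = TRUE, ip3r = TRUE, cicr = TRUE, leak = TRUE,
         mcu = TRUE, mncx = TRUE, diffusion = TRUE, membrane = TRUE), enable)
  p <- params
  n <- geometry$n_shells
  n_sub <- 1L
  repeat {
    st <- state
    h_sub <- dt / n_sub
    ok <- TRUE
    for (s in seq_len(n_sub)) {
      ca <- st$ca; ca_er <- st$ca_er; ca_mt <- st$ca_mt
      dy <- apply_dye(ca[1], dye, p)
      cyt_dye <- !is.null(dye) && dye$compartment == "cyt"
      mt_dye <- !is.null(dye) && dye$compartment == "mt"
      beta_dye_v <- if (cyt_dye) binding_ratio(dye$kb, dye$btot, ca) else 0 * ca
      divisor <- 1 + p$beta_cyt + beta_dye_v
      d_fac <- if (cyt_dye) {
        (p$d_ca + beta_dye_v[-n] * dye$d_dye) / divisor[-n]
      } else {
        rep(p$d_ca / (1 + p$beta_cyt), n - 1)
      }
      fl <- er_fluxes(ca, ca_er, st$ip3, st$h, p)
      if (!en$serca) fl$j_serca <- 0 * ca
      if (!en$ip3r) fl$j_ip3r <- 0 * ca
      if (!en$cicr) fl$j_cicr <- 0 * ca
      if (!en$leak) fl$j_leak <- 0 * ca
      mt <- mito_fluxes(ca, ca_mt, na_i, p)
      if (!en$mcu) mt$j_mcu <- 0 * ca
      if (!en$mncx) mt$j_mncx <- 0 * ca
      j_er_cyt <- fl$j_ip3r + fl$j_cicr + fl$j_leak - fl$j_serca
      j_mt_cyt <- mt$j_mncx - mt$j_mcu
      j_mem <- numeric(n)
      if (en$membrane) {
        j_mem[1] <- membrane_ca_flux(i_ca_nA, geometry$v_cyt[1])
      }
      j_pmca <- numeric(n)
      pm <- NULL
      if (en$pmca) {
        pm <- pmca_step(ca[1], ca_o, st$pump_free, st$pump_bound,
                        list(k1 = p$pmca_k1, k2 = p$pmca_k2,
                             k3 = p$pmca_k3, k4 = p$pmca_k4), h_sub)
        # surface flux (mol/cm2/ms) -> outer-shell concentration rate
        j_pmca[1] <- pm$j_cyt * area_cm2 / (geometry$v_cyt[1] * 1e-15) * 1e3
      }
      # diffusion between adjacent shells (amount conserved)
      rate_diff <- numeric(n)
      if (en$diffusion && n > 1) {
        amt <- d_fac * geometry$area * (ca[-1] - ca[-n]) / geometry$dr
        rate_diff[-n] <- rate_diff[-n] + amt / geometry$v_cyt[-n]
        rate_diff[-1] <- rate_diff[-1] - amt / geometry$v_cyt[-1]
      }
      dca <- (j_mem - j_pmca + j_er_cyt + j_mt_cyt) / divisor + rate_diff
      beta_er <- binding_ratio(p$kb_er, p$btot_er, ca_er)
      dca_er <- (fl$j_serca - fl$j_ip3r - fl$j_cicr - fl$j_leak) / (1 + beta_er)
      beta_mt <- binding_ratio(p$kb_mt, p$btot_mt, ca_mt)
      if (mt_dye) beta_mt <- beta_mt + binding_ratio(dye$kb, dye$btot, ca_mt)
      dca_mt <- (mt$j_mcu - mt$j_mncx) / (1 + beta_mt)
      ca_new <- ca + h_sub * dca
      ca_er_new <- ca_er + h_sub * dca_er
      ca_mt_new <- ca_mt + h_sub * dca_mt
      if (any(ca_new <= 0) || any(ca_er_new <= 0) || any(ca_mt_new <= 0)) {
        ok <- FALSE
        break
      }
      st$ca <- ca_new; st$ca_er <- ca_er_new; st$ca_mt <- ca_mt_new
      st$ip3 <- ip3_step(st$ip3, geometry, h_sub, p)
      st$h <- ip3r_gate_step(st$h, ca, h_sub, p)
      if (!is.null(pm)) {
        st$pump_free <- pm$pump_free
        st$pump_bound <- pm$pump_bound
      }
    }
    if (ok) return(st)
    n_sub <- n_sub * 2L
    if (n_sub > 1024L) {
      abort("Calcium step failed to remain positive even with substepping.",
            class = "drgsoma_step_size_error")
    }
  }
}
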