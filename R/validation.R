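# Single-mechanism validation contexts: each channel is exercised in
# isolation with the geometry, reversal potentials, density and fixed
# near-membrane [Ca]i of its source voltage-clamp recordings, which differ
# from the assembled-model settings.

#' Build a single-mechanism validation model
#'
#' Returns a `soma_model` in which only the named mechanism carries current,
#' configured with its validation-context density, reversal potential(s) and
#' geometry. The shell Ca2+ system is off; clamp it with
#' `ca_fixed` (defaulting to the context value) through the clamp engines.
#'
#' @param name One of `"ttxs"`, `"nav18"`, `"ka"`, `"kdr"`, `"bk"`, `"sk"`,
#'   `"cal"`, `"can"`.
#' @param rectify For `"sk"`: include the inward-rectification gate.
#' @return A list with `model` (the `soma_model`) and `ca_fixed` (mM, the
#'   context's near-membrane \[Ca\]i).
#' @export
validation_model <- function(name, rectify = TRUE) {
  rtf <- 1e3 * .GAS_CONSTANT * (22 + 273.15) / .FARADAY
  base_cond <- ionic_conditions()
  ctx <- switch(
    name,
    ttxs = list(dens = 0.0076, diam = 32.4, cap = 31.7,
                cond = update_conditions(base_cond,
                                         na_o = 10 * exp(38 / rtf)),
                ca = 1.36e-4),
    nav18 = list(dens = 0.0086, diam = 24, cap = 28,
                 cond = update_conditions(base_cond,
                                          na_o = 10 * exp(38 / rtf)),
                 ca = 1.36e-4),
    ka = list(dens = 0.00108, diam = 24, cap = 28, cond = base_cond,
              ca = 1.36e-4),
    kdr = list(dens = 0.00072, diam = 24, cap = 28, cond = base_cond,
               ca = 1.36e-4),
    bk = list(dens = 0.00416, diam = 24, cap = 28, cond = base_cond,
              ca = 1.36e-4),
    sk = list(dens = 0.0051, diam = 24, cap = 28,
              cond = update_conditions(base_cond,
                                       k_o = 140 * exp(-3 / rtf)),
              ca = 0.003),
    cal = list(dens = 0.0113, diam = 24, cap = 28,
               cond = update_conditions(base_cond, ca_o = 0.037),
               ca = 1.36e-4),
    can = list(dens = 0.0113, diam = 24, cap = 28,
               cond = update_conditions(base_cond, ca_o = 0.017),
               ca = 1.36e-4),
    abort(paste0("No validation context for mechanism: ", name),
          class = "drgsoma_unknown_mechanism")
  )
  mech <- default_mechanisms()
  for (nm in names(mech)) {
    mech[[nm]]$density <- 0
  }
  mech[[name]]$density <- ctx$dens
  if (name == "sk") mech$sk$params$rectify <- rectify
  cfg <- soma_config(diameter_um = ctx$diam, capacitance_pF = ctx$cap,
                     conditions = ctx$cond, mechanisms = mech)
  list(model = assemble(cfg), ca_fixed = ctx$ca)
}
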