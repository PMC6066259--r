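# Shared fixtures: calibrated models are expensive enough to build once per
# test run and reuse.

.fixtures <- new.env(parent = emptyenv())

control_model <- function() {
  if (is.null(.fixtures$control)) {
    .fixtures$control <- calibrate_rest(assemble(soma_config()))
  }
  .fixtures$control
}

inflamed_model <- function() {
  if (is.null(.fixtures$inflamed)) {
    .fixtures$inflamed <- inflammation_preset(control_model())
  }
  .fixtures$inflamed
}

# inflamed model with the SK rectification gate removed
inflamed_model_noir <- function() {
  if (is.null(.fixtures$inflamed_noir)) {
    m <- inflamed_model()
    m$config$mechanisms$sk$params$rectify <- FALSE
    .fixtures$inflamed_noir <- calibrate_rest(m)
  }
  .fixtures$inflamed_noir
}
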