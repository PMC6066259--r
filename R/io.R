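# Configuration files, trace persistence and run manifests.

#' Load a model configuration from a YAML file
#'
#' The file may override any subset of the defaults; omitted keys take the
#' package defaults (an empty file yields the full default configuration).
#' Top-level keys: `diameter_um`, `capacitance_pF`, `r_m`, `dt`,
#' `target_rmp`, `conditions` (named concentration/temperature fields),
#' `mechanisms` (name -> `density` and/or `block`), `calcium` (any
#' [calcium_params()] field). Unknown keys are rejected with the list of
#' valid names.
#'
#' @param path Path to a YAML file.
#' @return A [soma_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "drgsoma_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_ok <- c("diameter_um", "capacitance_pF", "r_m", "dt", "target_rmp",
              "conditions", "mechanisms", "calcium")
  bad <- setdiff(names(raw), top_ok)
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", "),
                 ". Valid keys: ", paste(top_ok, collapse = ", ")),
          class = "drgsoma_config_error")
  }
  cond <- ionic_conditions()
  if (!is.null(raw$conditions)) {
    cond <- do.call(update_conditions, c(list(cond), raw$conditions))
  }
  mech_over <- list()
  if (!is.null(raw$mechanisms)) {
    for (nm in names(raw$mechanisms)) {
      if (!nm %in% .MECHANISM_NAMES) {
        abort(paste0("Unknown mechanism '", nm, "'. Valid names: ",
                     paste(.MECHANISM_NAMES, collapse = ", ")),
              class = "drgsoma_unknown_mechanism")
      }
      d <- raw$mechanisms[[nm]]$density
      if (!is.null(d)) mech_over[[nm]] <- d
    }
  }
  mech <- default_mechanisms(mech_over)
  if (!is.null(raw$mechanisms)) {
    for (nm in names(raw$mechanisms)) {
      b <- raw$mechanisms[[nm]]$block
      if (!is.null(b)) mech[[nm]]$block <- b
    }
  }
  cap <- calcium_params()
  if (!is.null(raw$calcium)) {
    bad <- setdiff(names(raw$calcium), names(cap))
    if (length(bad)) {
      abort(paste0("Unknown calcium parameter(s): ",
                   paste(bad, collapse = ", ")),
            class = "drgsoma_config_error")
    }
    cap <- utils::modifyList(cap, raw$calcium)
  }
  args <- list(conditions = cond, mechanisms = mech, calcium = cap)
  for (k in c("diameter_um", "capacitance_pF", "r_m", "dt", "target_rmp")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(soma_config, args)
}

#' Write a trace to CSV
#'
#' Column names carry units (`time_ms`, `vm_mv`, `cai_mM`, ...). Values are
#' written in full precision.
#'
#' @param trace A `drg_trace` tibble (non-empty).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (is.null(trace) || nrow(trace) == 0) {
    abort("Refusing to write an empty trace.", class = "drgsoma_io_error")
  }
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A `drg_trace` tibble.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Trace file not found: ", path), class = "drgsoma_io_error")
  }
  out <- as_tibble(utils::read.csv(path, check.names = FALSE))
  class(out) <- c("drg_trace", class(out))
  out
}

#' Write a trace to a columnar (Parquet) container
#'
#' Lossless binary round trip via the arrow package (a Suggests dependency).
#'
#' @param trace A `drg_trace` tibble (non-empty).
#' @param path Output path (conventionally `.parquet`).
#' @return The path, invisibly.
#' @export
write_trace_parquet <- function(trace, path) {
  if (is.null(trace) || nrow(trace) == 0) {
    abort("Refusing to write an empty trace.", class = "drgsoma_io_error")
  }
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("The arrow package is required for the columnar format.",
          class = "drgsoma_io_error")
  }
  arrow::write_parquet(as.data.frame(trace), path)
  invisible(path)
}

#' Read a columnar trace written by [write_trace_parquet()]
#'
#' @param path Parquet path.
#' @return A `drg_trace` tibble.
#' @export
read_trace_parquet <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("The arrow package is required for the columnar format.",
          class = "drgsoma_io_error")
  }
  out <- as_tibble(arrow::read_parquet(path))
  class(out) <- c("drg_trace", class(out))
  out
}

#' Run manifest
#'
#' Captures everything needed to reproduce a simulation: a hash of the
#' effective configuration, integrator settings, protocol name, package
#' version and step counts. The hash changes if and only if an effective
#' parameter changes.
#'
#' @param model A `soma_model`.
#' @param protocol A [soma_protocol()] (optional).
#' @param outputs Character vector of output paths (optional).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(model, protocol = NULL, outputs = character()) {
  eff <- list(config = model$config, e_pas = model$e_pas,
              area = model$area_cm2,
              protocol = if (is.null(protocol)) NULL else
                protocol[c("stages", "dye", "record_dt")])
  structure(list(
    config_hash = rlang::hash(eff),
    protocol = if (is.null(protocol)) NA_character_ else
      (protocol$name %||% "unnamed"),
    dt_ms = model$config$dt,
    n_mechanisms = length(model$config$mechanisms),
    package_version = as.character(utils::packageVersion("drgsoma")),
    outputs = outputs,
    created = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
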