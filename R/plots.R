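# ggplot2 display methods for traces, I-V tables and gating curves.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal
NULL

#' Plot a simulated trace
#'
#' Shows the membrane potential and, when informative, the outer-shell
#' \[Ca\]i and instantaneous SK conductance as stacked facets.
#'
#' @param object A `drg_trace` tibble.
#' @param vars Columns to display (default `vm_mv`, plus `cai_mM` when it
#'   varies).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drg_trace <- function(object, vars = NULL, ...) {
  if (is.null(vars)) {
    vars <- "vm_mv"
    if ("cai_mM" %in% names(object) &&
        diff(range(object$cai_mM)) > 1e-12) {
      vars <- c(vars, "cai_mM")
    }
  }
  long <- purrr::map_dfr(vars, function(v) {
    tibble(time_ms = object$time_ms, value = object[[v]], signal = v)
  })
  ggplot(long, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' Plot an I-V relationship
#'
#' @param iv A tibble from [extract_iv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_iv <- function(iv, ...) {
  ggplot(iv, aes(x = .data$test_mv, y = .data$current)) +
    geom_line() + geom_point() +
    labs(x = "test potential (mV)", y = "current (mA/cm2)") +
    theme_minimal()
}

#' Plot steady-state and time-constant curves of a channel
#'
#' @param kin A kinetics tibble (e.g. from [ttxs_kinetics()]).
#' @param ... Unused.
#' @return A ggplot object with one facet per gating quantity.
#' @export
plot_kinetics <- function(kin, ...) {
  vars <- setdiff(names(kin), c("vm", "ca_i", "current"))
  long <- purrr::map_dfr(vars, function(v) {
    tibble(vm = kin$vm, value = kin[[v]], quantity = v)
  })
  ggplot(long, aes(x = .data$vm, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "membrane potential (mV)", y = NULL) +
    theme_minimal()
}
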