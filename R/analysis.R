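# Feature extraction and statistics: spike counting, AP/AHP features, I-V
# extraction, Ca2+-transient features and the residual-standard-error
# goodness-of-fit statistic.

#' Count action potentials by upward 0 mV crossings
#'
#' A spike is counted whenever Vm crosses 0 mV from negative to positive. A
#' sample exactly at 0 followed by a positive sample counts once (the
#' crossing is attributed to the interval in which the sign change completes).
#'
#' @param trace A `drg_trace` tibble or numeric Vm vector (mV).
#' @return Integer spike count.
#' @export
count_spikes <- function(trace) {
  vm <- if (is.data.frame(trace)) trace$vm_mv else trace
  if (length(vm) < 2) return(0L)
  # upward crossing: strictly negative sample followed (possibly through
  # zeros) by a strictly positive one
  sgn <- sign(vm)
  nz <- sgn[sgn != 0]
  if (length(nz) < 2) return(0L)
  sum(nz[-1] > 0 & nz[-length(nz)] < 0)
}

#' Action-potential and afterhyperpolarization features
#'
#' Computes the standard feature set from a membrane-potential trace:
#' \itemize{
#' \item RMP: mean Vm over the `rmp_window_ms` just before stimulus onset;
#' \item AP peak and overshoot (maximum Vm above 0 mV);
#' \item AP amplitude: peak - RMP;
#' \item AP duration: half-width, the time between the two crossings of
#'   RMP + amplitude/2;
#' \item AHP peak: minimum Vm after the (first) spike peak; AHP amplitude:
#'   RMP - AHP peak (or baseline - AHP peak, see `ahp_reference`);
#' \item time to AHP peak, measured from the AHP start (the downward crossing
#'   of the reference level after the spike peak);
#' \item AHP 80% recovery time: from AHP start until Vm has recovered 80% of
#'   the AHP amplitude after the AHP peak.
#' }
#'
#' Two AHP reference conventions are provided: `"rmp"` measures the trough
#' against the pre-stimulus RMP; `"stim"` measures it within and against the
#' during-stimulus depolarized baseline (the convention that matches reported
#' troughs lying above RMP for long stimuli). The default `"rmp"` applies to
#' brief stimuli where the AHP develops after stimulus offset.
#'
#' @param trace A `drg_trace` tibble with `time_ms`, `vm_mv`.
#' @param stim_window Two-element `(on, off)` ms; defaults to the trace
#'   attribute.
#' @param rmp_window_ms Pre-stimulus window for the RMP (default 5 ms).
#' @param ahp_reference `"rmp"` or `"stim"` (see Details).
#' @return A one-row tibble: `rmp_mv`, `n_spikes`, `peak_mv`, `overshoot_mv`,
#'   `amplitude_mv`, `duration_ms`, `ahp_peak_mv`, `ahp_amplitude_mv`,
#'   `time_to_ahp_peak_ms`, `ahp80_ms`. Spike features are NA when no spike
#'   is present.
#' @export
extract_ap_features <- function(trace, stim_window = attr(trace, "stim_window"),
                                rmp_window_ms = 5, ahp_reference = c("rmp", "stim")) {
  ahp_reference <- match.arg(ahp_reference)
  if (is.null(stim_window)) {
    abort("stim_window is required (none stored on the trace).",
          class = "drgsoma_invalid_input")
  }
  t <- trace$time_ms; v <- trace$vm_mv
  on <- stim_window[1]; off <- stim_window[2]
  pre <- v[t >= on - rmp_window_ms & t < on]
  rmp <- if (length(pre)) mean(pre) else v[1]
  n_sp <- count_spikes(v[t >= on])
  out <- tibble(rmp_mv = rmp, n_spikes = n_sp, peak_mv = NA_real_,
                overshoot_mv = NA_real_, amplitude_mv = NA_real_,
                duration_ms = NA_real_, ahp_peak_mv = NA_real_,
                ahp_amplitude_mv = NA_real_, time_to_ahp_peak_ms = NA_real_,
                ahp80_ms = NA_real_)
  if (n_sp == 0) return(out)
  sel <- t >= on
  tv <- t[sel]; vv <- v[sel]
  ip <- which.max(vv)
  peak <- vv[ip]
  out$peak_mv <- peak
  out$overshoot_mv <- if (peak > 0) peak else NA_real_
  out$amplitude_mv <- peak - rmp
  half <- rmp + (peak - rmp) / 2
  # half-width: crossings of the half level around the first peak
  iup <- which(vv[-1] >= half & vv[-length(vv)] < half)
  iup <- iup[iup < ip]
  idn <- which(vv[-1] < half & vv[-length(vv)] >= half)
  idn <- idn[idn >= ip]
  if (length(iup) && length(idn)) {
    i1 <- max(iup); i2 <- min(idn)
    tcross <- function(i, level) {
      tv[i] + (level - vv[i]) / (vv[i + 1] - vv[i]) * (tv[i + 1] - tv[i])
    }
    out$duration_ms <- tcross(i2, half) - tcross(i1, half)
  }
  # AHP: after the first spike peak
  ref <- if (ahp_reference == "rmp") rmp else {
    # depolarized baseline late in the stimulus, before the next spike
    mean(vv[tv > off - min(5, (off - on) / 4) & tv <= off])
  }
  post <- which(seq_along(vv) > ip)
  if (length(post)) {
    # AHP start: first downward crossing of the reference level after peak
    istart <- post[which(vv[post] <= ref)[1]]
    end_idx <- length(vv)
    if (n_sp > 1) {
      # confine to the interval before the next upward 0-crossing
      nxt <- post[which(vv[post - 1] < 0 & vv[post] >= 0)]
      nxt <- nxt[nxt > ip + 2]
      if (length(nxt)) end_idx <- nxt[1] - 1
    }
    seg <- seq_len(end_idx)
    seg <- seg[seg > ip]
    imin <- seg[which.min(vv[seg])]
    out$ahp_peak_mv <- vv[imin]
    out$ahp_amplitude_mv <- ref - vv[imin]
    if (!is.na(istart) && length(istart) && imin > istart) {
      out$time_to_ahp_peak_ms <- tv[imin] - tv[istart]
      # 80% recovery after the AHP peak
      target <- vv[imin] + 0.8 * (ref - vv[imin])
      after <- seq(imin, end_idx)
      irec <- after[which(vv[after] >= target)[1]]
      if (!is.na(irec) && length(irec)) {
        out$ahp80_ms <- tv[irec] - tv[istart]
      }
    }
  }
  out
}

#' Extract an I-V table from a family of clamp traces
#'
#' @param traces Long tibble from [voltage_clamp_step()] (a `test_mv` column
#'   plus a current column).
#' @param current Name of the current column (e.g. `"i_nav18"`).
#' @param mode `"peak"` (extremum by absolute value within the test window)
#'   or `"steady"` (mean over the final 5% of the window).
#' @param window Two-element `(start, end)` ms of the test step; defaults to
#'   the stored stimulus window.
#' @return A tibble `test_mv`, `current`.
#' @export
extract_iv <- function(traces, current, mode = c("peak", "steady"),
                       window = attr(traces, "stim_window")) {
  mode <- match.arg(mode)
  if (is.null(window)) {
    abort("No test window available.", class = "drgsoma_invalid_input")
  }
  sub <- traces[traces$time_ms > window[1] & traces$time_ms <= window[2], ]
  if (nrow(sub) == 0) {
    abort("Empty clamp window.", class = "drgsoma_invalid_input")
  }
  dplyr::summarise(
    dplyr::group_by(sub, .data$test_mv),
    current = if (mode == "peak") {
      .data[[current]][which.max(abs(.data[[current]]))]
    } else {
      w <- .data$time_ms >= window[1] + 0.95 * (window[2] - window[1])
      mean(.data[[current]][w])
    },
    .groups = "drop"
  )
}

#' Residual standard error goodness-of-fit (S statistic)
#'
#' \eqn{S = \sqrt{\sum (Y_{expt} - Y_{fit})^2 / v}} with residual degrees of
#' freedom \eqn{v = n - n_{params}}. Following the convention of the source
#' analyses, S is not computed when v < 4 (returns NA with a warning).
#'
#' @param y_expt,y_fit Equal-length numeric series.
#' @param n_params Number of fitted parameters (1 for direct trace
#'   comparisons).
#' @return S (same units as the series), or NA if v < 4.
#' @export
s_statistic <- function(y_expt, y_fit, n_params = 1) {
  if (length(y_expt) != length(y_fit)) {
    abort("Series lengths differ.", class = "drgsoma_invalid_input")
  }
  v <- length(y_expt) - n_params
  if (v < 4) {
    warn("Residual degrees of freedom < 4; S not computed.")
    return(NA_real_)
  }
  sqrt(sum((y_expt - y_fit)^2) / v)
}

#' Ca2+-transient features
#'
#' @param trace A `drg_trace` tibble (uses `cai_mM` by default).
#' @param baseline_window Two-element `(start, end)` ms over which the
#'   baseline is averaged.
#' @param value Column to analyse (default `"cai_mM"`).
#' @param decay_frac Recovery fraction defining the decay time (default 0.2:
#'   time from peak until the transient has decayed to baseline + 20% of the
#'   peak elevation, i.e. 80% recovered).
#' @return A one-row tibble: `baseline`, `peak`, `delta`, `time_to_peak_ms`,
#'   `decay_ms` (NA if the trace does not recover within the record).
#' @export
transient_features <- function(trace, baseline_window, value = "cai_mM",
                               decay_frac = 0.2) {
  t <- trace$time_ms
  y <- trace[[value]]
  sel <- t >= baseline_window[1] & t <= baseline_window[2]
  if (!any(sel)) {
    abort("Baseline window outside the trace.", class = "drgsoma_invalid_input")
  }
  base <- mean(y[sel])
  after <- t > baseline_window[2]
  ta <- t[after]; ya <- y[after]
  ip <- which.max(ya)
  peak <- ya[ip]
  delta <- peak - base
  decay <- NA_real_
  if (delta > 0) {
    target <- base + decay_frac * delta
    rest <- seq(ip, length(ya))
    idn <- rest[which(ya[rest] <= target)[1]]
    if (!is.na(idn) && length(idn)) decay <- ta[idn] - ta[ip]
  }
  tibble(baseline = base, peak = peak, delta = delta,
         time_to_peak_ms = ta[ip] - baseline_window[2], decay_ms = decay)
}

#' Tidy a drg_trace (no-op passthrough returning the tibble)
#'
#' @param x A `drg_trace`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.drg_trace <- function(x, ...) {
  class(x) <- setdiff(class(x), "drg_trace")
  as_tibble(x)
}

#' One-row summary of a trace
#'
#' @param x A `drg_trace`.
#' @param ... Unused.
#' @return Tibble with duration, sampling, spike count, Vm and \[Ca\]i ranges.
#' @export
glance.drg_trace <- function(x, ...) {
  tibble(duration_ms = max(x$time_ms) - min(x$time_ms),
         n_samples = nrow(x),
         n_spikes = count_spikes(x),
         vm_min_mv = min(x$vm_mv), vm_max_mv = max(x$vm_mv),
         cai_max_mM = max(x$cai_mM))
}
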