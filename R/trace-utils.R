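#' Voltage derivative of a sweep
#'
#' Central-difference derivative `(v[k+1] - v[k-1]) / (2 dt)` at interior
#' samples and one-sided differences at the two edges.  With voltage in
#' mV and time in ms the result is in mV/ms, which is numerically equal
#' to V/s — the unit in which the 20 V/s firing-threshold criterion is
#' stated.
#'
#' @param sweep A [sweep_trace()] object (at least 3 samples).
#' @return Numeric vector of dV/dt values (V/s), same length as `sweep$v`.
#' @export
trace_derivative <- function(sweep) {
  v <- sweep$v
  n <- length(v)
  if (n < 3L)
    cp_stop("derivative needs at least 3 samples", "cp_insufficient_data")
  dt <- sweep$dt
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  d
}

#' Pre-step baseline voltage
#'
#' Mean voltage over the `window_ms` immediately preceding the step
#' onset; the reference against which step deflections are measured.
#'
#' @param sweep A [sweep_trace()] object.
#' @param window_ms Averaging window (ms); must fit between the trace
#'   start and the step onset.
#' @return Baseline voltage (mV).
#' @export
trace_baseline <- function(sweep, window_ms = 50) {
  if (window_ms <= 0)
    cp_stop("'window_ms' must be positive", "cp_format_error")
  if (sweep$step_onset - window_ms < sweep$t0 - sweep$dt / 2)
    cp_stop("baseline window extends before the start of the trace",
            "cp_insufficient_data")
  t <- sweep_times(sweep)
  sel <- t >= sweep$step_onset - window_ms & t < sweep$step_onset
  if (!any(sel))
    cp_stop("no samples in the baseline window", "cp_insufficient_data")
  mean(sweep$v[sel])
}
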