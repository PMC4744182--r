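#' Construct a single current-clamp sweep
#'
#' A sweep is one membrane-voltage trace recorded while a square current
#' step is injected.  Time is measured in ms from the first sample
#' (`t0 = 0` by convention), voltage in mV, current in pA.
#'
#' @param v Numeric vector of voltage samples (mV), at least 2.
#' @param dt Sampling interval (ms), positive.
#' @param i_step Injected step current (pA).
#' @param step_onset,step_offset Step start/end (ms from `t0`); the step
#'   window must lie within the sampled interval.
#' @param t0 Time of the first sample (ms); defaults to 0.
#' @return An object of class `cp_sweep`.
#' @examples
#' sw <- sweep_trace(rep(-67, 100), dt = 0.1, i_step = -200,
#'                   step_onset = 2, step_offset = 8)
#' sw
#' @export
sweep_trace <- function(v, dt, i_step, step_onset, step_offset, t0 = 0) {
  if (!is.numeric(v) || length(v) < 2L || anyNA(v))
    cp_stop("'v' must be a numeric vector with at least 2 finite samples",
            "cp_format_error")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    cp_stop("'dt' must be a single positive number (ms)", "cp_format_error")
  if (!is.numeric(i_step) || length(i_step) != 1L || !is.finite(i_step))
    cp_stop("'i_step' must be a single finite number (pA)", "cp_format_error")
  if (!is.finite(step_onset) || !is.finite(step_offset) ||
      step_onset >= step_offset)
    cp_stop("'step_onset' must be earlier than 'step_offset'",
            "cp_format_error")
  t_end <- t0 + (length(v) - 1L) * dt
  if (step_onset < t0 || step_offset > t_end + dt / 2)
    cp_stop(sprintf(
      "step window [%g, %g] ms must lie within the sampled interval [%g, %g]",
      step_onset, step_offset, t0, t_end), "cp_format_error")
  structure(
    list(v = as.numeric(v), dt = dt, i_step = i_step,
         step_onset = step_onset, step_offset = step_offset, t0 = t0),
    class = "cp_sweep")
}

#' Sample times of a sweep
#'
#' @param sweep A [sweep_trace()] object.
#' @return Numeric vector of sample times (ms), same length as `sweep$v`.
#' @export
sweep_times <- function(sweep) {
  sweep$t0 + (seq_along(sweep$v) - 1L) * sweep$dt
}

#' @export
print.cp_sweep <- function(x, ...) {
  cat(sprintf(
    "<cp_sweep> %d samples @ dt=%g ms, i_step=%g pA, step [%g, %g] ms\n",
    length(x$v), x$dt, x$i_step, x$step_onset, x$step_offset))
  invisible(x)
}

#' Construct a sweep set
#'
#' A sweep set is one cell's family of voltage responses to a ladder of
#' current steps recorded under a single protocol: `"passive_500ms"`
#' (hyperpolarizing to small depolarizing 500 ms steps, used for input
#' resistance and sag) or `"firing_2s"` (2 s depolarizing steps in fixed
#' increments, used for spike analysis).
#'
#' @param cell_id Character cell identifier.
#' @param protocol `"passive_500ms"` or `"firing_2s"`.
#' @param sweeps List of [sweep_trace()] objects sharing `dt`,
#'   `step_onset`, `step_offset` and trace length, with unique `i_step`.
#' @param holding_v Nominal holding potential (mV).
#' @return An object of class `cp_sweep_set`.
#' @export
sweep_set <- function(cell_id, protocol = c("passive_500ms", "firing_2s"),
                      sweeps, holding_v = -67) {
  protocol <- match.arg(protocol)
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id))
    cp_stop("'cell_id' must be a non-empty string", "cp_format_error")
  if (!is.list(sweeps) || length(sweeps) == 0L)
    cp_stop("'sweeps' must be a non-empty list of sweeps", "cp_format_error")
  if (!all(vapply(sweeps, inherits, logical(1), "cp_sweep")))
    cp_stop("all elements of 'sweeps' must be cp_sweep objects",
            "cp_format_error")
  first <- sweeps[[1L]]
  same <- function(f) all(vapply(sweeps, function(s) isTRUE(all.equal(
    s[[f]], first[[f]])), logical(1)))
  for (f in c("dt", "step_onset", "step_offset", "t0"))
    if (!same(f))
      cp_stop(sprintf("all sweeps must share '%s'", f), "cp_format_error")
  if (length(unique(vapply(sweeps, function(s) length(s$v), integer(1)))) != 1L)
    cp_stop("all sweeps must have the same number of samples",
            "cp_format_error")
  cur <- vapply(sweeps, `[[`, numeric(1), "i_step")
  if (anyDuplicated(cur))
    cp_stop(sprintf("duplicate i_step values: %s",
                    paste(cur[duplicated(cur)], collapse = ", ")),
            "cp_format_error")
  sweeps <- sweeps[order(cur)]
  structure(
    list(cell_id = cell_id, protocol = protocol, sweeps = sweeps,
         holding_v = holding_v),
    class = "cp_sweep_set")
}

#' Injected currents of a sweep set
#' @param s A [sweep_set()] object.
#' @return Numeric vector of `i_step` values (pA), in sweep order.
#' @export
sweep_currents <- function(s) {
  vapply(s$sweeps, `[[`, numeric(1), "i_step")
}

#' @export
print.cp_sweep_set <- function(x, ...) {
  cur <- sweep_currents(x)
  cat(sprintf("<cp_sweep_set> cell '%s', protocol %s\n", x$cell_id,
              x$protocol))
  cat(sprintf("  %d sweeps, dt=%g ms, step [%g, %g] ms, holding %g mV\n",
              length(x$sweeps), x$sweeps[[1L]]$dt, x$sweeps[[1L]]$step_onset,
              x$sweeps[[1L]]$step_offset, x$holding_v))
  cat(sprintf("  currents (pA): %s\n", paste(cur, collapse = ", ")))
  invisible(x)
}

#' @export
plot.cp_sweep_set <- function(x, ...) {
  t <- sweep_times(x$sweeps[[1L]])
  vr <- range(vapply(x$sweeps, function(s) range(s$v),
                     numeric(2)))
  graphics::plot(NA, xlim = range(t), ylim = vr, xlab = "time (ms)",
                 ylab = "V (mV)", main = x$cell_id, ...)
  for (s in x$sweeps) graphics::lines(t, s$v, col = "grey25")
  graphics::abline(v = c(x$sweeps[[1L]]$step_onset,
                         x$sweeps[[1L]]$step_offset), lty = 3)
  invisible(x)
}
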