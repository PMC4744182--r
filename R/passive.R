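#' Peak and steady-state deflection of a passive sweep
#'
#' The peak is the extremum of the voltage within the step window in the
#' direction of the injected current (minimum for hyperpolarizing steps,
#' maximum for depolarizing ones), restricted to the first
#' `peak_window_ms` of the step so that late rebound artifacts are
#' ignored.  The steady state is the mean voltage over the last
#' `ss_frac` of the step.  A light centred boxcar (`smooth_ms`) is
#' applied to the trace for the peak search only, so that the extremum
#' estimate is not dominated by the expected extreme value of the
#' sampling noise; `smooth_ms = 0` searches the raw samples.
#'
#' @param sweep A passive-protocol [sweep_trace()].
#' @param peak_window_ms Peak search window from step onset (ms).
#' @param ss_frac Fraction of the step used for the steady-state mean.
#' @param smooth_ms Boxcar width for the peak search (ms); 0 disables.
#' @return List with `v_peak` (mV), `t_peak` (ms from step onset) and
#'   `v_ss` (mV).
#' @export
step_extrema <- function(sweep, peak_window_ms = 250, ss_frac = 0.1,
                         smooth_ms = 3) {
  t <- sweep_times(sweep)
  on <- sweep$step_onset
  off <- sweep$step_offset
  in_step <- t >= on & t < off
  if (!any(in_step))
    cp_stop("no samples inside the step window", "cp_insufficient_data")
  pk_sel <- which(in_step & t <= min(on + peak_window_ms, off))
  vs <- if (smooth_ms > 0)
    moving_average(sweep$v, round(smooth_ms / sweep$dt)) else sweep$v
  dir <- sign(sweep$i_step)
  if (dir == 0) {
    base <- trace_baseline(sweep)
    k <- pk_sel[which.max(abs(vs[pk_sel] - base))]
  } else if (dir < 0) {
    k <- pk_sel[which.min(vs[pk_sel])]
  } else {
    k <- pk_sel[which.max(vs[pk_sel])]
  }
  ss_sel <- in_step & t >= off - ss_frac * (off - on)
  list(v_peak = vs[k], t_peak = t[k] - on, v_ss = mean(sweep$v[ss_sel]))
}

#' Build I-V curves from a passive sweep set
#'
#' Assembles per-sweep [step_extrema()] into peak and steady-state I-V
#' curves, sorted by injected current.  Sweeps containing detected
#' action potentials are excluded, since spike deflections corrupt the
#' slope estimate.
#'
#' @param s A passive [sweep_set()].
#' @param exclude_spiking Drop sweeps with detected spikes (default TRUE).
#' @inheritParams step_extrema
#' @param ... Passed on to [detect_spikes()].
#' @return A `cp_iv` data frame with columns `i`, `v_peak`, `v_ss`,
#'   `t_peak`.
#' @export
build_iv_curves <- function(s, peak_window_ms = 250, ss_frac = 0.1,
                            smooth_ms = 3, exclude_spiking = TRUE, ...) {
  if (!inherits(s, "cp_sweep_set"))
    cp_stop("'s' must be a cp_sweep_set", "cp_format_error")
  keep <- rep(TRUE, length(s$sweeps))
  if (exclude_spiking)
    keep <- vapply(s$sweeps, function(sw)
      nrow(detect_spikes(sw, ...)) == 0L, logical(1))
  if (sum(keep) < 2L)
    cp_stop("fewer than 2 spike-free sweeps: cannot build an I-V curve",
            "cp_insufficient_data")
  ex <- lapply(s$sweeps[keep], step_extrema, peak_window_ms = peak_window_ms,
               ss_frac = ss_frac, smooth_ms = smooth_ms)
  iv <- data.frame(i = sweep_currents(s)[keep],
                   v_peak = vapply(ex, `[[`, numeric(1), "v_peak"),
                   v_ss = vapply(ex, `[[`, numeric(1), "v_ss"),
                   t_peak = vapply(ex, `[[`, numeric(1), "t_peak"))
  iv <- iv[order(iv$i), , drop = FALSE]
  rownames(iv) <- NULL
  class(iv) <- c("cp_iv", "data.frame")
  iv
}

#' @export
plot.cp_iv <- function(x, ...) {
  graphics::plot(x$i, x$v_peak, pch = 19, xlab = "I (pA)", ylab = "V (mV)",
                 ...)
  graphics::points(x$i, x$v_ss, pch = 1)
  graphics::legend("topleft", pch = c(19, 1), bty = "n",
                   legend = c("peak", "steady state"))
  invisible(x)
}

#' Input resistances from an I-V curve
#'
#' Ordinary least-squares slopes of `v_peak` vs `i` and `v_ss` vs `i`,
#' converted from mV/pA to megaohms (x 1000).  The peak slope is the
#' input resistance at peak (Rpeak), the steady-state slope Rss.
#'
#' @param iv A [build_iv_curves()] result (>= 2 points).
#' @return List with `r_peak` and `r_ss` (megaohms).
#' @export
input_resistances <- function(iv) {
  if (nrow(iv) < 2L)
    cp_stop("need at least 2 I-V points", "cp_insufficient_data")
  if (stats::var(iv$i) == 0)
    cp_stop("degenerate I-V curve: all currents equal", "cp_degenerate")
  slope <- function(y) stats::cov(iv$i, y) / stats::var(iv$i)
  r_peak <- slope(iv$v_peak) * 1000
  r_ss <- slope(iv$v_ss) * 1000
  if (r_peak <= 0 || r_ss <= 0)
    cp_warn("non-positive fitted input resistance (degenerate fit)",
            "cp_degenerate_fit")
  list(r_peak = r_peak, r_ss = r_ss)
}

#' Sag amplitude at -200 pA
#'
#' Difference between the steady-state and peak voltage of the -200 pA
#' sweep (`v_ss - v_peak`); positive when a sag — the Ih-like transient
#' hyperpolarization overshoot — is present.
#'
#' @param s A passive [sweep_set()] containing a -200 pA sweep.
#' @param target_i Current defining the sag sweep (pA, default -200).
#' @param tol_pA Matching tolerance for `target_i` (default 1 pA).
#' @inheritParams step_extrema
#' @return Sag amplitude (mV).
#' @export
sag <- function(s, target_i = -200, tol_pA = 1, peak_window_ms = 250,
                ss_frac = 0.1, smooth_ms = 3) {
  cur <- sweep_currents(s)
  j <- which(abs(cur - target_i) <= tol_pA)
  if (length(j) == 0L)
    cp_stop(sprintf("no %g pA sweep; available currents: %s", target_i,
                    paste(cur, collapse = ", ")), "cp_insufficient_data")
  ex <- step_extrema(s$sweeps[[j[1L]]], peak_window_ms = peak_window_ms,
                     ss_frac = ss_frac, smooth_ms = smooth_ms)
  ex$v_ss - ex$v_peak
}

#' Passive membrane properties of a cell
#'
#' One-call summary of the 500 ms step protocol: the I-V curves, the
#' input resistances at peak and steady state, the sag and the time to
#' peak at -200 pA.
#'
#' @inheritParams build_iv_curves
#' @inheritParams sag
#' @return An object of class `cp_passive` with fields `r_peak`, `r_ss`
#'   (megaohms), `sag`, `t_peak_200` (ms), and the `iv` table.
#' @examples
#' p <- passive_sim_params(r_m = 100, sag_frac = 0.15, noise_rms = 0)
#' s <- simulate_passive_sweeps(p)
#' passive_properties(s)
#' @export
passive_properties <- function(s, peak_window_ms = 250, ss_frac = 0.1,
                               smooth_ms = 3, target_i = -200, tol_pA = 1) {
  iv <- build_iv_curves(s, peak_window_ms = peak_window_ms,
                        ss_frac = ss_frac, smooth_ms = smooth_ms)
  r <- input_resistances(iv)
  cur <- sweep_currents(s)
  j <- which(abs(cur - target_i) <= tol_pA)
  sg <- if (length(j)) sag(s, target_i, tol_pA, peak_window_ms, ss_frac,
                           smooth_ms) else NA_real_
  tp <- if (length(j)) step_extrema(s$sweeps[[j[1L]]], peak_window_ms,
                                    ss_frac, smooth_ms)$t_peak else NA_real_
  structure(list(cell_id = s$cell_id, r_peak = r$r_peak, r_ss = r$r_ss,
                 sag = sg, t_peak_200 = tp, iv = iv),
            class = "cp_passive")
}

#' @export
print.cp_passive <- function(x, ...) {
  cat(sprintf("<cp_passive> cell '%s'\n", x$cell_id))
  cat(sprintf("  Rpeak = %.1f MOhm, Rss = %.1f MOhm\n", x$r_peak, x$r_ss))
  cat(sprintf("  sag at -200 pA = %.2f mV, time to peak = %.1f ms\n",
              x$sag, x$t_peak_200))
  cat(sprintf("  I-V curve: %d points, %g..%g pA\n", nrow(x$iv),
              min(x$iv$i), max(x$iv$i)))
  invisible(x)
}
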