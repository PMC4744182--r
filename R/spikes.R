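#' Detect action potentials in a firing sweep
#'
#' Local voltage maxima above `detect_level` whose upstroke (maximum
#' dV/dt over the `pre_window_ms` preceding the peak) exceeds
#' `thr_slope`, separated by at least `refractory_ms`.  The criteria are
#' deliberately weaker than any textbook action potential; they identify
#' candidate spikes, the 20 V/s threshold rule then localizes each
#' spike's firing threshold.
#'
#' @param sweep A firing-protocol [sweep_trace()].
#' @param detect_level Minimum peak voltage (mV, default 0).
#' @param thr_slope Minimum preceding upstroke slope (V/s, default 20).
#' @param refractory_ms Minimum peak separation (ms, default 1).
#' @param pre_window_ms Upstroke look-back window (ms, default 5).
#' @return Data frame with one row per spike: `idx` (sample index),
#'   `t_peak` (ms), `v_peak` (mV).  Zero rows when nothing fires.
#' @export
detect_spikes <- function(sweep, detect_level = 0, thr_slope = 20,
                          refractory_ms = 1, pre_window_ms = 5) {
  v <- sweep$v
  n <- length(v)
  empty <- data.frame(idx = integer(0), t_peak = numeric(0),
                      v_peak = numeric(0))
  if (n < 3L) return(empty)
  cand <- which(v[2:(n - 1L)] >= v[1:(n - 2L)] &
                v[2:(n - 1L)] > v[3:n] &
                v[2:(n - 1L)] > detect_level) + 1L
  if (length(cand) == 0L) return(empty)
  dv <- trace_derivative(sweep)
  pre <- max(1L, round(pre_window_ms / sweep$dt))
  ok <- vapply(cand, function(k) {
    lo <- max(1L, k - pre)
    max(dv[lo:k]) > thr_slope
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L) return(empty)
  t <- sweep_times(sweep)
  keep <- integer(0)
  last_t <- -Inf
  for (k in cand) {
    if (t[k] - last_t >= refractory_ms) {
      keep <- c(keep, k)
      last_t <- t[k]
    }
  }
  data.frame(idx = keep, t_peak = t[keep], v_peak = v[keep])
}

#' Interpolated firing threshold of one spike
#'
#' The firing threshold is the membrane potential at which dV/dt first
#' reaches `thr_slope` (20 V/s) on the spike upstroke.  Scanning
#' backward from the peak, the last sample pair `(k, k+1)` with
#' `dV/dt[k] < thr_slope <= dV/dt[k+1]` brackets the crossing; the
#' crossing fraction `f = (thr_slope - d[k]) / (d[k+1] - d[k])` is then
#' applied linearly to time and voltage.
#'
#' @param sweep The [sweep_trace()] containing the spike.
#' @param peak_idx Sample index of the spike peak.
#' @param thr_slope Threshold slope (V/s, default 20).
#' @return List with `t_thr` (ms) and `v_thr` (mV).
#' @export
interpolate_threshold <- function(sweep, peak_idx, thr_slope = 20) {
  dv <- trace_derivative(sweep)
  v <- sweep$v
  t <- sweep_times(sweep)
  k <- peak_idx - 1L
  while (k >= 1L && dv[k] >= thr_slope) k <- k - 1L
  if (k < 1L || k >= peak_idx)
    cp_stop("dV/dt never falls below the threshold slope before the peak (truncated upstroke)",
            "cp_undefined_threshold")
  f <- (thr_slope - dv[k]) / (dv[k + 1L] - dv[k])
  list(t_thr = t[k] + f * sweep$dt,
       v_thr = v[k] + f * (v[k + 1L] - v[k]))
}

# interpolated time at which v crosses `level` going up (dir = 1) or down
# (dir = -1), searching samples in [from, to]; NA when no crossing
interp_crossing <- function(sweep, level, from, to, dir = 1L) {
  v <- sweep$v
  t <- sweep_times(sweep)
  from <- max(1L, from)
  to <- min(length(v), to)
  if (to <= from) return(NA_real_)
  ks <- from:(to - 1L)
  hit <- if (dir > 0) v[ks] <= level & v[ks + 1L] > level
         else v[ks] > level & v[ks + 1L] <= level
  if (!any(hit)) return(NA_real_)
  k <- ks[which(hit)[1L]]
  if (v[k + 1L] == v[k]) return(t[k])
  t[k] + (level - v[k]) / (v[k + 1L] - v[k]) * sweep$dt
}

#' Waveform features of one action potential
#'
#' With the firing threshold as baseline: `amplitude` is peak minus
#' threshold voltage; `half_width` the time between the interpolated
#' upward and downward crossings of the half-amplitude level;
#' `duration` the time from the threshold to the interpolated return of
#' the voltage to the threshold level after the peak; `rise_time` the
#' time between the interpolated 10% and 90% amplitude crossings on the
#' upstroke.  A duration whose downward return lies beyond `search_end`
#' (trace end or the next spike) is returned as `NA`.
#'
#' @param sweep The [sweep_trace()] containing the spike.
#' @param peak_idx Sample index of the spike peak.
#' @param v_thr Interpolated threshold voltage (mV), see
#'   [interpolate_threshold()].
#' @param t_thr Interpolated threshold time (ms).
#' @param search_end Last sample index considered for the downward
#'   crossings (default: end of trace).
#' @return List with `amplitude` (mV), `half_width`, `duration`,
#'   `rise_time` (ms).
#' @export
ap_waveform_features <- function(sweep, peak_idx, v_thr, t_thr,
                                 search_end = length(sweep$v)) {
  v <- sweep$v
  amp <- v[peak_idx] - v_thr
  if (amp <= 0)
    cp_stop("non-positive amplitude: peak below threshold",
            "cp_undefined_feature")
  k_thr <- max(1L, floor((t_thr - sweep$t0) / sweep$dt) + 1L)
  lvl <- function(frac) v_thr + frac * amp
  up <- function(frac) interp_crossing(sweep, lvl(frac), k_thr, peak_idx, 1L)
  dn <- function(frac) interp_crossing(sweep, lvl(frac), peak_idx,
                                       search_end, -1L)
  t_half_up <- up(0.5)
  t_half_dn <- dn(0.5)
  t_ret <- dn(0)
  t10 <- up(0.1)
  t90 <- up(0.9)
  list(amplitude = amp,
       half_width = if (is.na(t_half_up) || is.na(t_half_dn)) NA_real_
                    else t_half_dn - t_half_up,
       duration = if (is.na(t_ret)) NA_real_ else t_ret - t_thr,
       rise_time = if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10)
}

#' Fast afterpotentials of one spike
#'
#' The fast afterhyperpolarization (fAHP) is the difference between the
#' firing threshold and the minimum voltage within `fahp_window_ms`
#' (3 ms) after the spike peak; `t_fahp` is the time from the peak to
#' that minimum.  The fast depolarizing afterpotential (fDAP) is the
#' difference between the maximum voltage within `fdap_window_ms` (5 ms)
#' after the fAHP minimum and that minimum; inside a doublet/triplet the
#' maximum is replaced by the threshold of the following spike
#' (`next_v_thr`).  Windows truncated by the end of the trace yield
#' `NA`, never silent zeros.
#'
#' @param sweep The [sweep_trace()] containing the spike.
#' @param peak_idx Sample index of the spike peak.
#' @param v_thr Firing threshold of this spike (mV).
#' @param next_v_thr Threshold of the next spike in the same burst, or
#'   `NULL` for the last/only spike.
#' @param fahp_window_ms,fdap_window_ms Search windows (ms).
#' @return List with `fahp`, `t_fahp`, `fdap` (`fahp`/`fdap` in mV,
#'   positive magnitudes; `t_fahp` in ms).
#' @export
fast_afterpotentials <- function(sweep, peak_idx, v_thr, next_v_thr = NULL,
                                 fahp_window_ms = 3, fdap_window_ms = 5) {
  w <- window_extremum(sweep, peak_idx, fahp_window_ms, "min")
  if (is.null(w))
    return(list(fahp = NA_real_, t_fahp = NA_real_, fdap = NA_real_))
  t <- sweep_times(sweep)
  fahp <- v_thr - w$value
  t_fahp <- w$t - t[peak_idx]
  if (!is.null(next_v_thr)) {
    fdap <- next_v_thr - w$value
  } else {
    w2 <- window_extremum(sweep, w$idx, fdap_window_ms, "max")
    fdap <- if (is.null(w2)) NA_real_ else w2$value - w$value
  }
  list(fahp = fahp, t_fahp = t_fahp, fdap = fdap)
}

#' Medium afterpotentials after a spike or burst
#'
#' The medium AHP (mAHP) is the difference between the firing threshold
#' of the (last) spike and the minimum voltage within `mahp_window_ms`
#' (50 ms) after its peak; the medium DAP (mDAP) the difference between
#' the maximum within `mdap_window_ms` (70 ms) after that minimum and
#' the minimum itself.  For a doublet/triplet both windows are anchored
#' on the last spike of the burst.
#'
#' @param sweep The [sweep_trace()].
#' @param last_peak_idx Sample index of the (last) spike peak.
#' @param v_thr Firing threshold of that spike (mV).
#' @param mahp_window_ms,mdap_window_ms Search windows (ms).
#' @return List with `mahp` and `mdap` (mV, positive magnitudes; `NA`
#'   when a window is truncated by the trace end).
#' @export
medium_afterpotentials <- function(sweep, last_peak_idx, v_thr,
                                   mahp_window_ms = 50, mdap_window_ms = 70) {
  w <- window_extremum(sweep, last_peak_idx, mahp_window_ms, "min")
  if (is.null(w)) return(list(mahp = NA_real_, mdap = NA_real_))
  w2 <- window_extremum(sweep, w$idx, mdap_window_ms, "max")
  list(mahp = v_thr - w$value,
       mdap = if (is.null(w2)) NA_real_ else w2$value - w$value)
}

# extremum of v over (t[anchor], t[anchor] + window_ms]; NULL when the
# window is truncated by the end of the trace
window_extremum <- function(sweep, anchor_idx, window_ms, what = "min") {
  t <- sweep_times(sweep)
  n <- length(t)
  t_end <- t[anchor_idx] + window_ms
  if (t_end > t[n] + sweep$dt / 2) return(NULL)
  sel <- which(t > t[anchor_idx] & t <= t_end + sweep$dt / 1e6)
  if (length(sel) == 0L) return(NULL)
  k <- if (what == "min") sel[which.min(sweep$v[sel])]
       else sel[which.max(sweep$v[sel])]
  list(idx = k, t = t[k], value = sweep$v[k])
}

#' Group spikes into doublet/triplet bursts
#'
#' Greedy left-to-right grouping: a spike joins the current burst when
#' its interspike interval to the previous spike is at most
#' `burst_isi_max` and the burst has fewer than 3 members; otherwise it
#' starts a new burst.  Singletons are bursts of size 1; every spike
#' belongs to exactly one burst.
#'
#' @param spike_times Time-ordered spike peak times (ms).
#' @param burst_isi_max Maximum intra-burst ISI (ms, default 15).
#' @return List of integer vectors, each holding the indices (into
#'   `spike_times`) of one burst, in time order.
#' @export
group_bursts <- function(spike_times, burst_isi_max = 15) {
  n <- length(spike_times)
  if (n == 0L) return(list())
  if (is.unsorted(spike_times))
    cp_stop("'spike_times' must be time-ordered", "cp_format_error")
  bursts <- list(1L)
  for (j in seq_len(n - 1L) + 1L) {
    cur <- bursts[[length(bursts)]]
    if (spike_times[j] - spike_times[j - 1L] <= burst_isi_max &&
        length(cur) < 3L) {
      bursts[[length(bursts)]] <- c(cur, j)
    } else {
      bursts[[length(bursts) + 1L]] <- j
    }
  }
  bursts
}

#' Full spike-feature table of one sweep
#'
#' Detects spikes, interpolates each firing threshold, measures the
#' waveform features and fast afterpotentials per spike, groups
#' doublets/triplets, and measures the medium afterpotentials after the
#' last spike of each burst.  Within a burst the fDAP of a non-final
#' spike uses the threshold of the following spike as its maximum.
#'
#' @param sweep A firing-protocol [sweep_trace()].
#' @param detect_level,thr_slope,refractory_ms Passed to
#'   [detect_spikes()] / [interpolate_threshold()].
#' @param burst_isi_max Maximum intra-burst ISI (ms), see
#'   [group_bursts()].
#' @return An object of class `cp_spikes`: list with `spikes` (one row
#'   per spike: times, threshold, amplitude, half_width, duration,
#'   rise_time, fahp, t_fahp, fdap, burst id/position) and `bursts`
#'   (one row per burst: size, mahp, mdap).
#' @export
analyze_spikes <- function(sweep, detect_level = 0, thr_slope = 20,
                           refractory_ms = 1, burst_isi_max = 15) {
  det <- detect_spikes(sweep, detect_level = detect_level,
                       thr_slope = thr_slope,
                       refractory_ms = refractory_ms)
  n <- nrow(det)
  if (n == 0L) {
    out <- list(spikes = data.frame(), bursts = data.frame(),
                sweep_i = sweep$i_step)
    class(out) <- "cp_spikes"
    return(out)
  }
  thr <- lapply(det$idx, function(k) interpolate_threshold(sweep, k,
                                                           thr_slope))
  v_thr <- vapply(thr, `[[`, numeric(1), "v_thr")
  t_thr <- vapply(thr, `[[`, numeric(1), "t_thr")
  bursts <- group_bursts(det$t_peak, burst_isi_max)
  burst_id <- integer(n)
  burst_pos <- integer(n)
  for (b in seq_along(bursts)) {
    burst_id[bursts[[b]]] <- b
    burst_pos[bursts[[b]]] <- seq_along(bursts[[b]])
  }
  feats <- vector("list", n)
  fast <- vector("list", n)
  for (j in seq_len(n)) {
    search_end <- if (j < n) det$idx[j + 1L] else length(sweep$v)
    feats[[j]] <- ap_waveform_features(sweep, det$idx[j], v_thr[j],
                                       t_thr[j], search_end)
    in_burst_next <- j < n && burst_id[j + 1L] == burst_id[j]
    fast[[j]] <- fast_afterpotentials(
      sweep, det$idx[j], v_thr[j],
      next_v_thr = if (in_burst_next) v_thr[j + 1L] else NULL)
  }
  spikes <- data.frame(
    t_peak = det$t_peak, v_peak = det$v_peak, t_thr = t_thr, v_thr = v_thr,
    amplitude = vapply(feats, `[[`, numeric(1), "amplitude"),
    half_width = vapply(feats, `[[`, numeric(1), "half_width"),
    duration = vapply(feats, `[[`, numeric(1), "duration"),
    rise_time = vapply(feats, `[[`, numeric(1), "rise_time"),
    fahp = vapply(fast, `[[`, numeric(1), "fahp"),
    t_fahp = vapply(fast, `[[`, numeric(1), "t_fahp"),
    fdap = vapply(fast, `[[`, numeric(1), "fdap"),
    burst = burst_id, burst_pos = burst_pos)
  med <- lapply(bursts, function(b) {
    last <- b[length(b)]
    medium_afterpotentials(sweep, det$idx[last], v_thr[last])
  })
  btab <- data.frame(
    burst = seq_along(bursts),
    size = lengths(bursts),
    t_first = det$t_peak[vapply(bursts, `[`, integer(1), 1L)],
    mahp = vapply(med, `[[`, numeric(1), "mahp"),
    mdap = vapply(med, `[[`, numeric(1), "mdap"))
  out <- list(spikes = spikes, bursts = btab, sweep_i = sweep$i_step)
  class(out) <- "cp_spikes"
  out
}

#' @export
print.cp_spikes <- function(x, ...) {
  cat(sprintf("<cp_spikes> i_step = %g pA: %d spikes in %d bursts\n",
              x$sweep_i, nrow(x$spikes), nrow(x$bursts)))
  if (nrow(x$spikes)) {
    cat(sprintf("  v_thr %.1f mV, amplitude %.1f mV, fAHP %.1f mV (means)\n",
                mean(x$spikes$v_thr), mean(x$spikes$amplitude),
                mean(x$spikes$fahp, na.rm = TRUE)))
  }
  invisible(x)
}

#' Firing profile of a cell
#'
#' From the 2 s firing ladder: the rheobase (smallest step current
#' eliciting at least one spike), the f-I curve (spike count within the
#' step divided by the step duration, per sweep), and the adaptation
#' index `isi_ratio` — first interspike interval over last — measured on
#' the sweep whose current is closest to twice the rheobase (ties broken
#' toward the larger step).  The ISI ratio needs at least 3 spikes on
#' that sweep, otherwise it is `NA`.
#'
#' @param s A firing [sweep_set()].
#' @param ... Passed to [detect_spikes()].
#' @return An object of class `cp_firing`: list with `rheobase` (pA),
#'   `fi` (data frame `i`, `n_spikes`, `rate_hz`), `isi_ratio`,
#'   `isi_sweep_i` (pA).
#' @export
firing_profile <- function(s, ...) {
  if (!inherits(s, "cp_sweep_set"))
    cp_stop("'s' must be a cp_sweep_set", "cp_format_error")
  cur <- sweep_currents(s)
  first <- s$sweeps[[1L]]
  dur_s <- (first$step_offset - first$step_onset) / 1000
  det <- lapply(s$sweeps, function(sw) {
    d <- detect_spikes(sw, ...)
    d[d$t_peak >= sw$step_onset & d$t_peak < sw$step_offset, , drop = FALSE]
  })
  n_sp <- vapply(det, nrow, integer(1))
  if (all(n_sp == 0L))
    cp_stop("no sweep elicited a spike: rheobase undefined",
            "cp_no_rheobase")
  rheo <- min(cur[n_sp > 0L])
  # nearest ladder step to 2x rheobase; ties broken upward
  d2 <- abs(cur - 2 * rheo)
  cand <- which(d2 == min(d2))
  isi_j <- cand[which.max(cur[cand])]
  isi_ratio <- NA_real_
  if (n_sp[isi_j] >= 3L) {
    isis <- diff(det[[isi_j]]$t_peak)
    isi_ratio <- isis[1L] / isis[length(isis)]
  }
  out <- list(rheobase = rheo,
              fi = data.frame(i = cur, n_spikes = n_sp,
                              rate_hz = n_sp / dur_s),
              isi_ratio = isi_ratio, isi_sweep_i = cur[isi_j])
  class(out) <- "cp_firing"
  out
}

#' @export
print.cp_firing <- function(x, ...) {
  cat(sprintf("<cp_firing> rheobase = %g pA; ISI ratio at %g pA: %s\n",
              x$rheobase, x$isi_sweep_i,
              if (is.na(x$isi_ratio)) "undefined (<3 spikes)"
              else sprintf("%.3f", x$isi_ratio)))
  cat(sprintf("  f-I: %s Hz over %g..%g pA\n",
              paste(round(x$fi$rate_hz, 1), collapse = ", "),
              min(x$fi$i), max(x$fi$i)))
  invisible(x)
}
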