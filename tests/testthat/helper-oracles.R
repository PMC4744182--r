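# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive every quantity with literal index
# arithmetic, separate from the package's implementations.

# random valid sweep with a step window, for I/O and scan tests
random_sweep <- function(n = 400, dt = 0.1, i_step = -100) {
  total <- (n - 1) * dt
  on <- total * 0.2
  off <- total * 0.8
  v <- -65 + cumsum(rnorm(n, 0, 0.5))
  sweep_trace(v, dt = dt, i_step = i_step, step_onset = on,
              step_offset = off)
}

random_sweep_set <- function(n_sweeps = 3, n = 60) {
  cur <- sort(sample(seq(-200, 80, by = 20), n_sweeps))
  sweeps <- lapply(cur, function(i) random_sweep(n = n, i_step = i))
  sweep_set(paste0("cell_", sample.int(1e6, 1)), "passive_500ms",
            sweeps, holding_v = -67)
}

# literal-loop extremum over the half-open window (t_anchor, t_anchor + w]
oracle_window_ext <- function(v, t, anchor_idx, window_ms, what, dt) {
  t_end <- t[anchor_idx] + window_ms
  if (t_end > t[length(t)] + dt / 2) return(NULL)
  best_k <- NA_integer_
  k <- anchor_idx
  while (k < length(t)) {
    k <- k + 1L
    if (t[k] > t_end + dt / 1e6) break
    if (is.na(best_k) ||
        (what == "min" && v[k] < v[best_k]) ||
        (what == "max" && v[k] > v[best_k])) best_k <- k
  }
  if (is.na(best_k)) return(NULL)
  list(idx = best_k, t = t[best_k], value = v[best_k])
}

# literal scan version of step_extrema with smoothing disabled
oracle_step_extrema <- function(sweep, peak_window_ms = 250,
                                ss_frac = 0.1) {
  t <- sweep_times(sweep)
  on <- sweep$step_onset
  off <- sweep$step_offset
  sel <- which(t >= on & t < off & t <= min(on + peak_window_ms, off))
  k <- if (sweep$i_step < 0) sel[which.min(sweep$v[sel])]
       else sel[which.max(sweep$v[sel])]
  ss <- which(t >= off - ss_frac * (off - on) & t < off)
  list(v_peak = sweep$v[k], t_peak = t[k] - on,
       v_ss = sum(sweep$v[ss]) / length(ss))
}

# closed-form OLS slope via the normal equations
oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# action potential whose dV/dt is piecewise linear through the 20 V/s
# crossing, with the crossing voltage known in closed form.  The
# upstroke derivative ramps d0 -> d1 (V/s) over `dur` ms starting at
# t_u, then jumps to 300 V/s for 0.2 ms (to the peak), then -200 V/s
# for 0.5 ms back down.
make_pld_ap <- function(offset = 0, dt = 0.1, v0 = -60, d0 = 14, d1 = 26,
                        dur = 2, total = 40) {
  t_u <- 20 + offset
  t <- seq(0, total, by = dt)
  v_at <- function(tt) {
    u <- tt - t_u
    g_ramp <- d0 * dur + (d1 - d0) * dur / 2
    ifelse(u <= 0, v0,
    ifelse(u <= dur, v0 + d0 * u + (d1 - d0) * u^2 / (2 * dur),
    ifelse(u <= dur + 0.2, v0 + g_ramp + 300 * (u - dur),
    ifelse(u <= dur + 0.7, v0 + g_ramp + 60 - 200 * (u - dur - 0.2),
           v0 + g_ramp + 60 - 100))))
  }
  u_x <- dur * (20 - d0) / (d1 - d0)
  v_x <- v0 + d0 * u_x + (d1 - d0) * u_x^2 / (2 * dur)
  list(sweep = sweep_trace(v_at(t), dt = dt, i_step = 100,
                           step_onset = 5, step_offset = total - 5),
       v_thr_true = v_x, t_thr_true = t_u + u_x)
}

# 3-component Gaussian mixture with all pairwise mean distances equal
# to `sep` and identical between-component variance in every feature,
# so that z-scaling rescales all dimensions uniformly and preserves
# the separation geometry
tri_mixture <- function(sep = 5, p = 10, n = 145, seed = NULL) {
  R <- sep / sqrt(3)
  V <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2)) * R
  u1 <- c(rep(1, p / 2), rep(-1, p / 2)) / sqrt(p)
  u2 <- rep(c(1, -1), length.out = p) / sqrt(p)
  mixture_spec(means = V %*% rbind(u1, u2), sds = 1, n = n,
               feature_names = paste0("f", seq_len(p)), seed = seed)
}

# brute-force silhouette from the definition, O(n^2) loops
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# rule-replay burst grouping oracle (independent loop formulation)
oracle_bursts <- function(times, isi_max) {
  out <- list()
  cur <- c()
  for (j in seq_along(times)) {
    if (length(cur) == 0L) {
      cur <- j
    } else if (times[j] - times[j - 1L] <= isi_max && length(cur) < 3L) {
      cur <- c(cur, j)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- j
    }
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  out
}
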