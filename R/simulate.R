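#' Parameters of the passive-membrane simulator
#'
#' Phenomenological RC membrane with an Ih-like sag: the step deflection
#' charges with time constant `tau_m` and then relaxes from its full
#' amplitude toward `(1 - sag_frac)` of it with time constant
#' `tau_sag`.  White Gaussian noise of RMS `noise_rms` is added to every
#' sample.
#'
#' @param r_m Membrane resistance (megaohms, > 0).
#' @param tau_m Membrane time constant (ms).
#' @param sag_frac Fractional peak-to-plateau relaxation in `[0, 1)`;
#'   0 disables the sag.
#' @param tau_sag Sag relaxation time (ms); must exceed `tau_m` when
#'   `sag_frac > 0`.
#' @param v_rest Resting potential (mV).
#' @param noise_rms Noise RMS (mV).
#' @param seed Optional RNG seed.
#' @return An object of class `cp_passive_sim`.
#' @export
passive_sim_params <- function(r_m = 100, tau_m = 12, sag_frac = 0.25,
                               tau_sag = 120, v_rest = -67, noise_rms = 0.2,
                               seed = NULL) {
  if (r_m <= 0) cp_stop("'r_m' must be positive", "cp_sim_error")
  if (sag_frac < 0 || sag_frac >= 1)
    cp_stop("'sag_frac' must be in [0, 1)", "cp_sim_error")
  if (sag_frac > 0 && tau_sag <= tau_m)
    cp_stop("'tau_sag' must exceed 'tau_m' when sag_frac > 0",
            "cp_sim_error")
  if (noise_rms < 0) cp_stop("'noise_rms' must be >= 0", "cp_sim_error")
  structure(list(r_m = r_m, tau_m = tau_m, sag_frac = sag_frac,
                 tau_sag = tau_sag, v_rest = v_rest,
                 noise_rms = noise_rms, seed = seed),
            class = "cp_passive_sim")
}

#' Simulate a passive 500 ms step protocol
#'
#' Generates one sweep per injected current with the deflection shape
#' `f(t) = (1 - exp(-t/tau_m)) ((1 - sag_frac) + sag_frac exp(-t/tau_sag))`
#' scaled by `i * r_m / 1000` (mV), plus Gaussian noise.  The analytic
#' ground truth (per-sweep peak/steady-state voltages, the implied
#' Rpeak, Rss, sag and time to peak) is attached as the `"truth"`
#' attribute so downstream estimates can be scored without circularity.
#'
#' @param p A [passive_sim_params()] object.
#' @param currents Injected currents (pA); default the -200..80 pA
#'   ladder in 40 pA steps.
#' @param dt Sampling interval (ms, default 0.1, i.e. 10 kHz).
#' @param step_onset Step start (ms, default 100).
#' @param step_dur Step duration (ms, default 500).
#' @param total Trace length (ms, default 700).
#' @param ss_frac Steady-state window fraction used for the analytic
#'   truth (default 0.1, matching [step_extrema()]).
#' @param cell_id Cell identifier.
#' @return A `"passive_500ms"` [sweep_set()] with attribute `"truth"`.
#' @export
simulate_passive_sweeps <- function(p, currents = seq(-200, 80, by = 40),
                                    dt = 0.1, step_onset = 100,
                                    step_dur = 500, total = 700,
                                    ss_frac = 0.1, cell_id = "sim_passive") {
  stopifnot(inherits(p, "cp_passive_sim"))
  f <- function(t) (1 - exp(-t / p$tau_m)) *
    ((1 - p$sag_frac) + p$sag_frac * exp(-t / p$tau_sag))
  opt <- stats::optimize(f, c(0, step_dur), maximum = TRUE,
                         tol = 1e-10)
  f_max <- opt$objective
  t_pk <- opt$maximum
  ss_w <- ss_frac * step_dur
  f_ss <- stats::integrate(f, step_dur - ss_w, step_dur,
                           rel.tol = 1e-10)$value / ss_w
  t <- seq(0, total, by = dt)
  off <- step_onset + step_dur
  in_step <- t >= step_onset & t < off
  shape <- numeric(length(t))
  shape[in_step] <- f(t[in_step] - step_onset)
  # post-step relaxation back to rest with tau_m
  post <- t >= off
  shape[post] <- f(step_dur) * exp(-(t[post] - off) / p$tau_m)
  sweeps <- with_seed(p$seed, lapply(currents, function(i) {
    amp <- i * p$r_m / 1000
    v <- p$v_rest + amp * shape
    if (p$noise_rms > 0) v <- v + stats::rnorm(length(v), 0, p$noise_rms)
    sweep_trace(v, dt = dt, i_step = i, step_onset = step_onset,
                step_offset = off)
  }))
  s <- sweep_set(cell_id, "passive_500ms", sweeps, holding_v = p$v_rest)
  amp <- currents * p$r_m / 1000
  attr(s, "truth") <- list(
    per_sweep = data.frame(i = currents,
                           v_peak = p$v_rest + amp * f_max,
                           v_ss = p$v_rest + amp * f_ss,
                           t_peak = t_pk),
    r_peak = p$r_m * f_max, r_ss = p$r_m * f_ss,
    sag = 0.2 * p$r_m * (f_max - f_ss), t_peak = t_pk, params = p)
  s
}

# ---------------------------------------------------------------------
# Spike-train simulator: stereotyped AP templates with an analytically
# placed 20 V/s crossing.
#
# Upstroke dV/dt profile (mV/ms, piecewise linear in time):
#   0 -> 35 over 1.0 ms      (the 20 V/s crossing sits mid-segment, so
#                             the sampled central difference is exact
#                             and the chord interpolation error stays
#                             below 0.05 mV at dt = 0.1 ms)
#   35 -> 250 over 0.3 ms
#   250 -> 0 over (amplitude - 54.536)/125 ms   (to the peak)
# The voltage at the crossing is v_thr by construction; the upstroke
# therefore starts 20^2/(2*35) = 5.714 mV below threshold, which is
# also the inter-spike plateau level.
# ---------------------------------------------------------------------
tpl_slope_a <- 35      # end slope of the crossing segment (V/s)
tpl_dur_a <- 1.0       # its duration (ms)
tpl_slope_max <- 250   # maximal upstroke slope (V/s)
tpl_dur_b <- 0.3
tpl_sub_gain <- 20^2 / (2 * tpl_slope_a)          # mV below thr at start
tpl_gain_a <- tpl_slope_a * tpl_dur_a / 2
tpl_gain_b <- (tpl_slope_a + tpl_slope_max) / 2 * tpl_dur_b

# closed-form template geometry for a given parameter set
tpl_geometry <- function(p) {
  a_c <- (p$ap_amplitude - (tpl_gain_a - tpl_sub_gain + tpl_gain_b)) /
    (tpl_slope_max / 2)
  t_pk <- tpl_dur_a + tpl_dur_b + a_c
  v_start <- p$v_thr_true - tpl_sub_gain
  v_pk <- p$v_thr_true + p$ap_amplitude
  up <- function(u) {   # voltage on the upstroke, u ms after its start
    ifelse(u <= tpl_dur_a,
           v_start + tpl_slope_a / (2 * tpl_dur_a) * u^2,
    ifelse(u <= tpl_dur_a + tpl_dur_b,
           v_start + tpl_gain_a + tpl_slope_a * (u - tpl_dur_a) +
             (tpl_slope_max - tpl_slope_a) / (2 * tpl_dur_b) *
             (u - tpl_dur_a)^2,
           v_start + tpl_gain_a + tpl_gain_b +
             tpl_slope_max * (u - tpl_dur_a - tpl_dur_b) -
             tpl_slope_max / (2 * a_c) * (u - tpl_dur_a - tpl_dur_b)^2))
  }
  half <- p$v_thr_true + p$ap_amplitude / 2
  t_half_up <- stats::uniroot(function(u) up(u) - half,
                              c(20 / tpl_slope_a, t_pk),
                              tol = 1e-10)$root
  list(a_c = a_c, t_pk = t_pk, v_start = v_start, v_pk = v_pk, up = up,
       t_uh = t_pk - t_half_up)   # half-level-to-peak time on the upstroke
}

#' Parameters of the spike-train simulator
#'
#' Stereotyped action-potential waveforms with prescribed threshold,
#' amplitude, half-width and afterpotential magnitudes are inserted at
#' deterministic spike times; trains adapt with a geometric ISI
#' progression, and bursts (doublets/triplets) repeat each event with a
#' fixed intra-burst interval.  The template is built so that every
#' prescribed feature is exactly recoverable by the analysis window
#' rules: the upstroke crosses 20 V/s exactly at `v_thr_true`, the fAHP
#' minimum sits `fahp_true` below threshold at `t_fahp` after the peak,
#' the medium trough (`mahp_true` below threshold) is the deepest point
#' of the 50 ms window, and the depolarizing afterpotentials are the
#' maxima of their 5/70 ms windows.  Geometric consequences: the
#' upstroke starts 5.71 mV below threshold, so `fahp_true` must exceed
#' 6 mV, `mahp_true >= fahp_true`, and `mdap_true > mahp_true - 5.5`.
#'
#' @param rheobase_pA Smallest spiking step current (pA).
#' @param gain_hz_per_pA f-I gain above rheobase (Hz/pA).
#' @param v_thr_true Firing threshold (mV).
#' @param ap_amplitude Peak minus threshold (mV, >= 60).
#' @param ap_halfwidth Width at half amplitude (ms).
#' @param fahp_true,mahp_true fAHP / mAHP magnitudes below threshold (mV).
#' @param fdap_true,mdap_true fDAP / mDAP magnitudes above the
#'   corresponding minima (mV).
#' @param t_fahp Time from spike peak to the fAHP minimum (ms, < 3).
#' @param burst_mode `"single"`, `"doublet"` or `"triplet"`.
#' @param intra_burst_isi Intra-burst peak-to-peak interval (ms).
#' @param adaptation_ratio First/last inter-event ISI (< 1 = adapting).
#' @param noise_rms Gaussian noise RMS (mV).
#' @param v_rest Resting potential (mV).
#' @param seed Optional RNG seed.
#' @return An object of class `cp_spike_sim`.
#' @export
spike_sim_params <- function(rheobase_pA = 80, gain_hz_per_pA = 0.04,
                             v_thr_true = -42, ap_amplitude = 80,
                             ap_halfwidth = 1.0, fahp_true = 7,
                             mahp_true = 10, fdap_true = 3, mdap_true = 6,
                             t_fahp = 1.5, burst_mode = c("single",
                                                          "doublet",
                                                          "triplet"),
                             intra_burst_isi = 8, adaptation_ratio = 0.5,
                             noise_rms = 0.1, v_rest = -67, seed = NULL) {
  burst_mode <- match.arg(burst_mode)
  p <- list(rheobase_pA = rheobase_pA, gain_hz_per_pA = gain_hz_per_pA,
            v_thr_true = v_thr_true, ap_amplitude = ap_amplitude,
            ap_halfwidth = ap_halfwidth, fahp_true = fahp_true,
            mahp_true = mahp_true, fdap_true = fdap_true,
            mdap_true = mdap_true, t_fahp = t_fahp,
            burst_mode = burst_mode, intra_burst_isi = intra_burst_isi,
            adaptation_ratio = adaptation_ratio, noise_rms = noise_rms,
            v_rest = v_rest, seed = seed)
  if (ap_amplitude < 60)
    cp_stop("'ap_amplitude' must be at least 60 mV for this template",
            "cp_sim_error")
  if (adaptation_ratio <= 0)
    cp_stop("'adaptation_ratio' must be positive", "cp_sim_error")
  if (fahp_true < tpl_sub_gain + 0.3)
    cp_stop(sprintf("'fahp_true' must exceed %.1f mV (the template's sub-threshold upstroke gain)",
                    tpl_sub_gain + 0.3), "cp_sim_error")
  if (mahp_true < fahp_true)
    cp_stop("'mahp_true' must be at least 'fahp_true' (otherwise the 50 ms window minimum is the fAHP, not the medium trough)",
            "cp_sim_error")
  if (mdap_true <= mahp_true - tpl_sub_gain + 0.2)
    cp_stop("'mdap_true' too small: the mDAP bump must rise above the inter-spike plateau",
            "cp_sim_error")
  if (t_fahp >= 3 || t_fahp <= 0.3)
    cp_stop("'t_fahp' must lie in (0.3, 3) ms", "cp_sim_error")
  g <- tpl_geometry(p)
  if (v_thr_true + ap_amplitude <= 5)
    cp_stop("spike peak must exceed 5 mV for detection headroom",
            "cp_sim_error")
  t_dh <- ap_halfwidth - g$t_uh
  if (t_dh < 0.1 || t_dh > t_fahp - 0.1)
    cp_stop(sprintf("'ap_halfwidth' incompatible with the template: the downward half-crossing (%.2f ms after the peak) must fall in [0.1, t_fahp - 0.1]",
                    t_dh), "cp_sim_error")
  if (burst_mode != "single" &&
      intra_burst_isi - g$t_pk <= t_fahp + 0.2)
    cp_stop("'intra_burst_isi' too short: successive APs in a burst would overlap",
            "cp_waveform_overlap")
  structure(p, class = "cp_spike_sim")
}

# piecewise-linear fall of one spike, as absolute (t, v) knots
tpl_fall_knots <- function(p, g, t_peak, final, next_up_start = NULL) {
  t_dh <- p$ap_halfwidth - g$t_uh
  v_half <- p$v_thr_true + p$ap_amplitude / 2
  v_minf <- p$v_thr_true - p$fahp_true
  kt <- c(0, t_dh, p$t_fahp)
  kv <- c(g$v_pk, v_half, v_minf)
  if (final) {
    trough <- p$v_thr_true - p$mahp_true
    kt <- c(kt, p$t_fahp + 1.5, 20, 40, 55)
    kv <- c(kv, v_minf + p$fdap_true, trough, trough + p$mdap_true,
            g$v_start)
  } else {
    kt <- c(kt, next_up_start - t_peak)
    kv <- c(kv, g$v_start)
  }
  list(t = t_peak + kt, v = kv)
}

#' Simulate a 2 s firing-ladder protocol
#'
#' One sweep per ladder current.  Below `rheobase_pA` the response is a
#' subthreshold depolarization; at and above it, bursts of stereotyped
#' action potentials (see [spike_sim_params()]) are placed with
#' geometric inter-event ISI adaptation filling the step.  The event
#' ground truth — spike times, thresholds, waveform and afterpotential
#' magnitudes per spike and burst — is attached as the `"truth"`
#' attribute (`events`, plus `isi_ratio` for the sweep nearest twice
#' rheobase).  Events whose medium-window truth is invalidated by a
#' following burst closer than 91 ms carry `NA` there.
#'
#' @param p A [spike_sim_params()] object.
#' @param ladder Step currents (pA); default 20..200 pA in 20 pA steps.
#' @param dt Sampling interval (ms, default 0.1).
#' @param step_onset Step start (ms, default 100).
#' @param step_dur Step duration (ms, default 2000).
#' @param total Trace length (ms, default 2300).
#' @param cell_id Cell identifier.
#' @return A `"firing_2s"` [sweep_set()] with attribute `"truth"`.
#' @export
simulate_spiking_sweeps <- function(p, ladder = seq(20, 200, by = 20),
                                    dt = 0.1, step_onset = 100,
                                    step_dur = 2000, total = 2300,
                                    cell_id = "sim_firing") {
  stopifnot(inherits(p, "cp_spike_sim"))
  g <- tpl_geometry(p)
  off <- step_onset + step_dur
  t <- seq(0, total, by = dt)
  size <- switch(p$burst_mode, single = 1L, doublet = 2L, triplet = 3L)
  tau_chg <- 15
  events_all <- list()
  make_sweep <- function(i) {
    supra <- i >= p$rheobase_pA
    plateau <- if (supra) g$v_start else p$v_rest + 0.03 * i
    v <- rep(p$v_rest, length(t))
    in_step <- t >= step_onset & t < off
    v[in_step] <- p$v_rest + (plateau - p$v_rest) *
      (1 - exp(-(t[in_step] - step_onset) / tau_chg))
    post <- t >= off
    v_off <- p$v_rest + (plateau - p$v_rest) *
      (1 - exp(-step_dur / tau_chg))
    v[post] <- p$v_rest + (v_off - p$v_rest) * exp(-(t[post] - off) / tau_chg)
    ev <- NULL
    if (supra) {
      f <- 1 + p$gain_hz_per_pA * (i - p$rheobase_pA)
      m <- max(1L, round(f * step_dur / 1000))
      first <- step_onset + 60
      onsets <- first
      if (m >= 2L) {
        span <- step_dur - 160
        gg <- if (m == 2L) 1 else p$adaptation_ratio^(-1 / (m - 2))
        isis <- gg^(seq_len(m - 1L) - 1L)
        isis <- isis / sum(isis) * span
        gaps <- isis - (size - 1L) * p$intra_burst_isi
        if (any(gaps < 55 + g$t_pk + 1.5))
          cp_stop(sprintf("at %g pA the waveform tails of adjacent bursts would overlap (smallest gap %.1f ms); lower the firing gain or shorten the afterpotential tail",
                          i, min(gaps)), "cp_waveform_overlap")
        onsets <- first + c(0, cumsum(isis))
      }
      peaks <- rep(onsets, each = size) +
        rep((seq_len(size) - 1L) * p$intra_burst_isi, length(onsets))
      peaks <- round(peaks / dt) * dt   # spike peaks sit on the grid
      burst_id <- rep(seq_along(onsets), each = size)
      burst_pos <- rep(seq_len(size), length(onsets))
      for (q in seq_along(peaks)) {
        pk <- peaks[q]
        up0 <- pk - g$t_pk
        sel <- which(t >= up0 - dt / 2 & t <= pk + dt / 1e6)
        v[sel] <- g$up(pmax(t[sel] - up0, 0))
        final <- burst_pos[q] == size
        nxt <- if (!final) peaks[q + 1L] - g$t_pk else NULL
        kn <- tpl_fall_knots(p, g, pk, final, nxt)
        fe <- kn$t[length(kn$t)]
        sel <- which(t > pk & t <= fe)
        if (length(sel))
          v[sel] <- stats::approx(kn$t, kn$v, xout = t[sel], rule = 2)$y
      }
      last_of_burst <- burst_pos == size
      next_first <- c(peaks[which(burst_pos == 1L)][-1L], Inf)
      mw_ok <- next_first[burst_id] - peaks >= 91
      ev <- data.frame(
        i_step = i, burst = burst_id, burst_pos = burst_pos,
        burst_size = size, t_peak = peaks,
        v_thr = p$v_thr_true, amplitude = p$ap_amplitude,
        half_width = p$ap_halfwidth, fahp = p$fahp_true,
        t_fahp = p$t_fahp,
        fdap = ifelse(last_of_burst, p$fdap_true, p$fahp_true),
        mahp = ifelse(last_of_burst, p$mahp_true, NA_real_),
        mdap = ifelse(last_of_burst & mw_ok, p$mdap_true, NA_real_))
    }
    list(v = v, ev = ev)
  }
  sim <- lapply(ladder, make_sweep)
  sweeps <- with_seed(p$seed, lapply(seq_along(ladder), function(j) {
    v <- sim[[j]]$v
    if (p$noise_rms > 0) v <- v + stats::rnorm(length(v), 0, p$noise_rms)
    sweep_trace(v, dt = dt, i_step = ladder[j], step_onset = step_onset,
                step_offset = off)
  }))
  s <- sweep_set(cell_id, "firing_2s", sweeps, holding_v = p$v_rest)
  events <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(sim, `[[`, "ev")))
  d2 <- abs(ladder - 2 * p$rheobase_pA)
  cand <- which(d2 == min(d2))
  isi_i <- ladder[cand[which.max(ladder[cand])]]
  attr(s, "truth") <- list(
    events = events,
    isi_ratio = if (p$burst_mode == "single") p$adaptation_ratio else 1,
    isi_sweep_i = isi_i, rheobase = p$rheobase_pA, params = p)
  s
}

#' Gaussian mixture specification for morphometric tables
#'
#' @param means k x p matrix of component means (rows = components,
#'   columns = features).
#' @param sds k x p matrix (or scalar) of component standard
#'   deviations, all positive.
#' @param weights Component weights (summing to 1; normalized if not).
#' @param n Number of neurons to draw (default 145).
#' @param feature_names Feature column names (default
#'   [morph_feature_names()] truncated/recycled to p).
#' @param seed Optional RNG seed.
#' @return An object of class `cp_mixture_spec`.
#' @export
mixture_spec <- function(means, sds = 1, weights = NULL, n = 145,
                         feature_names = NULL, seed = NULL) {
  means <- as.matrix(means)
  k <- nrow(means)
  p <- ncol(means)
  if (length(sds) == 1L) sds <- matrix(sds, k, p)
  sds <- as.matrix(sds)
  if (!all(dim(sds) == dim(means)))
    cp_stop("'sds' must match the dimensions of 'means'", "cp_sim_error")
  if (any(sds <= 0))
    cp_stop("all component standard deviations must be positive",
            "cp_sim_error")
  weights <- weights %||% rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    cp_stop("'weights' must be k non-negative numbers", "cp_sim_error")
  weights <- weights / sum(weights)
  if (is.null(feature_names)) {
    feature_names <- morph_feature_names()
    if (p <= length(feature_names)) feature_names <- feature_names[1:p]
    else feature_names <- paste0("f", seq_len(p))
  }
  colnames(means) <- colnames(sds) <- feature_names
  structure(list(means = means, sds = sds, weights = weights, n = n,
                 feature_names = feature_names, seed = seed),
            class = "cp_mixture_spec")
}

#' Simulate a morphometric feature table
#'
#' Draws component labels from the mixture weights, then feature
#' vectors from the component's diagonal Gaussian.  Canonical physical
#' features (lengths, areas, volumes, counts, angles) are clipped at 0
#' and the shape indices (`sphericity`, `oblate_ellipticity`) to
#' `(0, 1]`; abstract feature names are left untouched.  The true
#' component of every neuron is returned in the `component` column.
#'
#' @param m A [mixture_spec()].
#' @return Data frame with `neuron_id`, `group` (`"comp<label>"`),
#'   `component` (integer truth) and one column per feature.
#' @export
simulate_morphology_table <- function(m) {
  stopifnot(inherits(m, "cp_mixture_spec"))
  k <- nrow(m$means)
  p <- ncol(m$means)
  with_seed(m$seed, {
    lab <- sample.int(k, m$n, replace = TRUE, prob = m$weights)
    x <- m$means[lab, , drop = FALSE] +
      m$sds[lab, , drop = FALSE] * matrix(stats::rnorm(m$n * p), m$n, p)
    clip0 <- intersect(colnames(x),
                       c("soma_diameter", "soma_area", "soma_volume",
                         "apical_diameter_5um", "radial_position",
                         "bifurcation_distance", "ramification_count",
                         "n_basal_dendrites", "basal_angle_mean"))
    for (f in clip0) x[, f] <- pmax(x[, f], 0)
    for (f in intersect(colnames(x), c("sphericity", "oblate_ellipticity")))
      x[, f] <- pmin(pmax(x[, f], 1e-6), 1)
    data.frame(neuron_id = sprintf("n%03d", seq_len(m$n)),
               group = paste0("comp", lab), component = lab, x,
               check.names = FALSE)
  })
}

#' Default three-subtype morphology mixture
#'
#' A plausible layer-V pyramidal-neuron mixture with three morphological
#' profiles (small deep soma with early apical bifurcation; large soma;
#' intermediate, highly ramified), used by the demo pipeline.
#'
#' @param n Number of neurons (default 145).
#' @param seed Optional RNG seed.
#' @return A [mixture_spec()].
#' @export
default_morphology_mixture <- function(n = 145, seed = NULL) {
  means <- rbind(
    c(13, 420, 1100, 0.45, 0.78, 2.2, 720, 180, 6, 5, 62),
    c(20, 950, 3600, 0.62, 0.68, 3.8, 560, 420, 9, 7, 78),
    c(16, 640, 2000, 0.50, 0.73, 2.9, 640, 300, 12, 6, 70))
  sds <- rbind(
    c(0.8, 36, 120, 0.032, 0.024, 0.20, 28, 20, 0.8, 0.6, 3.2),
    c(1.0, 56, 240, 0.032, 0.024, 0.24, 28, 28, 1.0, 0.7, 3.2),
    c(0.8, 44, 160, 0.032, 0.024, 0.20, 28, 24, 1.0, 0.6, 3.2))
  mixture_spec(means, sds, weights = c(0.30, 0.40, 0.30), n = n,
               feature_names = morph_feature_names(), seed = seed)
}

#' Laminar cell-map specification
#'
#' Layer boundaries follow the bin scheme (so generator layers and
#' analysis layers coincide exactly); each cell's depth is uniform
#' within the cortex, its Ctip2/Satb2 class is drawn from the layer's
#' class probabilities, Lmo4 is drawn conditionally within `C+/S+`
#' cells, and GFP/tracer labels independently per layer.
#'
#' @param scheme A [bin_scheme()] (default 10-bin).
#' @param class_probs 3 x 4 matrix of per-layer (rows VI, V, UL)
#'   probabilities of the classes `C+/S+`, `C+/S-`, `C-/S+`, `C-/S-`;
#'   rows must sum to 1.
#' @param lmo4_given_cspp Per-layer probability of Lmo4 within `C+/S+`.
#' @param gfp_prob,tracer_prob Per-layer labelling probabilities.
#' @param cells_per_animal,n_animals Sample sizes (defaults 500 and 3).
#' @param cortex_thickness_um Radial thickness (default 1300).
#' @param area,age Metadata labels.
#' @param seed Optional RNG seed.
#' @return An object of class `cp_cellmap_spec`.
#' @export
cell_map_spec <- function(scheme = bin_scheme(10),
                          class_probs = rbind(VI = c(0.10, 0.25, 0.30, 0.35),
                                              V = c(0.20, 0.35, 0.20, 0.25),
                                              UL = c(0.03, 0.02, 0.70, 0.25)),
                          lmo4_given_cspp = c(VI = 0.3, V = 0.6, UL = 0.2),
                          gfp_prob = c(VI = 0.1, V = 0.2, UL = 0.4),
                          tracer_prob = c(VI = 0.05, V = 0.15, UL = 0.02),
                          cells_per_animal = 500, n_animals = 3,
                          cortex_thickness_um = 1300, area = "S1",
                          age = "P7", seed = NULL) {
  class_probs <- as.matrix(class_probs)
  if (any(class_probs < 0 | class_probs > 1))
    cp_stop("class probabilities must lie in [0, 1]", "cp_sim_error")
  if (any(abs(rowSums(class_probs) - 1) > 1e-8))
    cp_stop("each layer's class probabilities must sum to 1",
            "cp_sim_error")
  for (v in list(lmo4_given_cspp, gfp_prob, tracer_prob))
    if (any(v < 0 | v > 1))
      cp_stop("marker probabilities must lie in [0, 1]", "cp_sim_error")
  if (!is_count(cells_per_animal) || !is_count(n_animals))
    cp_stop("'cells_per_animal' and 'n_animals' must be positive integers",
            "cp_sim_error")
  if (nrow(class_probs) != 3L || ncol(class_probs) != 4L)
    cp_stop("'class_probs' must be 3 layers x 4 classes", "cp_sim_error")
  rownames(class_probs) <- names(lmo4_given_cspp) <- names(gfp_prob) <-
    names(tracer_prob) <- unique(scheme$layer_map)
  colnames(class_probs) <- c("C+/S+", "C+/S-", "C-/S+", "C-/S-")
  structure(list(scheme = scheme, class_probs = class_probs,
                 lmo4_given_cspp = lmo4_given_cspp, gfp_prob = gfp_prob,
                 tracer_prob = tracer_prob,
                 cells_per_animal = cells_per_animal,
                 n_animals = n_animals,
                 cortex_thickness_um = cortex_thickness_um,
                 area = area, age = age, seed = seed),
            class = "cp_cellmap_spec")
}

#' Simulate a laminar cell map
#'
#' @param cs A [cell_map_spec()].
#' @return A laminar cell table (data frame, one row per cell) with the
#'   generator probabilities attached as the `"truth"` attribute.
#' @export
simulate_cell_map <- function(cs) {
  stopifnot(inherits(cs, "cp_cellmap_spec"))
  classes <- c("C+/S+", "C+/S-", "C-/S+", "C-/S-")
  with_seed(cs$seed, {
    rows <- lapply(seq_len(cs$n_animals), function(a) {
      n <- cs$cells_per_animal
      depth <- stats::runif(n, 0, cs$cortex_thickness_um)
      d <- depth / cs$cortex_thickness_um
      bin <- pmin(floor(d * cs$scheme$n_bins) + 1L, cs$scheme$n_bins)
      layer <- cs$scheme$layer_map[bin]
      cls <- vapply(layer, function(l)
        sample(classes, 1L, prob = cs$class_probs[l, ]), character(1))
      ctip2 <- as.integer(cls %in% c("C+/S+", "C+/S-"))
      satb2 <- as.integer(cls %in% c("C+/S+", "C-/S+"))
      lmo4 <- as.integer(cls == "C+/S+" &
                           stats::runif(n) < cs$lmo4_given_cspp[layer])
      gfp <- as.integer(stats::runif(n) < cs$gfp_prob[layer])
      tracer <- as.integer(stats::runif(n) < cs$tracer_prob[layer])
      data.frame(cell_id = sprintf("a%d_c%04d", a, seq_len(n)),
                 animal_id = paste0("animal", a), area = cs$area,
                 age = cs$age, depth_um = depth,
                 cortex_thickness_um = cs$cortex_thickness_um,
                 window_width_um = 600, ctip2 = ctip2, satb2 = satb2,
                 lmo4 = lmo4, gfp = gfp, tracer = tracer)
    })
    tab <- do.call(rbind, rows)
    attr(tab, "truth") <- list(class_probs = cs$class_probs, spec = cs)
    tab
  })
}
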