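# triangular AP rising/falling at 800 V/s between -45 and +35 mV,
# sitting on a flat baseline
triangle_ap <- function(peak_t = 50, dt = 0.1, base = -45, peak = 35,
                        rise = 1, fall = 1, total = 100) {
  t <- seq(0, total, by = dt)
  up <- t >= peak_t - rise & t <= peak_t
  dn <- t > peak_t & t <= peak_t + fall
  v <- rep(base, length(t))
  v[up] <- peak + (peak - base) / rise * (t[up] - peak_t)
  v[dn] <- peak - (peak - base) / fall * (t[dn] - peak_t)
  sweep_trace(v, dt = dt, i_step = 120, step_onset = 5,
              step_offset = total - 5)
}

test_that("spike detection finds template APs and nothing else", {
  # 4 triangular APs at prescribed times
  t <- seq(0, 500, by = 0.1)
  v <- rep(-60, length(t))
  for (pt in c(100, 150, 230, 350)) {
    up <- t >= pt - 1 & t <= pt
    dn <- t > pt & t <= pt + 1
    v[up] <- 20 + 80 * (t[up] - pt)
    v[dn] <- 20 - 80 * (t[dn] - pt)
  }
  sw <- sweep_trace(v, 0.1, 120, 20, 480)
  det <- detect_spikes(sw)
  expect_equal(det$t_peak, c(100, 150, 230, 350))
  # subthreshold noisy trace (max -40 mV): empty result
  set.seed(5)
  sub <- sweep_trace(pmin(-60 + cumsum(rnorm(5000, 0, 0.3)), -40),
                     0.1, 40, 20, 480)
  expect_equal(nrow(detect_spikes(sub)), 0L)
})

test_that("threshold interpolation is linear in the derivative", {
  # craft samples whose central differences are 15 and 25 V/s with
  # voltages -45.0 and -44.8 at the bracketing pair
  dt <- 0.1
  v <- rep(-50, 40)
  v[10] <- -47.8; v[11] <- -45.0; v[12] <- -44.8; v[13] <- -40.0
  v[14] <- -20; v[15] <- 10; v[16] <- 30; v[17] <- 10; v[18] <- -20
  v[19:40] <- -50
  sw <- sweep_trace(v, dt, 120, 0.5, 3.5)
  d <- trace_derivative(sw)
  expect_equal(d[11], 15)
  expect_equal(d[12], 25)
  thr <- interpolate_threshold(sw, 16)
  expect_equal(thr$v_thr, -44.9)   # f = 0.5 -> midpoint
  # truncated upstroke: derivative never below 20 before the peak
  steep <- sweep_trace(seq(-60, 60, by = 4), 0.1, 120, 0.2, 2.8)
  pk <- which.max(steep$v)
  expect_error(interpolate_threshold(steep, pk),
               class = "cp_undefined_threshold")
})

test_that("interpolated threshold matches the closed form on
           piecewise-linear-derivative APs", {
  set.seed(13)
  for (off in runif(20, 0, 0.1)) {
    ap <- make_pld_ap(offset = off)
    det <- detect_spikes(ap$sweep)
    expect_equal(nrow(det), 1L)
    thr <- interpolate_threshold(ap$sweep, det$idx)
    expect_lt(abs(thr$v_thr - ap$v_thr_true), 0.01)
    expect_lt(abs(thr$t_thr - ap$t_thr_true), 0.05)
  }
})

test_that("waveform features follow the threshold-as-baseline geometry", {
  sw <- triangle_ap()
  det <- detect_spikes(sw)
  f <- ap_waveform_features(sw, det$idx, v_thr = -45,
                            t_thr = 50 - 1)
  expect_equal(f$amplitude, 80)
  expect_equal(f$half_width, 1, tolerance = 1e-6)
  expect_equal(f$duration, 2, tolerance = 1e-6)
  # 10-90% crossings on an 800 V/s linear upstroke: 0.8 ms apart
  expect_equal(f$rise_time, 0.8, tolerance = 1e-6)
  # trace truncated before the downward return: duration undefined
  half <- sweep_trace(sw$v[1:which.max(sw$v)], sw$dt, 120, 5, 49)
  fh <- ap_waveform_features(half, which.max(half$v), -45, 49)
  expect_true(is.na(fh$duration))
})

test_that("fast and medium afterpotentials equal windowed-extrema oracles", {
  # prescribed windows: v_thr -40, 3 ms minimum -52 at +1.8 ms
  dt <- 0.1
  t <- seq(0, 200, by = dt)
  v <- rep(-45, length(t))
  pk <- 501  # peak at 50 ms
  v[pk] <- 30
  v[t > 50 & t <= 53] <- -50
  v[t > 50 & t <= 51.85 & t >= 51.75] <- -52
  sw <- sweep_trace(v, dt, 160, 5, 195)
  fa <- fast_afterpotentials(sw, pk, v_thr = -40)
  expect_equal(fa$fahp, 12)
  expect_equal(fa$t_fahp, 1.8, tolerance = 1e-6)
  # fdap: maximum within 5 ms after the minimum, minus the minimum
  expect_equal(fa$fdap, -45 - (-52))
  # in-burst rule: the next spike's threshold replaces the maximum
  fa2 <- fast_afterpotentials(sw, pk, v_thr = -40, next_v_thr = -41)
  expect_equal(fa2$fdap, -41 - (-52))
  # truncated window is flagged, not zero
  fa3 <- fast_afterpotentials(sw, length(v) - 5L, v_thr = -40)
  expect_true(is.na(fa3$fahp))
  # random traces: exhaustive scan oracle for all window features
  set.seed(17)
  for (r in 1:30) {
    sw <- random_sweep(n = 2500)  # long enough for the 50 + 70 ms windows
    pk <- sample(200:700, 1)
    t <- sweep_times(sw)
    fa <- fast_afterpotentials(sw, pk, v_thr = -40)
    o_min <- oracle_window_ext(sw$v, t, pk, 3, "min", sw$dt)
    expect_equal(fa$fahp, -40 - o_min$value)
    expect_equal(fa$t_fahp, o_min$t - t[pk])
    o_max <- oracle_window_ext(sw$v, t, o_min$idx, 5, "max", sw$dt)
    expect_equal(fa$fdap, o_max$value - o_min$value)
    ma <- medium_afterpotentials(sw, pk, v_thr = -40)
    m_min <- oracle_window_ext(sw$v, t, pk, 50, "min", sw$dt)
    expect_equal(ma$mahp, -40 - m_min$value)
    m_max <- oracle_window_ext(sw$v, t, m_min$idx, 70, "max", sw$dt)
    expect_equal(ma$mdap, m_max$value - m_min$value)
  }
})

test_that("burst grouping follows the greedy ISI rule and conserves spikes", {
  b <- group_bursts(c(100, 106, 300), burst_isi_max = 15)
  expect_equal(b, list(1:2, 3L))
  # all ISIs above the bound: every spike its own burst
  b2 <- group_bursts(c(100, 150, 230), 15)
  expect_equal(lengths(b2), c(1L, 1L, 1L))
  # a 4th close spike starts a new burst (max size 3)
  b3 <- group_bursts(c(100, 106, 112, 118), 15)
  expect_equal(lengths(b3), c(3L, 1L))
  # random trains: rule-replay oracle; conservation; sizes in 1..3
  set.seed(23)
  for (r in 1:50) {
    times <- sort(runif(sample(1:12, 1), 0, 500))
    got <- group_bursts(times, 12)
    expect_equal(got, oracle_bursts(times, 12))
    expect_equal(sort(unlist(got)), seq_along(times))
    expect_true(all(lengths(got) %in% 1:3))
  }
})

test_that("firing profile extracts rheobase, f-I and the ISI ratio", {
  p <- spike_sim_params(noise_rms = 0)
  s <- simulate_spiking_sweeps(p)
  fp <- firing_profile(s)
  expect_equal(fp$rheobase, 80)
  expect_equal(fp$isi_sweep_i, 160)  # nearest step to 2x rheobase
  expect_equal(fp$isi_ratio, 0.5, tolerance = 0.02)
  expect_false(is.unsorted(fp$fi$rate_hz))
  # spikes at {100, 150, 230, 350} ms: first ISI 50, last 120
  expect_equal(50 / 120, 0.4167, tolerance = 1e-4)
  sub <- simulate_passive_sweeps(passive_sim_params(noise_rms = 0))
  sub$protocol <- "firing_2s"
  expect_error(firing_profile(sub), class = "cp_no_rheobase")
})

test_that("prescribed spike features are recovered from noiseless
           template trains within a sample period / 0.2 mV", {
  for (mode in c("single", "doublet", "triplet")) {
    p <- spike_sim_params(burst_mode = mode, noise_rms = 0)
    s <- simulate_spiking_sweeps(p)
    tr <- attr(s, "truth")
    j <- which(sweep_currents(s) == tr$isi_sweep_i)
    sa <- analyze_spikes(s$sweeps[[j]])
    ev <- tr$events[tr$events$i_step == tr$isi_sweep_i, ]
    expect_equal(nrow(sa$spikes), nrow(ev))
    expect_lt(max(abs(sa$spikes$t_peak - ev$t_peak)), 0.1 + 1e-9)
    expect_lt(max(abs(sa$spikes$v_thr - ev$v_thr)), 0.05)
    expect_lt(max(abs(sa$spikes$amplitude - ev$amplitude)), 0.05)
    expect_lt(max(abs(sa$spikes$half_width - ev$half_width)), 0.1)
    expect_lt(max(abs(sa$spikes$fahp - ev$fahp)), 0.05)
    expect_lt(max(abs(sa$spikes$fdap - ev$fdap)), 0.05)
    last <- ev$burst_pos == ev$burst_size
    expect_lt(max(abs(sa$bursts$mahp - ev$mahp[last])), 0.05)
    ok <- !is.na(ev$mdap[last])
    expect_lt(max(abs(sa$bursts$mdap[ok] - ev$mdap[last][ok])), 0.05)
  }
})
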