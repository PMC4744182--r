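test_that("simulator parameter objects validate their invariants", {
  expect_error(passive_sim_params(r_m = -5), class = "cp_sim_error")
  expect_error(passive_sim_params(sag_frac = 1.2), class = "cp_sim_error")
  expect_error(passive_sim_params(sag_frac = 0.2, tau_m = 50,
                                  tau_sag = 40), class = "cp_sim_error")
  expect_error(spike_sim_params(ap_amplitude = 40), class = "cp_sim_error")
  expect_error(spike_sim_params(fahp_true = 3), class = "cp_sim_error")
  expect_error(spike_sim_params(mahp_true = 6, fahp_true = 7),
               class = "cp_sim_error")
  expect_error(spike_sim_params(burst_mode = "doublet",
                                intra_burst_isi = 2),
               class = "cp_waveform_overlap")
  expect_error(mixture_spec(matrix(0, 2, 3), sds = -1),
               class = "cp_sim_error")
  expect_error(cell_map_spec(class_probs = rbind(c(2, -1, 0, 0),
                                                 c(.25, .25, .25, .25),
                                                 c(.25, .25, .25, .25))),
               class = "cp_sim_error")
})

test_that("generators are bit-deterministic given a seed and leave the
           caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_passive_sweeps(passive_sim_params(seed = 5))
  b <- simulate_passive_sweeps(passive_sim_params(seed = 5))
  expect_identical(lapply(a$sweeps, `[[`, "v"),
                   lapply(b$sweeps, `[[`, "v"))
  expect_identical(runif(1), before)
  m1 <- simulate_morphology_table(tri_mixture(seed = 4))
  m2 <- simulate_morphology_table(tri_mixture(seed = 4))
  expect_identical(m1, m2)
  c1 <- simulate_cell_map(cell_map_spec(seed = 4))
  c2 <- simulate_cell_map(cell_map_spec(seed = 4))
  expect_identical(c1, c2)
  s1 <- simulate_spiking_sweeps(spike_sim_params(seed = 4))
  s2 <- simulate_spiking_sweeps(spike_sim_params(seed = 4))
  expect_identical(lapply(s1$sweeps, `[[`, "v"),
                   lapply(s2$sweeps, `[[`, "v"))
})

test_that("noiseless passive sweeps recover the membrane exactly", {
  s <- simulate_passive_sweeps(passive_sim_params(r_m = 100, sag_frac = 0,
                                                  noise_rms = 0))
  pp <- passive_properties(s)
  expect_equal(pp$r_peak, 100, tolerance = 1e-4)
  expect_equal(pp$r_ss, 100, tolerance = 1e-6)
  # sag estimate stays below the noise floor when sag_frac = 0
  s2 <- simulate_passive_sweeps(passive_sim_params(sag_frac = 0,
                                                   noise_rms = 0.2,
                                                   seed = 7))
  n_ss <- 500
  expect_lt(abs(sag(s2)), 3 * 0.2 / sqrt(n_ss) + 0.25)
})

test_that("analytic passive truth matches an independent dense-grid scan", {
  p <- passive_sim_params(r_m = 120, tau_m = 15, sag_frac = 0.3,
                          tau_sag = 100, noise_rms = 0)
  s <- simulate_passive_sweeps(p)
  tr <- attr(s, "truth")
  # dense numeric scan of the deflection shape
  tt <- seq(0, 500, by = 1e-3)
  f <- (1 - exp(-tt / 15)) * (0.7 + 0.3 * exp(-tt / 100))
  expect_equal(tr$r_peak, 120 * max(f), tolerance = 1e-6)
  expect_equal(tr$t_peak, tt[which.max(f)], tolerance = 1e-2)
  f_ss <- mean(f[tt >= 450])
  expect_equal(tr$r_ss, 120 * f_ss, tolerance = 1e-5)
  expect_equal(tr$sag, 0.2 * 120 * (max(f) - f_ss), tolerance = 1e-4)
})

test_that("spike templates carry their prescribed geometry", {
  # noiseless: threshold recovered within 0.05 mV at dt = 0.1 ms
  p <- spike_sim_params(noise_rms = 0)
  s <- simulate_spiking_sweeps(p)
  tr <- attr(s, "truth")
  sw <- s$sweeps[[which(sweep_currents(s) == 160)]]
  sa <- analyze_spikes(sw)
  expect_lt(max(abs(sa$spikes$v_thr - (-42))), 0.05)
  # geometric ISI trains reproduce the adaptation ratio downstream
  for (r in c(0.3, 0.5, 0.8)) {
    p2 <- spike_sim_params(adaptation_ratio = r, noise_rms = 0)
    fp <- firing_profile(simulate_spiking_sweeps(p2))
    expect_equal(fp$isi_ratio, r, tolerance = 0.02)
  }
  # doublet construction: every burst has size 2
  p3 <- spike_sim_params(burst_mode = "doublet", noise_rms = 0)
  s3 <- simulate_spiking_sweeps(p3)
  sw3 <- s3$sweeps[[which(sweep_currents(s3) == 160)]]
  sa3 <- analyze_spikes(sw3)
  expect_true(all(sa3$bursts$size == 2L))
})

test_that("morphology mixtures honour weights, clipping and labels", {
  sp <- mixture_spec(means = rbind(c(10, 0.5), c(20, 0.9)),
                     sds = rbind(c(1, 0.05), c(1, 0.05)),
                     weights = c(1, 0), n = 50,
                     feature_names = c("soma_diameter", "sphericity"),
                     seed = 2)
  tab <- simulate_morphology_table(sp)
  expect_true(all(tab$component == 1L))
  expect_true(all(tab$sphericity > 0 & tab$sphericity <= 1))
  expect_true(all(tab$soma_diameter >= 0))
  # single isotropic component: the k = 2 silhouette shows no structure
  set.seed(83)
  sp1 <- mixture_spec(means = matrix(0, 1, 10), sds = 1, n = 100,
                      feature_names = paste0("f", 1:10), seed = 9)
  x <- zscore_table(simulate_morphology_table(sp1))$x
  km <- kmeans_pp(x, 2, n_init = 20, seed = 31)
  expect_lt(km$silhouette_mean, 0.3)
})

test_that("cell maps reproduce their generative layer probabilities", {
  # a class with probability 0 in layer V never appears there
  cp0 <- rbind(VI = c(0.2, 0.3, 0.3, 0.2),
               V = c(0, 0.5, 0.3, 0.2),
               UL = c(0.1, 0.1, 0.4, 0.4))
  map <- simulate_cell_map(cell_map_spec(class_probs = cp0, seed = 3))
  comp <- composition(map, bin_scheme(10), "dapi", "layer")
  v <- comp$summary
  expect_equal(v$mean[v$stratum == "V" & v$class == "C+/S+"], 0)
  # recovered layer percentages sit in the binomial 95% envelope
  map2 <- simulate_cell_map(cell_map_spec(seed = 11))
  tr <- attr(map2, "truth")
  comp2 <- composition(map2, bin_scheme(10), "dapi", "layer")
  ab <- assign_bins(map2, bin_scheme(10))
  # simultaneous 95% envelope across the 12 strata checked jointly
  z95 <- qnorm(1 - 0.05 / (2 * nrow(comp2$summary)))
  for (i in seq_len(nrow(comp2$summary))) {
    row <- comp2$summary[i, ]
    p_true <- tr$class_probs[row$stratum, row$class]
    n_l <- sum(ab$layer == row$stratum)
    env <- z95 * sqrt(p_true * (1 - p_true) / n_l) * 100
    expect_lt(abs(row$mean - 100 * p_true), env + 1e-9)
  }
})

test_that("areas generated with different class probabilities are told
           apart by the composition test", {
  set.seed(89)
  hits <- 0
  for (r in 1:20) {
    pa <- cell_map_spec(seed = NULL)
    cp_b <- pa$class_probs
    cp_b["V", ] <- c(0.05, 0.50, 0.20, 0.25)
    pb <- cell_map_spec(class_probs = cp_b)
    ca <- composition(simulate_cell_map(pa), bin_scheme(10), "dapi",
                      "layer")
    cb <- composition(simulate_cell_map(pb), bin_scheme(10), "dapi",
                      "layer")
    tst <- compare_compositions(composition_values(ca, "V", "C+/S+"),
                                composition_values(cb, "V", "C+/S+"))
    if (tst$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)  # 0.20 vs 0.05 at 3 animals x 500 cells
})
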