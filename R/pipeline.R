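#' Per-cell electrophysiology report with group contrasts
#'
#' Runs the passive and spike analyses for every cell and, when exactly
#' two groups with at least two cells each are present, compares every
#' feature between them with the two-sided Mann-Whitney U-test
#' ([compare_groups_mwu()]).  Action-potential waveform and
#' afterpotential features are measured on the rheobase sweep (the
#' response at threshold current) and averaged over its spikes; the
#' burst fraction is the fraction of bursts of size 2 or 3 there.
#'
#' @param cells Named list; each element a list with components
#'   `passive` and/or `firing` holding the cell's [sweep_set()]s.
#' @param groups Character vector of group labels, one per cell.
#' @param burst_isi_max Intra-burst ISI bound (ms), see
#'   [group_bursts()].
#' @param ... Passed to [detect_spikes()].
#' @return An object of class `cp_ephys_report`: `features` (one row
#'   per cell) and `tests` (per-feature MWU table, or `NULL`).
#' @export
run_ephys <- function(cells, groups, burst_isi_max = 15, ...) {
  if (length(cells) != length(groups))
    cp_stop("'groups' must have one label per cell", "cp_format_error")
  ids <- names(cells) %||% sprintf("cell%02d", seq_along(cells))
  rows <- lapply(seq_along(cells), function(j) {
    cell <- cells[[j]]
    row <- data.frame(cell_id = ids[j], group = groups[j],
                      r_peak = NA_real_, r_ss = NA_real_, sag = NA_real_,
                      t_peak_200 = NA_real_, rheobase = NA_real_,
                      isi_ratio = NA_real_, v_thr = NA_real_,
                      amplitude = NA_real_, half_width = NA_real_,
                      fahp = NA_real_, fdap = NA_real_, mahp = NA_real_,
                      mdap = NA_real_, burst_fraction = NA_real_)
    if (!is.null(cell$passive)) {
      if (cell$passive$protocol != "passive_500ms")
        cp_stop(sprintf("cell '%s': 'passive' slot holds a %s protocol",
                        ids[j], cell$passive$protocol), "cp_format_error")
      pp <- passive_properties(cell$passive)
      row$r_peak <- pp$r_peak; row$r_ss <- pp$r_ss
      row$sag <- pp$sag; row$t_peak_200 <- pp$t_peak_200
    }
    if (!is.null(cell$firing)) {
      if (cell$firing$protocol != "firing_2s")
        cp_stop(sprintf("cell '%s': 'firing' slot holds a %s protocol",
                        ids[j], cell$firing$protocol), "cp_format_error")
      fp <- firing_profile(cell$firing, ...)
      row$rheobase <- fp$rheobase
      row$isi_ratio <- fp$isi_ratio
      cur <- sweep_currents(cell$firing)
      rheo_sweep <- cell$firing$sweeps[[which(cur == fp$rheobase)[1L]]]
      sa <- analyze_spikes(rheo_sweep, burst_isi_max = burst_isi_max, ...)
      if (nrow(sa$spikes)) {
        m <- function(x) mean(x, na.rm = TRUE)
        row$v_thr <- m(sa$spikes$v_thr)
        row$amplitude <- m(sa$spikes$amplitude)
        row$half_width <- m(sa$spikes$half_width)
        row$fahp <- m(sa$spikes$fahp)
        row$fdap <- m(sa$spikes$fdap)
        row$mahp <- m(sa$bursts$mahp)
        row$mdap <- m(sa$bursts$mdap)
        row$burst_fraction <- mean(sa$bursts$size >= 2L)
      }
    }
    row
  })
  features <- do.call(rbind, rows)
  tests <- NULL
  gl <- unique(groups)
  if (length(gl) == 2L && all(table(groups) >= 2L)) {
    tests <- compare_groups_mwu(features, gl[1L], gl[2L])
    tests <- tests[!is.na(tests$p), , drop = FALSE]
  } else {
    cp_warn("group contrasts skipped: need exactly 2 groups with >= 2 cells each",
            "cp_contrast_skipped")
  }
  structure(list(features = features, tests = tests,
                 groups = gl), class = "cp_ephys_report")
}

#' @export
print.cp_ephys_report <- function(x, ...) {
  cat(sprintf("<cp_ephys_report> %d cells in group(s): %s\n",
              nrow(x$features), paste(x$groups, collapse = ", ")))
  if (!is.null(x$tests)) {
    sig <- x$tests[!is.na(x$tests$p) & x$tests$p <= 0.05, ]
    cat(sprintf("  %d/%d features differ at p <= 0.05%s\n", nrow(sig),
                nrow(x$tests),
                if (nrow(sig)) paste0(": ",
                                      paste(sig$feature, collapse = ", "))
                else ""))
  }
  invisible(x)
}

# deterministic TSV/JSON writers used by the demo (no timestamps, fixed
# numeric formatting, so reruns are byte-identical)
demo_write_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.10g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' End-to-end demonstration run
#'
#' Simulates all three data types and runs all three analyses with one
#' seed: (1) passive + firing protocols for two cell groups (9 high-
#' resistance vs 23 low-resistance cells, mirroring a Ctip2-only vs
#' Ctip2/Satb2 double-positive contrast) analysed by [run_ephys()];
#' (2) a 145-neuron three-profile morphology mixture clustered by
#' [select_k()]; (3) a 3-animal laminar cell map for two areas with
#' different layer-V `C+/S+` abundance, summarized by [composition()]
#' and compared per stratum.  All outputs are plain TSV/JSON embedding
#' the seed and settings; reruns with the same seed are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed driving every simulated input.
#' @return Invisibly, a list with the result objects and output paths.
#' @export
run_full_demo <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(seed, {
    ## 1 - electrophysiology: two groups differing in input resistance,
    ## sag and firing pattern
    make_cell <- function(id, r_m, sag_frac, burst_mode) {
      rm_j <- stats::rnorm(1, r_m, r_m * 0.06)
      list(
        passive = simulate_passive_sweeps(
          passive_sim_params(r_m = rm_j, sag_frac = sag_frac,
                             noise_rms = 0.2),
          cell_id = paste0(id, "_passive")),
        firing = simulate_spiking_sweeps(
          spike_sim_params(rheobase_pA = sample(c(60, 80, 100), 1),
                           burst_mode = burst_mode,
                           adaptation_ratio = stats::runif(1, 0.4, 0.8),
                           noise_rms = 0.1),
          cell_id = paste0(id, "_firing")))
    }
    cells <- c(
      lapply(sprintf("ctip2_%02d", 1:9), make_cell, r_m = 110,
             sag_frac = 0.20, burst_mode = "single"),
      lapply(sprintf("cs_%02d", 1:23), make_cell, r_m = 73,
             sag_frac = 0.10, burst_mode = "doublet"))
    names(cells) <- c(sprintf("ctip2_%02d", 1:9), sprintf("cs_%02d", 1:23))
    ephys <- run_ephys(cells, c(rep("Ctip2", 9), rep("CS", 23)))

    ## 2 - morphometric clustering
    morph <- simulate_morphology_table(default_morphology_mixture(n = 145))
    z <- zscore_table(morph)
    ks <- select_k(z$x)
    profiles <- cluster_profiles(morph, ks$best$labels)

    ## 3 - laminar composition, two areas
    map_a <- simulate_cell_map(cell_map_spec(area = "pS"))
    cp_b <- rbind(VI = c(0.10, 0.25, 0.30, 0.35),
                  V = c(0.05, 0.50, 0.20, 0.25),
                  UL = c(0.03, 0.02, 0.70, 0.25))
    map_b <- simulate_cell_map(cell_map_spec(area = "FM",
                                             class_probs = cp_b))
    comp_a <- composition(map_a, bin_scheme(10), "dapi", "layer")
    comp_b <- composition(map_b, bin_scheme(10), "dapi", "layer")
    comp_tests <- lapply(c("VI", "V", "UL"), function(l)
      compare_compositions(composition_values(comp_a, l, "C+/S+"),
                           composition_values(comp_b, l, "C+/S+")))
    names(comp_tests) <- c("VI", "V", "UL")
    list(ephys = ephys, morph = morph, kselect = ks, profiles = profiles,
         comp_a = comp_a, comp_b = comp_b, comp_tests = comp_tests)
  })
  paths <- list(
    ephys_features = file.path(out_dir, "ephys_features.tsv"),
    ephys_tests = file.path(out_dir, "ephys_tests.tsv"),
    cluster_labels = file.path(out_dir, "cluster_labels.tsv"),
    cluster_profiles = file.path(out_dir, "cluster_profiles.tsv"),
    composition = file.path(out_dir, "composition.tsv"),
    summary = file.path(out_dir, "summary.json"))
  demo_write_tsv(res$ephys$features, paths$ephys_features)
  demo_write_tsv(res$ephys$tests, paths$ephys_tests)
  demo_write_tsv(data.frame(neuron_id = res$morph$neuron_id,
                            group = res$morph$group,
                            cluster = res$kselect$best$labels,
                            silhouette = res$kselect$best$silhouette),
                 paths$cluster_labels)
  demo_write_tsv(res$profiles, paths$cluster_profiles)
  both <- rbind(cbind(area = "pS", res$comp_a$summary),
                cbind(area = "FM", res$comp_b$summary))
  demo_write_tsv(both, paths$composition)
  summary <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("cortiphys")),
    ephys = list(
      n_cells = nrow(res$ephys$features),
      groups = as.list(table(res$ephys$features$group)),
      significant_features =
        res$ephys$tests$feature[res$ephys$tests$p <= 0.05]),
    clustering = list(chosen_k = res$kselect$k,
                      silhouette_by_k = res$kselect$table$silhouette,
                      cluster_sizes = as.integer(
                        table(res$kselect$best$labels))),
    composition = lapply(res$comp_tests, function(ct)
      list(t = ct$t, p = ct$p, stars = ct$stars,
           mean_pS = ct$mean_a, mean_FM = ct$mean_b)))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(res, list(paths = paths)))
}
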