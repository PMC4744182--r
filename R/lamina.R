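#' Laminar bin schemes
#'
#' Equal-thickness radial divisions of the cortex mapped to layers.
#' The 6-bin scheme (used at P0, alias `"p0"`) maps bins 1-2 to layer
#' VI, 3-4 to layer V and 5-6 to the upper layers (UL); the 10-bin
#' scheme (P7, alias `"p7"`) maps bins 1-3 to VI, 4-6 to V and 7-10 to
#' UL.  Bin 1 is the deepest bin, adjacent to the white matter.
#'
#' @param scheme `6`, `10`, `"p0"` or `"p7"`.
#' @return An object of class `cp_bin_scheme`: `n_bins` and the
#'   bin-to-layer `layer_map`.
#' @export
bin_scheme <- function(scheme = 6) {
  if (is.character(scheme))
    scheme <- switch(tolower(scheme), p0 = 6L, p7 = 10L,
                     cp_stop(paste0("unknown scheme '", scheme,
                                    "' (use 6, 10, 'p0' or 'p7')"),
                             "cp_format_error"))
  if (scheme == 6) {
    map <- c("VI", "VI", "V", "V", "UL", "UL")
  } else if (scheme == 10) {
    map <- c("VI", "VI", "VI", "V", "V", "V", "UL", "UL", "UL", "UL")
  } else {
    cp_stop("n_bins must be 6 or 10", "cp_format_error")
  }
  structure(list(n_bins = as.integer(scheme), layer_map = map),
            class = "cp_bin_scheme")
}

#' @export
print.cp_bin_scheme <- function(x, ...) {
  cat(sprintf("<cp_bin_scheme> %d bins: %s\n", x$n_bins,
              paste(x$layer_map, collapse = " ")))
  invisible(x)
}

#' Assign laminar bins and layers to cells
#'
#' Relative depth `d = depth_um / cortex_thickness_um` (depth measured
#' from the cortical bottom, so bin 1 is the deepest) is cut into
#' `n_bins` half-open intervals `[i/n, (i+1)/n)`, with `d = 1` assigned
#' to the top bin; the layer label follows from the scheme's map.
#'
#' @param tab Laminar cell table: data frame with at least `depth_um`
#'   and `cortex_thickness_um` (and ideally `cell_id`).
#' @param scheme A [bin_scheme()].
#' @return `tab` with added integer `bin` and character `layer` columns.
#' @export
assign_bins <- function(tab, scheme = bin_scheme(6)) {
  for (col in c("depth_um", "cortex_thickness_um"))
    if (!col %in% names(tab))
      cp_stop(paste0("cell table missing column '", col, "'"),
              "cp_format_error")
  bad <- which(tab$depth_um < 0 | tab$depth_um > tab$cortex_thickness_um |
                 !is.finite(tab$depth_um))
  if (length(bad)) {
    id <- if ("cell_id" %in% names(tab)) tab$cell_id[bad[1L]]
          else paste0("row ", bad[1L])
    cp_stop(sprintf("depth outside [0, thickness] for cell %s (%g of %g um)",
                    id, tab$depth_um[bad[1L]],
                    tab$cortex_thickness_um[bad[1L]]), "cp_format_error")
  }
  d <- tab$depth_um / tab$cortex_thickness_um
  bin <- pmin(floor(d * scheme$n_bins) + 1L, scheme$n_bins)
  tab$bin <- as.integer(bin)
  tab$layer <- scheme$layer_map[bin]
  tab
}

#' Ctip2/Satb2 marker class of each cell
#'
#' Deterministic four-class partition of the boolean Ctip2/Satb2 calls:
#' `C+/S+` (double positive), `C+/S-`, `C-/S+`, `C-/S-`.  When an
#' `lmo4` column is present, the returned data frame also flags the
#' triple Lmo4/Ctip2/Satb2 subclass of `C+/S+`.
#'
#' @param tab Data frame with 0/1 or logical `ctip2` and `satb2`
#'   columns (optionally `lmo4`).
#' @return Character vector of class labels, with a `triple` logical
#'   attribute when `lmo4` is available.
#' @export
classify_markers <- function(tab) {
  for (col in c("ctip2", "satb2"))
    if (!col %in% names(tab) || anyNA(tab[[col]]))
      cp_stop(paste0("missing required marker call '", col, "'"),
              "cp_format_error")
  ctip2 <- as.logical(tab$ctip2)
  satb2 <- as.logical(tab$satb2)
  cls <- ifelse(ctip2 & satb2, "C+/S+",
         ifelse(ctip2 & !satb2, "C+/S-",
         ifelse(!ctip2 & satb2, "C-/S+", "C-/S-")))
  if ("lmo4" %in% names(tab))
    attr(cls, "triple") <- ctip2 & satb2 & as.logical(tab$lmo4)
  cls
}

#' Marker-class composition per laminar stratum
#'
#' Counts the four Ctip2/Satb2 classes per stratum (bin or layer) and
#' animal, normalizes by the chosen denominator population (all DAPI
#' cells, or the Ctip2+, Satb2+, GFP+ or tracer+ cells of the stratum)
#' and averages the per-animal percentages, with SEM = sd / sqrt(n)
#' across animals — animals, not cells, are the replication unit.
#' Strata with an empty denominator are undefined (`NA`), never 0%.
#'
#' @param tab Laminar cell table (one row per cell) with `animal_id`,
#'   `depth_um`, `cortex_thickness_um` and 0/1 marker columns `ctip2`,
#'   `satb2` (plus `gfp`/`tracer` when used as denominator).
#' @param scheme A [bin_scheme()].
#' @param denominator One of `"dapi"`, `"ctip2"`, `"satb2"`, `"gfp"`,
#'   `"tracer"`.
#' @param scope `"layer"` or `"bin"`.
#' @return An object of class `cp_composition`: `per_animal` (animal x
#'   stratum x class counts and percentages) and `summary` (stratum x
#'   class mean, sem, n_animals), plus the call settings.
#' @export
composition <- function(tab, scheme = bin_scheme(6),
                        denominator = c("dapi", "ctip2", "satb2", "gfp",
                                        "tracer"),
                        scope = c("layer", "bin")) {
  denominator <- match.arg(denominator)
  scope <- match.arg(scope)
  if (!"animal_id" %in% names(tab))
    cp_stop("cell table missing column 'animal_id'", "cp_format_error")
  tab <- assign_bins(tab, scheme)
  tab$class <- classify_markers(tab)
  tab$stratum <- if (scope == "layer") tab$layer else as.character(tab$bin)
  denom_ok <- if (denominator == "dapi") rep(TRUE, nrow(tab))
              else as.logical(tab[[denominator]])
  if (denominator %in% c("gfp", "tracer") && !denominator %in% names(tab))
    cp_stop(paste0("cell table missing column '", denominator, "'"),
            "cp_format_error")
  strata <- if (scope == "layer") unique(scheme$layer_map)
            else as.character(seq_len(scheme$n_bins))
  classes <- c("C+/S+", "C+/S-", "C-/S+", "C-/S-")
  animals <- sort(unique(tab$animal_id))
  grid <- expand.grid(animal_id = animals, stratum = strata,
                      class = classes, stringsAsFactors = FALSE)
  cnt <- function(sel) {
    as.data.frame(table(animal_id = tab$animal_id[sel],
                        stratum = factor(tab$stratum[sel], levels = strata),
                        class = factor(tab$class[sel], levels = classes)),
                  stringsAsFactors = FALSE)
  }
  num <- cnt(denom_ok)
  names(num)[names(num) == "Freq"] <- "n_class"
  den <- stats::aggregate(list(n_denom = denom_ok),
                          by = list(animal_id = tab$animal_id,
                                    stratum = tab$stratum), FUN = sum)
  per <- merge(merge(grid, num, all.x = TRUE), den, all.x = TRUE)
  per$n_class[is.na(per$n_class)] <- 0L
  per$n_denom[is.na(per$n_denom)] <- 0L
  per$pct <- ifelse(per$n_denom > 0, 100 * per$n_class / per$n_denom,
                    NA_real_)
  if (any(per$n_denom == 0))
    cp_warn(sprintf("%d animal x stratum cell(s) have an empty '%s' denominator; reported as undefined",
                    sum(per$n_denom == 0) / length(classes), denominator),
            "cp_empty_stratum")
  per <- per[order(per$stratum, per$class, per$animal_id), , drop = FALSE]
  rownames(per) <- NULL
  sm <- do.call(rbind, lapply(split(per, per[c("stratum", "class")]),
    function(g) {
      v <- g$pct[!is.na(g$pct)]
      data.frame(stratum = g$stratum[1L], class = g$class[1L],
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                       else NA_real_,
                 n_animals = length(v))
    }))
  rownames(sm) <- NULL
  structure(list(per_animal = per, summary = sm, scheme = scheme,
                 denominator = denominator, scope = scope),
            class = "cp_composition")
}

#' @export
print.cp_composition <- function(x, digits = 1, ...) {
  cat(sprintf("<cp_composition> %% of %s cells per %s (%d-bin scheme)\n",
              toupper(x$denominator), x$scope, x$scheme$n_bins))
  sm <- x$summary
  sm$mean <- round(sm$mean, digits)
  sm$sem <- round(sm$sem, digits)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' Extract per-animal percentages for one stratum and class
#'
#' @param comp A [composition()] result.
#' @param stratum Stratum label (layer name or bin number as character).
#' @param class Marker class label (e.g. `"C+/S+"`).
#' @return Named numeric vector of per-animal percentages.
#' @export
composition_values <- function(comp, stratum, class) {
  per <- comp$per_animal
  sel <- per$stratum == stratum & per$class == class
  stats::setNames(per$pct[sel], per$animal_id[sel])
}

#' Two-tailed Student's t-test between per-animal compositions
#'
#' Classic pooled-variance two-sample t-test (Welch optional) of
#' per-animal percentages, with significance stars at the 0.05 / 0.01 /
#' 0.001 thresholds.  When both groups have zero variance the test is
#' degenerate: equal means give p = 1, unequal means give p = 0 with a
#' warning.
#'
#' @param a,b Numeric vectors of per-animal values (each length >= 2;
#'   `NA`s dropped).
#' @param var_equal Pooled variance (TRUE, the default "Student"
#'   flavour) or Welch (FALSE).
#' @return An object of class `cp_ttest`: `t`, `df`, `p`, `stars`,
#'   `mean_a`, `mean_b`.
#' @export
compare_compositions <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    cp_stop("need at least 2 replicates per group", "cp_insufficient_data")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      out <- list(t = 0, df = length(a) + length(b) - 2L, p = 1)
    } else {
      cp_warn("zero variance in both groups with unequal means: degenerate test",
              "cp_degenerate_test")
      out <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2L, p = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  out$stars <- p_stars(out$p)
  out$mean_a <- mean(a)
  out$mean_b <- mean(b)
  class(out) <- "cp_ttest"
  out
}

#' @export
print.cp_ttest <- function(x, ...) {
  cat(sprintf("<cp_ttest> t = %.3f, df = %g, p = %.4g %s\n", x$t, x$df,
              x$p, x$stars))
  cat(sprintf("  means: %.2f vs %.2f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Threshold synthetic marker intensities into boolean calls
#'
#' Convenience for simulated intensity columns: `call = intensity >
#' theta`.  Image-derived intensity thresholding is upstream of this
#' package; this utility only serves synthetic data.
#'
#' @param intensity Numeric vector.
#' @param theta Threshold.
#' @return Integer 0/1 vector.
#' @export
threshold_calls <- function(intensity, theta) {
  as.integer(intensity > theta)
}

#' Read a laminar cell table from CSV
#'
#' Expected columns: `cell_id`, `animal_id`, `area`, `age`, `depth_um`,
#' `cortex_thickness_um`, `window_width_um`, and 0/1 marker columns
#' (`ctip2`, `satb2`, `lmo4`, `gfp`, `tracer`).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) cp_stop(paste0("no such file: ", path),
                                  "cp_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "animal_id", "depth_um", "cortex_thickness_um",
            "ctip2", "satb2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    cp_stop(paste0("cell table missing column(s): ",
                   paste(miss, collapse = ", ")), "cp_format_error")
  tab
}
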