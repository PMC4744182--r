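#' Canonical morphometric feature schema
#'
#' The fixed, named set of per-neuron morphometric features the
#' clustering pipeline operates on: soma geometry (diameter, area,
#' volume, oblate ellipticity, sphericity), the apical dendrite diameter
#' measured 5 um from the soma limit, the radial position (soma center
#' to pial membrane), the distance from the soma to the first apical
#' bifurcation, the count of secondary dendrites within ~70 um of the
#' soma, the number of basal dendrites, and the mean basal-dendrite
#' angle (the summary chosen for the angle sets).
#'
#' @return Character vector of feature column names.
#' @export
morph_feature_names <- function() {
  c("soma_diameter", "soma_area", "soma_volume", "oblate_ellipticity",
    "sphericity", "apical_diameter_5um", "radial_position",
    "bifurcation_distance", "ramification_count", "n_basal_dendrites",
    "basal_angle_mean")
}

#' Read / write a morphometric feature table
#'
#' Plain TSV with a header row; `neuron_id` and `group` columns plus
#' numeric feature columns (see [morph_feature_names()]).
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_morph_table <- function(path) {
  if (!file.exists(path)) cp_stop(paste0("no such file: ", path),
                                  "cp_io_error")
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c("neuron_id", "group"))
    if (!col %in% names(tab))
      cp_stop(paste0("morphometric table missing column '", col, "'"),
              "cp_format_error")
  tab
}

#' @rdname read_morph_table
#' @param tab Data frame to write.
#' @export
write_morph_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Inner-join two morphometric tables on neuron_id
#'
#' Supports matched-subset analyses in which features measured at two
#' magnifications are combined for the neurons present in both tables
#' (e.g. adding radial position and bifurcation distance for the
#' matched subset).
#'
#' @param a,b Data frames with a `neuron_id` column.
#' @return The joined data frame (columns of `a`, then the non-id
#'   feature columns of `b`).
#' @export
match_morph_tables <- function(a, b) {
  keep <- setdiff(names(b), setdiff(intersect(names(a), names(b)),
                                    "neuron_id"))
  merge(a, b[, keep, drop = FALSE], by = "neuron_id")
}

#' Z-scale standardization of a feature table
#'
#' Transforms each feature column to `(x - mean) / sd` so that scale
#' differences between features do not dominate the squared-Euclidean
#' distance.  Zero-variance columns are dropped with a warning; rows
#' with missing feature values are dropped for clustering (their ids
#' are reported in the result).
#'
#' @param tab Data frame (feature columns selected automatically,
#'   skipping `neuron_id`/`group`/`component`) or numeric matrix.
#' @param ddof Degrees-of-freedom correction for the sd: 0 (population
#'   sd, the default) or 1 (sample sd).
#' @return List with `x` (standardized matrix), `center`, `scale`
#'   (named per-feature parameters for reuse), `dropped` (zero-variance
#'   columns) and `dropped_rows` (row indices removed for missingness).
#' @export
zscore_table <- function(tab, ddof = 0) {
  if (is.data.frame(tab)) {
    meta <- intersect(c("neuron_id", "group", "component"), names(tab))
    num <- vapply(tab, is.numeric, logical(1)) & !(names(tab) %in% meta)
    x <- as.matrix(tab[, num, drop = FALSE])
  } else {
    x <- as.matrix(tab)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < 2L)
    cp_stop("need at least 2 rows to standardize", "cp_insufficient_data")
  dropped_rows <- which(apply(x, 1L, anyNA))
  if (length(dropped_rows)) x <- x[-dropped_rows, , drop = FALSE]
  ctr <- colMeans(x)
  n <- nrow(x)
  sdv <- sqrt(colSums((x - rep(ctr, each = n))^2) / (n - ddof))
  zero <- sdv == 0 | !is.finite(sdv)
  if (all(zero))
    cp_stop("all feature columns have zero variance", "cp_degenerate")
  if (any(zero))
    cp_warn(paste0("dropping zero-variance feature(s): ",
                   paste(colnames(x)[zero], collapse = ", ")),
            "cp_dropped_features")
  x <- x[, !zero, drop = FALSE]
  ctr <- ctr[!zero]
  sdv <- sdv[!zero]
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, sdv, "/")
  list(x = z, center = ctr, scale = sdv,
       dropped = names(zero)[zero], dropped_rows = dropped_rows)
}

# squared Euclidean distances from every row of x to every row of c
dist2_to_centroids <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(x, centroids)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first centre uniform, later centres with
# probability proportional to the squared distance to the nearest
# chosen centre
kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - rep(x[idx[1L], ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    idx[j] <- if (tot <= 0) sample.int(n, 1L)
              else sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, rowSums((x - rep(x[idx[j], ], each = n))^2))
  }
  x[idx, , drop = FALSE]
}

# one Lloyd run from given centroids; returns labels, centroids,
# inertia and the per-pass inertia trace
lloyd <- function(x, centroids, max_iter = 300L) {
  n <- nrow(x)
  k <- nrow(centroids)
  labels <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(x, centroids)
    new_labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters by re-seeding the farthest point
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      centroids[j, ] <- x[far, ]
      new_labels[far] <- j
      d2 <- dist2_to_centroids(x, centroids)
      new_labels <- max.col(-d2, ties.method = "first")
      new_labels[far] <- j
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), new_labels)]))
    if (identical(new_labels, labels)) break
    labels <- new_labels
    centroids <- rowsum(x, labels) / tabulate(labels, k)
  }
  d2 <- dist2_to_centroids(x, centroids)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = centroids, inertia = inertia,
       trace = trace, iter = it)
}

#' k-means++ clustering with restarts
#'
#' k-means with squared-Euclidean distance: k-means++ seeding followed
#' by Lloyd iterations to assignment stability (at most `max_iter`
#' passes), repeated `n_init` times with the best restart (lowest total
#' within-cluster squared distance, the inertia) retained.  Empty
#' clusters are repaired by re-seeding the farthest point.  Given a
#' seed the result is fully deterministic.
#'
#' @param x Standardized numeric matrix (rows = neurons), see
#'   [zscore_table()].
#' @param k Number of clusters, `2 <= k < nrow(x)`.
#' @param n_init Number of random restarts (default 20).
#' @param seed Optional RNG seed; the caller's RNG stream is preserved.
#' @param max_iter Maximum Lloyd passes per restart (default 300).
#' @return An object of class `cp_kmeans`: `k`, `labels`, `centroids`,
#'   `inertia`, `inertia_trace` (per-pass inertia of the winning
#'   restart), `silhouette_mean`, `silhouette` (per sample), `n_init`,
#'   `seed`.
#' @export
kmeans_pp <- function(x, k, n_init = 20, seed = NULL, max_iter = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 2L)
    cp_stop("'k' must be an integer >= 2 (the cluster scan starts at k = 2)",
            "cp_format_error")
  if (k >= n)
    cp_stop("'k' must be smaller than the number of rows", "cp_format_error")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(x, kmeanspp_seed(x, k), max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  sil <- mean_silhouette(x, best$labels)
  structure(list(k = as.integer(k), labels = best$labels,
                 centroids = best$centroids, inertia = best$inertia,
                 inertia_trace = best$trace,
                 silhouette_mean = sil$mean, silhouette = sil$values,
                 n_init = n_init, seed = seed),
            class = "cp_kmeans")
}

#' @export
print.cp_kmeans <- function(x, ...) {
  cat(sprintf(
    "<cp_kmeans> k = %d, n = %d, inertia = %.3f, mean silhouette = %.3f\n",
    x$k, length(x$labels), x$inertia, x$silhouette_mean))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Silhouette values of a clustering
#'
#' The standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distance, where `a(i)` is the mean distance of sample `i`
#' to its own cluster (excluding itself) and `b(i)` the smallest mean
#' distance to any other cluster.  Members of singleton clusters get
#' `s(i) = 0`.
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels Integer cluster assignment (at least 2 non-empty
#'   clusters).
#' @return List with `mean` and per-sample `values` in `[-1, 1]`.
#' @export
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L)
    cp_stop("silhouette needs at least 2 clusters", "cp_degenerate")
  D <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sizes <- table(factor(labels, levels = cl))
  # mean distance from every sample to every cluster
  md <- vapply(cl, function(g) rowSums(D[, labels == g, drop = FALSE]),
               numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], cl)
    ng <- sizes[[g]]
    if (ng <= 1L) { s[i] <- 0; next }
    a <- md[i, g] / (ng - 1L)
    b <- min(md[i, -g] / as.numeric(sizes[-g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(mean = mean(s), values = s)
}

#' Silhouette-guided choice of the cluster number
#'
#' Runs [kmeans_pp()] for each `k` in `k_range` (default 2..5), scores
#' each solution by its mean silhouette, picks the argmax (ties broken
#' toward the smaller k, i.e. parsimony), and re-runs the chosen `k`
#' with a large number of restarts (`final_n_init`, default 1000) for
#' the final partition.
#'
#' @param x Standardized numeric matrix.
#' @param k_range Candidate cluster numbers (default `2:5`).
#' @param n_init Restarts per candidate during the scan (default 20).
#' @param seed Optional RNG seed for the whole selection.
#' @param final_n_init Restarts of the final clustering (default 1000).
#' @return An object of class `cp_kselect`: the final `cp_kmeans` fit in
#'   `$best`, the chosen `$k`, and the per-k scan table `$table`
#'   (columns `k`, `silhouette`, `inertia`).
#' @export
select_k <- function(x, k_range = 2:5, n_init = 20, seed = NULL,
                     final_n_init = 1000) {
  x <- as.matrix(x)
  if (nrow(x) <= max(k_range))
    cp_stop("too few rows for the requested k range",
            "cp_insufficient_data")
  out <- with_seed(seed, {
    scan <- lapply(k_range, function(k) kmeans_pp(x, k, n_init = n_init))
    sil <- vapply(scan, `[[`, numeric(1), "silhouette_mean")
    k_best <- k_range[which.max(sil)]   # which.max takes the first maximum
    best <- kmeans_pp(x, k_best, n_init = final_n_init)
    list(best = best, k = k_best,
         table = data.frame(k = k_range, silhouette = sil,
                            inertia = vapply(scan, `[[`, numeric(1),
                                             "inertia")))
  })
  out$seed <- seed
  class(out) <- "cp_kselect"
  out
}

#' @export
print.cp_kselect <- function(x, ...) {
  cat(sprintf("<cp_kselect> chosen k = %d (mean silhouette %.3f)\n",
              x$k, x$best$silhouette_mean))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cp_kselect <- function(x, ...) {
  graphics::plot(x$table$k, x$table$silhouette, type = "b", pch = 19,
                 xlab = "k", ylab = "mean silhouette", ...)
  graphics::abline(v = x$k, lty = 3)
  invisible(x)
}

#' Per-cluster feature profiles
#'
#' Mean of every feature column by cluster label, on the original
#' (unstandardized) scale.
#'
#' @param tab The feature data frame used for clustering.
#' @param labels Cluster labels, one per retained row.
#' @return Data frame of per-cluster means (first column `cluster`,
#'   then `n`).
#' @export
cluster_profiles <- function(tab, labels) {
  meta <- intersect(c("neuron_id", "group", "component"), names(tab))
  num <- vapply(tab, is.numeric, logical(1)) & !(names(tab) %in% meta)
  x <- tab[, num, drop = FALSE]
  if (nrow(x) != length(labels))
    cp_stop("'labels' must have one entry per row of 'tab'",
            "cp_format_error")
  agg <- stats::aggregate(x, by = list(cluster = labels), FUN = mean)
  agg <- cbind(agg[1L], n = as.integer(table(labels)[as.character(agg$cluster)]),
               agg[-1L])
  agg
}

#' Per-feature Mann-Whitney group comparison
#'
#' Two-sided Wilcoxon Mann-Whitney U-test of every feature between two
#' groups of a morphometric table.  The p-value is exact (by
#' enumeration of the U null distribution) when the smaller group has
#' at most `exact_max` members and there are no ties, and uses the
#' normal approximation with tie correction otherwise.  Missing feature
#' values are dropped per feature, so a neuron missing one measurement
#' still contributes to the others.
#'
#' @param tab Data frame with a `group` column and numeric features.
#' @param group_a,group_b The two group labels to compare.
#' @param features Feature columns (default: all numeric non-metadata).
#' @param exact_max Largest "small" group size for the exact test
#'   (default 8).
#' @return Data frame with one row per feature: `feature`, `n_a`,
#'   `n_b`, `U`, `p`, `stars`.
#' @export
compare_groups_mwu <- function(tab, group_a, group_b, features = NULL,
                               exact_max = 8) {
  if (!"group" %in% names(tab))
    cp_stop("'tab' must contain a 'group' column", "cp_format_error")
  for (g in c(group_a, group_b))
    if (!any(tab$group == g))
      cp_stop(paste0("empty group: '", g, "'"), "cp_insufficient_data")
  if (is.null(features)) {
    meta <- intersect(c("neuron_id", "group", "component"), names(tab))
    features <- names(tab)[vapply(tab, is.numeric, logical(1)) &
                             !(names(tab) %in% meta)]
  }
  res <- lapply(features, function(f) {
    a <- tab[[f]][tab$group == group_a]
    b <- tab[[f]][tab$group == group_b]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L)
      return(data.frame(feature = f, n_a = length(a), n_b = length(b),
                        U = NA_real_, p = NA_real_))
    ties <- anyDuplicated(c(a, b)) > 0L
    use_exact <- min(length(a), length(b)) <= exact_max && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                              correct = TRUE))
    data.frame(feature = f, n_a = length(a), n_b = length(b),
               U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$stars <- p_stars(out$p)
  out
}
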