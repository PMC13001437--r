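#' Clustering configuration
#'
#' Defaults: a 12-feature subset spanning the lesion-sensitive measurements
#' (ONL thickness mean/SD/max/range, TRT, sclera total, total area, total
#' bifurcations, total domains, detachment area and fraction, and the sum
#' of sub-173-degree inflections across layers), per-feature z-scoring,
#' Euclidean distance, Ward linkage, and a 4-cluster cut.
#'
#' @param feature_subset character vector of feature-table columns.
#' @param n_clusters number of clusters at the dendrogram cut.
#' @param linkage hclust method (default `ward.D2`).
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(feature_subset = c(
                             "ONL_thick_mean", "ONL_thick_sd",
                             "ONL_thick_max", "ONL_thick_range",
                             "trt", "sclera_total", "total_area",
                             "total_bifurcations", "total_domains",
                             "rd_area", "rd_fraction",
                             "total_inflections_lt173"),
                           n_clusters = 4L, linkage = "ward.D2") {
  stopifnot(length(feature_subset) >= 1L, n_clusters >= 1L)
  structure(list(feature_subset = feature_subset,
                 n_clusters = as.integer(n_clusters), linkage = linkage),
            class = "cluster_config")
}

#' Hierarchical clustering of per-crop feature vectors
#'
#' Z-scores the configured feature subset using full-table means and SDs
#' (dropping all-constant features with a warning), clusters crops with
#' Euclidean distance and Ward linkage, and cuts the tree at the configured
#' cluster count. The z-scored matrix in dendrogram order is returned for
#' heatmap export.
#'
#' @param features data frame of image feature vectors (one row per crop).
#' @param cfg a [cluster_config()].
#' @return object of class `cluster_result`: list with `tree` (hclust),
#'   `labels` (integer per crop), `matrix` (z-scored, dendrogram order),
#'   and `features_used`.
#' @export
cluster_images <- function(features, cfg = cluster_config()) {
  missing <- setdiff(cfg$feature_subset, names(features))
  if (length(missing))
    stop("feature(s) absent from table: ", paste(missing, collapse = ", "))
  if (nrow(features) < 2L) stop("need >= 2 crops to cluster")
  m <- as.matrix(features[cfg$feature_subset])
  mode(m) <- "numeric"
  keep <- apply(m, 2, function(v) {
    v <- v[is.finite(v)]
    length(unique(v)) > 1L
  })
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  m <- m[, keep, drop = FALSE]
  if (!ncol(m)) stop("no non-constant features left to cluster on")
  z <- scale(m)
  z[!is.finite(z)] <- 0
  tree <- stats::hclust(stats::dist(z), method = cfg$linkage)
  k <- min(cfg$n_clusters, nrow(z))
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels,
                 matrix = z[tree$order, , drop = FALSE],
                 features_used = colnames(m)),
            class = "cluster_result")
}

#' Validate clusters against phenotype truth
#'
#' For every (cluster, phenotype) pair, membership in the cluster is
#' treated as the positive call for the phenotype:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param labels integer cluster labels per crop.
#' @param truth character/factor phenotype label per crop.
#' @return data frame: cluster, phenotype, tp, fn, fp, tn, sensitivity,
#'   specificity (`NA` when undefined).
#' @export
validate_clusters <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  truth <- as.character(truth)
  out <- list()
  for (cl in sort(unique(labels))) {
    for (ph in sort(unique(truth))) {
      call_pos <- labels == cl
      is_pos <- truth == ph
      tp <- sum(call_pos & is_pos); fn <- sum(!call_pos & is_pos)
      fp <- sum(call_pos & !is_pos); tn <- sum(!call_pos & !is_pos)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, phenotype = ph, tp = tp, fn = fn, fp = fp, tn = tn,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
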