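#' Statistics configuration
#'
#' @param alpha per-family significance level.
#' @param fdr_method multiple-testing correction across features.
#' @param sem_offset offset added to group SEMs before fold-change to keep
#'   the ratio finite for zero-variance features.
#' @param exact use the exact rank-sum null distribution (only possible
#'   without ties). Default FALSE: the tie-corrected normal approximation
#'   without continuity correction, whose per-test rejection rate tracks
#'   the nominal level even at very small group sizes (the exact test is
#'   markedly conservative there: at n = 4 per group its smallest
#'   attainable two-sided p is 0.0286).
#' @return object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, fdr_method = "BH",
                         sem_offset = 1e-4, exact = FALSE) {
  stopifnot(alpha > 0, alpha < 1, sem_offset > 0)
  structure(list(alpha = alpha, fdr_method = fdr_method,
                 sem_offset = sem_offset, exact = exact),
            class = "stats_config")
}

#' Cliff's delta
#'
#' `delta = (#\{x > y\} - #\{x < y\}) / (n_x * n_y)` over all pairs; in
#' \[-1, 1\], antisymmetric under group swap.
#'
#' @param x,y numeric samples.
#' @return delta.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Epsilon-squared effect size for the Kruskal-Wallis test
#'
#' `eps2 = H * (n + 1) / (n^2 - 1)` with `H` the (tie-corrected)
#' Kruskal-Wallis statistic and `n` the total sample size.
#'
#' @param H Kruskal-Wallis statistic.
#' @param n total observations.
#' @return epsilon-squared in \[0, 1\].
#' @export
epsilon_squared <- function(H, n) H * (n + 1) / (n^2 - 1)

.group_summaries <- function(v, g) {
  out <- list()
  for (lev in levels(g)) {
    vv <- v[g == lev & is.finite(v)]
    k <- length(vv)
    out[[lev]] <- list(n = k, mean = if (k) mean(vv) else NA_real_,
                       sd = if (k > 1) sd(vv) else NA_real_,
                       sem = if (k > 1) sd(vv) / sqrt(k) else NA_real_)
  }
  out
}

#' Two-group nonparametric comparison of every feature
#'
#' Per feature: a two-sided Wilcoxon rank-sum test (tie-corrected normal
#' approximation by default, exact on request; see [stats_config()]) with
#' Cliff's delta as the effect size, and Benjamini-Hochberg q-values across
#' all features tested together. A feature constant in both groups is
#' reported degenerate with `p = 1`, `delta = 0`.
#'
#' @param mat numeric matrix or data frame, rows = units of inference
#'   (mice), columns = features.
#' @param groups length-`nrow(mat)` factor or vector with exactly 2 levels.
#' @param cfg a [stats_config()].
#' @return data frame: feature, method, p, q, effect (Cliff's delta of
#'   group 1 vs group 2), per-group n/mean/sd/sem, degenerate flag.
#' @export
two_group <- function(mat, groups, cfg = stats_config()) {
  mat <- as.data.frame(mat)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("two_group requires exactly 2 groups, got ",
                             nlevels(g))
  lv <- levels(g)
  rows <- lapply(names(mat), function(f) {
    v <- as.numeric(mat[[f]])
    x <- v[g == lv[1] & is.finite(v)]
    y <- v[g == lv[2] & is.finite(v)]
    if (length(x) < 2L || length(y) < 2L)
      stop("feature ", f, ": need >= 2 observations per group")
    gs <- .group_summaries(v, g)
    if (length(unique(c(x, y))) == 1L) {
      p <- 1; delta <- 0; degen <- TRUE
    } else {
      degen <- FALSE
      ties <- anyDuplicated(c(x, y)) > 0L
      p <- suppressWarnings(
        wilcox.test(x, y, exact = cfg$exact && !ties,
                    correct = FALSE)$p.value)
      delta <- cliffs_delta(x, y)
    }
    data.frame(feature = f, method = "wilcoxon", p = p, q = NA_real_,
               effect = delta,
               n1 = gs[[1]]$n, mean1 = gs[[1]]$mean, sd1 = gs[[1]]$sd,
               sem1 = gs[[1]]$sem,
               n2 = gs[[2]]$n, mean2 = gs[[2]]$mean, sd2 = gs[[2]]$sd,
               sem2 = gs[[2]]$sem,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = cfg$fdr_method)
  attr(res, "groups") <- lv
  res
}

#' Dunn's post hoc pairwise z-tests
#'
#' Rank-based pairwise comparisons after a Kruskal-Wallis test, with the
#' tie-corrected pooled variance and BH adjustment across the pairwise
#' family.
#'
#' @param v numeric response.
#' @param g grouping factor.
#' @param fdr_method adjustment method across the pairwise comparisons.
#' @return data frame: group1, group2, z, p, q.
#' @export
dunn_test <- function(v, g, fdr_method = "BH") {
  ok <- is.finite(v)
  v <- v[ok]; g <- droplevels(factor(g[ok]))
  n <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  tie_tab <- table(v)
  tie_adj <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  out <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_adj) *
               (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- p.adjust(out$p, method = fdr_method)
  rownames(out) <- NULL
  out
}

#' Multi-group nonparametric comparison of every feature
#'
#' Per feature: tie-corrected Kruskal-Wallis test with epsilon-squared
#' effect size and BH q-values across features, plus Dunn's post hoc
#' pairwise tests with BH adjustment within each feature's pairwise family.
#'
#' @param mat numeric matrix/data frame, rows = units of inference.
#' @param groups factor with 2 or more levels (e.g. timepoint).
#' @param cfg a [stats_config()].
#' @return list with `omnibus` (feature, H, p, q, effect = eps2) and
#'   `pairwise` (feature x Dunn rows).
#' @export
multi_group <- function(mat, groups, cfg = stats_config()) {
  mat <- as.data.frame(mat)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("multi_group requires >= 2 groups")
  if (any(tapply(seq_along(g), g, length) < 2L))
    stop("every group needs >= 2 observations")
  omnibus <- list(); pairwise <- list()
  for (f in names(mat)) {
    v <- as.numeric(mat[[f]])
    if (length(unique(v[is.finite(v)])) == 1L) {
      omnibus[[f]] <- data.frame(feature = f, H = 0, p = 1, q = NA_real_,
                                 effect = 0, stringsAsFactors = FALSE)
      next
    }
    kw <- kruskal.test(v, g)
    omnibus[[f]] <- data.frame(feature = f, H = unname(kw$statistic),
                               p = kw$p.value, q = NA_real_,
                               effect = epsilon_squared(
                                 unname(kw$statistic),
                                 sum(is.finite(v))),
                               stringsAsFactors = FALSE)
    dn <- dunn_test(v, g, cfg$fdr_method)
    dn$feature <- f
    pairwise[[f]] <- dn
  }
  omnibus <- do.call(rbind, omnibus)
  omnibus$q <- p.adjust(omnibus$p, method = cfg$fdr_method)
  rownames(omnibus) <- NULL
  list(omnibus = omnibus,
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL)
}

#' SEM volcano table
#'
#' Per feature: `log2((SEM_a + offset) / (SEM_b + offset))` between the two
#' groups' standard errors of the mean, and `-log10(p)` from the matching
#' two-group rank-sum test on the underlying values. Features whose SEM is
#' undefined in either group (n = 1) are dropped with a warning.
#'
#' @param mat numeric matrix/data frame of features (rows = units).
#' @param groups two-level factor.
#' @param cfg a [stats_config()].
#' @return data frame: feature, sem1, sem2, log2_fc_sem, p, neg_log10_p.
#' @export
sem_volcano <- function(mat, groups, cfg = stats_config()) {
  res <- two_group(mat, groups, cfg)
  bad <- !is.finite(res$sem1) | !is.finite(res$sem2)
  if (any(bad))
    warning(sum(bad), " feature(s) with undefined SEM dropped")
  res <- res[!bad, , drop = FALSE]
  off <- cfg$sem_offset
  data.frame(feature = res$feature, sem1 = res$sem1, sem2 = res$sem2,
             log2_fc_sem = log2((res$sem1 + off) / (res$sem2 + off)),
             p = res$p, neg_log10_p = -log10(res$p),
             stringsAsFactors = FALSE)
}

#' Build a statistical report folder
#'
#' Writes the comparison's tables: `summary_stats.csv` (all test results),
#' `significant_features.csv` (q below alpha), `volcano.csv` (effect vs
#' -log10 q and the SEM volcano columns), `correlations_all.csv` and
#' `correlations_top50.csv` (Spearman feature correlations, the latter for
#' the 50 smallest-p features), `pca_scores.csv` (PCA of the units on
#' z-scored features) and `sample_counts.csv`, plus a `config.yaml` echo.
#'
#' @param results a [two_group()] result.
#' @param mat the feature matrix the tests were run on.
#' @param groups the group labels.
#' @param outdir output directory (created).
#' @param cfg a [stats_config()].
#' @return invisibly, the output directory.
#' @export
build_report <- function(results, mat, groups, outdir,
                         cfg = stats_config()) {
  if (!nrow(results)) stop("empty results")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mat <- as.data.frame(mat)
  write.csv(results, file.path(outdir, "summary_stats.csv"),
            row.names = FALSE)
  sig <- results[!is.na(results$q) & results$q < cfg$alpha, , drop = FALSE]
  write.csv(sig, file.path(outdir, "significant_features.csv"),
            row.names = FALSE)

  sv <- sem_volcano(mat, groups, cfg)
  volcano <- merge(
    data.frame(feature = results$feature, effect = results$effect,
               q = results$q, neg_log10_q = -log10(results$q)),
    sv, by = "feature", all.x = TRUE)
  write.csv(volcano, file.path(outdir, "volcano.csv"), row.names = FALSE)

  keep <- vapply(mat, function(v) length(unique(v[is.finite(v)])) > 1L, TRUE)
  cm <- suppressWarnings(
    cor(mat[keep], method = "spearman", use = "pairwise.complete.obs"))
  write.csv(cm, file.path(outdir, "correlations_all.csv"))
  top <- head(results$feature[order(results$p)], 50L)
  top <- intersect(top, colnames(cm))
  write.csv(cm[top, top, drop = FALSE],
            file.path(outdir, "correlations_top50.csv"))

  z <- scale(mat[keep])
  z <- z[, apply(is.finite(z), 2, all), drop = FALSE]
  if (ncol(z) >= 2L) {
    pc <- prcomp(z, center = FALSE, scale. = FALSE)
    k <- min(5L, ncol(pc$x))
    scores <- data.frame(unit = rownames(mat) %||% seq_len(nrow(mat)),
                         group = as.character(groups),
                         pc$x[, seq_len(k), drop = FALSE])
    write.csv(scores, file.path(outdir, "pca_scores.csv"),
              row.names = FALSE)
  }
  counts <- as.data.frame(table(group = groups))
  write.csv(counts, file.path(outdir, "sample_counts.csv"),
            row.names = FALSE)
  yaml::write_yaml(list(alpha = cfg$alpha, fdr_method = cfg$fdr_method,
                        sem_offset = cfg$sem_offset,
                        n_features = nrow(results),
                        n_significant = nrow(sig)),
                   file.path(outdir, "config.yaml"))
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
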