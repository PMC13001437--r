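test_that("Cliff's delta: boundary cases, oracle agreement, antisymmetry", {
  expect_equal(cliffs_delta(1:10, 1:10), 0)
  expect_equal(cliffs_delta(11:20, 1:10), 1)
  expect_equal(cliffs_delta(1:10, 11:20), -1)
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    expect_equal(cliffs_delta(x, y), cliffs_delta_oracle(x, y))
    expect_equal(cliffs_delta(y, x), -cliffs_delta(x, y))
  }
})

test_that("BH q-values match the brute-force step-up oracle", {
  set.seed(32)
  for (n in c(5, 50, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
  # and via two_group across features: q >= p always, never violated
  mat <- matrix(rnorm(8 * 40), 8, 40,
                dimnames = list(NULL, paste0("f", 1:40)))
  res <- two_group(mat, rep(c("a", "b"), each = 4))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$q, bh_oracle(res$p))
})

test_that("two-group testing handles separation, constants, exactness", {
  mat <- data.frame(sep = c(1:4, 101:104), const = rep(5, 8),
                    noise = c(2, 4, 3, 5, 3.5, 4.5, 2.5, 5.5))
  g <- rep(c("a", "b"), each = 4)
  res <- two_group(mat, g)
  expect_equal(res$effect[res$feature == "sep"], -1)
  expect_true(res$degenerate[res$feature == "const"])
  expect_equal(res$p[res$feature == "const"], 1)
  expect_equal(res$effect[res$feature == "const"], 0)
  expect_equal(res$n1, rep(4L, 3), ignore_attr = TRUE)
  expect_error(two_group(mat, rep("a", 8)), "exactly 2 groups")
  expect_error(two_group(mat[1:3, ], g[c(1, 1, 5)]), ">= 2 observations")
  # exact option reproduces wilcox.test's exact p
  res_ex <- two_group(data.frame(f = c(1:4, 11:14)), g,
                      stats_config(exact = TRUE))
  expect_equal(res_ex$p, wilcox.test(1:4, 11:14, exact = TRUE)$p.value)
})

test_that("Kruskal-Wallis on 2 groups matches the rank-sum z-test (H = z^2)", {
  set.seed(33)
  x <- rnorm(120)
  g <- rep(c("a", "b"), each = 60)
  pw <- two_group(data.frame(f = x), g)$p
  pk <- multi_group(data.frame(f = x), g)$omnibus$p
  expect_lt(abs(pw - pk), 1e-6)
})

test_that("multi-group testing: null case, effect size, Dunn structure", {
  same <- data.frame(f = rep(c(1, 2, 3, 4), 3))
  g3 <- rep(c("t1", "t2", "t3"), each = 4)
  r <- multi_group(same, g3)
  expect_lt(r$omnibus$effect, 0.05)
  expect_true(all(r$pairwise$q > 0.9))
  expect_equal(nrow(r$pairwise), 3L)             # 3 pairwise comparisons

  # epsilon-squared formula against a hand computation
  set.seed(34)
  v <- rnorm(30); gg <- rep(c("a", "b", "c"), each = 10)
  H <- unname(kruskal.test(v, factor(gg))$statistic)
  expect_equal(multi_group(data.frame(f = v), gg)$omnibus$effect,
               H * 31 / (900 - 1))
  expect_error(multi_group(same, rep("a", 12)), ">= 2 groups")

  # a strongly shifted group is detected with high power
  set.seed(35)
  rej <- replicate(200, {
    v <- c(rnorm(8), rnorm(8), rnorm(8, mean = 2))
    multi_group(data.frame(f = v),
                rep(c("t1", "t2", "t3"), each = 8))$omnibus$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("Dunn z-statistics match a direct rank computation", {
  set.seed(36)
  v <- c(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  g <- rep(c("a", "b", "c"), each = 6)
  d <- dunn_test(v, g)
  r <- rank(v); n <- 18
  se <- sqrt((n * (n + 1) / 12) * (1 / 6 + 1 / 6))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab)
  expect_equal(d$q, p.adjust(d$p, "BH"))
})

test_that("SEM volcano applies the offset fold-change", {
  set.seed(37)
  mat <- data.frame(f1 = c(1, 2, 3, 4, 1, 2, 3, 4),       # equal SEMs
                    f2 = c(5, 5, 5, 5, 5, 5, 5, 5),       # SEM 0 both
                    f3 = rnorm(8))
  g <- rep(c("a", "b"), each = 4)
  sv <- sem_volcano(mat, g)
  expect_equal(sv$log2_fc_sem[sv$feature == "f1"], 0)
  expect_equal(sv$log2_fc_sem[sv$feature == "f2"], 0)     # offsets: 1 -> 0
  # asymmetric SEM: 0.0999 vs 0 -> log2(0.1 / 1e-4) ~ 9.966
  d <- 0.0999 * sqrt(3)
  x <- 50 + c(-d, d, -d, d)                               # sample SEM 0.0999
  y <- rep(50, 4)
  sv2 <- sem_volcano(data.frame(f = c(x, y)), g)
  expect_equal(sv2$sem1, 0.0999, tolerance = 1e-9)
  expect_equal(sv2$log2_fc_sem, log2((0.0999 + 1e-4) / 1e-4),
               tolerance = 1e-6)
})

test_that("report folder contains the full table set", {
  set.seed(38)
  mat <- as.data.frame(matrix(rnorm(10 * 60), 10, 60,
                              dimnames = list(NULL, paste0("f", 1:60))))
  g <- rep(c("a", "b"), each = 5)
  res <- two_group(mat, g)
  out <- withr::local_tempdir()
  build_report(res, mat, g, out)
  for (f in c("summary_stats.csv", "significant_features.csv",
              "volcano.csv", "correlations_all.csv",
              "correlations_top50.csv", "pca_scores.csv",
              "sample_counts.csv", "config.yaml"))
    expect_true(file.exists(file.path(out, f)), info = f)
  expect_equal(nrow(read.csv(file.path(out, "summary_stats.csv"))), 60L)
  top <- read.csv(file.path(out, "correlations_top50.csv"), row.names = 1)
  expect_lte(nrow(top), 50L)
  counts <- read.csv(file.path(out, "sample_counts.csv"))
  expect_equal(sum(counts$Freq), 10L)
})
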