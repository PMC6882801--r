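test_that("Spearman correlation matches hand-ranked values and cor.test", {
  expect_equal(spearman_cor(1:5, 1:5)$r, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$r, -1)
  s <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$r, 0.8)     # ranks are the values; cov 4 / var 5
  expect_equal(s$n, 5)
  # independent route: stats::cor
  set.seed(2)
  x <- rnorm(40)
  y <- rnorm(40)
  expect_equal(spearman_cor(x, y)$r, cor(x, y, method = "spearman"))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("partial Spearman reduces to Spearman with no confounders", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  p <- partial_spearman(x, y, NULL)
  expect_equal(p$partial_r, 0.8)
  expect_equal(p$df, 3)
  expect_equal(p$p_value, spearman_cor(x, y)$p_value)
})

test_that("single-confounder partial Spearman equals the recursion formula", {
  # worked 4-point example: (0.8 - 0.32)/sqrt(0.36 * 0.84)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  z <- c(1, 2, 4, 3)
  p <- partial_spearman(x, y, z)
  expect_equal(p$partial_r, (0.8 - 0.8 * 0.4) / sqrt((1 - 0.64) * (1 - 0.16)),
               tolerance = 1e-12)
  expect_equal(p$partial_r, 0.87287156, tolerance = 1e-6)

  # 300 random instances against the independent recursion oracle
  set.seed(7)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    # skip the rare draws where z is rank-identical to x or y (degenerate)
    if (abs(cor(rank(x), rank(z))) > 0.999 ||
        abs(cor(rank(y), rank(z))) > 0.999) next
    expect_equal(partial_spearman(x, y, z)$partial_r,
                 recursion_partial_spearman(x, y, z), tolerance = 1e-10)
  }
})

test_that("partial Spearman is symmetric and rank-invariant", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30)
  z <- cbind(a = rnorm(30), b = rnorm(30))
  p1 <- partial_spearman(x, y, z)
  p2 <- partial_spearman(y, x, z)
  expect_identical(p1$partial_r, p2$partial_r)
  p3 <- partial_spearman(exp(x), y^3 + 2 * y, cbind(a = exp(z[, "a"]),
                                                    b = 5 * z[, "b"]))
  expect_equal(p3$partial_r, p1$partial_r, tolerance = 1e-12)
  expect_equal(p1$df, 30 - 2 - 2)
})

test_that("collinear or degenerate confounders raise errors", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  expect_error(partial_spearman(x, y, cbind(x, x)), "rank deficient")
  expect_error(partial_spearman(x, y, x), "fully explained")
})

test_that("residualization returns mean-zero residuals and recovers structure", {
  y <- c(4, 8, 15, 16, 23, 42)
  expect_equal(residualize(y, NULL), y - mean(y))
  z <- c(1, 2, 3, 4, 5, 6)
  expect_equal(residualize(2 * z + 1, z), rep(0, 6), tolerance = 1e-9)
  set.seed(9)
  z <- rnorm(200)
  e <- rnorm(200)
  e <- residualize(e, z)              # make the noise orthogonal to z
  res <- residualize(z + e, z)
  expect_gt(cor(res, e), 0.99)
  expect_lt(abs(mean(res)), 1e-9)
})

test_that("residual pair realizes the partial-correlation identity", {
  set.seed(10)
  x <- rnorm(50)
  y <- rnorm(50)
  z <- cbind(z1 = rnorm(50), z2 = rnorm(50))
  rp <- residual_pair(x, y, z)
  # definitional identity with the raw-scale partial correlation
  fit_x <- lm(x ~ z)
  fit_y <- lm(y ~ z)
  expect_equal(cor(rp$x_residuals, rp$y_residuals),
               cor(resid(fit_x), resid(fit_y)), tolerance = 1e-10)
  rp0 <- residual_pair(x, y, NULL)
  expect_equal(rp0$x_residuals, x - mean(x))
  expect_lt(abs(mean(rp$x_residuals)), 1e-9)
})

test_that("anchor-immune residual pair carries the sign of the true coupling", {
  co <- simulate_cohort(tiny_cohort_config(seed = 12, n_samples = 400,
                                           anchor_immune_coupling = -0.6))
  rp <- residual_pair(co$expression["ANCHOR", ], co$fractions[, "immune"],
                      co$fractions[, "fibroblast"])
  expect_lt(cor(rp$x_residuals, rp$y_residuals), 0)
})

test_that("association matrices agree cellwise with the scalar functions", {
  co <- simulate_cohort(tiny_cohort_config(seed = 15, n_samples = 150))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  am <- association_matrix(co$expression, "ANCHOR", sc, "immune_score")
  ref <- spearman_cor(co$expression["ANCHOR", ], sc$immune_score)
  expect_equal(am$r["ANCHOR", "immune_score"], ref$r)
  expect_equal(am$p["ANCHOR", "immune_score"], ref$p_value)

  genes <- c("ANCHOR", co$gene_sets$stromal_set[1:3])
  am2 <- association_matrix(co$expression, genes, sc,
                            c("immune_score", "estimate_score"),
                            confounders = "stromal_score")
  ref2 <- partial_spearman(co$expression[genes[2], ], sc$immune_score,
                           sc$stromal_score)
  expect_equal(am2$r[genes[2], "immune_score"], ref2$partial_r)
  long <- association_long(am2)
  expect_equal(nrow(long), length(genes) * 2)
  expect_true(all(abs(long$r) <= 1))
  expect_error(association_matrix(co$expression, "NOPE", sc,
                                  "immune_score"), "NOPE")
})

test_that("stromal markers correlate positively with the stromal score", {
  co <- simulate_cohort(tiny_cohort_config(seed = 16, n_samples = 500))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  am <- association_matrix(co$expression, co$gene_sets$stromal_set, sc,
                           "stromal_score")
  expect_true(all(am$r[, "stromal_score"] > 0))
})

test_that("stroma adjustment flips the anchor-immune association under negative coupling", {
  # mild suppression: naively masked by stromal confounding, revealed by
  # adjustment (the published EMT-TF pattern)
  co <- simulate_cohort(tiny_cohort_config(seed = 17, n_samples = 500,
                                           n_genes = 300,
                                           anchor_immune_coupling = -0.15))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  naive <- association_matrix(co$expression, "ANCHOR", sc, "immune_score")
  adj <- association_matrix(co$expression, "ANCHOR", sc, "immune_score",
                            confounders = "stromal_score")
  expect_gt(naive$r[1, 1], 0)
  expect_lt(adj$r[1, 1], 0)
})

test_that("subgroup associations reduce to the pooled matrix for one group", {
  co <- simulate_cohort(tiny_cohort_config(seed = 18, n_samples = 120))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  pooled <- association_matrix(co$expression, "ANCHOR", sc, "immune_score")
  one <- subgroup_associations(co$expression, "ANCHOR", sc, "immune_score",
                               grouping = rep("all", 120))
  expect_equal(one$all$r, pooled$r)

  grouping <- c(rep("big", 118), rep("tiny", 2))
  expect_warning(
    out <- subgroup_associations(co$expression, "ANCHOR", sc,
                                 "immune_score", grouping,
                                 confounders = "stromal_score"),
    "tiny")
  expect_named(out, "big")
})

test_that("per-subtype partial correlations share the sign of the coupling", {
  co <- simulate_cohort(tiny_cohort_config(seed = 19, n_samples = 900,
                                           n_genes = 300,
                                           anchor_immune_coupling = -0.3))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  grouping <- co$clinical$subtype[match(colnames(co$expression),
                                        co$clinical$sample_id)]
  out <- subgroup_associations(co$expression, "ANCHOR", sc, "immune_score",
                               grouping, confounders = "stromal_score")
  rs <- vapply(out, function(am) am$r[1, 1], numeric(1))
  expect_true(all(rs < 0))
})

test_that("coefficient of determination is squared Pearson correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(coefficient_of_determination(x, 3 * x), 1)
  expect_equal(coefficient_of_determination(x, c(2, 1, 4, 3, 5)), 0.64)
  set.seed(23)
  z <- rnorm(20)
  y <- residualize(rnorm(20), z)      # orthogonal to z by construction
  expect_lt(coefficient_of_determination(z, y), 1e-12)
  expect_error(coefficient_of_determination(rep(1, 5), x), "constant")
})

test_that("confounder screening keeps real predictors and drops noise", {
  set.seed(20)
  z1 <- rnorm(300)
  z2 <- rnorm(300)
  noise <- rnorm(300)
  y <- 2 * z1 + 1.5 * z2 + rnorm(300)
  sel <- select_confounders(y, data.frame(z1 = z1, z2 = z2, noise = noise))
  expect_setequal(sel, c("z1", "z2"))
})
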