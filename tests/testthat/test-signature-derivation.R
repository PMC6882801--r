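test_that("identical arms give zero fold change and null p-values", {
  set.seed(1)
  m <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(paste0("g", 1:40)))
  de <- differential_expression(m, m)
  expect_equal(de$log2_fold_change, rep(0, 40))
  expect_true(all(de$p_value == 1))
  expect_error(differential_expression(m[, 1, drop = FALSE], m),
               "replicates")
})

test_that("Welch statistics agree with t.test per gene", {
  set.seed(2)
  a <- matrix(rnorm(10 * 4, mean = 1), 10, 4,
              dimnames = list(paste0("g", 1:10)))
  b <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(paste0("g", 1:10)))
  de <- differential_expression(a, b)
  for (i in c(1, 5, 10)) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2_fold_change[i],
                 unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("FDR adjustment equals the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle on random vectors
  step_up <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * m / rank(p)[o]))
    adj[order(o)]
  }
  set.seed(3)
  for (i in 1:100) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_fdr(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("downregulated selection applies strict thresholds", {
  de <- data.frame(
    gene = paste0("g", 1:6),
    log2_fold_change = c(-2.5, -2.0, -3.0, -1.0, -4.0, 1.0),
    p_value = rep(0.001, 6),
    fdr = c(0.01, 0.01, 0.05, 0.01, 0.001, 0.001))
  # g2 fails lfc boundary (-2 not < -2); g3 fails fdr boundary (0.05)
  expect_setequal(select_downregulated(de), c("g1", "g5"))
})

test_that("anchor co-expression selection honors sign and threshold", {
  expr <- rbind(ANCHOR = c(1, 2, 3, 4, 5, 6),
                same = c(10, 20, 30, 40, 50, 60),
                anti = c(6, 5, 4, 3, 2, 1),
                weak = c(2, 1, 4, 3, 6, 5))
  colnames(expr) <- paste0("s", 1:6)
  sel <- select_correlated(expr, "ANCHOR", 0.5)
  expect_true("same" %in% sel)
  expect_false("anti" %in% sel)
  expect_false("ANCHOR" %in% sel)
  expect_error(select_correlated(expr, "MISSING"), "MISSING")
  # raising the threshold never grows the set
  expect_true(all(select_correlated(expr, "ANCHOR", 0.9) %in% sel))
})

test_that("hypergeometric enrichment matches exact enumeration and printed counts", {
  # small case: N=10, K=4, n=5, k>=3 -> 66/252
  enr <- overlap_and_enrich(paste0("g", 1:4), paste0("g", c(1:3, 9, 10)),
                            10)
  expect_equal(enr$overlap_k, 3)
  expect_equal(enr$p_value, 66 / 252, tolerance = 1e-12)

  # exhaustive rational-enumeration oracle over all N <= 25 configurations
  for (N in c(6, 12, 25)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(3, N %/% 3)) {
        for (k in 0:min(K, n)) {
          tail_oracle <- sum(choose(K, k:min(K, n)) *
                               choose(N - K, n - (k:min(K, n)))) /
            choose(N, n)
          set_a <- paste0("g", seq_len(K))
          set_b <- paste0("g", c(seq_len(k),
                                 if (n > k) N - seq_len(n - k) + 1))
          enr <- overlap_and_enrich(set_a, set_b, N)
          expect_equal(enr$overlap_k, k)
          expect_equal(enr$p_value, tail_oracle, tolerance = 1e-9)
        }
      }
    }
  }

  # the published-count configuration: 3023 x 823 overlap 186 in 20,000
  printed <- overlap_and_enrich(paste0("d", 1:3023),
                                c(paste0("d", 1:186), paste0("c", 1:637)),
                                20000)
  expect_equal(round(printed$fold_enrichment, 1), 1.5)
  expect_lt(printed$p_value, 1e-6)

  # fold of exactly the expectation is 1
  enr1 <- overlap_and_enrich(paste0("g", 1:5),
                             c(paste0("g", 1), paste0("x", 1:1)), 10)
  expect_equal(enr1$fold_enrichment, 1)
  expect_error(overlap_and_enrich(paste0("g", 1:30), "g1", 10), "universe")
})

test_that("the stroma-adjusted filter separates co-regulation from confounding", {
  co <- simulate_cohort(tiny_cohort_config(seed = 22, n_samples = 400,
                                           n_genes = 300,
                                           anchor_immune_coupling = -0.3))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  prog <- co$truth$program_genes
  stromal10 <- co$gene_sets$stromal_set[1:10]
  kept <- stroma_adjusted_filter(co$expression, "ANCHOR",
                                 c(prog, stromal10), sc$stromal_score)
  expect_gte(sum(prog %in% kept), 9)
  expect_lte(sum(stromal10 %in% kept), 1)
  # a candidate identical to the anchor is retained (partial r = 1)
  expr2 <- rbind(co$expression, TWIN = co$expression["ANCHOR", ])
  expect_true("TWIN" %in%
                stroma_adjusted_filter(expr2, "ANCHOR", "TWIN",
                                       sc$stromal_score))
  # a candidate equal to the stromal score itself is excluded
  expr3 <- rbind(co$expression, CONF = sc$stromal_score)
  expect_false("CONF" %in%
                 stroma_adjusted_filter(expr3, "ANCHOR", "CONF",
                                        sc$stromal_score))
})

test_that("signature association table mirrors the scalar statistics", {
  co <- simulate_cohort(tiny_cohort_config(seed = 24, n_samples = 300,
                                           n_genes = 300,
                                           anchor_immune_coupling = -0.3))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  tab <- signature_association_table(co$expression,
                                     co$truth$program_genes,
                                     sc$stromal_score, sc$immune_score)
  g <- co$truth$program_genes[1]
  expect_equal(tab$stromal_r[tab$gene == g],
               spearman_cor(co$expression[g, ], sc$stromal_score)$r)
  expect_equal(tab$adj_immune_r[tab$gene == g],
               partial_spearman(co$expression[g, ], sc$immune_score,
                                sc$stromal_score)$partial_r)
  expect_true(all(tab$stromal_r > 0))
  expect_true(all(tab$adj_immune_r < 0))
  # degenerate gene (equal to the stromal score) is flagged, not numeric
  expr2 <- rbind(co$expression, CONF = sc$stromal_score)
  tab2 <- signature_association_table(expr2, "CONF", sc$stromal_score,
                                      sc$immune_score)
  expect_true(tab2$degenerate)
  expect_error(signature_association_table(co$expression, "ANCHOR",
                                           sc$stromal_score,
                                           rep(1, 300)), "constant")
})

test_that("full derivation keeps its set algebra and recovers the program", {
  co <- simulate_cohort(tiny_cohort_config(seed = 25, n_samples = 400,
                                           n_genes = 300,
                                           anchor_immune_coupling = -0.3))
  sc <- estimate_scores(co$expression, co$gene_sets$stromal_set,
                        co$gene_sets$immune_set)
  set.seed(25)
  kd <- simulate_knockdown(co$profiles$genes,
                           c("ANCHOR", co$truth$program_genes,
                             co$gene_sets$stromal_set[1:10]))
  de <- differential_expression(kd$condition, kd$control)
  sig <- derive_signature(co$expression, "ANCHOR", de, sc$stromal_score,
                          sc$immune_score)
  expect_true(all(sig$final_signature %in% sig$overlap_set))
  expect_true(all(sig$overlap_set %in% sig$down_set))
  expect_true(all(sig$overlap_set %in% sig$correlated_set))
  expect_gte(sum(co$truth$program_genes %in% sig$final_signature), 9)
  expect_lte(sum(co$gene_sets$stromal_set %in% sig$final_signature), 1)
  # impossible thresholds give a clean empty signature
  sig0 <- derive_signature(co$expression, "ANCHOR", de, sc$stromal_score,
                           sc$immune_score, partial_r_min = 0.9999)
  expect_length(sig0$final_signature, 0)
  expect_equal(nrow(sig0$signature_table), 0)
})
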