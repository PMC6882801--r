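# Small cohort configurations shared across test files. Sizes are kept
# modest so the whole suite runs quickly; statistical checks use medians
# over replicate seeds where single draws would be noisy.

tiny_cohort_config <- function(seed = 1L, n_samples = 200L, n_genes = 60L,
                               ...) {
  cohort_config(n_samples = n_samples, n_genes = n_genes, seed = seed, ...)
}

# independent oracle for the single-confounder partial Spearman recursion
recursion_partial_spearman <- function(x, y, z) {
  rxy <- stats::cor(rank(x), rank(y))
  rxz <- stats::cor(rank(x), rank(z))
  ryz <- stats::cor(rank(y), rank(z))
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# brute-force grid maximization of the Cox partial likelihood for
# all-distinct event times (no ties), one covariate
grid_cox_coef <- function(time, x, lo = -3, hi = 3, step = 1e-4) {
  ord <- order(time)
  x <- x[ord]
  grid <- seq(lo, hi, by = step)
  loglik <- vapply(grid, function(b) {
    eta <- b * x
    sum(eta - log(rev(cumsum(rev(exp(eta))))))
  }, numeric(1))
  grid[which.max(loglik)]
}

# direct running-sum enumeration of the single-sample enrichment walk
enumerate_ssgsea <- function(ranks, set_genes, w) {
  ord <- order(ranks)
  genes <- names(ranks)[ord]
  n <- length(genes)
  member <- genes %in% set_genes
  stat <- (n - ranks[ord] + 1)^w
  hit <- 0
  miss <- 0
  total <- 0
  for (i in seq_len(n)) {
    if (member[i]) hit <- hit + stat[i] / sum(stat[member])
    else miss <- miss + 1 / (n - sum(member))
    total <- total + (hit - miss)
  }
  unname(total)
}
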