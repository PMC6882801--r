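#' Two-arm differential expression (Welch t-test)
#'
#' Per-gene Welch two-sample t-test between a condition and a control arm
#' of log2-scale expression, with Benjamini-Hochberg FDR across all genes.
#' The fold change is the difference of arm means (condition minus
#' control), in log2 units.
#'
#' @param expr_condition,expr_control Gene-by-replicate matrices sharing
#'   the same gene universe (>= 2 replicates each).
#' @return `data.frame` with columns `gene`, `log2_fold_change`, `p_value`,
#'   `fdr`.
#' @export
differential_expression <- function(expr_condition, expr_control) {
  expr_condition <- as.matrix(expr_condition)
  expr_control <- as.matrix(expr_control)
  if (!identical(rownames(expr_condition), rownames(expr_control)))
    stop("the two arms must share an identical gene universe",
         call. = FALSE)
  n1 <- ncol(expr_condition)
  n2 <- ncol(expr_control)
  if (n1 < 2 || n2 < 2)
    stop("each arm needs at least 2 replicates to estimate variance",
         call. = FALSE)
  m1 <- rowMeans(expr_condition)
  m2 <- rowMeans(expr_control)
  v1 <- rowSums((expr_condition - m1)^2) / (n1 - 1)
  v2 <- rowSums((expr_control - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  # Welch-Satterthwaite df; zero-variance genes handled explicitly
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(se2 == 0, ifelse(diff == 0, 1, 0),
              2 * stats::pt(-abs(diff / sqrt(se2)), df))
  data.frame(gene = rownames(expr_condition),
             log2_fold_change = unname(diff),
             p_value = unname(p),
             fdr = adjust_fdr(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values.
#' @return FDR-adjusted p-values in the original order.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Select significantly downregulated genes
#'
#' Strict thresholds on both FDR and log2 fold change.
#'
#' @param de A [differential_expression()] table.
#' @param fdr_max FDR cutoff (exclusive).
#' @param lfc_max Log2 fold-change cutoff (exclusive, negative for
#'   downregulation).
#' @return Character vector of gene IDs.
#' @export
select_downregulated <- function(de, fdr_max = 0.05, lfc_max = -2) {
  stopifnot(all(c("gene", "log2_fold_change", "fdr") %in% names(de)))
  de$gene[de$fdr < fdr_max & de$log2_fold_change < lfc_max]
}

#' Select genes co-expressed with an anchor gene
#'
#' Genes whose Spearman correlation with the anchor gene's expression
#' exceeds `r_min` (strict), the anchor itself excluded.
#'
#' @param expr Gene-by-sample matrix.
#' @param anchor_gene Row name of the anchor.
#' @param r_min Correlation threshold.
#' @return Character vector of gene IDs.
#' @export
select_correlated <- function(expr, anchor_gene, r_min = 0.5) {
  if (!anchor_gene %in% rownames(expr))
    stop("anchor gene '", anchor_gene, "' not found in expression matrix",
         call. = FALSE)
  ra <- rank(expr[anchor_gene, ])
  others <- setdiff(rownames(expr), anchor_gene)
  rmat <- t(apply(expr[others, , drop = FALSE], 1, rank))
  r <- as.vector(stats::cor(ra, t(rmat)))
  others[!is.na(r) & r > r_min]
}

#' Overlap of two gene sets with hypergeometric enrichment
#'
#' Fold enrichment is the observed overlap relative to the expectation
#' `|A| * |B| / N` under independent draws from a universe of `universe_n`
#' genes; the p-value is the upper tail `P(X >= k)` of the hypergeometric
#' law, evaluated in log space for numerical stability.
#'
#' @param set_a,set_b Character vectors of gene IDs.
#' @param universe_n Size of the gene universe (>= both sets).
#' @return Object of class `enrichment_result`: list with `overlap_k`,
#'   `set_K`, `draw_n`, `universe_N`, `overlap_genes`, `fold_enrichment`,
#'   `p_value`, `log10_p`.
#' @export
overlap_and_enrich <- function(set_a, set_b, universe_n) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  K <- length(set_a)
  n <- length(set_b)
  if (universe_n < max(K, n))
    stop("`universe_n` must be at least as large as each set",
         call. = FALSE)
  overlap <- intersect(set_a, set_b)
  k <- length(overlap)
  expected <- K * n / universe_n
  logp <- stats::phyper(k - 1, K, universe_n - K, n,
                        lower.tail = FALSE, log.p = TRUE)
  structure(list(overlap_k = k, set_K = K, draw_n = n,
                 universe_N = universe_n, overlap_genes = overlap,
                 fold_enrichment = if (expected > 0) k / expected else NaN,
                 p_value = exp(logp),
                 log10_p = logp / log(10)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of sets %d x %d in universe %d: %.2f-fold enrichment, p = %.3g\n",
    x$overlap_k, x$set_K, x$draw_n, x$universe_N, x$fold_enrichment,
    x$p_value))
  invisible(x)
}

#' Stroma-adjusted partial-correlation filter
#'
#' Retains candidate genes whose partial Spearman correlation with the
#' anchor gene, given the stromal score, exceeds `partial_r_min` (strict).
#' This removes genes whose co-expression with the anchor is carried
#' entirely by shared stromal content.
#'
#' @param expr Gene-by-sample matrix.
#' @param anchor_gene Row name of the anchor.
#' @param candidates Candidate gene IDs (rows of `expr`).
#' @param stromal_scores Per-sample stromal score vector aligned with the
#'   columns of `expr`.
#' @param partial_r_min Partial correlation threshold.
#' @return Character vector of retained gene IDs.
#' @export
stroma_adjusted_filter <- function(expr, anchor_gene, candidates,
                                   stromal_scores, partial_r_min = 0.5) {
  missing <- setdiff(c(anchor_gene, candidates), rownames(expr))
  if (length(missing))
    stop("genes not in expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  anchor <- expr[anchor_gene, ]
  keep <- vapply(candidates, function(g) {
    pr <- tryCatch(
      partial_spearman(expr[g, ], anchor, stromal_scores)$partial_r,
      error = function(e) NA_real_)
    !is.na(pr) && pr > partial_r_min
  }, logical(1))
  candidates[keep]
}

#' Per-gene stromal and stroma-adjusted immune associations
#'
#' For each signature gene: the Spearman correlation with the stromal score
#' (with p-value), and the partial Spearman correlation with the immune
#' score given the stromal score (with p-value). Genes degenerate under
#' adjustment (e.g. identical to the stromal score) are flagged rather than
#' reported as numbers.
#'
#' @param expr Gene-by-sample matrix.
#' @param signature Character vector of signature gene IDs.
#' @param stromal_scores,immune_scores Per-sample score vectors aligned
#'   with `colnames(expr)`.
#' @return `data.frame` with columns `gene`, `stromal_r`, `stromal_p`,
#'   `adj_immune_r`, `adj_immune_p`, `degenerate`.
#' @export
signature_association_table <- function(expr, signature, stromal_scores,
                                        immune_scores) {
  if (!length(signature)) stop("empty signature", call. = FALSE)
  if (stats::sd(immune_scores) == 0)
    stop("correlation undefined: immune score is constant", call. = FALSE)
  rows <- lapply(signature, function(g) {
    gx <- expr[g, ]
    s <- spearman_cor(gx, stromal_scores)
    adj <- tryCatch(partial_spearman(gx, immune_scores, stromal_scores),
                    error = function(e) NULL)
    data.frame(gene = g, stromal_r = s$r, stromal_p = s$p_value,
               adj_immune_r = if (is.null(adj)) NA_real_ else adj$partial_r,
               adj_immune_p = if (is.null(adj)) NA_real_ else adj$p_value,
               degenerate = is.null(adj), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive a stroma-corrected anchor-activated gene signature
#'
#' The full derivation pipeline: (1) genes significantly downregulated by
#' anchor knockdown (`fdr < fdr_max`, `log2FC < lfc_max`); (2) genes
#' co-expressed with the anchor in the cohort (`Spearman r > r_min`);
#' (3) their intersection, with hypergeometric enrichment against the gene
#' universe; (4) the stroma-adjusted partial-correlation filter
#' (`partial r > partial_r_min` given the stromal score); (5) the per-gene
#' stromal / adjusted-immune association table for the final signature.
#'
#' @param expr Gene-by-sample cohort matrix (z-scores).
#' @param anchor_gene Row name of the anchor.
#' @param de A [differential_expression()] table (or one read with
#'   [read_de_table()]).
#' @param stromal_scores,immune_scores Per-sample score vectors aligned
#'   with `colnames(expr)`.
#' @param fdr_max,lfc_max,r_min,partial_r_min Stage thresholds.
#' @param universe_n Gene universe size for the enrichment test; defaults
#'   to the number of genes in the DE table.
#' @return Object of class `signature_result`: list with `down_set`,
#'   `correlated_set`, `overlap_set`, `enrichment`, `signature_table`,
#'   `final_signature`, `thresholds`.
#' @export
derive_signature <- function(expr, anchor_gene, de, stromal_scores,
                             immune_scores, fdr_max = 0.05, lfc_max = -2,
                             r_min = 0.5, partial_r_min = 0.5,
                             universe_n = NULL) {
  if (is.null(universe_n)) universe_n <- nrow(de)
  down <- select_downregulated(de, fdr_max, lfc_max)
  correlated <- select_correlated(expr, anchor_gene, r_min)
  enr <- overlap_and_enrich(down, correlated, universe_n)
  overlap <- intersect(enr$overlap_genes, rownames(expr))
  final <- if (length(overlap))
    stroma_adjusted_filter(expr, anchor_gene, overlap, stromal_scores,
                           partial_r_min)
  else character(0)
  tab <- if (length(final))
    signature_association_table(expr, final, stromal_scores, immune_scores)
  else data.frame(gene = character(0), stromal_r = numeric(0),
                  stromal_p = numeric(0), adj_immune_r = numeric(0),
                  adj_immune_p = numeric(0), degenerate = logical(0))
  stopifnot(all(final %in% overlap),
            all(overlap %in% down), all(overlap %in% correlated))
  structure(list(down_set = down, correlated_set = correlated,
                 overlap_set = overlap, enrichment = enr,
                 signature_table = tab, final_signature = final,
                 thresholds = list(fdr_max = fdr_max, lfc_max = lfc_max,
                                   r_min = r_min,
                                   partial_r_min = partial_r_min,
                                   universe_n = universe_n)),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Signature derivation:\n")
  cat("  downregulated set:", length(x$down_set), "genes\n")
  cat("  anchor-correlated set:", length(x$correlated_set), "genes\n")
  cat("  overlap:", length(x$overlap_set), "genes (",
      sprintf("%.2f-fold enrichment, p = %.3g",
              x$enrichment$fold_enrichment, x$enrichment$p_value), ")\n")
  cat("  final signature after stroma-adjusted filter:",
      length(x$final_signature), "genes\n")
  invisible(x)
}
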