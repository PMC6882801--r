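#' Rank genes within each sample
#'
#' Ranks expression per sample in descending order (rank 1 = most highly
#' expressed), with average ranks on ties — the same tie convention used by
#' the Spearman machinery.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @return Gene-by-sample matrix of per-sample ranks.
#' @export
rank_genes_per_sample <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 genes to rank", call. = FALSE)
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  apply(expr, 2, function(col) rank(-col, ties.method = "average"))
}

#' Single-sample gene-set enrichment score
#'
#' Walks the sample's genes from the best to the worst rank, accumulating a
#' hit weight for set members and a miss weight otherwise, and returns the
#' sum over positions of (cumulative hit - cumulative miss). Hit weights are
#' the rank statistic `(N - rank + 1)^weight_exponent`, normalized so the
#' hits sum to one; each miss contributes `1/(N - |S|)`. With
#' `weight_exponent = 0` every member counts equally. A set covering the
#' whole universe has no misses and the score is defined as 0.
#'
#' @param sample_ranks Named numeric vector of per-sample ranks for one
#'   sample (one column of [rank_genes_per_sample()]).
#' @param genes Character vector: the gene set.
#' @param weight_exponent Nonnegative exponent on the rank statistic
#'   (0.25 by default, the usual stromal/immune scoring convention).
#' @param set_name Label used in error messages.
#' @return A single numeric enrichment score.
#' @export
ssgsea_score <- function(sample_ranks, genes, weight_exponent = 0.25,
                         set_name = "gene set") {
  if (weight_exponent < 0)
    stop("`weight_exponent` must be nonnegative", call. = FALSE)
  if (is.null(names(sample_ranks)))
    stop("`sample_ranks` must be named by gene", call. = FALSE)
  n <- length(sample_ranks)
  member <- names(sample_ranks) %in% genes
  n_s <- sum(member)
  if (n_s == 0)
    stop("gene set '", set_name, "' has empty intersection with the ",
         "expression gene universe", call. = FALSE)
  if (n_s == n) return(0)

  ord <- order(sample_ranks)
  member <- member[ord]
  stat <- (n - sample_ranks[ord] + 1)^weight_exponent
  hit_inc <- numeric(n)
  hit_inc[member] <- stat[member] / sum(stat[member])
  miss_inc <- numeric(n)
  miss_inc[!member] <- 1 / (n - n_s)
  sum(cumsum(hit_inc) - cumsum(miss_inc))
}

#' Stromal, immune and combined enrichment scores per sample
#'
#' Rank-based single-sample scoring of a stromal and an immune gene set,
#' the ESTIMATE-style combined score being their sum. Scores are reported
#' on their natural running-sum scale.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param stromal_set,immune_set Character vectors of gene IDs.
#' @param weight_exponent Passed to [ssgsea_score()].
#' @return A `data.frame` with columns `sample_id`, `stromal_score`,
#'   `immune_score`, `estimate_score`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set,
                            weight_exponent = 0.25) {
  ranks <- rank_genes_per_sample(expr)
  stromal <- apply(ranks, 2, ssgsea_score, genes = stromal_set,
                   weight_exponent = weight_exponent,
                   set_name = "stromal_set")
  immune <- apply(ranks, 2, ssgsea_score, genes = immune_set,
                  weight_exponent = weight_exponent,
                  set_name = "immune_set")
  data.frame(sample_id = colnames(expr),
             stromal_score = unname(stromal),
             immune_score = unname(immune),
             estimate_score = unname(stromal + immune),
             stringsAsFactors = FALSE)
}

#' Score an expression matrix on an arbitrary gene-set collection
#'
#' One score column per set, computed with [ssgsea_score()].
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param weight_exponent Passed to [ssgsea_score()].
#' @return A `data.frame` with `sample_id` plus one column per set.
#' @export
score_gene_sets <- function(expr, gene_sets, weight_exponent = 0.25) {
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("`gene_sets` must be a named list", call. = FALSE)
  ranks <- rank_genes_per_sample(expr)
  out <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  for (nm in names(gene_sets))
    out[[nm]] <- apply(ranks, 2, ssgsea_score, genes = gene_sets[[nm]],
                       weight_exponent = weight_exponent, set_name = nm)
  out
}
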