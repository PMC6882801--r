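#' Pipeline configuration
#'
#' Centralizes every path and threshold of the end-to-end analysis. All
#' thresholds default to the package's standard values; a YAML file with
#' the same field names can be loaded with [read_pipeline_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param expression,gene_sets,clinical,score_table,de_table Input paths;
#'   any of them may be `NULL` when the `simulate` stage generates them.
#' @param anchor_gene Anchor gene symbol.
#' @param confounder Score column used for stroma adjustment.
#' @param immune_score Score column treated as the immune readout.
#' @param fdr_max,lfc_max,r_min,partial_r_min,universe_n,ssgsea_exponent
#'   Analysis thresholds.
#' @param grouping Optional clinical column for per-subgroup association
#'   matrices (e.g. `"subtype"`).
#' @param simulate Logical: generate a synthetic cohort as input.
#' @param cohort A [cohort_config()] used when `simulate = TRUE`.
#' @param seed Integer seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            expression = NULL, gene_sets = NULL,
                            clinical = NULL, score_table = NULL,
                            de_table = NULL,
                            anchor_gene = "ANCHOR",
                            confounder = "stromal_score",
                            immune_score = "immune_score",
                            fdr_max = 0.05, lfc_max = -2,
                            r_min = 0.5, partial_r_min = 0.5,
                            universe_n = 20000L,
                            ssgsea_exponent = 0.25,
                            grouping = NULL,
                            simulate = FALSE,
                            cohort = cohort_config(),
                            seed = 1L) {
  if (fdr_max <= 0 || fdr_max > 1)
    stop("`fdr_max` must be in (0, 1]", call. = FALSE)
  if (r_min < -1 || r_min > 1 || partial_r_min < -1 || partial_r_min > 1)
    stop("correlation thresholds must be in [-1, 1]", call. = FALSE)
  if (ssgsea_exponent < 0)
    stop("`ssgsea_exponent` must be nonnegative", call. = FALSE)
  structure(list(out_dir = out_dir, expression = expression,
                 gene_sets = gene_sets, clinical = clinical,
                 score_table = score_table, de_table = de_table,
                 anchor_gene = anchor_gene, confounder = confounder,
                 immune_score = immune_score,
                 fdr_max = fdr_max, lfc_max = lfc_max, r_min = r_min,
                 partial_r_min = partial_r_min,
                 universe_n = as.integer(universe_n),
                 ssgsea_exponent = ssgsea_exponent,
                 grouping = grouping, simulate = isTRUE(simulate),
                 cohort = cohort, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the optional
#' `cohort:` block mirrors [cohort_config()].
#'
#' @param path YAML file path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort
  y$cohort <- NULL
  if (!is.null(cohort_args$mixing_concentration))
    cohort_args$mixing_concentration <-
      unlist(cohort_args$mixing_concentration)
  if (!is.null(cohort_args$survival_log_hazards))
    cohort_args$survival_log_hazards <-
      unlist(cohort_args$survival_log_hazards)
  cohort <- do.call(cohort_config, cohort_args %||% list())
  do.call(pipeline_config, c(y, list(cohort = cohort)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_path <- function(cfg, file) file.path(cfg$out_dir, file)

ensure_out_dir <- function(cfg) {
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  invisible(cfg$out_dir)
}

#' Simulate-stage runner: synthetic cohort artifacts on disk
#'
#' Writes the z-scored expression matrix, true mixing fractions, clinical
#' table, marker gene sets (GMT), a simulated knockdown DE table for the
#' signature stage, and the ground-truth record (JSON) into the output
#' directory, then updates the run manifest.
#'
#' @param cfg A [pipeline_config()] with `simulate = TRUE` (the embedded
#'   [cohort_config()] defines the cohort).
#' @return Invisibly, the `synthetic_cohort`.
#' @export
run_simulate <- function(cfg) {
  ensure_out_dir(cfg)
  cohort_cfg <- cfg$cohort
  cohort_cfg$seed <- cfg$seed
  cohort <- simulate_cohort(cohort_cfg)

  write_expression(cohort$expression, stage_path(cfg, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(cohort$fractions), cohort$fractions),
    stage_path(cfg, "fractions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_clinical(cohort$clinical, stage_path(cfg, "clinical.tsv"))
  write_gmt(cohort$gene_sets, stage_path(cfg, "gene_sets.gmt"))

  # knockdown of the anchor downregulates the anchor program
  down_truth <- c(cfg$anchor_gene, cohort$truth$program_genes)
  kd <- simulate_knockdown(cohort$profiles$genes, down_truth)
  de <- differential_expression(kd$condition, kd$control)
  write_de_table(de, stage_path(cfg, "de_table.tsv"))

  truth <- cohort$truth
  truth$anchor_activity <- unname(truth$anchor_activity)
  truth$stromal_immune_latent <- unname(truth$stromal_immune_latent)
  jsonlite::write_json(truth, stage_path(cfg, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  update_manifest(cfg, "simulate",
                  list(n_samples = ncol(cohort$expression),
                       n_genes = nrow(cohort$expression)))
  invisible(cohort)
}

#' Score-stage runner: stromal/immune score table on disk
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the score `data.frame`.
#' @export
run_score <- function(cfg) {
  ensure_out_dir(cfg)
  expr <- read_expression(cfg$expression %||%
                            stage_path(cfg, "expression.tsv"))
  sets <- read_gmt(cfg$gene_sets %||% stage_path(cfg, "gene_sets.gmt"))
  if (!all(c("stromal_set", "immune_set") %in% names(sets)))
    stop("gene-set collection must contain `stromal_set` and `immune_set`",
         call. = FALSE)
  scores <- estimate_scores(expr, sets$stromal_set, sets$immune_set,
                            weight_exponent = cfg$ssgsea_exponent)
  extra <- setdiff(names(sets), c("stromal_set", "immune_set"))
  if (length(extra)) {
    more <- score_gene_sets(expr, sets[extra],
                            weight_exponent = cfg$ssgsea_exponent)
    scores <- merge(scores, more, by = "sample_id", sort = FALSE)
  }
  write_score_table(scores, stage_path(cfg, "scores.tsv"))
  update_manifest(cfg, "score", list(n_scores = ncol(scores) - 1L))
  invisible(scores)
}

#' Correlate-stage runner: adjusted and unadjusted association matrices
#'
#' Writes wide and long TSVs of gene-vs-score Spearman correlations, both
#' unadjusted and adjusted for the configured confounder score, plus
#' per-subgroup variants when `grouping` is set.
#'
#' @param cfg A [pipeline_config()].
#' @param genes Genes to correlate (default: anchor gene only).
#' @return Invisibly, a list with the two `association_matrix` objects.
#' @export
run_correlate <- function(cfg, genes = NULL) {
  ensure_out_dir(cfg)
  expr <- read_expression(cfg$expression %||%
                            stage_path(cfg, "expression.tsv"))
  scores <- read_score_table(cfg$score_table %||%
                               stage_path(cfg, "scores.tsv"))
  genes <- genes %||% cfg$anchor_gene
  targets <- setdiff(names(scores), c("sample_id", cfg$confounder))

  unadj <- association_matrix(expr, genes, scores, targets)
  adj <- association_matrix(expr, genes, scores, targets,
                            confounders = cfg$confounder)
  write_assoc <- function(am, tag) {
    utils::write.table(
      data.frame(gene = rownames(am$r), am$r, check.names = FALSE),
      stage_path(cfg, paste0("associations_", tag, "_wide.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      association_long(am),
      stage_path(cfg, paste0("associations_", tag, "_long.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_assoc(unadj, "unadjusted")
  write_assoc(adj, "adjusted")

  if (!is.null(cfg$grouping)) {
    clin <- read_clinical(cfg$clinical %||% stage_path(cfg, "clinical.tsv"))
    grouping <- clin[[cfg$grouping]][match(colnames(expr),
                                           clin$sample_id)]
    by_grp <- subgroup_associations(expr, genes, scores, targets,
                                    grouping, confounders = cfg$confounder)
    long <- do.call(rbind, lapply(names(by_grp), function(g)
      association_long(by_grp[[g]], group = g)))
    utils::write.table(long,
                       stage_path(cfg, "associations_by_group_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  update_manifest(cfg, "correlate",
                  list(n_genes = length(genes), n_targets = length(targets)))
  invisible(list(unadjusted = unadj, adjusted = adj))
}

#' Signature-stage runner
#'
#' Runs the full derivation pipeline and writes the JSON summary plus the
#' per-gene association table (TSV). An empty signature is a valid,
#' cleanly reported outcome, not an error.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the `signature_result`.
#' @export
run_derive_signature <- function(cfg) {
  ensure_out_dir(cfg)
  expr <- read_expression(cfg$expression %||%
                            stage_path(cfg, "expression.tsv"))
  scores <- read_score_table(cfg$score_table %||%
                               stage_path(cfg, "scores.tsv"))
  scores <- align_scores(scores, colnames(expr))
  de <- read_de_table(cfg$de_table %||% stage_path(cfg, "de_table.tsv"))

  res <- derive_signature(
    expr, cfg$anchor_gene, de,
    stromal_scores = scores[[cfg$confounder]],
    immune_scores = scores[[cfg$immune_score]],
    fdr_max = cfg$fdr_max, lfc_max = cfg$lfc_max, r_min = cfg$r_min,
    partial_r_min = cfg$partial_r_min, universe_n = cfg$universe_n)

  jsonlite::write_json(
    list(down_set = res$down_set, correlated_set = res$correlated_set,
         overlap_set = res$overlap_set,
         final_signature = res$final_signature,
         enrichment = unclass(res$enrichment)[
           c("overlap_k", "set_K", "draw_n", "universe_N",
             "fold_enrichment", "p_value")],
         thresholds = res$thresholds),
    stage_path(cfg, "signature.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(res$signature_table,
                     stage_path(cfg, "signature_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(cfg, "derive_signature",
                  list(n_down = length(res$down_set),
                       n_correlated = length(res$correlated_set),
                       n_overlap = length(res$overlap_set),
                       n_final = length(res$final_signature)))
  invisible(res)
}

#' Survival-stage runner: unadjusted and stroma-adjusted Cox scans
#'
#' Scans the final signature genes (or all genes if no signature file is
#' present) through the multivariate Cox model, once with raw expression
#' and once with stroma-adjusted residuals as the gene covariate, writing
#' forest-plot-schema TSVs.
#'
#' @param cfg A [pipeline_config()].
#' @param genes Genes to scan; defaults to the derived signature if its
#'   JSON artifact exists, else the anchor gene.
#' @return Invisibly, a list with both scan tables.
#' @export
run_survival <- function(cfg, genes = NULL) {
  ensure_out_dir(cfg)
  expr <- read_expression(cfg$expression %||%
                            stage_path(cfg, "expression.tsv"))
  clin <- read_clinical(cfg$clinical %||% stage_path(cfg, "clinical.tsv"))
  scores <- read_score_table(cfg$score_table %||%
                               stage_path(cfg, "scores.tsv"))
  scores <- align_scores(scores, clin$sample_id)
  if (is.null(genes)) {
    sig_path <- stage_path(cfg, "signature.json")
    genes <- if (file.exists(sig_path)) {
      sig <- jsonlite::read_json(sig_path, simplifyVector = TRUE)
      c(cfg$anchor_gene, sig$final_signature)
    } else cfg$anchor_gene
  }
  genes <- intersect(genes, rownames(expr))

  unadj <- gene_survival_scan(expr, clin, genes = genes)
  adj <- gene_survival_scan(expr, clin, genes = genes,
                            stromal_scores = scores[[cfg$confounder]])
  utils::write.table(unadj, stage_path(cfg, "survival_scan_unadjusted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(adj, stage_path(cfg, "survival_scan_adjusted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(cfg, "survival",
                  list(n_genes = length(genes),
                       n_nonconverged = sum(!unadj$converged)))
  invisible(list(unadjusted = unadj, adjusted = adj))
}

#' Run the full pipeline
#'
#' Stages in order: simulate (when configured), score, correlate, derive
#' signature, survival scan. Fails fast with the stage name on error; the
#' manifest records configuration, input checksums and per-stage counts.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(cfg) {
  ensure_out_dir(cfg)
  stages <- c(if (cfg$simulate) "simulate",
              "score", "correlate", "derive_signature", "survival")
  runners <- list(simulate = run_simulate, score = run_score,
                  correlate = run_correlate,
                  derive_signature = run_derive_signature,
                  survival = run_survival)
  for (st in stages) {
    tryCatch(runners[[st]](cfg),
             error = function(e)
               stop("pipeline stage '", st, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }
  invisible(read_manifest(cfg))
}

# --- run manifest -----------------------------------------------------------

manifest_path <- function(cfg) stage_path(cfg, "manifest.json")

read_manifest <- function(cfg) {
  p <- manifest_path(cfg)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(package_version =
              as.character(utils::packageVersion("stromascan")),
            seed = cfg$seed, stages = list())
}

update_manifest <- function(cfg, stage, counts) {
  m <- read_manifest(cfg)
  m$config <- config_snapshot(cfg)
  m$stages[[stage]] <- counts
  outputs <- list.files(cfg$out_dir, pattern = "\\.(tsv|gmt|json)$",
                        full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  sums <- tools::md5sum(outputs)
  m$checksums <- as.list(stats::setNames(unname(sums), basename(outputs)))
  jsonlite::write_json(m, manifest_path(cfg), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(m)
}

config_snapshot <- function(cfg) {
  snap <- unclass(cfg)
  snap$cohort <- unclass(snap$cohort)
  snap$cohort$mixing_concentration <-
    as.list(snap$cohort$mixing_concentration)
  snap$cohort$survival_log_hazards <-
    as.list(snap$cohort$survival_log_hazards)
  snap
}
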