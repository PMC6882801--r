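#' Configuration for a synthetic bulk-tumor cohort
#'
#' Bulk tumor expression profiles are modelled as convex mixtures of four
#' cell-population profiles (epithelial cancer, EMT-like cancer,
#' fibroblast/stromal, immune). Two mechanisms couple the mixture to the
#' cancer cells' intrinsic state:
#'
#' * a shared latent factor multiplies the fibroblast and immune Dirichlet
#'   weights, inducing the positive stromal-immune abundance correlation
#'   seen in real bulk cohorts (`stromal_immune_coupling`);
#' * a per-sample cancer-intrinsic "anchor activity" drives both the anchor
#'   gene's expression and, through `anchor_immune_coupling`, the immune
#'   fraction. With the coupling at zero the anchor gene is associated with
#'   immune content only through the stromal confounder; with a negative
#'   coupling the anchor genuinely suppresses immune infiltration.
#'
#' @param n_samples Number of bulk samples (>= 4).
#' @param n_genes Number of genes, including the anchor and program genes.
#' @param mixing_concentration Named Dirichlet concentrations for the four
#'   cell types `epithelial`, `emt`, `fibroblast`, `immune`. All must be
#'   positive unless `degenerate_ok = TRUE`, in which case exact zeros pin
#'   the corresponding fraction at zero.
#' @param stromal_immune_coupling Loading of the shared latent Gaussian on
#'   the fibroblast and immune mixture weights (log scale). Positive values
#'   give a positive stromal-immune fraction correlation.
#' @param anchor_immune_coupling Effect (log scale) of the standardized
#'   cancer-intrinsic anchor activity on the immune mixture weight;
#'   negative values model immune suppression by the anchor program.
#' @param anchor_activity_sd Standard deviation, in log-expression units, of
#'   the cancer-intrinsic term added to the anchor gene.
#' @param n_program_genes Number of genes co-regulated with the anchor: they
#'   share the anchor's cell-type profile and receive the same
#'   cancer-intrinsic activity term (scaled by `program_activity_scale`).
#' @param program_activity_scale Multiplier on `anchor_activity_sd` for the
#'   program genes.
#' @param noise_sd Additive Gaussian noise on the log expression scale.
#' @param survival_log_hazards Named log-hazard coefficients; names must be
#'   a subset of `stage`, `age`, `er_status`, `anchor_activity`.
#' @param baseline_hazard Constant baseline hazard (events per month).
#' @param censoring_rate Probability that a sample is censored.
#' @param ihc_noise_sd Gaussian noise, in percentage points, added to the
#'   IHC readouts of the true fractions.
#' @param degenerate_ok Allow exact-zero mixing concentrations (degenerate
#'   limit where a cell type is absent from every sample).
#' @param seed Integer seed used by [simulate_cohort()].
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()], [sample_fractions()]
#' @export
cohort_config <- function(n_samples = 500L,
                          n_genes = 600L,
                          mixing_concentration = c(epithelial = 10, emt = 2,
                                                   fibroblast = 4, immune = 3),
                          stromal_immune_coupling = 1.2,
                          anchor_immune_coupling = 0,
                          anchor_activity_sd = 0.5,
                          n_program_genes = 10L,
                          program_activity_scale = 1,
                          noise_sd = 0.1,
                          survival_log_hazards = c(stage = 0.4, age = 0.02,
                                                   er_status = -0.5,
                                                   anchor_activity = 0.2),
                          baseline_hazard = 0.01,
                          censoring_rate = 0.3,
                          ihc_noise_sd = 5,
                          degenerate_ok = FALSE,
                          seed = 1L) {
  cell_types <- c("epithelial", "emt", "fibroblast", "immune")
  if (!is.numeric(n_samples) || n_samples < 4)
    stop("`n_samples` must be >= 4", call. = FALSE)
  if (!is.numeric(n_genes) || n_genes < 20)
    stop("`n_genes` must be >= 20", call. = FALSE)
  if (is.null(names(mixing_concentration)) ||
      !setequal(names(mixing_concentration), cell_types))
    stop("`mixing_concentration` must be named with: ",
         paste(cell_types, collapse = ", "), call. = FALSE)
  mixing_concentration <- mixing_concentration[cell_types]
  if (degenerate_ok) {
    if (any(mixing_concentration < 0) || all(mixing_concentration == 0))
      stop("mixing concentrations must be >= 0 with at least one positive",
           call. = FALSE)
  } else if (any(mixing_concentration <= 0)) {
    stop("mixing concentrations must all be positive ",
         "(set `degenerate_ok = TRUE` for exact-zero limits)", call. = FALSE)
  }
  if (noise_sd < 0 || ihc_noise_sd < 0)
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  if (baseline_hazard <= 0)
    stop("`baseline_hazard` must be positive", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("`censoring_rate` must be in [0, 1]", call. = FALSE)
  allowed <- c("stage", "age", "er_status", "anchor_activity")
  if (length(survival_log_hazards) &&
      !all(names(survival_log_hazards) %in% allowed))
    stop("`survival_log_hazards` names must be a subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (n_program_genes < 0 || n_program_genes > n_genes / 4)
    stop("`n_program_genes` must be in [0, n_genes/4]", call. = FALSE)

  structure(list(
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    cell_types = cell_types,
    mixing_concentration = mixing_concentration,
    stromal_immune_coupling = stromal_immune_coupling,
    anchor_immune_coupling = anchor_immune_coupling,
    anchor_activity_sd = anchor_activity_sd,
    n_program_genes = as.integer(n_program_genes),
    program_activity_scale = program_activity_scale,
    noise_sd = noise_sd,
    survival_log_hazards = survival_log_hazards,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    ihc_noise_sd = ihc_noise_sd,
    degenerate_ok = isTRUE(degenerate_ok),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  samples:", x$n_samples, " genes:", x$n_genes,
      " program genes:", x$n_program_genes, "\n")
  cat("  Dirichlet concentrations:",
      paste(sprintf("%s=%g", names(x$mixing_concentration),
                    x$mixing_concentration), collapse = ", "), "\n")
  cat("  stromal-immune coupling:", x$stromal_immune_coupling,
      " anchor-immune coupling:", x$anchor_immune_coupling, "\n")
  cat("  noise sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}

#' Cell-type mean log-expression profiles and marker annotation
#'
#' Builds the deterministic per-gene mean log-expression of each of the four
#' cell populations. Marker genes are expressed `marker_delta` log units
#' above a gene-specific baseline in their own population; the anchor gene
#' and the program genes are elevated in both the EMT-like cancer cells and
#' the fibroblasts, which is what makes stromal content a confounder for
#' them in bulk mixtures.
#'
#' @param config A [cohort_config()].
#' @param marker_delta Log-expression elevation of a marker in its own
#'   population.
#' @return A list with `genes`, the `mean_log_expression` gene-by-cell-type
#'   matrix, and a `marker` factor (one disjoint class per gene:
#'   `stromal_marker`, `immune_marker`, `epithelial_marker`, `emt_marker`,
#'   `program`, `anchor`, or `none`).
#' @export
cell_type_profiles <- function(config, marker_delta = 2.5) {
  stopifnot(inherits(config, "cohort_config"))
  ng <- config$n_genes
  npr <- config$n_program_genes
  # marker blocks are kept a small share of the universe: within-sample
  # ranks are competitive, and oversized marker blocks would let stromal
  # content mechanically depress the immune score (real cohorts use
  # ~141-gene sets among ~20,000 genes)
  n_strm <- max(5L, round(0.08 * ng))
  n_immn <- max(5L, round(0.08 * ng))
  n_epit <- max(5L, round(0.06 * ng))
  n_emtm <- max(5L, round(0.06 * ng))
  n_bg <- ng - 1L - npr - n_strm - n_immn - n_epit - n_emtm
  if (n_bg < 0) stop("`n_genes` too small for marker blocks", call. = FALSE)

  genes <- c("ANCHOR",
             if (npr > 0) sprintf("PROG%03d", seq_len(npr)),
             sprintf("STRM%03d", seq_len(n_strm)),
             sprintf("IMMN%03d", seq_len(n_immn)),
             sprintf("EPIT%03d", seq_len(n_epit)),
             sprintf("EMTM%03d", seq_len(n_emtm)),
             if (n_bg > 0) sprintf("BKGD%03d", seq_len(n_bg)))
  marker <- c("anchor",
              rep("program", npr),
              rep("stromal_marker", n_strm),
              rep("immune_marker", n_immn),
              rep("epithelial_marker", n_epit),
              rep("emt_marker", n_emtm),
              rep("none", max(n_bg, 0)))

  baseline <- seq(1, 3, length.out = ng)
  mu <- matrix(baseline, nrow = ng, ncol = 4,
               dimnames = list(genes, config$cell_types))
  mu[marker == "stromal_marker", "fibroblast"] <-
    mu[marker == "stromal_marker", "fibroblast"] + marker_delta
  mu[marker == "immune_marker", "immune"] <-
    mu[marker == "immune_marker", "immune"] + marker_delta
  mu[marker == "epithelial_marker", "epithelial"] <-
    mu[marker == "epithelial_marker", "epithelial"] + marker_delta
  mu[marker == "emt_marker", "emt"] <-
    mu[marker == "emt_marker", "emt"] + marker_delta
  # The anchor and its program are expressed by both EMT-like cancer cells
  # and fibroblasts, with the stronger loading on fibroblasts: a large
  # EMT-cell loading would open a second, non-stromal compositional pathway
  # between the anchor and the immune fraction and muddy the pure
  # stromal-confounding mechanism the generator is meant to realize.
  anchor_like <- marker %in% c("anchor", "program")
  mu[anchor_like, "emt"] <- mu[anchor_like, "emt"] + 0.4 * marker_delta
  mu[anchor_like, "fibroblast"] <- mu[anchor_like, "fibroblast"] + marker_delta

  list(genes = genes,
       mean_log_expression = mu,
       marker = factor(marker,
                       levels = c("anchor", "program", "stromal_marker",
                                  "immune_marker", "epithelial_marker",
                                  "emt_marker", "none")))
}
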