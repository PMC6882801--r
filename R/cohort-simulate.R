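#' Draw per-sample cell-type mixing fractions
#'
#' Samples one convex mixing vector per bulk sample from a Dirichlet law,
#' then tilts the fibroblast and immune components by a shared latent
#' Gaussian (positive stromal-immune coupling) and the immune component by
#' the per-sample cancer-intrinsic anchor activity (anchor-immune coupling)
#' before renormalizing. Tilting happens on the unnormalized gamma weights,
#' so every row remains an exact convex combination.
#'
#' Draws from the current RNG stream; call `set.seed()` (or use
#' [simulate_cohort()], which seeds from the config) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @return A `n_samples` by 4 matrix of fractions whose rows sum to 1, with
#'   attributes `anchor_activity` (the standardized cancer-intrinsic
#'   activity, N(0,1)) and `latent` (the shared stromal-immune factor).
#' @export
sample_fractions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  alpha <- config$mixing_concentration
  n <- config$n_samples
  w <- vapply(alpha, function(a) {
    if (a == 0) rep(0, n) else stats::rgamma(n, shape = a)
  }, numeric(n))
  colnames(w) <- names(alpha)

  latent <- stats::rnorm(n)
  activity <- stats::rnorm(n)
  cpl <- config$stromal_immune_coupling
  beta <- config$anchor_immune_coupling
  w[, "fibroblast"] <- w[, "fibroblast"] * exp(cpl * latent)
  w[, "immune"] <- w[, "immune"] * exp(cpl * latent + beta * activity)

  tot <- rowSums(w)
  if (any(tot == 0))
    stop("degenerate gamma draw produced an all-zero mixing row", call. = FALSE)
  f <- w / tot
  rownames(f) <- sprintf("S%04d", seq_len(n))
  attr(f, "anchor_activity") <- activity
  attr(f, "latent") <- latent
  f
}

#' Synthesize bulk expression from cell-type profiles and fractions
#'
#' Per-gene bulk signal is the fraction-weighted sum of the cell-type
#' profiles in linear space, log-transformed, perturbed by Gaussian noise,
#' and (by default) z-scored per gene across samples. The anchor gene and
#' the program genes additionally receive the per-sample cancer-intrinsic
#' activity term carried by `fractions` (see [sample_fractions()]), scaled
#' by `anchor_activity_sd` and `program_activity_scale`.
#'
#' @param profiles Output of [cell_type_profiles()].
#' @param fractions Output of [sample_fractions()] (cell types in columns).
#' @param config The [cohort_config()] used to draw `fractions`.
#' @param zscore If `FALSE`, return the noisy log expression without
#'   per-gene standardization (zero-variance genes retained).
#' @return Gene-by-sample matrix. When `zscore = TRUE` genes with zero
#'   variance across samples are dropped with a warning and recorded in the
#'   `dropped_genes` attribute.
#' @export
synthesize_expression <- function(profiles, fractions, config, zscore = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!identical(colnames(fractions), colnames(profiles$mean_log_expression)))
    stop("fraction columns do not match profile cell types", call. = FALSE)
  mu <- profiles$mean_log_expression
  raw <- exp(mu) %*% t(fractions)        # genes x samples, linear mixing
  x <- log(raw)
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                    nrow = nrow(x))

  activity <- attr(fractions, "anchor_activity")
  if (is.null(activity))
    stop("`fractions` lacks the anchor_activity attribute; ",
         "use sample_fractions()", call. = FALSE)
  x["ANCHOR", ] <- x["ANCHOR", ] + config$anchor_activity_sd * activity
  prog <- profiles$genes[profiles$marker == "program"]
  if (length(prog))
    x[prog, ] <- x[prog, ] +
      matrix(config$anchor_activity_sd * config$program_activity_scale *
               activity, nrow = length(prog), ncol = ncol(x), byrow = TRUE)

  if (!zscore) return(x)
  zscore_genes(x)
}

#' Z-score a gene-by-sample matrix per gene
#'
#' Genes with zero variance across samples cannot be standardized and are
#' dropped with a warning (rank-based downstream statistics require finite
#' values).
#'
#' @param x Gene-by-sample numeric matrix.
#' @return The standardized matrix (per-gene mean 0, sd 1) with a
#'   `dropped_genes` attribute naming removed genes.
#' @export
zscore_genes <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  keep <- s > 1e-12
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped during z-scoring: ",
            paste(utils::head(rownames(x)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "", call. = FALSE)
  z <- (x[keep, , drop = FALSE] - m[keep]) / s[keep]
  attr(z, "dropped_genes") <- rownames(x)[!keep]
  z
}

#' Attach survival and clinical covariates to a cohort
#'
#' Event times follow an exponential law with per-sample hazard
#' `baseline_hazard * exp(linear predictor)`, the linear predictor being the
#' configured log-hazards applied to stage (ordinal 1-4), age (years),
#' estrogen-receptor status (0/1) and the standardized anchor activity.
#' Censoring is independent of covariates: each sample is censored with
#' probability `censoring_rate`, at a uniform fraction of its event time.
#' IHC columns are noisy percentage readouts of the true stromal and immune
#' fractions, clipped to [0, 100].
#'
#' Draws from the current RNG stream (see [sample_fractions()]).
#'
#' @param fractions Output of [sample_fractions()].
#' @param truth List carrying `anchor_activity` (as recorded by
#'   [simulate_cohort()]); may be `NULL` when the anchor term is unused.
#' @param config A [cohort_config()].
#' @return A clinical `data.frame` with columns `sample_id`, `os_time`
#'   (months), `os_event`, `stage`, `age`, `er_status`, `subtype`,
#'   `ihc_stromal_pct`, `ihc_immune_pct`.
#' @export
attach_clinical <- function(fractions, truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(fractions)
  stage <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  age <- pmin(pmax(stats::rnorm(n, 58, 13), 25), 90)
  er <- stats::rbinom(n, 1, 0.75)
  subtype <- sample(c("LumA", "LumB", "Her2", "Basal"), n, replace = TRUE,
                    prob = c(0.45, 0.25, 0.12, 0.18))

  covs <- list(stage = stage, age = age, er_status = er,
               anchor_activity = if (!is.null(truth$anchor_activity))
                 truth$anchor_activity else rep(0, n))
  lh <- config$survival_log_hazards
  lp <- rep(0, n)
  for (nm in names(lh)) lp <- lp + lh[[nm]] * covs[[nm]]

  event_time <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  censored <- stats::runif(n) < config$censoring_rate
  os_time <- ifelse(censored, stats::runif(n) * event_time, event_time)

  clip01 <- function(p) pmin(pmax(p, 0), 100)
  ihc_noise <- function() if (config$ihc_noise_sd > 0)
    stats::rnorm(n, sd = config$ihc_noise_sd) else 0

  data.frame(
    sample_id = rownames(fractions),
    os_time = os_time,
    os_event = as.integer(!censored),
    stage = stage,
    age = age,
    er_status = er,
    subtype = subtype,
    ihc_stromal_pct = clip01(100 * fractions[, "fibroblast"] + ihc_noise()),
    ihc_immune_pct = clip01(100 * fractions[, "immune"] + ihc_noise()),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic bulk-tumor cohort
#'
#' Seeds the RNG from `config$seed` and runs profile construction, fraction
#' sampling, expression synthesis, clinical attachment and gene-set
#' assembly, returning everything a downstream analysis needs together with
#' the ground truth (mixing fractions, cancer-intrinsic anchor activity,
#' true survival coefficients) for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `expression`
#'   (z-scored gene-by-sample matrix), `fractions`, `clinical`, `gene_sets`
#'   (named list of marker gene vectors, including `stromal_set` and
#'   `immune_set`), `profiles`, `truth` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  profiles <- cell_type_profiles(config)
  fractions <- sample_fractions(config)
  expr <- synthesize_expression(profiles, fractions, config)
  truth <- list(
    anchor_immune_coupling = config$anchor_immune_coupling,
    anchor_activity = attr(fractions, "anchor_activity"),
    stromal_immune_latent = attr(fractions, "latent"),
    survival_log_hazards = config$survival_log_hazards,
    baseline_hazard = config$baseline_hazard,
    program_genes = profiles$genes[profiles$marker == "program"]
  )
  clinical <- attach_clinical(fractions, truth, config)
  gene_sets <- list(
    stromal_set = profiles$genes[profiles$marker == "stromal_marker"],
    immune_set = profiles$genes[profiles$marker == "immune_marker"],
    epithelial_set = profiles$genes[profiles$marker == "epithelial_marker"],
    emt_set = profiles$genes[profiles$marker == "emt_marker"]
  )
  structure(list(expression = expr, fractions = fractions,
                 clinical = clinical, gene_sets = gene_sets,
                 profiles = profiles, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic bulk-tumor cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes\n")
  cat("  anchor-immune coupling:", x$truth$anchor_immune_coupling,
      "  stromal-immune coupling:", x$config$stromal_immune_coupling, "\n")
  cat("  events:", sum(x$clinical$os_event), "of", nrow(x$clinical), "\n")
  invisible(x)
}

#' Simulate a two-arm knockdown experiment
#'
#' Generates replicate log2 expression columns for a knockdown condition and
#' a control, with the listed genes shifted down in the knockdown arm. Used
#' to exercise the differential-expression stage of the signature pipeline
#' without external microarray data.
#'
#' Draws from the current RNG stream.
#'
#' @param genes Character vector naming the gene universe.
#' @param down_genes Genes downregulated in the knockdown arm.
#' @param n_rep Replicates per arm (>= 2).
#' @param lfc True log2 fold change (knockdown minus control) applied to
#'   `down_genes`; negative for downregulation.
#' @param sd Replicate noise standard deviation (log2 units).
#' @return List of two gene-by-replicate matrices, `condition` and
#'   `control`.
#' @export
simulate_knockdown <- function(genes, down_genes, n_rep = 4, lfc = -3,
                               sd = 0.3) {
  if (n_rep < 2) stop("`n_rep` must be >= 2", call. = FALSE)
  if (!all(down_genes %in% genes))
    stop("`down_genes` must be a subset of `genes`", call. = FALSE)
  ng <- length(genes)
  base <- stats::runif(ng, 4, 10)
  mk <- function(shift) {
    m <- matrix(base + stats::rnorm(ng * n_rep, sd = sd), ng, n_rep,
                dimnames = list(genes, NULL))
    m[down_genes, ] <- m[down_genes, ] + shift
    m
  }
  control <- mk(0)
  condition <- mk(lfc)
  colnames(control) <- sprintf("ctrl_%d", seq_len(n_rep))
  colnames(condition) <- sprintf("kd_%d", seq_len(n_rep))
  list(condition = condition, control = control)
}
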