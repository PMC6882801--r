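#' Cox proportional-hazards fit on clinical covariates
#'
#' Fits a Cox model (Efron tie handling by default) of overall survival on
#' the named clinical columns, optionally with one extra per-sample
#' covariate (e.g. a gene's expression or its stroma-adjusted residuals).
#' Samples with missing values among the used columns are dropped
#' complete-case with a message. Monotone-likelihood divergence (infinite
#' coefficient drift) is reported via the `converged` column rather than
#' returned as silent numbers.
#'
#' @param clinical Clinical `data.frame` with `os_time`, `os_event` and the
#'   requested covariate columns; `stage` is treated as a single ordinal
#'   numeric covariate.
#' @param covariates Character vector of clinical column names (may be
#'   empty when `extra_covariate` is given).
#' @param extra_covariate Optional numeric vector aligned with the rows of
#'   `clinical`.
#' @param extra_name Label for the extra covariate.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: a `data.frame` with one row per
#'   covariate (`term`, `coef`, `hazard_ratio`, `ci95_low`, `ci95_high`,
#'   `p_value`, `converged`) and attributes `n`, `n_events`, `model`.
#' @export
cox_fit <- function(clinical, covariates, extra_covariate = NULL,
                    extra_name = "gene", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("os_time", "os_event") %in% names(clinical)))
  missing_c <- setdiff(covariates, names(clinical))
  if (length(missing_c))
    stop("covariates not in clinical table: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  df <- clinical[c("os_time", "os_event", covariates)]
  if (!is.null(extra_covariate)) {
    if (length(extra_covariate) != nrow(clinical))
      stop("`extra_covariate` must match the clinical rows", call. = FALSE)
    df[[extra_name]] <- extra_covariate
  }
  terms <- setdiff(names(df), c("os_time", "os_event"))
  if (!length(terms)) stop("no covariates to fit", call. = FALSE)
  cc <- stats::complete.cases(df)
  if (any(!cc))
    message(sum(!cc), " sample(s) dropped for missing values")
  df <- df[cc, , drop = FALSE]
  if (sum(df$os_event) < 1) stop("no events in the data", call. = FALSE)
  if (sum(df$os_event) < length(terms) + 1)
    stop("too few events (", sum(df$os_event), ") for ", length(terms),
         " covariate(s)", call. = FALSE)

  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  coefs <- sm$coefficients
  se <- coefs[, "se(coef)"]
  b <- coefs[, "coef"]
  converged <- rep(!diverged, length(b)) & is.finite(b) & is.finite(se) &
    abs(b) < 15
  out <- data.frame(
    term = terms,
    coef = unname(b),
    hazard_ratio = unname(exp(b)),
    ci95_low = unname(exp(b - 1.96 * se)),
    ci95_high = unname(exp(b + 1.96 * se)),
    p_value = unname(coefs[, "Pr(>|z|)"]),
    converged = unname(converged),
    stringsAsFactors = FALSE)
  attr(out, "n") <- sm$n
  attr(out, "n_events") <- sm$nevent
  attr(out, "model") <- terms
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Per-gene Cox survival scan
#'
#' Fits, for each gene, the multivariate Cox model of the base clinical
#' covariates plus that gene's expression as one additional covariate. In
#' stroma-adjusted mode the gene covariate is its expression residualized
#' on the stromal score ([residualize()]). Genes whose fit fails or is
#' collinear are flagged per row and the scan continues.
#'
#' @param expr Gene-by-sample matrix with columns matching
#'   `clinical$sample_id`.
#' @param clinical Clinical `data.frame`.
#' @param base_covariates Clinical columns of the base model (default
#'   stage, age, ER status).
#' @param stromal_scores Optional per-sample stromal score vector; when
#'   given, each gene is residualized on it before entering the model.
#' @param genes Genes to scan (default: all rows of `expr`).
#' @return `data.frame` in forest-plot schema: `gene`, `hazard_ratio`,
#'   `ci95_low`, `ci95_high`, `p_value`, `converged`, `note`.
#' @export
gene_survival_scan <- function(expr, clinical,
                               base_covariates = c("stage", "age",
                                                   "er_status"),
                               stromal_scores = NULL,
                               genes = rownames(expr)) {
  idx <- match(clinical$sample_id, colnames(expr))
  if (any(is.na(idx)))
    stop("clinical samples missing from expression matrix", call. = FALSE)
  rows <- lapply(genes, function(g) {
    gx <- expr[g, idx]
    if (!is.null(stromal_scores))
      gx <- tryCatch(residualize(gx, stromal_scores),
                     error = function(e) rep(NA_real_, length(gx)))
    fit <- tryCatch(
      cox_fit(clinical, base_covariates, extra_covariate = gx,
              extra_name = "gene"),
      error = function(e) e)
    if (inherits(fit, "error") || all(is.na(gx)))
      return(data.frame(gene = g, hazard_ratio = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        p_value = NA_real_, converged = FALSE,
                        note = if (inherits(fit, "error"))
                          conditionMessage(fit) else "degenerate covariate",
                        stringsAsFactors = FALSE))
    row <- fit[fit$term == "gene", ]
    collinear <- is.na(row$coef)
    data.frame(gene = g,
               hazard_ratio = row$hazard_ratio,
               ci95_low = row$ci95_low,
               ci95_high = row$ci95_high,
               p_value = row$p_value,
               converged = !collinear && row$converged,
               note = if (collinear) "collinear with base covariates"
               else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split samples at the median
#'
#' Values less than or equal to the median go to the `low` group, values
#' strictly above to `high`; with continuous values and odd n the groups
#' differ by exactly one sample, and ties at the median all fall low.
#'
#' @param values Numeric vector (n >= 2), not all identical.
#' @param na.rm Drop missing values before splitting.
#' @return Factor with levels `low`, `high` and attribute `median`.
#' @export
median_split <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("degenerate split: all values identical", call. = FALSE)
  med <- stats::median(values)
  out <- factor(ifelse(values <= med, "low", "high"),
                levels = c("low", "high"))
  attr(out, "median") <- med
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups: exact by enumeration when
#' the combined sample size is at most 12 and there are no ties, otherwise
#' the normal approximation with tie and continuity corrections. The
#' reported statistic is the rank sum of the first group.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return Object of class `rank_sum_result`: list with `statistic`
#'   (rank sum of `a`), `p_value`, `n1`, `n2`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  rank_sum <- sum(rank(pooled)[seq_len(n1)])
  if (length(unique(pooled)) == 1) {
    # all observations identical: no evidence of a shift
    return(structure(list(statistic = rank_sum, p_value = 1,
                          n1 = n1, n2 = n2, method = "normal_approx"),
                     class = "rank_sum_result"))
  }
  exact <- (n1 + n2) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(statistic = rank_sum,
                 p_value = min(wt$p.value, 1),
                 n1 = n1, n2 = n2,
                 method = if (exact) "exact" else "normal_approx"),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, n = %d/%d, p = %.4g\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Compare an IHC percentage readout across a median split
#'
#' Splits samples at the median of a gene's (optionally stroma-adjusted)
#' expression and compares the IHC cell-percentage column between the two
#' groups with the Wilcoxon rank-sum test.
#'
#' @param gene_values Per-sample expression values aligned with the rows of
#'   `clinical`.
#' @param clinical Clinical `data.frame` holding the IHC column.
#' @param ihc_column Name of the percentage column.
#' @param stromal_scores Optional stromal score vector; when given the gene
#'   values are residualized on it before splitting.
#' @return List with the `rank_sum_result` (`test`), `split_median`, and
#'   per-group IHC medians (`group_medians`).
#' @export
ihc_group_comparison <- function(gene_values, clinical, ihc_column,
                                 stromal_scores = NULL) {
  if (!ihc_column %in% names(clinical))
    stop("IHC column '", ihc_column, "' not in clinical table",
         call. = FALSE)
  if (!is.null(stromal_scores))
    gene_values <- residualize(gene_values, stromal_scores)
  grp <- median_split(gene_values)
  ihc <- clinical[[ihc_column]]
  test <- wilcoxon_rank_sum(ihc[grp == "low"], ihc[grp == "high"])
  list(test = test,
       split_median = attr(grp, "median"),
       group_medians = c(low = stats::median(ihc[grp == "low"]),
                         high = stats::median(ihc[grp == "high"])))
}
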