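#' Spearman correlation with t-based p-value
#'
#' Pearson correlation of the average-tie ranked data; the two-sided
#' p-value uses `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite.
#' @return An object of class `correlation_result`: list with `r`,
#'   `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  check_xy(x, y)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined: constant input vector", call. = FALSE)
  r <- stats::cor(rx, ry)
  n <- length(x)
  structure(list(r = r, p_value = cor_t_pvalue(r, n - 2L), n = n,
                 method = "spearman"),
            class = "correlation_result")
}

#' Partial Spearman correlation given confounders
#'
#' Rank-transforms `x`, `y` and every confounder column (average ties),
#' regresses the ranked `x` and ranked `y` on the ranked confounders plus an
#' intercept by least squares, and correlates the two residual vectors. For
#' a single confounder this is algebraically the classical recursion
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` on Spearman
#' correlations. The two-sided p-value uses a t statistic on
#' `n - 2 - k` degrees of freedom, `k` the number of confounders. With no
#' confounders the result coincides with [spearman_cor()].
#'
#' @param x,y Numeric vectors.
#' @param confounders `NULL`, a numeric vector, or a matrix/data.frame with
#'   one column per confounder; must be full rank after ranking.
#' @return An object of class `partial_correlation_result`: list with
#'   `partial_r`, `p_value`, `n`, `confounders` (labels), `df`.
#' @export
partial_spearman <- function(x, y, confounders = NULL) {
  check_xy(x, y)
  z <- as_confounder_matrix(confounders, length(x))
  k <- ncol(z)
  n <- length(x)
  if (n < k + 3)
    stop("need at least ", k + 3, " samples for ", k, " confounder(s)",
         call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined: constant input vector", call. = FALSE)
  if (k == 0) {
    s <- spearman_cor(x, y)
    return(structure(list(partial_r = s$r, p_value = s$p_value, n = n,
                          confounders = character(0), df = n - 2L),
                     class = "partial_correlation_result"))
  }
  rz <- apply(z, 2, rank)
  ex <- ls_residuals(rx, rz)
  ey <- ls_residuals(ry, rz)
  if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12)
    stop("correlation undefined: variable is fully explained by the ",
         "confounders", call. = FALSE)
  r <- stats::cor(ex, ey)
  df <- n - 2L - k
  if (df < 1) stop("insufficient degrees of freedom", call. = FALSE)
  structure(list(partial_r = r, p_value = cor_t_pvalue(r, df), n = n,
                 confounders = colnames(z), df = df),
            class = "partial_correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f (n = %d, p = %.3g)\n",
              x$method, x$r, x$n, x$p_value))
  invisible(x)
}

#' @export
print.partial_correlation_result <- function(x, ...) {
  cat(sprintf("partial Spearman: r = %.4f (n = %d, df = %d, p = %.3g)\n",
              x$partial_r, x$n, x$df, x$p_value))
  if (length(x$confounders))
    cat("  adjusted for:", paste(x$confounders, collapse = ", "), "\n")
  invisible(x)
}

#' Stroma-adjusted expression: residuals on confounders
#'
#' Least-squares residuals of `y` regressed on the raw (unranked)
#' confounders plus an intercept. This is the "stroma-adjusted expression"
#' used for median splits and as survival covariates.
#'
#' @param y Numeric response vector.
#' @param confounders As in [partial_spearman()]; `NULL` means
#'   intercept-only (mean-centering).
#' @return Residual vector with mean zero.
#' @export
residualize <- function(y, confounders = NULL) {
  if (!is.numeric(y) || !all(is.finite(y)))
    stop("`y` must be finite numeric", call. = FALSE)
  z <- as_confounder_matrix(confounders, length(y))
  ls_residuals(y, z)
}

#' Residual pair for partial-correlation scatter plots
#'
#' Residualizes both variables on the same confounders; the Pearson
#' correlation of the two residual vectors equals the (rank-free) partial
#' correlation of `x` and `y` given the confounders, so plotting one against
#' the other visualizes the adjusted association.
#'
#' @inheritParams partial_spearman
#' @return List with `x_residuals`, `y_residuals`, `model_description`.
#' @export
residual_pair <- function(x, y, confounders = NULL) {
  check_xy(x, y, min_n = 3L)
  z <- as_confounder_matrix(confounders, length(x))
  desc <- if (ncol(z) == 0) "mean-centered (no confounders)" else
    paste("residuals on:", paste(colnames(z), collapse = " + "))
  list(x_residuals = ls_residuals(x, z),
       y_residuals = ls_residuals(y, z),
       model_description = desc)
}

#' Gene-by-target association matrix
#'
#' Computes the (partial) Spearman correlation of each listed gene's
#' expression against each target score column, optionally adjusting every
#' cell for the same confounder scores. Samples with missing values are
#' dropped per cell (complete-case), and the per-cell `n` is reported.
#'
#' @param expr Gene-by-sample numeric matrix.
#' @param genes Gene labels (rows of `expr`).
#' @param scores Score `data.frame` with `sample_id` plus numeric columns
#'   (targets and confounders).
#' @param targets Score column names to correlate against.
#' @param confounders Score column names to adjust for, or `NULL`.
#' @return Object of class `association_matrix`: list with matrices `r`,
#'   `p`, `n` (genes x targets), plus `adjusted_for`. Use
#'   [association_long()] for the long-format table.
#' @export
association_matrix <- function(expr, genes, scores, targets,
                               confounders = NULL) {
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("genes not in expression matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  missing_t <- setdiff(c(targets, confounders), colnames(scores))
  if (length(missing_t))
    stop("columns not in score table: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  scores <- align_scores(scores, colnames(expr))

  r <- p <- nn <- matrix(NA_real_, length(genes), length(targets),
                         dimnames = list(genes, targets))
  for (g in genes) {
    gx <- expr[g, ]
    for (t in targets) {
      ty <- scores[[t]]
      zc <- if (length(confounders))
        as.matrix(scores[confounders]) else NULL
      ok <- is.finite(gx) & is.finite(ty)
      if (!is.null(zc)) ok <- ok & apply(is.finite(zc), 1, all)
      res <- partial_spearman(gx[ok], ty[ok],
                              if (is.null(zc)) NULL
                              else zc[ok, , drop = FALSE])
      r[g, t] <- res$partial_r
      p[g, t] <- res$p_value
      nn[g, t] <- res$n
    }
  }
  structure(list(r = r, p = p, n = nn,
                 adjusted_for = if (length(confounders)) confounders
                 else character(0)),
            class = "association_matrix")
}

#' Long-format view of an association matrix
#'
#' @param am An [association_matrix()] result.
#' @param group Optional group label column value.
#' @return `data.frame` with columns `gene`, `target`, `group`, `n`, `r`,
#'   `p`.
#' @export
association_long <- function(am, group = NA_character_) {
  stopifnot(inherits(am, "association_matrix"))
  grid <- expand.grid(gene = rownames(am$r), target = colnames(am$r),
                      stringsAsFactors = FALSE)
  data.frame(grid, group = group,
             n = as.vector(am$n), r = as.vector(am$r), p = as.vector(am$p),
             stringsAsFactors = FALSE)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix:", nrow(x$r), "gene(s) x", ncol(x$r),
      "target(s)\n")
  if (length(x$adjusted_for))
    cat("  adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Per-group association matrices
#'
#' Restricts the association analysis to each level of a per-sample
#' grouping (e.g. molecular subtype). Groups too small for the requested
#' adjustment (fewer than `length(confounders) + 3` samples) are skipped
#' with a warning.
#'
#' @inheritParams association_matrix
#' @param grouping Per-sample labels, aligned with `colnames(expr)`.
#' @return Named list of `association_matrix` objects, one per retained
#'   group.
#' @export
subgroup_associations <- function(expr, genes, scores, targets,
                                  grouping, confounders = NULL) {
  if (length(grouping) != ncol(expr))
    stop("`grouping` must label every sample", call. = FALSE)
  if (all(is.na(grouping)) || length(grouping) == 0)
    stop("empty grouping", call. = FALSE)
  min_n <- length(confounders) + 3L
  out <- list()
  for (g in unique(stats::na.omit(grouping))) {
    idx <- which(!is.na(grouping) & grouping == g)
    if (length(idx) < min_n) {
      warning("group '", g, "' skipped: ", length(idx),
              " sample(s) < required ", min_n, call. = FALSE)
      next
    }
    out[[as.character(g)]] <- association_matrix(
      expr[, idx, drop = FALSE], genes,
      scores[match(colnames(expr)[idx], scores$sample_id), , drop = FALSE],
      targets, confounders)
  }
  out
}

#' Coefficient of determination of a simple linear fit
#'
#' Squared Pearson correlation, i.e. the r-squared of the simple linear
#' model with intercept.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return r-squared in [0, 1].
#' @export
coefficient_of_determination <- function(x, y) {
  check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("r-squared undefined: constant input", call. = FALSE)
  stats::cor(x, y)^2
}

#' Parsimonious confounder selection by linear-model screening
#'
#' Candidate covariates enter when their univariable linear-model F-test
#' against the response has p < `enter_p`; covariates whose multivariable
#' p-value is >= `stay_p` are then dropped, iterating to stability. This is
#' the conventional univariable-then-multivariable screen used to pick the
#' adjustment set when it is not fixed a priori.
#'
#' @param response Numeric response vector.
#' @param candidates `data.frame` of numeric candidate covariates.
#' @param enter_p,stay_p Entry and retention thresholds (default 0.05).
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_confounders <- function(response, candidates, enter_p = 0.05,
                               stay_p = 0.05) {
  stopifnot(is.data.frame(candidates))
  uni_p <- vapply(candidates, function(v) {
    f <- summary(stats::lm(response ~ v))$fstatistic
    if (is.null(f)) return(1)
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }, numeric(1))
  keep <- names(candidates)[uni_p < enter_p]
  repeat {
    if (length(keep) <= 1) break
    fit <- stats::lm(response ~ ., data = candidates[keep])
    pv <- summary(fit)$coefficients[-1, 4]
    worst <- which.max(pv)
    if (pv[worst] < stay_p) break
    keep <- setdiff(keep, keep[worst])
  }
  keep
}

# --- internal helpers -------------------------------------------------------

check_xy <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  invisible(TRUE)
}

# coerce confounders to a labelled matrix; ncol 0 means none
as_confounder_matrix <- function(confounders, n) {
  if (is.null(confounders))
    return(matrix(numeric(0), nrow = n, ncol = 0))
  z <- as.matrix(confounders)
  if (!is.numeric(z) || !all(is.finite(z)))
    stop("confounders must be finite numeric", call. = FALSE)
  if (nrow(z) != n)
    stop("confounder rows must match the sample count", call. = FALSE)
  if (is.null(colnames(z)))
    colnames(z) <- paste0("z", seq_len(ncol(z)))
  z
}

# least-squares residuals of y on [1, z]; errors on rank deficiency
ls_residuals <- function(y, z) {
  design <- cbind(`(Intercept)` = 1, z)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("confounder matrix is rank deficient (collinear columns)",
         call. = FALSE)
  as.vector(y - design %*% qr.coef(qr_d, y))
}

cor_t_pvalue <- function(r, df) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}
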