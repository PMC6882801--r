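#' Read and write gene-by-sample expression matrices
#'
#' Tab-separated layout: first column is the gene ID, the header row holds
#' the sample IDs. Writers and readers round-trip losslessly (full double
#' precision).
#'
#' @param path File path.
#' @return `read_expression()`: a numeric matrix with gene rownames and
#'   sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @param expr Gene-by-sample numeric matrix.
#' @rdname read_expression
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample score tables
#'
#' TSV with a `sample_id` column plus one numeric column per score.
#' Externally computed score tables (cell-type deconvolution, immune-cycle
#' step scores) load through the same reader.
#'
#' @param path File path.
#' @return `read_score_table()`: a `data.frame`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("score table must have a `sample_id` column", call. = FALSE)
  num <- setdiff(names(df), "sample_id")
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' @param scores Score `data.frame` with `sample_id`.
#' @rdname read_score_table
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(format(scores, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, `name TAB description TAB gene...`.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional per-set description strings.
#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- rep("na", length(gene_sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(gene_sets), descriptions, gene_sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write clinical tables
#'
#' Tab- or comma-separated, detected from the extension (`.csv` vs
#' anything else); must contain `sample_id`, `os_time`, `os_event`.
#'
#' @param path File path.
#' @return `read_clinical()`: a `data.frame`.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(df)))
    stop("clinical table must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @param clinical Clinical `data.frame`.
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(format(clinical, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write differential-expression tables
#'
#' TSV schema: `gene`, `log2_fold_change`, `p_value`, `fdr`. Externally
#' computed DE tables in this schema bypass the built-in Welch test.
#'
#' @param path File path.
#' @return `read_de_table()`: a `data.frame`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2_fold_change", "p_value", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @param de DE `data.frame`.
#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  utils::write.table(format(de, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a score table to an expression matrix's sample order
align_scores <- function(scores, sample_ids) {
  idx <- match(sample_ids, scores$sample_id)
  if (any(is.na(idx)))
    stop("score table is missing samples: ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  scores[idx, , drop = FALSE]
}
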