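#' Normalize an expression matrix to log2 z-scores
#'
#' Applies `log2(x + 1)` (unless the values are already on a log2 scale) and
#' then z-scores each gene across samples. Genes with more than
#' `max_missing_fraction` missing values are dropped; remaining missing
#' values are mean-imputed before transformation. Constant genes map to
#' all-zero columns.
#'
#' @param data Data frame: first column sample identifiers, remaining columns
#'   one per gene (cBioPortal-style samples-by-genes table).
#' @param already_log2 If `TRUE` the values are taken to be log2-scale
#'   already and only z-scoring is applied.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1) standard deviation.
#' @param max_missing_fraction Genes missing in more than this fraction of
#'   samples are dropped (default 0.2).
#' @return A tibble of the same shape (sample_id + gene columns) holding
#'   z-scored values.
#' @export
normalize_expression <- function(data, already_log2 = FALSE,
                                 sd_type = c("population", "sample"),
                                 max_missing_fraction = 0.2) {
  sd_type <- match.arg(sd_type)
  x <- expr_to_matrix(data)
  if (nrow(x) == 0 || ncol(x) == 0) {
    stop("expression matrix is empty", call. = FALSE)
  }
  # drop heavily-missing genes, mean-impute the rest
  miss <- colMeans(is.na(x))
  if (any(miss > max_missing_fraction)) {
    x <- x[, miss <= max_missing_fraction, drop = FALSE]
  }
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  if (!already_log2) {
    if (any(x < 0)) {
      stop("raw (non-log) expression values must be non-negative", call. = FALSE)
    }
    x <- log2(x + 1)
  }
  m <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ss <- colSums(xc^2)
  denom <- if (sd_type == "population") m else max(m - 1, 1)
  s <- sqrt(ss / denom)
  s[s < .Machine$double.eps^0.5] <- Inf # constant genes -> all-zero column
  out <- sweep(xc, 2, s, "/")
  matrix_to_expr(out, id_col = names(data)[1])
}

#' Select high-variance genes (plus an always-keep list)
#'
#' Keeps the union of the `top_k_by_variance` genes by cross-sample variance
#' and an `always_keep` list (e.g. known oncogenes), in stable original
#' column order. Variance is intended to be computed on log2 values before
#' z-scoring; pass the matrix at that stage. The selected gene set is
#' attached as attribute `"gene_set"` so the identical selection can be
#' re-applied to a validation cohort via the `gene_set` argument.
#'
#' @param data Samples-by-genes data frame (sample_id first column).
#' @param top_k_by_variance Number of genes to keep by variance.
#' @param always_keep Character vector of gene ids kept regardless of
#'   variance rank; ids absent from the matrix are skipped with a warning.
#' @param gene_set Optional character vector: re-apply a previously persisted
#'   selection instead of recomputing it.
#' @return Tibble with the selected gene columns; attribute `"gene_set"`
#'   holds the selected gene ids.
#' @export
select_genes <- function(data, top_k_by_variance = 5596L,
                         always_keep = character(), gene_set = NULL) {
  x <- expr_to_matrix(data)
  genes <- colnames(x)
  if (is.null(gene_set)) {
    top_k_by_variance <- min(as.integer(top_k_by_variance), ncol(x))
    v <- apply(x, 2, stats::var)
    ranked <- genes[order(-v, seq_along(v))]
    keep <- ranked[seq_len(top_k_by_variance)]
    missing_keep <- setdiff(always_keep, genes)
    if (length(missing_keep) > 0) {
      warning(sprintf("always_keep genes absent from matrix, skipped: %s",
                      paste(missing_keep, collapse = ", ")), call. = FALSE)
    }
    gene_set <- genes[genes %in% union(keep, always_keep)]
  } else {
    absent <- setdiff(gene_set, genes)
    if (length(absent) > 0) {
      warning(sprintf("%d persisted genes absent from this cohort, skipped",
                      length(absent)), call. = FALSE)
      gene_set <- intersect(gene_set, genes)
    }
    gene_set <- genes[genes %in% gene_set]
  }
  out <- data[, c(names(data)[1], gene_set), drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "gene_set") <- gene_set
  out
}

#' Read an expression table from TSV/CSV
#'
#' Reads a cBioPortal-style matrix with genes as columns or rows. The first
#' column (or row, for `orientation = "genes_by_samples"`) holds identifiers.
#'
#' @param path File path (delimiter inferred from extension: `.csv` = comma,
#'   otherwise tab).
#' @param orientation `"samples_by_genes"`, `"genes_by_samples"`, or
#'   `"auto"` (transpose when there are many more rows than columns, the
#'   typical genes-in-rows layout).
#' @return Samples-by-genes tibble with `sample_id` first.
#' @export
read_expression <- function(path, orientation = c("samples_by_genes",
                                                  "genes_by_samples", "auto")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (orientation == "auto") {
    orientation <- if (nrow(raw) > 3 * (ncol(raw) - 1)) "genes_by_samples"
                   else "samples_by_genes"
  }
  if (orientation == "genes_by_samples") {
    genes <- as.character(raw[[1]])
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(mat) <- genes
    return(matrix_to_expr(mat))
  }
  out <- tibble::as_tibble(raw)
  names(out)[1] <- "sample_id"
  out
}

#' Write a statuses (or any samples-by-columns) table to TSV
#'
#' @param data Tibble with sample identifiers in the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_statuses <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}
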