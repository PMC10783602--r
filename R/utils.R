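#' Area under the ROC curve
#'
#' Rank-based AUROC with the midrank (Wilcoxon) convention for tied scores.
#' Pairs with a missing score or label are dropped.
#'
#' @param scores Numeric vector of prediction scores (higher = more positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cosine similarity between a predicted and a true state vector
#'
#' Compares two length-d gene-group state vectors (binary or real scores)
#' by the cosine of the angle between them.
#'
#' @param predicted Numeric or binary vector.
#' @param truth Binary vector of the same length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' state_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0.5
state_similarity <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length", call. = FALSE)
  }
  predicted <- as.numeric(predicted)
  truth <- as.numeric(truth)
  np <- sqrt(sum(predicted^2))
  nt <- sqrt(sum(truth^2))
  if (np == 0 || nt == 0) {
    stop("cosine similarity is undefined for a zero-norm vector", call. = FALSE)
  }
  sum(predicted * truth) / (np * nt)
}

# Greedy optimal-ish one-to-one matching of discovered groups to planted
# factors by agreement (used by recovery checks and examples). Returns an
# integer vector: for each truth column, the matched discovered column and
# the agreement achieved after optimal polarity flip.
match_factors <- function(statuses, truth) {
  statuses <- as.matrix(statuses)
  truth <- as.matrix(truth)
  m <- nrow(truth)
  agree <- function(a, b) max(mean(a == b), mean(a != b))
  d_true <- ncol(truth)
  d_est <- ncol(statuses)
  A <- matrix(0, d_true, d_est)
  for (i in seq_len(d_true)) {
    for (j in seq_len(d_est)) A[i, j] <- agree(truth[, i], statuses[, j])
  }
  matched <- integer(d_true)
  agreement <- numeric(d_true)
  taken <- rep(FALSE, d_est)
  # assign best pairs first so a weak factor cannot steal a strong one's match
  ord <- order(-A)
  for (idx in ord) {
    i <- (idx - 1) %% d_true + 1
    j <- (idx - 1) %/% d_true + 1
    if (matched[i] == 0L && !taken[j]) {
      matched[i] <- j
      agreement[i] <- A[i, j]
      taken[j] <- TRUE
    }
    if (all(matched > 0L)) break
  }
  list(matched = matched, agreement = agreement)
}

# internal: coerce a samples-by-genes tibble (sample_id first column) to a
# numeric matrix with rownames, and back
expr_to_matrix <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  if (nrow(data) == 0) stop("expression matrix is empty", call. = FALSE)
  ids <- as.character(data[[1]])
  x <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!vapply(data[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric expression values in column '%s'",
                 names(data)[-1][bad]), call. = FALSE)
  }
  rownames(x) <- ids
  x
}

matrix_to_expr <- function(x, id_col = "sample_id") {
  out <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(x)), out)
  out
}
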