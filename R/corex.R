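# Total-correlation explanation with binary latent factors.
#
# The model: d binary latent variables ("gene groups"), each explaining the
# co-dependence of a subset of genes. Genes are discretized into equal-mass
# expression bins; each factor's status for a sample is the posterior of a
# naive-Bayes model over the genes currently assigned to that factor; genes
# are (re)assigned competitively to the factor with which they share the
# most mutual information. Iterating the two updates maximizes a lower bound
# on the total correlation explained by the factors.

#' Discover binary gene-group latent factors
#'
#' Fits `n_groups` binary latent factors to a z-scored expression matrix by
#' iterative total-correlation explanation: genes are discretized into
#' `n_bins` equal-mass bins, factor posteriors are computed under a
#' conditional-independence model of the genes assigned to each factor, and
#' genes are competitively reassigned to the factor with maximal mutual
#' information. Initialization is a varimax-rotated principal-component
#' split, so the fit is deterministic given the data and `seed`.
#'
#' @param data Samples-by-genes data frame of z-scored expression
#'   (first column sample ids), as produced by [normalize_expression()].
#' @param n_groups Number of binary latent factors d.
#' @param n_iterations Maximum number of update iterations (default 100).
#' @param seed Integer seed (used for degenerate initializations and
#'   recorded in the model).
#' @param n_bins Number of equal-mass expression bins for mutual-information
#'   estimation (default 3).
#' @param tol Stop early when total TC changes by less than this (default 1e-6).
#' @return A `group_model` object with elements `mi` (genes x groups mutual
#'   information, nats), `tc` (per-group total correlation, sorted
#'   non-increasing), `statuses` (samples x groups binary tibble),
#'   `direction` (genes x groups sign matrix) and the parameters needed by
#'   [infer_status()].
#' @seealso [infer_status()], [group_composition()], [tc_curve()]
#' @export
discover_groups <- function(data, n_groups, n_iterations = 100L, seed = 0L,
                            n_bins = 3L, tol = 1e-6) {
  x <- expr_to_matrix(data)
  m <- nrow(x)
  n <- ncol(x)
  d <- as.integer(n_groups)
  if (d < 1L) stop("n_groups must be >= 1", call. = FALSE)
  if (d > n) stop("n_groups cannot exceed the number of genes", call. = FALSE)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  B <- as.integer(n_bins)

  withr::local_seed(as.integer(seed))

  # --- discretize into equal-mass bins -------------------------------------
  cutpoints <- apply(x, 2, stats::quantile,
                     probs = seq_len(B - 1L) / B, names = FALSE)
  cutpoints <- matrix(cutpoints, nrow = B - 1L)
  bins <- matrix(1L, m, n)
  for (j in seq_len(n)) {
    bins[, j] <- findInterval(x[, j], cutpoints[, j]) + 1L
  }
  # indicator matrices per bin, reused throughout
  Bind <- lapply(seq_len(B), function(b) (bins == b) * 1)

  # --- initialize factor activity from rotated principal components -------
  q <- init_factor_posteriors(x, d)

  prev_total <- -Inf
  alpha <- NULL
  iter_run <- 0L
  converged <- FALSE
  for (it in seq_len(n_iterations)) {
    iter_run <- it
    ms <- corex_m_step(Bind, q, m, alpha_prev = alpha)
    alpha <- ms$alpha
    q <- corex_e_step(Bind, ms)
    total <- sum(ms$tc)
    if (is.finite(prev_total) && abs(total - prev_total) < tol) {
      converged <- TRUE
      break
    }
    prev_total <- total
  }
  # final statistics consistent with the final posteriors
  ms <- corex_m_step(Bind, q, m, alpha_prev = alpha)

  model <- structure(list(
    gene_ids = colnames(x),
    sample_ids = rownames(x),
    n_groups = d,
    n_bins = B,
    cutpoints = cutpoints,
    alpha = ms$alpha,
    cond_llr = ms$llr,
    prior_logodds = ms$prior_logodds,
    mi = ms$mi,
    tc = ms$tc,
    seed = as.integer(seed),
    n_iterations = as.integer(n_iterations),
    iterations_run = iter_run,
    converged = converged
  ), class = "group_model")

  # statuses are defined as the inference output on the training matrix, so
  # infer_status(model, train) reproduces them exactly
  st <- infer_core(model, x)

  # direction: +1 where a gene's median expression is higher at status = 1
  dirm <- direction_matrix(x, st, ms$mi)

  # polarity: orient each factor so its top-MI gene points up, then rebuild
  # statuses/directions through the inference path so stored statuses match
  # infer_status() bit-exactly
  flipped <- FALSE
  for (k in seq_len(d)) {
    jtop <- order(-ms$mi[, k], seq_len(n))[1]
    if (dirm[jtop, k] < 0) {
      model$prior_logodds[k] <- -model$prior_logodds[k]
      for (b in seq_len(B)) model$cond_llr[[b]][, k] <- -model$cond_llr[[b]][, k]
      flipped <- TRUE
    }
  }
  if (flipped) {
    st <- infer_core(model, x)
    dirm <- direction_matrix(x, st, ms$mi)
  }

  # order groups by decreasing total correlation
  ord <- order(-model$tc, seq_len(d))
  model$tc <- model$tc[ord]
  model$mi <- model$mi[, ord, drop = FALSE]
  model$alpha <- model$alpha[, ord, drop = FALSE]
  model$prior_logodds <- model$prior_logodds[ord]
  model$cond_llr <- lapply(model$cond_llr, function(L) L[, ord, drop = FALSE])
  dirm <- dirm[, ord, drop = FALSE]
  st <- st[, ord, drop = FALSE]

  gnames <- sprintf("g%03d", seq_len(d))
  colnames(model$mi) <- colnames(model$alpha) <- colnames(dirm) <- gnames
  colnames(st) <- gnames
  model$direction <- dirm
  model$statuses <- matrix_to_expr(st, id_col = "sample_id")
  model
}

# varimax-rotated PCA initialization: each rotated component concentrates on
# one block of co-varying genes; thresholding its sample scores at the
# median gives an initial binary activity per factor.
init_factor_posteriors <- function(x, d) {
  m <- nrow(x)
  n <- ncol(x)
  rank_max <- min(m - 1L, n)
  d_pc <- min(d, rank_max)
  pc <- stats::prcomp(x, center = FALSE, rank. = d_pc)
  W <- pc$rotation
  if (d_pc >= 2L) {
    W <- W %*% stats::varimax(W, normalize = FALSE)$rotmat
  }
  scores <- x %*% W
  q <- matrix(stats::runif(m * d, 0.45, 0.55), m, d) # extra factors: random
  for (k in seq_len(d_pc)) {
    q[, k] <- ifelse(scores[, k] > stats::median(scores[, k]), 0.95, 0.05)
  }
  q
}

# M-step: soft-count conditionals, mutual information, competitive gene
# assignment, and the per-factor total-correlation lower bound.
corex_m_step <- function(Bind, q, m, alpha_prev = NULL, smooth = 0.5) {
  B <- length(Bind)
  d <- ncol(q)
  n <- ncol(Bind[[1]])
  p1 <- pmin(pmax(colMeans(q), 1e-6), 1 - 1e-6)
  C1 <- lapply(Bind, function(M) crossprod(M, q))         # n x d per bin
  C0 <- lapply(seq_len(B), function(b) {
    colSums(Bind[[b]]) - C1[[b]]
  })
  tot1 <- Reduce(`+`, C1)
  tot0 <- m - tot1
  # smoothed conditionals for the posterior; plug-in (unsmoothed) joint for MI
  llr <- vector("list", B)
  mi <- matrix(0, n, d)
  for (b in seq_len(B)) {
    pb1 <- (C1[[b]] + smooth) / (tot1 + B * smooth)
    pb0 <- (C0[[b]] + smooth) / (tot0 + B * smooth)
    llr[[b]] <- log(pb1) - log(pb0)
    # plug-in MI contribution of (bin = b, y = 1) and (bin = b, y = 0)
    j1 <- C1[[b]] / m
    j0 <- C0[[b]] / m
    pb <- (C1[[b]] + C0[[b]]) / m
    t1 <- j1 * (log(j1) - log(pb %*% diag(p1, d, d) + 0))
    t1[j1 <= 0] <- 0
    t0 <- j0 * (log(j0) - log(pb %*% diag(1 - p1, d, d) + 0))
    t0[j0 <= 0] <- 0
    mi <- mi + t1 + t0
  }
  mi[mi < 0] <- 0 # guard fp rounding; plug-in MI is non-negative
  # competitive assignment: each gene to its max-MI factor (ties: first)
  amax <- max.col(mi, ties.method = "first")
  alpha <- matrix(0, n, d)
  alpha[cbind(seq_len(n), amax)] <- 1
  hy <- -(p1 * log(p1) + (1 - p1) * log(1 - p1))
  tc <- pmax(0, colSums(alpha * mi) - hy)
  list(alpha = alpha, llr = llr, mi = mi, tc = tc,
       prior_logodds = log(p1) - log(1 - p1))
}

# E-step: naive-Bayes posterior of each factor given its assigned genes.
corex_e_step <- function(Bind, ms) {
  B <- length(Bind)
  lo <- matrix(ms$prior_logodds, nrow(Bind[[1]]), length(ms$prior_logodds),
               byrow = TRUE)
  for (b in seq_len(B)) {
    lo <- lo + Bind[[b]] %*% (ms$alpha * ms$llr[[b]])
  }
  stats::plogis(lo)
}

direction_matrix <- function(x, st, mi) {
  n <- ncol(x)
  d <- ncol(st)
  dirm <- matrix(1L, n, d)
  for (k in seq_len(d)) {
    s <- st[, k]
    if (length(unique(s)) == 2L) {
      md <- apply(x[s == 1L, , drop = FALSE], 2, stats::median) -
        apply(x[s == 0L, , drop = FALSE], 2, stats::median)
      dirm[, k] <- ifelse(md >= 0, 1L, -1L)
    }
  }
  dirm[mi <= 0] <- 0L
  dirm
}

# shared inference core: bin with stored cutpoints, sum weighted
# log-likelihood ratios, threshold the posterior at 0.5 (log-odds at 0)
infer_core <- function(model, x) {
  m <- nrow(x)
  B <- model$n_bins
  n <- length(model$gene_ids)
  bins <- matrix(1L, m, n)
  for (j in seq_len(n)) {
    bins[, j] <- findInterval(x[, j], model$cutpoints[, j]) + 1L
  }
  lo <- matrix(model$prior_logodds, m, model$n_groups, byrow = TRUE)
  for (b in seq_len(B)) {
    lo <- lo + ((bins == b) * 1) %*% (model$alpha * model$cond_llr[[b]])
  }
  st <- (lo > 0) * 1L
  rownames(st) <- rownames(x)
  st
}

#' Infer gene-group statuses for new samples
#'
#' Applies a trained [discover_groups()] model to a new z-scored expression
#' matrix without refitting. Genes the model uses that are absent from the
#' new cohort are mean-imputed (zero on the z-score scale) and logged; a
#' group missing more than half of its composition genes is flagged
#' unreliable.
#'
#' @param data Samples-by-genes data frame of z-scored expression.
#' @param model A `group_model`.
#' @return Tibble `sample_id` + one binary column per group. Attributes:
#'   `unreliable_groups` (logical per group) and `missing_genes`.
#' @export
infer_status <- function(data, model) {
  stopifnot(inherits(model, "group_model"))
  x <- expr_to_matrix(data)
  need <- model$gene_ids
  missing_genes <- setdiff(need, colnames(x))
  full <- matrix(0, nrow(x), length(need),
                 dimnames = list(rownames(x), need))
  present <- intersect(need, colnames(x))
  full[, present] <- x[, present]
  if (length(missing_genes) > 0) {
    message(sprintf("infer_status: %d model genes absent, mean-imputed (0)",
                    length(missing_genes)))
  }
  st <- infer_core(model, full)
  # a group is unreliable if > 50% of its composition genes are missing
  miss_idx <- need %in% missing_genes
  used <- model$alpha > 0 & model$mi > 0
  frac_missing <- colSums(used & miss_idx) / pmax(colSums(used), 1L)
  out <- matrix_to_expr(st, id_col = "sample_id")
  attr(out, "unreliable_groups") <- frac_missing > 0.5
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Ranked gene composition of a group
#'
#' Lists the genes defining a group, ranked by descending mutual information
#' with the group status, truncated to `max_genes` and filtered at
#' `mi > mi_threshold`, with each gene's expression direction attached
#' (+1 when the gene is higher-expressed at status 1).
#'
#' @param model A `group_model`.
#' @param group_id Group index, 1-based (1..d).
#' @param max_genes Maximum number of genes returned (default 400).
#' @param mi_threshold Minimum mutual information in nats (default 0.002).
#' @return Tibble `gene`, `mi`, `direction`, descending `mi`.
#' @export
group_composition <- function(model, group_id, max_genes = 400L,
                              mi_threshold = 0.002) {
  stopifnot(inherits(model, "group_model"))
  if (group_id < 1L || group_id > model$n_groups) {
    stop("group_id out of range", call. = FALSE)
  }
  mi <- model$mi[, group_id]
  keep <- which(mi > mi_threshold)
  ord <- keep[order(-mi[keep], keep)]
  ord <- utils::head(ord, max_genes)
  tibble::tibble(
    gene = model$gene_ids[ord],
    mi = unname(mi[ord]),
    direction = unname(model$direction[ord, group_id])
  )
}

#' Total-correlation curve over a grid of group counts
#'
#' Fits a model at each value of `d_grid` and records the total TC
#' (sum of per-group total correlations), used to locate the plateau at
#' which adding groups stops explaining additional co-dependence.
#'
#' @inheritParams discover_groups
#' @param d_grid Integer vector of group counts to fit.
#' @return A tibble (`n_groups`, `total_tc`) of class `tc_curve`.
#' @export
tc_curve <- function(data, d_grid, n_iterations = 100L, seed = 0L,
                     n_bins = 3L) {
  stopifnot(length(d_grid) >= 1)
  out <- purrr::map_dfr(as.integer(d_grid), function(d) {
    fit <- discover_groups(data, n_groups = d, n_iterations = n_iterations,
                           seed = seed, n_bins = n_bins)
    tibble::tibble(n_groups = d, total_tc = sum(fit$tc))
  })
  class(out) <- c("tc_curve", class(out))
  out
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> %d binary gene groups over %d genes, %d samples\n",
              x$n_groups, length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  total TC %.3f nats | %d/%d iterations%s | seed %d\n",
              sum(x$tc), x$iterations_run, x$n_iterations,
              if (x$converged) " (converged)" else "", x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group model into a gene-group table
#'
#' @param x A `group_model`.
#' @param mi_threshold Keep rows with `mi` above this (default 0: all).
#' @param ... Unused.
#' @return Tibble `gene`, `group`, `mi`, `direction`.
#' @export
tidy.group_model <- function(x, mi_threshold = 0, ...) {
  d <- x$n_groups
  out <- purrr::map_dfr(seq_len(d), function(k) {
    tibble::tibble(
      gene = x$gene_ids, group = colnames(x$mi)[k],
      mi = unname(x$mi[, k]), direction = unname(x$direction[, k])
    )
  })
  dplyr::filter(out, .data$mi > mi_threshold)
}

#' One-row model summary
#'
#' @param x A `group_model`.
#' @param ... Unused.
#' @export
glance.group_model <- function(x, ...) {
  tibble::tibble(
    n_groups = x$n_groups, n_genes = length(x$gene_ids),
    n_samples = length(x$sample_ids), total_tc = sum(x$tc),
    iterations_run = x$iterations_run, converged = x$converged,
    seed = x$seed
  )
}

#' Plot the total-correlation curve
#'
#' @param object A `tc_curve` tibble from [tc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_groups, y = .data$total_tc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of latent groups",
                  y = "total correlation explained (nats)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
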