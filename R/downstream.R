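# Downstream clinical predictors: multi-output perceptrons mapping the
# predicted gene-group score vector (the length-K latent representation of
# a patient) to clinical targets, trained with the identical ranking loss /
# validation / early-stop / queue protocol as the slide model, and
# evaluated by bootstrap AUROC.

# represent a bare feature vector as a single-node, zero-edge graph so the
# slide-model machinery (loss, optimizer, queue) is reused verbatim
features_as_graphs <- function(features) {
  features <- as.matrix(features)
  ids <- rownames(features) %||% sprintf("P%04d", seq_len(nrow(features)))
  out <- lapply(seq_len(nrow(features)), function(i) {
    structure(list(
      slide_id = ids[i],
      nodes = tibble::tibble(node = 1L, x = 0, y = 0, cx = 0, cy = 0),
      features = features[i, , drop = FALSE],
      edges = tibble::tibble(from = integer(), to = integer()),
      feature_dim = ncol(features),
      edge_distance_max = Inf
    ), class = "wsi_graph")
  })
  names(out) <- ids
  out
}

#' Train a downstream multi-output perceptron
#'
#' Maps per-patient gene-group scores (the latent representation from
#' [predict_ensemble()]) to one or more binary clinical targets with a
#' one-hidden-layer multi-output perceptron, trained with the same pairwise
#' ranking loss and the same training / validation / early-stopping /
#' checkpoint-queue protocol as the slide model. Targets with a single
#' observed class are excluded with a warning. Inputs are continuous
#' scores by default; set `binarize` to threshold them at 0 first.
#'
#' @param features Patients x K numeric matrix, or a tibble with patient
#'   ids in the first column (e.g. the output of [predict_ensemble()]).
#' @param targets Patients x T binary matrix or tibble (ids first column);
#'   NA allowed.
#' @param tc A [train_config()].
#' @param hidden_width Perceptron hidden width (default 16).
#' @param binarize Threshold features at 0 before training (default FALSE).
#' @return A `downstream_fit`: the underlying `slidegraph_fit` plus target
#'   names.
#' @export
train_downstream <- function(features, targets, tc = train_config(),
                             hidden_width = 16L, binarize = FALSE) {
  if (is.data.frame(features)) {
    fm <- as.matrix(features[, -1, drop = FALSE])
    rownames(fm) <- as.character(features[[1]])
  } else fm <- as.matrix(features)
  if (is.data.frame(targets)) {
    tm <- as.matrix(targets[, -1, drop = FALSE])
    rownames(tm) <- as.character(targets[[1]])
    if (!is.null(rownames(fm)) && all(rownames(fm) %in% rownames(tm))) {
      tm <- tm[rownames(fm), , drop = FALSE]
    }
  } else tm <- as.matrix(targets)
  stopifnot(nrow(fm) == nrow(tm))
  if (binarize) fm <- (fm > 0) * 1
  single_class <- vapply(seq_len(ncol(tm)), function(k) {
    y <- tm[, k]
    length(unique(y[!is.na(y)])) < 2
  }, logical(1))
  if (any(single_class)) {
    warning(sprintf("excluding %d single-class target(s): %s",
                    sum(single_class),
                    paste(colnames(tm)[single_class], collapse = ", ")),
            call. = FALSE)
    tm <- tm[, !single_class, drop = FALSE]
    if (ncol(tm) == 0) stop("no trainable target remains", call. = FALSE)
  }
  graphs <- features_as_graphs(fm)
  cfg <- model_config(n_layers = 0L, n_outputs = ncol(tm),
                      head_hidden_width = hidden_width, seed = tc$seed)
  fit <- train_slidegraph(graphs, tm, config = cfg, tc = tc)
  structure(list(fit = fit, targets = colnames(tm)),
            class = "downstream_fit")
}

#' Predict downstream targets for new patients
#'
#' @param object A `downstream_fit`.
#' @param features Patients x K matrix or tibble (ids first column).
#' @param ... Unused.
#' @return Tibble patient id + one score column per target.
#' @export
predict.downstream_fit <- function(object, features, ...) {
  if (is.data.frame(features)) {
    fm <- as.matrix(features[, -1, drop = FALSE])
    rownames(fm) <- as.character(features[[1]])
  } else fm <- as.matrix(features)
  p <- predict_ensemble(object$fit, features_as_graphs(fm))
  names(p) <- c("patient_id", object$targets %||%
                  names(p)[-1])
  attr(p, "node_scores") <- NULL
  p
}

#' Cross-validated downstream evaluation
#'
#' 5-fold cross-validation of [train_downstream()] with out-of-fold
#' per-target AUROC.
#'
#' @inheritParams train_downstream
#' @return List `predictions`, `auroc`, `fits` as in
#'   [cross_validate_slidegraph()].
#' @export
cross_validate_downstream <- function(features, targets, tc = train_config(),
                                      hidden_width = 16L, binarize = FALSE) {
  if (is.data.frame(features)) {
    fm <- as.matrix(features[, -1, drop = FALSE])
    rownames(fm) <- as.character(features[[1]])
  } else fm <- as.matrix(features)
  if (is.data.frame(targets)) {
    tm <- as.matrix(targets[, -1, drop = FALSE])
    rownames(tm) <- as.character(targets[[1]])
  } else tm <- as.matrix(targets)
  if (binarize) fm <- (fm > 0) * 1
  cfg <- model_config(n_layers = 0L, n_outputs = ncol(tm),
                      head_hidden_width = hidden_width, seed = tc$seed)
  cross_validate_slidegraph(features_as_graphs(fm), tm, config = cfg, tc = tc)
}

#' Bootstrap AUROC distribution
#'
#' Draws `n_resamples` seeded resamples of `ceil(fraction * m)` patients
#' with replacement and computes the AUROC on each; resamples with a single
#' observed class are skipped and counted.
#'
#' @param scores Numeric vector (one target) or matrix (targets in
#'   columns).
#' @param labels Binary vector/matrix matching `scores`; NA allowed.
#' @param fraction Resample fraction (default 0.67).
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_result`: `draws` tibble (`target`, `resample`,
#'   `auroc`), `summary` tibble (`target`, `median`, `q025`, `q975`,
#'   `n_valid`, `n_skipped`).
#' @export
bootstrap_auroc <- function(scores, labels, fraction = 0.67,
                            n_resamples = 1000L, seed = 0L) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)), fraction > 0, fraction <= 1)
  m <- nrow(scores)
  tnames <- colnames(scores) %||% sprintf("target%02d", seq_len(ncol(scores)))
  size <- ceiling(fraction * m)
  withr::local_seed(as.integer(seed))
  idx <- matrix(sample.int(m, size * n_resamples, replace = TRUE),
                size, n_resamples)
  draws <- vector("list", ncol(scores))
  summaries <- vector("list", ncol(scores))
  for (k in seq_len(ncol(scores))) {
    a <- vapply(seq_len(n_resamples), function(r) {
      auroc(scores[idx[, r], k], labels[idx[, r], k])
    }, numeric(1))
    ok <- !is.na(a)
    draws[[k]] <- tibble::tibble(target = tnames[k],
                                 resample = which(ok), auroc = a[ok])
    summaries[[k]] <- tibble::tibble(
      target = tnames[k],
      median = stats::median(a[ok]),
      q025 = stats::quantile(a[ok], 0.025, names = FALSE),
      q975 = stats::quantile(a[ok], 0.975, names = FALSE),
      n_valid = sum(ok), n_skipped = sum(!ok)
    )
  }
  structure(list(
    draws = dplyr::bind_rows(draws),
    summary = dplyr::bind_rows(summaries),
    fraction = fraction, n_resamples = as.integer(n_resamples),
    seed = as.integer(seed)
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d resamples at %.0f%%\n",
              x$n_resamples, 100 * x$fraction))
  print(x$summary)
  invisible(x)
}

#' Tidy bootstrap draws
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) x$draws

#' Bootstrap summary, one row per target
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
glance.bootstrap_result <- function(x, ...) x$summary

#' Plot the bootstrap AUROC distributions
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$target, y = .data$auroc)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "bootstrap AUROC") +
    ggplot2::theme_minimal()
}
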