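# Multi-output EdgeConv graph network over WSI patch graphs.
#
# Layer update: h_m^l = sum over neighbours k of H^l([h_m^{l-1} ||
# h_k^{l-1} - h_m^{l-1}]), with H^l a single-hidden-layer perceptron.
# Per-layer heads f_l map each layer's embedding (including the raw
# features at l = 0) to K scores; the node score is the sum over layers and
# the slide score is the sum over nodes. Training minimizes a pairwise
# hinge ranking loss with Adam, early stopping, and a bounded queue of
# best-validation checkpoints that is ensembled at inference.

#' Model architecture configuration
#'
#' @param n_layers Number of EdgeConv layers L (default 3; 0 gives a plain
#'   perceptron on the raw node features).
#' @param n_outputs Number of outputs K (one score per gene group); `NULL`
#'   infers it from the training labels.
#' @param layer_hidden_width Hidden width of each EdgeConv perceptron and
#'   width of the per-layer embeddings (default 16).
#' @param head_hidden_width Hidden width of each prediction head (default
#'   64). Early in training the learnable score direction lives in the
#'   span of the head's hidden layer, so a width at least the feature
#'   dimension avoids capping the attainable signal alignment.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param seed Integer seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_layers = 3L, n_outputs = NULL,
                         layer_hidden_width = 16L, head_hidden_width = 64L,
                         activation = "relu", seed = 0L) {
  stopifnot(n_layers >= 0, layer_hidden_width >= 1, head_hidden_width >= 1)
  structure(list(
    n_layers = as.integer(n_layers),
    n_outputs = if (is.null(n_outputs)) NULL else as.integer(n_outputs),
    layer_hidden_width = as.integer(layer_hidden_width),
    head_hidden_width = as.integer(head_hidden_width),
    activation = activation, seed = as.integer(seed)
  ), class = "model_config")
}

#' Training protocol configuration
#'
#' Defaults follow the training protocol: 300 epochs, minibatches of 8,
#' Adam with learning rate 1e-3 and weight decay 1e-4, early stop after 20
#' epochs without validation improvement, a queue of the 10 most recent
#' validation-improving checkpoints, 5 cross-validation folds with 10% of
#' each training split held out for validation.
#'
#' @param epochs,batch_size,learning_rate,weight_decay Optimizer protocol.
#' @param patience_epochs Early-stopping patience (consecutive epochs).
#' @param model_queue_size Checkpoint queue capacity (FIFO eviction).
#' @param n_folds Cross-validation folds.
#' @param val_fraction_of_train Fraction of each training split held out
#'   for validation/parameter tuning.
#' @param seed Integer seed for splits, shuffling and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 8L,
                         learning_rate = 1e-3, weight_decay = 1e-4,
                         patience_epochs = 20L, model_queue_size = 10L,
                         n_folds = 5L, val_fraction_of_train = 0.10,
                         seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0, patience_epochs >= 1, model_queue_size >= 1,
            n_folds >= 2, val_fraction_of_train > 0,
            val_fraction_of_train < 1)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, weight_decay = weight_decay,
    patience_epochs = as.integer(patience_epochs),
    model_queue_size = as.integer(model_queue_size),
    n_folds = as.integer(n_folds),
    val_fraction_of_train = val_fraction_of_train,
    seed = as.integer(seed)
  ), class = "train_config")
}

# initialize parameters for input dimension D and K outputs
init_slidegraph <- function(config, input_dim, n_outputs) {
  withr::local_seed(config$seed)
  L <- config$n_layers
  w <- config$layer_hidden_width
  dims <- c(input_dim, rep(w, L)) # embedding dim per layer 0..L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- mlp_init(2L * dims[l], w, dims[l + 1L])
    # variance-preserving under SUM aggregation: a planar (Delaunay) graph
    # has average degree < 6, so damp the message output by 1/6 at init to
    # keep embedding magnitudes O(1) across layers (otherwise downstream
    # tanh units saturate and the deep heads start out as sign noise)
    layers[[l]]$W2 <- layers[[l]]$W2 / 6
  }
  heads <- vector("list", L + 1L)
  for (l in 0:L) {
    heads[[l + 1L]] <- mlp_init(dims[l + 1L], config$head_hidden_width,
                                n_outputs, zero_out = TRUE)
  }
  structure(list(config = config, input_dim = as.integer(input_dim),
                 n_outputs = as.integer(n_outputs),
                 layers = layers, heads = heads),
            class = "slidegraph_model")
}

# per-graph arrays used by the batched forward/backward pass: features plus
# directed edges in both orientations (dst = centre node m, src = neighbour)
graph_arrays <- function(graph) {
  e <- graph$edges
  list(X = graph$features,
       src = c(e$to, e$from), dst = c(e$from, e$to),
       n = nrow(graph$features))
}

# compiled-engine wrappers. The C++ step mirrors sg_forward/sg_backward
# exactly (cross-checked in tests); training and batch inference use it,
# the exported single-graph operations keep the R reference path.
act_code <- function(name) match(name, c("relu", "tanh")) - 1L

engine_forward <- function(model, ba) {
  gid <- ba$gid %||% rep(1L, ba$n)
  .cpp_sg_forward(ba$X, as.integer(ba$src), as.integer(ba$dst),
                  as.integer(gid), max(gid), model$layers, model$heads,
                  act_code(model$config$activation),
                  model$config$layer_hidden_width)
}

engine_step <- function(model, ba, labels) {
  gid <- ba$gid %||% rep(1L, ba$n)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  res <- .cpp_sg_step(ba$X, as.integer(ba$src), as.integer(ba$dst),
                      as.integer(gid), max(gid), model$layers, model$heads,
                      act_code(model$config$activation),
                      model$config$layer_hidden_width, labels)
  # normalize gradient leaf shapes (arma vectors come back as columns)
  res$grads$layers <- lapply(res$grads$layers, function(g) {
    g$b1 <- as.numeric(g$b1)
    g$b2 <- as.numeric(g$b2)
    g
  })
  res$grads$heads <- lapply(res$grads$heads, function(g) {
    g$b1 <- as.numeric(g$b1)
    g$b2 <- as.numeric(g$b2)
    g
  })
  res
}

concat_arrays <- function(arrs) {
  ns <- vapply(arrs, `[[`, integer(1), "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  list(
    X = do.call(rbind, lapply(arrs, `[[`, "X")),
    src = unlist(Map(function(a, o) a$src + o, arrs, off)),
    dst = unlist(Map(function(a, o) a$dst + o, arrs, off)),
    n = sum(ns),
    gid = rep(seq_along(arrs), ns)
  )
}

# full forward pass over a (batched) node array; returns embeddings, node
# scores, slide scores and the caches needed for backprop
sg_forward <- function(model, ba, want_cache = FALSE) {
  act <- activation_fns(model$config$activation)
  L <- model$config$n_layers
  H <- vector("list", L + 1L)
  H[[1]] <- ba$X
  layer_caches <- vector("list", L)
  has_edges <- length(ba$dst) > 0
  for (l in seq_len(L)) {
    if (has_edges) {
      fw <- edgeconv_layer_forward(model$layers[[l]], H[[l]], ba$src,
                                   ba$dst, ba$n, act)
      H[[l + 1L]] <- fw$H
      if (want_cache) layer_caches[[l]] <- fw[c("A", "R")]
    } else {
      H[[l + 1L]] <- matrix(0, ba$n, model$config$layer_hidden_width)
    }
  }
  S <- matrix(0, ba$n, model$n_outputs)
  head_caches <- vector("list", L + 1L)
  for (l in 0:L) {
    fw <- mlp_forward(model$heads[[l + 1L]], H[[l + 1L]], act)
    S <- S + fw$Y
    if (want_cache) head_caches[[l + 1L]] <- fw
  }
  slide <- if (!is.null(ba$gid)) scatter_sum(S, ba$gid, max(ba$gid))
           else matrix(colSums(S), 1)
  list(H = H, node_scores = S, slide_scores = slide,
       layer_caches = layer_caches, head_caches = head_caches)
}

# backward pass: gradient of the loss w.r.t. all parameters, given
# d(loss)/d(slide_scores)
sg_backward <- function(model, ba, fw, dSlide) {
  act <- activation_fns(model$config$activation)
  L <- model$config$n_layers
  gid <- if (!is.null(ba$gid)) ba$gid else rep(1L, ba$n)
  dS <- dSlide[gid, , drop = FALSE]
  dH <- vector("list", L + 1L)
  grads <- list(layers = vector("list", L), heads = vector("list", L + 1L))
  for (l in 0:L) {
    bw <- mlp_backward(model$heads[[l + 1L]], fw$head_caches[[l + 1L]], dS, act)
    grads$heads[[l + 1L]] <- bw$grads
    dH[[l + 1L]] <- bw$dX
  }
  has_edges <- length(ba$dst) > 0
  for (l in rev(seq_len(L))) {
    if (!has_edges) {
      grads$layers[[l]] <- lapply(model$layers[[l]], function(x) x * 0)
      next
    }
    bw <- edgeconv_layer_backward(model$layers[[l]], fw$layer_caches[[l]],
                                  fw$H[[l]], dH[[l + 1L]], ba$src, ba$dst,
                                  ba$n, act)
    grads$layers[[l]] <- bw$grads
    dH[[l]] <- dH[[l]] + bw$dHprev
  }
  grads
}

#' EdgeConv embeddings of every node, layer by layer
#'
#' Returns the list `h^0 .. h^L` of per-node embeddings. `h^0` is the input
#' feature matrix; `h^l` is the neighbour sum of the layer-l perceptron
#' applied to `[h_m || h_k - h_m]`. An isolated node has a zero embedding
#' at every layer `l >= 1` (empty neighbour sum).
#'
#' @param model A `slidegraph_model` (from [train_slidegraph()]'s queue or
#'   [init_slidegraph] via the training entry points).
#' @param graph A `wsi_graph` with `feature_dim == model$input_dim`.
#' @return List of L+1 matrices (n_nodes x embedding dim).
#' @export
edgeconv_forward <- function(model, graph) {
  check_dims(model, graph)
  ba <- graph_arrays(graph)
  isolated_aware_forward(model, ba)$H
}

# forward that zeroes embeddings of nodes with no incident edge (the empty
# sum), which scatter_sum already guarantees; kept as a named wrapper
isolated_aware_forward <- function(model, ba, want_cache = FALSE) {
  sg_forward(model, ba, want_cache = want_cache)
}

check_dims <- function(model, graph) {
  if (graph$feature_dim != model$input_dim) {
    stop(sprintf("graph feature dim %d does not match model input dim %d",
                 graph$feature_dim, model$input_dim), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-node K-dimensional scores
#'
#' The node score is the sum over layers 0..L of the layer head applied to
#' that layer's embedding.
#'
#' @inheritParams edgeconv_forward
#' @return n_nodes x K matrix.
#' @export
node_score <- function(model, graph) {
  check_dims(model, graph)
  sg_forward(model, graph_arrays(graph))$node_scores
}

#' Slide-level K-dimensional score
#'
#' The slide score is the sum of the node scores over all nodes of the
#' graph.
#'
#' @inheritParams edgeconv_forward
#' @return Numeric vector of length K.
#' @export
slide_score <- function(model, graph) {
  check_dims(model, graph)
  if (nrow(graph$features) == 0) stop("empty graph", call. = FALSE)
  as.vector(sg_forward(model, graph_arrays(graph))$slide_scores)
}

#' Pairwise hinge ranking loss
#'
#' For each output k, every ordered pair (a, b) with observed labels
#' `y_a = 1`, `y_b = 0` contributes `max(0, 1 - (s_a - s_b))`; the loss is
#' the sum over outputs and pairs. Pairs involving a missing label are
#' skipped; an output with no valid pair contributes 0.
#'
#' @param scores N x K numeric matrix of slide scores.
#' @param labels N x K binary matrix (NA allowed).
#' @return The total hinge loss (a single number).
#' @export
ranking_loss <- function(scores, labels) {
  ranking_loss_grad(scores, labels)$loss
}

ranking_loss_grad <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  G <- matrix(0, nrow(scores), ncol(scores))
  loss <- 0
  n_pairs <- 0L
  for (k in seq_len(ncol(scores))) {
    y <- labels[, k]
    pos <- which(!is.na(y) & y == 1)
    neg <- which(!is.na(y) & y == 0)
    if (length(pos) == 0 || length(neg) == 0) next
    M <- outer(scores[pos, k], scores[neg, k], `-`) # margins
    act <- M < 1
    loss <- loss + sum(1 - M[act])
    n_pairs <- n_pairs + length(M)
    G[pos, k] <- G[pos, k] - rowSums(act)
    G[neg, k] <- G[neg, k] + colSums(act)
  }
  list(loss = loss, grad = G, n_pairs = n_pairs)
}

align_labels <- function(graphs, labels) {
  if (is.data.frame(labels)) {
    ids <- as.character(labels[[1]])
    lm <- as.matrix(labels[, -1, drop = FALSE])
    rownames(lm) <- ids
    gids <- names(graphs) %||% vapply(graphs, `[[`, character(1), "slide_id")
    if (!is.null(gids) && all(gids %in% ids)) {
      lm <- lm[gids, , drop = FALSE]
    }
    lm
  } else {
    as.matrix(labels)
  }
}

#' Train the multi-output EdgeConv slide model
#'
#' Minibatch Adam on the pairwise ranking loss with early stopping on a
#' held-out validation split and a bounded FIFO queue of checkpoints: a
#' snapshot enters the queue whenever the validation loss at epoch n is
#' below that at epoch n-1 (capacity `model_queue_size`, oldest evicted).
#' Training stops early when the best validation loss has not improved for
#' `patience_epochs` consecutive epochs.
#'
#' @param graphs List of `wsi_graph` (optionally named by slide id).
#' @param labels N x K binary matrix, or tibble with slide ids in the first
#'   column; NA marks a missing label (the slide is excluded from that
#'   output's ranking pairs only).
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param val_graphs,val_labels Optional explicit validation set; by default
#'   `val_fraction_of_train` of `graphs` is held out.
#' @return A `slidegraph_fit`: `queue` (checkpoints), `model` (final),
#'   `history` tibble, configs.
#' @export
train_slidegraph <- function(graphs, labels, config = model_config(),
                             tc = train_config(), val_graphs = NULL,
                             val_labels = NULL) {
  lm <- align_labels(graphs, labels)
  stopifnot(length(graphs) == nrow(lm))
  K <- config$n_outputs %||% ncol(lm)
  config$n_outputs <- K
  stopifnot(ncol(lm) == K)

  withr::local_seed(tc$seed)
  n <- length(graphs)
  if (is.null(val_graphs)) {
    n_val <- max(1L, round(tc$val_fraction_of_train * n))
    # the validation loss is a ranking loss: the held-out split must
    # contain at least one (positive, negative) pair for some output
    for (try in 1:100) {
      val_idx <- sample.int(n, n_val)
      vl <- lm[val_idx, , drop = FALSE]
      ok <- any(vapply(seq_len(K), function(k) {
        y <- vl[, k]
        any(!is.na(y) & y == 1) && any(!is.na(y) & y == 0)
      }, logical(1)))
      if (ok) break
    }
    val_graphs <- graphs[val_idx]
    val_labels <- lm[val_idx, , drop = FALSE]
    graphs <- graphs[-val_idx]
    lm <- lm[-val_idx, , drop = FALSE]
    n <- length(graphs)
  } else {
    val_labels <- align_labels(val_graphs, val_labels)
  }
  if (n < 1 || length(val_graphs) < 1) {
    stop("need at least one training and one validation graph", call. = FALSE)
  }
  # abort if no output has any valid ranking pair in the training set
  has_pair <- vapply(seq_len(K), function(k) {
    y <- lm[, k]
    any(!is.na(y) & y == 1) && any(!is.na(y) & y == 0)
  }, logical(1))
  if (!any(has_pair)) {
    stop("no output has both a positive and a negative training label; ",
         "ranking loss is undefined", call. = FALSE)
  }

  arrs <- lapply(graphs, graph_arrays)
  val_ba <- concat_arrays(lapply(val_graphs, graph_arrays))

  model <- init_slidegraph(config, input_dim = ncol(arrs[[1]]$X),
                           n_outputs = K)
  params <- list(layers = model$layers, heads = model$heads)
  state <- adam_init(params)

  queue <- list()
  history <- vector("list", tc$epochs)
  prev_val <- Inf
  best_val <- Inf
  stall <- 0L
  val_pairs <- max(ranking_loss_grad(matrix(0, nrow(val_labels), K),
                                     val_labels)$n_pairs, 1L)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / tc$batch_size)
    tr_loss <- 0
    tr_pairs <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * tc$batch_size + 1L):min(b * tc$batch_size, n)]
      ba <- concat_arrays(arrs[idx])
      model$layers <- params$layers
      model$heads <- params$heads
      rl <- engine_step(model, ba, lm[idx, , drop = FALSE])
      tr_loss <- tr_loss + rl$loss
      tr_pairs <- tr_pairs + rl$n_pairs
      if (rl$n_pairs == 0L) next
      upd <- adam_step(params, rl$grads, state, lr = tc$learning_rate,
                       weight_decay = tc$weight_decay)
      params <- upd$params
      state <- upd$state
    }
    model$layers <- params$layers
    model$heads <- params$heads
    vfw <- engine_forward(model, val_ba)
    vl <- ranking_loss_grad(vfw$slide_scores, val_labels)
    val_loss <- vl$loss / max(vl$n_pairs, 1L)
    entered <- FALSE
    if (val_loss < prev_val) {
      queue[[length(queue) + 1L]] <- list(layers = params$layers,
                                          heads = params$heads)
      if (length(queue) > tc$model_queue_size) queue <- queue[-1L]
      entered <- TRUE
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = tr_loss / max(tr_pairs, 1L),
      val_loss = val_loss, entered_queue = entered
    )
    prev_val <- val_loss
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience_epochs) break
    }
  }
  structure(list(
    queue = lapply(queue, function(p) {
      m <- model
      m$layers <- p$layers
      m$heads <- p$heads
      m
    }),
    model = model,
    history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
    config = config, train_config = tc
  ), class = "slidegraph_fit")
}

#' @export
print.slidegraph_fit <- function(x, ...) {
  cat(sprintf(
    "<slidegraph_fit> L=%d, K=%d | %d epochs run | queue of %d checkpoints\n",
    x$config$n_layers, x$model$n_outputs, nrow(x$history), length(x$queue)))
  invisible(x)
}

#' Ensemble prediction over the checkpoint queue
#'
#' Slide and node scores are the arithmetic mean over all queued
#' checkpoints. An element of `graphs` may itself be a list of graphs (a
#' multi-slide patient "bag"); the patient score is then the mean of the
#' per-slide ensemble scores.
#'
#' @param fit A `slidegraph_fit` (or a bare list of `slidegraph_model`s).
#' @param graphs List of `wsi_graph`, or list of lists for patient bags.
#' @return Tibble `slide_id` + K score columns; attribute `node_scores`
#'   holds the per-slide ensemble node-score matrices (flat graph input
#'   only).
#' @export
predict_ensemble <- function(fit, graphs) {
  models <- if (inherits(fit, "slidegraph_fit")) fit$queue else fit
  stopifnot(length(models) >= 1)
  is_bag <- vapply(graphs, function(g) !inherits(g, "wsi_graph"), logical(1))
  score_one <- function(graph) {
    ba <- graph_arrays(graph)
    ss <- NULL
    ns <- NULL
    for (mod in models) {
      check_dims(mod, graph)
      fw <- engine_forward(mod, ba)
      ss <- if (is.null(ss)) fw$slide_scores else ss + fw$slide_scores
      ns <- if (is.null(ns)) fw$node_scores else ns + fw$node_scores
    }
    list(slide = as.vector(ss) / length(models), node = ns / length(models))
  }
  K <- models[[1]]$n_outputs
  out <- matrix(0, length(graphs), K)
  node_scores <- vector("list", length(graphs))
  ids <- character(length(graphs))
  for (i in seq_along(graphs)) {
    if (is_bag[i]) {
      bag <- graphs[[i]]
      per <- lapply(bag, function(g) score_one(g)$slide)
      out[i, ] <- Reduce(`+`, per) / length(per)
      ids[i] <- names(graphs)[i] %||% bag[[1]]$slide_id
    } else {
      sc <- score_one(graphs[[i]])
      out[i, ] <- sc$slide
      node_scores[[i]] <- sc$node
      ids[i] <- graphs[[i]]$slide_id
    }
  }
  colnames(out) <- sprintf("g%03d", seq_len(K))
  res <- dplyr::bind_cols(tibble::tibble(slide_id = ids),
                          tibble::as_tibble(out))
  attr(res, "node_scores") <- stats::setNames(node_scores, ids)
  res
}

#' Cross-validated training and per-output AUROC
#'
#' Splits the slides into `tc$n_folds` non-overlapping 80/20 train/test
#' folds, holds out `val_fraction_of_train` of each training split for
#' validation, trains a model per fold, ensembles its checkpoint queue on
#' the test fold, and reports AUROC per output on the concatenated
#' out-of-fold predictions. An output with a single observed class gets
#' `NA`.
#'
#' @inheritParams train_slidegraph
#' @return List: `predictions` (out-of-fold slide-score tibble with fold
#'   ids), `auroc` tibble (`group`, `auroc`), `fits` (per-fold
#'   `slidegraph_fit`s).
#' @export
cross_validate_slidegraph <- function(graphs, labels, config = model_config(),
                                      tc = train_config()) {
  lm <- align_labels(graphs, labels)
  n <- length(graphs)
  stopifnot(n >= tc$n_folds)
  withr::local_seed(tc$seed + 1L)
  fold_of <- sample(rep_len(seq_len(tc$n_folds), n))
  preds <- vector("list", tc$n_folds)
  fits <- vector("list", tc$n_folds)
  for (f in seq_len(tc$n_folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    fit <- train_slidegraph(graphs[tr], lm[tr, , drop = FALSE],
                            config = config, tc = tc)
    p <- predict_ensemble(fit, graphs[te])
    p$fold <- f
    p$.row <- te
    preds[[f]] <- p
    fits[[f]] <- fit
  }
  pred <- dplyr::bind_rows(preds)
  K <- ncol(lm)
  scores <- as.matrix(pred[, sprintf("g%03d", seq_len(K))])
  truth <- lm[pred$.row, , drop = FALSE]
  aucs <- vapply(seq_len(K), function(k) auroc(scores[, k], truth[, k]),
                 numeric(1))
  list(
    predictions = pred,
    auroc = tibble::tibble(group = colnames(lm) %||% sprintf("g%03d", seq_len(K)),
                           auroc = aucs),
    fits = fits,
    folds = fold_of
  )
}

#' Tidy the training history of a fit
#'
#' @param x A `slidegraph_fit`.
#' @param ... Unused.
#' @return The epoch-by-epoch history tibble.
#' @export
tidy.slidegraph_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x A `slidegraph_fit`.
#' @param ... Unused.
#' @export
glance.slidegraph_fit <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers, n_outputs = x$model$n_outputs,
    epochs_run = nrow(x$history), queue_size = length(x$queue),
    best_val_loss = min(x$history$val_loss),
    final_train_loss = x$history$train_loss[nrow(x$history)]
  )
}
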