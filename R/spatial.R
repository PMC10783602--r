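# Spatially resolved interpretation of node-level predictions: heatmaps,
# exemplar-patient selection, percentile patch harvesting, k-medoid motif
# mining, and the sub-patch aggregation geometry for pluggable patch
# annotators.

#' Export a node-score heatmap
#'
#' Paints each node's score over its patch footprint with a diverging
#' colormap centred at 0 (blue = status-0 evidence, red = status-1
#' evidence). Rendering is flat per-patch (no interpolation) so the
#' exported values are exact.
#'
#' @param prediction Node-score matrix (n_nodes x K) or a prediction tibble
#'   from [predict_ensemble()] whose `node_scores` attribute covers the
#'   slide.
#' @param graph The `wsi_graph` the scores belong to.
#' @param factor_ids Integer indices (1-based) of the outputs to export.
#' @param patch_size Patch footprint in working pixels (default 512).
#' @param png_path Optional path: writes a raster overlay PNG (one file per
#'   factor, suffixed `_g<k>.png` when several are requested).
#' @param geojson_path Optional path: writes patch-footprint polygons with
#'   score properties (GeoJSON-style).
#' @return A `heatmap` tibble: `slide_id`, `cx`, `cy`, `patch_size`, one
#'   `score_g<k>` column per requested factor.
#' @export
export_heatmap <- function(prediction, graph, factor_ids = 1L,
                           patch_size = 512, png_path = NULL,
                           geojson_path = NULL) {
  ns <- if (is.matrix(prediction)) prediction
        else attr(prediction, "node_scores")[[graph$slide_id]]
  if (is.null(ns)) stop("no node scores available for this slide", call. = FALSE)
  if (nrow(ns) != nrow(graph$nodes)) {
    stop("prediction and graph node counts differ", call. = FALSE)
  }
  if (any(factor_ids < 1 | factor_ids > ncol(ns))) {
    stop("unknown factor id", call. = FALSE)
  }
  out <- tibble::tibble(
    slide_id = graph$slide_id,
    cx = graph$nodes$cx, cy = graph$nodes$cy,
    patch_size = patch_size
  )
  for (k in factor_ids) out[[sprintf("score_g%03d", k)]] <- ns[, k]
  class(out) <- c("heatmap", class(out))
  if (!is.null(png_path)) {
    for (k in factor_ids) {
      path <- if (length(factor_ids) == 1) png_path
              else sub("\\.png$", sprintf("_g%03d.png", k), png_path)
      write_heatmap_png(out, sprintf("score_g%03d", k), path)
    }
  }
  if (!is.null(geojson_path)) write_heatmap_geojson(out, geojson_path)
  out
}

# diverging blue-white-red map centred at zero
diverging_colour <- function(v) {
  vmax <- max(abs(v), 1e-12)
  t <- v / vmax # [-1, 1]
  r <- ifelse(t >= 0, 1, 1 + t)
  g <- 1 - abs(t)
  b <- ifelse(t <= 0, 1, 1 - t)
  cbind(r, g, b)
}

write_heatmap_png <- function(hm, column, path, cell_px = 8L) {
  cx <- hm$cx
  cy <- hm$cy
  ps <- hm$patch_size[1]
  ci <- as.integer(round((cx - min(cx)) / ps)) + 1L
  ri <- as.integer(round((cy - min(cy)) / ps)) + 1L
  img <- array(1, dim = c(max(ri) * cell_px, max(ci) * cell_px, 3))
  cols <- diverging_colour(hm[[column]])
  for (i in seq_along(ci)) {
    ys <- ((ri[i] - 1L) * cell_px + 1L):(ri[i] * cell_px)
    xs <- ((ci[i] - 1L) * cell_px + 1L):(ci[i] * cell_px)
    for (ch in 1:3) img[ys, xs, ch] <- cols[i, ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

write_heatmap_geojson <- function(hm, path) {
  half <- hm$patch_size / 2
  feats <- purrr::pmap(list(hm$cx, hm$cy, half, seq_len(nrow(hm))),
    function(cx, cy, h, i) {
      ring <- list(c(cx - h, cy - h), c(cx + h, cy - h),
                   c(cx + h, cy + h), c(cx - h, cy + h), c(cx - h, cy - h))
      props <- as.list(hm[i, grep("^score_", names(hm)), drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a heatmap tibble
#'
#' @param object A `heatmap` from [export_heatmap()].
#' @param factor_id Which exported score column to show (default the first).
#' @param ... Unused.
#' @export
autoplot.heatmap <- function(object, factor_id = NULL, ...) {
  cols <- grep("^score_", names(object), value = TRUE)
  col <- if (is.null(factor_id)) cols[1] else sprintf("score_g%03d", factor_id)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cx, y = .data$cy,
                                       fill = .data[[col]])) +
    ggplot2::geom_tile(width = object$patch_size, height = object$patch_size) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = col) +
    ggplot2::theme_minimal()
}

#' Select exemplar patients per status for a group
#'
#' Among patients whose predicted score classifies them correctly at the
#' Youden-optimal threshold (computed on the provided scores and labels),
#' takes the `n_per_status` with the largest label-concordant signed margin
#' for each status.
#'
#' @param predictions Tibble from [predict_ensemble()] (slide_id + score
#'   columns) or a named score vector for the group.
#' @param labels Tibble slide_id + per-group binary columns, or a vector
#'   aligned with `predictions`.
#' @param group_id Group index (1-based).
#' @param n_per_status Maximum patients per status (default 50).
#' @return List with tibbles `status1` and `status0` (`slide_id`, `score`,
#'   `margin`), ordered by decreasing margin, plus the `threshold` used.
#' @export
select_exemplar_patients <- function(predictions, labels, group_id,
                                     n_per_status = 50L) {
  if (is.data.frame(predictions)) {
    ids <- as.character(predictions[[1]])
    scores <- predictions[[sprintf("g%03d", group_id)]]
  } else {
    ids <- names(predictions) %||% as.character(seq_along(predictions))
    scores <- as.numeric(predictions)
  }
  if (is.data.frame(labels)) {
    lid <- as.character(labels[[1]])
    y <- as.numeric(as.matrix(labels[, -1, drop = FALSE])[, group_id])
    y <- y[match(ids, lid)]
  } else {
    y <- as.numeric(labels)
  }
  keep <- !is.na(y)
  ids <- ids[keep]
  scores <- scores[keep]
  y <- y[keep]
  thr <- youden_threshold(scores, y)
  pred1 <- scores > thr
  correct <- (pred1 & y == 1) | (!pred1 & y == 0)
  margin <- ifelse(y == 1, scores - thr, thr - scores)
  pick <- function(status) {
    sel <- which(correct & y == status)
    sel <- sel[order(-margin[sel], sel)]
    sel <- utils::head(sel, n_per_status)
    tibble::tibble(slide_id = ids[sel], score = scores[sel],
                   margin = margin[sel])
  }
  list(status1 = pick(1), status0 = pick(0), threshold = thr)
}

# threshold maximizing sensitivity + specificity - 1 over candidate
# midpoints between consecutive sorted scores
youden_threshold <- function(scores, y) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(s - 0.5)
  cand <- (s[-1] + s[-length(s)]) / 2
  j <- vapply(cand, function(t) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Harvest top- or bottom-percentile patches of a slide
#'
#' For status 1, the highest-scoring `ceil(fraction * n_nodes)` nodes (at
#' least 1); for status 0, the lowest-scoring. Ties break deterministically
#' by node index.
#'
#' @param node_scores Numeric vector of node scores for one output (or an
#'   n x K matrix with `factor_id`).
#' @param graph The `wsi_graph`.
#' @param status 1 (top) or 0 (bottom).
#' @param fraction Fraction of nodes to take (default 0.01).
#' @param factor_id Column when `node_scores` is a matrix.
#' @return Tibble `slide_id`, `node`, `x`, `y`, `cx`, `cy`, `score`,
#'   ordered by extremity.
#' @export
harvest_patches <- function(node_scores, graph, status = 1L,
                            fraction = 0.01, factor_id = 1L) {
  if (is.matrix(node_scores)) node_scores <- node_scores[, factor_id]
  stopifnot(fraction > 0, fraction <= 1,
            length(node_scores) == nrow(graph$nodes))
  n_take <- max(1L, ceiling(fraction * length(node_scores)))
  ord <- if (status == 1L) order(-node_scores, seq_along(node_scores))
         else order(node_scores, seq_along(node_scores))
  sel <- ord[seq_len(n_take)]
  tibble::tibble(
    slide_id = graph$slide_id, node = sel,
    x = graph$nodes$x[sel], y = graph$nodes$y[sel],
    cx = graph$nodes$cx[sel], cy = graph$nodes$cy[sel],
    score = node_scores[sel]
  )
}

#' Mine histological motifs by k-medoid clustering
#'
#' Partitioning-around-medoids (PAM, build + swap) clustering of harvested
#' patches in feature space with Euclidean distance. Medoids are actual
#' members of the input set. PAM is deterministic; `seed` is accepted for
#' interface stability.
#'
#' @param patches Tibble of harvested patches (one row per patch).
#' @param features Numeric matrix, one row per patch.
#' @param k Number of medoids (default 25); capped at the number of patches.
#' @param seed Unused by PAM (deterministic); kept for interface stability.
#' @param group_id,status Metadata recorded in the result.
#' @return A `motif_set`: `medoids` tibble (the k medoid patch rows with a
#'   `motif` index and `cluster_size`), `assignment` (cluster per input
#'   patch), `k`.
#' @export
mine_motifs <- function(patches, features, k = 25L, seed = 0L,
                        group_id = NA_integer_, status = NA_integer_) {
  features <- as.matrix(features)
  stopifnot(nrow(patches) == nrow(features), nrow(features) >= 1)
  k <- min(as.integer(k), nrow(features))
  if (k == nrow(features)) {
    assignment <- seq_len(nrow(features))
    med_idx <- seq_len(nrow(features))
  } else {
    fit <- cluster::pam(features, k = k, metric = "euclidean",
                        pamonce = 5, keep.diss = FALSE, keep.data = FALSE)
    assignment <- as.integer(fit$clustering)
    med_idx <- as.integer(fit$id.med)
  }
  med <- patches[med_idx, , drop = FALSE]
  med$motif <- seq_len(k)
  med$cluster_size <- as.integer(table(factor(assignment, levels = seq_len(k))))
  structure(list(
    group_id = group_id, status = status, k = k,
    medoids = tibble::as_tibble(med),
    medoid_index = med_idx,
    assignment = assignment
  ), class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d medoids over %d patches (group %s, status %s)\n",
              x$k, length(x$assignment), x$group_id, x$status))
  invisible(x)
}

#' Enumerate the child tiles covering a parent patch
#'
#' Decomposes a parent patch into the lattice of child tiles (at a finer or
#' equal resolution) that exactly cover the parent's physical footprint.
#' The count is `(parent_size * parent_mpp / (child_size * child_mpp))^2`;
#' the default geometry (512 px at 0.50 MPP into 256 px at 0.25 MPP) gives
#' a 4 x 4 grid of 16 tiles.
#'
#' @param parent_origin `(x, y)` of the parent's top-left, in parent-scale
#'   pixels.
#' @param parent_size_px,parent_mpp Parent patch geometry.
#' @param child_size_px,child_mpp Child tile geometry; the parent footprint
#'   must be an integer multiple of the child footprint.
#' @return Tibble of child origins `x`, `y` in child-scale pixels, row-major.
#' @export
subpatch_grid <- function(parent_origin = c(0, 0), parent_size_px = 512L,
                          parent_mpp = 0.50, child_size_px = 256L,
                          child_mpp = 0.25) {
  stopifnot(child_mpp <= parent_mpp)
  ratio <- (parent_size_px * parent_mpp) / (child_size_px * child_mpp)
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf(
      "parent footprint (%d px @ %.3g MPP) is not an integer multiple of the child footprint (%d px @ %.3g MPP): ratio %.6g",
      parent_size_px, parent_mpp, child_size_px, child_mpp, ratio),
      call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  origin_child <- parent_origin * (parent_mpp / child_mpp)
  grid <- expand.grid(col = seq_len(ratio) - 1L, row = seq_len(ratio) - 1L)
  tibble::tibble(
    x = origin_child[1] + grid$col * child_size_px,
    y = origin_child[2] + grid$row * child_size_px
  )
}

#' Synthetic stub patch annotator
#'
#' A deterministic annotator satisfying the patch-annotator contract
#' (counts of neoplastic, inflammatory, connective and epithelial cells,
#' plus a mitotic count) for testing the aggregation geometry without a
#' trained cellular-composition model. Counts are a deterministic function
#' of the child-tile origin.
#'
#' @param constant Optional named integer vector: return these counts for
#'   every tile instead of the coordinate hash.
#' @return A `patch_annotator` (list with `name` and
#'   `fn(x, y) -> named counts`).
#' @export
stub_annotator <- function(constant = NULL) {
  fields <- c("neoplastic", "inflammatory", "connective", "epithelial",
              "mitoses")
  fn <- if (!is.null(constant)) {
    stopifnot(all(fields %in% names(constant)))
    function(x, y) constant[fields]
  } else {
    function(x, y) {
      h <- abs(as.integer((x * 31 + y * 17) %% 7))
      c(neoplastic = h, inflammatory = (h + 1) %% 5, connective = (h + 2) %% 3,
        epithelial = (h + 3) %% 4, mitoses = h %% 2)
    }
  }
  structure(list(name = if (is.null(constant)) "stub-hash" else "stub-constant",
                 fn = fn), class = "patch_annotator")
}

#' Annotate parent patches via sub-tile aggregation
#'
#' Applies a patch annotator to every child tile of each parent patch (per
#' [subpatch_grid()]) and sums the counts; cellularity is the sum of the
#' four cell-type counts. Aggregation is exactly additive.
#'
#' @param patches Tibble with parent origins `x`, `y` (parent-scale px).
#' @param annotator A `patch_annotator` contract object.
#' @param parent_size_px,parent_mpp,child_size_px,child_mpp Geometry passed
#'   to [subpatch_grid()].
#' @return `patches` with columns `neoplastic`, `inflammatory`,
#'   `connective`, `epithelial`, `cellularity`, `mitoses` appended.
#' @export
annotate_patches <- function(patches, annotator = stub_annotator(),
                             parent_size_px = 512L, parent_mpp = 0.50,
                             child_size_px = 256L, child_mpp = 0.25) {
  fields <- c("neoplastic", "inflammatory", "connective", "epithelial",
              "mitoses")
  agg <- purrr::map(seq_len(nrow(patches)), function(i) {
    kids <- subpatch_grid(c(patches$x[i], patches$y[i]), parent_size_px,
                          parent_mpp, child_size_px, child_mpp)
    counts <- purrr::map(seq_len(nrow(kids)), function(j) {
      v <- annotator$fn(kids$x[j], kids$y[j])
      if (any(v < 0)) {
        stop("annotator contract violation: negative counts", call. = FALSE)
      }
      v[fields]
    })
    Reduce(`+`, counts)
  })
  am <- do.call(rbind, agg)
  out <- patches
  for (f in fields) out[[f]] <- as.numeric(am[, f])
  out$cellularity <- out$neoplastic + out$inflammatory + out$connective +
    out$epithelial
  out
}
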