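# WSI graph representation: nodes are patches (centroid + feature vector),
# edges come from a Delaunay triangulation of the centroids pruned at a
# maximum Euclidean length.

#' Build a patch graph from centroids and features
#'
#' Edges are the Delaunay triangulation of the patch centroids with edges
#' longer than `edge_distance_max` pixels removed (the bound is inclusive:
#' an edge exactly at the limit is kept). With fewer than three patches, or
#' a collinear centroid set, the triangulation is undefined and all pairs
#' within the distance bound are connected instead. Node order follows
#' patch order; centroids are min-subtracted before triangulating, so the
#' adjacency is exactly translation invariant.
#'
#' @param patches Data frame with centroid columns `cx`, `cy` (and
#'   optionally `slide_id`, origins `x`, `y`), e.g. from [tile_slide()] /
#'   [filter_patches()], or any per-node coordinate table.
#' @param features Numeric matrix, one row per patch (fixed dimension D).
#' @param edge_distance_max Maximum edge length in working pixels
#'   (default 4000).
#' @param edges Optional precomputed edge tibble (`from`, `to`) for these
#'   centroids; skips triangulation (used when many slides share a lattice).
#' @return A `wsi_graph`: list with `slide_id`, `nodes` tibble
#'   (`node`, `x`, `y`, `cx`, `cy`), `features` matrix, `edges` tibble
#'   (`from` < `to`), `feature_dim`.
#' @export
build_graph <- function(patches, features, edge_distance_max = 4000,
                        edges = NULL) {
  stopifnot(nrow(patches) >= 1, all(c("cx", "cy") %in% names(patches)))
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(patches))
  if (is.null(edges)) {
    edges <- delaunay_edge_table(patches$cx, patches$cy,
                                 edge_distance_max = edge_distance_max)
  }
  n <- nrow(patches)
  nodes <- tibble::tibble(
    node = seq_len(n),
    x = if ("x" %in% names(patches)) patches$x else patches$cx,
    y = if ("y" %in% names(patches)) patches$y else patches$cy,
    cx = patches$cx, cy = patches$cy
  )
  structure(list(
    slide_id = if ("slide_id" %in% names(patches)) patches$slide_id[1] else "slide",
    nodes = nodes,
    features = features,
    edges = edges,
    feature_dim = ncol(features),
    edge_distance_max = edge_distance_max
  ), class = "wsi_graph")
}

#' @export
print.wsi_graph <- function(x, ...) {
  cat(sprintf("<wsi_graph> '%s': %d nodes, %d edges, %d-d features\n",
              x$slide_id, nrow(x$nodes), nrow(x$edges), x$feature_dim))
  invisible(x)
}

#' Write a graph as node + edge TSV tables
#'
#' @param graph A `wsi_graph`.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` (slide_id,
#'   coordinates, feature columns) and `<prefix>_edges.tsv` (from, to).
#' @return `prefix`, invisibly.
#' @export
write_graph <- function(graph, prefix) {
  feat <- tibble::as_tibble(as.data.frame(graph$features))
  names(feat) <- sprintf("feat_%04d", seq_len(ncol(feat)))
  nodes <- dplyr::bind_cols(
    tibble::tibble(slide_id = graph$slide_id), graph$nodes, feat
  )
  readr::write_tsv(nodes, paste0(prefix, "_nodes.tsv"), progress = FALSE)
  readr::write_tsv(graph$edges, paste0(prefix, "_edges.tsv"), progress = FALSE)
  invisible(prefix)
}

#' Read a graph written by [write_graph()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `wsi_graph`.
#' @export
read_graph <- function(prefix) {
  nodes <- readr::read_tsv(paste0(prefix, "_nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  edges <- readr::read_tsv(paste0(prefix, "_edges.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  featcols <- grep("^feat_", names(nodes), value = TRUE)
  features <- as.matrix(nodes[, featcols])
  dimnames(features) <- NULL
  build_graph(nodes[, c("slide_id", "x", "y", "cx", "cy")], features,
              edges = tibble::as_tibble(edges))
}

#' Plot a patch graph
#'
#' @param object A `wsi_graph`.
#' @param ... Unused.
#' @return A ggplot of nodes and edges in slide coordinates.
#' @export
autoplot.wsi_graph <- function(object, ...) {
  seg <- tibble::tibble(
    x = object$nodes$cx[object$edges$from],
    y = object$nodes$cy[object$edges$from],
    xend = object$nodes$cx[object$edges$to],
    yend = object$nodes$cy[object$edges$to]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(data = object$nodes,
                        ggplot2::aes(x = .data$cx, y = .data$cy), size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", title = object$slide_id) +
    ggplot2::theme_minimal()
}
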