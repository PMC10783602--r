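# Planar Delaunay triangulation (Bowyer-Watson incremental insertion).
# Written for patch-graph scale (hundreds to a few thousand points); the
# per-insertion in-circumcircle test is vectorized over triangles. Points
# exactly on a circumcircle (co-circular lattice configurations) are treated
# as outside, which yields a valid triangulation with a deterministic,
# insertion-order tie-break.

delaunay_triangles <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  # center and scale for numerical conditioning
  ctr <- colMeans(pts)
  p <- sweep(pts, 2, ctr)
  scale <- max(abs(p), 1)
  p <- p / scale
  # super-triangle enclosing everything; far enough out that its vertices
  # behave as points at infinity (hull-triangle circumcircles must not
  # contain them, or boundary edges would be lost)
  big <- 1e7
  sp <- rbind(c(0, 3 * big), c(-3 * big, -2 * big), c(3 * big, -2 * big))
  P <- rbind(sp, p)
  # triangle store: rows of vertex indices into P, plus circumcircle cache
  tris <- matrix(c(1L, 2L, 3L), ncol = 3)
  cc <- circumcircles(P, tris)
  for (ip in seq_len(n)) {
    v <- ip + 3L
    px <- P[v, 1]
    py <- P[v, 2]
    d2 <- (px - cc[, 1])^2 + (py - cc[, 2])^2
    eps <- 1e-13 * (cc[, 3] + 1) # relative: on-circle counts as outside
    bad <- which(d2 < cc[, 3] - eps)
    if (length(bad) == 0) {
      # numerical fallback: the containing triangle must exist; widen test
      bad <- which(d2 < cc[, 3] + eps)
    }
    bt <- tris[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(ekey %in% ekey[duplicated(ekey)]) # boundary = appears once
    poly <- edges[keep, , drop = FALSE]
    newt <- cbind(poly, v)
    tris <- rbind(tris[-bad, , drop = FALSE], newt)
    cc <- rbind(cc[-bad, , drop = FALSE], circumcircles(P, newt))
  }
  real <- tris[rowSums(tris <= 3L) == 0L, , drop = FALSE] - 3L
  real
}

circumcircles <- function(P, tris) {
  ax <- P[tris[, 1], 1]; ay <- P[tris[, 1], 2]
  bx <- P[tris[, 2], 1]; by <- P[tris[, 2], 2]
  cx <- P[tris[, 3], 1]; cy <- P[tris[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  a2 <- ax^2 + ay^2
  b2 <- bx^2 + by^2
  c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  cbind(ux, uy, r2)
}

# Edge table (from < to) of the pruned Delaunay graph of centroids.
# Fewer than 3 points, or a collinear point set, fall back to connecting
# all pairs within the distance bound (triangulation is undefined there).
delaunay_edge_table <- function(cx, cy, edge_distance_max = 4000) {
  n <- length(cx)
  if (n <= 1) {
    return(tibble::tibble(from = integer(), to = integer()))
  }
  # translation invariance: work on min-subtracted coordinates
  x <- cx - min(cx)
  y <- cy - min(cy)
  collinear <- FALSE
  if (n >= 3) {
    dx <- x - x[1]; dy <- y - y[1]
    cr <- dx * dy[2] - dy * dx[2]
    span <- max(abs(c(dx, dy)), 1)
    collinear <- all(abs(cr) <= 1e-9 * span^2)
  }
  if (n < 3 || collinear) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d2 <- (x[pairs[, 1]] - x[pairs[, 2]])^2 + (y[pairs[, 1]] - y[pairs[, 2]])^2
    keep <- d2 <= edge_distance_max^2
    return(tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2]))
  }
  tris <- delaunay_triangles(cbind(x, y))
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d2 <- (x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2
  e <- e[d2 <= edge_distance_max^2, , drop = FALSE]
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  tibble::tibble(from = as.integer(e[, 1]), to = as.integer(e[, 2]))
}
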