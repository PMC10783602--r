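# Shared fixtures and independent oracles, built in code at test time.

# cache expensive fixtures across test files within one run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default planted-factor expression cohort + fitted group model
expr_fixture <- function() {
  fixture("expr_default", function() {
    sim <- generate_expression(synth_expression_config(seed = 0L))
    z <- normalize_expression(sim$expression, already_log2 = TRUE)
    fit <- discover_groups(z, n_groups = 10, n_iterations = 100, seed = 0)
    list(sim = sim, z = z, fit = fit)
  })
}

# the default coupled cohort used by the end-to-end recovery checks
cohort_fixture <- function() {
  fixture("cohort_default", function() {
    generate_cohort(
      synth_expression_config(n_samples = 200L, n_factors = 8L, seed = 0L),
      synth_slide_config(seed = 0L))
  })
}

# small coupled cohort for graph/GNN tests (kept small: the full-scale run
# lives in the acceptance suite)
small_cohort <- function() {
  fixture("cohort_small", function() {
    generate_cohort(
      synth_expression_config(n_samples = 40L, n_factors = 4L,
                              genes_per_factor = 10L,
                              n_background_genes = 20L, seed = 1L),
      synth_slide_config(grid_rows = 8L, grid_cols = 8L, feature_dim = 16L,
                         n_factors = 4L, seed = 1L)
    )
  })
}

# brute-force Delaunay oracle, independent of the package's incremental
# algorithm: an edge (i, j) belongs to the triangulation iff some
# circumcircle through (i, j, k) contains no other point (points in general
# position); O(n^4), fine for small n
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  # unit-scale coordinates so the epsilon is meaningful for flat triangles
  s <- max(x - min(x), y - min(y), 1)
  x <- (x - min(x)) / s
  y <- (y - min(y)) / s
  edges <- matrix(integer(), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      r2 <- (ax - ux)^2 + (ay - uy)^2
      others <- setdiff(seq_len(n), c(i, j, k))
      if (all((x[others] - ux)^2 + (y[others] - uy)^2 >= r2 * (1 - 1e-12))) {
        found <- TRUE
        break
      }
    }
    if (found) edges <- rbind(edges, c(i, j))
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# uniform random RGB patch with a given fraction of pixels below the
# intensity threshold (for filter boundary tests)
patch_with_dark_fraction <- function(frac, side = 20L, dark = 50, light = 250) {
  n <- side * side
  n_dark <- round(frac * n)
  vals <- c(rep(dark, n_dark), rep(light, n - n_dark))
  array(rep(matrix(vals, side, side), 3), dim = c(side, side, 3))
}

# agreement between predicted and planted statuses after optimal matching
matched_agreement <- function(statuses, truth) {
  slidegroups:::match_factors(as.matrix(statuses), as.matrix(truth))$agreement
}
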