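# Synthetic cohorts with planted ground truth: expression matrices driven by
# binary latent factors over overlapping gene blocks, and slides whose patch
# features carry spatially contiguous signal regions tied to the same factor
# statuses. Every generator is a pure function of its config + seed.

#' Configuration for the synthetic expression generator
#'
#' @param n_samples Number of samples m (default 300).
#' @param n_factors Number of planted binary factors d* (default 10).
#' @param genes_per_factor Genes loading on each factor (default 30).
#' @param n_background_genes Pure-noise genes (default 200).
#' @param status_prevalence Bernoulli prevalence of status 1 (default 0.5).
#' @param effect_size Shift in z-units a status-1 factor adds to its genes
#'   (default 2.0).
#' @param noise_sd Gaussian noise standard deviation (default 1.0).
#' @param overlap_fraction Fraction of each factor's genes shared with the
#'   next (adjacent) factor; shared genes receive the sum of both factors'
#'   contributions (default 0.1).
#' @param seed Integer seed for the sampled quantities (statuses, noise).
#' @param structure_seed Integer seed for the fixed gene model (per-gene
#'   directions). Keeping it constant while varying `seed` draws fresh
#'   samples from the *same* planted generator, as needed to validate
#'   inference on an independent cohort.
#' @return A `synth_expression_config` list.
#' @export
synth_expression_config <- function(n_samples = 300L, n_factors = 10L,
                                    genes_per_factor = 30L,
                                    n_background_genes = 200L,
                                    status_prevalence = 0.5,
                                    effect_size = 2.0, noise_sd = 1.0,
                                    overlap_fraction = 0.1, seed = 0L,
                                    structure_seed = 0L) {
  stopifnot(n_samples > 0, n_factors > 0, genes_per_factor > 0,
            n_background_genes >= 0, status_prevalence > 0,
            status_prevalence < 1, effect_size > 0, noise_sd >= 0,
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(
    n_samples = as.integer(n_samples), n_factors = as.integer(n_factors),
    genes_per_factor = as.integer(genes_per_factor),
    n_background_genes = as.integer(n_background_genes),
    status_prevalence = status_prevalence, effect_size = effect_size,
    noise_sd = noise_sd, overlap_fraction = overlap_fraction,
    seed = as.integer(seed), structure_seed = as.integer(structure_seed)
  ), class = "synth_expression_config")
}

#' Generate a synthetic expression matrix with planted binary factors
#'
#' Statuses are independent Bernoulli draws; each planted gene's value is
#' `direction * effect_size * status` summed over the factors it loads on,
#' plus Gaussian noise; background genes are pure noise. Gene directions
#' (+1/-1) are assigned at random. Values are on an already-log2-like
#' scale; pass through [normalize_expression()] with `already_log2 = TRUE`
#' before factor discovery.
#'
#' @param cfg A [synth_expression_config()].
#' @return List: `expression` (samples-by-genes tibble), `statuses`
#'   (samples x factors binary tibble), `membership` (genes x factors 0/1
#'   loading matrix), `directions` (per-gene sign vector).
#' @export
generate_expression <- function(cfg = synth_expression_config()) {
  stopifnot(inherits(cfg, "synth_expression_config"))
  m <- cfg$n_samples
  d <- cfg$n_factors
  g <- cfg$genes_per_factor
  n_sig <- d * g
  n <- n_sig + cfg$n_background_genes

  directions <- withr::with_seed(cfg$structure_seed + 4242L,
                                 sample(c(-1, 1), n, replace = TRUE))
  withr::local_seed(cfg$seed)
  statuses <- matrix(stats::rbinom(m * d, 1L, cfg$status_prevalence), m, d)

  # block membership: factor k owns genes [(k-1)g+1 .. kg]; the last
  # round(overlap * g) genes of block k also load on factor k+1
  membership <- matrix(0L, n, d)
  for (k in seq_len(d)) {
    membership[((k - 1L) * g + 1L):(k * g), k] <- 1L
  }
  n_over <- round(cfg$overlap_fraction * g)
  if (n_over > 0 && d > 1) {
    for (k in seq_len(d - 1L)) {
      shared <- (k * g - n_over + 1L):(k * g)
      membership[shared, k + 1L] <- 1L
    }
  }

  signal <- statuses %*% t(membership * directions) * cfg$effect_size
  values <- signal + matrix(stats::rnorm(m * n, 0, cfg$noise_sd), m, n)

  sample_ids <- sprintf("S%04d", seq_len(m))
  gene_ids <- c(sprintf("FG%03d", seq_len(n_sig)),
                if (cfg$n_background_genes > 0)
                  sprintf("BG%03d", seq_len(cfg$n_background_genes)))
  dimnames(values) <- list(sample_ids, gene_ids)
  rownames(membership) <- gene_ids
  colnames(membership) <- sprintf("f%02d", seq_len(d))
  st <- statuses
  dimnames(st) <- list(sample_ids, colnames(membership))

  list(
    expression = matrix_to_expr(values),
    statuses = matrix_to_expr(st, id_col = "sample_id"),
    membership = membership,
    directions = stats::setNames(directions, gene_ids),
    config = cfg
  )
}

#' Configuration for the synthetic slide generator
#'
#' @param grid_rows,grid_cols Patch-lattice dimensions (default 24 x 24).
#' @param feature_dim Node feature dimension D (default 64; the full-scale
#'   1024 is a config switch).
#' @param n_factors Number of factors driving spatial signal (default 8).
#' @param blob_area_fraction Fraction of patches covered by each active
#'   factor's signal region (default 0.15).
#' @param shift_magnitude Feature-space shift magnitude applied inside a
#'   signal region (default 1.5), along a per-factor unit direction.
#' @param noise_sd Background feature noise sd (default 1.0).
#' @param patch_size_px Lattice spacing in working pixels (default 512).
#' @param seed Integer seed; also fixes the per-factor unit shift directions.
#' @return A `synth_slide_config` with the factor `directions`
#'   (n_factors x feature_dim, unit rows) materialized.
#' @export
synth_slide_config <- function(grid_rows = 24L, grid_cols = 24L,
                               feature_dim = 64L, n_factors = 8L,
                               blob_area_fraction = 0.15,
                               shift_magnitude = 1.5, noise_sd = 1.0,
                               patch_size_px = 512L, seed = 0L) {
  stopifnot(grid_rows > 0, grid_cols > 0, feature_dim > 0, n_factors > 0,
            blob_area_fraction > 0, blob_area_fraction <= 1,
            shift_magnitude > 0, noise_sd >= 0)
  dirs <- withr::with_seed(as.integer(seed) + 777L, {
    M <- matrix(stats::rnorm(n_factors * feature_dim), n_factors, feature_dim)
    M / sqrt(rowSums(M^2))
  })
  rownames(dirs) <- sprintf("f%02d", seq_len(n_factors))
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    feature_dim = as.integer(feature_dim), n_factors = as.integer(n_factors),
    blob_area_fraction = blob_area_fraction,
    shift_magnitude = shift_magnitude, noise_sd = noise_sd,
    patch_size_px = as.integer(patch_size_px),
    directions = dirs, seed = as.integer(seed)
  ), class = "synth_slide_config")
}

# contiguous irregular region by random-walk growth from a seed patch
grow_blob <- function(rows, cols, target) {
  start <- c(sample.int(rows, 1), sample.int(cols, 1))
  inblob <- matrix(FALSE, rows, cols)
  inblob[start[1], start[2]] <- TRUE
  frontier <- matrix(start, ncol = 2)
  while (sum(inblob) < target) {
    i <- sample.int(nrow(frontier), 1)
    cell <- frontier[i, ]
    nb <- rbind(cell + c(1, 0), cell + c(-1, 0), cell + c(0, 1), cell + c(0, -1))
    ok <- nb[, 1] >= 1 & nb[, 1] <= rows & nb[, 2] >= 1 & nb[, 2] <= cols
    nb <- nb[ok, , drop = FALSE]
    fresh <- nb[!inblob[nb], , drop = FALSE]
    if (nrow(fresh) == 0) {
      frontier <- frontier[-i, , drop = FALSE]
      if (nrow(frontier) == 0) break
      next
    }
    pick <- fresh[sample.int(nrow(fresh), 1), ]
    inblob[pick[1], pick[2]] <- TRUE
    frontier <- rbind(frontier, pick)
  }
  inblob
}

#' Generate one synthetic slide tied to a sample's factor statuses
#'
#' Produces a lattice of patches with Gaussian noise features; for every
#' active factor a contiguous blob of roughly `blob_area_fraction` of the
#' patches is shifted by `shift_magnitude` along that factor's unit
#' direction. Masks record blob membership per factor (empty when the
#' status is 0).
#'
#' @param cfg A [synth_slide_config()].
#' @param sample_statuses Binary vector of length `cfg$n_factors`.
#' @param seed Per-slide integer seed.
#' @param slide_id Slide identifier.
#' @param edges Optional precomputed edge tibble for this lattice (all
#'   synthetic slides share the same centroid lattice, so the Delaunay
#'   edges can be computed once and reused).
#' @return List: `graph` (a `wsi_graph`), `masks` (patches x factors logical
#'   matrix), `statuses`.
#' @export
generate_slide <- function(cfg, sample_statuses, seed = 0L,
                           slide_id = "slide", edges = NULL) {
  stopifnot(inherits(cfg, "synth_slide_config"),
            length(sample_statuses) == cfg$n_factors)
  withr::local_seed(as.integer(seed))
  rows <- cfg$grid_rows
  cols <- cfg$grid_cols
  n <- rows * cols
  D <- cfg$feature_dim
  feats <- matrix(stats::rnorm(n * D, 0, cfg$noise_sd), n, D)
  masks <- matrix(FALSE, n, cfg$n_factors,
                  dimnames = list(NULL, rownames(cfg$directions)))
  target <- max(1L, round(cfg$blob_area_fraction * n))
  for (k in seq_len(cfg$n_factors)) {
    if (sample_statuses[k] == 1) {
      blob <- grow_blob(rows, cols, target)
      idx <- which(as.vector(blob)) # column-major over (row, col)
      masks[idx, k] <- TRUE
      feats[idx, ] <- feats[idx, ] +
        matrix(cfg$directions[k, ] * cfg$shift_magnitude,
               length(idx), D, byrow = TRUE)
    }
  }
  # centroids on the tiling lattice (row-major patch order to mirror tiling)
  px <- cfg$patch_size_px
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cx <- (grid$col - 0.5) * px
  cy <- (grid$row - 0.5) * px
  patches <- tibble::tibble(
    slide_id = slide_id,
    x = (grid$col - 1L) * px, y = (grid$row - 1L) * px,
    cx = cx, cy = cy
  )
  # reindex masks/features from (row, col) column-major to the patch order
  lin <- (grid$col - 1L) * rows + grid$row # column-major index of each patch
  feats <- feats[lin, , drop = FALSE]
  masks <- masks[lin, , drop = FALSE]
  graph <- build_graph(patches, feats, edges = edges)
  list(graph = graph, masks = masks, statuses = sample_statuses)
}

#' Generate a coupled expression + slides cohort with planted truth
#'
#' Draws an expression matrix with planted binary factors and, for each
#' sample, a slide whose patch features carry contiguous signal regions for
#' exactly the factors active in that sample. The slide config's
#' `n_factors` must match the expression config's.
#'
#' @param expr_cfg A [synth_expression_config()].
#' @param slide_cfg A [synth_slide_config()] with the same `n_factors`.
#' @param out_dir Optional directory: when given, writes expression,
#'   statuses, per-slide node/edge tables, masks and configs as TSV/JSON.
#' @return A `synthetic_cohort` list: `expression`, `statuses`, `graphs`
#'   (named list of `wsi_graph`), `masks` (named list), `membership`,
#'   `configs`.
#' @export
generate_cohort <- function(expr_cfg = synth_expression_config(n_samples = 200L,
                                                               n_factors = 8L),
                            slide_cfg = synth_slide_config(),
                            out_dir = NULL) {
  stopifnot(expr_cfg$n_factors == slide_cfg$n_factors)
  expr <- generate_expression(expr_cfg)
  st <- as.matrix(expr$statuses[, -1])
  m <- nrow(st)
  # shared lattice -> compute Delaunay edges once
  proto <- lattice_patches(slide_cfg)
  edges <- delaunay_edge_table(proto$cx, proto$cy,
                               edge_distance_max = 4000)
  graphs <- vector("list", m)
  masks <- vector("list", m)
  ids <- expr$expression[[1]]
  for (i in seq_len(m)) {
    sl <- generate_slide(slide_cfg, st[i, ],
                         seed = slide_cfg$seed + i,
                         slide_id = ids[i], edges = edges)
    graphs[[i]] <- sl$graph
    masks[[i]] <- sl$masks
  }
  names(graphs) <- names(masks) <- ids
  cohort <- structure(list(
    expression = expr$expression, statuses = expr$statuses,
    membership = expr$membership, graphs = graphs, masks = masks,
    configs = list(expression = expr_cfg, slide = slide_cfg)
  ), class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

lattice_patches <- function(cfg) {
  px <- cfg$patch_size_px
  grid <- expand.grid(col = seq_len(cfg$grid_cols), row = seq_len(cfg$grid_rows))
  tibble::tibble(
    x = (grid$col - 1L) * px, y = (grid$row - 1L) * px,
    cx = (grid$col - 0.5) * px, cy = (grid$row - 0.5) * px
  )
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$expression, file.path(out_dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$statuses, file.path(out_dir, "statuses.tsv"),
                   progress = FALSE)
  slides_dir <- file.path(out_dir, "slides")
  dir.create(slides_dir, showWarnings = FALSE)
  for (id in names(cohort$graphs)) {
    write_graph(cohort$graphs[[id]], file.path(slides_dir, id))
    mk <- tibble::as_tibble(as.data.frame(cohort$masks[[id]] * 1L))
    readr::write_tsv(mk, file.path(slides_dir, paste0(id, "_masks.tsv")),
                     progress = FALSE)
  }
  cfgs <- lapply(cohort$configs, function(cf) {
    cf$directions <- NULL
    unclass(cf)
  })
  jsonlite::write_json(cfgs, file.path(out_dir, "configs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a synthetic slide as a small RGB raster
#'
#' Draws darker textured pixels on tissue patches and leaves margins white,
#' so the tiling and informative-pixel filter can be exercised end-to-end
#' at desk scale.
#'
#' @param tissue_mask Logical matrix (rows x cols): which lattice cells are
#'   tissue.
#' @param patch_px Rendered pixels per patch (default 16).
#' @param margin_patches White margin rings around the lattice (default 1).
#' @param seed Integer seed for the texture.
#' @return An H x W x 3 array in `[0, 1]`.
#' @export
render_slide_raster <- function(tissue_mask, patch_px = 16L,
                                margin_patches = 1L, seed = 0L) {
  withr::local_seed(as.integer(seed))
  rows <- nrow(tissue_mask) + 2L * margin_patches
  cols <- ncol(tissue_mask) + 2L * margin_patches
  h <- rows * patch_px
  w <- cols * patch_px
  img <- array(1, dim = c(h, w, 3)) # white background
  for (r in seq_len(nrow(tissue_mask))) {
    for (cc in seq_len(ncol(tissue_mask))) {
      if (!tissue_mask[r, cc]) next
      y0 <- (r - 1L + margin_patches) * patch_px
      x0 <- (cc - 1L + margin_patches) * patch_px
      tex <- matrix(stats::runif(patch_px^2, 0.25, 0.55), patch_px, patch_px)
      for (ch in 1:3) {
        img[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px), ch] <-
          tex * c(1.0, 0.75, 0.9)[ch] # eosin-ish tint
      }
    }
  }
  img
}
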