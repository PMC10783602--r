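# Heatmaps, exemplar selection, patch harvesting, motif mining, and the
# sub-patch aggregation geometry.

test_that("heatmap export preserves exact node scores and colour semantics", {
  co <- small_cohort()
  g <- co$graphs[[1]]
  n <- nrow(g$nodes)
  ns <- matrix(seq(-1, 1, length.out = n), n, 1)
  hm <- export_heatmap(ns, g, factor_ids = 1, patch_size = 512)
  expect_equal(nrow(hm), n)
  expect_equal(hm$score_g001, ns[, 1])
  # colour semantics: negative -> blue dominant, positive -> red dominant
  cols <- slidegroups:::diverging_colour(c(-1, 0, 1))
  expect_equal(cols[1, ], c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(cols[3, ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(cols[2, ], c(1, 1, 1), ignore_attr = TRUE)
  # constant scores export uniformly
  hm2 <- export_heatmap(matrix(2, n, 1), g)
  expect_true(all(hm2$score_g001 == 2))
  # unknown factor id
  expect_error(export_heatmap(ns, g, factor_ids = 5), "unknown factor")
  # file outputs
  png_f <- withr::local_tempfile(fileext = ".png")
  gj_f <- withr::local_tempfile(fileext = ".json")
  export_heatmap(ns, g, png_path = png_f, geojson_path = gj_f)
  expect_true(file.exists(png_f))
  gj <- jsonlite::read_json(gj_f)
  expect_equal(length(gj$features), n)
})

test_that("heatmap scores are higher inside the planted signal region", {
  co <- small_cohort()
  st <- as.matrix(co$statuses[, -1])
  i <- which(st[, 1] == 1)[1]
  g <- co$graphs[[i]]
  msk <- co$masks[[i]][, 1]
  dirs <- co$configs$slide$directions
  ns <- g$features %*% dirs[1, ] # oracle score: projection on the shift
  hm <- export_heatmap(matrix(ns), g)
  expect_gt(mean(hm$score_g001[msk]), mean(hm$score_g001[!msk]))
})

test_that("exemplar selection equals a sort-by-margin oracle", {
  set.seed(4)
  n <- 30
  y <- rbinom(n, 1, 0.5)
  scores <- y * 2 - 1 + rnorm(n, 0, 0.6)
  preds <- tibble::tibble(slide_id = sprintf("p%02d", 1:n), g001 = scores)
  labels <- tibble::tibble(slide_id = preds$slide_id, g001 = y)
  sel <- select_exemplar_patients(preds, labels, group_id = 1,
                                  n_per_status = 5)
  thr <- sel$threshold
  # oracle: correctly-classified, sorted by signed margin
  correct1 <- which(scores > thr & y == 1)
  oracle1 <- preds$slide_id[correct1[order(-(scores[correct1] - thr))][1:5]]
  expect_equal(sel$status1$slide_id, oracle1)
  correct0 <- which(scores <= thr & y == 0)
  oracle0 <- preds$slide_id[correct0[order(-(thr - scores[correct0]))][1:5]]
  expect_equal(sel$status0$slide_id, oracle0)
  # margins are non-increasing and at most n returned
  expect_true(all(diff(sel$status1$margin) <= 0))
  few <- select_exemplar_patients(preds[1:10, ], labels[1:10, ], 1,
                                  n_per_status = 50)
  expect_lte(nrow(few$status1), 10)
  expect_lte(nrow(few$status0), 10)
})

test_that("patch harvesting takes the extreme percentile with deterministic ties", {
  co <- small_cohort()
  g <- co$graphs[[1]]
  n <- nrow(g$nodes) # 64 nodes
  set.seed(9)
  sc <- rnorm(n)
  h1 <- harvest_patches(sc, g, status = 1, fraction = 0.01)
  expect_equal(nrow(h1), 1) # ceil(0.64) = 1
  expect_equal(h1$node, which.max(sc))
  # 250-score case: ceil(2.5) = 3, equals a sort oracle
  g250 <- build_graph(tibble::tibble(cx = seq_len(250) * 600, cy = 0),
                      matrix(0, 250, 2))
  sc250 <- rnorm(250)
  h3 <- harvest_patches(sc250, g250, status = 1, fraction = 0.01)
  expect_equal(nrow(h3), 3)
  expect_equal(h3$node, order(-sc250)[1:3])
  h0 <- harvest_patches(sc250, g250, status = 0, fraction = 0.01)
  expect_equal(h0$node, order(sc250)[1:3])
  # ties break by node index
  tied <- rep(1, 10)
  gt <- build_graph(tibble::tibble(cx = 1:10 * 600, cy = 0), matrix(0, 10, 2))
  expect_equal(harvest_patches(tied, gt, 1, fraction = 0.2)$node, 1:2)
})

test_that("harvested status-1 patches are exactly the reddest heatmap entries", {
  co <- small_cohort()
  g <- co$graphs[[3]]
  set.seed(2)
  sc <- rnorm(nrow(g$nodes))
  hm <- export_heatmap(matrix(sc), g)
  h <- harvest_patches(sc, g, status = 1, fraction = 0.05)
  k <- nrow(h)
  expect_setequal(h$node, order(-hm$score_g001)[1:k])
})

test_that("k-medoid motifs recover separated clusters and are input members", {
  set.seed(6)
  k <- 25
  per <- 8
  centers <- matrix(runif(k * 5) * 100, k, 5)
  feats <- centers[rep(1:k, each = per), ] + matrix(rnorm(k * per * 5, 0, 0.5),
                                                    k * per, 5)
  patches <- tibble::tibble(slide_id = "s", node = seq_len(k * per),
                            x = 0, y = 0, cx = 0, cy = 0, score = 0)
  ms <- mine_motifs(patches, feats, k = 25, seed = 0)
  expect_equal(ms$k, 25)
  expect_true(all(ms$medoid_index %in% seq_len(nrow(feats))))
  # one medoid per true cluster, matched by nearest-centre oracle
  medoid_cluster <- apply(feats[ms$medoid_index, ], 1, function(f) {
    which.min(colSums((t(centers) - f)^2))
  })
  expect_setequal(medoid_cluster, 1:25)
  # exactly k patches: every patch is a medoid
  ms2 <- mine_motifs(patches[1:25, ], feats[1:25, ], k = 25)
  expect_setequal(ms2$medoid_index, 1:25)
  # deterministic
  ms3 <- mine_motifs(patches, feats, k = 25, seed = 42)
  expect_identical(ms$medoid_index, ms3$medoid_index)
})

test_that("sub-patch geometry decomposes 512@0.50 into 16 tiles of 256@0.25", {
  kids <- subpatch_grid(c(0, 0), 512L, 0.50, 256L, 0.25)
  expect_equal(nrow(kids), 16)
  # lattice oracle: 4x4 grid of 256-px origins at the child scale
  oracle <- expand.grid(x = (0:3) * 256, y = (0:3) * 256)
  expect_setequal(paste(kids$x, kids$y), paste(oracle$x, oracle$y))
  # identical geometry -> a single tile
  expect_equal(nrow(subpatch_grid(c(0, 0), 512L, 0.5, 512L, 0.5)), 1)
  # same pixel size, half the mpp -> 2x2
  k4 <- subpatch_grid(c(512, 0), 512L, 0.50, 512L, 0.25)
  expect_equal(nrow(k4), 4)
  expect_setequal(paste(k4$x, k4$y),
                  paste(c(1024, 1536, 1024, 1536), c(0, 0, 512, 512)))
  expect_error(subpatch_grid(c(0, 0), 512L, 0.50, 300L, 0.25),
               "integer multiple")
})

test_that("annotation aggregates child tiles additively", {
  patches <- tibble::tibble(x = c(0, 512), y = c(0, 1024))
  zero <- stub_annotator(constant = c(neoplastic = 0, inflammatory = 0,
                                      connective = 0, epithelial = 0,
                                      mitoses = 0))
  a0 <- annotate_patches(patches, zero)
  expect_true(all(a0$cellularity == 0) && all(a0$mitoses == 0))
  one_inf <- stub_annotator(constant = c(neoplastic = 0, inflammatory = 1,
                                         connective = 0, epithelial = 0,
                                         mitoses = 0))
  a1 <- annotate_patches(patches, one_inf)
  expect_true(all(a1$inflammatory == 16)) # 16 child tiles per parent
  expect_true(all(a1$cellularity == 16))
  # cellularity is the four-way sum for an arbitrary annotator
  ah <- annotate_patches(patches, stub_annotator())
  expect_equal(ah$cellularity,
               ah$neoplastic + ah$inflammatory + ah$connective + ah$epithelial)
  # contract violation
  neg <- structure(list(name = "neg", fn = function(x, y)
    c(neoplastic = -1, inflammatory = 0, connective = 0, epithelial = 0,
      mitoses = 0)), class = "patch_annotator")
  expect_error(annotate_patches(patches, neg), "negative")
})
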