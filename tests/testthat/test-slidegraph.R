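# EdgeConv forward semantics, scoring conservation and locality, ranking
# loss, gradients, and the training protocol.

make_line_graph <- function(feats, spacing = 500) {
  n <- nrow(feats)
  build_graph(tibble::tibble(cx = (seq_len(n) - 1) * spacing, cy = 0),
              feats)
}

# explicit path graph (edges i -- i+1 only), independent of triangulation
make_path_graph <- function(feats) {
  n <- nrow(feats)
  build_graph(tibble::tibble(cx = (seq_len(n) - 1) * 500, cy = 0), feats,
              edges = tibble::tibble(from = seq_len(n - 1),
                                     to = seq_len(n - 1) + 1L))
}

test_that("an isolated node has exactly zero embeddings at every layer", {
  cfg <- model_config(n_layers = 3, n_outputs = 2, seed = 1)
  g <- build_graph(tibble::tibble(cx = c(0, 9000), cy = c(0, 0)),
                   matrix(rnorm(8), 2, 4)) # too far apart: no edges
  model <- slidegroups:::init_slidegraph(cfg, 4, 2)
  H <- edgeconv_forward(model, g)
  expect_length(H, 4)
  for (l in 2:4) expect_true(all(H[[l]] == 0))
})

test_that("a two-node layer matches a by-hand EdgeConv computation", {
  cfg <- model_config(n_layers = 1, n_outputs = 1, layer_hidden_width = 2,
                      activation = "relu", seed = 0)
  g <- make_path_graph(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  model <- slidegroups:::init_slidegraph(cfg, 2, 1)
  # hand-set weights: perceptron [h_m || h_k - h_m] -> 2-d embedding
  W1 <- matrix(c(1, 0, 0, 1, -1, 1, 2, 0), 4, 2)
  b1 <- c(0.5, -0.5)
  W2 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  b2 <- c(0.25, -1)
  model$layers[[1]] <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  H <- edgeconv_forward(model, g)
  # manual forward: node 1 has the single neighbour 2 and vice versa
  manual <- function(hm, hk) {
    z <- c(hm, hk - hm)
    a <- pmax(as.vector(z %*% W1) + b1, 0)
    as.vector(a %*% W2) + b2
  }
  expect_equal(H[[2]][1, ], manual(c(1, 2), c(3, 4)))
  expect_equal(H[[2]][2, ], manual(c(3, 4), c(1, 2)))
})

test_that("node scores equal the sum of separately evaluated layer heads", {
  cfg <- model_config(n_layers = 2, n_outputs = 3, seed = 4)
  co <- small_cohort()
  g <- co$graphs[[1]]
  model <- slidegroups:::init_slidegraph(cfg, g$feature_dim, 3)
  # make head outputs non-zero (they are zero-initialized)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  S <- node_score(model, g)
  H <- edgeconv_forward(model, g)
  act <- slidegroups:::activation_fns(cfg$activation)
  S_oracle <- 0
  for (l in seq_along(model$heads)) {
    S_oracle <- S_oracle +
      slidegroups:::mlp_forward(model$heads[[l]], H[[l]], act)$Y
  }
  expect_equal(S, S_oracle, tolerance = 1e-12)
})

test_that("an L = 0 model scores nodes with the raw-feature head only", {
  cfg <- model_config(n_layers = 0, n_outputs = 2, head_hidden_width = 4,
                      seed = 2)
  g <- make_line_graph(matrix(rnorm(12), 4, 3))
  model <- slidegroups:::init_slidegraph(cfg, 3, 2)
  model$heads[[1]]$W2 <- matrix(rnorm(8), 4, 2)
  act <- slidegroups:::activation_fns(cfg$activation)
  expect_equal(node_score(model, g),
               slidegroups:::mlp_forward(model$heads[[1]],
                                         g$features, act)$Y)
})

test_that("slide score is the exact column sum of node scores", {
  co <- small_cohort()
  cfg <- model_config(n_outputs = 4, seed = 3)
  model <- slidegroups:::init_slidegraph(cfg, co$graphs[[1]]$feature_dim, 4)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  for (g in co$graphs[1:5]) {
    ns <- node_score(model, g)
    expect_equal(slide_score(model, g), colSums(ns),
                 tolerance = 1e-5)
  }
  # single node: slide score equals the node score
  g1 <- build_graph(tibble::tibble(cx = 0, cy = 0),
                    matrix(rnorm(co$graphs[[1]]$feature_dim), 1))
  expect_equal(slide_score(model, g1), as.vector(node_score(model, g1)))
})

test_that("disconnected components score additively", {
  cfg <- model_config(n_outputs = 2, seed = 5)
  fa <- matrix(rnorm(6 * 4), 6, 4)
  fb <- matrix(rnorm(4 * 4), 4, 4)
  ga <- make_line_graph(fa)
  gb <- make_line_graph(fb)
  # joint graph: component B displaced far beyond the edge bound
  joint <- build_graph(
    tibble::tibble(cx = c((0:5) * 500, (0:3) * 500 + 1e6),
                   cy = rep(0, 10)),
    rbind(fa, fb))
  model <- slidegroups:::init_slidegraph(cfg, 4, 2)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  expect_equal(slide_score(model, joint),
               slide_score(model, ga) + slide_score(model, gb),
               tolerance = 1e-9)
})

test_that("node scores are invariant to perturbations beyond L hops", {
  cfg <- model_config(n_layers = 3, n_outputs = 2, seed = 6)
  n <- 9
  feats <- matrix(rnorm(n * 3), n, 3)
  g <- make_path_graph(feats) # path graph: hop distance = index distance
  model <- slidegroups:::init_slidegraph(cfg, 3, 2)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  s_before <- node_score(model, g)
  feats2 <- feats
  feats2[c(5:9), ] <- rnorm(5 * 3) + 10 # nodes >= 4 hops from node 1
  g2 <- make_path_graph(feats2)
  s_after <- node_score(model, g2)
  expect_identical(s_before[1, ], s_after[1, ]) # bit-identical
  expect_false(all(s_before[5, ] == s_after[5, ]))
})

test_that("permuting node order permutes node scores and preserves the slide score", {
  co <- small_cohort()
  g <- co$graphs[[2]]
  cfg <- model_config(n_outputs = 3, seed = 8)
  model <- slidegroups:::init_slidegraph(cfg, g$feature_dim, 3)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  set.seed(1)
  perm <- sample(nrow(g$features))
  inv <- order(perm)
  # relabel the identical graph (edges remapped explicitly so lattice
  # triangulation tie-breaks cannot alter the adjacency)
  gp <- build_graph(
    tibble::tibble(cx = g$nodes$cx[perm], cy = g$nodes$cy[perm]),
    g$features[perm, , drop = FALSE],
    edges = tibble::tibble(from = pmin(inv[g$edges$from], inv[g$edges$to]),
                           to = pmax(inv[g$edges$from], inv[g$edges$to])))
  sp <- node_score(model, gp)
  s <- node_score(model, g)
  expect_equal(sp[inv, ], s, tolerance = 1e-9)
  expect_equal(colSums(sp), colSums(s), tolerance = 1e-9)
})

test_that("ranking loss matches hand-computed cases", {
  expect_equal(ranking_loss(matrix(c(2, 0)), matrix(c(1, 0))), 0)
  expect_equal(ranking_loss(matrix(c(0.5, 0)), matrix(c(1, 0))), 0.5)
  # all scores equal: every one of p*q pairs contributes exactly 1
  sc <- matrix(1, 7, 1)
  lb <- matrix(c(rep(1, 3), rep(0, 4)))
  expect_equal(ranking_loss(sc, lb), 3 * 4)
  # missing labels are excluded from pair construction: the only valid pair
  # is (score 0 positive, score 3 negative) -> max(0, 1 - (0 - 3)) = 4
  expect_equal(ranking_loss(matrix(c(0, 5, 3)), matrix(c(1, NA, 0))), 4)
  # an output with no valid pair contributes zero
  expect_equal(ranking_loss(matrix(c(1, 2)), matrix(c(1, 1))), 0)
})

test_that("ranking loss equals a brute-force double loop on random batches", {
  brute <- function(s, y) {
    total <- 0
    for (k in seq_len(ncol(s))) for (a in seq_len(nrow(s)))
      for (b in seq_len(nrow(s))) {
        if (!is.na(y[a, k]) && !is.na(y[b, k]) && y[a, k] > y[b, k]) {
          total <- total + max(0, 1 - (s[a, k] - s[b, k]))
        }
      }
    total
  }
  set.seed(99)
  for (trial in 1:25) {
    N <- sample(1:8, 1)
    K <- sample(c(1, 3, 17), 1)
    s <- matrix(rnorm(N * K, 0, 2), N, K)
    y <- matrix(rbinom(N * K, 1, 0.5), N, K)
    y[runif(N * K) < 0.2] <- NA
    expect_equal(ranking_loss(s, y), brute(s, y))
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  g1 <- make_line_graph(matrix(rnorm(5 * 4), 5, 4))
  g2 <- make_line_graph(matrix(rnorm(3 * 4), 3, 4))
  cfg <- model_config(n_layers = 2, n_outputs = 3, layer_hidden_width = 4,
                      head_hidden_width = 4, activation = "tanh", seed = 1)
  model <- slidegroups:::init_slidegraph(cfg, 4, 3)
  for (l in seq_along(model$heads)) {
    model$heads[[l]]$W2 <- matrix(rnorm(length(model$heads[[l]]$W2), 0, 0.3),
                                  nrow(model$heads[[l]]$W2))
  }
  labels <- matrix(c(1, 0, 0, 1, 1, NA), 2, 3)
  ba <- slidegroups:::concat_arrays(
    lapply(list(g1, g2), slidegroups:::graph_arrays))
  fw <- slidegroups:::sg_forward(model, ba, want_cache = TRUE)
  rl <- slidegroups:::ranking_loss_grad(fw$slide_scores, labels)
  gr <- slidegroups:::sg_backward(model, ba, fw, rl$grad)
  lossfn <- function(m) {
    f <- slidegroups:::sg_forward(m, ba)
    slidegroups:::ranking_loss_grad(f$slide_scores, labels)$loss
  }
  eps <- 1e-6
  for (part in c("layers", "heads")) {
    for (i in seq_along(model[[part]])) {
      for (nm in c("W1", "W2")) {
        P <- model[[part]][[i]][[nm]]
        set.seed(i)
        for (j in sample(length(P), min(4, length(P)))) {
          mp <- model; mp[[part]][[i]][[nm]][j] <- P[j] + eps
          mm <- model; mm[[part]][[i]][[nm]][j] <- P[j] - eps
          num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
          expect_equal(gr[[part]][[i]][[nm]][j], num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("training runs, early-stops, and fills a bounded queue", {
  co <- small_cohort()
  labels <- as.matrix(co$statuses[, -1])
  # one factor with zero positives trains without failure
  lab0 <- labels
  lab0[, 2] <- 0
  fit <- train_slidegraph(
    co$graphs[1:30], lab0[1:30, ],
    config = model_config(layer_hidden_width = 4, head_hidden_width = 4,
                          seed = 0),
    tc = train_config(epochs = 10, seed = 0))
  expect_s3_class(fit, "slidegraph_fit")
  expect_lte(length(fit$queue), 10)
  expect_gte(length(fit$queue), 1)
  expect_lte(nrow(fit$history), 10)
  # abort when no output has a valid pair
  expect_error(
    train_slidegraph(co$graphs[1:10], matrix(1, 10, 2),
                     config = model_config(seed = 0),
                     tc = train_config(epochs = 2, seed = 0)),
    "ranking loss is undefined")
})

test_that("training is deterministic given identical seeds", {
  co <- small_cohort()
  labels <- as.matrix(co$statuses[, -1])
  run <- function() train_slidegraph(
    co$graphs[1:16], labels[1:16, , drop = FALSE],
    config = model_config(layer_hidden_width = 4, head_hidden_width = 4,
                          seed = 7),
    tc = train_config(epochs = 4, seed = 7))
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$heads, f2$model$heads)
  expect_identical(f1$queue[[length(f1$queue)]]$layers,
                   f2$queue[[length(f2$queue)]]$layers)
})

test_that("ensembling averages models, and bags average their slides", {
  co <- small_cohort()
  cfg <- model_config(n_outputs = 4, seed = 1)
  D <- co$graphs[[1]]$feature_dim
  mk <- function(seed) {
    cfg$seed <- seed
    m <- slidegroups:::init_slidegraph(cfg, D, 4)
    for (l in seq_along(m$heads)) {
      m$heads[[l]]$W2 <- matrix(rnorm(length(m$heads[[l]]$W2), 0, 0.3),
                                nrow(m$heads[[l]]$W2))
    }
    m
  }
  m1 <- mk(1)
  m2 <- mk(2)
  g <- co$graphs[1:3]
  p1 <- predict_ensemble(list(m1), g)
  expect_equal(as.numeric(p1[1, -1]), slide_score(m1, g[[1]]),
               tolerance = 1e-9, ignore_attr = TRUE)
  p12 <- predict_ensemble(list(m1, m2), g)
  p2 <- predict_ensemble(list(m2), g)
  expect_equal(as.matrix(p12[, -1]),
               (as.matrix(p1[, -1]) + as.matrix(p2[, -1])) / 2,
               tolerance = 1e-9)
  # 5 models on a 3-graph bag: nested-loop oracle
  models <- lapply(1:5, mk)
  bag <- list(patient1 = co$graphs[1:3])
  pb <- predict_ensemble(models, bag)
  oracle <- rowMeans(sapply(co$graphs[1:3], function(gg) {
    rowMeans(sapply(models, function(m) slide_score(m, gg)))
  }))
  expect_equal(as.numeric(pb[1, -1]), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("cross-validation partitions slides into disjoint test folds", {
  co <- small_cohort()
  labels <- as.matrix(co$statuses[, -1])
  cv <- cross_validate_slidegraph(
    co$graphs[1:20], labels[1:20, ],
    config = model_config(layer_hidden_width = 4, head_hidden_width = 4,
                          seed = 0),
    tc = train_config(epochs = 3, n_folds = 5, seed = 0))
  expect_equal(sort(cv$predictions$.row), 1:20) # each slide in exactly one fold
  expect_equal(nrow(cv$auroc), 4)
})

test_that("label-permuted training yields chance-level out-of-fold AUROC", {
  co <- small_cohort()
  labels <- as.matrix(co$statuses[, -1])
  set.seed(123)
  perm_labels <- labels[sample(nrow(labels)), ]
  cv <- cross_validate_slidegraph(
    co$graphs, perm_labels,
    config = model_config(layer_hidden_width = 4, head_hidden_width = 4,
                          seed = 0),
    tc = train_config(epochs = 8, n_folds = 5, seed = 0))
  expect_gte(mean(cv$auroc$auroc, na.rm = TRUE), 0.4)
  expect_lte(mean(cv$auroc$auroc, na.rm = TRUE), 0.6)
})
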