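# Gene-group discovery: recovery of planted factors, reproducibility,
# inference, composition, and the total-correlation curve.

test_that("planted factors are recovered at >= 95% matched agreement", {
  fx <- expr_fixture()
  ag <- matched_agreement(fx$fit$statuses[, -1], fx$sim$statuses[, -1])
  expect_length(ag, 10)
  expect_true(all(ag >= 0.95))
})

test_that("planted genes out-rank every background gene in their factor", {
  fx <- expr_fixture()
  truth <- as.matrix(fx$sim$statuses[, -1])
  st <- as.matrix(fx$fit$statuses[, -1])
  mm <- slidegroups:::match_factors(st, truth)
  membership <- fx$sim$membership
  for (i in seq_len(ncol(truth))) {
    k <- mm$matched[i]
    mi <- fx$fit$mi[, k]
    planted <- membership[, i] == 1
    background <- grepl("^BG", rownames(membership))
    expect_gt(min(mi[planted]), max(mi[background]))
  }
})

test_that("discovery is bitwise reproducible for a fixed seed", {
  fx <- expr_fixture()
  fit2 <- discover_groups(fx$z, n_groups = 10, n_iterations = 100, seed = 0)
  expect_identical(fit2$statuses, fx$fit$statuses)
  expect_identical(fit2$mi, fx$fit$mi)
  expect_identical(fit2$tc, fx$fit$tc)
})

test_that("model invariants hold: binary statuses, non-negative mi/tc, sorted tc", {
  fx <- expr_fixture()
  st <- as.matrix(fx$fit$statuses[, -1])
  expect_true(all(st %in% c(0L, 1L)))
  expect_true(all(fx$fit$mi >= 0))
  expect_true(all(fx$fit$tc >= 0))
  expect_true(all(diff(fx$fit$tc) <= 1e-12)) # non-increasing
  expect_true(all(fx$fit$direction[fx$fit$mi <= 0] == 0))
})

test_that("inference on the training matrix reproduces training statuses exactly", {
  fx <- expr_fixture()
  st <- infer_status(fx$z, fx$fit)
  expect_identical(as.matrix(st[, -1]), as.matrix(fx$fit$statuses[, -1]))
  # idempotent
  st2 <- infer_status(fx$z, fx$fit)
  expect_identical(st, st2)
})

test_that("statuses of fresh samples from the same generator are recovered", {
  fx <- expr_fixture()
  sim2 <- generate_expression(synth_expression_config(seed = 99L))
  z2 <- normalize_expression(sim2$expression, already_log2 = TRUE)
  st2 <- infer_status(z2, fx$fit)
  ag <- matched_agreement(st2[, -1], sim2$statuses[, -1])
  expect_true(all(ag >= 0.95))
})

test_that("heavily missing groups are flagged unreliable at inference", {
  fx <- expr_fixture()
  comp <- group_composition(fx$fit, 1, max_genes = 400, mi_threshold = 0.002)
  # drop ~all of group 1's genes from the cohort
  drop <- intersect(names(fx$z), comp$gene)
  z_missing <- fx$z[, !(names(fx$z) %in% drop)]
  suppressMessages(st <- infer_status(z_missing, fx$fit))
  expect_true(attr(st, "unreliable_groups")[1])
  expect_setequal(attr(st, "missing_genes"), drop)
})

test_that("a perfectly redundant gene set yields its pattern as the factor", {
  set.seed(5)
  pattern <- rbinom(80, 1, 0.5)
  x <- matrix(rep(pattern, 12), 80, 12) + matrix(rnorm(80 * 12, 0, 1e-3), 80)
  colnames(x) <- sprintf("gene%02d", 1:12)
  rownames(x) <- sprintf("s%02d", 1:80)
  z <- normalize_expression(matrix_to_expr(x), already_log2 = TRUE)
  fit <- discover_groups(z, n_groups = 1, seed = 0)
  st <- as.matrix(fit$statuses[, -1])[, 1]
  expect_true(mean(st == pattern) == 1 || mean(st != pattern) == 1)
  expect_gt(fit$tc, 0)
})

test_that("group composition ranks by descending mi with threshold and cap", {
  fx <- expr_fixture()
  comp <- group_composition(fx$fit, 1)
  expect_true(all(diff(comp$mi) <= 0))
  expect_true(all(comp$mi > 0.002))
  expect_lte(nrow(comp), 400)
  expect_true(all(comp$direction %in% c(-1L, 1L)))
  # the 30 planted genes of the matched factor occupy the top 30 ranks
  truth <- as.matrix(fx$sim$statuses[, -1])
  st <- as.matrix(fx$fit$statuses[, -1])
  mm <- slidegroups:::match_factors(st, truth)
  i <- which(mm$matched == 1) # planted factor matched to discovered group 1
  # planted genes for a factor include the genes shared with its neighbour
  planted <- rownames(fx$sim$membership)[fx$sim$membership[, i] == 1]
  expect_true(all(comp$gene[1:30] %in% planted))
  # threshold above every mi -> empty
  empty <- group_composition(fx$fit, 1, mi_threshold = 1e6)
  expect_equal(nrow(empty), 0)
  expect_error(group_composition(fx$fit, 0), "out of range")
})

test_that("direction convention: top gene of each group points up", {
  fx <- expr_fixture()
  for (k in 1:3) {
    comp <- group_composition(fx$fit, k)
    expect_equal(comp$direction[1], 1L)
  }
})

test_that("total correlation collapses under column permutation", {
  fx <- expr_fixture()
  zp <- fx$z
  set.seed(11)
  for (j in 2:ncol(zp)) zp[[j]] <- sample(zp[[j]])
  null_fit <- discover_groups(zp, n_groups = 10, seed = 0)
  # permutation-null distribution from additional independent permutations
  null_tc <- c(null_fit$tc)
  for (r in 1:3) {
    zr <- fx$z
    for (j in 2:ncol(zr)) zr[[j]] <- sample(zr[[j]])
    null_tc <- c(null_tc, discover_groups(zr, n_groups = 10, seed = r)$tc)
  }
  q95 <- quantile(null_tc, 0.95)
  expect_true(all(null_fit$tc <= max(null_tc)))
  # every real-factor tc is far above the permutation null
  expect_gt(min(fx$fit$tc), q95)
})

test_that("tc curve grows to a plateau on planted data and stays near zero on noise", {
  fx <- expr_fixture()
  # subset of genes for speed: 4 planted blocks + background
  keep <- c("sample_id",
            rownames(fx$sim$membership)[fx$sim$membership[, 1:4] %*% rep(1, 4) > 0],
            grep("^BG", rownames(fx$sim$membership), value = TRUE)[1:40])
  z4 <- fx$z[, names(fx$z) %in% keep]
  curve <- tc_curve(z4, d_grid = c(1, 2, 4, 6), seed = 0)
  expect_s3_class(curve, "tc_curve")
  # non-decreasing in d within a small optimizer tolerance
  tol <- 0.02 * max(curve$total_tc)
  expect_true(all(diff(curve$total_tc) >= -tol))
  # plateau: moving past the planted number of factors adds little
  gain_before <- curve$total_tc[3] - curve$total_tc[1]
  gain_after <- abs(curve$total_tc[4] - curve$total_tc[3])
  expect_gt(gain_before, 5 * gain_after)

  # pure-noise matrix: total TC below a permutation-calibrated bound
  set.seed(2)
  noise <- matrix(rnorm(120 * 30), 120, 30)
  colnames(noise) <- sprintf("n%02d", 1:30)
  rownames(noise) <- sprintf("s%03d", 1:120)
  zn <- normalize_expression(matrix_to_expr(noise), already_log2 = TRUE)
  cn <- tc_curve(zn, d_grid = c(2, 5), seed = 0)
  expect_lt(max(cn$total_tc), 0.05 * max(curve$total_tc))
})

test_that("cosine state similarity matches hand-computed cases", {
  expect_equal(state_similarity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(state_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(state_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_error(state_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(state_similarity(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("tidy and glance summarize a group model", {
  fx <- expr_fixture()
  td <- tidy(fx$fit, mi_threshold = 0.01)
  expect_true(all(td$mi > 0.01))
  expect_named(td, c("gene", "group", "mi", "direction"))
  gl <- glance(fx$fit)
  expect_equal(gl$n_groups, 10)
  expect_equal(gl$total_tc, sum(fx$fit$tc))
})
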