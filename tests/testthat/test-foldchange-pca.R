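test_that("fold changes are log2 ratios of week4 to baseline", {
  sim <- tiny_sim(n_features = 3L)
  st <- sim$study
  # doubling a feature's week4 values adds exactly +1
  wk4 <- st$samples$timepoint == "week4"
  st$values[wk4, 1L] <- 2 * st$values[wk4, 1L]
  fc <- compute_fold_changes(st)
  st0 <- sim$study
  fc0 <- compute_fold_changes(st0)
  expect_equal(fc$values[, 1L], fc0$values[, 1L] + 1)
  expect_equal(fc$values[, 2L], fc0$values[, 2L])

  # identical timepoints give the all-zero matrix
  null_sim <- simulate_study(
    n_per_group = c(SAL = 2, GOP = 2, VLCD = 2, RYGB = 2), n_features = 3L,
    effect = effect_spec(delta = matrix(0, 3L, 4L)),
    noise = noise_spec(sigma_subject = 0, sigma_resid = 0), seed = 2)
  expect_equal(max(abs(compute_fold_changes(null_sim$study)$values)), 0)
})

test_that("platform groupings concatenate features and reject empty selections", {
  sim <- tiny_sim(n_features = 9L)
  st <- sim$study
  fc_all <- compute_fold_changes(st, platforms = c("lipidRPCpos", "lipidRPCneg",
                                                   "HILICpos"))
  expect_equal(ncol(fc_all$values), 9L)
  fc_one <- compute_fold_changes(st, platforms = "HILICpos")
  expect_equal(ncol(fc_one$values), sum(st$features$platform == "HILICpos"))
  expect_error(compute_fold_changes(st, platforms = "NMR1D"), "zero features")
})

test_that("subjects lacking a timepoint are dropped from the fold-change matrix", {
  suppressWarnings(
    sim <- simulate_study(n_per_group = c(SAL = 4, GOP = 4, VLCD = 4, RYGB = 4),
                          n_features = 3L, seed = 9, n_missing_week4 = 3L))
  expect_message(fc <- compute_fold_changes(sim$study), "dropping 3 subject")
  expect_equal(nrow(fc$values), 13L)
})

test_that("PCA matches an eigendecomposition oracle and reconstructs the data", {
  set.seed(101)
  X <- matrix(rnorm(30 * 12), 30, 12)
  colnames(X) <- paste0("f", 1:12)
  rownames(X) <- paste0("s", 1:30)
  p <- run_pca(X, n_components = 12L)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc), symmetric = TRUE)$values
  expect_equal(p$explained_variance_ratio, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)

  # full-rank reconstruction and loading orthonormality
  expect_equal(max(abs(Xc - p$scores %*% t(p$loadings))), 0, tolerance = 1e-8)
  expect_equal(crossprod(p$loadings), diag(12L), tolerance = 1e-10,
               ignore_attr = TRUE)

  # deterministic sign convention: the dominant loading entry is positive
  for (k in 1:12) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
})

test_that("a rank-1 matrix loads a single component", {
  u <- rnorm(20); v <- rnorm(8)
  X <- tcrossprod(u, v)
  p <- run_pca(X, n_components = 3L)
  expect_gte(p$explained_variance_ratio[1L], 0.999)
})

test_that("PCA scores permute with subject rows", {
  sim <- tiny_sim(n_features = 20L, seed = 31)
  fc <- compute_fold_changes(sim$study)
  p1 <- run_pca(fc, n_components = 3L)
  perm <- sample(nrow(fc$values))
  fc2 <- fc
  fc2$values <- fc$values[perm, ]
  fc2$subjects <- fc$subjects[perm, ]
  p2 <- run_pca(fc2, n_components = 3L)
  expect_equal(p2$scores, p1$scores[perm, ], tolerance = 1e-8)
  expect_equal(p2$loadings, p1$loadings, tolerance = 1e-8)
})

test_that("constant features under UV scaling fall back to unit scale", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(p <- run_pca(X, n_components = 1L, preprocessing = "center_uv"),
                 "constant feature")
  expect_equal(unname(p$scale["b"] == 1), TRUE)
})

test_that("two-group score test reduces to the pooled t-test (F = t^2)", {
  set.seed(7)
  sim <- simulate_study(n_per_group = c(SAL = 6, GOP = 6, VLCD = 2, RYGB = 2),
                        n_features = 15L, seed = 7)
  fc <- compute_fold_changes(sim$study)
  keep <- fc$subjects$group %in% c("SAL", "GOP")
  fc$values <- fc$values[keep, ]; fc$subjects <- fc$subjects[keep, ]
  p <- run_pca(fc, n_components = 2L)
  st <- score_group_tests(p)
  sc <- p$scores[, 1L]
  g <- fc$subjects$group
  tt <- t.test(sc[g == "GOP"], sc[g == "SAL"], var.equal = TRUE)
  expect_equal(st$anova$F[1L], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("a strongly shifted group is flagged on every pairwise comparison", {
  sim <- tiny_sim(n_features = 40L, seed = 13,
                  effect = effect_spec(delta = cbind(
                    SAL = rep(0, 40), GOP = rep(0, 40),
                    VLCD = rep(c(3, -3), 20), RYGB = rep(0, 40))),
                  noise = noise_spec(sigma_resid = 0.1))
  fc <- compute_fold_changes(sim$study)
  p <- run_pca(fc, n_components = 2L)
  st <- score_group_tests(p)
  pw <- st$pairwise[st$pairwise$component == "PC1", ]
  vl <- pw[pw$group_a == "VLCD" | pw$group_b == "VLCD", ]
  expect_true(all(vl$p < 1e-4))
})

test_that("groups with fewer than 2 subjects are excluded with a warning", {
  sim <- simulate_study(n_per_group = c(SAL = 5, GOP = 5, VLCD = 5, RYGB = 2),
                        n_features = 10L, seed = 3)
  fc <- compute_fold_changes(sim$study)
  p <- run_pca(fc, n_components = 2L)
  groups <- fc$subjects$group
  groups[which(groups == "RYGB")[-1L]] <- "VLCD"  # leave a single RYGB subject
  expect_warning(st <- score_group_tests(p, groups = groups), "RYGB")
  expect_false("RYGB" %in% c(st$pairwise$group_a, st$pairwise$group_b))
})
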