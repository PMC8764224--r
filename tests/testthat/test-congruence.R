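test_that("group mean fold changes carry exact t-based confidence intervals", {
  sim <- tiny_sim(n_features = 4L, seed = 61)
  fc <- compute_fold_changes(sim$study)
  means <- mean_fold_changes(fc)

  g <- fc$subjects$group
  v <- fc$values[g == "VLCD", 2L]
  row <- means[means$group == "VLCD" &
                 means$feature_id == colnames(fc$values)[2L], ]
  expect_equal(row$mean, mean(v))
  half <- qt(0.975, length(v) - 1L) * sd(v) / sqrt(length(v))
  expect_equal(row$ci_upper - row$ci_lower, 2 * half)

  # all-zero fold changes give zero means with CIs containing zero
  null_sim <- simulate_study(
    n_per_group = c(SAL = 3, GOP = 3, VLCD = 3, RYGB = 3), n_features = 2L,
    effect = effect_spec(delta = matrix(0, 2L, 4L)),
    noise = noise_spec(sigma_subject = 0, sigma_resid = 0), seed = 2)
  m0 <- mean_fold_changes(compute_fold_changes(null_sim$study))
  expect_true(all(m0$mean == 0))
  expect_true(all(m0$ci_lower <= 0 & m0$ci_upper >= 0))
})

test_that("group means are equivariant under group relabelling", {
  sim <- tiny_sim(n_features = 3L, seed = 67)
  fc <- compute_fold_changes(sim$study)
  means <- mean_fold_changes(fc)
  fc2 <- fc
  swap <- c(SAL = "GOP", GOP = "SAL", VLCD = "RYGB", RYGB = "VLCD")
  fc2$subjects$group <- unname(swap[fc$subjects$group])
  means2 <- mean_fold_changes(fc2)
  for (grp in names(swap)) {
    a <- means[means$group == grp, "mean"]
    b <- means2[means2$group == swap[[grp]], "mean"]
    expect_equal(a, b)
  }
})

test_that("identical effect vectors give r = 1 and categories partition features", {
  delta <- matrix(0, 30L, 4L, dimnames = list(NULL, c("SAL", "GOP", "VLCD", "RYGB")))
  delta[, "VLCD"] <- delta[, "RYGB"] <- rep(c(1, -1, 0.5), 10L)
  sim <- simulate_study(n_features = 30L, seed = 71,
                        effect = effect_spec(delta = delta),
                        noise = noise_spec(sigma_subject = 0, sigma_resid = 0))
  fc <- compute_fold_changes(sim$study)
  means <- mean_fold_changes(fc)
  M <- means[means$group == "VLCD", "mean"]
  R <- means[means$group == "RYGB", "mean"]
  expect_equal(cor(M, R), 1, tolerance = 1e-12)

  # with noise, the report's pairwise r is symmetric and categories partition
  sim2 <- simulate_study(n_features = 30L, seed = 72,
                         effect = effect_spec(delta = delta))
  fc2 <- compute_fold_changes(sim2$study)
  scan <- lme_scan(sim2$study)
  rep <- pairwise_congruence(mean_fold_changes(fc2), scan)
  expect_equal(nrow(rep$pairwise), 6L)
  expect_equal(nrow(rep$categories), 30L)
  expect_true(all(rep$categories$category %in%
                    c("shared", "unique_GOP", "unique_VLCD", "unique_RYGB",
                      "nonsignificant")))
  # effects identical in both arms: no feature should be unique to one of them
  expect_gt(sum(rep$categories$category == "shared"), 0L)
})

test_that("disjoint effects produce non-overlapping unique categories", {
  delta <- matrix(0, 40L, 4L, dimnames = list(NULL, c("SAL", "GOP", "VLCD", "RYGB")))
  delta[1:8, "VLCD"] <- 2
  delta[9:16, "RYGB"] <- -2
  sim <- simulate_study(n_features = 40L, seed = 73,
                        effect = effect_spec(delta = delta),
                        noise = noise_spec(sigma_resid = 0.15))
  fc <- compute_fold_changes(sim$study)
  scan <- lme_scan(sim$study)
  rep <- pairwise_congruence(mean_fold_changes(fc), scan)
  cats <- rep$categories
  uv <- cats$feature_id[cats$category == "unique_VLCD"]
  ur <- cats$feature_id[cats$category == "unique_RYGB"]
  expect_length(intersect(uv, ur), 0L)
  # uniquely-significant sets recover the disjoint truth (an occasional false
  # positive on the other arm moves a feature to "shared", never across)
  expect_true(all(uv %in% sprintf("feat_%04d", 1:8)))
  expect_true(all(ur %in% sprintf("feat_%04d", 9:16)))
  expect_gte(length(uv), 6L)
  expect_gte(length(ur), 6L)
  expect_true(all(cats$category[match(sprintf("feat_%04d", 17:40),
                                      cats$feature_id)] == "nonsignificant"))
})

test_that("clinical correlations recover an injected verbatim factor", {
  sim <- tiny_sim(n_features = 3L, seed = 79)
  fc <- compute_fold_changes(sim$study)
  clin <- sim$study$clinical
  # inject the weight delta verbatim as a feature's fold change
  fc$values[, 1L] <- clin$delta_weight[match(fc$subjects$subject_id,
                                             clin$subject_id)]
  cc <- clinical_correlations(fc, clin, factors = "delta_weight")
  row <- cc[cc$feature_id == colnames(fc$values)[1L], ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$display)
})

test_that("per-group scope and zero-variance factors are handled", {
  sim <- tiny_sim(n_features = 2L, seed = 83)
  fc <- compute_fold_changes(sim$study)
  clin <- sim$study$clinical
  cc <- clinical_correlations(fc, clin, factors = "delta_weight",
                              scope = "per-group")
  expect_setequal(unique(cc$scope_group), c("SAL", "GOP", "VLCD", "RYGB"))

  clin$delta_weight <- 0
  expect_warning(cc0 <- clinical_correlations(fc, clin, factors = "delta_weight"),
                 "zero-variance")
  expect_true(all(is.na(cc0$r)))
})

test_that("null-feature correlations flag about five percent at p < 0.05", {
  sim <- simulate_study(n_features = 400L, seed = 89,
                        effect = effect_spec(delta = matrix(0, 400L, 4L)))
  fc <- compute_fold_changes(sim$study)
  cc <- clinical_correlations(fc, sim$study$clinical, factors = "delta_weight")
  rate <- mean(cc$display)
  expect_lt(abs(rate - 0.05), 0.03)
})
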