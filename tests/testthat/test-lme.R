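test_that("zero-noise null data give zero interaction coefficients", {
  sim <- simulate_study(
    n_per_group = c(SAL = 3, GOP = 3, VLCD = 3, RYGB = 3), n_features = 2L,
    effect = effect_spec(delta = matrix(0, 2L, 4L)),
    noise = noise_spec(sigma_subject = 0.4, sigma_resid = 0), seed = 6)
  fit <- fit_lme(log(sim$study$values[, 1L]), sim$study$samples,
                 method = "profile")
  ints <- fit$beta[grep("^week4\\.group", names(fit$beta))]
  expect_equal(unname(ints), rep(0, 3), tolerance = 1e-10)
})

test_that("balanced interaction contrast equals the difference of group mean paired log changes", {
  sim <- tiny_sim(n_features = 3L, seed = 17)
  st <- sim$study
  y <- log(st$values[, 2L])
  fit <- fit_lme(y, st$samples)
  ct <- interaction_contrasts(fit, "vs-sal")

  s <- st$samples
  base <- s$timepoint == "baseline"
  dd <- y[!base][match(s$subject_id[base], s$subject_id[!base])] - y[base]
  g <- s$group[base]
  for (grp in c("GOP", "VLCD", "RYGB")) {
    expect_equal(ct$estimate[ct$group_a == grp],
                 mean(dd[g == grp]) - mean(dd[g == "SAL"]),
                 tolerance = 1e-8)
  }
})

test_that("closed-form and profiled REML agree on balanced data to 1e-8", {
  for (seed in 1:5) {
    sim <- tiny_sim(n_features = 1L, seed = seed)
    y <- log(sim$study$values[, 1L])
    f_cf <- fit_lme(y, sim$study$samples, method = "auto")
    f_pr <- fit_lme(y, sim$study$samples, method = "profile")
    expect_lt(max(abs(f_cf$beta - f_pr$beta)), 1e-8)
    expect_lt(abs(f_cf$sigma2_subject - f_pr$sigma2_subject), 1e-8)
    expect_lt(abs(f_cf$sigma2_resid - f_pr$sigma2_resid), 1e-8)
  }
})

test_that("REML estimates match a brute-force GLS lambda-grid oracle", {
  # balanced and unbalanced small fixtures, <= 20 subjects
  sim <- simulate_study(n_per_group = c(SAL = 5, GOP = 4, VLCD = 6, RYGB = 5),
                        n_features = 2L, seed = 23)
  y <- log(sim$study$values[, 1L])
  fit <- fit_lme(y, sim$study$samples)
  oracle <- gls_reml_oracle(y, sim$study$samples)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$sigma2_subject, oracle$sigma2_subject, tolerance = 1e-6)
  expect_equal(fit$sigma2_resid, oracle$sigma2_resid, tolerance = 1e-6)

  suppressWarnings(
    sim2 <- simulate_study(n_per_group = c(SAL = 5, GOP = 4, VLCD = 6, RYGB = 5),
                           n_features = 2L, seed = 24, n_missing_week4 = 3L))
  y2 <- log(sim2$study$values[, 2L])
  fit2 <- fit_lme(y2, sim2$study$samples)
  oracle2 <- gls_reml_oracle(y2, sim2$study$samples)
  expect_equal(unname(fit2$beta), unname(oracle2$beta), tolerance = 1e-6)
  expect_equal(fit2$sigma2_subject, oracle2$sigma2_subject, tolerance = 1e-6)
  expect_equal(fit2$sigma2_resid, oracle2$sigma2_resid, tolerance = 1e-6)
})

test_that("fits agree with lme4 on fixed effects, variances and vcov", {
  suppressWarnings(
    sim <- simulate_study(n_per_group = c(SAL = 5, GOP = 5, VLCD = 5, RYGB = 5),
                          n_features = 2L, seed = 25, n_missing_week4 = 2L))
  st <- sim$study
  y <- log(st$values[, 1L])
  fit <- fit_lme(y, st$samples)
  d <- data.frame(y = y, tp = st$samples$timepoint,
                  g = factor(st$samples$group,
                             levels = c("SAL", "GOP", "VLCD", "RYGB")),
                  subj = st$samples$subject_id)
  m <- lme4::lmer(y ~ tp * g + (1 | subj), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(fit$sigma2_subject, vc$vcov[1L], tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, vc$vcov[2L], tolerance = 1e-6)
  expect_equal(unname(fit$vcov_beta), unname(as.matrix(vcov(m))),
               tolerance = 1e-5)
})

test_that("contrasts are antisymmetric and reject absent groups", {
  sim <- tiny_sim(n_features = 1L, seed = 19)
  fit <- fit_lme(log(sim$study$values[, 1L]), sim$study$samples)
  ab <- interaction_contrasts(fit, list(c("VLCD", "GOP")))
  ba <- interaction_contrasts(fit, list(c("GOP", "VLCD")))
  expect_identical(ab$estimate, -ba$estimate)
  expect_identical(ab$se, ba$se)
  expect_error(interaction_contrasts(fit, list(c("VLCD", "SHAM"))), "absent")
})

test_that("estimates are invariant to row permutation and feature rescaling", {
  sim <- tiny_sim(n_features = 1L, seed = 29)
  st <- sim$study
  y <- log(st$values[, 1L])
  fit <- fit_lme(y, st$samples)

  perm <- sample(length(y))
  fit_p <- fit_lme(y[perm], st$samples[perm, ], method = "profile")
  expect_equal(fit_p$beta, fit$beta, tolerance = 1e-7)

  # multiplying intensities by a constant shifts only the intercept
  fit_s <- fit_lme(log(10 * st$values[, 1L]), st$samples)
  expect_equal(fit_s$beta[["(Intercept)"]], fit$beta[["(Intercept)"]] + log(10),
               tolerance = 1e-8)
  expect_equal(fit_s$beta[-1L], fit$beta[-1L], tolerance = 1e-8)
})

test_that("BH q-values follow the step-up definition, with NA propagation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, NA, 0.04, 0.9)
  q <- bh_fdr(p)
  expect_true(is.na(q[2L]))
  expect_equal(q[-2L], bh_stepup_oracle(p[-2L]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("vs-SAL contrast p-values are uniform under the null", {
  sim <- simulate_study(n_features = 1000L, seed = 37,
                        effect = effect_spec(delta = matrix(0, 1000L, 4L)))
  scan <- lme_scan(sim$study)
  pv <- scan$contrasts$p[scan$contrasts$group_a == "VLCD"]
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the vectorised balanced scan equals per-feature fits", {
  sim <- tiny_sim(n_features = 4L, seed = 41)
  scan <- lme_scan(sim$study)
  for (j in 1:4) {
    fit <- fit_lme(log(sim$study$values[, j]), sim$study$samples)
    ct <- interaction_contrasts(fit, "vs-sal")
    sub <- scan$contrasts[scan$contrasts$feature_id ==
                            sim$study$features$feature_id[j], ]
    expect_equal(sub$estimate, ct$estimate, tolerance = 1e-8)
    expect_equal(sub$se, ct$se, tolerance = 1e-8)
    expect_equal(sub$p, ct$p, tolerance = 1e-8)
  }
})

test_that("a zero covariate reproduces the unadjusted fit", {
  sim <- tiny_sim(n_features = 1L, seed = 43)
  st <- sim$study
  y <- log(st$values[, 1L])
  f0 <- fit_lme(y, st$samples, method = "profile")
  suppressWarnings(f1 <- fit_lme(y, st$samples,
                                 covariate = rep(0, nrow(st$samples))))
  expect_equal(f1$beta[names(f0$beta)], f0$beta, tolerance = 1e-10)
  expect_equal(f1$sigma2_resid, f0$sigma2_resid, tolerance = 1e-10)
})

test_that("the adjusted design adds four three-way columns of full rank", {
  sim <- tiny_sim(n_features = 1L, seed = 47)
  st <- sim$study
  cov_vec <- st$clinical$delta_weight[match(st$samples$subject_id,
                                            st$clinical$subject_id)]
  d <- metaboresponse:::lme_design_frame(st$samples)
  X0 <- metaboresponse:::lme_model_matrix(d)
  X1 <- metaboresponse:::lme_model_matrix(d, covariate = cov_vec)
  expect_equal(ncol(X0), 8L)
  expect_equal(ncol(X1), 12L)
  expect_equal(qr(X1)$rank, 12L)
})

test_that("a purely weight-driven feature loses vs-SAL significance under adjustment", {
  # feature 1 responds only to weight change; group means differ in weight,
  # so the unadjusted contrast confounds treatment with weight loss
  hits_unadj <- 0L; hits_adj <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_study(
      n_features = 5L, seed = 600L + s,
      effect = effect_spec(delta = matrix(0, 5L, 4L)),
      noise = noise_spec(sigma_resid = 0.2),
      clinical_link = data.frame(feature_id = "feat_0001",
                                 factor = "delta_weight", slope = 0.12))
    un <- lme_scan(sim$study)
    ad <- suppressWarnings(lme_scan(sim$study, covariate = "delta_weight"))
    p_un <- un$contrasts$p[un$contrasts$feature_id == "feat_0001" &
                             un$contrasts$group_a == "RYGB"]
    p_ad <- ad$contrasts$p[ad$contrasts$feature_id == "feat_0001" &
                             ad$contrasts$group_a == "RYGB"]
    hits_unadj <- hits_unadj + (p_un < 0.05)
    hits_adj <- hits_adj + (p_ad < 0.05)
  }
  expect_gte(hits_unadj, 8L)
  expect_lte(hits_adj, 4L)
  # and the flagging helper reports exactly those features
  sens <- confounder_sensitivity(un, ad)
  expect_true(all(c("q_unadjusted", "q_adjusted", "confounder_sensitive")
                  %in% names(sens)))
})

test_that("power simulation brackets the observed count and vanishes under the null", {
  delta <- matrix(0, 40L, 4L, dimnames = list(NULL, study_groups()))
  delta[1:12, "GOP"] <- 0.3
  sim <- simulate_study(n_features = 40L, seed = 53,
                        effect = effect_spec(delta = delta),
                        noise = noise_spec(sigma_resid = 0.25))
  scan <- lme_scan(sim$study)
  obs <- sum(scan$contrasts$q[scan$contrasts$group_a == "GOP"] < 0.05)
  ps <- power_simulation(sim$study, target_n = 14L, B = 30L, seed = 2)
  expect_gte(obs, ps$interval[[1L]])
  expect_lte(obs, ps$interval[[2L]])

  ps_big <- power_simulation(sim$study, target_n = 28L, B = 30L, seed = 2)
  expect_gt(ps_big$mean, ps$mean)   # power grows with the arm size

  # all-null data at the current arm size: resamples stay non-significant
  sim0 <- simulate_study(n_features = 40L, seed = 54,
                         effect = effect_spec(delta = matrix(0, 40L, 4L)))
  ps0 <- power_simulation(sim0$study, target_n = 14L, B = 20L, seed = 3)
  expect_lt(ps0$mean, 1)
  expect_error(power_simulation(sim$study, target_n = 5L, B = 10L, seed = 1),
               "below the current")
})
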