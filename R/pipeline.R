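#' Default pipeline configuration
#'
#' Returns the default configuration list consumed by [run_pipeline()]:
#' either a `simulate` block (the default study: arm sizes 11/14/22/21, 500
#' features, caloric-restriction template effects) or an `input` block of
#' CSV paths; platform groupings; the FDR level; and the PLS block
#' (`B = 1000` permutations, validity thresholds `q2 > 0.15` and
#' `perm_p < 0.01`, 7-fold CV). All randomness flows from the single root
#' `seed` via fixed per-stage offsets.
#'
#' @param seed root seed.
#' @param out_dir output directory.
#' @return named list, to be edited and passed to [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out_dir = "metaboresponse_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_features = 500L, template = TRUE, rho = 0.9,
                    frac_affected = 1 / 3),
    input = NULL,
    biofluid = "plasma",
    groupings = NULL,  # NULL = one grouping over all platforms present
    alpha = 0.05,
    contrasts = "vs-sal",
    pca = list(n_components = 5L, preprocessing = "center"),
    pls = list(enabled = TRUE, factor = "delta_weight", B = 1000L,
               folds = 7L, q2_threshold = 0.15, perm_p_threshold = 0.01,
               max_components = 5L)
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_config()
  out <- utils::modifyList(base, config)
  # an explicit input block replaces the default simulate block
  if (!is.null(config$input)) out$simulate <- NULL
  out
}

validate_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config must provide either a 'simulate' or an 'input' block")
  }
  if (!is.null(cfg$pls) && isTRUE(cfg$pls$enabled)) {
    if (!is.null(cfg$input) && is.null(cfg$input$clinical_csv)) {
      stop("PLS stage requested but no clinical table configured")
    }
    stopifnot(cfg$pls$B > 0, cfg$pls$q2_threshold > 0,
              cfg$pls$perm_p_threshold > 0)
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

write_stage_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Config-driven orchestration of simulate/read -> fold-change PCA -> mixed
#' models -> PLS -> congruence -> chain matching, writing every stage output
#' as CSV into `out_dir` plus a `report.md` summary. Every output file starts
#' with a comment line carrying the config hash and the seed, and two runs
#' with identical config and seed produce byte-identical outputs.
#'
#' @param config a configuration list as produced by [default_config()], or a
#'   path to a YAML file with the same structure.
#' @return Invisibly, a list with the in-memory stage results (`study`,
#'   `truth`, `fold_changes`, `pca`, `score_tests`, `lme`, `summary`, `pls`,
#'   `congruence`, `clinical_corr`, `matches`, `covariation`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(read_config(config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  # hash the analysis-relevant configuration (the output location does not
  # change any result, so it is excluded from the provenance hash)
  hash_path <- tempfile()
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], hash_path)
  cfg_hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  hdr <- paste0("# metaboresponse config_hash=", cfg_hash, " seed=", cfg$seed)
  out <- list(out_dir = cfg$out_dir)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  ## stage: study -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    n_feat <- sim_cfg$n_features %||% 500L
    features <- synthetic_feature_table(n_feat)
    eff <- if (isTRUE(sim_cfg$template)) {
      caloric_restriction_template(features)
    } else {
      effect_spec(congruence_rho = sim_cfg$rho %||% 0.9,
                  frac_affected = sim_cfg$frac_affected %||% 1 / 3)
    }
    n_per_group <- unlist(sim_cfg$n_per_group %||% default_group_sizes())
    sim <- simulate_study(n_per_group = n_per_group, n_features = n_feat,
                          effect = eff, features = features,
                          seed = cfg$seed, biofluid = cfg$biofluid)
    study <- sim$study
    out$truth <- sim$truth
    note("simulated study: ", nrow(study$values), " samples x ", n_feat,
         " features, seed ", cfg$seed)
  } else {
    study <- do.call(read_study, cfg$input)
    note("read study from ", cfg$input$feature_csv)
  }
  out$study <- study

  groupings <- cfg$groupings %||%
    stats::setNames(list(unique(study$features$platform)), "all")

  ## stage: fold-change PCA -------------------------------------------------
  fcs <- lapply(names(groupings), function(gn) {
    compute_fold_changes(study, platforms = groupings[[gn]],
                         biofluid = cfg$biofluid, grouping_label = gn)
  })
  names(fcs) <- names(groupings)
  out$fold_changes <- fcs
  out$pca <- list(); out$score_tests <- list()
  for (gn in names(fcs)) {
    pca <- run_pca(fcs[[gn]], n_components = cfg$pca$n_components,
                   preprocessing = cfg$pca$preprocessing)
    st <- score_group_tests(pca)
    out$pca[[gn]] <- pca; out$score_tests[[gn]] <- st
    write_stage_csv(data.frame(subject_id = rownames(pca$scores), pca$scores,
                               grouping = gn),
                    file.path(cfg$out_dir, paste0("scores_", gn, ".csv")), hdr)
    write_stage_csv(data.frame(feature_id = rownames(pca$loadings),
                               pca$loadings, grouping = gn),
                    file.path(cfg$out_dir, paste0("loadings_", gn, ".csv")), hdr)
    write_stage_csv(data.frame(component = colnames(pca$scores),
                               explained_variance_ratio =
                                 pca$explained_variance_ratio, grouping = gn),
                    file.path(cfg$out_dir, paste0("explained_variance_", gn, ".csv")),
                    hdr)
    write_stage_csv(cbind(st$pairwise, grouping = gn),
                    file.path(cfg$out_dir, paste0("score_tests_", gn, ".csv")), hdr)
  }

  ## stage: mixed models ----------------------------------------------------
  out$lme <- list(); summaries <- list()
  for (gn in names(groupings)) {
    scan <- lme_scan(study, platforms = groupings[[gn]],
                     biofluid = cfg$biofluid, contrasts = cfg$contrasts,
                     alpha = cfg$alpha)
    out$lme[[gn]] <- scan
    write_stage_csv(scan$contrasts,
                    file.path(cfg$out_dir, paste0("contrasts_", gn, ".csv")), hdr)
    summaries[[gn]] <- cbind(percent_significant(scan, cfg$alpha),
                             grouping = gn)
    if (length(scan$diagnostics)) {
      note("lme diagnostics [", gn, "]: ",
           paste(scan$diagnostics, collapse = "; "))
    }
  }
  out$summary <- do.call(rbind, summaries)
  write_stage_csv(out$summary, file.path(cfg$out_dir, "summary.csv"), hdr)

  ## stage: PLS -------------------------------------------------------------
  if (isTRUE(cfg$pls$enabled)) {
    if (is.null(study$clinical)) stop("PLS stage: study has no clinical table")
    fc1 <- fcs[[1L]]
    yv <- study$clinical[[cfg$pls$factor]][match(fc1$subjects$subject_id,
                                                 study$clinical$subject_id)]
    X <- fc1$values
    strata <- fc1$subjects$group
    pick <- choose_n_components(X, yv, max_components = cfg$pls$max_components,
                                folds = cfg$pls$folds, seed = cfg$seed + 101L,
                                strata = strata)
    model <- fit_pls(X, yv, n_components = pick$n_components)
    report <- permutation_validity(X, yv, model, B = cfg$pls$B,
                                   seed = cfg$seed + 102L,
                                   folds = cfg$pls$folds,
                                   q2_threshold = cfg$pls$q2_threshold,
                                   perm_p_threshold = cfg$pls$perm_p_threshold,
                                   strata = strata)
    out$pls <- list(model = model, report = report,
                    n_components = pick$n_components)
    write_stage_csv(data.frame(scope = "full-cohort", factor = cfg$pls$factor,
                               n_components = pick$n_components,
                               r2y = model$r2y, q2y = report$q2y,
                               perm_p = report$perm_p, valid = report$valid),
                    file.path(cfg$out_dir, "pls_models.csv"), hdr)
    write_stage_csv(report$features,
                    file.path(cfg$out_dir, "pls_selected.csv"), hdr)
    note("pls [", cfg$pls$factor, "]: q2y=", signif(report$q2y, 4),
         " perm_p=", signif(report$perm_p, 4), " valid=", report$valid)
  }

  ## stage: congruence ------------------------------------------------------
  means <- mean_fold_changes(fcs[[1L]])
  cong <- pairwise_congruence(means, out$lme[[1L]], alpha = cfg$alpha)
  out$means <- means
  out$congruence <- cong
  write_stage_csv(cong$pairwise, file.path(cfg$out_dir, "congruence.csv"), hdr)
  write_stage_csv(cong$categories, file.path(cfg$out_dir, "categories.csv"), hdr)
  if (!is.null(study$clinical)) {
    cc <- clinical_correlations(fcs[[1L]], study$clinical)
    out$clinical_corr <- cc
    write_stage_csv(cc, file.path(cfg$out_dir, "clinical_corr.csv"), hdr)
  }

  ## stage: chain matching --------------------------------------------------
  matches <- build_matches(study)
  out$matches <- matches
  write_stage_csv(matches, file.path(cfg$out_dir, "matches.csv"), hdr)
  if (nrow(matches)) {
    cov <- match_covariation(matches, means)
    out$covariation <- cov
    write_stage_csv(cov$class_r, file.path(cfg$out_dir, "covariation.csv"), hdr)
  }

  ## report -----------------------------------------------------------------
  rpt <- c(paste0("# Pipeline report (config ", cfg_hash, ", seed ", cfg$seed, ")"),
           "", "## Percent significant per grouping and pair", "",
           utils::capture.output(print(out$summary, row.names = FALSE)),
           "", "## Fold-change congruence (Pearson r)", "",
           utils::capture.output(print(cong$pairwise, row.names = FALSE)))
  if (!is.null(out$pls)) {
    rpt <- c(rpt, "", "## PLS validity", "",
             paste0("factor=", cfg$pls$factor,
                    " q2y=", signif(out$pls$report$q2y, 4),
                    " perm_p=", signif(out$pls$report$perm_p, 4),
                    " valid=", out$pls$report$valid,
                    " selected=", sum(out$pls$report$features$selected)))
  }
  writeLines(rpt, file.path(cfg$out_dir, "report.md"))
  writeLines(c(hdr, log_lines), logf)
  invisible(out)
}
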