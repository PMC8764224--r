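#' Per-subject log2 fold changes
#'
#' For each subject with both timepoints present in the requested biofluid,
#' computes `log2(week4) - log2(baseline)` for every feature in the platform
#' grouping. Subjects missing either timepoint are dropped with a message;
#' cells where either intensity is missing are `NA`.
#'
#' @param x a [metabo_study()].
#' @param platforms character vector of platform labels to include; `NULL`
#'   selects every platform present.
#' @param biofluid which biofluid to use.
#' @param grouping_label optional name recorded on the result (e.g.
#'   `"plasma UPLC-MS"` for the combined lipid RPC+/RPC-/HILIC+ grouping).
#' @return A `fold_change_matrix`: list with `values` (subjects x features
#'   matrix of log2 fold changes), `subjects` (data.frame with `subject_id`,
#'   `group`) and `grouping`.
#' @export
compute_fold_changes <- function(x, platforms = NULL, biofluid = "plasma",
                                 grouping_label = NULL) {
  stopifnot(inherits(x, "metabo_study"))
  keep_f <- if (is.null(platforms)) rep(TRUE, nrow(x$features)) else
    x$features$platform %in% platforms
  if (!any(keep_f)) stop("platform grouping selects zero features")

  s <- x$samples
  in_bf <- s$biofluid == biofluid
  base_idx <- which(in_bf & s$timepoint == "baseline")
  wk4_idx <- which(in_bf & s$timepoint == "week4")
  subj <- intersect(s$subject_id[base_idx], s$subject_id[wk4_idx])
  dropped <- setdiff(unique(s$subject_id[in_bf]), subj)
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " subject(s) without both timepoints: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  if (length(subj) < 2L) stop("need paired samples for at least 2 subjects")

  b <- base_idx[match(subj, s$subject_id[base_idx])]
  w <- wk4_idx[match(subj, s$subject_id[wk4_idx])]
  fc <- log2(x$values[w, keep_f, drop = FALSE]) -
    log2(x$values[b, keep_f, drop = FALSE])
  rownames(fc) <- subj

  structure(
    list(values = fc,
         subjects = data.frame(subject_id = subj,
                               group = s$group[b],
                               stringsAsFactors = FALSE),
         grouping = grouping_label %||%
           paste(sort(unique(x$features$platform[keep_f])), collapse = "+")),
    class = "fold_change_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis of a fold-change matrix
#'
#' Thin-SVD PCA with a choice of preprocessing: mean-centering only (the
#' default, the minimal valid choice), unit-variance scaling (`center_uv`) or
#' Pareto scaling (`center_pareto`, dividing by the square root of the SD).
#' Missing cells are imputed by the feature-wise mean for this stage only and
#' flagged in the result. A feature that is constant under UV scaling has its
#' scale set to 1 with a warning. Component signs follow a deterministic
#' convention: the largest-magnitude loading element of each component is
#' positive. Explained-variance ratios are computed against the total variance
#' of the preprocessed matrix, so they are non-increasing and sum to at most 1
#' for truncated decompositions.
#'
#' @param fc a [compute_fold_changes()] result (or any numeric matrix with
#'   subjects in rows).
#' @param n_components number of components; default `min(10, rank bound)`.
#' @param preprocessing one of `"center"`, `"center_uv"`, `"center_pareto"`.
#' @return A `pca_result`: list with `scores`, `loadings`,
#'   `explained_variance_ratio`, `preprocessing`, `center`, `scale`,
#'   `imputed` (logical), `subjects`.
#' @export
run_pca <- function(fc, n_components = NULL,
                    preprocessing = c("center", "center_uv", "center_pareto")) {
  preprocessing <- match.arg(preprocessing)
  X <- if (inherits(fc, "fold_change_matrix")) fc$values else as.matrix(fc)
  subjects <- if (inherits(fc, "fold_change_matrix")) fc$subjects else NULL

  imputed <- anyNA(X)
  if (imputed) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j])
    }
  }
  if (anyNA(X)) stop("fold-change matrix has features with no observed values")

  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- rep(1, ncol(X))
  if (preprocessing != "center") {
    sds <- apply(Xc, 2L, stats::sd)
    const <- sds == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s); scale set to 1")
      sds[const] <- 1
    }
    scl <- if (preprocessing == "center_uv") sds else sqrt(sds)
    Xc <- sweep(Xc, 2L, scl, "/")
  }

  rank_bound <- min(nrow(Xc) - 1L, ncol(Xc))
  if (is.null(n_components)) n_components <- min(10L, rank_bound)
  if (n_components > rank_bound) {
    stop("n_components exceeds min(n_subjects - 1, n_features) = ", rank_bound)
  }

  sv <- svd(Xc, nu = n_components, nv = n_components)
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(n_components)) {
    i_max <- which.max(abs(sv$v[, k]))
    if (sv$v[i_max, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), colnames(scores))

  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
         preprocessing = preprocessing, center = ctr, scale = scl,
         imputed = imputed, subjects = subjects),
    class = "pca_result"
  )
}

#' Per-component group tests on PCA scores
#'
#' For each component, runs a one-way ANOVA of the scores over treatment
#' groups plus all pairwise Welch t-tests, with Benjamini-Hochberg adjustment
#' of the pairwise p-values within each component. Groups with fewer than two
#' subjects are excluded with a warning.
#'
#' @param p a [run_pca()] result.
#' @param groups group labels per score row; defaults to the subject table
#'   carried on the PCA result.
#' @return list with `anova` (component, F, p) and `pairwise` (component,
#'   group_a, group_b, t, p, q) data.frames, plus a `method` string recorded
#'   for auditability.
#' @export
score_group_tests <- function(p, groups = NULL) {
  stopifnot(inherits(p, "pca_result"))
  if (is.null(groups)) {
    if (is.null(p$subjects)) stop("no group labels available")
    groups <- p$subjects$group
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(p$scores))

  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 subjects: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    groups <- groups[keep]
    p$scores <- p$scores[keep, , drop = FALSE]
  }
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")

  g <- factor(groups)
  pairs <- utils::combn(levels(g), 2L)
  av_rows <- vector("list", ncol(p$scores))
  pw_rows <- vector("list", ncol(p$scores))
  for (k in seq_len(ncol(p$scores))) {
    sc <- p$scores[, k]
    fit <- stats::anova(stats::lm(sc ~ g))
    av_rows[[k]] <- data.frame(component = colnames(p$scores)[k],
                               F = fit[["F value"]][1L],
                               p = fit[["Pr(>F)"]][1L])
    pp <- apply(pairs, 2L, function(pr) {
      tt <- stats::t.test(sc[g == pr[1L]], sc[g == pr[2L]])
      c(t = unname(tt$statistic), p = tt$p.value)
    })
    pw_rows[[k]] <- data.frame(component = colnames(p$scores)[k],
                               group_a = pairs[1L, ], group_b = pairs[2L, ],
                               t = pp["t", ], p = pp["p", ],
                               q = stats::p.adjust(pp["p", ], method = "BH"))
  }
  list(anova = do.call(rbind, av_rows),
       pairwise = do.call(rbind, pw_rows),
       method = "one-way ANOVA + pairwise Welch t, BH within component")
}
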