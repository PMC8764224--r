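#' Per-feature per-group mean log2 fold changes with 95% CIs
#'
#' Group mean of the per-subject log2 fold changes for every feature, with a
#' t-based 95% confidence interval (`mean +/- t[0.975, n-1] * sd / sqrt(n)`).
#'
#' @param fc a [compute_fold_changes()] result.
#' @param conf confidence level.
#' @return data.frame with `feature_id`, `group`, `n`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`.
#' @export
mean_fold_changes <- function(fc, conf = 0.95) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  g <- fc$subjects$group
  tab <- table(g)
  if (any(tab < 2L)) {
    stop("need at least 2 subjects per group: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  rows <- lapply(names(tab), function(grp) {
    V <- fc$values[g == grp, , drop = FALSE]
    n <- colSums(!is.na(V))
    m <- colMeans(V, na.rm = TRUE)
    s <- apply(V, 2L, stats::sd, na.rm = TRUE)
    half <- stats::qt(1 - (1 - conf) / 2, n - 1L) * s / sqrt(n)
    data.frame(feature_id = colnames(V), group = grp, n = n, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Cross-intervention congruence of mean fold changes
#'
#' Computes Pearson correlations between the mean log2 fold-change vectors of
#' every intervention pair, and categorises each feature by where its vs-SAL
#' contrasts reach significance: `shared` when both VLCD and RYGB pass
#' `q < alpha`, `unique_<X>` when exactly one arm passes, `nonsignificant`
#' otherwise. Within-category correlations between the VLCD and RYGB means
#' are reported as well (NA when a category holds fewer than 3 features).
#'
#' @param means a [mean_fold_changes()] table.
#' @param lme_result an [lme_scan()] result (or its `contrasts` data.frame)
#'   providing vs-SAL q-values for the same features.
#' @param alpha FDR threshold for the categorisation.
#' @return A `congruence_report`: list with `pairwise` (group_a, group_b, r,
#'   p, n), `categories` (feature_id, category), and `subset_r` (per-category
#'   VLCD-RYGB correlation).
#' @export
pairwise_congruence <- function(means, lme_result, alpha = 0.05) {
  ct <- if (is.data.frame(lme_result)) lme_result else lme_result$contrasts
  M <- stats::reshape(means[, c("feature_id", "group", "mean")],
                      idvar = "feature_id", timevar = "group",
                      direction = "wide")
  names(M) <- sub("^mean\\.", "", names(M))
  groups <- intersect(study_groups(), names(M))

  pairs <- utils::combn(groups, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- M[[pairs[1L, i]]]; b <- M[[pairs[2L, i]]]
    ok <- stats::complete.cases(a, b)
    tst <- stats::cor.test(a[ok], b[ok])
    data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
               r = unname(tst$estimate), p = tst$p.value, n = sum(ok))
  })
  pw <- do.call(rbind, pw)

  sig_for <- function(g) {
    sub <- ct[ct$group_a == g & ct$group_b == "SAL", ]
    out <- stats::setNames(rep(FALSE, nrow(M)), M$feature_id)
    hit <- !is.na(sub$q) & sub$q < alpha
    out[sub$feature_id[hit]] <- TRUE
    out
  }
  sig <- sapply(intersect(c("GOP", "VLCD", "RYGB"), unique(ct$group_a)), sig_for)
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = 1L,
                                       dimnames = list(M$feature_id, unique(ct$group_a)))
  n_sig <- rowSums(sig)
  category <- rep("nonsignificant", nrow(M))
  has <- function(g) g %in% colnames(sig)
  if (has("VLCD") && has("RYGB")) {
    category[sig[, "VLCD"] & sig[, "RYGB"]] <- "shared"
  }
  for (g in colnames(sig)) {
    category[sig[, g] & n_sig == 1L] <- paste0("unique_", g)
  }
  # >=2 significant arms not covered above (e.g. GOP+VLCD) count as shared
  category[n_sig >= 2L & category == "nonsignificant"] <- "shared"
  categories <- data.frame(feature_id = M$feature_id, category = category)

  subset_r <- NULL
  if (all(c("VLCD", "RYGB") %in% names(M))) {
    subset_r <- do.call(rbind, lapply(unique(category), function(cc) {
      idx <- category == cc
      r <- if (sum(idx) >= 3L) {
        stats::cor(M$VLCD[idx], M$RYGB[idx], use = "complete.obs")
      } else NA_real_
      data.frame(category = cc, n = sum(idx), r = r)
    }))
  }
  structure(list(pairwise = pw, categories = categories, subset_r = subset_r,
                 alpha = alpha),
            class = "congruence_report")
}

#' Per-feature correlations with clinical factors
#'
#' Pearson correlation of each feature's per-subject log2 fold change against
#' a clinical delta, across the whole cohort or within each treatment group.
#' P-values come from the t transform of r (two-sided, unadjusted, matching
#' the display convention of masking at `p < 0.05`); a BH-adjusted column is
#' included for stricter use.
#'
#' @param fc a [compute_fold_changes()] result.
#' @param clinical clinical table with `subject_id` plus delta columns.
#' @param factors clinical delta column names to correlate.
#' @param scope `"cohort"` or `"per-group"`.
#' @param display_alpha threshold for the `display` mask.
#' @return data.frame with `feature_id`, `factor`, `scope_group`, `n`, `r`,
#'   `p`, `q`, `display`.
#' @export
clinical_correlations <- function(fc, clinical,
                                  factors = c("delta_weight",
                                              "delta_fasting_glucose"),
                                  scope = c("cohort", "per-group"),
                                  display_alpha = 0.05) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  scope <- match.arg(scope)
  idx <- match(fc$subjects$subject_id, clinical$subject_id)
  if (anyNA(idx)) stop("clinical table missing subject(s): ",
                       paste(utils::head(fc$subjects$subject_id[is.na(idx)], 3L),
                             collapse = ", "))
  clin <- clinical[idx, , drop = FALSE]
  groups_of <- if (scope == "cohort") list(cohort = rep(TRUE, nrow(fc$values)))
  else {
    sapply(unique(fc$subjects$group),
           function(g) fc$subjects$group == g, simplify = FALSE)
  }

  out <- list()
  for (fac in factors) {
    if (!fac %in% names(clin)) stop("unknown clinical factor: ", fac)
    for (gname in names(groups_of)) {
      sel <- groups_of[[gname]]
      yv <- clin[[fac]][sel]
      if (sum(sel) < 4L) {
        warning("fewer than 4 subjects in scope '", gname, "'; skipped")
        next
      }
      if (stats::sd(yv, na.rm = TRUE) == 0) {
        warning("zero-variance factor '", fac, "' in scope '", gname, "'")
        r <- rep(NA_real_, ncol(fc$values)); p <- r
      } else {
        V <- fc$values[sel, , drop = FALSE]
        r <- suppressWarnings(stats::cor(V, yv, use = "pairwise.complete.obs"))[, 1L]
        n <- colSums(!is.na(V) & !is.na(yv))
        tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
        p <- 2 * stats::pt(-abs(tstat), n - 2)
        p[n < 3L] <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        feature_id = colnames(fc$values), factor = fac, scope_group = gname,
        n = sum(sel), r = r, p = p, q = bh_fdr(p),
        display = !is.na(p) & p < display_alpha, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
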