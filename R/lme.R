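## Random-intercept linear mixed models for paired intervention designs.
##
## Model per feature:  log(y) ~ timepoint * group + (1 | subject)
## Estimation is REML, profiled over the variance ratio
## lambda = sigma2_subject / sigma2_resid. Two paths:
##   - closed form for complete balanced pairs, via the between/within-subject
##     stratum decomposition (sums and differences per subject);
##   - general profiled REML, with per-subject Woodbury inversion of
##     V = I + lambda Z Z' and Brent optimisation over log(lambda).
## The two must agree to 1e-8 on balanced data (asserted in the test suite).

lme_design_frame <- function(samples) {
  data.frame(subject_id = samples$subject_id,
             group = factor(samples$group, levels = study_groups()),
             week4 = as.numeric(samples$timepoint == "week4"),
             stringsAsFactors = FALSE)
}

lme_model_matrix <- function(d, covariate = NULL) {
  g <- droplevels(d$group)
  X <- stats::model.matrix(~ week4 * g, data = data.frame(week4 = d$week4, g = g))
  colnames(X) <- sub("week4:g", "week4.group", colnames(X), fixed = TRUE)
  colnames(X) <- sub("^g(?=[A-Z])", "group", colnames(X), perl = TRUE)
  if (!is.null(covariate)) {
    for (lev in levels(g)) {
      col <- d$week4 * (g == lev) * covariate
      cand <- cbind(X, col)
      if (qr(cand)$rank <= qr(X)$rank) {
        warning("collinear covariate column for group ", lev, " dropped")
        next
      }
      X <- cand
      colnames(X)[ncol(X)] <- paste0("week4.group", lev, ".factor")
    }
  }
  X
}

## V(lambda)^{-1} A for block-diagonal V = I + lambda Z Z', subject blocks
vinv_mult <- function(A, subj_idx, m_per_subj, lambda) {
  A <- as.matrix(A)
  S <- rowsum(A, subj_idx, reorder = FALSE)
  w <- lambda / (1 + lambda * m_per_subj)
  A - w[match(subj_idx, rownames(S))] * S[match(subj_idx, rownames(S)), , drop = FALSE]
}

reml_pieces <- function(lambda, y, X, subj_idx, m_per_subj) {
  ViX <- vinv_mult(X, subj_idx, m_per_subj, lambda)
  Viy <- vinv_mult(y, subj_idx, m_per_subj, lambda)
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  beta <- solve(XtViX, XtViy)
  r <- y - drop(X %*% beta)
  Vir <- vinv_mult(r, subj_idx, m_per_subj, lambda)
  rss <- sum(r * Vir)
  n <- length(y)
  p <- ncol(X)
  logdetV <- sum(log1p(lambda * m_per_subj))
  logdetXtViX <- determinant(XtViX, logarithm = TRUE)$modulus
  sigma2 <- rss / (n - p)
  crit <- (n - p) * log(sigma2) + logdetV + as.numeric(logdetXtViX)
  list(beta = drop(beta), XtViX = XtViX, sigma2 = sigma2, crit = crit,
       loglik = -0.5 * (crit + (n - p) * (1 + log(2 * pi))))
}

#' Fit a random-intercept mixed model for one feature
#'
#' Fits `y ~ timepoint * group + (1 | subject)` (optionally with
#' timepoint:group:covariate three-way columns) by REML, profiling the
#' likelihood over the subject-to-residual variance ratio. For complete
#' balanced paired designs a closed-form stratum decomposition is used
#' (falling back to the iterative path at the boundary
#' `sigma2_subject = 0`); otherwise the profile is optimised by Brent search
#' over `log(lambda)` with per-subject Woodbury inversion.
#'
#' @param y numeric vector of log-scale responses, one per sample row of
#'   `design`. (Responses must be logged by the caller; see [lme_scan()].)
#' @param design data.frame with `subject_id`, `group`, `timepoint` columns
#'   (one row per sample), e.g. the `samples` table of a [metabo_study()].
#' @param covariate optional per-sample numeric covariate (a clinical delta,
#'   constant within subject) entering as timepoint:group:covariate columns.
#' @param method `"auto"` (default: closed form when balanced), `"profile"`,
#'   or `"closed_form"` (errors when the design is not balanced-complete).
#' @return An `lme_fit`: list with `beta`, `vcov_beta`, `sigma2_subject`,
#'   `sigma2_resid`, `df` (containment: subjects minus groups), `converged`,
#'   `boundary`, `reml_loglik`, `n_subjects`, `groups`, `method`.
#' @export
fit_lme <- function(y, design, covariate = NULL,
                    method = c("auto", "profile", "closed_form")) {
  method <- match.arg(method)
  d <- lme_design_frame(design)
  stopifnot(length(y) == nrow(d))
  ok <- !is.na(y)
  if (!all(ok)) {
    y <- y[ok]; d <- d[ok, , drop = FALSE]
    if (!is.null(covariate)) covariate <- covariate[ok]
  }
  d$group <- droplevels(d$group)
  if (nlevels(d$group) < 2L) stop("need at least 2 groups")
  n_subj <- length(unique(d$subject_id))
  if (n_subj < 4L) stop("need at least 4 subjects")

  obs_per_subj <- table(d$subject_id)
  tp_per_subj <- tapply(d$week4, d$subject_id, function(w) length(unique(w)))
  balanced <- all(obs_per_subj == 2L) && all(tp_per_subj == 2L) &&
    is.null(covariate)

  if (method == "closed_form" && !balanced) {
    stop("closed-form path requires a complete balanced paired design")
  }
  use_closed <- balanced && method != "profile"

  X <- lme_model_matrix(d, covariate)
  df_contain <- n_subj - nlevels(d$group)

  if (use_closed) {
    fit <- lme_closed_form(y, d, X)
    if (!is.null(fit)) return(fit)
    # boundary (sigma2_subject would be negative): fall through to profile
  }

  subj_idx <- d$subject_id
  m_per_subj <- as.vector(obs_per_subj[unique(subj_idx)])
  names(m_per_subj) <- unique(subj_idx)
  m_lookup <- m_per_subj

  crit_fun <- function(theta) {
    reml_pieces(exp(theta), y, X, subj_idx, m_lookup)$crit
  }
  at0 <- reml_pieces(0, y, X, subj_idx, m_lookup)
  opt <- stats::optimize(crit_fun, interval = c(-15, 15), tol = 1e-10)
  boundary <- at0$crit <= opt$objective
  lambda <- if (boundary) 0 else exp(opt$minimum)
  pieces <- if (boundary) at0 else reml_pieces(lambda, y, X, subj_idx, m_lookup)

  vcov_beta <- pieces$sigma2 * solve(pieces$XtViX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  structure(
    list(beta = stats::setNames(pieces$beta, colnames(X)),
         vcov_beta = vcov_beta,
         sigma2_subject = lambda * pieces$sigma2,
         sigma2_resid = pieces$sigma2,
         df = df_contain, converged = TRUE, boundary = boundary,
         reml_loglik = pieces$loglik, n_subjects = n_subj,
         groups = levels(d$group), method = "profile"),
    class = "lme_fit"
  )
}

## closed-form REML for complete balanced pairs via sum/difference strata;
## returns NULL when the between-subject variance estimate is negative
lme_closed_form <- function(y, d, X) {
  base_i <- which(d$week4 == 0)
  wk4_i <- which(d$week4 == 1)
  wk4_i <- wk4_i[match(d$subject_id[base_i], d$subject_id[wk4_i])]
  yb <- y[base_i]; yw <- y[wk4_i]
  g <- d$group[base_i]
  n <- length(yb); G <- nlevels(g)

  dd <- yw - yb
  uu <- yw + yb
  mean_d <- tapply(dd, g, mean)
  mean_b <- tapply(yb, g, mean)
  mean_u <- tapply(uu, g, mean)
  ss_d <- sum((dd - mean_d[g])^2)
  ss_u <- sum((uu - mean_u[g])^2)
  dfree <- n - G
  sigma2_e <- ss_d / (2 * dfree)
  sigma2_u <- ss_u / dfree              # estimates 2*sigma2_e + 4*sigma2_b
  sigma2_b <- (sigma2_u - 2 * sigma2_e) / 4
  if (sigma2_b < 0) return(NULL)

  levs <- levels(g)
  beta <- c(mean_b[[1L]], mean_d[[1L]],
            mean_b[-1L] - mean_b[[1L]],
            mean_d[-1L] - mean_d[[1L]])
  names(beta) <- c("(Intercept)", "week4",
                   paste0("group", levs[-1L]),
                   paste0("week4.group", levs[-1L]))
  beta <- beta[colnames(X)]

  lambda <- sigma2_b / sigma2_e
  subj_idx <- d$subject_id
  m <- stats::setNames(rep(2L, n), unique(subj_idx))
  ViX <- vinv_mult(X, subj_idx, m, lambda)
  vcov_beta <- sigma2_e * solve(crossprod(X, ViX))
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  pieces <- reml_pieces(lambda, y, X, subj_idx, m)
  structure(
    list(beta = beta, vcov_beta = vcov_beta,
         sigma2_subject = sigma2_b, sigma2_resid = sigma2_e,
         df = dfree, converged = TRUE, boundary = FALSE,
         reml_loglik = pieces$loglik, n_subjects = n, groups = levs,
         method = "closed_form"),
    class = "lme_fit"
  )
}

#' Wald interaction contrasts between treatment arms
#'
#' For each requested pair of groups, tests the difference of their
#' timepoint-by-group interaction coefficients (the difference in
#' within-subject log change between the arms). Wald t statistics use
#' containment degrees of freedom (subjects minus groups).
#'
#' @param fit an [fit_lme()] result.
#' @param pairs list of length-2 character vectors, or the shorthand
#'   `"vs-sal"` (each non-SAL group against SAL) or `"all-pairs"`.
#' @return data.frame with `group_a`, `group_b`, `estimate` (log scale of the
#'   response), `se`, `df`, `t`, `p`.
#' @export
interaction_contrasts <- function(fit, pairs = "vs-sal") {
  stopifnot(inherits(fit, "lme_fit"))
  if (!fit$converged) stop("fit did not converge")
  levs <- fit$groups
  if (identical(pairs, "vs-sal")) {
    pairs <- lapply(setdiff(levs, "SAL"), function(g) c(g, "SAL"))
  } else if (identical(pairs, "all-pairs")) {
    cmb <- utils::combn(levs, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[2:1, i])
  }
  ref <- levs[1L]
  coef_of <- function(g) {
    if (g == ref) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(1, paste0("week4.group", g))
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% levs)) stop("group(s) absent from fit: ",
                                 paste(setdiff(pr, levs), collapse = ", "))
    cvec <- stats::setNames(rep(0, length(fit$beta)), names(fit$beta))
    ca <- coef_of(pr[1L]); cb <- coef_of(pr[2L])
    cvec[names(ca)] <- cvec[names(ca)] + ca
    cvec[names(cb)] <- cvec[names(cb)] - cb
    est <- sum(cvec * fit$beta)
    se <- sqrt(drop(cvec %*% fit$vcov_beta %*% cvec))
    tval <- est / se
    data.frame(group_a = pr[1L], group_b = pr[2L], estimate = est, se = se,
               df = fit$df, t = tval,
               p = 2 * stats::pt(-abs(tval), fit$df))
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. `NA` p-values propagate as `NA`
#' and do not count towards the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return numeric vector of q-values, monotone in `p`, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Per-feature mixed-model scan with FDR control
#'
#' Fits the random-intercept interaction model to every feature in a platform
#' grouping (natural-log response), computes the requested pairwise
#' interaction contrasts and applies Benjamini-Hochberg adjustment within
#' each (grouping x pair) family. For complete balanced paired designs the
#' scan is fully vectorised across features via the closed-form path.
#'
#' Contrast estimates are reported both on the natural-log scale of the model
#' (`estimate`) and converted to log2 units (`estimate_log2 = estimate /
#' log(2)`) for display parity with fold changes.
#'
#' @param x a [metabo_study()].
#' @param platforms,biofluid feature/sample selection as in
#'   [compute_fold_changes()].
#' @param contrasts `"vs-sal"` or `"all-pairs"`.
#' @param covariate optional name of a clinical delta column; when given, the
#'   three-way timepoint:group:covariate adjusted model is fitted instead
#'   (subjects missing the factor are dropped with a message).
#' @param alpha FDR level used by downstream summaries.
#' @return list with `contrasts` (data.frame: feature_id, group_a, group_b,
#'   estimate, estimate_log2, se, df, p, q), `alpha`, `grouping`,
#'   `diagnostics` (features skipped and why), and `covariate`.
#' @export
lme_scan <- function(x, platforms = NULL, biofluid = "plasma",
                     contrasts = c("vs-sal", "all-pairs"),
                     covariate = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "metabo_study"))
  contrasts <- match.arg(contrasts)
  keep_f <- if (is.null(platforms)) rep(TRUE, nrow(x$features)) else
    x$features$platform %in% platforms
  if (!any(keep_f)) stop("platform grouping selects zero features")
  sel <- x$samples$biofluid == biofluid
  samples <- x$samples[sel, , drop = FALSE]
  Y <- log(x$values[sel, keep_f, drop = FALSE])
  feat_ids <- colnames(Y)

  cov_vec <- NULL
  if (!is.null(covariate)) {
    if (is.null(x$clinical) || !covariate %in% names(x$clinical)) {
      stop("clinical factor not available: ", covariate)
    }
    cov_vec <- x$clinical[[covariate]][match(samples$subject_id,
                                             x$clinical$subject_id)]
    drop_subj <- unique(samples$subject_id[is.na(cov_vec)])
    if (length(drop_subj)) {
      message("dropping ", length(drop_subj), " subject(s) missing '",
              covariate, "'")
      keep <- !samples$subject_id %in% drop_subj
      samples <- samples[keep, , drop = FALSE]
      Y <- Y[keep, , drop = FALSE]
      cov_vec <- cov_vec[keep]
    }
  }

  d <- lme_design_frame(samples)
  obs_per_subj <- table(d$subject_id)
  tp_per_subj <- tapply(d$week4, d$subject_id, function(w) length(unique(w)))
  balanced <- all(obs_per_subj == 2L) && all(tp_per_subj == 2L) &&
    is.null(cov_vec) && !anyNA(Y)

  pair_list <- if (contrasts == "vs-sal") {
    lapply(setdiff(levels(droplevels(d$group)), "SAL"), function(g) c(g, "SAL"))
  } else {
    cmb <- utils::combn(levels(droplevels(d$group)), 2L)
    lapply(seq_len(ncol(cmb)), function(i) cmb[2:1, i])
  }

  diagnostics <- character(0)
  if (balanced) {
    ct <- lme_scan_balanced(Y, d, pair_list)
  } else {
    rows <- vector("list", length(feat_ids))
    for (j in seq_along(feat_ids)) {
      fit <- tryCatch(fit_lme(Y[, j], samples, covariate = cov_vec),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        diagnostics <- c(diagnostics,
                         paste0(feat_ids[j], ": ", conditionMessage(fit)))
        next
      }
      cc <- interaction_contrasts(fit, pair_list)
      cc$feature_id <- feat_ids[j]
      rows[[j]] <- cc
    }
    ct <- do.call(rbind, rows)
  }
  if (is.null(ct) || !nrow(ct)) stop("no feature could be modelled")
  ct$feature_id <- if ("feature_id" %in% names(ct)) ct$feature_id else NA
  ct$estimate_log2 <- ct$estimate / log(2)
  ct$q <- NA_real_
  fam <- paste(ct$group_a, ct$group_b)
  for (f in unique(fam)) {
    i <- fam == f
    ct$q[i] <- bh_fdr(ct$p[i])
  }
  ct <- ct[, c("feature_id", "group_a", "group_b", "estimate", "estimate_log2",
               "se", "df", "t", "p", "q")]
  rownames(ct) <- NULL
  list(contrasts = ct, alpha = alpha,
       grouping = paste(sort(unique(x$features$platform[keep_f])), collapse = "+"),
       diagnostics = diagnostics, covariate = covariate,
       method = "REML random-intercept LME, Wald t (containment df), BH per pair")
}

## vectorised closed-form scan across features (complete balanced pairs)
lme_scan_balanced <- function(Y, d, pair_list) {
  base_i <- which(d$week4 == 0)
  wk4_i <- which(d$week4 == 1)
  wk4_i <- wk4_i[match(d$subject_id[base_i], d$subject_id[wk4_i])]
  g <- droplevels(d$group[base_i])
  n <- length(base_i); G <- nlevels(g)
  D <- Y[wk4_i, , drop = FALSE] - Y[base_i, , drop = FALSE]

  n_g <- as.vector(table(g))
  names(n_g) <- levels(g)
  mean_d <- rowsum(D, g, reorder = TRUE) / n_g        # G x features
  resid <- D - mean_d[as.integer(g), , drop = FALSE]
  sigma2_e <- colSums(resid^2) / (2 * (n - G))
  dfree <- n - G

  rows <- lapply(pair_list, function(pr) {
    est <- mean_d[pr[1L], ] - mean_d[pr[2L], ]
    se <- sqrt(2 * sigma2_e * (1 / n_g[[pr[1L]]] + 1 / n_g[[pr[2L]]]))
    tval <- est / se
    data.frame(feature_id = colnames(Y), group_a = pr[1L], group_b = pr[2L],
               estimate = est, se = se, df = dfree, t = tval,
               p = 2 * stats::pt(-abs(tval), dfree), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Percent-significant summary of a contrast table
#'
#' Fig-2B-style summary: the percentage of features in the scan that pass
#' `q < alpha` for each group pair, recomputed directly from the contrast
#' table (single source of truth).
#'
#' @param scan an [lme_scan()] result (or its `contrasts` data.frame).
#' @param alpha FDR threshold.
#' @return data.frame with `group_a`, `group_b`, `n_features`,
#'   `n_significant`, `percent_significant`.
#' @export
percent_significant <- function(scan, alpha = 0.05) {
  ct <- if (is.data.frame(scan)) scan else scan$contrasts
  fam <- unique(ct[, c("group_a", "group_b")])
  out <- lapply(seq_len(nrow(fam)), function(i) {
    sub <- ct[ct$group_a == fam$group_a[i] & ct$group_b == fam$group_b[i], ]
    data.frame(group_a = fam$group_a[i], group_b = fam$group_b[i],
               n_features = nrow(sub),
               n_significant = sum(sub$q < alpha, na.rm = TRUE),
               percent_significant = 100 * mean(sub$q < alpha, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Flag confounder-sensitive features
#'
#' Compares an unadjusted scan with a clinical-factor-adjusted scan and flags
#' features whose vs-SAL contrast is significant (`q < alpha`) without
#' adjustment but loses significance once the three-way
#' timepoint:group:factor term is included.
#'
#' @param unadjusted,adjusted [lme_scan()] results on the same features (the
#'   adjusted one fitted with `covariate =` a clinical delta).
#' @param alpha FDR threshold.
#' @return data.frame of vs-SAL contrasts with `q_unadjusted`, `q_adjusted`
#'   and logical `confounder_sensitive`.
#' @export
confounder_sensitivity <- function(unadjusted, adjusted, alpha = 0.05) {
  a <- unadjusted$contrasts
  b <- adjusted$contrasts
  key <- function(d) paste(d$feature_id, d$group_a, d$group_b)
  m <- match(key(a), key(b))
  out <- data.frame(feature_id = a$feature_id, group_a = a$group_a,
                    group_b = a$group_b, q_unadjusted = a$q,
                    q_adjusted = b$q[m])
  out$confounder_sensitive <- !is.na(out$q_unadjusted) &
    out$q_unadjusted < alpha &
    (is.na(out$q_adjusted) | out$q_adjusted >= alpha)
  out
}

#' Group-size power simulation by subject bootstrap
#'
#' Estimates how the number of FDR-significant features for `target_group`
#' vs SAL changes if that arm were enlarged: subjects of the target arm are
#' resampled with replacement to size `target_n` (the SAL arm is held fixed
#' as the control), the full scan plus BH adjustment is re-run per resample,
#' and the distribution of significant-feature counts is reported.
#'
#' Verbatim duplicates of a subject would shrink the residual variance
#' estimate and make the null anti-conservative, so the default `"smooth"`
#' scheme perturbs every duplicate copy beyond the first with fresh Gaussian
#' noise on the log2 scale, at the per-feature residual SD estimated from the
#' original within-group paired differences; copies then behave like new
#' patients drawn near the resampled one. `scheme = "naive"` resamples
#' verbatim.
#'
#' @param x a [metabo_study()].
#' @param target_group arm to enlarge (default `"GOP"`).
#' @param target_n resampled arm size; must be at least the current size.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param alpha FDR threshold.
#' @param platforms,biofluid selection as in [lme_scan()].
#' @param scheme `"smooth"` (default) or `"naive"` duplicate handling.
#' @return list with `counts` (length-B integer vector), `mean`, the
#'   2.5/97.5 percent `interval`, and the `scheme` used.
#' @export
power_simulation <- function(x, target_group = "GOP", target_n, B = 100L,
                             seed = 1L, alpha = 0.05, platforms = NULL,
                             biofluid = "plasma",
                             scheme = c("smooth", "naive")) {
  stopifnot(inherits(x, "metabo_study"))
  scheme <- match.arg(scheme)
  if (B < 10L) warning("B < 10 gives a very coarse interval")
  s <- x$samples
  cur <- unique(s$subject_id[s$group == target_group])
  if (target_n < length(cur)) stop("target_n below the current group size")
  sal <- unique(s$subject_id[s$group == "SAL"])

  # per-feature residual SD on the log2 scale from within-group paired diffs
  in_bf <- s$biofluid == biofluid
  bi <- which(in_bf & s$timepoint == "baseline")
  wi <- which(in_bf & s$timepoint == "week4")
  wi <- wi[match(s$subject_id[bi], s$subject_id[wi])]
  keep <- !is.na(wi)
  D <- log2(x$values[wi[keep], , drop = FALSE]) -
    log2(x$values[bi[keep], , drop = FALSE])
  gD <- s$group[bi][keep]
  Dm <- rowsum(D, gD) / as.vector(table(gD))
  resid_sd <- sqrt(colSums((D - Dm[match(gD, rownames(Dm)), , drop = FALSE])^2,
                           na.rm = TRUE) /
                     (2 * (nrow(D) - length(unique(gD)))))

  set.seed(seed)
  counts <- integer(B)
  for (b in seq_len(B)) {
    pick <- sample(cur, target_n, replace = TRUE)
    dup <- duplicated(pick)
    ids <- c(sal, pick)
    # duplicated draws become distinct pseudo-subjects
    new_id <- c(sal, paste0(pick, "_bs", seq_along(pick)))
    is_dup <- c(rep(FALSE, length(sal)), dup)
    rows <- lapply(seq_along(ids), function(i) {
      r <- s[s$subject_id == ids[i], , drop = FALSE]
      r$subject_id <- new_id[i]
      r$sample_id <- paste0(new_id[i], "_", r$timepoint, "_", r$biofluid)
      cbind(r, .orig = which(s$subject_id == ids[i]), .dup = is_dup[i])
    })
    meta <- do.call(rbind, rows)
    vals <- x$values[meta$.orig, , drop = FALSE]
    if (scheme == "smooth" && any(meta$.dup)) {
      di <- which(meta$.dup)
      noise <- matrix(stats::rnorm(length(di) * ncol(vals)), length(di)) *
        rep(resid_sd, each = length(di))
      vals[di, ] <- 2^(log2(vals[di, , drop = FALSE]) + noise)
    }
    study_b <- metabo_study(vals, meta[, setdiff(names(meta), c(".orig", ".dup"))],
                            x$features)
    sc <- lme_scan(study_b, platforms = platforms, biofluid = biofluid,
                   contrasts = "vs-sal", alpha = alpha)
    ct <- sc$contrasts
    ct <- ct[ct$group_a == target_group, , drop = FALSE]
    counts[b] <- sum(ct$q < alpha, na.rm = TRUE)
  }
  list(counts = counts, mean = mean(counts),
       interval = stats::quantile(counts, c(0.025, 0.975)), scheme = scheme)
}
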