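## NIPALS PLS1 regression of a metabolite block on a single clinical factor,
## with cross-validated Q2, permutation-based model validation and empirical
## weight-based feature selection. Deterministic given (data, seed): the
## NIPALS weight for a single y needs no iteration or random start.

scale_train <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (is.null(scale)) {
    scale <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
    scale[scale == 0] <- 1
  }
  list(X = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

nipals_pls1 <- function(Xs, ys, n_components) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tt <- matrix(0, n, n_components)
  cvec <- numeric(n_components)
  Xd <- Xs; yd <- ys
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # residual X carries no covariance with y; stop early
      W <- W[, seq_len(k - 1L), drop = FALSE]
      P <- P[, seq_len(k - 1L), drop = FALSE]
      Tt <- Tt[, seq_len(k - 1L), drop = FALSE]
      cvec <- cvec[seq_len(k - 1L)]
      break
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pk <- drop(crossprod(Xd, tt)) / tt2
    ck <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pk)
    yd <- yd - ck * tt
    W[, k] <- w; P[, k] <- pk; Tt[, k] <- tt; cvec[k] <- ck
  }
  # regression coefficients on the scaled data: b = W (P'W)^-1 c
  b <- if (ncol(W)) drop(W %*% solve(crossprod(P, W), cvec)) else rep(0, p)
  list(W = W, P = P, T = Tt, c = cvec, b = b)
}

#' Fit a PLS1 regression of a metabolite block on a clinical factor
#'
#' NIPALS partial least squares with a single response: X is mean-centred and
#' unit-variance scaled, y is mean-centred and scaled, and components are
#' extracted by deflation. The fit is deterministic (the PLS1 weight has a
#' closed form per component, so there is no iterative or random
#' initialisation). Missing X cells are imputed by feature-wise means, as in
#' the PCA stage.
#'
#' @param X numeric matrix (samples x features), e.g. the `values` of a
#'   [compute_fold_changes()] result.
#' @param y numeric response, one value per row of X (a clinical delta).
#' @param n_components number of latent components.
#' @return A `pls_model`: list with `weights` (W), `loadings` (P), `scores`
#'   (T), `y_loadings` (c), `coefficients` (original X units), `r2y`,
#'   `n_components`, preprocessing constants, and the training data carried
#'   for downstream permutation work.
#' @export
fit_pls <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (nrow(X) < 5L) stop("need at least 5 samples")
  if (stats::var(y) == 0) stop("factor has zero variance")
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j])
    }
  }
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))

  sx <- scale_train(X)
  y_center <- mean(y); y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale
  fit <- nipals_pls1(sx$X, ys, n_components)

  yhat <- drop(sx$X %*% fit$b)
  r2y <- 1 - sum((ys - yhat)^2) / sum(ys^2)

  structure(
    list(weights = fit$W, loadings = fit$P, scores = fit$T,
         y_loadings = fit$c,
         coefficients = fit$b / sx$scale * y_scale,
         b_scaled = fit$b,
         r2y = r2y, n_components = ncol(fit$W),
         x_center = sx$center, x_scale = sx$scale,
         y_center = y_center, y_scale = y_scale,
         X = X, y = y,
         preprocessing = "center_uv"),
    class = "pls_model"
  )
}

#' Predict from a PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix with the same features as the training X.
#' @param ... unused.
#' @return numeric vector of predicted y.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$x_center), 2L,
              object$x_scale, "/")
  drop(Xs %*% object$b_scaled) * object$y_scale + object$y_center
}

#' Cross-validated Q2 for a PLS model
#'
#' K-fold cross-validation of the predicted-variance statistic
#' `Q2 = 1 - PRESS / TSS`, with centring and scaling re-estimated on each
#' training fold only, and TSS taken around the training-fold mean. Fold
#' assignment is deterministic given `seed`; folds can be stratified by a
#' grouping factor so each fold spans treatment arms.
#'
#' @param X,y as in [fit_pls()].
#' @param n_components latent components per fold.
#' @param folds number of folds (>= 2, <= n samples).
#' @param seed integer seed for the fold shuffle.
#' @param strata optional factor for stratified fold assignment.
#' @return numeric Q2 value.
#' @export
q2y_cv <- function(X, y, n_components = 2L, folds = 7L, seed = 1L,
                   strata = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("more folds than samples")
  fold_id <- make_folds(n, folds, seed, strata)

  press <- 0; tss <- 0
  for (k in seq_len(folds)) {
    test <- fold_id == k
    if (!any(test)) stop("a fold has no test sample")
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    sx <- scale_train(Xtr)
    ysc <- stats::sd(ytr); yc <- mean(ytr)
    fit <- nipals_pls1(sx$X, (ytr - yc) / ysc,
                       min(n_components, nrow(Xtr) - 1L, ncol(Xtr)))
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2L, sx$center), 2L, sx$scale, "/")
    pred <- drop(Xte %*% fit$b) * ysc + yc
    press <- press + sum((y[test] - pred)^2)
    tss <- tss + sum((y[test] - yc)^2)
  }
  1 - press / tss
}

make_folds <- function(n, folds, seed, strata = NULL) {
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(seed)
  fold_id <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Permutation validity test and empirical weight selection for PLS
#'
#' Refits the entire PLS pipeline (model plus cross-validated Q2) on `B`
#' permutations of y, keeping the true model's component count. The model is
#' declared valid when `Q2 > q2_threshold` and the permutation p-value —
#' `(1 + #\{null Q2 >= true Q2\}) / (B + 1)` — is below `perm_p_threshold`.
#' Per-feature empirical p-values compare the magnitude of each true
#' component-1 weight against its null distribution:
#' `(1 + #\{|w_null| >= |w_true|\}) / (B + 1)` (a signed one-sided variant is
#' available). Features are selected when the model is valid and
#' `empirical_p < select_alpha`.
#'
#' Weights are compared on the cross-covariance scale (`X'y` of the scaled
#' data — the NIPALS weight before unit normalisation). Normalised weights
#' are unsuitable here: every model's weight vector has unit norm, so a
#' permuted model redistributes, rather than loses, weight magnitude, and
#' with many informative features no feature could ever beat its null at the
#' nominal rate. On the covariance scale a permuted model's weights shrink
#' towards zero, making the comparison a genuine association test.
#'
#' @param X,y training data of `model`.
#' @param model a [fit_pls()] result on `(X, y)`.
#' @param B number of permutations (1000 to match the reference workflow;
#'   reduce for exploratory runs).
#' @param seed integer seed driving permutations and CV folds.
#' @param folds CV folds for each Q2 evaluation.
#' @param q2_threshold,perm_p_threshold validity thresholds (defaults 0.15
#'   and 0.01).
#' @param select_alpha empirical-p threshold for feature selection.
#' @param strata optional stratification factor for the CV folds.
#' @param signed if `TRUE`, compare signed weights one-sidedly instead of
#'   magnitudes.
#' @return A `permutation_report`: list with `q2y`, `null_q2y`, `perm_p`,
#'   `valid`, `features` (data.frame: feature, `w_true` — the component-1
#'   weight on the covariance scale —, `empirical_p`, `selected`) and the
#'   thresholds used.
#' @export
permutation_validity <- function(X, y, model, B = 1000L, seed = 1L, folds = 7L,
                                 q2_threshold = 0.15, perm_p_threshold = 0.01,
                                 select_alpha = 0.05, strata = NULL,
                                 signed = FALSE) {
  stopifnot(inherits(model, "pls_model"))
  if (B <= 0L) stop("B must be positive")
  X <- as.matrix(X)
  n <- nrow(X)
  k <- model$n_components

  q2_true <- q2y_cv(X, y, n_components = k, folds = folds, seed = seed,
                    strata = strata)

  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j])
    }
  }
  sx <- scale_train(X)
  ys <- (y - mean(y)) / stats::sd(y)
  cov_w <- function(yv) drop(crossprod(sx$X, yv))

  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(seed + 1L)
  null_q2 <- numeric(B)
  null_w <- matrix(0, ncol(X), B)
  for (b in seq_len(B)) {
    pi_b <- sample.int(n)
    null_q2[b] <- q2y_cv(X, y[pi_b], n_components = k, folds = folds,
                         seed = seed, strata = strata)
    null_w[, b] <- cov_w(ys[pi_b])
  }

  perm_p <- (1 + sum(null_q2 >= q2_true)) / (B + 1)
  valid <- (q2_true > q2_threshold) && (perm_p < perm_p_threshold)

  w_true <- cov_w(ys)
  emp_p <- if (signed) {
    (1 + rowSums(null_w >= w_true)) / (B + 1)
  } else {
    (1 + rowSums(abs(null_w) >= abs(w_true))) / (B + 1)
  }
  features <- data.frame(
    feature = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    w_true = w_true, empirical_p = emp_p,
    selected = valid & emp_p < select_alpha
  )
  structure(
    list(q2y = q2_true, null_q2y = null_q2, perm_p = perm_p, valid = valid,
         B = B, features = features,
         thresholds = c(q2 = q2_threshold, perm_p = perm_p_threshold,
                        select_alpha = select_alpha)),
    class = "permutation_report"
  )
}

#' Features selected by the permutation report
#'
#' Convenience accessor: the feature ids whose empirical weight p-value
#' passes the selection threshold in a valid model. Selection is only
#' reported when the model is valid.
#'
#' @param report a [permutation_validity()] result.
#' @return character vector of selected feature ids (empty when the model is
#'   not valid).
#' @export
select_features <- function(report) {
  stopifnot(inherits(report, "permutation_report"))
  if (!report$valid) return(character(0))
  report$features$feature[report$features$selected]
}

#' Choose the PLS component count by cross-validation
#'
#' Evaluates Q2 for 1..`max_components` and returns the count maximising it.
#'
#' @param X,y as in [fit_pls()].
#' @param max_components upper bound (default 5).
#' @param folds,seed,strata passed to [q2y_cv()].
#' @return list with `n_components` and the per-count `q2` vector.
#' @export
choose_n_components <- function(X, y, max_components = 5L, folds = 7L,
                                seed = 1L, strata = NULL) {
  kmax <- min(max_components, nrow(as.matrix(X)) - 2L, ncol(as.matrix(X)))
  q2 <- vapply(seq_len(kmax), function(k) {
    q2y_cv(X, y, n_components = k, folds = folds, seed = seed, strata = strata)
  }, 0)
  list(n_components = which.max(q2), q2 = q2)
}
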