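#' Cross-validated ridge fit of the linear feature summation model
#'
#' Fits ratings as a weighted linear sum of stimulus features with ridge
#' regression. The data are split into `n_folds` outer folds; within each outer
#' training set the penalty is chosen by nested (inner) cross-validation, the
#' model is refit at that penalty, and the held-out stimuli are predicted.
#' Predictive accuracy is the Pearson correlation between the pooled
#' out-of-fold predictions and the observed ratings. Feature columns are
#' z-scored with training-fold statistics only; the intercept is unpenalized
#' (fit on centred data).
#'
#' @param features stimuli x features numeric matrix.
#' @param ratings numeric vector of ratings, one per stimulus (the 0-3 liking
#'   scale is treated as continuous).
#' @param n_folds outer folds (default 20).
#' @param penalty_grid ridge penalties searched by the inner CV.
#' @param inner_folds folds of the nested CV used to pick the penalty.
#' @param folds optional integer vector of pre-assigned outer folds.
#' @param seed seed for the fold assignment when `folds` is NULL.
#' @return List of class `lfs_ridge_fit`: `weights` (original scale),
#'   `intercept`, `weights_std` (standardized scale), `lambda` (penalty used
#'   for the final refit on all data), `predictions` (pooled out-of-fold),
#'   `fold` assignment, `accuracy`, and `flag` (`"constant_ratings"` when
#'   accuracy is undefined).
#' @export
fit_ridge_cv <- function(features, ratings, n_folds = 20,
                         penalty_grid = 10^seq(-4, 3, length.out = 15),
                         inner_folds = 5, folds = NULL, seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(ratings)
  stopifnot(nrow(X) == length(y), n_folds >= 2)
  if (is.null(folds))
    folds <- withr_seed(seed, sample(rep_len(seq_len(n_folds), length(y))))

  cv <- ridge_cv_pooled(X, matrix(y, ncol = 1), folds, inner_folds,
                        penalty_grid)
  preds <- cv$pred[, 1]

  # final penalty: CV over the same folds on all data; refit everything
  full <- ridge_inner_select(X, matrix(y, ncol = 1), folds, penalty_grid)
  lambda <- penalty_grid[full$best_idx[1]]
  fit <- ridge_solve(X, y, lambda)

  flag <- NULL
  acc <- if (stats::sd(y) == 0) { flag <- "constant_ratings"; NA_real_ }
         else stats::cor(preds, y)
  structure(list(weights = fit$weights, intercept = fit$intercept,
                 weights_std = fit$weights_std, lambda = lambda,
                 predictions = preds, fold = folds, accuracy = acc,
                 flag = flag),
            class = "lfs_ridge_fit")
}

#' @export
print.lfs_ridge_fit <- function(x, ...) {
  cat(sprintf("<lfs_ridge_fit: %d features, lambda=%.4g, CV accuracy r=%.3f>\n",
              length(x$weights), x$lambda, x$accuracy))
  invisible(x)
}

#' Permutation test of LFS predictive accuracy
#'
#' Builds a null distribution for the cross-validated predictive accuracy by
#' permuting stimulus labels of the ratings and re-running the identical
#' cross-validation pipeline (including the nested penalty selection) for each
#' permutation. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; the chance
#' level is the mean of the null.
#'
#' @param fit a [fit_ridge_cv()] result (supplies the observed accuracy and
#'   fold assignment).
#' @param features,ratings the data the fit was computed on.
#' @param n_perm number of label permutations (default 10000).
#' @param penalty_grid,inner_folds as in [fit_ridge_cv()].
#' @param seed seed for the permutations.
#' @return List: `p_value`, `null` (vector of null accuracies), `chance`
#'   (null mean), `observed`.
#' @export
permutation_test <- function(fit, features, ratings, n_perm = 10000,
                             penalty_grid = 10^seq(-4, 3, length.out = 15),
                             inner_folds = 5, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  X <- as.matrix(features)
  y <- as.numeric(ratings)
  Y <- withr_seed(seed, vapply(seq_len(n_perm), function(b) sample(y),
                               numeric(length(y))))
  cv <- ridge_cv_pooled(X, Y, fit$fold, inner_folds, penalty_grid)
  # each permuted analysis is scored against its own (permuted) ratings
  null <- vapply(seq_len(n_perm), function(b)
    stats::cor(cv$pred[, b], Y[, b]), numeric(1))
  obs <- fit$accuracy
  list(p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       null = null, chance = mean(null), observed = obs)
}

# -- internal ridge machinery -------------------------------------------------

# Closed-form ridge on z-scored columns (SVD). Constant columns are dropped
# with a warning. Returns weights on both scales.
ridge_solve <- function(X, y, lambda) {
  sdx <- apply(X, 2, stats::sd)
  keep <- sdx > 0
  if (!all(keep)) warning("dropping constant feature column(s): ",
                          paste(colnames(X)[!keep], collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  mx <- colMeans(Xk); sx <- sdx[keep]
  Xs <- sweep(sweep(Xk, 2, mx), 2, sx, "/")
  my <- mean(y)
  sv <- svd(Xs)
  bs <- sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, y - my))
  w_std <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w_std[keep] <- as.numeric(bs)
  w <- w_std
  w[keep] <- w_std[keep] / sx
  list(weights = w, weights_std = w_std,
       intercept = my - sum(w[keep] * mx))
}

# For a training set (X, multi-column Y) return a function lambda-index ->
# predictions at new X rows. Standardization from training rows only.
ridge_train_ops <- function(Xtr, Xte) {
  sdx <- apply(Xtr, 2, stats::sd)
  keep <- sdx > 0
  mx <- colMeans(Xtr[, keep, drop = FALSE]); sx <- sdx[keep]
  Xs <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mx), 2, sx, "/")
  Xts <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mx), 2, sx, "/")
  sv <- svd(Xs)
  XteV <- Xts %*% sv$v                    # n_te x r
  # returns n_te x B prediction matrix for centred Ytr and penalty lambda
  function(Ytr_centred, lambda) {
    UtY <- crossprod(sv$u, Ytr_centred)   # r x B
    XteV %*% ((sv$d / (sv$d^2 + lambda)) * UtY)
  }
}

# Inner-CV penalty selection: for each column of Y, pick the grid index with
# the lowest pooled validation SSE over the folds.
ridge_inner_select <- function(X, Y, folds, grid) {
  sse <- matrix(0, length(grid), ncol(Y))
  for (g in sort(unique(folds))) {
    tr <- folds != g
    ops <- ridge_train_ops(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    my <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, my)
    Yv <- Y[!tr, , drop = FALSE]
    for (l in seq_along(grid)) {
      P <- sweep(ops(Yc, grid[l]), 2, my, "+")
      sse[l, ] <- sse[l, ] + colSums((P - Yv)^2)
    }
  }
  list(best_idx = apply(sse, 2, which.min), sse = sse)
}

# Pooled out-of-fold predictions for every column of Y (each column is an
# independent rating vector run through the identical pipeline).
ridge_cv_pooled <- function(X, Y, folds, inner_folds, grid) {
  pred <- matrix(NA_real_, nrow(Y), ncol(Y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    Ytr <- Y[tr, , drop = FALSE]
    ifolds <- rep_len(seq_len(inner_folds), sum(tr))  # deterministic inner split
    sel <- ridge_inner_select(Xtr, Ytr, ifolds, grid)
    ops <- ridge_train_ops(Xtr, X[!tr, , drop = FALSE])
    my <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2, my)
    for (l in unique(sel$best_idx)) {
      cols <- which(sel$best_idx == l)
      P <- ops(Yc[, cols, drop = FALSE], grid[l])
      pred[!tr, cols] <- sweep(P, 2, my[cols], "+")
    }
  }
  list(pred = pred)
}
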