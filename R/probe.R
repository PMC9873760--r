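#' Decode one feature from one layer's activations
#'
#' Cross-validated linear probe: within each training fold the activations are
#' reduced by PCA to the smallest number of components explaining at least
#' `var_explained` of the training variance; test activations are projected
#' with the training transform (no leakage). Continuous features are decoded
#' with ridge regression and scored by the Pearson correlation between pooled
#' out-of-fold predictions and the feature; categorical features with
#' L2-regularized logistic regression scored by accuracy (AUC and F1 are also
#' returned). The ridge/logistic penalty is grid searched and the
#' best-performing penalty's score is reported.
#'
#' @param acts stimuli x units activation matrix (one layer).
#' @param feature numeric vector (continuous) or 0/1 vector (categorical).
#' @param kind `"continuous"` or `"categorical"`.
#' @param n_folds CV folds (default 10); categorical folds are stratified.
#' @param var_explained PCA variance threshold (default 0.8).
#' @param lambda_grid penalty grid (13 log-spaced points in 1e-3..1e3).
#' @param seed fold seed.
#' @return List: `score` (primary metric), `metric`, for categorical also
#'   `accuracy`, `auc`, `f1`; plus `n_components` used per fold.
#' @export
decode_feature_from_layer <- function(acts, feature,
                                      kind = c("continuous", "categorical"),
                                      n_folds = 10, var_explained = 0.8,
                                      lambda_grid = 10^seq(-3, 3,
                                                           length.out = 13),
                                      seed = 1L) {
  kind <- match.arg(kind)
  A <- as.matrix(acts)
  y <- as.numeric(feature)
  n <- length(y)
  stopifnot(nrow(A) == n)
  if (kind == "categorical" && length(unique(y)) < 2)
    stop("categorical feature has a single class; nothing to decode")
  folds <- withr_seed(seed, {
    if (kind == "categorical") {          # stratified: split classes evenly
      f <- integer(n)
      for (cl in unique(y)) {
        ix <- sample(which(y == cl))
        f[ix] <- rep_len(seq_len(n_folds), length(ix))
      }
      f
    } else sample(rep_len(seq_len(n_folds), n))
  })

  preds <- matrix(NA_real_, n, length(lambda_grid))
  ncomp_used <- integer(0)
  for (fd in sort(unique(folds))) {
    tr <- folds != fd
    ctr <- colMeans(A[tr, , drop = FALSE])
    Atr <- sweep(A[tr, , drop = FALSE], 2, ctr)
    Ate <- sweep(A[!tr, , drop = FALSE], 2, ctr)
    sv <- svd(Atr, nu = 0)
    if (sum(sv$d^2) < .Machine$double.eps) {  # dead layer: no variance
      preds[!tr, ] <- if (kind == "continuous") mean(y[tr]) else
        mean(y[tr] == 1)
      ncomp_used <- c(ncomp_used, 0L)
      next
    }
    cumvar <- cumsum(sv$d^2) / sum(sv$d^2)
    k <- max(1L, which(cumvar >= var_explained)[1])
    ncomp_used <- c(ncomp_used, k)
    V <- sv$v[, seq_len(k), drop = FALSE]
    Ptr <- Atr %*% V
    Pte <- Ate %*% V
    if (kind == "continuous") {
      svp <- svd(Ptr)
      my <- mean(y[tr])
      uty <- crossprod(svp$u, y[tr] - my)
      for (l in seq_along(lambda_grid))
        preds[!tr, l] <- my + Pte %*% (svp$v %*%
          ((svp$d / (svp$d^2 + lambda_grid[l])) * uty))
    } else {
      if (ncol(Ptr) == 1L) {      # glmnet requires >= 2 columns
        Ptr <- cbind(Ptr, 0)
        Pte <- cbind(Pte, 0)
      }
      fit <- glmnet::glmnet(Ptr, y[tr], family = "binomial", alpha = 0,
                            lambda = rev(sort(lambda_grid)) / nrow(Ptr),
                            standardize = FALSE)
      pr <- stats::predict(fit, Pte, type = "response")
      # glmnet orders by its own (descending) lambda sequence and may stop
      # early; reuse the last converged solution for the remaining penalties
      pr <- pr[, pmin(seq_along(lambda_grid), ncol(pr)), drop = FALSE]
      lam_order <- order(-lambda_grid)
      preds[!tr, lam_order] <- pr
    }
  }

  if (kind == "continuous") {
    scores <- apply(preds, 2, function(p)
      if (stats::sd(p) == 0) 0 else stats::cor(p, y))
    best <- which.max(scores)
    list(score = scores[best], metric = "pearson_r",
         n_components = ncomp_used)
  } else {
    acc <- apply(preds, 2, function(p) mean((p > 0.5) == y))
    best <- which.max(acc)
    p <- preds[, best]
    auc <- {
      r <- rank(p)
      n1 <- sum(y == 1); n0 <- n - n1
      if (n1 == 0 || n0 == 0) NA_real_
      else (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    tp <- sum(p > 0.5 & y == 1)
    f1 <- if (tp == 0) 0 else 2 * tp / (sum(p > 0.5) + sum(y == 1))
    list(score = acc[best], metric = "accuracy", accuracy = acc[best],
         auc = auc, f1 = f1, n_components = ncomp_used)
  }
}

#' Layerwise decoding profile of a feature
#'
#' @param acts a [layer_activations()] object.
#' @param feature the feature values (one per stimulus).
#' @param kind,... passed to [decode_feature_from_layer()].
#' @return numeric vector of per-layer decoding scores.
#' @export
decoding_profile <- function(acts, feature, kind = "continuous", ...) {
  vapply(acts, function(a)
    decode_feature_from_layer(a, feature, kind = kind, ...)$score, numeric(1))
}

#' Classify a feature as low- or high-level from its decoding slope
#'
#' Fits a least-squares slope to decoding score vs layer index, then builds a
#' permutation null by shuffling the layer labels `n_perm` times. The feature
#' is classified high-level when the slope is significantly positive
#' (`p_positive < alpha`), low-level when significantly negative, otherwise
#' unclassified. Constant score profiles are unclassified.
#'
#' @param scores per-layer decoding scores (>= 3 layers).
#' @param n_perm layer-label permutations (default 10000).
#' @param alpha significance level (default 0.001).
#' @param seed permutation seed.
#' @return List: `slope`, `p_positive`, `p_negative`, `classification`.
#' @export
classify_feature_level <- function(scores, n_perm = 10000, alpha = 0.001,
                                   seed = 1L) {
  s <- as.numeric(scores)
  L <- length(s)
  stopifnot(L >= 3)
  if (stats::sd(s) == 0)
    return(list(slope = 0, p_positive = 1, p_negative = 1,
                classification = "unclassified"))
  x <- seq_len(L)
  slope_of <- function(v) stats::cov(x, v) / stats::var(x)
  obs <- slope_of(s)
  null <- withr_seed(seed, vapply(seq_len(n_perm),
                                  function(b) slope_of(sample(s)), numeric(1)))
  p_pos <- (1 + sum(null >= obs)) / (1 + n_perm)
  p_neg <- (1 + sum(null <= obs)) / (1 + n_perm)
  cls <- if (p_pos < alpha) "high" else if (p_neg < alpha) "low" else
    "unclassified"
  list(slope = obs, p_positive = p_pos, p_negative = p_neg,
       classification = cls)
}

#' Leading principal components of each layer, as encoding regressors
#'
#' Extracts the first `n_pcs` PCA scores of every layer's activations (z-scored
#' scores) for use as parametric modulators in the encoding GLM, together with
#' the layer index of each column.
#'
#' @param acts a [layer_activations()] object.
#' @param n_pcs components per layer (default 3).
#' @return stimuli x (layers * n_pcs) matrix, with attribute `layer` (integer
#'   layer index per column).
#' @export
layer_pcs <- function(acts, n_pcs = 3) {
  out <- list(); layer_of <- integer(0)
  for (l in seq_along(acts)) {
    A <- acts[[l]]
    keep <- apply(A, 2, stats::sd) > 0
    pc <- stats::prcomp(A[, keep, drop = FALSE], center = TRUE)
    k <- min(n_pcs, ncol(pc$x))
    sc <- pc$x[, seq_len(k), drop = FALSE]
    sc <- sweep(sc, 2, apply(sc, 2, stats::sd), "/")
    colnames(sc) <- sprintf("layer%02d_pc%d", l, seq_len(k))
    out[[l]] <- sc
    layer_of <- c(layer_of, rep(l, k))
  }
  res <- do.call(cbind, out)
  attr(res, "layer") <- layer_of
  res
}

#' Layer grouping for group-level encoding tests
#'
#' The canonical grouping for the 13-convolution + 2-FC layout is layers 1-4,
#' 5-9, 10-13 and 14-15. For other depths the convolution layers are split
#' into three contiguous chunks and the fully connected layers form the fourth
#' group.
#'
#' @param n_conv,n_fc layer counts.
#' @return Named list of integer layer-index vectors.
#' @export
layer_groups <- function(n_conv = 13, n_fc = 2) {
  if (n_conv == 13 && n_fc == 2)
    return(list(`1-4` = 1:4, `5-9` = 5:9, `10-13` = 10:13, `14-15` = 14:15))
  cuts <- round(seq(0, n_conv, length.out = 4))
  g <- list(seq_len(cuts[2]),
            seq(cuts[2] + 1, cuts[3]),
            seq(cuts[3] + 1, n_conv),
            n_conv + seq_len(n_fc))
  names(g) <- vapply(g, function(ix) paste0(min(ix), "-", max(ix)),
                     character(1))
  g
}
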