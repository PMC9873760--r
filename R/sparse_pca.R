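#' Sparse principal components of a feature matrix
#'
#' Orthogonalizes a feature matrix with sparse PCA before group-level feature
#' selection. Components are extracted one at a time by power iteration with a
#' soft-threshold step on the loadings: at each iteration the fraction
#' `sparsity` of the smallest absolute loadings is shrunk to zero (quantile
#' soft threshold), the loading vector is re-normalized, and the matrix is
#' deflated by projecting out the component scores. With `sparsity = 0` the
#' procedure reduces exactly to ordinary PCA.
#'
#' The sparse loadings are retained as the back-transformation map from
#' selected components to original features.
#'
#' @param features stimuli x features matrix (z-scored internally).
#' @param n_components number of components (must be <= n. features).
#' @param sparsity fraction of loadings zeroed per component, in \[0, 1).
#' @param max_iter,tol power-iteration controls.
#' @return List of class `sparse_pca`: `loadings` (features x k), `scores`
#'   (stimuli x k), `center`, `scale`, `sparsity`, `dropped` (indices of
#'   components abandoned because all loadings were shrunk to zero).
#' @export
orthogonalize_sparse_pca <- function(features, n_components,
                                     sparsity = 0.5, max_iter = 2000,
                                     tol = 1e-14) {
  X <- as.matrix(features)
  stopifnot(n_components <= ncol(X), sparsity >= 0, sparsity < 1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  p <- ncol(Xs)
  L <- matrix(0, p, 0)
  S <- matrix(0, nrow(Xs), 0)
  dropped <- integer(0)
  Xc <- Xs
  for (k in seq_len(n_components)) {
    # deterministic init: direction of the highest-variance residual column
    v <- numeric(p); v[which.max(colSums(Xc^2))] <- 1
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, Xc %*% v)
      if (sparsity > 0) {
        thr <- stats::quantile(abs(w), sparsity, names = FALSE)
        w <- sign(w) * pmax(abs(w) - thr, 0)
      }
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) { v <- numeric(p); break }
      w <- w / nw
      if (sum((w - v)^2) < tol) { v <- w; break }
      v <- w
    }
    if (all(v == 0)) {
      warning("component ", k, " has all-zero loadings at sparsity ",
              sparsity, "; dropped")
      dropped <- c(dropped, k)
      next
    }
    s <- Xc %*% v
    L <- cbind(L, v)
    S <- cbind(S, s)
    Xc <- Xc - s %*% crossprod(s, Xc) / sum(s^2)   # projection deflation
  }
  rownames(L) <- colnames(X)
  if (ncol(L) > 0)
    colnames(L) <- colnames(S) <- paste0("PC", seq_len(ncol(L)))
  structure(list(loadings = L, scores = S, center = ctr, scale = scl,
                 sparsity = sparsity, dropped = dropped),
            class = "sparse_pca")
}

#' @export
print.sparse_pca <- function(x, ...) {
  cat(sprintf("<sparse_pca: %d components, sparsity=%.2f, %d nonzero loadings>\n",
              ncol(x$loadings), x$sparsity, sum(x$loadings != 0)))
  invisible(x)
}
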