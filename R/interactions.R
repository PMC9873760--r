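#' Nonlinear interaction feature groups
#'
#' Builds pairwise product features from a feature matrix, grouped by level:
#' all unordered pairs of low-level features (`low_low`), all unordered pairs
#' of high-level features (`high_high`), and all low x high cross pairs
#' (`low_high`). Columns are z-scored before multiplication, so the products
#' are centred and scale-free; no self-products are included. Column order is
#' deterministic (lexicographic by contributing pair names).
#'
#' @param features stimuli x features matrix.
#' @param level character vector ("low"/"high") per column.
#' @return Object of class `interaction_groups`: list of three matrices keyed
#'   `low_low`, `high_high`, `low_high` (possibly 0-column), each with a
#'   `pairs` attribute (2-column character matrix of contributing names).
#' @export
build_interaction_groups <- function(features, level) {
  X <- as.matrix(features)
  stopifnot(ncol(X) == length(level), !is.null(colnames(X)))
  sdx <- apply(X, 2, stats::sd); sdx[sdx == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdx, "/")

  prods <- function(a, b, within) {
    if (within && length(a) < 2) {
      warning("fewer than 2 features in level; empty interaction group")
      m <- matrix(numeric(0), nrow(Z), 0)
      attr(m, "pairs") <- matrix(character(0), 0, 2)
      return(m)
    }
    pr <- if (within) t(utils::combn(sort(a), 2))
          else as.matrix(expand.grid(sort(a), sort(b),
                                     stringsAsFactors = FALSE))[, 1:2]
    if (length(pr) == 0) {
      m <- matrix(numeric(0), nrow(Z), 0)
      attr(m, "pairs") <- matrix(character(0), 0, 2)
      return(m)
    }
    ord <- order(pr[, 1], pr[, 2])
    pr <- pr[ord, , drop = FALSE]
    m <- Z[, pr[, 1], drop = FALSE] * Z[, pr[, 2], drop = FALSE]
    colnames(m) <- paste(pr[, 1], pr[, 2], sep = "_x_")
    attr(m, "pairs") <- pr
    m
  }
  lo <- colnames(X)[level == "low"]
  hi <- colnames(X)[level == "high"]
  structure(list(low_low = prods(lo, lo, TRUE),
                 high_high = prods(hi, hi, TRUE),
                 low_high = prods(lo, hi, FALSE)),
            class = "interaction_groups")
}

#' @export
print.interaction_groups <- function(x, ...) {
  cat(sprintf("<interaction_groups: low_low=%d, high_high=%d, low_high=%d columns>\n",
              ncol(x$low_low), ncol(x$high_high), ncol(x$low_high)))
  invisible(x)
}

#' Reduce interaction groups to leading principal components
#'
#' Performs PCA (on the correlation scale: inputs are z-scored) within each
#' nonempty interaction group and keeps the first `n_pcs` components, matching
#' the dimensionality of the high-level feature set. Component scores are
#' z-scored. A group with fewer columns than `n_pcs` keeps all its components
#' and is flagged.
#'
#' @param groups an [build_interaction_groups()] result.
#' @param n_pcs components kept per group (default 5).
#' @return Matrix of stimuli x (<= 3 * n_pcs) component scores with names like
#'   `low_low_pc1`; attributes `loadings` (per-group list) and `flag`
#'   (names of short groups, if any).
#' @export
reduce_groups <- function(groups, n_pcs = 5) {
  stopifnot(inherits(groups, "interaction_groups"))
  out <- list(); loadings <- list(); short <- character(0)
  for (g in names(groups)) {
    M <- groups[[g]]
    if (ncol(M) == 0) next
    k <- min(n_pcs, ncol(M))
    if (k < n_pcs) short <- c(short, g)
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(k), drop = FALSE]
    sc <- sweep(sc, 2, apply(sc, 2, stats::sd), "/")
    colnames(sc) <- paste0(g, "_pc", seq_len(k))
    out[[g]] <- sc
    loadings[[g]] <- pc$rotation[, seq_len(k), drop = FALSE]
  }
  res <- do.call(cbind, out)
  attr(res, "loadings") <- loadings
  if (length(short)) attr(res, "flag") <- short
  res
}
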