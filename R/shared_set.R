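#' Finalize the shared feature set
#'
#' Turns a group-lasso selection over sparse principal components into a named
#' feature set: components active in fewer than `min_participants` participants
#' are removed; the survivors are mapped back to original features through the
#' sparse loadings; among any feature pair whose squared correlation on the
#' selection data exceeds `r2_threshold`, the feature entering later in catalog
#' order is dropped (deterministic tie-break); finally the high-level
#' (annotated) features are appended, reflecting the two-stage procedure of
#' selecting a low-level set first and then augmenting it with the annotated
#' attributes.
#'
#' @param selection a [group_lasso_select()] fit on sparse PC scores.
#' @param spca the [orthogonalize_sparse_pca()] object that produced the scores.
#' @param features the stimuli x features matrix the selection was run on
#'   (used for the correlation dedup), columns in catalog order.
#' @param min_participants a component must be active in at least this many
#'   participants to survive (default 2).
#' @param r2_threshold squared-correlation threshold for the dedup (default 0.5).
#' @param high_level character vector of high-level feature names to append.
#' @return Object of class `shared_feature_set`: character vector of feature
#'   names with attribute `level` ("low"/"high" per entry).
#' @export
finalize_shared_set <- function(selection, spca, features,
                                min_participants = 2, r2_threshold = 0.5,
                                high_level = character(0)) {
  stopifnot(inherits(selection, "group_lasso_fit"),
            inherits(spca, "sparse_pca"))
  shared_pcs <- rowSums(selection$active_by_participant) >= min_participants
  if (!any(shared_pcs))
    stop("no component is shared by >= ", min_participants,
         " participants; revise the lambda grid (selection too sparse)")

  keep_load <- spca$loadings[, shared_pcs, drop = FALSE]
  feat_names <- rownames(keep_load)[rowSums(abs(keep_load) > 1e-8) > 0]
  if (!length(feat_names))
    stop("surviving components have no nonzero loadings; revise lambda grid")

  # dedup in catalog (column) order: keep the earlier feature of any pair
  # with r^2 above threshold
  feat_names <- intersect(colnames(features), feat_names)  # catalog order
  Xs <- as.matrix(features)[, feat_names, drop = FALSE]
  r2 <- stats::cor(Xs)^2
  keep <- rep(TRUE, length(feat_names))
  for (i in seq_along(feat_names)) {
    if (!keep[i]) next
    for (j in seq_along(feat_names)) {
      if (j <= i || !keep[j]) next
      if (r2[i, j] > r2_threshold) keep[j] <- FALSE
    }
  }
  low <- feat_names[keep]
  out <- c(low, high_level)
  structure(out,
            level = c(rep("low", length(low)), rep("high", length(high_level))),
            class = "shared_feature_set")
}

#' @export
print.shared_feature_set <- function(x, ...) {
  lv <- attr(x, "level")
  cat(sprintf("<shared_feature_set: %d features (%d low, %d high)>\n",
              length(x), sum(lv == "low"), sum(lv == "high")))
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' Shared-feature selection pipeline
#'
#' Convenience wrapper running the full group-level selection: z-scored
#' low-level features are orthogonalized by sparse PCA, a group lasso picks the
#' components predictive across participants (penalty by stimulus-level CV),
#' and [finalize_shared_set()] maps the surviving components back to named
#' features, dedups them, and appends the high-level features.
#'
#' @param features stimuli x features matrix (catalog order).
#' @param ratings stimuli x participants matrix.
#' @param level character vector, "low"/"high" per feature column.
#' @param n_components sparse-PCA components (default: n. low-level columns,
#'   capped at n. stimuli - 1).
#' @param sparsity sparse-PCA sparsity.
#' @param ... further arguments to [group_lasso_select()].
#' @inheritParams finalize_shared_set
#' @return A `shared_feature_set`; the selection objects are attached as
#'   attributes `spca` and `selection`.
#' @export
select_shared_features <- function(features, ratings, level,
                                   n_components = NULL, sparsity = 0.25,
                                   min_participants = 2, r2_threshold = 0.5,
                                   ...) {
  stopifnot(ncol(features) == length(level))
  low <- level == "low"
  Xlow <- as.matrix(features)[, low, drop = FALSE]
  k <- n_components %||% min(ncol(Xlow), nrow(Xlow) - 1L)
  spca <- orthogonalize_sparse_pca(Xlow, n_components = k, sparsity = sparsity)
  sel <- group_lasso_select(spca$scores, ratings, ...)
  out <- finalize_shared_set(sel, spca, Xlow,
                             min_participants = min_participants,
                             r2_threshold = r2_threshold,
                             high_level = colnames(features)[!low])
  attr(out, "spca") <- spca
  attr(out, "selection") <- sel
  out
}
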