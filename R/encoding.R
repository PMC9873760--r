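#' Build a GLM design matrix from an event design
#'
#' Constructs HRF-convolved task regressors: an unmodulated stimulus regressor,
#' stick regressors at decision, action and feedback onsets, and one parametric
#' regressor per modulator column. Parametric modulators are mean-centred
#' before convolution and are never serially orthogonalized against each other.
#' In `onset_stick` mode the per-trial amplitude enters as an impulse at the
#' stimulus onset; in `epoch_boxcar` mode it is spread over the 3 s stimulus
#' epoch (used by the PPI variant, where feature integration is assumed to span
#' the whole presentation). Nuisance columns are appended unconvolved, plus one
#' intercept column per run. Convolution is performed within run.
#'
#' @param design an [make_design()] result.
#' @param modulators optional trials x k matrix of per-trial amplitudes
#'   (features and/or ratings), rows in `design$events` order.
#' @param nuisance optional timepoints x m matrix.
#' @param mode `"onset_stick"` or `"epoch_boxcar"` for the parametric columns.
#' @param center_modulators mean-centre modulators before convolution
#'   (default TRUE; required for interpretable main effects when no
#'   orthogonalization is applied).
#' @return Object of class `glm_design`: `X` (timepoints x regressors),
#'   `names`, `task` (logical: HRF-convolved task column), `run` (run per
#'   timepoint), `tr`.
#' @export
build_design_matrix <- function(design, modulators = NULL, nuisance = NULL,
                                mode = c("onset_stick", "epoch_boxcar"),
                                center_modulators = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  mode <- match.arg(mode)
  ev <- design$events
  if (!is.null(modulators)) {
    modulators <- as.matrix(modulators)
    if (nrow(modulators) != nrow(ev))
      stop("modulator rows (", nrow(modulators),
           ") do not align with trials (", nrow(ev), ")")
    if (is.null(colnames(modulators)))
      colnames(modulators) <- paste0("mod", seq_len(ncol(modulators)))
    if (center_modulators) modulators <- sweep(modulators, 2,
                                               colMeans(modulators))
  }
  n_time <- design$n_time
  tr <- design$tr
  total_t <- sum(n_time)
  run_of_t <- rep(seq_len(design$runs), n_time)

  k <- if (is.null(modulators)) 0L else ncol(modulators)
  task_names <- c("stimulus", "decision", "action", "feedback",
                  if (k) colnames(modulators))
  Xt <- matrix(0, total_t, length(task_names),
               dimnames = list(NULL, task_names))
  t_off <- 0L
  for (r in seq_len(design$runs)) {
    er <- ev[ev$run == r, ]
    idx <- which(ev$run == r)
    rows <- t_off + seq_len(n_time[r])
    ones <- rep(1, nrow(er))
    Xt[rows, "stimulus"] <- convolve_events(er$onset_stimulus, ones,
                                            n_time[r], tr)
    Xt[rows, "decision"] <- convolve_events(er$onset_decision, ones,
                                            n_time[r], tr)
    Xt[rows, "action"] <- convolve_events(er$onset_action, ones,
                                          n_time[r], tr)
    Xt[rows, "feedback"] <- convolve_events(er$onset_feedback, ones,
                                            n_time[r], tr)
    if (k) for (j in seq_len(k)) {
      Xt[rows, 4L + j] <- if (mode == "onset_stick")
        convolve_events(er$onset_stimulus, modulators[idx, j], n_time[r], tr)
      else
        convolve_events(er$onset_stimulus, modulators[idx, j], n_time[r], tr,
                        mode = "boxcar", durations = er$stimulus_duration)
    }
    t_off <- t_off + n_time[r]
  }

  Xr <- matrix(0, total_t, design$runs,
               dimnames = list(NULL, paste0("run", seq_len(design$runs))))
  Xr[cbind(seq_len(total_t), run_of_t)] <- 1
  X <- cbind(Xt, Xr)
  task <- c(rep(TRUE, ncol(Xt)), rep(FALSE, ncol(Xr)))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == total_t)
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    task <- c(task, rep(FALSE, ncol(nuisance)))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qr_x$pivot[seq_len(qr_x$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, names = colnames(X), task = task, run = run_of_t,
                 tr = tr),
            class = "glm_design")
}

#' @export
print.glm_design <- function(x, ...) {
  cat(sprintf("<glm_design: %d timepoints x %d regressors (%d task)>\n",
              nrow(x$X), ncol(x$X), sum(x$task)))
  invisible(x)
}

# Multi-voxel OLS: coefficients, residual sum of squares and residual df for
# Y (timepoints x voxels) on X.
fit_glm <- function(X, Y) {
  qx <- qr(X)
  B <- qr.coef(qx, Y)
  B[is.na(B)] <- 0
  R <- Y - X %*% B
  list(coef = B, rss = colSums(R^2), df = nrow(X) - qx$rank, qr = qx)
}

#' Per-trial response amplitudes (betas) at each voxel
#'
#' Ordinary least squares on a GLM with one HRF-convolved stick regressor per
#' trial at the stimulus onset, plus decision/action/feedback sticks, run
#' intercepts and any supplied nuisance columns. This is the single-GLM
#' scheme: all trial regressors are estimated jointly.
#'
#' @param bold a [make_bold()] result (or a list with `signal`, `tr`, `run`).
#' @param design the [make_design()] the session was generated from.
#' @param nuisance optional timepoints x m matrix (defaults to
#'   `bold$nuisance` when present).
#' @return trials x voxels matrix of beta estimates, trial order preserved.
#' @export
estimate_trial_betas <- function(bold, design, nuisance = bold$nuisance) {
  ev <- design$events
  n_time <- design$n_time
  tr <- design$tr
  total_t <- sum(n_time)
  n_trials <- nrow(ev)
  if (n_trials + design$runs + 3 >= total_t)
    stop("more regressors than timepoints; estimate per run instead")

  Xtr <- matrix(0, total_t, n_trials)
  Xep <- matrix(0, total_t, 3,
                dimnames = list(NULL, c("decision", "action", "feedback")))
  t_off <- 0L
  for (r in seq_len(design$runs)) {
    er <- ev[ev$run == r, ]
    idx <- which(ev$run == r)
    rows <- t_off + seq_len(n_time[r])
    for (k in seq_along(idx))
      Xtr[rows, idx[k]] <- convolve_events(er$onset_stimulus[k], 1,
                                           n_time[r], tr)
    ones <- rep(1, nrow(er))
    Xep[rows, 1] <- convolve_events(er$onset_decision, ones, n_time[r], tr)
    Xep[rows, 2] <- convolve_events(er$onset_action, ones, n_time[r], tr)
    Xep[rows, 3] <- convolve_events(er$onset_feedback, ones, n_time[r], tr)
    t_off <- t_off + n_time[r]
  }
  run_of_t <- rep(seq_len(design$runs), n_time)
  Xr <- matrix(0, total_t, design$runs)
  Xr[cbind(seq_len(total_t), run_of_t)] <- 1
  X <- cbind(Xtr, Xep, Xr)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  fit <- fit_glm(X, t(bold$signal))
  B <- fit$coef[seq_len(n_trials), , drop = FALSE]
  rownames(B) <- ev$stimulus
  B
}

#' Group F-test over a set of parametric regressors
#'
#' Partial F-statistic per voxel for the null that all coefficients of the
#' named regressor group are zero, against the full model:
#' `F = ((RSS_reduced - RSS_full) / q) / (RSS_full / df_res)` with
#' `q` = group size. Significance is the parametric upper-tail p-value at
#' `alpha`, uncorrected (the voxelwise replacement for cluster-level
#' correction).
#'
#' @param dm a [build_design_matrix()] result.
#' @param bold a `bold_dataset` (or any list with `signal` voxels x time).
#' @param group character vector of regressor names to test jointly.
#' @param alpha significance level (default 0.001).
#' @return Object of class `voxel_stat_map`: data.frame with `statistic`
#'   (F), `p`, `significant`; attributes `df` and `group`.
#' @export
group_f_test <- function(dm, bold, group, alpha = 0.001) {
  stopifnot(inherits(dm, "glm_design"))
  missing <- setdiff(group, dm$names)
  if (length(missing))
    stop("regressor(s) not in the design: ", paste(missing, collapse = ", "))
  Y <- t(bold$signal)
  full <- fit_glm(dm$X, Y)
  # Wald form of the partial F (identical to the full-vs-reduced RSS form for
  # least squares, but needs only the one fit)
  g <- match(group, colnames(dm$X))
  xtxi <- chol2inv(chol(crossprod(dm$X)))
  q <- length(group)
  Tq <- chol(solve(xtxi[g, g, drop = FALSE])) %*%
    full$coef[g, , drop = FALSE]
  f <- (colSums(Tq^2) / q) / (full$rss / full$df)
  p <- stats::pf(f, q, full$df, lower.tail = FALSE)
  structure(data.frame(statistic = f, p = p, significant = p < alpha),
            df = c(q, full$df), group = group, alpha = alpha,
            class = c("voxel_stat_map", "data.frame"))
}

#' Cross-validated sparse (lasso) encoding with shuffled-label nulls
#'
#' At each voxel, per-trial response amplitudes are regressed on the z-scored
#' features with a lasso penalty; the penalty is optimized by `n_folds`-fold
#' cross-validation. The encoding statistic per feature group (e.g. low/high
#' level) is the sum of squared weights of the group's features. The null
#' distribution is built per ROI by re-running the identical fit with stimulus
#' labels shuffled anew at every regression and pooling the resulting
#' statistics over the ROI's voxels; a voxel is significant for a group when
#' its statistic exceeds the `1 - alpha` quantile of that ROI's pooled null.
#'
#' @param betas trials x voxels matrix ([estimate_trial_betas()] output);
#'   standardized per voxel internally.
#' @param features trials x features matrix (z-scored internally).
#' @param groups named list of feature-name (or column-index) vectors, e.g.
#'   `list(low = ..., high = ...)`.
#' @param roi factor of ROI labels, one per voxel.
#' @param n_folds CV folds for the penalty (default 12).
#' @param n_null shuffled-label regressions per voxel used to build the pooled
#'   ROI null (default 200).
#' @param alpha significance level on the empirical null (default 0.001).
#' @param seed seed for folds and shuffles.
#' @return List of class `sparse_encoding_map`: `stat` (voxels x groups),
#'   `significant` (logical, same shape), `null_quantile` (ROIs x groups),
#'   `roi`, `alpha`.
#' @export
voxelwise_sparse_encoding <- function(betas, features, groups, roi,
                                      n_folds = 12, n_null = 200,
                                      alpha = 0.001, seed = 1L) {
  B <- as.matrix(betas)
  X <- as.matrix(features)
  stopifnot(nrow(B) == nrow(X), length(roi) == ncol(B))
  if (nrow(B) < n_folds) stop("fewer trials than folds")
  roi <- droplevels(as.factor(roi))
  Xz <- scale(X)
  gidx <- lapply(groups, function(g)
    if (is.character(g)) match(g, colnames(X)) else as.integer(g))

  ssw_fit <- function(y, foldid) {
    y <- as.numeric(scale(y))
    cv <- glmnet::cv.glmnet(Xz, y, alpha = 1, foldid = foldid,
                            standardize = FALSE)
    w <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    vapply(gidx, function(ix) sum(w[ix]^2), numeric(1))
  }

  withr_seed(seed, {
    n <- nrow(B)
    foldid <- sample(rep_len(seq_len(n_folds), n))
    stat <- t(vapply(seq_len(ncol(B)), function(v) ssw_fit(B[, v], foldid),
                     numeric(length(groups))))
    colnames(stat) <- names(groups)

    thr <- matrix(NA_real_, nlevels(roi), length(groups),
                  dimnames = list(levels(roi), names(groups)))
    sig <- stat
    for (rr in levels(roi)) {
      vix <- which(roi == rr)
      null <- do.call(rbind, lapply(seq_len(n_null), function(s) {
        v <- vix[(s - 1L) %% length(vix) + 1L]   # cycle the ROI's voxels
        ssw_fit(B[sample(n), v], foldid)
      }))
      thr[rr, ] <- apply(null, 2, stats::quantile, probs = 1 - alpha)
      sig[vix, ] <- sweep(stat[vix, , drop = FALSE], 2, thr[rr, ], ">")
    }
    structure(list(stat = stat, significant = sig > 0, null_quantile = thr,
                   roi = roi, alpha = alpha),
              class = "sparse_encoding_map")
  })
}

#' ROI proportion profile and hierarchy index
#'
#' For each ROI (in the supplied anatomical order) computes the proportion of
#' voxels significant for each feature group, and summarizes the low-to-high
#' progression as the hierarchy index: the Spearman rank correlation between
#' the ROI order and the difference (high proportion - low proportion).
#'
#' @param significant voxels x groups logical matrix (from [group_f_test()]
#'   per group, or a `sparse_encoding_map`).
#' @param roi factor of ROI labels per voxel.
#' @param roi_order character vector of ROI names, ordered (e.g. early visual
#'   to higher visual).
#' @param low,high group (column) names used for the hierarchy index.
#' @return Object of class `roi_profile`: data.frame with one row per ROI and
#'   one proportion column per group; attribute `hierarchy_index`.
#' @export
roi_proportion_profile <- function(significant, roi, roi_order,
                                   low = "low", high = "high") {
  S <- as.matrix(significant)
  stopifnot(length(roi) == nrow(S))
  prop <- t(vapply(roi_order, function(rr) {
    ix <- roi == rr
    if (!any(ix)) return(rep(NA_real_, ncol(S)))
    colMeans(S[ix, , drop = FALSE])
  }, numeric(ncol(S))))
  colnames(prop) <- colnames(S)
  out <- data.frame(roi = roi_order, prop, row.names = NULL)
  d <- prop[, high] - prop[, low]
  hi <- if (all(is.na(d)) || stats::sd(d, na.rm = TRUE) == 0) 0
        else stats::cor(seq_along(roi_order), d, method = "spearman",
                        use = "complete.obs")
  structure(out, hierarchy_index = hi, class = c("roi_profile", "data.frame"))
}
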