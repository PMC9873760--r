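#' Group-lasso selection of features shared across participants
#'
#' Solves the joint regression of every participant's ratings on a shared
#' design matrix with a lasso penalty at the group level, one group per design
#' column collecting that column's coefficients across all participants:
#' \deqn{\min_B \; \tfrac12 \|Y - Z B\|_F^2 + \lambda \sum_j \|B_{j\cdot}\|_2}
#' where `Z` is stimuli x columns (z-scored, shared across participants), `Y`
#' is stimuli x participants (centred per participant) and row `j` of `B` is
#' group `j`. A group with zero norm is unselected for every participant; a
#' group that survives may still be active in only a subset of participants.
#'
#' The solver is FISTA with a group soft-threshold proximal step and
#' backtracking line search (step halving). A monotone safeguard re-takes the
#' proximal step from the current iterate whenever the extrapolated step would
#' increase the objective, so the objective is non-increasing. Convergence is
#' declared when the relative objective change drops below `tol`.
#'
#' When `lambda` is NULL it is chosen by cross-validation over stimulus-level
#' folds shared across participants, on a log-spaced grid of `n_lambda` points
#' spanning `[1e-4, 1] * lambda_max`.
#'
#' @param design stimuli x columns shared design matrix (e.g. sparse PC scores).
#' @param ratings stimuli x participants matrix of ratings.
#' @param lambda penalty; NULL for cross-validated selection.
#' @param n_folds CV folds (stimulus level, shared across participants).
#' @param n_lambda grid size for the CV path.
#' @param max_iter,tol FISTA controls.
#' @param seed fold-assignment seed.
#' @return List of class `group_lasso_fit`: `coefficients` (columns x
#'   participants, on the standardized design scale), `intercepts`, `active`
#'   (logical, per group), `active_by_participant` (logical matrix), `lambda`,
#'   `lambda_grid`, `cv_error`, `converged`, `objective`.
#' @export
group_lasso_select <- function(design, ratings, lambda = NULL, n_folds = 10,
                               n_lambda = 30, max_iter = 10000, tol = 1e-8,
                               seed = 1L) {
  Z <- as.matrix(design)
  Y <- as.matrix(ratings)
  stopifnot(nrow(Z) == nrow(Y))
  sz <- apply(Z, 2, stats::sd); sz[sz == 0] <- 1
  Zs <- sweep(sweep(Z, 2, colMeans(Z)), 2, sz, "/")
  my <- colMeans(Y)
  Yc <- sweep(Y, 2, my)

  lam_max <- max(sqrt(rowSums(crossprod(Zs, Yc)^2)))
  grid <- NULL; cv_err <- NULL
  if (is.null(lambda)) {
    grid <- lam_max * 10^seq(0, -4, length.out = n_lambda)
    folds <- withr_seed(seed, sample(rep_len(seq_len(n_folds), nrow(Zs))))
    errs <- matrix(0, n_folds, n_lambda)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      Ztr <- Zs[tr, , drop = FALSE]; Ytr <- Yc[tr, , drop = FALSE]
      Zva <- Zs[!tr, , drop = FALSE]; Yva <- Yc[!tr, , drop = FALSE]
      B <- matrix(0, ncol(Zs), ncol(Yc))
      for (l in seq_along(grid)) {   # warm-started path, large -> small
        fit <- fista_group_lasso(Ztr, Ytr, grid[l], B0 = B,
                                 max_iter = max_iter, tol = tol)
        B <- fit$B
        act <- rowSums(abs(B) > 1e-8) > 0
        # relaxed validation: unpenalized refit on the active set, so the
        # CV curve reflects selection rather than shrinkage bias
        P <- if (any(act)) {
          Br <- qr.coef(qr(Ztr[, act, drop = FALSE]), Ytr)
          Zva[, act, drop = FALSE] %*% Br
        } else 0
        errs[f, l] <- mean((P - Yva)^2)
      }
    }
    cv_err <- colMeans(errs)
    # one-standard-error rule: sparsest model within one SE of the minimum
    se <- apply(errs, 2, stats::sd) / sqrt(n_folds)
    imin <- which.min(cv_err)
    lambda <- grid[which(cv_err <= cv_err[imin] + se[imin])[1]]
  }

  fit <- fista_group_lasso(Zs, Yc, lambda, max_iter = max_iter, tol = tol)
  B <- fit$B
  rownames(B) <- colnames(Z)
  colnames(B) <- colnames(Y)
  act_mat <- abs(B) > 1e-8
  structure(list(coefficients = B,
                 intercepts = my,
                 active = rowSums(act_mat) > 0,
                 active_by_participant = act_mat,
                 lambda = lambda, lambda_grid = grid, cv_error = cv_err,
                 converged = fit$converged, objective = fit$objective),
            class = "group_lasso_fit")
}

#' @export
print.group_lasso_fit <- function(x, ...) {
  cat(sprintf("<group_lasso_fit: %d/%d groups active, lambda=%.4g%s>\n",
              sum(x$active), length(x$active), x$lambda,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

# FISTA with group soft-threshold prox, backtracking (step halving) and a
# monotone safeguard. Z and Y are assumed centred/standardized by the caller.
fista_group_lasso <- function(Z, Y, lambda, B0 = NULL, max_iter = 10000,
                              tol = 1e-8) {
  J <- ncol(Z); P <- ncol(Y)
  B <- B0 %||% matrix(0, J, P)
  ZtZ <- crossprod(Z)
  ZtY <- crossprod(Z, Y)
  yss <- sum(Y^2)

  loss <- function(B) 0.5 * (yss - 2 * sum(B * ZtY) + sum(B * (ZtZ %*% B)))
  pen <- function(B) lambda * sum(sqrt(rowSums(B^2)))
  prox <- function(M, step) {
    nrm <- sqrt(rowSums(M^2))
    shrink <- pmax(0, 1 - step * lambda / pmax(nrm, .Machine$double.xmin))
    M * shrink
  }

  L <- max(1, sum(diag(ZtZ)) / J)   # initial Lipschitz guess; grown as needed
  A <- B; tk <- 1
  obj <- loss(B) + pen(B)
  objs <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- ZtZ %*% A - ZtY
    fA <- loss(A)
    repeat {                         # backtracking: halve the step
      Bn <- prox(A - G / L, 1 / L)
      D <- Bn - A
      if (loss(Bn) <= fA + sum(G * D) + 0.5 * L * sum(D^2)) break
      L <- L * 2
    }
    objn <- loss(Bn) + pen(Bn)
    if (objn > obj) {                # monotone safeguard: step from B, reset
      G <- ZtZ %*% B - ZtY
      fB <- loss(B)
      repeat {
        Bn <- prox(B - G / L, 1 / L)
        D <- Bn - B
        if (loss(Bn) <= fB + sum(G * D) + 0.5 * L * sum(D^2)) break
        L <- L * 2
      }
      objn <- loss(Bn) + pen(Bn)
      tk <- 1
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    A <- Bn + ((tk - 1) / tn) * (Bn - B)
    rel <- abs(obj - objn) / max(1, abs(obj))
    B <- Bn; obj <- objn; tk <- tn
    objs <- c(objs, obj)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(B = B, converged = converged, objective = objs)
}
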