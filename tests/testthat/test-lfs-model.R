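test_that("noiseless linear ratings are predicted essentially perfectly", {
  set.seed(11)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- as.numeric(X %*% rnorm(8))
  fit <- fit_ridge_cv(X, y, n_folds = 20)
  expect_gte(fit$accuracy, 0.999)
  expect_equal(length(fit$predictions), 200)
  expect_equal(sort(unique(table(fit$fold))), 10L)  # every stimulus once
})

test_that("ridge weights at SNR 1 recover the planted taste direction", {
  set.seed(21)
  rs <- replicate(3, {
    X <- matrix(rnorm(500 * 18), 500, 18)
    w <- rnorm(18)
    v <- as.numeric(X %*% w)
    y <- v + rnorm(500, sd = stats::sd(v))
    fit <- fit_ridge_cv(X, y, n_folds = 20)
    cor(fit$weights, w)
  })
  expect_true(all(rs > 0.85))
})

test_that("accuracy is invariant to the fold labelling order", {
  set.seed(5)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(120)
  folds <- rep_len(1:10, 120)
  f1 <- fit_ridge_cv(X, y, folds = folds)
  f2 <- fit_ridge_cv(X, y, folds = 11 - folds)  # reversed labels, same split
  expect_equal(f1$accuracy, f2$accuracy, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged or dropped", {
  set.seed(3)
  X <- cbind(rnorm(60), rep(1, 60))
  colnames(X) <- c("a", "const")
  expect_warning(fit <- fit_ridge_cv(X, rnorm(60), n_folds = 5), "const")
  expect_equal(unname(fit$weights["const"]), 0)
  f2 <- suppressWarnings(fit_ridge_cv(matrix(rnorm(60), 60, 1), rep(2, 60),
                                      n_folds = 5))
  expect_true(is.na(f2$accuracy))
  expect_equal(f2$flag, "constant_ratings")
})

test_that("permutation test is extreme for planted signal and calibrated under the null", {
  set.seed(31)
  X <- matrix(rnorm(300 * 10), 300, 10)
  v <- as.numeric(X %*% rnorm(10))
  y <- v + rnorm(300, sd = sd(v))         # SNR 1
  fit <- fit_ridge_cv(X, y, n_folds = 20)
  pt <- permutation_test(fit, X, y, n_perm = 500, seed = 2)
  expect_equal(pt$p_value, 1 / 501)       # observed beats every null draw
  # chance = null mean; near zero up to the pessimism bias of pooled CV
  expect_lt(abs(pt$chance), 0.15)
  # no-signal case: accuracy falls inside the null band
  y0 <- sample(y)
  fit0 <- fit_ridge_cv(X, y0, n_folds = 20)
  pt0 <- permutation_test(fit0, X, y0, n_perm = 300, seed = 3)
  expect_gt(pt0$p_value, 0.001)
  expect_gte(fit0$accuracy, min(pt0$null))
  expect_lte(fit0$accuracy, max(pt0$null))
  expect_warning(permutation_test(fit, X, y, n_perm = 50), "unstable")
})

test_that("sparse PCA at sparsity 0 reduces to ordinary PCA", {
  set.seed(41)
  X <- matrix(rnorm(80 * 10), 80, 10)
  sp <- orthogonalize_sparse_pca(X, 4, sparsity = 0)
  pr <- stats::prcomp(scale(X))
  # same reconstruction error from 4 components
  rec_sp <- sp$scores %*% t(sp$loadings)
  rec_pr <- pr$x[, 1:4] %*% t(pr$rotation[, 1:4])
  expect_equal(sum((scale(X) - rec_sp)^2), sum((scale(X) - rec_pr)^2),
               tolerance = 1e-6)
})

test_that("sparse PCA matches an independent implementation on leading loadings", {
  set.seed(42)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 5] <- X[, 1] + rnorm(60, sd = 0.05)
  sp <- orthogonalize_sparse_pca(X, 2, sparsity = 0.5)
  mx <- mixOmics::spca(scale(X), ncomp = 2,
                       keepX = rep(sum(sp$loadings[, 1] != 0), 2))
  a1 <- abs(cor(sp$scores[, 1], mx$variates$X[, 1]))
  expect_gt(a1, 0.95)
})

test_that("duplicated feature columns load on a single sparse component", {
  set.seed(43)
  base <- matrix(rnorm(100 * 4), 100, 4)
  X <- cbind(base, base[, 2])   # duplicate column
  colnames(X) <- paste0("f", 1:5)
  sp <- orthogonalize_sparse_pca(X, 3, sparsity = 0.4)
  ld <- abs(sp$loadings)
  dup_comp <- which.max(ld["f2", ])
  expect_gt(ld["f5", dup_comp], 0)
  # component scores approximately orthogonal
  cc <- abs(cor(sp$scores))
  expect_true(all(cc[upper.tri(cc)] <= 0.1))
})

test_that("a component whose loadings all shrink to zero is dropped with a warning", {
  set.seed(44)
  # identical columns give tied loadings; the quantile soft-threshold then
  # zeroes the whole vector
  X <- matrix(rep(rnorm(30), 3), 30, 3)
  w <- capture_warnings(sp <- orthogonalize_sparse_pca(X, 2, sparsity = 0.5))
  expect_true(any(grepl("dropped", w)))
  expect_lt(ncol(sp$loadings), 2)
})

test_that("group lasso matches per-participant least squares at lambda 0", {
  set.seed(51)
  Z <- matrix(rnorm(100 * 5), 100, 5)
  Y <- Z %*% matrix(rnorm(15), 5, 3) + matrix(rnorm(300, sd = .5), 100)
  gl <- group_lasso_select(Z, Y, lambda = 0)
  Zs <- scale(Z); Yc <- scale(Y, scale = FALSE)
  ols <- qr.coef(qr(Zs), Yc)
  obj_gl <- 0.5 * sum((Yc - Zs %*% gl$coefficients)^2)
  obj_ols <- 0.5 * sum((Yc - Zs %*% ols)^2)
  expect_lt(obj_gl - obj_ols, 1e-6)
})

test_that("a large enough lambda shrinks every group to zero", {
  set.seed(52)
  Z <- matrix(rnorm(80 * 6), 80, 6)
  Y <- matrix(rnorm(160), 80, 2)
  gl <- group_lasso_select(Z, Y, lambda = 1e6)
  expect_false(any(gl$active))
})

test_that("FISTA objective is non-increasing and the path is nested in lambda", {
  set.seed(53)
  Z <- scale(matrix(rnorm(120 * 8), 120, 8))
  Y <- scale(Z %*% matrix(rnorm(32), 8, 4) + matrix(rnorm(480), 120),
             scale = FALSE)
  lams <- max(sqrt(rowSums(crossprod(Z, Y)^2))) * 10^seq(0, -3, length.out = 8)
  n_active <- integer(0)
  for (l in lams) {
    f <- lfsvalue:::fista_group_lasso(Z, Y, l)
    expect_true(all(diff(f$objective) <= 1e-9))
    n_active <- c(n_active, sum(rowSums(abs(f$B) > 1e-8) > 0))
  }
  expect_true(all(diff(n_active) >= 0))   # active set grows as lambda falls
})

test_that("group lasso recovers a planted shared support across seeds", {
  # the full 20-seed recovery suite runs in the acceptance tests; this is a
  # quick smoke version
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    Z <- matrix(rnorm(200 * 10), 200, 10)
    B <- matrix(0, 10, 6); B[c(1, 4, 7), ] <- rnorm(18)
    Y <- Z %*% B + matrix(rnorm(1200), 200)
    gl <- group_lasso_select(Z, Y, seed = s)
    if (identical(which(gl$active), c(1L, 4L, 7L))) hits <- hits + 1L
  }
  expect_gte(hits, 4)
})

test_that("shared-set finalization applies the sharing and dedup rules", {
  co <- lfs_cohort(seed = 8)
  low <- co$level == "low"
  Xlow <- co$features[, low]
  # build a selection where PC2 is active in one participant only
  sp <- orthogonalize_sparse_pca(Xlow, 4, sparsity = 0.5)
  sel <- group_lasso_select(sp$scores, co$ratings, lambda = 0)
  sel$active_by_participant[2, ] <- c(TRUE, rep(FALSE, 4))
  out <- finalize_shared_set(sel, sp, Xlow, high_level = c("high1", "high2"))
  expect_s3_class(out, "shared_feature_set")
  expect_true(all(c("high1", "high2") %in% out))
  lone_pc_feats <- rownames(sp$loadings)[abs(sp$loadings[, 2]) > 1e-8]
  # dedup: no surviving pair above the r^2 threshold
  kept_low <- setdiff(unclass(out), c("high1", "high2"))
  if (length(kept_low) > 1) {
    r2 <- cor(Xlow[, kept_low])^2
    expect_true(all(r2[upper.tri(r2)] <= 0.5))
  }
  # a pair with r^2 = 0.9 keeps only the earlier feature
  X2 <- cbind(a = rnorm(100), b = rnorm(100))
  X2 <- cbind(X2, c = X2[, "a"] * 0.97 + rnorm(100, sd = 0.1))
  sp2 <- orthogonalize_sparse_pca(X2, 2, sparsity = 0)
  sel2 <- group_lasso_select(sp2$scores, matrix(rnorm(300), 100, 3),
                             lambda = 0)
  out2 <- finalize_shared_set(sel2, sp2, X2)
  expect_true("a" %in% out2)
  expect_false("c" %in% out2)
})

test_that("empty selections raise an actionable error", {
  set.seed(61)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  sp <- orthogonalize_sparse_pca(X, 2, sparsity = 0)
  sel <- group_lasso_select(sp$scores, matrix(rnorm(100), 50, 2),
                            lambda = 1e6)
  expect_error(finalize_shared_set(sel, sp, X), "lambda")
})

test_that("the full selection pipeline recovers a planted generative set", {
  hits <- 0L
  for (s in 1:5) {
    co <- lfs_cohort(n_stim = 200, n_participants = 6, active_low = 1:4,
                     noise_sd = 0.7, seed = s)
    out <- select_shared_features(co$features, co$ratings, co$level,
                                  sparsity = 0, seed = s)
    planted <- paste0("low", 1:4)
    if (all(planted %in% out)) hits <- hits + 1L
  }
  expect_gte(hits, 4)
})
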