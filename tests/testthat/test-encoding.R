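# shared small session: 2 runs x 25 trials, 4 low + 2 high features
enc_session <- local({
  des <- make_design(runs = 2, trials_per_run = 25, seed = 21)
  n <- nrow(des$events)
  set.seed(22)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(des$events$stimulus,
                              c(paste0("low", 1:4), paste0("high", 1:2))))
  lev <- c(rep("low", 4), rep("high", 2))
  truth <- synthetic_ground_truth(n_voxels_per_roi = 20, seed = 23)
  bold <- make_bold(des, X, lev, rnorm(n), truth)
  list(des = des, X = X, lev = lev, truth = truth, bold = bold)
})

test_that("an unmodulated single-event regressor equals the sampled HRF", {
  des <- make_design(runs = 1, trials_per_run = 1, seed = 1)
  dm <- build_design_matrix(des)
  onset <- des$events$onset_stimulus[1]
  tt <- (seq_len(des$n_time) - 1) * des$tr - onset
  h <- hrf_double_gamma(pmax(tt, 0)) / max(hrf_double_gamma(seq(0, 32, .1)))
  h[tt < 0] <- 0
  expect_gt(cor(dm$X[, "stimulus"], h), 0.999)
})

test_that("identical modulators are rejected as rank deficient", {
  s <- enc_session
  M <- cbind(a = s$X[, 1], b = s$X[, 1])
  expect_error(build_design_matrix(s$des, modulators = M), "collinear")
})

test_that("t statistics are invariant to modulator scaling", {
  s <- enc_session
  tmap <- function(M) {
    dm <- build_design_matrix(s$des, modulators = M,
                              nuisance = s$bold$nuisance)
    fit <- lfsvalue:::fit_glm(dm$X, t(s$bold$signal))
    j <- which(colnames(dm$X) == "m")
    xtxi <- chol2inv(chol(crossprod(dm$X)))
    fit$coef[j, ] / sqrt(fit$rss / fit$df * xtxi[j, j])
  }
  raw <- matrix(s$X[, 1], dimnames = list(NULL, "m"), ncol = 1)
  zed <- matrix(scale(s$X[, 1]), dimnames = list(NULL, "m"), ncol = 1)
  expect_equal(tmap(raw), tmap(zed), tolerance = 1e-8)
})

test_that("trial betas identify planted amplitudes exactly without noise", {
  des <- make_design(runs = 2, trials_per_run = 20, seed = 2)
  amp <- rnorm(40)
  sig <- matrix(0, 1, sum(des$n_time))
  toff <- 0
  for (r in 1:2) {
    er <- des$events[des$events$run == r, ]
    Rm <- vapply(er$onset_stimulus, function(o)
      lfsvalue:::convolve_events(o, 1, des$n_time[r], des$tr),
      numeric(des$n_time[r]))
    sig[1, toff + seq_len(des$n_time[r])] <- Rm %*% amp[des$events$run == r]
    toff <- toff + des$n_time[r]
  }
  bold <- list(signal = sig, tr = des$tr, nuisance = NULL)
  tb <- estimate_trial_betas(bold, des)
  expect_equal(unname(tb[, 1]), amp, tolerance = 1e-6)
  # a drift absorbed by a nuisance column leaves betas unchanged
  drift <- seq(0, 1, length.out = ncol(sig))
  bold2 <- list(signal = sig + 5 * matrix(drift, 1), tr = des$tr)
  tb2 <- estimate_trial_betas(bold2, des, nuisance = cbind(drift))
  expect_equal(unname(tb2[, 1]), amp, tolerance = 1e-6)
})

test_that("beta estimation refuses designs with more regressors than scans", {
  des <- make_design(runs = 1, trials_per_run = 3, seed = 3,
                     iti_range = c(2, 2.2))
  short <- des
  short$n_time <- 5L    # 3 trial + 3 epoch + 1 run regressors > 5 scans
  bold <- list(signal = matrix(rnorm(2 * 5), 2), tr = des$tr,
               nuisance = NULL)
  expect_error(estimate_trial_betas(bold, short), "regressors")
})

test_that("pure-noise trial betas are centred", {
  des <- make_design(runs = 2, trials_per_run = 15, seed = 4)
  set.seed(5)
  bold <- list(signal = matrix(rnorm(3 * sum(des$n_time)), 3), tr = des$tr,
               nuisance = NULL)
  tb <- estimate_trial_betas(bold, des)
  se <- apply(tb, 2, sd) / sqrt(nrow(tb))
  expect_true(all(abs(colMeans(tb)) < 3.5 * se))
})

test_that("group F-tests separate planted low- and high-level voxels", {
  s <- enc_session
  dm <- build_design_matrix(s$des, modulators = s$X,
                            nuisance = s$bold$nuisance)
  fl <- group_f_test(dm, s$bold, paste0("low", 1:4))
  fh <- group_f_test(dm, s$bold, paste0("high", 1:2))
  v1 <- which(s$bold$roi == "V1")      # gradient 0.1: low-dominated
  phc <- which(s$bold$roi == "PHC")    # gradient 0.9: high-dominated
  expect_gt(mean(fl$significant[v1]), mean(fh$significant[v1]))
  expect_gt(mean(fh$significant[phc]), mean(fl$significant[phc]))
  expect_error(group_f_test(dm, s$bold, "nonexistent"), "not in the design")
  # single-column group: F equals the squared t statistic
  f1 <- group_f_test(dm, s$bold, "low1")
  fit <- lfsvalue:::fit_glm(dm$X, t(s$bold$signal))
  j <- which(colnames(dm$X) == "low1")
  xtxi <- chol2inv(chol(crossprod(dm$X)))
  tj <- fit$coef[j, ] / sqrt(fit$rss / fit$df * xtxi[j, j])
  expect_equal(unname(f1$statistic), unname(tj^2), tolerance = 1e-8)
})

# (F-test null calibration at 5000 voxels runs in the acceptance suite)

test_that("voxelwise lasso encoding flags the planted feature group", {
  s <- enc_session
  tb <- estimate_trial_betas(s$bold, s$des)
  ix <- c(which(s$bold$roi == "V1"), which(s$bold$roi == "PHC"))
  se <- voxelwise_sparse_encoding(
    tb[, ix], s$X, list(low = paste0("low", 1:4), high = paste0("high", 1:2)),
    droplevels(s$bold$roi[ix]), n_null = 20, seed = 41)
  v1 <- seq_len(20); phc <- 20 + seq_len(20)
  expect_gt(mean(se$significant[v1, "low"]), mean(se$significant[v1, "high"]))
  expect_gt(mean(se$significant[phc, "high"]),
            mean(se$significant[phc, "low"]))
  # statistic invariant to feature column order
  perm <- c(3, 1, 4, 2, 6, 5)
  se2 <- voxelwise_sparse_encoding(
    tb[, ix[1:4]], s$X[, perm],
    list(low = paste0("low", 1:4), high = paste0("high", 1:2)),
    droplevels(s$bold$roi[ix[1:4]]), n_null = 5, seed = 41)
  se1 <- voxelwise_sparse_encoding(
    tb[, ix[1:4]], s$X,
    list(low = paste0("low", 1:4), high = paste0("high", 1:2)),
    droplevels(s$bold$roi[ix[1:4]]), n_null = 5, seed = 41)
  expect_equal(se1$stat, se2$stat, tolerance = 1e-4)
  expect_error(voxelwise_sparse_encoding(tb[1:5, ix], s$X[1:5, ],
                                         list(low = "low1"),
                                         droplevels(s$bold$roi[ix])),
               "fewer trials")
})

test_that("ROI profiles are bounded and symmetric maps give index zero", {
  sig <- cbind(low = c(rep(TRUE, 10), rep(FALSE, 10)),
               high = c(rep(TRUE, 10), rep(FALSE, 10)))
  roi <- factor(rep(c("A", "B"), each = 10))
  pr <- roi_proportion_profile(sig, roi, c("A", "B"))
  expect_true(all(pr$low >= 0 & pr$low <= 1))
  expect_equal(attr(pr, "hierarchy_index"), 0)
  # empty ROI flagged as NA
  pr2 <- roi_proportion_profile(sig, roi, c("A", "B", "C"))
  expect_true(is.na(pr2$low[3]))
})

test_that("adding the rating regressor leaves the feature classification unchanged", {
  s <- enc_session
  set.seed(43)
  rating <- as.numeric(scale(s$X %*% rnorm(6) + rnorm(nrow(s$X))))
  dm1 <- build_design_matrix(s$des, modulators = s$X,
                             nuisance = s$bold$nuisance)
  dm2 <- build_design_matrix(s$des, modulators = cbind(s$X, rating = rating),
                             nuisance = s$bold$nuisance)
  prof <- function(dm) {
    fl <- group_f_test(dm, s$bold, paste0("low", 1:4))
    fh <- group_f_test(dm, s$bold, paste0("high", 1:2))
    roi_proportion_profile(cbind(low = fl$significant,
                                 high = fh$significant),
                           s$bold$roi, s$truth$feature_rois)
  }
  p1 <- prof(dm1); p2 <- prof(dm2)
  # the low-dominated and high-dominated ends keep their identity, and the
  # gradient survives, when the rating regressor is added
  expect_equal(sign(p1$high[c(1, 5)] - p1$low[c(1, 5)]),
               sign(p2$high[c(1, 5)] - p2$low[c(1, 5)]))
  expect_gt(attr(p2, "hierarchy_index"), 0.5)
  expect_lt(abs(attr(p1, "hierarchy_index") - attr(p2, "hierarchy_index")),
            0.35)
})
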