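test_that("the default design reproduces the task layout", {
  des <- make_design(seed = 1)
  ev <- des$events
  expect_equal(nrow(ev), 1000)
  expect_equal(length(unique(ev$stimulus)), 1000)   # no repeats
  expect_true(all(ev$stimulus_duration == 3.0))
  expect_true(all(ev$feedback_duration == 0.5))
  expect_true(all(ev$iti >= 2 & ev$iti <= 9))
  expect_equal(des$tr, 1.12)
  expect_equal(des$runs, 20)
  expect_equal(max(table(ev$run)), 50)
  # epochs are ordered within a trial
  expect_true(all(ev$onset_decision > ev$onset_stimulus))
  expect_true(all(ev$onset_action > ev$onset_decision))
  expect_true(all(ev$onset_feedback >= ev$onset_action))
})

test_that("events TSVs are written one per run", {
  des <- make_design(runs = 3, trials_per_run = 5, seed = 2)
  d <- tempfile()
  paths <- write_events_tsv(des, d)
  expect_equal(length(list.files(d)), 3)
  ev1 <- read.delim(file.path(d, "run-01_events.tsv"))
  expect_equal(nrow(ev1), 5)
  expect_true(all(ev1$duration == 3))
})

test_that("stimulus generation is reproducible and honours its controls", {
  s1 <- make_stimulus_images(10, seed = 6)
  s2 <- make_stimulus_images(10, seed = 6)
  expect_identical(lapply(s1$images, `[[`, "pixels"),
                   lapply(s2$images, `[[`, "pixels"))
  # a forced-symmetric image has exactly zero horizontal-mirror error
  sym <- make_stimulus_images(5, seed = 3, p_symmetric = 1, blur_levels = 0)
  img <- sym$images[[1]]
  seg <- segment_image(img, "srm")
  f <- compute_segment_features(img, seg, 0L)
  expect_true(all(sym$truth$symmetric))
  g <- to_gray(img)
  expect_equal(mean((g - g[, ncol(g):1])^2), 0)
  # blur flag: sharp variant scores strictly higher than a blurred one
  sharp <- make_stimulus_images(1, seed = 12, blur_levels = 0)$images[[1]]
  px <- sharp$pixels
  for (ch in 1:3) px[, , ch] <- lfsvalue:::gaussian_blur(px[, , ch], 4)
  expect_gt(as.numeric(compute_blur(sharp)),
            as.numeric(compute_blur(raster_image(px))))
})

test_that("annotations are linear reconstructions at zero noise", {
  set.seed(7)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  ann0 <- make_annotations(X, noise_sd = 0, seed = 2)
  for (nm in c("concreteness", "dynamics", "temperature", "valence")) {
    r2 <- suppressWarnings(summary(lm(ann0[[nm]] ~ scale(X)))$r.squared)
    expect_gte(r2, 1 - 1e-9)
  }
  expect_true(all(ann0$presence_person %in% c(0, 1)))
  # heavy noise destroys the reconstruction
  ann9 <- make_annotations(X, noise_sd = 50, seed = 2)
  r2h <- summary(lm(ann9$concreteness ~ scale(X)))$r.squared
  expect_lt(r2h, 0.3)
})

test_that("ratings follow the planted weights and quartile binning", {
  set.seed(8)
  X <- matrix(rnorm(400 * 5), 400, 5)
  w <- c(2, 0, 0, 0, 0)
  rd <- make_ratings(X, w, noise_sd = 0, seed = 1)
  expect_true(all(rd$ratings %in% 0:3))
  # monotone in the single active feature: rating levels partition the
  # feature range without overlap
  r1 <- as.numeric(rd$ratings[1, ])
  for (lv in 0:2)
    expect_lt(max(X[r1 == lv, 1]), min(X[r1 == lv + 1, 1]))
  expect_equal(as.numeric(table(rd$ratings[1, ])), rep(100, 4))  # balanced
  # all-zero weights give featureless ratings
  rd0 <- make_ratings(X, rep(0, 5), noise_sd = 1, seed = 2)
  expect_lt(abs(cor(X[, 1], as.numeric(rd0$ratings[1, ]))), 0.15)
})

test_that("ratings at default SNR support weight recovery by the ridge fit", {
  set.seed(9)
  X <- matrix(rnorm(500 * 18), 500, 18)
  w <- rnorm(18)
  rd <- make_ratings(X, w, seed = 3)   # default: noise SD = signal SD
  fit <- fit_ridge_cv(X, as.numeric(rd$ratings[1, ]), n_folds = 20)
  expect_gte(cor(fit$weights, w), 0.9)
})

test_that("the ground-truth manifest round-trips and regenerates identically", {
  truth <- synthetic_ground_truth(n_voxels_per_roi = 10, seed = 5)
  p <- tempfile(fileext = ".json")
  write_manifest_json(truth, p)
  truth2 <- read_manifest_json(p)
  expect_equal(truth, truth2)
  des <- make_design(runs = 1, trials_per_run = 8, seed = 2)
  X <- matrix(rnorm(8 * 6), 8, 6)
  lev <- c("low", "low", "low", "low", "high", "high")
  v <- rnorm(8)
  b1 <- make_bold(des, X, lev, v, truth)
  b2 <- make_bold(des, X, lev, v, read_manifest_json(p))
  expect_identical(b1$signal, b2$signal)
  expect_identical(b1$nuisance, b2$nuisance)
})

test_that("a noise-free voxel tracks its convolved modulated regressor exactly", {
  des <- make_design(runs = 1, trials_per_run = 12, seed = 4)
  n <- 12
  set.seed(10)
  X <- matrix(rnorm(n * 2), n, 2)
  lev <- c("low", "high")
  truth <- synthetic_ground_truth(
    n_voxels_per_roi = 1, gradient = 0, feature_rois = "V1",
    integrator_rois = character(0), value_roi = "mPFC",
    coupling = 0, noise_sd = 0, ar_rho = 0, seed = 6)
  bold <- make_bold(des, X, lev, rnorm(n), truth)
  # rebuild the voxel's regressor from the manifest (gradient 0: low only)
  v1 <- bold$signal[1, ] - 0.5 * rowSums(bold$nuisance[, 1:3])
  er <- des$events
  Rmat <- vapply(er$onset_stimulus, function(o)
    lfsvalue:::convolve_events(o, 1, des$n_time, des$tr),
    numeric(des$n_time))
  base <- rowSums(Rmat)
  resid <- v1 - truth$signal_sd * base
  # the residual is an exact linear combination of the trial responses
  fit <- lm(resid ~ Rmat - 1)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("bold datasets expose consistent dimensions and labels", {
  des <- make_design(runs = 2, trials_per_run = 6, seed = 3)
  X <- matrix(rnorm(12 * 4), 12, 4)
  truth <- synthetic_ground_truth(n_voxels_per_roi = 3, seed = 2)
  bold <- make_bold(des, X, c("low", "low", "high", "high"), rnorm(12), truth)
  expect_equal(ncol(bold$signal), sum(des$n_time))
  expect_equal(length(bold$roi), nrow(bold$signal))
  expect_equal(nlevels(bold$roi), 8)   # 5 feature + 2 integrator + value
  expect_true(all(is.finite(bold$signal)))
  expect_error(make_bold(des, X[1:5, ], c("low", "low", "high", "high"),
                         rnorm(12), truth), "align")
})

test_that("bold NIfTI round-trip preserves signal, labels, and TR", {
  des <- make_design(runs = 1, trials_per_run = 5, seed = 8)
  X <- matrix(rnorm(5 * 2), 5, 2)
  truth <- synthetic_ground_truth(n_voxels_per_roi = 2, seed = 3)
  bold <- make_bold(des, X, c("low", "high"), rnorm(5), truth)
  pre <- file.path(tempdir(), "synth")
  write_bold_nifti(bold, pre)
  back <- read_bold_nifti(pre, levels(bold$roi))
  expect_equal(back$signal, unname(bold$signal), tolerance = 1e-6)
  expect_equal(back$roi, bold$roi)
  expect_equal(back$tr, bold$tr, tolerance = 1e-6)
})
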