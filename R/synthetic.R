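#' Procedural stimulus images with known structure
#'
#' Generates abstract "paintings": a solid background overlaid with random
#' solid-colour rectangles, optionally mirrored (exact left-right symmetry) and
#' optionally Gaussian-blurred. The constructor's intended values for checkable
#' properties (largest-region fraction, symmetry class, blur level) are
#' returned alongside the pixels, so feature operators can be validated against
#' ground truth.
#'
#' @param n number of images.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param width,height image size in pixels.
#' @param n_shapes_range range of rectangle counts per image.
#' @param p_symmetric probability an image is constructed mirror-symmetric.
#' @param blur_levels pool of Gaussian blur SDs sampled per image (0 = sharp).
#' @return List of class `stimulus_set`: `images` (list of [raster_image()]),
#'   `truth` (data.frame: stimulus, n_shapes, symmetric, blur_sigma,
#'   background fraction).
#' @export
make_stimulus_images <- function(n, seed = 1L, width = 64L, height = 64L,
                                 n_shapes_range = c(2L, 4L),
                                 p_symmetric = 0.25,
                                 blur_levels = c(0, 0, 0, 1, 2)) {
  stopifnot(n >= 1)
  gen <- function() {
    imgs <- vector("list", n)
    truth <- data.frame(stimulus = paste0("stim", seq_len(n)),
                        n_shapes = integer(n), symmetric = logical(n),
                        blur_sigma = numeric(n), background_frac = numeric(n))
    for (i in seq_len(n)) {
      px <- array(rep(stats::runif(3), each = height * width),
                  c(height, width, 3))
      ns <- sample(seq(n_shapes_range[1], n_shapes_range[2]), 1)
      sym <- stats::runif(1) < p_symmetric
      covered <- matrix(FALSE, height, width)
      for (s in seq_len(ns)) {
        w0 <- sample(ceiling(width / 6):floor(width / 2), 1)
        h0 <- sample(ceiling(height / 6):floor(height / 2), 1)
        r0 <- sample(height - h0 + 1, 1); c0 <- sample(width - w0 + 1, 1)
        colr <- stats::runif(3)
        for (ch in 1:3) px[r0:(r0 + h0 - 1), c0:(c0 + w0 - 1), ch] <- colr[ch]
        covered[r0:(r0 + h0 - 1), c0:(c0 + w0 - 1)] <- TRUE
      }
      if (sym) {                     # mirror the left half onto the right
        half <- floor(width / 2)
        for (ch in 1:3)
          px[, width:(width - half + 1), ch] <- px[, 1:half, ch]
      }
      sig <- sample(blur_levels, 1)
      if (sig > 0) for (ch in 1:3) px[, , ch] <- gaussian_blur(px[, , ch], sig)
      imgs[[i]] <- raster_image(px)
      truth$n_shapes[i] <- ns
      truth$symmetric[i] <- sym
      truth$blur_sigma[i] <- sig
      truth$background_frac[i] <- mean(!covered)
    }
    names(imgs) <- truth$stimulus
    list(images = imgs, truth = truth)
  }
  out <- withr_seed(seed, gen())
  structure(c(out, list(seed = seed)), class = "stimulus_set")
}

# Separable Gaussian blur with edge replication. The kernel is truncated at
# 6 sigma so that the stopband ripple stays far below the spectral power
# threshold used by the blur feature.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(6 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' High-level annotations as noisy mixtures of low-level features
#'
#' Emulates human annotation of abstract attributes: each of concreteness,
#' dynamics, temperature and valence is a linear mixture of the (z-scored)
#' low-level features plus independent Gaussian noise; presence-of-a-person is
#' a median-split binarization of its own latent mixture. With `noise_sd = 0`
#' the four continuous columns are exactly linear in the low-level features.
#'
#' @param low_features stimuli x low-level-features matrix.
#' @param mixing optional features x 5 mixing matrix (columns: concreteness,
#'   dynamics, temperature, valence, presence_person). Default: a seeded sparse
#'   random mixture (about a third of features load on each attribute).
#' @param noise_sd annotation noise SD relative to unit-variance latents.
#' @param seed RNG seed.
#' @return data.frame with the 5 annotation columns; the mixing matrix is
#'   attached as attribute `mixing`.
#' @export
make_annotations <- function(low_features, mixing = NULL, noise_sd = 0.5,
                             seed = 1L) {
  X <- as.matrix(low_features)
  sdx <- apply(X, 2, stats::sd); sdx[sdx == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdx, "/")
  nms <- c("concreteness", "dynamics", "temperature", "valence",
           "presence_person")
  out <- withr_seed(seed, {
    if (is.null(mixing)) {
      mixing <- matrix(stats::rnorm(ncol(Z) * 5), ncol(Z), 5,
                       dimnames = list(colnames(Z), nms))
      mixing[stats::runif(length(mixing)) > 1 / 3] <- 0
    }
    lat <- Z %*% mixing
    lat <- scale(lat)   # unit-variance latents so noise_sd is interpretable
    lat <- lat + stats::rnorm(length(lat), sd = noise_sd)
    df <- as.data.frame(lat)
    names(df) <- nms
    df$presence_person <- as.numeric(df$presence_person >
                                       stats::median(df$presence_person))
    df
  })
  attr(out, "mixing") <- mixing
  out
}

#' Ratings generated from the linear feature summation model
#'
#' Continuous value = weighted sum of the (z-scored) features per participant,
#' plus Gaussian noise, discretized to the 0-3 liking scale by population
#' quartile binning (balanced classes). The noiseless continuous values are
#' retained for recovery tests.
#'
#' @param features stimuli x features matrix.
#' @param weights features x participants matrix (or vector for one
#'   participant) of planted taste weights, rows aligned to feature columns.
#' @param noise_sd rating noise SD; NULL (default) uses the SD of each
#'   participant's noiseless value signal (signal-to-noise ratio 1).
#' @param seed RNG seed.
#' @return List of class `rating_dataset`: `ratings` (participants x stimuli
#'   integer matrix, 0-3), `value` (stimuli x participants continuous truth),
#'   `value_noisy`, `weights`, `noise_sd`.
#' @export
make_ratings <- function(features, weights, noise_sd = NULL, seed = 1L) {
  X <- as.matrix(features)
  W <- as.matrix(weights)
  stopifnot(nrow(W) == ncol(X))
  sdx <- apply(X, 2, stats::sd); sdx[sdx == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdx, "/")
  V <- Z %*% W                                    # stimuli x participants
  sds <- if (is.null(noise_sd)) apply(V, 2, stats::sd) else
    rep_len(noise_sd, ncol(V))
  Vn <- withr_seed(seed, V + matrix(stats::rnorm(length(V)), nrow(V)) *
                     rep(sds, each = nrow(V)))
  R <- apply(Vn, 2, function(v) {
    if (stats::sd(v) == 0) return(rep(0L, length(v)))
    q <- stats::quantile(v, c(.25, .5, .75))
    findInterval(v, q)
  })
  structure(list(ratings = t(R), value = V, value_noisy = Vn,
                 weights = W, noise_sd = sds),
            class = "rating_dataset")
}

#' Event design for the art rating task
#'
#' Lays out `runs` runs of `trials_per_run` trials each: 3 s stimulus
#' presentation, a decision epoch of up to 3 s (button press after a uniform
#' 0.4-2.5 s reaction time), 0.5 s feedback, then an inter-trial interval
#' jittered uniformly between 2 and 9 s. Stimulus ids are unique across the
#' whole session (no repeats). Each run has its own clock starting at
#' `lead_in` seconds.
#'
#' @param runs,trials_per_run design size (defaults 20 x 50 = 1000 trials).
#' @param tr repetition time in seconds (default 1.12).
#' @param seed RNG seed for the jitter and reaction times.
#' @param iti_range ITI jitter bounds in seconds.
#' @param stimulus_duration,decision_duration,feedback_duration epoch lengths.
#' @param lead_in,lead_out dead time at run boundaries (seconds).
#' @return Object of class `experiment_design`: `events` data.frame (run,
#'   trial, stimulus, onset_stimulus, onset_decision, onset_action,
#'   onset_feedback, stimulus_duration, feedback_duration, iti), `tr`,
#'   `n_time` (timepoints per run), `runs`, `trials_per_run`.
#' @export
make_design <- function(runs = 20, trials_per_run = 50, tr = 1.12, seed = 1L,
                        iti_range = c(2, 9), stimulus_duration = 3,
                        decision_duration = 3, feedback_duration = 0.5,
                        lead_in = 4, lead_out = 10) {
  stopifnot(runs >= 1, trials_per_run >= 1)
  ev <- withr_seed(seed, {
    rows <- vector("list", runs)
    sid <- 0L
    for (r in seq_len(runs)) {
      t0 <- lead_in
      m <- trials_per_run
      onset <- rt <- iti <- numeric(m)
      for (k in seq_len(m)) {
        rt[k] <- stats::runif(1, 0.4, 2.5)
        iti[k] <- stats::runif(1, iti_range[1], iti_range[2])
        onset[k] <- t0
        t0 <- t0 + stimulus_duration + decision_duration +
          feedback_duration + iti[k]
      }
      rows[[r]] <- data.frame(
        run = r, trial = seq_len(m),
        stimulus = paste0("stim", sid + seq_len(m)),
        onset_stimulus = onset,
        onset_decision = onset + stimulus_duration,
        onset_action = onset + stimulus_duration + rt,
        onset_feedback = onset + stimulus_duration + decision_duration,
        stimulus_duration = stimulus_duration,
        feedback_duration = feedback_duration,
        iti = iti)
      sid <- sid + m
    }
    do.call(rbind, rows)
  })
  run_end <- tapply(ev$onset_feedback + ev$feedback_duration + ev$iti,
                    ev$run, max) + lead_out
  structure(list(events = ev, tr = tr,
                 n_time = as.integer(ceiling(run_end / tr)),
                 runs = runs, trials_per_run = trials_per_run),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design: %d runs x %d trials, TR=%.2fs, %d timepoints>\n",
              x$runs, x$trials_per_run, x$tr, sum(x$n_time)))
  invisible(x)
}

#' Write a design as BIDS-style events TSVs (one file per run)
#' @param design an [make_design()] result
#' @param dir output directory
#' @return paths, invisibly.
#' @export
write_events_tsv <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(design$runs)
  for (r in seq_len(design$runs)) {
    ev <- design$events[design$events$run == r, ]
    df <- data.frame(onset = ev$onset_stimulus, duration = ev$stimulus_duration,
                     trial_type = "stimulus", stimulus = ev$stimulus,
                     onset_decision = ev$onset_decision,
                     onset_action = ev$onset_action,
                     onset_feedback = ev$onset_feedback, iti = ev$iti)
    paths[r] <- file.path(dir, sprintf("run-%02d_events.tsv", r))
    utils::write.table(df, paths[r], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
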