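#' Ground-truth parameters for simulated multi-region BOLD
#'
#' Describes the planted structure of a simulated session: an ordered set of
#' feature-coding ROIs whose mixture of low- and high-level feature signal
#' follows a gradient `g` (share of high-level signal, emulating the
#' low-to-high progression along the visual hierarchy), "integrator" ROIs
#' (posterior parietal / lateral prefrontal analogues) with mixed coding that
#' are additionally noise-coupled to the value region during stimulus epochs,
#' and one value ROI (medial prefrontal analogue) modulated by the continuous
#' rating signal. The full manifest is reproducible from `seed`.
#'
#' @param n_voxels_per_roi voxels simulated per ROI.
#' @param gradient high-level signal share per ordered feature ROI.
#' @param feature_rois names of the ordered feature ROIs (visual-stream
#'   analogues).
#' @param integrator_rois names of the coupled mixed-coding ROIs.
#' @param value_roi name of the value ROI (PPI seed in synthetic runs).
#' @param coupling strength of the shared stimulus-epoch noise injected into
#'   the value and integrator ROIs (0 = no planted coupling).
#' @param signal_sd amplitude of the feature/value modulation.
#' @param noise_sd white noise SD.
#' @param ar_rho AR(1) coefficient of the temporal noise.
#' @param seed seed for voxel weights and noise.
#' @return List of class `synthetic_ground_truth` (the manifest).
#' @export
synthetic_ground_truth <- function(n_voxels_per_roi = 60,
                                   gradient = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                   feature_rois = c("V1", "V2", "V4", "LO", "PHC"),
                                   integrator_rois = c("PPC", "lPFC"),
                                   value_roi = "mPFC",
                                   coupling = 1, signal_sd = 0.5, noise_sd = 1,
                                   ar_rho = 0.3, seed = 1L) {
  stopifnot(length(gradient) == length(feature_rois))
  structure(list(n_voxels_per_roi = n_voxels_per_roi, gradient = gradient,
                 feature_rois = feature_rois,
                 integrator_rois = integrator_rois, value_roi = value_roi,
                 coupling = coupling, signal_sd = signal_sd,
                 noise_sd = noise_sd, ar_rho = ar_rho, seed = seed),
            class = "synthetic_ground_truth")
}

#' Simulate multi-region BOLD for a session
#'
#' Each feature-ROI voxel responds at stimulus onsets with a per-trial
#' amplitude equal to a voxel-specific random mixture of the stimulus's
#' low-level (weight `1 - g_r`) and high-level (weight `g_r`) feature values;
#' value-ROI voxels are modulated by the continuous rating. All task responses
#' are convolved with the canonical double-gamma HRF. During stimulus epochs
#' only, a shared latent noise series (scaled by `coupling`) is injected into
#' the value ROI and the integrator ROIs, creating the stimulus-locked noise
#' correlation a PPI analysis detects. Voxel noise is AR(1) plus white noise,
#' and six smooth motion-like nuisance regressors contribute weakly to every
#' voxel (they are returned so analyses can regress them out).
#'
#' @param design an [make_design()] result.
#' @param features stimuli x features matrix (z-scored internally), rows in
#'   `design$events$stimulus` order.
#' @param level "low"/"high" tag per feature column.
#' @param value continuous value signal per stimulus (e.g.
#'   `rating_dataset$value_noisy[, p]` or the 0-3 ratings).
#' @param truth a [synthetic_ground_truth()] manifest.
#' @return Object of class `bold_dataset`: `signal` (voxels x timepoints),
#'   `tr`, `roi` (factor per voxel), `nuisance` (timepoints x 6), `run`
#'   (run index per timepoint), `truth`, `design`.
#' @export
make_bold <- function(design, features, level, value, truth) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "synthetic_ground_truth"))
  ev <- design$events
  X <- as.matrix(features)
  if (nrow(X) != nrow(ev))
    stop("features (", nrow(X), " rows) do not align with the design (",
         nrow(ev), " trials)")
  stopifnot(length(level) == ncol(X), length(value) == nrow(ev))
  sdx <- apply(X, 2, stats::sd); sdx[sdx == 0] <- 1
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sdx, "/")
  zval <- as.numeric(scale(value))

  rois <- c(truth$feature_rois, truth$integrator_rois, truth$value_roi)
  nv <- truth$n_voxels_per_roi
  n_vox <- nv * length(rois)
  roi <- factor(rep(rois, each = nv), levels = rois)
  g_by_roi <- c(truth$gradient, rep(0.5, length(truth$integrator_rois)), NA)
  coupled <- roi %in% c(truth$integrator_rois, truth$value_roi)

  tr <- design$tr
  n_time <- design$n_time
  total_t <- sum(n_time)
  run_of_t <- rep(seq_len(design$runs), n_time)

  withr_seed(truth$seed, {
    lowZ <- Z[, level == "low", drop = FALSE]
    highZ <- Z[, level == "high", drop = FALSE]
    # per-voxel unit-variance low and high modulator series
    wl <- matrix(stats::rnorm(ncol(lowZ) * n_vox), ncol(lowZ))
    wh <- matrix(stats::rnorm(ncol(highZ) * n_vox), ncol(highZ))
    ml <- scale(lowZ %*% wl)   # trials x voxels
    mh <- scale(highZ %*% wh)

    sig <- matrix(0, n_vox, total_t)
    nuis <- matrix(0, total_t, 6)
    latent <- stats::rnorm(total_t)
    t_off <- 0L
    for (r in seq_len(design$runs)) {
      er <- ev[ev$run == r, ]
      idx <- ev$run == r
      tcols <- t_off + seq_len(n_time[r])
      box <- sample_boxcar(er$onset_stimulus,
                           er$onset_stimulus + er$stimulus_duration,
                           n_time[r], tr)
      # task responses, all voxels at once: amplitudes trials x voxels
      gv <- g_by_roi[as.integer(roi)]
      amp <- matrix(0, sum(idx), n_vox)
      fr <- !is.na(gv)
      amp[, fr] <- sweep(ml[idx, fr, drop = FALSE], 2, 1 - gv[fr], "*") +
        sweep(mh[idx, fr, drop = FALSE], 2, gv[fr], "*")
      amp[, !fr] <- zval[idx]                       # value ROI
      # per-trial HRF response basis (timepoints x trials), shared by voxels
      Rmat <- vapply(er$onset_stimulus, function(o)
        convolve_events(o, 1, n_time[r], tr), numeric(n_time[r]))
      base <- rowSums(Rmat)     # unmodulated stimulus response
      sig[, tcols] <- truth$signal_sd * t(base + Rmat %*% amp)
      # stimulus-locked shared noise into coupled ROIs
      lb <- latent[tcols] * box * truth$coupling
      sig[coupled, tcols] <- sig[coupled, tcols] +
        matrix(lb, sum(coupled), n_time[r], byrow = TRUE)
      # smooth nuisance series per run
      tt <- seq_len(n_time[r]) / n_time[r]
      for (j in 1:6)
        nuis[tcols, j] <- sin(2 * pi * stats::runif(1, 0.5, 3) * tt +
                                stats::runif(1, 0, 2 * pi))
      # AR(1) + white noise (recursion vectorized across voxels)
      e <- matrix(stats::rnorm(n_vox * n_time[r]), n_vox)
      for (tt2 in 2:n_time[r])
        e[, tt2] <- e[, tt2] + truth$ar_rho * e[, tt2 - 1L]
      sig[, tcols] <- sig[, tcols] + truth$noise_sd * e +
        0.5 * matrix(rep(rowSums(nuis[tcols, 1:3]), each = n_vox), n_vox)
      t_off <- t_off + n_time[r]
    }
    structure(list(signal = sig, tr = tr, roi = roi, nuisance = nuis,
                   run = run_of_t, truth = truth, design = design),
              class = "bold_dataset")
  })
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("<bold_dataset: %d voxels x %d timepoints, %d ROIs, TR=%.2fs>\n",
              nrow(x$signal), ncol(x$signal), nlevels(x$roi), x$tr))
  invisible(x)
}

#' Write/read a bold_dataset as NIfTI volumes
#'
#' The voxels are arranged in labeled blocks along the first axis of a 4-D
#' volume (voxels x 1 x 1 x time); the ROI labels go to a companion 3-D mask
#' volume with integer codes in ROI order, and the nuisance table to a TSV.
#'
#' @param bold a [make_bold()] result
#' @param prefix output path prefix; writes `<prefix>_bold.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_nuisance.tsv`.
#' @return the paths, invisibly.
#' @export
write_bold_nifti <- function(bold, prefix) {
  arr <- array(bold$signal, c(nrow(bold$signal), 1, 1, ncol(bold$signal)))
  bold_path <- paste0(prefix, "_bold.nii.gz")
  mask_path <- paste0(prefix, "_mask.nii.gz")
  nuis_path <- paste0(prefix, "_nuisance.tsv")
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(1, 1, 1, bold$tr)
  RNifti::writeNifti(nii, bold_path)
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(bold$roi), c(nrow(bold$signal), 1, 1))),
    mask_path)
  utils::write.table(as.data.frame(bold$nuisance), nuis_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(bold = bold_path, mask = mask_path, nuisance = nuis_path))
}

#' @rdname write_bold_nifti
#' @param roi_names ROI names in mask-code order.
#' @export
read_bold_nifti <- function(prefix, roi_names) {
  arr <- RNifti::readNifti(paste0(prefix, "_bold.nii.gz"))
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  tr <- RNifti::pixdim(arr)[4]
  sig <- matrix(arr, dim(arr)[1], dim(arr)[4])
  nuis <- as.matrix(utils::read.delim(paste0(prefix, "_nuisance.tsv")))
  list(signal = sig, tr = tr,
       roi = factor(roi_names[as.integer(mask)], levels = roi_names),
       nuisance = nuis)
}

#' Serialize a ground-truth manifest to JSON (and back)
#' @param truth a [synthetic_ground_truth()]
#' @param path JSON path
#' @export
write_manifest_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_ground_truth, x)
}
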