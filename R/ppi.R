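#' Psychophysiological interaction regressors
#'
#' Builds the three PPI columns at the signal level (no hemodynamic
#' deconvolution): the seed timecourse (mean signal over the seed voxels), the
#' psychological boxcar (1 during the chosen epochs, sampled at the TR grid and
#' then mean-centred), and the interaction, which is the elementwise product of
#' the seed and the centred boxcar.
#'
#' @param bold a `bold_dataset` (or list with `signal`, `tr`).
#' @param seed_voxels logical or integer index of the seed voxels.
#' @param design the session's [make_design()].
#' @param epoch `"stimulus"` (the 3 s presentation epochs) or `"iti"` (the
#'   inter-trial intervals; the control regressor).
#' @return Object of class `ppi_regressors`: `seed`, `psych` (centred),
#'   `interaction`, `epoch`.
#' @export
build_ppi_regressor <- function(bold, seed_voxels, design,
                                epoch = c("stimulus", "iti")) {
  epoch <- match.arg(epoch)
  if (is.logical(seed_voxels)) seed_voxels <- which(seed_voxels)
  if (!length(seed_voxels)) stop("empty seed mask")
  seed <- colMeans(bold$signal[seed_voxels, , drop = FALSE])

  ev <- design$events
  n_time <- design$n_time
  box <- numeric(sum(n_time))
  t_off <- 0L
  for (r in seq_len(design$runs)) {
    er <- ev[ev$run == r, ]
    rows <- t_off + seq_len(n_time[r])
    box[rows] <- if (epoch == "stimulus")
      sample_boxcar(er$onset_stimulus,
                    er$onset_stimulus + er$stimulus_duration, n_time[r],
                    design$tr)
    else
      sample_boxcar(er$onset_feedback + er$feedback_duration,
                    er$onset_feedback + er$feedback_duration + er$iti,
                    n_time[r], design$tr)
    t_off <- t_off + n_time[r]
  }
  psych <- box - mean(box)
  structure(list(seed = seed, psych = psych, interaction = seed * psych,
                 epoch = epoch),
            class = "ppi_regressors")
}

#' Voxelwise PPI t-map
#'
#' Adds the seed main effect, the psychological main effect and the PPI
#' interaction to a base design in which all feature and value signals are
#' modelled (boxcar-modulated parametric regressors), and returns the t-map of
#' the interaction column. Because the task signals are regressed out, a
#' positive interaction reflects stimulus-epoch-specific noise coupling with
#' the seed. Significance is the positive tail at `alpha`, uncorrected.
#'
#' @param bold a `bold_dataset`.
#' @param ppi a [build_ppi_regressor()] result.
#' @param dm the base [build_design_matrix()] (boxcar-mode features + rating).
#' @param alpha one-sided significance level (default 0.001).
#' @param collinearity_limit warn when the correlation between the interaction
#'   and either main effect exceeds this value.
#' @return Object of class `voxel_stat_map`: data.frame with `statistic` (t),
#'   `p` (one-sided), `significant`.
#' @export
ppi_map <- function(bold, ppi, dm, alpha = 0.001, collinearity_limit = 0.95) {
  stopifnot(inherits(ppi, "ppi_regressors"), inherits(dm, "glm_design"))
  r_mains <- max(abs(stats::cor(ppi$interaction, ppi$seed)),
                 abs(stats::cor(ppi$interaction, ppi$psych)))
  if (is.finite(r_mains) && r_mains > collinearity_limit)
    warning(sprintf("PPI interaction is nearly collinear with a main effect (|r| = %.3f)",
                    r_mains))
  X <- cbind(dm$X, seed = ppi$seed, psych = ppi$psych,
             ppi = ppi$interaction)
  Y <- t(bold$signal)
  fit <- fit_glm(X, Y)
  xtxi <- chol2inv(chol(crossprod(X)))
  j <- ncol(X)
  se <- sqrt(fit$rss / fit$df * xtxi[j, j])
  tstat <- fit$coef[j, ] / se
  p <- stats::pt(tstat, fit$df, lower.tail = FALSE)
  structure(data.frame(statistic = tstat, p = p, significant = p < alpha),
            df = fit$df, alpha = alpha, side = "positive",
            class = c("voxel_stat_map", "data.frame"))
}

#' Overlap between feature-encoding voxels and PPI-coupled voxels
#'
#' Per ROI: counts the voxels significant in the all-features F-map, how many
#' of those are also significantly positively correlated with the PPI
#' interaction, and their ratio (the overlap fraction). An ROI with no
#' feature-significant voxels has an undefined (NA) fraction and is flagged.
#'
#' @param feature_map a [group_f_test()] map over all shared features.
#' @param ppi_t_map a [ppi_map()] result on the same voxel grid.
#' @param roi factor of ROI labels per voxel.
#' @param roi_order ROI ordering for the report.
#' @return Object of class `overlap_report`: data.frame with `roi`,
#'   `n_feature`, `n_overlap`, `fraction`.
#' @export
feature_ppi_overlap <- function(feature_map, ppi_t_map, roi,
                                roi_order = levels(as.factor(roi))) {
  stopifnot(nrow(feature_map) == nrow(ppi_t_map),
            length(roi) == nrow(feature_map))
  fsig <- feature_map$significant
  psig <- ppi_t_map$significant
  out <- do.call(rbind, lapply(roi_order, function(rr) {
    ix <- roi == rr
    nf <- sum(fsig[ix])
    no <- sum(fsig[ix] & psig[ix])
    data.frame(roi = rr, n_feature = nf, n_overlap = no,
               fraction = if (nf > 0) no / nf else NA_real_)
  }))
  structure(out, flagged = out$roi[out$n_feature == 0],
            class = c("overlap_report", "data.frame"))
}
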