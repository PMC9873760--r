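#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / ratio`: a response gamma
#' peaking near 5-6 s and an undershoot gamma near 15-16 s with peak-to-
#' undershoot ratio 6. No derivative terms.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot gamma shape parameters (scale 1).
#' @param ratio undershoot attenuation.
#' @return h(t), unit peak not enforced.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
}

# Convolve event amplitudes with the HRF on a fine grid and sample at the TR
# grid of one run. mode "stick" places impulses at onsets; "boxcar" spreads
# the amplitude over [onset, onset + duration).
convolve_events <- function(onsets, amplitudes, n_time, tr,
                            mode = c("stick", "boxcar"), durations = NULL,
                            dt = 0.1) {
  mode <- match.arg(mode)
  n_fine <- ceiling(n_time * tr / dt) + 1L
  x <- numeric(n_fine)
  if (mode == "stick") {
    idx <- pmin(floor(onsets / dt) + 1L, n_fine)
    for (k in seq_along(idx)) x[idx[k]] <- x[idx[k]] + amplitudes[k]
  } else {
    stopifnot(!is.null(durations))
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] / dt) + 1L
      i1 <- min(floor((onsets[k] + durations[k]) / dt), n_fine)
      if (i1 >= i0) x[i0:i1] <- x[i0:i1] + amplitudes[k]
    }
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  h <- h / max(h)   # unit-peak kernel: a lone stick yields a peak-1 response
  if (mode == "boxcar") h <- h * dt
  if (mode == "stick" && length(onsets) == 1L) {
    # single impulse: the convolution is just the shifted kernel
    i0 <- min(floor(onsets / dt) + 1L, n_fine)
    y <- numeric(n_fine)
    idx <- i0:min(n_fine, i0 + length(h) - 1L)
    y[idx] <- amplitudes * h[seq_along(idx)]
  } else {
    y <- stats::convolve(x, rev(h), type = "open")[seq_len(n_fine)]
  }
  y[pmin(floor((seq_len(n_time) - 1L) * tr / dt) + 1L, n_fine)]
}

# Boxcar sampled at the TR grid: 1 where the frame start falls inside any
# [start, end) epoch.
sample_boxcar <- function(starts, ends, n_time, tr) {
  tt <- (seq_len(n_time) - 1L) * tr
  out <- numeric(n_time)
  for (k in seq_along(starts)) out[tt >= starts[k] & tt < ends[k]] <- 1
  out
}
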