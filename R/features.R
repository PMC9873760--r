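#' Spectral blur estimate of an image
#'
#' Measures sharpness as the highest spatial frequency carrying non-negligible
#' spectral power. The image is reduced to 0-255 luminance, the unnormalized
#' 2-D DFT is taken, and each frequency component (u, v) is assigned the index
#' `max(|k_x|, |k_y|)` where `k_x`, `k_y` are signed frequencies scaled to
#' \[-1, 1\] (1 = Nyquist). The blur statistic is the maximum of that index
#' over all components whose squared modulus exceeds `power_threshold`; it is
#' inversely related to the width of a hypothetical Gaussian blur applied to a
#' sharp source image. A uniform image (power only at DC) scores 0.
#'
#' Power is the squared modulus of the pixel-count-normalized DFT of the 0-255
#' luminance image, so the default threshold of 4 admits components whose
#' amplitude is at least two gray levels. Normalizing is what makes the
#' statistic usable: the raw DFT of any finite image carries wrap-around
#' leakage whose power exceeds any fixed threshold at all frequencies, which
#' would pin the statistic at 1 regardless of blur.
#'
#' @param image a [raster_image()]
#' @param power_threshold power cutoff on the normalized power scale
#'   (default 4, i.e. amplitude 2 gray levels).
#' @param gray_standard luma standard passed to [to_gray()].
#' @return A number in \[0, 1\]. If no component passes the threshold the
#'   result is 0 with attribute `flag = "no_power"`.
#' @export
compute_blur <- function(image, power_threshold = 4, gray_standard = "601") {
  g <- to_gray(image, gray_standard) * 255
  ny <- nrow(g); nx <- ncol(g)
  pw <- (Mod(stats::fft(g)) / length(g))^2
  kfreq <- function(n) {
    i <- seq_len(n) - 1L
    f <- ifelse(i <= n / 2, i, i - n)
    abs(2 * f / n)
  }
  kmax <- outer(kfreq(ny), kfreq(nx), pmax)
  keep <- pw > power_threshold
  if (!any(keep)) return(structure(0, flag = "no_power"))
  max(kmax[keep])
}

#' Shape, colour and texture statistics of one image segment
#'
#' Computes the local feature block used by the feature catalog for the first
#' and second largest segments: area fraction, mean hue/saturation/value, mean
#' R channel, mean/SD luminance, centre of mass, second and third spatial
#' moments of the pixel mass, intensity-histogram entropy, and mirror-symmetry
#' mean squared errors of the segment's bounding-box crop.
#'
#' Coordinates are 0-based with x = column and y = row. With
#' `normalize_coords = TRUE` (default) coordinates are divided by the image
#' width/height before the moments are taken, making the moments comparable
#' across image sizes. The skew statistic is the raw third central moment sum
#' divided by segment area (not standardized by variance^1.5).
#'
#' @param image a [raster_image()]
#' @param seg a [segment_image()] result on the same image
#' @param segment_index 0-based segment rank (0 = largest, 1 = second largest)
#' @param normalize_coords divide pixel coordinates by image dimensions first
#' @param entropy_bins number of intensity histogram bins for the entropy term
#' @param hue_circular if TRUE use the circular mean for hue (convention flag;
#'   default is the plain arithmetic mean on hue in \[0, 1\)).
#' @param gray_standard luma standard for intensity-based statistics.
#' @return Named numeric vector of 14 statistics. If the requested segment does
#'   not exist, all values are `NA` and the attribute `flag = "missing_segment"`
#'   is set.
#' @export
compute_segment_features <- function(image, seg, segment_index,
                                     normalize_coords = TRUE,
                                     entropy_bins = 256,
                                     hue_circular = FALSE,
                                     gray_standard = "601") {
  stopifnot(inherits(image, "raster_image"), inherits(seg, "segmentation"),
            segment_index %in% c(0L, 1L))
  nms <- c("segment_size", "mean_hue", "mean_saturation", "mean_value",
           "mean_r", "mean_intensity", "sd_intensity",
           "com_x", "com_y", "mass_variance", "mass_skew", "entropy",
           "symmetry_horizontal", "symmetry_vertical")
  if (segment_index >= seg$n_segments) {
    out <- stats::setNames(rep(NA_real_, length(nms)), nms)
    return(structure(out, flag = "missing_segment"))
  }
  mask <- seg$label_map == segment_index
  n_pix <- sum(mask)
  h <- image$height; w <- image$width

  hsv <- rgb_to_hsv_mat(image$pixels)          # 3 x N, pixel column-major
  mv <- as.vector(mask)
  hue <- hsv[1, mv]
  mean_hue <- if (hue_circular) {
    ang <- atan2(mean(sin(2 * pi * hue)), mean(cos(2 * pi * hue))) / (2 * pi)
    ang %% 1
  } else mean(hue)

  gray <- to_gray(image, gray_standard)
  rows0 <- (row(seg$label_map) - 1L)[mask]
  cols0 <- (col(seg$label_map) - 1L)[mask]
  xs <- if (normalize_coords) cols0 / w else as.numeric(cols0)
  ys <- if (normalize_coords) rows0 / h else as.numeric(rows0)
  cx <- mean(xs); cy <- mean(ys)

  # entropy of the segment's 0-255 intensity histogram
  gi <- pmin(floor(gray[mask] * 256), 255)
  p <- tabulate(findInterval(gi, seq(0, 256, length.out = entropy_bins + 1),
                             rightmost.closed = TRUE), entropy_bins)
  p <- p / sum(p)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))

  # symmetry MSEs on the bounding-box crop of the (whole-image) luminance
  rr <- range(rows0); cc <- range(cols0)
  crop <- gray[(rr[1] + 1L):(rr[2] + 1L), (cc[1] + 1L):(cc[2] + 1L),
               drop = FALSE]
  sym_h <- mean((crop - crop[, ncol(crop):1, drop = FALSE])^2)
  sym_v <- mean((crop - crop[nrow(crop):1, , drop = FALSE])^2)

  c(segment_size = n_pix / (h * w),
    mean_hue = mean_hue,
    mean_saturation = mean(hsv[2, mv]),
    mean_value = mean(hsv[3, mv]),
    mean_r = mean(image$pixels[, , 1][mask]),
    mean_intensity = mean(gray[mask]),
    sd_intensity = stats::sd(gray[mask]),
    com_x = cx,
    com_y = cy,
    mass_variance = mean((xs - cx)^2 + (ys - cy)^2),
    mass_skew = mean((xs - cx)^3 + (ys - cy)^3),
    entropy = ent,
    symmetry_horizontal = sym_h,
    symmetry_vertical = sym_v)
}

#' Whole-image feature block
#'
#' Computes the global entries of the feature catalog: mean/SD of hue,
#' saturation and value, mean/SD luminance, spectral blur, edge density, mean
#' gradient magnitude, colorfulness, five equal-width intensity-bin area
#' fractions on the 0-255 scale, fixed-histogram modes of hue/saturation/value,
#' aspect ratio, and intensity-histogram entropy.
#'
#' @param image a [raster_image()]
#' @param intensity_bins number of equal bins tiling \[0, 255\] (default 5).
#' @param mode_bins histogram bins per HSV channel for the mode estimates
#'   (mode = centre of the fullest bin; default 64).
#' @param entropy_bins bins for the global entropy term.
#' @param power_threshold passed to [compute_blur()].
#' @param edge_threshold gradient magnitude (luminance units per pixel) above
#'   which a pixel counts as an edge pixel (default 0.1).
#' @param gray_standard luma standard.
#' @return Named numeric vector of `17 + intensity_bins` global statistics.
#' @export
compute_global_features <- function(image, intensity_bins = 5, mode_bins = 64,
                                    entropy_bins = 256, power_threshold = 4,
                                    edge_threshold = 0.1,
                                    gray_standard = "601") {
  stopifnot(inherits(image, "raster_image"))
  hsv <- rgb_to_hsv_mat(image$pixels)
  gray <- to_gray(image, gray_standard)
  h <- image$height; w <- image$width

  # intensity bin fractions on the 0-255 scale
  gi <- pmin(floor(gray * 256), 255)
  bins <- tabulate(findInterval(gi, seq(0, 256, length.out = intensity_bins + 1),
                                rightmost.closed = TRUE), intensity_bins)
  bins <- bins / sum(bins)
  names(bins) <- paste0("intensity_bin", seq_len(intensity_bins))

  # HSV modes on fixed histograms
  mode_of <- function(v) {
    br <- seq(0, 1, length.out = mode_bins + 1)
    ct <- tabulate(findInterval(v, br, rightmost.closed = TRUE), mode_bins)
    (which.max(ct) - 0.5) / mode_bins
  }

  gi255 <- pmin(floor(gray * 256), 255)
  p <- tabulate(findInterval(gi255, seq(0, 256, length.out = entropy_bins + 1),
                             rightmost.closed = TRUE), entropy_bins)
  p <- p / sum(p)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))

  # Sobel-like gradients via central differences
  gx <- (cbind(gray[, -1], gray[, w]) - cbind(gray[, 1], gray[, -w])) / 2
  gy <- (rbind(gray[-1, ], gray[h, ]) - rbind(gray[1, ], gray[-h, ])) / 2
  gmag <- sqrt(gx^2 + gy^2)

  # colorfulness (opponent-axis statistic)
  rg <- image$pixels[, , 1] - image$pixels[, , 2]
  yb <- (image$pixels[, , 1] + image$pixels[, , 2]) / 2 - image$pixels[, , 3]
  colorfulness <- sqrt(stats::var(as.vector(rg)) + stats::var(as.vector(yb))) +
    0.3 * sqrt(mean(rg)^2 + mean(yb)^2)

  c(mean_hue = mean(hsv[1, ]),
    mean_saturation = mean(hsv[2, ]),
    mean_value = mean(hsv[3, ]),
    sd_hue = stats::sd(hsv[1, ]),
    sd_saturation = stats::sd(hsv[2, ]),
    sd_value = stats::sd(hsv[3, ]),
    mean_intensity = mean(gray),
    sd_intensity = stats::sd(gray),
    blur = as.numeric(compute_blur(image, power_threshold, gray_standard)),
    edge_density = mean(gmag > edge_threshold),
    mean_gradient = mean(gmag),
    colorfulness = colorfulness,
    bins,
    mode_hue = mode_of(hsv[1, ]),
    mode_saturation = mode_of(hsv[2, ]),
    mode_value = mode_of(hsv[3, ]),
    aspect_ratio = w / h,
    entropy = ent)
}
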