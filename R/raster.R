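#' Raster image container
#'
#' Wraps an H x W x 3 array of RGB values in \[0, 1\]. All feature operators in
#' the package take this container, so that readers (PNG/JPEG) and the
#' procedural stimulus generator share one entry point.
#'
#' @param pixels numeric array, H x W x 3, values in \[0, 1\]. 8-bit integer
#'   input (0-255) is divided by 255.
#' @return An object of class `raster_image` with elements `pixels`, `width`
#'   (n. columns) and `height` (n. rows).
#' @examples
#' img <- raster_image(array(runif(16 * 16 * 3), c(16, 16, 3)))
#' img$width
#' @export
raster_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[3] != 3L)
    stop("exactly 3 channels (RGB) are required; got ", dim(pixels)[3],
         " (alpha channels are not supported)")
  if (is.integer(pixels) || max(pixels, na.rm = TRUE) > 1 + 1e-8)
    pixels <- pixels / 255
  if (anyNA(pixels) || min(pixels) < -1e-8 || max(pixels) > 1 + 1e-8)
    stop("channel values must lie in [0, 1]")
  pixels <- pmin(pmax(pixels, 0), 1)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 8L || w < 8L) stop("images must be at least 8 x 8 pixels")
  structure(list(pixels = pixels, width = w, height = h),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d (H x W), RGB in [0,1]>\n",
              x$height, x$width))
  invisible(x)
}

#' Read a PNG or JPEG image as a raster_image
#'
#' @param path file path; format chosen by extension (.png, .jpg, .jpeg).
#' @return A [raster_image()].
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (PNG and JPEG are supported)")
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L)
    stop("image has an alpha channel; flatten it before reading: ", path)
  raster_image(px)
}

#' Write a raster_image to PNG
#' @param image a [raster_image()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

# -- colour space helpers -----------------------------------------------------

# RGB [0,1] H x W x 3 array -> 3 x N HSV matrix (columns are pixels,
# column-major pixel order). Hue and value in [0,1].
rgb_to_hsv_mat <- function(pixels) {
  n <- prod(dim(pixels)[1:2])
  m <- matrix(pixels, nrow = n) # N x 3
  grDevices::rgb2hsv(t(m), maxColorValue = 1)
}

# Luminance in [0,1]. ITU-R BT.601 coefficients by default; 709 available.
#' Convert a raster image to a luminance (grayscale) matrix
#'
#' @param image a [raster_image()]
#' @param standard `"601"` (default) or `"709"` luma coefficients.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
to_gray <- function(image, standard = c("601", "709")) {
  standard <- match.arg(standard)
  co <- if (standard == "601") c(0.299, 0.587, 0.114)
        else c(0.2126, 0.7152, 0.0722)
  px <- image$pixels
  co[1] * px[, , 1] + co[2] * px[, , 2] + co[3] * px[, , 3]
}

# RGB [0,1] -> N x 3 Lab matrix (D65), via grDevices::convertColor.
rgb_to_lab_mat <- function(pixels) {
  n <- prod(dim(pixels)[1:2])
  m <- matrix(pixels, nrow = n)
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}
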