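#' Sinogram container
#'
#' One detector row per projection angle: `data[i, ]` is the line-integral
#' profile acquired at `angles[i]` degrees. Line integrals are in pixel-step
#' units (one sample per reconstructed pixel along the ray), so a noiseless
#' forward projection / reconstruction round trip preserves image values.
#'
#' @param data Numeric matrix, rows = angles, cols = detector bins.
#' @param angles Strictly increasing projection angles, degrees.
#' @param detector_pixel Detector bin spacing, mm.
#' @param height Optional slice height above the soil surface, mm.
#' @return An object of class `"sinogram"`.
#' @export
sinogram <- function(data, angles, detector_pixel = 0.097, height = NA_real_) {
  data <- as.matrix(data)
  if (nrow(data) != length(angles))
    stop("sinogram row count must equal angle count")
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("angles must be strictly increasing")
  if (detector_pixel <= 0) stop("detector_pixel must be positive")
  structure(list(data = data, angles = as.numeric(angles),
                 detector_pixel = detector_pixel, height = height),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles (%.1f-%.1f deg) x %d detector bins, %g mm bins\n",
              nrow(x$data), min(x$angles), max(x$angles), ncol(x$data),
              x$detector_pixel))
  invisible(x)
}

#' Reconstructed transverse slice
#'
#' @param data Square numeric matrix of attenuation values (x right along
#'   columns, y down along rows).
#' @param pixel_size Pixel side, mm.
#' @param height Slice height above the soil surface, mm.
#' @return An object of class `"slice_image"`.
#' @export
slice_image <- function(data, pixel_size, height = NA_real_) {
  data <- as.matrix(data)
  if (nrow(data) != ncol(data)) stop("slice must be square")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(data = data, pixel_size = pixel_size, height = height),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("Slice image: %d x %d px, %g mm/px (%.1f mm field)%s\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              nrow(x$data) * x$pixel_size,
              if (is.finite(x$height))
                sprintf(", height %.2f mm", x$height) else ""))
  invisible(x)
}

#' @export
plot.slice_image <- function(x, ...) {
  ext <- nrow(x$data) * x$pixel_size / 2
  image(seq(-ext, ext, length.out = nrow(x$data)),
        seq(-ext, ext, length.out = ncol(x$data)),
        t(x$data)[, rev(seq_len(nrow(x$data)))],
        col = gray.colors(256, 0, 1), asp = 1,
        xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

#' Forward-project a slice into a sinogram
#'
#' Parallel-beam line-integral projection of a square attenuation image at
#' each requested angle (bilinear sampling along rays, one sample per pixel
#' step). Optional additive Gaussian detector noise.
#'
#' @param image A [slice_image()] or square numeric matrix.
#' @param angles Projection angles, degrees (non-empty, strictly increasing).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   line integrals (0 = noiseless).
#' @param seed Optional RNG seed for the noise.
#' @param pixel_size Detector bin / pixel size, mm (ignored when `image` is a
#'   [slice_image()], which carries its own).
#' @return A [sinogram()].
#' @export
forward_project <- function(image, angles, noise_sd = 0, seed = NULL,
                            pixel_size = 0.097) {
  if (inherits(image, "slice_image")) {
    px <- image$pixel_size
    h <- image$height
    image <- image$data
  } else {
    px <- pixel_size
    h <- NA_real_
  }
  image <- as.matrix(image)
  if (length(angles) == 0) stop("angle list must be non-empty")
  if (nrow(image) != ncol(image)) stop("image must be square")
  sino <- cpp_radon(image, as.numeric(angles))
  if (noise_sd > 0)
    sino <- sino + with_seed(seed, matrix(stats::rnorm(length(sino), 0, noise_sd),
                                          nrow(sino), ncol(sino)))
  sinogram(sino, angles, detector_pixel = px, height = h)
}
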