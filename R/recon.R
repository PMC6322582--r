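#' Extract a fixed-height sinogram from a projection stack
#'
#' Each projection image contributes the detector row at the requested height;
#' stacking these rows across all rotation angles yields the sinogram of one
#' transverse plane.
#'
#' @param stack List of projection images (numeric matrices of equal shape),
#'   or a 3-D array with the projection index last.
#' @param row Detector row to extract, 1-based.
#' @param angles Projection angles, degrees (default taken from
#'   `attr(stack, "angles")` as written by [simulate_bundle()]).
#' @param detector_pixel Detector bin spacing, mm.
#' @return A [sinogram()] with one row per projection.
#' @export
extract_sinogram <- function(stack, row, angles = attr(stack, "angles"),
                             detector_pixel = 0.097) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (length(stack) == 0) stop("projection stack is empty")
  shp <- dim(stack[[1]])
  if (!all(vapply(stack, function(m) identical(dim(m), shp), logical(1))))
    stop("format error: projection stack images differ in shape")
  if (row < 1 || row > shp[1])
    stop("row ", row, " out of range [1, ", shp[1], "]")
  if (is.null(angles)) stop("projection angles must be supplied")
  if (length(angles) != length(stack))
    stop("angle count must equal number of projections")
  data <- t(vapply(stack, function(m) m[row, ], numeric(shp[2])))
  sinogram(data, angles, detector_pixel = detector_pixel)
}

# Frequency response of the reconstruction filter, built from the
# spatial-domain ramp kernel (avoids the DC bias of sampling |omega|).
fbp_filter <- function(m, filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  f <- numeric(m)
  f[1] <- 0.25
  k <- seq_len(m %/% 2)
  odd <- k[k %% 2 == 1]
  f[1 + odd] <- -1 / (pi * odd)^2
  f[m + 1 - odd] <- -1 / (pi * odd)^2
  resp <- 2 * Re(stats::fft(f))
  if (filter == "hann") {
    freq <- c(seq(0, m / 2), seq(-m / 2 + 1, -1)) / m # cycles per sample
    resp <- resp * 0.5 * (1 + cos(2 * pi * freq))
  }
  resp
}

#' Filtered back-projection reconstruction
#'
#' Conventional FBP: each projection is ramp-filtered in the frequency domain
#' (Ram-Lak kernel, optional Hann apodization), back-projected along its ray
#' direction with linear interpolation, summed over angles and scaled by
#' `pi / (2 * n_angles)`. The same normalization is applied to limited-angle
#' scans (e.g. the 228-degree protocol); the resulting streaks and intensity
#' bias are handled downstream by morphological cleanup and thresholding.
#' Negative values are clipped to zero, since attenuation is non-negative.
#'
#' @param sino A [sinogram()] with at least two angles.
#' @param output_size Side of the reconstructed square image, pixels
#'   (default: the detector bin count).
#' @param filter `"ramlak"` (default) or `"hann"`.
#' @param clip_negative Clip negative reconstructed values to zero.
#' @return A [slice_image()].
#' @export
fbp_reconstruct <- function(sino, output_size = NULL,
                            filter = c("ramlak", "hann"),
                            clip_negative = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  if (nrow(sino$data) < 2)
    stop("insufficient data: at least 2 projection angles required")
  nd <- ncol(sino$data)
  if (is.null(output_size)) output_size <- nd
  m <- max(64, 2^ceiling(log2(2 * nd)))
  resp <- fbp_filter(m, filter)
  pad <- matrix(0, nrow(sino$data), m)
  pad[, seq_len(nd)] <- sino$data
  filt <- t(apply(pad, 1, function(p)
    Re(stats::fft(stats::fft(p) * resp, inverse = TRUE)) / m))[, seq_len(nd),
                                                              drop = FALSE]
  rec <- cpp_backproject(filt, sino$angles, as.integer(output_size))
  rec <- rec * pi / (2 * length(sino$angles))
  if (clip_negative) rec[rec < 0] <- 0
  slice_image(rec, pixel_size = sino$detector_pixel, height = sino$height)
}

#' Reconstruct slices at several detector rows
#'
#' Convenience wrapper: extract the sinogram at each requested detector row
#' and reconstruct it, attaching the physical height `row * pixel_size`
#' (row-to-mm scale of the reconstructed geometry).
#'
#' @inheritParams extract_sinogram
#' @param rows Detector rows, 1-based.
#' @param geom A [scanner_geometry()]; supplies `pixel_size` and the
#'   row-to-height scale.
#' @param ... Passed to [fbp_reconstruct()].
#' @return List of [slice_image()], one per row.
#' @export
reconstruct_heights <- function(stack, rows, geom = scanner_geometry(),
                                angles = attr(stack, "angles"), ...) {
  lapply(rows, function(r) {
    sino <- extract_sinogram(stack, r, angles = angles,
                             detector_pixel = geom$pixel_size)
    sino$height <- r * geom$pixel_size
    fbp_reconstruct(sino, ...)
  })
}
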