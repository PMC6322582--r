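#' Scanner acquisition geometry
#'
#' Physical parameters of the cone-beam micro-CT unit: source-detector and
#' source-rotation-center distances, source cone angle, detector extents, the
#' rotation protocol and the reconstructed pixel size. The default instance is
#' the production scanner configuration (634 mm source-detector distance,
#' 484 mm source-center distance, 33 degree cone, 195 x 244 mm detector,
#' 380 projections at 0.6 degree steps, 0.097 mm pixels).
#'
#' @param d_sd Source-to-detector distance, mm.
#' @param d_sc Source-to-rotation-center distance, mm; must be < `d_sd`.
#' @param cone_angle Full cone angle of the X-ray source, degrees, in (0, 180).
#' @param detector_vl,detector_hl Vertical / horizontal detector extent, mm.
#' @param n_projections Number of projections per scan.
#' @param angle_step Rotation step between projections, degrees.
#' @param pixel_size Reconstructed pixel size, mm.
#' @return An object of class `"scanner_geometry"`.
#' @examples
#' g <- scanner_geometry()
#' fov_vertical(g)    # 149 mm on the default scanner
#' fov_horizontal(g)  # 186 mm
#' @export
scanner_geometry <- function(d_sd = 634, d_sc = 484, cone_angle = 33,
                             detector_vl = 195, detector_hl = 244,
                             n_projections = 380, angle_step = 0.6,
                             pixel_size = 0.097) {
  if (!is.numeric(d_sd) || !is.numeric(d_sc) || d_sd <= 0 || d_sc <= 0)
    stop("invalid geometry: distances must be strictly positive")
  if (d_sd <= d_sc)
    stop("invalid geometry: d_sd must exceed d_sc (detector beyond rotation center)")
  if (cone_angle <= 0 || cone_angle >= 180)
    stop("invalid geometry: cone_angle must lie in (0, 180) degrees")
  if (detector_vl <= 0 || detector_hl <= 0)
    stop("invalid geometry: detector extents must be positive")
  if (n_projections < 1) stop("invalid geometry: n_projections must be >= 1")
  if (angle_step <= 0) stop("invalid geometry: angle_step must be positive")
  if (pixel_size <= 0) stop("invalid geometry: pixel_size must be positive")
  structure(list(d_sd = d_sd, d_sc = d_sc, cone_angle = cone_angle,
                 detector_vl = detector_vl, detector_hl = detector_hl,
                 n_projections = n_projections, angle_step = angle_step,
                 pixel_size = pixel_size),
            class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("Scanner geometry\n")
  cat(sprintf("  D_sd = %g mm, D_sc = %g mm, cone angle = %g deg\n",
              x$d_sd, x$d_sc, x$cone_angle))
  cat(sprintf("  detector VL x HL = %g x %g mm\n", x$detector_vl, x$detector_hl))
  cat(sprintf("  FOV  VL x HL = %.1f x %.1f mm\n",
              fov_vertical(x), fov_horizontal(x)))
  cat(sprintf("  %d projections, step %g deg (total %g deg), pixel %g mm\n",
              x$n_projections, x$angle_step, total_scan_angle(x), x$pixel_size))
  invisible(x)
}

#' Side-view camera geometry
#'
#' Thin-lens geometry of the RGB side-view camera: object and image distances
#' and the physical sensor extents. Defaults are the production camera
#' (object distance 1520 mm, image distance 8 mm, 8.46 x 7.09 mm sensor).
#'
#' @param object_distance,image_distance Distances from the lens, mm.
#' @param sensor_v,sensor_h Vertical / horizontal sensor extent, mm.
#' @return An object of class `"camera_geometry"`.
#' @export
camera_geometry <- function(object_distance = 1520, image_distance = 8,
                            sensor_v = 8.46, sensor_h = 7.09) {
  vals <- c(object_distance, image_distance, sensor_v, sensor_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid geometry: all camera distances and extents must be positive")
  if (object_distance <= image_distance)
    stop("invalid geometry: object_distance must exceed image_distance")
  structure(list(object_distance = object_distance,
                 image_distance = image_distance,
                 sensor_v = sensor_v, sensor_h = sensor_h),
            class = "camera_geometry")
}

#' Vertical field of view of the CT unit
#'
#' The vertical extent of the cylindrical field of view at the rotation
#' center: the detector extent demagnified by the ratio of the
#' source-to-center and source-to-detector distances,
#' `VL_FOV = VL * D_sc / D_sd`.
#'
#' @param geom A [scanner_geometry()].
#' @return Length in mm.
#' @export
fov_vertical <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  geom$detector_vl * geom$d_sc / geom$d_sd
}

#' Horizontal field of view of the CT unit
#'
#' `HL_FOV = HL * D_sc / D_sd`; see [fov_vertical()].
#'
#' @inheritParams fov_vertical
#' @return Length in mm.
#' @export
fov_horizontal <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  geom$detector_hl * geom$d_sc / geom$d_sd
}

#' Projection diameter of the X-ray source at the detector
#'
#' Diameter of the cone-beam footprint at the detector plane,
#' `PD_source = 2 * D_sd * tan(cone_angle / 2)`.
#'
#' @inheritParams fov_vertical
#' @return Length in mm.
#' @export
projection_diameter <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  2 * geom$d_sd * tan(geom$cone_angle * pi / 360)
}

#' Field of view of the side-view camera
#'
#' Sensor extents scaled to the object plane by the distance ratio
#' `object_distance / image_distance`.
#'
#' @param cam A [camera_geometry()].
#' @return Named numeric vector `c(vertical = , horizontal = )`, mm.
#' @export
camera_fov <- function(cam) {
  stopifnot(inherits(cam, "camera_geometry"))
  m <- cam$object_distance / cam$image_distance
  c(vertical = cam$sensor_v * m, horizontal = cam$sensor_h * m)
}

#' Total angular coverage of a scan
#'
#' `n_projections * angle_step` degrees; the production protocol covers
#' 380 x 0.6 = 228 degrees, i.e. limited-angle acquisition.
#'
#' @inheritParams fov_vertical
#' @return Degrees.
#' @export
total_scan_angle <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  geom$n_projections * geom$angle_step
}

#' Projection angles of a scan protocol
#'
#' @inheritParams fov_vertical
#' @return Numeric vector of `n_projections` angles starting at 0, degrees.
#' @export
scan_angles <- function(geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  seq(0, by = geom$angle_step, length.out = geom$n_projections)
}
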