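#' Segmentation configuration
#'
#' Parameters of the slice-cleanup chain: global threshold (Otsu by default),
#' a binary opening that erases thin reconstruction streaks, a minimum
#' particle area that drops specks, and a minimum circularity that rejects
#' elongated leaf-blade sections (an irregular-shape particle filter;
#' circularity `4*pi*A/P^2` is ~1 for the round culm sections and well below
#' 0.3 for blades).
#'
#' @param threshold `"otsu"` or a fixed numeric threshold on attenuation.
#' @param opening_radius Radius of the disc structuring element, px
#'   (0 disables the opening).
#' @param min_area Minimum filled component area, px.
#' @param min_circularity Minimum circularity of the filled component.
#' @param min_hole_area Minimum interior hole, px, for a section to count as
#'   hollow (fertile).
#' @param min_intensity_frac Relative-attenuation gate: components whose mean
#'   reconstructed intensity falls below this fraction of the brightest
#'   retained component are discarded. Culm walls are markedly denser than
#'   leaf laminae (about 2.5x in relative attenuation), so bright-but-stubby
#'   blade remnants that slip past the shape gate are still removed; set to 0
#'   to disable.
#' @return List of class `"seg_config"`.
#' @export
seg_config <- function(threshold = "otsu", opening_radius = 1, min_area = 20,
                       min_circularity = 0.3, min_hole_area = 5,
                       min_intensity_frac = 0.7) {
  stopifnot(identical(threshold, "otsu") || is.numeric(threshold),
            opening_radius >= 0, min_area >= 0,
            min_circularity >= 0, min_circularity <= 1,
            min_intensity_frac >= 0, min_intensity_frac <= 1)
  structure(list(threshold = threshold, opening_radius = opening_radius,
                 min_area = min_area, min_circularity = min_circularity,
                 min_hole_area = min_hole_area,
                 min_intensity_frac = min_intensity_frac),
            class = "seg_config")
}

# Outer-boundary chain length of each labeled object, px (orthogonal steps
# count 1, diagonal steps sqrt(2)).
perimeter_px <- function(labels) {
  oc <- EBImage::ocontour(labels)
  vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(4) # lone pixel: unit-square boundary
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(pmin(d, sqrt(2))) # closing step of a traced 8-connected contour
  }, numeric(1))
}

#' Segment tiller cross-sections in a reconstructed slice
#'
#' Threshold, binary opening (erosion then dilation), hole filling (so that a
#' hollow culm is one object and its pith cavity is bookkept as a hole),
#' 8-connected labeling, then removal of small particles and of components
#' whose circularity betrays a leaf blade. Returns the label matrix with the
#' pre-fill binary mask attached, ready for [measure_regions()].
#'
#' @param slice A [slice_image()] (or plain matrix).
#' @param cfg A [seg_config()].
#' @return Integer label matrix (0 = background, labels 1..K on the filled
#'   sections) with attributes `binary` (thresholded + opened mask before
#'   hole filling), `pixel_size` and `config`. All-background slices give an
#'   all-zero labeling.
#' @export
segment_tillers <- function(slice, cfg = seg_config()) {
  px <- if (inherits(slice, "slice_image")) slice$pixel_size else NA_real_
  img <- if (inherits(slice, "slice_image")) slice$data else as.matrix(slice)
  finish <- function(lab, bin) {
    storage.mode(lab) <- "integer"
    structure(lab, binary = bin, pixel_size = px, config = cfg)
  }
  mx <- max(img)
  if (!is.finite(mx) || mx <= 0)
    return(finish(matrix(0L, nrow(img), ncol(img)), img > 0))
  thr <- if (identical(cfg$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(img / mx)) * mx else cfg$threshold
  bin <- (img > thr) * 1
  if (cfg$opening_radius > 0) {
    k <- EBImage::makeBrush(2 * cfg$opening_radius + 1, shape = "disc")
    bin <- EBImage::dilate(EBImage::erode(bin, k), k)
  }
  filled <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(filled)
  nlab <- max(lab)
  if (nlab == 0) return(finish(lab, bin))
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  per <- perimeter_px(lab)
  circ <- 4 * pi * areas / per^2
  keep <- which(areas >= cfg$min_area & circ >= cfg$min_circularity)
  if (length(keep) > 1 && cfg$min_intensity_frac > 0) {
    # leaf laminae reconstruct much fainter than culm walls; drop components
    # well below the brightest section's mean attenuation
    means <- vapply(keep, function(k) mean(img[lab == k & bin > 0]),
                    numeric(1))
    keep <- keep[means >= cfg$min_intensity_frac * max(means)]
  }
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out[sel] <- remap[lab[sel]]
  bin[out == 0] <- 0
  finish(out, bin)
}

#' Measure tiller regions in a labeled slice
#'
#' Per-region geometry in physical units. The section area is the filled
#' area bounded by the outer contour (pith cavity included); the wall area is
#' the above-threshold part only. The equivalent diameter is that of the
#' circle with the section's area, and the wall thickness is the difference
#' of the outer and cavity equivalent radii (0 for solid sections).
#' Coordinates are pixel centers, 0-based, x right / y down, scaled to mm.
#'
#' @param labels Label matrix from [segment_tillers()].
#' @param pixel_size Pixel size, mm (default: carried on `labels`).
#' @return Data frame with one row per region: `label`, `area` (mm^2),
#'   `wall_area`, `hole_area`, `perimeter` (mm), `x`, `y` (centroid, mm,
#'   relative to the image center), `equivalent_diameter`, `wall_thickness`
#'   (mm), `hollow`, `circularity`.
#' @export
measure_regions <- function(labels, pixel_size = attr(labels, "pixel_size")) {
  if (is.null(pixel_size) || !is.finite(pixel_size)) pixel_size <- 1
  cfg <- attr(labels, "config")
  min_hole <- if (is.null(cfg)) 5 else cfg$min_hole_area
  bin <- attr(labels, "binary")
  nlab <- max(labels)
  empty <- data.frame(label = integer(), area = numeric(),
                      wall_area = numeric(), hole_area = numeric(),
                      perimeter = numeric(), x = numeric(), y = numeric(),
                      equivalent_diameter = numeric(),
                      wall_thickness = numeric(), hollow = logical(),
                      circularity = numeric())
  if (nlab == 0) return(empty)
  filled_px <- tabulate(labels[labels > 0], nbins = nlab)
  wall_px <- if (is.null(bin)) filled_px else
    tabulate(labels[labels > 0 & bin > 0], nbins = nlab)
  hole_px <- filled_px - wall_px
  per_px <- perimeter_px(labels)
  idx <- which(labels > 0)
  lv <- labels[idx]
  c0 <- (nrow(labels) - 1) / 2
  rows <- (idx - 1) %% nrow(labels)        # 0-based y
  cols <- (idx - 1) %/% nrow(labels)       # 0-based x
  cx <- vapply(split(cols, lv), mean, numeric(1))
  cy <- vapply(split(rows, lv), mean, numeric(1))
  hollow <- hole_px >= min_hole
  r_out <- sqrt(filled_px / pi)
  r_in <- ifelse(hollow, sqrt(hole_px / pi), 0)
  data.frame(label = seq_len(nlab),
             area = filled_px * pixel_size^2,
             wall_area = wall_px * pixel_size^2,
             hole_area = hole_px * pixel_size^2,
             perimeter = per_px * pixel_size,
             x = (cx - c0) * pixel_size,
             y = (cy - c0) * pixel_size,
             equivalent_diameter = 2 * r_out * pixel_size,
             wall_thickness = ifelse(hollow, (r_out - r_in) * pixel_size, 0),
             hollow = hollow,
             circularity = 4 * pi * filled_px / per_px^2,
             row.names = NULL)
}
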