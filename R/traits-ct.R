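# --- exact minimum enclosing circle (Welzl) -------------------------------

circle_from <- function(p1, p2 = NULL, p3 = NULL) {
  if (is.null(p2)) return(c(p1, 0))
  if (is.null(p3)) {
    c0 <- (p1 + p2) / 2
    return(c(c0, sqrt(sum((p1 - c0)^2))))
  }
  # circumcircle of a (non-degenerate) triangle
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

in_circle <- function(p, circ, tol = 1e-9) {
  sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] + tol
}

welzl <- function(pts, boundary) {
  if (nrow(pts) == 0 || length(boundary) == 3) {
    circ <- switch(length(boundary) + 1,
                   c(0, 0, -1),
                   circle_from(boundary[[1]]),
                   circle_from(boundary[[1]], boundary[[2]]),
                   circle_from(boundary[[1]], boundary[[2]], boundary[[3]]))
    if (is.null(circ)) circ <- c(0, 0, -1)
    return(circ)
  }
  p <- pts[nrow(pts), ]
  circ <- welzl(pts[-nrow(pts), , drop = FALSE], boundary)
  if (circ[3] >= 0 && in_circle(p, circ)) return(circ)
  welzl(pts[-nrow(pts), , drop = FALSE], c(boundary, list(p)))
}

#' Minimum enclosing circle of a point set
#'
#' Exact smallest circle covering all points (Welzl's algorithm over the
#' convex hull vertices, with a deterministic internal shuffle).
#'
#' @param pts Two-column matrix of point coordinates.
#' @return Numeric vector `c(x, y, r)`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 0) stop("no points")
  if (nrow(pts) == 1) return(c(pts[1, ], 0))
  hull <- if (nrow(pts) > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  hull <- with_seed(7193, hull[sample(nrow(hull)), , drop = FALSE])
  unname(welzl(hull, list()))
}

# Count pixel centers (0-based integer coords) covered by the convex hull of
# `pts`, inflating the hull by a hair so centers on hull edges count as in.
hull_pixel_count <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3) return(nrow(pts))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3) return(nrow(pts)) # collinear set
  cen <- colMeans(hull)
  infl <- sweep(sweep(hull, 2, cen), 1, 1 + 1e-7, "*")
  infl <- sweep(infl, 2, cen, "+")
  xs <- seq(floor(min(hull[, 1])), ceiling(max(hull[, 1])))
  ys <- seq(floor(min(hull[, 2])), ceiling(max(hull[, 2])))
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  sum(mgcv::in.out(rbind(infl, infl[1, ]), grid))
}

# Count pixel centers within radius r of (cx, cy), restricted to a bbox.
circle_pixel_count <- function(circ) {
  r <- circ[3] + 1e-7
  xs <- seq(floor(circ[1] - r), ceiling(circ[1] + r))
  ys <- seq(floor(circ[2] - r), ceiling(circ[2] + r))
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  sum((X - circ[1])^2 + (Y - circ[2])^2 <= r^2)
}

#' Per-slice CT tiller traits
#'
#' Aggregates region measurements into the slice-level trait record: tiller
#' number TN, total tiller area TTA, convex hull area CHA, the compactness
#' ratios THR = TTA/CHA and TCR = TTA/(minimum enclosing circle area), and
#' max/mean/population-SD statistics of per-tiller diameters (MAXTD, MEANTD,
#' SDTD), area/perimeter ratios (MAXTAPR, MEANTAPR, SDTAPR) and section areas
#' (MAXTTA, MEANTTA, SDTTA), plus the effective (hollow, i.e. booted) tiller
#' count. CHA and the circumcircle area are measured by counting covered
#' pixels, so `TCR <= THR <= 1` holds exactly; on an empty slice the ratio
#' traits are missing values, not zeros.
#'
#' @param regions Data frame from [measure_regions()].
#' @param labels Label matrix from [segment_tillers()]; required for CHA/TCR
#'   (they are `NA` when omitted).
#' @param pixel_size Pixel size, mm.
#' @param height Slice height, mm (carried into the record).
#' @return One-row data frame of slice traits.
#' @export
slice_traits <- function(regions, labels = NULL,
                         pixel_size = attr(labels, "pixel_size"),
                         height = NA_real_) {
  if (is.null(pixel_size) || !is.finite(pixel_size)) pixel_size <- 1
  tn <- nrow(regions)
  out <- data.frame(height = height, TN = tn, TTA = NA_real_, CHA = NA_real_,
                    THR = NA_real_, TCR = NA_real_,
                    MEANTD = NA_real_, MAXTD = NA_real_, SDTD = NA_real_,
                    MEANTAPR = NA_real_, MAXTAPR = NA_real_, SDTAPR = NA_real_,
                    MAXTTA = NA_real_, MEANTTA = NA_real_, SDTTA = NA_real_,
                    effective_TN = if (tn > 0) sum(regions$hollow) else 0L)
  if (tn == 0) return(out)
  out$TTA <- sum(regions$area)
  tapr <- regions$area / regions$perimeter
  out$MEANTD <- mean(regions$equivalent_diameter)
  out$MAXTD <- max(regions$equivalent_diameter)
  out$SDTD <- sd_pop(regions$equivalent_diameter)
  out$MEANTAPR <- mean(tapr)
  out$MAXTAPR <- max(tapr)
  out$SDTAPR <- sd_pop(tapr)
  out$MAXTTA <- max(regions$area)
  out$MEANTTA <- mean(regions$area)
  out$SDTTA <- sd_pop(regions$area)
  if (!is.null(labels) && max(labels) > 0) {
    idx <- which(labels > 0)
    pts <- cbind((idx - 1) %/% nrow(labels), (idx - 1) %% nrow(labels))
    tta_px <- length(idx)
    cha_px <- hull_pixel_count(pts)
    mec_px <- circle_pixel_count(min_enclosing_circle(pts))
    out$CHA <- cha_px * pixel_size^2
    out$THR <- tta_px / cha_px
    out$TCR <- tta_px / mec_px
  }
  out
}

#' Plant-level CT traits from per-slice records
#'
#' The plant record is taken from the reference slice, the lowest analyzed
#' height (tiller sections are best separated near the soil surface); the
#' max/mean/SD aggregates are the per-tiller statistics of that slice.
#'
#' @param per_slice Data frame (rows = slices) or list of one-row data frames
#'   from [slice_traits()].
#' @return One-row data frame of plant CT traits.
#' @export
plant_ct_traits <- function(per_slice) {
  if (is.data.frame(per_slice)) per_slice <- split(per_slice, seq_len(nrow(per_slice)))
  if (length(per_slice) == 0) stop("at least one slice is required")
  tab <- do.call(rbind, per_slice)
  h <- tab$height
  ref <- if (all(is.finite(h))) which.min(h) else 1L
  out <- tab[ref, , drop = FALSE]
  rownames(out) <- NULL
  out
}
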