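#' Render a synthetic side view of a plant phantom
#'
#' Orthographic projection of the phantom onto the x-z plane, producing a
#' color side-view image for testing the RGB trait extraction: each tiller is
#' a straight stem leaning by its projected inclination, with a pair of
#' slanted leaf blades; a configurable fraction of stems is rendered
#' senescent (yellow) instead of green. The soil surface is the bottom image
#' row. Real side views differ in many ways (overlapping canopies, lighting,
#' soil background); the renderer only guarantees known plant pixels, known
#' height and a known green/yellow partition.
#'
#' @param plant A [plant_phantom()].
#' @param plant_height Culm length, mm.
#' @param pixel_mm Image scale, mm per pixel.
#' @param width_px,height_px Image size.
#' @param senescent_frac Fraction of tillers drawn yellow.
#' @param n_leaves Leaf blades per stem.
#' @param seed RNG seed for leaf placement and color jitter.
#' @return List of class `"side_view"`: `image` (height x width x 3 array in
#'   `[0, 1]`), `mask` (logical ground-truth plant pixels), `green_mask`
#'   (ground-truth green subset), `pixel_mm`, `height_px` (rendered plant
#'   height in pixels).
#' @export
render_side_view <- function(plant, plant_height = 450, pixel_mm = 2,
                             width_px = 480, height_px = 320,
                             senescent_frac = 0, n_leaves = 2, seed = 1) {
  stopifnot(inherits(plant, "plant_phantom"))
  img <- array(0, dim = c(height_px, width_px, 3))
  mask <- matrix(FALSE, height_px, width_px)
  green <- matrix(FALSE, height_px, width_px)
  cx <- width_px / 2
  tl <- plant$tillers
  with_seed(seed, {
    n_sen <- if (nrow(tl) > 0) round(senescent_frac * nrow(tl)) else 0
    senescent <- rep(FALSE, nrow(tl))
    if (n_sen > 0) senescent[sample(nrow(tl), n_sen)] <- TRUE
    draw_band <- function(x0, z0, x1, z1, half_w, col) {
      # thick line in mm coordinates (x from center, z above soil)
      n <- max(2, ceiling(sqrt((x1 - x0)^2 + (z1 - z0)^2) / (pixel_mm / 2)))
      xs <- seq(x0, x1, length.out = n)
      zs <- seq(z0, z1, length.out = n)
      hw <- max(1L, round(half_w / pixel_mm))
      for (k in seq_len(n)) {
        c0 <- round(cx + xs[k] / pixel_mm)
        r0 <- height_px - round(zs[k] / pixel_mm)
        if (r0 < 1 || r0 > height_px) next
        cc <- max(1, c0 - hw):min(width_px, c0 + hw)
        if (c0 + hw < 1 || c0 - hw > width_px) next
        for (ch in 1:3) img[r0, cc, ch] <<- col[ch]
        mask[r0, cc] <<- TRUE
        green[r0, cc] <<- col[2] > col[1] # green dominates red
      }
    }
    if (nrow(tl) > 0) {
      for (i in seq_len(nrow(tl))) {
        slope <- tan(deg2rad(tl$inclination[i])) * cos(deg2rad(tl$azimuth[i]))
        col <- if (senescent[i]) c(0.72, 0.68, 0.12) + runif(1, -0.03, 0.03)
               else c(0.10, 0.50, 0.12) + runif(1, -0.03, 0.03)
        x0 <- tl$base_x[i]
        draw_band(x0, 0, x0 + slope * plant_height, plant_height,
                  tl$outer_diameter[i] / 2, col)
        for (l in seq_len(n_leaves)) {
          z_node <- runif(1, 0.35, 0.85) * plant_height
          xn <- x0 + slope * z_node
          th <- deg2rad(runif(1, 30, 60)) * sample(c(-1, 1), 1)
          len <- runif(1, 100, 180)
          lcol <- if (senescent[i]) c(0.70, 0.66, 0.10) else c(0.12, 0.55, 0.15)
          draw_band(xn, z_node, xn + sin(th) * len, z_node + cos(th) * len,
                    1.5, lcol)
        }
      }
    }
  })
  rows <- which(rowSums(mask) > 0)
  structure(list(image = img, mask = mask, green_mask = green & mask,
                 pixel_mm = pixel_mm,
                 height_px = if (length(rows)) diff(range(rows)) + 1L else 0L),
            class = "side_view")
}

#' @export
print.side_view <- function(x, ...) {
  cat(sprintf("Side view: %d x %d px (%g mm/px), %d plant px, height %d px\n",
              dim(x$image)[1], dim(x$image)[2], x$pixel_mm, sum(x$mask),
              x$height_px))
  invisible(x)
}
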