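#' Specify a single tiller (culm)
#'
#' A tiller is modelled as an inclined circular cylinder: an annulus in cross
#' section when fertile (the pith cavity of a booted culm), solid otherwise.
#' The culm axis starts at `(base_x, base_y)` in the soil-surface plane
#' (z = 0) and leans by `inclination` degrees from vertical towards compass
#' direction `azimuth`.
#'
#' @param base_x,base_y Culm axis position at the soil surface, mm.
#' @param inclination Degrees from vertical, in `[0, 90)`.
#' @param azimuth Lean direction, degrees.
#' @param outer_diameter Outer culm diameter, mm.
#' @param wall_thickness Culm wall thickness, mm; `2 * wall_thickness` must
#'   not exceed `outer_diameter`.
#' @param fertile Logical; fertile (booted) tillers are rendered hollow.
#' @return A one-row data frame; rows from several calls can be bound into the
#'   `tillers` table of a [plant_phantom()].
#' @export
tiller_spec <- function(base_x, base_y, inclination, azimuth,
                        outer_diameter, wall_thickness, fertile = TRUE) {
  if (inclination < 0 || inclination >= 90)
    stop("inclination must lie in [0, 90) degrees")
  if (outer_diameter <= 0 || wall_thickness <= 0 ||
      2 * wall_thickness > outer_diameter)
    stop("need 0 < 2 * wall_thickness <= outer_diameter")
  data.frame(base_x = base_x, base_y = base_y, inclination = inclination,
             azimuth = azimuth, outer_diameter = outer_diameter,
             wall_thickness = wall_thickness, fertile = as.logical(fertile))
}

#' Construct a plant phantom from explicit components
#'
#' @param tillers Data frame of tiller rows as returned by [tiller_spec()]
#'   (may have zero rows).
#' @param leaves Data frame of leaf blades with columns `x`, `y` (center, mm),
#'   `length`, `width` (mm), `orientation` (degrees), `z_min`, `z_max`
#'   (height interval over which the blade is present, mm).
#' @param seed Integer recorded for provenance (the seed that generated the
#'   phantom, or `NA` for hand-built ones).
#' @return An object of class `"plant_phantom"`.
#' @seealso [sample_plant()] for randomized phantoms.
#' @export
plant_phantom <- function(tillers = NULL, leaves = NULL, seed = NA_integer_) {
  empty_t <- tiller_spec(0, 0, 0, 0, 1, 0.5)[0, ]
  empty_l <- data.frame(x = numeric(), y = numeric(), length = numeric(),
                        width = numeric(), orientation = numeric(),
                        z_min = numeric(), z_max = numeric())
  if (is.null(tillers)) tillers <- empty_t
  if (is.null(leaves)) leaves <- empty_l
  stopifnot(all(names(empty_t) %in% names(tillers)),
            all(names(empty_l) %in% names(leaves)))
  structure(list(tillers = tillers, leaves = leaves, seed = seed),
            class = "plant_phantom")
}

#' @export
print.plant_phantom <- function(x, ...) {
  cat(sprintf("Plant phantom: %d tillers (%d fertile), %d leaf blades, seed %s\n",
              nrow(x$tillers), sum(x$tillers$fertile), nrow(x$leaves),
              format(x$seed)))
  invisible(x)
}

#' Sample a random multi-tiller plant phantom
#'
#' Draws a virtual rice plant: tiller bases uniform in a circular crown,
#' inclinations, diameters and wall thicknesses uniform in the given ranges,
#' a Bernoulli fertile flag, plus elongated leaf-blade clutter. Tillers are
#' rejection-sampled so that culm cross sections do not overlap at the soil
#' surface or at any height in `check_heights`, and leaf blades keep clear of
#' culm sections at those heights, so that ground truth stays unambiguous for
#' segmentation tests. Identical `seed` and parameters give an identical
#' phantom.
#'
#' @param seed Integer RNG seed.
#' @param n_tillers Tiller count, or a length-2 range to sample from.
#' @param crown_radius Radius of the disc holding culm bases, mm.
#' @param inclination_range,diameter_range,wall_range Uniform sampling ranges
#'   (degrees from vertical; outer diameter mm; wall thickness mm).
#' @param fertile_prob Probability that a tiller is fertile (hollow).
#' @param n_leaves Number of leaf blades.
#' @param leaf_length_range,leaf_width_range Blade dimension ranges, mm.
#' @param min_clearance Minimum surface-to-surface gap between culm sections,
#'   and between blades and culm sections, mm.
#' @param check_heights Heights (mm) at which non-overlap is enforced; the
#'   defaults are the two reconstruction heights of the standard protocol.
#' @param max_tries Rejection-sampling attempts per tiller before a packing
#'   error is raised.
#' @return A [plant_phantom()].
#' @export
sample_plant <- function(seed, n_tillers = c(3, 15), crown_radius = 18,
                         inclination_range = c(0, 30),
                         diameter_range = c(4.5, 7.5),
                         wall_range = c(0.8, 1.6),
                         fertile_prob = 0.7,
                         n_leaves = 3,
                         leaf_length_range = c(15, 30),
                         leaf_width_range = c(1, 2),
                         min_clearance = 2,
                         check_heights = c(0, 50, 55),
                         max_tries = 2000) {
  with_seed(seed, {
    nt <- if (length(n_tillers) == 2)
      sample(seq(n_tillers[1], n_tillers[2]), 1) else n_tillers
    tillers <- plant_phantom()$tillers
    centroids_at <- function(tl, h) {
      drift <- h * tan(deg2rad(tl$inclination))
      cbind(tl$base_x + drift * cos(deg2rad(tl$azimuth)),
            tl$base_y + drift * sin(deg2rad(tl$azimuth)))
    }
    if (nt > 0) {
      # dense plants can paint themselves into a corner: on a stuck tiller,
      # restart the whole placement (bounded) before declaring infeasibility
      for (restart in seq_len(20)) {
        tillers <- plant_phantom()$tillers
        failed_at <- 0L
        for (i in seq_len(nt)) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            r <- crown_radius * sqrt(runif(1))
            a <- runif(1, 0, 2 * pi)
            # tillers fan outward from the crown center (jittered radial
            # lean), as in real rice plants; keeps sections apart at height
            cand <- tiller_spec(
              base_x = r * cos(a), base_y = r * sin(a),
              inclination = runif(1, inclination_range[1],
                                  inclination_range[2]),
              azimuth = (rad2deg(a) + runif(1, -45, 45)) %% 360,
              outer_diameter = runif(1, diameter_range[1], diameter_range[2]),
              wall_thickness = runif(1, wall_range[1], wall_range[2]),
              fertile = runif(1) < fertile_prob)
            ok <- TRUE
            if (nrow(tillers) > 0) {
              for (h in check_heights) {
                d <- sqrt(rowSums((centroids_at(tillers, h) -
                                   matrix(centroids_at(cand, h),
                                          nrow(tillers), 2, byrow = TRUE))^2))
                lim <- (tillers$outer_diameter + cand$outer_diameter) / 2 +
                  min_clearance
                if (any(d < lim)) { ok <- FALSE; break }
              }
            }
            if (ok) { tillers <- rbind(tillers, cand); placed <- TRUE; break }
          }
          if (!placed) { failed_at <- i; break }
        }
        if (failed_at == 0L) break
        if (restart == 20)
          stop("packing error: could not place tiller ", failed_at,
               " after ", max_tries, " tries and 20 restarts")
      }
    }
    leaves <- plant_phantom()$leaves
    if (n_leaves > 0) {
      reach <- crown_radius +
        max(check_heights) * tan(deg2rad(inclination_range[2]))
      for (i in seq_len(n_leaves)) {
        for (try in seq_len(max_tries)) {
          len <- runif(1, leaf_length_range[1], leaf_length_range[2])
          wid <- runif(1, leaf_width_range[1], leaf_width_range[2])
          # keep blades elongated enough to fail any roundness filter
          if (len < 10 * wid) wid <- len / 10
          cand <- data.frame(
            x = runif(1, -reach, reach), y = runif(1, -reach, reach),
            length = len, width = wid, orientation = runif(1, 0, 180),
            z_min = 0, z_max = max(check_heights) + 10)
          clear <- TRUE
          if (nrow(tillers) > 0) {
            u <- c(cos(deg2rad(cand$orientation)), sin(deg2rad(cand$orientation)))
            for (h in check_heights) {
              cen <- centroids_at(tillers, h)
              rel <- sweep(cen, 2, c(cand$x, cand$y))
              along <- pmin(pmax(rel %*% u, -len / 2), len / 2)
              closest <- cbind(cand$x + along * u[1], cand$y + along * u[2])
              d <- sqrt(rowSums((cen - closest)^2))
              lim <- tillers$outer_diameter / 2 + wid / 2 + min_clearance
              if (any(d < lim)) { clear <- FALSE; break }
            }
          }
          if (clear) { leaves <- rbind(leaves, cand); break }
        }
        # blades that cannot be placed without touching a culm are dropped
      }
    }
    plant_phantom(tillers, leaves, seed = seed)
  })
}

#' Ground-truth tiller geometry at given heights
#'
#' The culm axis is a straight line, so the section centroid at height `h` is
#' `base + h * tan(inclination) * (cos(azimuth), sin(azimuth))`; diameters and
#' wall thicknesses are constant along the culm.
#'
#' @param plant A [plant_phantom()].
#' @param heights Heights above the soil surface, mm.
#' @return Data frame with one row per tiller per height: `tiller`, `height`,
#'   `x`, `y`, `outer_diameter`, `wall_thickness`, `inclination`, `azimuth`,
#'   `fertile`.
#' @export
ground_truth <- function(plant, heights) {
  stopifnot(inherits(plant, "plant_phantom"))
  tl <- plant$tillers
  out <- do.call(rbind, lapply(heights, function(h) {
    if (nrow(tl) == 0)
      return(data.frame(tiller = integer(), height = numeric(), x = numeric(),
                        y = numeric(), outer_diameter = numeric(),
                        wall_thickness = numeric(), inclination = numeric(),
                        azimuth = numeric(), fertile = logical()))
    drift <- h * tan(deg2rad(tl$inclination))
    data.frame(tiller = seq_len(nrow(tl)), height = h,
               x = tl$base_x + drift * cos(deg2rad(tl$azimuth)),
               y = tl$base_y + drift * sin(deg2rad(tl$azimuth)),
               outer_diameter = tl$outer_diameter,
               wall_thickness = tl$wall_thickness,
               inclination = tl$inclination, azimuth = tl$azimuth,
               fertile = tl$fertile)
  }))
  rownames(out) <- NULL
  out
}

#' Rasterize a transverse slice of a phantom
#'
#' Draws the analytic cross section of the plant at height `height` on a
#' square attenuation grid centred on the rotation axis. Culm walls get
#' attenuation 1.0, the pith cavity of fertile tillers 0.05, leaf blades 0.4
#' and background 0; only relative contrast matters downstream. A tiller
#' whose section falls (partly) outside the grid is clipped with a warning.
#'
#' @param plant A [plant_phantom()].
#' @param height Slice height above the soil surface, mm.
#' @param geom A [scanner_geometry()]; supplies `pixel_size`.
#' @param size Grid side, pixels.
#' @param attenuation Named numeric: `wall`, `pith`, `leaf` levels.
#' @return A [slice_image()] with ground-truth attenuation values.
#' @export
rasterize_slice <- function(plant, height, geom = scanner_geometry(pixel_size = 0.2),
                            size = 544,
                            attenuation = c(wall = 1, pith = 0.05, leaf = 0.4)) {
  stopifnot(inherits(plant, "plant_phantom"), height >= 0, size >= 2)
  px <- geom$pixel_size
  img <- matrix(0, size, size)
  c0 <- (size - 1) / 2
  # pixel-center coordinates in mm, x right (columns), y down (rows)
  xs <- (seq_len(size) - 1 - c0) * px
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size, byrow = FALSE)
  half <- (size - 1) / 2 * px

  lv <- plant$leaves
  if (nrow(lv) > 0) {
    for (i in seq_len(nrow(lv))) {
      if (height < lv$z_min[i] || height > lv$z_max[i]) next
      th <- deg2rad(lv$orientation[i])
      dx <- X - lv$x[i]; dy <- Y - lv$y[i]
      along <- dx * cos(th) + dy * sin(th)
      across <- -dx * sin(th) + dy * cos(th)
      img[abs(along) <= lv$length[i] / 2 &
          abs(across) <= lv$width[i] / 2] <- attenuation[["leaf"]]
    }
  }
  tl <- plant$tillers
  if (nrow(tl) > 0) {
    gt <- ground_truth(plant, height)
    for (i in seq_len(nrow(tl))) {
      R <- tl$outer_diameter[i] / 2
      if (abs(gt$x[i]) + R > half || abs(gt$y[i]) + R > half)
        warning("tiller ", i, " extends outside the field of view; clipped")
      d2 <- (X - gt$x[i])^2 + (Y - gt$y[i])^2
      img[d2 <= R^2] <- attenuation[["wall"]]
      if (tl$fertile[i]) {
        r <- R - tl$wall_thickness[i]
        if (r > 0) img[d2 <= r^2] <- attenuation[["pith"]]
      }
    }
  }
  slice_image(img, pixel_size = px, height = height)
}
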