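# Shared fixture builders and independent brute-force oracles.

# Binary disk / annulus drawn on an n x n grid (pixel-center test, 0-based).
draw_disk <- function(n, cx, cy, r, value = 1, img = matrix(0, n, n)) {
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  img[(X - cx)^2 + (Y - cy)^2 <= r^2] <- value
  img
}

draw_annulus <- function(n, cx, cy, r_out, r_in, img = matrix(0, n, n)) {
  img <- draw_disk(n, cx, cy, r_out, 1, img)
  draw_disk(n, cx, cy, r_in, 0, img)
}

# Axis-aligned rectangle of given extents (a low-circularity "blade").
draw_rect <- function(n, r0, r1, c0, c1, value = 1, img = matrix(0, n, n)) {
  img[r0:r1, c0:c1] <- value
  img
}

# Brute-force minimum enclosing circle: smallest of all pair/triple candidate
# circles that covers every point. O(n^4); for tiny point sets only.
brute_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  covers <- function(circ) all(sqrt((pts[, 1] - circ[1])^2 +
                                    (pts[, 2] - circ[2])^2) <= circ[3] + 1e-9)
  best <- c(0, 0, Inf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      cen <- (pts[i, ] + pts[j, ]) / 2
      circ <- c(cen, sqrt(sum((pts[i, ] - cen)^2)))
      if (circ[3] < best[3] && covers(circ)) best <- circ
      for (k in seq_len(n)) if (k > j) {
        ax <- pts[i, 1]; ay <- pts[i, 2]; bx <- pts[j, 1]; by <- pts[j, 2]
        cx <- pts[k, 1]; cy <- pts[k, 2]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / d
        circ <- c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
        if (circ[3] < best[3] && covers(circ)) best <- circ
      }
    }
  }
  best
}

# Independent point-in-convex-hull test: inside iff on the inner side of
# every hull edge (counter-clockwise orientation via chull).
brute_hull_count <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3) return(nrow(pts))
  h <- pts[rev(grDevices::chull(pts)), , drop = FALSE] # ccw order
  if (nrow(h) < 3) return(nrow(pts))
  xs <- seq(floor(min(pts[, 1])), ceiling(max(pts[, 1])))
  ys <- seq(floor(min(pts[, 2])), ceiling(max(pts[, 2])))
  count <- 0
  for (x in xs) for (y in ys) {
    inside <- TRUE
    for (e in seq_len(nrow(h))) {
      a <- h[e, ]; b <- h[if (e == nrow(h)) 1 else e + 1, ]
      cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      if (cross < -1e-9) { inside <- FALSE; break }
    }
    if (inside) count <- count + 1
  }
  count
}

# Exhaustive pair-counting GLCM oracle (symmetric, 4 directions, distance 1).
brute_glcm <- function(q, mask, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    if (!mask[r, cc]) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!mask[r2, c2]) next
      i <- q[r, cc] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts
}

# Brute-force assignment by enumerating all permutations (n <= 6).
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; bestc <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    cost_p <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cost_p < bestc) { bestc <- cost_p; best <- p[seq_len(n)] }
  }
  list(assignment = best, cost = bestc)
}

# Small fast run configuration for pipeline tests (coarse grid, short scan,
# low heights so that phantoms stay inside the reduced field of view).
fast_config <- function(seed = 1,
                        phantom = list(n_tillers = c(3, 6), crown_radius = 10,
                                       inclination_range = c(0, 20),
                                       check_heights = c(0, 20, 25)),
                        ...) {
  run_config(seed = seed, image_size = 192, pixel_size = 0.35,
             n_projections = 95, angle_step = 2.4,
             analysis_heights = c(20, 25), phantom = phantom,
             render = list(width_px = 240, height_px = 160, pixel_mm = 3),
             ...)
}
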