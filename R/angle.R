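# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials).
# Returns, for each row of the cost matrix, the assigned column (requires
# nrow <= ncol).
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)   # row matched to each column; index m+1 is virtual
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

#' Match tiller sections between two reconstruction heights
#'
#' Culm sections in the lower and upper slices are paired by an optimal
#' one-to-one assignment minimizing total centroid distance (Hungarian
#' algorithm on the distance matrix); pairs further apart than `max_shift`
#' are discarded, and unmatched sections are excluded from the angle
#' statistics.
#'
#' @param low,high Region tables from [measure_regions()] for the lower and
#'   upper slice.
#' @param max_shift Maximum plausible centroid displacement, mm.
#' @return Data frame with one row per matched pair: `label_low`,
#'   `label_high`, `displacement` (mm).
#' @export
match_tillers <- function(low, high, max_shift = 10) {
  stopifnot(max_shift > 0)
  empty <- data.frame(label_low = integer(), label_high = integer(),
                      displacement = numeric())
  if (nrow(low) == 0 || nrow(high) == 0) return(empty)
  d <- sqrt(outer(low$x, high$x, "-")^2 + outer(low$y, high$y, "-")^2)
  swap <- nrow(low) > nrow(high)
  a <- if (swap) hungarian(t(d)) else hungarian(d)
  res <- if (swap) data.frame(label_low = low$label[a],
                              label_high = high$label[seq_along(a)],
                              displacement = d[cbind(a, seq_along(a))])
         else data.frame(label_low = low$label[seq_along(a)],
                         label_high = high$label[a],
                         displacement = d[cbind(seq_along(a), a)])
  res <- res[res$displacement <= max_shift, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tiller inclination angle from centroid displacement
#'
#' The culm axis is taken as the straight line through the section centroids
#' at two heights `dz` apart: `angle = atan(displacement / dz)`, in degrees
#' from vertical (0 = upright). The default `dz` corresponds to the standard
#' protocol's two reconstruction rows, 50 detector rows apart at 0.097 mm.
#'
#' @param match Data frame from [match_tillers()] (or a numeric vector of
#'   displacements, mm).
#' @param dz Height difference between the two slices, mm; must be > 0.
#' @return Numeric vector of angles, degrees.
#' @export
tiller_angle <- function(match, dz = 4.85) {
  if (dz <= 0) stop("dz must be positive")
  disp <- if (is.data.frame(match)) match$displacement else as.numeric(match)
  if (any(disp < 0)) stop("displacement must be non-negative")
  rad2deg(atan(disp / dz))
}

#' Plant-level tiller angle statistics
#'
#' Arithmetic mean (MEANTA), maximum (MAXTA) and population standard
#' deviation (SDTA) of the per-tiller inclination angles.
#'
#' @param angles Numeric vector of angles, degrees, each in `[0, 90)`.
#' @return Named numeric vector `c(MEANTA, MAXTA, SDTA)`; all `NA` when
#'   `angles` is empty.
#' @export
angle_stats <- function(angles) {
  if (length(angles) == 0)
    return(c(MEANTA = NA_real_, MAXTA = NA_real_, SDTA = NA_real_))
  if (any(angles < 0 | angles >= 90))
    stop("angles must lie in [0, 90) degrees")
  c(MEANTA = mean(angles), MAXTA = max(angles), SDTA = sd_pop(angles))
}
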