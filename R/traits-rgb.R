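# --- plant segmentation ----------------------------------------------------

#' Segment the plant in a side-view color image
#'
#' Excess-green index segmentation: a pixel is plant if `2G - R - B`
#' exceeds a threshold, with small connected components removed. Works on
#' dark-background chamber images; the rule and parameters are recorded on
#' the mask for provenance.
#'
#' @param image Height x width x 3 array in `[0, 1]` (or 8-bit, auto-scaled),
#'   or a `"side_view"` object.
#' @param exg_threshold Excess-green threshold.
#' @param min_size Minimum component size, px.
#' @return Logical plant mask with attribute `provenance`.
#' @export
segment_plant <- function(image, exg_threshold = 0.05, min_size = 10) {
  if (inherits(image, "side_view")) image <- image$image
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (max(image) > 1) image <- image / 255
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  mask <- exg > exg_threshold
  if (any(mask) && min_size > 1) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    mask <- matrix(lab > 0 & sizes[pmax(lab, 1)] >= min_size,
                   nrow(mask), ncol(mask))
  }
  attr(mask, "provenance") <- list(rule = "excess-green",
                                   exg_threshold = exg_threshold,
                                   min_size = min_size)
  mask
}

# Grayscale by standard luminance weights (fixed for reproducibility).
to_gray <- function(image) {
  if (max(image) > 1) image <- image / 255
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# --- color / digital biomass ----------------------------------------------

#' Color and digital-biomass traits
#'
#' `TPA` (total projected area) counts plant pixels, `GPA` those whose hue
#' falls in the green window, `GPAR = GPA / TPA`, and `GCV` is the mean green
#' channel value over plant pixels on a `[0, 1]` scale. On an empty mask the
#' ratio traits are missing.
#'
#' @param image Color array as in [segment_plant()].
#' @param mask Logical plant mask.
#' @param hue_window Hue interval (degrees, 0-360) classified as green.
#' @return One-row data frame: `GCV`, `GPA`, `TPA`, `GPAR`.
#' @export
biomass_color_traits <- function(image, mask, hue_window = c(70, 170)) {
  if (inherits(image, "side_view")) image <- image$image
  if (max(image) > 1) image <- image / 255
  tpa <- sum(mask)
  if (tpa == 0)
    return(data.frame(GCV = NA_real_, GPA = 0L, TPA = 0L, GPAR = NA_real_))
  rgb <- rbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  gpa <- sum(hue >= hue_window[1] & hue <= hue_window[2])
  data.frame(GCV = mean(rgb[2, ]), GPA = gpa, TPA = tpa, GPAR = gpa / tpa)
}

# --- architecture ----------------------------------------------------------

# boundary pixels: plant pixels with at least one 4-neighbor off the plant
boundary_count <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  inner <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  up <- pad[1:nrow(mask), 2:(ncol(mask) + 1)]
  dn <- pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)]
  lf <- pad[2:(nrow(mask) + 1), 1:ncol(mask)]
  rt <- pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  sum(inner & !(up & dn & lf & rt))
}

#' Plant architecture traits from a binary mask
#'
#' Bounding-box extents `W` and `H` (px), `HWR = H/W`, the box-fill ratio
#' `TBR = TPA / (W * H)`, the boundary-to-area ratio `PAR`, the vertical
#' density profile `F1..F20` (fraction of plant pixels in 20 equal-height
#' horizontal bands of the bounding box, `F1` at the bottom), and band-wise
#' compactness `PC1..PC6` (plant area over convex-hull area in 6 equal-height
#' bands, bottom first; hull areas are counted in covered pixels, so each
#' `PCk` lies in `(0, 1]`).
#'
#' @param mask Logical plant mask.
#' @return One-row data frame with `W`, `H`, `HWR`, `TBR`, `PAR`,
#'   `PC1..PC6`, `F1..F20`; all missing for an empty mask.
#' @export
architecture_traits <- function(mask) {
  fnames <- paste0("F", 1:20)
  pcnames <- paste0("PC", 1:6)
  out <- as.data.frame(as.list(setNames(
    rep(NA_real_, 5 + 6 + 20), c("W", "H", "HWR", "TBR", "PAR", pcnames, fnames))))
  if (!any(mask)) return(out)
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  H <- r1 - r0 + 1; W <- c1 - c0 + 1
  tpa <- sum(mask)
  out$W <- W; out$H <- H; out$HWR <- H / W
  out$TBR <- tpa / (W * H)
  out$PAR <- boundary_count(mask) / tpa
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  # band index from the bottom: bottom row of the bbox belongs to band 1
  band_of <- function(r, nb) pmin(nb, 1 + ((H - r) * nb) %/% H)
  rowcounts <- rowSums(sub)
  f_idx <- band_of(seq_len(H), 20)
  f <- vapply(1:20, function(b) sum(rowcounts[f_idx == b]), numeric(1)) / tpa
  out[fnames] <- as.list(f)
  pc_idx <- band_of(seq_len(H), 6)
  for (b in 1:6) {
    bs <- sub[pc_idx == b, , drop = FALSE]
    n <- sum(bs)
    if (n == 0) { out[[pcnames[b]]] <- NA_real_; next }
    idx <- which(bs)
    pts <- cbind((idx - 1) %/% nrow(bs), (idx - 1) %% nrow(bs))
    out[[pcnames[b]]] <- n / max(n, hull_pixel_count(pts))
  }
  out
}

# --- fractal dimension -----------------------------------------------------

#' Box-counting fractal dimension of a binary mask
#'
#' Least-squares slope of `log(box count)` against `log(1 / box size)` over
#' dyadic box sizes (1, 2, 4, ... up to half the mask extent). `cropped`
#' first restricts the mask to its bounding box (the FDIC variant;
#' `cropped = FALSE` gives FDNIC). The estimate is clamped to the valid
#' planar range `[0, 2]`.
#'
#' @param mask Logical matrix.
#' @param cropped Crop to the bounding box before counting.
#' @return Dimension estimate, or `NA` if the (cropped) mask is smaller than
#'   2 px in either axis or empty.
#' @export
fractal_dimension <- function(mask, cropped = FALSE) {
  if (!any(mask)) return(NA_real_)
  if (cropped) {
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  }
  if (nrow(mask) < 2 || ncol(mask) < 2) return(NA_real_)
  smax <- max(nrow(mask), ncol(mask)) / 2
  sizes <- 2^(0:floor(log2(smax)))
  counts <- vapply(sizes, function(s) {
    nr <- ceiling(nrow(mask) / s) * s
    nc <- ceiling(ncol(mask) / s) * s
    pad <- matrix(FALSE, nr, nc)
    pad[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
    blocks <- rowsum(t(rowsum(pad * 1, (seq_len(nr) - 1) %/% s)),
                     (seq_len(nc) - 1) %/% s)
    sum(blocks > 0)
  }, numeric(1))
  if (length(sizes) < 2) return(NA_real_)
  slope <- unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
  min(2, max(0, slope))
}

# --- histogram texture -----------------------------------------------------

#' Histogram texture statistics of the plant region
#'
#' First-order statistics of the normalized 256-bin gray-level histogram of
#' plant pixels (Gonzalez-Woods conventions): mean `M` and standard
#' deviation `SE` in gray levels (0-255), smoothness
#' `S = 1 - 1/(1 + sigma^2)` with the variance on unit-normalized levels,
#' normalized third central moment `MU3`, uniformity (energy) `U = sum p^2`
#' and entropy `E = -sum p log2 p` in bits.
#'
#' @param gray Grayscale matrix in `[0, 1]` (or 0-255).
#' @param mask Logical plant mask.
#' @return One-row data frame: `M`, `SE`, `S`, `MU3`, `U`, `E`; missing on an
#'   empty mask.
#' @export
histogram_texture <- function(gray, mask) {
  if (sum(mask) == 0)
    return(data.frame(M = NA_real_, SE = NA_real_, S = NA_real_,
                      MU3 = NA_real_, U = NA_real_, E = NA_real_))
  g <- gray[mask]
  if (max(gray) <= 1) g <- g * 255
  lev <- pmin(255, pmax(0, round(g)))
  p <- tabulate(lev + 1, nbins = 256) / length(lev)
  z <- 0:255
  m <- sum(z * p)
  v <- sum((z - m)^2 * p)
  pn <- p[p > 0]
  data.frame(M = m, SE = sqrt(v), S = 1 - 1 / (1 + v / 255^2),
             MU3 = sum((z - m)^3 * p) / 255^2,
             U = sum(p^2), E = -sum(pn * log2(pn)))
}

# --- gray-level co-occurrence texture -------------------------------------

# Symmetric normalized GLCM restricted to the mask: distance-1 pairs in the
# given (drow, dcol) offsets, both pixels inside the mask.
glcm_matrix <- function(q, mask, n_levels,
                        offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, n_levels, n_levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(n_levels - 1)),
                 factor(b[ok], levels = 0:(n_levels - 1)))
    counts <- counts + tab + t(tab)
  }
  counts
}

#' Gray-level co-occurrence texture traits
#'
#' Haralick-style statistics of the symmetric co-occurrence matrix at
#' distance 1, averaged over the four directions (0, 45, 90, 135 degrees),
#' with gray levels quantized to `n_levels`. The fifteen features, in fixed
#' order T1..T15, are: angular second moment, contrast, correlation, sum of
#' squares variance, inverse difference moment, sum average, sum variance,
#' sum entropy, entropy, difference variance, difference entropy, the two
#' information measures of correlation, maximum probability, and
#' dissimilarity. Level indices are the 0-based quantized values; logs are
#' base 2. Correlation is missing for constant regions (zero variance).
#'
#' @param gray Grayscale matrix in `[0, 1]` (or 0-255).
#' @param mask Logical plant mask.
#' @param n_levels Number of quantized gray levels.
#' @return One-row data frame `T1..T15`; all missing with fewer than 2 valid
#'   pixel pairs.
#' @export
glcm_traits <- function(gray, mask, n_levels = 32) {
  tnames <- paste0("T", 1:15)
  na_row <- as.data.frame(as.list(setNames(rep(NA_real_, 15), tnames)))
  if (sum(mask) < 2) return(na_row)
  g <- gray
  if (max(gray) <= 1) g <- g * 255
  q <- matrix(pmin(n_levels - 1, floor(pmin(255, pmax(0, g)) / 256 * n_levels)),
              nrow(gray), ncol(gray))
  counts <- glcm_matrix(q, mask, n_levels)
  if (sum(counts) < 4) return(na_row) # < 2 distinct pixel pairs
  p <- counts / sum(counts)
  i <- matrix(0:(n_levels - 1), n_levels, n_levels)
  j <- t(i)
  px <- rowSums(p) # == colSums(p) by symmetry
  mu <- sum((0:(n_levels - 1)) * px)
  sig2 <- sum(((0:(n_levels - 1)) - mu)^2 * px)
  # diagonal-band distributions
  psum <- vapply(0:(2 * n_levels - 2), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(n_levels - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  sa <- sum((0:(2 * n_levels - 2)) * psum)
  md <- sum((0:(n_levels - 1)) * pdif)
  hxy <- ent(p)
  pxy <- outer(px, px)
  sel <- pxy > 0
  hxy1 <- -sum(p[sel] * log2(pxy[sel]))
  hxy2 <- ent(pxy)
  hx <- ent(px)
  out <- na_row
  out$T1 <- sum(p^2)
  out$T2 <- sum((i - j)^2 * p)
  out$T3 <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_
  out$T4 <- sum((i - mu)^2 * p)
  out$T5 <- sum(p / (1 + (i - j)^2))
  out$T6 <- sa
  out$T7 <- sum(((0:(2 * n_levels - 2)) - sa)^2 * psum)
  out$T8 <- ent(psum)
  out$T9 <- hxy
  out$T10 <- sum(((0:(n_levels - 1)) - md)^2 * pdif)
  out$T11 <- ent(pdif)
  out$T12 <- if (hx > 0) (hxy - hxy1) / hx else 0
  out$T13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out$T14 <- max(p)
  out$T15 <- sum(abs(i - j) * p)
  out
}

# --- the 58-trait record ---------------------------------------------------

#' Extract the full side-view RGB trait record
#'
#' Segments the plant and computes all 58 RGB traits: color and digital
#' biomass (GCV, GPA, TPA, GPAR), architecture (PC1-PC6, PAR, W, H, FDNIC,
#' TBR, HWR, FDIC, F1-F20), histogram texture (M, SE, S, MU3, U, E) and
#' co-occurrence texture (T1-T15).
#'
#' @param image Color array or `"side_view"` object.
#' @param mask Optional precomputed plant mask (default: [segment_plant()]).
#' @param hue_window,n_levels Passed to the color / texture extractors.
#' @return One-row data frame with the 58 trait columns.
#' @export
rgb_traits <- function(image, mask = NULL, hue_window = c(70, 170),
                       n_levels = 32) {
  if (inherits(image, "side_view")) image <- image$image
  if (is.null(mask)) mask <- segment_plant(image)
  gray <- to_gray(image)
  arch <- architecture_traits(mask)
  cbind(biomass_color_traits(image, mask, hue_window),
        arch[c("PC1", "PC2", "PC3", "PC4", "PC5", "PC6")],
        arch[c("PAR", "W", "H")],
        data.frame(FDNIC = fractal_dimension(mask, cropped = FALSE)),
        arch[c("TBR", "HWR")],
        data.frame(FDIC = fractal_dimension(mask, cropped = TRUE)),
        arch[paste0("F", 1:20)],
        histogram_texture(gray, mask),
        glcm_traits(gray, mask, n_levels))
}
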