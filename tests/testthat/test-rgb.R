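mk_img <- function(n = 60, m = 80) array(0, dim = c(n, m, 3))

test_that("excess-green segmentation recovers exact synthetic regions", {
  img <- mk_img()
  img[20:40, 30:50, 2] <- 1 # pure green rectangle on black
  mask <- segment_plant(img)
  truth <- matrix(FALSE, 60, 80); truth[20:40, 30:50] <- TRUE
  expect_equal(unclass(mask)[], truth, ignore_attr = TRUE)
  expect_false(any(segment_plant(mk_img())))
  # rendered phantom: mask within 2% of ground-truth pixel count
  view <- render_side_view(sample_plant(seed = 4, n_tillers = 6), seed = 4)
  m <- segment_plant(view$image)
  expect_lt(abs(sum(m) - sum(view$mask)) / sum(view$mask), 0.02)
})

test_that("color traits count green and total plant pixels exactly", {
  img <- mk_img(40, 40)
  img[1:20, , 1] <- 0.1; img[1:20, , 2] <- 0.8; img[1:20, , 3] <- 0.1 # green
  img[21:40, , 1] <- 0.8; img[21:40, , 2] <- 0.8; img[21:40, , 3] <- 0.1 # yellow
  mask <- matrix(TRUE, 40, 40)
  b <- biomass_color_traits(img, mask)
  expect_equal(b$TPA, 1600)
  expect_equal(b$GPAR, 0.5) # half green, half yellow, equal counts
  expect_equal(b$GCV, 0.8)
  # uniform green level 128 in 8-bit terms
  img2 <- mk_img(10, 10); img2[, , 2] <- 128 / 255
  b2 <- biomass_color_traits(img2, matrix(TRUE, 10, 10))
  expect_equal(b2$GCV, 128 / 255)
  expect_equal(b2$GPAR, 1)
  # empty mask: ratios missing
  b3 <- biomass_color_traits(img2, matrix(FALSE, 10, 10))
  expect_true(is.na(b3$GCV) && is.na(b3$GPAR))
  expect_equal(b3$TPA, 0)
})

test_that("architecture traits of a solid rectangle are exact", {
  mask <- matrix(FALSE, 120, 60)
  mask[11:110, 21:40] <- TRUE # H = 100, W = 20
  a <- architecture_traits(mask)
  expect_equal(a$H, 100)
  expect_equal(a$W, 20)
  expect_equal(a$HWR, 5)
  expect_equal(a$TBR, 1)
  expect_equal(unlist(a[paste0("F", 1:20)], use.names = FALSE), rep(0.05, 20))
  expect_true(all(unlist(a[paste0("PC", 1:6)]) > 0.9))
  expect_true(all(unlist(a[paste0("PC", 1:6)]) <= 1))
})

test_that("the F-profile matches brute-force per-row counting", {
  mask <- matrix(FALSE, 90, 90)
  mask <- mask | draw_disk(90, 30, 25, 12) > 0
  mask <- mask | draw_disk(90, 60, 70, 9) > 0
  a <- architecture_traits(mask)
  f <- unlist(a[paste0("F", 1:20)], use.names = FALSE)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # brute force: band of each row counted bottom-up inside the bbox
  rows <- which(rowSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows); H <- r1 - r0 + 1
  fb <- numeric(20)
  for (r in r0:r1) {
    b <- min(20, 1 + ((r1 - r) * 20) %/% H)
    fb[b] <- fb[b] + sum(mask[r, ])
  }
  expect_equal(f, fb / sum(mask))
  # translation leaves every architecture trait unchanged
  shifted <- matrix(FALSE, 90, 90)
  shifted[4:90, 3:90] <- mask[1:87, 1:88]
  expect_equal(architecture_traits(shifted), a)
})

test_that("box-counting dimension matches known sets", {
  sq <- matrix(TRUE, 64, 64)
  expect_equal(fractal_dimension(sq, cropped = TRUE), 2, tolerance = 0.05)
  line <- matrix(FALSE, 64, 64); line[30, ] <- TRUE
  expect_equal(fractal_dimension(line, cropped = FALSE), 1, tolerance = 0.1)
  # Sierpinski triangle, depth 6: dimension log 3 / log 2
  idx <- 0:63
  sier <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0)
  expect_equal(fractal_dimension(sier, cropped = TRUE), log(3) / log(2),
               tolerance = 0.032)
  expect_true(is.na(fractal_dimension(line[30, , drop = FALSE], cropped = TRUE)))
  expect_true(is.na(fractal_dimension(matrix(FALSE, 8, 8))))
})

test_that("histogram statistics match direct per-pixel accumulation", {
  # uniform region: single occupied bin
  g <- matrix(0.5, 20, 20)
  h <- histogram_texture(g, matrix(TRUE, 20, 20))
  expect_equal(h$SE, 0)
  expect_equal(h$S, 0)
  expect_equal(h$U, 1)
  expect_equal(h$E, 0)
  # two equal bins
  g2 <- matrix(c(0, 1), 16, 16)
  h2 <- histogram_texture(g2, matrix(TRUE, 16, 16))
  expect_equal(h2$U, 0.5)
  expect_equal(h2$E, 1)
  # random image: moments equal brute-force accumulation over pixels
  set.seed(9)
  g3 <- matrix(runif(400), 20, 20)
  mask <- matrix(runif(400) > 0.3, 20, 20)
  h3 <- histogram_texture(g3, mask)
  lev <- round(g3[mask] * 255)
  expect_equal(h3$M, mean(lev))
  expect_equal(h3$SE, sqrt(mean((lev - mean(lev))^2)))
  expect_equal(h3$MU3, mean((lev - mean(lev))^3) / 255^2)
})

test_that("GLCM counting equals the exhaustive pair oracle on small images", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(4:8, 1); m <- sample(4:8, 1)
    g <- matrix(sample(0:255, n * m, replace = TRUE), n, m)
    mask <- matrix(runif(n * m) > 0.2, n, m)
    q <- matrix(pmin(7, g %/% 32), n, m)
    ours <- tillerct:::glcm_matrix(q, mask, 8)
    expect_equal(unclass(ours)[], brute_glcm(q, mask, 8), ignore_attr = TRUE)
    # features from the brute matrix: simple hand formulas
    if (sum(ours) >= 4) {
      p <- brute_glcm(q, mask, 8) / sum(ours)
      tr <- glcm_traits(g / 255, mask, n_levels = 8)
      iv <- matrix(0:7, 8, 8); jv <- t(iv)
      expect_equal(tr$T1, sum(p^2))
      expect_equal(tr$T2, sum((iv - jv)^2 * p))
      expect_equal(tr$T14, max(p))
      expect_equal(tr$T15, sum(abs(iv - jv) * p))
    }
  }
})

test_that("GLCM landmarks: uniform image and checkerboard", {
  g <- matrix(0.7, 12, 12)
  tr <- glcm_traits(g, matrix(TRUE, 12, 12))
  expect_equal(tr$T1, 1) # ASM
  expect_equal(tr$T2, 0) # contrast
  expect_equal(tr$T9, 0) # entropy
  # 2-level checkerboard, horizontal direction only: every pair differs by
  # the full level step, so contrast = (31 - 0)^2
  cb <- outer(1:8, 1:8, "+") %% 2
  q <- matrix(ifelse(cb > 0, 31, 0), 8, 8)
  counts <- tillerct:::glcm_matrix(q, matrix(TRUE, 8, 8), 32,
                                   offsets = list(c(0, 1)))
  p <- counts / sum(counts)
  iv <- matrix(0:31, 32, 32)
  expect_equal(sum((iv - t(iv))^2 * p), 961)
  # fewer than 2 valid pairs: missing
  lone <- matrix(FALSE, 8, 8); lone[3, 3] <- TRUE
  expect_true(all(is.na(glcm_traits(g, lone))))
})

test_that("GLCM features are invariant to transposition", {
  set.seed(31)
  g <- matrix(runif(900), 30, 30)
  mask <- draw_disk(30, 14, 14, 11) > 0
  expect_equal(glcm_traits(g, mask), glcm_traits(t(g), t(mask)),
               tolerance = 1e-12)
})

test_that("the rendered plant height is recovered within 2 px", {
  view <- render_side_view(sample_plant(seed = 8, n_tillers = 5), seed = 8)
  tr <- rgb_traits(view)
  expect_lt(abs(tr$H - view$height_px), 2.5)
  expect_equal(ncol(tr), 58)
  expect_true(tr$GPAR > 0.99) # fully green plant
  # senescent rendering drops GPAR
  vy <- render_side_view(sample_plant(seed = 8, n_tillers = 5),
                         senescent_frac = 0.5, seed = 8)
  expect_lt(rgb_traits(vy)$GPAR, 0.9)
})
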