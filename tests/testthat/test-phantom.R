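test_that("sample_plant is reproducible and respects separation", {
  p1 <- sample_plant(seed = 11)
  p2 <- sample_plant(seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_plant(seed = 12)))

  # 12 tillers with >= 5 mm axis separation inside a 40 mm crown
  p <- sample_plant(seed = 5, n_tillers = 12, crown_radius = 20,
                    diameter_range = c(3, 3), wall_range = c(0.5, 1),
                    min_clearance = 2, check_heights = 0)
  d <- as.matrix(dist(p$tillers[, c("base_x", "base_y")]))
  expect_true(all(d[upper.tri(d)] >= 5))

  expect_equal(nrow(sample_plant(seed = 1, n_tillers = 0)$tillers), 0)
  expect_error(sample_plant(seed = 1, n_tillers = 40, crown_radius = 5,
                            max_tries = 30),
               "packing error")
})

test_that("ground-truth centroids follow the closed-form affine trajectory", {
  p <- plant_phantom(tiller_spec(2, -3, 45, 0, 6, 1, TRUE))
  gt <- ground_truth(p, c(0, 10, 20))
  expect_equal(gt$x, c(2, 12, 22)) # tan(45) = 1, azimuth 0 -> +x drift
  expect_equal(gt$y, rep(-3, 3))
  # vertical tiller: centroid identical at every height
  pv <- plant_phantom(tiller_spec(4, 4, 0, 123, 5, 1))
  gtv <- ground_truth(pv, c(0, 30, 60))
  expect_equal(gtv$x, rep(4, 3))
  expect_equal(gtv$y, rep(4, 3))
  # general case equals base + h tan(incl) (cos az, sin az)
  pg <- plant_phantom(tiller_spec(-1, 2, 20, 135, 5, 1))
  h <- 37.5
  gg <- ground_truth(pg, h)
  expect_equal(gg$x, -1 + h * tan(20 * pi / 180) * cos(135 * pi / 180))
  expect_equal(gg$y, 2 + h * tan(20 * pi / 180) * sin(135 * pi / 180))
})

test_that("rasterized annulus area matches the analytic ring area within 3%", {
  geom <- scanner_geometry() # 0.097 mm pixels
  p <- plant_phantom(tiller_spec(0, 0, 0, 0, 6, 1, fertile = TRUE))
  sl <- rasterize_slice(p, 10, geom, size = 128)
  ring_px <- sum(sl$data == 1)
  analytic <- pi * (3^2 - 2^2) / geom$pixel_size^2
  expect_lt(abs(ring_px - analytic) / analytic, 0.03)
  # pith cavity present and distinct
  expect_gt(sum(sl$data == 0.05), 0)
  # non-fertile tiller is solid
  ps <- plant_phantom(tiller_spec(0, 0, 0, 0, 6, 1, fertile = FALSE))
  sls <- rasterize_slice(ps, 10, geom, size = 128)
  expect_equal(sum(sls$data == 0.05), 0)
})

test_that("tillers outside the field of view are clipped with a warning", {
  p <- plant_phantom(tiller_spec(40, 0, 0, 0, 6, 1))
  expect_warning(rasterize_slice(p, 0, scanner_geometry(pixel_size = 0.2),
                                 size = 128),
                 "outside the field of view")
})

test_that("forward projection conserves mass and is linear", {
  n <- 96
  img1 <- draw_disk(n, 48, 48, 20)
  img2 <- draw_annulus(n, 30, 60, 14, 8)
  ang <- seq(0, 170, by = 10)
  s1 <- forward_project(img1, ang, pixel_size = 1)
  # mass conservation at every angle
  expect_true(all(abs(rowSums(s1$data) - sum(img1)) / sum(img1) < 0.01))
  # linearity
  s2 <- forward_project(img2, ang, pixel_size = 1)
  s12 <- forward_project(2 * img1 + 3 * img2, ang, pixel_size = 1)
  expect_equal(s12$data, 2 * s1$data + 3 * s2$data, tolerance = 1e-10)
  # zero image projects to zero
  expect_true(all(forward_project(matrix(0, n, n), ang,
                                  pixel_size = 1)$data == 0))
})

test_that("projections of a centered disk are rotation invariant", {
  n <- 128
  # antialiased edge so the discretized disk is truly rotation symmetric
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  d <- sqrt((X - n / 2)^2 + (t(X) - n / 2)^2)
  img <- matrix(pmin(1, pmax(0, 30.5 - d)), n, n)
  s <- forward_project(img, c(0, 30, 45, 90, 133), pixel_size = 1)
  ref <- s$data[1, ]
  for (i in 2:nrow(s$data))
    expect_lt(max(abs(s$data[i, ] - ref)) / max(ref), 0.03)
})

test_that("sinogram noise is seeded and reproducible", {
  img <- draw_disk(64, 32, 32, 10)
  a <- forward_project(img, c(0, 45, 90), noise_sd = 0.5, seed = 3,
                       pixel_size = 1)
  b <- forward_project(img, c(0, 45, 90), noise_sd = 0.5, seed = 3,
                       pixel_size = 1)
  cc <- forward_project(img, c(0, 45, 90), noise_sd = 0.5, seed = 4,
                        pixel_size = 1)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, cc$data))
  expect_error(forward_project(img, numeric(0), pixel_size = 1), "non-empty")
})
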