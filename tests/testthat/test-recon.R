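test_that("extract_sinogram honors the shape contract", {
  stack <- lapply(1:5, function(i) matrix(i, 8, 16))
  s <- extract_sinogram(stack, 3, angles = seq(0, 40, by = 10))
  expect_equal(dim(s$data), c(5, 16))
  # constant projection i gives constant sinogram row i
  expect_equal(s$data[, 1], 1:5)
  expect_error(extract_sinogram(stack, 9, angles = seq(0, 40, by = 10)),
               "out of range")
  ragged <- c(stack, list(matrix(0, 4, 16)))
  expect_error(extract_sinogram(ragged, 1, angles = seq(0, 50, by = 10)),
               "format error")
})

test_that("stack row extraction round-trips against direct forward projection", {
  n <- 96
  img <- draw_disk(n, 40, 55, 18)
  ang <- seq(0, 176, by = 4)
  sino_direct <- forward_project(img, ang, pixel_size = 1)
  # build a projection stack whose row 2 is this slice
  stack <- lapply(seq_along(ang), function(i)
    rbind(0, sino_direct$data[i, ], 0))
  s <- extract_sinogram(stack, 2, angles = ang, detector_pixel = 1)
  expect_equal(s$data, sino_direct$data, tolerance = 1e-12)
})

test_that("FBP recovers a centered disk's size on full 180-degree coverage", {
  n <- 256
  r_true <- 40
  img <- draw_disk(n, n / 2, n / 2, r_true)
  s <- forward_project(img, seq(0, 179.5, by = 1), pixel_size = 1)
  rec <- fbp_reconstruct(s)
  expect_true(all(rec$data >= 0)) # clipped
  lab <- segment_tillers(rec, seg_config(min_area = 50))
  regs <- measure_regions(lab, pixel_size = 1)
  expect_equal(nrow(regs), 1)
  expect_lt(abs(regs$equivalent_diameter - 2 * r_true), 2)
  # all-zero sinogram reconstructs to zero
  z <- sinogram(matrix(0, 10, 64), seq(0, 90, by = 10), 1)
  expect_true(all(fbp_reconstruct(z)$data == 0))
  expect_error(fbp_reconstruct(sinogram(matrix(0, 1, 64), 0, 1)),
               "insufficient")
})

test_that("limited-angle FBP localizes an off-center annulus within 2 px", {
  n <- 192
  cx <- 120; cy <- 70
  img <- draw_annulus(n, cx, cy, 15, 10)
  ang <- seq(0, 227.4, by = 0.6) # the 228-degree protocol
  rec <- fbp_reconstruct(forward_project(img, ang, pixel_size = 1))
  regs <- measure_regions(segment_tillers(rec), pixel_size = 1)
  expect_equal(nrow(regs), 1)
  c0 <- (n - 1) / 2
  expect_lt(abs(regs$x + c0 - cx), 2)
  expect_lt(abs(regs$y + c0 - cy), 2)
  expect_true(regs$hollow)
})

test_that("the extract-and-reconstruct chain is linear without noise", {
  n <- 96
  img1 <- draw_disk(n, 40, 40, 12)
  img2 <- draw_disk(n, 60, 62, 9)
  ang <- seq(0, 175, by = 5)
  rec <- function(img) {
    fbp_reconstruct(forward_project(img, ang, pixel_size = 1),
                    clip_negative = FALSE)$data
  }
  expect_equal(rec(img1 + 2 * img2), rec(img1) + 2 * rec(img2),
               tolerance = 1e-8)
})

test_that("reconstruct_heights assigns physical heights from rows", {
  geom <- scanner_geometry() # 0.097 mm rows
  ang <- seq(0, 170, by = 10)
  base <- forward_project(draw_disk(64, 32, 32, 10), ang, pixel_size = 1)$data
  # stack with 700 detector rows, all equal to the disk sinogram rows
  stack <- lapply(seq_along(ang), function(i)
    matrix(rep(base[i, ], each = 700), nrow = 700))
  slices <- reconstruct_heights(stack, c(600, 650), geom, angles = ang)
  expect_length(slices, 2)
  expect_equal(slices[[2]]$height - slices[[1]]$height, 4.85)
  expect_equal(reconstruct_heights(stack, integer(0), geom, angles = ang),
               list())
  dup <- reconstruct_heights(stack, c(600, 600), geom, angles = ang)
  expect_identical(dup[[1]]$data, dup[[2]]$data)
})
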