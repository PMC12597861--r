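test_that("aspect ratio is 1 for discs, equals unweighted under uniform weights", {
  d <- disc_mask(64, 20)
  expect_lt(abs(aspect_ratio(d) - 1), 0.02)
  w <- matrix(3.7, 64, 64)
  expect_equal(aspect_ratio(d, w), aspect_ratio(d))
  expect_true(is.na(aspect_ratio(matrix(FALSE, 8, 8))))
})

test_that("aspect ratio collapses for two separated point masses", {
  m <- matrix(FALSE, 32, 32)
  m[16, 8] <- TRUE
  m[16, 24] <- TRUE
  expect_lt(aspect_ratio(m), 0.2)
})

test_that("gradient RMS is zero for flat images and drops under blurring", {
  n <- 48
  flat <- one_channel_event(matrix(7, n, n))
  mask <- disc_mask(n, 15)
  expect_equal(gradient_rms(flat, "CH", mask), 0)

  set.seed(5)
  x <- matrix(100, n, n)
  x[disc_mask(n, 15)] <- 60 + 10 * rnorm(sum(disc_mask(n, 15)))
  x <- abs(x)
  blurred <- erymorph:::gauss_blur(x, 2.5)
  sharp_score <- gradient_rms(one_channel_event(x), "CH", mask)
  blur_score <- gradient_rms(one_channel_event(blurred), "CH", mask)
  expect_lt(blur_score, sharp_score)
})

test_that("gradient RMS matches hand evaluation of the central-difference stencil", {
  n <- 12
  x <- matrix(0, n, n)
  x[, 7:n] <- 1      # vertical unit step between columns 6 and 7
  mask <- rect_mask(n, 4:9, 4:9)
  # central differences: gy = 0.5 at columns 6 and 7, 0 elsewhere; gx = 0
  g2 <- matrix(0, n, n)
  g2[, c(6, 7)] <- 0.25
  inner <- mask
  inner[c(1, n), ] <- FALSE; inner[, c(1, n)] <- FALSE
  expected <- sqrt(mean(g2[inner])) / mean(x[inner])
  expect_equal(gradient_rms(one_channel_event(x), "CH", mask), expected)
})

test_that("circularity ranks discs above rectangles and is translation invariant", {
  d <- disc_mask(64, 16)
  r <- rect_mask(64, 20:44, 25:40)   # comparable area, 25x16
  expect_gt(circularity(d), circularity(r))
  shifted <- rect_mask(64, 25:49, 30:45)
  expect_equal(circularity(r), circularity(shifted))
  expect_true(is.na(circularity(rect_mask(64, 30, 30))))
})

test_that("circularity of a rectangle matches brute-force boundary enumeration", {
  m <- rect_mask(64, 11:50, 21:30)   # 40 x 10 rectangle
  idx <- which(m, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  on_boundary <- function(i, j) {
    i == 11 || i == 50 || j == 21 || j == 30
  }
  d <- c()
  for (k in seq_len(nrow(idx))) {
    if (on_boundary(idx[k, 1], idx[k, 2])) {
      d <- c(d, sqrt((idx[k, 1] - cx)^2 + (idx[k, 2] - cy)^2))
    }
  }
  expect_equal(circularity(m), mean(d) / sd(d))
})

test_that("compactness anchors at 1 for a uniform disc and falls for split mass", {
  d <- disc_mask(64, 18)
  w <- matrix(1, 64, 64)
  expect_lt(abs(compactness(d, w) - 1), 0.05)
  # two distant blobs: closed-form two-point RMS radius is half the
  # separation, far above the equal-area disc RMS radius
  two <- disc_mask(64, 5, 16, 32) | disc_mask(64, 5, 48, 32)
  expect_lt(compactness(two, w), 0.7)
  expect_equal(compactness(d, w * 13), compactness(d, w))
  expect_true(is.na(compactness(d, w * 0)))
})

test_that("symmetry2 scores bilobed layouts high, blobs low, reflections equal", {
  n <- 64
  g <- grid_xy(n)
  blob <- exp(-((g$X - 32)^2 + (g$Y - 32)^2) / 50)
  d <- disc_mask(n, 20)
  single <- symmetry2(d, blob)
  two <- exp(-((g$X - 22)^2 + (g$Y - 32)^2) / 18) +
    exp(-((g$X - 42)^2 + (g$Y - 32)^2) / 18)
  double <- symmetry2(d, two)
  expect_gt(double, single)
  expect_equal(symmetry2(d[n:1, ], two[n:1, ]), double, tolerance = 1e-8)
})

test_that("symmetry2 reaches 1 in the two-point-mass limit", {
  m <- matrix(FALSE, 32, 32)
  m[16, 10] <- TRUE
  m[16, 22] <- TRUE
  w <- matrix(1, 32, 32)
  # half-centroids at the two points: distance 2d over extent 2d
  expect_equal(symmetry2(m, w), 1)
})

test_that("lobe count distinguishes one nucleus, two nuclei and a pinched dumbbell", {
  n <- 64
  g <- grid_xy(n)
  d <- disc_mask(n, 20)
  one <- exp(-((g$X - 32)^2 + (g$Y - 32)^2) / 60)
  expect_equal(lobe_count(d, one, 0.2), 1L)

  two_mask <- disc_mask(n, 7, 22, 32) | disc_mask(n, 7, 44, 32)
  two_w <- matrix(0, n, n); two_w[two_mask] <- 1
  expect_equal(lobe_count(two_mask | d, two_w, 0.2), 2L)

  # dumbbell with a 30% central pinch: two gaussian lobes whose midpoint
  # sits at 70% of the peak height
  lobes <- exp(-((g$X - 23)^2 + (g$Y - 32)^2) / 30) +
    exp(-((g$X - 41)^2 + (g$Y - 32)^2) / 30)
  lobes <- lobes / max(lobes)
  expect_equal(lobe_count(d, lobes, 0.2, smooth_sigma = 1), 2L)
  expect_true(is.na(lobe_count(matrix(FALSE, 8, 8), matrix(1, 8, 8), 0.2)))
})

test_that("bright detail intensity isolates sub-disc structure", {
  n <- 48
  mask <- disc_mask(n, 15)
  expect_equal(bright_detail_intensity(one_channel_event(matrix(5, n, n)),
                                       "CH", mask), 0)
  spike <- matrix(0, n, n)
  spike[24, 24] <- 17.5
  expect_equal(bright_detail_intensity(one_channel_event(spike), "CH", mask, 3),
               17.5)
})

test_that("clumping the same total intensity raises bright detail intensity", {
  n <- 48
  mask <- disc_mask(n, 12)
  total <- 1000
  smooth <- matrix(0, n, n)
  smooth[mask] <- total / sum(mask)
  clumped <- matrix(0, n, n)
  set.seed(8)
  pos <- sample(which(mask), 12)
  clumped[pos] <- total / 12
  v_smooth <- bright_detail_intensity(one_channel_event(smooth), "CH", mask)
  v_clumped <- bright_detail_intensity(one_channel_event(clumped), "CH", mask)
  expect_gt(v_clumped, v_smooth)
})

test_that("intensity stats: totals, linearity, and hand-computed centroids", {
  n <- 32
  sq <- matrix(0, n, n)
  sq[13:20, 13:20] <- 2
  ev <- one_channel_event(sq)
  st <- intensity_stats(ev, "CH", sq > 0)
  expect_equal(st$centroid_x, 16.5)
  expect_equal(st$centroid_y, 16.5)
  st2 <- intensity_stats(one_channel_event(sq * 2), "CH", sq > 0)
  expect_equal(st2$total, 2 * st$total)
  expect_equal(st2$centroid_x, st$centroid_x)

  blob <- matrix(0, n, n)
  blob[5, 7] <- 1; blob[6, 7] <- 3
  st3 <- intensity_stats(one_channel_event(blob), "CH", blob > 0)
  expect_equal(st3$total, 4)
  expect_equal(st3$centroid_x, (5 * 1 + 6 * 3) / 4)
  expect_equal(st3$centroid_y, 7)
  st4 <- intensity_stats(ev, "CH", matrix(FALSE, n, n))
  expect_true(is.na(st4$total))
})

test_that("shape features are invariant to whole-event translation", {
  n <- 64
  g <- grid_xy(n)
  base <- exp(-((g$X - 28)^2 + (g$Y - 28)^2) / 40)
  mask <- disc_mask(n, 12, 28, 28)
  shift <- function(m, dx, dy) {
    out <- matrix(0, n, n)
    out[(1 + dx):n, (1 + dy):n] <- m[1:(n - dx), 1:(n - dy)]
    out
  }
  mask2 <- shift(mask, 6, 4) > 0
  w2 <- shift(base, 6, 4)
  expect_equal(aspect_ratio(mask2, w2), aspect_ratio(mask, base), tolerance = 1e-10)
  expect_equal(circularity(mask2), circularity(mask), tolerance = 1e-10)
  expect_equal(compactness(mask2, w2), compactness(mask, base), tolerance = 1e-10)
  expect_equal(symmetry2(mask2, w2), symmetry2(mask, base), tolerance = 1e-10)
  expect_equal(lobe_count(mask2, w2, 0.2), lobe_count(mask, base, 0.2))
})
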