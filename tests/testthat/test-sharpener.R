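test_that("local mean uses only existing neighbours, from the original image", {
  expect_equal(local_mean(matrix(80, 5, 5), 3, 3), 80)
  patch <- matrix(10, 3, 3); patch[2, 2] <- 100
  expect_equal(local_mean(patch, 2, 2), 20)        # (8*10 + 100)/9
  corner <- matrix(c(0, 0, 0, 90), 2, 2)
  expect_equal(local_mean(corner, 1, 1), 22.5)     # mean of 4 existing pixels
  expect_error(local_mean(patch, 0, 1), class = "greysharp_invalid_input")
  expect_error(local_mean(patch, 2, 4), class = "greysharp_invalid_input")

  set.seed(31)
  img <- random_image(6, 7)
  for (i in 1:10) {
    r <- sample(6, 1); c <- sample(7, 1)
    expect_equal(local_mean(img, r, c), naive_local_mean(img, r, c))
  }
})

test_that("adaptive magnitude follows the two-branch rule and its bounds", {
  expect_equal(additive_magnitude(120, 100, 1, 40), 40 * 100 / 120)
  expect_equal(additive_magnitude(50, 100, 0.5, 40), 10)
  expect_equal(additive_magnitude(0, 0, 1, 40), 0)   # defined degenerate case
  expect_equal(additive_magnitude(100, 100, 1, 40), 40)  # x == LocalMean

  # always within [0, s*Delta]; larger near the local mean (adaptivity)
  set.seed(13)
  for (i in 1:20) {
    x <- runif(1, 0, 255); lm_ <- runif(1, 1, 255)
    s <- runif(1); d <- runif(1, 0, 60)
    dx <- additive_magnitude(x, lm_, s, d)
    expect_gte(dx, 0); expect_lte(dx, s * d + 1e-12)
  }
  xs <- seq(10, 90, by = 10)                 # approaching LocalMean = 100
  expect_true(all(diff(additive_magnitude(xs, 100, 1, 40)) > 0))
  xs <- seq(250, 110, by = -20)              # approaching from above
  expect_true(all(diff(additive_magnitude(xs, 100, 1, 40)) > 0))
})

test_that("pixel sharpening rounds half away from zero then clamps", {
  expect_identical(sharpen_pixel(120, 100, 40 * 100 / 120), 153L)
  expect_identical(sharpen_pixel(50, 100, 10), 40L)
  expect_identical(sharpen_pixel(250, 100, 40), 255L)   # clamped high
  expect_identical(sharpen_pixel(3, 100, 10), 0L)       # clamped low (-7)
  expect_identical(sharpen_pixel(100, 99, 0.5), 101L)   # .5 rounds away
})

test_that("full pipeline: identity cases, exact hand-evaluation, invariants", {
  step <- make_fixture("vstep", c(8, 8), c(50, 150), split = 4)

  # s = 0 is the identity on any fixture
  for (kind in c("vstep", "ramp", "checkerboard", "smooth-field")) {
    img <- make_fixture(kind, c(12, 12), seed = 2)
    expect_identical(sharpen_image(img, sharpen_params(s = 0))$image, img)
  }
  # constant image: Delta = 0, no edges, bit-exact output
  res <- suppressWarnings(sharpen_image(matrix(100L, 10, 10)))
  expect_identical(res$image, matrix(100L, 10, 10))
  expect_identical(res$delta, 0)
  expect_equal(sum(res$edge_map), 0)

  # ideal step at theta_lpf = 3: the one-pixel-wide HVD line is removed,
  # so the sharpened image is untouched
  res3 <- sharpen_image(step, sharpen_params(theta_eth = 18, s = 1,
                                             delta_override = 40))
  expect_equal(res3$edge_pixel_count, 0)
  expect_identical(res3$image, step)

  # with the filter off, flagged step pixels move away from their local
  # mean by exactly round(40 * min(x, LM)/max(x, LM))
  p <- sharpen_params(theta_eth = 18, s = 1, delta_override = 40,
                      lpf_enabled = FALSE)
  res <- sharpen_image(step, p)
  idx <- which(res$edge_map == 1L, arr.ind = TRUE)
  expect_equal(nrow(idx), 8)                 # first high-side column
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    x <- step[r, c]; lm_ <- naive_local_mean(step, r, c)
    dx <- 40 * (if (x < lm_) x / lm_ else lm_ / x)
    want <- if (x < lm_) x - dx else x + dx
    want <- as.integer(min(255, max(0, floor(abs(want) + 0.5) * sign(want))))
    expect_identical(res$image[r, c], want)
    # contrast expansion: moved further from the local mean
    expect_gte(abs(res$image[r, c] - lm_), abs(x - lm_))
  }
  # non-edge pixels bit-exact
  expect_identical(res$image[res$edge_map == 0L], step[res$edge_map == 0L])
  # bounded change
  expect_true(all(abs(res$image - step) <= ceiling(1 * 40)))
  # determinism
  expect_identical(sharpen_image(step, p)$image, res$image)
})

test_that("pipeline matches the straight-line naive oracle on small images", {
  set.seed(101)
  for (i in 1:12) {
    img <- random_image(sample(3:8, 1), sample(3:8, 1))
    th <- sample(8:18, 1); s <- sample(c(0.5, 0.8, 1), 1)
    for (lpf in c(TRUE, FALSE)) {
      # delta fixed: isolates the edge-detection + sharpening passes
      p <- sharpen_params(theta_eth = th, s = s, delta_override = 37.25,
                          lpf_enabled = lpf)
      expect_identical(sharpen_image(img, p)$image,
                       naive_sharpen(img, th, 3, s, 37.25, lpf))
    }
    # full pipeline including the Grey-model Delta (independent lm route)
    p <- sharpen_params(theta_eth = th, s = s)
    expect_identical(sharpen_image(img, p)$image,
                     naive_sharpen(img, th, 3, s, naive_delta(img)))
  }
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sharpen_params(s = 1.5), class = "greysharp_invalid_parameter")
  expect_error(sharpen_params(s = -0.1), class = "greysharp_invalid_parameter")
  expect_error(sharpen_params(theta_eth = 0),
               class = "greysharp_invalid_parameter")
  expect_error(sharpen_params(theta_lpf = 9),
               class = "greysharp_invalid_parameter")
  expect_error(sharpen_params(delta_override = -1),
               class = "greysharp_invalid_parameter")
  expect_error(sharpen_image(matrix(300, 2, 2)),
               class = "greysharp_invalid_input")
  expect_identical(sharpen_params()$theta_lpf, 3L)   # hvd default
})
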