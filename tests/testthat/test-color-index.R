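# Colour conversion and the dark green colour index.

test_that("rgb_to_hsb reproduces the closed-form corner cases", {
  expect_equal(rgb_to_hsb(1, 0, 0), data.frame(h = 0, s = 1, b = 1))
  expect_equal(rgb_to_hsb(0, 1, 0), data.frame(h = 120, s = 1, b = 1))
  expect_equal(rgb_to_hsb(0, 0, 1), data.frame(h = 240, s = 1, b = 1))
  grey <- rgb_to_hsb(0.5, 0.5, 0.5)
  expect_true(is.na(grey$h))
  expect_equal(grey$s, 0)
  expect_equal(grey$b, 0.5)
  # black: max = 0, saturation defined as 0
  black <- rgb_to_hsb(0, 0, 0)
  expect_equal(black$s, 0)
  expect_true(is.na(black$h))
  expect_equal(rgb_to_hsb(0.2, 0.8, 0.4),
               data.frame(h = 140, s = 0.75, b = 0.8))
})

test_that("rgb_to_hsb matches the standard colorimetric conversion on random pixels", {
  set.seed(42)
  n <- 2000
  r <- runif(n); g <- runif(n); b <- runif(n)
  ours <- rgb_to_hsb(r, g, b)
  oracle <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  expect_equal(ours$h, unname(oracle["h", ] * 360), tolerance = 1e-12)
  expect_equal(ours$s, unname(oracle["s", ]), tolerance = 1e-12)
  expect_equal(ours$b, unname(oracle["v", ]), tolerance = 1e-12)
})

test_that("hue wraps into [0, 360) when the branch formula goes negative", {
  # max = red, green slightly below blue -> negative branch value
  out <- rgb_to_hsb(0.9, 0.1, 0.2)
  expect_true(out$h >= 0 && out$h < 360)
  expect_gt(out$h, 300) # magenta-ish, not a small positive hue
})

test_that("channels outside [0, 1] are rejected by name", {
  expect_error(rgb_to_hsb(1.2, 0, 0), "`r`", class = "maizeNrec_domain_error")
  expect_error(rgb_to_hsb(0, -0.1, 0), "`g`", class = "maizeNrec_domain_error")
  expect_error(rgb_to_hsb(0, 0, 2), "`b`", class = "maizeNrec_domain_error")
})

test_that("hsb_to_rgb inverts rgb_to_hsb on chromatic pixels", {
  set.seed(7)
  n <- 500
  r <- runif(n); g <- runif(n); b <- runif(n)
  hsb <- rgb_to_hsb(r, g, b)
  ok <- !is.na(hsb$h)
  back <- hsb_to_rgb(hsb$h[ok], hsb$s[ok], hsb$b[ok])
  expect_equal(back$r, r[ok], tolerance = 1e-12)
  expect_equal(back$g, g[ok], tolerance = 1e-12)
  expect_equal(back$b, b[ok], tolerance = 1e-12)
})

test_that("pixel_dgci matches hand-computed values and is unclamped", {
  expect_identical(pixel_dgci(120, 1, 1), 1 / 3)
  expect_identical(pixel_dgci(60, 1, 1), 0)
  expect_equal(pixel_dgci(100, 0.8, 0.6), ((100 / 60 - 1) + 0.2 + 0.4) / 3)
  expect_equal(pixel_dgci(100, 0.8, 0.6), 0.422222, tolerance = 1e-6)
  # mathematical range for h in [0, 360): no clamping at either end
  expect_lt(pixel_dgci(0, 1, 1), 0)
  expect_gt(pixel_dgci(359, 0, 0), 1)
  expect_true(is.na(pixel_dgci(NA_real_, 0.5, 0.5)))
})

test_that("pixel_dgci is monotone in each HSB coordinate", {
  h <- seq(60, 180, by = 5)
  expect_true(all(diff(pixel_dgci(h, 0.7, 0.7)) > 0))
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pixel_dgci(120, s, 0.7)) < 0))
  expect_true(all(diff(pixel_dgci(120, 0.7, s)) < 0))
})

test_that("8-bit round trip loses less than one quantization step per channel", {
  set.seed(11)
  x <- runif(300)
  eight <- round(x * 255)
  expect_true(all(abs(eight / 255 - x) < 1 / 255))
})

test_that("segment_leaf finds a green disc and rejects non-green images", {
  img <- make_leaf_image(60, 60, target_mean_dgci = 1 / 3, noise_sd = 0)
  mask <- segment_leaf(img)
  expect_identical(mask, img$mask)
  white <- leaf_image(array(1, dim = c(8, 8, 3)))
  expect_error(segment_leaf(white), "no leaf pixels",
               class = "maizeNrec_domain_error")
})

test_that("segmentation is robust to 5% sensor noise", {
  img <- make_leaf_image(80, 80, target_mean_dgci = 1 / 3, noise_sd = 0)
  set.seed(99)
  noisy <- img$pixels + array(rnorm(length(img$pixels), 0, 0.05),
                              dim = dim(img$pixels))
  noisy[] <- pmin(1, pmax(0, noisy))
  mask <- segment_leaf(leaf_image(noisy))
  recovered <- sum(mask & img$mask) / sum(img$mask)
  expect_gte(recovered, 0.95)
})

test_that("image_dgci aggregates only usable pixels", {
  # uniform pure green, full mask
  px <- array(0, dim = c(4, 5, 3)); px[, , 2] <- 1
  s <- image_dgci(leaf_image(px))
  expect_equal(s$mean_dgci, 1 / 3)
  expect_equal(s$dgci_sd, 0)
  expect_equal(s$pixel_count, 20)
  expect_equal(s$excluded_count, 0)

  # half the pixels at DGCI 0.2, half at 0.6 -> mean 0.4
  hsb_lo <- c(60 * (3 * 0.2 + 1), 1, 1)  # s = b = 1
  hsb_hi <- c(60 * (3 * 0.6 + 1), 1, 1)
  lo <- hsb_to_rgb(hsb_lo[1], 1, 1); hi <- hsb_to_rgb(hsb_hi[1], 1, 1)
  px <- array(0, dim = c(2, 2, 3))
  px[1, , 1] <- lo$r; px[1, , 2] <- lo$g; px[1, , 3] <- lo$b
  px[2, , 1] <- hi$r; px[2, , 2] <- hi$g; px[2, , 3] <- hi$b
  expect_equal(image_dgci(leaf_image(px))$mean_dgci, 0.4, tolerance = 1e-12)

  # achromatic pixels are excluded, never averaged in
  px[2, , ] <- 0.5
  s <- image_dgci(leaf_image(px))
  expect_equal(s$mean_dgci, 0.2, tolerance = 1e-12)
  expect_equal(s$pixel_count, 2)
  expect_equal(s$excluded_count, 2)

  # all achromatic -> error
  expect_error(image_dgci(leaf_image(array(0.5, dim = c(2, 2, 3)))),
               class = "maizeNrec_domain_error")
})

test_that("image-level DGCI is invariant to pixel order and 90-degree rotation", {
  img <- make_leaf_image(40, 60, target_mean_dgci = 0.5, noise_sd = 0.05,
                         seed = 3)
  base <- image_dgci(img)
  rot <- leaf_image(
    aperm(img$pixels[dim(img$pixels)[1]:1, , , drop = FALSE], c(2, 1, 3)),
    mask = t(img$mask[dim(img$mask)[1]:1, ])
  )
  expect_equal(image_dgci(rot)$mean_dgci, base$mean_dgci, tolerance = 1e-12)
  # shuffle mask-selected pixels via a permuted single-row image
  idx <- which(img$mask)
  set.seed(5)
  perm <- sample(idx)
  one_row <- array(0, dim = c(1, length(idx), 3))
  for (k in 1:3) one_row[1, , k] <- img$pixels[, , k][perm]
  expect_equal(image_dgci(leaf_image(one_row))$mean_dgci, base$mean_dgci,
               tolerance = 1e-12)
})

test_that("hue-band restriction drops out-of-band pixels from the mean", {
  px <- array(0, dim = c(2, 1, 3))
  green <- hsb_to_rgb(120, 1, 1); blue <- hsb_to_rgb(240, 1, 1)
  px[1, 1, ] <- unlist(green); px[2, 1, ] <- unlist(blue)
  all_px <- image_dgci(leaf_image(px))
  banded <- image_dgci(leaf_image(px), hue_band = c(60, 180))
  expect_equal(banded$mean_dgci, 1 / 3)
  expect_equal(banded$pixel_count, 1)
  expect_gt(all_px$mean_dgci, banded$mean_dgci)
})

test_that("PNG round trip preserves the image to 8-bit precision", {
  img <- make_leaf_image(30, 30, target_mean_dgci = 0.5, noise_sd = 0.03,
                         seed = 8)
  path <- withr::local_tempfile(fileext = ".png")
  write_leaf_png(img, path)
  back <- read_leaf_image(path)
  expect_true(max(abs(back$pixels - img$pixels)) <= 1 / 255)
  expect_equal(image_dgci(back, img$mask)$mean_dgci,
               image_dgci(img)$mean_dgci, tolerance = 0.01)
})
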