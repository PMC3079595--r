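test_that("intensity channel is the per-pixel RGB mean", {
  img <- array(1, c(16, 16, 3))
  expect_equal(intensity_channel(img), matrix(1, 16, 16))
  img2 <- array(rep(c(0.3, 0.6, 0.9), each = 256), c(16, 16, 3))
  expect_equal(intensity_channel(img2), matrix(0.6, 16, 16))
  fx <- generate_fixture(fixture_spec(seed = 4))
  I <- intensity_channel(fx$image)
  expect_true(all(I >= 0 & I <= 1))
})

test_that("center-surround maps vanish on constant input and localize a point", {
  cfg <- pyramid_config(4, 1, c(1, 2))
  maps <- center_surround_maps(matrix(0.4, 32, 32), cfg)
  expect_equal(length(maps), 2)
  for (m in maps) expect_equal(max(abs(m)), 0)

  x <- matrix(0, 32, 32); x[16, 16] <- 1
  m <- center_surround_maps(x, cfg)[[1]] # at level 1 (16x16)
  peak <- which(m == max(m), arr.ind = TRUE)
  expect_true(all(abs(peak[1, ] - 8) <= 1))
})

test_that("pyramid reduce and bilinear resampling match naive loop references", {
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(historoi:::pyr_reduce(x), naive_reduce(x), tolerance = 1e-12)
  expect_equal(historoi:::resample_bilinear(x[1:16, 1:16], 32, 32),
               naive_resample(x[1:16, 1:16], 32, 32), tolerance = 1e-12)
  # full single-scale center-surround against the composed naive pipeline
  cfg <- pyramid_config(4, 1, 2)
  m <- center_surround_maps(x, cfg)[["c1_s3"]]
  l1 <- naive_reduce(x); l2 <- naive_reduce(l1); l3 <- naive_reduce(l2)
  expect_equal(m, abs(l1 - naive_resample(l3, nrow(l1), ncol(l1))),
               tolerance = 1e-9)
})

test_that("map normalization preserves single peaks and cancels twin peaks", {
  z <- matrix(0, 16, 16)
  expect_equal(normalize_map(z), z)

  single <- z; single[8, 8] <- 1
  expect_equal(normalize_map(single), single)

  twin <- z; twin[4, 4] <- 1; twin[12, 12] <- 1
  expect_equal(max(abs(normalize_map(twin))), 0)
})

test_that("map normalization factor agrees with brute-force maxima enumeration", {
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(runif(16 * 16), 16, 16)
    m <- matrix(as.numeric(EBImage::gblur(m, 1)), 16, 16)
    m <- m - min(m) # non-negative feature map
    peaks <- naive_peak_values(m)
    mbar <- if (length(peaks) > 1) mean(peaks[-which.max(peaks)]) else 0
    expect_equal(normalize_map(m), m / max(m) * (1 - mbar)^2,
                 tolerance = 1e-12)
  }
})

test_that("constant images give identically zero conspicuity in all channels", {
  img <- array(0.37, c(32, 32, 3))
  for (ch in c("intensity", "color", "orientation"))
    expect_equal(max(abs(conspicuity(img, ch))), 0, info = ch)
  expect_equal(max(abs(entropy_conspicuity(img))), 0)
})

test_that("an isoluminant hue disc excites colour but not intensity", {
  img <- array(0.5, c(64, 64, 3))
  disc <- (row(matrix(0, 64, 64)) - 32)^2 + (col(matrix(0, 64, 64)) - 32)^2 <= 12^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- c(0.7, 0.4, 0.4)[ch] # same channel sum as background
    img[, , ch] <- plane
  }
  expect_equal(max(abs(conspicuity(img, "intensity"))), 0)
  cmap <- conspicuity(img, "color")
  expect_gt(mean(cmap[disc]), mean(cmap[!disc]))
  expect_gt(max(cmap), 0)
})

test_that("Gabor responses match direct convolution and prefer the bar orientation", {
  set.seed(11)
  x <- matrix(runif(32 * 32), 32, 32)
  for (th in c(0, 45, 90)) {
    kern <- gabor_kernel(th)
    expect_equal(gabor_response(x, th), abs(naive_conv_replicate(x, kern)),
                 tolerance = 1e-6, info = paste("theta", th))
  }
  bar <- matrix(0, 32, 32); bar[, 15:17] <- 1 # vertical bar
  r90 <- gabor_response(bar, 90); r0 <- gabor_response(bar, 0)
  expect_gt(max(r90), max(r0))
  expect_gt(mean(r90[, 13:19]), mean(r0[, 13:19]))
  # vertical bar image: the 90-degree channel dominates the orientation map
  img <- array(rep(bar, 3), c(32, 32, 3))
  omap <- conspicuity(img, "orientation")
  expect_gt(max(omap), 0)
})

test_that("entropy map matches the analytic and naive references", {
  expect_equal(max(abs(entropy_conspicuity(matrix(0.2, 16, 16)))), 0)
  stripes <- matrix(rep(c(0, 0.999), each = 16, times = 8), 16, 16)
  e <- entropy_conspicuity(stripes, window = 2, n_bins = 2)
  expect_equal(as.vector(e), rep(1, 256))
  set.seed(21)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_equal(unclass(entropy_conspicuity(x, window = 5, n_bins = 8)),
               naive_entropy(x, 5, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(entropy_conspicuity(x, window = 1), "window")
  expect_error(entropy_conspicuity(x, n_bins = 1), "n_bins")
})

test_that("entropy and Gabor maps are shift-equivariant away from borders", {
  set.seed(31)
  big <- matrix(runif(64 * 64), 64, 64)
  a <- big[9:40, 9:40]
  b <- big[12:43, 14:45] # shifted crop by (3, 5)
  ea <- entropy_conspicuity(a, window = 5, n_bins = 8)
  eb <- entropy_conspicuity(b, window = 5, n_bins = 8)
  expect_equal(ea[9:24, 11:24], eb[6:21, 6:19], tolerance = 1e-12,
               ignore_attr = TRUE)
  ga <- gabor_response(a, 45); gb <- gabor_response(b, 45)
  expect_equal(ga[9:24, 11:24], gb[6:21, 6:19], tolerance = 1e-9)
})

test_that("conspicuity maps stay within [0, 1] and image shape", {
  fx <- generate_fixture(fixture_spec(seed = 17))
  for (ch in c("intensity", "color", "orientation")) {
    m <- conspicuity(fx$image, ch)
    expect_equal(dim(m), dim(fx$mask))
    expect_true(all(m >= 0 & m <= 1))
  }
  e <- entropy_conspicuity(fx$image)
  expect_true(all(e >= 0 & e <= 1))
})

test_that("undersized images are rejected by the pyramid configuration", {
  expect_error(center_surround_maps(matrix(0, 8, 8), pyramid_config(5, 1, 1)),
               "too small")
  expect_error(pyramid_config(5, c(1, 2), c(2, 3)), "n_levels")
})
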