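test_that("pattern search minimizes quadratics to within the final mesh", {
  r1 <- pattern_search(function(x) (x[["a"]] - 2)^2, c(a = 0),
                       lower = -10, upper = 10, scales = 1, delta0 = 1,
                       max_refinements = 20)
  expect_lt(abs(r1$par[["a"]] - 2), 1 / 2^20 + 1e-12)
  expect_true(all(diff(r1$trace$best) <= 0))

  r2 <- pattern_search(function(x) x[["x"]]^2 + x[["y"]]^2, c(x = 3, y = -3),
                       lower = -10, upper = 10, scales = 1, delta0 = 1,
                       max_refinements = 20)
  expect_lt(sqrt(sum(r2$par^2)), 1 / 2^20 + 1e-12)

  # off-mesh minimum: still within the final mesh size
  r3 <- pattern_search(function(x) (x[["a"]] - 2.3)^2, c(a = 0),
                       lower = -10, upper = 10, scales = 1, delta0 = 1,
                       max_refinements = 15)
  expect_lt(abs(r3$par[["a"]] - 2.3), 1 / 2^15)
})

test_that("constant objectives exhaust exactly the refinement budget", {
  r <- pattern_search(function(x) 1, c(a = 0, b = 0), lower = -5, upper = 5,
                      scales = 1, delta0 = 1, max_refinements = 6)
  expect_equal(r$par, c(a = 0, b = 0))
  expect_equal(r$n_refinements, 6)
  # 1 initial evaluation + 2 * dim per failed poll round
  expect_equal(r$n_evaluations, 1 + 2 * 2 * 6)
})

test_that("non-finite objective values are rejected, not propagated", {
  f <- function(x) if (x[["a"]] > 1) NaN else (x[["a"]] + 2)^2
  r <- pattern_search(f, c(a = 0), lower = -5, upper = 5, scales = 1,
                      delta0 = 1, max_refinements = 10)
  expect_lt(abs(r$par[["a"]] + 2), 1e-2)
  expect_true(is.finite(r$value))
})

test_that("segmentation learning recovers the two-region micro-partition", {
  h <- micro_image("halves4")
  s <- list(list(image = h$image, partition = h$labels))
  learned <- learn_segmentation_params(
    s, x0 = c(k = 500, smooth_sigma = 0, min_size = 1),
    upper = c(k = 5000, smooth_sigma = 0, min_size = 1),
    lower = c(k = 10, smooth_sigma = 0, min_size = 1),
    gps = list(delta0 = 1, max_refinements = 6,
               scales = c(logk = 0.25, smooth_sigma = 0.25,
                          min_size = 25)))
  expect_equal(attr(learned, "objective"), 0)
  seg <- felzenszwalb_segment(h$image, learned)
  expect_equal(n_regions(seg), 2)
})

test_that("uniform images accept the starting parameters with zero energy", {
  s <- list(list(image = matrix(0.5, 16, 16), partition = matrix(1L, 16, 16)))
  learned <- learn_segmentation_params(s,
    gps = list(delta0 = 1, max_refinements = 2,
               scales = c(logk = 0.25, smooth_sigma = 0.25, min_size = 25)))
  expect_equal(attr(learned, "objective"), 0)
  expect_equal(learned$k, 500)
})

test_that("weight learning follows the discriminative channel", {
  gps <- list(delta0 = 1, max_refinements = 4, scales = 0.25)
  # fixed still-segmentations that isolate both the true and the distractor
  # structures -- the premise of the weight-learning stage: textured islets
  # need a larger k to stay whole, the weak-contrast hue islets a smaller one
  ent <- make_training_suite(4, seed = 61, size = 96,
                             variant = "entropy_only", n_islets = 1,
                             radius = c(12, 16))
  w_ent <- learn_feature_weights(ent,
    segmentation_params(k = 800, smooth_sigma = 0.8, min_size = 30),
    gps = gps)
  expect_equal(names(which.max(w_ent)), "entropy")

  col <- make_training_suite(4, seed = 61, size = 96,
                             variant = "color_only", n_islets = 2,
                             radius = c(10, 13))
  w_col <- learn_feature_weights(col,
    segmentation_params(k = 400, smooth_sigma = 0.8, min_size = 30),
    gps = gps)
  expect_equal(names(which.max(w_col)), "color")

  expect_equal(sum(w_ent), 1)
  expect_equal(sum(w_col), 1)
})

test_that("degenerate weight learning returns the uniform start", {
  s <- list(list(image = array(0.5, c(32, 32, 3)),
                 mask = matrix(1, 32, 32)))
  w <- learn_feature_weights(s, segmentation_params(),
                             gps = list(delta0 = 1, max_refinements = 2,
                                        scales = 0.25))
  expect_equal(unname(as.numeric(w)), rep(0.25, 4))
})

test_that("cross-validation folds partition the data deterministically", {
  smp <- make_training_suite(22, seed = 3, size = 48)
  n <- length(smp)
  folds1 <- historoi:::with_local_seed(3, sample(rep_len(1:11, n)))
  folds2 <- historoi:::with_local_seed(3, sample(rep_len(1:11, n)))
  expect_identical(folds1, folds2)
  expect_equal(sort(unique(folds1)), 1:11)
  expect_true(all(table(folds1) == 2)) # every sample in exactly one test fold
})

test_that("cross-validation of identical samples yields identical fold rows", {
  one <- generate_fixture(fixture_spec(width = 48, height = 48, n_islets = 1,
                                       islet_radius_range = c(8, 12),
                                       seed = 4))
  smp <- rep(list(list(image = one$image, mask = one$mask)), 11)
  tab <- crossvalidate(smp, n_folds = 11, seed = 1,
                       gps_seg = list(delta0 = 1, max_refinements = 1,
                                      scales = c(logk = 0.25,
                                                 smooth_sigma = 0.25,
                                                 min_size = 25)),
                       gps_weights = list(delta0 = 1, max_refinements = 1,
                                          scales = 0.25))
  expect_equal(nrow(tab), 11)
  expect_equal(length(unique(tab$mean_energy)), 1)
  expect_equal(length(unique(tab$sensitivity)), 1)
  expect_error(crossvalidate(smp[1:5], n_folds = 11), "fewer")
})
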