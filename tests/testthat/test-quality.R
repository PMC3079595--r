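w_id <- distance_weighting(slope = 1, offset = 0, d_max = 20) # w(i) = i
w_def <- distance_weighting()

test_that("missing foreground reproduces trivial and closed-form cases", {
  g <- micro_image("square3in8")$mask
  expect_equal(missing_foreground(g, g, w_id), 0)

  c1 <- g; c1[3, 3] <- 0 # corner pixel removed, at distance 1 from c
  expect_equal(missing_foreground(g, c1, w_id), 1)

  big <- g; big[2:6, 2:6] <- 1 # strict superset
  expect_equal(missing_foreground(g, big, w_id), 0)

  # empty prediction: every missing pixel at the capped distance
  empty <- g * 0
  expect_equal(missing_foreground(g, empty, w_id), 9 * 20)
})

test_that("added background mirrors missing foreground with roles swapped", {
  g <- micro_image("square3in8")$mask
  expect_equal(added_background(g, g, w_id), 0)

  c1 <- g; c1[2, 3] <- 1 # one pixel adjacent to g's border
  expect_equal(added_background(g, c1, w_id), 1)

  sub <- g; sub[3, 3] <- 0 # subset of g adds nothing
  expect_equal(added_background(g, sub, w_id), 0)

  set.seed(14)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_equal(missing_foreground(a, b, w_def), naive_mf(a, b, w_def),
                 tolerance = 1e-9)
    expect_equal(added_background(a, b, w_def), naive_mf(b, a, w_def),
                 tolerance = 1e-9)
  }
})

test_that("foreground-background quality normalizes and floors as documented", {
  g <- micro_image("square3in8")$mask
  q <- fg_quality(g, g, w_id)
  expect_equal(q$normalized, 0)
  expect_equal(q$db, 10 * log10(1e-7))

  qe <- fg_quality(g, g * 0, w_id)
  expect_equal(qe$normalized, 9 / 64) # 9 * w(d_max) / (64 * w(d_max))

  # moving an added pixel farther from the border increases the error
  near <- g; near[2, 3] <- 1
  far <- g; far[1, 1] <- 1
  expect_gt(fg_quality(g, far, w_id)$raw, fg_quality(g, near, w_id)$raw)
})

test_that("region matching is maximal-overlap with greedy uniqueness", {
  h <- micro_image("halves4")
  m <- match_regions(h$labels, h$labels)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$g, m$pairs$c)
  expect_equal(length(m$uncoupled_g), 0)
  expect_equal(length(m$uncoupled_c), 0)

  # one ground-truth region split 60/40 across two predicted regions
  g <- matrix(1L, 6, 6); g[, 6] <- 2L
  c <- matrix(1L, 6, 6); c[, 4:6] <- 2L # overlaps g1 18/12 out of 30
  mm <- match_regions(g == 1, c) # single-mask ground truth
  expect_equal(mm$pairs$c, 1)
  expect_true(2 %in% mm$uncoupled_c)

  # two ground-truth regions best-overlapping the same prediction
  g2 <- matrix(0L, 6, 6); g2[1:4, ] <- 1L; g2[5:6, ] <- 2L
  c2 <- matrix(1L, 6, 6)
  m2 <- match_regions(g2, c2)
  expect_equal(m2$pairs$g, 1) # larger overlap wins
  expect_equal(m2$uncoupled_g, 2)
})

test_that("over/under-segmentation errors follow the empty-reference convention", {
  c <- matrix(0L, 8, 8); c[1:2, 1:2] <- 1L; c[7:8, 7:8] <- 2L
  expect_equal(oversegmentation_error(c, integer(0), w_id), 0)
  expect_equal(oversegmentation_error(c, 1L, w_id), 4 * 20)
  expect_equal(oversegmentation_error(c, c(1L, 2L), w_id), 8 * 20) # additive
  expect_equal(undersegmentation_error(c, c(1L, 2L), w_id), 8 * 20) # symmetric
})

test_that("total energy is zero exactly at the ground truth and positive off it", {
  for (nm in c("uniform4", "halves4", "checker4")) {
    lab <- micro_image(nm)$labels
    expect_equal(total_energy(lab, lab, w_def)$energy, 0, info = nm)
  }
  for (s in c(2, 9)) {
    part <- partition_from_mask(generate_fixture(fixture_spec(seed = s))$mask)
    r <- total_energy(part, part, w_def)
    expect_equal(r$energy, 0)
    expect_equal(r$db_total, 10 * log10(1e-7))
  }
  h <- micro_image("halves4")
  other <- matrix(1L, 4, 4); other[3:4, ] <- 2L
  expect_gt(total_energy(h$labels, other, w_def)$energy, 0)
})

test_that("degrading a perfect segmentation never decreases the energy", {
  g <- matrix(1L, 6, 6); g[3:5, 3:5] <- 2L
  base <- total_energy(g, g, w_def)$energy
  # grow the misclassified set by inclusion: energy is nondecreasing
  bad_pixels <- list(c(4, 4), c(4, 5), c(5, 5), c(1, 1))
  prev <- base
  c <- g
  for (p in bad_pixels) {
    c[p[1], p[2]] <- ifelse(g[p[1], p[2]] == 1L, 2L, 1L)
    e <- total_energy(g, c, w_def)$energy
    expect_gte(e, prev)
    prev <- e
  }
})

test_that("over- and under-segmentation conventions are mutually symmetric", {
  p <- matrix(1L, 8, 8); p[2:4, 2:4] <- 2L; p[6:8, 6:8] <- 3L
  q <- matrix(1L, 8, 8)
  a <- total_energy(q, p, w_def) # p's extra regions are over-segmentation
  b <- total_energy(p, q, w_def) # same regions now under-segmented
  expect_equal(a$e_ov, b$e_un)
  expect_equal(a$e_un, b$e_ov)
})

test_that("dB scores are finite and non-positive", {
  set.seed(77)
  for (i in 1:5) {
    g <- partition_from_mask(matrix(rbinom(64, 1, 0.4), 8, 8))
    c <- partition_from_mask(matrix(rbinom(64, 1, 0.4), 8, 8))
    r <- total_energy(g, c, w_def)
    for (v in c(r$db_mf, r$db_ab, r$db_total)) {
      expect_true(is.finite(v))
      expect_lte(v, 0)
    }
  }
})
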