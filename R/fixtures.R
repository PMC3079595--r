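#' Specification for a synthetic histology-like fixture
#'
#' Describes a synthetic haematoxylin-eosin-like field: a near-uniform pale
#' eosin stroma background carrying darker, heavily speckled carcinoma-like
#' "islets" with smooth closed contours. The speckle inside islets drives
#' high local intensity entropy, emulating the cluttered texture of tumour
#' tissue against quiet stroma.
#'
#' @param width,height image size in pixels (>= 16).
#' @param n_islets number of islets (>= 0).
#' @param islet_radius_range numeric length-2, min/max islet radius in
#'   pixels; must be below \code{min(width, height)/2}.
#' @param background_color,islet_color RGB triples in [0, 1]. Defaults
#'   emulate eosin-pale stroma (230,200,210)/255 and dark haematoxylin
#'   (120,90,160)/255.
#' @param islet_texture_noise_sd,background_noise_sd speckle standard
#'   deviations in 8-bit intensity units (0-255). High islet speckle is
#'   what makes islets high-entropy.
#' @param blur_sigma Gaussian blur (pixels) applied to the colour layout
#'   before speckle, softening islet contours.
#' @param seed integer; the same (spec, seed) pair yields a bit-identical
#'   fixture.
#' @param variant one of \code{"default"}, \code{"entropy_only"} (the true
#'   islets have the background colour and only their speckle texture
#'   discriminates them; an equal number of dark, texture-quiet distractor
#'   islets outside the ground truth makes intensity misleading) or
#'   \code{"color_only"} (the true islets are an isoluminant hue shift with
#'   background-level speckle; dark hue-neutral distractors make intensity
#'   misleading, so only colour finds the truth).
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(width = 128, height = 128, n_islets = 3,
                         islet_radius_range = c(12, 24),
                         background_color = c(230, 200, 210) / 255,
                         islet_color = c(120, 90, 160) / 255,
                         islet_texture_noise_sd = 40,
                         background_noise_sd = 4,
                         blur_sigma = 1, seed = 1,
                         variant = c("default", "entropy_only", "color_only")) {
  variant <- match.arg(variant)
  n_distractors <- 0L
  distractor_color <- islet_color
  if (variant == "entropy_only") {
    islet_color <- background_color
    islet_texture_noise_sd <- max(islet_texture_noise_sd, 40)
    n_distractors <- as.integer(n_islets)
    distractor_color <- c(120, 90, 160) / 255 # dark but texture-quiet
  } else if (variant == "color_only") {
    # strong hue shift with only a mild darkening: just enough intensity
    # contrast for the still-segmentation to isolate the islet, while the
    # distractors carry a four-fold stronger intensity step
    islet_color <- c(160, 230, 180) / 255
    islet_texture_noise_sd <- background_noise_sd
    n_distractors <- as.integer(n_islets)
    distractor_color <- background_color * 0.55 # dark, hue kept
  }
  spec <- structure(list(
    width = as.integer(width), height = as.integer(height),
    n_islets = as.integer(n_islets),
    islet_radius_range = as.numeric(islet_radius_range),
    background_color = background_color, islet_color = islet_color,
    islet_texture_noise_sd = islet_texture_noise_sd,
    background_noise_sd = background_noise_sd,
    blur_sigma = blur_sigma, seed = as.integer(seed), variant = variant,
    n_distractors = n_distractors, distractor_color = distractor_color
  ), class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  with(spec, {
    if (width < 16 || height < 16) stop("width and height must be >= 16")
    if (n_islets < 0) stop("n_islets must be >= 0")
    if (length(islet_radius_range) != 2 ||
        islet_radius_range[1] > islet_radius_range[2] ||
        islet_radius_range[1] <= 0)
      stop("islet_radius_range must be (min, max) with 0 < min <= max")
    if (islet_radius_range[2] >= min(width, height) / 2)
      stop("islet radii must be below min(width, height)/2")
    if (islet_texture_noise_sd < 0 || background_noise_sd < 0)
      stop("noise standard deviations must be >= 0")
    if (any(background_color < 0) || any(background_color > 1) ||
        any(islet_color < 0) || any(islet_color > 1))
      stop("colors must be RGB triples in [0, 1]")
  })
  invisible(spec)
}

#' Generate a synthetic histology-like image with ground truth
#'
#' Places \code{n_islets} non-overlapping islets (discs deformed by a
#' low-frequency radial perturbation of amplitude at most a quarter radius,
#' so contours stay smooth and closed), blurs the colour layout, then adds
#' intensity speckle: strong inside islets, weak outside. The returned mask
#' is exactly the union of the islet supports before blurring.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{image} (height x width x 3 array in [0, 1]) and
#'   \code{mask} (height x width matrix in {0, 1}).
#' @export
generate_fixture <- function(spec) {
  validate_fixture_spec(spec)
  with_local_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    n_distr <- if (is.null(spec$n_distractors)) 0L else spec$n_distractors
    n_blobs <- spec$n_islets + n_distr
    mask <- matrix(0, H, W)
    distr <- matrix(0, H, W)
    centers <- matrix(numeric(0), 0, 3) # x, y, r
    for (i in seq_len(n_blobs)) {
      placed <- FALSE
      for (try in seq_len(1000)) {
        r <- runif(1, spec$islet_radius_range[1], spec$islet_radius_range[2])
        margin <- r * 1.25 + 1
        if (W - margin <= margin || H - margin <= margin) next
        cx <- runif(1, margin, W - margin)
        cy <- runif(1, margin, H - margin)
        ok <- TRUE
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          ok <- all(d > (centers[, 3] + r) * 1.25 + 2)
        }
        if (ok) {
          centers <- rbind(centers, c(cx, cy, r))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place islets without overlap after 1000 attempts")
    }
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1]; cy <- centers[i, 2]; r0 <- centers[i, 3]
      amp <- runif(3, -0.25 / 3, 0.25 / 3)   # harmonics 2..4, total <= 0.25 r
      phi <- runif(3, 0, 2 * pi)
      dx <- xs - cx; dy <- ys - cy
      theta <- atan2(dy, dx)
      redge <- r0 * (1 + amp[1] * cos(2 * theta + phi[1]) +
                         amp[2] * cos(3 * theta + phi[2]) +
                         amp[3] * cos(4 * theta + phi[3]))
      support <- sqrt(dx^2 + dy^2) <= redge
      if (i <= spec$n_islets) mask[support] <- 1 else distr[support] <- 1
    }
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_color[ch], H, W)
      plane[mask == 1] <- spec$islet_color[ch]
      plane[distr == 1] <- spec$distractor_color[ch]
      img[, , ch] <- plane
    }
    if (spec$blur_sigma > 0)
      for (ch in 1:3)
        img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch],
                                                sigma = spec$blur_sigma))
    # scalar (intensity) speckle shared by the three channels; distractor
    # islets stay as texture-quiet as the background
    speckle <- matrix(rnorm(H * W), H, W) *
      ifelse(mask == 1, spec$islet_texture_noise_sd / 255,
             spec$background_noise_sd / 255)
    for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] + speckle)
    list(image = img, mask = mask)
  })
}

#' Analytic micro-images for oracle tests
#'
#' A catalogue of hand-specified tiny images with analytically known
#' partitions or masks, used as exact oracle inputs.
#'
#' @param name one of \code{"uniform4"} (4x4 constant, one region),
#'   \code{"halves4"} (4x4, left half 0 / right half 1, two regions),
#'   \code{"checker4"} (4x4 checkerboard, sixteen 4-connected regions),
#'   \code{"square3in8"} (8x8 zeros with a 3x3 foreground square, mask of
#'   nine pixels).
#' @return list with \code{image} (matrix) and \code{labels} and/or
#'   \code{mask}.
#' @export
micro_image <- function(name) {
  switch(name,
    uniform4 = list(image = matrix(0.5, 4, 4),
                    labels = matrix(1L, 4, 4)),
    halves4 = {
      img <- matrix(0, 4, 4); img[, 3:4] <- 1
      lab <- matrix(1L, 4, 4); lab[, 3:4] <- 2L
      list(image = img, labels = lab)
    },
    checker4 = {
      img <- matrix(as.numeric((outer(1:4, 1:4, "+") %% 2) == 0), 4, 4)
      list(image = img, labels = matrix(seq_len(16L), 4, 4))
    },
    square3in8 = {
      img <- matrix(0, 8, 8); img[3:5, 3:5] <- 1
      list(image = img, mask = img)
    },
    stop(sprintf("unknown micro image '%s'", name))
  )
}

#' Names of the micro-image catalogue
#' @return character vector of valid \code{\link{micro_image}} names.
#' @export
micro_catalogue <- function() c("uniform4", "halves4", "checker4", "square3in8")

#' Partition an RoI mask into labelled ground-truth regions
#'
#' Connected foreground components become regions 1..K and the background
#' becomes region K+1, giving a full image partition suitable for the
#' segmentation-quality energy.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer label matrix with consecutive labels.
#' @export
partition_from_mask <- function(mask, connectivity = 8) {
  stopifnot_mask(mask)
  comp <- label_components_cpp(matrix(as.integer(mask), nrow(mask)),
                               as.integer(connectivity))
  k <- attr(comp, "n_components")
  out <- matrix(as.integer(comp), nrow(mask))
  out[out == 0L] <- k + 1L
  out
}

#' Generate a deterministic suite of fixtures
#'
#' @param n number of fixtures.
#' @param seed base seed; fixture i uses seed \code{seed + 101 * i}.
#' @param ... passed to \code{\link{fixture_spec}}.
#' @return list of \code{list(image, mask, spec)}.
#' @export
fixture_suite <- function(n, seed = 1, ...) {
  lapply(seq_len(n), function(i) {
    spec <- fixture_spec(..., seed = seed + 101L * i)
    fx <- generate_fixture(spec)
    fx$spec <- spec
    fx
  })
}
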