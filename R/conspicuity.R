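#' Intensity channel of an RGB image
#'
#' @param img height x width x 3 array in [0, 1] (a matrix is returned
#'   unchanged for convenience).
#' @return height x width matrix, the per-pixel mean (R+G+B)/3.
#' @export
intensity_channel <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Configuration of the multiscale pyramid
#'
#' Levels are indexed from 0 (full resolution); each reduction halves both
#' dimensions. Center-surround maps are taken between a center level c and
#' a surround level c + delta.
#'
#' @param n_levels number of pyramid levels.
#' @param center_levels integer vector of center level indices.
#' @param surround_deltas integer vector of positive center-surround gaps.
#' @param n_orientations number of Gabor orientations (>= 1).
#' @return object of class \code{pyramid_config}.
#' @export
pyramid_config <- function(n_levels = 9, center_levels = c(2, 3, 4),
                           surround_deltas = c(3, 4), n_orientations = 4) {
  if (max(center_levels) + max(surround_deltas) >= n_levels)
    stop("max(center_levels) + max(surround_deltas) must be < n_levels")
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  structure(list(n_levels = as.integer(n_levels),
                 center_levels = as.integer(center_levels),
                 surround_deltas = as.integer(surround_deltas),
                 n_orientations = as.integer(n_orientations)),
            class = "pyramid_config")
}

#' Default pyramid configuration for an image size
#'
#' The canonical 9-level configuration (centers 2-4, deltas 3-4, four
#' orientations) for images of at least 256 px on the short side; a reduced
#' 5-level configuration (centers 1-2, deltas 1-2) below that, so small
#' fixtures and micro-images remain analysable.
#'
#' @param dim integer length-2 (rows, cols) image size.
#' @return a \code{\link{pyramid_config}}.
#' @export
default_pyramid_config <- function(dim) {
  if (min(dim) >= 256) pyramid_config(9, c(2, 3, 4), c(3, 4), 4)
  else pyramid_config(5, c(1, 2), c(1, 2), 4)
}

# --- separable binomial smoothing + dyadic pyramid ------------------------

# 1-D convolution with the binomial kernel [1,4,6,4,1]/16 along rows or
# columns, replicate padding; written with index shifts so a naive loop
# oracle can cross-check it.
binom1d <- function(x, along = c("rows", "cols")) {
  along <- match.arg(along)
  k <- c(1, 4, 6, 4, 1) / 16
  n <- if (along == "rows") nrow(x) else ncol(x)
  out <- 0
  for (j in -2:2) {
    idx <- clamp(seq_len(n) + j, 1, n)
    shifted <- if (along == "rows") x[idx, , drop = FALSE]
               else x[, idx, drop = FALSE]
    out <- out + k[j + 3] * shifted
  }
  out
}

binom_smooth <- function(x) binom1d(binom1d(x, "rows"), "cols")

# halve both dimensions: binomial smooth, then keep odd-indexed pixels
pyr_reduce <- function(x) {
  s <- binom_smooth(x)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

# bilinear resampling with pixel-center alignment (used for both expansion
# of surround levels and across-scale accumulation)
resample_bilinear <- function(x, H, W) {
  h <- nrow(x); w <- ncol(x)
  interp_idx <- function(n_src, n_dst) {
    t <- (seq_len(n_dst) - 0.5) * n_src / n_dst   # target centers, src units
    l <- floor(t + 0.5)
    frac <- t - (l - 0.5)
    l <- clamp(l, 1, n_src)
    l2 <- clamp(l + 1, 1, n_src)
    list(l = l, l2 = l2, f = clamp(frac, 0, 1))
  }
  ri <- interp_idx(h, H); ci <- interp_idx(w, W)
  a <- x[ri$l, ci$l, drop = FALSE]; b <- x[ri$l2, ci$l, drop = FALSE]
  cc <- x[ri$l, ci$l2, drop = FALSE]; d <- x[ri$l2, ci$l2, drop = FALSE]
  fr <- matrix(ri$f, H, W); fc <- matrix(ci$f, H, W, byrow = TRUE)
  (1 - fr) * (1 - fc) * a + fr * (1 - fc) * b +
    (1 - fr) * fc * cc + fr * fc * d
}

gaussian_pyramid <- function(x, n_levels) {
  levels <- vector("list", n_levels)
  levels[[1]] <- x
  for (i in seq_len(n_levels - 1)) levels[[i + 1]] <- pyr_reduce(levels[[i]])
  levels
}

#' Center-surround feature maps of a scalar channel
#'
#' Builds a dyadic Gaussian pyramid and returns, for every (center,
#' surround) pair of the configuration, the absolute difference between the
#' center level and the surround level bilinearly upsampled to the center
#' resolution. This preserves localized high-frequency contrast across
#' scales.
#'
#' @param channel scalar image matrix.
#' @param cfg a \code{\link{pyramid_config}} (default chosen from the size).
#' @return named list of feature-map matrices (names like \code{"c2_s5"}).
#' @export
center_surround_maps <- function(channel, cfg = NULL) {
  if (is.null(cfg)) cfg <- default_pyramid_config(dim(channel))
  if (min(dim(channel)) < 2^(cfg$n_levels - 1))
    stop("image too small for the requested number of pyramid levels")
  pyr <- gaussian_pyramid(channel, cfg$n_levels)
  maps <- list()
  for (cl in cfg$center_levels) {
    for (d in cfg$surround_deltas) {
      s <- cl + d
      ctr <- pyr[[cl + 1]]
      sur <- resample_bilinear(pyr[[s + 1]], nrow(ctr), ncol(ctr))
      maps[[sprintf("c%d_s%d", cl, s)]] <- abs(ctr - sur)
    }
  }
  maps
}

#' Itti map normalization N(.)
#'
#' Rescales a non-negative feature map to [0, 1] by its maximum and
#' multiplies it by \eqn{(M - \bar m)^2}, where M = 1 is the rescaled global
#' maximum and \eqn{\bar m} is the mean of the other local maxima (strictly
#' positive 3x3-neighbourhood maxima; plateaus counted once). A map with a
#' single dominant peak is preserved; a map with many comparable peaks is
#' suppressed, so only localized information survives. All-zero (or
#' constant) maps return all-zero.
#'
#' @param m feature-map matrix with finite, non-negative values.
#' @return normalized matrix in [0, 1].
#' @export
normalize_map <- function(m) {
  if (max(m) - min(m) <= .Machine$double.eps) return(m * 0)
  m <- m / max(m)
  peaks <- local_maxima_values(m)
  mbar <- if (length(peaks) > 1) mean(peaks[-which.max(peaks)]) else 0
  m * (1 - mbar)^2
}

# values of strictly positive local maxima (3x3 neighbourhood, plateau
# connected components counted once)
local_maxima_values <- function(m) {
  H <- nrow(m); W <- ncol(m)
  dil <- matrix(-Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- clamp(seq_len(H) + dr, 1, H)
    cc <- clamp(seq_len(W) + dc, 1, W)
    dil <- pmax(dil, m[rr, cc, drop = FALSE])
  }
  cand <- (m == dil) & (m > 0)
  if (!any(cand)) return(numeric(0))
  lab <- label_components_cpp(matrix(as.integer(cand), H), 8L)
  k <- attr(lab, "n_components")
  vapply(seq_len(k), function(i) m[which(lab == i)[1]], numeric(1))
}

#' Even-symmetric Gabor kernel
#'
#' @param theta_deg stripe orientation in degrees (90 = vertical stripes,
#'   responding maximally to vertical bars).
#' @param size odd kernel size in pixels.
#' @param lambda carrier wavelength (pixels).
#' @param sigma Gaussian envelope standard deviation (pixels).
#' @param gamma spatial aspect ratio of the envelope.
#' @return size x size matrix with zero mean (no DC response).
#' @export
gabor_kernel <- function(theta_deg, size = 9, lambda = 5, sigma = 2,
                         gamma = 0.5) {
  stopifnot(size %% 2 == 1)
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), size, size) # column offset
  ys <- matrix(rep(-half:half, size), size, size)        # row offset
  th <- theta_deg * pi / 180
  xr <- xs * sin(th) - ys * cos(th)  # modulation axis, perpendicular to stripes
  yr <- xs * cos(th) + ys * sin(th)
  g <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  g - mean(g)
}

conv_replicate <- function(x, kernel) {
  r <- EBImage::filter2(x, kernel, boundary = "replicate")
  matrix(as.numeric(r), nrow(x), ncol(x))
}

#' Gabor orientation response of a scalar image
#'
#' Absolute response to an even-symmetric, zero-DC Gabor filter, replicate
#' padding at the borders.
#'
#' @inheritParams gabor_kernel
#' @param channel scalar image matrix.
#' @export
gabor_response <- function(channel, theta_deg, size = 9, lambda = 5,
                           sigma = 2, gamma = 0.5) {
  abs(conv_replicate(channel, gabor_kernel(theta_deg, size, lambda, sigma,
                                           gamma)))
}

# broadly tuned colour channels and the two double-opponency axes
opponency_channels <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  R <- pmax(r - (g + b) / 2, 0)
  G <- pmax(g - (r + b) / 2, 0)
  B <- pmax(b - (r + g) / 2, 0)
  Y <- pmax((r + g) / 2 - abs(r - g) / 2 - b, 0)
  list(rg = R - G, by = B - Y)
}

#' Conspicuity map of one low-level channel
#'
#' Computes the across-scale sum of normalized center-surround maps for a
#' channel, following the classical bottom-up attention architecture:
#' intensity uses the (R+G+B)/3 channel; colour uses the RG and BY
#' double-opponency axes of broadly tuned channels; orientation uses Gabor
#' responses at \code{n_orientations} angles across the pyramid. The sum is
#' accumulated at the coarsest center level, rescaled to [0, 1] and
#' bilinearly upsampled to the full image resolution.
#'
#' @param img RGB array in [0, 1].
#' @param channel one of \code{"intensity"}, \code{"color"},
#'   \code{"orientation"}.
#' @param cfg optional \code{\link{pyramid_config}}.
#' @return matrix in [0, 1] of the image size, with attribute
#'   \code{channel}.
#' @export
conspicuity <- function(img, channel = c("intensity", "color", "orientation"),
                        cfg = NULL) {
  channel <- match.arg(channel)
  I <- intensity_channel(img)
  if (is.null(cfg)) cfg <- default_pyramid_config(dim(I))
  feats <- switch(channel,
    intensity = center_surround_maps(I, cfg),
    color = {
      if (is.matrix(img)) stop("color conspicuity needs an RGB image")
      opp <- opponency_channels(img)
      c(center_surround_maps(opp$rg, cfg), center_surround_maps(opp$by, cfg))
    },
    orientation = {
      pyr <- gaussian_pyramid(I, cfg$n_levels)
      thetas <- (seq_len(cfg$n_orientations) - 1) * 180 / cfg$n_orientations
      out <- list()
      for (th in thetas) {
        # filter each level that fits the kernel; for coarser levels the
        # response of the previous level is reduced instead
        resp <- vector("list", length(pyr))
        for (li in seq_along(pyr)) {
          resp[[li]] <- if (min(dim(pyr[[li]])) >= 9 || li == 1)
            gabor_response(pyr[[li]], theta_deg = th)
          else pyr_reduce(resp[[li - 1]])
        }
        for (cl in cfg$center_levels) for (d in cfg$surround_deltas) {
          s <- cl + d
          ctr <- resp[[cl + 1]]
          sur <- resample_bilinear(resp[[s + 1]], nrow(ctr), ncol(ctr))
          out[[sprintf("t%g_c%d_s%d", th, cl, s)]] <- abs(ctr - sur)
        }
      }
      out
    })
  target_level <- max(cfg$center_levels)
  tdim <- dim(I)
  for (i in seq_len(target_level)) tdim <- ceiling(tdim / 2)
  acc <- matrix(0, tdim[1], tdim[2])
  for (m in feats)
    acc <- acc + resample_bilinear(normalize_map(m), tdim[1], tdim[2])
  out <- resample_bilinear(rescale01(acc), nrow(I), ncol(I))
  structure(clamp(out), channel = channel)
}

#' Local-entropy texture conspicuity map
#'
#' Per-pixel Shannon entropy (bits) of the windowed intensity histogram,
#' mirrored at the borders and rescaled to [0, 1] by dividing by
#' \code{log2(n_bins)}. Heterogeneous, cluttered tissue (tumour islets)
#' yields high values; quiet stroma yields low values.
#'
#' @param img RGB array or scalar matrix in [0, 1].
#' @param window window side length in pixels (>= 2; odd windows are
#'   centred, even windows extend one extra pixel towards the bottom-right).
#' @param n_bins number of histogram bins (>= 2).
#' @return matrix in [0, 1] with attribute \code{channel = "entropy"}.
#' @export
entropy_conspicuity <- function(img, window = 9, n_bins = 32) {
  if (window < 2) stop("window must be >= 2")
  if (n_bins < 2) stop("n_bins must be >= 2")
  I <- intensity_channel(img)
  e <- local_entropy_cpp(I, as.integer(window), as.integer(n_bins))
  structure(clamp(e / log2(n_bins)), channel = "entropy")
}
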