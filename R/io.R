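#' Default pipeline configuration
#'
#' Nested named list with every tunable of the pipeline and its default;
#' the schema accepted by \code{\link{load_config}}.
#'
#' @return nested list with sections \code{fixtures}, \code{pyramid},
#'   \code{entropy}, \code{segmentation}, \code{metric}, \code{gps},
#'   \code{weights} and a top-level \code{seed}.
#' @export
default_config <- function() {
  list(
    fixtures = list(width = 128L, height = 128L, n_islets = 3L,
                    islet_radius_min = 12, islet_radius_max = 24,
                    background_color = c(230, 200, 210),
                    islet_color = c(120, 90, 160),
                    islet_texture_noise_sd = 40, background_noise_sd = 4,
                    blur_sigma = 1),
    pyramid = list(n_levels = NULL, center_levels = NULL,
                   surround_deltas = NULL, n_orientations = 4L),
    entropy = list(window = 9L, bins = 32L),
    segmentation = list(k = 500, smooth_sigma = 0.8, min_size = 20L,
                        connectivity = 4L),
    metric = list(slope = 1, offset = 1, d_max = 20),
    gps = list(delta0 = 1, max_refinements = 8),
    weights = list(intensity = 0.25, color = 0.25, orientation = 0.25,
                   entropy = 0.25),
    seed = 1L
  )
}

check_config_keys <- function(cfg, defaults, path = character(0)) {
  for (nm in names(cfg)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown configuration key: %s",
                   paste(c(path, nm), collapse = ".")))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], defaults[[nm]], c(path, nm))
  }
  invisible(TRUE)
}

#' Load a YAML pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (naming the offending key) and
#' merges the values over \code{\link{default_config}}. An empty file
#' yields the defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(defaults)
  if (!is.list(cfg)) stop("configuration file must contain a YAML mapping")
  check_config_keys(cfg, defaults)
  modifyList(defaults, cfg)
}

#' Save a pipeline configuration as YAML
#' @param cfg nested configuration list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) yaml::write_yaml(cfg, path)

# configuration section -> typed parameter objects
config_segmentation_params <- function(cfg) {
  s <- cfg$segmentation
  segmentation_params(s$k, s$smooth_sigma, s$min_size, s$connectivity)
}

config_weighting <- function(cfg) {
  m <- cfg$metric
  distance_weighting(m$slope, m$offset, m$d_max)
}

config_roi_params <- function(cfg) {
  pyr <- NULL
  p <- cfg$pyramid
  if (!is.null(p$n_levels))
    pyr <- pyramid_config(p$n_levels, p$center_levels, p$surround_deltas,
                          p$n_orientations)
  roi_params(segmentation = config_segmentation_params(cfg),
             weights = unlist(cfg$weights),
             entropy_window = cfg$entropy$window,
             entropy_bins = cfg$entropy$bins,
             pyramid = pyr, weighting = config_weighting(cfg))
}

config_fixture_spec <- function(cfg, seed = cfg$seed, variant = "default") {
  f <- cfg$fixtures
  fixture_spec(width = f$width, height = f$height, n_islets = f$n_islets,
               islet_radius_range = c(f$islet_radius_min, f$islet_radius_max),
               background_color = f$background_color / 255,
               islet_color = f$islet_color / 255,
               islet_texture_noise_sd = f$islet_texture_noise_sd,
               background_noise_sd = f$background_noise_sd,
               blur_sigma = f$blur_sigma, seed = seed, variant = variant)
}

#' Read an RGB image
#'
#' Reads a PNG/JPEG/TIFF image and returns a height x width x 3 array in
#' [0, 1] (grayscale images are replicated across channels).
#'
#' @param path image file path.
#' @return numeric array.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  aperm(a, c(2, 1, 3)) |> clamp()
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Masks are {0, 1} in memory and {0, 255} on disk.
#'
#' @param mask binary matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}

#' Write / read a label map as PNG with JSON sidecar
#'
#' Region ids (up to 65535) are split across two 8-bit PNG channels (red =
#' low byte, green = high byte), giving an exact 16-bit round-trip; a JSON
#' sidecar \code{<path>.json} records \code{n_regions} and optional
#' parameters.
#'
#' @param labels integer label matrix.
#' @param path PNG path.
#' @param params optional list stored in the sidecar.
#' @export
write_labelmap <- function(labels, path, params = NULL) {
  v <- as.integer(labels)
  if (any(v < 0) || any(v > 65535)) stop("labels must be in 0..65535")
  H <- nrow(labels); W <- ncol(labels)
  arr <- array(0, c(H, W, 3))
  arr[, , 1] <- matrix(v %% 256L, H, W) / 255
  arr[, , 2] <- matrix(v %/% 256L, H, W) / 255
  png::writePNG(arr, path)
  side <- list(n_regions = n_regions(labels))
  if (!is.null(params)) side$params <- params
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  a <- png::readPNG(path)
  lab <- matrix(as.integer(round(a[, , 1] * 255)) +
                256L * as.integer(round(a[, , 2] * 255)),
                dim(a)[1], dim(a)[2])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(lab, "n_regions") <- jsonlite::read_json(sidecar)$n_regions
  lab
}

#' Write an RGB image as PNG
#' @param img height x width x 3 array in [0, 1].
#' @param path PNG path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img), path)
  invisible(path)
}
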