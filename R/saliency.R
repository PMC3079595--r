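#' Detector parameter set
#'
#' Bundles everything \code{\link{detect}} needs: segmentation parameters,
#' non-negative channel weights (intensity, colour, orientation, entropy),
#' the entropy window/binning, an optional pyramid configuration and the
#' distance weighting used when scoring against ground truth.
#'
#' @param segmentation a \code{\link{segmentation_params}}.
#' @param weights named non-negative numeric of length 4 with names
#'   \code{intensity}, \code{color}, \code{orientation}, \code{entropy};
#'   not all zero.
#' @param entropy_window,entropy_bins passed to
#'   \code{\link{entropy_conspicuity}}.
#' @param pyramid optional \code{\link{pyramid_config}} (chosen from the
#'   image size when NULL).
#' @param weighting a \code{\link{distance_weighting}}.
#' @return object of class \code{roi_params}.
#' @export
roi_params <- function(segmentation = segmentation_params(),
                       weights = c(intensity = 0.25, color = 0.25,
                                   orientation = 0.25, entropy = 0.25),
                       entropy_window = 9, entropy_bins = 32,
                       pyramid = NULL, weighting = distance_weighting()) {
  weights <- weights[c("intensity", "color", "orientation", "entropy")]
  if (anyNA(weights) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be named, non-negative and not all zero")
  structure(list(segmentation = segmentation, weights = weights,
                 entropy_window = entropy_window, entropy_bins = entropy_bins,
                 pyramid = pyramid, weighting = weighting),
            class = "roi_params")
}

# The four per-pixel channel maps used by the detector. The entropy map is
# used on its absolute [0,1] scale: the peak-promoting N(.) normalization
# would cancel it, because a texture region is a plateau of comparable
# local maxima -- precisely the configuration N(.) suppresses -- while the
# V4 signal of interest is that plateau itself.
conspicuity_stack <- function(img, params = roi_params()) {
  I <- intensity_channel(img)
  cfg <- params$pyramid
  if (is.null(cfg)) cfg <- default_pyramid_config(dim(I))
  list(intensity = conspicuity(img, "intensity", cfg),
       color = conspicuity(img, "color", cfg),
       orientation = conspicuity(img, "orientation", cfg),
       entropy = entropy_conspicuity(I, params$entropy_window,
                                     params$entropy_bins))
}

#' Per-region mean of a conspicuity map
#'
#' The per-region feature index: the pixel-value average of the map inside
#' each region of the label matrix.
#'
#' @param labels integer label matrix (labels 1..K).
#' @param m matrix of the same shape.
#' @return numeric vector of length K, indexed by region label.
#' @export
region_feature_index <- function(labels, m) {
  stopifnot(all(dim(labels) == dim(m)))
  sums <- rowsum(as.vector(m), as.vector(labels))
  cnts <- rowsum(rep(1, length(labels)), as.vector(labels))
  idx <- as.vector(sums / cnts)
  names(idx) <- rownames(sums)
  idx[order(as.integer(names(idx)))]
}

#' Combine per-region feature indices into region saliency
#'
#' The total region saliency is the weighted mean of the per-region feature
#' indices (weights renormalized to sum 1), then min-max normalized across
#' regions; if all regions tie, every saliency becomes 0.5.
#'
#' @param table data.frame with columns \code{mean_intensity_consp},
#'   \code{mean_color_consp}, \code{mean_orientation_consp},
#'   \code{mean_entropy_consp}.
#' @param weights named non-negative weights (see \code{\link{roi_params}}),
#'   not all zero.
#' @return the table with \code{combined_raw} and \code{combined_saliency}
#'   columns added.
#' @export
combine_saliency <- function(table, weights) {
  weights <- weights[c("intensity", "color", "orientation", "entropy")]
  if (anyNA(weights) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  idx <- as.matrix(table[, c("mean_intensity_consp", "mean_color_consp",
                             "mean_orientation_consp", "mean_entropy_consp")])
  raw <- as.vector(idx %*% weights) / sum(weights)
  rng <- range(raw)
  table$combined_raw <- raw
  table$combined_saliency <-
    if (diff(rng) <= .Machine$double.eps) rep(0.5, length(raw))
    else (raw - rng[1]) / diff(rng)
  table
}

#' Select salient regions into an RoI mask
#'
#' Foreground is the union of regions whose combined saliency is strictly
#' greater than the unweighted mean of the region saliencies; when every
#' region ties (degenerate single-region images) the mask is empty.
#'
#' @param labels integer label matrix.
#' @param table region saliency table from \code{\link{combine_saliency}}.
#' @return binary matrix.
#' @export
extract_rois <- function(labels, table) {
  sel <- table$combined_saliency > mean(table$combined_saliency)
  selected <- table$region[sel]
  matrix(as.numeric(labels %in% selected), nrow(labels))
}

# region table from precomputed labels and channel maps
region_saliency_table <- function(labels, maps, weights) {
  tab <- data.frame(
    region = sort(unique(as.vector(labels))),
    area = as.vector(rowsum(rep(1, length(labels)), as.vector(labels))),
    mean_intensity_consp = region_feature_index(labels, maps$intensity),
    mean_color_consp = region_feature_index(labels, maps$color),
    mean_orientation_consp = region_feature_index(labels, maps$orientation),
    mean_entropy_consp = region_feature_index(labels, maps$entropy)
  )
  tab <- combine_saliency(tab, weights)
  tab$selected <- tab$combined_saliency > mean(tab$combined_saliency)
  tab
}

#' Detect diagnostic Regions of Interest in an image
#'
#' The full pipeline: four conspicuity maps (intensity, colour,
#' orientation, local entropy), graph-based still-segmentation of the
#' intensity channel, per-region averaging of each map, linear combination
#' with the channel weights, and selection of the regions whose saliency
#' exceeds the mean region saliency. Deterministic for fixed inputs.
#'
#' @param img RGB array in [0, 1] (height x width x 3).
#' @param params an \code{\link{roi_params}}.
#' @return object of class \code{roi_detection}: \code{mask} (binary
#'   matrix), \code{table} (region saliency table with columns region,
#'   area, the four feature means, combined_raw, combined_saliency,
#'   selected) and \code{labels} (the still-segmentation).
#' @export
detect <- function(img, params = roi_params()) {
  I <- intensity_channel(img)
  labels <- felzenszwalb_segment(I, params$segmentation)
  maps <- conspicuity_stack(img, params)
  tab <- region_saliency_table(labels, maps, params$weights)
  structure(list(mask = extract_rois(labels, tab), table = tab,
                 labels = labels, params = params),
            class = "roi_detection")
}

#' @export
print.roi_detection <- function(x, ...) {
  cat(sprintf("RoI detection: %d regions, %d selected, foreground %.1f%%\n",
              nrow(x$table), sum(x$table$selected),
              100 * mean(x$mask)))
  invisible(x)
}
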