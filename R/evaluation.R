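#' Pixel-level confusion between predicted and ground-truth RoI masks
#'
#' @param pred,gt binary matrices of equal shape.
#' @return object of class \code{pixel_confusion}: counts \code{tp},
#'   \code{fp}, \code{tn}, \code{fn} plus \code{sensitivity} and
#'   \code{specificity} in percent (NA with \code{undefined = TRUE} when a
#'   denominator is empty).
#' @export
pixel_confusion <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  stopifnot_mask(pred, "pred"); stopifnot_mask(gt, "gt")
  tp <- sum(pred == 1 & gt == 1); fp <- sum(pred == 1 & gt == 0)
  tn <- sum(pred == 0 & gt == 0); fn <- sum(pred == 0 & gt == 1)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 undefined = is.na(sens) || is.na(spec)),
            class = "pixel_confusion")
}

#' @export
print.pixel_confusion <- function(x, ...) {
  cat(sprintf("pixels: tp=%d fp=%d tn=%d fn=%d | sens %.1f%% spec %.1f%%\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Region-level sensitivity and meaningless-region count
#'
#' Connected components (8-connectivity) of the predicted mask are the
#' predicted regions. A predicted region is "meaningful" when at least
#' \code{coverage_threshold} of its area lies inside a single ground-truth
#' region, otherwise it counts as meaningless. A ground-truth region is
#' "detected" when at least one meaningful predicted region intersects it;
#' region sensitivity is the percentage of detected ground-truth regions.
#'
#' @param pred binary predicted mask.
#' @param gt binary ground-truth mask (components are the ground-truth
#'   regions) or an integer label matrix / list of masks.
#' @param coverage_threshold fraction in (0, 1], default 0.70.
#' @param connectivity connectivity for components (default 8).
#' @return object of class \code{region_hit_report}: \code{n_gt_regions},
#'   \code{n_pred_regions}, \code{n_detected_gt}, \code{n_meaningless_pred},
#'   \code{region_sensitivity} (percent; NA with \code{undefined = TRUE}
#'   when there is no ground-truth region).
#' @export
region_sensitivity <- function(pred, gt, coverage_threshold = 0.70,
                               connectivity = 8) {
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stop("coverage_threshold must be in (0, 1]")
  stopifnot_mask(pred, "pred")
  pl <- label_components_cpp(matrix(as.integer(pred), nrow(pred)),
                             as.integer(connectivity))
  np <- attr(pl, "n_components")
  gl <- if (is.matrix(gt) && all(gt %in% c(0, 1)))
    label_components_cpp(matrix(as.integer(gt), nrow(gt)),
                         as.integer(connectivity))
  else as_label_matrix(gt)
  gids <- sort(setdiff(unique(as.vector(gl)), 0L))
  ng <- length(gids)
  meaningful <- logical(np)
  detected <- logical(ng)
  for (p in seq_len(np)) {
    pm <- pl == p
    area <- sum(pm)
    inside <- gl[pm]
    cover <- if (ng > 0)
      vapply(gids, function(g) sum(inside == g) / area, numeric(1))
    else numeric(0)
    meaningful[p] <- length(cover) > 0 && max(cover) >= coverage_threshold
    if (meaningful[p]) detected[inside[inside > 0]] <- TRUE
  }
  # detected[] indexed by gt label id; compress onto gids
  ndet <- if (ng > 0) sum(detected[gids]) else 0L
  structure(list(
    n_gt_regions = ng, n_pred_regions = np, n_detected_gt = ndet,
    n_meaningless_pred = sum(!meaningful),
    region_sensitivity = if (ng > 0) 100 * ndet / ng else NA_real_,
    undefined = ng == 0
  ), class = "region_hit_report")
}

#' @export
print.region_hit_report <- function(x, ...) {
  cat(sprintf(
    "regions: %d gt, %d predicted, %d detected, %d meaningless | sens %.1f%%\n",
    x$n_gt_regions, x$n_pred_regions, x$n_detected_gt,
    x$n_meaningless_pred, x$region_sensitivity))
  invisible(x)
}

#' Evaluate predicted masks against ground truth over a dataset
#'
#' @param preds,gts lists of binary masks of equal length.
#' @param coverage_threshold see \code{\link{region_sensitivity}}.
#' @param weighting a \code{\link{distance_weighting}} for the dB score.
#' @return data.frame with one row per image: sensitivity, specificity,
#'   region_sensitivity, n_meaningless_pred, db_total.
#' @export
evaluate_dataset <- function(preds, gts, coverage_threshold = 0.70,
                             weighting = distance_weighting()) {
  stopifnot(length(preds) == length(gts))
  rows <- lapply(seq_along(preds), function(i) {
    conf <- pixel_confusion(preds[[i]], gts[[i]])
    reg <- region_sensitivity(preds[[i]], gts[[i]], coverage_threshold)
    q <- fg_quality(gts[[i]], preds[[i]], weighting)
    data.frame(image = i, sensitivity = conf$sensitivity,
               specificity = conf$specificity,
               region_sensitivity = reg$region_sensitivity,
               n_meaningless_pred = reg$n_meaningless_pred,
               db_total = q$db)
  })
  do.call(rbind, rows)
}
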