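#' Generalized pattern search (GPS)
#'
#' Derivative-free minimization over a box. At each iteration the poll set
#' \eqn{L_k = \{x_k \pm \Delta_k s_i \hat e_i\}} (coordinates in declared
#' order, + direction before -) is evaluated opportunistically: the first
#' strict improvement is accepted and the mesh size kept; if no poll point
#' improves, the mesh size is halved. The search stops after the mesh has
#' been refined \code{max_refinements} times. Candidates are clipped to the
#' bounds, non-finite objective values are treated as +Inf, and objective
#' values are cached on the parameter tuple.
#'
#' @param f objective: takes a named numeric vector, returns a scalar.
#' @param x0 named numeric start point.
#' @param lower,upper bounds (recycled to length of x0).
#' @param scales per-coordinate step scales s_i (> 0); default a quarter of
#'   the box width.
#' @param delta0 initial mesh size factor.
#' @param max_refinements number of mesh halvings before termination.
#' @param max_iterations safety cap on poll rounds.
#' @return list with \code{par}, \code{value}, \code{trace} (data.frame
#'   with one row per objective evaluation: value, best so far, mesh size)
#'   and \code{n_refinements}.
#' @export
pattern_search <- function(f, x0, lower = -Inf, upper = Inf, scales = NULL,
                           delta0 = 1, max_refinements = 10,
                           max_iterations = 1000) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (is.null(scales)) {
    scales <- (upper - lower) / 4
    scales[!is.finite(scales) | scales <= 0] <- 1
  }
  scales <- rep_len(scales, n)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  trace <- list()
  feval <- function(x) {
    key <- paste(signif(x, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- f(x)
    if (!is.finite(v)) v <- Inf
    cache[[key]] <- v
    v
  }
  record <- function(v, best, delta) {
    evals <<- evals + 1L
    trace[[evals]] <<- c(value = v, best = best, delta = delta)
  }
  x <- clamp(x0, lower, upper)
  fx <- feval(x)
  record(fx, fx, delta0)
  delta <- delta0
  refinements <- 0L
  iter <- 0L
  while (refinements < max_refinements && iter < max_iterations) {
    iter <- iter + 1L
    improved <- FALSE
    for (i in seq_len(n)) {
      for (sgn in c(1, -1)) {
        cand <- x
        cand[i] <- clamp(x[i] + sgn * delta * scales[i], lower[i], upper[i])
        if (cand[i] == x[i]) next
        v <- feval(cand)
        record(v, min(fx, v), delta)
        if (v < fx) {
          x <- cand; fx <- v; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) {
      delta <- delta / 2
      refinements <- refinements + 1L
    }
  }
  tr <- as.data.frame(do.call(rbind, trace))
  tr$best <- cummin(tr$best)
  list(par = x, value = fx, trace = tr, n_refinements = refinements,
       n_evaluations = evals)
}

# ground-truth partition of a training sample: explicit partition if given,
# else derived from the RoI mask (islets + background)
sample_partition <- function(s) {
  if (!is.null(s$partition)) as_label_matrix(s$partition)
  else partition_from_mask(s$mask)
}

#' Learn still-segmentation parameters from ground truth (stage 1)
#'
#' Minimizes the mean total perceptual energy between each training
#' image's still-segmentation and its ground-truth partition, over
#' (k, smooth_sigma, min_size), by generalized pattern search. Because k
#' is a scale factor spanning more than two decades, the search polls it
#' on the log10 scale (through the per-coordinate scale s_i of the
#' pattern search); smoothing and minimum size are polled linearly. Before
#' polling, a search step sweeps a coarse factorial grid of mesh points
#' around the start and begins the poll from its best point: the energy is
#' piecewise constant in the segmentation parameters, and the sweep places
#' the poll in the right basin.
#'
#' @param samples list of training samples; each a list with \code{image}
#'   (RGB array or scalar matrix) and \code{partition} (label matrix) or
#'   \code{mask} (binary RoI mask, partitioned into islets + background).
#' @param x0 named start vector (k, smooth_sigma, min_size), natural units.
#' @param lower,upper named bounds, natural units.
#' @param weighting a \code{\link{distance_weighting}}.
#' @param gps list of \code{\link{pattern_search}} settings; scales are in
#'   the polled coordinates (log10 k, smooth_sigma, min_size).
#' @return a \code{\link{segmentation_params}} with attributes
#'   \code{objective} (achieved mean energy) and \code{trace}.
#' @export
learn_segmentation_params <- function(samples,
    x0 = c(k = 500, smooth_sigma = 0.8, min_size = 20),
    lower = c(k = 10, smooth_sigma = 0, min_size = 1),
    upper = c(k = 5000, smooth_sigma = 2, min_size = 500),
    weighting = distance_weighting(),
    gps = list(delta0 = 2, max_refinements = 8,
               scales = c(logk = 0.25, smooth_sigma = 0.25,
                          min_size = 25))) {
  if (length(samples) < 1) stop("at least one training sample is required")
  channels <- lapply(samples, function(s) intensity_channel(s$image))
  parts <- lapply(samples, sample_partition)
  objective <- function(x) {
    p <- segmentation_params(k = 10^x[["logk"]],
                             smooth_sigma = x[["smooth_sigma"]],
                             min_size = round(x[["min_size"]]))
    mean(vapply(seq_along(samples), function(i) {
      total_energy(parts[[i]], felzenszwalb_segment(channels[[i]], p),
                   weighting)$energy
    }, numeric(1)))
  }
  x0t <- c(logk = log10(x0[["k"]]), smooth_sigma = x0[["smooth_sigma"]],
           min_size = x0[["min_size"]])
  lot <- c(log10(lower[["k"]]), lower[["smooth_sigma"]],
           lower[["min_size"]])
  upt <- c(log10(upper[["k"]]), upper[["smooth_sigma"]],
           upper[["min_size"]])
  # search step on the mesh M(x0, delta0): a coarse factorial sweep over
  # mesh points around x0 picks the poll starting point, so the subsequent
  # coordinate polling starts in the right basin of the (piecewise
  # constant) energy landscape
  sc <- gps$scales[names(x0t)]
  mesh <- expand.grid(logk = x0t[["logk"]] + gps$delta0 * sc[["logk"]] * (-3:2),
                      smooth_sigma = x0t[["smooth_sigma"]] +
                        gps$delta0 * sc[["smooth_sigma"]] * (-1:1),
                      min_size = x0t[["min_size"]])
  mesh <- mesh[mesh$logk >= lot[1] & mesh$logk <= upt[1] &
               mesh$smooth_sigma >= lot[2] & mesh$smooth_sigma <= upt[2], ,
               drop = FALSE]
  mesh_vals <- vapply(seq_len(nrow(mesh)), function(i)
    objective(c(logk = mesh$logk[i], smooth_sigma = mesh$smooth_sigma[i],
                min_size = mesh$min_size[i])), numeric(1))
  # the start point wins ties, so flat objectives keep x0
  if (objective(x0t) > min(mesh_vals))
    x0t <- unlist(mesh[which.min(mesh_vals), ])
  res <- pattern_search(objective, x0t, lot, upt,
                        scales = gps$scales[names(x0t)], delta0 = gps$delta0,
                        max_refinements = gps$max_refinements)
  out <- segmentation_params(k = 10^res$par[["logk"]],
                             smooth_sigma = res$par[["smooth_sigma"]],
                             min_size = round(res$par[["min_size"]]))
  attr(out, "objective") <- res$value
  attr(out, "trace") <- res$trace
  out
}

#' Learn channel weights from ground truth (stage 2)
#'
#' With the segmentation fixed, minimizes the mean normalized
#' foreground-background quality between each sample's ground-truth RoI
#' mask and the mask the detector extracts, over the four non-negative
#' channel weights (intensity, colour, orientation, entropy). The
#' conspicuity maps, still-segmentations and per-region feature indices are
#' precomputed once, so each poll only recombines and rethresholds. An
#' all-zero weight poll is evaluated with uniform weights as fallback. The
#' returned weights are renormalized to sum 1.
#'
#' @param samples list of training samples with \code{image} and
#'   \code{mask} (the ground-truth RoI).
#' @param seg_params fixed \code{\link{segmentation_params}} (stage 1
#'   output).
#' @param x0 start weights.
#' @param weighting a \code{\link{distance_weighting}}.
#' @param entropy_window,entropy_bins entropy-map settings.
#' @param gps list of \code{\link{pattern_search}} settings.
#' @return named weight vector summing to 1, with attributes
#'   \code{objective} and \code{trace}.
#' @export
learn_feature_weights <- function(samples, seg_params,
    x0 = c(intensity = 0.25, color = 0.25, orientation = 0.25,
           entropy = 0.25),
    weighting = distance_weighting(),
    entropy_window = 9, entropy_bins = 32,
    gps = list(delta0 = 1, max_refinements = 8, scales = 0.25)) {
  if (length(samples) < 1) stop("at least one training sample is required")
  base <- roi_params(segmentation = seg_params,
                     entropy_window = entropy_window,
                     entropy_bins = entropy_bins, weighting = weighting)
  pre <- lapply(samples, function(s) {
    labels <- felzenszwalb_segment(intensity_channel(s$image),
                                   seg_params)
    maps <- conspicuity_stack(s$image, base)
    idx <- cbind(
      mean_intensity_consp = region_feature_index(labels, maps$intensity),
      mean_color_consp = region_feature_index(labels, maps$color),
      mean_orientation_consp = region_feature_index(labels, maps$orientation),
      mean_entropy_consp = region_feature_index(labels, maps$entropy))
    list(labels = labels, idx = as.data.frame(idx),
         regions = sort(unique(as.vector(labels))), gt = s$mask)
  })
  objective <- function(w) {
    if (sum(w) <= 0) w <- rep(0.25, 4)       # uniform fallback
    names(w) <- names(x0)
    mean(vapply(pre, function(p) {
      tab <- p$idx
      tab$region <- p$regions
      tab <- combine_saliency(tab, w)
      mask <- extract_rois(p$labels, tab)
      fg_quality(p$gt, mask, weighting)$normalized
    }, numeric(1)))
  }
  res <- pattern_search(objective, x0, lower = 0, upper = 1,
                        scales = gps$scales, delta0 = gps$delta0,
                        max_refinements = gps$max_refinements)
  w <- res$par
  if (sum(w) <= 0) w <- setNames(rep(0.25, 4), names(x0))
  w <- w / sum(w)
  attr(w, "objective") <- res$value
  attr(w, "trace") <- res$trace
  w
}

#' Two-stage supervised learning of the full detector
#'
#' Stage 1 learns the still-segmentation parameters against the
#' ground-truth partitions; stage 2 learns the channel weights with the
#' segmentation fixed.
#'
#' @inheritParams learn_segmentation_params
#' @param entropy_window,entropy_bins entropy-map settings.
#' @param gps_seg,gps_weights GPS settings for the two stages.
#' @return an \code{\link{roi_params}} ready for \code{\link{detect}}.
#' @export
learn_roi_detector <- function(samples, weighting = distance_weighting(),
                               entropy_window = 9, entropy_bins = 32,
                               gps_seg = list(delta0 = 2, max_refinements = 8,
                                 scales = c(logk = 0.25, smooth_sigma = 0.25,
                                            min_size = 25)),
                               gps_weights = list(delta0 = 1,
                                 max_refinements = 8, scales = 0.25)) {
  seg <- learn_segmentation_params(samples, weighting = weighting,
                                   gps = gps_seg)
  w <- learn_feature_weights(samples, seg, weighting = weighting,
                             entropy_window = entropy_window,
                             entropy_bins = entropy_bins, gps = gps_weights)
  roi_params(segmentation = seg, weights = as.numeric(w) |>
               setNames(names(w)),
             entropy_window = entropy_window, entropy_bins = entropy_bins,
             weighting = weighting)
}

#' k-fold cross-validation of the learned detector
#'
#' Splits the dataset into \code{n_folds} folds (deterministic assignment
#' from \code{seed}), learns the two-stage detector on the training folds
#' and evaluates pixel- and region-level metrics plus the perceptual
#' quality on the held-out fold.
#'
#' @param samples list of samples with \code{image} and \code{mask}.
#' @param n_folds number of folds (default 11).
#' @param seed integer controlling the fold assignment.
#' @param ... passed to \code{\link{learn_roi_detector}}.
#' @return data.frame with one row per fold: fold, n_test, mean_energy,
#'   mean_db_total, sensitivity, specificity, region_sensitivity.
#' @export
crossvalidate <- function(samples, n_folds = 11, seed = 1, ...) {
  n <- length(samples)
  if (n < n_folds) stop("fewer samples than folds")
  folds <- with_local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  rows <- lapply(seq_len(n_folds), function(fd) {
    test_idx <- which(folds == fd)
    params <- learn_roi_detector(samples[-test_idx], ...)
    evals <- lapply(samples[test_idx], function(s) {
      det <- detect(s$image, params)
      conf <- pixel_confusion(det$mask, s$mask)
      reg <- region_sensitivity(det$mask, s$mask)
      en <- total_energy(sample_partition(s), det$labels, params$weighting)
      c(energy = en$energy, db = en$db_total, sens = conf$sensitivity,
        spec = conf$specificity, rsens = reg$region_sensitivity)
    })
    m <- do.call(rbind, evals)
    data.frame(fold = fd, n_test = length(test_idx),
               mean_energy = mean(m[, "energy"]),
               mean_db_total = mean(m[, "db"]),
               sensitivity = mean(m[, "sens"], na.rm = TRUE),
               specificity = mean(m[, "spec"], na.rm = TRUE),
               region_sensitivity = mean(m[, "rsens"], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
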