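#' Linear distance weighting for segmentation errors
#'
#' Misclassified pixels are weighted by their Euclidean distance to the
#' reference region, through \eqn{w(i) = offset + slope \cdot \min(i,
#' d_{max})}: errors far from the border are perceptually worse than
#' hairline boundary errors.
#'
#' @param slope per-pixel weight increment (> 0).
#' @param offset base weight (>= 0).
#' @param d_max distance cap in pixels.
#' @return object of class \code{distance_weighting}.
#' @export
distance_weighting <- function(slope = 1, offset = 1, d_max = 20) {
  if (slope <= 0) stop("slope must be > 0")
  if (offset < 0) stop("offset must be >= 0")
  if (d_max <= 0) stop("d_max must be > 0")
  structure(list(slope = slope, offset = offset, d_max = d_max),
            class = "distance_weighting")
}

#' Evaluate a distance weighting at given distances
#' @param w a \code{\link{distance_weighting}}.
#' @param i distances (pixels).
#' @return numeric weights.
#' @export
weight_at <- function(w, i) w$offset + w$slope * pmin(i, w$d_max)

# Euclidean distance from every pixel to the nearest pixel of the set
# (binary matrix); pixels inside the set get 0. The set must be non-empty.
dist_to_set <- function(set) {
  dm <- EBImage::distmap(1 - set, metric = "euclidean")
  matrix(as.numeric(dm), nrow(set), ncol(set))
}

#' Distance-weighted missing-foreground error
#'
#' Sum over the missing foreground pixels (in the ground truth g but not in
#' the prediction c) of the weight of their Euclidean distance to c, capped
#' at \code{d_max}. When c is empty every missing pixel is weighted at
#' \code{w(d_max)} (documented convention).
#'
#' @param g,c binary matrices of equal shape (ground truth, prediction).
#' @param w a \code{\link{distance_weighting}}.
#' @return non-negative weighted count.
#' @export
missing_foreground <- function(g, c, w = distance_weighting()) {
  stopifnot(all(dim(g) == dim(c)))
  miss <- g == 1 & c == 0
  if (!any(miss)) return(0)
  if (sum(c) == 0) return(sum(miss) * weight_at(w, w$d_max))
  d <- dist_to_set(c)
  sum(weight_at(w, d[miss]))
}

#' Distance-weighted added-background error
#'
#' Mirror of \code{\link{missing_foreground}} with the roles swapped: sums
#' the weights of the false foreground pixels (in the prediction c but not
#' in the ground truth g) by their Euclidean distance to g. When g is empty
#' every added pixel is weighted at \code{w(d_max)}.
#'
#' @inheritParams missing_foreground
#' @return non-negative weighted count.
#' @export
added_background <- function(g, c, w = distance_weighting()) {
  missing_foreground(g = c, c = g, w = w)
}

#' Foreground-background perceptual segmentation quality
#'
#' Combines the missing-foreground and added-background weighted errors of
#' a foreground-background segmentation into a raw sum, a normalized value
#' in [0, 1] (divided by image area times the maximal pixel weight), and a
#' decibel score \eqn{10 \log_{10}(normalized + 10^{-7})}. A perfect
#' segmentation reports the dB floor of -70 dB; all dB values are capped at
#' 0.
#'
#' @inheritParams missing_foreground
#' @param w_mf,w_ab distance weightings for the two error types.
#' @return list with \code{q_mf}, \code{q_ab}, \code{raw},
#'   \code{normalized}, \code{db}.
#' @export
fg_quality <- function(g, c, w_mf = distance_weighting(), w_ab = w_mf) {
  q_mf <- missing_foreground(g, c, w_mf)
  q_ab <- added_background(g, c, w_ab)
  raw <- q_mf + q_ab
  denom <- length(g) * max(weight_at(w_mf, w_mf$d_max),
                           weight_at(w_ab, w_ab$d_max))
  normalized <- raw / denom
  list(q_mf = q_mf, q_ab = q_ab, raw = raw, normalized = normalized,
       db = min(10 * log10(normalized + 1e-7), 0))
}

# normalize partitions to an integer label matrix; a list of disjoint
# binary masks becomes labels 1..Q (pixels in no mask stay 0)
as_label_matrix <- function(x) {
  if (is.matrix(x) && !is.list(x)) return(matrix(as.integer(x), nrow(x)))
  lab <- matrix(0L, nrow(x[[1]]), ncol(x[[1]]))
  for (i in seq_along(x)) {
    if (any(lab[x[[i]] == 1] != 0L)) stop("partition masks must be disjoint")
    lab[x[[i]] == 1] <- i
  }
  lab
}

#' Maximal-overlap region correspondence
#'
#' Pairs every ground-truth region with the segmentation region of maximal
#' overlap; pairs are made unique greedily in descending overlap (a region
#' already claimed leaves later claimants uncoupled). Regions with no
#' overlap stay uncoupled.
#'
#' @param G ground-truth partition: integer label matrix or list of
#'   disjoint binary masks.
#' @param C still-segmentation label matrix (or list of masks).
#' @return list with \code{pairs} (data.frame g, c, overlap),
#'   \code{uncoupled_g}, \code{uncoupled_c} (integer label vectors).
#' @export
match_regions <- function(G, C) {
  gl <- as_label_matrix(G); cl <- as_label_matrix(C)
  stopifnot(all(dim(gl) == dim(cl)))
  gids <- sort(setdiff(unique(as.vector(gl)), 0L))
  cids <- sort(setdiff(unique(as.vector(cl)), 0L))
  inside <- gl != 0L & cl != 0L
  if (any(inside)) {
    ov <- table(g = gl[inside], c = cl[inside])
  } else ov <- table(g = integer(0), c = integer(0))
  cand <- data.frame(g = integer(0), c = integer(0), overlap = numeric(0))
  for (g in gids) {
    grow <- if (as.character(g) %in% rownames(ov)) ov[as.character(g), , drop = TRUE] else NULL
    if (is.null(grow) || length(grow) == 0 || max(grow) == 0) next
    best <- which.max(grow) # first maximal column: lowest c id on ties
    cand <- rbind(cand, data.frame(
      g = g, c = as.integer(colnames(ov)[best]), overlap = as.numeric(grow[best])))
  }
  cand <- cand[order(-cand$overlap, cand$g, cand$c), , drop = FALSE]
  taken_c <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$c[i] %in% taken_c)) {
      keep[i] <- TRUE
      taken_c <- c(taken_c, cand$c[i])
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       uncoupled_g = setdiff(gids, pairs$g),
       uncoupled_c = setdiff(cids, pairs$c))
}

#' Boundary-inaccuracy error over matched region pairs
#'
#' Sum of the raw foreground-background quality over the corresponding
#' (ground truth, segmentation) region pairs.
#'
#' @param G,C partitions as in \code{\link{match_regions}}.
#' @param matching result of \code{\link{match_regions}} (recomputed when
#'   omitted).
#' @param w_mf,w_ab distance weightings.
#' @return list with \code{e_bl} and the per-pair \code{q_mf}, \code{q_ab}
#'   totals.
#' @export
boundary_inaccuracy <- function(G, C, matching = NULL,
                                w_mf = distance_weighting(), w_ab = w_mf) {
  gl <- as_label_matrix(G); cl <- as_label_matrix(C)
  if (is.null(matching)) matching <- match_regions(gl, cl)
  e <- 0; mf <- 0; ab <- 0
  for (i in seq_len(nrow(matching$pairs))) {
    gmask <- (gl == matching$pairs$g[i]) * 1
    cmask <- (cl == matching$pairs$c[i]) * 1
    q <- fg_quality(gmask, cmask, w_mf, w_ab)
    e <- e + q$raw; mf <- mf + q$q_mf; ab <- ab + q$q_ab
  }
  list(e_bl = e, q_mf = mf, q_ab = ab)
}

#' Over-segmentation error
#'
#' Uncoupled segmentation regions are penalized as false foreground against
#' a black (empty) reference: every pixel of an uncoupled predicted region
#' is weighted at \code{w(d_max)}.
#'
#' @param C segmentation partition.
#' @param uncoupled_c integer labels of the uncoupled regions of C.
#' @param w distance weighting.
#' @return non-negative error.
#' @export
oversegmentation_error <- function(C, uncoupled_c, w = distance_weighting()) {
  if (length(uncoupled_c) == 0) return(0)
  cl <- as_label_matrix(C)
  u <- matrix(as.numeric(cl %in% uncoupled_c), nrow(cl))
  added_background(g = matrix(0, nrow(cl), ncol(cl)), c = u, w = w)
}

#' Under-segmentation error
#'
#' Symmetric to \code{\link{oversegmentation_error}}: uncoupled
#' ground-truth regions count as missing foreground against an empty
#' prediction.
#'
#' @param G ground-truth partition.
#' @param uncoupled_g integer labels of the uncoupled regions of G.
#' @param w distance weighting.
#' @return non-negative error.
#' @export
undersegmentation_error <- function(G, uncoupled_g, w = distance_weighting()) {
  if (length(uncoupled_g) == 0) return(0)
  gl <- as_label_matrix(G)
  u <- matrix(as.numeric(gl %in% uncoupled_g), nrow(gl))
  missing_foreground(g = u, c = matrix(0, nrow(gl), ncol(gl)), w = w)
}

#' Total perceptual segmentation energy
#'
#' The supervised learning energy: the unweighted sum of the boundary
#' inaccuracy over matched region pairs, the over-segmentation error and
#' the under-segmentation error, together with normalized decibel scores
#' for the missing-foreground, added-background and total errors.
#'
#' @param G ground-truth partition (label matrix or list of disjoint
#'   masks).
#' @param C still-segmentation partition.
#' @param w_mf,w_ab distance weightings.
#' @return object of class \code{quality_report}: fields \code{q_mf},
#'   \code{q_ab}, \code{e_bl}, \code{e_ov}, \code{e_un}, \code{energy},
#'   \code{db_mf}, \code{db_ab}, \code{db_total}.
#' @export
total_energy <- function(G, C, w_mf = distance_weighting(), w_ab = w_mf) {
  gl <- as_label_matrix(G); cl <- as_label_matrix(C)
  m <- match_regions(gl, cl)
  bl <- boundary_inaccuracy(gl, cl, m, w_mf, w_ab)
  e_ov <- oversegmentation_error(cl, m$uncoupled_c, w_ab)
  e_un <- undersegmentation_error(gl, m$uncoupled_g, w_mf)
  q_mf <- bl$q_mf + e_un
  q_ab <- bl$q_ab + e_ov
  denom <- length(gl) * max(weight_at(w_mf, w_mf$d_max),
                            weight_at(w_ab, w_ab$d_max))
  db <- function(x) min(10 * log10(x / denom + 1e-7), 0)
  structure(list(
    q_mf = q_mf, q_ab = q_ab, e_bl = bl$e_bl, e_ov = e_ov, e_un = e_un,
    energy = bl$e_bl + e_ov + e_un, n_pairs = nrow(m$pairs),
    db_mf = db(q_mf), db_ab = db(q_ab), db_total = db(q_mf + q_ab)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Perceptual segmentation quality\n")
  cat(sprintf("  matched pairs: %d\n", x$n_pairs))
  cat(sprintf("  e_bl = %.2f, e_ov = %.2f, e_un = %.2f, energy = %.2f\n",
              x$e_bl, x$e_ov, x$e_un, x$energy))
  cat(sprintf("  MF = %.1f dB, AB = %.1f dB, total = %.1f dB\n",
              x$db_mf, x$db_ab, x$db_total))
  invisible(x)
}
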