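#' Parameters of the graph-based still-segmentation
#'
#' @param k scale factor (intensity units, on the 0-255 scale, times
#'   pixels); larger k prefers larger components via the size-dependent
#'   threshold k/|c|.
#' @param smooth_sigma Gaussian pre-smoothing in pixels (0 disables).
#' @param min_size minimum region size in pixels; smaller regions are
#'   merged with their lowest-weight-edge neighbour in a post-pass.
#' @param connectivity pixel adjacency, 4 or 8.
#' @return object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(k = 500, smooth_sigma = 0.8, min_size = 20,
                                connectivity = 4) {
  if (k <= 0) stop("k must be > 0")
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (min_size < 1) stop("min_size must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(k = k, smooth_sigma = smooth_sigma,
                 min_size = as.integer(round(min_size)),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Pixel-adjacency graph of a scalar image
#'
#' One weighted edge per adjacent pixel pair; the weight is the absolute
#' intensity difference on the 0-255 scale (in-memory images are [0, 1]).
#' Pixel indices are column-major and 1-based.
#'
#' @param channel scalar image matrix in [0, 1].
#' @param connectivity 4 or 8.
#' @return data.frame with columns \code{p}, \code{q} (p < q) and \code{w}.
#' @export
build_graph <- function(channel, connectivity = 4) {
  H <- nrow(channel); W <- ncol(channel)
  idx <- matrix(seq_len(H * W), H, W)
  v <- as.vector(channel) * 255
  pairs <- rbind(
    cbind(as.vector(idx[-H, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE])),
    cbind(as.vector(idx[, -W, drop = FALSE]), as.vector(idx[, -1, drop = FALSE]))
  )
  if (connectivity == 8) {
    pairs <- rbind(pairs,
      cbind(as.vector(idx[-H, -W, drop = FALSE]), as.vector(idx[-1, -1, drop = FALSE])),
      cbind(as.vector(idx[-1, -W, drop = FALSE]), as.vector(idx[-H, -1, drop = FALSE]))
    )
  }
  p <- pmin(pairs[, 1], pairs[, 2]); q <- pmax(pairs[, 1], pairs[, 2])
  data.frame(p = p, q = q, w = abs(v[p] - v[q]))
}

#' Graph-based still-segmentation (Felzenszwalb-Huttenlocher merge rule)
#'
#' Edges are processed in nondecreasing weight order (ties broken by the
#' column-major index of the endpoints, for platform determinism); two
#' components merge when the between-region difference, i.e. the connecting
#' edge weight, does not exceed
#' \eqn{\min(Int(c_1) + k/|c_1|,\; Int(c_2) + k/|c_2|)}, where Int(c) is the
#' largest merge weight inside c. Afterwards every region smaller than
#' \code{min_size} is merged with its lowest-weight-edge neighbour and
#' labels are renumbered consecutively from 1 by first occurrence.
#'
#' @param channel scalar image matrix in [0, 1] (use
#'   \code{\link{intensity_channel}} for RGB input).
#' @param params a \code{\link{segmentation_params}}.
#' @return integer label matrix with attribute \code{n_regions}.
#' @export
felzenszwalb_segment <- function(channel, params = segmentation_params()) {
  if (nrow(channel) < 2 || ncol(channel) < 2) stop("image must be >= 2x2")
  x <- channel
  if (params$smooth_sigma > 0)
    x <- matrix(as.numeric(EBImage::gblur(x, sigma = params$smooth_sigma)),
                nrow(x), ncol(x))
  labels <- fh_segment_cpp(x * 255, params$k, params$min_size,
                           params$connectivity)
  n <- attr(labels, "n_regions")
  out <- matrix(as.integer(labels), nrow(channel), ncol(channel))
  attr(out, "n_regions") <- n
  out
}

#' Number of regions of a label matrix
#' @param labels integer label matrix.
#' @return integer count.
#' @export
n_regions <- function(labels) {
  n <- attr(labels, "n_regions")
  if (is.null(n)) n <- length(unique(as.vector(labels)))
  n
}
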