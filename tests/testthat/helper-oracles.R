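# Independent brute-force references used to cross-check the implementation.

# Graph-merge segmentation reference: keeps only a label vector and the list
# of accepted edges; at every step the within-region difference of a
# component is recomputed by scanning the accepted edges lying inside it,
# and sizes by counting labels. No union-find, no incremental state.
oracle_fh <- function(img, k, min_size = 1, connectivity = 4) {
  g <- build_graph(img, connectivity)
  g <- g[order(g$w, g$p, g$q), ]
  n <- length(img)
  labels <- seq_len(n)
  acc_p <- integer(0); acc_w <- numeric(0)
  int_of <- function(lab) {
    w <- acc_w[labels[acc_p] == lab]
    if (length(w)) max(w) else 0
  }
  for (i in seq_len(nrow(g))) {
    a <- labels[g$p[i]]; b <- labels[g$q[i]]
    if (a == b) next
    ta <- int_of(a) + k / sum(labels == a)
    tb <- int_of(b) + k / sum(labels == b)
    if (g$w[i] <= min(ta, tb)) {
      labels[labels == b] <- a
      acc_p <- c(acc_p, g$p[i]); acc_w <- c(acc_w, g$w[i])
    }
  }
  if (min_size > 1) {
    for (i in seq_len(nrow(g))) {
      a <- labels[g$p[i]]; b <- labels[g$q[i]]
      if (a == b) next
      if (sum(labels == a) < min_size || sum(labels == b) < min_size)
        labels[labels == b] <- a
    }
  }
  matrix(match(labels, unique(labels)), nrow(img), ncol(img))
}

# plain double-loop 2-D convolution with replicate padding
naive_conv_replicate <- function(x, kern) {
  H <- nrow(x); W <- ncol(x)
  kh <- (nrow(kern) - 1) / 2; kw <- (ncol(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    s <- 0
    for (i in -kh:kh) for (j in -kw:kw) {
      rr <- min(max(r + i, 1), H); cc <- min(max(c + j, 1), W)
      s <- s + x[rr, cc] * kern[kh + 1 + i, kw + 1 + j]
    }
    out[r, c] <- s
  }
  out
}

# loop version of the binomial reduce (smooth + decimate)
naive_reduce <- function(x) {
  k1 <- c(1, 4, 6, 4, 1) / 16
  kern <- outer(k1, k1)
  s <- naive_conv_replicate(x, kern)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

# loop version of pixel-center bilinear resampling
naive_resample <- function(x, H, W) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    tr <- (r - 0.5) * h / H; tc <- (c - 0.5) * w / W
    lr <- floor(tr + 0.5); lc <- floor(tc + 0.5)
    fr <- min(max(tr - (lr - 0.5), 0), 1)
    fc <- min(max(tc - (lc - 0.5), 0), 1)
    lr <- min(max(lr, 1), h); lc <- min(max(lc, 1), w)
    lr2 <- min(lr + 1, h); lc2 <- min(lc + 1, w)
    out[r, c] <- (1 - fr) * (1 - fc) * x[lr, lc] + fr * (1 - fc) * x[lr2, lc] +
      (1 - fr) * fc * x[lr, lc2] + fr * fc * x[lr2, lc2]
  }
  out
}

# mirror (no edge repeat) index into 1..n
mirror_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# loop version of the windowed-histogram entropy map (bits / log2(bins))
naive_entropy <- function(x, window, bins) {
  H <- nrow(x); W <- ncol(x)
  lo <- -(window - 1) %/% 2; hi <- window %/% 2
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    vals <- numeric(0)
    for (i in lo:hi) for (j in lo:hi)
      vals <- c(vals, x[mirror_idx(r + i, H), mirror_idx(c + j, W)])
    b <- pmin(floor(vals * bins), bins - 1)
    p <- table(b) / length(b)
    out[r, c] <- -sum(p * log2(p))
  }
  out / log2(bins)
}

# brute-force distance-weighted missing foreground
naive_mf <- function(g, c, w) {
  miss <- which(g == 1 & c == 0, arr.ind = TRUE)
  if (nrow(miss) == 0) return(0)
  ref <- which(c == 1, arr.ind = TRUE)
  tot <- 0
  for (i in seq_len(nrow(miss))) {
    d <- if (nrow(ref) == 0) w$d_max
    else sqrt(min((ref[, 1] - miss[i, 1])^2 + (ref[, 2] - miss[i, 2])^2))
    tot <- tot + weight_at(w, min(d, w$d_max))
  }
  tot
}

# brute-force positive local maxima (plateaus once) of a map rescaled by max
naive_peak_values <- function(m) {
  m <- m / max(m)
  H <- nrow(m); W <- ncol(m)
  is_peak <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (m[r, c] <= 0) next
    nb <- c()
    for (i in -1:1) for (j in -1:1) {
      rr <- r + i; cc <- c + j
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && !(i == 0 && j == 0))
        nb <- c(nb, m[rr, cc])
    }
    is_peak[r, c] <- all(m[r, c] >= nb)
  }
  if (!any(is_peak)) return(numeric(0))
  lab <- historoi:::label_components_cpp(matrix(as.integer(is_peak), H), 8L)
  vapply(seq_len(attr(lab, "n_components")),
         function(i) m[which(lab == i)[1]], numeric(1))
}

# small deterministic training suites used by learning tests; islet radii
# scale with the field size so non-overlapping placement always succeeds
make_training_suite <- function(n, seed, size = 80, variant = "default",
                                n_islets = 2,
                                radius = round(size * c(0.11, 0.17))) {
  fixture_suite(n, seed = seed, width = size, height = size,
                n_islets = n_islets, islet_radius_range = radius,
                variant = variant)
}
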