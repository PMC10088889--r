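# Independent brute-force oracles used across the suite.

# O(N * |boundary|) nearest-boundary scan
brute_distance_map <- function(points, height, width) {
  out <- matrix(0, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      out[r, c] <- sqrt(min((points$row - (r - 1))^2 + (points$col - (c - 1))^2))
    }
  }
  out
}

# inner-boundary scan by explicit neighbour enumeration (4-connectivity)
brute_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- list()
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (mask[r, c] != 1) next
      nb <- c(if (r > 1) mask[r - 1, c] else 0,
              if (r < h) mask[r + 1, c] else 0,
              if (c > 1) mask[r, c - 1] else 0,
              if (c < w) mask[r, c + 1] else 0)
      if (any(nb == 0)) pts[[length(pts) + 1]] <- c(r - 1, c - 1)
    }
  }
  if (length(pts) == 0) return(data.frame(row = integer(), col = integer()))
  m <- do.call(rbind, pts)
  data.frame(row = m[, 1], col = m[, 2])
}

# O(|A| * |B|) pairwise directed Hausdorff
brute_hausdorff <- function(a, b) {
  h_dir <- function(x, y) {
    mx <- 0
    for (i in seq_len(nrow(x))) {
      mn <- Inf
      for (j in seq_len(nrow(y))) {
        d <- sqrt((x$row[i] - y$row[j])^2 + (x$col[i] - y$col[j])^2)
        if (d < mn) mn <- d
      }
      if (mn > mx) mx <- mn
    }
    mx
  }
  max(h_dir(a, b), h_dir(b, a))
}

# per-pixel counting of the confusion cells
brute_confusion <- function(pred, target) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && target[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && target[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && target[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && target[i] == 1) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# random mask with at least one foreground and one background pixel
random_mask <- function(h, w, p = 0.4) {
  repeat {
    m <- matrix(rbinom(h * w, 1, p), h, w)
    s <- sum(m)
    if (s > 0 && s < h * w) return(m)
  }
}

# central finite-difference check of grad at n random pixels; returns the
# maximum relative error
fd_grad_check <- function(value_fn, grad, x, n = 20, h = 1e-6) {
  idx <- sample(length(x), min(n, length(x)))
  maxrel <- 0
  for (i in idx) {
    x1 <- x; x1[i] <- x[i] + h
    x2 <- x; x2[i] <- x[i] - h
    fd <- (value_fn(x1) - value_fn(x2)) / (2 * h)
    an <- grad[i]
    maxrel <- max(maxrel, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
  }
  maxrel
}

# binary disk of given radius centred in an n x n grid
disk_mask <- function(n, radius, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(as.numeric((g$r - cy)^2 + (g$c - cx)^2 <= radius^2), n, n)
  m
}

# k-pointed star of comparable area (polar rose)
star_mask <- function(n, r0, k = 8, amp = 0.6, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  th <- atan2(g$r - cy, g$c - cx)
  rad <- sqrt((g$r - cy)^2 + (g$c - cx)^2)
  matrix(as.numeric(rad <= r0 * (1 + amp * cos(k * th))), n, n)
}
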