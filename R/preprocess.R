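#' Augmentation specification
#'
#' Bundles the tunable parameters of the augmentation pipeline. Kernel sizes
#' must be odd. Defaults: blur kernels {3,5,7}, CLAHE clip limit 2 on an 8x8
#' tile grid, elastic field sigma 8 px with strength alpha 10, brightness and
#' contrast jitter of +/-10%, right-angle rotations plus flips.
#'
#' @param blur_kernels candidate odd Gaussian kernel sizes.
#' @param clahe_clip CLAHE clip limit (> 0).
#' @param clahe_tiles CLAHE tile grid size (scalar or length-2).
#' @param elastic_sigma Gaussian smoothing sd of the displacement field (px).
#' @param elastic_alpha displacement scaling factor (>= 0).
#' @param brightness_delta max additive brightness jitter.
#' @param contrast_delta max relative contrast jitter.
#' @param rotation_set allowed rotations in degrees.
#' @param seed integer seed.
#' @return list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(blur_kernels = c(3, 5, 7), clahe_clip = 2,
                              clahe_tiles = 8, elastic_sigma = 8,
                              elastic_alpha = 10, brightness_delta = 0.1,
                              contrast_delta = 0.1,
                              rotation_set = c(0, 90, 180, 270), seed = 1L) {
  if (any(blur_kernels %% 2 == 0)) stop("blur kernel sizes must be odd")
  if (elastic_alpha < 0) stop("elastic_alpha must be >= 0")
  if (elastic_sigma <= 0) stop("elastic_sigma must be > 0")
  structure(list(blur_kernels = blur_kernels, clahe_clip = clahe_clip,
                 clahe_tiles = rep(clahe_tiles, length.out = 2),
                 elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha,
                 brightness_delta = brightness_delta,
                 contrast_delta = contrast_delta,
                 rotation_set = rotation_set, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Keep the image quadrant containing the tumor
#'
#' Splits the image at `floor(h/2)` / `floor(w/2)` into four quadrants
#' (reading order: 1 top-left, 2 top-right, 3 bottom-left, 4 bottom-right)
#' and returns the quadrant with the largest tumor pixel count, enlarging the
#' foreground-to-background ratio before training. If the tumor straddles
#' quadrants the overlap fraction left outside the chosen quadrant is
#' reported in the result and as a message.
#'
#' @param image numeric matrix.
#' @param mask binary matrix with at least one foreground pixel.
#' @return list with `image`, `mask`, `index` (1-4) and `overlap_fraction`.
#' @export
quadrant_split <- function(image, mask) {
  assert_binary_mask(mask)
  check_shapes(image, mask, "image/mask")
  if (sum(mask) == 0) stop("empty mask: no tumor quadrant to select")
  h <- nrow(mask); w <- ncol(mask)
  hs <- floor(h / 2); ws <- floor(w / 2)
  rows <- list(seq_len(hs), seq((hs + 1), h))
  cols <- list(seq_len(ws), seq((ws + 1), w))
  counts <- c(sum(mask[rows[[1]], cols[[1]]]), sum(mask[rows[[1]], cols[[2]]]),
              sum(mask[rows[[2]], cols[[1]]]), sum(mask[rows[[2]], cols[[2]]]))
  idx <- which.max(counts)
  ri <- rows[[(idx - 1) %/% 2 + 1]]; ci <- cols[[(idx - 1) %% 2 + 1]]
  overlap <- 1 - counts[idx] / sum(mask)
  if (overlap > 0) {
    message(sprintf("tumor straddles quadrants: %.1f%% of foreground outside quadrant %d",
                    100 * overlap, idx))
  }
  list(image = image[ri, ci, drop = FALSE], mask = mask[ri, ci, drop = FALSE],
       index = idx, overlap_fraction = overlap)
}

# 1-D Gaussian kernel for a given odd size, sigma from the kernel size by the
# usual convention sigma = 0.3*((k-1)/2 - 1) + 0.8
gaussian_kernel_1d <- function(k, sigma = NULL) {
  if (k %% 2 == 0 || k < 1) stop("kernel size must be odd and >= 1")
  if (is.null(sigma)) sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  r <- (k - 1) / 2
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable 1-D convolution along rows and columns with replicate padding
sep_filter <- function(x, kern) {
  k <- length(kern)
  if (k == 1) return(x * kern)
  r <- (k - 1) / 2
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
  y <- matrix(0, h, w)
  for (o in seq_len(k)) y <- y + kern[o] * xp[o:(o + h - 1), , drop = FALSE]
  yp <- y[, c(rep(1, r), seq_len(w), rep(w, r)), drop = FALSE]
  z <- matrix(0, h, w)
  for (o in seq_len(k)) z <- z + kern[o] * yp[, o:(o + w - 1), drop = FALSE]
  z
}

#' Gaussian blur with a given kernel size
#'
#' Separable Gaussian filtering with edge-replicated padding; the standard
#' deviation follows the kernel size as `0.3*((k-1)/2 - 1) + 0.8`. `k = 1` is
#' the identity. Shape and value range are preserved.
#'
#' @param image numeric matrix.
#' @param kernel_size odd kernel size.
#' @param sigma optional explicit standard deviation.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(image, kernel_size, sigma = NULL) {
  sep_filter(image, gaussian_kernel_1d(kernel_size, sigma))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipped histograms and bilinear
#' interpolation between the tile mappings (delegates to the CLAHE
#' implementation in \pkg{EBImage}). Output is rescaled to the input's value
#' range.
#'
#' @param image numeric matrix with values in \[0,1\].
#' @param clip clip limit (> 0).
#' @param tiles tile grid (scalar or length 2: columns, rows).
#' @return equalized matrix in the input's range.
#' @export
clahe <- function(image, clip = 2, tiles = 8) {
  tiles <- rep(tiles, length.out = 2)
  rng <- range(image)
  if (diff(rng) == 0) return(image)
  x <- (image - rng[1]) / diff(rng)
  y <- EBImage::clahe(x, nx = tiles[1], ny = tiles[2], limit = clip,
                      keep.range = TRUE)
  y <- matrix(as.numeric(y), nrow(image), ncol(image))
  pmin(pmax(y, 0), 1) * diff(rng) + rng[1]
}

#' Min-max normalization to \[0,1\]
#'
#' @param image numeric matrix.
#' @return rescaled matrix (all-constant input maps to 0).
#' @export
normalize_minmax <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(image * 0)
  (image - rng[1]) / diff(rng)
}

# bilinear sampling of matrix x at fractional (row, col) positions
bilinear_sample <- function(x, rr, cc) {
  h <- nrow(x); w <- ncol(x)
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  r0 <- pmin(floor(rr), h - 1); c0 <- pmin(floor(cc), w - 1)
  fr <- rr - r0; fc <- cc - c0
  v00 <- x[cbind(r0, c0)]; v01 <- x[cbind(r0, c0 + 1)]
  v10 <- x[cbind(r0 + 1, c0)]; v11 <- x[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Elastic deformation of an image/mask pair
#'
#' Draws a uniform displacement field in (-1,1), smooths it with a Gaussian
#' of standard deviation `sigma`, scales it by `alpha`, and warps image
#' (bilinear) and mask (nearest-neighbour, preserving binarity) with the same
#' field. Fully deterministic given the seed; `alpha = 0` is the identity.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param sigma field smoothing sd in pixels (> 0).
#' @param alpha displacement strength (>= 0).
#' @param seed integer seed.
#' @return list with warped `image` and `mask`.
#' @export
elastic_deform <- function(image, mask, sigma = 8, alpha = 10, seed = 1L) {
  check_shapes(image, mask, "image/mask")
  if (sigma <= 0) stop("sigma must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  h <- nrow(image); w <- ncol(image)
  if (alpha == 0) return(list(image = image, mask = mask))
  set.seed(seed)
  k <- 2L * ceiling(2 * sigma) + 1L
  kern <- gaussian_kernel_1d(k, sigma)
  dr <- alpha * sep_filter(matrix(runif(h * w, -1, 1), h, w), kern)
  dc <- alpha * sep_filter(matrix(runif(h * w, -1, 1), h, w), kern)
  gr <- matrix(seq_len(h), h, w)
  gc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- gr + dr; cc <- gc + dc
  img2 <- matrix(bilinear_sample(image, as.numeric(rr), as.numeric(cc)), h, w)
  rn <- pmin(pmax(round(rr), 1), h)
  cn <- pmin(pmax(round(cc), 1), w)
  msk2 <- matrix(mask[cbind(as.numeric(rn), as.numeric(cn))], h, w)
  list(image = img2, mask = msk2)
}

# clockwise rotation by k*90 degrees
rot90k <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Photometric and geometric jitter
#'
#' Applies a random right-angle rotation and random horizontal/vertical flips
#' identically to image and mask, then additive brightness and multiplicative
#' contrast jitter (about the image mean) to the image only, clipped to
#' \[0,1\]. Deterministic given the seed; the mask stays binary.
#'
#' @inheritParams elastic_deform
#' @param spec an [augmentation_spec()].
#' @return list with jittered `image` and `mask`.
#' @export
photometric_geometric_jitter <- function(image, mask, spec = augmentation_spec(),
                                         seed = 1L) {
  check_shapes(image, mask, "image/mask")
  set.seed(seed)
  rot <- sample(spec$rotation_set, 1)
  image <- rot90k(image, rot / 90); mask <- rot90k(mask, rot / 90)
  if (runif(1) < 0.5) { image <- image[, ncol(image):1]; mask <- mask[, ncol(mask):1] }
  if (runif(1) < 0.5) { image <- image[nrow(image):1, ]; mask <- mask[nrow(mask):1, ] }
  b <- runif(1, -spec$brightness_delta, spec$brightness_delta)
  cfac <- 1 + runif(1, -spec$contrast_delta, spec$contrast_delta)
  m <- mean(image)
  image <- (image - m) * cfac + m + b
  list(image = pmin(pmax(image, 0), 1), mask = mask)
}

# morphological erosion/dilation with a diamond (4-connected) brush;
# zero-padded so the outside of the frame counts as background
morph_op <- function(mask, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (radius < 1) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  r <- as.integer(radius)
  p <- matrix(0, h + 2L * r, w + 2L * r)
  p[r + seq_len(h), r + seq_len(w)] <- mask
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "diamond")
  out <- if (op == "erode") EBImage::erode(p, brush) else EBImage::dilate(p, brush)
  matrix(as.numeric(out), nrow(p), ncol(p))[r + seq_len(h), r + seq_len(w)]
}

#' Derive an edge ground-truth band from a region mask
#'
#' A boundary band of the requested thickness obtained by morphology with a
#' diamond (4-connected) structuring element: dilation by `floor(t/2)` minus
#' erosion by `ceiling(t/2)`. Thickness 1 gives the inner boundary (the same
#' pixel set as [extract_boundary()] with 4-connectivity); larger values
#' thicken the band symmetrically outward and inward.
#'
#' @param mask binary matrix.
#' @param thickness band thickness in pixels (>= 1).
#' @return binary matrix of the edge band (empty for an empty mask).
#' @export
edge_ground_truth <- function(mask, thickness = 1) {
  assert_binary_mask(mask)
  if (thickness < 1) stop("thickness must be >= 1")
  if (sum(mask) == 0) return(mask * 0)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  dil <- morph_op(m, floor(thickness / 2), "dilate")
  ero <- morph_op(m, ceiling(thickness / 2), "erode")
  dil - ero
}

#' Apply the full augmentation pipeline to one image/mask pair
#'
#' Blur with a randomly chosen kernel, CLAHE, min-max normalization, elastic
#' deformation, then photometric/geometric jitter, all driven by one seed.
#'
#' @inheritParams elastic_deform
#' @param spec an [augmentation_spec()].
#' @return list with augmented `image` and `mask`.
#' @export
augment_pair <- function(image, mask, spec = augmentation_spec(), seed = 1L) {
  set.seed(seed)
  k <- sample(spec$blur_kernels, 1)
  sub_seeds <- sample.int(.Machine$integer.max, 2)
  image <- gaussian_blur(image, k)
  image <- clahe(image, spec$clahe_clip, spec$clahe_tiles)
  image <- normalize_minmax(image)
  ed <- elastic_deform(image, mask, spec$elastic_sigma, spec$elastic_alpha,
                       seed = sub_seeds[1])
  photometric_geometric_jitter(ed$image, ed$mask, spec, seed = sub_seeds[2])
}
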