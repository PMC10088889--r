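#' Generate one synthetic lesion sample
#'
#' Draws an MRI-like grayscale image with a single bright lesion on a textured
#' background with elliptical distractor structures, plus its binary mask and
#' 1-pixel edge ground truth. The lesion outline is a harmonic polar blob
#' `r(theta) = r0 * (1 + sum of low-order harmonics)`; `"spiculated"` samples
#' add a high-frequency spike harmonic (8-16 spikes, amplitude 0.25-0.5 of
#' `r0`) emulating the burred margins of malignant tumors, while `"smooth"`
#' samples keep only gentle low-order modulation as in benign tumors. The
#' foreground occupies roughly 1-8% of the pixels (small-target regime);
#' lesion intensity is about 0.8 with texture, background about 0.3 with
#' smoothed noise. Fully deterministic per seed.
#'
#' @param size image side length (>= 32).
#' @param shape_label `"smooth"` or `"spiculated"`.
#' @param seed integer seed.
#' @param fg_range admissible foreground fraction range.
#' @return list of class `synthetic_sample` with `image`, `mask`, `edge`,
#'   `shape_label`, and `params` (center, base radius, spike count/amplitude,
#'   foreground fraction, noise sigma, seed).
#' @export
generate_sample <- function(size = 64, shape_label = c("smooth", "spiculated"),
                            seed = 1L, fg_range = c(0.01, 0.08)) {
  if (size < 32) stop("size must be >= 32")
  shape_label <- match.arg(shape_label)
  set.seed(seed)
  cy <- runif(1, 0.35, 0.65) * size
  cx <- runif(1, 0.35, 0.65) * size
  frac_target <- runif(1, 0.02, 0.06)
  r0 <- size * sqrt(frac_target / pi)
  amps <- runif(3, 0, 0.05)
  phases <- runif(3, 0, 2 * pi)
  spike_count <- 0L; spike_amp <- 0
  if (shape_label == "spiculated") {
    spike_count <- sample(8:16, 1)
    spike_amp <- runif(1, 0.25, 0.5)
    spike_phase <- runif(1, 0, 2 * pi)
  }
  gr <- matrix(seq_len(size), size, size)
  gc <- matrix(seq_len(size), size, size, byrow = TRUE)
  th <- atan2(gr - cy, gc - cx)
  dist <- sqrt((gr - cy)^2 + (gc - cx)^2)
  radius_at <- function(r0) {
    r <- r0 * (1 + amps[1] * cos(2 * th + phases[1]) +
                 amps[2] * cos(3 * th + phases[2]) +
                 amps[3] * cos(4 * th + phases[3]))
    if (shape_label == "spiculated") {
      r <- r + r0 * spike_amp * cos(spike_count * th + spike_phase)
    }
    r
  }
  mask <- 1 * (dist <= radius_at(r0))
  frac <- mean(mask)
  for (i in 1:10) {
    if (frac >= fg_range[1] && frac <= fg_range[2]) break
    r0 <- r0 * sqrt(mean(fg_range) / max(frac, 1e-6))
    mask <- 1 * (dist <= radius_at(r0))
    frac <- mean(mask)
  }
  noise_sigma <- 0.05
  bg <- 0.3 + gaussian_blur(matrix(rnorm(size^2, 0, 0.25), size, size), 7, sigma = 2)
  # 1-3 elliptical glandular distractors away from the lesion
  for (d in seq_len(sample(1:3, 1))) {
    dcy <- runif(1, 0.1, 0.9) * size; dcx <- runif(1, 0.1, 0.9) * size
    a <- runif(1, 0.05, 0.12) * size; b <- runif(1, 0.03, 0.08) * size
    ang <- runif(1, 0, pi)
    u <- (gr - dcy) * cos(ang) + (gc - dcx) * sin(ang)
    v <- -(gr - dcy) * sin(ang) + (gc - dcx) * cos(ang)
    ell <- 1 * ((u / a)^2 + (v / b)^2 <= 1) * (1 - mask)
    bg <- bg + runif(1, 0.15, 0.3) * ell
  }
  img <- bg * (1 - mask) + mask * (0.8 + matrix(rnorm(size^2, 0, noise_sigma), size, size))
  img <- gaussian_blur(img, 3, sigma = 0.6)
  img <- pmin(pmax(img, 0), 1)
  structure(list(
    image = img, mask = mask, edge = edge_ground_truth(mask, 1),
    shape_label = shape_label,
    params = list(center = c(cy, cx), r0 = r0, spike_count = spike_count,
                  spike_amp = spike_amp, fg_fraction = frac,
                  noise_sigma = noise_sigma, seed = seed)),
    class = "synthetic_sample")
}

#' Generate a stratified synthetic dataset
#'
#' @param n number of samples.
#' @param smooth_fraction fraction of smooth-labelled samples (stratification
#'   is exact: `round(n * smooth_fraction)` smooth samples).
#' @param size image side length.
#' @param seed master seed; per-sample seeds are drawn from it and recorded
#'   in the manifest so any sample can be regenerated bit-identically.
#' @param dir optional output directory; when given, writes `images/`,
#'   `masks/`, `edges/` PNG files and `manifest.csv`.
#' @return list with `samples` (list of [generate_sample()] results) and
#'   `manifest` (data.frame: id, label, seed, size, r0, spike_count,
#'   spike_amp, fg_fraction).
#' @export
generate_dataset <- function(n, smooth_fraction = 0.5, size = 64, seed = 1L,
                             dir = NULL) {
  set.seed(seed)
  if (n == 0) {
    return(list(samples = list(),
                manifest = data.frame(id = character(), label = character(),
                                      seed = integer(), size = integer(),
                                      r0 = numeric(), spike_count = integer(),
                                      spike_amp = numeric(), fg_fraction = numeric())))
  }
  n_smooth <- round(n * smooth_fraction)
  labels <- sample(c(rep("smooth", n_smooth), rep("spiculated", n - n_smooth)))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  samples <- mapply(function(lab, sd) generate_sample(size, lab, sd),
                    labels, seeds, SIMPLIFY = FALSE)
  names(samples) <- sprintf("sample_%03d", seq_len(n))
  manifest <- data.frame(
    id = names(samples), label = labels, seed = seeds, size = size,
    r0 = vapply(samples, function(s) s$params$r0, numeric(1)),
    spike_count = vapply(samples, function(s) s$params$spike_count, integer(1)),
    spike_amp = vapply(samples, function(s) s$params$spike_amp, numeric(1)),
    fg_fraction = vapply(samples, function(s) s$params$fg_fraction, numeric(1)),
    row.names = NULL)
  if (!is.null(dir)) {
    for (sub in c("images", "masks", "edges")) {
      dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_len(n)) {
      id <- names(samples)[i]
      png::writePNG(samples[[i]]$image, file.path(dir, "images", paste0(id, ".png")))
      png::writePNG(samples[[i]]$mask, file.path(dir, "masks", paste0(id, ".png")))
      png::writePNG(samples[[i]]$edge, file.path(dir, "edges", paste0(id, ".png")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

# perimeter estimate: number of 4-adjacent foreground/background pixel pairs,
# counting the outside of the frame as background
perimeter_crossings <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  sum(abs(p[1:(h + 1L), 2:(w + 1L)] - p[2:(h + 2L), 2:(w + 1L)])) +
    sum(abs(p[2:(h + 1L), 1:(w + 1L)] - p[2:(h + 1L), 2:(w + 2L)]))
}

#' Segmentation-derived shape features
#'
#' Features used by the benign/malignant shape classifier: foreground area
#' fraction (the tumor-to-region ratio), discrete compactness `P^2/(4*pi*A)`
#' (1 for a continuous disk, larger for irregular shapes; the digital
#' perimeter overestimates slightly), mean image-gradient magnitude on the
#' boundary pixels, and eccentricity of the best-fitting ellipse from second
#' moments.
#'
#' @param mask non-empty binary matrix.
#' @param image grayscale matrix of the same shape.
#' @return named numeric vector `area_fraction`, `compactness`,
#'   `boundary_gradient`, `eccentricity`.
#' @export
shape_features <- function(mask, image) {
  assert_binary_mask(mask)
  check_shapes(image, mask, "image/mask")
  A <- sum(mask)
  if (A == 0) stop("empty mask: shape features are undefined")
  P <- perimeter_crossings(mask)
  comp <- P^2 / (4 * pi * A)
  b <- extract_boundary(mask)
  h <- nrow(image); w <- ncol(image)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gm <- sqrt(gx^2 + gy^2)
  bg <- mean(gm[cbind(b$row + 1L, b$col + 1L)])
  idx <- which(mask == 1, arr.ind = TRUE)
  mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
  m20 <- mean((idx[, 1] - mu_r)^2); m02 <- mean((idx[, 2] - mu_c)^2)
  m11 <- mean((idx[, 1] - mu_r) * (idx[, 2] - mu_c))
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(1 - l2 / l1, 0))
  c(area_fraction = A / length(mask), compactness = comp,
    boundary_gradient = bg, eccentricity = ecc)
}

#' Stratified train/test split of a synthetic dataset
#'
#' The default keeps roughly 31% of the samples for training and 69% for
#' testing, the small-training-set regime these losses are designed for.
#'
#' @param dataset result of [generate_dataset()].
#' @param train_fraction fraction of samples used for training.
#' @param seed split seed.
#' @return list with `train` and `test` sample lists and index vectors.
#' @export
split_dataset <- function(dataset, train_fraction = 114 / 365, seed = 1L) {
  n <- length(dataset$samples)
  set.seed(seed)
  n_train <- max(1L, round(n * train_fraction))
  idx <- sample.int(n, n_train)
  list(train = dataset$samples[idx], test = dataset$samples[-idx],
       train_idx = sort(idx), test_idx = setdiff(seq_len(n), idx))
}
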