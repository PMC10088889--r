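#' @useDynLib boundseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm
NULL

# probability clamp applied before any logarithm
.CLAMP <- 1e-7

clamp01 <- function(p, eps = .CLAMP) pmin(pmax(p, eps), 1 - eps)

check_shapes <- function(a, b, what = "pred/target") {
  if (!all(dim(a) == dim(b))) {
    stop(sprintf("shape mismatch (%s): %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

#' Compound-loss specification
#'
#' Holds the three mixture weights of the focal boundary Dice loss together
#' with the focal exponent and the Dice smoothing constant. Weights are
#' normalized to sum to 1 on construction. The defaults are the published
#' operating point: Dice 0.5, focal 0.3, boundary 0.2.
#'
#' @param lambda_dice,lambda_focal,lambda_boundary non-negative mixture weights.
#' @param gamma focal exponent (>= 0), default 2.
#' @param alpha focal class-balance factor in (0,1), default 0.25.
#' @param epsilon Dice smoothing constant, default 1e-6.
#' @return a list of class `compound_spec`.
#' @export
compound_spec <- function(lambda_dice = 0.5, lambda_focal = 0.3,
                          lambda_boundary = 0.2, gamma = 2, alpha = 0.25,
                          epsilon = 1e-6) {
  w <- c(lambda_dice, lambda_focal, lambda_boundary)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (sum(w) <= 0) stop("at least one loss weight must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  w <- w / sum(w)
  structure(list(lambda_dice = w[1], lambda_focal = w[2], lambda_boundary = w[3],
                 gamma = gamma, alpha = alpha, epsilon = epsilon),
            class = "compound_spec")
}

#' Shape-aware loss specification
#'
#' @param o stability constant (> 0) in the compactness term.
#' @param margin contrastive distance margin (> 0) of the smoothness term.
#' @param embed_dim dimension of the low-dimensional embedding space.
#' @param weights length-3 weights for (cross-entropy, compactness,
#'   smoothness); equal by default.
#' @return a list of class `shape_spec`.
#' @export
shape_spec <- function(o = 1e-6, margin = 1, embed_dim = 8,
                       weights = c(1, 1, 1)) {
  if (o <= 0) stop("o must be > 0")
  if (margin <= 0) stop("margin must be > 0")
  structure(list(o = o, margin = margin, embed_dim = as.integer(embed_dim),
                 weights = weights), class = "shape_spec")
}

# ---- Dice ---------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred*target) + eps) / (sum(pred) + sum(target) + eps)`.
#'
#' @param pred probability matrix in \[0,1\].
#' @param target binary matrix of the same shape.
#' @param epsilon smoothing constant.
#' @return scalar loss in \[0, 1).
#' @export
dice_loss <- function(pred, target, epsilon = 1e-6) {
  dice_loss_grad(pred, target, epsilon)$value
}

#' @rdname dice_loss
#' @return for `dice_loss_grad`, a list with `value` and `grad` (the analytic
#'   gradient with respect to `pred`).
#' @export
dice_loss_grad <- function(pred, target, epsilon = 1e-6) {
  check_shapes(pred, target)
  num <- 2 * sum(pred * target) + epsilon
  den <- sum(pred) + sum(target) + epsilon
  grad <- -(2 * target * den - num) / den^2
  list(value = 1 - num / den, grad = grad)
}

# ---- Focal --------------------------------------------------------------

#' Alpha-balanced focal loss
#'
#' Mean over all pixels of `-alpha * (1-p)^gamma * log(p)` on positives and
#' `-(1-alpha) * p^gamma * log(1-p)` on negatives, with `p` clamped away from
#' 0 and 1 before the logarithm. At `gamma = 0` this reduces to an
#' alpha-weighted binary cross-entropy; increasing `gamma` damps the
#' contribution of well-classified pixels so that hard (typically
#' boundary-adjacent) pixels dominate, which is how the edge head is
#' supervised under severe class imbalance.
#'
#' @inheritParams dice_loss
#' @param gamma focusing exponent (>= 0).
#' @param alpha balance factor in (0,1) applied to the positive class.
#' @return scalar loss (>= 0).
#' @export
focal_loss <- function(pred, target, gamma = 2, alpha = 0.25) {
  focal_loss_grad(pred, target, gamma, alpha)$value
}

#' @rdname focal_loss
#' @export
focal_loss_grad <- function(pred, target, gamma = 2, alpha = 0.25) {
  check_shapes(pred, target)
  if (gamma < 0) stop("gamma must be >= 0")
  p <- clamp01(pred)
  n <- length(p)
  pos <- target == 1
  v <- numeric(n); dim(v) <- dim(p)
  g <- numeric(n); dim(g) <- dim(p)
  # positives: -alpha (1-p)^g log p
  pp <- p[pos]
  v[pos] <- -alpha * (1 - pp)^gamma * log(pp)
  gt <- if (gamma == 0) 0 else gamma * (1 - pp)^(gamma - 1) * log(pp)
  g[pos] <- alpha * gt - alpha * (1 - pp)^gamma / pp
  # negatives: -(1-alpha) p^g log(1-p)
  pn <- p[!pos]
  v[!pos] <- -(1 - alpha) * pn^gamma * log(1 - pn)
  gtn <- if (gamma == 0) 0 else gamma * pn^(gamma - 1) * log(1 - pn)
  g[!pos] <- -(1 - alpha) * (gtn - pn^gamma / (1 - pn))
  # clamp saturates the loss outside [eps, 1-eps]; zero gradient there
  g[pred < .CLAMP | pred > 1 - .CLAMP] <- 0
  list(value = sum(v) / n, grad = g / n)
}

# ---- Boundary (level-set) -----------------------------------------------

#' Level-set boundary loss
#'
#' Mean over the image domain of `phi * pred`, where `phi` is the signed
#' distance map of the ground-truth region (negative inside). The loss
#' decreases as predicted probability mass concentrates inside the target and
#' grows with the distance of misplaced mass from the boundary; it is linear
#' in `pred` and unbounded on both sides.
#'
#' @param pred probability matrix.
#' @param phi signed distance map from [signed_distance()].
#' @return scalar loss.
#' @export
boundary_loss <- function(pred, phi) boundary_loss_grad(pred, phi)$value

#' @rdname boundary_loss
#' @export
boundary_loss_grad <- function(pred, phi) {
  check_shapes(pred, phi, "pred/phi")
  list(value = mean(phi * pred), grad = phi / length(pred))
}

# ---- Compound: focal boundary Dice --------------------------------------

#' Focal boundary Dice compound loss
#'
#' The weighted sum
#' `lambda_dice * Dice(pred, target) + lambda_focal * Focal(edge_pred,
#' edge_target) + lambda_boundary * Boundary(pred, phi(target))`, combining
#' region overlap, hard-pixel edge supervision, and distance-weighted boundary
#' placement in one objective. If the target is degenerate (all-0 or all-1)
#' the boundary term is undefined; it is skipped with a warning and the
#' remaining weights are renormalized.
#'
#' @param pred region probability map.
#' @param target binary ground-truth region.
#' @param edge_pred edge probability map.
#' @param edge_target binary edge ground truth.
#' @param spec a [compound_spec()].
#' @return scalar loss.
#' @export
focal_boundary_dice <- function(pred, target, edge_pred, edge_target,
                                spec = compound_spec()) {
  fbd_components(pred, target, edge_pred, edge_target, spec)$value
}

#' Focal boundary Dice with components and gradients
#'
#' @inheritParams focal_boundary_dice
#' @param phi optional precomputed signed distance map of `target`.
#' @return list with `value`, the three `components`, and gradients
#'   `grad_pred` / `grad_edge`.
#' @export
fbd_components <- function(pred, target, edge_pred, edge_target,
                           spec = compound_spec(), phi = NULL) {
  l1 <- spec$lambda_dice; l2 <- spec$lambda_focal; l3 <- spec$lambda_boundary
  s <- sum(target)
  degenerate <- s == 0 || s == length(target)
  if (degenerate && l3 > 0) {
    warning("degenerate target (all-0/all-1): boundary term skipped, weights renormalized")
    sc <- l1 + l2
    if (sc <= 0) stop("cannot renormalize: dice and focal weights are both zero")
    l1 <- l1 / sc; l2 <- l2 / sc; l3 <- 0
  }
  d <- dice_loss_grad(pred, target, spec$epsilon)
  f <- focal_loss_grad(edge_pred, edge_target, spec$gamma, spec$alpha)
  if (l3 > 0) {
    if (is.null(phi)) phi <- signed_distance(target)
    b <- boundary_loss_grad(pred, phi)
  } else {
    b <- list(value = 0, grad = 0 * pred)
  }
  list(value = l1 * d$value + l2 * f$value + l3 * b$value,
       components = c(dice = d$value, focal = f$value, boundary = b$value),
       grad_pred = l1 * d$grad + l3 * b$grad,
       grad_edge = l2 * f$grad)
}

#' Deeply supervised total loss
#'
#' Sum over supervised layers of the region part of the compound loss
#' (`lambda_dice * Dice + lambda_boundary * Boundary`) plus one focal edge
#' term `lambda_focal * Focal(edge_pred, edge_target)`. Each layer prediction
#' must already be upsampled to the ground-truth resolution. With
#' `focal_on = "region"` the focal term is instead applied per region layer
#' (against `target`) and the edge head is unsupervised.
#'
#' @param layer_preds list of region probability maps at ground-truth size.
#' @param edge_pred edge probability map.
#' @param target,edge_target binary ground truths.
#' @param spec a [compound_spec()].
#' @param focal_on `"edge"` (default) or `"region"`.
#' @return scalar loss.
#' @export
deep_supervision_total <- function(layer_preds, edge_pred, target, edge_target,
                                   spec = compound_spec(), focal_on = "edge") {
  if (length(layer_preds) == 0L) stop("layer_preds must be a non-empty list")
  focal_on <- match.arg(focal_on, c("edge", "region"))
  s <- sum(target)
  degenerate <- s == 0 || s == length(target)
  phi <- if (degenerate) NULL else signed_distance(target)
  total <- 0
  for (p in layer_preds) {
    total <- total + spec$lambda_dice * dice_loss(p, target, spec$epsilon)
    if (!degenerate) {
      total <- total + spec$lambda_boundary * boundary_loss(p, phi)
    }
    if (focal_on == "region") {
      total <- total + spec$lambda_focal * focal_loss(p, target, spec$gamma, spec$alpha)
    }
  }
  if (degenerate && spec$lambda_boundary > 0) {
    warning("degenerate target: boundary terms skipped in deep supervision total")
  }
  if (focal_on == "edge") {
    total <- total + spec$lambda_focal *
      focal_loss(edge_pred, edge_target, spec$gamma, spec$alpha)
  }
  total
}

# ---- Weighted BCE / IoU -------------------------------------------------

# box mean with edge-replicated padding (same-size, zero-phase)
box_mean_replicate <- function(x, k) {
  if (k %% 2 == 0 || k < 1) stop("pool size must be an odd positive integer")
  r <- (k - 1L) / 2L
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(h), rep(h, r)), c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  # summed-area table
  cs <- apply(apply(xp, 2, cumsum), 1, cumsum)  # transposed after second apply
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  i2 <- seq_len(h) + 2L * r; i1 <- seq_len(h) - 1L + 1L
  j2 <- seq_len(w) + 2L * r; j1 <- seq_len(w) - 1L + 1L
  s <- cs[i2 + 1L, j2 + 1L, drop = FALSE] - cs[i1, j2 + 1L, drop = FALSE] -
       cs[i2 + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
  s / (k * k)
}

#' Hard-pixel weight map from mean pooling
#'
#' `omega = 1 + amplification * |avgpool(target) - target|`, with same-size
#' mean pooling under edge-replicated padding. The weight is exactly 1
#' wherever the ground truth is constant over the pooling window and rises
#' towards `1 + amplification` near label transitions, so pixels around the
#' tumor boundary receive the largest weights.
#'
#' @param target binary matrix.
#' @param pool_size odd window size (>= 3), default 15.
#' @param amplification weight gain (> 0), default 5.
#' @return numeric weight matrix (values >= 1).
#' @export
weight_map <- function(target, pool_size = 15, amplification = 5) {
  assert_binary_mask(target, "target")
  if (pool_size %% 2 == 0 || pool_size < 3) stop("pool_size must be odd and >= 3")
  if (amplification <= 0) stop("amplification must be > 0")
  1 + amplification * abs(box_mean_replicate(target, pool_size) - target)
}

#' Weighted binary cross-entropy
#'
#' Weight-normalized mean `sum(w * BCE) / sum(w)` of the per-pixel binary
#' cross-entropy, with weights typically from [weight_map()].
#'
#' @inheritParams dice_loss
#' @param weights positive weight matrix, same shape.
#' @return scalar loss.
#' @export
weighted_bce <- function(pred, target, weights) {
  weighted_bce_grad(pred, target, weights)$value
}

#' @rdname weighted_bce
#' @export
weighted_bce_grad <- function(pred, target, weights) {
  check_shapes(pred, target)
  check_shapes(pred, weights, "pred/weights")
  p <- clamp01(pred)
  sw <- sum(weights)
  bce <- -(target * log(p) + (1 - target) * log(1 - p))
  g <- weights * (-target / p + (1 - target) / (1 - p)) / sw
  g[pred < .CLAMP | pred > 1 - .CLAMP] <- 0
  list(value = sum(weights * bce) / sw, grad = g)
}

#' Weighted soft IoU loss
#'
#' `1 - (sum(w*p*t) + eps) / (sum(w*(p + t - p*t)) + eps)`: a soft
#' intersection-over-union in which hard pixels (large weights) dominate both
#' the intersection and the union.
#'
#' @inheritParams weighted_bce
#' @param epsilon smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
weighted_iou <- function(pred, target, weights, epsilon = 1e-6) {
  weighted_iou_grad(pred, target, weights, epsilon)$value
}

#' @rdname weighted_iou
#' @export
weighted_iou_grad <- function(pred, target, weights, epsilon = 1e-6) {
  check_shapes(pred, target)
  check_shapes(pred, weights, "pred/weights")
  num <- sum(weights * pred * target) + epsilon
  den <- sum(weights * (pred + target - pred * target)) + epsilon
  dnum <- weights * target
  dden <- weights * (1 - target)
  grad <- -(dnum * den - num * dden) / den^2
  list(value = 1 - num / den, grad = grad)
}

#' BCE-IoU total loss
#'
#' Sum over supervised layers of weighted BCE plus weighted IoU, plus a plain
#' mean-BCE edge term. The weight map is derived from the segmentation target.
#'
#' @inheritParams deep_supervision_total
#' @param pool_size,amplification weight-map parameters.
#' @return scalar loss.
#' @export
bce_iou_total <- function(layer_preds, edge_pred, target, edge_target,
                          pool_size = 15, amplification = 5) {
  if (length(layer_preds) == 0L) stop("layer_preds must be a non-empty list")
  w <- weight_map(target, pool_size, amplification)
  total <- 0
  for (p in layer_preds) {
    total <- total + weighted_bce(p, target, w) + weighted_iou(p, target, w)
  }
  w1 <- matrix(1, nrow(edge_pred), ncol(edge_pred))
  total + weighted_bce(edge_pred, edge_target, w1)
}

#' Signed distance map of the edge band of a region mask
#'
#' An edge mask on its own has no interior, so the level set that supervises
#' the edge head is taken from a thin band around the region boundary: the
#' edge ground truth dilated/eroded to a `thickness`-pixel band whose signed
#' distance map is negative inside the band.
#'
#' @param target binary region mask.
#' @param thickness band thickness in pixels (default 3).
#' @return signed distance matrix of the band.
#' @export
edge_band_level_set <- function(target, thickness = 3) {
  band <- edge_ground_truth(target, thickness)
  signed_distance(band)
}

#' BCE-boundary total loss
#'
#' Sum over supervised layers of weighted BCE plus weighted IoU, with the edge
#' head supervised by the level-set boundary loss against the signed distance
#' map of a thin band around the region boundary (see
#' [edge_band_level_set()]).
#'
#' @inheritParams bce_iou_total
#' @param band_thickness thickness of the edge band in pixels.
#' @return scalar loss.
#' @export
bce_boundary_total <- function(layer_preds, edge_pred, target, edge_target,
                               pool_size = 15, amplification = 5,
                               band_thickness = 3) {
  if (length(layer_preds) == 0L) stop("layer_preds must be a non-empty list")
  w <- weight_map(target, pool_size, amplification)
  total <- 0
  for (p in layer_preds) {
    total <- total + weighted_bce(p, target, w) + weighted_iou(p, target, w)
  }
  if (sum(target) > 0 && sum(target) < length(target)) {
    phi_e <- edge_band_level_set(target, band_thickness)
    total <- total + boundary_loss(edge_pred, phi_e)
  } else {
    warning("degenerate target: boundary edge term skipped")
  }
  total
}

# ---- Shape-aware: compactness + smoothness ------------------------------

#' Compactness loss (inverse equivalence quotient)
#'
#' The equivalence quotient `C_EQM = 4*pi*A / P^2` equals 1 for a perfect disk
#' and shrinks as a shape grows irregular. Minimizing its inverse,
#' `P^2 / (4*pi*A + o)`, with the perimeter `P` taken as the sum of
#' probability-gradient magnitudes and the area `A` as the sum of `|pred|`,
#' drives predictions towards complete, compact shapes. `o` stabilizes both
#' the square root and the division.
#'
#' @param pred probability matrix.
#' @param o stability constant (> 0).
#' @return scalar loss (>= 0); lower is more compact.
#' @export
compactness_loss <- function(pred, o = 1e-6) compactness_loss_grad(pred, o)$value

#' @rdname compactness_loss
#' @export
compactness_loss_grad <- function(pred, o = 1e-6) {
  if (o <= 0) stop("o must be > 0")
  h <- nrow(pred); w <- ncol(pred)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w > 1) gx[, -w] <- pred[, -1] - pred[, -w]
  if (h > 1) gy[-h, ] <- pred[-1, ] - pred[-h, ]
  s <- sqrt(gx^2 + gy^2 + o)
  P <- sum(s)
  A <- sum(abs(pred))
  den <- 4 * pi * A + o
  value <- P^2 / den
  # adjoint of the forward-difference operators
  nx <- gx / s; ny <- gy / s
  dP <- matrix(0, h, w)
  if (w > 1) {
    dP[, -w] <- dP[, -w] - nx[, -w]
    dP[, -1] <- dP[, -1] + nx[, -w]
  }
  if (h > 1) {
    dP[-h, ] <- dP[-h, ] - ny[-h, ]
    dP[-1, ] <- dP[-1, ] + ny[-h, ]
  }
  grad <- (2 * P / den) * dP - (4 * pi * P^2 / den^2) * sign(pred)
  list(value = value, grad = grad)
}

#' Contrastive smoothness loss on contour/background embeddings
#'
#' Mean over all embedding pairs of the squared distance for same-class pairs
#' (contour-contour, background-background) and the squared hinge
#' `max(0, margin - d)^2` for contour-background pairs: same-class embeddings
#' are pulled together while the two classes are pushed apart up to the
#' margin, sharpening the learned edge representation.
#'
#' @param contour_embeddings,background_embeddings numeric matrices with one
#'   embedding per row (equal column count).
#' @param margin distance margin (> 0).
#' @return scalar loss (>= 0).
#' @export
smoothness_loss <- function(contour_embeddings, background_embeddings, margin = 1) {
  smoothness_loss_grad(contour_embeddings, background_embeddings, margin)$value
}

#' @rdname smoothness_loss
#' @return for `smoothness_loss_grad`, a list with `value`, `grad_contour`
#'   and `grad_background` (matrices matching the inputs).
#' @export
smoothness_loss_grad <- function(contour_embeddings, background_embeddings,
                                 margin = 1) {
  ce <- as.matrix(contour_embeddings); be <- as.matrix(background_embeddings)
  if (nrow(ce) == 0L || nrow(be) == 0L) stop("both embedding sets must be non-empty")
  if (ncol(ce) != ncol(be)) stop("embedding dimension mismatch")
  gc <- 0 * ce; gb <- 0 * be
  total <- 0; npairs <- 0
  pair_same <- function(E, G) {
    n <- nrow(E)
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d2 <- sum((E[i, ] - E[j, ])^2)
        total <<- total + d2
        G[i, ] <- G[i, ] + 2 * (E[i, ] - E[j, ])
        G[j, ] <- G[j, ] - 2 * (E[i, ] - E[j, ])
        npairs <<- npairs + 1
      }
    }
    G
  }
  gc <- pair_same(ce, gc)
  gb <- pair_same(be, gb)
  for (i in seq_len(nrow(ce))) for (j in seq_len(nrow(be))) {
    diff <- ce[i, ] - be[j, ]
    d <- sqrt(sum(diff^2))
    npairs <- npairs + 1
    if (d < margin) {
      total <- total + (margin - d)^2
      if (d > 0) {
        g <- -2 * (margin - d) * diff / d
        gc[i, ] <- gc[i, ] + g
        gb[j, ] <- gb[j, ] - g
      }
    }
  }
  list(value = total / npairs, grad_contour = gc / npairs,
       grad_background = gb / npairs)
}

# mask-averaged feature embedding: mean feature vector over mask, linearly
# projected to the low-dimensional embedding space
mask_average_embed <- function(features, mask, projection) {
  idx <- which(mask == 1)
  if (length(idx) == 0L) return(NULL)
  ch <- dim(features)[3]
  fmat <- matrix(features, ncol = ch)
  v <- colMeans(fmat[idx, , drop = FALSE])
  as.numeric(v %*% projection)
}

# fixed, seeded projection matrix for the embedding network (a single linear
# map; the embedding architecture is otherwise unconstrained)
embedding_projection <- function(n_features, embed_dim, seed = 7L) {
  set.seed(seed)
  matrix(rnorm(n_features * embed_dim, sd = 1 / sqrt(n_features)),
         n_features, embed_dim)
}

#' Shape-aware total loss
#'
#' Segmentation cross-entropy (mean BCE summed over the supervised layers)
#' plus the compactness constraint on the final layer prediction plus the
#' contrastive smoothness constraint on mask-averaged feature embeddings of
#' the contour band versus the background, combined with the weights in
#' `spec` (equal by default). If either embedding class is empty (degenerate
#' contour or background) the smoothness term is skipped with a warning.
#'
#' @param layer_preds list of region probability maps (last = final).
#' @param features H x W x C feature array from a convolutional layer, at the
#'   same spatial size as the target.
#' @param target binary ground truth.
#' @param spec a [shape_spec()].
#' @return scalar loss.
#' @export
shape_aware_total <- function(layer_preds, features, target,
                              spec = shape_spec()) {
  if (length(layer_preds) == 0L) stop("layer_preds must be a non-empty list")
  w <- spec$weights
  ones <- matrix(1, nrow(target), ncol(target))
  ce <- 0
  for (p in layer_preds) ce <- ce + weighted_bce(p, target, ones)
  comp <- compactness_loss(layer_preds[[length(layer_preds)]], spec$o)
  smooth <- 0
  emb <- shape_aware_embeddings(features, target, spec)
  if (is.null(emb)) {
    warning("degenerate contour/background: smoothness term skipped")
  } else {
    smooth <- smoothness_loss(emb$contour, emb$background, spec$margin)
  }
  w[1] * ce + w[2] * comp + w[3] * smooth
}

# contour/background mask-averaged embeddings used by the shape-aware loss;
# masks can be precomputed once per sample and passed in
shape_aware_embeddings <- function(features, target, spec = shape_spec(),
                                   masks = NULL) {
  if (sum(target) == 0 || sum(target) == length(target)) return(NULL)
  if (is.null(masks)) {
    contour <- edge_ground_truth(target, 3)
    background <- 1 * ((contour + target) == 0)
  } else {
    contour <- masks$contour; background <- masks$background
  }
  proj <- embedding_projection(dim(features)[3], spec$embed_dim)
  ec <- mask_average_embed(features, contour, proj)
  eb <- mask_average_embed(features, background, proj)
  if (is.null(ec) || is.null(eb)) return(NULL)
  list(contour = matrix(ec, nrow = 1), background = matrix(eb, nrow = 1),
       projection = proj, contour_mask = contour, background_mask = background)
}
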