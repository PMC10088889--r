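test_that("dice_loss follows its closed form", {
  set.seed(31)
  t <- random_mask(8, 8, 0.3)
  expect_lt(dice_loss(t + 0, t, epsilon = 1e-9), 1e-8)
  k <- sum(t)
  expect_equal(dice_loss(matrix(0, 8, 8), t, epsilon = 1), 1 - 1 / (k + 1))
  p <- 1 - t  # disjoint supports
  expect_gt(dice_loss(p, t, epsilon = 1e-6), 1 - 1e-5)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("focal loss reduces to scaled BCE at gamma 0 and damps easy pixels", {
  set.seed(32)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- random_mask(8, 8)
  bce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(focal_loss(p, t, gamma = 0, alpha = 0.5), 0.5 * bce,
               tolerance = 1e-12)
  # hand evaluation: single positive pixel at p = 0.5, gamma 2, alpha 0.25
  expect_equal(focal_loss(matrix(0.5), matrix(1), gamma = 2, alpha = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # strictly decreasing in p on a positive pixel, vanishing at p -> 1
  vals <- vapply(c(0.3, 0.6, 0.9, 0.999),
                 function(q) focal_loss(matrix(q), matrix(1)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-5)
  expect_error(focal_loss(p, t, gamma = -1), "gamma")
})

test_that("focal loss is non-increasing in gamma when pixels are well classified", {
  set.seed(33)
  t <- random_mask(8, 8)
  p <- ifelse(t == 1, runif(64, 0.6, 0.95), runif(64, 0.05, 0.4))
  dim(p) <- c(8, 8)
  gammas <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(gammas, function(g) focal_loss(p, t, gamma = g), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("boundary loss is linear in pred with the level-set integrand", {
  m <- matrix(0, 7, 7); m[2:6, 2:6] <- 1
  phi <- signed_distance(m)
  expect_equal(boundary_loss(matrix(0, 7, 7), phi), 0)
  # indicator prediction: mean over the domain of phi restricted to G
  expect_equal(boundary_loss(m + 0, phi), sum(phi[m == 1]) / 49)
  expect_lt(boundary_loss(m + 0, phi), 0)
})

test_that("translating a predicted blob away from the target increases boundary loss", {
  t <- matrix(0, 32, 32); t[13:20, 5:12] <- 1
  phi <- signed_distance(t)
  vals <- vapply(c(0, 4, 8), function(dx) {
    p <- matrix(0, 32, 32); p[13:20, 5:12 + dx] <- 1
    boundary_loss(p, phi)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("weight_map emphasizes label transitions only", {
  expect_true(all(weight_map(matrix(0, 6, 6), 3, 5) == 1))
  step <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6)
  w <- weight_map(step, 3, 5)
  expect_equal(as.numeric(w), c(1, 1, 1 + 5 / 3, 1 + 5 / 3, 1, 1),
               tolerance = 1e-12)
  # complement invariance
  set.seed(34)
  t <- random_mask(10, 10)
  expect_equal(weight_map(t, 5, 5), weight_map(1 - t, 5, 5), tolerance = 1e-12)
  expect_error(weight_map(t, 4, 5), "odd")
})

test_that("weighted BCE and IoU reduce to their unweighted forms", {
  set.seed(35)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- random_mask(8, 8)
  ones <- matrix(1, 8, 8)
  bce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(weighted_bce(p, t, ones), bce, tolerance = 1e-12)
  expect_lt(weighted_bce(t + 0, t, ones), 1e-5)

  for (i in 1:10) {
    a <- random_mask(16, 16); b <- random_mask(16, 16)
    inter <- sum(a == 1 & b == 1); uni <- sum(a == 1 | b == 1)
    expect_equal(weighted_iou(a + 0, b, matrix(1, 16, 16)),
                 1 - inter / uni, tolerance = 1e-5)
  }
  expect_lt(weighted_iou(t + 0, t, ones), 1e-5)
  expect_gt(weighted_iou((1 - t) + 0, t, ones), 1 - 1e-4)
})

test_that("raising the amplification shifts loss mass to boundary pixels", {
  step <- matrix(rep(c(0, 0, 0, 1, 1, 1), 6), 6, 6, byrow = TRUE)
  set.seed(36)
  p <- matrix(runif(36, 0.2, 0.8), 6, 6)
  w1 <- weight_map(step, 3, 2); w2 <- weight_map(step, 3, 8)
  near <- w1 > 1
  share <- function(w) {
    px <- w * -(step * log(p) + (1 - step) * log(1 - p))
    sum(px[near]) / sum(px)
  }
  expect_gt(share(w2), share(w1))
})

test_that("focal boundary dice collapses to its components at unit weights", {
  set.seed(37)
  t <- random_mask(12, 12, 0.25)
  et <- edge_ground_truth(t, 1)
  p <- matrix(runif(144, 0.05, 0.95), 12, 12)
  ep <- matrix(runif(144, 0.05, 0.95), 12, 12)
  d <- dice_loss(p, t)
  f <- focal_loss(ep, et)
  b <- boundary_loss(p, signed_distance(t))
  expect_equal(focal_boundary_dice(p, t, ep, et, compound_spec(1, 0, 0)), d)
  expect_equal(focal_boundary_dice(p, t, ep, et, compound_spec(0, 1, 0)), f)
  expect_equal(focal_boundary_dice(p, t, ep, et, compound_spec(0, 0, 1)), b)
  # published operating point equals the hand-weighted sum
  expect_equal(focal_boundary_dice(p, t, ep, et, compound_spec(0.5, 0.3, 0.2)),
               0.5 * d + 0.3 * f + 0.2 * b, tolerance = 1e-12)
})

test_that("degenerate targets skip the boundary term with a warning", {
  p <- matrix(0.5, 4, 4); ep <- matrix(0.5, 4, 4)
  t0 <- matrix(0, 4, 4)
  expect_warning(v <- focal_boundary_dice(p, t0, ep, t0), "degenerate")
  d <- dice_loss(p, t0); f <- focal_loss(ep, t0)
  expect_equal(v, (0.5 * d + 0.3 * f) / 0.8, tolerance = 1e-12)
})

test_that("deep supervision total sums layer terms plus one edge term", {
  set.seed(38)
  t <- random_mask(12, 12, 0.25)
  et <- edge_ground_truth(t, 1)
  p <- matrix(runif(144, 0.05, 0.95), 12, 12)
  ep <- matrix(runif(144, 0.05, 0.95), 12, 12)
  spec <- compound_spec(0.5, 0, 0.5)
  expect_equal(deep_supervision_total(list(p), ep, t, et, spec),
               focal_boundary_dice(p, t, ep, et, spec), tolerance = 1e-12)
  # three identical layers: additivity
  spec2 <- compound_spec()
  phi <- signed_distance(t)
  lseg <- 0.5 * dice_loss(p, t) + 0.2 * boundary_loss(p, phi)
  expect_equal(deep_supervision_total(list(p, p, p), ep, t, et, spec2),
               3 * lseg + 0.3 * focal_loss(ep, et), tolerance = 1e-9)
  expect_error(deep_supervision_total(list(), ep, t, et), "non-empty")
})

test_that("bce_iou and bce_boundary totals equal hand-summed components", {
  set.seed(39)
  t <- random_mask(16, 16, 0.25)
  et <- edge_ground_truth(t, 1)
  ps <- lapply(1:3, function(i) matrix(runif(256, 0.05, 0.95), 16, 16))
  ep <- matrix(runif(256, 0.05, 0.95), 16, 16)
  w <- weight_map(t, 15, 5)
  comp <- sum(vapply(ps, function(p) {
    weighted_bce(p, t, w) + weighted_iou(p, t, w)
  }, numeric(1)))
  ones <- matrix(1, 16, 16)
  expect_equal(bce_iou_total(ps, ep, t, et), comp + weighted_bce(ep, et, ones),
               tolerance = 1e-9)
  phi_e <- edge_band_level_set(t, 3)
  expect_equal(bce_boundary_total(ps, ep, t, et),
               comp + boundary_loss(ep, phi_e), tolerance = 1e-9)
  # zero edge prediction kills the boundary edge term
  expect_equal(bce_boundary_total(ps, matrix(0, 16, 16), t, et), comp,
               tolerance = 1e-9)
})

test_that("compactness orders disk < square < star at equal area and is scale-free", {
  disk <- disk_mask(64, 20)
  a <- sum(disk)
  sq <- matrix(0, 64, 64); side <- round(sqrt(a))
  sq[32 - side %/% 2 + seq_len(side), 32 - side %/% 2 + seq_len(side)] <- 1
  star <- star_mask(64, 18, k = 8, amp = 0.6)
  # comparable areas (within 15%)
  expect_lt(abs(sum(star) - a) / a, 0.15)
  # the loss consumes probability maps; rasterize softly (1 px of blur),
  # since on hard binary masks the staircase inflates the disk's digital
  # perimeter above the axis-aligned square's
  soft <- function(m) gaussian_blur(m, 7, sigma = 1)
  ld <- compactness_loss(soft(disk)); lq <- compactness_loss(soft(sq))
  ls <- compactness_loss(soft(star))
  expect_lt(ld, lq)
  expect_lt(lq, ls)
  # on hard masks the disk still beats the star outright
  expect_lt(compactness_loss(disk), compactness_loss(star))
  # doubling the scale leaves the loss within 10% (discretization tolerance)
  small <- soft(disk_mask(64, 10))
  big <- gaussian_blur(disk_mask(128, 20), 13, sigma = 2)  # blur scales too
  expect_lt(abs(compactness_loss(big) / compactness_loss(small) - 1), 0.1)
  # all-zero prediction stays finite
  expect_true(is.finite(compactness_loss(matrix(0, 16, 16), o = 1e-6)))
})

test_that("smoothness loss counts pairs as a contrastive objective", {
  e <- matrix(1, 1, 4)
  ce <- rbind(e, e); be <- rbind(e, e, e)
  # identical embeddings: same-class pairs 0, each cross pair costs margin^2
  n_same <- 1 + 3; n_cross <- 6
  expect_equal(smoothness_loss(ce, be, margin = 1),
               n_cross / (n_same + n_cross), tolerance = 1e-12)
  # satisfied margin: coincident within class, distant across
  ce2 <- rbind(c(0, 0), c(0, 0)); be2 <- rbind(c(5, 0), c(5, 0))
  expect_equal(smoothness_loss(ce2, be2, margin = 1), 0)
  # rotation invariance
  set.seed(40)
  ce3 <- matrix(rnorm(8), 2, 4); be3 <- matrix(rnorm(12), 3, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(smoothness_loss(ce3, be3, 1.5),
               smoothness_loss(ce3 %*% q, be3 %*% q, 1.5), tolerance = 1e-12)
  expect_error(smoothness_loss(ce3, matrix(0, 2, 3)), "dimension")
})

test_that("shape-aware total equals its component sum and guards degeneracy", {
  set.seed(41)
  t <- random_mask(16, 16, 0.25)
  ps <- lapply(1:3, function(i) matrix(runif(256, 0.05, 0.95), 16, 16))
  feats <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  spec <- shape_spec()
  ones <- matrix(1, 16, 16)
  ce <- sum(vapply(ps, function(p) weighted_bce(p, t, ones), numeric(1)))
  cp <- compactness_loss(ps[[3]], spec$o)
  emb <- boundseg:::shape_aware_embeddings(feats, t, spec)
  sm <- smoothness_loss(emb$contour, emb$background, spec$margin)
  expect_equal(shape_aware_total(ps, feats, t, spec), ce + cp + sm,
               tolerance = 1e-9)
  # degenerate target: cross-entropy + compactness with a warning
  t0 <- matrix(0, 16, 16)
  expect_warning(v <- shape_aware_total(ps, feats, t0, spec), "degenerate")
  ce0 <- sum(vapply(ps, function(p) weighted_bce(p, t0, ones), numeric(1)))
  expect_equal(v, ce0 + cp, tolerance = 1e-9)
})

test_that("replacing a spiculated prediction by an equal-area disk lowers the shape total", {
  star <- star_mask(64, 16.5, k = 8, amp = 0.6)
  disk <- disk_mask(64, sqrt(sum(star) / pi))
  t <- disk  # fixed target; compare compactness-driven difference
  feats <- array(1, c(64, 64, 2))
  suppressWarnings({
    v_star <- compactness_loss(star)
    v_disk <- compactness_loss(disk)
  })
  expect_lt(v_disk, v_star)
})

test_that("every differentiable loss passes central finite differences", {
  set.seed(42)
  t <- random_mask(16, 16, 0.3)
  et <- edge_ground_truth(t, 1)
  p <- matrix(runif(256, 0.05, 0.95), 16, 16)
  w <- weight_map(t, 5, 5)
  phi <- signed_distance(t)

  expect_lt(fd_grad_check(function(x) dice_loss(x, t),
                          dice_loss_grad(p, t)$grad, p), 1e-4)
  expect_lt(fd_grad_check(function(x) focal_loss(x, t),
                          focal_loss_grad(p, t)$grad, p), 1e-4)
  expect_lt(fd_grad_check(function(x) boundary_loss(x, phi),
                          boundary_loss_grad(p, phi)$grad, p), 1e-4)
  expect_lt(fd_grad_check(function(x) weighted_bce(x, t, w),
                          weighted_bce_grad(p, t, w)$grad, p), 1e-4)
  expect_lt(fd_grad_check(function(x) weighted_iou(x, t, w),
                          weighted_iou_grad(p, t, w)$grad, p), 1e-4)
  expect_lt(fd_grad_check(function(x) compactness_loss(x),
                          compactness_loss_grad(p)$grad, p), 1e-4)

  # compound gradients
  fb <- fbd_components(p, t, p, et)
  expect_lt(fd_grad_check(function(x) focal_boundary_dice(x, t, p, et),
                          fb$grad_pred, p), 1e-4)
  expect_lt(fd_grad_check(function(x) focal_boundary_dice(p, t, x, et),
                          fb$grad_edge, p), 1e-4)

  # smoothness w.r.t. embeddings
  ce <- matrix(rnorm(12), 3, 4); be <- matrix(rnorm(8), 2, 4)
  sg <- smoothness_loss_grad(ce, be, 1.5)
  expect_lt(fd_grad_check(function(x) smoothness_loss(x, be, 1.5),
                          sg$grad_contour, ce), 1e-4)
  expect_lt(fd_grad_check(function(x) smoothness_loss(ce, x, 1.5),
                          sg$grad_background, be), 1e-4)
})

test_that("losses are invariant under simultaneous horizontal flips", {
  set.seed(43)
  t <- random_mask(12, 12, 0.3)
  p <- matrix(runif(144, 0.05, 0.95), 12, 12)
  w <- weight_map(t, 3, 5)
  fl <- function(m) m[, ncol(m):1]
  expect_equal(dice_loss(p, t), dice_loss(fl(p), fl(t)), tolerance = 1e-12)
  expect_equal(focal_loss(p, t), focal_loss(fl(p), fl(t)), tolerance = 1e-12)
  expect_equal(weighted_bce(p, t, w), weighted_bce(fl(p), fl(t), fl(w)),
               tolerance = 1e-12)
  expect_equal(weighted_iou(p, t, w), weighted_iou(fl(p), fl(t), fl(w)),
               tolerance = 1e-12)
  expect_equal(boundary_loss(p, signed_distance(t)),
               boundary_loss(fl(p), signed_distance(fl(t))), tolerance = 1e-12)
})
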