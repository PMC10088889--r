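test_that("forward pass satisfies the shape and range contract", {
  mdl <- build_model(model_config(base_channels = 2, seed = 3))
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- model_forward(mdl, img)
  expect_length(fw$region_probs, 3)
  for (P in fw$region_probs) {
    expect_equal(dim(P), c(64, 64))
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_equal(dim(fw$edge_prob), c(64, 64))
  expect_true(all(fw$edge_prob >= 0 & fw$edge_prob <= 1))

  # same seed, same outputs
  mdl2 <- build_model(model_config(base_channels = 2, seed = 3))
  fw2 <- model_forward(mdl2, img)
  expect_identical(fw$region_probs, fw2$region_probs)

  # the edge-attention-at-layer-1 ablation variant is constructible
  mdl3 <- build_model(model_config(base_channels = 2, edge_layer = 1, seed = 3))
  fw3 <- model_forward(mdl3, img)
  expect_equal(dim(fw3$edge_prob), c(64, 64))
  expect_error(model_config(edge_layer = 3), "edge_layer")
  expect_error(model_config(supervised_layers = 1:2), "supervised_layers")
  expect_error(model_forward(mdl, matrix(0, 30, 30)), "divisible")
})

test_that("analytic network gradients match finite differences", {
  set.seed(71)
  for (el in c(2, 1)) {
    mdl <- build_model(model_config(base_channels = 2, edge_layer = el, seed = 4))
    img <- matrix(runif(256), 16, 16)
    t <- matrix(0, 16, 16); t[6:10, 6:11] <- 1
    phi <- signed_distance(t)
    et <- edge_ground_truth(t, 1)
    lossfn <- function(m) {
      fw <- model_forward(m, img)
      v <- 0
      for (P in fw$region_probs) v <- v + 0.5 * dice_loss(P, t) +
        0.2 * boundary_loss(P, phi)
      v + 0.3 * focal_loss(fw$edge_prob, et) + 0.01 * sum(fw$features^2)
    }
    fw <- model_forward(mdl, img)
    dR <- lapply(fw$region_probs, function(P) {
      0.5 * dice_loss_grad(P, t)$grad + 0.2 * boundary_loss_grad(P, phi)$grad
    })
    g <- model_backward(mdl, fw, dR,
                        0.3 * focal_loss_grad(fw$edge_prob, et)$grad,
                        0.02 * fw$features)
    maxrel <- 0
    for (nm in names(mdl$params)) for (f in c("w", "b")) {
      arr <- mdl$params[[nm]][[f]]
      for (i in sample(length(arr), min(2, length(arr)))) {
        h <- 1e-5
        m1 <- mdl; m1$params[[nm]][[f]][i] <- arr[i] + h
        m2 <- mdl; m2$params[[nm]][[f]][i] <- arr[i] - h
        fd <- (lossfn(m1) - lossfn(m2)) / (2 * h)
        an <- g[[nm]][[f]][i]
        maxrel <- max(maxrel, abs(fd - an) / max(abs(fd), abs(an), 1e-6))
      }
    }
    expect_lt(maxrel, 1e-4)
  }
})

test_that("every loss family yields non-zero gradients at initialization", {
  set.seed(72)
  ds <- generate_dataset(4, 0.5, 32, seed = 8)
  mdl <- build_model(model_config(base_channels = 2, seed = 5))
  for (ln in c("focal_boundary_dice", "bce_iou", "bce_boundary", "shape_aware")) {
    lc <- loss_config(ln)
    prep <- boundseg:::prepare_samples(ds$samples, lc)
    fws <- lapply(prep, function(pr) model_forward(mdl, pr$image))
    bl <- boundseg:::batch_loss_grads(fws, prep, lc)
    g <- model_backward(mdl, fws[[1]], bl$grads[[1]]$d_region,
                        bl$grads[[1]]$d_edge, bl$grads[[1]]$d_features)
    total <- sum(vapply(g, function(x) sum(abs(x$w)) + sum(abs(x$b)), numeric(1)))
    expect_gt(total, 0)
    expect_true(is.finite(bl$value))
  }
})

test_that("training runs deterministically and epochs = 0 only evaluates", {
  ds <- generate_dataset(10, 0.5, 32, seed = 13)
  sp <- split_dataset(ds, seed = 13)
  mdl <- build_model(model_config(base_channels = 2, seed = 6))
  r0 <- train(mdl, sp$train, sp$test, loss_config(), epochs = 0, seed = 1)
  expect_true(all(r0$record$epoch == 0))
  expect_setequal(r0$record$split, c("train", "test"))

  r1 <- train(build_model(model_config(base_channels = 2, seed = 6)),
              sp$train, sp$test, loss_config(), epochs = 2, seed = 2)
  r2 <- train(build_model(model_config(base_channels = 2, seed = 6)),
              sp$train, sp$test, loss_config(), epochs = 2, seed = 2)
  expect_identical(r1$record, r2$record)
  expect_true(all(r1$record$miou >= 0 & r1$record$miou <= 1, na.rm = TRUE))
  expect_true(all(r1$record$pa >= 0 & r1$record$pa <= 1, na.rm = TRUE))
  expect_error(train(mdl, list(), sp$test, loss_config(), 1), "empty")
})

test_that("loss decreases on a small training set", {
  # a loss with a fixed scale across epochs (the compound loss ramps its
  # boundary weight in, so its recorded total is not epoch-comparable early)
  ds <- generate_dataset(12, 0.5, 32, seed = 21)
  mdl <- build_model(model_config(base_channels = 2, seed = 7))
  res <- train(mdl, ds$samples, list(), loss_config("bce_iou"), epochs = 6,
               seed = 3, batch_size = 4)
  tr <- res$record[res$record$split == "train" & res$record$epoch > 0, ]
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
})

test_that("cross-validation folds partition the data and aggregate by epoch", {
  ds <- generate_dataset(9, 0.5, 32, seed = 31)
  cv <- cross_validate(ds$samples, k = 3, epochs = 1, loss_config(), seed = 4,
                       config = model_config(base_channels = 2))
  idx <- sort(unname(unlist(cv$folds)))
  expect_equal(idx, 1:9)                       # coverage
  expect_equal(vapply(cv$folds, length, integer(1)), rep(3L, 3),
               ignore_attr = TRUE)             # 9 into 3 folds of 3
  expect_length(cv$records, 3)
  # aggregate equals the hand-averaged fold curves
  te <- do.call(rbind, lapply(cv$records, function(r) r[r$split == "test", ]))
  for (ep in unique(cv$aggregate$epoch)) {
    expect_equal(cv$aggregate$dice[cv$aggregate$epoch == ep],
                 mean(te$dice[te$epoch == ep]))
  }
  # non-divisible case spreads the remainder
  cv2 <- cross_validate(ds$samples[1:8], k = 3, epochs = 0, loss_config(),
                        seed = 4, config = model_config(base_channels = 2))
  expect_setequal(vapply(cv2$folds, length, integer(1)), c(3L, 3L, 2L))
  expect_error(cross_validate(ds$samples[1:2], k = 3, epochs = 1), "exceed")
})

test_that("compare_losses tabulates one row per loss-seed pair, reproducibly", {
  ds <- generate_dataset(8, 0.5, 32, seed = 41)
  sp <- split_dataset(ds, seed = 41)
  a <- compare_losses(sp$train, sp$test, loss_names = "focal_boundary_dice",
                      epochs = 1, seeds = 5,
                      config = model_config(base_channels = 2))
  expect_equal(nrow(a$table), 1)
  b <- compare_losses(sp$train, sp$test, loss_names = "focal_boundary_dice",
                      epochs = 1, seeds = 5,
                      config = model_config(base_channels = 2))
  expect_identical(a$table, b$table)
})

test_that("the shape classifier separates separable classes and is seeded", {
  set.seed(73)
  ds <- generate_dataset(60, 0.5, 64, seed = 51)
  r <- classify_shapes(ds$samples, seed = 1)
  expect_gte(r$accuracy, 0.9)   # compactness separates the generated classes
  r2 <- classify_shapes(ds$samples, seed = 1)
  expect_equal(r$accuracy, r2$accuracy)
  one_class <- ds$samples[ds$manifest$label == "smooth"]
  expect_error(classify_shapes(one_class), "classes")
})

test_that("label-shuffled features classify at chance", {
  ds <- generate_dataset(40, 0.5, 64, seed = 61)
  accs <- vapply(1:6, function(s) {
    set.seed(s)
    shuffled <- ds$samples
    labs <- sample(vapply(shuffled, `[[`, character(1), "shape_label"))
    for (i in seq_along(shuffled)) shuffled[[i]]$shape_label <- labs[i]
    classify_shapes(shuffled, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})
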