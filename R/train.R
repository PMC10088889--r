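#' Training-loss configuration
#'
#' Selects one of the four loss families and carries its parameters.
#'
#' @param name one of `"focal_boundary_dice"`, `"bce_iou"`, `"bce_boundary"`,
#'   `"shape_aware"`.
#' @param compound a [compound_spec()] (focal boundary Dice).
#' @param pool_size,amplification weight-map parameters (BCE-based losses).
#' @param band_thickness edge-band thickness for the BCE-boundary loss.
#' @param shape a [shape_spec()] (shape-aware loss).
#' @param focal_on where the compound loss applies its focal term during
#'   deeply supervised training: `"region"` (default) adds it to every
#'   region head against the segmentation target -- the per-layer compound
#'   reading, which also keeps a live cross-entropy-family gradient on the
#'   region heads -- while `"edge"` restricts it to the edge head. The edge
#'   head itself is always supervised by the focal edge term.
#' @return list of class `loss_config`.
#' @export
loss_config <- function(name = c("focal_boundary_dice", "bce_iou",
                                 "bce_boundary", "shape_aware"),
                        compound = compound_spec(), pool_size = 15,
                        amplification = 5, band_thickness = 3,
                        shape = shape_spec(),
                        focal_on = c("region", "edge")) {
  name <- match.arg(name)
  structure(list(name = name, compound = compound, pool_size = pool_size,
                 amplification = amplification,
                 band_thickness = band_thickness, shape = shape,
                 focal_on = match.arg(focal_on)),
            class = "loss_config")
}

# precompute per-sample ground-truth derivatives needed by a loss family
prepare_samples <- function(samples, lc) {
  lapply(samples, function(s) {
    out <- list(image = s$image, target = s$mask, edge_target = s$edge,
                label = s$shape_label)
    deg <- sum(s$mask) == 0 || sum(s$mask) == length(s$mask)
    if (lc$name == "focal_boundary_dice" && !deg) {
      out$phi <- signed_distance(s$mask)
    }
    if (lc$name %in% c("bce_iou", "bce_boundary")) {
      out$wmap <- weight_map(s$mask, lc$pool_size, lc$amplification)
    }
    if (lc$name == "bce_boundary" && !deg) {
      out$phi_edge <- edge_band_level_set(s$mask, lc$band_thickness)
    }
    if (lc$name == "shape_aware" && !deg) {
      contour <- edge_ground_truth(s$mask, 3)
      out$shape_masks <- list(contour = contour,
                              background = 1 * ((contour + s$mask) == 0))
    }
    out
  })
}

# per-batch loss and output gradients; fws and prep are parallel lists
batch_loss_grads <- function(fws, prep, lc, supervised = c(3, 4, 5),
                             boundary_scale = 1) {
  sup_idx <- supervised - 2L  # heads 3,4,5 -> list positions 1,2,3
  n <- length(fws)
  zero_like <- function(m) matrix(0, nrow(m), ncol(m))
  out <- vector("list", n)
  total <- 0
  embeds <- NULL
  if (lc$name == "shape_aware") {
    embeds <- lapply(seq_len(n), function(i) {
      shape_aware_embeddings(fws[[i]]$features, prep[[i]]$target, lc$shape,
                             prep[[i]]$shape_masks)
    })
    have <- !vapply(embeds, is.null, logical(1))
    sm <- NULL
    if (sum(have) > 0) {
      ce_mat <- do.call(rbind, lapply(embeds[have], `[[`, "contour"))
      be_mat <- do.call(rbind, lapply(embeds[have], `[[`, "background"))
      sm <- smoothness_loss_grad(ce_mat, be_mat, lc$shape$margin)
      total <- total + lc$shape$weights[3] * sm$value
    }
  }
  for (i in seq_len(n)) {
    fw <- fws[[i]]; pr <- prep[[i]]
    P <- fw$region_probs
    dR <- lapply(P, zero_like)
    dE <- zero_like(fw$edge_prob)
    dF <- NULL
    val <- 0
    if (lc$name == "focal_boundary_dice") {
      sp <- lc$compound
      for (j in sup_idx) {
        d <- dice_loss_grad(P[[j]], pr$target, sp$epsilon)
        val <- val + sp$lambda_dice * d$value
        dR[[j]] <- dR[[j]] + sp$lambda_dice * d$grad
        if (identical(lc$focal_on, "region")) {
          fr <- focal_loss_grad(P[[j]], pr$target, sp$gamma, sp$alpha)
          val <- val + sp$lambda_focal * fr$value
          dR[[j]] <- dR[[j]] + sp$lambda_focal * fr$grad
        }
        if (!is.null(pr$phi)) {
          b <- boundary_loss_grad(P[[j]], pr$phi)
          val <- val + boundary_scale * sp$lambda_boundary * b$value
          dR[[j]] <- dR[[j]] + boundary_scale * sp$lambda_boundary * b$grad
        }
      }
      f <- focal_loss_grad(fw$edge_prob, pr$edge_target, sp$gamma, sp$alpha)
      val <- val + sp$lambda_focal * f$value
      dE <- dE + sp$lambda_focal * f$grad
    } else if (lc$name %in% c("bce_iou", "bce_boundary")) {
      for (j in sup_idx) {
        wb <- weighted_bce_grad(P[[j]], pr$target, pr$wmap)
        wi <- weighted_iou_grad(P[[j]], pr$target, pr$wmap)
        val <- val + wb$value + wi$value
        dR[[j]] <- dR[[j]] + wb$grad + wi$grad
      }
      if (lc$name == "bce_iou") {
        ones <- matrix(1, nrow(dE), ncol(dE))
        eb <- weighted_bce_grad(fw$edge_prob, pr$edge_target, ones)
        val <- val + eb$value
        dE <- dE + eb$grad
      } else if (!is.null(pr$phi_edge)) {
        eb <- boundary_loss_grad(fw$edge_prob, pr$phi_edge)
        val <- val + boundary_scale * eb$value
        dE <- dE + boundary_scale * eb$grad
      }
    } else if (lc$name == "shape_aware") {
      w <- lc$shape$weights
      ones <- matrix(1, nrow(P[[1]]), ncol(P[[1]]))
      for (j in sup_idx) {
        cb <- weighted_bce_grad(P[[j]], pr$target, ones)
        val <- val + w[1] * cb$value
        dR[[j]] <- dR[[j]] + w[1] * cb$grad
      }
      cp <- compactness_loss_grad(P[[3]], lc$shape$o)
      val <- val + w[2] * cp$value
      dR[[3]] <- dR[[3]] + w[2] * cp$grad
      if (!is.null(embeds[[i]]) && !is.null(sm)) {
        k <- sum(!vapply(embeds[seq_len(i)], is.null, logical(1)))
        em <- embeds[[i]]
        gE <- lc$shape$weights[3] *
          rbind(sm$grad_contour[k, ], sm$grad_background[k, ])
        # back through projection and mask averaging into the feature array
        dch_c <- as.numeric(em$projection %*% gE[1, ])
        dch_b <- as.numeric(em$projection %*% gE[2, ])
        dF <- array(0, dim(fw$features))
        nc <- sum(em$contour_mask); nb <- sum(em$background_mask)
        for (ch in seq_along(dch_c)) {
          dF[, , ch] <- dF[, , ch] + em$contour_mask * (dch_c[ch] / nc) +
            em$background_mask * (dch_b[ch] / nb)
        }
      }
    }
    if (!is.finite(val)) {
      stop(sprintf("non-finite loss (%s) on sample %d: check component values",
                   lc$name, i))
    }
    total <- total + val
    out[[i]] <- list(d_region = dR, d_edge = dE, d_features = dF)
  }
  list(value = total / n, grads = out)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      g <- grads[[nm]][[f]]
      m[[nm]][[f]] <- beta1 * m[[nm]][[f]] + (1 - beta1) * g
      v[[nm]][[f]] <- beta2 * v[[nm]][[f]] + (1 - beta2) * g^2
      mh <- m[[nm]][[f]] / (1 - beta1^t)
      vh <- v[[nm]][[f]] / (1 - beta2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, m = m, v = v)
}

scale_grads <- function(grads, s) {
  rapply(grads, function(x) x * s, how = "replace")
}
add_grads <- function(a, b) {
  for (nm in names(a)) for (f in names(a[[nm]])) {
    a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
  }
  a
}

# evaluate the final (full-resolution) head on a sample list
eval_split <- function(model, prep, threshold = 0.5) {
  preds <- lapply(prep, function(pr) model_forward(model, pr$image)$region_probs$layer5)
  targets <- lapply(prep, `[[`, "target")
  ev <- evaluate_batch(preds, targets, threshold)
  c(dice = unname(ev$means["dice"]), miou = ev$miou,
    pa = unname(ev$means["pa"]), hausdorff = unname(ev$means["hausdorff"]))
}

#' Train the segmentation model
#'
#' Mini-batch Adam training under any of the four loss families, with
#' per-epoch metrics (total loss, Dice, mIoU, pixel accuracy, mean Hausdorff)
#' recorded on the training and held-out splits and the best-Dice parameters
#' checkpointed. Deterministic given the seed. Epoch 0 rows hold the
#' evaluation of the untrained model.
#'
#' @param model a [build_model()] result.
#' @param train_samples,test_samples lists of samples ([generate_sample()]
#'   objects or lists with `image`, `mask`, `edge` fields).
#' @param lc a [loss_config()].
#' @param epochs number of epochs (0 = evaluate only).
#' @param seed training seed (shuffling).
#' @param batch_size mini-batch size, default 8.
#' @param lr Adam learning rate, default 3e-3.
#' @param threshold evaluation binarization threshold.
#' @param eval_train compute train-split metrics per epoch from the training
#'   forward passes; when FALSE the train rows keep the loss curve but no
#'   metrics. Default TRUE.
#' @param eval_every evaluate the held-out split every `eval_every` epochs
#'   (always at epoch 0 and the final epoch); default 1.
#' @param boundary_warmup epochs over which the weight of the level-set
#'   boundary terms is ramped linearly from 0 to its configured value
#'   (default 10; 0 disables the ramp). The unbounded distance-weighted term
#'   otherwise overwhelms the overlap terms before discriminative features
#'   exist and drives the network into all-background saturation; after the
#'   ramp the objective is exactly the configured compound loss.
#' @return list with `record` (data.frame of per-epoch metrics), trained
#'   `model`, `best_params` and `best_dice`.
#' @export
train <- function(model, train_samples, test_samples, lc = loss_config(),
                  epochs = 30, seed = 1L, batch_size = 8, lr = 3e-3,
                  threshold = 0.5, eval_train = TRUE, boundary_warmup = 10,
                  eval_every = 1) {
  if (length(train_samples) == 0L) stop("empty training set")
  prep_tr <- prepare_samples(train_samples, lc)
  prep_te <- prepare_samples(test_samples, lc)
  sup <- model$config$supervised_layers
  m <- adam_init(model$params); v <- adam_init(model$params)
  set.seed(seed)
  rec <- list()
  add_row <- function(epoch, split, loss, met) {
    data.frame(epoch = epoch, split = split, loss = loss,
               dice = met["dice"], miou = met["miou"], pa = met["pa"],
               hausdorff = met["hausdorff"], row.names = NULL)
  }
  met0_tr <- eval_split(model, prep_tr, threshold)
  met0_te <- if (length(prep_te) > 0) eval_split(model, prep_te, threshold) else rep(NA_real_, 4)
  rec[[1]] <- add_row(0, "train", NA_real_, met0_tr)
  if (length(prep_te) > 0) rec[[2]] <- add_row(0, "test", NA_real_, met0_te)
  best_dice <- if (length(prep_te) > 0) met0_te["dice"] else met0_tr["dice"]
  best_params <- model$params
  step <- 0
  n <- length(prep_tr)
  for (ep in seq_len(epochs)) {
    bscale <- if (boundary_warmup > 0) min(1, ep / boundary_warmup) else 1
    ord <- sample.int(n)
    epoch_loss <- 0; nb <- 0
    train_preds <- vector("list", n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fws <- lapply(idx, function(i) model_forward(model, prep_tr[[i]]$image))
      bl <- batch_loss_grads(fws, prep_tr[idx], lc, sup, bscale)
      g <- NULL
      for (k in seq_along(idx)) {
        gk <- model_backward(model, fws[[k]], bl$grads[[k]]$d_region,
                             bl$grads[[k]]$d_edge, bl$grads[[k]]$d_features)
        g <- if (is.null(g)) gk else add_grads(g, gk)
        train_preds[[idx[k]]] <- fws[[k]]$region_probs$layer5
      }
      g <- scale_grads(g, 1 / length(idx))
      step <- step + 1
      upd <- adam_step(model$params, g, m, v, step, lr)
      model$params <- upd$params; m <- upd$m; v <- upd$v
      epoch_loss <- epoch_loss + bl$value; nb <- nb + 1
    }
    epoch_loss <- epoch_loss / nb
    met_tr <- rep(NA_real_, 4)
    names(met_tr) <- c("dice", "miou", "pa", "hausdorff")
    if (eval_train) {
      ev <- evaluate_batch(train_preds, lapply(prep_tr, `[[`, "target"), threshold)
      met_tr <- c(dice = unname(ev$means["dice"]), miou = ev$miou,
                  pa = unname(ev$means["pa"]), hausdorff = unname(ev$means["hausdorff"]))
    }
    rec[[length(rec) + 1]] <- add_row(ep, "train", epoch_loss, met_tr)
    if (length(prep_te) > 0 && (ep %% eval_every == 0 || ep == epochs)) {
      met_te <- eval_split(model, prep_te, threshold)
      rec[[length(rec) + 1]] <- add_row(ep, "test", epoch_loss, met_te)
      if (!is.na(met_te["dice"]) && met_te["dice"] >= best_dice) {
        best_dice <- met_te["dice"]; best_params <- model$params
      }
    }
  }
  record <- do.call(rbind, rec)
  rownames(record) <- NULL
  list(record = record, model = model, best_params = best_params,
       best_dice = unname(best_dice))
}

#' k-fold cross-validation
#'
#' Random seeded fold assignment (remainder samples spread one per fold);
#' trains one model per fold on the complement and evaluates on the fold.
#'
#' @param samples list of samples.
#' @param k number of folds (e.g. 3, 6 or 9).
#' @param epochs epochs per fold.
#' @param lc a [loss_config()].
#' @param seed seed controlling folds, model init and training.
#' @param ... further arguments passed to [train()].
#' @param config a [model_config()] template.
#' @return list with `folds` (per-fold index vectors), `records` (one
#'   TrainRecord per fold, with `fold` column) and `aggregate` (per-epoch
#'   mean of the test metrics over folds).
#' @export
cross_validate <- function(samples, k, epochs, lc = loss_config(), seed = 1L,
                           config = model_config(), ...) {
  n <- length(samples)
  if (k > n) stop("k must not exceed the number of samples")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))
  folds <- split(seq_len(n), fold_of)
  records <- list()
  for (f in seq_len(k)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
    cfg <- config; cfg$seed <- seed + f
    mdl <- build_model(cfg)
    res <- train(mdl, samples[tr], samples[te], lc, epochs,
                 seed = seed + 1000L * f, ...)
    res$record$fold <- f
    records[[f]] <- res$record
  }
  test_rows <- do.call(rbind, lapply(records, function(r) r[r$split == "test", ]))
  aggregate <- do.call(rbind, lapply(split(test_rows, test_rows$epoch), function(d) {
    data.frame(epoch = d$epoch[1], loss = mean(d$loss), dice = mean(d$dice),
               miou = mean(d$miou), pa = mean(d$pa),
               hausdorff = mean(d$hausdorff, na.rm = TRUE))
  }))
  rownames(aggregate) <- NULL
  list(folds = folds, records = records, aggregate = aggregate)
}

# first epoch whose loss is within 5% of the loss range above the final loss
epochs_to_plateau <- function(record) {
  tr <- record[record$split == "train" & record$epoch > 0, ]
  if (nrow(tr) < 2) return(NA_integer_)
  final <- tr$loss[nrow(tr)]
  rng <- max(tr$loss) - min(tr$loss)
  hit <- which(tr$loss <= final + 0.05 * rng)
  if (length(hit) == 0) NA_integer_ else tr$epoch[min(hit)]
}

#' Compare loss functions under identical conditions
#'
#' Trains one model per (loss, seed) pair with identical data, architecture
#' and optimizer, and tabulates the final test Dice and Hausdorff distance
#' and the epochs-to-plateau of the training loss.
#'
#' @param train_samples,test_samples sample lists shared by all runs.
#' @param loss_names character vector of [loss_config()] names.
#' @param epochs epochs per run.
#' @param seeds integer vector of seeds (one run per loss per seed).
#' @param config a [model_config()] template.
#' @param ... passed to [train()].
#' @return list with `table` (loss, seed, final_dice, final_hausdorff,
#'   plateau_epoch) and `records` (named list of TrainRecords).
#' @export
compare_losses <- function(train_samples, test_samples,
                           loss_names = c("focal_boundary_dice", "bce_iou",
                                          "bce_boundary", "shape_aware"),
                           epochs = 30, seeds = 1L,
                           config = model_config(), ...) {
  rows <- list(); records <- list()
  for (ln in loss_names) {
    lc <- loss_config(ln)
    for (sd in seeds) {
      cfg <- config; cfg$seed <- sd
      mdl <- build_model(cfg)
      res <- train(mdl, train_samples, test_samples, lc, epochs, seed = sd,
                   eval_train = FALSE, ...)
      te <- res$record[res$record$split == "test", ]
      fin <- te[which.max(te$epoch), ]
      key <- sprintf("%s_seed%d", ln, sd)
      records[[key]] <- res$record
      rows[[key]] <- data.frame(loss = ln, seed = sd,
                                final_dice = fin$dice,
                                final_hausdorff = fin$hausdorff,
                                plateau_epoch = epochs_to_plateau(res$record))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, records = records)
}

#' Benign/malignant shape classification with a small MLP
#'
#' Extracts [shape_features()] from every sample, holds out a stratified test
#' split, trains a single-hidden-layer perceptron (\pkg{nnet}) on the
#' standardized features and reports accuracy, sensitivity and specificity
#' with `"spiculated"` (the malignant analogue) as the positive class.
#'
#' @param samples list of samples with `mask`, `image` and `shape_label`.
#' @param seed seed for the split and the network initialization.
#' @param hidden hidden-layer size, default 8.
#' @param train_fraction fraction used for training, default 0.7.
#' @return list with `accuracy`, `sensitivity`, `specificity`, the fitted
#'   `fit` and the test-set `confusion` table.
#' @export
classify_shapes <- function(samples, seed = 1L, hidden = 8,
                            train_fraction = 0.7) {
  labels <- vapply(samples, `[[`, character(1), "shape_label")
  if (length(unique(labels)) < 2) stop("need both classes to train a classifier")
  feats <- t(vapply(samples, function(s) shape_features(s$mask, s$image),
                    numeric(4)))
  mu <- colMeans(feats); sdv <- apply(feats, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  y <- factor(labels, levels = c("smooth", "spiculated"))
  set.seed(seed)
  tr <- unlist(lapply(split(seq_along(y), y), function(ix) {
    sample(ix, max(1, round(length(ix) * train_fraction)))
  }))
  fit <- nnet::nnet(x[tr, , drop = FALSE], as.numeric(y[tr] == "spiculated"),
                    size = hidden, decay = 1e-3, maxit = 300, trace = FALSE,
                    entropy = TRUE)
  te <- setdiff(seq_along(y), tr)
  pred <- as.numeric(stats::predict(fit, x[te, , drop = FALSE]) >= 0.5)
  truth <- as.numeric(y[te] == "spiculated")
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  list(accuracy = (tp + tn) / length(te),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fit = fit, confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}
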