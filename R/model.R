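# leaky rectifier (slope 0.01) so units cannot die permanently
relu <- function(x) pmax(x, 0) + 0.001 * pmin(x, 0)
relu_mask <- function(z) (z > 0) + 0.001 * (z <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# apply A %*% X %*% t(B) to every channel of an [H,W,C] array: one GEMM over
# rows for all channels at once, a permute, one GEMM over columns, permute back
ch_apply <- function(x, A, B) {
  d <- dim(x)
  m <- A %*% matrix(x, nrow = d[1])                   # (H2 x W*C)
  m <- aperm(array(m, c(nrow(A), d[2], d[3])), c(2, 1, 3))
  m <- B %*% matrix(m, nrow = d[2])                   # (W2 x H2*C)
  aperm(array(m, c(nrow(B), nrow(A), d[3])), c(2, 1, 3))
}

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# 2x average-pooling matrix (n/2 x n)
.pool_mat <- function(n) {
  P <- matrix(0, n / 2, n)
  P[cbind(rep(seq_len(n / 2), each = 2), seq_len(n))] <- 0.5
  P
}

# 2x upsampling matrix (2n x n); bilinear (half-pixel centers) or nearest
.up_mat <- function(n, mode = "bilinear") {
  U <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    s <- (i - 0.5) / 2 - 0.5  # 0-based source position
    l <- floor(s); f <- s - l
    if (mode == "nearest") { l <- round(s); f <- 0 }
    l0 <- min(max(l, 0), n - 1)
    l1 <- min(max(l + 1, 0), n - 1)
    U[i, l0 + 1] <- U[i, l0 + 1] + (1 - f)
    U[i, l1 + 1] <- U[i, l1 + 1] + f
  }
  U
}

# cache of pooling/upsampling matrices keyed by size and mode
.get_mat <- function(model, kind, n) {
  key <- paste0(kind, n)
  if (is.null(model$ops[[key]])) {
    model$ops[[key]] <- switch(kind,
      pool = .pool_mat(n),
      up = .up_mat(n, model$config$upsampling))
  }
  model$ops[[key]]
}

pool2 <- function(model, x) {
  d <- dim(x)
  ch_apply(x, .get_mat(model, "pool", d[1]), .get_mat(model, "pool", d[2]))
}
pool2_adj <- function(model, dy) {
  d <- dim(dy)
  ch_apply(dy, t(.get_mat(model, "pool", 2 * d[1])), t(.get_mat(model, "pool", 2 * d[2])))
}
up2 <- function(model, x) {
  d <- dim(x)
  ch_apply(x, .get_mat(model, "up", d[1]), .get_mat(model, "up", d[2]))
}
up2_adj <- function(model, dy) {
  d <- dim(dy)
  ch_apply(dy, t(.get_mat(model, "up", d[1] / 2)), t(.get_mat(model, "up", d[2] / 2)))
}

conv3 <- function(x, w, b) {
  d <- dim(x); co <- dim(w)[4]
  array(conv3x3_fwd_cpp(as.numeric(x), as.numeric(w), b, d[1], d[2], d[3], co),
        c(d[1], d[2], co))
}
conv3_bwd <- function(x, w, dy) {
  d <- dim(x); co <- dim(w)[4]
  r <- conv3x3_bwd_cpp(as.numeric(x), as.numeric(w), as.numeric(dy),
                       d[1], d[2], d[3], co)
  list(dx = array(r$dx, d), dw = array(r$dw, dim(w)), db = r$db)
}

# per-channel instance normalization (zero mean, unit variance over H x W);
# keeps head logits on a bounded scale regardless of feature magnitude
inorm_fwd <- function(x, eps = 1e-3) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  s <- sqrt(colMeans(ctr^2) + eps)
  list(y = array(sweep(ctr, 2, s, "/"), d), s = s)
}
inorm_bwd <- function(y, s, dy) {
  d <- dim(y)
  ym <- matrix(y, ncol = d[3]); dym <- matrix(dy, ncol = d[3])
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(ym, 2, colMeans(dym * ym), "*")
  array(sweep(t1 - t2, 2, s, "/"), d)
}

conv1 <- function(x, w, b) {
  d <- dim(x)
  y <- matrix(x, ncol = d[3]) %*% w
  array(sweep(y, 2, b, "+"), c(d[1], d[2], ncol(w)))
}
conv1_bwd <- function(x, w, dy) {
  d <- dim(x)
  dym <- matrix(dy, ncol = ncol(w))
  xm <- matrix(x, ncol = d[3])
  list(dx = array(dym %*% t(w), d), dw = t(xm) %*% dym, db = colSums(dym))
}

#' Model configuration for the toy segmentation network
#'
#' A five-level fully convolutional encoder-decoder. The decoder exposes
#' three deeply supervised region heads -- at 1/4, 1/2 and full resolution,
#' referred to as layers 3, 4 and 5 -- each upsampled to the input size, plus
#' an edge head whose sigmoid map gates the decoder features at the
#' configured level through a residual boundary attention module
#' (`features * (1 + edge_map)`).
#'
#' @param base_channels channels at the first level (doubled down the
#'   encoder), default 4.
#' @param supervised_layers which of the three region heads (3, 4, 5) enter
#'   the training loss.
#' @param edge_layer decoder level carrying the boundary attention module:
#'   2 (default, half resolution) or 1 (full resolution).
#' @param upsampling `"bilinear"` (default) or `"nearest"`.
#' @param seed parameter-initialization seed.
#' @return list of class `model_config`.
#' @export
model_config <- function(base_channels = 4, supervised_layers = c(3, 4, 5),
                         edge_layer = 2, upsampling = c("bilinear", "nearest"),
                         seed = 1L) {
  if (!all(supervised_layers %in% 3:5) || length(supervised_layers) == 0) {
    stop("supervised_layers must be a non-empty subset of {3,4,5}")
  }
  if (!edge_layer %in% c(1, 2)) stop("edge_layer must be 1 or 2")
  structure(list(base_channels = as.integer(base_channels),
                 supervised_layers = sort(unique(supervised_layers)),
                 edge_layer = as.integer(edge_layer),
                 upsampling = match.arg(upsampling), seed = as.integer(seed)),
            class = "model_config")
}

.he_conv <- function(cin, cout) {
  array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
}

#' Build the segmentation model
#'
#' Allocates seeded parameters for the five-level encoder-decoder described
#' in [model_config()]. Activations are leaky rectifiers (slope 0.001) and
#' every prediction head reads instance-normalized features, so units cannot
#' die permanently and head logits stay on a bounded scale; head biases start
#' at -2 so that initial predictions reflect the small-foreground prior. The
#' network is fully convolutional and accepts any input whose sides are
#' divisible by 16.
#'
#' @param config a [model_config()].
#' @return list of class `boundseg_model` with `params`, `config` and an
#'   operator cache.
#' @export
build_model <- function(config = model_config()) {
  C <- config$base_channels
  ch <- list(c1 = C, c2 = 2L * C, c3 = 4L * C, c4 = 8L * C, c5 = 8L * C,
             d4 = 4L * C, d3 = 2L * C, d2 = 2L * C, d1 = C)
  set.seed(config$seed)
  pr <- list(
    c1 = list(w = .he_conv(1, ch$c1), b = numeric(ch$c1)),
    c2 = list(w = .he_conv(ch$c1, ch$c2), b = numeric(ch$c2)),
    c3 = list(w = .he_conv(ch$c2, ch$c3), b = numeric(ch$c3)),
    c4 = list(w = .he_conv(ch$c3, ch$c4), b = numeric(ch$c4)),
    c5 = list(w = .he_conv(ch$c4, ch$c5), b = numeric(ch$c5)),
    g4 = list(w = .he_conv(ch$c5 + ch$c4, ch$d4), b = numeric(ch$d4)),
    g3 = list(w = .he_conv(ch$d4 + ch$c3, ch$d3), b = numeric(ch$d3)),
    g2 = list(w = .he_conv(ch$d3 + ch$c2, ch$d2), b = numeric(ch$d2)),
    g1 = list(w = .he_conv(ch$d2 + ch$c1, ch$d1), b = numeric(ch$d1)),
    h3 = list(w = matrix(rnorm(ch$d3, sd = sqrt(1 / ch$d3)), ch$d3, 1), b = -2),
    h4 = list(w = matrix(rnorm(ch$d2, sd = sqrt(1 / ch$d2)), ch$d2, 1), b = -2),
    h5 = list(w = matrix(rnorm(ch$d1, sd = sqrt(1 / ch$d1)), ch$d1, 1), b = -2),
    he = list(w = matrix(rnorm(ifelse(config$edge_layer == 2, ch$d2, ch$d1),
                               sd = 0.1), ncol = 1), b = -2))
  structure(list(params = pr, config = config, channels = ch,
                 ops = new.env(parent = emptyenv())),
            class = "boundseg_model")
}

#' Forward pass
#'
#' @param model a [build_model()] result.
#' @param image numeric H x W matrix (sides divisible by 16), values in
#'   \[0,1\].
#' @return list with `region_probs` (three probability maps -- layers 3, 4, 5
#'   -- all at input size), `edge_prob` (input size), `features` (final
#'   decoder feature array) and an internal `cache` for the backward pass.
#' @export
model_forward <- function(model, image) {
  p <- model$params
  H <- nrow(image); W <- ncol(image)
  if (H %% 16 != 0 || W %% 16 != 0) stop("image sides must be divisible by 16")
  x <- array(image, c(H, W, 1))
  z1 <- conv3(x, p$c1$w, p$c1$b); e1 <- relu(z1)
  p1 <- pool2(model, e1)
  z2 <- conv3(p1, p$c2$w, p$c2$b); e2 <- relu(z2)
  p2 <- pool2(model, e2)
  z3 <- conv3(p2, p$c3$w, p$c3$b); e3 <- relu(z3)
  p3 <- pool2(model, e3)
  z4 <- conv3(p3, p$c4$w, p$c4$b); e4 <- relu(z4)
  p4 <- pool2(model, e4)
  z5 <- conv3(p4, p$c5$w, p$c5$b); e5 <- relu(z5)

  cat4 <- concat_ch(up2(model, e5), e4)
  zg4 <- conv3(cat4, p$g4$w, p$g4$b); d4 <- relu(zg4)
  cat3 <- concat_ch(up2(model, d4), e3)
  zg3 <- conv3(cat3, p$g3$w, p$g3$b); d3 <- relu(zg3)
  cat2 <- concat_ch(up2(model, d3), e2)
  zg2 <- conv3(cat2, p$g2$w, p$g2$b); d2 <- relu(zg2)

  edge_at_2 <- model$config$edge_layer == 2
  if (edge_at_2) {
    ne <- inorm_fwd(d2)
    elog <- conv1(ne$y, p$he$w, p$he$b)
    E <- sigmoid(elog)
    gated <- d2 * as.numeric(1 + E)  # broadcast over channels
    cat1 <- concat_ch(up2(model, gated), e1)
  } else {
    E <- NULL; gated <- d2; ne <- NULL
    cat1 <- concat_ch(up2(model, d2), e1)
  }
  zg1 <- conv3(cat1, p$g1$w, p$g1$b); d1 <- relu(zg1)
  if (!edge_at_2) {
    ne <- inorm_fwd(d1)
    elog <- conv1(ne$y, p$he$w, p$he$b)
    E <- sigmoid(elog)
    d1_out <- d1 * as.numeric(1 + E)
  } else {
    d1_out <- d1
  }

  n3 <- inorm_fwd(d3)
  r3log <- conv1(n3$y, p$h3$w, p$h3$b); P3 <- sigmoid(r3log)
  head_src4 <- if (edge_at_2) gated else d2
  n4 <- inorm_fwd(head_src4)
  r4log <- conv1(n4$y, p$h4$w, p$h4$b); P4 <- sigmoid(r4log)
  n5 <- inorm_fwd(d1_out)
  r5log <- conv1(n5$y, p$h5$w, p$h5$b); P5 <- sigmoid(r5log)

  P3up <- up2(model, up2(model, P3))
  P4up <- up2(model, P4)
  Eup <- if (edge_at_2) up2(model, E) else E

  cache <- list(x = x, z1 = z1, e1 = e1, p1 = p1, z2 = z2, e2 = e2, p2 = p2,
                z3 = z3, e3 = e3, p3 = p3, z4 = z4, e4 = e4, p4 = p4,
                z5 = z5, e5 = e5, cat4 = cat4, zg4 = zg4, d4 = d4,
                cat3 = cat3, zg3 = zg3, d3 = d3, cat2 = cat2, zg2 = zg2,
                d2 = d2, E = E, gated = gated, cat1 = cat1, zg1 = zg1,
                d1 = d1, d1_out = d1_out, P3 = P3, P4 = P4, P5 = P5,
                head_src4 = head_src4, n3 = n3, n4 = n4, n5 = n5, ne = ne)
  list(region_probs = list(layer3 = P3up[, , 1], layer4 = P4up[, , 1],
                           layer5 = P5[, , 1]),
       edge_prob = Eup[, , 1], features = d1_out, cache = cache)
}

#' Backward pass
#'
#' Propagates gradients of a scalar loss taken with respect to the model
#' outputs back to every parameter.
#'
#' @param model the model.
#' @param fw result of [model_forward()].
#' @param d_region list of three gradient matrices w.r.t. the upsampled
#'   region probability maps (zeros allowed).
#' @param d_edge gradient matrix w.r.t. the upsampled edge probability map.
#' @param d_features optional gradient array w.r.t. the final decoder
#'   features.
#' @return list of parameter gradients parallel to `model$params`.
#' @export
model_backward <- function(model, fw, d_region, d_edge, d_features = NULL) {
  p <- model$params; cc <- fw$cache
  edge_at_2 <- model$config$edge_layer == 2
  g <- list()
  arr1 <- function(m) array(m, c(nrow(m), ncol(m), 1L))

  # heads
  dP5 <- arr1(d_region[[3]])
  dr5 <- dP5 * cc$P5 * (1 - cc$P5)
  b5 <- conv1_bwd(cc$n5$y, p$h5$w, dr5)
  g$h5 <- list(w = b5$dw, b = b5$db)
  dd1_out <- inorm_bwd(cc$n5$y, cc$n5$s, b5$dx)
  if (!is.null(d_features)) dd1_out <- dd1_out + d_features

  dP4 <- up2_adj(model, arr1(d_region[[2]]))
  dr4 <- dP4 * cc$P4 * (1 - cc$P4)
  b4 <- conv1_bwd(cc$n4$y, p$h4$w, dr4)
  g$h4 <- list(w = b4$dw, b = b4$db)
  dhead4 <- inorm_bwd(cc$n4$y, cc$n4$s, b4$dx)

  dP3 <- up2_adj(model, up2_adj(model, arr1(d_region[[1]])))
  dr3 <- dP3 * cc$P3 * (1 - cc$P3)
  b3 <- conv1_bwd(cc$n3$y, p$h3$w, dr3)
  g$h3 <- list(w = b3$dw, b = b3$db)
  dd3_extra <- inorm_bwd(cc$n3$y, cc$n3$s, b3$dx)

  if (edge_at_2) {
    dE <- up2_adj(model, arr1(d_edge))
    dgated <- dhead4
    # d1 path
    dz1g <- dd1_out * relu_mask(cc$zg1)
    bb <- conv3_bwd(cc$cat1, p$g1$w, dz1g)
    g$g1 <- list(w = bb$dw, b = bb$db)
    D2 <- dim(cc$d2)[3]
    dgated <- dgated + up2_adj(model, bb$dx[, , seq_len(D2), drop = FALSE])
    de1 <- bb$dx[, , D2 + seq_len(dim(cc$e1)[3]), drop = FALSE]
    # gating: gated = d2 * (1 + E)
    dd2 <- dgated * as.numeric(1 + cc$E)
    dE <- dE + array(rowSums(matrix(dgated * cc$d2, ncol = D2)), dim(cc$E))
    delog <- dE * cc$E * (1 - cc$E)
    be <- conv1_bwd(cc$ne$y, p$he$w, delog)
    g$he <- list(w = be$dw, b = be$db)
    dd2 <- dd2 + inorm_bwd(cc$ne$y, cc$ne$s, be$dx)
  } else {
    # attention at layer 1: d1_out = d1 * (1 + E), E = sigmoid(conv1(d1))
    dE <- arr1(d_edge)
    dd1 <- dd1_out * as.numeric(1 + cc$E)
    dE <- dE + array(rowSums(matrix(dd1_out * cc$d1, ncol = dim(cc$d1)[3])),
                     dim(cc$E))
    delog <- dE * cc$E * (1 - cc$E)
    be <- conv1_bwd(cc$ne$y, p$he$w, delog)
    g$he <- list(w = be$dw, b = be$db)
    dd1 <- dd1 + inorm_bwd(cc$ne$y, cc$ne$s, be$dx)
    dz1g <- dd1 * relu_mask(cc$zg1)
    bb <- conv3_bwd(cc$cat1, p$g1$w, dz1g)
    g$g1 <- list(w = bb$dw, b = bb$db)
    D2 <- dim(cc$d2)[3]
    dd2 <- dhead4 + up2_adj(model, bb$dx[, , seq_len(D2), drop = FALSE])
    de1 <- bb$dx[, , D2 + seq_len(dim(cc$e1)[3]), drop = FALSE]
  }

  # decoder level 2
  dz2g <- dd2 * relu_mask(cc$zg2)
  bb <- conv3_bwd(cc$cat2, p$g2$w, dz2g)
  g$g2 <- list(w = bb$dw, b = bb$db)
  D3 <- dim(cc$d3)[3]
  dd3 <- dd3_extra + up2_adj(model, bb$dx[, , seq_len(D3), drop = FALSE])
  de2 <- bb$dx[, , D3 + seq_len(dim(cc$e2)[3]), drop = FALSE]

  dz3g <- dd3 * relu_mask(cc$zg3)
  bb <- conv3_bwd(cc$cat3, p$g3$w, dz3g)
  g$g3 <- list(w = bb$dw, b = bb$db)
  D4 <- dim(cc$d4)[3]
  dd4 <- up2_adj(model, bb$dx[, , seq_len(D4), drop = FALSE])
  de3 <- bb$dx[, , D4 + seq_len(dim(cc$e3)[3]), drop = FALSE]

  dz4g <- dd4 * relu_mask(cc$zg4)
  bb <- conv3_bwd(cc$cat4, p$g4$w, dz4g)
  g$g4 <- list(w = bb$dw, b = bb$db)
  C5 <- dim(cc$e5)[3]
  de5 <- up2_adj(model, bb$dx[, , seq_len(C5), drop = FALSE])
  de4 <- bb$dx[, , C5 + seq_len(dim(cc$e4)[3]), drop = FALSE]

  # encoder chain
  dz5 <- de5 * relu_mask(cc$z5)
  bb <- conv3_bwd(cc$p4, p$c5$w, dz5)
  g$c5 <- list(w = bb$dw, b = bb$db)
  de4 <- de4 + pool2_adj(model, bb$dx)

  dz4 <- de4 * relu_mask(cc$z4)
  bb <- conv3_bwd(cc$p3, p$c4$w, dz4)
  g$c4 <- list(w = bb$dw, b = bb$db)
  de3 <- de3 + pool2_adj(model, bb$dx)

  dz3 <- de3 * relu_mask(cc$z3)
  bb <- conv3_bwd(cc$p2, p$c3$w, dz3)
  g$c3 <- list(w = bb$dw, b = bb$db)
  de2 <- de2 + pool2_adj(model, bb$dx)

  dz2 <- de2 * relu_mask(cc$z2)
  bb <- conv3_bwd(cc$p1, p$c2$w, dz2)
  g$c2 <- list(w = bb$dw, b = bb$db)
  de1 <- de1 + pool2_adj(model, bb$dx)

  dz1 <- de1 * relu_mask(cc$z1)
  bb <- conv3_bwd(cc$x, p$c1$w, dz1)
  g$c1 <- list(w = bb$dw, b = bb$db)

  g[names(model$params)]
}
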