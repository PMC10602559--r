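# Ventricle segmentation: a U-Net-backbone network with recurrent residual
# convolutional units (RRCU), skip connections fusing two consecutive encoder
# levels, attention gates plus channel attention, and an atrous spatial
# pyramid pooling (ASPP) bottleneck; a classical threshold baseline; and the
# overlap metrics (IoU, Dice, precision, recall).

#' Segmentation model configuration
#'
#' @param input_channels Input image channels (fluorescence videos: 1).
#' @param base_width Channels of the first encoder level; doubled per level.
#' @param depth Number of encoder levels (>= 2); inputs must be divisible by
#'   `2^depth`.
#' @param rrcu_steps Recurrence steps unrolled in each recurrent conv layer.
#' @param use_attention Enable attention gates on skip paths and channel
#'   attention in encoder/decoder stages.
#' @param use_aspp Enable the ASPP bottleneck.
#' @param aspp_dilations Dilation rates of the ASPP branches.
#' @param dropout Dropout fraction applied to bottleneck features during
#'   training (0 disables).
#' @return A `seg_config` list.
#' @export
seg_config <- function(input_channels = 1L, base_width = 8L, depth = 2L,
                       rrcu_steps = 2L, use_attention = TRUE,
                       use_aspp = TRUE, aspp_dilations = c(1L, 2L, 4L, 8L),
                       dropout = 0) {
  stopifnot(depth >= 2L, base_width >= 4L, rrcu_steps >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(input_channels = as.integer(input_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 rrcu_steps = as.integer(rrcu_steps),
                 use_attention = isTRUE(use_attention),
                 use_aspp = isTRUE(use_aspp),
                 aspp_dilations = as.integer(aspp_dilations),
                 dropout = dropout),
            class = "seg_config")
}

# ---- architecture blocks ---------------------------------------------------

# Recurrent residual convolutional unit: a 1x1 input projection followed by
# two recurrent 3x3 conv layers (weights shared across `steps` unrolled
# iterations, each re-injecting the projected input), with a residual
# connection around the pair.
rrcu_block <- function(tape, P, x, cout, steps, prefix) {
  cin <- dim(x$value)[3L]
  w0 <- P(paste0(prefix, ".in.w"), function() init_conv(1L, 1L, cin, cout))
  b0 <- P(paste0(prefix, ".in.b"), function() numeric(cout))
  x1 <- ad_conv2d(tape, x, w0, b0)
  h <- x1
  for (layer in 1:2) {
    wl <- P(sprintf("%s.rcl%d.w", prefix, layer),
            function() init_conv(3L, 3L, cout, cout))
    bl <- P(sprintf("%s.rcl%d.b", prefix, layer),
            function() numeric(cout))
    z <- h
    for (s in seq_len(steps)) {
      z <- ad_relu(tape, ad_add(tape, ad_conv2d(tape, z, wl, bl), h))
    }
    h <- z
  }
  ad_add(tape, x1, h)
}

# channel attention (squeeze-and-excitation): global pooled descriptor ->
# bottleneck 1x1 convs -> per-channel sigmoid scale
se_block <- function(tape, P, x, prefix) {
  C <- dim(x$value)[3L]
  Cr <- max(4L, C %/% 2L)
  g <- ad_gap_hw(tape, x)
  w1 <- P(paste0(prefix, ".w1"), function() init_conv(1L, 1L, C, Cr))
  b1 <- P(paste0(prefix, ".b1"), function() numeric(Cr))
  w2 <- P(paste0(prefix, ".w2"), function() init_conv(1L, 1L, Cr, C))
  b2 <- P(paste0(prefix, ".b2"), function() numeric(C))
  a <- ad_relu(tape, ad_conv2d(tape, g, w1, b1))
  s <- ad_sigmoid(tape, ad_conv2d(tape, a, w2, b2))
  ad_mul_bcast(tape, x, s)
}

# additive attention gate on a skip path: the decoder features g gate the
# encoder features x through a single-channel sigmoid map
attn_gate <- function(tape, P, x, g, prefix) {
  Cx <- dim(x$value)[3L]
  Cg <- dim(g$value)[3L]
  Fi <- max(4L, Cx %/% 2L)
  wx <- P(paste0(prefix, ".wx"), function() init_conv(1L, 1L, Cx, Fi))
  wg <- P(paste0(prefix, ".wg"), function() init_conv(1L, 1L, Cg, Fi))
  bg <- P(paste0(prefix, ".bg"), function() numeric(Fi))
  wp <- P(paste0(prefix, ".wp"), function() init_conv(1L, 1L, Fi, 1L))
  bp <- P(paste0(prefix, ".bp"), function() numeric(1L))
  a <- ad_relu(tape, ad_add(tape, ad_conv2d(tape, x, wx),
                            ad_conv2d(tape, g, wg, bg)))
  psi <- ad_sigmoid(tape, ad_conv2d(tape, a, wp, bp))
  ad_mul_bcast(tape, x, psi)
}

# atrous spatial pyramid pooling: parallel dilated 3x3 branches, concatenated
# and fused back to the input width by a 1x1 conv
aspp_block <- function(tape, P, x, dilations, prefix) {
  C <- dim(x$value)[3L]
  Cb <- max(4L, C %/% length(dilations))
  branches <- lapply(seq_along(dilations), function(k) {
    wk <- P(sprintf("%s.d%d.w", prefix, k),
            function() init_conv(3L, 3L, C, Cb))
    bk <- P(sprintf("%s.d%d.b", prefix, k), function() numeric(Cb))
    ad_relu(tape, ad_conv2d(tape, x, wk, bk,
                            dil = c(dilations[k], dilations[k])))
  })
  cc <- ad_concat_c(tape, branches)
  wf <- P(paste0(prefix, ".fuse.w"),
          function() init_conv(1L, 1L, Cb * length(dilations), C))
  bf <- P(paste0(prefix, ".fuse.b"), function() numeric(C))
  ad_relu(tape, ad_conv2d(tape, cc, wf, bf))
}

ad_dropout <- function(tape, x, p) {
  keep <- array(stats::runif(length(x$value)) >= p, dim(x$value)) / (1 - p)
  ad_mul_bcast(tape, x, ad_leaf(tape, keep, track = FALSE))
}

# full network graph; P provides parameters by name (creating them on first
# use during initialisation). Returns per-pixel logits.
zvseg_graph <- function(tape, P, x, cfg, training = FALSE) {
  d <- cfg$depth
  bw <- cfg$base_width
  enc <- vector("list", d)
  cur <- x
  for (i in seq_len(d)) {
    e <- rrcu_block(tape, P, cur, bw * 2L^(i - 1L), cfg$rrcu_steps,
                    paste0("enc", i))
    if (cfg$use_attention) e <- se_block(tape, P, e, paste0("enc", i, ".se"))
    enc[[i]] <- e
    cur <- ad_maxpool(tape, e, 2L, 2L)
  }
  b <- rrcu_block(tape, P, cur, bw * 2L^d, cfg$rrcu_steps, "bottleneck")
  if (cfg$use_aspp) b <- aspp_block(tape, P, b, cfg$aspp_dilations, "aspp")
  if (training && cfg$dropout > 0) b <- ad_dropout(tape, b, cfg$dropout)
  cur <- b
  for (i in seq(d, 1L)) {
    up <- ad_upsample(tape, cur, 2L, 2L)
    # fuse two consecutive encoder levels into this decoder level
    s1 <- enc[[i]]
    s2 <- if (i > 1L) ad_maxpool(tape, enc[[i - 1L]], 2L, 2L)
          else ad_upsample(tape, enc[[2L]], 2L, 2L)
    if (cfg$use_attention) {
      s1 <- attn_gate(tape, P, s1, up, paste0("dec", i, ".att1"))
      s2 <- attn_gate(tape, P, s2, up, paste0("dec", i, ".att2"))
    }
    cur <- ad_concat_c(tape, list(up, s1, s2))
    cur <- rrcu_block(tape, P, cur, bw * 2L^(i - 1L), cfg$rrcu_steps,
                      paste0("dec", i))
    if (cfg$use_attention) cur <- se_block(tape, P, cur, paste0("dec", i, ".se"))
  }
  wo <- P("head.w", function() init_conv(1L, 1L, bw, 1L))
  bo <- P("head.b", function() numeric(1L))
  ad_conv2d(tape, cur, wo, bo)
}

# ---- model construction and inference --------------------------------------

#' Build the ventricle segmentation network
#'
#' Instantiates the segmentation model: a U-Net backbone whose double
#' convolutions are replaced by recurrent residual convolutional units, with
#' each decoder level fusing skip features from two consecutive encoder
#' levels, optional attention gates / channel attention, and an optional ASPP
#' bottleneck. The forward pass maps an H x W single-channel image (H and W
#' divisible by `2^depth`) to an H x W foreground probability map in
#' `[0, 1]`.
#'
#' @param config A [seg_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `zvsegnet` model object (config plus named parameter arrays).
#' @export
build_zvsegnet <- function(config = seg_config(), seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  store <- new.env(parent = emptyenv())
  ord <- character(0)
  P <- function(name, init) {
    if (is.null(store[[name]])) {
      store[[name]] <- init()
      ord <<- c(ord, name)
    }
    ad_leaf(NULL, store[[name]], track = FALSE)
  }
  sz <- 2L^config$depth * 2L
  dummy <- array(0, c(sz, sz, config$input_channels, 1L))
  with_seed(seed, zvseg_graph(NULL, P, ad_leaf(NULL, dummy, track = FALSE),
                              config))
  params <- mget(ord, envir = store)
  structure(list(config = config, params = params), class = "zvsegnet")
}

#' Number of trainable parameters of a model
#'
#' @param model A `zvsegnet` or `hrnet` model.
#' @return Total parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_seg_input <- function(model, h, w) {
  m <- 2L^model$config$depth
  if (h %% m != 0L || w %% m != 0L)
    stop("input size ", h, "x", w, " is not divisible by 2^depth = ", m,
         "; pad the input or use segment_video(), which pads and crops")
}

# run the network on an (H, W, C, N) batch without gradient tracking
seg_forward_prob <- function(model, x, chunk = 16L) {
  d <- dim(x)
  check_seg_input(model, d[1L], d[2L])
  out <- array(0, c(d[1L], d[2L], 1L, d[4L]))
  Pf <- function(name, init) ad_leaf(NULL, model$params[[name]],
                                     track = FALSE)
  for (start in seq(1L, d[4L], by = chunk)) {
    idx <- start:min(start + chunk - 1L, d[4L])
    xb <- ad_leaf(NULL, x[, , , idx, drop = FALSE], track = FALSE)
    lg <- zvseg_graph(NULL, Pf, xb, model$config)
    out[, , , idx] <- 1 / (1 + exp(-lg$value))
  }
  out
}

#' Segmentation forward pass
#'
#' @param model A trained `zvsegnet`.
#' @param image H x W matrix (or H x W x C array) with H, W divisible by
#'   `2^depth`.
#' @return H x W foreground probability map in `[0, 1]`.
#' @export
predict_seg <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  x <- array(normalize_frame(image[, , 1L]), c(dim(image)[1:2], 1L, 1L))
  seg_forward_prob(model, x)[, , 1L, 1L]
}

# per-frame min-max normalisation to [0, 1]; constant frames map to zeros
normalize_frame <- function(f) {
  r <- range(f)
  if (r[2] - r[1] < 1e-12) return(f * 0)
  (f - r[1]) / (r[2] - r[1])
}

# pad an (H, W) frame to multiples of m by edge replication; returns padded
# matrix plus the original size for cropping back
pad_to_multiple <- function(f, m) {
  h <- nrow(f); w <- ncol(f)
  H <- as.integer(ceiling(h / m) * m)
  W <- as.integer(ceiling(w / m) * m)
  if (H > h) f <- f[c(seq_len(h), rep(h, H - h)), , drop = FALSE]
  if (W > w) f <- f[, c(seq_len(w), rep(w, W - w)), drop = FALSE]
  list(frame = f, h = h, w = w)
}

# ---- training ---------------------------------------------------------------

frames_to_batch <- function(frames) {
  h <- nrow(frames[[1]]$image)
  w <- ncol(frames[[1]]$image)
  n <- length(frames)
  x <- array(0, c(h, w, 1L, n))
  y <- array(0, c(h, w, 1L, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- normalize_frame(frames[[i]]$image)
    m <- frames[[i]]$mask
    if (!all(m %in% c(0L, 1L))) stop("non-binary mask in training data")
    y[, , 1L, i] <- m
  }
  list(x = x, y = y)
}

#' Train the segmentation network
#'
#' Supervised training with a Dice + binary cross-entropy loss and the Adam
#' optimiser; the model with the best validation loss across epochs is
#' returned. Deterministic for a fixed seed.
#'
#' @param train_set,val_set Lists of `labeled_frame`s (see
#'   [make_seg_dataset()]); all frames must share one size divisible by
#'   `2^depth`.
#' @param config A [seg_config()].
#' @param epochs,batch_size,lr Training loop settings.
#' @param dice_weight Weight of the Dice term relative to cross-entropy.
#' @param seed Integer seed (weights, shuffling, dropout).
#' @param threshold Binarisation threshold for the validation IoU.
#' @param verbose Print per-epoch progress.
#' @return A `seg_training` list: `model` (best-on-validation `zvsegnet`) and
#'   `history` (data frame: epoch, train_loss, val_loss, val_iou, val_dice).
#' @export
train_segmenter <- function(train_set, val_set, config = seg_config(),
                            epochs = 8L, batch_size = 8L, lr = 2e-3,
                            dice_weight = 1, seed = 1L, threshold = 0.5,
                            verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("empty training or validation set")
  tr <- frames_to_batch(train_set)
  va <- frames_to_batch(val_set)
  d <- dim(tr$x)
  check_seg_input(list(config = config), d[1L], d[2L])

  model <- build_zvsegnet(config, seed = seed)
  params <- model$params
  opt <- adam_init(params)
  n <- d[4L]
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_iou = numeric(),
                        val_dice = numeric())
  best <- list(loss = Inf, params = params)

  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      tl <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        tape <- ad_tape_new()
        pn <- ad_wrap_params(tape, params)
        Pb <- function(name, init) pn[[name]]
        xb <- ad_leaf(tape, tr$x[, , , bi, drop = FALSE], track = FALSE)
        lg <- zvseg_graph(tape, Pb, xb, config,
                          training = config$dropout > 0)
        loss <- ad_bce_dice_loss(tape, lg, tr$y[, , , bi, drop = FALSE],
                                 dice_weight)
        ad_backward(tape, loss)
        grads <- ad_collect_grads(pn)
        st <- adam_step(params, grads, opt, lr = lr)
        params <- st$params
        opt <- st$state
        tl <- tl + loss$value
        nb <- nb + 1L
      }
      mdl <- structure(list(config = config, params = params),
                       class = "zvsegnet")
      pr <- seg_forward_prob(mdl, va$x)
      eps <- 1e-12
      vbce <- mean(-(va$y * log(pr + eps) + (1 - va$y) * log(1 - pr + eps)))
      vdice <- (2 * sum(pr * va$y) + 1e-6) / (sum(pr) + sum(va$y) + 1e-6)
      vloss <- vbce + dice_weight * (1 - vdice)
      pm <- (pr > threshold) * 1L
      mt <- overlap_counts(pm, va$y)
      viou <- if (mt$union == 0) 1 else mt$tp / mt$union
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tl / nb, val_loss = vloss,
        val_iou = viou, val_dice = 2 * viou / (1 + viou)))
      if (vloss < best$loss) best <- list(loss = vloss, params = params)
      if (verbose)
        message(sprintf("epoch %d  train %.4f  val %.4f  IoU %.3f",
                        ep, tl / nb, vloss, viou))
    }
  })
  structure(list(model = structure(list(config = config,
                                        params = best$params),
                                   class = "zvsegnet"),
                 history = history),
            class = "seg_training")
}

# ---- video segmentation -----------------------------------------------------

# keep only the largest 4-connected foreground component (ties broken by
# lowest label; empty masks pass through)
largest_component <- function(mask) {
  if (!any(mask > 0)) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  lab <- EBImage::bwlabel(mask > 0)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- (lab == keep) * 1L
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' Segment a heart video with a trained model
#'
#' Runs the network per frame (with per-frame min-max normalisation and
#' edge padding to the divisibility constraint, cropped back afterwards),
#' binarises at `threshold`, and keeps the largest connected component.
#' Frames with no pixel above threshold yield empty masks.
#'
#' @param model A trained `zvsegnet`, or the string `"baseline"` for the
#'   classical threshold segmenter.
#' @param video A [heart_video()].
#' @param threshold Probability binarisation threshold in (0, 1).
#' @return A [mask_sequence()].
#' @export
segment_video <- function(model, video, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (identical(model, "baseline")) return(baseline_segment(video))
  d <- dim(video)
  m <- 2L^model$config$depth
  p1 <- pad_to_multiple(video[, , 1L], m)
  dp <- dim(p1$frame)
  x <- array(0, c(dp[1L], dp[2L], 1L, d[3L]))
  for (t in seq_len(d[3L]))
    x[, , 1L, t] <- pad_to_multiple(normalize_frame(video[, , t]), m)$frame
  pr <- seg_forward_prob(model, x)
  out <- array(0L, d)
  for (t in seq_len(d[3L])) {
    mk <- (pr[seq_len(d[1L]), seq_len(d[2L]), 1L, t] > threshold) * 1L
    out[, , t] <- largest_component(mk)
  }
  mask_sequence(out)
}

#' Classical baseline segmentation
#'
#' Deterministic model-free segmenter: per-frame min-max normalisation, a
#' global threshold (Otsu's method, or a rank-based quantile threshold that
#' is invariant to affine intensity rescaling), hole filling and selection of
#' the largest connected component. Frames without separable foreground
#' (dynamic range ~ 0) yield empty masks.
#'
#' @param video A [heart_video()] or H x W x T array.
#' @param method `"otsu"` or `"quantile"`.
#' @param q Quantile for the rank-based threshold.
#' @return A [mask_sequence()].
#' @export
baseline_segment <- function(video, method = c("otsu", "quantile"),
                             q = 0.8) {
  method <- match.arg(method)
  d <- dim(video)
  out <- array(0L, d)
  for (t in seq_len(d[3L])) {
    f <- video[, , t]
    r <- range(f)
    if (r[2] - r[1] < 1e-9) next
    if (method == "otsu") {
      fn <- normalize_frame(f)
      th <- EBImage::otsu(fn, range = c(0, 1))
      mk <- fn > th
    } else {
      mk <- f > stats::quantile(f, q)
    }
    mk <- EBImage::fillHull(mk * 1L)
    out[, , t] <- largest_component(mk)
  }
  mask_sequence(out)
}

# ---- evaluation -------------------------------------------------------------

overlap_counts <- function(pred, truth) {
  p <- pred > 0
  t <- truth > 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  list(tp = tp, fp = fp, fn = fn, union = tp + fp + fn)
}

metrics_from_counts <- function(ct) {
  if (ct$union == 0) return(list(iou = 1, dice = 1, precision = 1, recall = 1))
  iou <- ct$tp / ct$union
  list(iou = iou,
       dice = 2 * ct$tp / (2 * ct$tp + ct$fp + ct$fn),
       precision = if (ct$tp + ct$fp == 0) 1 else ct$tp / (ct$tp + ct$fp),
       recall = if (ct$tp + ct$fn == 0) 1 else ct$tp / (ct$tp + ct$fn))
}

#' Segmentation overlap metrics
#'
#' Computes IoU (`TP / (TP + FP + FN)`), Dice (`2 TP / (2 TP + FP + FN)`),
#' precision and recall between aligned binary mask sequences. By default
#' confusion counts are pooled over all frames; `mode = "per_frame"` averages
#' per-frame metrics instead. An empty union (both masks empty) scores 1 in
#' every metric; precision (recall) with no predicted (true) foreground is
#' reported as 1, vacuously.
#'
#' @param predicted,truth [mask_sequence()]s (or single binary matrices) of
#'   identical shape.
#' @param mode `"pooled"` or `"per_frame"`.
#' @return A `seg_metrics` list: `iou`, `dice`, `precision`, `recall`.
#' @export
seg_metrics <- function(predicted, truth, mode = c("pooled", "per_frame")) {
  mode <- match.arg(mode)
  if (is.matrix(predicted)) predicted <- array(predicted, c(dim(predicted), 1L))
  if (is.matrix(truth)) truth <- array(truth, c(dim(truth), 1L))
  if (!all(dim(predicted) == dim(truth)))
    stop("mask sequences must have identical shape")
  if (mode == "pooled") {
    m <- metrics_from_counts(overlap_counts(predicted, truth))
  } else {
    nt <- dim(predicted)[3L]
    per <- lapply(seq_len(nt), function(t)
      metrics_from_counts(overlap_counts(predicted[, , t], truth[, , t])))
    m <- list(iou = mean(vapply(per, `[[`, 0, "iou")),
              dice = mean(vapply(per, `[[`, 0, "dice")),
              precision = mean(vapply(per, `[[`, 0, "precision")),
              recall = mean(vapply(per, `[[`, 0, "recall")))
  }
  structure(c(m, list(mode = mode)), class = "seg_metrics")
}
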