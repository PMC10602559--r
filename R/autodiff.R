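# Reverse-mode automatic differentiation over dense arrays.
#
# A "tape" records operation nodes in execution order; ad_backward() walks it
# in reverse, accumulating gradients into leaf nodes. Tensors are plain R
# arrays; images/feature maps use dim (H, W, C, N), matrices (N, D). The
# engine implements only the operations the networks in this package need;
# every gradient is checked against central finite differences in the test
# suite.

ad_tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$track <- track
  if (track && !is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ad_leaf <- function(tape, value, track = TRUE) {
  ad_node(tape, value, track = track)
}

ad_accum <- function(node, g) {
  if (!node$track) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- broadcasting helpers -------------------------------------------------

.bcast <- function(s, dx) {
  ds <- dim(s)
  idx <- lapply(seq_along(dx), function(k)
    if (ds[k] == dx[k]) seq_len(dx[k]) else rep(1L, dx[k]))
  do.call(`[`, c(list(s), idx, list(drop = FALSE)))
}

# sum array over axis k, keeping that axis with extent 1
.sum_along <- function(a, k) {
  d <- dim(a)
  nd <- length(d)
  perm <- c(k, seq_len(nd)[-k])
  m <- matrix(aperm(a, perm), nrow = d[k])
  s <- colSums(m)
  arr <- array(s, dim = c(1L, d[-k]))
  aperm(arr, order(perm))
}

.reduce_to <- function(g, ds) {
  for (k in seq_along(ds)) {
    if (ds[k] != dim(g)[k]) g <- .sum_along(g, k)
  }
  g
}

# ---- elementwise ----------------------------------------------------------

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], nd$grad)
  })
}

ad_relu <- function(tape, x) {
  v <- x$value
  v[v < 0] <- 0
  ad_node(tape, v, list(x), function(nd) {
    g <- nd$grad
    g[nd$parents[[1L]]$value <= 0] <- 0
    ad_accum(nd$parents[[1L]], g)
  })
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), function(nd) {
    s <- nd$value
    ad_accum(nd$parents[[1L]], nd$grad * s * (1 - s))
  })
}

ad_softplus <- function(tape, x) {
  v <- x$value
  out <- ifelse(v > 30, v, log1p(exp(pmin(v, 30))))
  ad_node(tape, out, list(x), function(nd) {
    v <- nd$parents[[1L]]$value
    ad_accum(nd$parents[[1L]], nd$grad / (1 + exp(-v)))
  })
}

# multiply x by s; dim(s) equals dim(x) except broadcast axes of extent 1
ad_mul_bcast <- function(tape, x, s) {
  dx <- dim(x$value)
  ds <- dim(s$value)
  stopifnot(length(dx) == length(ds), all(ds == dx | ds == 1L))
  ad_node(tape, x$value * .bcast(s$value, dx), list(x, s), function(nd) {
    x <- nd$parents[[1L]]
    s <- nd$parents[[2L]]
    ad_accum(x, nd$grad * .bcast(s$value, dim(x$value)))
    ad_accum(s, .reduce_to(nd$grad * x$value, dim(s$value)))
  })
}

# ---- convolution / pooling / resampling (H, W, C, N) ----------------------

# stride-1 same-size convolution with optional dilation; bias per out-channel
ad_conv2d <- function(tape, x, w, b = NULL, dil = c(1L, 1L)) {
  dil <- as.integer(dil)
  y <- conv2d_fwd(x$value, w$value, dil)
  if (!is.null(b)) {
    d <- dim(y)
    y <- y + .bcast(array(b$value, c(1L, 1L, d[3L], 1L)), d)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(tape, y, parents, function(nd) {
    x <- nd$parents[[1L]]
    w <- nd$parents[[2L]]
    r <- conv2d_bwd(x$value, w$value, nd$grad, dil)
    ad_accum(x, r$gx)
    ad_accum(w, r$gw)
    if (length(nd$parents) == 3L) {
      d <- dim(nd$grad)
      gb <- .reduce_to(nd$grad, c(1L, 1L, d[3L], 1L))
      ad_accum(nd$parents[[3L]], as.numeric(gb))
    }
  })
}

# max pooling with window (ph, pw) == stride; dims must be divisible
ad_maxpool <- function(tape, x, ph = 2L, pw = 2L) {
  v <- x$value
  d <- dim(v)
  stopifnot(d[1L] %% ph == 0L, d[2L] %% pw == 0L)
  Ho <- d[1L] %/% ph
  Wo <- d[2L] %/% pw
  best <- array(-Inf, c(Ho, Wo, d[3L], d[4L]))
  arg <- array(1L, c(Ho, Wo, d[3L], d[4L]))
  slot <- 0L
  for (j in seq_len(pw)) {
    for (i in seq_len(ph)) {
      slot <- slot + 1L
      sub <- v[seq(i, d[1L], by = ph), seq(j, d[2L], by = pw), , ,
               drop = FALSE]
      upd <- sub > best
      best[upd] <- sub[upd]
      arg[upd] <- slot
    }
  }
  ad_node(tape, best, list(x), function(nd) {
    x <- nd$parents[[1L]]
    d <- dim(x$value)
    gx <- array(0, d)
    slot <- 0L
    for (j in seq_len(pw)) {
      for (i in seq_len(ph)) {
        slot <- slot + 1L
        g <- nd$grad
        g[arg != slot] <- 0
        gx[seq(i, d[1L], by = ph), seq(j, d[2L], by = pw), , ] <-
          gx[seq(i, d[1L], by = ph), seq(j, d[2L], by = pw), , ,
             drop = FALSE] + g
      }
    }
    ad_accum(x, gx)
  })
}

# nearest-neighbour upsampling by (fh, fw)
ad_upsample <- function(tape, x, fh = 2L, fw = 2L) {
  v <- x$value
  d <- dim(v)
  y <- v[rep(seq_len(d[1L]), each = fh), rep(seq_len(d[2L]), each = fw), , ,
         drop = FALSE]
  ad_node(tape, y, list(x), function(nd) {
    d <- dim(nd$parents[[1L]]$value)
    g <- nd$grad
    gx <- array(0, d)
    for (j in seq_len(fw)) {
      for (i in seq_len(fh)) {
        gx <- gx + g[seq(i, d[1L] * fh, by = fh),
                     seq(j, d[2L] * fw, by = fw), , , drop = FALSE]
      }
    }
    ad_accum(nd$parents[[1L]], gx)
  })
}

# concatenate along the channel axis (3rd)
ad_concat_c <- function(tape, xs) {
  vals <- lapply(xs, function(x) x$value)
  dims <- vapply(vals, function(v) dim(v)[3L], integer(1))
  d1 <- dim(vals[[1L]])
  y <- array(0, c(d1[1L], d1[2L], sum(dims), d1[4L]))
  off <- 0L
  for (k in seq_along(vals)) {
    y[, , off + seq_len(dims[k]), ] <- vals[[k]]
    off <- off + dims[k]
  }
  ad_node(tape, y, xs, function(nd) {
    off <- 0L
    for (k in seq_along(nd$parents)) {
      ck <- dim(nd$parents[[k]]$value)[3L]
      ad_accum(nd$parents[[k]],
               nd$grad[, , off + seq_len(ck), , drop = FALSE])
      off <- off + ck
    }
  })
}

# global average pool over H and W -> (1, 1, C, N)
ad_gap_hw <- function(tape, x) {
  d <- dim(x$value)
  m <- .sum_along(.sum_along(x$value, 1L), 2L) / (d[1L] * d[2L])
  ad_node(tape, m, list(x), function(nd) {
    d <- dim(nd$parents[[1L]]$value)
    ad_accum(nd$parents[[1L]],
             .bcast(nd$grad, d) / (d[1L] * d[2L]))
  })
}

# (1, 1, C, N) feature map -> (N, C) matrix
ad_flatten <- function(tape, x) {
  d <- dim(x$value)
  stopifnot(d[1L] == 1L, d[2L] == 1L)
  y <- t(matrix(x$value, d[3L], d[4L]))
  ad_node(tape, y, list(x), function(nd) {
    d <- dim(nd$parents[[1L]]$value)
    ad_accum(nd$parents[[1L]], array(t(nd$grad), d))
  })
}

# ---- dense layers (N, D) --------------------------------------------------

ad_matmul <- function(tape, x, w) {
  ad_node(tape, x$value %*% w$value, list(x, w), function(nd) {
    x <- nd$parents[[1L]]
    w <- nd$parents[[2L]]
    ad_accum(x, nd$grad %*% t(w$value))
    ad_accum(w, t(x$value) %*% nd$grad)
  })
}

# add a length-D bias row to an (N, D) matrix
ad_bias_row <- function(tape, x, b) {
  ad_node(tape, sweep(x$value, 2L, b$value, `+`), list(x, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], colSums(nd$grad))
  })
}

# ---- losses (fused; return scalar node) -----------------------------------

# mean over all elements of binary cross-entropy with logits, plus
# dice_weight * (1 - soft Dice) pooled over the whole batch
ad_bce_dice_loss <- function(tape, logits, target, dice_weight = 1,
                             eps = 1e-6) {
  z <- logits$value
  t <- target
  m <- length(z)
  bce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  inter <- sum(p * t)
  denom <- sum(p) + sum(t) + eps
  dice <- (2 * inter + eps) / denom
  loss <- bce + dice_weight * (1 - dice)
  ad_node(tape, loss, list(logits), function(nd) {
    g_bce <- (p - t) / m
    g_dice <- -(2 * t * denom - (2 * inter + eps)) / denom^2
    gz <- nd$grad * (g_bce + dice_weight * g_dice * p * (1 - p))
    ad_accum(nd$parents[[1L]], gz)
  })
}

# mean squared error between an (N, 1) prediction and a length-N target
ad_mse_loss <- function(tape, pred, target) {
  e <- as.numeric(pred$value) - as.numeric(target)
  n <- length(e)
  ad_node(tape, mean(e^2), list(pred), function(nd) {
    g <- nd$grad * 2 * e / n
    ad_accum(nd$parents[[1L]], array(g, dim(nd$parents[[1L]]$value)))
  })
}

# ---- parameter handling and optimiser -------------------------------------

# He-normal weight initialisation for conv kernels (kh, kw, Cin, Cout)
init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_dense <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
}

# wrap a named list of parameter arrays as tracked leaves on a tape
ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

ad_collect_grads <- function(nodes) {
  lapply(nodes, function(nd) {
    if (is.null(nd$grad)) array(0, dim(as.array(nd$value))) else nd$grad
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
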