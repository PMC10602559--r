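# Heart-rate estimation from 1-D ventricular-area traces: a 3-layer 1-D CNN
# feeding a multi-kernel inception stage and a 3-layer MLP regressor, plus a
# classical peak-counting oracle and the evaluation metrics (RMSE, MAE,
# Pearson r, error SD).

#' Heart-rate model configuration
#'
#' The architecture is fixed to three parts: a 3-layer 1-D CNN extracting
#' low-level features, an inception stage with parallel kernels capturing
#' peaks at multiple scales, and a 3-layer MLP that maps the globally pooled
#' features to a single non-negative heart rate.
#'
#' @param input_length Input sequence length in samples; traces of other
#'   lengths are resampled (see [preprocess_trace()]).
#' @param cnn_channels Exactly 3 channel counts for the CNN layers.
#' @param inception_kernel_sizes Kernel sizes of the parallel inception
#'   branches (odd integers).
#' @param mlp_widths Exactly 3 MLP layer widths; the last must be 1.
#' @return An `hr_config` list.
#' @export
hr_config <- function(input_length = 100L, cnn_channels = c(8L, 16L, 16L),
                      inception_kernel_sizes = c(3L, 7L, 15L),
                      mlp_widths = c(32L, 16L, 1L)) {
  if (length(cnn_channels) != 3L)
    stop("the CNN part has exactly 3 layers; give 3 channel counts")
  if (length(mlp_widths) != 3L || mlp_widths[3L] != 1L)
    stop("the MLP part has exactly 3 layers ending in width 1")
  if (any(inception_kernel_sizes %% 2L == 0L))
    stop("inception kernel sizes must be odd")
  structure(list(input_length = as.integer(input_length),
                 cnn_channels = as.integer(cnn_channels),
                 inception_kernel_sizes = as.integer(inception_kernel_sizes),
                 mlp_widths = as.integer(mlp_widths)),
            class = "hr_config")
}

#' Preprocess an area trace for the heart-rate network
#'
#' Linearly resamples the trace to `input_length` samples, then standardises
#' it to zero mean and unit variance; constant traces map to all zeros.
#'
#' @param trace An [as_area_trace()] object or numeric vector (length >= 2).
#' @param input_length Target length.
#' @return A standardised numeric vector of length `input_length`.
#' @export
preprocess_trace <- function(trace, input_length = 100L) {
  x <- as.numeric(trace)
  if (length(x) < 2L) stop("trace must have at least 2 samples")
  if (length(x) != input_length)
    x <- stats::approx(seq_along(x), x, n = input_length)$y
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, input_length))
  (x - mean(x)) / s
}

# traces are carried as (1, L, C, N) arrays so the 2-D conv kernels apply
hr_graph <- function(tape, P, x, cfg) {
  cur <- x
  for (k in 1:3) {
    cin <- dim(cur$value)[3L]
    co <- cfg$cnn_channels[k]
    wk <- P(sprintf("cnn%d.w", k), function() init_conv(1L, 5L, cin, co))
    bk <- P(sprintf("cnn%d.b", k), function() numeric(co))
    cur <- ad_relu(tape, ad_conv2d(tape, cur, wk, bk))
    if (k < 3L) cur <- ad_maxpool(tape, cur, 1L, 2L)
  }
  cin <- dim(cur$value)[3L]
  branches <- lapply(seq_along(cfg$inception_kernel_sizes), function(j) {
    ks <- cfg$inception_kernel_sizes[j]
    wj <- P(sprintf("inc%d.w", j), function() init_conv(1L, ks, cin, 8L))
    bj <- P(sprintf("inc%d.b", j), function() numeric(8L))
    ad_relu(tape, ad_conv2d(tape, cur, wj, bj))
  })
  feat <- ad_flatten(tape, ad_gap_hw(tape, ad_concat_c(tape, branches)))
  din <- ncol(feat$value)
  for (k in 1:3) {
    dout <- cfg$mlp_widths[k]
    wk <- P(sprintf("mlp%d.w", k), function() init_dense(din, dout))
    bk <- P(sprintf("mlp%d.b", k),
            function() if (k == 3L) 100 else numeric(dout))
    feat <- ad_bias_row(tape, ad_matmul(tape, feat, wk), bk)
    if (k < 3L) feat <- ad_relu(tape, feat)
    din <- dout
  }
  ad_softplus(tape, feat)   # non-negative bpm, (N, 1)
}

#' Build the heart-rate estimation network
#'
#' @param config An [hr_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An `hrnet` model object.
#' @export
build_hrnet <- function(config = hr_config(), seed = 1L) {
  stopifnot(inherits(config, "hr_config"))
  store <- new.env(parent = emptyenv())
  ord <- character(0)
  P <- function(name, init) {
    if (is.null(store[[name]])) {
      store[[name]] <- init()
      ord <<- c(ord, name)
    }
    ad_leaf(NULL, store[[name]], track = FALSE)
  }
  dummy <- array(0, c(1L, config$input_length, 1L, 1L))
  with_seed(seed, hr_graph(NULL, P, ad_leaf(NULL, dummy, track = FALSE),
                           config))
  structure(list(config = config, params = mget(ord, envir = store)),
            class = "hrnet")
}

traces_to_batch <- function(traces, input_length) {
  n <- length(traces)
  x <- array(0, c(1L, input_length, 1L, n))
  for (i in seq_len(n))
    x[1L, , 1L, i] <- preprocess_trace(traces[[i]], input_length)
  x
}

#' Estimate heart rates with a trained network
#'
#' @param model A trained `hrnet`.
#' @param traces A single trace or a list of traces (see
#'   [preprocess_trace()]).
#' @return Numeric vector of heart rates, beats/minute.
#' @export
predict_hr <- function(model, traces) {
  if (!is.list(traces)) traces <- list(traces)
  x <- traces_to_batch(traces, model$config$input_length)
  Pf <- function(name, init) ad_leaf(NULL, model$params[[name]],
                                     track = FALSE)
  out <- hr_graph(NULL, Pf, ad_leaf(NULL, x, track = FALSE), model$config)
  as.numeric(out$value)
}

#' Classical peak-counting heart-rate oracle
#'
#' Detects cardiac cycles on the raw area trace and converts the complete
#' cycle count to beats/minute over the trace duration. Deterministic and
#' model-free.
#'
#' @param trace An [as_area_trace()] object.
#' @param ... Passed to [detect_cycles()].
#' @return Heart rate in beats/minute, with attribute `status` (`"ok"` or
#'   `"no heartbeat"`, in which case the value is 0).
#' @export
hr_peak_oracle <- function(trace, ...) {
  cm <- detect_cycles(trace, ...)
  duration <- length(trace) / attr(trace, "fps")
  bpm <- hr_from_cycles(cm$n_cycles, duration)
  attr(bpm, "status") <- cm$status
  bpm
}

#' Train the heart-rate network
#'
#' Mean-squared-error regression on beats/minute with the Adam optimiser.
#' Deterministic for a fixed seed.
#'
#' @param traces List of area traces (length >= 10).
#' @param bpm Numeric vector of true heart rates (> 0), one per trace.
#' @param config An [hr_config()].
#' @param ratio Train:validation ratio for the internal split.
#' @param epochs,batch_size,lr Training loop settings.
#' @param seed Integer seed (split, weights, shuffling).
#' @return An `hr_training` list: `model`, `metrics` (validation
#'   [hr_metrics()]), `history` (per-epoch losses), and the validation
#'   indices used.
#' @export
train_hrnet <- function(traces, bpm, config = hr_config(), ratio = c(4, 1),
                        epochs = 60L, batch_size = 32L, lr = 3e-3,
                        seed = 1L) {
  if (length(traces) < 10L) stop("need at least 10 training examples")
  if (length(bpm) != length(traces)) stop("one label per trace required")
  if (any(bpm <= 0)) stop("heart-rate labels must be positive")
  if (stats::sd(bpm) < 1e-12)
    warning("all labels are equal; validation r will be undefined")

  sp <- split_dataset(seq_along(traces), ratio = ratio, seed = seed)
  tr_i <- unlist(sp$train)
  va_i <- unlist(sp$validation)
  xt <- traces_to_batch(traces[tr_i], config$input_length)
  xv <- traces_to_batch(traces[va_i], config$input_length)
  yt <- bpm[tr_i]
  yv <- bpm[va_i]

  model <- build_hrnet(config, seed = seed)
  params <- model$params
  opt <- adam_init(params)
  n <- length(tr_i)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_rmse = numeric())
  pred_batch <- function(params, x) {
    Pf <- function(name, init) ad_leaf(NULL, params[[name]], track = FALSE)
    as.numeric(hr_graph(NULL, Pf, ad_leaf(NULL, x, track = FALSE),
                        config)$value)
  }
  best <- list(rmse = Inf, params = params)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      tl <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        tape <- ad_tape_new()
        pn <- ad_wrap_params(tape, params)
        Pb <- function(name, init) pn[[name]]
        xb <- ad_leaf(tape, xt[, , , bi, drop = FALSE], track = FALSE)
        out <- hr_graph(tape, Pb, xb, config)
        loss <- ad_mse_loss(tape, out, yt[bi])
        ad_backward(tape, loss)
        st <- adam_step(params, ad_collect_grads(pn), opt, lr = lr)
        params <- st$params
        opt <- st$state
        tl <- tl + loss$value
        nb <- nb + 1L
      }
      pv <- pred_batch(params, xv)
      vr <- sqrt(mean((pv - yv)^2))
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                           val_rmse = vr))
      if (vr < best$rmse) best <- list(rmse = vr, params = params)
    }
  })
  final <- structure(list(config = config, params = best$params),
                     class = "hrnet")
  metrics <- hr_metrics(pred_batch(best$params, xv), yv)
  structure(list(model = final, metrics = metrics, history = history,
                 validation_idx = va_i),
            class = "hr_training")
}

#' Heart-rate estimation metrics
#'
#' RMSE, MAE, Pearson correlation and the population standard deviation of
#' signed errors, so that `rmse^2 = mean_error^2 + sd^2`. With zero variance
#' in either vector the correlation is undefined and reported as `NA`.
#'
#' @param predicted,truth Equal-length numeric vectors of heart rates.
#' @return An `hr_metrics` list: `rmse`, `mae`, `r`, `sd`, `mean_error`.
#' @export
hr_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  e <- predicted - truth
  r <- if (stats::sd(predicted) < 1e-12 || stats::sd(truth) < 1e-12) {
    warning("zero variance: Pearson correlation undefined")
    NA_real_
  } else stats::cor(predicted, truth)
  structure(list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), r = r,
                 sd = sqrt(mean((e - mean(e))^2)), mean_error = mean(e)),
            class = "hr_metrics")
}

#' @export
print.hr_metrics <- function(x, ...) {
  cat(sprintf("hr_metrics: RMSE=%.2f MAE=%.2f r=%.3f SD=%.2f bpm\n",
              x$rmse, x$mae, x$r, x$sd))
  invisible(x)
}
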