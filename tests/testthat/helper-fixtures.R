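# Shared fixtures and lazily trained models, cached across test files so the
# scaled-down training runs happen once per session.

.zf_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.zf_cache[[key]])) .zf_cache[[key]] <- builder()
  .zf_cache[[key]]
}

# scaled-down segmentation training: 200 frames, 6 epochs, fixed seed
seg_training_run <- function() {
  cached("seg_training", function() {
    frames <- make_seg_dataset(250, seed = 7)
    sp <- split_dataset(frames, c(4, 1), seed = 7)
    train_segmenter(sp$train[1:200], sp$validation, seg_config(),
                    epochs = 6, batch_size = 8, lr = 2e-3, seed = 11)
  })
}

seg_validation_frames <- function() {
  cached("seg_val_frames", function() {
    frames <- make_seg_dataset(250, seed = 7)
    split_dataset(frames, c(4, 1), seed = 7)$validation
  })
}

# scaled-down heart-rate training: 500 traces spanning 60-240 bpm, 4:1 split
hr_training_run <- function() {
  cached("hr_training", function() {
    ds <- make_hr_dataset(500, seed = 3)
    train_hrnet(ds$traces, ds$bpm, seed = 5)
  })
}

# noiseless simulations across heart rates (shared by recovery tests)
recovery_runs <- function() {
  cached("recovery", function() {
    lapply(c(90, 120, 150, 180), function(hr) {
      spec <- synth_heart_spec(hr_bpm = hr, noise_sd = 0, blur_sigma = 0,
                               jitter_px = 0,
                               contraction_frac = c(0.25, 0.25),
                               orientation_deg = 25)
      sim <- simulate_heart_video(spec)
      params <- analyze_video(baseline_segment(sim$video), 50)
      list(hr = hr, sim = sim, params = params)
    })
  })
}

screen_run <- function(seed = 21) {
  cached(paste0("screen", seed), function() {
    scr <- simulate_screen(seed = seed)
    list(scr = scr, result = screen_compounds(scr$larvae))
  })
}

# brute-force minimum-area rectangle over an angle grid (independent oracle)
brute_rect <- function(mask, step_deg = 0.5) {
  px <- which(mask > 0, arr.ind = TRUE)
  corners <- rbind(
    cbind(px[, 1] - 0.5, px[, 2] - 0.5), cbind(px[, 1] - 0.5, px[, 2] + 0.5),
    cbind(px[, 1] + 0.5, px[, 2] - 0.5), cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  best <- list(area = Inf)
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- corners[, 2] * cos(th) + corners[, 1] * sin(th)
    v <- -corners[, 2] * sin(th) + corners[, 1] * cos(th)
    a <- max(u) - min(u)
    b <- max(v) - min(v)
    if (a * b < best$area)
      best <- list(area = a * b, a = max(a, b), b = min(a, b))
  }
  best
}

random_blob <- function(h = 24, w = 24, n = 12) {
  m <- matrix(0L, h, w)
  m[cbind(sample(2:(h - 1), n, replace = TRUE),
          sample(2:(w - 1), n, replace = TRUE))] <- 1L
  m
}

# central finite-difference gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
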