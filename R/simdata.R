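# Synthetic beating-heart videos with exact ground truth, plus the
# dataset-construction protocol (train/validation split, augmentation,
# training-set expansion) used for the networks.

#' Specification of a simulated beating heart
#'
#' Describes one larval heart video as a bright, roughly elliptical ventricle
#' contracting periodically on a dim noisy background, optionally with an
#' out-of-phase atrium blob. Ground truth (masks, per-frame areas and axes,
#' heart rate, fractional area change / shortening) follows in closed form.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param fps Frame rate, frames per second.
#' @param n_frames Number of frames.
#' @param hr_bpm True heart rate, beats per minute.
#' @param ed_semi_axes Length-2 vector `(a0, b0)`: ellipse semi-axes in pixels
#'   at end-diastole, `a0 >= b0 > 0`.
#' @param contraction_frac Length-2 vector `(ca, cb)` in `[0, 1)`: fractional
#'   shortening of each semi-axis at end-systole.
#' @param orientation_deg Long-axis orientation, degrees counter-clockwise
#'   from the horizontal (column) axis.
#' @param centre Length-2 `(row, col)` centre in pixels; default image centre.
#' @param jitter_px Per-frame Gaussian translation noise scale, pixels.
#' @param fg_intensity,bg_intensity Foreground/background intensity in
#'   `[0, 1]`.
#' @param noise_sd Additive Gaussian noise scale.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param waveform Contraction waveform shape: `"raised_cosine"` (smooth,
#'   symmetric) or `"asymmetric"` (faster systole, slower diastole).
#' @param systole_frac For the asymmetric waveform, fraction of the cycle
#'   spent contracting.
#' @param atrium Optional atrium descriptor: a list with elements `offset`
#'   (row/col pixels from the ventricle centre), `semi_axes`, `intensity`,
#'   contracting in anti-phase. Not part of the ground-truth mask.
#' @param seed Integer seed controlling jitter and noise.
#'
#' @return An object of class `synth_heart_spec`.
#' @export
synth_heart_spec <- function(image_height = 64, image_width = 64,
                             fps = 50, n_frames = 100, hr_bpm = 120,
                             ed_semi_axes = c(16, 10),
                             contraction_frac = c(0.25, 0.25),
                             orientation_deg = 0,
                             centre = NULL,
                             jitter_px = 0,
                             fg_intensity = 0.85, bg_intensity = 0.15,
                             noise_sd = 0.03, blur_sigma = 1,
                             waveform = c("raised_cosine", "asymmetric"),
                             systole_frac = 0.35,
                             atrium = NULL, seed = 1L) {
  waveform <- match.arg(waveform)
  if (is.null(centre)) centre <- c((image_height + 1) / 2, (image_width + 1) / 2)
  spec <- structure(list(
    image_height = image_height, image_width = image_width,
    fps = fps, n_frames = as.integer(n_frames), hr_bpm = hr_bpm,
    ed_semi_axes = as.numeric(ed_semi_axes),
    contraction_frac = as.numeric(contraction_frac),
    orientation_deg = orientation_deg, centre = as.numeric(centre),
    jitter_px = jitter_px, fg_intensity = fg_intensity,
    bg_intensity = bg_intensity, noise_sd = noise_sd,
    blur_sigma = blur_sigma, waveform = waveform,
    systole_frac = systole_frac, atrium = atrium, seed = as.integer(seed)),
    class = "synth_heart_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  num <- unlist(spec[c("image_height", "image_width", "fps", "n_frames",
                       "hr_bpm", "ed_semi_axes", "contraction_frac",
                       "orientation_deg", "centre", "jitter_px",
                       "fg_intensity", "bg_intensity", "noise_sd",
                       "blur_sigma", "systole_frac")])
  if (!all(is.finite(num))) stop("spec contains non-finite fields")
  a0 <- spec$ed_semi_axes[1]; b0 <- spec$ed_semi_axes[2]
  ca <- spec$contraction_frac[1]; cb <- spec$contraction_frac[2]
  if (!(a0 >= b0 && b0 > 0)) stop("require ed_semi_axes a0 >= b0 > 0")
  if (!(ca >= 0 && ca < 1 && cb >= 0 && cb < 1))
    stop("contraction_frac must lie in [0, 1)")
  if (spec$hr_bpm <= 0) stop("hr_bpm must be positive")
  if (spec$fps <= 0) stop("fps must be positive")
  if (spec$n_frames < 1) stop("n_frames must be >= 1")
  if (!(spec$systole_frac > 0 && spec$systole_frac < 1))
    stop("systole_frac must lie in (0, 1)")
  invisible(spec)
}

# Periodic contraction waveform s(t) in [0, 1]; s = 0 at end-diastole
# (t = 0), s = 1 at end-systole. Frequency hr_bpm / 60 Hz.
contraction_waveform <- function(t_sec, hr_bpm,
                                 shape = c("raised_cosine", "asymmetric"),
                                 systole_frac = 0.35) {
  shape <- match.arg(shape)
  phase <- (t_sec * hr_bpm / 60) %% 1
  if (shape == "raised_cosine") return(0.5 * (1 - cos(2 * pi * phase)))
  sf <- systole_frac
  ifelse(phase < sf,
         0.5 * (1 - cos(pi * phase / sf)),
         0.5 * (1 + cos(pi * (phase - sf) / (1 - sf))))
}

# Rasterise an ellipse: pixel (r, c) is foreground iff its centre lies inside.
ellipse_mask <- function(h, w, centre, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(h), h, w) - centre[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - centre[2]
  u <- cc * cos(th) + r * sin(th)
  v <- -cc * sin(th) + r * cos(th)
  m <- (u / a)^2 + (v / b)^2 <= 1
  storage.mode(m) <- "integer"
  m
}

# Render one frame: mask-driven foreground plus optional atrium blob,
# Gaussian blur, additive noise, clipped to [0, 1]. Noise is drawn from the
# current RNG stream.
render_frame <- function(h, w, mask, fg, bg, noise_sd, blur_sigma,
                         atrium_img = NULL) {
  img <- bg + (fg - bg) * mask
  if (!is.null(atrium_img)) img <- pmax(img, atrium_img)
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Simulate a fluorescent beating-heart video with ground truth
#'
#' Generates `n_frames` frames in which the ventricle ellipse semi-axes
#' follow `a0 * (1 - ca * s(t))` and `b0 * (1 - cb * s(t))`, with `s(t)` a
#' periodic contraction waveform in `[0, 1]` at `hr_bpm / 60` Hz. The
#' returned masks are the exact rasterised ellipses before blur and noise.
#'
#' @param spec A [synth_heart_spec()].
#' @return A list with components `video` (`heart_video`: H x W x T array in
#'   `[0, 1]` with an `fps` attribute), `masks` (`mask_sequence`: H x W x T
#'   binary array), and `truth`, a list holding the analytic
#'   [cardiac_params()] (`EDA` ~ pi*a0*b0 etc.), a `per_frame` data frame
#'   (`frame`, `area_px`, `a_px`, `b_px` with full axes), and the spec.
#'   Deterministic for a fixed `spec$seed`.
#' @export
simulate_heart_video <- function(spec) {
  validate_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  n <- spec$n_frames
  a0 <- spec$ed_semi_axes[1]; b0 <- spec$ed_semi_axes[2]
  ca <- spec$contraction_frac[1]; cb <- spec$contraction_frac[2]

  video <- array(0, c(h, w, n))
  masks <- array(0L, c(h, w, n))
  per_frame <- data.frame(frame = seq_len(n), area_px = 0,
                          a_px = 0, b_px = 0)
  with_seed(spec$seed, {
    jit <- if (spec$jitter_px > 0)
      matrix(stats::rnorm(2 * n, sd = spec$jitter_px), n, 2) else
      matrix(0, n, 2)
    for (t in seq_len(n)) {
      s <- contraction_waveform((t - 1) / spec$fps, spec$hr_bpm,
                                spec$waveform, spec$systole_frac)
      at <- a0 * (1 - ca * s)
      bt <- b0 * (1 - cb * s)
      ctr <- spec$centre + jit[t, ]
      m <- ellipse_mask(h, w, ctr, at, bt, spec$orientation_deg)
      atr <- NULL
      if (!is.null(spec$atrium)) {
        sa <- contraction_waveform((t - 1) / spec$fps, spec$hr_bpm,
                                   spec$waveform, spec$systole_frac)
        shrink <- 1 - 0.2 * (1 - sa)   # anti-phase: largest at ventricle ES
        am <- ellipse_mask(h, w, ctr + spec$atrium$offset,
                           spec$atrium$semi_axes[1] * shrink,
                           spec$atrium$semi_axes[2] * shrink,
                           spec$orientation_deg)
        atr <- am * spec$atrium$intensity
      }
      video[, , t] <- render_frame(h, w, m, spec$fg_intensity,
                                   spec$bg_intensity, spec$noise_sd,
                                   spec$blur_sigma, atr)
      masks[, , t] <- m
      per_frame$area_px[t] <- sum(m)
      per_frame$a_px[t] <- 2 * at
      per_frame$b_px[t] <- 2 * bt
    }
  })

  eda <- pi * a0 * b0
  esa <- pi * a0 * (1 - ca) * b0 * (1 - cb)
  truth_params <- cardiac_params(
    EDA = eda, ESA = esa,
    ED_axes = axis_pair(2 * a0, 2 * b0, spec$orientation_deg),
    ES_axes = axis_pair(2 * a0 * (1 - ca), 2 * b0 * (1 - cb),
                        spec$orientation_deg),
    FAC = (1 - (1 - ca) * (1 - cb)) * 100,
    FS = ca * 100,
    SV = sv(axis_pair(2 * a0, 2 * b0), axis_pair(2 * a0 * (1 - ca),
                                                 2 * b0 * (1 - cb))),
    HR = spec$hr_bpm, edema = 1L,
    n_cycles = floor(spec$hr_bpm / 60 * n / spec$fps),
    status = "ok")

  list(video = heart_video(video, spec$fps),
       masks = mask_sequence(masks),
       truth = list(params = truth_params, per_frame = per_frame,
                    spec = spec))
}

#' Simulate a ventricular-area trace analytically
#'
#' Fast path for building heart-rate training data: produces the area signal
#' `pi * a(t) * b(t)` (arbitrary units, scaled and offset) directly from the
#' contraction waveform, without rasterising frames.
#'
#' @param hr_bpm True heart rate, beats/minute.
#' @param fps Frames per second.
#' @param n_frames Trace length.
#' @param baseline,amplitude Baseline area level and relative contraction
#'   depth of the signal.
#' @param phase Phase offset in cycles (`[0, 1)`).
#' @param noise_sd Additive noise as a fraction of `baseline`.
#' @param waveform,systole_frac As in [synth_heart_spec()].
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return An [as_area_trace()] object with attribute `true_bpm`.
#' @export
simulate_area_trace <- function(hr_bpm, fps = 50, n_frames = 100,
                                baseline = 1, amplitude = 0.45, phase = 0,
                                noise_sd = 0, waveform = "raised_cosine",
                                systole_frac = 0.35, seed = NULL) {
  gen <- function() {
    t_sec <- (seq_len(n_frames) - 1) / fps + phase * 60 / hr_bpm
    s <- contraction_waveform(t_sec, hr_bpm, waveform, systole_frac)
    x <- baseline * (1 - amplitude * s)
    if (noise_sd > 0) x <- x + stats::rnorm(n_frames, sd = noise_sd * baseline)
    x
  }
  x <- if (is.null(seed)) gen() else with_seed(seed, gen())
  tr <- as_area_trace(x, fps)
  attr(tr, "true_bpm") <- hr_bpm
  tr
}

#' Generate a labelled segmentation dataset of single frames
#'
#' Draws `n` independent frames with randomised ventricle size, contraction
#' state, orientation, position, optional dimmer atrium blob, blur and noise,
#' each paired with its exact rasterised mask.
#'
#' @param n Number of frames.
#' @param seed Integer seed.
#' @param image_height,image_width Frame size in pixels.
#' @param noise_range,blur_range Ranges for per-frame noise sd / blur sigma.
#' @param atrium_prob Probability a frame carries an atrium blob.
#' @return A list of `labeled_frame` objects: `image`, `mask`,
#'   `true_area_px`, `true_axes` (full axes, pixels).
#' @export
make_seg_dataset <- function(n, seed = 1L, image_height = 64,
                             image_width = 64, noise_range = c(0.02, 0.05),
                             blur_range = c(0.5, 1.2), atrium_prob = 0.5) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a0 <- stats::runif(1, 10, 15)
      b0 <- a0 * stats::runif(1, 0.5, 0.85)
      s <- stats::runif(1)                      # contraction state
      cfr <- stats::runif(1, 0, 0.35)
      a <- a0 * (1 - cfr * s); b <- b0 * (1 - cfr * s)
      th <- stats::runif(1, 0, 180)
      ctr <- c((image_height + 1) / 2, (image_width + 1) / 2) +
        stats::runif(2, -4, 4)
      m <- ellipse_mask(image_height, image_width, ctr, a, b, th)
      atr <- NULL
      if (stats::runif(1) < atrium_prob) {
        dir <- th * pi / 180
        off <- (a + 4) * c(sin(dir), cos(dir)) * sample(c(-1, 1), 1)
        am <- ellipse_mask(image_height, image_width, ctr + off,
                           a * 0.45, b * 0.45, th)
        atr <- am * stats::runif(1, 0.35, 0.5)
      }
      img <- render_frame(image_height, image_width, m,
                          fg = stats::runif(1, 0.75, 0.95),
                          bg = stats::runif(1, 0.1, 0.2),
                          noise_sd = stats::runif(1, noise_range[1], noise_range[2]),
                          blur_sigma = stats::runif(1, blur_range[1], blur_range[2]),
                          atrium_img = atr)
      structure(list(image = img, mask = m, true_area_px = sum(m),
                     true_axes = c(a = 2 * a, b = 2 * b)),
                class = "labeled_frame")
    })
  })
}

#' Generate a heart-rate training dataset of area traces
#'
#' @param n Number of traces.
#' @param bpm_range Range of true heart rates, beats/minute.
#' @param fps,n_frames Sampling rate and trace length.
#' @param noise_sd Additive noise fraction (per trace, up to this value).
#' @param seed Integer seed.
#' @return A list with `traces` (list of area traces) and `bpm`
#'   (numeric true heart rates).
#' @export
make_hr_dataset <- function(n, bpm_range = c(60, 240), fps = 50,
                            n_frames = 100, noise_sd = 0.04, seed = 1L) {
  with_seed(seed, {
    bpm <- stats::runif(n, bpm_range[1], bpm_range[2])
    traces <- lapply(seq_len(n), function(i) {
      simulate_area_trace(
        bpm[i], fps = fps, n_frames = n_frames,
        baseline = stats::runif(1, 0.5, 2),
        amplitude = stats::runif(1, 0.25, 0.6),
        phase = stats::runif(1),
        noise_sd = stats::runif(1, 0, noise_sd),
        waveform = if (stats::runif(1) < 0.5) "raised_cosine" else "asymmetric",
        systole_frac = stats::runif(1, 0.3, 0.5))
    })
    list(traces = traces, bpm = bpm)
  })
}

# ---- augmentation ---------------------------------------------------------

# Rotate an image about its centre by angle_deg (counter-clockwise in the
# row/col display convention) via inverse mapping. filter "bilinear" for
# intensity images, "nearest" for masks (preserves binarity). Output size
# unchanged; out-of-frame samples take `fill`.
rotate_image <- function(img, angle_deg, filter = c("bilinear", "nearest"),
                         fill = 0) {
  filter <- match.arg(filter)
  if (angle_deg %% 360 == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- -angle_deg * pi / 180          # inverse rotation
  rc <- (h + 1) / 2; cc <- (w + 1) / 2
  r <- matrix(seq_len(h), h, w) - rc
  cl <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  src_c <- cl * cos(th) - r * sin(th) + cc
  src_r <- cl * sin(th) + r * cos(th) + rc
  out <- matrix(fill, h, w)
  if (filter == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- matrix(fill, h, w)
      v[ok] <- img[cbind(ri[ok], ci[ok])]
      v
    }
    out <- gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  }
  out
}

#' Augment a labelled frame
#'
#' Applies a random rotation (image bilinear, mask nearest-neighbour, same
#' angle), horizontal/vertical flips, and brightness/contrast factors drawn
#' uniformly from `[0.9, 1.1]` to the image only. Explicit arguments override
#' the random draws; with all transforms disabled the frame is returned
#' unchanged.
#'
#' @param frame A `labeled_frame` (see [make_seg_dataset()]).
#' @param seed Integer seed for the random draws; `NULL` uses the current
#'   RNG stream.
#' @param angle Rotation angle in degrees (`NULL` = random in `[0, 360)`).
#' @param flip_h,flip_v Logical flips (`NULL` = random).
#' @param brightness,contrast Multiplicative factors (`NULL` = random in
#'   `[0.9, 1.1]`). Contrast pivots on mid-range 0.5; output clipped to
#'   `[0, 1]`.
#' @return The augmented `labeled_frame`; mask stays binary, dimensions
#'   unchanged.
#' @export
augment <- function(frame, seed = NULL, angle = NULL, flip_h = NULL,
                    flip_v = NULL, brightness = NULL, contrast = NULL) {
  stopifnot(inherits(frame, "labeled_frame"))
  draw <- function() {
    list(angle = if (is.null(angle)) stats::runif(1, 0, 360) else angle,
         flip_h = if (is.null(flip_h)) stats::runif(1) < 0.5 else flip_h,
         flip_v = if (is.null(flip_v)) stats::runif(1) < 0.5 else flip_v,
         brightness = if (is.null(brightness)) stats::runif(1, 0.9, 1.1)
                      else brightness,
         contrast = if (is.null(contrast)) stats::runif(1, 0.9, 1.1)
                    else contrast)
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())

  img <- frame$image
  msk <- frame$mask
  if (p$angle %% 360 != 0) {
    img <- rotate_image(img, p$angle, "bilinear", fill = min(img))
    msk <- rotate_image(msk, p$angle, "nearest", fill = 0L)
  }
  if (isTRUE(p$flip_h)) { img <- img[, ncol(img):1]; msk <- msk[, ncol(msk):1] }
  if (isTRUE(p$flip_v)) { img <- img[nrow(img):1, ]; msk <- msk[nrow(msk):1, ] }
  if (p$contrast != 1) img <- (img - 0.5) * p$contrast + 0.5
  if (p$brightness != 1) img <- img * p$brightness
  if (p$contrast != 1 || p$brightness != 1) {
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  storage.mode(msk) <- "integer"
  structure(list(image = img, mask = msk, true_area_px = sum(msk),
                 true_axes = frame$true_axes),
            class = "labeled_frame")
}

#' Split items into training and validation parts
#'
#' Random disjoint, exhaustive partition at an integer ratio (default 4:1).
#' The validation size is `floor(n * val / (train + val))`; the remainder
#' goes to training. Deterministic for a fixed seed.
#'
#' @param items A list (or vector) of items.
#' @param ratio Length-2 integer vector `c(train, val)`.
#' @param seed Integer seed.
#' @return A list with `train` and `validation` subsets.
#' @export
split_dataset <- function(items, ratio = c(4, 1), seed = 1L) {
  n <- length(items)
  n_val <- floor(n * ratio[2] / sum(ratio))
  if (n_val < 1 || n - n_val < 1)
    stop("split would leave an empty part (n = ", n, ")")
  idx <- with_seed(seed, sample.int(n))
  val_idx <- sort(idx[seq_len(n_val)])
  train_idx <- sort(idx[-seq_len(n_val)])
  list(train = items[train_idx], validation = items[val_idx])
}

#' Expand a training set by augmentation
#'
#' Returns the original frames plus `factor - 1` independently augmented
#' copies of each, so the result has `factor * length(train)` frames.
#'
#' @param train List of `labeled_frame`s.
#' @param factor Integer expansion factor (>= 1).
#' @param seed Integer seed.
#' @return The expanded list (originals first, verbatim).
#' @export
expand_training_set <- function(train, factor = 3L, seed = 1L) {
  stopifnot(factor >= 1)
  if (factor == 1L) return(train)
  with_seed(seed, {
    extra <- vector("list", (factor - 1L) * length(train))
    k <- 0L
    for (rep_i in seq_len(factor - 1L)) {
      for (fr in train) {
        k <- k + 1L
        extra[[k]] <- augment(fr)
      }
    }
    c(train, extra)
  })
}
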