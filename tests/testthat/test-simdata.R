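# Simulator ground truth, augmentation and dataset-construction protocol.

test_that("simulated video matches its closed-form ground truth", {
  spec <- synth_heart_spec(hr_bpm = 120, fps = 50, n_frames = 100,
                           ed_semi_axes = c(20, 10),
                           contraction_frac = c(0.25, 0.25),
                           noise_sd = 0, blur_sigma = 0, jitter_px = 0,
                           image_height = 64, image_width = 64)
  sim <- simulate_heart_video(spec)
  expect_equal(dim(sim$video), c(64, 64, 100))
  expect_equal(sim$truth$params$HR, 120)
  # 120 bpm over 2 s = 4 full cycles by construction
  expect_equal(sim$truth$params$n_cycles, 4)
  # ED frame mask area ~ pi*a0*b0 within rasterisation error
  expect_lt(abs(sum(sim$masks[, , 1]) - pi * 200) / (pi * 200), 0.03)
  # analytic FAC/FS from the contraction fractions
  expect_equal(sim$truth$params$FAC, (1 - 0.75^2) * 100)
  expect_equal(sim$truth$params$FS, 25)
  # per-frame truth area equals the mask pixel count
  expect_equal(sim$truth$per_frame$area_px,
               apply(sim$masks, 3, sum))
})

test_that("per-frame mask areas track pi*a(t)*b(t) within 3% for axes >= 8 px", {
  spec <- synth_heart_spec(hr_bpm = 150, ed_semi_axes = c(18, 9),
                           contraction_frac = c(0.2, 0.1),
                           orientation_deg = 40, noise_sd = 0,
                           blur_sigma = 0, jitter_px = 0)
  sim <- simulate_heart_video(spec)
  pf <- sim$truth$per_frame
  analytic <- pi * (pf$a_px / 2) * (pf$b_px / 2)
  expect_true(all(abs(pf$area_px - analytic) / analytic <= 0.03))
})

test_that("area trace is periodic at fps*60/hr frames (autocorrelation peak)", {
  spec <- synth_heart_spec(hr_bpm = 120, fps = 50, n_frames = 100,
                           noise_sd = 0, blur_sigma = 0)
  sim <- simulate_heart_video(spec)
  x <- sim$truth$per_frame$area_px
  lag_expected <- 50 * 60 / 120   # 25 frames
  ac <- stats::acf(x, lag.max = 40, plot = FALSE)$acf[-1]
  # the strongest positive-lag peak beyond half a period sits at the period
  peak <- which.max(ac[13:40]) + 12
  expect_equal(peak, lag_expected)
})

test_that("zero contraction gives a constant trace and zero FAC/FS", {
  spec <- synth_heart_spec(contraction_frac = c(0, 0), noise_sd = 0,
                           blur_sigma = 0, jitter_px = 0)
  sim <- simulate_heart_video(spec)
  expect_equal(length(unique(sim$truth$per_frame$area_px)), 1L)
  expect_equal(sim$truth$params$FAC, 0)
  expect_equal(sim$truth$params$FS, 0)
})

test_that("simulation is deterministic for a fixed seed and rejects bad specs", {
  s1 <- simulate_heart_video(synth_heart_spec(seed = 9, noise_sd = 0.05))
  s2 <- simulate_heart_video(synth_heart_spec(seed = 9, noise_sd = 0.05))
  expect_identical(s1$video, s2$video)
  expect_error(synth_heart_spec(ed_semi_axes = c(5, 10)), "a0 >= b0")
  expect_error(synth_heart_spec(hr_bpm = -3), "hr_bpm")
  expect_error(synth_heart_spec(contraction_frac = c(1, 0.2)), "contraction")
  expect_error(synth_heart_spec(fps = NaN), "non-finite")
})

test_that("augmentation: identity, involution, brightness arithmetic, binarity", {
  fr <- make_seg_dataset(1, seed = 2)[[1]]

  ident <- augment(fr, angle = 0, flip_h = FALSE, flip_v = FALSE,
                   brightness = 1, contrast = 1)
  expect_identical(ident$image, fr$image)
  expect_identical(ident$mask, fr$mask)

  f1 <- augment(fr, angle = 0, flip_h = TRUE, flip_v = FALSE,
                brightness = 1, contrast = 1)
  f2 <- augment(f1, angle = 0, flip_h = TRUE, flip_v = FALSE,
                brightness = 1, contrast = 1)
  expect_identical(f2$image, fr$image)

  # brightness factor multiplies intensities, clipped to [0, 1]
  flat <- fr
  flat$image <- matrix(c(0.5, 0.95), 64, 64)
  br <- augment(flat, angle = 0, flip_h = FALSE, flip_v = FALSE,
                brightness = 1.1, contrast = 1)
  expect_equal(br$image[1, 1], 0.55)
  expect_equal(br$image[2, 1], 1)   # 1.045 clipped

  set.seed(5)
  for (i in 1:5) {
    a <- augment(fr, seed = i)
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_equal(dim(a$image), dim(fr$image))
    expect_equal(a$true_area_px, sum(a$mask))
  }
})

test_that("rotating image and mask together preserves their overlap", {
  spec <- synth_heart_spec(noise_sd = 0, blur_sigma = 0)
  sim <- simulate_heart_video(spec)
  fr <- structure(list(image = sim$video[, , 1], mask = sim$masks[, , 1],
                       true_area_px = sum(sim$masks[, , 1]),
                       true_axes = c(a = 32, b = 20)),
                  class = "labeled_frame")
  rot <- augment(fr, angle = 33, flip_h = FALSE, flip_v = FALSE,
                 brightness = 1, contrast = 1)
  fg <- rot$image > 0.5
  inter <- sum(fg & rot$mask)
  uni <- sum(fg | rot$mask)
  expect_gt(inter / uni, 0.9)
})

test_that("split_dataset partitions disjointly, exhaustively and reproducibly", {
  items <- as.list(seq_len(2125))
  sp <- split_dataset(items, c(4, 1), seed = 3)
  expect_length(sp$train, 1700)
  expect_length(sp$validation, 425)
  ids <- c(unlist(sp$train), unlist(sp$validation))
  expect_setequal(ids, seq_len(2125))
  expect_length(intersect(unlist(sp$train), unlist(sp$validation)), 0)

  sp5 <- split_dataset(as.list(1:5), c(4, 1), seed = 1)
  expect_length(sp5$train, 4)
  expect_length(sp5$validation, 1)

  again <- split_dataset(items, c(4, 1), seed = 3)
  expect_identical(unlist(sp$validation), unlist(again$validation))
  expect_error(split_dataset(as.list(1:3), c(4, 1), seed = 1), "empty part")
})

test_that("expand_training_set yields factor x n frames with originals verbatim", {
  train <- make_seg_dataset(10, seed = 4)
  ex <- expand_training_set(train, factor = 2, seed = 9)
  expect_length(ex, 20)
  expect_identical(ex[1:10], train)
  expect_identical(expand_training_set(train, factor = 1), train)
  # the protocol's arithmetic: 1700 originals at factor 3 give 5100
  expect_equal(1700 * 3, 5100)
})
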