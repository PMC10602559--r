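# Segmentation network contracts, the classical baseline, and the overlap
# metrics.

test_that("network maps H x W inputs to probability maps of the same size", {
  model <- build_zvsegnet(seg_config(base_width = 4), seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  p <- predict_seg(model, img)
  expect_equal(dim(p), c(64, 64))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_seg(model, matrix(0.5, 30, 30)), "divisible")
})

test_that("attention and ASPP add trainable parameters", {
  base <- seg_config(use_attention = FALSE, use_aspp = FALSE)
  att <- seg_config(use_attention = TRUE, use_aspp = FALSE)
  aspp <- seg_config(use_attention = FALSE, use_aspp = TRUE)
  both <- seg_config(use_attention = TRUE, use_aspp = TRUE)
  n0 <- n_params(build_zvsegnet(base, seed = 1))
  expect_gt(n_params(build_zvsegnet(att, seed = 1)), n0)
  expect_gt(n_params(build_zvsegnet(aspp, seed = 1)), n0)
  expect_gt(n_params(build_zvsegnet(both, seed = 1)),
            n_params(build_zvsegnet(att, seed = 1)))
})

test_that("baseline segmenter is exact on a clean two-level ellipse", {
  spec <- synth_heart_spec(noise_sd = 0, blur_sigma = 0, n_frames = 3)
  sim <- simulate_heart_video(spec)
  masks <- baseline_segment(sim$video)
  expect_identical(unclass(masks)[], unclass(sim$masks)[])
})

test_that("baseline segmenter returns empty masks on uniform frames", {
  v <- heart_video(array(0.4, c(32, 32, 2)), 50)
  m <- baseline_segment(v)
  expect_equal(sum(m), 0)
})

test_that("rank-threshold baseline is invariant to affine intensity rescaling", {
  spec <- synth_heart_spec(noise_sd = 0.03, blur_sigma = 1, n_frames = 5)
  sim <- simulate_heart_video(spec)
  v2 <- heart_video(unclass(sim$video) * 0.37 + 0.21, 50)
  m1 <- baseline_segment(sim$video, method = "quantile")
  m2 <- baseline_segment(v2, method = "quantile")
  expect_identical(unclass(m1)[], unclass(m2)[])
})

test_that("segmented masks have at most one connected component", {
  spec <- synth_heart_spec(noise_sd = 0.08, blur_sigma = 1,
                           atrium = list(offset = c(0, 22),
                                         semi_axes = c(7, 5),
                                         intensity = 0.5))
  sim <- simulate_heart_video(spec)
  masks <- baseline_segment(sim$video)
  for (t in seq_len(dim(masks)[3])) {
    if (sum(masks[, , t]) == 0) next
    lab <- EBImage::bwlabel(masks[, , t])
    expect_equal(max(lab), 1)
  }
})

test_that("baseline pipeline hits IoU >= 0.95 on noiseless ellipse videos", {
  sim <- recovery_runs()[[2]]$sim
  masks <- baseline_segment(sim$video)
  m <- seg_metrics(masks, sim$masks, mode = "per_frame")
  expect_gte(m$iou, 0.95)
})

test_that("overlap metrics match confusion-count arithmetic", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L      # 4 px
  b <- matrix(0L, 6, 6); b[2:3, 2:5] <- 1L      # 8 px, contains a
  m <- seg_metrics(a, b)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$iou, 0.5)
  expect_equal(m$dice, 2 / 3)

  same <- seg_metrics(b, b)
  expect_equal(unlist(same[c("iou", "dice", "precision", "recall")]),
               c(iou = 1, dice = 1, precision = 1, recall = 1))

  disj <- matrix(0L, 6, 6); disj[5:6, 5:6] <- 1L
  m0 <- seg_metrics(a, disj)
  expect_equal(m0$iou, 0)
  expect_equal(m0$dice, 0)

  empty <- matrix(0L, 6, 6)
  me <- seg_metrics(empty, empty)
  expect_equal(me$iou, 1)

  expect_error(seg_metrics(a, matrix(0L, 5, 5)), "identical shape")
})

test_that("dice equals 2*iou/(1+iou) and precision/recall bound iou on random masks", {
  set.seed(123)
  for (i in 1:100) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.7)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.7)), 8, 8)
    m <- seg_metrics(a, b)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    expect_gte(m$precision, m$iou)
    expect_gte(m$recall, m$iou)
  }
})

test_that("trained network segments held-out synthetic frames well", {
  run <- seg_training_run()
  val <- seg_validation_frames()
  expect_gte(tail(run$history$val_iou, 1), 0.8)
  expect_lt(tail(run$history$val_loss, 1), run$history$val_loss[1])

  # flip equivariance after training on orientation-randomised data:
  # flipping the input and unflipping the prediction moves IoU by < 0.05
  fr <- val[[1]]
  p1 <- predict_seg(run$model, fr$image)
  p2 <- predict_seg(run$model, fr$image[, ncol(fr$image):1])[, 64:1]
  iou1 <- seg_metrics((p1 > 0.5) * 1L, fr$mask)$iou
  iou2 <- seg_metrics((p2 > 0.5) * 1L, fr$mask)$iou
  expect_lt(abs(iou1 - iou2), 0.05)
})

test_that("segment_video applies threshold and padding on arbitrary sizes", {
  run <- seg_training_run()
  spec <- synth_heart_spec(image_height = 60, image_width = 70,
                           centre = c(30, 35), n_frames = 4)
  sim <- simulate_heart_video(spec)
  masks <- segment_video(run$model, sim$video, threshold = 0.5)
  expect_equal(dim(masks), c(60, 70, 4))
  m <- seg_metrics(masks, sim$masks, mode = "per_frame")
  expect_gte(m$iou, 0.7)
  expect_error(segment_video(run$model, sim$video, threshold = 1.2))
})
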