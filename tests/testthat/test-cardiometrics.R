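# Geometric measurements and the closed-form cardiac parameters.

test_that("closed forms match independent hand computation to 1e-12 relative", {
  set.seed(10)
  for (i in 1:25) {
    eda <- runif(1, 100, 900)
    esa <- runif(1, 0, eda)
    expect_equal(fac(eda, esa), (eda - esa) / eda * 100, tolerance = 1e-12)
    eda_a <- runif(1, 10, 50)
    esa_a <- runif(1, 0, eda_a)
    expect_equal(fs(eda_a, esa_a), (eda_a - esa_a) / eda_a * 100,
                 tolerance = 1e-12)
    ed <- axis_pair(runif(1, 20, 40), runif(1, 5, 19))
    es <- axis_pair(runif(1, 10, 19), runif(1, 1, 9))
    expect_equal(sv(ed, es),
                 4 / 3 * pi * (ed$a * ed$b^2 - es$a * es$b^2),
                 tolerance = 1e-12)
    expect_equal(sv(ed, es, "semi-axis"), sv(ed, es) / 8, tolerance = 1e-12)
    n <- sample(1:9, 1)
    dur <- runif(1, 1, 5)
    expect_equal(hr_from_cycles(n, dur), n / dur * 60, tolerance = 1e-12)
  }
  expect_equal(fac(200, 150), 25)
  expect_equal(fac(100, 100), 0)
  expect_equal(fac(100, 0), 100)
  expect_equal(fs(40, 30), 25)
  expect_equal(sv(axis_pair(3, 1), axis_pair(0, 0)), 4 * pi)
  expect_equal(hr_from_cycles(4, 2), 120)
  expect_equal(hr_from_cycles(7, 3.5), 120)
  expect_equal(hr_from_cycles(0, 2), 0)
  expect_error(fac(0, 0), "EDA")
  expect_error(fs(0, 0), "EDa")
  expect_error(hr_from_cycles(3, 0), "duration")
  expect_warning(sv(axis_pair(10, 5), axis_pair(20, 10)), "negative")
})

test_that("mask_area counts foreground pixels", {
  expect_equal(mask_area(matrix(0L, 7, 7)), 0)
  r <- matrix(0L, 20, 20); r[4:13, 3:6] <- 1L
  expect_equal(mask_area(r), 40)
  e <- zfcardio:::ellipse_mask(64, 64, c(32.5, 32.5), 20, 10, 0)
  expect_lt(abs(mask_area(e) - pi * 200) / (pi * 200), 0.03)
})

test_that("min_area_rect: axis-aligned, single pixel and rotated rectangles", {
  m <- matrix(0L, 20, 20); m[5:14, 8:11] <- 1L
  r <- min_area_rect(m)
  expect_equal(r$a, 10)
  expect_equal(r$b, 4)

  p <- matrix(0L, 5, 5); p[3, 3] <- 1L
  rp <- min_area_rect(p)
  expect_equal(rp$a, 1)
  expect_equal(rp$b, 1)

  expect_error(min_area_rect(matrix(0L, 4, 4)), "no ventricle")

  # 10 x 4 rectangle rasterised at 30 degrees (pixel centres inside the
  # continuous rectangle). Under the unit-square convention each side can
  # only grow, by at most |cos|+|sin| <= 1.37 px from the corner squares,
  # and never shrink below the centre-point extent (side - 1).
  h <- 24; w <- 24; th <- 30 * pi / 180
  rws <- matrix(seq_len(h), h, w) - 12.5
  cls <- matrix(seq_len(w), h, w, byrow = TRUE) - 12.5
  u <- cls * cos(th) + rws * sin(th)
  v <- -cls * sin(th) + rws * cos(th)
  rot <- (abs(u) <= 5 & abs(v) <= 2) * 1L
  rr <- min_area_rect(rot)
  expect_gt(rr$a, 9)
  expect_lt(rr$a, 10 + 1.37)
  expect_gt(rr$b, 3)
  expect_lt(rr$b, 4 + 1.37)
  expect_equal(rr$angle, 30, tolerance = 0.15)
  br <- brute_rect(rot)
  expect_lt(abs(rr$a * rr$b - br$area) / br$area, 0.02)
})

test_that("min_area_rect agrees with the angle-grid brute force on random blobs", {
  set.seed(77)
  for (i in 1:50) {
    m <- random_blob(sample(12:28, 1), sample(12:28, 1), sample(3:20, 1))
    r <- min_area_rect(m)
    br <- brute_rect(m)
    # calipers result can only be smaller than (or equal to) any grid angle,
    # and the 0.5-degree grid can only miss by its resolution
    expect_lte(r$a * r$b, br$area + 1e-9)
    expect_lt((br$area - r$a * r$b) / br$area, 0.01)
    # rectangle area >= hull area >= pixel count (unit squares)
    expect_gte(r$a * r$b + 1e-9, mask_area(m))
  }
})

test_that("area_trace reflects masks frame by frame", {
  m <- array(0L, c(8, 8, 3))
  m[2:4, 2:4, 1] <- 1L
  tr <- area_trace(mask_sequence(m), fps = 50)
  expect_equal(as.numeric(tr), c(9, 0, 0))
  expect_equal(attr(tr, "fps"), 50)
})

test_that("detect_cycles finds sinusoid extrema and flags flat traces", {
  t <- seq_len(100)
  x <- 100 + 50 * sin(2 * pi * 4 * (t - 1) / 100)
  cm <- detect_cycles(as_area_trace(x, 50))
  expect_equal(cm$n_cycles, 4)
  expect_equal(cm$status, "ok")
  # ED frames at the sinusoid maxima (period 25, first max at t = 7.25)
  expect_true(all(abs(cm$cycles$ed - c(7, 32, 57, 82)) <= 1))

  flat <- detect_cycles(as_area_trace(rep(5, 60), 50))
  expect_equal(flat$n_cycles, 0)
  expect_equal(flat$status, "no heartbeat")

  mono <- detect_cycles(as_area_trace(seq(1, 60), 50))
  expect_equal(mono$n_cycles, 0)
})

test_that("detect_cycles ignores low-prominence ripple", {
  t <- seq_len(200)
  x <- 100 + 40 * sin(2 * pi * 4 * (t - 1) / 200) +
    1.5 * sin(2 * pi * 37 * (t - 1) / 200)
  cm <- detect_cycles(as_area_trace(x, 100))
  expect_equal(cm$n_cycles, 4)
})

test_that("analyze_video recovers simulator parameters on noiseless data", {
  for (run in recovery_runs()) {
    p <- run$params
    expect_equal(p$HR, run$hr)
    expect_equal(p$n_cycles, run$hr / 30)   # cycles in 2 s
    expect_lt(abs(p$FAC - 43.75), 3)
    expect_lt(abs(p$FS - 25), 3)
    expect_gte(p$EDA, p$ESA)
    expect_gte(p$ED_axes$a, p$ES_axes$a)
  }
})

test_that("analyze_video reports a partial result when nothing beats", {
  spec <- synth_heart_spec(contraction_frac = c(0, 0), noise_sd = 0,
                           blur_sigma = 0)
  sim <- simulate_heart_video(spec)
  p <- analyze_video(sim$masks, 50, edema = 0L)
  expect_equal(p$status, "no heartbeat")
  expect_true(is.na(p$FAC) && is.na(p$FS) && is.na(p$SV) && is.na(p$HR))
  expect_equal(p$edema, 0L)
  expect_equal(p$n_cycles, 0L)
})

test_that("extremum aggregation mode uses the global ED/ES frames", {
  sim <- recovery_runs()[[2]]$sim
  masks <- baseline_segment(sim$video)
  pm <- analyze_video(masks, 50, ed_es_mode = "extremum")
  tr <- as.numeric(area_trace(masks, 50))
  expect_equal(pm$EDA, max(tr[detect_cycles(area_trace(masks, 50))$cycles$ed]))
  expect_gte(pm$EDA, analyze_video(masks, 50)$EDA - 1e-9)
})
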