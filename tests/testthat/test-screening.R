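# Screening layer: group means, rescue index, efficacy score, hit calling,
# ranking and invariances.

test_that("group_means averages parameters and codes edema as fraction normal", {
  l1 <- cardiac_params(EDA = 100, ESA = 50, FAC = 50, FS = 25, SV = 200,
                       HR = 100, edema = 1L)
  l2 <- cardiac_params(EDA = 120, ESA = 70, FAC = 40, FS = 20, SV = 220,
                       HR = 120, edema = 1L)
  one <- group_means(list(l1))
  expect_equal(unname(one$means["HR"]), 100)
  expect_equal(one$n_larvae, 1)

  gm <- group_means(list(l1, l2))
  expect_equal(unname(gm$means["HR"]), 110)
  expect_equal(unname(gm$means["EDA"]), 110)

  df <- data.frame(EDA = 1:4, ESA = 1:4, FAC = 1:4, FS = 1:4, SV = 1:4,
                   HR = 1:4, edema = c(1, 1, 0, 1))
  expect_equal(unname(group_means(df)$means["edema"]), 0.75)

  df$SV <- NA_real_
  expect_warning(g2 <- group_means(df), "no usable values")
  expect_true(is.na(g2$means["SV"]))
  expect_equal(unname(g2$n_used["SV"]), 0L)
})

test_that("rescue index follows its defining ratio, with optional clamping", {
  expect_equal(rescue_index(100, 50, 100), 1)
  expect_equal(rescue_index(50, 50, 100), 0)
  expect_equal(rescue_index(75, 50, 100), 0.5)
  expect_equal(rescue_index(25, 50, 100), -0.5)      # worse than model
  expect_equal(rescue_index(125, 50, 100), 1.5)      # over-rescue
  expect_equal(rescue_index(25, 50, 100, clamp = TRUE), 0)
  expect_equal(rescue_index(125, 50, 100, clamp = TRUE), 1)
  expect_warning(ri <- rescue_index(75, 100, 100), "coincide")
  expect_true(is.na(ri))
})

test_that("efficacy score averages usable indices and records their count", {
  expect_equal(as.numeric(efficacy_score(rep(1, 7))), 1)
  expect_equal(as.numeric(efficacy_score(c(1, 0))), 0.5)
  es <- efficacy_score(c(1.0, 0.8, 0.6, 0.4, 0.2, 0.0, 1.0))
  expect_equal(as.numeric(es), 4 / 7, tolerance = 1e-12)
  expect_equal(attr(es, "n_parameters"), 7L)
  es2 <- efficacy_score(c(0.5, NA, 1))
  expect_equal(as.numeric(es2), 0.75)
  expect_equal(attr(es2, "n_parameters"), 2L)
  expect_error(efficacy_score(c(NA_real_, NA_real_)), "no usable")
})

test_that("hits require a score strictly above the threshold", {
  res <- data.frame(compound = c("a", "b", "c"),
                    efficacy_score = c(0.71, 0.70, 0.30))
  out <- call_hits(res, 0.7)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE))
})

test_that("ranking is by descending score with lexicographic tie-break", {
  res <- data.frame(compound = c("zeta", "alpha", "mid"),
                    efficacy_score = c(0.2, 0.9, 0.5))
  r <- rank_compounds(res)
  expect_equal(r$compound, c("alpha", "mid", "zeta"))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(compound = c("b", "a"), efficacy_score = c(0.5, 0.5))
  expect_equal(rank_compounds(tie)$compound, c("a", "b"))
})

test_that("scoring recovers known group relations and affine invariance", {
  set.seed(31)
  mk <- function(group, shift, n = 5) {
    data.frame(larva_id = paste0(group, "_", 1:n), group = group,
               EDA = 100 + shift * 20 + rnorm(n, 0, 0),
               ESA = 60 - shift * 10, FAC = 40 + shift * 20,
               FS = 20 + shift * 10, SV = 150 + shift * 50,
               HR = 90 + shift * 60, edema = rep(round(shift), n))
  }
  df <- rbind(mk("control", 1), mk("model", 0), mk("half", 0.5),
              mk("full", 1), mk("none", 0))
  res <- screen_compounds(df)
  expect_equal(res$efficacy_score[res$compound == "full"], 1)
  expect_equal(res$efficacy_score[res$compound == "none"], 0)
  expect_equal(res$efficacy_score[res$compound == "half"],
               (6 * 0.5 + 0) / 7)   # edema rounds to 0 at shift 0.5

  # scoring the model group against itself: 0; the control group: 1
  df2 <- rbind(mk("control", 1), mk("model", 0), mk("ctrl2", 1),
               mk("model2", 0))
  res2 <- screen_compounds(df2)
  expect_equal(res2$efficacy_score[res2$compound == "ctrl2"], 1)
  expect_equal(res2$efficacy_score[res2$compound == "model2"], 0)

  # common affine rescale of one parameter leaves the score unchanged
  df3 <- df
  df3$SV <- df3$SV * 3.7 + 11
  expect_equal(screen_compounds(df3)$efficacy_score, res$efficacy_score,
               tolerance = 1e-12)
})

test_that("degenerate parameters are dropped from the denominator count", {
  df <- data.frame(larva_id = 1:15,
                   group = rep(c("control", "model", "x"), each = 5),
                   EDA = rep(c(100, 100, 100), each = 5),   # degenerate
                   ESA = rep(c(50, 80, 65), each = 5),
                   FAC = rep(c(50, 20, 35), each = 5),
                   FS = rep(c(25, 10, 17.5), each = 5),
                   SV = rep(c(200, 100, 150), each = 5),
                   HR = rep(c(150, 90, 120), each = 5),
                   edema = rep(c(1, 0, 1), each = 5))
  expect_warning(res <- screen_compounds(df), "coincide")
  expect_equal(res$n_parameters, 6L)
  expect_equal(res$efficacy_score, (0.5 * 5 + 1) / 6, tolerance = 1e-12)
})

test_that("a full synthetic screen recovers injected effect sizes end to end", {
  run <- screen_run()
  res <- run$result
  lv <- run$scr$rescue_levels
  expect_equal(res$efficacy_score[res$compound == "fullrescue"], 1,
               tolerance = 1e-9)
  expect_equal(res$efficacy_score[res$compound == "null"], 0,
               tolerance = 1e-9)
  # ranking matches the injected ordering of rescue levels
  expect_equal(res$compound, names(sort(lv, decreasing = TRUE)))
  expect_equal(res$is_hit, res$efficacy_score > 0.7)
  # permuting larva rows never changes the scores
  set.seed(8)
  shuffled <- run$scr$larvae[sample(nrow(run$scr$larvae)), ]
  res2 <- screen_compounds(shuffled)
  expect_equal(res2$efficacy_score, res$efficacy_score, tolerance = 1e-12)
})
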