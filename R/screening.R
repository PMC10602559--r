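# Phenotypic-screening layer: group aggregation, per-parameter rescue index,
# efficacy score, hit calling and compound ranking.
#
# Groups are "control" (healthy), "model" (diseased) and one group per
# compound. For each parameter X, the rescue index of a compound is
# (X_drug - X_model) / (X_ctrl - X_model) on group means; the efficacy score
# is the mean rescue index over the usable parameters (the six cardiac
# parameters plus the pericardial-edema fraction), and hits are compounds
# whose score exceeds the threshold strictly.

SCREEN_PARAMS <- c("EDA", "ESA", "FAC", "FS", "SV", "HR", "edema")

#' Per-parameter group means
#'
#' Means of each numeric cardiac parameter over the larvae of one group;
#' the edema Boolean (normal = 1, edema = 0) averages to the fraction of
#' normal larvae. Missing values are excluded, with counts recorded; an
#' all-missing parameter is marked unavailable (`NA`) with a warning.
#'
#' @param larvae List of [cardiac_params()] objects, or a data frame with
#'   columns `EDA, ESA, FAC, FS, SV, HR, edema`.
#' @return A list with `means` (named numeric), `n_used` (named integer
#'   counts of non-missing values) and `n_larvae`.
#' @export
group_means <- function(larvae) {
  if (is.data.frame(larvae)) {
    df <- larvae
  } else {
    stopifnot(length(larvae) >= 1L)
    df <- do.call(rbind, lapply(larvae, function(p)
      data.frame(EDA = p$EDA, ESA = p$ESA, FAC = p$FAC, FS = p$FS,
                 SV = p$SV, HR = p$HR, edema = as.numeric(p$edema))))
  }
  if (nrow(df) < 1L) stop("group must contain at least one larva")
  means <- vapply(SCREEN_PARAMS, function(p) {
    v <- df[[p]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  n_used <- vapply(SCREEN_PARAMS, function(p) sum(!is.na(df[[p]])),
                   integer(1))
  if (any(is.na(means)))
    warning("parameter(s) with no usable values: ",
            paste(SCREEN_PARAMS[is.na(means)], collapse = ", "))
  list(means = means, n_used = n_used, n_larvae = nrow(df))
}

#' Rescue index of one parameter
#'
#' `(x_drug - x_model) / (x_ctrl - x_model)`: 0 means no improvement over the
#' disease model, 1 full restoration to the control level. Not clamped by
#' default, so worsening (< 0) and over-rescue (> 1) are visible;
#' `clamp = TRUE` truncates to `[0, 1]`. A degenerate parameter
#' (`x_ctrl == x_model`) yields `NA` with a warning and is excluded from the
#' efficacy score downstream.
#'
#' @param x_drug,x_model,x_ctrl Group means of the parameter.
#' @param clamp Truncate the index to `[0, 1]`.
#' @return Dimensionless rescue index (vectorised).
#' @export
rescue_index <- function(x_drug, x_model, x_ctrl, clamp = FALSE) {
  denom <- x_ctrl - x_model
  out <- (x_drug - x_model) / denom
  deg <- is.finite(x_ctrl) & is.finite(x_model) & denom == 0
  if (any(deg, na.rm = TRUE)) {
    warning("control and model means coincide; parameter excluded")
    out[deg] <- NA_real_
  }
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Efficacy score from rescue indices
#'
#' Arithmetic mean of the usable (non-`NA`) rescue indices; the number of
#' parameters entering the mean is recorded as attribute `n_parameters`
#' (7 when all six cardiac parameters plus edema are usable).
#'
#' @param rescue_indices Numeric vector of per-parameter rescue indices.
#' @return The efficacy score with attribute `n_parameters`.
#' @export
efficacy_score <- function(rescue_indices) {
  ok <- !is.na(rescue_indices)
  if (!any(ok)) stop("no usable rescue index")
  structure(mean(rescue_indices[ok]), n_parameters = sum(ok))
}

#' Call screening hits
#'
#' Marks compounds whose efficacy score is strictly greater than the
#' threshold as hits.
#'
#' @param results A `screen_result` data frame (see [screen_compounds()]).
#' @param threshold Efficacy-score threshold; default 0.7.
#' @return The data frame with `is_hit` set.
#' @export
call_hits <- function(results, threshold = 0.7) {
  stopifnot(is.finite(threshold))
  results$is_hit <- results$efficacy_score > threshold
  results
}

#' Rank compounds by efficacy score
#'
#' Descending by score; ties broken by compound id in lexicographic order.
#'
#' @param results A `screen_result` data frame.
#' @return The data frame reordered, with a `rank` column.
#' @export
rank_compounds <- function(results) {
  stopifnot(nrow(results) >= 1L)
  o <- order(-results$efficacy_score, results$compound, method = "radix")
  results <- results[o, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Score a phenotypic screen
#'
#' Computes per-parameter rescue indices and the efficacy score of every
#' compound group against the control and model groups, calls hits and ranks
#' the compounds.
#'
#' @param larvae_df Data frame with one row per larva: columns `larva_id`,
#'   `group` (values `"control"`, `"model"`, or a compound id) and the
#'   parameters `EDA, ESA, FAC, FS, SV, HR, edema`.
#' @param threshold Hit threshold on the efficacy score (strict).
#' @param clamp Clamp rescue indices to `[0, 1]` (see [rescue_index()]).
#' @param per_larva Compute rescue indices per larva before averaging
#'   (sensitivity analysis) instead of on group means.
#' @return A `screen_result` data frame: `compound`, one `rescue_<param>`
#'   column per parameter, `efficacy_score`, `n_parameters`, `is_hit`,
#'   `rank`.
#' @export
screen_compounds <- function(larvae_df, threshold = 0.7, clamp = FALSE,
                             per_larva = FALSE) {
  stopifnot(all(c("group", SCREEN_PARAMS) %in% names(larvae_df)))
  groups <- unique(larvae_df$group)
  if (!all(c("control", "model") %in% groups))
    stop("screen requires 'control' and 'model' groups")
  compounds <- sort(setdiff(groups, c("control", "model")))
  if (length(compounds) == 0L) stop("no compound groups to score")

  gm <- function(g) group_means(larvae_df[larvae_df$group == g, ])$means
  ctrl <- gm("control")
  model <- gm("model")

  rows <- lapply(compounds, function(cmp) {
    sub <- larvae_df[larvae_df$group == cmp, ]
    ri <- if (per_larva) {
      per <- vapply(SCREEN_PARAMS, function(p)
        mean(rescue_index(sub[[p]], model[[p]], ctrl[[p]], clamp = clamp),
             na.rm = TRUE), numeric(1))
      per[is.nan(per)] <- NA_real_
      per
    } else {
      drug <- group_means(sub)$means
      vapply(SCREEN_PARAMS, function(p)
        rescue_index(drug[[p]], model[[p]], ctrl[[p]], clamp = clamp),
        numeric(1))
    }
    es <- efficacy_score(ri)
    out <- data.frame(compound = cmp, t(ri))
    names(out)[-1L] <- paste0("rescue_", SCREEN_PARAMS)
    out$efficacy_score <- as.numeric(es)
    out$n_parameters <- attr(es, "n_parameters")
    out
  })
  res <- do.call(rbind, rows)
  res <- call_hits(res, threshold)
  res <- rank_compounds(res)
  class(res) <- c("screen_result", class(res))
  res
}

#' Simulate a complete synthetic screen
#'
#' Builds one video per larva for a control group, a disease-model group
#' (weaker, slower contraction with pericardial edema) and one group per
#' compound, where each compound's ventricle dynamics interpolate between
#' model and control according to its rescue level in `[0, 1]`. A compound
#' at level 1 reproduces the control group's larvae exactly (same
#' specifications and seeds), and at level 0 the model group's, so their
#' efficacy scores are exactly 1 and 0. Edema flags follow the rescue level
#' as a deterministic fraction of normal larvae.
#'
#' @param rescue_levels Named numeric vector of per-compound rescue levels
#'   in `[0, 1]`.
#' @param n_larvae Larvae per group (the screening protocol uses >= 5).
#' @param seed Integer seed.
#' @param segmenter Segmentation route for the analysis:`"truth"` uses the
#'   simulator's ground-truth masks, `"baseline"` the classical segmenter.
#' @param ctrl,model Named lists giving the control / disease condition:
#'   `hr_bpm`, `contraction_frac` and `size_scale` (ventricle size relative
#'   to the 16 x 10 px reference ellipse; the diseased heart is smaller and
#'   contracts less and slower).
#' @return A list: `larvae` (per-larva parameter data frame suitable for
#'   [screen_compounds()]), `rescue_levels`.
#' @export
simulate_screen <- function(rescue_levels = c(fullrescue = 1, null = 0,
                                              low = 0.25, mid = 0.5,
                                              high = 0.75),
                            n_larvae = 5L, seed = 1L,
                            segmenter = c("truth", "baseline"),
                            ctrl = list(hr_bpm = 150,
                                        contraction_frac = c(0.30, 0.30),
                                        size_scale = 1),
                            model = list(hr_bpm = 90,
                                         contraction_frac = c(0.12, 0.12),
                                         size_scale = 0.85)) {
  segmenter <- match.arg(segmenter)
  stopifnot(all(rescue_levels >= 0 & rescue_levels <= 1),
            !is.null(names(rescue_levels)))

  larva_specs <- function(level, seeds) {
    lapply(seq_len(n_larvae), function(i) {
      hr <- model$hr_bpm + level * (ctrl$hr_bpm - model$hr_bpm)
      cf <- model$contraction_frac +
        level * (ctrl$contraction_frac - model$contraction_frac)
      sc <- model$size_scale + level * (ctrl$size_scale - model$size_scale)
      with_seed(seeds[i], {
        synth_heart_spec(
          hr_bpm = hr, contraction_frac = cf,
          ed_semi_axes = c(16, 10) * sc * stats::runif(1, 0.97, 1.03),
          orientation_deg = stats::runif(1, 0, 180),
          centre = c(32.5, 32.5) + stats::runif(2, -2, 2),
          noise_sd = 0.02, blur_sigma = 0.8,
          seed = seeds[i])
      })
    })
  }
  analyze_larva <- function(spec, edema_flag) {
    sim <- simulate_heart_video(spec)
    masks <- if (segmenter == "truth") sim$masks
             else baseline_segment(sim$video)
    analyze_video(masks, attr(sim$video, "fps"), edema = edema_flag)
  }
  group_rows <- function(gname, level, seeds, edema_flags) {
    specs <- larva_specs(level, seeds)
    do.call(rbind, lapply(seq_len(n_larvae), function(i) {
      p <- analyze_larva(specs[[i]], edema_flags[i])
      data.frame(larva_id = paste0(gname, "_", i), group = gname,
                 EDA = p$EDA, ESA = p$ESA, FAC = p$FAC, FS = p$FS,
                 SV = p$SV, HR = p$HR, edema = p$edema)
    }))
  }

  ctrl_seeds <- seed + seq_len(n_larvae)
  model_seeds <- seed + n_larvae + seq_len(n_larvae)
  rows <- list(
    group_rows("control", 1, ctrl_seeds, rep(1L, n_larvae)),
    group_rows("model", 0, model_seeds, rep(0L, n_larvae)))
  for (k in seq_along(rescue_levels)) {
    lvl <- rescue_levels[k]
    nm <- names(rescue_levels)[k]
    seeds <- if (lvl == 1) ctrl_seeds
             else if (lvl == 0) model_seeds
             else seed + (k + 1L) * n_larvae + seq_len(n_larvae)
    n_normal <- round(lvl * n_larvae)
    edema_flags <- c(rep(1L, n_normal), rep(0L, n_larvae - n_normal))
    rows[[length(rows) + 1L]] <- group_rows(nm, lvl, seeds, edema_flags)
  }
  list(larvae = do.call(rbind, rows), rescue_levels = rescue_levels)
}
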