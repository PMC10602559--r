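# File formats: multi-page TIFF videos (16-bit), per-frame PNG masks,
# deterministic CSV tables, JSON sidecars, model checkpoints.

#' Write a heart video as multi-page TIFF
#'
#' Intensities in `[0, 1]` are stored at 16 bits per sample; a JSON sidecar
#' (`<path>.json`) records the frame rate.
#'
#' @param video A [heart_video()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_heart_video <- function(video, path) {
  fps <- attr(video, "fps")
  frames <- lapply(seq_len(dim(video)[3L]), function(t) {
    f <- video[, , t]
    f[f < 0] <- 0
    f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(list(fps = fps, n_frames = length(frames)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a heart video from a multi-page TIFF
#'
#' Intensities are returned in `[0, 1]` (any bit depth). The frame rate is
#' taken from the `fps` argument, or else from a `<path>.json` sidecar; if
#' neither is available an error names the missing field.
#'
#' @param path TIFF path.
#' @param fps Frames per second (overrides the sidecar).
#' @return A [heart_video()].
#' @export
read_heart_video <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("cannot read video: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("video has zero frames: ", path)
  if (is.null(fps)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) fps <- jsonlite::read_json(sidecar)$fps
  }
  if (is.null(fps))
    stop("missing field 'fps': pass fps= or provide ", path, ".json")
  arr <- array(0, c(dim(frames[[1L]])[1:2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]  # grayscale written as RGB
    arr[, , t] <- f
  }
  heart_video(arr, fps)
}

#' Write a mask sequence as per-frame 8-bit PNGs (0/255)
#'
#' @param masks A [mask_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; frames are `<prefix>_0001.png`, ...
#' @return The file paths, invisibly.
#' @export
write_mask_pngs <- function(masks, dir, prefix = "mask") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(dim(masks)[3L])
  for (t in seq_len(dim(masks)[3L])) {
    paths[t] <- file.path(dir, sprintf("%s_%04d.png", prefix, t))
    png::writePNG(masks[, , t] * 1.0, paths[t])
  }
  invisible(paths)
}

#' Read a mask sequence from PNG files
#'
#' @param paths PNG file paths, in frame order.
#' @return A [mask_sequence()] (pixels > 0.5 are foreground).
#' @export
read_mask_pngs <- function(paths) {
  frames <- lapply(paths, function(p) {
    f <- png::readPNG(p)
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    (f > 0.5) * 1L
  })
  arr <- array(0L, c(dim(frames[[1L]]), length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  mask_sequence(arr)
}

#' Write a simulation's ground truth
#'
#' One CSV row per frame (`frame_index`, `area_px`, `a_px`, `b_px`) plus a
#' JSON sidecar with the generating specification and true heart rate.
#'
#' @param sim Result of [simulate_heart_video()].
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(sim, csv_path,
                               json_path = paste0(csv_path, ".json")) {
  pf <- sim$truth$per_frame
  df <- data.frame(frame_index = pf$frame, area_px = pf$area_px,
                   a_px = pf$a_px, b_px = pf$b_px)
  write_csv_deterministic(df, csv_path)
  spec <- sim$truth$spec
  spec$atrium <- NULL
  jsonlite::write_json(list(spec = unclass(spec),
                            hr_bpm = sim$truth$params$HR),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

# format a value for CSV output: floats at 6 significant digits
fmt_csv <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- formatC(x, digits = 6, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else as.character(x)
}

#' Write a data frame as a byte-deterministic CSV
#'
#' Fixed column order as given, floats at 6 significant digits, `\n` line
#' endings; identical input yields byte-identical output.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_deterministic <- function(df, path) {
  header <- paste(names(df), collapse = ",")
  if (nrow(df) == 0L) {
    writeLines(header, path, sep = "\n")
    return(invisible(path))
  }
  cols <- lapply(df, fmt_csv)
  lines <- do.call(paste, c(cols, list(sep = ",")))
  writeLines(c(header, lines), path, sep = "\n")
  invisible(path)
}

#' Convert per-larva cardiac parameters to the results table
#'
#' @param params_list Named list of [cardiac_params()] (names are larva ids).
#' @return Data frame with columns `id, EDA, ESA, EDa, EDb, ESa, ESb, FAC,
#'   FS, SV, HR, edema, n_cycles, status`.
#' @export
params_table <- function(params_list) {
  stopifnot(!is.null(names(params_list)))
  do.call(rbind, lapply(names(params_list), function(id) {
    p <- params_list[[id]]
    data.frame(id = id, EDA = p$EDA, ESA = p$ESA,
               EDa = if (is.null(p$ED_axes)) NA_real_ else p$ED_axes$a,
               EDb = if (is.null(p$ED_axes)) NA_real_ else p$ED_axes$b,
               ESa = if (is.null(p$ES_axes)) NA_real_ else p$ES_axes$a,
               ESb = if (is.null(p$ES_axes)) NA_real_ else p$ES_axes$b,
               FAC = p$FAC, FS = p$FS, SV = p$SV, HR = p$HR,
               edema = p$edema, n_cycles = p$n_cycles, status = p$status)
  }))
}

#' Read a parameter table written by [write_csv_deterministic()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_params_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save a model checkpoint
#'
#' Weights in R's native serialisation plus a JSON sidecar describing the
#' configuration.
#'
#' @param model A `zvsegnet` or `hrnet`.
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(class = class(model)[1L],
                            config = unclass(model$config)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path written by [save_model()].
#' @return The model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
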