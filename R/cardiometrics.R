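# Cardiac-function quantification from binary ventricle mask sequences:
# area trace, end-diastole / end-systole cycle detection, minimum-area
# rotated rectangle axes, fractional area change (FAC), fractional
# shortening (FS), stroke volume (SV) and heart rate (HR).
#
# Conventions (used throughout the package): images are H x W matrices in
# (row, col) coordinates, frame indices are 1-based, and a pixel is a unit
# square centred on its integer coordinates (so a single pixel has extent
# 1 x 1 and rectangle sides are measured across pixel edges).

#' Heart video container
#'
#' @param frames H x W x T numeric array with intensities in `[0, 1]`.
#' @param fps Frames per second.
#' @return A `heart_video` array with an `fps` attribute.
#' @export
heart_video <- function(frames, fps) {
  stopifnot(length(dim(frames)) == 3L, fps > 0)
  structure(frames, fps = fps, class = "heart_video")
}

#' Binary mask sequence container
#'
#' @param masks H x W x T array of 0/1 values.
#' @return A `mask_sequence` integer array.
#' @export
mask_sequence <- function(masks) {
  stopifnot(length(dim(masks)) == 3L)
  if (!all(masks %in% c(0L, 1L))) stop("masks must be binary (0/1)")
  storage.mode(masks) <- "integer"
  structure(masks, class = "mask_sequence")
}

#' Ventricular area trace container
#'
#' @param areas Per-frame ventricular area (pixel counts), length >= 1.
#' @param fps Frames per second.
#' @return An `area_trace` numeric vector with an `fps` attribute; the video
#'   duration in seconds is `length(areas) / fps`.
#' @export
as_area_trace <- function(areas, fps) {
  stopifnot(length(areas) >= 1L, all(areas >= 0), fps > 0)
  structure(as.numeric(areas), fps = fps, class = "area_trace")
}

#' Axis pair of a rotated rectangle
#'
#' @param a Long side, pixels (`a >= b`).
#' @param b Short side, pixels.
#' @param angle Orientation of the long side, degrees in `[0, 180)`.
#' @return An `axis_pair` list.
#' @export
axis_pair <- function(a, b, angle = 0) {
  if (a < b) { tmp <- a; a <- b; b <- tmp; angle <- angle + 90 }
  structure(list(a = a, b = b, angle = angle %% 180), class = "axis_pair")
}

#' Cardiac parameters of one larva
#'
#' Bundles the six cardiac-function parameters plus the pericardial-edema
#' flag (`1` = normal, `0` = edema) and bookkeeping fields.
#'
#' @param EDA,ESA End-diastolic / end-systolic ventricular area, pixels^2.
#' @param ED_axes,ES_axes [axis_pair()]s at end-diastole / end-systole.
#' @param FAC Fractional area change, percent.
#' @param FS Fractional shortening, percent.
#' @param SV Stroke volume (pixel^3, convention-dependent; see [sv()]).
#' @param HR Heart rate, beats/minute.
#' @param edema Boolean flag: normal = 1, edema = 0.
#' @param n_cycles Number of complete cardiac cycles detected.
#' @param status `"ok"` or `"no heartbeat"`.
#' @return A `cardiac_params` list.
#' @export
cardiac_params <- function(EDA = NA_real_, ESA = NA_real_, ED_axes = NULL,
                           ES_axes = NULL, FAC = NA_real_, FS = NA_real_,
                           SV = NA_real_, HR = NA_real_, edema = 1L,
                           n_cycles = 0L, status = "ok") {
  structure(list(EDA = EDA, ESA = ESA, ED_axes = ED_axes, ES_axes = ES_axes,
                 FAC = FAC, FS = FS, SV = SV, HR = HR, edema = edema,
                 n_cycles = n_cycles, status = status),
            class = "cardiac_params")
}

#' @export
print.cardiac_params <- function(x, ...) {
  cat(sprintf(
    "cardiac_params: EDA=%.1f ESA=%.1f FAC=%.2f%% FS=%.2f%% SV=%.1f HR=%.1f bpm edema=%d cycles=%d [%s]\n",
    x$EDA, x$ESA, x$FAC, x$FS, x$SV, x$HR, x$edema, x$n_cycles, x$status))
  invisible(x)
}

# ---- elementary measurements ----------------------------------------------

#' Ventricular area of a binary mask
#'
#' @param mask Binary matrix (0/1 or logical).
#' @return Foreground pixel count.
#' @export
mask_area <- function(mask) {
  sum(mask > 0)
}

#' Minimum-area rotated rectangle enclosing a mask
#'
#' Computes the smallest-area rectangle at any rotation that encloses the
#' foreground, treating each pixel as a unit square (corners at +- 0.5 around
#' the pixel centre). Uses the rotating-calipers property: the minimal
#' rectangle has a side collinear with an edge of the convex hull of the
#' pixel corners.
#'
#' @param mask Binary matrix; must contain at least one foreground pixel.
#' @return An [axis_pair()] with the long side `a`, short side `b` and the
#'   long-side orientation in degrees.
#' @export
min_area_rect <- function(mask) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("no ventricle: mask is empty")
  # boundary pixels suffice to define the hull of all pixel corners
  if (nrow(px) > 4L) {
    m <- mask > 0
    h <- nrow(m); w <- ncol(m)
    pad <- matrix(FALSE, h + 2L, w + 2L)
    pad[2:(h + 1), 2:(w + 1)] <- m
    interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
      pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
    keep <- m & !interior
    px <- which(keep, arr.ind = TRUE)
  }
  corners <- rbind(
    cbind(px[, 1] - 0.5, px[, 2] - 0.5),
    cbind(px[, 1] - 0.5, px[, 2] + 0.5),
    cbind(px[, 1] + 0.5, px[, 2] - 0.5),
    cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  hull <- corners[grDevices::chull(corners[, 2], corners[, 1]), , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 1L) return(axis_pair(1, 1, 0))  # single point cannot occur (corners)
  best <- NULL
  for (i in seq_len(nh)) {
    p1 <- hull[i, ]
    p2 <- hull[if (i == nh) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    # u along the edge in (col, row) i.e. (x, y); v normal
    ux <- e[2] / len; uy <- e[1] / len
    pu <- hull[, 2] * ux + hull[, 1] * uy
    pv <- -hull[, 2] * uy + hull[, 1] * ux
    wdt <- max(pu) - min(pu)
    hgt <- max(pv) - min(pv)
    area <- wdt * hgt
    if (is.null(best) || area < best$area) {
      ang <- atan2(uy, ux) * 180 / pi
      best <- list(area = area, w = wdt, h = hgt, angle = ang)
    }
  }
  if (best$w >= best$h) axis_pair(best$w, best$h, best$angle)
  else axis_pair(best$h, best$w, best$angle + 90)
}

#' Per-frame ventricular area trace of a mask sequence
#'
#' @param masks A [mask_sequence()].
#' @param fps Frames per second.
#' @return An [as_area_trace()] object.
#' @export
area_trace <- function(masks, fps) {
  d <- dim(masks)
  areas <- colSums(matrix(masks > 0, d[1] * d[2], d[3]))
  as_area_trace(areas, fps)
}

# ---- cycle detection -------------------------------------------------------

# centred moving average with shrinking window at the edges
smooth_trace <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect cardiac cycles from an area trace
#'
#' Smooths the trace with a centred moving average (window
#' `max(3, round(fps / 20))` frames by default), extracts alternating local
#' maxima (end-diastole) and minima (end-systole) with a prominence of at
#' least 5% of the trace dynamic range, and pairs each end-diastole with the
#' following end-systole. Endpoint maxima may serve as end-diastole (a video
#' may start or end at full relaxation), but a minimum at the final sample is
#' an unfinished systole and never counts as end-systole.
#'
#' @param trace An [as_area_trace()] object.
#' @param smooth_window Moving-average window in frames; `NULL` for the
#'   default rule.
#' @param min_prominence Minimal max-min amplitude, as a fraction of the
#'   trace dynamic range.
#' @return A `cycle_markers` list: `cycles` (data frame with columns `ed` and
#'   `es`, 1-based frame indices), `n_cycles`, and `status` (`"ok"` or
#'   `"no heartbeat"` for constant/monotone traces).
#' @export
detect_cycles <- function(trace, smooth_window = NULL,
                          min_prominence = 0.05) {
  fps <- attr(trace, "fps")
  x <- as.numeric(trace)
  n <- length(x)
  if (is.null(smooth_window)) smooth_window <- max(3L, round(fps / 20))
  s <- if (n >= smooth_window) smooth_trace(x, smooth_window) else x
  rng <- max(s) - min(s)
  none <- structure(list(cycles = data.frame(ed = integer(), es = integer()),
                         n_cycles = 0L, status = "no heartbeat"),
                    class = "cycle_markers")
  if (n < 3L || rng <= .Machine$double.eps * max(abs(s), 1)) return(none)

  # alternating extrema: local max/min including endpoints
  dxs <- diff(s)
  sgn <- sign(dxs)
  # carry sign through plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  ext <- integer(0); typ <- integer(0)   # +1 max, -1 min
  add <- function(i, ty) { ext <<- c(ext, i); typ <<- c(typ, ty) }
  if (sgn[1] < 0) add(1L, 1L) else if (sgn[1] > 0) add(1L, -1L)
  for (i in seq_len(n - 2L)) {
    if (sgn[i] > 0 && sgn[i + 1] < 0) add(i + 1L, 1L)
    if (sgn[i] < 0 && sgn[i + 1] > 0) add(i + 1L, -1L)
  }
  # a trailing maximum can seed a (discarded) incomplete cycle, but a
  # trailing minimum is an unfinished systole, not an end-systole
  if (sgn[n - 1] > 0) add(n, 1L)
  if (length(ext) < 2L) return(none)

  # prune low-prominence alternations: repeatedly drop the adjacent
  # max/min pair with the smallest amplitude below threshold
  thr <- min_prominence * rng
  repeat {
    if (length(ext) < 2L) return(none)
    amp <- abs(diff(s[ext]))
    k <- which.min(amp)
    if (amp[k] >= thr) break
    drop <- c(k, k + 1L)
    # keep the more extreme of equal-type neighbours after removal
    ext <- ext[-drop]; typ <- typ[-drop]
    # merge consecutive same-type extrema
    j <- 1L
    while (j < length(ext)) {
      if (typ[j] == typ[j + 1L]) {
        keep_first <- if (typ[j] > 0) s[ext[j]] >= s[ext[j + 1L]]
                      else s[ext[j]] <= s[ext[j + 1L]]
        rm_idx <- if (keep_first) j + 1L else j
        ext <- ext[-rm_idx]; typ <- typ[-rm_idx]
      } else j <- j + 1L
    }
  }

  ed <- ext[typ > 0]
  es <- ext[typ < 0]
  cyc <- data.frame(ed = integer(), es = integer())
  w <- smooth_window
  for (e in ed) {
    nxt <- es[es > e]
    nxt_ed <- ed[ed > e]
    if (length(nxt) == 0L) next
    if (length(nxt_ed) > 0L && nxt[1] > nxt_ed[1]) next
    # refine each extremum on the raw trace, locally around its smoothed
    # position (smoothing can shift an extremum by at most the window)
    lo <- max(1L, e - w); hi <- min(n, e + w)
    ed_raw <- lo - 1L + which.max(x[lo:hi])
    m <- nxt[1]
    lo2 <- max(ed_raw + 1L, m - w); hi2 <- min(n, m + w)
    es_raw <- lo2 - 1L + which.min(x[lo2:hi2])
    cyc <- rbind(cyc, data.frame(ed = ed_raw, es = es_raw))
  }
  if (nrow(cyc) == 0L) return(none)
  structure(list(cycles = cyc, n_cycles = nrow(cyc), status = "ok"),
            class = "cycle_markers")
}

# ---- closed-form parameters ------------------------------------------------

#' Fractional area change (percent)
#'
#' `FAC = (EDA - ESA) / EDA * 100`.
#'
#' @param EDA End-diastolic area (> 0).
#' @param ESA End-systolic area.
#' @return FAC in percent.
#' @export
fac <- function(EDA, ESA) {
  if (any(EDA <= 0)) stop("EDA must be positive")
  (EDA - ESA) / EDA * 100
}

#' Fractional shortening (percent)
#'
#' `FS = (EDa - ESa) / EDa * 100`, with `EDa`/`ESa` the long axes of the
#' minimum-area rectangles at end-diastole / end-systole.
#'
#' @param EDa End-diastolic long axis (> 0).
#' @param ESa End-systolic long axis.
#' @return FS in percent.
#' @export
fs <- function(EDa, ESa) {
  if (any(EDa <= 0)) stop("EDa must be positive")
  (EDa - ESa) / EDa * 100
}

#' Stroke volume from rectangle axes
#'
#' `SV = 4/3 * pi * (EDa * EDb^2 - ESa * ESb^2)` with the rectangle sides
#' used as printed (`convention = "as-printed"`), or with all axes halved
#' (`convention = "semi-axis"`, the prolate-spheroid volume difference,
#' exactly 1/8 of the former). A negative result (end-systole larger than
#' end-diastole) is returned with a warning, as it usually indicates cycle
#' mis-detection.
#'
#' @param ED_axes,ES_axes [axis_pair()]s at end-diastole / end-systole.
#' @param convention `"as-printed"` or `"semi-axis"`.
#' @return Stroke volume in pixel^3.
#' @export
sv <- function(ED_axes, ES_axes, convention = c("as-printed", "semi-axis")) {
  convention <- match.arg(convention)
  f <- if (convention == "semi-axis") 0.5 else 1
  out <- 4 / 3 * pi * ((f * ED_axes$a) * (f * ED_axes$b)^2 -
                       (f * ES_axes$a) * (f * ES_axes$b)^2)
  if (is.finite(out) && out < 0)
    warning("negative stroke volume: end-systole larger than end-diastole")
  out
}

#' Heart rate from cycle count and video duration
#'
#' `HR = n_cycles / duration_seconds * 60`.
#'
#' @param n_cycles Number of complete contraction cycles.
#' @param duration_seconds Video length in seconds (> 0).
#' @return Heart rate in beats/minute.
#' @export
hr_from_cycles <- function(n_cycles, duration_seconds) {
  if (any(duration_seconds <= 0)) stop("duration must be positive")
  n_cycles / duration_seconds * 60
}

# ---- full per-larva analysis ----------------------------------------------

#' Analyse a ventricle mask sequence into cardiac parameters
#'
#' Builds the area trace, detects cardiac cycles, measures end-diastolic and
#' end-systolic areas and minimum-area-rectangle axes, and computes FAC, FS,
#' SV and HR. End-diastole/end-systole values are aggregated across cycles
#' either as per-cycle means (`ed_es_mode = "mean"`, default) or from the
#' single global extrema (`"extremum"`). Cycles in which the end-systolic
#' area exceeds the end-diastolic area are rejected with a warning.
#'
#' @param masks A [mask_sequence()].
#' @param fps Frames per second.
#' @param edema Pericardial-edema flag for this larva (normal = 1,
#'   edema = 0); passed through.
#' @param sv_convention Stroke-volume axis convention, see [sv()].
#' @param ed_es_mode `"mean"` or `"extremum"`.
#' @param smooth_window,min_prominence Passed to [detect_cycles()].
#' @return A [cardiac_params()] object. With no detectable cycle, FAC, FS,
#'   SV and HR are `NA` and `status` is `"no heartbeat"`.
#' @export
analyze_video <- function(masks, fps, edema = 1L,
                          sv_convention = c("as-printed", "semi-axis"),
                          ed_es_mode = c("mean", "extremum"),
                          smooth_window = NULL, min_prominence = 0.05) {
  sv_convention <- match.arg(sv_convention)
  ed_es_mode <- match.arg(ed_es_mode)
  tr <- area_trace(masks, fps)
  cm <- detect_cycles(tr, smooth_window, min_prominence)
  duration <- length(tr) / fps
  if (cm$n_cycles == 0L) {
    return(cardiac_params(edema = edema, n_cycles = 0L,
                          status = "no heartbeat"))
  }
  cyc <- cm$cycles
  areas <- as.numeric(tr)
  ok <- areas[cyc$ed] >= areas[cyc$es]
  if (any(!ok)) {
    warning(sum(!ok), " cycle(s) rejected: end-systolic area exceeds ",
            "end-diastolic area")
    cyc <- cyc[ok, , drop = FALSE]
  }
  if (nrow(cyc) == 0L)
    return(cardiac_params(edema = edema, n_cycles = 0L,
                          status = "no heartbeat"))

  if (ed_es_mode == "extremum") {
    ed_frames <- cyc$ed[which.max(areas[cyc$ed])]
    es_frames <- cyc$es[which.min(areas[cyc$es])]
  } else {
    ed_frames <- cyc$ed
    es_frames <- cyc$es
  }
  eda <- mean(areas[ed_frames])
  esa <- mean(areas[es_frames])
  rect_of <- function(frames) {
    rects <- lapply(frames, function(t) min_area_rect(masks[, , t]))
    axis_pair(mean(vapply(rects, `[[`, 0, "a")),
              mean(vapply(rects, `[[`, 0, "b")),
              rects[[1]]$angle)
  }
  ed_ax <- rect_of(ed_frames)
  es_ax <- rect_of(es_frames)
  cardiac_params(
    EDA = eda, ESA = esa, ED_axes = ed_ax, ES_axes = es_ax,
    FAC = fac(eda, esa), FS = fs(ed_ax$a, es_ax$a),
    SV = sv(ed_ax, es_ax, sv_convention),
    HR = hr_from_cycles(nrow(cyc), duration),
    edema = edema, n_cycles = nrow(cyc), status = "ok")
}
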