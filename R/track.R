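#' Build a detection track
#'
#' A detection track is a tibble of per-frame detector output for a single
#' focal subject, one row per detected frame, carrying the session context
#' (`total_frames`, `fps`) as attributes. Frames with no row are the frames
#' the detector left unlabeled (subject out of view, or below confidence).
#'
#' Columns: `frame` (0-based frame index, strictly increasing), `time_s`
#' (seconds from session start, `frame / fps`), `behavior` (factor over the
#' four detector categories, plus the false-positive category in corrected
#' tracks), `confidence` (fraction in \[0, 1\]), and the box geometry
#' `x`, `y`, `width`, `height` in pixels with the origin at the image
#' top-left, x rightward, y downward. The box bottom corner is
#' `(x, y + height)`.
#'
#' @param detections data frame with columns `frame`, `behavior`,
#'   `confidence`, `x`, `y`, `width`, `height` (`time_s` optional; it is
#'   recomputed from `frame / fps`).
#' @param total_frames total number of frames in the session, labeled and
#'   unlabeled. Defaults to `max(frame) + 1`.
#' @param fps frames per second of the (sub-sampled) stream. Default 1.
#' @param allow_fp allow the derived false-positive category in `behavior`
#'   (used for corrected tracks). Default FALSE.
#' @return a `detection_track` tibble.
#' @examples
#' detection_track(
#'   tibble::tibble(
#'     frame = 0:2, behavior = "Locomotion", confidence = 0.9,
#'     x = 10, y = 20, width = 80, height = 120
#'   ),
#'   total_frames = 10
#' )
#' @export
detection_track <- function(detections, total_frames = NULL, fps = 1,
                            allow_fp = FALSE) {
  stopifnot(is.data.frame(detections))
  needed <- c("frame", "behavior", "confidence", "x", "y", "width", "height")
  missing_cols <- setdiff(needed, names(detections))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("detections is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  d <- tibble::as_tibble(detections)
  levels <- if (allow_fp) track_levels() else detector_levels()
  d$behavior <- as_behavior(d$behavior, levels)
  d$frame <- as.integer(d$frame)
  d <- dplyr::arrange(d, .data$frame)
  if (anyDuplicated(d$frame) > 0) {
    dup <- unique(d$frame[duplicated(d$frame)])
    rlang::abort(paste0(
      "Duplicate frame index (single focal subject expects at most one ",
      "detection per frame): ", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (nrow(d) > 0 && min(d$frame) < 0) {
    rlang::abort("frame indices must be >= 0 (0-based)")
  }
  if (nrow(d) > 0 &&
      (any(d$width <= 0) || any(d$height <= 0) ||
       any(d$x < 0) || any(d$y < 0))) {
    rlang::abort("boxes need width > 0, height > 0, x >= 0, y >= 0")
  }
  if (any(d$confidence < 0 | d$confidence > 1)) {
    rlang::abort("confidence must lie in [0, 1]")
  }
  if (is.null(total_frames)) {
    total_frames <- if (nrow(d) == 0) 0L else max(d$frame) + 1L
  }
  total_frames <- as.integer(total_frames)
  if (nrow(d) > total_frames) {
    rlang::abort("more detections than total_frames")
  }
  if (nrow(d) > 0 && max(d$frame) >= total_frames) {
    rlang::abort("frame index beyond total_frames - 1")
  }
  d$time_s <- d$frame / fps
  d <- d[, c("frame", "time_s", "behavior", "confidence",
             "x", "y", "width", "height")]
  structure(d,
    class = c("detection_track", class(tibble::tibble())),
    total_frames = total_frames, fps = fps
  )
}

#' Session context of a track, coding or budget
#'
#' @param x a `detection_track`, `manual_coding` or `time_budget`.
#' @return `total_frames()`: the session frame count; `track_fps()`: frames
#'   per second.
#' @export
total_frames <- function(x) {
  tf <- attr(x, "total_frames", exact = TRUE)
  if (is.null(tf)) rlang::abort("object carries no total_frames attribute")
  tf
}

#' @rdname total_frames
#' @export
track_fps <- function(x) {
  f <- attr(x, "fps", exact = TRUE)
  if (is.null(f)) 1 else f
}

#' @export
print.detection_track <- function(x, ...) {
  cat(sprintf("# Detection track: %d detections over %d frames (%.3g fps)\n",
              nrow(x), total_frames(x), track_fps(x)))
  NextMethod()
  invisible(x)
}

#' Build a manual ethogram coding
#'
#' Continuous focal sampling: every frame in `[0, total_frames)` carries
#' exactly one of the six ethogram categories.
#'
#' @param records data frame with columns `frame` (0-based) and `behavior`
#'   (any of the six ethogram categories, see [behavior_levels()]).
#' @param total_frames session frame count; defaults to `max(frame) + 1`.
#' @return a `manual_coding` tibble with columns `frame`, `behavior`.
#' @export
manual_coding <- function(records, total_frames = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("frame", "behavior") %in% names(records))) {
    rlang::abort("records needs columns `frame` and `behavior`")
  }
  m <- tibble::as_tibble(records)[, c("frame", "behavior")]
  m$frame <- as.integer(m$frame)
  m$behavior <- as_behavior(m$behavior, behavior_levels())
  m <- dplyr::arrange(m, .data$frame)
  if (is.null(total_frames)) {
    total_frames <- if (nrow(m) == 0) 0L else max(m$frame) + 1L
  }
  total_frames <- as.integer(total_frames)
  expected <- seq_len(total_frames) - 1L
  if (nrow(m) != total_frames || !identical(m$frame, expected)) {
    gaps <- setdiff(expected, m$frame)
    rlang::abort(paste0(
      "manual coding must cover every frame in [0, total_frames) exactly ",
      "once; missing/extra frames, e.g.: ",
      paste(utils::head(if (length(gaps)) gaps else
        m$frame[duplicated(m$frame)], 5), collapse = ", ")
    ))
  }
  structure(m,
    class = c("manual_coding", class(tibble::tibble())),
    total_frames = total_frames
  )
}

#' @export
print.manual_coding <- function(x, ...) {
  cat(sprintf("# Manual ethogram coding: %d frames\n", total_frames(x)))
  NextMethod()
  invisible(x)
}
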