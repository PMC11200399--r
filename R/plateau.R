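#' Bottom-corner coordinate series of Locomotion detections
#'
#' For every frame the detector labeled `Locomotion`, the bottom corner of
#' the label box — `(x, y + height)` under the top-left-origin convention —
#' is extracted in frame order. Plotted over time, genuine locomotion shows
#' sustained change in these coordinates, while a stationary subject that
#' was mislabeled produces a flat plateau; the plateaus are what the
#' false-positive filter removes.
#'
#' @param track a [detection_track()].
#' @return a `coordinate_series` tibble with columns `frame`, `x_bottom`,
#'   `y_bottom` (possibly empty).
#' @export
extract_coordinate_series <- function(track) {
  stopifnot(inherits(track, "detection_track"))
  loc <- track[track$behavior == "Locomotion", , drop = FALSE]
  structure(
    tibble::tibble(
      frame = loc$frame,
      x_bottom = loc$x,
      y_bottom = loc$y + loc$height
    ),
    class = c("coordinate_series", class(tibble::tibble()))
  )
}

#' Plateau-detection settings
#'
#' A plateau is a maximal run of Locomotion-labeled frames whose box
#' coordinates stay within a small tolerance — the signature of a
#' stationary subject mislabeled as moving. Tolerances are expressed as
#' coordinate *ranges* over the run (max minus min), which tolerates
#' sub-pixel jitter better than frame-to-frame deltas and matches the
#' visual notion of a flat stretch in a coordinate plot.
#'
#' @param epsilon_x,epsilon_y maximum coordinate range (pixels) a run may
#'   span per axis. Default 5.
#' @param min_run minimum number of Locomotion detections in a run (>= 2).
#'   Default 3.
#' @param max_gap maximum number of intervening frames *without* a
#'   Locomotion detection allowed between consecutive run members.
#'   Default 2.
#' @param require_both_axes_still if TRUE (default) a run must be still on
#'   both axes (x range <= epsilon_x AND y range <= epsilon_y); if FALSE,
#'   stillness on either axis suffices. Both readings of "no movement in
#'   the x- and y-coordinate" are defensible; the stricter one is the
#'   default because true locomotion normally moves both.
#' @return a `plateau_config` list.
#' @export
plateau_config <- function(epsilon_x = 5, epsilon_y = 5, min_run = 3,
                           max_gap = 2, require_both_axes_still = TRUE) {
  if (epsilon_x < 0 || epsilon_y < 0) rlang::abort("epsilons must be >= 0")
  if (min_run < 2) rlang::abort("min_run must be >= 2")
  if (max_gap < 0) rlang::abort("max_gap must be >= 0")
  structure(
    list(epsilon_x = epsilon_x, epsilon_y = epsilon_y,
         min_run = as.integer(min_run), max_gap = as.integer(max_gap),
         require_both_axes_still = isTRUE(require_both_axes_still)),
    class = "plateau_config"
  )
}

still_ok <- function(xr, yr, cfg) {
  if (cfg$require_both_axes_still) {
    xr <= cfg$epsilon_x && yr <= cfg$epsilon_y
  } else {
    xr <= cfg$epsilon_x || yr <= cfg$epsilon_y
  }
}

#' Detect coordinate plateaus in a Locomotion series
#'
#' Scans the series left to right and greedily grows each candidate run:
#' starting from the earliest unused entry, the run is extended while (a)
#' the frame gap to the next entry is at most `max_gap` and (b) the
#' coordinate ranges of the grown run still satisfy the stillness
#' predicate. A run of at least `min_run` entries is emitted and the scan
#' resumes after it, so the reported runs are disjoint and ordered.
#'
#' @param series a `coordinate_series` from [extract_coordinate_series()].
#' @param cfg a [plateau_config()].
#' @return a `plateau_runs` tibble with columns `start_frame`, `end_frame`,
#'   `n_frames` (Locomotion detections in the run), `x_range`, `y_range`.
#' @export
detect_plateaus <- function(series, cfg = plateau_config()) {
  stopifnot(inherits(series, "coordinate_series"),
            inherits(cfg, "plateau_config"))
  m <- nrow(series)
  runs <- list()
  i <- 1L
  while (i <= m) {
    xmin <- xmax <- series$x_bottom[i]
    ymin <- ymax <- series$y_bottom[i]
    j <- i
    while (j < m) {
      gap <- series$frame[j + 1L] - series$frame[j] - 1L
      if (gap > cfg$max_gap) break
      nxmin <- min(xmin, series$x_bottom[j + 1L])
      nxmax <- max(xmax, series$x_bottom[j + 1L])
      nymin <- min(ymin, series$y_bottom[j + 1L])
      nymax <- max(ymax, series$y_bottom[j + 1L])
      if (!still_ok(nxmax - nxmin, nymax - nymin, cfg)) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    len <- j - i + 1L
    if (len >= cfg$min_run && still_ok(xmax - xmin, ymax - ymin, cfg)) {
      runs[[length(runs) + 1L]] <- tibble::tibble(
        start_frame = series$frame[i], end_frame = series$frame[j],
        n_frames = len, x_range = xmax - xmin, y_range = ymax - ymin
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- if (length(runs) == 0) {
    tibble::tibble(start_frame = integer(0), end_frame = integer(0),
                   n_frames = integer(0), x_range = numeric(0),
                   y_range = numeric(0))
  } else {
    dplyr::bind_rows(runs)
  }
  structure(out,
    class = c("plateau_runs", class(tibble::tibble())),
    config = cfg
  )
}

#' Reclassify plateau frames as false-positive Locomotion
#'
#' Every Locomotion detection inside a plateau run is moved to the derived
#' category `"False Positive (Locomotion)"`. False positives are kept as
#' their own category rather than reassigned to any behavior: the method
#' diagnoses that the frame is *not* locomotion but not what it is.
#' Conservation holds exactly on unrounded percentages:
#' `fp_percent_of_total + corrected_locomotion_percent` equals the raw
#' Locomotion percentage.
#'
#' @param track the [detection_track()] the runs were computed from.
#' @param runs a `plateau_runs` tibble from [detect_plateaus()].
#' @return a `locomotion_correction` list: `corrected_track`, `runs`,
#'   `fp_count`, `fp_percent_of_total`, `corrected_locomotion_percent`,
#'   `raw_locomotion_percent`.
#' @export
reclassify_false_positives <- function(track, runs) {
  stopifnot(inherits(track, "detection_track"), is.data.frame(runs))
  is_loc <- track$behavior == "Locomotion"
  in_run <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(runs))) {
    span <- track$frame >= runs$start_frame[k] &
      track$frame <= runs$end_frame[k]
    if (!any(span & is_loc)) {
      rlang::abort(sprintf(
        "run [%d, %d] references no Locomotion detection in this track",
        runs$start_frame[k], runs$end_frame[k]
      ))
    }
    in_run <- in_run | span
  }
  flip <- in_run & is_loc
  d <- as.data.frame(track)
  d$behavior <- as.character(d$behavior)
  d$behavior[flip] <- fp_level()
  total <- total_frames(track)
  corrected <- detection_track(d, total_frames = total,
                               fps = track_fps(track), allow_fp = TRUE)
  n_loc_raw <- sum(is_loc)
  fp_count <- sum(flip)
  structure(
    list(
      corrected_track = corrected,
      runs = runs,
      fp_count = fp_count,
      fp_percent_of_total = 100 * fp_count / total,
      corrected_locomotion_percent = 100 * (n_loc_raw - fp_count) / total,
      raw_locomotion_percent = 100 * n_loc_raw / total
    ),
    class = "locomotion_correction"
  )
}

#' Filter false-positive Locomotion in one call
#'
#' Convenience wrapper: extract the bottom-corner coordinate series, detect
#' plateaus, and reclassify the frames they cover.
#'
#' @param track a [detection_track()].
#' @param cfg a [plateau_config()].
#' @return a `locomotion_correction` (see [reclassify_false_positives()]).
#' @export
filter_locomotion <- function(track, cfg = plateau_config()) {
  series <- extract_coordinate_series(track)
  runs <- detect_plateaus(series, cfg)
  reclassify_false_positives(track, runs)
}

#' Corrected time budget
#'
#' Rebuilds the detector-side budget after false-positive correction: the
#' four behavior categories plus `"False Positive (Locomotion)"` plus
#' `"Out of View/Not Labeled"`. Totals are conserved — the FP row and the
#' corrected Locomotion row sum exactly to the raw Locomotion row.
#'
#' @param result a `locomotion_correction` from
#'   [reclassify_false_positives()] / [filter_locomotion()].
#' @param base_budget the `time_budget` of the uncorrected track, used as a
#'   consistency check.
#' @return a `time_budget` tibble.
#' @export
corrected_budget <- function(result, base_budget) {
  stopifnot(inherits(result, "locomotion_correction"),
            inherits(base_budget, "time_budget"))
  out <- budget_from_detections(result$corrected_track)
  if (total_frames(out) != total_frames(base_budget)) {
    rlang::abort("base budget and corrected result disagree on total_frames")
  }
  cnt <- function(b, bud) {
    i <- match(b, bud$behavior)
    if (is.na(i)) 0L else bud$n_frames[i]
  }
  loc_split <- cnt("Locomotion", out) + cnt(fp_level(), out)
  if (loc_split != cnt("Locomotion", base_budget)) {
    rlang::abort("corrected result does not derive from this base budget")
  }
  for (b in setdiff(detector_levels(), "Locomotion")) {
    if (cnt(b, out) != cnt(b, base_budget)) {
      rlang::abort("corrected result does not derive from this base budget")
    }
  }
  attr(out, "source") <- "corrected"
  out
}

#' @export
print.locomotion_correction <- function(x, ...) {
  cat("# Locomotion false-positive correction\n")
  cat(sprintf("  plateaus: %d; frames reclassified: %d\n",
              nrow(x$runs), x$fp_count))
  cat(sprintf("  Locomotion %% of session: raw %.2f = FP %.2f + kept %.2f\n",
              x$raw_locomotion_percent, x$fp_percent_of_total,
              x$corrected_locomotion_percent))
  invisible(x)
}

#' Tidy and summarize a Locomotion correction
#'
#' `tidy()` returns the plateau-run table; `glance()` a one-row summary of
#' the false-positive split.
#'
#' @param x a `locomotion_correction`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy locomotion_correction
#' @export
tidy.locomotion_correction <- function(x, ...) {
  tibble::as_tibble(x$runs)
}

#' @rdname tidy.locomotion_correction
#' @method glance locomotion_correction
#' @export
glance.locomotion_correction <- function(x, ...) {
  tibble::tibble(
    n_plateaus = nrow(x$runs),
    fp_count = x$fp_count,
    fp_percent_of_total = x$fp_percent_of_total,
    corrected_locomotion_percent = x$corrected_locomotion_percent,
    raw_locomotion_percent = x$raw_locomotion_percent
  )
}

#' Plot a Locomotion coordinate series with detected plateaus
#'
#' The diagnostic plot behind the correction: bottom-corner x and y
#' coordinates of every Locomotion-labeled frame against frame index, with
#' detected plateau spans shaded.
#'
#' @param object a `coordinate_series`.
#' @param runs optional `plateau_runs` to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coordinate_series
#' @export
autoplot.coordinate_series <- function(object, runs = NULL, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("x_bottom", "y_bottom"),
                        names_to = "axis", values_to = "pixels")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$pixels,
                                       color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "bottom-corner coordinate (px)",
                  title = "Locomotion label-box coordinates") +
    ggplot2::theme_minimal()
  if (!is.null(runs) && nrow(runs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(runs),
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE
    )
  }
  p
}
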