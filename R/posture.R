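#' Height/width ratio of a label box
#'
#' The aspect ratio of the detection box is a cheap posture proxy: a
#' sitting subject gives a roughly square box, raised arms stretch it tall,
#' lying down flattens it.
#'
#' @param width,height box dimensions in pixels (vectorized); width must be
#'   positive.
#' @return `height / width`.
#' @examples
#' box_ratio(width = 100, height = 200) # 2
#' @export
box_ratio <- function(width, height) {
  if (any(width <= 0)) rlang::abort("width must be > 0")
  height / width
}

#' Posture-classification limits
#'
#' @param upper_limit ratio at or above which a box is called `"Arms up"`.
#'   Default 2.0.
#' @param lower_limit ratio at or below which a box is called
#'   `"Lying down"`. Default 0.6.
#'
#' @details The defaults are placeholders: sensible for a roughly 2:3
#'   sitting box, but any real deployment must calibrate both limits on
#'   footage of the subject actually performing the postures. Boundaries
#'   are inclusive toward the extreme call (a ratio exactly at
#'   `upper_limit` is `"Arms up"`).
#' @return a `ratio_config` list.
#' @export
ratio_config <- function(upper_limit = 2.0, lower_limit = 0.6) {
  if (!(lower_limit > 0 && lower_limit < upper_limit)) {
    rlang::abort("need 0 < lower_limit < upper_limit")
  }
  structure(list(upper_limit = upper_limit, lower_limit = lower_limit),
            class = "ratio_config")
}

posture_levels <- function() c("Arms up", "Lying down", "Neutral")

#' Classify posture from a box aspect ratio
#'
#' Pure threshold rule: `ratio >= upper_limit` is `"Arms up"`,
#' `ratio <= lower_limit` is `"Lying down"`, anything between is
#' `"Neutral"`.
#'
#' @param ratio height/width ratio(s), positive.
#' @param cfg a [ratio_config()].
#' @return factor over `"Arms up"`, `"Lying down"`, `"Neutral"`.
#' @examples
#' classify_posture(c(2.5, 1.0, 0.4))
#' @export
classify_posture <- function(ratio, cfg = ratio_config()) {
  if (any(ratio <= 0)) rlang::abort("ratio must be > 0")
  out <- ifelse(ratio >= cfg$upper_limit, "Arms up",
         ifelse(ratio <= cfg$lower_limit, "Lying down", "Neutral"))
  factor(out, levels = posture_levels())
}

#' Per-frame posture calls for a detection track
#'
#' One call per detection, in frame order; posture is a separate channel
#' reported alongside the behavior label, not merged into it.
#'
#' @param track a [detection_track()].
#' @param cfg a [ratio_config()].
#' @return a `posture_series` tibble with columns `frame`, `ratio`,
#'   `posture`; per-posture counts are attached as a `summary` attribute
#'   (also via [glance()][generics::glance]).
#' @export
posture_series <- function(track, cfg = ratio_config()) {
  stopifnot(inherits(track, "detection_track"))
  ratio <- if (nrow(track) > 0) box_ratio(track$width, track$height) else numeric(0)
  out <- tibble::tibble(
    frame = track$frame,
    ratio = ratio,
    posture = classify_posture(ratio, cfg)
  )
  counts <- table(factor(out$posture, levels = posture_levels()))
  structure(out,
    class = c("posture_series", class(tibble::tibble())),
    summary = counts, config = cfg
  )
}

#' @rdname tidy.time_budget
#' @method glance posture_series
#' @export
glance.posture_series <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    n_calls = nrow(x),
    arms_up = as.integer(s[["Arms up"]]),
    lying_down = as.integer(s[["Lying down"]]),
    neutral = as.integer(s[["Neutral"]])
  )
}

#' Plot a posture-ratio series
#'
#' Height/width ratio per frame with the two classification limits drawn as
#' horizontal lines — frames above the upper line read as arms raised,
#' below the lower line as lying down.
#'
#' @param object a `posture_series`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot posture_series
#' @export
autoplot.posture_series <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame, y = .data$ratio)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$posture), size = 1) +
    ggplot2::geom_hline(yintercept = cfg$upper_limit, linetype = 2) +
    ggplot2::geom_hline(yintercept = cfg$lower_limit, linetype = 2) +
    ggplot2::labs(x = "frame", y = "height / width ratio",
                  title = "Label-box aspect ratio and posture calls") +
    ggplot2::theme_minimal()
}
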