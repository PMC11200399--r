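#' Apply a confidence threshold to a detection track
#'
#' Removes detections whose confidence falls below `tau`; the boundary is
#' inclusive (a detection at exactly `tau` survives), reading a "set to 80%
#' confidence" detector as a minimum-acceptance rule. The session context
#' (`total_frames`, `fps`) is unchanged: frames losing their detection
#' simply become unlabeled.
#'
#' @param track a [detection_track()].
#' @param tau confidence threshold in \[0, 1\]. Default 0.8.
#' @return a [detection_track()] with the surviving detections.
#' @export
apply_confidence_threshold <- function(track, tau = 0.8) {
  stopifnot(inherits(track, "detection_track"))
  if (tau < 0 || tau > 1) rlang::abort("tau must lie in [0, 1]")
  keep <- track$confidence >= tau
  detection_track(as.data.frame(track)[keep, , drop = FALSE],
                  total_frames = total_frames(track),
                  fps = track_fps(track),
                  allow_fp = fp_level() %in% levels(track$behavior))
}

new_time_budget <- function(behavior, n_frames, total, source) {
  pct <- if (total > 0) 100 * n_frames / total else rep(NA_real_, length(behavior))
  structure(
    tibble::tibble(behavior = behavior, n_frames = as.integer(n_frames),
                   percent = pct),
    class = c("time_budget", class(tibble::tibble())),
    total_frames = as.integer(total), source = source
  )
}

#' Time budget from detector output
#'
#' Tallies the frames per detected behavior over the whole session; every
#' frame without a (surviving) detection is counted as
#' `"Out of View/Not Labeled"` — detector output cannot distinguish a
#' subject that is truly out of view from one the model was not confident
#' about, so the two are one category on the model side. Percentages are
#' over `total_frames`; at ~1 frame/s, frame shares and time shares
#' coincide.
#'
#' @param track a [detection_track()] (threshold it first with
#'   [apply_confidence_threshold()] if desired).
#' @return a `time_budget` tibble with columns `behavior`, `n_frames`,
#'   `percent` (exact, unrounded; use [tidy()][generics::tidy] or `print`
#'   for the one-decimal report).
#' @examples
#' trk <- detection_track(
#'   tibble::tibble(frame = 0:1, behavior = "Locomotion", confidence = 1,
#'                  x = 0, y = 0, width = 10, height = 10),
#'   total_frames = 10
#' )
#' budget_from_detections(trk)
#' @export
budget_from_detections <- function(track) {
  stopifnot(inherits(track, "detection_track"))
  total <- total_frames(track)
  if (total == 0) rlang::abort("total_frames is 0; nothing to budget")
  lv <- detector_levels()
  if (fp_level() %in% levels(track$behavior)) lv <- track_levels()
  counts <- table(factor(track$behavior, levels = lv))
  behavior <- c(lv, oov_level())
  n <- c(as.integer(counts), total - nrow(track))
  new_time_budget(behavior, n, total, source = "detections")
}

#' Time budget from a manual ethogram coding
#'
#' @param coding a [manual_coding()] covering every frame.
#' @return a `time_budget` tibble over the six ethogram categories.
#' @export
budget_from_manual <- function(coding) {
  stopifnot(inherits(coding, "manual_coding"))
  total <- total_frames(coding)
  if (total == 0) rlang::abort("total_frames is 0; nothing to budget")
  counts <- table(factor(coding$behavior, levels = behavior_levels()))
  new_time_budget(names(counts), as.integer(counts), total, source = "manual")
}

#' Labeled fraction of a detector-side budget
#'
#' Percentage of session frames that carried a surviving detection, i.e.
#' `100 - percent(Out of View/Not Labeled)`, to one decimal.
#'
#' @param budget a `time_budget` from [budget_from_detections()].
#' @return percent, one decimal.
#' @export
labeled_fraction <- function(budget) {
  stopifnot(inherits(budget, "time_budget"))
  oov <- budget$percent[budget$behavior == oov_level()]
  round_half_up(100 - oov, 1)
}

#' Compare a manual and a model time budget
#'
#' Per-behavior differences (model minus manual) over the union of
#' categories. `Other` (structurally absent from detector output) and
#' `Out of View/Not Labeled` are reported but excluded from the
#' disagreement total, which sums absolute differences over the four
#' detector-visible behaviors only.
#'
#' @param manual a `time_budget` from [budget_from_manual()].
#' @param model a `time_budget` from [budget_from_detections()] or
#'   [corrected_budget()].
#' @return a `budget_comparison` tibble with columns `behavior`,
#'   `manual_percent`, `model_percent`, `difference`, plus a
#'   `total_disagreement` attribute (see [glance.budget_comparison()]).
#' @export
compare_budgets <- function(manual, model) {
  stopifnot(inherits(manual, "time_budget"), inherits(model, "time_budget"))
  if (total_frames(manual) != total_frames(model)) {
    rlang::abort(sprintf(
      "total_frames differ (manual %d, model %d); budgets are not comparable",
      total_frames(manual), total_frames(model)
    ))
  }
  behaviors <- union(manual$behavior, model$behavior)
  pick <- function(b, bud) {
    i <- match(b, bud$behavior)
    ifelse(is.na(i), 0, bud$percent[i])
  }
  cmp <- tibble::tibble(
    behavior = behaviors,
    manual_percent = pick(behaviors, manual),
    model_percent = pick(behaviors, model),
    difference = .data$model_percent - .data$manual_percent
  )
  td <- sum(abs(cmp$difference[cmp$behavior %in% detector_levels()]))
  structure(cmp,
    class = c("budget_comparison", class(tibble::tibble())),
    total_disagreement = td, total_frames = total_frames(manual)
  )
}

#' @export
print.time_budget <- function(x, ...) {
  cat(sprintf("# Time budget (%s): %d frames\n",
              attr(x, "source") %||% "?", total_frames(x)))
  out <- tibble::as_tibble(x)
  out$percent <- round_half_up(out$percent, 1)
  print(out, ...)
  invisible(x)
}

#' @export
print.budget_comparison <- function(x, ...) {
  cat("# Manual vs model time budget (percent of session frames)\n")
  out <- tibble::as_tibble(x)
  out[-1] <- lapply(out[-1], round_half_up, digits = 1)
  print(out, ...)
  cat(sprintf("# total disagreement over detector behaviors: %.1f\n",
              round_half_up(attr(x, "total_disagreement"), 1)))
  invisible(x)
}

#' Tidy and summarize budgets and comparisons
#'
#' `tidy()` returns the table with percentages rounded to one decimal
#' (round half up, the reporting convention); `glance()` returns one-row
#' summaries.
#'
#' @param x a `time_budget` or `budget_comparison`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy time_budget
#' @export
tidy.time_budget <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$percent <- round_half_up(out$percent, 1)
  out
}

#' @rdname tidy.time_budget
#' @method glance time_budget
#' @export
glance.time_budget <- function(x, ...) {
  tibble::tibble(
    total_frames = total_frames(x),
    n_categories = nrow(x),
    labeled_percent = if (oov_level() %in% x$behavior) {
      round_half_up(100 - x$percent[x$behavior == oov_level()], 1)
    } else NA_real_
  )
}

#' @rdname tidy.time_budget
#' @method tidy budget_comparison
#' @export
tidy.budget_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out[-1] <- lapply(out[-1], round_half_up, digits = 1)
  out
}

#' @rdname tidy.time_budget
#' @method glance budget_comparison
#' @export
glance.budget_comparison <- function(x, ...) {
  tibble::tibble(
    total_frames = attr(x, "total_frames"),
    total_disagreement = attr(x, "total_disagreement")
  )
}

#' Plot a time budget or a manual-vs-model comparison
#'
#' Bar charts of the per-behavior percentages, the usual way ethogram time
#' budgets are displayed.
#'
#' @param object a `time_budget` or `budget_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot time_budget
#' @export
autoplot.time_budget <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$behavior <- factor(d$behavior, levels = d$behavior)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$behavior, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", round_half_up(.data$percent, 1))),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of session frames",
                  title = sprintf("Time budget (%s)", attr(object, "source"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.time_budget
#' @method autoplot budget_comparison
#' @export
autoplot.budget_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("manual_percent", "model_percent"),
                        names_to = "method", values_to = "percent")
  d$method <- sub("_percent$", "", d$method)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$behavior, y = .data$percent,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of session frames",
                  title = "Manual vs model time budget") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
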