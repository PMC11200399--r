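#' Behavior vocabulary
#'
#' The ethogram used throughout the package has six categories. Detector
#' output may only carry the first four; `"Out of View/Not Labeled"` and
#' `"Other"` appear in manual codings, and detector-side budgets use
#' `"Out of View/Not Labeled"` for every frame without a surviving
#' detection. After false-positive correction a seventh, derived category
#' `"False Positive (Locomotion)"` can appear in corrected tracks and
#' budgets.
#'
#' @return `behavior_levels()` returns the six ethogram category names;
#'   `detector_levels()` the four categories a detector can emit;
#'   `fp_level()` the derived false-positive category name.
#' @examples
#' behavior_levels()
#' detector_levels()
#' @export
behavior_levels <- function() {
  c("Locomotion", "Inactive", "Covered Inactive", "Foraging/Feeding",
    "Out of View/Not Labeled", "Other")
}

#' @rdname behavior_levels
#' @export
detector_levels <- function() {
  behavior_levels()[1:4]
}

#' @rdname behavior_levels
#' @export
fp_level <- function() {
  "False Positive (Locomotion)"
}

# levels legal in a (corrected) detection track
track_levels <- function() {
  c(detector_levels(), fp_level())
}

oov_level <- function() "Out of View/Not Labeled"

# Validate + normalize behavior strings against an allowed vocabulary.
# Returns a factor over `levels`; unknown strings abort with the valid list.
as_behavior <- function(x, levels, what = "behavior") {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Unknown %s label(s): %s. Valid names: %s",
      what, paste(sQuote(bad), collapse = ", "),
      paste(sQuote(levels), collapse = ", ")
    ))
  }
  factor(x, levels = levels)
}

#' Round half up
#'
#' Percentages in reports are rounded to one decimal with ties going up
#' (so 0.25 -> 0.3 at one decimal), matching conventional hand-reported
#' figures rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(98.45, 33.3333, 6.8992))
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
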