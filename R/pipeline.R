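#' Run the full post-detection analysis pipeline
#'
#' Wires the whole analysis together, from raw detector output and a manual
#' ethogram coding to the corrected, comparable time budgets: (1) threshold
#' detections at `tau`; (2) build the raw detector-side budget; (3) detect
#' coordinate plateaus and reclassify false-positive Locomotion; (4) build
#' the corrected budget; (5) classify postures from box aspect ratios;
#' (6) compare the manual budget against both the raw and corrected model
#' budgets. All stage outputs are written to `out_dir` as CSV, re-readable
#' by the package's own readers, together with a text summary and an echo
#' of the effective configuration (YAML), so a run is fully reproducible
#' from its output directory.
#'
#' @param detections_path detection CSV (see [read_detections_csv()]).
#' @param manual_path manual coding CSV (see [read_manual_csv()]); optional
#'   — without it the comparison stage is skipped.
#' @param out_dir output directory (created if needed).
#' @param tau confidence threshold. Default 0.8.
#' @param plateau a [plateau_config()].
#' @param ratio a [ratio_config()].
#' @param fps frames per second, for files without an `#fps=` comment.
#' @return invisibly, a list with `thresholded_track`, `raw_budget`,
#'   `correction`, `corrected_budget`, `postures`, and (when a manual file
#'   was given) `manual_budget`, `comparison_raw`, `comparison_corrected`,
#'   plus `paths` of all files written.
#' @export
run_full_pipeline <- function(detections_path, manual_path = NULL,
                              out_dir, tau = 0.8,
                              plateau = plateau_config(),
                              ratio = ratio_config(), fps = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  track <- read_detections_csv(detections_path, fps = fps)
  thresholded <- apply_confidence_threshold(track, tau)
  raw_budget <- budget_from_detections(thresholded)
  correction <- filter_locomotion(thresholded, plateau)
  corr_budget <- corrected_budget(correction, raw_budget)
  postures <- posture_series(thresholded, ratio)

  paths <- c(
    thresholded = file.path(out_dir, "detections_thresholded.csv"),
    corrected = file.path(out_dir, "detections_corrected.csv"),
    raw_budget = file.path(out_dir, "budget_raw.csv"),
    corrected_budget = file.path(out_dir, "budget_corrected.csv"),
    plateaus = file.path(out_dir, "plateau_report.csv"),
    postures = file.path(out_dir, "posture_series.csv"),
    config = file.path(out_dir, "config.yaml"),
    summary = file.path(out_dir, "summary.txt")
  )
  write_detections_csv(thresholded, paths[["thresholded"]])
  write_detections_csv(correction$corrected_track, paths[["corrected"]])
  write_budget_csv <- function(b, p) {
    readr::write_csv(tidy(b), p, progress = FALSE)
  }
  write_budget_csv(raw_budget, paths[["raw_budget"]])
  write_budget_csv(corr_budget, paths[["corrected_budget"]])
  readr::write_csv(
    tibble::as_tibble(correction$runs) |>
      dplyr::rename(start = "start_frame", end = "end_frame"),
    paths[["plateaus"]], progress = FALSE
  )
  readr::write_csv(tibble::as_tibble(postures), paths[["postures"]],
                   progress = FALSE)

  result <- list(
    thresholded_track = thresholded, raw_budget = raw_budget,
    correction = correction, corrected_budget = corr_budget,
    postures = postures, paths = paths
  )

  if (!is.null(manual_path)) {
    coding <- read_manual_csv(manual_path)
    manual_budget <- budget_from_manual(coding)
    cmp_raw <- compare_budgets(manual_budget, raw_budget)
    cmp_corr <- compare_budgets(manual_budget, corr_budget)
    paths[["manual_budget"]] <- file.path(out_dir, "budget_manual.csv")
    paths[["comparison_raw"]] <- file.path(out_dir, "comparison_raw.csv")
    paths[["comparison_corrected"]] <-
      file.path(out_dir, "comparison_corrected.csv")
    write_budget_csv(manual_budget, paths[["manual_budget"]])
    readr::write_csv(tidy(cmp_raw), paths[["comparison_raw"]],
                     progress = FALSE)
    readr::write_csv(tidy(cmp_corr), paths[["comparison_corrected"]],
                     progress = FALSE)
    result$manual_budget <- manual_budget
    result$comparison_raw <- cmp_raw
    result$comparison_corrected <- cmp_corr
    result$paths <- paths
  }

  cfg <- list(
    ethotrack_version = as.character(utils::packageVersion("ethotrack")),
    detections = normalizePath(detections_path),
    manual = if (is.null(manual_path)) NULL else normalizePath(manual_path),
    tau = tau, fps = fps,
    plateau = unclass(plateau), ratio = unclass(ratio)
  )
  yaml::write_yaml(cfg, paths[["config"]])

  summary_lines <- c(
    "ethotrack pipeline summary",
    sprintf("detections: %s (%d rows >= tau %.2f of %d frames)",
            detections_path, nrow(thresholded), tau,
            total_frames(thresholded)),
    sprintf("labeled fraction: %.1f%%", labeled_fraction(raw_budget)),
    sprintf("plateaus: %d; false-positive Locomotion frames: %d",
            nrow(correction$runs), correction$fp_count),
    sprintf("Locomotion %%: raw %.2f = FP %.2f + kept %.2f",
            correction$raw_locomotion_percent,
            correction$fp_percent_of_total,
            correction$corrected_locomotion_percent),
    sprintf("posture calls: %d arms-up, %d lying-down, %d neutral",
            glance(postures)$arms_up, glance(postures)$lying_down,
            glance(postures)$neutral)
  )
  if (!is.null(manual_path)) {
    summary_lines <- c(summary_lines, sprintf(
      "disagreement with manual budget (detector behaviors, |sum|): raw %.2f, corrected %.2f",
      attr(result$comparison_raw, "total_disagreement"),
      attr(result$comparison_corrected, "total_disagreement")
    ))
  }
  writeLines(summary_lines, paths[["summary"]])
  result$paths <- paths
  invisible(result)
}
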