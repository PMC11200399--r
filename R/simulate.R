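#' Synthetic detection-stream scenario
#'
#' Parameters of the generator that stands in for a camera, a focal subject
#' and a trained box detector. It produces (i) a ground-truth behavior
#' sequence as alternating bouts, (ii) a box trajectory — directed motion
#' during locomotion, an anchored, jittering box during stationary
#' behaviors, no box while out of view — and (iii) detector output with
#' missed detections, label confusion and confidence scores. The label
#' confusion from stationary behaviors to `Locomotion` is the mechanism
#' behind the coordinate plateaus the false-positive filter removes.
#'
#' @param seed default master seed; each stage derives its own stream from
#'   it so stages are independently reproducible.
#' @param total_frames session length in frames. Default 4348, a
#'   one-tenth-scale stand-in for a 12-h session at ~1 frame/s.
#' @param fps frames per second of the stream. Default 1.
#' @param behavior_mix named probabilities over the six ethogram
#'   categories; the long-run *frame* fraction spent in each (bout
#'   categories are drawn with probability proportional to
#'   `mix / bout_mean` so this holds whatever the bout means are). Defaults
#'   to the manual time budget of a captive orangutan session:
#'   Locomotion 3.6%, Inactive 13.9%, Covered Inactive 15.6%,
#'   Foraging/Feeding 18.1%, Out of View 41.3%, Other 7.5%.
#' @param bout_mean_s named mean bout durations in seconds (geometric
#'   durations, minimum 1 frame).
#' @param arena camera field of view, `c(width, height)` in pixels.
#' @param locomotion_speed displacement per frame (px) during locomotion.
#' @param stationary_jitter_sd per-frame Gaussian box jitter (px) during
#'   stationary behaviors.
#' @param box_size_base `c(width, height)` of the neutral-posture box (px).
#' @param detect_prob named per-frame detection probabilities given the
#'   true behavior; must be 0 for `Other` and `Out of View/Not Labeled`
#'   (the detector has no class for them).
#' @param mislabel_matrix 4x4 row-stochastic matrix over
#'   [detector_levels()]: `P(predicted | true)` given a detection.
#' @param mislabel_mode `"bout"` (default): one label draw per true bout,
#'   so confusion is persistent — a stationary bout mislabeled as
#'   Locomotion yields a whole plateau, as background-driven confusion
#'   does; `"frame"`: independent per-frame draws. Per-frame marginal
#'   mislabel probabilities equal the matrix entries in both modes.
#' @param confidence_model list with `correct` and `incorrect` elements,
#'   each `c(mean, sd)` of the (truncated-to-\[0,1\]) normal confidence of
#'   correctly and incorrectly labeled detections.
#' @param armsup_ratio,lying_ratio box height/width ratios planted during
#'   arms-up and lying-down bouts.
#' @param posture_prob `c(arms_up, lying_down)` probability that an
#'   `Inactive` bout carries each planted posture.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    seed = 1L,
    total_frames = 4348L,
    fps = 1,
    behavior_mix = c(
      "Locomotion" = 0.036, "Inactive" = 0.139, "Covered Inactive" = 0.156,
      "Foraging/Feeding" = 0.181, "Out of View/Not Labeled" = 0.413,
      "Other" = 0.075
    ),
    bout_mean_s = c(
      "Locomotion" = 20, "Inactive" = 90, "Covered Inactive" = 120,
      "Foraging/Feeding" = 45, "Out of View/Not Labeled" = 120,
      "Other" = 20
    ),
    arena = c(width = 1280, height = 720),
    locomotion_speed = 15,
    stationary_jitter_sd = 1,
    box_size_base = c(width = 80, height = 120),
    detect_prob = c(
      "Locomotion" = 0.95, "Inactive" = 0.9, "Covered Inactive" = 0.9,
      "Foraging/Feeding" = 0.9, "Out of View/Not Labeled" = 0, "Other" = 0
    ),
    mislabel_matrix = default_mislabel_matrix(),
    mislabel_mode = c("bout", "frame"),
    confidence_model = list(correct = c(mean = 0.93, sd = 0.04),
                            incorrect = c(mean = 0.89, sd = 0.05)),
    armsup_ratio = 2.5,
    lying_ratio = 0.4,
    posture_prob = c(arms_up = 0.03, lying_down = 0.03)) {
  mislabel_mode <- rlang::arg_match(mislabel_mode)
  lv <- behavior_levels()
  stop_unless <- function(ok, msg) if (!ok) rlang::abort(msg)
  stop_unless(all(lv %in% names(behavior_mix)),
              "behavior_mix must name all six ethogram categories")
  behavior_mix <- behavior_mix[lv]
  stop_unless(abs(sum(behavior_mix) - 1) < 1e-9, "behavior_mix must sum to 1")
  stop_unless(all(behavior_mix >= 0 & behavior_mix <= 1),
              "behavior_mix probabilities must lie in [0,1]")
  stop_unless(all(lv %in% names(bout_mean_s)),
              "bout_mean_s must name all six ethogram categories")
  bout_mean_s <- bout_mean_s[lv]
  stop_unless(all(bout_mean_s * fps >= 1),
              "bout means must be at least one frame")
  stop_unless(all(lv %in% names(detect_prob)),
              "detect_prob must name all six ethogram categories")
  detect_prob <- detect_prob[lv]
  stop_unless(all(detect_prob >= 0 & detect_prob <= 1),
              "detect_prob values must lie in [0,1]")
  stop_unless(all(detect_prob[c(oov_level(), "Other")] == 0),
              "detect_prob must be 0 for Other and Out of View/Not Labeled")
  dl <- detector_levels()
  stop_unless(is.matrix(mislabel_matrix) &&
                identical(rownames(mislabel_matrix), dl) &&
                identical(colnames(mislabel_matrix), dl),
              "mislabel_matrix must be 4x4 with detector_levels() dimnames")
  stop_unless(all(abs(rowSums(mislabel_matrix) - 1) < 1e-9),
              "mislabel_matrix rows must sum to 1")
  stop_unless(all(mislabel_matrix >= 0), "mislabel_matrix must be nonnegative")
  max_h <- max(box_size_base[["height"]],
               armsup_ratio * box_size_base[["width"]])
  stop_unless(arena[["width"]] > box_size_base[["width"]] &&
                arena[["height"]] > max_h,
              "arena is smaller than the (tallest) box")
  structure(
    list(
      seed = as.integer(seed), total_frames = as.integer(total_frames),
      fps = fps, behavior_mix = behavior_mix, bout_mean_s = bout_mean_s,
      arena = arena, locomotion_speed = locomotion_speed,
      stationary_jitter_sd = stationary_jitter_sd,
      box_size_base = box_size_base, detect_prob = detect_prob,
      mislabel_matrix = mislabel_matrix, mislabel_mode = mislabel_mode,
      confidence_model = confidence_model, armsup_ratio = armsup_ratio,
      lying_ratio = lying_ratio, posture_prob = posture_prob
    ),
    class = "synthetic_scenario"
  )
}

#' @rdname synthetic_scenario
#' @export
default_mislabel_matrix <- function() {
  dl <- detector_levels()
  m <- diag(4)
  dimnames(m) <- list(dl, dl)
  # stationary behaviors are confused with Locomotion 10% of the time
  m["Inactive", ] <- c(0.1, 0.9, 0, 0)
  m["Covered Inactive", ] <- c(0.1, 0, 0.9, 0)
  m
}

# independent per-stage RNG streams derived from one master seed
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 1299709) %% 2147483647)
}

#' Simulate a ground-truth behavior sequence
#'
#' Semi-Markov bout process: categories drawn with probability proportional
#' to `behavior_mix / bout_mean`, durations geometric (minimum one frame)
#' with the stated means, until `total_frames` frames are filled. The
#' long-run frame fraction of each category is therefore `behavior_mix`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed master seed; defaults to `scenario$seed`.
#' @return a tibble with columns `frame` (0-based), `behavior` (factor over
#'   the six categories), `bout_id`.
#' @export
simulate_behavior_sequence <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  mix <- scenario$behavior_mix
  mean_frames <- scenario$bout_mean_s * scenario$fps
  active <- names(mix)[mix > 0]
  if (length(active) == 0) rlang::abort("behavior_mix has no positive entry")
  w <- mix[active] / mean_frames[active]
  w <- w / sum(w)
  n <- scenario$total_frames
  withr::with_seed(stage_seed(seed, 1L), {
    behaviors <- vector("list", 0L)
    durations <- integer(0)
    filled <- 0L
    while (filled < n) {
      b <- sample(active, 1, prob = w)
      dur <- stats::rgeom(1, prob = 1 / mean_frames[[b]]) + 1L
      dur <- min(dur, n - filled)
      behaviors[[length(behaviors) + 1L]] <- b
      durations[length(durations) + 1L] <- dur
      filled <- filled + dur
    }
  })
  tibble::tibble(
    frame = seq_len(n) - 1L,
    behavior = factor(rep(unlist(behaviors), durations),
                      levels = behavior_levels()),
    bout_id = rep(seq_along(durations), durations)
  )
}

#' Simulate the box trajectory
#'
#' Adds ground-truth box geometry to a behavior sequence. The subject's
#' position persists across bouts. During `Locomotion` the box moves at
#' `locomotion_speed` px/frame in a per-bout random direction, reflecting
#' off the arena bounds; during stationary behaviors the box sits at a
#' fixed anchor with per-frame Gaussian jitter; out-of-view frames carry no
#' box. `Inactive` bouts may be planted with an arms-up or lying-down
#' posture, which reshapes the box to the corresponding height/width ratio.
#'
#' @param truth tibble from [simulate_behavior_sequence()].
#' @param scenario a [synthetic_scenario()].
#' @param seed master seed; defaults to `scenario$seed`.
#' @return `truth` with columns `in_view`, `x`, `y`, `width`, `height`,
#'   `posture` added (`NA` geometry while out of view).
#' @export
simulate_trajectory <- function(truth, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- nrow(truth)
  w_base <- scenario$box_size_base[["width"]]
  h_base <- scenario$box_size_base[["height"]]
  h_max <- max(h_base, scenario$armsup_ratio * w_base)
  xmax_dom <- scenario$arena[["width"]] - w_base
  ymax_dom <- scenario$arena[["height"]] - h_max
  bounce <- function(p, v, lo, hi) {
    # advance one step, reflecting position AND velocity at the bounds so
    # the path leaves a wall instead of oscillating against it
    p <- p + v
    if (p > hi) {
      p <- 2 * hi - p
      v <- -v
    } else if (p < lo) {
      p <- 2 * lo - p
      v <- -v
    }
    c(min(max(p, lo), hi), v)
  }
  x <- y <- wd <- ht <- rep(NA_real_, n)
  posture <- rep(NA_character_, n)
  in_view <- truth$behavior != oov_level()
  bouts <- split(seq_len(n), truth$bout_id)
  withr::with_seed(stage_seed(seed, 2L), {
    pos <- c(stats::runif(1, 0, xmax_dom), stats::runif(1, 0, ymax_dom))
    for (idx in bouts) {
      b <- as.character(truth$behavior[idx[1]])
      if (b == oov_level()) next
      bw <- w_base
      bh <- h_base
      post <- "Neutral"
      if (b == "Inactive") {
        u <- stats::runif(1)
        if (u < scenario$posture_prob[["arms_up"]]) {
          post <- "Arms up"
          bh <- scenario$armsup_ratio * bw
        } else if (u < sum(scenario$posture_prob)) {
          post <- "Lying down"
          bh <- scenario$lying_ratio * bw
        }
      }
      if (b == "Locomotion") {
        theta <- stats::runif(1, 0, 2 * pi)
        v <- scenario$locomotion_speed * c(cos(theta), sin(theta))
        for (i in idx) {
          sx <- bounce(pos[1], v[1], 0, xmax_dom)
          sy <- bounce(pos[2], v[2], 0, ymax_dom)
          pos <- c(sx[1], sy[1])
          v <- c(sx[2], sy[2])
          x[i] <- pos[1]; y[i] <- pos[2]
        }
      } else {
        anchor <- pos
        jit <- matrix(stats::rnorm(2 * length(idx), 0,
                                   scenario$stationary_jitter_sd),
                      ncol = 2)
        x[idx] <- pmin(pmax(anchor[1] + jit[, 1], 0), xmax_dom)
        y[idx] <- pmin(pmax(anchor[2] + jit[, 2], 0), ymax_dom)
      }
      wd[idx] <- bw
      ht[idx] <- bh
      posture[idx] <- post
    }
  })
  truth$in_view <- in_view
  truth$x <- x
  truth$y <- y
  truth$width <- wd
  truth$height <- ht
  truth$posture <- factor(posture, levels = posture_levels())
  truth
}

#' Simulate detector output
#'
#' Emits a detection for each in-view frame with probability
#' `detect_prob[true behavior]`; the predicted label comes from the
#' corresponding `mislabel_matrix` row (drawn once per bout by default, see
#' [synthetic_scenario()]); the confidence from the correct/incorrect
#' stratum of `confidence_model`. Frames whose true behavior is stationary
#' but whose emitted label is `Locomotion` form the planted false-positive
#' set the plateau filter is meant to recover.
#'
#' @param truth tibble from [simulate_trajectory()].
#' @param scenario a [synthetic_scenario()].
#' @param seed master seed; defaults to `scenario$seed`.
#' @return list with `track` (a [detection_track()]) and `truth` (input
#'   augmented with `detected`, `detected_label`, `confidence`,
#'   `is_planted_fp`).
#' @export
simulate_detections <- function(truth, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!"x" %in% names(truth)) {
    rlang::abort("truth has no trajectory; run simulate_trajectory() first")
  }
  n <- nrow(truth)
  dl <- detector_levels()
  M <- scenario$mislabel_matrix
  withr::with_seed(stage_seed(seed, 3L), {
    p_det <- scenario$detect_prob[as.character(truth$behavior)]
    detected <- stats::runif(n) < p_det & truth$in_view
    label <- rep(NA_character_, n)
    is_det_class <- as.character(truth$behavior) %in% dl
    if (scenario$mislabel_mode == "bout") {
      for (bid in unique(truth$bout_id[detected & is_det_class])) {
        idx <- which(truth$bout_id == bid)
        b <- as.character(truth$behavior[idx[1]])
        lab <- sample(dl, 1, prob = M[b, ])
        label[idx] <- lab
      }
    } else {
      for (i in which(detected & is_det_class)) {
        b <- as.character(truth$behavior[i])
        label[i] <- sample(dl, 1, prob = M[b, ])
      }
    }
    label[!detected] <- NA_character_
    correct <- !is.na(label) & label == as.character(truth$behavior)
    cm <- scenario$confidence_model
    conf <- rep(NA_real_, n)
    k <- which(!is.na(label))
    mu <- ifelse(correct[k], cm$correct[["mean"]], cm$incorrect[["mean"]])
    sd <- ifelse(correct[k], cm$correct[["sd"]], cm$incorrect[["sd"]])
    conf[k] <- pmin(pmax(stats::rnorm(length(k), mu, sd), 0), 1)
  })
  truth$detected <- !is.na(label)
  truth$detected_label <- factor(label, levels = dl)
  truth$confidence <- conf
  truth$is_planted_fp <- truth$detected &
    as.character(truth$behavior) != "Locomotion" &
    !is.na(label) & label == "Locomotion"
  det <- truth[truth$detected, , drop = FALSE]
  track <- detection_track(
    tibble::tibble(
      frame = det$frame, behavior = as.character(det$detected_label),
      confidence = det$confidence, x = det$x, y = det$y,
      width = det$width, height = det$height
    ),
    total_frames = n, fps = scenario$fps
  )
  list(track = track, truth = truth)
}

#' Run all three generator stages
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed master seed; defaults to `scenario$seed`.
#' @return list with `track` and `truth` (see [simulate_detections()]).
#' @export
simulate_study <- function(scenario, seed = scenario$seed) {
  truth <- simulate_behavior_sequence(scenario, seed)
  truth <- simulate_trajectory(truth, scenario, seed)
  simulate_detections(truth, scenario, seed)
}

#' False-positive filter performance against planted ground truth
#'
#' Scores a Locomotion correction against the generator's planted
#' false-positive set. Sensitivity is the fraction of planted
#' false-positive frames the filter reclassified; specificity is the
#' fraction of genuine locomotion detections (true behavior `Locomotion`,
#' emitted label `Locomotion`) it left untouched.
#'
#' @param truth augmented truth tibble from [simulate_detections()].
#' @param correction a `locomotion_correction` from [filter_locomotion()]
#'   run on the simulated track.
#' @return one-row tibble: `n_planted`, `n_flagged`, `n_recovered` (planted
#'   frames the filter flagged), `n_genuine` (genuine locomotion
#'   detections), `n_kept` (genuine ones left untouched), `sensitivity`
#'   (`n_recovered / n_planted`), `specificity` (`n_kept / n_genuine`).
#' @export
fp_filter_performance <- function(truth, correction) {
  stopifnot(inherits(correction, "locomotion_correction"))
  ct <- correction$corrected_track
  flagged <- ct$frame[ct$behavior == fp_level()]
  planted <- truth$frame[truth$is_planted_fp]
  genuine <- truth$frame[truth$detected &
                           as.character(truth$behavior) == "Locomotion" &
                           as.character(truth$detected_label) == "Locomotion"]
  n_recovered <- sum(planted %in% flagged)
  n_kept <- sum(!genuine %in% flagged)
  tibble::tibble(
    n_planted = length(planted),
    n_flagged = length(flagged),
    n_recovered = n_recovered,
    n_genuine = length(genuine),
    n_kept = n_kept,
    sensitivity = if (length(planted) == 0) NA_real_ else
      n_recovered / length(planted),
    specificity = if (length(genuine) == 0) NA_real_ else
      n_kept / length(genuine)
  )
}

#' Write a complete synthetic study fixture to disk
#'
#' Generates one session and writes three files in the package's dialects:
#' `detections.csv` (detector output), `manual.csv` (the idealized manual
#' coding — the ground-truth behaviors, since manual coding is treated as
#' the error-free reference), and `truth.csv`
#' (`frame,true_behavior,is_planted_fp,planted_posture`).
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @param seed master seed; defaults to `scenario$seed`.
#' @return named character vector of the three paths, invisibly; the
#'   generated `track` and `truth` are attached as attributes.
#' @export
make_study_fixture <- function(scenario, dir, seed = scenario$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_study(scenario, seed)
  paths <- c(
    detections = file.path(dir, "detections.csv"),
    manual = file.path(dir, "manual.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_detections_csv(sim$track, paths[["detections"]])
  write_manual_csv(
    manual_coding(sim$truth[, c("frame", "behavior")],
                  total_frames = scenario$total_frames),
    paths[["manual"]]
  )
  readr::write_csv(
    tibble::tibble(
      frame = sim$truth$frame,
      true_behavior = as.character(sim$truth$behavior),
      is_planted_fp = sim$truth$is_planted_fp,
      planted_posture = as.character(sim$truth$posture)
    ),
    paths[["truth"]], progress = FALSE
  )
  out <- paths
  attr(out, "track") <- sim$track
  attr(out, "truth") <- sim$truth
  invisible(out)
}
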