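mix_only <- function(...) {
  m <- c("Locomotion" = 0, "Inactive" = 0, "Covered Inactive" = 0,
         "Foraging/Feeding" = 0, "Out of View/Not Labeled" = 0, "Other" = 0)
  v <- c(...)
  m[names(v)] <- v
  m
}

test_that("a degenerate mix yields a single-behavior sequence", {
  sc <- synthetic_scenario(total_frames = 500,
                           behavior_mix = mix_only("Inactive" = 1))
  truth <- simulate_behavior_sequence(sc, seed = 4)
  expect_equal(nrow(truth), 500)
  expect_true(all(truth$behavior == "Inactive"))
  expect_error(synthetic_scenario(behavior_mix = mix_only("Inactive" = 0.5)),
               "sum to 1")
})

test_that("the generator is deterministic under (scenario, seed)", {
  sc <- synthetic_scenario(total_frames = 600)
  a <- simulate_study(sc, seed = 42)
  b <- simulate_study(sc, seed = 42)
  expect_identical(as.data.frame(a$track), as.data.frame(b$track))
  expect_identical(a$truth, b$truth)
  c <- simulate_study(sc, seed = 43)
  expect_false(identical(as.data.frame(a$track), as.data.frame(c$track)))
})

test_that("long-run frame fractions match the behavior mix", {
  sc <- synthetic_scenario(
    total_frames = 100000,
    bout_mean_s = c("Locomotion" = 10, "Inactive" = 10,
                    "Covered Inactive" = 10, "Foraging/Feeding" = 10,
                    "Out of View/Not Labeled" = 10, "Other" = 10)
  )
  truth <- simulate_behavior_sequence(sc, seed = 7)
  oov <- mean(truth$behavior == "Out of View/Not Labeled")
  expect_lt(abs(oov - 0.413), 0.02)
})

test_that("stationary bouts hold still and locomotion moves", {
  sc <- synthetic_scenario(total_frames = 2000, stationary_jitter_sd = 0,
                           locomotion_speed = 10)
  truth <- simulate_trajectory(simulate_behavior_sequence(sc, seed = 8),
                               sc, seed = 8)
  by_bout <- split(truth, truth$bout_id)
  for (bout in by_bout) {
    b <- as.character(bout$behavior[1])
    if (b == "Out of View/Not Labeled") {
      expect_true(all(is.na(bout$x)))
    } else if (b == "Locomotion") {
      if (nrow(bout) > 1) {
        step <- sqrt(diff(bout$x)^2 + diff(bout$y)^2)
        expect_true(all(step > 0))
        expect_true(all(step <= sc$locomotion_speed + 1e-9))
        expect_gte(max(step), sc$locomotion_speed / 2)
      }
    } else {
      expect_equal(diff(range(bout$x)), 0)
      expect_equal(diff(range(bout$y)), 0)
    }
  }
})

test_that("all boxes stay inside the arena", {
  sc <- synthetic_scenario(total_frames = 10000)
  truth <- simulate_trajectory(simulate_behavior_sequence(sc, seed = 9),
                               sc, seed = 9)
  vis <- truth[truth$in_view, ]
  expect_true(all(vis$x >= 0))
  expect_true(all(vis$y >= 0))
  expect_true(all(vis$x + vis$width <= sc$arena[["width"]]))
  expect_true(all(vis$y + vis$height <= sc$arena[["height"]]))
})

test_that("zero detection probability yields an all-unlabeled budget", {
  sc <- synthetic_scenario(
    total_frames = 300,
    detect_prob = c("Locomotion" = 0, "Inactive" = 0,
                    "Covered Inactive" = 0, "Foraging/Feeding" = 0,
                    "Out of View/Not Labeled" = 0, "Other" = 0)
  )
  sim <- simulate_study(sc, seed = 10)
  expect_equal(nrow(sim$track), 0)
  b <- budget_from_detections(sim$track)
  expect_equal(b$percent[b$behavior == "Out of View/Not Labeled"], 100)
})

test_that("in the noise-free limit the model budget equals the truth budget", {
  dl <- detector_levels()
  sc <- synthetic_scenario(
    total_frames = 1500,
    behavior_mix = mix_only("Locomotion" = 0.25, "Inactive" = 0.25,
                            "Covered Inactive" = 0.25,
                            "Foraging/Feeding" = 0.25),
    detect_prob = c("Locomotion" = 1, "Inactive" = 1,
                    "Covered Inactive" = 1, "Foraging/Feeding" = 1,
                    "Out of View/Not Labeled" = 0, "Other" = 0),
    mislabel_matrix = {
      m <- diag(4); dimnames(m) <- list(dl, dl); m
    }
  )
  sim <- simulate_study(sc, seed = 11)
  expect_equal(nrow(sim$track), 1500)
  expect_false(any(sim$truth$is_planted_fp))
  db <- budget_from_detections(sim$track)
  truth_counts <- table(factor(sim$truth$behavior, levels = dl))
  expect_equal(db$n_frames[match(dl, db$behavior)],
               as.integer(truth_counts))
})

test_that("per-frame confusion plants a binomial false-positive count", {
  sc <- synthetic_scenario(
    total_frames = 50000,
    behavior_mix = mix_only("Inactive" = 1),
    bout_mean_s = c("Locomotion" = 20, "Inactive" = 30,
                    "Covered Inactive" = 30, "Foraging/Feeding" = 20,
                    "Out of View/Not Labeled" = 30, "Other" = 20),
    detect_prob = c("Locomotion" = 1, "Inactive" = 1,
                    "Covered Inactive" = 1, "Foraging/Feeding" = 1,
                    "Out of View/Not Labeled" = 0, "Other" = 0),
    mislabel_mode = "frame"
  )
  sim <- simulate_study(sc, seed = 12)
  n_fp <- sum(sim$truth$is_planted_fp)
  expectation <- 50000 * 0.1
  half_width <- qnorm(0.995) * sqrt(50000 * 0.1 * 0.9)
  expect_gt(n_fp, expectation - half_width)
  expect_lt(n_fp, expectation + half_width)
})

test_that("bout-level confusion keeps the same marginal rate", {
  sc <- synthetic_scenario(
    total_frames = 50000,
    behavior_mix = mix_only("Inactive" = 1),
    bout_mean_s = c("Locomotion" = 20, "Inactive" = 30,
                    "Covered Inactive" = 30, "Foraging/Feeding" = 20,
                    "Out of View/Not Labeled" = 30, "Other" = 20),
    detect_prob = c("Locomotion" = 1, "Inactive" = 1,
                    "Covered Inactive" = 1, "Foraging/Feeding" = 1,
                    "Out of View/Not Labeled" = 0, "Other" = 0),
    mislabel_mode = "bout"
  )
  sim <- simulate_study(sc, seed = 12)
  # clustered draws: same 10% mean, bout-sized fluctuation
  expect_lt(abs(mean(sim$truth$is_planted_fp) - 0.1), 0.04)
})

test_that("study fixtures round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sc <- synthetic_scenario(total_frames = 800)
  paths <- make_study_fixture(sc, dir, seed = 13)
  expect_true(all(file.exists(paths)))

  track <- attr(paths, "track")
  back <- read_detections_csv(paths[["detections"]])
  expect_equal(as.data.frame(back), as.data.frame(track))
  expect_equal(total_frames(back), 800)

  coding <- read_manual_csv(paths[["manual"]])
  expect_equal(total_frames(coding), 800)
  expect_identical(as.character(coding$behavior),
                   as.character(attr(paths, "truth")$behavior))

  truth_csv <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_identical(names(truth_csv),
                   c("frame", "true_behavior", "is_planted_fp",
                     "planted_posture"))
  expect_equal(sum(truth_csv$is_planted_fp),
               sum(attr(paths, "truth")$is_planted_fp))

  # same seed, same bytes; different seed, different data, same schema
  dir2 <- withr::local_tempdir()
  paths2 <- make_study_fixture(sc, dir2, seed = 13)
  expect_identical(readr::read_file(paths[["detections"]]),
                   readr::read_file(paths2[["detections"]]))
  dir3 <- withr::local_tempdir()
  paths3 <- make_study_fixture(sc, dir3, seed = 14)
  expect_false(identical(readr::read_file(paths[["detections"]]),
                         readr::read_file(paths3[["detections"]])))
  expect_identical(readr::read_lines(paths3[["detections"]], n_max = 2),
                   readr::read_lines(paths[["detections"]], n_max = 2))
})

test_that("a generated manual coding reproduces the target mix", {
  sc <- synthetic_scenario(
    total_frames = 43483,
    bout_mean_s = c("Locomotion" = 8, "Inactive" = 8, "Covered Inactive" = 8,
                    "Foraging/Feeding" = 8, "Out of View/Not Labeled" = 8,
                    "Other" = 8)
  )
  truth <- simulate_behavior_sequence(sc, seed = 15)
  b <- budget_from_manual(manual_coding(truth[, c("frame", "behavior")]))
  target <- c("Locomotion" = 3.6, "Foraging/Feeding" = 18.1,
              "Inactive" = 13.9, "Covered Inactive" = 15.6,
              "Other" = 7.5, "Out of View/Not Labeled" = 41.3)
  got <- stats::setNames(b$percent, b$behavior)[names(target)]
  expect_true(all(abs(got - target) < 2),
              info = paste(round(got, 2), collapse = ", "))
})

test_that("planted postures are recovered by bracketing limits", {
  # short Inactive bouts give the session enough bouts to plant postures in
  sc <- synthetic_scenario(total_frames = 6000,
                           bout_mean_s = c(
                             "Locomotion" = 20, "Inactive" = 15,
                             "Covered Inactive" = 60,
                             "Foraging/Feeding" = 45,
                             "Out of View/Not Labeled" = 60, "Other" = 20
                           ),
                           posture_prob = c(arms_up = 0.15,
                                            lying_down = 0.15))
  sim <- simulate_study(sc, seed = 16)
  truth <- sim$truth
  ps <- posture_series(sim$track, ratio_config(2, 0.6))
  det <- truth[truth$detected, ]
  expect_gt(sum(det$posture == "Arms up"), 0)
  expect_gt(sum(det$posture == "Lying down"), 0)
  expect_identical(as.character(ps$posture),
                   as.character(det$posture[match(ps$frame, det$frame)]))
})

test_that("the plateau filter recovers planted false positives end to end", {
  perf <- purrr::map_dfr(1:5, function(r) {
    sc <- synthetic_scenario(total_frames = 4348)
    sim <- simulate_study(sc, seed = 100 + r)
    fp_filter_performance(sim$truth, filter_locomotion(sim$track))
  })
  expect_gt(sum(perf$n_planted), 0)
  expect_gte(sum(perf$n_recovered) / sum(perf$n_planted), 0.9)
  expect_gte(sum(perf$n_kept) / sum(perf$n_genuine), 0.9)
})
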