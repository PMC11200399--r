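# Shared fixtures: random-but-valid tracks and an independent brute-force
# plateau oracle used to cross-check detect_plateaus().

# drop S3 classes and ancillary attributes so only the data is compared
plain <- function(df) {
  tibble::as_tibble(lapply(df, identity))
}

random_track <- function(n_det = 50, total = 200, seed = 1,
                         behaviors = detector_levels()) {
  withr::with_seed(seed, {
    frames <- sort(sample.int(total, n_det) - 1L)
    detection_track(
      tibble::tibble(
        frame = frames,
        behavior = sample(behaviors, n_det, replace = TRUE),
        confidence = runif(n_det),
        x = runif(n_det, 0, 1000),
        y = runif(n_det, 0, 600),
        width = runif(n_det, 20, 120),
        height = runif(n_det, 20, 160)
      ),
      total_frames = total
    )
  })
}

random_series <- function(n = 100, seed = 1, step_sd = 4, gap_prob = 0.3) {
  # coordinate walk with occasional frame gaps; mixes near-still stretches
  # (small steps) with moving ones, so plateaus of all shapes occur
  withr::with_seed(seed, {
    gaps <- 1L + stats::rgeom(n, prob = 1 - gap_prob)
    frames <- cumsum(gaps) - 1L
    structure(
      tibble::tibble(
        frame = frames,
        x_bottom = cumsum(stats::rnorm(n, 0, step_sd)),
        y_bottom = cumsum(stats::rnorm(n, 0, step_sd))
      ),
      class = c("coordinate_series", class(tibble::tibble()))
    )
  })
}

# Exhaustive all-windows oracle: for every start entry, test every window
# [i, j] with naive range()/gap checks and keep the longest valid one; emit
# it when it reaches min_run and continue after it (same disjoint-run
# semantics as the scanner, arrived at by enumeration instead of
# incremental growth).
oracle_plateaus <- function(series, cfg) {
  m <- nrow(series)
  window_ok <- function(i, j) {
    f <- series$frame[i:j]
    if (j > i && any(diff(f) - 1L > cfg$max_gap)) return(FALSE)
    xr <- diff(range(series$x_bottom[i:j]))
    yr <- diff(range(series$y_bottom[i:j]))
    if (cfg$require_both_axes_still) {
      xr <= cfg$epsilon_x && yr <= cfg$epsilon_y
    } else {
      xr <= cfg$epsilon_x || yr <= cfg$epsilon_y
    }
  }
  res <- list()
  i <- 1L
  while (i <= m) {
    valid_j <- Filter(function(j) window_ok(i, j), i:m)
    j <- if (length(valid_j)) max(valid_j) else i - 1L
    if (j >= i && j - i + 1L >= cfg$min_run) {
      res[[length(res) + 1L]] <- tibble::tibble(
        start_frame = series$frame[i], end_frame = series$frame[j],
        n_frames = j - i + 1L,
        x_range = diff(range(series$x_bottom[i:j])),
        y_range = diff(range(series$y_bottom[i:j]))
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0) {
    tibble::tibble(start_frame = integer(0), end_frame = integer(0),
                   n_frames = integer(0), x_range = numeric(0),
                   y_range = numeric(0))
  } else {
    dplyr::bind_rows(res)
  }
}

# track whose per-behavior counts match the published 12-h session tally
study_counts_track <- function() {
  counts <- c("Locomotion" = 3000, "Foraging/Feeding" = 870,
              "Inactive" = 609, "Covered Inactive" = 1174)
  behavior <- rep(names(counts), counts)
  n <- length(behavior)
  detection_track(
    tibble::tibble(
      frame = seq_len(n) - 1L, behavior = behavior, confidence = 0.9,
      x = 10, y = 10, width = 80, height = 120
    ),
    total_frames = 43483L
  )
}
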