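test_that("detection CSV writer and reader are inverse (field-for-field)", {
  trk <- random_track(n_det = 50, total = 120, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(trk, path)
  back <- read_detections_csv(path)
  expect_s3_class(back, "detection_track")
  expect_equal(total_frames(back), total_frames(trk))
  expect_equal(track_fps(back), track_fps(trk))
  expect_equal(as.data.frame(back), as.data.frame(trk))
})

test_that("write-read-write is byte-identical", {
  trk <- random_track(n_det = 100, total = 300, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(trk, p1)
  write_detections_csv(read_detections_csv(p1), p2)
  expect_identical(readr::read_file(p1), readr::read_file(p2))
})

test_that("empty and single-row tracks serialize with full metadata", {
  empty <- detection_track(
    tibble::tibble(frame = integer(0), behavior = character(0),
                   confidence = numeric(0), x = numeric(0), y = numeric(0),
                   width = numeric(0), height = numeric(0)),
    total_frames = 40
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(empty, path)
  lines <- readr::read_lines(path)
  expect_identical(lines[1], "#total_frames=40")
  expect_identical(lines[2], "frame,time_s,behavior,confidence,x,y,width,height")
  expect_length(lines, 2)
  back <- read_detections_csv(path)
  expect_equal(nrow(back), 0)
  expect_equal(total_frames(back), 40)

  one <- detection_track(
    tibble::tibble(frame = 3, behavior = "Covered Inactive",
                   confidence = 0.91, x = 5, y = 6, width = 70, height = 90),
    total_frames = 10
  )
  write_detections_csv(one, path)
  lines <- readr::read_lines(path)
  expect_length(lines, 3)
  expect_length(strsplit(lines[3], ",", fixed = TRUE)[[1]], 8)
})

test_that("the behavior vocabulary is closed and errors are informative", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(c(
    "#total_frames=5",
    "frame,time_s,behavior,confidence,x,y,width,height",
    "0,0,Flying,0.9,1,1,10,10"
  ), path)
  expect_error(read_detections_csv(path), "Flying")
  expect_error(read_detections_csv(path), "Locomotion")

  readr::write_lines(c(
    "frame,time_s,behavior,confidence,x,y,width,height",
    "0,0,Locomotion,0.9,1,1,10,10",
    "1,1,Inactive,oops,1,1,10,10"
  ), path)
  expect_error(read_detections_csv(path), "line 3")
})

test_that("duplicate frames error unless highest confidence is requested", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(c(
    "#total_frames=5",
    "frame,time_s,behavior,confidence,x,y,width,height",
    "0,0,Locomotion,0.70,1,1,10,10",
    "0,0,Inactive,0.95,2,2,10,10"
  ), path)
  expect_error(read_detections_csv(path), "Duplicate frame")
  kept <- read_detections_csv(path, keep_highest_confidence = TRUE)
  expect_equal(nrow(kept), 1)
  expect_equal(as.character(kept$behavior), "Inactive")
})

write_voc <- function(dir, frame, name, xmin, ymin, xmax, ymax,
                      bndbox = TRUE) {
  box <- if (bndbox) sprintf(
    "<bndbox><xmin>%d</xmin><ymin>%d</ymin><xmax>%d</xmax><ymax>%d</ymax></bndbox>",
    xmin, ymin, xmax, ymax
  ) else ""
  xml <- sprintf(
    "<annotation><filename>frame_%04d.png</filename><object><name>%s</name>%s</object></annotation>",
    frame, name, box
  )
  readr::write_lines(xml, file.path(dir, sprintf("frame_%04d.xml", frame)))
}

test_that("PASCAL-VOC corners convert to x/y/width/height", {
  dir <- withr::local_tempdir()
  write_voc(dir, 0, "Locomotion", 10, 20, 110, 220)
  write_voc(dir, 1, "Inactive", 5, 5, 25, 25)
  trk <- read_voc_annotations(dir)
  expect_equal(as.numeric(trk[1, c("x", "y", "width", "height")]),
               c(10, 20, 100, 200))
  expect_equal(as.character(trk$behavior), c("Locomotion", "Inactive"))
  expect_true(all(trk$confidence == 1.0))
})

test_that("a generated VOC directory parses back in frame order", {
  dir <- withr::local_tempdir()
  frames <- sample(0:19)
  for (f in frames) {
    write_voc(dir, f, "Foraging/Feeding", 10 + f, 20, 60 + f, 90)
  }
  trk <- read_voc_annotations(dir, total_frames = 25)
  expect_equal(nrow(trk), 20)
  expect_identical(trk$frame, 0:19)
  expect_equal(trk$x, 10 + 0:19)
  expect_equal(total_frames(trk), 25)
})

test_that("malformed VOC files are rejected", {
  dir <- withr::local_tempdir()
  write_voc(dir, 0, "Locomotion", 10, 20, 110, 220, bndbox = FALSE)
  expect_error(read_voc_annotations(dir), "bndbox")
  unlink(file.path(dir, "frame_0000.xml"))
  write_voc(dir, 0, "Locomotion", 110, 20, 110, 220)
  expect_error(read_voc_annotations(dir), "degenerate")
})

test_that("every-nth sampling enumerates the labeled frames", {
  expect_length(sample_every_nth(3331, 10), 334)
  expect_identical(sample_every_nth(25, 10), c(0L, 10L, 20L))
  expect_identical(sample_every_nth(7, 1), 0:6)
  expect_identical(sample_every_nth(0, 10), integer(0))
  expect_error(sample_every_nth(10, 0), "n must be")
  for (t in c(1, 9, 10, 11, 100, 3331)) {
    for (n in c(1, 3, 10)) {
      idx <- sample_every_nth(t, n)
      expect_identical(idx[1], 0L)
      expect_true(all(idx < t))
      expect_length(idx, ceiling(t / n))
    }
  }
})

test_that("auto-label coverage is a one-decimal percentage", {
  expect_identical(autolabel_coverage(3281, 3331), 98.5)
  expect_identical(autolabel_coverage(0, 10), 0)
  expect_identical(autolabel_coverage(1, 3), 33.3)
  expect_error(autolabel_coverage(1, 0), "total_frames")
  expect_error(autolabel_coverage(5, 3), "labeled_count")
  cov <- vapply(0:50, autolabel_coverage, numeric(1), total_frames = 50)
  expect_true(all(diff(cov) >= 0))
})

test_that("manual coding CSVs round-trip and enforce complete coverage", {
  coding <- manual_coding(tibble::tibble(
    frame = 0:99,
    behavior = rep(behavior_levels(), length.out = 100)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manual_csv(coding, path)
  back <- read_manual_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(coding))
  expect_error(
    manual_coding(tibble::tibble(frame = c(0, 2), behavior = "Other")),
    "missing"
  )
})
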