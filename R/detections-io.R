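#' Read a detection CSV
#'
#' Reads per-frame detector output in the package's CSV dialect: UTF-8,
#' comma-separated, header `frame,time_s,behavior,confidence,x,y,width,height`,
#' optionally preceded by comment lines `#total_frames=N` (and `#fps=F`)
#' carrying session context that the detections alone cannot encode —
#' unlabeled frames are invisible in the rows. Behaviors are serialized as
#' `Locomotion`, `Inactive`, `Covered Inactive`, `Foraging/Feeding` (plus
#' `False Positive (Locomotion)` in corrected files).
#'
#' @param path path to the CSV file.
#' @param fps frames per second, used when the file carries no `#fps=`
#'   comment. Default 1.
#' @param keep_highest_confidence if TRUE, several rows for one frame are
#'   resolved by keeping the highest-confidence one; the default (FALSE)
#'   treats duplicates as an error, since the study design tracks a single
#'   focal subject.
#' @param allow_fp accept the corrected-track false-positive category.
#' @return a [detection_track()].
#' @export
read_detections_csv <- function(path, fps = 1,
                                keep_highest_confidence = FALSE,
                                allow_fp = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  is_meta <- grepl("^#", lines)
  # only leading comment lines are metadata
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  meta <- lines[seq_len(n_meta)]
  body <- lines[setdiff(seq_along(lines), seq_len(n_meta))]

  tf <- parse_meta_int(meta, "total_frames")
  fps_meta <- parse_meta_num(meta, "fps")
  if (!is.null(fps_meta)) fps <- fps_meta

  cols <- c("frame", "time_s", "behavior", "confidence",
            "x", "y", "width", "height")
  if (length(body) == 0) rlang::abort(paste0("empty file: ", path))
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!identical(header, cols)) {
    rlang::abort(paste0(
      "unexpected header in ", path, "; expected `",
      paste(cols, collapse = ","), "`"
    ))
  }
  d <- readr::read_csv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # numbers are converted with base R's parser so that the shortest decimal
  # representations the writer emits round-trip bit-exactly
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad) > 0 || anyNA(d[[col]])) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(d[[col]]))[1]
      rlang::abort(sprintf(
        "malformed row in %s at line %d: cannot parse column `%s` value `%s` as a number",
        path, row + n_meta + 1L, col,
        if (is.na(d[[col]][row])) "" else d[[col]][row]
      ))
    }
    v
  }
  for (col in c("time_s", "confidence", "x", "y", "width", "height")) {
    d[[col]] <- parse_num(col)
  }
  d$frame <- as.integer(parse_num("frame"))
  if (keep_highest_confidence && nrow(d) > 0) {
    d <- d |>
      dplyr::group_by(.data$frame) |>
      dplyr::slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  detection_track(d, total_frames = tf, fps = fps, allow_fp = allow_fp)
}

parse_meta_int <- function(meta, key) {
  v <- parse_meta_num(meta, key)
  if (is.null(v)) NULL else as.integer(v)
}

parse_meta_num <- function(meta, key) {
  pat <- paste0("^#\\s*", key, "\\s*=\\s*([0-9.eE+-]+)\\s*$")
  hit <- grep(pat, meta, value = TRUE)
  if (length(hit) == 0) return(NULL)
  as.numeric(sub(pat, "\\1", hit[1]))
}

#' Write a detection CSV
#'
#' Emits the dialect documented in [read_detections_csv()]; a
#' `#total_frames=` comment (and `#fps=` when fps differs from 1) precedes
#' the header so that `read(write(track))` reproduces the track exactly.
#'
#' @param track a [detection_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(track, path) {
  stopifnot(inherits(track, "detection_track"))
  meta <- sprintf("#total_frames=%d", total_frames(track))
  if (track_fps(track) != 1) {
    meta <- c(meta, sprintf("#fps=%.17g", track_fps(track)))
  }
  d <- tibble::as_tibble(track)
  d$behavior <- as.character(d$behavior)
  for (col in c("time_s", "confidence", "x", "y", "width", "height")) {
    d[[col]] <- fmt_double(d[[col]])
  }
  body <- readr::format_csv(d)
  readr::write_lines(c(meta, sub("\n$", "", body)), path)
  invisible(path)
}

# shortest decimal representation that parses back to the same double, so
# write -> read -> write is byte-identical
fmt_double <- function(x) {
  vapply(x, function(v) {
    for (digits in 1:17) {
      s <- sprintf("%.*g", digits, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Read PASCAL-VOC annotation XML files
#'
#' Reads a directory of per-frame PASCAL-VOC XML files (the native export
#' of common box-labeling tools) into a detection track. Each file is
#' expected to contain one `object` element; the frame index is the
#' trailing integer of the filename stem (e.g. `frame_0012.xml` -> 12).
#' Human labels carry confidence 1.0. VOC corner coordinates
#' `(xmin, ymin, xmax, ymax)` are converted to `(x, y, width, height)`
#' under the top-left-origin convention.
#'
#' @param dir directory containing `.xml` files.
#' @param index_base `"zero"` (default) if filename numbers are 0-based,
#'   `"one"` if 1-based (then 1 is subtracted on read).
#' @param total_frames optional session frame count.
#' @param fps frames per second. Default 1.
#' @param multiple how to treat several `object` elements in one file:
#'   `"error"` (default, single focal subject) or `"first"`.
#' @return a [detection_track()].
#' @export
read_voc_annotations <- function(dir, index_base = c("zero", "one"),
                                 total_frames = NULL, fps = 1,
                                 multiple = c("error", "first")) {
  index_base <- rlang::arg_match(index_base)
  multiple <- rlang::arg_match(multiple)
  files <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  if (length(files) == 0) rlang::abort(paste0("no .xml files in ", dir))
  rows <- purrr::map(files, function(f) {
    stem <- sub("\\.xml$", "", basename(f))
    m <- regmatches(stem, regexpr("[0-9]+$", stem))
    if (length(m) == 0) {
      rlang::abort(paste0("cannot parse a frame index from filename: ", f))
    }
    frame <- as.integer(m) - (index_base == "one")
    doc <- xml2::read_xml(f)
    objs <- xml2::xml_find_all(doc, ".//object")
    if (length(objs) == 0) rlang::abort(paste0("no <object> element in ", f))
    if (length(objs) > 1 && multiple == "error") {
      rlang::abort(paste0(
        length(objs), " <object> elements in ", f,
        " (single focal subject); use multiple = \"first\" to keep the first"
      ))
    }
    obj <- objs[[1]]
    name <- xml2::xml_text(xml2::xml_find_first(obj, "./name"))
    bb <- xml2::xml_find_first(obj, "./bndbox")
    if (inherits(bb, "xml_missing")) {
      rlang::abort(paste0("missing <bndbox> element in ", f))
    }
    co <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
    }, numeric(1))
    if (any(is.na(co))) rlang::abort(paste0("incomplete <bndbox> in ", f))
    if (co["xmax"] <= co["xmin"] || co["ymax"] <= co["ymin"]) {
      rlang::abort(paste0("degenerate box (xmax <= xmin or ymax <= ymin) in ", f))
    }
    tibble::tibble(
      frame = frame, behavior = name, confidence = 1.0,
      x = co[["xmin"]], y = co[["ymin"]],
      width = co[["xmax"]] - co[["xmin"]],
      height = co[["ymax"]] - co[["ymin"]]
    )
  })
  detection_track(dplyr::bind_rows(rows), total_frames = total_frames,
                  fps = fps)
}

#' Read / write a manual ethogram coding CSV
#'
#' Dialect: header `frame,behavior`, one row per frame, any of the six
#' ethogram categories (see [behavior_levels()]).
#'
#' @param path CSV path.
#' @param coding a [manual_coding()].
#' @return `read_manual_csv()` a [manual_coding()]; `write_manual_csv()`
#'   `path`, invisibly.
#' @export
read_manual_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    behavior = readr::col_character()
  ), progress = FALSE)
  manual_coding(d)
}

#' @rdname read_manual_csv
#' @export
write_manual_csv <- function(coding, path) {
  stopifnot(inherits(coding, "manual_coding"))
  readr::write_csv(as.data.frame(coding), path, progress = FALSE)
  invisible(path)
}

#' Frames selected when labeling every n-th frame
#'
#' Training material for the detector is built by hand-labeling every n-th
#' extracted frame (every tenth, in the workflow this package supports).
#'
#' @param total_frames number of extracted frames.
#' @param n sampling step (>= 1).
#' @return integer vector of 0-based frame indices `0, n, 2n, ...` below
#'   `total_frames`; its length is `ceiling(total_frames / n)`.
#' @examples
#' length(sample_every_nth(3331, 10)) # 334 frames to hand-label
#' @export
sample_every_nth <- function(total_frames, n) {
  if (n < 1) rlang::abort("n must be >= 1")
  total_frames <- as.integer(total_frames)
  if (total_frames < 0) rlang::abort("total_frames must be >= 0")
  if (total_frames == 0) return(integer(0))
  seq.int(0L, total_frames - 1L, by = as.integer(n))
}

#' Auto-labeling coverage
#'
#' Share of extracted frames that a first-pass model managed to label
#' automatically, as a percentage to one decimal (round half up).
#'
#' @param labeled_count frames labeled automatically.
#' @param total_frames all extracted frames (> 0).
#' @return percent, one decimal.
#' @examples
#' autolabel_coverage(3281, 3331) # 98.5
#' @export
autolabel_coverage <- function(labeled_count, total_frames) {
  if (total_frames <= 0) rlang::abort("total_frames must be > 0")
  if (labeled_count < 0 || labeled_count > total_frames) {
    rlang::abort("labeled_count must lie in [0, total_frames]")
  }
  round_half_up(100 * labeled_count / total_frames, 1)
}
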