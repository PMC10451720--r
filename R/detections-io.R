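#' @importFrom rlang .data
NULL

detection_columns <- c("frame", "cls", "cx", "cy", "w", "h", "conf")

#' Build a validated per-frame detection stream
#'
#' A detection stream is a tibble with one row per detected bounding box and
#' columns `frame`, `cls`, `cx`, `cy`, `w`, `h`, `conf`. Box centers use
#' pixel coordinates with the origin at the top-left of the image and y
#' increasing downward (the detector convention); `conf` is the detector's
#' objectness/confidence score in \[0, 1\]. Frames with no detections are
#' represented explicitly through the `frames` attribute, so clip lengths
#' stay fixed even when every animal is missed.
#'
#' @param detections A data frame with columns `frame`, `cls`, `cx`, `cy`,
#'   `w`, `h`, `conf` (pixel coordinates). May have zero rows.
#' @param geometry A [frame_geometry()].
#' @param frames Integer vector of frame indices covered by the stream,
#'   contiguous and increasing. Defaults to `min(frame):max(frame)` of the
#'   rows present, so explicitly pass it when leading/trailing frames are
#'   empty.
#' @param label Optional clip label: 1 = aggression, 0 = non-aggression.
#'
#' @return A `video_detections` tibble with attributes `geometry`, `frames`,
#'   and `label`.
#' @examples
#' det <- tibble::tibble(frame = c(0L, 0L, 1L), cls = "sheep",
#'                       cx = c(100, 600, 110), cy = c(200, 700, 205),
#'                       w = 120, h = 80, conf = 0.9)
#' video_detections(det, frame_geometry())
#' @export
video_detections <- function(detections, geometry, frames = NULL, label = NULL) {
  assert_geometry(geometry)
  det <- tibble::as_tibble(detections)
  missing_cols <- setdiff(detection_columns, names(det))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("`detections` is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  det <- det[detection_columns]
  det$frame <- as.integer(det$frame)
  det$cls <- as.character(det$cls)
  for (col in c("cx", "cy", "w", "h", "conf")) det[[col]] <- as.double(det[[col]])

  if (is.null(frames)) {
    frames <- if (nrow(det) == 0) integer(0) else seq(min(det$frame), max(det$frame))
  }
  frames <- as.integer(frames)
  if (length(frames) > 0 && !identical(frames, seq(frames[1], frames[length(frames)]))) {
    rlang::abort("`frames` must be contiguous increasing frame indices (no gaps).")
  }
  if (length(frames) > 0 && frames[1] < 0L) {
    rlang::abort("frame indices must be >= 0.")
  }
  if (nrow(det) > 0 && !all(det$frame %in% frames)) {
    rlang::abort("`detections` contains frame indices outside `frames`.")
  }
  validate_boxes(det, geometry)
  if (!is.null(label)) {
    if (!label %in% c(0, 1)) rlang::abort("`label` must be 0 or 1.")
    label <- as.integer(label)
  }
  det <- det[order(det$frame), , drop = FALSE]
  structure(det,
            geometry = geometry, frames = frames, label = label,
            class = c("video_detections", class(tibble::tibble())))
}

validate_boxes <- function(det, geometry, call = rlang::caller_env()) {
  if (nrow(det) == 0) return(invisible(det))
  bad <- det$cx < 0 | det$cx > geometry$width |
    det$cy < 0 | det$cy > geometry$height
  if (any(bad)) {
    rlang::abort(sprintf(
      "%d detection(s) have centers outside the %d x %d image.",
      sum(bad), geometry$width, geometry$height), call = call)
  }
  if (any(det$w <= 0 | det$h <= 0)) {
    rlang::abort("box width and height must be > 0.", call = call)
  }
  if (any(det$conf < 0 | det$conf > 1)) {
    rlang::abort("`conf` must lie in [0, 1].", call = call)
  }
  invisible(det)
}

#' @export
geometry_of <- function(x) attr(x, "geometry", exact = TRUE)

#' @export
frames_of <- function(x) attr(x, "frames", exact = TRUE)

#' @export
label_of <- function(x) attr(x, "label", exact = TRUE)

# keep video attributes when dplyr-style subsetting returns a new tibble
reattach_video_attrs <- function(new, old, frames = frames_of(old)) {
  structure(tibble::as_tibble(new),
            geometry = geometry_of(old), frames = frames,
            label = label_of(old),
            class = c("video_detections", class(tibble::tibble())))
}

map_numeric_class <- function(cls, class_labels) {
  idx <- suppressWarnings(as.integer(cls))
  mapped <- !is.na(idx) & idx >= 0 & idx < length(class_labels)
  cls[mapped] <- class_labels[idx[mapped] + 1L]
  cls
}

filter_classes <- function(det, keep, call = rlang::caller_env()) {
  if (is.null(keep)) return(det)
  drop_n <- sum(!det$cls %in% keep)
  if (drop_n > 0) {
    rlang::inform(sprintf("Dropped %d detection(s) with class outside [%s].",
                          drop_n, paste(keep, collapse = ", ")))
  }
  det[det$cls %in% keep, , drop = FALSE]
}

#' Read YOLO-style per-frame detection files
#'
#' Reads a directory of whitespace-separated text files, one per frame,
#' named `<stem>_<frameindex>.txt`, each row `cls cx cy w h [conf]`. The
#' `normalized` dialect (the YOLO default, coordinates as fractions of the
#' image) and the `pixel` dialect are both supported; internally everything
#' is converted to pixel box-centers with the origin at the image top-left.
#' A missing confidence column defaults to 1.0. Empty files denote frames
#' with no detections and are kept so clip lengths stay fixed.
#'
#' Numeric class tokens are mapped onto `class_labels` the YOLO way (id 0 is
#' the first label); rows whose class is not in `keep` are dropped with a
#' message.
#'
#' @param path Directory containing the per-frame files.
#' @param geometry A [frame_geometry()] used to convert normalized
#'   coordinates and validate pixel ones.
#' @param coordinate_mode `"normalized"` or `"pixel"`.
#' @param class_labels Character vector naming the detector's classes in id
#'   order. Default `"sheep"`.
#' @param keep Classes to retain (default `"sheep"`); `NULL` keeps all.
#' @param label Optional 0/1 clip label to attach.
#'
#' @return A [video_detections()] tibble.
#' @export
read_yolo_frames <- function(path, geometry,
                             coordinate_mode = c("normalized", "pixel"),
                             class_labels = "sheep", keep = "sheep",
                             label = NULL) {
  assert_geometry(geometry)
  coordinate_mode <- match.arg(coordinate_mode)
  if (!dir.exists(path)) rlang::abort(sprintf("directory not found: %s", path))
  files <- list.files(path, pattern = "_[0-9]+\\.txt$", full.names = TRUE)
  if (length(files) == 0) {
    rlang::abort(sprintf("no files matching '<stem>_<frameindex>.txt' in %s", path))
  }
  idx <- as.integer(sub("^.*_([0-9]+)\\.txt$", "\\1", basename(files)))
  ord <- order(idx)
  files <- files[ord]
  idx <- idx[ord]
  if (anyDuplicated(idx)) {
    rlang::abort("duplicate frame indices among detection files.")
  }

  per_frame <- purrr::map2(files, idx, function(f, i) {
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(tibble::tibble(frame = integer(0), cls = character(0),
                            cx = double(0), cy = double(0),
                            w = double(0), h = double(0), conf = double(0)))
    }
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    n_tok <- lengths(toks)
    bad <- which(n_tok < 5 | n_tok > 6)
    if (length(bad) > 0) {
      rlang::abort(sprintf("malformed row in %s, line %d: expected 5 or 6 columns, found %d",
                           basename(f), bad[1], n_tok[bad[1]]))
    }
    num <- lapply(seq_along(toks), function(j) {
      v <- suppressWarnings(as.numeric(toks[[j]][-1]))
      if (anyNA(v)) {
        rlang::abort(sprintf("malformed row in %s, line %d: non-numeric value",
                             basename(f), j))
      }
      v
    })
    cls <- vapply(toks, `[[`, character(1), 1L)
    m <- do.call(rbind, lapply(num, function(v) c(v, if (length(v) == 4) 1.0)))
    tibble::tibble(frame = i, cls = cls, cx = m[, 1], cy = m[, 2],
                   w = m[, 3], h = m[, 4], conf = m[, 5])
  })
  det <- dplyr::bind_rows(per_frame)

  if (coordinate_mode == "normalized" && nrow(det) > 0) {
    vals <- c(det$cx, det$cy, det$w, det$h)
    if (any(vals < 0 | vals > 1)) {
      rlang::abort("normalized coordinates must lie in [0, 1].")
    }
    det$cx <- det$cx * geometry$width
    det$cy <- det$cy * geometry$height
    det$w <- det$w * geometry$width
    det$h <- det$h * geometry$height
  }
  det$cls <- map_numeric_class(det$cls, class_labels)
  det <- filter_classes(det, keep)
  frames <- seq(idx[1], idx[length(idx)])
  if (!identical(sort(idx), frames)) {
    rlang::abort("frame files must cover a contiguous index range (no gaps).")
  }
  video_detections(det, geometry, frames = frames, label = label)
}

#' Write a detection stream as YOLO-style per-frame files
#'
#' Inverse of [read_yolo_frames()]: one text file per frame (including empty
#' frames), rows `cls cx cy w h conf` with the confidence always written.
#' Classes found in `class_labels` are written as numeric YOLO ids; other
#' class tokens are written verbatim.
#'
#' @param video A [video_detections()] stream.
#' @param path Output directory (created if needed).
#' @param coordinate_mode `"normalized"` or `"pixel"`.
#' @param stem Filename stem; files are named `<stem>_<frameindex>.txt`.
#' @param class_labels Class-name-to-id mapping, as in [read_yolo_frames()].
#'
#' @return Invisibly, the vector of files written.
#' @export
write_yolo_frames <- function(video, path,
                              coordinate_mode = c("normalized", "pixel"),
                              stem = "frame", class_labels = "sheep") {
  coordinate_mode <- match.arg(coordinate_mode)
  geometry <- geometry_of(video)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) rlang::abort(sprintf("cannot create directory: %s", path))
  det <- tibble::as_tibble(video)
  if (coordinate_mode == "normalized" && nrow(det) > 0) {
    det$cx <- det$cx / geometry$width
    det$cy <- det$cy / geometry$height
    det$w <- det$w / geometry$width
    det$h <- det$h / geometry$height
  }
  cls_id <- match(det$cls, class_labels) - 1L
  cls_out <- ifelse(is.na(cls_id), det$cls, as.character(cls_id))
  files <- character(0)
  for (fr in frames_of(video)) {
    f <- file.path(path, sprintf("%s_%06d.txt", stem, fr))
    rows <- which(det$frame == fr)
    lines <- if (length(rows) == 0) character(0) else {
      sprintf("%s %.12g %.12g %.12g %.12g %.12g",
              cls_out[rows], det$cx[rows], det$cy[rows],
              det$w[rows], det$h[rows], det$conf[rows])
    }
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a long-format detection CSV
#'
#' Reads a CSV with header `frame,cls,cx,cy,w,h,conf` in pixel coordinates.
#' Rows are grouped and sorted by frame index; duplicate rows are kept (a
#' duplicated box is a detector artifact, not an error).
#'
#' @inheritParams read_yolo_frames
#' @param path CSV file path.
#' @param frames Optional explicit contiguous frame range (to represent
#'   empty leading/trailing frames); defaults to the observed range.
#' @return A [video_detections()] tibble.
#' @export
read_detections_csv <- function(path, geometry, keep = "sheep",
                                frames = NULL, label = NULL) {
  assert_geometry(geometry)
  det <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), cls = readr::col_character(),
    cx = readr::col_double(), cy = readr::col_double(),
    w = readr::col_double(), h = readr::col_double(),
    conf = readr::col_double()), progress = FALSE)
  if (!identical(names(det), detection_columns)) {
    rlang::abort(sprintf(
      "CSV header must be '%s'; found '%s'.",
      paste(detection_columns, collapse = ","), paste(names(det), collapse = ",")))
  }
  det <- filter_classes(det, keep)
  video_detections(det, geometry, frames = frames, label = label)
}

#' Write a detection stream as a long-format CSV
#'
#' Inverse of [read_detections_csv()]; pixel coordinates, header
#' `frame,cls,cx,cy,w,h,conf`.
#'
#' @param video A [video_detections()] stream.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections_csv <- function(video, path) {
  readr::write_csv(tibble::as_tibble(video)[detection_columns], path, progress = FALSE)
  invisible(path)
}

#' Read camera geometry from a YAML config
#'
#' Convenience for command-line use: a YAML file with keys `width`, `height`
#' and `fps` becomes a [frame_geometry()].
#'
#' @param path YAML file path.
#' @return A [frame_geometry()].
#' @export
read_geometry_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    rlang::abort("the 'yaml' package is required to read YAML configs.")
  }
  cfg <- yaml::read_yaml(path)
  frame_geometry(cfg$width, cfg$height, cfg$fps %||% 25L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
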