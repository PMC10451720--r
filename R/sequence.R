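#' Frame-skipping configuration
#'
#' A clip is one second of video; `skip = k` keeps one frame after
#' discarding `k`, so an `n`-frame window yields `floor(n / (k + 1))` kept
#' frames. At 25 fps this gives 25, 12, 8, 6 frames for k = 0..3; `k = 1`
#' is the default — it halves detector and training time while making the
#' frame-to-frame displacement of an aggressive charge roughly twice as
#' pronounced.
#'
#' @param skip Number of frames skipped between kept frames (k >= 0).
#' @param clip_seconds Clip duration in seconds (default 1, the minimum
#'   observed duration of an aggression bout).
#' @return A `skip_config` object.
#' @export
skip_config <- function(skip = 1L, clip_seconds = 1) {
  skip <- as.integer(skip)
  if (is.na(skip) || skip < 0L) rlang::abort("`skip` must be an integer >= 0.")
  if (!is.numeric(clip_seconds) || clip_seconds <= 0) {
    rlang::abort("`clip_seconds` must be > 0.")
  }
  structure(list(skip = skip, clip_seconds = clip_seconds), class = "skip_config")
}

#' Cut a detection stream into one-second windows
#'
#' Consecutive, non-overlapping windows of `fps * clip_seconds` frames; a
#' trailing partial window is discarded. A `stride` shorter than the window
#' produces overlapping windows for data augmentation (off by default).
#'
#' @param video A [video_detections()] stream.
#' @param skip_config A [skip_config()] (only `clip_seconds` is used here).
#' @param stride Window start spacing in frames; defaults to the window
#'   length (disjoint windows).
#' @return A tibble with one row per window: `clip_id`, `start_frame`,
#'   `end_frame`.
#' @export
segment_clips <- function(video, skip_config = flockwatch::skip_config(),
                          stride = NULL) {
  geometry <- geometry_of(video)
  frames <- frames_of(video)
  win <- as.integer(round(geometry$fps * skip_config$clip_seconds))
  stride <- as.integer(stride %||% win)
  if (stride <= 0L) rlang::abort("`stride` must be positive.")
  n <- length(frames)
  if (n < win) {
    return(tibble::tibble(clip_id = integer(0), start_frame = integer(0),
                          end_frame = integer(0)))
  }
  starts <- seq.int(1L, n - win + 1L, by = stride)
  tibble::tibble(clip_id = seq_along(starts),
                 start_frame = frames[starts],
                 end_frame = frames[starts + win - 1L])
}

#' Subsample a frame window by skipping
#'
#' Implements the "skip k, keep one, repeat" rule starting with a skip: the
#' kept local indices are `(k+1)*j + k` for `j = 0 .. floor(n/(k+1)) - 1`.
#' This is the unique simple rule reproducing the 25 -> 12/8/6 frame counts
#' for k = 1, 2, 3.
#'
#' @param window A vector of frame indices (or anything indexable).
#' @param k Number of frames skipped between kept frames.
#' @return The kept subsequence, of length `floor(length(window) / (k+1))`.
#' @examples
#' length(skip_frames(1:25, 1))  # 12
#' length(skip_frames(1:25, 2))  # 8
#' length(skip_frames(1:25, 3))  # 6
#' @export
skip_frames <- function(window, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) rlang::abort("`k` must be an integer >= 0.")
  n <- length(window)
  m <- n %/% (k + 1L)
  if (m == 0L) return(window[0])
  window[(k + 1L) * (seq_len(m) - 1L) + k + 1L]
}

#' Min-max normalization spec for box coordinates
#'
#' Per-channel `(value - min) / (max - min)` rescaling of `cx`, `cy`, `w`,
#' `h` to \[0, 1\]. The default `image_bounds` mode uses the image raster as
#' the range (x and w over `[0, width]`, y and h over `[0, height]`) so the
#' constants are data-independent and identical between training and
#' deployment; `dataset_minmax` derives the ranges from a reference set of
#' detections instead.
#'
#' @param geometry A [frame_geometry()] (used by `image_bounds` mode).
#' @param mode `"image_bounds"` or `"dataset_minmax"`.
#' @param reference For `dataset_minmax`: a data frame of detections whose
#'   per-channel ranges define the spec.
#' @return A `norm_spec` object: a list of `c(min, max)` per channel.
#' @export
norm_spec <- function(geometry = frame_geometry(),
                      mode = c("image_bounds", "dataset_minmax"),
                      reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "image_bounds") {
    assert_geometry(geometry)
    ch <- list(cx = c(0, geometry$width), cy = c(0, geometry$height),
               w = c(0, geometry$width), h = c(0, geometry$height))
  } else {
    if (is.null(reference) || nrow(reference) == 0) {
      rlang::abort("`dataset_minmax` mode needs a nonempty `reference` detection set.")
    }
    ch <- lapply(reference[c("cx", "cy", "w", "h")], range)
  }
  for (nm in names(ch)) {
    if (ch[[nm]][2] <= ch[[nm]][1]) {
      rlang::abort(sprintf("degenerate normalization range for channel '%s' (max <= min).", nm))
    }
  }
  structure(list(channels = ch, mode = mode), class = "norm_spec")
}

#' Min-max normalize box coordinates
#'
#' Maps each channel by `(value - min) / (max - min)`; values outside the
#' spec's range are clipped to \[0, 1\] with a warning (this can only happen
#' in `dataset_minmax` mode, when deployment data exceed the reference
#' ranges).
#'
#' @param detections A data frame with `cx`, `cy`, `w`, `h` columns.
#' @param spec A [norm_spec()].
#' @return A tibble with the four channels rescaled to \[0, 1\]; other
#'   columns are preserved.
#' @export
normalize_box <- function(detections, spec) {
  det <- tibble::as_tibble(detections)
  clipped <- 0L
  for (nm in c("cx", "cy", "w", "h")) {
    r <- spec$channels[[nm]]
    x <- (det[[nm]] - r[1]) / (r[2] - r[1])
    out_of_range <- x < 0 | x > 1
    clipped <- clipped + sum(out_of_range)
    det[[nm]] <- pmin(pmax(x, 0), 1)
  }
  if (clipped > 0) {
    rlang::warn(sprintf("%d value(s) outside the normalization range were clipped to [0, 1].",
                        clipped))
  }
  det
}

#' Build the clip tensor for one window
#'
#' For each kept frame of the window (after [skip_frames()]), detections are
#' normalized and packed by [pack_frame()]; the rows are stacked into a
#' `T x 600` matrix where `T = floor(window / (skip + 1))`.
#'
#' @param video A [video_detections()] stream.
#' @param start_frame,end_frame Window bounds (inclusive); default to the
#'   first `fps * clip_seconds` frames of the stream.
#' @param config A [heuristic_config()].
#' @param skip_config A [skip_config()].
#' @param spec A [norm_spec()].
#' @param order Passed to [pack_frame()] (`"heuristic"` or `"shuffled"`).
#' @return A `clip_tensor`: a `T x 600` numeric matrix with attributes
#'   `label` and `provenance` (start/end frame).
#' @export
build_clip_tensor <- function(video, start_frame = NULL, end_frame = NULL,
                              config = heuristic_config(),
                              skip_config = flockwatch::skip_config(),
                              spec = norm_spec(geometry_of(video)),
                              order = c("heuristic", "shuffled")) {
  order <- match.arg(order)
  geometry <- geometry_of(video)
  frames <- frames_of(video)
  win <- as.integer(round(geometry$fps * skip_config$clip_seconds))
  start_frame <- as.integer(start_frame %||% frames[1])
  end_frame <- as.integer(end_frame %||% (start_frame + win - 1L))
  window <- seq.int(start_frame, end_frame)
  if (!all(window %in% frames)) {
    rlang::abort("window extends beyond the frames covered by `video`.")
  }
  kept <- skip_frames(window, skip_config$skip)
  det <- tibble::as_tibble(video)
  rows <- lapply(kept, function(fr) {
    pack_frame(det[det$frame == fr, , drop = FALSE], geometry, config,
               spec = spec, order = order)
  })
  m <- do.call(rbind, c(rows, list(matrix(numeric(0), 0, packed_length(config)))))
  tuples <- NULL
  if (order == "shuffled") {
    # keep the raw normalized tuples so training can re-randomize the
    # packing order each epoch (the ablation's point is that order carries
    # no information, not that one arbitrary arrangement is memorable)
    tuples <- lapply(kept, function(fr) {
      fd <- det[det$frame == fr & det$conf >= config$conf_threshold, , drop = FALSE]
      as.matrix(normalize_box(fd, spec)[, c("cx", "cy", "w", "h")])
    })
  }
  structure(m, label = label_of(video),
            provenance = list(start_frame = start_frame, end_frame = end_frame,
                              skip = skip_config$skip),
            tuples = tuples, pack_config = config,
            class = c("clip_tensor", "matrix", "array"))
}

#' Build clip tensors for a labeled clip set
#'
#' Maps [build_clip_tensor()] over the `detections` list-column of a clip
#' manifest (as produced by [make_dataset()]), returning the manifest with a
#' `tensor` list-column added. One tensor per clip, first window of each
#' stream.
#'
#' @param clips A tibble with at least `clip_id`, `label` and a
#'   `detections` list-column of [video_detections()].
#' @param config,skip_config,spec,order Passed to [build_clip_tensor()].
#' @return The input tibble with a `tensor` list-column.
#' @export
build_clip_set <- function(clips, config = heuristic_config(),
                           skip_config = flockwatch::skip_config(),
                           spec = NULL, order = c("heuristic", "shuffled")) {
  order <- match.arg(order)
  clips$tensor <- purrr::map(clips$detections, function(v) {
    sp <- spec %||% norm_spec(geometry_of(v))
    build_clip_tensor(v, config = config, skip_config = skip_config,
                      spec = sp, order = order)
  })
  clips
}
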