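#' Frame geometry of a surveillance camera
#'
#' Describes the pixel raster and frame rate of the camera that produced a
#' detection stream. The default matches a 2560 x 1440 dome network camera
#' recording at 25 frames per second, the setup typical of pen surveillance.
#'
#' @param width Image width in pixels (positive integer).
#' @param height Image height in pixels (positive integer).
#' @param fps Frames per second (positive integer).
#'
#' @return A `frame_geometry` object (a named list with `width`, `height`,
#'   `fps`).
#' @examples
#' frame_geometry()
#' frame_geometry(1920, 1080, fps = 30)
#' @export
frame_geometry <- function(width = 2560L, height = 1440L, fps = 25L) {
  width <- as.integer(width)
  height <- as.integer(height)
  fps <- as.integer(fps)
  if (is.na(width) || width <= 0L) rlang::abort("`width` must be a positive integer.")
  if (is.na(height) || height <= 0L) rlang::abort("`height` must be a positive integer.")
  if (is.na(fps) || fps <= 0L) rlang::abort("`fps` must be a positive integer.")
  structure(list(width = width, height = height, fps = fps),
            class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> %d x %d px @ %d fps\n", x$width, x$height, x$fps))
  invisible(x)
}

is_frame_geometry <- function(x) inherits(x, "frame_geometry")

assert_geometry <- function(geometry, call = rlang::caller_env()) {
  if (!is_frame_geometry(geometry)) {
    rlang::abort("`geometry` must be created with `frame_geometry()`.", call = call)
  }
  invisible(geometry)
}
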