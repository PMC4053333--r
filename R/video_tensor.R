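#' Grayscale video tensor
#'
#' A `video_tensor` holds one recording as a 3-D array of grayscale
#' intensities in \[0, 1\], indexed `[y, x, t]` (row, column, frame) as is
#' conventional for raster images in R. It carries the seconds-per-frame
#' period and an opaque recording identifier, and is the object both
#' variation filters operate on.
#'
#' @param intensities numeric 3-D array with dimensions (rows, columns,
#'   frames); all values must lie in \[0, 1\]. A matrix is promoted to a
#'   single-frame tensor.
#' @param frame_period seconds per frame; must be positive.
#' @param source_id opaque recording identifier (a string).
#'
#' @return An object of class `video_tensor`: the intensity array with
#'   attributes `frame_period` and `source_id`.
#'
#' @examples
#' v <- video_tensor(array(0.5, dim = c(4, 4, 3)), frame_period = 0.5)
#' n_frames(v)
#' frame_dim(v)
#' @export
video_tensor <- function(intensities, frame_period = 1, source_id = "") {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("'intensities' must be a 3-D array (rows, columns, frames)")
  }
  if (!is.numeric(intensities)) stop("'intensities' must be numeric")
  if (any(dim(intensities) < 1L)) {
    stop("empty video: every dimension must be at least 1")
  }
  rng <- range(intensities)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    stop("intensity values must lie in [0, 1] and contain no NA")
  }
  if (!is.numeric(frame_period) || length(frame_period) != 1L ||
      frame_period <= 0) {
    stop("'frame_period' must be a single positive number")
  }
  structure(intensities,
            frame_period = as.numeric(frame_period),
            source_id = as.character(source_id),
            class = "video_tensor")
}

#' @rdname video_tensor
#' @param v a `video_tensor`.
#' @export
n_frames <- function(v) dim(v)[3L]

#' @rdname video_tensor
#' @export
frame_dim <- function(v) dim(v)[1:2]

#' @rdname video_tensor
#' @export
frame_period <- function(v) attr(v, "frame_period")

#' @rdname video_tensor
#' @export
source_id <- function(v) attr(v, "source_id")

#' Total represented duration of a video in seconds
#'
#' @param v a `video_tensor`.
#' @return frames times seconds-per-frame.
#' @export
video_duration <- function(v) n_frames(v) * frame_period(v)

#' @export
print.video_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "video_tensor '%s': %d x %d pixels, %d frames (%.3g s/frame, %.3g s)\n",
    source_id(x), d[2L], d[1L], d[3L], frame_period(x), video_duration(x)))
  invisible(x)
}

# Rebuild a tensor around a plain array, inheriting metadata from `template`.
# Internal: callers guarantee values stay in [0,1].
.retensor <- function(a, template, frame_period = NULL) {
  structure(a,
            frame_period = if (is.null(frame_period))
              attr(template, "frame_period") else frame_period,
            source_id = attr(template, "source_id"),
            class = "video_tensor")
}
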