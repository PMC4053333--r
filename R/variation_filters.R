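#' Per-frame variation series
#'
#' Both filters quantify how much the pixel values of a recording change
#' over time; the per-frame result is a non-negative series d(t).
#'
#' `frame_variation_filter1()` measures the deviation of each frame from
#' the time-averaged frame: with \eqn{\bar A(x,y)} the mean over frames
#' of the pixel values \eqn{A(x,y,t)},
#' \deqn{d(t) = \sum_{x,y} (A(x,y,t) - \bar A(x,y))^2,}
#' one value per frame. A subject that lingers anywhere in the clip pulls
#' frames away from the average frame.
#'
#' `frame_variation_filter2()` measures the change between consecutive
#' frames,
#' \deqn{d(t) = \sum_{x,y} (A(x,y,t+1) - A(x,y,t))^2,}
#' giving one fewer value than there are frames. It responds to motion
#' between adjacent frames regardless of where the subject sits relative
#' to the whole-clip average.
#'
#' Sums over pixels are not divided by the pixel count by default; the
#' discard threshold is dataset-relative, so any fixed normalization is
#' absorbed by it (see the `per_pixel` option of [preprocess_config()]).
#'
#' @param v a [video_tensor()]; filter 2 needs at least 2 frames.
#' @return An object of class `frame_variation`: the numeric vector d(t)
#'   with attributes `method` and `source_id`.
#' @seealso [d_statistic()], [compute_d()]
#' @export
frame_variation_filter1 <- function(v) {
  stopifnot(inherits(v, "video_tensor"))
  a <- unclass(v)
  abar <- rowMeans(a, dims = 2L)
  nt <- dim(a)[3L]
  d <- vapply(seq_len(nt),
              function(k) sum((a[, , k] - abar)^2),
              numeric(1))
  structure(d, method = "filter1", source_id = source_id(v),
            class = "frame_variation")
}

#' @rdname frame_variation_filter1
#' @export
frame_variation_filter2 <- function(v) {
  stopifnot(inherits(v, "video_tensor"))
  nt <- n_frames(v)
  if (nt < 2L) {
    stop("degenerate video: frame-to-frame differencing needs >= 2 frames")
  }
  a <- unclass(v)
  d <- vapply(seq_len(nt - 1L),
              function(k) sum((a[, , k + 1L] - a[, , k])^2),
              numeric(1))
  structure(d, method = "filter2", source_id = source_id(v),
            class = "frame_variation")
}

#' Reduce a variation series to the scalar D statistic
#'
#' D summarizes the amount of pixel variation in one recording. The
#' default reduction is the mean of d(t) minus its minimum: the per-video
#' minimum is taken as the environment's baseline variation (rippling
#' water, waving vegetation) and subtracting it makes recordings from
#' restless and quiet backgrounds comparable, while the mean makes D
#' insensitive to clip length. `max_minus_min` and `sum_minus_n_min`
#' (the un-averaged sum with n times the minimum removed) are provided as
#' alternative reductions; all three are zero on a constant series and
#' non-negative by construction.
#'
#' @param d a `frame_variation` series (or a bare non-negative numeric
#'   vector).
#' @param reduction one of `"mean_minus_min"`, `"max_minus_min"`,
#'   `"sum_minus_n_min"`.
#' @return An object of class `d_statistic`: a single non-negative
#'   number with attributes `method` and `source_id`.
#' @export
d_statistic <- function(d, reduction = c("mean_minus_min",
                                         "max_minus_min",
                                         "sum_minus_n_min")) {
  reduction <- match.arg(reduction)
  if (length(d) == 0L) stop("empty variation series")
  x <- as.numeric(d)
  m <- min(x)
  val <- switch(reduction,
                mean_minus_min  = mean(x) - m,
                max_minus_min   = max(x) - m,
                sum_minus_n_min = sum(x) - length(x) * m)
  structure(max(val, 0),
            method = attr(d, "method"),
            source_id = attr(d, "source_id"),
            class = "d_statistic")
}

#' Compute D for one recording
#'
#' Runs the full per-recording pipeline: remove leading frames, mask the
#' timestamp overlay if configured, average-pool in space and time, apply
#' the chosen variation filter, and reduce the series to D.
#'
#' @param v a [video_tensor()].
#' @param method `"filter1"` (deviation from the time-averaged frame) or
#'   `"filter2"` (frame-to-frame differencing).
#' @param cfg a [preprocess_config()].
#' @return A `d_statistic`.
#' @examples
#' v <- generate_scene(scene_config(object_present = TRUE, seed = 1))$video
#' compute_d(v, "filter1")
#' @export
compute_d <- function(v, method = c("filter1", "filter2"),
                      cfg = preprocess_config()) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "preprocess_config"))
  v <- drop_leading_frames(v, cfg$drop_leading_frames)
  if (!is.null(cfg$timestamp_mask)) v <- mask_region(v, cfg$timestamp_mask)
  v <- downsample(v, cfg)
  d <- switch(method,
              filter1 = frame_variation_filter1(v),
              filter2 = frame_variation_filter2(v))
  if (cfg$per_pixel) {
    d <- structure(as.numeric(d) / prod(frame_dim(v)),
                   method = attr(d, "method"),
                   source_id = attr(d, "source_id"),
                   class = "frame_variation")
  }
  d_statistic(d, reduction = cfg$reduction)
}

#' @export
print.d_statistic <- function(x, ...) {
  cat(sprintf("D = %.6g (%s, '%s')\n", as.numeric(x),
              attr(x, "method"), attr(x, "source_id")))
  invisible(x)
}
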