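#' Preprocessing configuration
#'
#' Bundles the preprocessing steps applied to every recording before the
#' variation filters run: removal of leading frames (the camera prints a
#' time stamp on the first frame and the illumination is unstable while it
#' starts up), spatio-temporal average pooling that suppresses sensor
#' noise and small vegetation/water movement, an optional rectangular mask
#' over a burned-in timestamp overlay, and the baseline reduction used to
#' turn the per-frame variation series into the scalar D.
#'
#' @param drop_leading_frames non-negative integer; frames removed from
#'   the start of every clip. Default 2.
#' @param pool_x,pool_y,pool_t positive integer pooling factors along
#'   columns, rows and frames. Defaults 5, 5, 10: with large, slowly
#'   moving study animals the signal survives this reduction while
#'   pixel-level noise is averaged out.
#' @param grayscale_mode how multi-channel frames are collapsed:
#'   `"mean"` (mean of channels, the default) or `"luma"`
#'   (Rec. 601 weights 0.299 R + 0.587 G + 0.114 B).
#' @param timestamp_mask `NULL`, or `c(x0, y0, x1, y1)`: a 0-based,
#'   half-open pixel rectangle replaced by the per-frame spatial mean
#'   before filtering, to null out a continuously printed timestamp.
#' @param reduction reduction of the variation series d(t) to D:
#'   `"mean_minus_min"` (default), `"max_minus_min"` or
#'   `"sum_minus_n_min"`. All three subtract the per-video minimum as the
#'   environment's baseline variation.
#' @param per_pixel logical; divide each d(t) by the pixel count of the
#'   pooled frame so D is comparable across resolutions. Default `FALSE`:
#'   thresholds are dataset-relative, so a fixed normalization is
#'   absorbed by the threshold.
#'
#' @return A list of class `preprocess_config`.
#' @seealso [compute_d()], [read_preprocess_config()]
#' @export
preprocess_config <- function(drop_leading_frames = 2L,
                              pool_x = 5L, pool_y = 5L, pool_t = 10L,
                              grayscale_mode = c("mean", "luma"),
                              timestamp_mask = NULL,
                              reduction = c("mean_minus_min",
                                            "max_minus_min",
                                            "sum_minus_n_min"),
                              per_pixel = FALSE) {
  grayscale_mode <- match.arg(grayscale_mode)
  reduction <- match.arg(reduction)
  stopifnot(drop_leading_frames >= 0,
            pool_x >= 1, pool_y >= 1, pool_t >= 1)
  if (!is.null(timestamp_mask)) {
    if (length(timestamp_mask) != 4L || any(timestamp_mask < 0) ||
        timestamp_mask[3L] <= timestamp_mask[1L] ||
        timestamp_mask[4L] <= timestamp_mask[2L]) {
      stop("'timestamp_mask' must be c(x0, y0, x1, y1), 0-based half-open")
    }
  }
  structure(list(drop_leading_frames = as.integer(drop_leading_frames),
                 pool_x = as.integer(pool_x),
                 pool_y = as.integer(pool_y),
                 pool_t = as.integer(pool_t),
                 grayscale_mode = grayscale_mode,
                 timestamp_mask = timestamp_mask,
                 reduction = reduction,
                 per_pixel = isTRUE(per_pixel)),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from a YAML file
#'
#' Recognized keys are the arguments of [preprocess_config()];
#' `timestamp_mask` is a 4-element sequence `[x0, y0, x1, y1]`. Unknown
#' keys are an error so typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(preprocess_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$timestamp_mask)) {
    raw$timestamp_mask <- as.numeric(unlist(raw$timestamp_mask))
  }
  do.call(preprocess_config, raw)
}

# Collapse a [y, x, channel] raster to one channel.
.collapse_channels <- function(fr, mode) {
  if (length(dim(fr)) == 2L) return(fr)
  nc <- dim(fr)[3L]
  if (nc == 1L) return(fr[, , 1L])
  if (mode == "luma" && nc >= 3L) {
    return(0.299 * fr[, , 1L] + 0.587 * fr[, , 2L] + 0.114 * fr[, , 3L])
  }
  # mean of channels; an alpha channel, if present, is ignored
  use <- if (nc == 4L) 1:3 else seq_len(nc)
  rowMeans(fr[, , use, drop = FALSE], dims = 2L)
}

.read_frame <- function(path, mode) {
  ext <- tolower(tools::file_ext(path))
  fr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format '", ext, "' in ", path))
  .collapse_channels(fr, mode)
}

#' Load a recording as a grayscale video tensor
#'
#' Accepts either a directory of still frames (PNG/TIFF; lexicographic
#' file order is temporal order) or a single multi-page TIFF. Intensities
#' are rescaled to \[0, 1\] by the image reader; multi-channel frames are
#' collapsed to one channel. Video containers such as AVI are handled by
#' exporting their frames to one of these sequence formats first (e.g.
#' `ffmpeg -i clip.avi frames/%06d.png`); no in-process container decoder
#' is bundled.
#'
#' @param path a frame-sequence directory or a multi-page TIFF file.
#' @param grayscale_mode `"mean"` (mean of channels) or `"luma"`.
#' @param frame_period seconds per frame. Supplied by the caller because
#'   still-frame sequences carry no timing metadata; no downstream
#'   operation assumes a particular frame rate.
#' @param source_id recording identifier; defaults to the file or
#'   directory base name.
#'
#' @return A [video_tensor()].
#' @export
load_video <- function(path, grayscale_mode = c("mean", "luma"),
                       frame_period = 1,
                       source_id = basename(path)) {
  grayscale_mode <- match.arg(grayscale_mode)
  if (!file.exists(path)) stop("cannot read video input: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) {
      stop("empty video: no frame images found in ", path)
    }
    frames <- lapply(files, .read_frame, mode = grayscale_mode)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff")) {
      stop("decode error: ", path,
           " is not a frame directory or multi-page TIFF")
    }
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) {
                        stop("decode error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("empty video: no frames in ", path)
    frames <- lapply(pages, .collapse_channels, mode = grayscale_mode)
  }
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("decode error: frames in ", path, " have inconsistent dimensions")
  }
  a <- array(unlist(frames, use.names = FALSE),
             dim = c(d[1L], d[2L], length(frames)))
  a[a < 0] <- 0
  a[a > 1] <- 1
  video_tensor(a, frame_period = frame_period, source_id = source_id)
}

#' Remove leading frames from a recording
#'
#' Trail cameras print a time stamp on the first frame and the lighting is
#' unstable while the camera starts, so the first frames are removed
#' before any variation is measured.
#'
#' @param v a [video_tensor()].
#' @param n non-negative number of leading frames to drop; must be
#'   smaller than the number of frames.
#' @return The tensor with frames `n+1, ...` retained; all other fields
#'   unchanged.
#' @export
drop_leading_frames <- function(v, n) {
  stopifnot(inherits(v, "video_tensor"), n >= 0)
  n <- as.integer(n)
  if (n >= n_frames(v)) {
    stop("degenerate video: cannot drop ", n, " of ", n_frames(v),
         " frames")
  }
  if (n == 0L) return(v)
  .retensor(unclass(v)[, , (n + 1L):n_frames(v), drop = FALSE], v)
}

#' Mask a rectangular region of every frame
#'
#' Replaces the pixels inside a 0-based, half-open rectangle
#' `(x0, y0)--(x1, y1)` with the spatial mean of the rest of that frame,
#' so a burned-in timestamp overlay contributes no spurious frame-to-frame
#' variation.
#'
#' @param v a [video_tensor()].
#' @param mask `c(x0, y0, x1, y1)` in pixel coordinates.
#' @return The masked tensor.
#' @export
mask_region <- function(v, mask) {
  stopifnot(inherits(v, "video_tensor"), length(mask) == 4L)
  d <- dim(v)
  cols <- (floor(mask[1L]) + 1L):min(ceiling(mask[3L]), d[2L])
  rows <- (floor(mask[2L]) + 1L):min(ceiling(mask[4L]), d[1L])
  a <- unclass(v)
  for (k in seq_len(d[3L])) {
    fr <- a[, , k]
    inside <- matrix(FALSE, d[1L], d[2L])
    inside[rows, cols] <- TRUE
    fr[inside] <- mean(fr[!inside])
    a[, , k] <- fr
  }
  .retensor(a, v)
}

# Average-pool one axis of a 3-D array by factor f; a trailing partial
# block is averaged over its actual size.
.pool_dim <- function(a, along, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  perm <- c(setdiff(1:3, along), along)
  ap <- aperm(a, perm)
  n <- d[along]
  ng <- as.integer(ceiling(n / f))
  out <- array(0, dim = c(d[perm[1L]], d[perm[2L]], ng))
  for (g in seq_len(ng)) {
    idx <- ((g - 1L) * f + 1L):min(g * f, n)
    out[, , g] <- rowMeans(ap[, , idx, drop = FALSE], dims = 2L)
  }
  aperm(out, order(perm))
}

#' Spatio-temporal average pooling
#'
#' Downsamples a recording by averaging non-overlapping blocks of
#' `pool_x` columns, `pool_y` rows and `pool_t` frames. Averaging (rather
#' than decimation) suppresses sensor noise, small vegetation movement
#' and water reflections while preserving the displacement signal of a
#' large, slow subject. Output extents are `ceiling(extent / factor)`;
#' a trailing partial block is averaged over its actual size so
#' end-of-clip motion is not discarded. The frame period is multiplied by
#' `pool_t`.
#'
#' @param v a [video_tensor()].
#' @param cfg a [preprocess_config()] supplying the pooling factors.
#' @return The pooled [video_tensor()].
#' @export
downsample <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "video_tensor"), inherits(cfg, "preprocess_config"))
  a <- unclass(v)
  a <- .pool_dim(a, 2L, cfg$pool_x)   # columns (x)
  a <- .pool_dim(a, 1L, cfg$pool_y)   # rows (y)
  a <- .pool_dim(a, 3L, cfg$pool_t)   # frames (t)
  .retensor(a, v, frame_period = frame_period(v) * cfg$pool_t)
}
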