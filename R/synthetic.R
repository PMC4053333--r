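#' Synthetic scene configuration
#'
#' Describes a generated night-vision clip: a mid-gray background with
#' per-pixel Gaussian sensor noise, optionally a water-like region whose
#' intensity ripples sinusoidally and drifts over time ("wet"
#' background), and optionally a large rectangular subject that
#' translates slowly across the frame — the geometry is deliberately
#' abstract because the variation filters are shape-agnostic.
#'
#' The defaults emulate a trail-camera clip at desk scale: a 96 x 64
#' frame, 60 frames spanning 15 s (0.25 s per frame), sensor noise of
#' 0.02 intensity units per pixel per frame, and a subject spanning 30\%
#' of the frame width moving at 1.5 pixels per frame — large and slow,
#' as a beaver-sized mammal filmed from a few meters appears after the
#' camera's own downscaling.
#'
#' @param width,height,n_frames frame size in pixels and clip length in
#'   frames.
#' @param frame_period seconds per frame (default 0.25, so 60 frames
#'   represent a 15 s clip).
#' @param background `"dry"` or `"wet"`.
#' @param background_noise_sd standard deviation of the per-pixel,
#'   per-frame Gaussian sensor noise (intensity units).
#' @param wet_ripple_amplitude amplitude of the drifting sinusoidal
#'   ripple field; forced to 0 for dry backgrounds.
#' @param wet_region_fraction fraction of the frame height (from the
#'   bottom) covered by water.
#' @param object_present logical; add the moving subject?
#' @param object_size_fraction subject width as a fraction of frame
#'   width, in (0, 1]; a clip is labeled `"target"` only when a subject
#'   of fraction >= 0.15 is present (smaller objects play the role of
#'   non-target species).
#' @param object_speed horizontal speed in pixels per frame.
#' @param object_contrast intensity offset of the subject above the
#'   background, in (0, 1].
#' @param seed integer seed; generation is deterministic given the
#'   config.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 96L, height = 64L, n_frames = 60L,
                         frame_period = 0.25,
                         background = c("dry", "wet"),
                         background_noise_sd = 0.02,
                         wet_ripple_amplitude = 0.05,
                         wet_region_fraction = 0.4,
                         object_present = FALSE,
                         object_size_fraction = 0.3,
                         object_speed = 1.5,
                         object_contrast = 0.4,
                         seed = 1L) {
  background <- match.arg(background)
  stopifnot(width >= 1, height >= 1, n_frames >= 1,
            background_noise_sd >= 0, wet_ripple_amplitude >= 0,
            wet_region_fraction >= 0, wet_region_fraction <= 1,
            object_size_fraction > 0, object_size_fraction <= 1,
            object_contrast > 0, object_contrast <= 1)
  if (background == "dry") wet_ripple_amplitude <- 0
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 frame_period = frame_period,
                 background = background,
                 background_noise_sd = background_noise_sd,
                 wet_ripple_amplitude = wet_ripple_amplitude,
                 wet_region_fraction = wet_region_fraction,
                 object_present = isTRUE(object_present),
                 object_size_fraction = object_size_fraction,
                 object_speed = object_speed,
                 object_contrast = object_contrast,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic labeled scene
#'
#' Renders the clip described by a [scene_config()]: background 0.5 plus
#' Gaussian noise; for wet backgrounds, a sinusoidal ripple field over
#' the lower `wet_region_fraction` of the frame whose phase drifts with
#' time (adding genuine frame-to-frame variance, not just static
#' texture); if requested, a rectangle of the configured size and
#' contrast entering from the left and translating rightward at constant
#' speed, wrapping around the frame. All intensities are clipped to
#' \[0, 1\].
#'
#' The same seed always produces the same clip, and configs that differ
#' only in `object_present` share the identical noise and ripple
#' realization, enabling exactly paired with/without-subject
#' comparisons.
#'
#' @param cfg a [scene_config()].
#' @return A list with elements `video` (a [video_tensor()]) and `label`
#'   (`"target"` if a subject with `object_size_fraction >= 0.15` is
#'   present, else `"non-target"`).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  h <- cfg$height; w <- cfg$width; nt <- cfg$n_frames
  a <- array(stats::rnorm(h * w * nt, mean = 0.5,
                          sd = cfg$background_noise_sd),
             dim = c(h, w, nt))

  if (cfg$background == "wet" && cfg$wet_ripple_amplitude > 0 &&
      cfg$wet_region_fraction > 0) {
    wet_rows <- (h - floor(h * cfg$wet_region_fraction) + 1L):h
    wavelength <- max(w / 8, 2)
    xs <- seq_len(w)
    for (k in seq_len(nt)) {
      ripple <- cfg$wet_ripple_amplitude *
        sin(2 * pi * (xs / wavelength + k / 7))
      a[wet_rows, , k] <- a[wet_rows, , k] +
        matrix(ripple, length(wet_rows), w, byrow = TRUE)
    }
  }

  if (cfg$object_present) {
    ow <- max(1L, round(cfg$object_size_fraction * w))
    oh <- max(1L, round(ow / 2))
    top <- max(1L, floor((h - oh) / 2))
    rows <- top:(top + oh - 1L)
    for (k in seq_len(nt)) {
      x0 <- 1 + (k - 1) * cfg$object_speed
      cols <- (round(x0) + seq_len(ow) - 1L - 1L) %% w + 1L
      a[rows, cols, k] <- a[rows, cols, k] + cfg$object_contrast
    }
  }

  a[a < 0] <- 0
  a[a > 1] <- 1
  label <- if (cfg$object_present && cfg$object_size_fraction >= 0.15) {
    "target"
  } else {
    "non-target"
  }
  list(video = video_tensor(a, frame_period = cfg$frame_period,
                            source_id = sprintf("scene-%d", cfg$seed)),
       label = label)
}

#' Synthetic D-population configuration
#'
#' Describes a surrogate population of per-recording D values: both
#' classes are drawn from log-normal distributions — D is non-negative
#' and right-skewed, being a baseline-corrected mean of squared sums —
#' with targets centered above non-targets. The defaults mirror a
#' season-scale field campaign: 1043 target and 948 non-target
#' recordings of 15 s each.
#'
#' Condition presets encode the ordering the field situation imposes
#' rather than any measured distribution: wet locations (rippling water)
#' have noisier backgrounds, so their non-target D distribution sits
#' higher and overlaps the target distribution more than at dry
#' locations, making discrimination harder. Dry preset:
#' non-target meanlog -0.6, sdlog 0.6; wet preset: non-target meanlog
#' 0.2, sdlog 0.8; targets meanlog 1.0, sdlog 0.6 in both.
#'
#' @param n_target,n_nontarget class sizes.
#' @param condition `"dry"` or `"wet"`; chooses the preset for any
#'   log-scale parameter not supplied explicitly.
#' @param target_log_mean,target_log_sd,nontarget_log_mean,nontarget_log_sd
#'   log-scale location and scale of the two classes; `NULL` means use
#'   the condition preset.
#' @param duration_s clip duration attached to every recording.
#' @param seed integer seed.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_target = 1043L, n_nontarget = 948L,
                              condition = c("dry", "wet"),
                              target_log_mean = NULL,
                              target_log_sd = NULL,
                              nontarget_log_mean = NULL,
                              nontarget_log_sd = NULL,
                              duration_s = 15,
                              seed = 1L) {
  condition <- match.arg(condition)
  preset <- if (condition == "dry") {
    list(target_log_mean = 1.0, target_log_sd = 0.6,
         nontarget_log_mean = -0.6, nontarget_log_sd = 0.6)
  } else {
    list(target_log_mean = 1.0, target_log_sd = 0.6,
         nontarget_log_mean = 0.2, nontarget_log_sd = 0.8)
  }
  pick <- function(x, nm) if (is.null(x)) preset[[nm]] else as.numeric(x)
  stopifnot(n_target >= 0, n_nontarget >= 0, duration_s > 0)
  structure(list(n_target = as.integer(n_target),
                 n_nontarget = as.integer(n_nontarget),
                 condition = condition,
                 target_log_mean = pick(target_log_mean, "target_log_mean"),
                 target_log_sd = pick(target_log_sd, "target_log_sd"),
                 nontarget_log_mean = pick(nontarget_log_mean,
                                           "nontarget_log_mean"),
                 nontarget_log_sd = pick(nontarget_log_sd,
                                         "nontarget_log_sd"),
                 duration_s = as.numeric(duration_s),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a synthetic labeled D population
#'
#' Draws D values for both classes from the log-normal populations of a
#' [population_config()] and assembles a [labeled_recordings()] table
#' (the single drawn score is used for both filter columns; the
#' surrogate models the score distribution, not the filters'
#' correlation structure). Deterministic given the config.
#'
#' @param cfg a [population_config()].
#' @return A [labeled_recordings()] table with `n_target + n_nontarget`
#'   rows.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  if (cfg$n_target + cfg$n_nontarget < 2L ||
      cfg$n_target == 0L || cfg$n_nontarget == 0L) {
    stop("population needs both classes non-empty")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  d_t <- stats::rlnorm(cfg$n_target, cfg$target_log_mean, cfg$target_log_sd)
  d_n <- stats::rlnorm(cfg$n_nontarget, cfg$nontarget_log_mean,
                       cfg$nontarget_log_sd)
  n <- cfg$n_target + cfg$n_nontarget
  d <- c(d_t, d_n)
  labeled_recordings(
    source_id = sprintf("rec-%05d", seq_len(n)),
    label = rep(c("target", "non-target"), c(cfg$n_target, cfg$n_nontarget)),
    d_filter1 = d,
    d_filter2 = d,
    condition = cfg$condition,
    duration_s = cfg$duration_s)
}
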