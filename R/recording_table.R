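#' Recording metadata table I/O
#'
#' The per-recording metadata travels as a UTF-8 CSV with a header row
#' and the stable columns `filename`, `datetime` (ISO-8601), `location`,
#' `camera`, `condition`, `label`, `duration_s`, `d_filter1`,
#' `d_filter2`. `label` and `condition` may be empty on input (they are
#' read as `NA` / `"unknown"`); D columns are written with full double
#' precision so a round-trip is loss-free.
#'
#' @param path CSV file path.
#' @return `read_recording_table()` returns a `data.frame` with the
#'   columns above; `write_recording_table()` returns `path`,
#'   invisibly.
#' @export
read_recording_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  required <- c("filename")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("recording table lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (cl in c("datetime", "location", "camera", "condition", "label",
               "duration_s", "d_filter1", "d_filter2")) {
    if (!cl %in% names(df)) df[[cl]] <- NA_character_
  }
  for (cl in c("duration_s", "d_filter1", "d_filter2")) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df$condition[is.na(df$condition) | df$condition == ""] <- "unknown"
  df$label[df$label == ""] <- NA_character_
  df$duration_s[is.na(df$duration_s)] <- 15
  if (anyDuplicated(df$filename)) {
    stop("recording table has duplicate filenames")
  }
  bad <- c(df$d_filter1, df$d_filter2)
  if (any(bad < 0, na.rm = TRUE)) stop("D values must be non-negative")
  df
}

#' @rdname read_recording_table
#' @param table a recording table (see above).
#' @export
write_recording_table <- function(table, path) {
  out <- table
  for (cl in intersect(c("duration_s", "d_filter1", "d_filter2"),
                       names(out))) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Convert a recording table to a labeled-recordings table
#'
#' Keeps the rows whose manual label is present and reshapes them into
#' the [labeled_recordings()] layout used by [roc_curve()],
#' [threshold_for_fp()] and [bootstrap_fp_rate()].
#'
#' @param df a recording table from [read_recording_table()] or
#'   [compute_d_table()].
#' @return A [labeled_recordings()] table.
#' @export
table_to_recordings <- function(df) {
  keep <- !is.na(df$label)
  if (!any(keep)) stop("no labeled rows in recording table")
  labeled_recordings(source_id = df$filename[keep],
                     label = df$label[keep],
                     d_filter1 = df$d_filter1[keep],
                     d_filter2 = df$d_filter2[keep],
                     condition = df$condition[keep],
                     duration_s = df$duration_s[keep])
}

#' Compute D for a batch of recordings
#'
#' Runs [compute_d()] with both filter methods over a set of video
#' inputs (frame directories or multi-page TIFFs; see [load_video()])
#' and returns a recording table with the two D columns populated. A
#' recording that fails to decode does not abort the batch: its D
#' columns stay `NA`, the error message is kept, and the failure count
#' is reported, so one corrupt file never costs a night's processing
#' run.
#'
#' @param inputs character vector of video paths, or a single directory
#'   whose immediate subdirectories/TIFF files are the recordings.
#' @param cfg a [preprocess_config()].
#' @param frame_period seconds per frame passed to [load_video()].
#' @return A recording table (see [read_recording_table()]) with
#'   attributes `n_failed` and `failures` (named character vector of
#'   error messages).
#' @export
compute_d_table <- function(inputs, cfg = preprocess_config(),
                            frame_period = 1) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    subs <- list.dirs(inputs, recursive = FALSE)
    tifs <- list.files(inputs, pattern = "\\.(tif|tiff)$",
                       ignore.case = TRUE, full.names = TRUE)
    inputs <- sort(c(subs, tifs))
  }
  if (length(inputs) == 0L) stop("no video inputs found")
  n <- length(inputs)
  d1 <- d2 <- dur <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      v <- load_video(inputs[i], grayscale_mode = cfg$grayscale_mode,
                      frame_period = frame_period)
      c(as.numeric(compute_d(v, "filter1", cfg)),
        as.numeric(compute_d(v, "filter2", cfg)),
        video_duration(v))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[basename(inputs[i])] <- res
    } else {
      d1[i] <- res[1L]
      d2[i] <- res[2L]
      dur[i] <- res[3L]
    }
  }
  df <- data.frame(filename = basename(inputs),
                   datetime = NA_character_,
                   location = NA_character_,
                   camera = NA_character_,
                   condition = "unknown",
                   label = NA_character_,
                   duration_s = dur,
                   d_filter1 = d1,
                   d_filter2 = d2,
                   stringsAsFactors = FALSE)
  structure(df, n_failed = length(failures), failures = failures)
}
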