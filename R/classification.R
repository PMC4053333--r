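#' Labeled recordings table
#'
#' The unit of classification, ROC analysis and bootstrapping is a plain
#' data frame with one row per recording and columns:
#' \describe{
#'   \item{source_id}{unique recording identifier}
#'   \item{label}{`"target"` or `"non-target"` (manual annotation)}
#'   \item{condition}{`"dry"`, `"wet"` or `"unknown"`; camera locations
#'     with more than 10\% visible water surface are `"wet"`}
#'   \item{duration_s}{clip duration in seconds (default 15)}
#'   \item{d_filter1, d_filter2}{the D statistic per filter method
#'     (`NA` when not yet computed)}
#' }
#' `labeled_recordings()` builds and validates such a table.
#'
#' @param source_id character vector of unique identifiers.
#' @param label `"target"`/`"non-target"` per recording.
#' @param d_filter1,d_filter2 non-negative D values (either may be `NA`).
#' @param condition `"dry"`, `"wet"` or `"unknown"`, recycled.
#' @param duration_s clip durations in seconds, recycled.
#' @return A `data.frame` as described.
#' @export
labeled_recordings <- function(source_id, label,
                               d_filter1 = NA_real_,
                               d_filter2 = NA_real_,
                               condition = "unknown",
                               duration_s = 15) {
  n <- length(source_id)
  if (anyDuplicated(source_id)) stop("'source_id' must be unique")
  if (!all(label %in% c("target", "non-target"))) {
    stop("'label' must be 'target' or 'non-target'")
  }
  df <- data.frame(source_id = as.character(source_id),
                   label = rep_len(label, n),
                   condition = rep_len(condition, n),
                   duration_s = rep_len(as.numeric(duration_s), n),
                   d_filter1 = rep_len(as.numeric(d_filter1), n),
                   d_filter2 = rep_len(as.numeric(d_filter2), n),
                   stringsAsFactors = FALSE)
  if (!all(df$condition %in% c("dry", "wet", "unknown"))) {
    stop("'condition' must be dry, wet or unknown")
  }
  if (any(df$duration_s <= 0)) stop("'duration_s' must be positive")
  for (cl in c("d_filter1", "d_filter2")) {
    if (any(df[[cl]] < 0, na.rm = TRUE)) stop("D values must be >= 0")
  }
  df
}

# Extract the D column for a method, failing loudly on missing values.
.d_column <- function(recordings, method) {
  method <- match.arg(method, c("filter1", "filter2"))
  col <- paste0("d_", method)
  if (!col %in% names(recordings)) {
    stop("recordings table has no column '", col, "'")
  }
  d <- recordings[[col]]
  if (anyNA(d)) {
    bad <- recordings$source_id[is.na(d)]
    stop("missing D (", method, ") for recording(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  }
  d
}

#' Threshold decision for one D value
#'
#' A recording is flagged as a discardable non-target recording when its
#' D value lies strictly below the threshold; ties are kept for visual
#' inspection (the asymmetric cost is losing target footage, so the tie
#' goes to the safe side).
#'
#' @param d a D value (or `d_statistic`), vectorized.
#' @param threshold the discard threshold.
#' @return `"discard"` or `"keep"` per value.
#' @export
classify <- function(d, threshold) {
  ifelse(as.numeric(d) < threshold, "discard", "keep")
}

#' Confusion matrix of the discard decision
#'
#' The positive class is the *non-target* recording: correctly discarding
#' an empty clip is the success being counted. At threshold \eqn{\theta}:
#' TP = non-target with D < \eqn{\theta}, FP = target with D <
#' \eqn{\theta} (valuable footage wrongly discarded), FN = non-target
#' kept, TN = target kept.
#'
#' @param recordings a [labeled_recordings()] table.
#' @param threshold discard threshold.
#' @param method `"filter1"` or `"filter2"`.
#' @return A list of class `classification_matrix` with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(recordings, threshold,
                      method = c("filter1", "filter2")) {
  method <- match.arg(method)
  d <- .d_column(recordings, method)
  nontarget <- recordings$label == "non-target"
  below <- d < threshold
  structure(list(tp = sum(nontarget & below),
                 fp = sum(!nontarget & below),
                 fn = sum(nontarget & !below),
                 tn = sum(!nontarget & !below)),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2L, 2L, byrow = TRUE,
              dimnames = list(classified = c("non-target", "target"),
                              reality = c("non-target", "target")))
  print(m)
  invisible(x)
}

#' True- and false-positive rates of a confusion matrix
#'
#' TP-rate = TP / (TP + FN), the fraction of non-target recordings
#' correctly discarded (the workload saved); FP-rate = FP / (FP + TN),
#' the fraction of target recordings wrongly discarded (the footage
#' lost). Both classes must be present.
#'
#' @param m a `classification_matrix` from [confusion()].
#' @return Named numeric vector `c(tp_rate, fp_rate)`.
#' @export
rates <- function(m) {
  stopifnot(inherits(m, "classification_matrix"))
  if (m$tp + m$fn == 0L) stop("undefined rate: no non-target recordings")
  if (m$fp + m$tn == 0L) stop("undefined rate: no target recordings")
  c(tp_rate = m$tp / (m$tp + m$fn),
    fp_rate = m$fp / (m$fp + m$tn))
}

# Candidate thresholds: midpoints between consecutive distinct sorted D
# values, with -Inf/+Inf sentinels. Achieved rates are invariant to
# infinitesimal perturbation of any of these thresholds.
.candidate_thresholds <- function(d) {
  u <- sort(unique(d))
  if (length(u) > 1L) {
    mids <- (u[-length(u)] + u[-1L]) / 2
  } else {
    mids <- numeric(0)
  }
  c(-Inf, mids, Inf)
}

#' ROC curve of the discard classifier
#'
#' Sweeps the discard threshold over the full range of D values and
#' records the (FP-rate, TP-rate) pair at each candidate threshold.
#' Candidates are the midpoints between consecutive distinct D values
#' plus a sentinel below the minimum (rates (0, 0)) and above the maximum
#' (rates (1, 1)), so every achievable operating point appears exactly
#' once and both rates are non-decreasing in the threshold.
#'
#' @param recordings a [labeled_recordings()] table containing both
#'   classes.
#' @param method `"filter1"` or `"filter2"`.
#' @param condition optionally restrict to `"dry"` or `"wet"` recordings
#'   before sweeping; `"all"` (default) uses every row.
#' @return A `data.frame` of class `roc_curve` with columns `threshold`,
#'   `fp_rate`, `tp_rate`, ordered by increasing threshold, and
#'   attributes `method` and `condition`.
#' @export
roc_curve <- function(recordings, method = c("filter1", "filter2"),
                      condition = c("all", "dry", "wet")) {
  method <- match.arg(method)
  condition <- match.arg(condition)
  if (condition != "all") {
    recordings <- recordings[recordings$condition == condition, ,
                             drop = FALSE]
  }
  d <- .d_column(recordings, method)
  nontarget <- recordings$label == "non-target"
  n_pos <- sum(nontarget)
  n_neg <- sum(!nontarget)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both target and non-target recordings")
  }
  th <- .candidate_thresholds(d)
  tp <- vapply(th, function(x) sum(nontarget & d < x), numeric(1))
  fp <- vapply(th, function(x) sum(!nontarget & d < x), numeric(1))
  out <- data.frame(threshold = th,
                    fp_rate = fp / n_neg,
                    tp_rate = tp / n_pos)
  structure(out, method = method, condition = condition,
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under TP-rate as a function of FP-rate; 0.5 for a
#' classifier no better than chance, 1 for perfect separation.
#'
#' @param roc a [roc_curve()].
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  x <- roc$fp_rate
  y <- roc$tp_rate
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Plot a ROC curve
#'
#' @param x a [roc_curve()].
#' @param fp_mark vertical reference line at a tolerated FP-rate
#'   (`NULL` for none).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, fp_mark = 0.05, ...) {
  graphics::plot(x$fp_rate, x$tp_rate, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "FP-rate (target recordings lost)",
                 ylab = "TP-rate (non-target recordings discarded)",
                 main = sprintf("ROC, %s (%s), AUC = %.3f",
                                attr(x, "method"), attr(x, "condition"),
                                roc_auc(x)), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  if (!is.null(fp_mark)) graphics::abline(v = fp_mark, lty = 3)
  invisible(x)
}

#' Screening-time savings of a discard decision
#'
#' Every discarded recording — correctly (TP) or wrongly (FP) — no longer
#' has to be watched, so the time saved is the summed duration of all
#' discarded recordings.
#'
#' @param m a `classification_matrix` from [confusion()].
#' @param duration_s duration of one recording in seconds.
#' @return Minutes of viewing time saved.
#' @export
time_savings <- function(m, duration_s = 15) {
  stopifnot(inherits(m, "classification_matrix"), duration_s > 0)
  (m$tp + m$fp) * duration_s / 60
}

#' Operating point at a tolerated FP-rate
#'
#' Chooses the largest candidate threshold whose achieved FP-rate does
#' not exceed the tolerance: discarding is maximized subject to losing no
#' more target footage than tolerated. The sentinel threshold below all D
#' values (rates (0, 0)) always qualifies, so an operating point always
#' exists.
#'
#' @param recordings a [labeled_recordings()] table with both classes.
#' @param method `"filter1"` or `"filter2"`.
#' @param tolerated_fp maximal acceptable fraction of target recordings
#'   lost, in (0, 1); studies of frequently recorded species typically
#'   tolerate 0.05 to 0.20.
#' @param condition restrict to `"dry"` or `"wet"` recordings, or
#'   `"all"`.
#' @return A list of class `operating_point`: `threshold`,
#'   `achieved_fp_rate`, `achieved_tp_rate`, `discarded_count`,
#'   `time_savings_min` (summed duration of discarded recordings),
#'   `method`, `tolerated_fp`.
#' @export
threshold_for_fp <- function(recordings, method = c("filter1", "filter2"),
                             tolerated_fp = 0.05,
                             condition = c("all", "dry", "wet")) {
  method <- match.arg(method)
  condition <- match.arg(condition)
  stopifnot(tolerated_fp > 0, tolerated_fp < 1)
  if (condition != "all") {
    recordings <- recordings[recordings$condition == condition, ,
                             drop = FALSE]
  }
  roc <- roc_curve(recordings, method)
  ok <- roc$fp_rate <= tolerated_fp
  th <- roc$threshold[max(which(ok))]
  d <- .d_column(recordings, method)
  m <- confusion(recordings, th, method)
  r <- rates(m)
  discarded <- d < th
  structure(list(threshold = th,
                 achieved_fp_rate = unname(r["fp_rate"]),
                 achieved_tp_rate = unname(r["tp_rate"]),
                 discarded_count = sum(discarded),
                 time_savings_min = sum(recordings$duration_s[discarded]) / 60,
                 method = method,
                 tolerated_fp = tolerated_fp),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    paste0("Operating point (%s, FP tolerance %.3g):\n",
           "  threshold          %.6g\n",
           "  achieved FP-rate   %.4f\n",
           "  achieved TP-rate   %.4f\n",
           "  discarded          %d recordings\n",
           "  time savings       %.0f min\n"),
    x$method, x$tolerated_fp, x$threshold, x$achieved_fp_rate,
    x$achieved_tp_rate, x$discarded_count, round(x$time_savings_min)))
  invisible(x)
}
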