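#' Bootstrap stability of the FP-rate at a fixed threshold
#'
#' A discard threshold is chosen once, on the full labeled dataset; in
#' future field seasons the camera will sample new recordings from a
#' similar population. To quantify how much the realized loss of target
#' footage can drift under that sampling variation, subsamples are drawn
#' from the dataset with replacement, each is classified at the fixed
#' threshold, and the FP-rate (fraction of target recordings falling
#' below the threshold) is recorded per replicate.
#'
#' Replicates that happen to contain no target recording leave the
#' FP-rate undefined; they are skipped and counted (at realistic dataset
#' sizes the probability is negligible). The summary reports the mean,
#' sample standard deviation (n - 1 denominator) and the empirical 2.5
#' and 97.5 percentiles (type-7 linear interpolation) over the used
#' replicates.
#'
#' @param recordings a [labeled_recordings()] table containing at least
#'   one target recording.
#' @param threshold the fixed discard threshold, e.g. the threshold of a
#'   [threshold_for_fp()] operating point on the full dataset.
#' @param method `"filter1"` or `"filter2"`.
#' @param subsample_size recordings drawn per replicate (default 500).
#' @param reps number of replicates (default 1000).
#' @param seed integer seed; the run is fully reproducible from it.
#' @return A list of class `bootstrap_summary`: `mean`, `sd`, `p2_5`,
#'   `p97_5`, `fp_rates` (the per-replicate values), `n_reps_used`,
#'   `n_reps_skipped`, `subsample_size`, `seed`.
#' @examples
#' pop <- generate_population(population_config(seed = 1))
#' op <- threshold_for_fp(pop, "filter1", 0.05)
#' bootstrap_fp_rate(pop, op$threshold, "filter1", seed = 2)
#' @export
bootstrap_fp_rate <- function(recordings, threshold,
                              method = c("filter1", "filter2"),
                              subsample_size = 500L, reps = 1000L,
                              seed) {
  method <- match.arg(method)
  stopifnot(subsample_size >= 1, reps >= 1)
  d <- .d_column(recordings, method)
  is_target <- recordings$label == "target"
  if (!any(is_target)) stop("bootstrap needs at least one target recording")
  target_below <- is_target & d < threshold

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n <- nrow(recordings)
  fp_rates <- numeric(reps)
  skipped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(n, subsample_size, replace = TRUE)
    nt <- sum(is_target[idx])
    if (nt == 0L) {
      skipped <- skipped + 1L
      fp_rates[r] <- NA_real_
    } else {
      fp_rates[r] <- sum(target_below[idx]) / nt
    }
  }
  used <- fp_rates[!is.na(fp_rates)]
  if (length(used) == 0L) stop("all bootstrap replicates lacked targets")
  q <- stats::quantile(used, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(mean = mean(used),
                 sd = stats::sd(used),
                 p2_5 = q[1L],
                 p97_5 = q[2L],
                 fp_rates = used,
                 n_reps_used = length(used),
                 n_reps_skipped = skipped,
                 subsample_size = as.integer(subsample_size),
                 seed = as.integer(seed)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Bootstrap of the FP-rate (%d reps of %d, %d skipped, ",
           "seed %d):\n  mean %.3f  sd %.3f  [2.5%%, 97.5%%] = ",
           "[%.3f, %.3f]\n"),
    x$n_reps_used + x$n_reps_skipped, x$subsample_size,
    x$n_reps_skipped, x$seed, x$mean, x$sd, x$p2_5, x$p97_5))
  invisible(x)
}
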