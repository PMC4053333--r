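make_recs <- function(d_nontarget, d_target, condition = "unknown") {
  n1 <- length(d_nontarget); n2 <- length(d_target)
  labeled_recordings(
    source_id = sprintf("r%03d", seq_len(n1 + n2)),
    label = rep(c("non-target", "target"), c(n1, n2)),
    d_filter1 = c(d_nontarget, d_target),
    d_filter2 = c(d_nontarget, d_target),
    condition = condition)
}

test_that("classify discards strictly below the threshold, ties kept", {
  expect_equal(classify(0.5, 1.0), "discard")
  expect_equal(classify(1.0, 1.0), "keep")
  expect_equal(classify(0, 0), "keep")
})

test_that("confusion counts follow the non-target-positive orientation", {
  recs <- make_recs(d_nontarget = c(0.1, 0.9), d_target = c(0.8, 2.0))
  m <- confusion(recs, 0.85, "filter1")
  expect_equal(m$tp, 1); expect_equal(m$fn, 1)
  expect_equal(m$fp, 1); expect_equal(m$tn, 1)

  m0 <- confusion(recs, 0, "filter1")
  expect_equal(m0$tp + m0$fp, 0)
  expect_equal(m0$fn, 2); expect_equal(m0$tn, 2)

  minf <- confusion(recs, Inf, "filter1")
  expect_equal(minf$fn + minf$tn, 0)

  # marginals conserved across thresholds
  for (th in c(-1, 0.5, 0.85, 3)) {
    mm <- confusion(recs, th, "filter1")
    expect_equal(mm$tp + mm$fn, 2)
    expect_equal(mm$fp + mm$tn, 2)
  }
})

test_that("confusion refuses missing D values, naming the recording", {
  recs <- make_recs(c(0.1), c(0.8))
  recs$d_filter2[1] <- NA
  expect_error(confusion(recs, 0.5, "filter2"), "r001")
})

test_that("rates compute TP/(TP+FN) and FP/(FP+TN) and reject empty classes", {
  m <- structure(list(tp = 1, fn = 1, fp = 1, tn = 2),
                 class = "classification_matrix")
  r <- rates(m)
  expect_equal(unname(r["tp_rate"]), 0.5)
  expect_equal(unname(r["fp_rate"]), 1 / 3)
  perfect <- structure(list(tp = 5, fn = 0, fp = 0, tn = 7),
                       class = "classification_matrix")
  expect_equal(unname(rates(perfect)), c(1, 0))
  empty <- structure(list(tp = 0, fn = 0, fp = 1, tn = 1),
                     class = "classification_matrix")
  expect_error(rates(empty), "no non-target")
})

test_that("roc_curve hits hand-enumerated points and the sentinels", {
  recs <- make_recs(d_nontarget = c(0.5, 1.5), d_target = c(1, 2, 3))
  roc <- roc_curve(recs, "filter1")
  # theta = 1.25 midpoint: one non-target (0.5) and one target (1) below
  i <- which.min(abs(roc$threshold - 1.25))
  expect_equal(roc$tp_rate[i], 0.5)
  expect_equal(roc$fp_rate[i], 1 / 3)
  expect_equal(roc$fp_rate[1], 0); expect_equal(roc$tp_rate[1], 0)
  expect_equal(roc$fp_rate[nrow(roc)], 1)
  expect_equal(roc$tp_rate[nrow(roc)], 1)
  expect_true(is.infinite(roc$threshold[1]))
  expect_error(roc_curve(make_recs(0.5, numeric(0))), "both")
})

test_that("ROC rates are monotone and agree with a brute-force sweep", {
  set.seed(31)
  for (rep in 1:5) {
    n_nt <- sample(20:100, 1); n_t <- sample(20:100, 1)
    recs <- make_recs(rlnorm(n_nt, 0, 0.8), rlnorm(n_t, 0.7, 0.8))
    roc <- roc_curve(recs, "filter1")
    expect_true(all(diff(roc$fp_rate) >= 0))
    expect_true(all(diff(roc$tp_rate) >= 0))
    d <- recs$d_filter1
    pts <- oracle_roc_points(d, recs$label == "non-target", roc$threshold)
    expect_equal(roc$fp_rate, unname(pts[, "fp_rate"]))
    expect_equal(roc$tp_rate, unname(pts[, "tp_rate"]))
    # every observed D value as a threshold yields a point on the curve:
    # its rates must appear among the curve's achievable rate pairs
    obs <- oracle_roc_points(d, recs$label == "non-target", sort(unique(d)))
    curve_pairs <- paste(roc$fp_rate, roc$tp_rate)
    expect_true(all(paste(obs[, "fp_rate"], obs[, "tp_rate"]) %in%
                      curve_pairs))
  }
})

test_that("AUC is ~0.5 when labels are independent of D", {
  set.seed(99)
  d <- rlnorm(1000, 0, 1)
  lab <- sample(rep(c("target", "non-target"), 500))
  recs <- labeled_recordings(sprintf("x%04d", 1:1000), lab, d, d)
  auc <- roc_auc(roc_curve(recs, "filter1"))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("separable classes drive the ROC through (0, 1) and AUC to 1", {
  recs <- make_recs(d_nontarget = runif(30, 0, 0.4),
                    d_target = runif(30, 0.6, 1))
  roc <- roc_curve(recs, "filter1")
  expect_true(any(roc$fp_rate == 0 & roc$tp_rate == 1))
  expect_equal(roc_auc(roc), 1)
})

test_that("threshold_for_fp maximizes discarding within the tolerance", {
  set.seed(13)
  for (rep in 1:5) {
    recs <- make_recs(rlnorm(80, 0, 0.8), rlnorm(100, 0.8, 0.8))
    tol <- sample(c(0.05, 0.1, 0.2), 1)
    op <- threshold_for_fp(recs, "filter1", tol)
    expect_lte(op$achieved_fp_rate, tol)
    # maximality: no larger candidate threshold also satisfies tolerance
    roc <- roc_curve(recs, "filter1")
    larger <- roc$threshold > op$threshold
    expect_true(all(roc$fp_rate[larger] > tol))
    # discarded count and time savings agree with the confusion matrix
    m <- confusion(recs, op$threshold, "filter1")
    expect_equal(op$discarded_count, m$tp + m$fp)
    expect_equal(op$time_savings_min, time_savings(m, 15))
  }
})

test_that("threshold_for_fp limiting cases behave", {
  # 100 targets with distinct D: 5% tolerance admits at most 5 below
  recs <- make_recs(d_nontarget = seq(0.5, 50, length.out = 60),
                    d_target = as.numeric(1:100))
  op <- threshold_for_fp(recs, "filter1", 0.05)
  expect_lte(sum(recs$d_filter1[recs$label == "target"] < op$threshold), 5)
  # near-1 tolerance pushes the threshold above all but the top D values
  op99 <- threshold_for_fp(recs, "filter1", 0.99)
  expect_equal(op99$achieved_fp_rate, 0.99)
  # separable data reach TP-rate 1 at any tolerance; with a tolerance
  # finer than 1/n_target the maximal threshold admits no target at all
  sep <- make_recs(runif(30, 0, 0.3), runif(30, 0.5, 1))
  opsep <- threshold_for_fp(sep, "filter1", 0.01)
  expect_equal(opsep$achieved_fp_rate, 0)
  expect_equal(opsep$achieved_tp_rate, 1)
  op5 <- threshold_for_fp(sep, "filter1", 0.05)
  expect_equal(op5$achieved_tp_rate, 1)
  expect_lte(op5$achieved_fp_rate, 0.05)
})

test_that("time savings equal the summed duration of discarded recordings", {
  m <- structure(list(tp = 398, fp = 52, fn = 550, tn = 991),
                 class = "classification_matrix")
  expect_equal(time_savings(m, 15), 450 * 15 / 60)
  zero <- structure(list(tp = 0, fp = 0, fn = 10, tn = 10),
                    class = "classification_matrix")
  expect_equal(time_savings(zero, 15), 0)
})

test_that("condition subsets reuse the same operations on filtered rows", {
  dry <- generate_population(population_config(n_target = 150,
                                               n_nontarget = 150,
                                               condition = "dry", seed = 5))
  wet <- generate_population(population_config(n_target = 150,
                                               n_nontarget = 150,
                                               condition = "wet", seed = 6))
  wet$source_id <- paste0("w-", wet$source_id)
  both <- rbind(dry, wet)
  roc_dry_sub <- roc_curve(both, "filter1", condition = "dry")
  roc_dry_direct <- roc_curve(dry, "filter1")
  expect_equal(roc_dry_sub$fp_rate, roc_dry_direct$fp_rate)
  expect_equal(roc_dry_sub$tp_rate, roc_dry_direct$tp_rate)
})

test_that("dry populations separate better than wet at a fixed FP tolerance", {
  # the generator's wet preset has a noisier non-target background, so
  # at any tolerated FP-rate the achievable TP-rate must order dry > wet
  dry <- generate_population(population_config(n_target = 800,
                                               n_nontarget = 800,
                                               condition = "dry", seed = 8))
  wet <- generate_population(population_config(n_target = 800,
                                               n_nontarget = 800,
                                               condition = "wet", seed = 8))
  for (tol in c(0.05, 0.2)) {
    expect_gt(threshold_for_fp(dry, "filter1", tol)$achieved_tp_rate,
              threshold_for_fp(wet, "filter1", tol)$achieved_tp_rate)
  }
})
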