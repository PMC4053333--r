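# Independent brute-force oracles, written as plain triple loops so they
# share no code path with the package implementation.

oracle_filter1 <- function(a) {
  d <- dim(a)
  abar <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- 0
    for (k in seq_len(d[3])) s <- s + a[i, j, k]
    abar[i, j] <- s / d[3]
  }
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- s + (a[i, j, k] - abar[i, j])^2
    }
    out[k] <- s
  }
  out
}

oracle_filter2 <- function(a) {
  d <- dim(a)
  out <- numeric(d[3] - 1)
  for (k in seq_len(d[3] - 1)) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- s + (a[i, j, k + 1] - a[i, j, k])^2
    }
    out[k] <- s
  }
  out
}

# Brute-force ROC sweep: test every observed D value (and +/- sentinels)
# as a threshold, computing rates by direct counting.
oracle_roc_points <- function(d, is_nontarget, thresholds) {
  t(vapply(thresholds, function(th) {
    tp <- sum(is_nontarget & d < th)
    fp <- sum(!is_nontarget & d < th)
    c(fp_rate = fp / sum(!is_nontarget),
      tp_rate = tp / sum(is_nontarget))
  }, numeric(2)))
}

random_tensor <- function(ny, nx, nt) {
  array(runif(ny * nx * nt), dim = c(ny, nx, nt))
}

# Write a tensor out as a directory of PNG frames; returns the directory.
write_frame_dir <- function(a, dir = tempfile("clip")) {
  dir.create(dir)
  for (k in seq_len(dim(a)[3])) {
    png::writePNG(a[, , k], file.path(dir, sprintf("frame%03d.png", k)))
  }
  dir
}
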