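# Independent brute-force oracles and fixture builders.  These deliberately
# avoid the package's own code paths: Pearson correlations are computed from
# raw sums, moments from their textbook formulas.

pearson_manual <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  num / den
}

# recompute every reported entry of a crosscorr matrix from scratch
naive_crosslag_entries <- function(a, b, m, fps, window_sec, cap_eps = 1e-7) {
  w <- round(window_sec * fps)
  starts <- round(attr(m, "window_starts") * fps) + 1
  lags <- round(attr(m, "lags") * fps)
  out <- matrix(NA_real_, nrow = length(starts), ncol = length(lags))
  for (i in seq_along(starts)) {
    for (j in seq_along(lags)) {
      aw <- a[starts[i]:(starts[i] + w - 1)]
      bw <- b[(starts[i] + lags[j]):(starts[i] + lags[j] + w - 1)]
      if (var(aw) == 0 || var(bw) == 0) next
      r <- pearson_manual(aw, bw)
      r <- max(min(r, 1 - cap_eps), -1 + cap_eps)
      out[i, j] <- abs(atanh(r))
    }
  }
  out
}

naive_summary <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  g1 <- m3 / m2^1.5
  c(min = min(v), max = max(v), mean = m, median = median(v),
    sd = sqrt(sum((v - m)^2) / (n - 1)),
    skew = g1 * sqrt(n * (n - 1)) / (n - 2),
    kurtosis = m4 / m2^2 - 3)
}

# feature table of pure Gaussian noise features with an optional mean shift
# of the case group, bypassing the synchrony pipeline
make_gaussian_table <- function(n_case, n_ctrl, p = 10, delta = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_case + n_ctrl
    x <- matrix(rnorm(n * p), nrow = n)
    x[seq_len(n_case), ] <- x[seq_len(n_case), ] + delta
    colnames(x) <- sprintf("feat_%02d", seq_len(p))
    tab <- data.frame(dyad_id = sprintf("d%03d", seq_len(n)),
                      label = rep(c("ASD", "CC"), c(n_case, n_ctrl)),
                      age = runif(n, 6, 20))
    tab <- cbind(tab, as.data.frame(x))
    attr(tab, "feature_cols") <- colnames(x)
    class(tab) <- c("feature_table", "data.frame")
    tab
  })
}

# fake nested-cv fit holding only what importance analyses need
make_fake_fit <- function(weight_rows, perms, outer_folds, inner_folds) {
  models <- lapply(seq_len(nrow(weight_rows)), function(i) {
    list(id = i, perm = perms[i], outer_fold = outer_folds[i],
         inner_fold = inner_folds[i],
         weights = stats::setNames(as.numeric(weight_rows[i, ]),
                                   colnames(weight_rows)))
  })
  structure(list(models = models, feature_cols = colnames(weight_rows)),
            class = "nested_cv_result")
}

# small frame pair with controlled absolute differences inside a roi
frames_with_diffs <- function(diffs, nrow_f = 5, ncol_f = 5, r) {
  prev <- matrix(100, nrow_f, ncol_f)
  curr <- prev
  rows <- (r$y0 + 1):r$y1
  cols <- (r$x0 + 1):r$x1
  curr[rows, cols] <- 100 + matrix(diffs, length(rows), length(cols))
  list(prev = prev, curr = curr)
}
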