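#' Centered moving average with shrinking edges
#'
#' Smooths a numeric series with a centered window of `n` samples.  Near the
#' series boundaries the window shrinks so that the output has the same length
#' as the input and no padding values are invented.  For even `n` the window
#' extends one sample further to the right than to the left.
#'
#' @param x numeric vector.
#' @param n window length in samples; `n <= 1` returns `x` unchanged.
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, n) {
  stopifnot(is.numeric(x), length(n) == 1L, n >= 0)
  n <- as.integer(round(n))
  if (n <= 1L || length(x) == 0L) return(x)
  lo <- (n - 1L) %/% 2L
  hi <- n %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, length(x))
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

# Deterministic stream of derived seeds: keeps every derived seed a valid
# 32-bit integer regardless of the user seed.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(i)) %% 2147483647)
}

# Mann-Whitney rank statistic form of the area under the ROC curve.
# `case` scores are expected to be high; ties contribute 1/2.
auc_rank <- function(scores, truth, case_label) {
  is_case <- truth == case_label
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
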