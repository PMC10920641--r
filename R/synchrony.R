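#' Windowed cross-lagged synchrony
#'
#' Interpersonal motor synchrony is measured by Pearson-correlating
#' fixed-length segments of two movement series at a range of temporal
#' offsets (lags), repeating along the recording with a step size, and
#' transforming each correlation to an absolute Fisher-Z value.  High entries
#' mean strongly coupled movement in that window at that lag, regardless of
#' direction.  The same machinery applied to one person's head vs body series
#' (with a shorter window) measures intrapersonal coordination.
#'
#' @name synchrony
NULL

#' Cross-correlation configuration
#'
#' Interpersonal defaults: 60 s windows stepping by 30 s, lags up to +-5 s.
#' Intrapersonal coordination uses 30 s windows stepping by 15 s
#' ([intra_crosscorr_config()]).  Lags advance in 1 s increments.  All
#' second-valued parameters are converted to samples by `round(sec * fps)`.
#'
#' @param window_sec window length in seconds.
#' @param max_lag_sec maximal absolute lag in seconds.
#' @param step_sec distance between window starts in seconds.
#' @param lag_increment_sec lag grid spacing in seconds.
#' @return list of class `crosscorr_config`.
#' @export
crosscorr_config <- function(window_sec = 60, max_lag_sec = 5,
                             step_sec = 30, lag_increment_sec = 1) {
  stopifnot(window_sec > 0, max_lag_sec >= 0, step_sec > 0,
            lag_increment_sec > 0)
  structure(list(window_sec = window_sec, max_lag_sec = max_lag_sec,
                 step_sec = step_sec, lag_increment_sec = lag_increment_sec),
            class = "crosscorr_config")
}

#' @rdname crosscorr_config
#' @export
intra_crosscorr_config <- function(window_sec = 30, max_lag_sec = 5,
                                   step_sec = 15, lag_increment_sec = 1) {
  crosscorr_config(window_sec, max_lag_sec, step_sec, lag_increment_sec)
}

#' Preprocess a motion energy series
#'
#' Scales the series by its standard deviation and smooths it with a centered
#' moving average (default 0.5 s), mitigating between-video differences in
#' signal amplitude and pixel noise.
#'
#' @param series an [mea_series()] or numeric vector.
#' @param fps frames per second; taken from the series attribute when absent.
#' @param sd_scale divide by the series standard deviation first?
#' @param smooth_sec moving-average length in seconds.
#' @return numeric vector of the same length.
#' @export
preprocess_series <- function(series, fps = NULL, sd_scale = TRUE,
                              smooth_sec = 0.5) {
  fps <- fps %||% series_fps(series)
  if (is.null(fps)) stop("fps not given and not carried by the series")
  stopifnot(smooth_sec >= 0)
  x <- as.numeric(series)
  if (sd_scale) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate input: series has zero variance, cannot scale by sd")
    x <- x / s
  }
  moving_average(x, round(smooth_sec * fps))
}

#' Windowed cross-lagged correlation matrix
#'
#' For each window start `t` (stepping by `step_sec`) and each lag `l` on the
#' lag grid, computes the Pearson correlation between `a[t, t+w)` and
#' `b[t+l, t+l+w)` and stores `|atanh(r)|` with `r` clipped to
#' `|r| <= 1 - r_cap_eps`.  Windows that would need samples outside the
#' series at any lag on the grid are omitted entirely (no padding), so every
#' retained window covers the full lag range.  Windows in which either
#' segment has zero variance yield a missing entry.
#'
#' @param a,b numeric series of equal length (and equal fps if
#'   [mea_series()]).
#' @param cfg a [crosscorr_config()].
#' @param fps frames per second; taken from `a` when absent.
#' @param r_cap_eps correlations are clipped to `1 - r_cap_eps` in absolute
#'   value before the Fisher transform so entries stay finite.
#' @return matrix of class `crosscorr_matrix` (windows x lags, `NA` for
#'   missing) with attributes `window_starts` and `lags` in seconds.
#' @export
windowed_crosslag <- function(a, b, cfg = crosscorr_config(), fps = NULL,
                              r_cap_eps = 1e-7) {
  fps <- fps %||% series_fps(a)
  if (is.null(fps)) stop("fps not given and not carried by the series")
  fb <- series_fps(b)
  if (!is.null(fb) && !isTRUE(all.equal(fb, fps))) stop("fps mismatch")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("series lengths differ")
  n <- length(a)
  w <- as.integer(round(cfg$window_sec * fps))
  step <- as.integer(round(cfg$step_sec * fps))
  if (w < 3L) stop("window shorter than 3 samples")
  lag_secs <- seq(-cfg$max_lag_sec, cfg$max_lag_sec,
                  by = cfg$lag_increment_sec)
  lag_off <- as.integer(round(lag_secs * fps))
  starts <- seq.int(1L, n, by = step)
  ok <- starts + min(lag_off) >= 1L & starts + max(lag_off) + w - 1L <= n
  starts <- starts[ok]
  if (length(starts) == 0L)
    stop("series too short for one full window at the maximal lag")
  m <- matrix(NA_real_, nrow = length(starts), ncol = length(lag_off))
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    aw <- a[t0:(t0 + w - 1L)]
    va <- stats::var(aw)
    if (!is.finite(va) || va == 0) next
    for (j in seq_along(lag_off)) {
      bw <- b[(t0 + lag_off[j]):(t0 + lag_off[j] + w - 1L)]
      vb <- stats::var(bw)
      if (!is.finite(vb) || vb == 0) next
      r <- stats::cor(aw, bw)
      r <- max(min(r, 1 - r_cap_eps), -1 + r_cap_eps)
      m[i, j] <- abs(atanh(r))
    }
  }
  structure(m,
            window_starts = (starts - 1L) / fps,
            lags = lag_secs,
            fps = fps,
            class = c("crosscorr_matrix", "matrix"))
}

#' Intrapersonal head-body coordination
#'
#' [windowed_crosslag()] with the intrapersonal configuration (30 s windows,
#' +-5 s lags, 15 s steps) applied to one person's head and body series.
#'
#' @param head,body the person's two movement series.
#' @param cfg an intrapersonal [crosscorr_config()].
#' @inheritParams windowed_crosslag
#' @return a `crosscorr_matrix`.
#' @export
intrapersonal_coordination <- function(head, body,
                                       cfg = intra_crosscorr_config(),
                                       fps = NULL, r_cap_eps = 1e-7) {
  windowed_crosslag(head, body, cfg, fps = fps, r_cap_eps = r_cap_eps)
}

#' @export
print.crosscorr_matrix <- function(x, ...) {
  cat(sprintf("<crosscorr_matrix> %d windows x %d lags, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Serialize a cross-correlation matrix as long-format CSV
#'
#' Columns `window_start`, `lag`, `value` (missing entries written as empty).
#'
#' @param m a `crosscorr_matrix`.
#' @param path CSV file path.
#' @return [read_crosscorr_csv()] returns a `crosscorr_matrix`.
#' @export
write_crosscorr_csv <- function(m, path) {
  df <- data.frame(
    window_start = rep(attr(m, "window_starts"), times = ncol(m)),
    lag = rep(attr(m, "lags"), each = nrow(m)),
    value = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosscorr_csv
#' @export
read_crosscorr_csv <- function(path) {
  df <- utils::read.csv(path)
  ws <- sort(unique(df$window_start))
  lags <- sort(unique(df$lag))
  m <- matrix(NA_real_, nrow = length(ws), ncol = length(lags))
  m[cbind(match(df$window_start, ws), match(df$lag, lags))] <- df$value
  structure(m, window_starts = ws, lags = lags,
            class = c("crosscorr_matrix", "matrix"))
}

#' Generate surrogate pseudodyads
#'
#' Pairs each participant series with an administrator series from a
#' *different* dyad, giving a chance-level synchrony baseline that preserves
#' role-specific signal structure.  Pairings are sampled uniformly without
#' replacement from all non-genuine combinations (individuals may recur).
#'
#' @param dyad_ids character or integer ids of the genuine dyads (>= 2).
#' @param n number of pseudodyads; `NULL` returns all non-genuine pairings.
#' @param seed RNG seed for reproducibility.
#' @return data.frame with columns `participant` and `administrator` (dyad
#'   ids), of class `pseudodyad_set`.
#' @export
generate_pseudodyads <- function(dyad_ids, n = 500, seed = 1) {
  dyad_ids <- unique(dyad_ids)
  if (length(dyad_ids) < 2L) stop("need at least 2 dyads")
  all_pairs <- expand.grid(participant = dyad_ids, administrator = dyad_ids,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$participant != all_pairs$administrator, ,
                         drop = FALSE]
  if (!is.null(n)) {
    if (n > nrow(all_pairs))
      stop(sprintf("n = %d exceeds the %d available non-genuine pairings",
                   n, nrow(all_pairs)))
    idx <- withr::with_seed(seed, sample.int(nrow(all_pairs), n))
    all_pairs <- all_pairs[idx, , drop = FALSE]
  }
  rownames(all_pairs) <- NULL
  class(all_pairs) <- c("pseudodyad_set", "data.frame")
  all_pairs
}

#' Compare genuine synchrony against the pseudodyad null
#'
#' Reduces each matrix to its mean non-missing entry and compares the
#' per-dyad means of genuine dyads against pseudodyads with Welch's t-test,
#' answering whether observed synchrony exceeds chance pairing.
#'
#' @param real_matrices list of `crosscorr_matrix` for genuine dyads.
#' @param pseudo_matrices list of `crosscorr_matrix` for pseudodyads.
#' @return a `welch_result` (see [welch_t()]) with the per-side means
#'   attached as `mean_real` / `mean_pseudo`.
#' @export
pseudosynchrony_comparison <- function(real_matrices, pseudo_matrices) {
  mean_entry <- function(m) {
    v <- as.vector(m)
    v <- v[is.finite(v)]
    if (length(v) == 0L) stop("matrix with no valid entries")
    mean(v)
  }
  xr <- vapply(real_matrices, mean_entry, numeric(1))
  xp <- vapply(pseudo_matrices, mean_entry, numeric(1))
  if (length(xr) < 2L || length(xp) < 2L)
    stop("need at least 2 dyads per side")
  res <- welch_t(group_summary(length(xr), mean(xr), stats::sd(xr)),
                 group_summary(length(xp), mean(xp), stats::sd(xp)))
  res$mean_real <- mean(xr)
  res$mean_pseudo <- mean(xp)
  res
}
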