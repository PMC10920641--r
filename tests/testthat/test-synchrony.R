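test_that("preprocessing scales by sd and smooths with shrinking edges", {
  # hand computation with 3-sample centered average and edge shrinkage
  expect_equal(preprocess_series(c(0, 0, 3, 0, 0), fps = 6, sd_scale = FALSE,
                                 smooth_sec = 0.5),
               c(0, 1, 1, 1, 0))
  withr::with_seed(3, x <- rpois(200, 2))
  out <- preprocess_series(mea_series(x, 30), smooth_sec = 0)
  expect_equal(sd(out), 1)
  expect_length(out, 200)
  expect_error(preprocess_series(rep(2, 50), fps = 30), "zero variance")
})

test_that("perfect and delayed copies produce the expected lag structure", {
  fps <- 10
  withr::with_seed(21, a <- as.numeric(arima.sim(list(ar = 0.9), 1500)))
  cfg <- crosscorr_config(window_sec = 30, max_lag_sec = 5, step_sec = 15)
  m_self <- windowed_crosslag(a, a, cfg, fps = fps)
  lag0 <- m_self[, attr(m_self, "lags") == 0]
  expect_true(all(abs(lag0 - atanh(1 - 1e-7)) < 1e-9))

  k <- 2  # seconds of delay
  b <- c(rep(0, k * fps), a[1:(1500 - k * fps)])
  m <- windowed_crosslag(a, b, cfg, fps = fps)
  argmax <- attr(m, "lags")[apply(m, 1, which.max)]
  expect_true(all(argmax == k))
})

test_that("every reported entry matches a naive brute-force recomputation", {
  fps <- 7.5
  withr::with_seed(9, {
    a <- rpois(600, 1.5) * runif(600)
    b <- 0.5 * a + rnorm(600)
  })
  for (cfg in list(crosscorr_config(window_sec = 20, max_lag_sec = 4,
                                    step_sec = 10),
                   intra_crosscorr_config(window_sec = 10, max_lag_sec = 3,
                                          step_sec = 5,
                                          lag_increment_sec = 0.5))) {
    m <- windowed_crosslag(a, b, cfg, fps = fps)
    naive <- naive_crosslag_entries(a, b, m, fps, cfg$window_sec)
    expect_lt(max(abs(m - naive), na.rm = TRUE), 1e-10)
    expect_true(all(m >= 0, na.rm = TRUE))
  }
  # retained windows always cover the full lag range
  cfg <- crosscorr_config(window_sec = 20, max_lag_sec = 4, step_sec = 10)
  m <- windowed_crosslag(a, b, cfg, fps = fps)
  starts <- round(attr(m, "window_starts") * fps) + 1
  expect_true(min(starts) > round(4 * fps))
  expect_true(max(starts) + round(20 * fps) - 1 + round(4 * fps) <= 600)
  expect_error(windowed_crosslag(a[1:100], b[1:100],
                                 crosscorr_config(window_sec = 60), fps = fps),
               "too short")
  expect_error(windowed_crosslag(mea_series(a, 10), mea_series(a, 20)),
               "fps mismatch")
})

test_that("role swap mirrors the lag axis on full-coverage windows", {
  fps <- 5
  withr::with_seed(13, {
    a <- rnorm(300)
    b <- rnorm(300)
  })
  cfg <- crosscorr_config(window_sec = 10, max_lag_sec = 4, step_sec = 2,
                          lag_increment_sec = 2)
  ma <- windowed_crosslag(a, b, cfg, fps = fps)
  mb <- windowed_crosslag(b, a, cfg, fps = fps)
  lags <- attr(ma, "lags")
  for (l in lags[lags > 0]) {
    for (i in seq_along(attr(ma, "window_starts"))) {
      s2 <- attr(ma, "window_starts")[i] + l
      j <- match(s2, attr(mb, "window_starts"))
      if (is.na(j)) next
      expect_equal(ma[i, lags == l], mb[j, lags == -l], tolerance = 1e-12)
    }
  }
})

test_that("independent white noise stays well below the atanh(0.2) line", {
  fps <- 30
  cfg <- crosscorr_config()
  for (s in 1:3) {
    withr::with_seed(100 + s, {
      a <- rnorm(300 * fps)
      b <- rnorm(300 * fps)
    })
    m <- windowed_crosslag(a, b, cfg, fps = fps)
    expect_lt(mean(m, na.rm = TRUE), atanh(0.2))
  }
})

test_that("zero-variance windows yield missing entries", {
  fps <- 5
  a <- c(rep(0, 60), rnorm(240))
  b <- rnorm(300)
  cfg <- crosscorr_config(window_sec = 8, max_lag_sec = 2, step_sec = 4)
  m <- windowed_crosslag(a, b, cfg, fps = fps)
  expect_true(all(is.na(m[1, ])))
  expect_true(all(is.finite(m[nrow(m), ])))
})

test_that("pseudodyad generation is role-preserving, non-genuine and seeded", {
  ids <- c("d1", "d2")
  ex <- generate_pseudodyads(ids, n = NULL)
  expect_equal(nrow(ex), 2)
  expect_true(all(ex$participant != ex$administrator))

  ids <- sprintf("d%02d", 1:8)
  ps <- generate_pseudodyads(ids, n = 20, seed = 5)
  expect_equal(nrow(ps), 20)
  expect_true(all(ps$participant != ps$administrator))
  expect_equal(nrow(unique(ps)), 20)  # without replacement of pairings
  expect_identical(generate_pseudodyads(ids, n = 20, seed = 5), ps)
  expect_false(identical(generate_pseudodyads(ids, n = 20, seed = 6), ps))
  expect_error(generate_pseudodyads(ids, n = 100), "exceeds")
  expect_error(generate_pseudodyads("d1"), "at least 2")
})

test_that("pseudosynchrony comparison detects a shifted real distribution", {
  make_mats <- function(n, shift, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(i)
      matrix(abs(rnorm(20, 0.3 + shift, 0.1)), 4, 5)))
  }
  res <- pseudosynchrony_comparison(make_mats(50, 1, 1), make_mats(50, 0, 2))
  expect_lt(res$p, 0.001)
  expect_gt(res$mean_real, res$mean_pseudo)
  res0 <- pseudosynchrony_comparison(make_mats(50, 0, 3), make_mats(50, 0, 4))
  expect_gt(res0$p, 0.001)
  expect_error(pseudosynchrony_comparison(make_mats(1, 0, 5),
                                          make_mats(50, 0, 6)),
               "at least 2")
})

test_that("crosscorr matrices roundtrip through long-format CSV", {
  withr::with_seed(2, a <- rnorm(400))
  m <- windowed_crosslag(a, rev(a), crosscorr_config(window_sec = 10,
                                                     step_sec = 5),
                         fps = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosscorr_csv(m, path)
  back <- read_crosscorr_csv(path)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "lags"), attr(m, "lags"))
})
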