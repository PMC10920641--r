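test_that("dyad simulation is reproducible, nonnegative and zero-inflated", {
  cfg <- dyad_sim_config(duration_sec = 60, fps = 10)
  d1 <- simulate_dyad(cfg, coupling = 0.4, seed = 5)
  d2 <- simulate_dyad(cfg, coupling = 0.4, seed = 5)
  expect_identical(d1, d2)
  d3 <- simulate_dyad(cfg, coupling = 0.4, seed = 6)
  expect_false(identical(d1, d3))
  expect_named(d1, c("participant_head", "participant_body",
                     "administrator_head", "administrator_body"))
  for (s in d1) {
    expect_length(s, 600)
    expect_true(all(s >= 0))
    expect_true(any(s == 0))   # exact zeros, so movement quantity < 1
    expect_true(any(s > 0))
    expect_lt(movement_quantity(s), 1)
  }
  expect_error(simulate_dyad(cfg, coupling = 1.2), "coupling")
  expect_error(dyad_sim_config(ar_coef = 1.5))
})

test_that("uncoupled interactants are independent at the raw-series level", {
  cfg <- dyad_sim_config(duration_sec = 300, fps = 10)
  cors <- vapply(1:5, function(s) {
    d <- simulate_dyad(cfg, coupling = 0, seed = 200 + s)
    cor(as.numeric(d$participant_body), as.numeric(d$administrator_body))
  }, numeric(1))
  expect_lt(max(abs(cors)), 0.1)
})

test_that("strong coupling at a 2 s delay puts the synchrony peak at +2 s", {
  # ar_coef 0.8 keeps the latent autocorrelation short against the 1 s lag
  # grid, so the cross-correlation peak is sharp enough to localize
  cfg <- dyad_sim_config(duration_sec = 300, fps = 10, lag_sec = 2,
                         ar_coef = 0.8)
  ccfg <- crosscorr_config(window_sec = 30, step_sec = 15)
  hits <- vapply(1:10, function(s) {
    d <- simulate_dyad(cfg, coupling = 0.9, seed = 300 + s)
    a <- preprocess_series(d$participant_body)
    b <- preprocess_series(d$administrator_body)
    m <- windowed_crosslag(a, b, ccfg, fps = 10)
    col_means <- colMeans(m, na.rm = TRUE)
    attr(m, "lags")[which.max(col_means)] == 2
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("mean synchrony increases with the coupling parameter", {
  cfg <- dyad_sim_config(duration_sec = 240, fps = 10)
  ccfg <- crosscorr_config(window_sec = 60, step_sec = 30)
  mean_sync <- vapply(c(0, 0.4, 0.8), function(rho) {
    mean(vapply(1:5, function(s) {
      d <- simulate_dyad(cfg, coupling = rho, seed = 400 + s)
      a <- preprocess_series(d$participant_head)
      b <- preprocess_series(d$administrator_head)
      mean(windowed_crosslag(a, b, ccfg, fps = 10), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sync) > 0))
})

test_that("cohort metadata has group structure, ranges and missingness", {
  cfg <- dyad_sim_config(duration_sec = 30, fps = 5)
  co <- simulate_cohort(cfg,
                        group_params = list(ASD = list(n = 30, coupling = 0.2),
                                            CC = list(n = 20, coupling = 0.5)),
                        seed = 11)
  md <- co$metadata
  expect_equal(nrow(md), 50)
  expect_equal(unname(table(md$label)["ASD"]), 30)
  expect_length(co$series, 50)
  expect_equal(sum(is.na(md$iq)), 8)  # 16% of 50
  expect_true(all(md$ados_css_sa >= 1 & md$ados_css_sa <= 10, na.rm = TRUE))
  expect_true(all(md$adir_a >= 0 & md$adir_a <= 30, na.rm = TRUE))
  expect_true(all(md$sex %in% 0:1))
  expect_true(all(md$age >= 5 & md$age <= 29))
  # group-shifted clinical scores separate in the expected direction
  expect_gt(mean(md$adir_a[md$label == "ASD"], na.rm = TRUE),
            mean(md$adir_a[md$label == "CC"], na.rm = TRUE))
  co2 <- simulate_cohort(cfg,
                         group_params = list(ASD = list(n = 30, coupling = 0.2),
                                             CC = list(n = 20, coupling = 0.5)),
                         seed = 11)
  expect_identical(co$metadata, co2$metadata)
  expect_error(simulate_cohort(cfg, group_params = list(A = list(n = 0, coupling = 0))),
               "at least one")
})

test_that("synthetic blob video drives extraction through the real path", {
  fps <- 10
  nf <- 120
  r1 <- roi("participant_head", 0, 0, 10, 40)
  r2 <- roi("administrator_head", 20, 0, 30, 40)
  withr::with_seed(21, s <- abs(as.numeric(arima.sim(list(ar = 0.8), nf))) * 4)
  zero <- rep(0, nf)
  cfg <- video_sim_config(40, 50, fps, list(r1, r2),
                          driving = list(participant_head = s,
                                         administrator_head = zero))
  video <- render_synthetic_video(cfg)
  out <- extract_motion_energy(video, list(r1, r2))
  # administrator roi never changes; contamination is exactly zero
  expect_true(all(out$administrator_head == 0))
  # extracted motion follows the absolute driving increments
  target <- abs(diff(1 + round(s)))
  expect_gt(cor(as.numeric(out$participant_head), target,
                method = "spearman"), 0.8)

  cfg_zero <- video_sim_config(40, 50, fps, list(r1, r2),
                               driving = list(participant_head = zero,
                                              administrator_head = zero))
  out0 <- extract_motion_energy(render_synthetic_video(cfg_zero),
                                list(r1, r2))
  expect_true(all(out0$participant_head == 0))

  too_big <- video_sim_config(40, 50, fps, list(r1, r2),
                              driving = list(participant_head = s * 50,
                                             administrator_head = zero))
  expect_error(render_synthetic_video(too_big), "escapes")
})
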