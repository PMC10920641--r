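#' Synthetic dyadic motion-energy cohorts
#'
#' The generator emulates the data entering the synchrony pipeline: four
#' nonnegative motion-energy series per dyad (participant/administrator x
#' head/body) with group-dependent lagged coupling, plus group-shifted
#' clinical scores and demographics.  A latent first-order autoregressive
#' "movement drive" of the participant is coupled, at a fixed lag, into the
#' administrator's latent drive; head and body series of the same person
#' share their latent with independent components so intrapersonal
#' coordination is tunable separately.  Observed series are a shot-noise
#' (Poisson) transform of the latents, giving heavy-tailed nonnegative
#' counts with exact zeros -- as frame-differencing motion energy produces,
#' and as the movement-quantity feature requires to be nontrivial.
#'
#' @name synthetic_data
NULL

#' Dyad simulation configuration
#'
#' @param duration_sec clip length in seconds; `NULL` samples uniformly from
#'   315--877 s per dyad, mirroring heterogeneous interview clip lengths.
#' @param fps frames per second (default 29.95).
#' @param ar_coef AR(1) coefficient of the latent movement drive,
#'   `|phi| < 1`.  The default 0.95 gives a ~0.7 s autocorrelation time,
#'   i.e. smooth movement bursts at this frame rate.
#' @param lag_sec administrator response lag in seconds (<= 5 so it falls
#'   inside the lag grid).
#' @param intra_coupling mixing weight of the shared person-level drive in
#'   the head and body latents, in `[0, 1)`.  Head-body latent correlation
#'   is its square, and interpersonal channel-level correlation is
#'   attenuated by the same factor, so values well below 1 rapidly dilute
#'   the group coupling effect; the default 0.85 reflects strongly
#'   coordinated gross head and body movement within a person.
#' @param noise_sd standard deviation of white measurement noise added to
#'   each channel latent (relative to the unit-variance latent).
#' @param burst_rate baseline Poisson intensity of the shot-noise
#'   observation model; smaller values give more exact zeros.
#' @param burst_scale multiplier of the latent inside the log-intensity;
#'   larger values give heavier tails.
#' @return list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(duration_sec = NULL, fps = 29.95, ar_coef = 0.95,
                            lag_sec = 1, intra_coupling = 0.85,
                            noise_sd = 0.3, burst_rate = 0.8,
                            burst_scale = 1) {
  stopifnot(abs(ar_coef) < 1, lag_sec >= 0, lag_sec <= 5,
            intra_coupling >= 0, intra_coupling < 1,
            noise_sd >= 0, burst_rate > 0, burst_scale > 0, fps > 0)
  structure(list(duration_sec = duration_sec, fps = fps, ar_coef = ar_coef,
                 lag_sec = lag_sec, intra_coupling = intra_coupling,
                 noise_sd = noise_sd, burst_rate = burst_rate,
                 burst_scale = burst_scale),
            class = "dyad_sim_config")
}

# unit-variance stationary AR(1) path
ar1_unit <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

shot_noise_observe <- function(z, cfg) {
  if (cfg$noise_sd > 0) {
    z <- (z + stats::rnorm(length(z), sd = cfg$noise_sd)) /
      sqrt(1 + cfg$noise_sd^2)
  }
  stats::rpois(length(z), cfg$burst_rate * exp(cfg$burst_scale * z))
}

#' Simulate one dyad's four motion-energy series
#'
#' The participant's latent drive `u` is AR(1); the administrator's drive is
#' `coupling * u` delayed by `lag_sec`, completed to unit variance with an
#' independent AR(1) component.  With `coupling = 0` the two interactants
#' are fully independent, matching the pseudodyad null by construction.
#'
#' @param cfg a [dyad_sim_config()].
#' @param coupling interpersonal latent correlation `rho` in `[0, 1)` (a
#'   group-level parameter).
#' @param seed RNG seed; identical seeds give identical series.
#' @return named list of four [mea_series()]: `participant_head`,
#'   `participant_body`, `administrator_head`, `administrator_body`.
#' @export
simulate_dyad <- function(cfg = dyad_sim_config(), coupling = 0.4, seed = 1) {
  stopifnot(coupling >= 0, coupling < 1)
  withr::with_seed(seed, {
    dur <- cfg$duration_sec %||% stats::runif(1, 315, 877)
    n <- as.integer(round(dur * cfg$fps))
    kl <- as.integer(round(cfg$lag_sec * cfg$fps))
    phi <- cfg$ar_coef
    u_full <- ar1_unit(n + kl, phi)
    p_core <- u_full[(kl + 1L):(kl + n)]
    a_core <- coupling * u_full[seq_len(n)] +
      sqrt(1 - coupling^2) * ar1_unit(n, phi)
    alpha <- cfg$intra_coupling
    mix <- function(core) alpha * core + sqrt(1 - alpha^2) * ar1_unit(n, phi)
    latents <- list(participant_head = mix(p_core),
                    participant_body = mix(p_core),
                    administrator_head = mix(a_core),
                    administrator_body = mix(a_core))
    out <- lapply(names(latents), function(role) {
      mea_series(shot_noise_observe(latents[[role]], cfg), cfg$fps, role)
    })
    names(out) <- names(latents)
    out
  })
}

default_score_params <- function() {
  # group-shifted clinical score distributions; ASD/CC means and sds follow
  # published module-3 clinical summary tables, remaining groups default to
  # the CC distribution
  list(
    age = list(mean = c(.default = 13.5), sd = c(.default = 4.7),
               min = 5, max = 29, digits = 1),
    iq = list(mean = c(ASD = 93, .default = 102), sd = c(.default = 19),
              min = 40, max = 150, digits = 0),
    ados_css_sa = list(mean = c(ASD = 7.5, .default = 4), sd = c(.default = 2),
                       min = 1, max = 10, digits = 0),
    ados_css_rrb = list(mean = c(ASD = 7, .default = 5), sd = c(.default = 2.5),
                        min = 1, max = 10, digits = 0),
    ados_css_total = list(mean = c(ASD = 7.5, .default = 4), sd = c(.default = 2),
                          min = 1, max = 10, digits = 0),
    adir_a = list(mean = c(ASD = 17.58, .default = 6.25),
                  sd = c(ASD = 6.38, .default = 5.53),
                  min = 0, max = 30, digits = 0),
    adir_b = list(mean = c(ASD = 13.00, .default = 4.58),
                  sd = c(ASD = 4.67, .default = 4.09),
                  min = 0, max = 26, digits = 0),
    adir_c = list(mean = c(ASD = 4.81, .default = 1.12),
                  sd = c(ASD = 2.62, .default = 1.39),
                  min = 0, max = 12, digits = 0))
}

draw_score <- function(n, group, spec) {
  pick <- function(v) if (group %in% names(v)) v[[group]] else v[[".default"]]
  m <- pick(spec$mean)
  s <- pick(spec$sd)
  x <- stats::rnorm(n, m, s)
  x <- pmin(pmax(x, spec$min), spec$max)
  round(x, spec$digits)
}

#' Simulate a cohort of dyads with clinical metadata
#'
#' @param cfg a [dyad_sim_config()].
#' @param group_params named list, one entry per diagnostic group, each a
#'   list with `n` (dyad count) and `coupling` (interpersonal latent
#'   correlation).  Defaults mirror the 56 ASD / 38 clinical-control design
#'   with reduced synchrony in the ASD group.
#' @param score_params clinical score distributions (see
#'   `dyadsync:::default_score_params`); entries are lists with group-keyed
#'   `mean`/`sd` (fallback key `.default`), truncation `min`/`max`, and
#'   rounding `digits`.
#' @param iq_missing_rate fraction of dyads with missing IQ (default 0.16).
#' @param adir_missing_rate fraction of dyads with missing ADI-R scores.
#' @param female_rate probability of sex code 1 (female); sex is coded
#'   0 = male, 1 = female.
#' @param seed RNG seed.
#' @return list of class `synthetic_cohort`: `series` (named by dyad id,
#'   each a list of four [mea_series()]), `metadata` (data.frame with
#'   `dyad_id`, `label`, `age`, `sex`, `iq`, ADOS-2 calibrated severity and
#'   ADI-R domain scores), `params`.
#' @export
simulate_cohort <- function(cfg = dyad_sim_config(),
                            group_params = list(
                              ASD = list(n = 56, coupling = 0.25),
                              CC = list(n = 38, coupling = 0.45)),
                            score_params = default_score_params(),
                            iq_missing_rate = 0.16,
                            adir_missing_rate = 0,
                            female_rate = 0.21,
                            seed = 1) {
  if (length(group_params) < 1L || any(vapply(group_params, `[[`, numeric(1), "n") < 1))
    stop("every group needs at least one dyad")
  groups <- names(group_params)
  meta_rows <- list()
  series <- list()
  dyad_no <- 0L
  for (g in groups) {
    gp <- group_params[[g]]
    for (i in seq_len(gp$n)) {
      dyad_no <- dyad_no + 1L
      id <- sprintf("dyad_%03d", dyad_no)
      series[[id]] <- simulate_dyad(cfg, coupling = gp$coupling,
                                    seed = derive_seed(seed, dyad_no))
      meta_rows[[id]] <- data.frame(dyad_id = id, label = g,
                                    stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta_rows)
  n <- nrow(metadata)
  metadata <- withr::with_seed(derive_seed(seed, 900001L), {
    for (v in names(score_params)) {
      metadata[[v]] <- unlist(lapply(seq_len(n), function(i) {
        draw_score(1L, metadata$label[i], score_params[[v]])
      }))
    }
    metadata$sex <- stats::rbinom(n, 1, female_rate)
    if (iq_missing_rate > 0) {
      miss <- sample.int(n, round(iq_missing_rate * n))
      metadata$iq[miss] <- NA_real_
    }
    if (adir_missing_rate > 0) {
      miss <- sample.int(n, round(adir_missing_rate * n))
      metadata[miss, c("adir_a", "adir_b", "adir_c")] <- NA_real_
    }
    metadata
  })
  rownames(metadata) <- NULL
  structure(list(series = series, metadata = metadata,
                 params = list(cfg = cfg, group_params = group_params,
                               iq_missing_rate = iq_missing_rate,
                               adir_missing_rate = adir_missing_rate,
                               female_rate = female_rate, seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d dyads (%s)\n", nrow(x$metadata),
              paste(sprintf("%s: %d", names(table(x$metadata$label)),
                            table(x$metadata$label)), collapse = ", ")))
  invisible(x)
}

#' Video simulation configuration
#'
#' @param width,height frame size in pixels.
#' @param fps frames per second.
#' @param rois list of [roi()] objects.
#' @param driving named list (by ROI role) of nonnegative driving series,
#'   one value per frame; the blob in each ROI is a bright vertical bar
#'   whose length follows `gain * driving`, so the pixel change between
#'   consecutive frames is proportional to the absolute driving increment.
#' @param gain pixels of bar length per driving unit.
#' @param jitter amplitude (pixels) of uniform random bar-length jitter.
#' @param seed RNG seed for the jitter.
#' @return list of class `video_sim_config`.
#' @export
video_sim_config <- function(width, height, fps, rois, driving,
                             gain = 1, jitter = 0, seed = 1) {
  stopifnot(width > 0, height > 0, fps > 0, gain > 0, jitter >= 0)
  roles <- vapply(rois, `[[`, character(1), "role")
  if (!all(roles %in% names(driving)))
    stop("driving series missing for some ROI roles")
  structure(list(width = width, height = height, fps = fps, rois = rois,
                 driving = driving, gain = gain, jitter = jitter,
                 seed = seed),
            class = "video_sim_config")
}

#' Render a synthetic blob video
#'
#' Each ROI contains a bright vertical bar anchored at the ROI's top-left
#' corner whose length tracks its driving series; pixel changes are confined
#' to the ROIs by construction.  Errors if any bar would exceed its ROI.
#'
#' @param cfg a [video_sim_config()].
#' @return a [frame_sequence()].
#' @export
render_synthetic_video <- function(cfg) {
  stopifnot(inherits(cfg, "video_sim_config"))
  nf <- min(vapply(cfg$driving, length, integer(1)))
  if (nf < 2L) stop("need driving series of length >= 2")
  for (r in cfg$rois) check_roi_bounds(r, cfg$height, cfg$width)
  bar_len <- lapply(cfg$rois, function(r) {
    s <- cfg$driving[[r$role]][seq_len(nf)]
    if (any(s < 0)) stop("driving series must be nonnegative")
    len <- 1L + as.integer(round(cfg$gain * s))
    if (cfg$jitter > 0) {
      len <- len + withr::with_seed(
        derive_seed(cfg$seed, match(r$role, names(cfg$driving))),
        sample.int(2L * as.integer(cfg$jitter) + 1L, nf, replace = TRUE) -
          as.integer(cfg$jitter) - 1L)
      len <- pmax(len, 1L)
    }
    if (max(len) > r$y1 - r$y0)
      stop(sprintf("blob escapes roi '%s': bar length %d exceeds height %d",
                   r$role, max(len), r$y1 - r$y0))
    len
  })
  frames <- lapply(seq_len(nf), function(t) {
    fr <- matrix(0, nrow = cfg$height, ncol = cfg$width)
    for (k in seq_along(cfg$rois)) {
      r <- cfg$rois[[k]]
      bw <- min(4L, r$x1 - r$x0)
      rows <- (r$y0 + 1L):(r$y0 + bar_len[[k]][t])
      cols <- (r$x0 + 1L):(r$x0 + bw)
      fr[rows, cols] <- 255
    }
    fr
  })
  frame_sequence(frames, cfg$fps)
}
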