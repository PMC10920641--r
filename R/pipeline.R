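#' Pipeline orchestration
#'
#' End-to-end orchestration of the analysis stages -- simulate (or ingest),
#' synchronize, featurize, classify, posthoc -- with seeds and provenance
#' recorded next to every output.  Each stage reads the previous stage's
#' files, so stages are individually re-runnable, and identical configs and
#' seeds reproduce outputs byte for byte.  A thin command-line wrapper over
#' these functions ships in `inst/cli/dyadsync.R`.
#'
#' @name pipeline_cli
NULL

# polynomial rolling hash of a JSON-serialized config, for provenance stamps
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_provenance <- function(outdir, stage, config, seed) {
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("dyadsync"))),
    file.path(outdir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Default pipeline configuration
#'
#' @param feature_mode `"MEA"` or `"MEA+DEMO"`.
#' @param labeling `"asd-cc"` (autism group against everyone else) or
#'   `"ndd-cc"` (all neurodevelopmental-disorder groups pooled against the
#'   rest).
#' @param permutations label permutations for significance testing (0 to
#'   skip).
#' @return nested configuration list consumed by [run_pipeline()]; any
#'   element can be overridden before the run, or via a YAML file with the
#'   same structure.
#' @export
default_pipeline_config <- function(feature_mode = "MEA",
                                    labeling = "asd-cc",
                                    permutations = 0) {
  list(
    simulate = list(
      cfg = dyad_sim_config(),
      group_params = list(ASD = list(n = 56, coupling = 0.25),
                          CC = list(n = 38, coupling = 0.45)),
      iq_missing_rate = 0.16),
    synchrony = list(
      sd_scale = TRUE, smooth_sec = 0.5,
      interpersonal = crosscorr_config(),
      intrapersonal = intra_crosscorr_config()),
    features = list(mode = feature_mode),
    classify = list(
      labeling = labeling,
      ndd_groups = c("ASD", "ADHD", "ID", "DD", "Tourette", "PDD-NOS"),
      scheme = cv_scheme(),
      c_grid = default_c_grid(),
      pool = "median",
      permutations = permutations),
    posthoc = list(
      scales = c("ados_css_sa", "ados_css_rrb", "ados_css_total",
                 "adir_a", "adir_b", "adir_c")))
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()]; nested
#' keys override individually.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  # YAML 1.1 would turn bare y/n keys (like the group size field `n`) into
  # booleans; keep the single-letter forms as literal strings
  usr <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE))
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_cfg(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_cfg(default_pipeline_config(), usr)
}

#' Relabel a cohort for a classification contrast
#'
#' `"asd-cc"` keeps the `ASD` group as cases and pools every other group
#' into `CC`; `"ndd-cc"` pools the configured neurodevelopmental groups into
#' `NDD` against `CC`.
#'
#' @param labels diagnostic group per dyad.
#' @param labeling `"asd-cc"` or `"ndd-cc"`.
#' @param ndd_groups groups pooled into the NDD class.
#' @return list with `labels` (binary) and `case_label`.
#' @export
relabel_cohort <- function(labels, labeling = c("asd-cc", "ndd-cc"),
                           ndd_groups = c("ASD", "ADHD", "ID", "DD",
                                          "Tourette", "PDD-NOS")) {
  labeling <- match.arg(labeling)
  labels <- as.character(labels)
  if (labeling == "asd-cc") {
    list(labels = ifelse(labels == "ASD", "ASD", "CC"), case_label = "ASD")
  } else {
    list(labels = ifelse(labels %in% ndd_groups, "NDD", "CC"),
         case_label = "NDD")
  }
}

#' Compute the synchrony artifacts of one dyad
#'
#' Preprocesses the four series and returns the two interpersonal matrices,
#' the participant's intrapersonal matrix, and the four movement quantities
#' (computed on the raw series, before scaling).
#'
#' @param series named list of four [mea_series()] (roles as in
#'   [mea_roles()]).
#' @param sync_cfg the `synchrony` block of the pipeline config.
#' @return list `head_sync`, `body_sync`, `intra`, `movement`.
#' @export
dyad_synchrony <- function(series, sync_cfg = default_pipeline_config()$synchrony) {
  stopifnot(all(mea_roles() %in% names(series)))
  fps <- series_fps(series[[1L]])
  pre <- lapply(series[mea_roles()], preprocess_series,
                sd_scale = sync_cfg$sd_scale, smooth_sec = sync_cfg$smooth_sec)
  list(
    head_sync = windowed_crosslag(pre$participant_head,
                                  pre$administrator_head,
                                  sync_cfg$interpersonal, fps = fps),
    body_sync = windowed_crosslag(pre$participant_body,
                                  pre$administrator_body,
                                  sync_cfg$interpersonal, fps = fps),
    intra = intrapersonal_coordination(pre$participant_head,
                                       pre$participant_body,
                                       sync_cfg$intrapersonal, fps = fps),
    movement = c(
      mq_participant_head = movement_quantity(series$participant_head),
      mq_participant_body = movement_quantity(series$participant_body),
      mq_administrator_head = movement_quantity(series$administrator_head),
      mq_administrator_body = movement_quantity(series$administrator_body)))
}

#' Build the feature table of a cohort
#'
#' Runs [dyad_synchrony()] and [assemble_features()] over every dyad.
#'
#' @param cohort a `synthetic_cohort`, or a list with `series` (named list
#'   of per-dyad series lists) and `metadata`.
#' @param mode `"MEA"` or `"MEA+DEMO"`.
#' @param sync_cfg the `synchrony` block of the pipeline config.
#' @return a [feature_table()].
#' @export
cohort_features <- function(cohort, mode = c("MEA", "MEA+DEMO"),
                            sync_cfg = default_pipeline_config()$synchrony) {
  mode <- match.arg(mode)
  md <- cohort$metadata
  rows <- lapply(as.character(md$dyad_id), function(id) {
    art <- dyad_synchrony(cohort$series[[id]], sync_cfg)
    i <- match(id, md$dyad_id)
    assemble_features(art$head_sync, art$body_sync, art$intra, art$movement,
                      mode = mode,
                      iq = if (mode == "MEA+DEMO") md$iq[i] else NULL,
                      sex = if (mode == "MEA+DEMO") md$sex[i] else NULL)
  })
  names(rows) <- as.character(md$dyad_id)
  feature_table(rows, md, mode)
}

#' Run pipeline stages
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param outdir output directory; stage artifacts and provenance sidecars
#'   are written beneath it.
#' @param stages which stages to run, in order; `"all"` expands to
#'   simulate, synchronize, featurize, classify, posthoc.  An `extract`
#'   stage (not part of `"all"`) instead ingests real data: per-dyad PNG
#'   frame directories under `config$extract$frames_root`, with
#'   `config$extract$fps`, an ROI JSON at `config$extract$roi_file` and an
#'   optional `threshold`, writing the same per-dyad series CSVs the
#'   simulate stage produces (`metadata.csv` is supplied by the user).
#' @param seed global seed; stage seeds are derived from it.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         stages = "all", seed = 1) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (identical(stages, "all"))
    stages <- c("simulate", "synchronize", "featurize", "classify", "posthoc")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("simulate" %in% stages) {
    sim <- config$simulate
    cohort <- simulate_cohort(cfg = sim$cfg, group_params = sim$group_params,
                              iq_missing_rate = sim$iq_missing_rate %||% 0.16,
                              seed = derive_seed(seed, 1L))
    sdir <- file.path(outdir, "series")
    dir.create(sdir, showWarnings = FALSE)
    for (id in names(cohort$series))
      write_mea_csv(cohort$series[[id]], file.path(sdir, paste0(id, ".csv")))
    utils::write.csv(cohort$metadata, file.path(outdir, "metadata.csv"),
                     row.names = FALSE)
    write_provenance(outdir, "simulate", config$simulate, seed)
    res$cohort <- cohort
  }

  if ("extract" %in% stages) {
    ex <- config$extract
    if (is.null(ex$frames_root) || is.null(ex$fps) || is.null(ex$roi_file))
      stop("extract stage needs config$extract$frames_root, $fps and $roi_file")
    rois <- read_roi_json(ex$roi_file)
    sdir <- file.path(outdir, "series")
    dir.create(sdir, showWarnings = FALSE)
    for (dyad_dir in list.dirs(ex$frames_root, recursive = FALSE)) {
      video <- read_frames_png(dyad_dir, ex$fps)
      series <- extract_motion_energy(video, rois,
                                      threshold = ex$threshold %||% 8)
      write_mea_csv(series, file.path(sdir, paste0(basename(dyad_dir), ".csv")),
                    meta = list(threshold = ex$threshold %||% 8,
                                source = basename(dyad_dir)))
    }
    write_provenance(outdir, "extract", ex[c("fps", "threshold")], seed)
  }

  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) cohort <<- res$cohort %||% read_cohort_dir(outdir)
    cohort
  }

  if (any(c("synchronize", "featurize") %in% stages)) {
    cohort <- get_cohort()
    mode <- config$features$mode %||% "MEA"
    ft <- cohort_features(cohort, mode = mode, sync_cfg = config$synchrony)
    if ("synchronize" %in% stages) {
      mdir <- file.path(outdir, "synchrony")
      dir.create(mdir, showWarnings = FALSE)
      for (id in names(cohort$series)) {
        art <- dyad_synchrony(cohort$series[[id]], config$synchrony)
        for (nm in c("head_sync", "body_sync", "intra"))
          write_crosscorr_csv(art[[nm]],
                              file.path(mdir, sprintf("%s_%s.csv", id, nm)))
      }
      write_provenance(outdir, "synchronize", config$synchrony, seed)
    }
    write_feature_csv(ft, file.path(outdir, "features.csv"))
    write_provenance(outdir, "featurize", config[c("synchrony", "features")],
                     seed)
    res$features <- ft
  }

  if ("classify" %in% stages) {
    ft <- res$features %||% read_feature_csv(file.path(outdir, "features.csv"))
    cl <- config$classify
    rl <- relabel_cohort(ft$label, cl$labeling %||% "asd-cc",
                         cl$ndd_groups %||% "ASD")
    ft$label <- rl$labels
    preproc <- infold_preproc_spec(
      impute_k = if ((config$features$mode %||% "MEA") == "MEA+DEMO") 5 else NULL)
    fit <- run_nested_cv(ft, scheme = cl$scheme, c_grid = cl$c_grid,
                         preproc = preproc, case_label = rl$case_label,
                         pool = cl$pool %||% "median",
                         seed = derive_seed(seed, 2L))
    audit_leakage(fit)
    utils::write.csv(fit$pooled, file.path(outdir, "pooled_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fit$metrics[c("tn", "tp", "fn", "fp", "sensitivity",
                                       "specificity", "bac", "accuracy",
                                       "ppv", "npv", "nnd", "plr", "dor",
                                       "auc")],
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    imp <- merge(compute_cvr(fit), sign_consistency(fit), by = "feature",
                 sort = FALSE)
    utils::write.csv(imp, file.path(outdir, "importance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(fit$models, function(m) m[c("id", "perm", "outer_fold",
                                         "inner_fold", "C", "train_ids")]),
      file.path(outdir, "model_manifest.json"), auto_unbox = TRUE, digits = NA)
    if ((cl$permutations %||% 0) > 0) {
      pt <- permutation_test(ft, scheme = cl$scheme, c_grid = cl$c_grid,
                             preproc = preproc, case_label = rl$case_label,
                             B = cl$permutations,
                             seed = derive_seed(seed, 3L), observed = fit)
      jsonlite::write_json(pt[c("observed_bac", "B", "p")],
                           file.path(outdir, "permutation_test.json"),
                           auto_unbox = TRUE, digits = NA)
      res$permutation <- pt
    }
    write_provenance(outdir, "classify", cl, seed)
    res$fit <- fit
  }

  if ("posthoc" %in% stages) {
    fit <- res$fit
    pooled <- if (!is.null(fit)) fit$pooled
              else utils::read.csv(file.path(outdir, "pooled_scores.csv"))
    md <- get_cohort()$metadata
    scales <- intersect(config$posthoc$scales, names(md))
    scores <- pooled$score[match(md$dyad_id, pooled$dyad_id)]
    battery <- pearson_with_fdr(scores, md[scales], scales)
    utils::write.csv(battery, file.path(outdir, "posthoc_correlations.csv"),
                     row.names = FALSE)
    numvars <- intersect(c("age", "iq", scales), names(md))
    rl <- relabel_cohort(md$label, config$classify$labeling %||% "asd-cc",
                         config$classify$ndd_groups %||% "ASD")
    md$label <- rl$labels
    cmp <- group_comparison_table(md, numvars)
    utils::write.csv(cmp, file.path(outdir, "group_comparisons.csv"),
                     row.names = FALSE)
    write_provenance(outdir, "posthoc", config$posthoc, seed)
    res$posthoc <- list(correlations = battery, comparisons = cmp)
  }

  invisible(res)
}

read_cohort_dir <- function(outdir) {
  md <- utils::read.csv(file.path(outdir, "metadata.csv"))
  sdir <- file.path(outdir, "series")
  series <- lapply(as.character(md$dyad_id), function(id)
    read_mea_csv(file.path(sdir, paste0(id, ".csv"))))
  names(series) <- as.character(md$dyad_id)
  list(series = series, metadata = md)
}
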