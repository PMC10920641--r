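#' Repeated nested stratified cross-validated linear SVM
#'
#' The diagnostic classifier is a linear soft-margin (hinge-loss) support
#' vector machine embedded in a repeated, nested, stratified cross-validation
#' scheme: the outer loop (CV2, default 10 folds x 10 repetitions) estimates
#' generalization and produces out-of-sample decision scores, the inner loop
#' (CV1, default 10 folds) tunes the cost parameter C by balanced accuracy.
#' All preprocessing (0-1 scaling, pruning of non-informative features,
#' optional kNN imputation, age residualization) is fitted on training
#' partitions only.  Each held-out dyad collects one decision score per
#' inner model of the winning C in every outer repetition (10 x 10 = 100
#' scores under the default scheme) and is assigned the median as its pooled
#' score.  Class imbalance is corrected by inverse-prevalence hyperplane
#' weighting.
#'
#' @name classifier
NULL

#' Default SVM cost grid
#'
#' Eleven logarithmically spaced values of the soft-margin cost C.
#'
#' @return numeric vector.
#' @export
default_c_grid <- function() {
  c(0.0156, 0.0312, 0.0625, 0.1250, 0.2500, 0.5000, 1, 2, 4, 8, 16)
}

#' Cross-validation scheme
#'
#' @param outer_folds,outer_perms folds and repetitions of the outer (CV2)
#'   loop.
#' @param inner_folds,inner_perms folds and repetitions of the inner (CV1)
#'   loop (only `inner_perms = 1` is implemented).
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(outer_folds = 10, outer_perms = 10,
                      inner_folds = 10, inner_perms = 1) {
  stopifnot(outer_folds >= 2, inner_folds >= 2,
            outer_perms >= 1, inner_perms == 1)
  structure(list(outer_folds = outer_folds, outer_perms = outer_perms,
                 inner_folds = inner_folds, inner_perms = inner_perms),
            class = "cv_scheme")
}

#' In-fold preprocessing specification
#'
#' @param scale01 min-max scale each feature to `[0, 1]` using training
#'   extrema (test values clipped).
#' @param prune drop features that are constant or non-finite on the
#'   training partition.
#' @param impute_k `NULL` for no imputation, otherwise the k for in-fold
#'   [knn_impute()] (demographic mode).
#' @param age_residualize regress each feature on age by least squares on
#'   the training rows and carry the residuals (training coefficients are
#'   applied to test rows).
#' @return list of class `infold_preproc_spec`.
#' @export
infold_preproc_spec <- function(scale01 = TRUE, prune = TRUE,
                                impute_k = NULL, age_residualize = TRUE) {
  structure(list(scale01 = scale01, prune = prune, impute_k = impute_k,
                 age_residualize = age_residualize),
            class = "infold_preproc_spec")
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds so that every fold's class counts are within
#' one sample of an even split of each class, and fold sizes are balanced by
#' placing the leftover members of successive classes at opposite ends of
#' the fold sequence.
#'
#' @param labels class label per sample.
#' @param k number of folds.
#' @param seed RNG seed; identical seeds give identical folds.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(tab)[which.min(tab)], k))
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      idx <- sample(idx)
      n <- length(idx)
      base <- n %/% k
      extra <- n %% k
      sizes <- rep(base, k)
      if (extra > 0L) {
        # alternate which folds absorb the remainder so fold totals balance
        pos <- if (ci %% 2L == 1L) seq_len(extra) else k - seq_len(extra) + 1L
        sizes[pos] <- sizes[pos] + 1L
      }
      fold[idx] <- rep.int(seq_len(k), sizes)
    }
  })
  fold
}

#' Fit the in-fold preprocessor
#'
#' @param x_train numeric feature matrix of the training partition.
#' @param age_train ages of the training rows.
#' @param spec an [infold_preproc_spec()].
#' @return object of class `infold_preprocessor`; apply it with
#'   [apply_preprocessor()].
#' @export
fit_infold_preprocessor <- function(x_train, age_train, spec = infold_preproc_spec()) {
  x_train <- as.matrix(x_train)
  rng <- NULL
  if (spec$scale01) {
    mins <- apply(x_train, 2L, function(v) suppressWarnings(min(v, na.rm = TRUE)))
    maxs <- apply(x_train, 2L, function(v) suppressWarnings(max(v, na.rm = TRUE)))
    rng <- list(min = mins, max = maxs)
    x_train <- scale01_apply(x_train, rng)
  }
  keep <- rep(TRUE, ncol(x_train))
  if (spec$prune) {
    keep <- vapply(seq_len(ncol(x_train)), function(j) {
      v <- x_train[, j]
      obs <- v[!is.na(v)]
      length(obs) > 0L && all(is.finite(obs)) && stats::var(obs) > 0
    }, logical(1))
    if (!any(keep)) stop("all features pruned on this training partition")
    x_train <- x_train[, keep, drop = FALSE]
  }
  if (!is.null(spec$impute_k) && anyNA(x_train))
    x_train <- knn_impute(x_train, k = spec$impute_k)
  age_coefs <- NULL
  if (spec$age_residualize) {
    age_coefs <- vapply(seq_len(ncol(x_train)), function(j) {
      stats::coef(stats::lm.fit(cbind(1, age_train), x_train[, j]))
    }, numeric(2))
  }
  structure(list(spec = spec, rng = rng, keep = keep,
                 donors = x_train, age_coefs = age_coefs,
                 colnames = colnames(x_train)),
            class = "infold_preprocessor")
}

scale01_apply <- function(x, rng) {
  den <- rng$max - rng$min
  den[!is.finite(den) | den == 0] <- 1
  out <- sweep(sweep(x, 2L, rng$min), 2L, den, "/")
  pmin(pmax(out, 0), 1)
}

#' @param pp an `infold_preprocessor`.
#' @param x feature matrix (training or test rows).
#' @param age ages of the rows of `x`.
#' @rdname fit_infold_preprocessor
#' @export
apply_preprocessor <- function(pp, x, age) {
  x <- as.matrix(x)
  if (!is.null(pp$rng)) x <- scale01_apply(x, pp$rng)
  x <- x[, pp$keep, drop = FALSE]
  if (!is.null(pp$spec$impute_k) && anyNA(x)) {
    combined <- rbind(pp$donors, x)
    fit_rows <- seq_len(nrow(pp$donors))
    combined <- knn_impute(combined, k = pp$spec$impute_k, fit_rows = fit_rows)
    x <- combined[-fit_rows, , drop = FALSE]
  }
  if (!is.null(pp$age_coefs)) {
    pred <- cbind(1, age) %*% pp$age_coefs
    x <- x - pred
  }
  x
}

#' Train a class-weighted linear SVM
#'
#' Thin wrapper around the LIBSVM C-classification solver
#' ([e1071::svm()]) with a linear kernel and per-class misclassification
#' weights.  The default weights `N / (2 n_c)` equalize the aggregate loss
#' of the two classes (inverse prevalence).  The returned decision function
#' `w . x + b` is oriented so that positive scores indicate `case_label`.
#'
#' @param x numeric feature matrix.
#' @param y class labels (exactly two classes present).
#' @param C soft-margin cost.
#' @param case_label label treated as the positive class.
#' @param class_weights named vector of per-class weights; `NULL` for
#'   inverse prevalence.
#' @param tolerance solver termination tolerance.
#' @return list of class `linear_svm` with elements `w`, `b`, `case_label`,
#'   `other_label`.
#' @export
train_weighted_linear_svm <- function(x, y, C = 1, case_label = NULL,
                                      class_weights = NULL,
                                      tolerance = 1e-6) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) stop("need exactly 2 classes in y")
  case_label <- case_label %||% sort(classes)[1L]
  other_label <- setdiff(classes, case_label)
  if (is.null(class_weights)) {
    n <- length(y)
    class_weights <- stats::setNames(
      n / (2 * c(sum(y == case_label), sum(y == other_label))),
      c(case_label, other_label))
  }
  yf <- factor(y, levels = c(case_label, other_label))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = class_weights, tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function toward the class seen first in the
  # data; flip so positive always means case_label
  first_seen <- y[1L]
  if (first_seen != case_label) {
    w <- -w
    b <- -b
  }
  structure(list(w = stats::setNames(w, colnames(x)), b = b,
                 case_label = case_label, other_label = other_label),
            class = "linear_svm")
}

#' @param object a `linear_svm`.
#' @param newdata feature matrix.
#' @param type `"score"` for decision values, `"label"` for predicted labels.
#' @param ... unused.
#' @rdname train_weighted_linear_svm
#' @export
predict.linear_svm <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  s <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "score") s
  else ifelse(s > 0, object$case_label, object$other_label)
}

#' Confusion-derived classification metrics
#'
#' @param tn,tp,fn,fp confusion counts (cases are the positive class).
#' @return list of class `performance_metrics`: `sensitivity`,
#'   `specificity`, `bac`, `accuracy`, `ppv`, `npv`, `nnd` (number needed to
#'   diagnose, `1/(sens + spec - 1)`), `plr` (positive likelihood ratio,
#'   `sens/(1 - spec)`), `dor` (diagnostic odds ratio, `tp*tn/(fn*fp)`).
#'   Ratios with vanishing denominators are returned as `NA` with a
#'   `degenerate` flag.
#' @export
classification_metrics <- function(tn, tp, fn, fp) {
  counts <- c(tn = tn, tp = tp, fn = fn, fp = fp)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid confusion counts")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  bac <- (sens + spec) / 2
  youden <- sens + spec - 1
  out <- list(
    tn = tn, tp = tp, fn = fn, fp = fp,
    sensitivity = sens, specificity = spec, bac = bac,
    accuracy = (tp + tn) / sum(counts),
    ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
    nnd = if (is.na(youden) || youden == 0) NA_real_ else 1 / youden,
    plr = if (is.na(spec) || spec == 1) NA_real_ else sens / (1 - spec),
    dor = if (fn == 0 || fp == 0) NA_real_ else (tp * tn) / (fn * fp))
  out$degenerate <- any(vapply(out[c("sensitivity", "specificity", "nnd", "plr")],
                               is.na, logical(1)))
  class(out) <- "performance_metrics"
  out
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(paste0("BAC %.1f%%  sens %.1f%%  spec %.1f%%  acc %.1f%%\n",
                     "TN %d TP %d FN %d FP %d  NND %.1f  PLR %.1f\n"),
              100 * x$bac, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy, x$tn, x$tp, x$fn, x$fp, x$nnd, x$plr))
  invisible(x)
}

bac_of_predictions <- function(truth, predicted, case_label) {
  tp <- sum(truth == case_label & predicted == case_label)
  fn <- sum(truth == case_label & predicted != case_label)
  tn <- sum(truth != case_label & predicted != case_label)
  fp <- sum(truth != case_label & predicted == case_label)
  s1 <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  s0 <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  (s1 + s0) / 2
}

#' Run the repeated nested stratified cross-validation
#'
#' For every outer repetition and outer fold, an inner stratified
#' cross-validation grid search selects the cost C maximizing the mean
#' inner-validation balanced accuracy (ties go to the smallest C, i.e. the
#' strongest regularization).  The inner models refit with the winning C
#' then score the held-out outer fold, so each dyad accumulates
#' `outer_perms x inner_folds` decision scores from models that never saw it
#' during training or tuning.  The pooled per-dyad score is their median
#' (optionally mean) and drives predicted labels and performance metrics.
#'
#' @param tab a `feature_table` (see [feature_table()]).
#' @param scheme a [cv_scheme()].
#' @param c_grid cost grid, see [default_c_grid()].
#' @param preproc an [infold_preproc_spec()].
#' @param case_label positive-class label; defaults to the rarer group's
#'   complement being negative -- explicitly: the first of
#'   `sort(unique(labels))`.
#' @param pool `"median"` or `"mean"` pooling of per-dyad scores.
#' @param seed RNG seed governing all fold plans.
#' @return list of class `nested_cv_result`: `pooled` (data.frame dyad_id,
#'   score, predicted, truth), `scores` (long data.frame of raw scores with
#'   model ids), `models` (per-model weights, bias, C and training dyad
#'   ids), `selected_c`, `metrics` (a `performance_metrics` with `auc`
#'   added), `scheme`, `seed`.
#' @export
run_nested_cv <- function(tab, scheme = cv_scheme(),
                          c_grid = default_c_grid(),
                          preproc = infold_preproc_spec(),
                          case_label = NULL, pool = c("median", "mean"),
                          seed = 1) {
  pool <- match.arg(pool)
  fc <- feature_cols_of(tab)
  x_all <- as.matrix(as.data.frame(tab)[fc])
  storage.mode(x_all) <- "double"
  labels <- as.character(tab$label)
  age <- as.numeric(tab$age)
  ids <- as.character(tab$dyad_id)
  case_label <- case_label %||% sort(unique(labels))[1L]
  n <- nrow(x_all)

  models <- list()
  score_rows <- list()
  sel_rows <- list()
  model_id <- 0L

  for (perm in seq_len(scheme$outer_perms)) {
    outer_fold <- make_stratified_folds(labels, scheme$outer_folds,
                                        seed = derive_seed(seed, perm))
    for (f in seq_len(scheme$outer_folds)) {
      test_idx <- which(outer_fold == f)
      train_idx <- which(outer_fold != f)
      inner_fold <- make_stratified_folds(
        labels[train_idx], scheme$inner_folds,
        seed = derive_seed(seed, perm * 1000L + f))

      # grid search: mean inner-validation BAC per C
      inner_bac <- matrix(NA_real_, nrow = scheme$inner_folds,
                          ncol = length(c_grid))
      pps <- vector("list", scheme$inner_folds)
      for (g in seq_len(scheme$inner_folds)) {
        fit_idx <- train_idx[inner_fold != g]
        val_idx <- train_idx[inner_fold == g]
        pp <- fit_infold_preprocessor(x_all[fit_idx, , drop = FALSE],
                                      age[fit_idx], preproc)
        pps[[g]] <- list(pp = pp, fit_idx = fit_idx)
        x_fit <- apply_preprocessor(pp, x_all[fit_idx, , drop = FALSE], age[fit_idx])
        x_val <- apply_preprocessor(pp, x_all[val_idx, , drop = FALSE], age[val_idx])
        for (ci in seq_along(c_grid)) {
          mdl <- train_weighted_linear_svm(x_fit, labels[fit_idx],
                                           C = c_grid[ci],
                                           case_label = case_label)
          pred <- predict(mdl, x_val, type = "label")
          inner_bac[g, ci] <- bac_of_predictions(labels[val_idx], pred, case_label)
        }
      }
      mean_bac <- colMeans(inner_bac, na.rm = TRUE)
      best_c <- c_grid[which.max(mean_bac)]  # which.max takes the first (smallest C) maximum
      sel_rows[[length(sel_rows) + 1L]] <-
        data.frame(perm = perm, outer_fold = f, C = best_c)

      # winning inner models score the held-out outer fold
      for (g in seq_len(scheme$inner_folds)) {
        fit_idx <- pps[[g]]$fit_idx
        pp <- pps[[g]]$pp
        x_fit <- apply_preprocessor(pp, x_all[fit_idx, , drop = FALSE], age[fit_idx])
        mdl <- train_weighted_linear_svm(x_fit, labels[fit_idx], C = best_c,
                                         case_label = case_label)
        x_test <- apply_preprocessor(pp, x_all[test_idx, , drop = FALSE], age[test_idx])
        s <- predict(mdl, x_test, type = "score")
        model_id <- model_id + 1L
        w_full <- stats::setNames(rep(NA_real_, length(fc)), fc)
        w_full[names(mdl$w)] <- mdl$w
        models[[model_id]] <- list(
          id = model_id, perm = perm, outer_fold = f, inner_fold = g,
          C = best_c, weights = w_full, bias = mdl$b,
          train_ids = ids[fit_idx])
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          dyad_id = ids[test_idx], perm = perm, outer_fold = f,
          inner_fold = g, model_id = model_id, score = s)
      }
    }
  }

  scores <- do.call(rbind, score_rows)
  pool_fun <- if (pool == "median") stats::median else mean
  pooled_score <- tapply(scores$score, scores$dyad_id, pool_fun)
  pooled <- data.frame(
    dyad_id = ids,
    score = as.numeric(pooled_score[ids]),
    truth = labels, stringsAsFactors = FALSE)
  pooled$predicted <- ifelse(pooled$score > 0, case_label,
                             setdiff(unique(labels), case_label)[1L])
  tp <- sum(pooled$truth == case_label & pooled$predicted == case_label)
  fn <- sum(pooled$truth == case_label & pooled$predicted != case_label)
  tn <- sum(pooled$truth != case_label & pooled$predicted != case_label)
  fp <- sum(pooled$truth != case_label & pooled$predicted == case_label)
  metrics <- classification_metrics(tn, tp, fn, fp)
  metrics$auc <- auc_rank(pooled$score, pooled$truth, case_label)

  structure(list(pooled = pooled, scores = scores, models = models,
                 selected_c = do.call(rbind, sel_rows), metrics = metrics,
                 case_label = case_label, scheme = scheme, seed = seed,
                 feature_cols = fc),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d dyads, %d models, case = %s\n",
              nrow(x$pooled), length(x$models), x$case_label))
  print(x$metrics)
  invisible(x)
}

#' Audit strict train/test separation
#'
#' Verifies, from the recorded bookkeeping, that no pooled score was
#' produced by a model whose training rows contained the scored dyad.
#'
#' @param fit a `nested_cv_result`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_leakage <- function(fit) {
  train_sets <- lapply(fit$models, `[[`, "train_ids")
  bad <- mapply(function(dyad, mid) dyad %in% train_sets[[mid]],
                fit$scores$dyad_id, fit$scores$model_id)
  if (any(bad)) stop(sprintf("leakage: %d scores from models trained on the scored dyad",
                             sum(bad)))
  invisible(TRUE)
}

#' Label-permutation significance test
#'
#' Reruns the full nested cross-validation `B` times with the diagnostic
#' labels randomly permuted; the p-value is
#' `(1 + #\{BAC_perm >= BAC_obs\}) / (B + 1)`.  Each permutation regenerates
#' its fold plans from a derived seed.
#'
#' @inheritParams run_nested_cv
#' @param B number of permutations.
#' @param observed optional precomputed `nested_cv_result` for the observed
#'   labels (avoids refitting).
#' @return list of class `permutation_test_result`: `observed_bac`,
#'   `permuted_bac` (length `B`), `p`.
#' @export
permutation_test <- function(tab, scheme = cv_scheme(),
                             c_grid = default_c_grid(),
                             preproc = infold_preproc_spec(),
                             case_label = NULL, B = 1000, seed = 1,
                             observed = NULL) {
  stopifnot(B >= 1)
  if (is.null(observed))
    observed <- run_nested_cv(tab, scheme, c_grid, preproc, case_label,
                              seed = seed)
  obs_bac <- observed$metrics$bac
  perm_bac <- vapply(seq_len(B), function(b) {
    tab_b <- tab
    tab_b$label <- withr::with_seed(derive_seed(seed, 70000L + b),
                                    sample(as.character(tab$label)))
    fit_b <- run_nested_cv(tab_b, scheme, c_grid, preproc,
                           case_label = observed$case_label,
                           seed = derive_seed(seed, 80000L + b))
    fit_b$metrics$bac
  }, numeric(1))
  structure(list(observed_bac = obs_bac, permuted_bac = perm_bac,
                 B = B, p = (1 + sum(perm_bac >= obs_bac)) / (B + 1)),
            class = "permutation_test_result")
}

#' Cross-validation ratio of feature weights
#'
#' Pattern-stability score per feature: within each outer (CV2) fold the
#' median of the inner (CV1) model weights is divided by their standard
#' error, and these ratios are summed over CV2 folds and divided by the
#' number of CV2 folds.  Features pruned in some models are summarized over
#' the models that retained them; a fold with zero standard error
#' contributes a capped ratio and raises the `capped` flag.
#'
#' @param fit a `nested_cv_result`.
#' @param cap magnitude used in place of an infinite median/SE ratio.
#' @return data.frame: `feature`, `cvr`, `n_models` (models retaining the
#'   feature), `capped`.
#' @export
compute_cvr <- function(fit, cap = 1e6) {
  fc <- fit$feature_cols
  wmat <- do.call(rbind, lapply(fit$models, `[[`, "weights"))
  fold_key <- paste(vapply(fit$models, `[[`, numeric(1), "perm"),
                    vapply(fit$models, `[[`, numeric(1), "outer_fold"))
  folds <- unique(fold_key)
  out <- lapply(fc, function(j) {
    ratios <- vapply(folds, function(fk) {
      w <- wmat[fold_key == fk, j]
      w <- w[!is.na(w)]
      if (length(w) < 2L) return(NA_real_)
      med <- stats::median(w)
      se <- stats::sd(w) / sqrt(length(w))
      if (se == 0) sign(med) * cap else med / se
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    data.frame(feature = j,
               cvr = if (length(ratios) == 0L) NA_real_
                     else sum(ratios) / length(folds),
               n_models = sum(!is.na(wmat[, j])),
               capped = any(abs(ratios) >= cap))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sign-based consistency of feature weights
#'
#' For each feature, tests whether the sign of its weight agrees across all
#' models in the ensemble more often than a fair coin (two-sided exact
#' binomial test of the positive-weight count against 0.5).  Reported as
#' `-log10(p)` -- values >= 1.3 correspond to p <= 0.05 -- with
#' Benjamini-Hochberg false-discovery-rate flags at `alpha`.
#'
#' @param fit a `nested_cv_result`.
#' @param alpha FDR level for the significance flags.
#' @return data.frame: `feature`, `n_pos`, `n_models`, `p`, `neg_log10_p`,
#'   `fdr_significant`.
#' @export
sign_consistency <- function(fit, alpha = 0.05) {
  fc <- fit$feature_cols
  wmat <- do.call(rbind, lapply(fit$models, `[[`, "weights"))
  rows <- lapply(fc, function(j) {
    w <- wmat[, j]
    w <- w[!is.na(w)]
    if (length(w) < 2L)
      return(data.frame(feature = j, n_pos = NA_integer_,
                        n_models = length(w), p = NA_real_))
    p <- stats::binom.test(sum(w > 0), length(w), p = 0.5)$p.value
    data.frame(feature = j, n_pos = sum(w > 0), n_models = length(w), p = p)
  })
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(out$p)
  out$fdr_significant <- !is.na(out$p) &
    stats::p.adjust(out$p, method = "BH") <= alpha
  rownames(out) <- NULL
  out
}
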