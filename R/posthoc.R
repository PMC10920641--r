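#' Group comparisons and clinical association statistics
#'
#' Demographic and clinical group differences are assessed with Welch's
#' t-test for unequal variances computed from group summary statistics
#' (n, mean, sd), with Cohen's d effect sizes and Bonferroni-Holm adjustment
#' across a test family.  Sex-by-group independence uses the
#' continuity-corrected chi-square test.  Associations between pooled SVM
#' decision scores and clinical scales (ADOS-2 calibrated severity scores,
#' ADI-R domain scores) use Pearson correlations with Benjamini-Hochberg
#' false-discovery-rate correction across the battery.
#'
#' @name posthoc_stats
NULL

#' Group summary
#'
#' @param n group size (>= 2).
#' @param mean,sd group mean and standard deviation.
#' @return list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch's t-test from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return list of class `welch_result`: `t`, `df`, `p`.
#' @export
welch_t <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  se2 <- v1 + v2
  if (se2 == 0) stop("zero pooled standard error")
  t <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df)),
            class = "welch_result")
}

#' Cohen's d from group summaries
#'
#' Default standardizer is the unweighted root mean of the two variances,
#' `sqrt((s1^2 + s2^2)/2)`; `pooling = "n_weighted"` uses the
#' sample-size-weighted pooled standard deviation instead.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param pooling `"unweighted"` (default) or `"n_weighted"`.
#' @return numeric effect size.
#' @export
cohens_d <- function(g1, g2, pooling = c("unweighted", "n_weighted")) {
  pooling <- match.arg(pooling)
  s <- if (pooling == "unweighted") {
    sqrt((g1$sd^2 + g2$sd^2) / 2)
  } else {
    sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
  }
  if (s == 0) stop("zero pooled standard deviation")
  (g1$mean - g2$mean) / s
}

#' Continuity-corrected chi-square test of independence
#'
#' Yates-corrected chi-square for a 2x2 contingency table (e.g. diagnostic
#' group by sex).
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return list: `chisq`, `df` (1), `p`.
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson correlations of decision scores with clinical scales
#'
#' One correlation per scale using pairwise-complete observations (rows with
#' a missing scale value are dropped for that scale only), with
#' Benjamini-Hochberg q-values across the battery.
#'
#' @param scores pooled decision scores, one per dyad.
#' @param clinical data.frame of clinical scale columns aligned with
#'   `scores` (missing values allowed).
#' @param scales which columns of `clinical` to test (default: all).
#' @return data.frame: `scale`, `n`, `r`, `p`, `q`.
#' @export
pearson_with_fdr <- function(scores, clinical, scales = names(clinical)) {
  rows <- lapply(scales, function(sc) {
    y <- clinical[[sc]]
    ok <- is.finite(scores) & is.finite(y)
    if (sum(ok) < 3L) stop(sprintf("scale '%s' has < 3 complete pairs", sc))
    if (stats::sd(scores[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop(sprintf("constant input for scale '%s'", sc))
    ct <- stats::cor.test(scores[ok], y[ok], method = "pearson")
    data.frame(scale = sc, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction of a p-value family (monotone, capped at 1).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Welch comparison table for a cohort
#'
#' Convenience wrapper producing the per-variable group-difference table
#' (Welch t, df, raw and Holm-adjusted p, Cohen's d) between two groups of a
#' cohort metadata table.
#'
#' @param metadata data.frame with a `label` column and the variables.
#' @param variables character vector of numeric column names to compare.
#' @param groups length-2 character vector; first entry is group 1.
#' @return data.frame with one row per variable.
#' @export
group_comparison_table <- function(metadata, variables,
                                   groups = sort(unique(metadata$label))) {
  stopifnot(length(groups) == 2L)
  rows <- lapply(variables, function(v) {
    x1 <- metadata[[v]][metadata$label == groups[1L]]
    x2 <- metadata[[v]][metadata$label == groups[2L]]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    g1 <- group_summary(length(x1), mean(x1), stats::sd(x1))
    g2 <- group_summary(length(x2), mean(x2), stats::sd(x2))
    wt <- welch_t(g1, g2)
    data.frame(variable = v, n1 = g1$n, mean1 = g1$mean, sd1 = g1$sd,
               n2 = g2$n, mean2 = g2$mean, sd2 = g2$sd,
               t = wt$t, df = wt$df, p = wt$p, d = cohens_d(g1, g2))
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}
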