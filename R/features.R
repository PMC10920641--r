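#' Summary-statistic feature engineering
#'
#' Because interview clips differ in length and content, each synchrony
#' matrix is reduced to seven order-free summary statistics (minimum,
#' maximum, mean, median, standard deviation, skew, kurtosis) over all
#' non-missing entries pooled across windows and lags.  Together with the
#' four movement-quantity fractions this gives the fixed 25-feature vector
#' per dyad; a demographic variant appends IQ and sex (27 features).  Age is
#' carried as a covariate only -- it is regressed out in-fold by the
#' classifier and never enters the feature set.
#'
#' @name features
NULL

#' Summary statistics of a synchrony matrix
#'
#' Skew is the adjusted Fisher-Pearson sample skewness (`e1071::skewness`,
#' type 2); kurtosis is moment-based Fisher excess kurtosis
#' (`e1071::kurtosis`, type 1).  Only rank order matters to the downstream
#' linear classifier, so the convention choice is immaterial up to monotone
#' transformation; it is recorded here for reproducibility.
#'
#' @param m a `crosscorr_matrix` (or any numeric array); `NA` entries are
#'   dropped.
#' @return named numeric vector `min, max, mean, median, sd, skew, kurtosis`.
#'   On constant input `sd` is 0 and skew/kurtosis are non-finite; such
#'   columns are pruned in-fold by the classifier.
#' @export
summarize_matrix <- function(m) {
  v <- as.vector(as.matrix(m))
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 valid entries")
  c(min = min(v), max = max(v), mean = mean(v), median = stats::median(v),
    sd = stats::sd(v),
    skew = suppressWarnings(e1071::skewness(v, type = 2)),
    kurtosis = suppressWarnings(e1071::kurtosis(v, type = 1)))
}

#' Fixed feature column order
#'
#' @param mode `"MEA"` (25 behavioral features) or `"MEA+DEMO"` (adds `iq`
#'   and `sex`, 27).
#' @return character vector of feature column names in canonical order.
#' @export
feature_columns <- function(mode = c("MEA", "MEA+DEMO")) {
  mode <- match.arg(mode)
  stats7 <- c("min", "max", "mean", "median", "sd", "skew", "kurtosis")
  cols <- c(paste0("head_sync_", stats7),
            paste0("body_sync_", stats7),
            paste0("intra_", stats7),
            "mq_participant_head", "mq_participant_body",
            "mq_administrator_head", "mq_administrator_body")
  if (mode == "MEA+DEMO") cols <- c(cols, "iq", "sex")
  cols
}

#' Assemble the per-dyad feature vector
#'
#' @param head_sync interpersonal head synchrony `crosscorr_matrix`.
#' @param body_sync interpersonal body synchrony `crosscorr_matrix`.
#' @param intra participant head-body coordination `crosscorr_matrix`.
#' @param movement named numeric vector of the four movement quantities
#'   (`mq_participant_head`, `mq_participant_body`, `mq_administrator_head`,
#'   `mq_administrator_body`), each in `[0, 1]`.
#' @param mode `"MEA"` or `"MEA+DEMO"`.
#' @param iq participant IQ (may be `NA`; imputed in-fold); required slot in
#'   DEMO mode.
#' @param sex participant sex coded 0/1 (mapping recorded by the caller);
#'   required and non-missing in DEMO mode.
#' @return named numeric feature vector in [feature_columns()] order (25 or
#'   27 values).
#' @export
assemble_features <- function(head_sync, body_sync, intra, movement,
                              mode = c("MEA", "MEA+DEMO"),
                              iq = NULL, sex = NULL) {
  mode <- match.arg(mode)
  mq_names <- c("mq_participant_head", "mq_participant_body",
                "mq_administrator_head", "mq_administrator_body")
  if (!all(mq_names %in% names(movement)))
    stop("movement must contain: ", paste(mq_names, collapse = ", "))
  mq <- movement[mq_names]
  if (any(mq < 0 | mq > 1, na.rm = TRUE))
    stop("movement quantities must lie in [0, 1]")
  hs <- summarize_matrix(head_sync)
  bs <- summarize_matrix(body_sync)
  is <- summarize_matrix(intra)
  v <- c(stats::setNames(hs, paste0("head_sync_", names(hs))),
         stats::setNames(bs, paste0("body_sync_", names(bs))),
         stats::setNames(is, paste0("intra_", names(is))),
         mq)
  if (mode == "MEA+DEMO") {
    if (is.null(sex) || is.na(sex)) stop("DEMO mode requires non-missing sex")
    v <- c(v, iq = if (is.null(iq)) NA_real_ else as.numeric(iq),
           sex = as.numeric(sex))
  }
  v[feature_columns(mode)]
}

#' Build a feature table for a cohort
#'
#' @param rows named list (by dyad id) of feature vectors from
#'   [assemble_features()].
#' @param metadata data.frame with one row per dyad: `dyad_id`, `label`
#'   (diagnostic group) and `age` (covariate).
#' @param mode feature mode used to build the rows.
#' @return data.frame of class `feature_table`: metadata columns followed by
#'   the feature columns; the feature column names are stored in the
#'   `feature_cols` attribute.
#' @export
feature_table <- function(rows, metadata, mode = c("MEA", "MEA+DEMO")) {
  mode <- match.arg(mode)
  cols <- feature_columns(mode)
  stopifnot(all(c("dyad_id", "label", "age") %in% names(metadata)))
  mat <- do.call(rbind, rows[as.character(metadata$dyad_id)])
  if (!identical(colnames(mat), cols)) stop("feature rows out of order")
  out <- cbind(metadata[c("dyad_id", "label", "age")],
               as.data.frame(mat, row.names = NULL))
  rownames(out) <- NULL
  attr(out, "feature_cols") <- cols
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_cols_of <- function(tab) {
  attr(tab, "feature_cols") %||%
    setdiff(names(tab), c("dyad_id", "label", "age"))
}

#' Read and write feature tables as CSV
#'
#' @param tab a `feature_table`.
#' @param path CSV file path; a JSON sidecar (`<path>.json`) records the
#'   feature columns and statistic conventions.
#' @return [read_feature_csv()] returns a `feature_table`.
#' @export
write_feature_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  jsonlite::write_json(
    list(feature_cols = feature_cols_of(tab),
         skew = "adjusted Fisher-Pearson (type 2)",
         kurtosis = "Fisher excess (type 1)"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  side_path <- paste0(path, ".json")
  fc <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE)$feature_cols
  else setdiff(names(out), c("dyad_id", "label", "age"))
  attr(out, "feature_cols") <- fc
  class(out) <- c("feature_table", "data.frame")
  out
}

#' k-nearest-neighbor imputation
#'
#' Replaces each missing value by the mean of the `k` nearest donor rows in
#' Euclidean distance computed over the fully observed columns.  Donors are
#' restricted to `fit_rows` so the classifier can call this in-fold without
#' leaking test information.
#'
#' @param x numeric matrix or data.frame of features (missingness is expected
#'   to be confined to few columns, e.g. IQ).
#' @param k number of neighbors (default 5).
#' @param fit_rows integer indices of rows that may serve as donors
#'   (default: all rows).
#' @return object of the same shape with missing values filled in.
#' @export
knn_impute <- function(x, k = 5, fit_rows = seq_len(nrow(x))) {
  xm <- as.matrix(x)
  if (!anyNA(xm)) return(x)
  complete_cols <- which(colSums(is.na(xm)) == 0L)
  if (length(complete_cols) == 0L) stop("no fully observed columns for distances")
  miss <- which(is.na(xm), arr.ind = TRUE)
  for (i in seq_len(nrow(miss))) {
    r <- miss[i, 1L]; cl <- miss[i, 2L]
    donors <- setdiff(fit_rows[!is.na(xm[fit_rows, cl])], r)
    if (length(donors) < k)
      stop(sprintf("k = %d exceeds the %d available donors", k, length(donors)))
    d2 <- colSums((t(xm[donors, complete_cols, drop = FALSE]) -
                     xm[r, complete_cols])^2)
    nn <- donors[order(d2)[seq_len(k)]]
    xm[r, cl] <- mean(xm[nn, cl])
  }
  if (is.data.frame(x)) {
    x[] <- as.data.frame(xm)
    x
  } else xm
}
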