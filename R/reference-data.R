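#' Bundled reference tables
#'
#' Group-level summary tables from a clinical study of 94 ADOS-2
#' patient-administrator dyads (56 autism, 38 clinical controls), bundled as
#' worked-example inputs: per-module demographic and clinical group
#' summaries (n, mean, sd), the sex-by-group contingency counts, and the
#' pooled confusion counts of the two published synchrony classifiers.  No
#' individual-level data are included.
#'
#' @param which one of `"group_summaries"`, `"sex_by_group"`,
#'   `"confusion_counts"`.
#' @return data.frame.
#' @export
reference_table <- function(which = c("group_summaries", "sex_by_group",
                                      "confusion_counts")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "dyadsync", mustWork = TRUE)
  utils::read.csv(path)
}
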