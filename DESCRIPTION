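Package: dyadsync
Title: Interpersonal Motion Synchrony Analysis and Diagnostic
    Classification for Dyadic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying interpersonal motor synchrony in
    videotaped dyadic interactions and for diagnostic classification
    from synchrony features.  Implements frame-differencing motion
    energy extraction over regions of interest, windowed cross-lagged
    correlation with absolute Fisher-Z synchrony matrices, surrogate
    pseudodyad null distributions, summary-statistic feature
    engineering, repeated nested stratified cross-validated linear
    support vector machine classification with permutation inference
    and sign-based feature stability, post-hoc clinical association
    statistics, and a synthetic dyad generator with group-dependent
    lagged coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
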