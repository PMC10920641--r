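test_that("stratified folds balance class counts within one sample", {
  labs <- rep(c("ASD", "CC"), each = 50)
  f <- make_stratified_folds(labs, 10, seed = 1)
  tab <- table(f, labs)
  expect_true(all(tab == 5))

  labs <- rep(c("ASD", "CC"), c(56, 38))
  f <- make_stratified_folds(labs, 10, seed = 2)
  tab <- table(f, labs)
  expect_true(all(tab[, "ASD"] %in% 5:6))
  expect_true(all(tab[, "CC"] %in% 3:4))
  expect_true(all(rowSums(tab) %in% 9:10))

  expect_identical(make_stratified_folds(labs, 10, seed = 7),
                   make_stratified_folds(labs, 10, seed = 7))
  expect_false(identical(make_stratified_folds(labs, 10, seed = 7),
                         make_stratified_folds(labs, 10, seed = 8)))
  expect_error(make_stratified_folds(rep(c("a", "b"), c(5, 40)), 10),
               "fewer than")
})

test_that("in-fold preprocessing scales, prunes and residualizes age", {
  withr::with_seed(31, {
    n <- 80
    age <- runif(n, 6, 20)
    x <- cbind(f1 = rnorm(n), f2 = 2 * age + rnorm(n), f3 = rep(1, n))
    tr <- 1:60; te <- 61:80
    pp <- fit_infold_preprocessor(x[tr, ], age[tr])
    expect_identical(pp$colnames, c("f1", "f2"))  # constant column pruned
    xt <- apply_preprocessor(pp, x[tr, ], age[tr])
    xe <- apply_preprocessor(pp, x[te, ], age[te])
    expect_equal(ncol(xe), 2)
    # training residuals decorrelated from age
    expect_lt(abs(cor(xt[, "f2"], age[tr])), 0.05)
    expect_lt(abs(cor(xt[, "f1"], age[tr])), 0.05)
    # scaling alone maps training data into [0,1] and clips test data
    pp01 <- fit_infold_preprocessor(x[tr, 1:2], age[tr],
                                    infold_preproc_spec(age_residualize = FALSE))
    x01 <- apply_preprocessor(pp01, x[tr, 1:2], age[tr])
    expect_true(all(x01 >= 0 & x01 <= 1))
    expect_equal(range(x01[, 1]), c(0, 1))
    xe01 <- apply_preprocessor(pp01, x[te, 1:2] + 100, age[te])
    expect_true(all(xe01 <= 1))
    expect_error(fit_infold_preprocessor(x[, 3, drop = FALSE], age),
                 "pruned")
  })
})

test_that("weighted linear SVM separates, orients scores and honors weights", {
  withr::with_seed(41, {
    x <- matrix(c(rnorm(15, -1, 0.2), rnorm(15, 1, 0.2)), ncol = 1)
    y <- rep(c("CC", "ASD"), each = 15)
    m <- train_weighted_linear_svm(x, y, C = 100, case_label = "ASD")
    s <- predict(m, x, type = "score")
    expect_true(all(s[y == "ASD"] > 0))
    expect_true(all(s[y == "CC"] < 0))
    expect_identical(predict(m, x, type = "label"),
                     ifelse(s > 0, "ASD", "CC"))

    # with no active slack the optimum is unchanged by duplicating the data
    m2 <- train_weighted_linear_svm(rbind(x, x), c(y, y), C = 100,
                                    case_label = "ASD")
    expect_equal(m$w, m2$w, tolerance = 1e-6)
    expect_equal(m$b, m2$b, tolerance = 1e-6)

    # upweighting the minority class cannot reduce minority recall
    x2 <- matrix(c(rnorm(40, 0, 1), rnorm(8, 1, 1)), ncol = 1)
    y2 <- rep(c("CC", "ASD"), c(40, 8))
    base_w <- c(ASD = 1, CC = 1)
    rec <- function(wts) {
      mm <- train_weighted_linear_svm(x2, y2, C = 1, case_label = "ASD",
                                      class_weights = wts)
      mean(predict(mm, x2, type = "label")[y2 == "ASD"] == "ASD")
    }
    expect_gte(rec(c(ASD = 2, CC = 1)), rec(base_w))
    expect_error(train_weighted_linear_svm(x, rep("ASD", 30)), "2 classes")
  })
})

test_that("confusion metrics satisfy their defining identities", {
  perfect <- classification_metrics(tn = 20, tp = 30, fn = 0, fp = 0)
  expect_equal(perfect$bac, 1)
  expect_equal(perfect$nnd, 1)
  one_class <- classification_metrics(tn = 0, tp = 30, fn = 0, fp = 20)
  expect_equal(one_class$bac, 0.5)
  expect_equal(one_class$plr, 1)        # sens 1 over (1 - spec 0)
  expect_true(is.na(one_class$nnd))     # Youden index is zero
  expect_true(one_class$degenerate)
  m <- classification_metrics(tn = 7, tp = 9, fn = 4, fp = 5)
  expect_equal(m$bac, (m$sensitivity + m$specificity) / 2)
  expect_equal(m$accuracy, 16 / 25)
  expect_equal(m$dor, (9 * 7) / (4 * 5))
  expect_error(classification_metrics(-1, 2, 3, 4), "invalid")
})

test_that("nested CV recovers strong separation without leaking", {
  tab <- make_gaussian_table(30, 30, p = 6, delta = 4, seed = 51)
  scheme <- cv_scheme(outer_folds = 5, outer_perms = 2, inner_folds = 5)
  fit <- run_nested_cv(tab, scheme, seed = 9)
  expect_gte(fit$metrics$bac, 0.95)
  expect_true(audit_leakage(fit))
  # every dyad collects outer_perms x inner_folds scores
  expect_true(all(table(fit$scores$dyad_id) == 2 * 5))
  # BAC identity from pooled labels
  with(fit$pooled, {
    sens <- mean(predicted[truth == "ASD"] == "ASD")
    spec <- mean(predicted[truth == "CC"] == "CC")
    expect_equal(fit$metrics$bac, (sens + spec) / 2)
  })
  expect_gte(fit$metrics$auc, 0.95)

  # determinism under identical seeds
  fit2 <- run_nested_cv(tab, scheme, seed = 9)
  expect_identical(fit$pooled, fit2$pooled)
  expect_identical(fit$selected_c, fit2$selected_c)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(61, {
    truth <- rep(c("ASD", "CC"), c(20, 25))
    score <- rnorm(45) + (truth == "ASD")
  })
  ours <- dyadsync:::auc_rank(score, truth, "ASD")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score, levels = c("CC", "ASD"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation ratio matches a spreadsheet-style recomputation", {
  w <- data.frame(a = c(0.10, 0.12, 0.14, 0.30, 0.20, 0.40),
                  b = c(-0.5, -0.4, -0.6, -0.3, -0.2, -0.25))
  fake <- make_fake_fit(w, perms = rep(1, 6),
                        outer_folds = rep(1:2, each = 3),
                        inner_folds = rep(1:3, 2))
  cvr <- compute_cvr(fake)
  manual <- function(v) {
    f1 <- v[1:3]; f2 <- v[4:6]
    r1 <- median(f1) / (sd(f1) / sqrt(3))
    r2 <- median(f2) / (sd(f2) / sqrt(3))
    (r1 + r2) / 2
  }
  expect_equal(cvr$cvr[cvr$feature == "a"], manual(w$a))
  expect_equal(cvr$cvr[cvr$feature == "b"], manual(w$b))
  # antisymmetry under sign flip
  cvr_neg <- compute_cvr(make_fake_fit(-w, rep(1, 6),
                                       rep(1:2, each = 3), rep(1:3, 2)))
  expect_equal(cvr_neg$cvr, -cvr$cvr)
  # constant weights across inner models -> zero SE -> capped and flagged
  wc <- data.frame(a = rep(0.2, 6))
  cvr_c <- compute_cvr(make_fake_fit(wc, rep(1, 6),
                                     rep(1:2, each = 3), rep(1:3, 2)))
  expect_true(cvr_c$capped)
  expect_gt(cvr_c$cvr, 0)
})

test_that("sign consistency follows the exact binomial tail", {
  w <- data.frame(a = rep(0.3, 100), b = rep(c(0.1, -0.1), 50),
                  c = c(rep(0.2, 95), rep(-0.2, 5)))
  fake <- make_fake_fit(w, perms = rep(1:10, each = 10),
                        outer_folds = rep(1:10, 10),
                        inner_folds = rep(1, 100))
  sc <- sign_consistency(fake)
  # all positive: p = 2 * 0.5^100
  expect_equal(sc$neg_log10_p[sc$feature == "a"], 99 * log10(2),
               tolerance = 1e-9)
  expect_equal(sc$p[sc$feature == "b"], 1)
  expect_equal(sc$neg_log10_p[sc$feature == "b"], 0)
  # -log10(p) >= -log10(.05) is exactly p <= .05
  expect_identical(sc$neg_log10_p >= -log10(0.05), sc$p <= 0.05)
  expect_true(sc$fdr_significant[sc$feature == "a"])
  expect_false(sc$fdr_significant[sc$feature == "b"])
})

test_that("label permutation testing is valid at both extremes", {
  # strong signal: observed BAC should beat every permutation
  tab <- make_gaussian_table(12, 12, p = 4, delta = 4, seed = 71)
  scheme <- cv_scheme(outer_folds = 3, outer_perms = 1, inner_folds = 2)
  pt <- permutation_test(tab, scheme, B = 24, seed = 3)
  expect_lte(pt$p, 0.05)
  expect_equal(pt$p, (1 + sum(pt$permuted_bac >= pt$observed_bac)) / 25)
  expect_gt(pt$observed_bac, max(pt$permuted_bac))
})
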