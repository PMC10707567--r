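test_that("stratified folds partition subjects with balanced classes", {
  y <- rep(c(0, 1), each = 10)
  folds <- stratified_kfold(y, 10, seed = 1)
  expect_length(folds, 10L)
  sizes <- lengths(folds)
  expect_true(all(sizes == 2L))
  for (f in folds) expect_identical(sort(y[f]), c(0, 1))
  # partition property over random shapes
  set.seed(2)
  for (i in 1:10) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1); k <- sample(2:5, 1)
    yy <- sample(c(rep(0, n0), rep(1, n1)))
    fl <- stratified_kfold(yy, k, seed = i)
    all_idx <- sort(unlist(fl))
    expect_identical(all_idx, seq_along(yy))
    expect_identical(anyDuplicated(unlist(fl)), 0L)
    # class counts per fold within 1 of each other
    asd <- vapply(fl, function(f) sum(yy[f] == 1), numeric(1))
    expect_lte(max(asd) - min(asd), 1)
  }
  # the published cohort shape: 419 ASD / 530 HC over 10 folds
  yb <- c(rep(1, 419), rep(0, 530))
  fb <- stratified_kfold(yb, 10, seed = 3)
  expect_true(all(lengths(fb) %in% c(94L, 95L)))
  asd_counts <- vapply(fb, function(f) sum(yb[f] == 1), numeric(1))
  expect_true(all(asd_counts %in% c(41, 42)))
  # reproducible under seed
  expect_identical(fb, stratified_kfold(yb, 10, seed = 3))
  expect_error(stratified_kfold(c(0, 0, 0, 1), 3), "smaller k")
})

test_that("classification metrics evaluate their defining ratios", {
  cc <- confusion_counts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(classification_metrics(cc)), c(1, 1, 1))
  # TP=3 FN=1 TN=4 FP=2
  cc2 <- structure(list(TP = 3L, FP = 2L, TN = 4L, FN = 1L),
                   class = "confusion_counts")
  m2 <- classification_metrics(cc2)
  expect_equal(unname(m2["acc"]), 0.7)
  expect_equal(unname(m2["sen"]), 0.75)
  expect_equal(unname(m2["spec"]), 2 / 3, tolerance = 1e-4)
  # random counts against an independently coded formula oracle
  set.seed(4)
  for (i in 1:20) {
    k <- as.list(sample(0:20, 4, replace = TRUE))
    names(k) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(k)) == 0) next
    cc3 <- structure(k, class = "confusion_counts")
    m3 <- suppressWarnings(classification_metrics(cc3))
    tot <- k$TP + k$FP + k$TN + k$FN
    expect_equal(unname(m3["acc"]), (k$TP + k$TN) / tot)
    if (k$TP + k$FN > 0) expect_equal(unname(m3["sen"]), k$TP / (k$TP + k$FN))
    if (k$TN + k$FP > 0) expect_equal(unname(m3["spec"]), k$TN / (k$TN + k$FP))
  }
  # undefined denominators warn and return NA
  all_pos <- confusion_counts(c(1, 1), c(1, 0))
  expect_warning(mm <- classification_metrics(all_pos), "specificity undefined")
  expect_true(is.na(mm["spec"]))
})

test_that("AUC equals the concordant-pair statistic", {
  expect_equal(auc_score(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auc_score(c(1, 1, 0, 0), rep(0.4, 4)), 0.5)
  # brute-force O(N^2) pair oracle
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  y6 <- c(1, 1, 1, 0, 0, 0)
  s6 <- c(0.8, 0.55, 0.3, 0.6, 0.3, 0.1)
  expect_equal(auc_score(y6, s6), pair_auc(y6, s6))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_score(y, s), pair_auc(y, s))
  }
  expect_warning(a <- auc_score(c(1, 1), c(0.2, 0.4)), "single class")
  expect_true(is.na(a))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- sample(c(0, 1), 40, replace = TRUE)
  y[1:2] <- c(0, 1)
  s <- runif(40)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(auc_score(y, s), ref, tolerance = 1e-12)
})

test_that("RFE removes weakest features and recovers planted signal", {
  set.seed(7)
  x <- matrix(rnorm(60 * 12), 60, 12)
  y <- rep(c(0, 1), 30)
  expect_length(rfe_select(x, y, 11L), 11L)  # exactly one removed
  expect_error(rfe_select(x, y, 12L), "smaller than")
  # features 1-5 carry all the signal
  x2 <- matrix(rnorm(200 * 30), 200, 30)
  y2 <- rep(c(0, 1), each = 100)
  x2[y2 == 1, 1:5] <- x2[y2 == 1, 1:5] + 2
  sel <- rfe_select(x2, y2, 5L)
  expect_identical(sel, 1:5)
  # deterministic: same inputs, same selection
  expect_identical(rfe_select(x2, y2, 5L), sel)
})

test_that("cross-validation is reproducible and leakage-free", {
  cohort <- make_cohort(cohort_preset("separable", seed = 31))
  views <- cohort_features(cohort)
  y <- cohort$phenotypes$label
  cfg <- tiny_config()
  cv1 <- maacnn_cv(views, y, k = 3, config = cfg, seed = 9)
  expect_identical(cv1$leakage$violations, 0L)
  expect_gt(cv1$leakage$fits, 0L)
  # fold metrics average to the reported mean exactly
  expect_equal(unname(cv1$mean["acc"]), mean(cv1$per_fold$acc), tolerance = 1e-9)
  expect_identical(cv1$aggregation, "fold-averaged")
  # folds partition the cohort
  expect_identical(sort(unlist(cv1$folds)), seq_along(y))
  # determinism: identical seeds give identical reports
  cv2 <- maacnn_cv(views, y, k = 3, config = cfg, seed = 9)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$config_digest, cv2$config_digest)
})

test_that("the leakage guard detects a deliberately leaky fit", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("s%02d", 1:10), NULL))
  maacnn:::leakage_reset()
  maacnn:::leakage_guard_begin(c("s01", "s02"))
  maacnn:::fit_scaler(x)  # fits on all rows, including the guarded ones
  maacnn:::leakage_guard_end()
  rep <- leakage_report()
  expect_identical(rep$violations, 2L)
  expect_match(rep$details, "fit_scaler")
})

test_that("LOOCV pools counts over singleton folds", {
  set.seed(12)
  spec <- cohort_spec(n_per_class = c(HC = 6L, ASD = 6L),
                      atlases = list(atlas_spec("SIM10", 10L),
                                     atlas_spec("SIM12", 12L)),
                      t_len = 120L, n_affected_edges = 15L, delta = 0.8,
                      n_sites = 1L, seed = 13)
  cohort <- make_cohort(spec)
  views <- cohort_features(cohort)
  y <- cohort$phenotypes$label
  lo <- maacnn_loocv(views, y, config = tiny_config(60L), seed = 3)
  expect_identical(lo$n, 12L)
  cc <- lo$counts
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 12L)
  expect_identical(lo$aggregation, "pooled")
  expect_identical(lo$leakage$violations, 0L)
  expect_gte(lo$metrics["acc"], 80)
})

test_that("shuffled labels drive accuracy to chance", {
  spec <- cohort_spec(n_per_class = c(HC = 20L, ASD = 20L),
                      atlases = list(atlas_spec("SIM10", 10L),
                                     atlas_spec("SIM12", 12L)),
                      t_len = 120L, n_affected_edges = 15L, delta = 0.6,
                      n_sites = 1L, seed = 17)
  cohort <- make_cohort(spec)
  views <- cohort_features(cohort)
  y <- cohort$phenotypes$label
  cfg <- tiny_config(20L)
  accs <- numeric(20)
  set.seed(99)
  for (r in 1:20) {
    yp <- sample(y)
    cv <- maacnn_cv(views, yp, k = 3, config = cfg, seed = 1000 + r)
    accs[r] <- cv$mean["acc"] / 100
  }
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("the ablation harness runs four arms on identical folds", {
  cohort <- make_cohort(cohort_preset("complementary-views", seed = 23))
  views <- cohort_features(cohort)
  y <- cohort$phenotypes$label
  ab <- ablation_suite(views, y, k = 3, config = maacnn_desk_config(), seed = 7)
  expect_identical(nrow(as.data.frame(ab)), 4L)
  expect_identical(as.data.frame(ab)$arm,
                   c("CNN", "CNN + SDA", "CNN + attention (RFE features)",
                     "full model"))
  dg <- attr(ab, "fold_digest")
  expect_identical(length(unique(dg)), 1L)
  # complementary construction: fusing views should not hurt
  df <- as.data.frame(ab)
  expect_gte(df$acc[df$arm == "full model"], df$acc[df$arm == "CNN"])
})
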