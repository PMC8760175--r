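test_that("stratified folds partition and balance both classes", {
  labels <- c(rep("AIE", 134), rep("ACQ", 222))
  f <- make_folds(labels, k = 10, seed = 1)
  expect_length(f, 356L)
  expect_setequal(unique(f), 1:10)
  sizes <- tabulate(f, 10)
  expect_true(all(sizes %in% c(35L, 36L)))  # 356 = 10 x 35 + 6
  pos_per_fold <- vapply(1:10, function(k) {
    sum(labels[f == k] == "AIE")
  }, integer(1))
  expect_true(all(pos_per_fold %in% c(13L, 14L)))  # 134 = 10 x 13 + 4
  expect_identical(make_folds(labels, 10, seed = 1), f)
  expect_false(identical(make_folds(labels, 10, seed = 2), f))
  expect_error(make_folds(labels[1:5], k = 10), "fewer samples")
})

test_that("compute_metrics matches hand arithmetic and flags undefined", {
  m <- compute_metrics(tp = 1, tn = 1, fp = 0, fn = 0)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)

  # error decomposition oracle: 4 positives and 16 negatives
  # misclassified out of 134 / 222
  m2 <- compute_metrics(tp = 130, tn = 206, fp = 16, fn = 4)
  expect_equal(m2$accuracy, 336 / 356)
  expect_equal(m2$precision, 130 / 146)
  expect_equal(m2$recall, 130 / 134)
  expect_equal(m2$f1, 2 * (130 / 146) * (130 / 134) /
                 ((130 / 146) + (130 / 134)))
  expect_equal(m2$tpr, m2$recall)
  expect_equal(m2$fpr, 16 / 222)
  # accuracy identity
  expect_equal(m2$accuracy, 1 - (16 + 4) / 356)

  m3 <- compute_metrics(tp = 0, tn = 10, fp = 0, fn = 0)
  expect_true(is.na(m3$precision))
  expect_equal(m3$accuracy, 1)
  expect_error(compute_metrics(-1, 1, 1, 1), "non-negative")
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
})

test_that("compute_auc equals the pair-counting oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1),
                           c("AIE", "AIE", "ACQ", "ACQ")), 1)
  expect_equal(compute_auc(rep(0.5, 10),
                           rep(c("AIE", "ACQ"), 5)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.4, 0.6), c("AIE", "ACQ", "AIE")), 1)
  # pair counting: both positives (0.4, 0.6) rank below the negative 0.9
  expect_equal(compute_auc(c(0.4, 0.9, 0.6), c("AIE", "ACQ", "AIE")), 0)

  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    g <- outer(pos, neg, ">"); e <- outer(pos, neg, "==")
    (sum(g) + 0.5 * sum(e)) / (length(pos) * length(neg))
  }
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(compute_auc(s, y), pair_auc(s, y), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(compute_auc(exp(3 * s) - 1, y), compute_auc(s, y),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(c(0.1, 0.2), c("AIE", "AIE")), "both classes")
})

test_that("compute_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:20) {
    y <- c(1L, 0L, sample(0:1, 30, replace = TRUE))
    s <- round(runif(32), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("roc_points traces a valid curve consistent with the AUC", {
  set.seed(17)
  y <- sample(0:1, 50, replace = TRUE, prob = c(0.6, 0.4))
  s <- runif(50)
  pts <- roc_points(s, y)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  # trapezoid area equals the rank AUC
  area <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(area, compute_auc(s, y), tolerance = 1e-10)
})

test_that("run_cv tests every record exactly once and pools correctly", {
  ds <- tiny_dataset()
  cfg <- quick_config(families = c("logistic_regression", "knn"),
                      outer_folds = 2L)
  cv <- suppressWarnings(run_cv(ds, cfg, multimodal = FALSE, seed = 21))
  expect_s3_class(cv, "aie_cv")
  # 2 families x 2 modes + ensemble, per fold
  expect_equal(nrow(cv$results), (2 * 2 + 1) * 2)
  expect_setequal(cv$votes$id, ds$id)
  expect_equal(anyDuplicated(cv$votes$id), 0L)
  pooled <- dplyr::filter(cv$pooled_confusion, family == "ensemble")
  expect_equal(pooled$tp + pooled$tn + pooled$fp + pooled$fn, nrow(ds))
  # aggregation uses the sample sd over exactly K folds
  one <- dplyr::filter(cv$results, family == "knn", mode == "morgan")
  agg <- dplyr::filter(cv$summary, family == "knn", mode == "morgan",
                       metric == "accuracy")
  expect_equal(agg$mean_value, mean(one$accuracy))
  expect_equal(agg$sd_value, sd(one$accuracy))
  # report renders with one row per voter cell plus the ensemble
  tab <- cv_table(cv)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$family[nrow(tab)], "ensemble")

  expect_error(run_cv(ds[0, ], cfg), "empty")
  single_class <- ds[as.character(ds$label) == "ACQ", ]
  expect_error(suppressWarnings(run_cv(single_class, cfg)),
               "single class")
})

test_that("tidy/glance/autoplot expose the cv results", {
  ds <- tiny_dataset()
  cfg <- quick_config(families = "knn", outer_folds = 2L)
  cv <- suppressWarnings(run_cv(ds, cfg, seed = 3))
  td <- tidy(cv)
  expect_true(all(c("family", "mode", "fold", "accuracy", "auc", "f1")
                  %in% names(td)))
  gl <- glance(cv)
  expect_true("mean_value_accuracy" %in% names(gl))
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("deterministic families reproduce bit-identical reports", {
  ds <- tiny_dataset()
  cfg <- quick_config(families = c("logistic_regression", "knn"),
                      outer_folds = 2L)
  cv1 <- suppressWarnings(run_cv(ds, cfg, seed = 33))
  cv2 <- suppressWarnings(run_cv(ds, cfg, seed = 33))
  expect_identical(cv1$results, cv2$results)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_cv_report(cv1, f1)
  write_cv_report(cv2, f2)
  j1 <- jsonlite::fromJSON(f1)
  j2 <- jsonlite::fromJSON(f2)
  expect_identical(j1$results, j2$results)
  expect_identical(j1$summary, j2$summary)
})
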