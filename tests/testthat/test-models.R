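test_that("hyperparameter grids match the published search spaces", {
  knn <- build_grid("knn")
  expect_equal(knn$grid$k, c(3, 5, 7, 9, 11, 13, 15, 17, 18))

  rf <- build_grid("random_forest")
  expect_equal(rf$grid$min_samples_split, c(2, 4))
  expect_equal(rf$grid$n_estimators, c(10, 50, 100, 200, 500))
  expect_equal(nrow(aievote:::grid_rows(rf)), 10L)

  # log-spacing oracle: 7 points from 1e-3 to 1e3 are the integer powers
  lr <- build_grid("logistic_regression")
  expect_equal(lr$grid$C, 10^(-3:3), tolerance = 1e-12)

  gb <- build_grid("gradient_boost")
  expect_equal(gb$grid$min_leaf_frac, seq(0.1, 0.5, by = 0.1))
  expect_equal(gb$grid$max_depth, c(3, 5, 7))
  expect_equal(gb$grid$subsample, c(0.5, 0.75, 0.95))

  mlp <- build_grid("mlp")
  expect_equal(mlp$grid$alpha, c(1e-5, 1e-4, 1e-3))

  expect_error(build_grid("svm"), "unknown")

  # axis thinning keeps endpoints
  thin <- build_grid("knn", aie_config(grid_points_per_axis = 2))
  expect_equal(thin$grid$k, c(3, 18))
})

test_that("every family separates a noise-free linear toy problem", {
  toy <- toy_separable()
  cfg <- aie_config(mlp_size = 4L, mlp_maxit = 200L, gb_nrounds = 50L)
  for (fam in c("logistic_regression", "knn", "gradient_boost",
                "random_forest", "mlp")) {
    tuned <- suppressWarnings(
      tune_classifier(build_grid(fam, cfg), toy$X, toy$y,
                      inner_folds = 5, seed = 9, config = cfg)
    )
    expect_gte(max(tuned$inner_cv_scores), 1.0)
    # chosen values never leave the declared grid
    grid <- build_grid(fam, cfg)$grid
    for (nm in names(tuned$chosen_params)) {
      expect_true(tuned$chosen_params[[nm]] %in% grid[[nm]])
    }
    # training rows are reproduced by the refitted model
    pred <- predict_labels(tuned, toy$X)
    expect_gte(mean((pred == "AIE") == (toy$y == 1L)), 0.975)
    s <- predict_scores(tuned, toy$X)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("tuning is deterministic and honours grid-order tie-breaks", {
  toy <- toy_separable()
  cfg <- aie_config(grid_points_per_axis = 2)
  t1 <- suppressWarnings(tune_classifier(build_grid("knn", cfg), toy$X,
                                         toy$y, seed = 5, config = cfg))
  t2 <- suppressWarnings(tune_classifier(build_grid("knn", cfg), toy$X,
                                         toy$y, seed = 5, config = cfg))
  expect_identical(t1$chosen_params, t2$chosen_params)
  expect_identical(t1$inner_cv_scores, t2$inner_cv_scores)
  # all grid points tie at accuracy 1 on this toy set: the first wins
  expect_equal(t1$chosen_params$k, build_grid("knn", cfg)$grid$k[1])

  spec1 <- build_grid("knn", cfg)
  spec1$grid$k <- 3
  single <- suppressWarnings(tune_classifier(spec1, toy$X, toy$y,
                                             seed = 5, config = cfg))
  expect_equal(single$chosen_params$k, 3)
  expect_true(is.finite(single$inner_cv_score))
})

test_that("knn prediction agrees with a brute-force distance oracle", {
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(5, 5), c(6, 6), c(7, 7))
  y <- c(1L, 1L, 0L, 0L, 0L, 0L)  # 3-NN of query: 2 AIE / 1 ACQ
  cfg <- aie_config()
  spec <- build_grid("knn", cfg)
  spec$grid$k <- 3
  tuned <- suppressWarnings(
    tune_classifier(spec, X, y, inner_folds = 2, seed = 1, config = cfg))
  q <- matrix(c(0.02, 0.02), 1, 2)
  d <- sqrt(colSums((t(X) - as.numeric(q))^2))
  nn3 <- order(d)[1:3]
  expect_equal(sum(y[nn3] == 1L), 2L)  # oracle: AIE majority
  expect_equal(predict_labels(tuned, q), "AIE")
})

test_that("tuning input contracts are enforced", {
  toy <- toy_separable()
  cfg <- aie_config()
  expect_error(tune_classifier(build_grid("knn", cfg), toy$X,
                               rep(1L, nrow(toy$X)), config = cfg),
               "single class")
  tuned <- suppressWarnings(
    tune_classifier(build_grid("knn", cfg), toy$X, toy$y, seed = 2,
                    config = cfg))
  expect_error(predict_scores(tuned, toy$X[, 1, drop = FALSE]),
               "dimension mismatch")
  expect_error(predict_labels("not a model", toy$X), "tuned_classifier")
})
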