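# The five classifier families.
#
# Each family delegates to an established learner (glmnet, class::knn,
# xgboost, ranger, nnet) behind a uniform fit/score interface, with the
# published hyperparameter search grids and inner 5-fold selection.
# The positive class is AIE throughout; scores are P(AIE) in [0, 1].
#
# The learner namespaces are imported so their S3 predict methods are
# registered even when a fitted panel is deserialized in a fresh session.
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom nnet nnet
#' @importFrom xgboost xgb.train
#' @importFrom class knn
NULL

.families <- c("logistic_regression", "knn", "gradient_boost",
               "random_forest", "mlp")

#' Hyperparameter grid for one classifier family
#'
#' Grids follow the study protocol: discrete grids verbatim, continuous
#' ranges discretised log-uniformly. Axes:
#' * `logistic_regression`: inverse regularisation strength `C`, 7
#'   log-spaced points spanning `1e-3`..`1e3`.
#' * `knn`: neighbours `k` in `{3,5,7,9,11,13,15,17,18}`.
#' * `gradient_boost`: `min_leaf_frac` `{0.1..0.5}`, `max_depth`
#'   `{3,5,7}`, `subsample` `{0.5,0.75,0.95}` (minimum-samples-per-split
#'   collapses into the leaf constraint under this tree learner).
#' * `random_forest`: `min_samples_split` `{2,4}` x `n_estimators`
#'   `{10,50,100,200,500}`.
#' * `mlp`: weight decay `alpha` in `{1e-5,1e-4,1e-3}` (the quasi-Newton
#'   optimiser used here has no learning-rate hyperparameter).
#'
#' @param family One of the five family names.
#' @param config An [aie_config()]; `grid_points_per_axis` thins each axis
#'   evenly (endpoints kept) for faster runs.
#' @return A `classifier_spec` list with elements `family` and `grid`
#'   (named list of candidate vectors, in declared tie-break order).
#' @export
build_grid <- function(family, config = aie_config()) {
  if (!family %in% .families) {
    abort(paste0("unknown classifier family: ", family))
  }
  grid <- switch(family,
    logistic_regression = list(C = 10^seq(-3, 3, length.out = 7)),
    knn = list(k = c(3, 5, 7, 9, 11, 13, 15, 17, 18)),
    gradient_boost = list(
      min_leaf_frac = c(0.1, 0.2, 0.3, 0.4, 0.5),
      max_depth = c(3, 5, 7),
      subsample = c(0.5, 0.75, 0.95)
    ),
    random_forest = list(
      min_samples_split = c(2, 4),
      n_estimators = c(10, 50, 100, 200, 500)
    ),
    mlp = list(alpha = c(1e-5, 1e-4, 1e-3))
  )
  cap <- config$grid_points_per_axis
  if (is.finite(cap)) {
    grid <- lapply(grid, function(v) {
      if (length(v) <= cap) return(v)
      v[unique(round(seq(1, length(v), length.out = cap)))]
    })
  }
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

grid_rows <- function(spec) {
  g <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  # family-declared order: first axis varies slowest so earlier candidates
  # on the first axis win ties
  g[do.call(order, g[rev(names(g))]), , drop = FALSE] -> g
  rownames(g) <- NULL
  g
}

# ---- uniform fit / score interface ------------------------------------

# y is an integer 0/1 vector (1 = AIE).
fit_family <- function(family, params, X, y, seed, config) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0L, 1L)))
  fit <- switch(family,
    logistic_regression = {
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = 1 / (nrow(X) * params$C))
    },
    knn = list(train = X, y = y, k = as.integer(params$k), seed = seed),
    gradient_boost = with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(
          objective = "binary:logistic",
          max_depth = as.integer(params$max_depth),
          subsample = params$subsample,
          min_child_weight = 0.25 * params$min_leaf_frac * nrow(X),
          eta = config$gb_eta,
          nthread = 1
        ),
        data = dtrain, nrounds = config$gb_nrounds, verbose = 0
      )
    }),
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)),
      num.trees = as.integer(params$n_estimators),
      min.node.size = max(1L, as.integer(params$min_samples_split) %/% 2L),
      probability = TRUE, seed = seed, num.threads = 1
    ),
    mlp = with_seed(seed, {
      nnet::nnet(x = X, y = y, size = config$mlp_size,
                 decay = params$alpha, maxit = config$mlp_maxit,
                 entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
    }),
    abort(paste0("unknown classifier family: ", family))
  )
  structure(list(family = family, fit = fit, params = params,
                 p = ncol(X), seed = seed),
            class = "aie_fit")
}

score_family <- function(object, X) {
  stopifnot(is.matrix(X))
  if (ncol(X) != object$p) {
    abort(paste0("feature dimension mismatch: model expects ", object$p,
                 " columns, got ", ncol(X)))
  }
  s <- switch(object$family,
    logistic_regression =
      as.numeric(predict(object$fit, X, type = "response")),
    knn = {
      f <- object$fit
      pr <- with_seed(object$seed, {
        class::knn(f$train, X, factor(f$y, levels = c(0L, 1L)),
                   k = min(f$k, nrow(f$train)), prob = TRUE)
      })
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    gradient_boost = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    random_forest = {
      pr <- predict(object$fit, data = X, num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    mlp = as.numeric(predict(object$fit, X))
  )
  pmin(pmax(s, 0), 1)
}

#' Tune one classifier on one feature block
#'
#' Exhaustive grid search scored by inner k-fold cross-validation
#' (stratified), ties broken by declared grid order, final model refitted
#' on all rows with the selected hyperparameters.
#'
#' @param spec A `classifier_spec` from [build_grid()].
#' @param X Numeric feature matrix.
#' @param y Labels: factor/character with values `AIE`/`ACQ`, or 0/1.
#' @param inner_folds Number of inner folds (default 5).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   learner internals.
#' @param config An [aie_config()] carrying the fixed (non-grid)
#'   hyperparameters.
#' @param mode Optional feature-mode label stored on the result.
#' @return A `tuned_classifier` with the chosen hyperparameters, the inner
#'   CV score and the refitted model.
#' @export
tune_classifier <- function(spec, X, y, inner_folds = 5L, seed = 1L,
                            config = aie_config(), mode = NA_character_) {
  if (!inherits(spec, "classifier_spec")) {
    abort("`spec` must come from build_grid().")
  }
  y <- encode_labels(y)
  if (length(unique(y)) < 2L) {
    abort("`y` contains a single class; cannot tune a classifier.")
  }
  if (nrow(X) != length(y)) abort("`X` rows must match length(y).")
  if (nrow(X) < inner_folds) abort("fewer rows than inner folds.")
  rows <- grid_rows(spec)
  folds <- make_folds(y, k = inner_folds, seed = derive_seed(seed, "inner"))
  scores <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    params <- as.list(rows[r, , drop = FALSE])
    acc <- numeric(inner_folds)
    f1v <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        abort("degenerate inner fold: one class absent from sub-training.")
      }
      fit <- fit_family(spec$family, params, X[tr, , drop = FALSE], y[tr],
                        seed = derive_seed(seed, paste0("fit", r, ".", f)),
                        config = config)
      pred <- as.integer(score_family(fit, X[!tr, , drop = FALSE]) >= 0.5)
      cm <- confusion_counts(pred, y[!tr])
      acc[f] <- (cm$tp + cm$tn) / sum(unlist(cm))
      prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else 0
      rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
      f1v[f] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    scores[r] <- if (config$selection_metric == "f1") mean(f1v)
                 else mean(acc)
  }
  best <- which.max(scores)  # first maximum = declared grid order
  params <- as.list(rows[best, , drop = FALSE])
  final <- fit_family(spec$family, params, X, y,
                      seed = derive_seed(seed, "final"), config = config)
  structure(
    list(spec = spec, family = spec$family, mode = mode,
         chosen_params = params, inner_cv_score = scores[best],
         inner_cv_scores = setNames(scores, apply(rows, 1, paste,
                                                  collapse = "/")),
         fitted = final, n_train = nrow(X), p = ncol(X), seed = seed),
    class = "tuned_classifier"
  )
}

#' @export
print.tuned_classifier <- function(x, ...) {
  cat("<tuned_classifier> ", x$family,
      if (!is.na(x$mode)) paste0(" [", x$mode, "]"), "\n", sep = "")
  cat("  chosen: ",
      paste(names(x$chosen_params), unlist(x$chosen_params),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  inner-CV score: ", format(x$inner_cv_score, digits = 4),
      "  (n = ", x$n_train, ", p = ", x$p, ")\n", sep = "")
  invisible(x)
}

#' Predict hard labels / positive-class scores
#'
#' @param model A `tuned_classifier`.
#' @param X Feature matrix with the training dimensionality.
#' @return `predict_labels`: character vector in `{"AIE","ACQ"}`;
#'   `predict_scores`: numeric vector in `[0, 1]` (P(AIE)). A label is
#'   AIE exactly when the score is at least 0.5.
#' @export
predict_labels <- function(model, X) {
  ifelse(predict_scores(model, X) >= 0.5, "AIE", "ACQ")
}

#' @rdname predict_labels
#' @export
predict_scores <- function(model, X) {
  if (!inherits(model, "tuned_classifier")) {
    abort("`model` must be a tuned_classifier.")
  }
  score_family(model$fitted, X)
}

# labels -> integer 0/1 with AIE = 1
encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    up <- toupper(trimws(y))
    if (!all(up %in% c("AIE", "ACQ"))) {
      abort("labels must be AIE/ACQ (or 0/1).")
    }
    return(as.integer(up == "AIE"))
  }
  if (all(y %in% c(0, 1))) return(as.integer(y))
  abort("labels must be AIE/ACQ (or 0/1).")
}

confusion_counts <- function(pred, truth) {
  list(
    tp = sum(pred == 1L & truth == 1L),
    tn = sum(pred == 0L & truth == 0L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L)
  )
}
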