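# Nested cross-validation protocol and metrics.
#
# Outer stratified 10-fold CV estimates generalization; inside every
# outer training split an inner 5-fold grid search picks each voter's
# hyperparameters. Metrics follow the confusion-matrix definitions with
# AIE as the positive class; AUC is the Mann-Whitney pair statistic.

#' Stratified k-fold assignment
#'
#' Partitions indices into k folds preserving class proportions: each
#' class is split as evenly as possible and remainders are placed on the
#' currently smallest folds, so fold sizes never differ by more than one
#' within a class.
#'
#' @param labels Class labels (any type; AIE/ACQ, factor or 0/1).
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Integer vector of fold ids in `1..k`, one per label.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.")
  if (n < k) abort("fewer samples than folds.")
  fold <- integer(n)
  sizes <- integer(k)
  cls <- unique(labels)
  with_seed(seed, {
    for (cl in cls) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      counts <- rep(base, k)
      if (rem > 0) {
        # remainder goes to the currently smallest folds (ties by index)
        extra <- order(sizes, seq_len(k))[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      stops <- cumsum(counts)
      starts <- c(1L, head(stops, -1L) + 1L)
      for (f in seq_len(k)) {
        if (counts[f] > 0) fold[idx[starts[f]:stops[f]]] <- f
      }
      sizes <- sizes + counts
    }
  })
  fold
}

#' Confusion-matrix metrics
#'
#' Computes accuracy, precision, recall, F1, TPR and FPR from confusion
#' counts with AIE as the positive class. Ratios with a zero denominator
#' are reported as `NA` (undefined), never coerced to 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts. Alternatively `tp`
#'   may be a list with elements `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f1`, `tpr`, `fpr`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    c0 <- tp
    tp <- c0$tp; tn <- c0$tn; fp <- c0$fp; fn <- c0$fn
  }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers.")
  }
  total <- tp + tn + fp + fn
  if (total == 0) abort("confusion counts are all zero.")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    tpr = recall,
    fpr = safe_div(fp, tn + fp)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, counting ties as one half. Invariant
#' under any strictly monotone transform of the scores.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Labels (AIE positive; accepts AIE/ACQ, factor or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  y <- encode_labels(labels)
  if (length(scores) != length(y)) {
    abort("`scores` and `labels` lengths differ.")
  }
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) {
    abort("AUC needs both classes present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Nested cross-validation of all voters and the ensemble
#'
#' The full evaluation protocol: one shared stratified outer k-fold split;
#' per outer fold, every (family, mode) voter is tuned by inner grid
#' search on the training split, refitted, and scored on the held-out
#' fold; the majority-vote ensemble is evaluated on the same held-out
#' predictions. Multi-modal runs PCA-fuse each fingerprint with the
#' quantitative block — globally before splitting by default, or
#' refitted per training fold when `config$fold_safe` is `TRUE`.
#'
#' @param data A labeled `aie_dataset`.
#' @param config An [aie_config()].
#' @param multimodal Evaluate fused multi-modal features (4 modes) rather
#'   than single-modal features (5 modes)?
#' @param seed Integer seed for folds and stochastic learners.
#' @param cache_dir Optional feature cache directory.
#' @return An `aie_cv` object: per-fold results (`tidy()`), mean +/- sd
#'   aggregation (`glance()` / [cv_table()]), pooled confusion counts,
#'   per-record ensemble votes and the run manifest.
#' @export
run_cv <- function(data, config = aie_config(), multimodal = FALSE,
                   seed = 1L, cache_dir = NULL) {
  if (!nrow(data)) abort("empty dataset.")
  if (anyNA(data$label)) abort("run_cv requires labels on every record.")
  y <- encode_labels(data$label)
  if (length(unique(y)) < 2L) {
    abort("dataset contains a single class; cannot cross-validate.")
  }
  K <- config$outer_folds
  folds <- make_folds(y, k = K, seed = derive_seed(seed, "outer"))

  fps <- lapply(config$fingerprints, function(kind) {
    featurize_dataset(data, kind, config, cache_dir)
  })
  names(fps) <- config$fingerprints
  quant <- featurize_dataset(data, "quantitative", config, cache_dir)

  mode_matrices <- function(train_idx) {
    if (!multimodal) {
      mats <- c(lapply(fps, block_matrix),
                list(quantitative = block_matrix(quant)))
      return(list(train = lapply(mats, function(m) {
        m[train_idx, , drop = FALSE]
      }), test = lapply(mats, function(m) {
        m[-train_idx, , drop = FALSE]
      })))
    }
    fit_rows <- if (config$fold_safe) train_idx else seq_along(y)
    models <- lapply(fps, function(b) {
      fit_fusion(
        new_feature_block(b$mode,
                          b$matrix[fit_rows, , drop = FALSE],
                          b$row_ids[fit_rows]),
        new_feature_block("quantitative",
                          quant$matrix[fit_rows, , drop = FALSE],
                          quant$row_ids[fit_rows])
      )
    })
    project <- function(rows) {
      out <- lapply(names(fps), function(kind) {
        block_matrix(apply_fusion(
          models[[kind]],
          new_feature_block(kind, fps[[kind]]$matrix[rows, , drop = FALSE],
                            fps[[kind]]$row_ids[rows]),
          new_feature_block("quantitative",
                            quant$matrix[rows, , drop = FALSE],
                            quant$row_ids[rows])
        ))
      })
      names(out) <- paste0(names(fps), "+quantitative")
      out
    }
    list(train = project(train_idx),
         test = project(setdiff(seq_along(y), train_idx)))
  }

  per_fold <- list()
  vote_rows <- list()
  for (f in seq_len(K)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    mm <- mode_matrices(train_idx)
    modes <- names(mm$train)
    skeleton <- enumerate_voters(config$families, modes)

    votes <- matrix(NA_character_, length(test_idx), nrow(skeleton))
    vscores <- matrix(NA_real_, length(test_idx), nrow(skeleton))
    for (i in seq_len(nrow(skeleton))) {
      fam <- skeleton$family[i]
      mode <- skeleton$mode[i]
      tuned <- tryCatch(
        tune_classifier(build_grid(fam, config), mm$train[[mode]],
                        y[train_idx], inner_folds = config$inner_folds,
                        seed = derive_seed(seed,
                                           paste0("f", f, ".",
                                                  skeleton$voter[i])),
                        config = config, mode = mode),
        error = function(e) {
          abort(paste0("cross-validation failed at (", fam, ", ", mode,
                       ", fold ", f, "): ", conditionMessage(e)))
        }
      )
      tr_scores <- predict_scores(tuned, mm$train[[mode]])
      tr_cm <- confusion_counts(as.integer(tr_scores >= 0.5),
                                y[train_idx])
      te_scores <- predict_scores(tuned, mm$test[[mode]])
      te_pred <- as.integer(te_scores >= 0.5)
      te_cm <- confusion_counts(te_pred, y[test_idx])
      met <- compute_metrics(te_cm)
      per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          family = fam, mode = mode, fold = f,
          train_accuracy = (tr_cm$tp + tr_cm$tn) / length(train_idx),
          auc = compute_auc(te_scores, y[test_idx]),
          chosen = paste(names(tuned$chosen_params),
                         unlist(tuned$chosen_params),
                         sep = "=", collapse = ",")
        ),
        met
      )
      votes[, i] <- ifelse(te_pred == 1L, "AIE", "ACQ")
      vscores[, i] <- te_scores
    }

    majority_class <- if (sum(y[train_idx] == 1L) >
                          sum(y[train_idx] == 0L)) "AIE" else "ACQ"
    ens <- lapply(seq_along(test_idx), function(i) {
      majority_vote(votes[i, ], tie_break = config$tie_break,
                    majority_class = majority_class,
                    scores = vscores[i, ])
    })
    ens_label <- vapply(ens, `[[`, character(1), "final")
    ens_frac <- vapply(ens, `[[`, numeric(1), "vote_fraction")
    ens_cm <- confusion_counts(as.integer(ens_label == "AIE"),
                               y[test_idx])
    per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(family = "ensemble", mode = "ensemble", fold = f,
                     train_accuracy = NA_real_,
                     auc = compute_auc(ens_frac, y[test_idx]),
                     chosen = NA_character_),
      compute_metrics(ens_cm)
    )
    vote_rows[[f]] <- tibble::tibble(
      id = data$id[test_idx], fold = f,
      truth = ifelse(y[test_idx] == 1L, "AIE", "ACQ"),
      votes_AIE = vapply(seq_along(test_idx),
                         function(i) sum(votes[i, ] == "AIE"), integer(1)),
      votes_ACQ = vapply(seq_along(test_idx),
                         function(i) sum(votes[i, ] == "ACQ"), integer(1)),
      predicted_label = ens_label,
      vote_fraction = ens_frac,
      tie = vapply(ens, `[[`, logical(1), "tie")
    )
  }

  results <- dplyr::bind_rows(per_fold)
  summary <- results |>
    tidyr::pivot_longer(
      cols = c("train_accuracy", "accuracy", "auc", "f1"),
      names_to = "metric", values_to = "value") |>
    dplyr::group_by(family, mode, metric) |>
    dplyr::summarise(
      mean_value = mean(value),
      sd_value = sd(value),
      .groups = "drop"
    )
  pooled <- results |>
    dplyr::group_by(family, mode) |>
    dplyr::summarise(tp = sum(tp), tn = sum(tn), fp = sum(fp),
                     fn = sum(fn), .groups = "drop")

  structure(
    list(
      results = results,
      summary = summary,
      pooled_confusion = pooled,
      votes = dplyr::bind_rows(vote_rows),
      folds = folds,
      multimodal = multimodal,
      n_voters = length(config$families) *
        (length(config$fingerprints) + if (multimodal) 0L else 1L),
      manifest = run_manifest(config, seed, list(
        multimodal = multimodal,
        n = nrow(data),
        class_counts = as.list(class_counts(data)),
        outer_folds = K
      ))
    ),
    class = "aie_cv"
  )
}

#' @export
print.aie_cv <- function(x, ...) {
  cat("<aie_cv> ", if (x$multimodal) "multi-modal" else "single-modal",
      " nested CV: ", max(x$results$fold), " outer folds, ",
      x$n_voters, " voters + ensemble\n", sep = "")
  ens <- dplyr::filter(x$summary, family == "ensemble",
                       metric == "accuracy")
  cat(sprintf("  ensemble test accuracy: %.4f +/- %.4f\n",
              ens$mean_value, ens$sd_value))
  invisible(x)
}

#' Rendered mean +/- sd results table
#'
#' One row per (method, mode) plus the ensemble row; columns give train
#' accuracy, test accuracy, AUC and F1 as `mean +/- sd` over the outer
#' folds, rounded to 4 decimals (the underlying `aie_cv` keeps full
#' precision).
#'
#' @param cv An `aie_cv` from [run_cv()].
#' @return A wide tibble.
#' @export
cv_table <- function(cv) {
  fmt <- function(m, s) {
    ifelse(is.na(m), "-", sprintf("%.4f ± %.4f", m, s))
  }
  cv$summary |>
    dplyr::mutate(cell = fmt(mean_value, sd_value)) |>
    dplyr::select(family, mode, metric, cell) |>
    tidyr::pivot_wider(names_from = metric, values_from = cell) |>
    dplyr::select(family, mode,
                  train_accuracy, test_accuracy = accuracy,
                  auc, f1) |>
    dplyr::arrange(factor(family, levels = c(setdiff(unique(family),
                                                     "ensemble"),
                                             "ensemble")))
}

#' Serialise a CV report to JSON
#'
#' @param cv An `aie_cv`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  payload <- list(
    results = cv$results,
    summary = cv$summary,
    pooled_confusion = cv$pooled_confusion,
    manifest = cv$manifest
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
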