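# Majority-voting ensemble over (classifier family, feature mode) voters.
#
# Every combination is one voter casting a hard AIE/ACQ label per
# molecule; the category with more votes is the final call. With the five
# families this gives 25 voters single-modal (5 x 5 modes) and 20
# multi-modal (5 x 4 fused modes). Vote fraction (share of AIE votes)
# doubles as the ensemble's soft score for ROC/AUC.

#' Enumerate the voter panel skeleton
#'
#' @param families Classifier family names.
#' @param modes Feature mode names.
#' @return Tibble with one row per (family, mode) voter, in family-major
#'   order.
#' @export
enumerate_voters <- function(families, modes) {
  if (!length(families) || !length(modes)) {
    abort("`families` and `modes` must be non-empty.")
  }
  tibble::tibble(
    voter = paste(rep(families, each = length(modes)),
                  rep(modes, times = length(families)), sep = "."),
    family = rep(families, each = length(modes)),
    mode = rep(modes, times = length(families))
  )
}

#' Majority vote over hard labels
#'
#' @param votes Character vector of `"AIE"`/`"ACQ"` votes (one per voter).
#' @param tie_break Even-split policy: the training-majority class
#'   (default), a fixed class, or `"score"` (caller resolves by mean
#'   voter score via the `scores` argument).
#' @param majority_class Training-set majority class used by the default
#'   policy.
#' @param scores Optional voter scores, used only by `tie_break =
#'   "score"`.
#' @return List with `final` (category), `vote_fraction` (share of AIE
#'   votes) and `tie` (logical).
#' @export
majority_vote <- function(votes, tie_break = "majority-class",
                          majority_class = "ACQ", scores = NULL) {
  if (!length(votes)) abort("empty vote set.")
  if (!all(votes %in% c("AIE", "ACQ"))) {
    abort("votes must be 'AIE' or 'ACQ'.")
  }
  n_aie <- sum(votes == "AIE")
  n_acq <- length(votes) - n_aie
  frac <- n_aie / length(votes)
  if (n_aie == n_acq) {
    final <- switch(tie_break,
      "majority-class" = majority_class,
      "aie" = "AIE",
      "acq" = "ACQ",
      "score" = {
        if (is.null(scores)) {
          abort("tie_break='score' needs voter scores.")
        }
        if (mean(scores) >= 0.5) "AIE" else "ACQ"
      },
      abort(paste0("unknown tie_break: ", tie_break))
    )
    return(list(final = final, vote_fraction = frac, tie = TRUE))
  }
  list(final = if (n_aie > n_acq) "AIE" else "ACQ",
       vote_fraction = frac, tie = FALSE)
}

#' Train a full voter panel
#'
#' Tunes one classifier per (family, mode) combination on the supplied
#' feature blocks (inner k-fold grid search) and refits each on all rows.
#'
#' @param blocks Named list of `feature_block`s (one per mode), as from
#'   [assemble_modes()].
#' @param y Labels aligned with the block rows.
#' @param config An [aie_config()].
#' @param seed Integer seed.
#' @return An `aie_panel`: the ordered voter list plus panel metadata.
#' @export
train_panel <- function(blocks, y, config = aie_config(), seed = 1L) {
  skeleton <- enumerate_voters(config$families, names(blocks))
  y_int <- encode_labels(y)
  majority_class <- if (sum(y_int == 1L) > sum(y_int == 0L)) "AIE"
                    else "ACQ"
  voters <- vector("list", nrow(skeleton))
  names(voters) <- skeleton$voter
  for (i in seq_len(nrow(skeleton))) {
    fam <- skeleton$family[i]
    mode <- skeleton$mode[i]
    voters[[i]] <- tune_classifier(
      build_grid(fam, config),
      block_matrix(blocks[[mode]]), y_int,
      inner_folds = config$inner_folds,
      seed = derive_seed(seed, skeleton$voter[i]),
      config = config, mode = mode
    )
  }
  structure(
    list(voters = voters, skeleton = skeleton,
         modes = names(blocks), majority_class = majority_class,
         tie_break = config$tie_break, config = config, seed = seed),
    class = "aie_panel"
  )
}

#' @export
print.aie_panel <- function(x, ...) {
  cat("<aie_panel> ", length(x$voters), " voters (",
      length(unique(x$skeleton$family)), " families x ",
      length(x$modes), " modes), tie-break: ", x$tie_break, "\n", sep = "")
  invisible(x)
}

#' Ensemble prediction by majority vote
#'
#' @param panel An `aie_panel` from [train_panel()].
#' @param blocks Named list of `feature_block`s covering every panel mode,
#'   row-aligned across modes.
#' @param ids Optional record ids (default: row ids of the first block).
#' @param smiles Optional SMILES column carried into the output.
#' @return Tibble with one row per record: `id`, `votes_AIE`,
#'   `votes_ACQ`, `predicted_label`, `vote_fraction`, `tie` (and `smiles`
#'   when supplied). Vote tallies always sum to the panel size.
#' @export
ensemble_predict <- function(panel, blocks, ids = NULL, smiles = NULL) {
  if (!inherits(panel, "aie_panel")) abort("`panel` must be an aie_panel.")
  missing_modes <- setdiff(panel$modes, names(blocks))
  if (length(missing_modes)) {
    abort(paste0("missing feature block(s) for mode(s): ",
                 paste(missing_modes, collapse = ", ")))
  }
  n <- nrow(block_matrix(blocks[[panel$modes[1]]]))
  ids <- ids %||% blocks[[panel$modes[1]]]$row_ids %||%
    paste0("m", seq_len(n))

  votes <- matrix(NA_character_, n, length(panel$voters))
  score <- matrix(NA_real_, n, length(panel$voters))
  for (j in seq_along(panel$voters)) {
    v <- panel$voters[[j]]
    X <- block_matrix(blocks[[v$mode]])
    if (nrow(X) != n) abort("blocks are not row-aligned.")
    s <- predict_scores(v, X)
    score[, j] <- s
    votes[, j] <- ifelse(s >= 0.5, "AIE", "ACQ")
  }

  res <- lapply(seq_len(n), function(i) {
    majority_vote(votes[i, ], tie_break = panel$tie_break,
                  majority_class = panel$majority_class,
                  scores = score[i, ])
  })
  out <- tibble::tibble(
    id = ids,
    votes_AIE = vapply(seq_len(n), function(i) sum(votes[i, ] == "AIE"),
                       integer(1)),
    votes_ACQ = vapply(seq_len(n), function(i) sum(votes[i, ] == "ACQ"),
                       integer(1)),
    predicted_label = vapply(res, `[[`, character(1), "final"),
    vote_fraction = vapply(res, `[[`, numeric(1), "vote_fraction"),
    tie = vapply(res, `[[`, logical(1), "tie")
  )
  if (!is.null(smiles)) {
    out <- dplyr::mutate(out, smiles = smiles, .after = "id")
  }
  out
}

#' Predict AIE/ACQ for new molecules with a trained panel
#'
#' Featurizes `newdata` with the panel's stored configuration (reusing the
#' fitted fusion models for multi-modal panels, so the fused dimension is
#' fixed by the model, not the batch) and majority-votes.
#'
#' @param object An `aie_panel` trained by [train_panel()] through
#'   [run_cv()] or the CLI, carrying `fusion_models`/`multimodal`
#'   attributes set by [train_full_panel()].
#' @param newdata An `aie_dataset` (labels not required).
#' @param ... Unused.
#' @return The [ensemble_predict()] tibble.
#' @export
predict.aie_panel <- function(object, newdata, ...) {
  config <- object$config
  fps <- lapply(config$fingerprints, function(kind) {
    featurize_dataset(newdata, kind, config)
  })
  names(fps) <- config$fingerprints
  quant <- featurize_dataset(newdata, "quantitative", config)
  blocks <- if (isTRUE(attr(object, "multimodal"))) {
    models <- attr(object, "fusion_models")
    fused <- lapply(config$fingerprints, function(kind) {
      apply_fusion(models[[kind]], fps[[kind]], quant)
    })
    names(fused) <- paste0(config$fingerprints, "+quantitative")
    fused
  } else {
    c(fps, list(quantitative = quant))
  }
  ensemble_predict(object, blocks, ids = newdata$id,
                   smiles = newdata$smiles)
}

#' Train a deployable panel on a full labeled dataset
#'
#' Convenience wrapper used by the CLI `train` command: featurizes,
#' optionally fits fusion, trains the voter panel and attaches what
#' [predict.aie_panel()] needs.
#'
#' @param data A labeled `aie_dataset`.
#' @param config An [aie_config()].
#' @param multimodal Train on fused multi-modal features?
#' @param seed Integer seed.
#' @return An `aie_panel` ready for [predict.aie_panel()].
#' @export
train_full_panel <- function(data, config = aie_config(),
                             multimodal = FALSE, seed = 1L) {
  if (anyNA(data$label)) abort("training requires labels on every record.")
  blocks <- assemble_modes(data, config, multimodal = multimodal)
  panel <- train_panel(blocks, data$label, config,
                       seed = derive_seed(seed, "panel"))
  attr(panel, "multimodal") <- multimodal
  if (multimodal) {
    attr(panel, "fusion_models") <- attr(blocks, "fusion_models")
  }
  panel
}
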