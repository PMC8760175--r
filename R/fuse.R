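# Multi-modal feature fusion: PCA-reduce the fingerprint block, z-score
# the quantitative block, concatenate.

#' Fit a PCA + z-score fusion model
#'
#' PCA (centred, unscaled) on the binary fingerprint block with
#' `k = min(n_samples, n_features)` components by default — full rank, so
#' the projection conserves all variance — plus per-column mean/sd
#' statistics of the quantitative block for z-scoring.
#'
#' @param fingerprint_block,quantitative_block Row-aligned
#'   `feature_block`s (see [featurize_dataset()]).
#' @param k Number of principal components to retain; default
#'   `min(n_samples, n_features)`.
#' @return A `fusion_model` with loadings, explained-variance ratios and
#'   the z-score statistics.
#' @export
fit_fusion <- function(fingerprint_block, quantitative_block, k = NULL) {
  X <- block_matrix(fingerprint_block)
  Q <- block_matrix(quantitative_block)
  if (nrow(X) != nrow(Q)) {
    abort("fingerprint and quantitative blocks have mismatched rows.")
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) abort("need at least 2 samples to fit fusion.")
  kmax <- min(n, p)
  k <- if (is.null(k)) kmax else as.integer(k)
  if (k < 1L || k > kmax) {
    abort(paste0("`k` must be in 1..min(n_samples, n_features) = ", kmax))
  }

  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  # total variance over all columns, so ratios are fractions of the whole
  total_var <- sum(pc$sdev^2)
  navail <- length(pc$sdev)
  rotation <- matrix(0, p, k)
  evr <- numeric(k)
  kk <- min(k, navail)
  rotation[, seq_len(kk)] <- pc$rotation[, seq_len(kk), drop = FALSE]
  evr[seq_len(kk)] <- pc$sdev[seq_len(kk)]^2 / total_var
  colnames(rotation) <- paste0("PC", seq_len(k))

  mu <- colMeans(Q)
  sdv <- apply(Q, 2, sd)
  structure(
    list(
      components = rotation,
      component_count = k,
      explained_variance_ratio = evr,
      fingerprint_center = pc$center,
      column_means = mu,
      column_stds = sdv,
      fingerprint_mode = fingerprint_block$mode,
      quantitative_names = colnames(Q),
      n_train = n,
      schema_version = 1L
    ),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model> ", x$fingerprint_mode, " -> ", x$component_count,
      " PCs + ", length(x$column_means), " z-scored descriptors\n",
      sep = "")
  cat("  explained variance retained: ",
      format(sum(x$explained_variance_ratio), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Apply a fitted fusion model
#'
#' Projects centred fingerprints onto the retained principal axes and
#' concatenates the z-scored quantitative block. The fused width is fixed
#' by the model (`k + d`), independent of the batch being transformed;
#' constant training columns (sd 0) map to 0.
#'
#' @param model A `fusion_model`.
#' @param fingerprint_block,quantitative_block Row-aligned blocks with the
#'   fitted feature dimensions.
#' @return A `feature_block` whose matrix has `k + d` columns.
#' @export
apply_fusion <- function(model, fingerprint_block, quantitative_block) {
  if (!inherits(model, "fusion_model")) {
    abort("`model` must be a fusion_model.")
  }
  X <- block_matrix(fingerprint_block)
  Q <- block_matrix(quantitative_block)
  if (nrow(X) != nrow(Q)) abort("blocks have mismatched rows.")
  if (ncol(X) != length(model$fingerprint_center)) {
    abort("fingerprint dimension does not match the fitted model.")
  }
  if (ncol(Q) != length(model$column_means)) {
    abort("quantitative dimension does not match the fitted model.")
  }
  proj <- sweep(X, 2, model$fingerprint_center) %*% model$components
  sdv <- model$column_stds
  z <- sweep(Q, 2, model$column_means)
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  fused <- cbind(proj, z)
  colnames(fused) <- c(colnames(model$components),
                       model$quantitative_names)
  ids <- fingerprint_block$row_ids
  rownames(fused) <- ids
  new_feature_block(paste0(model$fingerprint_mode, "+quantitative"),
                    fused, ids,
                    spec = list(k = model$component_count,
                                d = length(model$column_means)))
}

block_matrix <- function(x) {
  if (inherits(x, "feature_block")) x$matrix
  else if (is.matrix(x)) x
  else abort("expected a feature_block or matrix.")
}

#' Assemble all feature matrices for one modality
#'
#' Single-modal: the four fingerprint blocks plus the quantitative block
#' (five modes). Multi-modal: each fingerprint PCA-fused with the
#' quantitative block (four modes).
#'
#' @param data An `aie_dataset`.
#' @param config An [aie_config()]; `config$fingerprints` selects the
#'   active fingerprint kinds.
#' @param multimodal Fuse each fingerprint with the quantitative block?
#' @param cache_dir Optional feature cache directory.
#' @return Named list of `feature_block`s. For the multi-modal case the
#'   fitted `fusion_model`s are attached as the `fusion_models` attribute.
#' @export
assemble_modes <- function(data, config = aie_config(),
                           multimodal = FALSE, cache_dir = NULL) {
  fps <- lapply(config$fingerprints, function(kind) {
    featurize_dataset(data, kind, config, cache_dir)
  })
  names(fps) <- config$fingerprints
  quant <- featurize_dataset(data, "quantitative", config, cache_dir)
  if (!multimodal) {
    return(c(fps, list(quantitative = quant)))
  }
  models <- lapply(fps, fit_fusion, quantitative_block = quant)
  fused <- lapply(names(fps), function(kind) {
    apply_fusion(models[[kind]], fps[[kind]], quant)
  })
  names(fused) <- paste0(config$fingerprints, "+quantitative")
  attr(fused, "fusion_models") <- models
  fused
}
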