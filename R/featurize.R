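# Dataset-level featurization: one FeatureBlock per mode.

#' Featurize a dataset in one feature mode
#'
#' Computes the molecules-by-features matrix for one of the five feature
#' modes: a 2048-bit fingerprint (`morgan`, `daylight_path`, `atom_pair`,
#' `torsion`) or the 108-dimensional `quantitative` descriptor block.
#' Rows align with the dataset order; results are deterministic, so
#' featurizing the same dataset twice is bitwise identical.
#'
#' @param data An `aie_dataset` (see [read_dataset()]).
#' @param mode Feature mode identifier.
#' @param config An [aie_config()].
#' @param cache_dir Optional directory: the matrix is stored there keyed
#'   by (dataset hash, mode, spec), with a JSON sidecar recording the
#'   provenance, and reused on the next call.
#' @return A `feature_block`: list with `mode`, `matrix` (rownames = record
#'   ids), `row_ids` and the generating `spec`.
#' @export
featurize_dataset <- function(data, mode, config = aie_config(),
                              cache_dir = NULL) {
  modes <- c(config$fingerprints, "quantitative")
  if (!mode %in% c("morgan", "daylight_path", "atom_pair", "torsion",
                   "quantitative")) {
    abort(paste0("unknown feature mode: ", mode))
  }
  if (!mode %in% modes) {
    abort(paste0("mode '", mode, "' is disabled in this config."))
  }
  key <- cache_key(data, mode, config)
  if (!is.null(cache_dir)) {
    hit <- cache_read(cache_dir, key)
    if (!is.null(hit)) return(hit)
  }

  if (mode == "quantitative") {
    mat <- compute_descriptors(setNames(data$smiles, data$id),
                               config$descriptors)
  } else {
    spec <- fingerprint_spec_for(mode, config)
    mols <- parse_molecules(data$smiles, data$id)
    bad <- vapply(mols, is.null, logical(1))
    if (any(bad)) {
      abort(paste0("featurization failed for record(s): ",
                   paste(data$id[bad], collapse = ", ")))
    }
    mat <- t(vapply(mols, function(m) {
      fold_bits(fingerprint_features(m, spec), spec$n_bits)
    }, integer(spec$n_bits)))
    storage.mode(mat) <- "double"
    colnames(mat) <- paste0("bit", seq_len(ncol(mat)))
  }
  rownames(mat) <- data$id
  block <- new_feature_block(mode, mat, data$id,
                             spec = if (mode == "quantitative") {
                               list(descriptors = config$descriptors)
                             } else {
                               unclass(fingerprint_spec_for(mode, config))
                             })
  if (!is.null(cache_dir)) cache_write(cache_dir, key, block)
  block
}

new_feature_block <- function(mode, matrix, row_ids, spec = NULL) {
  stopifnot(nrow(matrix) == length(row_ids))
  structure(list(mode = mode, matrix = matrix, row_ids = row_ids,
                 spec = spec),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat("<feature_block> mode=", x$mode, ": ", nrow(x$matrix), " x ",
      ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.feature_block <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = x$row_ids),
                   tibble::as_tibble(x$matrix, .name_repair = "minimal"))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

cache_key <- function(data, mode, config) {
  payload <- paste(
    paste(data$id, data$smiles, collapse = ";"),
    mode, config$n_bits, config$radius, config$min_path, config$max_path,
    paste(config$descriptors, collapse = ","),
    sep = "#"
  )
  sprintf("%s-%010.0f", mode, fnv1a32(payload))
}

cache_read <- function(cache_dir, key) {
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

cache_write <- function(cache_dir, key, block) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(block, file.path(cache_dir, paste0(key, ".rds")))
  sidecar <- list(
    key = key, mode = block$mode,
    dims = dim(block$matrix), spec = block$spec,
    chemminer_version = as.character(utils::packageVersion("ChemmineR"))
  )
  jsonlite::write_json(sidecar,
                       file.path(cache_dir, paste0(key, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
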