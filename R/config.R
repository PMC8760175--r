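#' Pipeline configuration
#'
#' Collects every tunable switch of the prediction pipeline in one list.
#' Defaults reproduce the study protocol: 2048-bit fingerprints, the
#' 108-descriptor quantitative block, five classifier families, outer
#' 10-fold / inner 5-fold nested cross-validation, global PCA fit and
#' majority-class tie-breaking.
#'
#' @param n_bits Fingerprint width in bits.
#' @param radius Morgan radius.
#' @param min_path,max_path Linear-path fingerprint bounds (bonds).
#' @param descriptors Ordered descriptor name list (default: all 108).
#' @param fingerprints Active fingerprint kinds.
#' @param families Active classifier families.
#' @param outer_folds,inner_folds Cross-validation fold counts.
#' @param fold_safe If `TRUE`, PCA/z-score fusion is refitted inside each
#'   outer training fold (leakage-safe). Default `FALSE` fits once on the
#'   full dataset, which is what uniquely reproduces an
#'   n-sample-dimensional PCA block on the full data.
#' @param tie_break Even-panel tie policy: `"majority-class"`, `"aie"`,
#'   `"acq"` or `"score"` (mean voter score).
#' @param selection_metric Inner-CV model-selection metric: `"accuracy"`
#'   (default) or `"f1"`.
#' @param grid_points_per_axis Optional cap on grid points per
#'   hyperparameter axis (evenly thinned, endpoints kept) for faster runs;
#'   `Inf` keeps the full grids.
#' @param mlp_size Hidden-layer width of the multilayer perceptron.
#' @param mlp_maxit Maximum optimiser iterations for the perceptron.
#' @param gb_nrounds,gb_eta Fixed boosting rounds and learning rate of the
#'   gradient-boosting family.
#' @return An `aie_config` list.
#' @export
aie_config <- function(n_bits = 2048L,
                       radius = 2L,
                       min_path = 1L,
                       max_path = 7L,
                       descriptors = descriptor_names(),
                       fingerprints = c("morgan", "daylight_path",
                                        "atom_pair", "torsion"),
                       families = c("logistic_regression", "knn",
                                    "gradient_boost", "random_forest",
                                    "mlp"),
                       outer_folds = 10L,
                       inner_folds = 5L,
                       fold_safe = FALSE,
                       tie_break = c("majority-class", "aie", "acq",
                                     "score"),
                       selection_metric = c("accuracy", "f1"),
                       grid_points_per_axis = Inf,
                       mlp_size = 4L,
                       mlp_maxit = 60L,
                       gb_nrounds = 100L,
                       gb_eta = 0.1) {
  tie_break <- match.arg(tie_break)
  selection_metric <- match.arg(selection_metric)
  fingerprints <- match.arg(fingerprints, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(n_bits > 0, radius >= 0, min_path >= 1,
            min_path <= max_path, outer_folds >= 2, inner_folds >= 2,
            mlp_size >= 1, mlp_maxit >= 1, gb_nrounds >= 1, gb_eta > 0)
  structure(
    list(
      n_bits = as.integer(n_bits), radius = as.integer(radius),
      min_path = as.integer(min_path), max_path = as.integer(max_path),
      descriptors = descriptors, fingerprints = fingerprints,
      families = families,
      outer_folds = as.integer(outer_folds),
      inner_folds = as.integer(inner_folds),
      fold_safe = isTRUE(fold_safe), tie_break = tie_break,
      selection_metric = selection_metric,
      grid_points_per_axis = grid_points_per_axis,
      mlp_size = as.integer(mlp_size),
      mlp_maxit = as.integer(mlp_maxit),
      gb_nrounds = as.integer(gb_nrounds), gb_eta = gb_eta
    ),
    class = "aie_config"
  )
}

fingerprint_spec_for <- function(kind, config) {
  fingerprint_spec(kind, n_bits = config$n_bits, radius = config$radius,
                   min_path = config$min_path, max_path = config$max_path)
}

# Deterministic fan-out of the global seed into per-stage seeds
# (kept below 2^31 so they are valid R integers).
derive_seed <- function(seed, stage) {
  as.integer((fnv1a32(paste0(seed, "/", stage)) %% 2147483647) + 1)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Run manifest: everything needed to re-run deterministic stages
# bit-identically.
run_manifest <- function(config, seed, extra = list()) {
  c(
    list(
      package_version = as.character(utils::packageVersion("aievote")),
      r_version = as.character(getRversion()),
      chemminer_version =
        as.character(utils::packageVersion("ChemmineR")),
      seed = seed,
      config = unclass(config),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extra
  )
}
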