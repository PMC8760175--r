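# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small planted-rule dataset used by most pipeline tests
tiny_dataset <- function() {
  cached("tiny48", generate_dataset(n = 48, n_positive = 20, seed = 101))
}

# the full study-scale synthetic dataset (acceptance scale)
full_dataset <- function() {
  cached("full356", generate_dataset(n = 356, n_positive = 134,
                                     label_noise = 0, seed = 42))
}

full_block <- function(mode, config = aie_config()) {
  cached(paste0("block356.", mode),
         featurize_dataset(full_dataset(), mode, config))
}

# linearly separable 2-feature toy set (20 + 20 points, unit margin)
toy_separable <- function(n_per_class = 20, seed = 7) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class, -2, 0.3)),
    cbind(rnorm(n_per_class, 2, 0.3), rnorm(n_per_class, 2, 0.3))
  )
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# quick config for CV tests: one fingerprint, thin grids, small nets
quick_config <- function(...) {
  args <- utils::modifyList(
    list(fingerprints = "morgan", outer_folds = 3L, inner_folds = 3L,
         grid_points_per_axis = 2, mlp_maxit = 40L, gb_nrounds = 30L),
    list(...)
  )
  do.call(aie_config, args)
}

write_tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(df, f, na = "")
  f
}
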