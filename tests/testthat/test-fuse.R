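make_block <- function(mat, mode = "morgan") {
  new_feature_block <- getFromNamespace("new_feature_block", "aievote")
  new_feature_block(mode, mat, rownames(mat) %||%
                      paste0("m", seq_len(nrow(mat))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("full-rank PCA conserves variance and reconstructs exactly", {
  set.seed(2)
  X <- matrix(rbinom(10 * 2048, 1, 0.15), 10, 2048)
  Q <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(NULL, paste0("q", 1:5)))
  fm <- fit_fusion(make_block(X), make_block(Q, "quantitative"))
  expect_equal(fm$component_count, 10L)
  expect_equal(sum(fm$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(fm$explained_variance_ratio) <= 1e-12))
  expect_true(all(fm$explained_variance_ratio >= -1e-15))

  # oracle: full SVD reconstruction of the centred matrix
  proj <- sweep(X, 2, fm$fingerprint_center) %*% fm$components
  recon <- proj %*% t(fm$components)
  centred <- sweep(X, 2, fm$fingerprint_center)
  expect_lt(norm(recon - centred, "F") / max(norm(centred, "F"), 1),
            1e-8)
})

test_that("a rank-1 matrix concentrates all variance in one component", {
  base <- rbinom(2048, 1, 0.2)
  scal <- c(1, 2, 3, 4.5, -1)
  X <- outer(scal, base)
  Q <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, paste0("q", 1:3)))
  fm <- fit_fusion(make_block(X), make_block(Q, "quantitative"))
  expect_equal(fm$explained_variance_ratio[1], 1, tolerance = 1e-9)
  expect_equal(sum(fm$explained_variance_ratio[-1]), 0, tolerance = 1e-9)
})

test_that("fusion z-scores the quantitative block and fixes the width", {
  set.seed(3)
  X <- matrix(rbinom(12 * 64, 1, 0.3), 12, 64)
  Q <- cbind(matrix(rnorm(12 * 4), 12, 4), constant = 7)
  colnames(Q) <- paste0("q", 1:5)
  fpb <- make_block(X)
  qb <- make_block(Q, "quantitative")
  fm <- fit_fusion(fpb, qb)
  fused <- apply_fusion(fm, fpb, qb)
  expect_equal(ncol(fused$matrix), fm$component_count + 5L)
  zpart <- fused$matrix[, (fm$component_count + 1):ncol(fused$matrix)]
  expect_equal(colMeans(zpart[, 1:4]), rep(0, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(zpart[, 1:4], 2, sd), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # constant column maps to zeros, not NaN
  expect_true(all(zpart[, 5] == 0))

  # full-rank projection is an isometry on the training rows
  D0 <- dist(sweep(X, 2, fm$fingerprint_center))
  D1 <- dist(fused$matrix[, seq_len(fm$component_count)])
  expect_equal(as.numeric(D1), as.numeric(D0), tolerance = 1e-6)

  # row-wise equivariance: permuting inputs permutes outputs
  perm <- sample(nrow(X))
  fused_p <- apply_fusion(fm, make_block(X[perm, , drop = FALSE]),
                          make_block(Q[perm, , drop = FALSE],
                                     "quantitative"))
  expect_equal(unname(fused_p$matrix), unname(fused$matrix[perm, ]),
               tolerance = 1e-10)
})

test_that("explained variance is monotone and k is capped", {
  set.seed(4)
  X <- matrix(rbinom(8 * 32, 1, 0.4), 8, 32)
  Q <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "q1"))
  cums <- vapply(1:8, function(k) {
    fm <- fit_fusion(make_block(X), make_block(Q, "quantitative"), k = k)
    sum(fm$explained_variance_ratio)
  }, numeric(1))
  expect_true(all(diff(cums) >= -1e-12))
  expect_equal(cums[8], 1, tolerance = 1e-9)
  expect_error(fit_fusion(make_block(X), make_block(Q, "quantitative"),
                          k = 9), "min")
  expect_error(fit_fusion(make_block(X),
                          make_block(Q[1:7, , drop = FALSE],
                                     "quantitative")), "mismatch")
  expect_error(fit_fusion(make_block(X[1, , drop = FALSE]),
                          make_block(Q[1, , drop = FALSE],
                                     "quantitative")), "2 samples")
})

test_that("assemble_modes yields 5 single-modal and 4 fused modes", {
  ds <- tiny_dataset()[1:8, ]
  cfg <- aie_config()
  single <- assemble_modes(ds, cfg, multimodal = FALSE)
  expect_named(single, c("morgan", "daylight_path", "atom_pair",
                         "torsion", "quantitative"))
  multi <- assemble_modes(ds, cfg, multimodal = TRUE)
  expect_length(multi, 4L)
  expect_true(all(grepl("\\+quantitative$", names(multi))))
  # every fused block: k = min(n, p) = 8 components + 108 descriptors
  expect_true(all(vapply(multi, function(b) ncol(b$matrix),
                         numeric(1)) == 8 + 108))
  cfg3 <- aie_config(fingerprints = c("morgan", "atom_pair",
                                      "torsion"))
  expect_length(assemble_modes(ds, cfg3, multimodal = TRUE), 3L)
})

test_that("a fitted fusion fixes the dimension of any future batch", {
  ds <- tiny_dataset()
  cfg <- aie_config(fingerprints = "morgan")
  fpb <- featurize_dataset(ds[1:10, ], "morgan", cfg)
  qb <- featurize_dataset(ds[1:10, ], "quantitative", cfg)
  fm <- fit_fusion(fpb, qb)
  new_fp <- featurize_dataset(ds[11:13, ], "morgan", cfg)
  new_q <- featurize_dataset(ds[11:13, ], "quantitative", cfg)
  fused <- apply_fusion(fm, new_fp, new_q)
  expect_equal(dim(fused$matrix), c(3L, 10L + 108L))
})
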