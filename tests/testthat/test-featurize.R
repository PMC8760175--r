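fp_kinds <- c("morgan", "daylight_path", "atom_pair", "torsion")

test_that("every fingerprint kind emits the configured width", {
  for (kind in fp_kinds) {
    fp <- compute_fingerprint("CCOc1ccccc1", fingerprint_spec(kind))
    expect_length(fp, 2048L)
    expect_true(all(fp %in% c(0L, 1L)))
  }
  fp512 <- compute_fingerprint("CCO", fingerprint_spec("morgan",
                                                       n_bits = 512))
  expect_length(fp512, 512L)
})

test_that("morgan on-bit counts respect the environment enumeration bound", {
  # methane: a single heavy atom has one circular environment
  expect_lte(sum(compute_fingerprint("C", fingerprint_spec("morgan"))), 1)
  # ethanol, radius 2: 3 atoms x radii {0,1,2} gives at most 9 distinct
  # substructures, each setting at most one bit
  expect_lte(sum(compute_fingerprint("CCO", fingerprint_spec("morgan"))),
             9)
})

test_that("fingerprints are invariant to atom order and explicit hydrogens", {
  for (kind in fp_kinds) {
    spec <- fingerprint_spec(kind)
    expect_identical(compute_fingerprint("OCC", spec),
                     compute_fingerprint("CCO", spec))
    expect_identical(compute_fingerprint("C([H])([H])([H])C", spec),
                     compute_fingerprint("CC", spec))
  }
})

test_that("fingerprint spec validation rejects bad parameters", {
  expect_error(fingerprint_spec("morgan", n_bits = 0), "n_bits")
  expect_error(fingerprint_spec("morgan", radius = -1), "radius")
  expect_error(fingerprint_spec("daylight_path", min_path = 5,
                                max_path = 3), "min_path")
  expect_error(compute_fingerprint("C(", fingerprint_spec("morgan")),
               "invalid SMILES")
})

test_that("the default descriptor set is 108 = 20 1D + 88 2D", {
  expect_length(descriptor_names(), 108L)
  expect_length(descriptor_names("1d"), 20L)
  expect_length(descriptor_names("2d"), 88L)
  expect_false(anyDuplicated(descriptor_names()) > 0)
})

test_that("descriptor values match closed-form oracles", {
  d <- compute_descriptors(c(etoh = "CCO", bz = "c1ccccc1"))
  expect_equal(dim(d), c(2L, 108L))
  expect_true(all(is.finite(d)))
  # molecular weight oracle: sum of standard atomic masses
  expect_equal(d["etoh", "mw"], 2 * 12.011 + 6 * 1.008 + 15.999,
               tolerance = 1e-6)
  expect_equal(d["bz", "n_aromatic_rings"], 1)
  expect_equal(d["bz", "n_heavy"], 6)
  expect_equal(d["bz", "n_aromatic_atoms"], 6)
  # terminal single bonds are not rotatable: ethanol has none, butane one
  expect_equal(d["etoh", "n_rotatable"], 0)
  expect_equal(compute_descriptors("CCCC", "n_rotatable")[1, 1], 1)
  # Wiener index of a 3-atom path graph: 1+1+2
  expect_equal(d["etoh", "wiener"], 4)
  expect_error(compute_descriptors("CCO", c("mw", "made_up")), "unknown")
  expect_error(compute_descriptors("CCO", c("mw", "mw")), "duplicates")
})

test_that("featurize_dataset aligns rows, is deterministic, and caches", {
  ds <- tiny_dataset()[1:10, ]
  cfg <- aie_config(fingerprints = "morgan")
  fb <- featurize_dataset(ds, "morgan", cfg)
  expect_equal(dim(fb$matrix), c(10L, 2048L))
  expect_true(all(fb$matrix %in% c(0, 1)))
  expect_identical(rownames(fb$matrix), ds$id)
  qb <- featurize_dataset(ds, "quantitative", cfg)
  expect_equal(dim(qb$matrix), c(10L, 108L))

  fb2 <- featurize_dataset(ds, "morgan", cfg)
  expect_identical(fb$matrix, fb2$matrix)

  cache <- tempfile("fpcache")
  f1 <- featurize_dataset(ds, "morgan", cfg, cache_dir = cache)
  expect_true(length(list.files(cache, pattern = "rds$")) == 1L)
  f2 <- featurize_dataset(ds, "morgan", cfg, cache_dir = cache)
  expect_identical(f1$matrix, f2$matrix)

  expect_error(featurize_dataset(ds, "3d_shape", cfg), "unknown")
  expect_error(featurize_dataset(ds, "torsion", cfg), "disabled")
})

test_that("feature count is constant across molecules of any size", {
  smis <- c("C", "CC", "CCCCCCCCCC",
            "c1ccc2cc3ccccc3cc2c1",
            "C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1")
  for (kind in fp_kinds) {
    widths <- vapply(smis, function(s) {
      length(compute_fingerprint(s, fingerprint_spec(kind)))
    }, integer(1))
    expect_true(all(widths == 2048L))
  }
  expect_equal(ncol(compute_descriptors(smis)), 108L)
})
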