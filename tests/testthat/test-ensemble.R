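test_that("voter enumeration covers the full cartesian product", {
  fams <- c("logistic_regression", "knn", "gradient_boost",
            "random_forest", "mlp")
  single <- enumerate_voters(fams, c("morgan", "daylight_path",
                                     "atom_pair", "torsion",
                                     "quantitative"))
  expect_equal(nrow(single), 25L)
  multi <- enumerate_voters(fams, paste0(c("morgan", "daylight_path",
                                           "atom_pair", "torsion"),
                                         "+quantitative"))
  expect_equal(nrow(multi), 20L)
  expect_equal(nrow(enumerate_voters("knn", "morgan")), 1L)
  # family-major order
  expect_equal(single$family[1:5], rep("logistic_regression", 5))
  expect_error(enumerate_voters(character(0), "morgan"), "non-empty")
})

test_that("majority_vote follows the tally and the tie policy", {
  v <- majority_vote(c(rep("AIE", 13), rep("ACQ", 12)))
  expect_equal(v$final, "AIE")
  expect_equal(v$vote_fraction, 0.52)
  expect_false(v$tie)

  v2 <- majority_vote(rep("ACQ", 25))
  expect_equal(v2$final, "ACQ")
  expect_equal(v2$vote_fraction, 0)

  tied <- c(rep("AIE", 10), rep("ACQ", 10))
  expect_equal(majority_vote(tied, majority_class = "ACQ")$final, "ACQ")
  expect_true(majority_vote(tied)$tie)
  expect_equal(majority_vote(tied, tie_break = "aie")$final, "AIE")
  expect_equal(majority_vote(tied, tie_break = "acq")$final, "ACQ")
  expect_equal(majority_vote(tied, tie_break = "score",
                             scores = rep(0.9, 20))$final, "AIE")
  expect_error(majority_vote(character(0)), "empty")
  expect_error(majority_vote(c("AIE", "maybe")), "AIE")

  # derived tally oracle on a 3-voter panel
  v3 <- majority_vote(c("AIE", "AIE", "ACQ"))
  expect_equal(v3$final, "AIE")
  expect_equal(v3$vote_fraction, 2 / 3)
})

test_that("vote properties: conservation, monotonicity, odd-panel ties", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    votes <- sample(c("AIE", "ACQ"), n, replace = TRUE)
    v <- majority_vote(votes)
    expect_equal(round(v$vote_fraction * n) +
                   sum(votes == "ACQ"), n)  # tally conservation
    if (n %% 2 == 1) expect_false(v$tie)
    # converting one ACQ vote to AIE never flips AIE -> ACQ
    if (any(votes == "ACQ")) {
      votes2 <- votes
      votes2[which(votes2 == "ACQ")[1]] <- "AIE"
      v2 <- majority_vote(votes2)
      if (v$final == "AIE") expect_equal(v2$final, "AIE")
    }
  }
})

test_that("a trained panel votes, predicts and round-trips new data", {
  ds <- tiny_dataset()
  cfg <- quick_config(families = c("logistic_regression", "knn"))
  blocks <- assemble_modes(ds, cfg, multimodal = FALSE)
  panel <- suppressWarnings(
    train_panel(blocks, ds$label, cfg, seed = 4))
  expect_length(panel$voters, 2 * 2)  # 2 families x (1 fp + quantitative)
  pred <- ensemble_predict(panel, blocks, ids = ds$id,
                           smiles = ds$smiles)
  expect_equal(nrow(pred), nrow(ds))
  expect_true(all(pred$votes_AIE + pred$votes_ACQ ==
                    length(panel$voters)))
  expect_true(all(pred$predicted_label %in% c("AIE", "ACQ")))
  # non-tied calls agree with the tally argmax
  nt <- pred$votes_AIE != pred$votes_ACQ
  expect_equal(pred$predicted_label[nt],
               ifelse(pred$votes_AIE[nt] > pred$votes_ACQ[nt], "AIE",
                      "ACQ"))
  expect_error(ensemble_predict(panel, blocks["morgan"]), "missing")

  # planted rule is learnable: in-sample ensemble accuracy is high
  expect_gte(mean(pred$predicted_label == as.character(ds$label)), 0.9)
})

test_that("a panel of identical voters equals the single model", {
  ds <- tiny_dataset()[1:24, ]
  cfg <- quick_config(families = "knn")
  blocks <- assemble_modes(ds, cfg, multimodal = FALSE)
  keep <- blocks["morgan"]
  panel <- suppressWarnings(train_panel(keep, ds$label, cfg, seed = 8))
  single <- panel$voters[[1]]
  # duplicate the same fitted voter three times
  panel$voters <- rep(panel$voters, 3)
  names(panel$voters) <- paste0("v", 1:3)
  panel$skeleton <- tibble::tibble(voter = paste0("v", 1:3),
                                   family = "knn", mode = "morgan")
  pred <- ensemble_predict(panel, keep)
  expect_equal(pred$predicted_label,
               unname(predict_labels(single,
                                     blocks$morgan$matrix)))
  expect_true(all(pred$vote_fraction %in% c(0, 1)))
})

test_that("train_full_panel + predict work end-to-end on new molecules", {
  ds <- tiny_dataset()
  cfg <- quick_config(families = "logistic_regression")
  panel <- suppressWarnings(
    train_full_panel(ds[1:40, ], cfg, multimodal = TRUE, seed = 6))
  newdata <- ds[41:48, ]
  pred <- suppressWarnings(predict(panel, newdata))
  expect_equal(pred$id, newdata$id)
  expect_equal(nrow(pred), 8L)
  expect_true(all(pred$votes_AIE + pred$votes_ACQ ==
                    length(panel$voters)))
})
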