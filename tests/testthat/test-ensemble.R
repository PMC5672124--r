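test_that("thresholding follows the 0.5 rule", {
  expect_equal(threshold_output(0.5), 1L)
  expect_equal(threshold_output(0.49), 0L)
  expect_equal(threshold_output(1.0), 1L)
  expect_equal(threshold_output(c(0, 0.2, 0.5, 0.9)), c(0L, 0L, 1L, 1L))
  expect_error(threshold_output(1.2), "outside")
  expect_error(threshold_output(NaN), "finite")
})

test_that("majority voting equals the brute-force plurality on all 2^3 inputs", {
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    v <- c(a, b, c)
    expect_equal(majority_vote(v), oracle_plurality(v))
  }
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 0)), 0L)
  expect_error(majority_vote(c(1, 0)), "three")
  expect_error(majority_vote(c(1, 0, 2)), "0 or 1")
})

make_stage_fixture <- function(seed = 1) {
  blobs <- make_blobs(n_per_class = 60, seed = seed)
  train_stage(blobs$x, blobs$y, hyper = classifier_hyper(rbf_centers = 10),
              seed = seed)
}

test_that("a trained stage votes with three classifiers and fuses them", {
  stage <- make_stage_fixture()
  blobs <- make_blobs(n_per_class = 60, seed = 1)
  v <- stage_votes(stage, blobs$x)
  expect_equal(dim(v), c(120, 3))
  expect_true(all(v %in% c(0L, 1L)))
  fused <- stage_predict(stage, blobs$x)
  expect_gte(mean(fused == blobs$y), 0.95)
})

test_that("identical base classifiers make fusion a no-op", {
  blobs <- make_blobs(n_per_class = 30, seed = 2)
  m <- fbann_train(apply_scaler(fit_scaler(blobs$x), blobs$x), blobs$y,
                   seed = 3)
  stage <- structure(list(scaler = fit_scaler(blobs$x),
                          models = list(a = m, b = m, c = m),
                          threshold = 0.5), class = "vote_stage")
  single <- threshold_output(
    base_score(m, apply_scaler(stage$scaler, blobs$x)))
  expect_identical(stage_predict(stage, blobs$x), single)
})

test_that("the two-stage decoder routes trials through both stages", {
  feats <- make_feature_fixture()
  model <- train_ensemble(feats, hyper = classifier_hyper(rbf_centers = 10),
                          seed = 5)
  dec <- decode_trials(model, feats)
  expect_true(all(dec$decision %in% c("rest", "left", "right")))
  # stage 2 is invoked exactly when stage 1 says movement
  expect_equal(sum(!is.na(dec$s2_fbann)), sum(dec$stage1_vote == 1L))
  expect_true(all(is.na(dec$s2_fbann[dec$decision == "rest"])))
  # on this separable fixture the decoding is accurate
  expect_gte(mean(dec$decision == feats$label), 0.9)
})

test_that("stage composition follows the vote encodings", {
  # stage-1 majority rest (0,0,1) -> rest regardless of stage 2
  expect_equal(majority_vote(c(0, 0, 1)), 0L)
  # stage-1 (1,1,1) then stage-2 (1,1,0) -> left under the left=1 encoding
  s1 <- majority_vote(c(1, 1, 1))
  s2 <- majority_vote(c(1, 1, 0))
  expect_equal(s1, 1L)
  expect_equal(c("right", "left")[s2 + 1], "left")
})

test_that("single-base decoding uses the same state machine", {
  feats <- make_feature_fixture()
  model <- train_ensemble(feats, hyper = classifier_hyper(rbf_centers = 10),
                          seed = 5)
  for (b in c("fbann", "rbfnn", "pnn")) {
    db <- decode_trials_base(model, feats, base = b)
    expect_true(all(db %in% c("rest", "left", "right")))
    expect_gte(mean(db == feats$label), 0.8)
  }
})

test_that("bootstrap balancing only augments the training side", {
  feats <- make_feature_fixture(n = 20)
  # unbalance: drop most rest trials
  feats <- feats[c(1:7, 21:60), ]
  fcols <- setdiff(names(feats), c("trial_id", "label"))
  bal <- lfpdecode:::balance_binary(as.matrix(feats[, fcols]),
                                    as.integer(feats$label != "rest"),
                                    list(r = 5, gaussian_mu = 0,
                                         gaussian_sigma = 1), seed = 2)
  expect_equal(sum(bal$y == 0), sum(bal$y == 1))
  expect_true(all(bal$provenance[seq_len(nrow(feats))] == "original"))
  expect_true(any(bal$provenance == "bootstrap"))
})
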