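test_that("epoch segmentation obeys window arithmetic and boundaries", {
  fs <- 256
  env <- make_flat_envelopes(20 * fs)
  ev <- data.frame(stimulus_time_s = 9.6, response_time_s = 10,
                   label = "left")
  ep <- segment_epoch(env, fs, ev, movement_epoch_spec())
  expect_equal(dim(ep$block), c(2, 7, 4 * fs))   # 1024 samples per band
  expect_false(ep$excluded)

  # event too close to the recording start
  ev2 <- data.frame(stimulus_time_s = 0.8, response_time_s = 1.0,
                    label = "right")
  expect_error(segment_epoch(env, fs, ev2, movement_epoch_spec()),
               "exceeds recording bounds")

  # rest epochs are 2 s wide, anchored at the stimulus
  evr <- data.frame(stimulus_time_s = 10, response_time_s = NA,
                    label = "rest")
  ep <- segment_epoch(env, fs, evr, rest_epoch_spec())
  expect_equal(dim(ep$block)[3], 2 * fs)
})

test_that("inter-event intervals outside 1-5 s flag the epoch excluded", {
  fs <- 256
  env <- make_flat_envelopes(30 * fs)
  ev <- data.frame(stimulus_time_s = 10, response_time_s = 10.4,
                   label = "left")
  spec <- movement_epoch_spec()
  expect_false(segment_epoch(env, fs, ev, spec,
                             prev_time_s = 8, next_time_s = 12)$excluded)
  # neighbor 0.5 s before -> excluded
  expect_true(segment_epoch(env, fs, ev, spec,
                            prev_time_s = 9.5)$excluded)
  # neighbor more than 5 s after -> excluded
  expect_true(segment_epoch(env, fs, ev, spec,
                            next_time_s = 16)$excluded)
  # missing neighbors are fine
  expect_false(segment_epoch(env, fs, ev, spec)$excluded)
})

test_that("features are window means in side x band x window order", {
  fs <- 256
  env <- make_flat_envelopes(20 * fs, value = 2.5)
  ev <- data.frame(stimulus_time_s = 9.6, response_time_s = 10,
                   label = "left")
  ep <- segment_epoch(env, fs, ev, movement_epoch_spec())
  f <- extract_features(ep)
  expect_length(f, 70)
  expect_true(all(abs(f - 2.5) < 1e-12))
  expect_identical(names(f), feature_names())

  # excluded epochs refuse feature extraction
  ep$excluded <- TRUE
  expect_error(extract_features(ep), "excluded")
})

test_that("feature windows shift exactly with the event time", {
  fs <- 256
  n <- 20 * fs
  # a ramp envelope makes window means encode absolute sample position
  ramp <- matrix(seq_len(n), n, 7)
  colnames(ramp) <- band_definitions()$name
  env <- list(left = ramp, right = ramp)
  spec <- movement_epoch_spec()
  f0 <- extract_features(segment_epoch(
    env, fs, data.frame(stimulus_time_s = 9.6, response_time_s = 10,
                        label = "left"), spec))
  k <- 13
  f1 <- extract_features(segment_epoch(
    env, fs, data.frame(stimulus_time_s = 9.6 + k / fs,
                        response_time_s = 10 + k / fs,
                        label = "left"), spec))
  expect_true(all(abs((f1 - f0) - k) < 1e-9))
})

test_that("movement epochs show suppressed beta relative to rest epochs", {
  cfg <- sim_config(n_left = 12, n_right = 12, n_rest = 12,
                    band_modulation = c(delta = 1, theta = 1, alpha = 1,
                                        low_beta = 0.4, high_beta = 0.4,
                                        low_gamma = 1, high_gamma = 1),
                    seed = 31)
  sess <- preprocess_session(simulate_session(cfg))
  feats <- session_features(sess)
  beta_cols <- grep("(low|high)_beta", names(feats), value = TRUE)
  mov <- rowMeans(feats[feats$label != "rest", beta_cols])
  rest <- rowMeans(feats[feats$label == "rest", beta_cols])
  expect_lt(mean(mov), mean(rest))
})
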