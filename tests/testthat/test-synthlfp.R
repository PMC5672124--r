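test_that("identical config and seed give bit-identical sessions", {
  cfg <- sim_config(n_left = 4, n_right = 4, n_rest = 4, seed = 5)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$signals, b$signals)
  expect_identical(a$events, b$events)
  # and the simulator does not disturb the caller's RNG stream
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(simulate_session(cfg)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(fs_raw = 100), "fs_raw")
  expect_error(sim_config(n_left = 0), "n_left")
  expect_error(sim_config(inter_event_gap_s = c(0.5, 5)),
               "inter_event_gap_s")
  bad_mod <- c(delta = 1, theta = 1, alpha = 1, low_beta = -1,
               high_beta = 1, low_gamma = 1, high_gamma = 1)
  expect_error(sim_config(band_modulation = bad_mod), "band_modulation")
})

test_that("event tables respect protocol invariants", {
  cfg <- sim_config(n_left = 10, n_right = 7, n_rest = 5, seed = 8)
  sess <- simulate_session(cfg)
  ev <- sess$events
  expect_equal(nrow(ev), 22)
  expect_true(all(diff(ev$stimulus_time_s) >= 1 - 1e-9))
  expect_true(all(diff(ev$stimulus_time_s) <= 5 + 1e-9))
  mov <- ev$label != "rest"
  expect_true(all(ev$response_time_s[mov] > ev$stimulus_time_s[mov]))
  expect_true(all(is.na(ev$response_time_s[!mov])))
})

test_that("trial summaries reproduce the per-patient bookkeeping", {
  mk <- function(nl, nr) {
    stim <- 3 + cumsum(rep(2, nl + nr))
    ev <- data.frame(stimulus_time_s = stim, response_time_s = stim + 0.4,
                     label = c(rep("left", nl), rep("right", nr)))
    new_lfp_session(list(left = numeric(round(max(stim) + 3) * 100),
                         right = numeric(round(max(stim) + 3) * 100)),
                    100, ev)
  }
  s <- session_trial_summary(mk(52, 41))
  expect_equal(s$total, 93)
  expect_equal(unname(s$counts["left"]), 52)
  s <- session_trial_summary(mk(113, 89))
  expect_equal(s$total, 202)
  expect_equal(s$imbalance, abs(113 - 89) / 202)
  s <- session_trial_summary(mk(10, 10))
  expect_equal(s$imbalance, 0)
})

test_that("spectral content shows the 50 Hz line and a 1/f slope", {
  cfg <- sim_config(n_left = 2, n_right = 2, n_rest = 2,
                    line_amp = 0.5, noise_exponent = -1, seed = 13)
  sess <- simulate_session(cfg)
  x <- sess$signals$left
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * cfg$fs_raw / n
  half <- freqs <= 1000
  p <- p[half]; freqs <- freqs[half]
  band_power <- function(lo, hi) mean(p[freqs >= lo & freqs < hi])
  # local maximum at the line frequency
  expect_gt(band_power(49.5, 50.5),
            2 * max(band_power(45, 48), band_power(52, 55)))
  # negative log-log slope of the background (line region excluded)
  sel <- freqs > 1 & freqs < 45
  fit <- stats::lm(log(p[sel]) ~ log(freqs[sel]))
  expect_lt(unname(stats::coef(fit)[2]), 0)
})

test_that("configured band gains are recovered from envelope ratios", {
  # beta ERD gain 0.5; gaps kept at 3-5 s so the 1-2 s pre-response
  # baseline is never contaminated by the preceding trial's modulation
  cfg <- sim_config(n_left = 50, n_right = 50, n_rest = 4,
                    band_modulation = c(delta = 1, theta = 1, alpha = 1,
                                        low_beta = 0.5, high_beta = 1,
                                        low_gamma = 1, high_gamma = 1),
                    delta_burst_amp = 0, line_amp = 0,
                    inter_event_gap_s = c(3, 5), seed = 7)
  sess <- preprocess_session(simulate_session(cfg))
  fs <- sess$fs
  bp <- signal::butter(4, c(13, 20) / (fs / 2), type = "pass")
  env <- lapply(sess$signals, function(ch)
    oracle_envelope(as.numeric(signal::filtfilt(bp, ch))))
  ev <- sess$events
  ratio_for <- function(channel_of) {
    vapply(which(ev$label != "rest"), function(i) {
      ch <- channel_of(ev$label[i])
      r <- ev$response_time_s[i]
      mean(env[[ch]][round(r * fs):round((r + 0.35) * fs)]) /
        mean(env[[ch]][round((r - 2) * fs):round((r - 1) * fs)])
    }, numeric(1))
  }
  contra <- ratio_for(function(l) if (l == "left") "right" else "left")
  ipsi <- ratio_for(function(l) if (l == "left") "left" else "right")
  expect_lt(abs(mean(contra) - 0.5), 0.1)
  # contralateral suppression is the stronger one
  expect_lt(mean(contra), mean(ipsi))
})

test_that("a null-modulation session shows no movement-locked band change", {
  cfg <- sim_config(n_left = 25, n_right = 25, n_rest = 4,
                    band_modulation = c(delta = 1, theta = 1, alpha = 1,
                                        low_beta = 1, high_beta = 1,
                                        low_gamma = 1, high_gamma = 1),
                    delta_burst_amp = 0, line_amp = 0,
                    inter_event_gap_s = c(3, 5), seed = 17)
  sess <- preprocess_session(simulate_session(cfg))
  fs <- sess$fs
  defs <- band_definitions()
  ev <- sess$events
  mov <- which(ev$label != "rest")
  for (b in c("alpha", "low_beta", "low_gamma")) {
    i <- match(b, defs$name)
    bp <- signal::butter(2, pmax(c(defs$f_lo[i], defs$f_hi[i]), 1) / (fs / 2),
                         type = "pass")
    env <- oracle_envelope(as.numeric(signal::filtfilt(bp,
                                                       sess$signals$left)))
    ratios <- vapply(mov, function(j) {
      r <- ev$response_time_s[j]
      mean(env[round(r * fs):round((r + 0.35) * fs)]) /
        mean(env[round((r - 2) * fs):round((r - 1) * fs)])
    }, numeric(1))
    # log-ratios centered at zero: no significant deviation at alpha 0.01
    p <- stats::t.test(log(ratios))$p.value
    expect_gt(p, 0.01)
  }
})
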