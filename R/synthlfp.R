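#' Simulation configuration for synthetic LFP sessions
#'
#' Parameters of the bilateral LFP simulator. Each channel is a sum of
#' seven amplitude-modulated narrowband Gaussian oscillations (one per
#' frequency band), a 1/f-type colored background, 50 Hz line interference,
#' and a transient delta burst at each event onset. Movement events
#' multiply the band envelopes by the configured gains (gain < 1 gives
#' event-related desynchronization, > 1 synchronization), more strongly on
#' the channel contralateral to the cued hand.
#'
#' Trial counts default to 58 per class, the typical per-class session size
#' for externalized DBS recordings; inter-event gaps are drawn uniformly
#' from the 1-5 s validity range.
#'
#' @param fs_raw Raw sampling rate in Hz (default 2000).
#' @param n_left,n_right,n_rest Trials per class.
#' @param band_modulation Named vector of per-band contralateral envelope
#'   gains during movement (names: the seven band names).
#' @param band_base_amp Named vector of baseline oscillation amplitudes
#'   (arbitrary voltage-like units).
#' @param laterality_contrast Contra/ipsi modulation contrast: the
#'   ipsilateral gain is `1 + (g - 1) / laterality_contrast`.
#' @param delta_burst_amp Amplitude of the transient delta burst at event
#'   onset (0 disables it).
#' @param noise_exponent Spectral slope of the background (power ~
#'   f^`noise_exponent`; negative for 1/f-like noise).
#' @param noise_sd Standard deviation of the background noise.
#' @param line_amp 50 Hz interference amplitude.
#' @param inter_event_gap_s Length-2 range the inter-event gaps are drawn
#'   from (must lie within the 1-5 s validity range).
#' @param reaction_time_s Length-2 range of cue-to-response latencies.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   bit-identical session.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(fs_raw = 2000,
                       n_left = 58, n_right = 58, n_rest = 58,
                       band_modulation = c(delta = 1, theta = 1, alpha = 0.8,
                                           low_beta = 0.5, high_beta = 0.6,
                                           low_gamma = 1.3, high_gamma = 1.2),
                       band_base_amp = c(delta = 1.2, theta = 0.9,
                                         alpha = 1.1, low_beta = 1.4,
                                         high_beta = 1.1, low_gamma = 0.5,
                                         high_gamma = 0.35),
                       laterality_contrast = 2,
                       delta_burst_amp = 1.5,
                       noise_exponent = -1,
                       noise_sd = 1,
                       line_amp = 0.25,
                       inter_event_gap_s = c(1, 5),
                       reaction_time_s = c(0.3, 0.6),
                       seed = 1) {
  band_names <- band_definitions()$name
  cfg <- list(fs_raw = fs_raw, n_left = n_left, n_right = n_right,
              n_rest = n_rest, band_modulation = band_modulation,
              band_base_amp = band_base_amp,
              laterality_contrast = laterality_contrast,
              delta_burst_amp = delta_burst_amp,
              noise_exponent = noise_exponent, noise_sd = noise_sd,
              line_amp = line_amp, inter_event_gap_s = inter_event_gap_s,
              reaction_time_s = reaction_time_s, seed = seed)
  check <- function(ok, field)
    if (!ok) stop(sprintf("invalid simulation config: `%s`", field))
  check(fs_raw > 2 * 90, "fs_raw")
  check(n_left >= 1 && n_right >= 1 && n_rest >= 1, "n_left/n_right/n_rest")
  check(all(band_names %in% names(band_modulation)) &&
          all(band_modulation > 0), "band_modulation")
  check(all(band_names %in% names(band_base_amp)) &&
          all(band_base_amp >= 0), "band_base_amp")
  check(laterality_contrast >= 1, "laterality_contrast")
  check(delta_burst_amp >= 0, "delta_burst_amp")
  check(noise_sd >= 0, "noise_sd")
  check(line_amp >= 0, "line_amp")
  check(length(inter_event_gap_s) == 2 &&
          inter_event_gap_s[1] >= 1 && inter_event_gap_s[2] <= 5 &&
          inter_event_gap_s[1] <= inter_event_gap_s[2], "inter_event_gap_s")
  check(length(reaction_time_s) == 2 && reaction_time_s[1] > 0 &&
          reaction_time_s[1] <= reaction_time_s[2], "reaction_time_s")
  check(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed")
  structure(cfg, class = "sim_config")
}

# Colored background noise with power spectrum ~ f^exponent, unit variance
# before scaling; generated by FFT spectral shaping of white noise.
colored_noise <- function(n, exponent, fs) {
  n_pad <- smooth_length(n)
  w <- stats::rnorm(n_pad)
  W <- stats::fft(w)
  freqs <- c(0, seq_len(n_pad - 1)) * fs / n_pad
  freqs <- pmin(freqs, fs - freqs)          # two-sided
  shape <- c(0, freqs[-1]^(exponent / 2))   # kill DC
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n_pad)[seq_len(n)]
  x / stats::sd(x)
}

# Narrowband Gaussian oscillation: band-pass-filtered white noise with unit
# standard deviation.
narrowband_noise <- function(n, f_lo, f_hi, fs) {
  w <- stats::rnorm(n)
  ny <- fs / 2
  bf <- if (f_lo <= 0) signal::butter(4, f_hi / ny, type = "low")
        else signal::butter(2, c(f_lo, f_hi) / ny, type = "pass")
  x <- as.numeric(signal::filtfilt(bf, w))
  x / stats::sd(x)
}

# Raised-cosine gain profile for one movement event: ramp from 1 to `gain`
# starting 150 ms pre-response (200 ms rise), plateau 500 ms, 200 ms
# recovery. Returns multiplicative envelope samples for the whole profile
# and the sample offset of its start relative to the response.
modulation_profile <- function(gain, fs) {
  rise <- round(0.2 * fs); hold <- round(0.5 * fs); fall <- round(0.2 * fs)
  ramp_up <- 1 + (gain - 1) * (1 - cos(pi * seq_len(rise) / rise)) / 2
  plateau <- rep(gain, hold)
  ramp_dn <- gain + (1 - gain) * (1 - cos(pi * seq_len(fall) / fall)) / 2
  list(profile = c(ramp_up, plateau, ramp_dn),
       start_offset = -round(0.15 * fs))
}

# Hann-windowed burst envelope (400 ms) used for the event-onset delta
# transient.
burst_window <- function(fs) {
  n <- round(0.4 * fs)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Simulate a bilateral LFP session
#'
#' Generates a two-channel synthetic LFP recording with an event table.
#' Movement trials carry the configured band-specific event-related
#' (de)synchronization around the motor response, stronger on the
#' contralateral channel; a transient delta burst marks each event onset;
#' rest trials are unmodulated baseline. The output reproduces the key
#' phenomenology of externalized DBS recordings: 1/f background, 50 Hz
#' line interference, beta-band movement-locked suppression and gamma
#' enhancement.
#'
#' @param config A [sim_config()].
#' @return Object of class `lfp_session`: `signals` (list `left`, `right`),
#'   `fs`, `events` (data frame `stimulus_time_s`, `response_time_s`,
#'   `label`).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_raw
  with_seed(config$seed, {
    labels <- sample(c(rep("left", config$n_left),
                       rep("right", config$n_right),
                       rep("rest", config$n_rest)))
    n_ev <- length(labels)
    gaps <- stats::runif(n_ev, config$inter_event_gap_s[1],
                         config$inter_event_gap_s[2])
    stim <- 3 + cumsum(gaps)              # 3 s lead-in pad
    rt <- stats::runif(n_ev, config$reaction_time_s[1],
                       config$reaction_time_s[2])
    resp <- ifelse(labels == "rest", NA_real_, stim + rt)
    dur <- max(stim, resp, na.rm = TRUE) + 3   # 3 s tail pad
    n <- ceiling(dur * fs)
    tvec <- (seq_len(n) - 1) / fs
    bands <- band_definitions()
    movers <- which(labels != "rest")
    channels <- list(left = numeric(n), right = numeric(n))
    for (side in c("left", "right")) {
      sig <- config$noise_sd * colored_noise(n, config$noise_exponent, fs)
      for (b in seq_len(nrow(bands))) {
        bname <- bands$name[b]
        osc <- config$band_base_amp[[bname]] *
          narrowband_noise(n, bands$f_lo[b], bands$f_hi[b], fs)
        g_contra <- config$band_modulation[[bname]]
        if (g_contra != 1 && length(movers) > 0) {
          env <- rep(1, n)
          for (i in movers) {
            # contralateral rule: left-cued movement modulates the right
            # channel at full strength
            contra <- (labels[i] == "left") == (side == "right")
            g <- if (contra) g_contra
                 else 1 + (g_contra - 1) / config$laterality_contrast
            prof <- modulation_profile(g, fs)
            i0 <- round(resp[i] * fs) + prof$start_offset + 1L
            idx <- i0:(i0 + length(prof$profile) - 1L)
            ok <- idx >= 1 & idx <= n
            env[idx[ok]] <- env[idx[ok]] * prof$profile[ok]
          }
          osc <- osc * env
        }
        sig <- sig + osc
      }
      if (config$delta_burst_amp > 0) {
        bw <- burst_window(fs)
        half <- length(bw) %/% 2L
        carrier <- config$delta_burst_amp *
          narrowband_noise(n, 0, 4, fs)
        burst_env <- numeric(n)
        for (i in seq_len(n_ev)) {
          i0 <- round(stim[i] * fs) - half + 1L
          idx <- i0:(i0 + length(bw) - 1L)
          ok <- idx >= 1 & idx <= n
          burst_env[idx[ok]] <- pmax(burst_env[idx[ok]], bw[ok])
        }
        sig <- sig + carrier * burst_env
      }
      if (config$line_amp > 0)
        sig <- sig + config$line_amp *
          sin(2 * pi * 50 * tvec + stats::runif(1, 0, 2 * pi))
      channels[[side]] <- sig
    }
    events <- data.frame(stimulus_time_s = stim, response_time_s = resp,
                         label = labels, stringsAsFactors = FALSE)
    new_lfp_session(channels, fs, events)
  })
}

#' Construct and validate an LFP session object
#'
#' @param signals List of two equal-length numeric channels (`left`,
#'   `right`).
#' @param fs Sampling rate in Hz.
#' @param events Data frame with `stimulus_time_s`, `response_time_s`,
#'   `label` (one of rest/left/right); stimulus times strictly increasing
#'   and inside the recording.
#' @return Object of class `lfp_session`.
#' @export
new_lfp_session <- function(signals, fs, events) {
  if (!is.list(signals) || length(signals) != 2 ||
      length(signals[[1]]) != length(signals[[2]]))
    stop("`signals` must be two equal-length channels")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  req <- c("stimulus_time_s", "response_time_s", "label")
  if (!all(req %in% names(events))) stop("malformed event table")
  if (is.unsorted(events$stimulus_time_s, strictly = TRUE))
    stop("event times must be strictly increasing")
  dur <- length(signals[[1]]) / fs
  if (any(events$stimulus_time_s < 0 | events$stimulus_time_s > dur))
    stop("event times must lie inside the recording")
  if (!all(events$label %in% c("rest", "left", "right")))
    stop("labels must be rest, left or right")
  mov <- events$label != "rest"
  if (any(mov & (!is.finite(events$response_time_s) |
                 events$response_time_s <= events$stimulus_time_s)))
    stop("movement events need response_time_s > stimulus_time_s")
  names(signals) <- c("left", "right")
  structure(list(signals = signals, fs = fs, events = events),
            class = "lfp_session")
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("LFP session: 2 channels, %d samples at %g Hz (%.1f s), %d events\n",
              length(x$signals[[1]]), x$fs,
              length(x$signals[[1]]) / x$fs, nrow(x$events)))
  print(table(x$events$label))
  invisible(x)
}

#' Per-class trial counts and imbalance of a session
#'
#' @param session An `lfp_session`.
#' @return List with `counts` (named per-class), `total`, and `imbalance`
#'   = |n_left - n_right| / (n_left + n_right).
#' @export
session_trial_summary <- function(session) {
  stopifnot(inherits(session, "lfp_session"))
  ev <- session$events
  if (nrow(ev) < 1) stop("session has no events")
  counts <- c(left = sum(ev$label == "left"),
              right = sum(ev$label == "right"),
              rest = sum(ev$label == "rest"))
  nl <- counts[["left"]]; nr <- counts[["right"]]
  imb <- if (nl + nr > 0) abs(nl - nr) / (nl + nr) else NA_real_
  list(counts = counts, total = nrow(ev), imbalance = imb)
}
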