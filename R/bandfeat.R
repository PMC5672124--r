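#' Frequency band definitions on the level-5 packet grid
#'
#' The seven named LFP bands -- delta (0-4 Hz), theta (4-8), alpha (8-12),
#' low beta (13-20), high beta (20-32), low gamma (32-60) and high gamma
#' (60-90) -- mapped to terminal wavelet packet nodes. At a 256 Hz sampling
#' rate a level-5 packet tree has 32 frequency-ordered nodes of 4 Hz width,
#' so band edges snap to the 4 Hz grid: the indivisible 12-13 Hz sliver is
#' assigned to low beta (keeping the analysis-critical beta range intact,
#' so low beta spans nodes 12-20 Hz) and high gamma extends to 92 Hz.
#' Nodes above 92 Hz are discarded.
#'
#' @param level Packet decomposition depth (default 5).
#' @param fs Sampling rate the node grid refers to (default 256).
#' @return Data frame with columns `name`, `f_lo`, `f_hi` (nominal edges),
#'   `node_lo`, `node_hi` (frequency-ordered 4 Hz slots, 1-based).
#' @export
band_definitions <- function(level = 5, fs = 256) {
  node_hz <- (fs / 2) / 2^level
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "low_beta", "high_beta",
             "low_gamma", "high_gamma"),
    f_lo = c(0, 4, 8, 13, 20, 32, 60),
    f_hi = c(4, 8, 12, 20, 32, 60, 90),
    stringsAsFactors = FALSE
  )
  # snap to the node grid; 12-13 Hz goes to low_beta, 90-92 to high_gamma
  snap_lo <- c(0, 4, 8, 12, 20, 32, 60)
  snap_hi <- c(4, 8, 12, 20, 32, 60, 92)
  bands$node_lo <- as.integer(snap_lo / node_hz) + 1L
  bands$node_hi <- as.integer(snap_hi / node_hz)
  bands
}

#' Decompose a signal into the seven LFP bands
#'
#' Level-5 discrete-Meyer wavelet packet decomposition followed by
#' reconstruction of each band from its frequency-ordered terminal nodes.
#' Summing the seven band signals plus the discarded >92 Hz component
#' reproduces the input to machine precision.
#'
#' @param x Numeric signal sampled at `fs`.
#' @param fs Sampling rate (default 256 Hz).
#' @param level Packet depth (default 5).
#' @return Numeric matrix `length(x)` x 7 with band-named columns.
#' @export
wpt_band_decompose <- function(x, fs = 256, level = 5) {
  bands <- band_definitions(level, fs)
  tree <- wpt_decompose(x, level)
  ord <- wpt_node_order(level)
  out <- matrix(0, length(x), nrow(bands),
                dimnames = list(NULL, bands$name))
  for (i in seq_len(nrow(bands))) {
    keep <- ord[bands$node_lo[i]:bands$node_hi[i]]
    out[, i] <- wpt_reconstruct(tree, keep = keep)
  }
  out
}

#' Hilbert envelope (instantaneous amplitude)
#'
#' Magnitude of the analytic signal computed through the FFT. For a
#' band-limited oscillation this is the instantaneous amplitude; for a pure
#' sinusoid of amplitude A the interior envelope equals A within a couple
#' of percent (edges carry the usual analytic-signal taper).
#'
#' @param x Numeric signal.
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (any(!is.finite(x))) stop("signal contains non-finite values")
  n <- length(x)
  if (n < 2) return(abs(x))
  n_pad <- smooth_length(n)
  X <- stats::fft(c(x, numeric(n_pad - n)))
  h <- numeric(n_pad)
  if (n_pad %% 2 == 0) {
    h[1] <- 1; h[n_pad / 2 + 1] <- 1; h[2:(n_pad / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n_pad + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n_pad)[seq_len(n)]
}

#' Epoch specification for feature extraction
#'
#' Defines how a trial epoch is cut around its anchor event and where the
#' five 100 ms feature windows sit. Movement epochs span 4 s around the
#' motor response with windows covering -150..+350 ms; rest epochs span 2 s
#' around the stimulus with windows covering -750..-250 ms (pre-stimulus
#' baseline).
#'
#' @param anchor `"response"` or `"stimulus"`.
#' @param half_width_s Epoch half width in seconds.
#' @param window_starts_s Start times (s, relative to the anchor) of the
#'   five 100 ms feature windows.
#' @return List of class `epoch_spec`.
#' @export
epoch_spec <- function(anchor = c("response", "stimulus"),
                       half_width_s = 2,
                       window_starts_s = seq(-0.15, 0.25, by = 0.1)) {
  anchor <- match.arg(anchor)
  if (length(window_starts_s) != 5)
    stop("exactly five feature windows are required")
  if (any(abs(diff(window_starts_s) - 0.1) > 1e-9))
    stop("feature windows must be contiguous 100 ms windows")
  if (min(window_starts_s) < -half_width_s - 1e-9 ||
      max(window_starts_s) + 0.1 > half_width_s + 1e-9)
    stop("feature windows must lie inside the epoch")
  structure(list(anchor = anchor, half_width_s = half_width_s,
                 window_starts_s = window_starts_s),
            class = "epoch_spec")
}

#' @rdname epoch_spec
#' @export
movement_epoch_spec <- function() epoch_spec("response", 2,
                                             seq(-0.15, 0.25, by = 0.1))

#' @rdname epoch_spec
#' @export
rest_epoch_spec <- function() epoch_spec("stimulus", 1,
                                         seq(-0.75, -0.35, by = 0.1))

#' Cut one epoch from per-band envelope series
#'
#' Extracts the `2 x 7 x samples` envelope block around one event and flags
#' epochs whose spacing to neighboring events falls outside the 1-5 s
#' validity range for inter-movement intervals.
#'
#' @param envelopes List of two matrices (`left`, `right` channel), each
#'   `n x 7` band envelopes at rate `fs`.
#' @param fs Sampling rate of the envelope series.
#' @param event One-row data frame with `stimulus_time_s`,
#'   `response_time_s`, `label`.
#' @param spec An [epoch_spec()].
#' @param prev_time_s,next_time_s Stimulus times of the neighboring events
#'   (`NA` when absent).
#' @return List of class `lfp_epoch`: `block` (array sides x bands x
#'   samples), `excluded` (logical), `anchor_index` (sample index of the
#'   anchor within the block), `label`.
#' @export
segment_epoch <- function(envelopes, fs, event, spec,
                          prev_time_s = NA, next_time_s = NA) {
  stopifnot(inherits(spec, "epoch_spec"))
  t_anchor <- if (spec$anchor == "response") event$response_time_s
              else event$stimulus_time_s
  if (!is.finite(t_anchor))
    stop(sprintf("event at stimulus %.3f s has no %s time",
                 event$stimulus_time_s, spec$anchor))
  n <- nrow(envelopes[[1]])
  c0 <- round(t_anchor * fs)            # 0-based anchor sample
  half <- round(spec$half_width_s * fs)
  lo <- c0 - half; hi <- c0 + half - 1  # 0-based inclusive
  if (lo < 0 || hi >= n)
    stop(sprintf("epoch for event at %.3f s exceeds recording bounds",
                 t_anchor))
  gaps <- c(event$stimulus_time_s - prev_time_s,
            next_time_s - event$stimulus_time_s)
  excluded <- any(!is.na(gaps) & (gaps < 1 | gaps > 5))
  nb <- ncol(envelopes[[1]])
  block <- array(0, dim = c(2, nb, hi - lo + 1),
                 dimnames = list(side = c("left_channel", "right_channel"),
                                 band = colnames(envelopes[[1]]), NULL))
  idx <- (lo:hi) + 1L
  block[1, , ] <- t(envelopes[[1]][idx, , drop = FALSE])
  block[2, , ] <- t(envelopes[[2]][idx, , drop = FALSE])
  structure(list(block = block, excluded = excluded,
                 anchor_index = half + 1L, fs = fs,
                 label = as.character(event$label), spec = spec),
            class = "lfp_epoch")
}

#' Extract the 70-dimensional feature vector from one epoch
#'
#' Each feature is the arithmetic mean of the band envelope over one of the
#' five 100 ms windows; ordering is side (left channel, right channel) x
#' band (delta..high gamma) x window (1..5), 2 x 7 x 5 = 70 values. Windows
#' map to half-open sample ranges `[round(t_lo fs), round(t_hi fs))`
#' relative to the anchor.
#'
#' @param epoch An `lfp_epoch` from [segment_epoch()].
#' @return Named numeric vector of length 70.
#' @export
extract_features <- function(epoch) {
  stopifnot(inherits(epoch, "lfp_epoch"))
  if (epoch$excluded)
    stop("epoch is flagged excluded (inter-event interval outside 1-5 s)")
  fs <- epoch$fs
  starts <- epoch$spec$window_starts_s
  sides <- dimnames(epoch$block)$side
  bands <- dimnames(epoch$block)$band
  vals <- numeric(0)
  nms <- character(0)
  for (s in seq_along(sides)) for (b in seq_along(bands)) {
    for (w in seq_along(starts)) {
      lo <- round(starts[w] * fs)             # 0-based rel. to anchor
      hi <- round((starts[w] + 0.1) * fs)     # half-open
      idx <- (epoch$anchor_index + lo):(epoch$anchor_index + hi - 1L)
      vals <- c(vals, mean(epoch$block[s, b, idx]))
      nms <- c(nms, sprintf("%s_%s_w%d", sub("_channel", "", sides[s]),
                            bands[b], w))
    }
  }
  names(vals) <- nms
  vals
}

#' Per-band Hilbert envelopes of a preprocessed session
#'
#' Runs the packet-band decomposition and Hilbert envelope over each whole
#' channel (envelopes are computed on the full recording, not per epoch, to
#' avoid epoch-edge analytic-signal artifacts).
#'
#' @param session A preprocessed `lfp_session` (at 256 Hz).
#' @return List of two `n x 7` envelope matrices (`left`, `right`).
#' @export
session_band_envelopes <- function(session) {
  stopifnot(inherits(session, "lfp_session"))
  lapply(session$signals, function(ch) {
    bands <- wpt_band_decompose(ch, fs = session$fs)
    apply(bands, 2, hilbert_envelope)
  })
}

#' Feature table for all usable trials of a session
#'
#' Segments every event (movement events anchored at the motor response
#' with the -150..+350 ms windows; rest events at the stimulus with the
#' -750..-250 ms windows), drops epochs flagged by the 1-5 s inter-event
#' rule or falling outside the recording, and returns one feature row per
#' retained trial.
#'
#' @param session A preprocessed `lfp_session`.
#' @param envelopes Optional precomputed [session_band_envelopes()] result.
#' @return Data frame: `trial_id`, `label`, then 70 feature columns.
#' @export
session_features <- function(session, envelopes = NULL) {
  if (is.null(envelopes)) envelopes <- session_band_envelopes(session)
  ev <- session$events
  mspec <- movement_epoch_spec()
  rspec <- rest_epoch_spec()
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    spec <- if (ev$label[i] == "rest") rspec else mspec
    prev_t <- if (i > 1) ev$stimulus_time_s[i - 1] else NA
    next_t <- if (i < nrow(ev)) ev$stimulus_time_s[i + 1] else NA
    epoch <- tryCatch(
      segment_epoch(envelopes, session$fs, ev[i, ], spec, prev_t, next_t),
      error = function(e) NULL)
    if (is.null(epoch) || epoch$excluded) next
    rows[[length(rows) + 1L]] <-
      c(list(trial_id = i, label = ev$label[i]),
        as.list(extract_features(epoch)))
  }
  if (length(rows) == 0) stop("no usable trials in session")
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Names of the 70 feature columns
#' @return Character vector, side x band x window order.
#' @export
feature_names <- function() {
  bands <- band_definitions()$name
  as.vector(vapply(c("left", "right"), function(s)
    as.vector(vapply(bands, function(b)
      sprintf("%s_%s_w%d", s, b, 1:5), character(5))), character(35)))
}
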