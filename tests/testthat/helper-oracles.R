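# Independent oracles used to check the implementation paths.

# Analytic-signal envelope, straight FFT construction (no padding tricks);
# independent of lfpdecode::hilbert_envelope's implementation details.
oracle_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Band energy fractions by direct FFT periodogram, the oracle for the
# packet-band assignment tests.
oracle_band_energy <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sum(p[freqs >= f_lo & freqs < f_hi]) / sum(p)
}

# Brute-force plurality count for the vote-fusion oracle.
oracle_plurality <- function(votes) {
  counts <- table(factor(votes, levels = c(0, 1)))
  as.integer(names(counts)[which.max(counts)])
}

# Scalar-loop evaluation of the feedforward network output, kept naive on
# purpose (no matrix algebra) to stay independent of fbann_forward.
oracle_fbann <- function(W1, b1, w2, b2, x) {
  f <- function(z) 1 / (1 + exp(-z))
  acc <- 0
  for (p in seq_along(w2)) {
    s <- 0
    for (q in seq_along(x)) s <- s + W1[q, p] * x[q]
    acc <- acc + w2[p] * f(s + b1[p])
  }
  f(acc + b2)
}

# Independent re-implementation of one weighted-neighbor bootstrap draw
# (loop form) used for the Monte-Carlo mean comparison.
oracle_bootstrap_draws <- function(x, r, n_draws, seed) {
  x <- as.matrix(x)
  set.seed(seed)
  out <- matrix(0, n_draws, ncol(x))
  for (s in seq_len(n_draws)) {
    k0 <- sample.int(nrow(x), 1)
    d <- sqrt(rowSums(sweep(x, 2, x[k0, ])^2))
    nb <- setdiff(order(d), k0)[seq_len(r)]
    repeat {
      ci <- pmin(abs(rnorm(r + 1)), r)
      if (sum(ci) > 0) break
    }
    w <- ci / sum(ci)
    out[s, ] <- as.numeric(w %*% x[c(k0, nb), , drop = FALSE])
  }
  out
}

# Two-class Gaussian blobs, the shared separable-data fixture.
make_blobs <- function(n_per_class = 100, sep = 4, dim = 2, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * dim, -sep / 2), n_per_class, dim),
             matrix(rnorm(n_per_class * dim, sep / 2), n_per_class, dim))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# Small session with hand-placed events, for epoching tests: constant-rate
# synthetic envelopes are built directly where needed.
make_flat_envelopes <- function(n, value = 1, bands = band_definitions()$name) {
  m <- matrix(value, n, length(bands), dimnames = list(NULL, bands))
  list(left = m, right = m)
}

# Synthetic 70-dim feature table with class structure mimicking beta
# suppression during movement and a lateralized contralateral contrast.
make_feature_fixture <- function(n = 40, seed = 10) {
  set.seed(seed)
  nm <- feature_names()
  mk <- function(label) {
    m <- matrix(rnorm(n * 70, mean = 5, sd = 0.6), n, 70,
                dimnames = list(NULL, nm))
    beta <- grep("beta", nm)
    left_ch <- grep("^left", nm)
    if (label != "rest") m[, beta] <- m[, beta] - 2
    if (label == "left") m[, intersect(beta, left_ch)] <- # ipsi partial
        m[, intersect(beta, left_ch)] + 1
    if (label == "right") m[, setdiff(beta, left_ch)] <-
        m[, setdiff(beta, left_ch)] + 1
    m
  }
  labs <- c("rest", "left", "right")
  X <- do.call(rbind, lapply(labs, mk))
  data.frame(trial_id = seq_len(3 * n),
             label = rep(labs, each = n), X, check.names = FALSE)
}

# The strong-modulation and null experiment configurations used by the
# end-to-end checks (beta-band ERD gain 0.4, 100 trials per class).
strong_config <- function(seed = 1, n = 100) {
  experiment_config(
    sim = sim_config(n_left = n, n_right = n, n_rest = n,
                     band_modulation = c(delta = 1, theta = 1, alpha = 0.8,
                                         low_beta = 0.4, high_beta = 0.4,
                                         low_gamma = 1.3, high_gamma = 1.2),
                     seed = seed),
    k_folds = 10, seed = seed)
}

null_config <- function(seed = 3, n = 40) {
  experiment_config(
    sim = sim_config(n_left = n, n_right = n, n_rest = n,
                     band_modulation = c(delta = 1, theta = 1, alpha = 1,
                                         low_beta = 1, high_beta = 1,
                                         low_gamma = 1, high_gamma = 1),
                     delta_burst_amp = 0, seed = seed),
    k_folds = 10, seed = seed)
}
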