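#' Synthetic SSVEP simulation configuration
#'
#' Describes a benchmark-shaped synthetic recording: a grid of flicker
#' frequencies with per-stimulus phases, a fixed visual latency, harmonic
#' SSVEP components mixed into channels with an occipital-dominant gain
#' profile, and pink + white background noise scaled to a target in-band SNR.
#' One trial is generated per (block, stimulus) pair; a fixed seed makes the
#' full dataset bit-reproducible.
#'
#' @param freqs stimulus frequencies in Hz (default the 40-target grid
#'   8.0-15.8 Hz in 0.2 Hz steps).
#' @param phases per-stimulus phase offsets in radians (default the linear
#'   progression `0.35 * pi * n`, wrapped).
#' @param Nc number of channels.
#' @param fs sampling rate in Hz.
#' @param B number of blocks.
#' @param trial_s stored epoch length in seconds (post-latency).
#' @param latency_s visual latency in seconds.
#' @param harmonics harmonic amplitudes `a_h` (default `1/h` for `h = 1..3`).
#' @param snr_db target in-band SNR in dB (`Inf` = noise-free).
#' @param pink_alpha pink-noise spectral exponent.
#' @param white_frac fraction of noise power from the white floor.
#' @param occipital_gain signal gain of the occipital channels relative to
#'   the rest (the last `min(3, Nc)` channels).
#' @param channel_names channel labels (default the nine-channel montage
#'   when `Nc = 9`).
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(freqs = seq(8, 15.8, by = 0.2),
                       phases = (0.35 * pi * (seq_along(freqs) - 1L)) %% (2 * pi),
                       Nc = 9L, fs = 250, B = 6L, trial_s = 1.0,
                       latency_s = 0.14, harmonics = 1 / (1:3),
                       snr_db = -10, pink_alpha = 1, white_frac = 0.1,
                       occipital_gain = 3,
                       channel_names = NULL, seed = 1L) {
  nh_sim <- length(harmonics)
  if (nh_sim * max(freqs) >= fs / 2)
    stop("highest simulated harmonic is at or above Nyquist")
  if (B < 1L) stop("B must be >= 1")
  if (!is.finite(snr_db) && snr_db < 0) stop("snr_db must be finite or +Inf")
  if (is.null(channel_names))
    channel_names <- if (Nc == 9L) default_channels() else paste0("ch", seq_len(Nc))
  structure(list(freqs = freqs, phases = phases, Nc = as.integer(Nc), fs = fs,
                 B = as.integer(B), trial_s = trial_s, latency_s = latency_s,
                 harmonics = harmonics, snr_db = snr_db,
                 pink_alpha = pink_alpha, white_frac = white_frac,
                 occipital_gain = occipital_gain,
                 channel_names = channel_names, seed = as.integer(seed)),
            class = "sim_config")
}

# 1/f^alpha noise by spectral synthesis, standardized to unit variance.
pink_noise <- function(n, alpha = 1) {
  nfft <- n
  half <- floor(nfft / 2)
  f <- seq_len(half)
  amp <- f^(-alpha / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(nfft))
  full[2:(half + 1)] <- spec
  if (nfft %% 2 == 0) {
    full[half + 1] <- complex(real = Re(spec[half]))
    if (half > 1) full[nfft:(nfft - half + 2)] <- Conj(spec[seq_len(half - 1)])
  } else {
    full[nfft:(nfft - half + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / nfft
  as.vector(scale(x))
}

#' Simulate a benchmark-shaped epoched SSVEP dataset
#'
#' The clean component of a trial at stimulus `n` is
#' `sum_h a_h * sin(2*pi*h*fn*(t - latency) + h*phi_n)` mixed into `Nc`
#' channels through a seeded random, occipital-dominant mixing matrix (fixed
#' across trials so templates and TRCA have stable structure). Pink + white
#' noise, independent per channel and trial, is added after scaling to the
#' target SNR measured in the 6-90 Hz analysis band. Epochs are extracted at
#' the configured latency, so stored trials are latency-aligned with the
#' sine-cosine references.
#'
#' @param cfg a `sim_config`.
#' @param keep_components store per-trial clean/noise components (needed by
#'   [realized_snr()]); default TRUE.
#' @return an `epoch_set`; when `keep_components`, attribute `"components"`
#'   holds per-trial `clean` and `noise` arrays.
#' @export
simulate_epochset <- function(cfg, keep_components = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    nf <- length(cfg$freqs)
    ns <- round_sample(cfg$trial_s * cfg$fs)
    start <- round_sample(cfg$latency_s * cfg$fs)
    n_raw <- start + ns
    nh <- length(cfg$harmonics)
    gains <- rep(1, cfg$Nc)
    occ <- seq.int(max(1L, cfg$Nc - 2L), cfg$Nc)
    gains[occ] <- cfg$occipital_gain
    mixing <- matrix(stats::runif(nh * cfg$Nc, 0.5, 1.5), nh, cfg$Nc) *
      rep(gains, each = nh)
    band <- design_subbands(cfg$fs, 1L)[[1L]]
    n_trials <- cfg$B * nf
    data <- array(0, dim = c(n_trials, cfg$Nc, ns))
    labels <- integer(n_trials)
    blocks <- integer(n_trials)
    clean_store <- if (keep_components) array(0, dim = c(n_trials, cfg$Nc, ns))
    noise_store <- if (keep_components) array(0, dim = c(n_trials, cfg$Nc, ns))
    t_raw <- seq_len(n_raw) / cfg$fs
    i <- 0L
    for (bl in seq_len(cfg$B) - 1L) {
      for (n0 in seq_len(nf) - 1L) {
        i <- i + 1L
        fn <- cfg$freqs[n0 + 1L]
        phi <- cfg$phases[n0 + 1L]
        clean_raw <- matrix(0, cfg$Nc, n_raw)
        for (h in seq_len(nh)) {
          s <- cfg$harmonics[h] *
            sin(2 * pi * h * fn * (t_raw - cfg$latency_s) + h * phi)
          clean_raw <- clean_raw + tcrossprod(mixing[h, ], s)
        }
        clean <- extract_epoch(clean_raw, cfg$fs, cfg$latency_s, cfg$trial_s)
        if (all(clean == 0)) stop("zero clean signal: SNR scaling impossible")
        if (is.finite(cfg$snr_db)) {
          noise <- t(vapply(seq_len(cfg$Nc), function(ch) {
            sqrt(1 - cfg$white_frac) * pink_noise(ns, cfg$pink_alpha) +
              sqrt(cfg$white_frac) * stats::rnorm(ns)
          }, numeric(ns)))
          noise_band <- t(apply(noise, 1L, function(v) filtfilt_reflect(band$filt, v)))
          ps <- mean(clean^2)
          pn <- mean(noise_band^2)
          sc <- sqrt(ps / (pn * 10^(cfg$snr_db / 10)))
          noise <- sc * noise
        } else {
          noise <- matrix(0, cfg$Nc, ns)
        }
        data[i, , ] <- clean + noise
        labels[i] <- n0
        blocks[i] <- bl
        if (keep_components) {
          clean_store[i, , ] <- clean
          noise_store[i, , ] <- noise
        }
      }
    }
    out <- epoch_set(data, cfg$fs, labels, blocks, cfg$freqs,
                     cfg$channel_names, cfg$latency_s)
    if (keep_components)
      attr(out, "components") <- list(clean = clean_store, noise = noise_store)
    out
  })
}

#' Realized in-band SNR of a simulated epoch set
#'
#' Recomputes per-trial `10*log10(P_signal / P_noise)` from the stored clean
#' and noise components, with noise power measured in the 6-90 Hz analysis
#' band (the definition used for scaling at generation time).
#'
#' @param x an `epoch_set` from [simulate_epochset()] with stored components.
#' @return numeric vector of per-trial SNRs in dB (`+Inf` for zero noise).
#' @export
realized_snr <- function(x) {
  comp <- attr(x, "components")
  if (is.null(comp)) stop("no stored components: simulate with keep_components = TRUE")
  band <- design_subbands(x$fs, 1L)[[1L]]
  n <- dim(comp$clean)[1L]
  vapply(seq_len(n), function(i) {
    clean <- comp$clean[i, , , drop = TRUE]
    noise <- comp$noise[i, , , drop = TRUE]
    if (all(noise == 0)) return(Inf)
    nb <- t(apply(noise, 1L, function(v) filtfilt_reflect(band$filt, v)))
    10 * log10(mean(clean^2) / mean(nb^2))
  }, numeric(1L))
}

#' Canonical synthetic test fixtures
#'
#' Deterministic small datasets used throughout the test suite: a noise-free
#' 8-class set, a noise-free 40-class set, a moderate-noise (-10 dB in-band)
#' 40-class set, and two degenerate sets (identical trials; one all-zero
#' channel).
#'
#' @param seed master seed.
#' @return named list of `epoch_set`s.
#' @export
make_fixture_suite <- function(seed = 1L) {
  base8 <- sim_config(freqs = seq(8, 15, by = 1), B = 3L, trial_s = 1.0,
                      snr_db = Inf, seed = seed)
  nf8 <- simulate_epochset(base8, keep_components = FALSE)
  nf40 <- simulate_epochset(
    sim_config(B = 3L, trial_s = 1.0, snr_db = Inf, seed = seed),
    keep_components = FALSE)
  noisy40 <- simulate_epochset(
    sim_config(B = 3L, trial_s = 1.0, snr_db = -10, seed = seed + 1L),
    keep_components = FALSE)
  ident <- nf8
  d <- epoch_dims(ident)
  for (b in unique(ident$blocks)) for (l in unique(ident$labels)) {
    i <- which(ident$blocks == b & ident$labels == l)
    j <- which(ident$blocks == 0L & ident$labels == l)
    ident$data[i, , ] <- nf8$data[j, , ]
  }
  zerochan <- nf8
  zerochan$data[, 1L, ] <- 0
  list(noisefree8 = nf8, noisefree40 = nf40, noisy40 = noisy40,
       identical_trials = ident, zero_channel = zerochan)
}
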