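#' Epoched SSVEP trial set
#'
#' Container for epoched multi-channel EEG trials in the geometry of the
#' public 40-target SSVEP benchmarks: one trial per (block, stimulus) pair,
#' all trials sharing a channel count `Nc` and sample count `Ns`.
#'
#' @param data numeric array `[n_trials x Nc x Ns]` (volts, arbitrary scale).
#' @param fs sampling rate in Hz.
#' @param labels integer stimulus index per trial, 0-based (`0 .. Nf-1`).
#' @param blocks integer block index per trial, 0-based.
#' @param freqs stimulus frequency table in Hz (length `Nf`).
#' @param channel_names ordered channel labels (length `Nc`).
#' @param latency_s visual-latency offset applied at extraction, seconds.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels, blocks, freqs, channel_names = NULL,
                      latency_s = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [n_trials x Nc x Ns]")
  n_trials <- dim(data)[1L]
  nc <- dim(data)[2L]
  ns <- dim(data)[3L]
  if (ns < 2L) stop("Ns must be >= 2")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  labels <- as.integer(labels)
  blocks <- as.integer(blocks)
  if (length(labels) != n_trials || length(blocks) != n_trials)
    stop("labels and blocks must have one entry per trial")
  nf <- length(freqs)
  if (any(labels < 0L) || any(labels >= nf))
    stop("labels must lie in 0 .. Nf-1")
  if (anyDuplicated(cbind(blocks, labels)))
    stop("every (block, stimulus) pair may occur at most once")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length must equal the channel dimension")
  structure(
    list(data = data, fs = fs, labels = labels, blocks = blocks,
         freqs = as.numeric(freqs), channel_names = as.character(channel_names),
         latency_s = latency_s),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials | %d channels x %d samples @ %g Hz | %d stimuli (%g-%g Hz) | %d blocks\n",
    d[1L], d[2L], d[3L], x$fs, length(x$freqs), min(x$freqs), max(x$freqs),
    length(unique(x$blocks))))
  invisible(x)
}

#' Number of trials, channels, samples of an epoch set
#' @param x an `epoch_set`.
#' @return named integer vector `(n_trials, Nc, Ns)`.
#' @export
epoch_dims <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  c(n_trials = d[1L], Nc = d[2L], Ns = d[3L])
}

#' Subset an epoch set by trial index
#' @param x an `epoch_set`.
#' @param i trial indices (1-based).
#' @return an `epoch_set` with the selected trials.
#' @export
epoch_subset <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  epoch_set(x$data[i, , , drop = FALSE], x$fs, x$labels[i], x$blocks[i],
            x$freqs, x$channel_names, x$latency_s)
}

#' Sine-cosine reference matrix for one stimulus frequency
#'
#' Builds the harmonic reference used by CCA-based SSVEP recognizers:
#' for harmonic `h = 1..Nh`, row `2h-1` is `sin(2*pi*h*fn*t)` and row `2h`
#' is `cos(2*pi*h*fn*t)`, with time samples `t = 1/fs, 2/fs, ..., Ns/fs`
#' (the one-based sample convention of the SSVEP literature).
#'
#' @param fn stimulus frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param Ns number of time samples.
#' @param Nh number of harmonics.
#' @return numeric matrix `[2*Nh x Ns]`.
#' @export
make_reference <- function(fn, fs, Ns, Nh) {
  if (fn <= 0) stop("fn must be positive")
  if (Ns < 1L) stop("Ns must be >= 1")
  if (Nh < 1L) stop("Nh must be >= 1")
  if (Nh * fn >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz (= %g Hz) is at or above Nyquist (%g Hz)",
                 Nh, fn, Nh * fn, fs / 2))
  t <- seq_len(Ns) / fs
  Y <- matrix(0, nrow = 2L * Nh, ncol = Ns)
  for (h in seq_len(Nh)) {
    ph <- 2 * pi * h * fn * t
    Y[2L * h - 1L, ] <- sin(ph)
    Y[2L * h, ] <- cos(ph)
  }
  Y
}

#' Reference bank for a stimulus frequency table
#'
#' @param freqs stimulus frequencies in Hz (distinct).
#' @param fs sampling rate in Hz.
#' @param Ns number of time samples.
#' @param Nh number of harmonics.
#' @return `reference_bank`: list with `Y` (list of `[2*Nh x Ns]` matrices),
#'   `freqs`, `fs`, `Ns`, `Nh`.
#' @export
make_reference_bank <- function(freqs, fs, Ns, Nh) {
  if (anyDuplicated(freqs))
    stop("duplicate stimulus frequencies: stimuli must be distinguishable")
  Y <- lapply(freqs, make_reference, fs = fs, Ns = Ns, Nh = Nh)
  structure(list(Y = Y, freqs = as.numeric(freqs), fs = fs, Ns = as.integer(Ns),
                 Nh = as.integer(Nh)),
            class = "reference_bank")
}

#' @export
print.reference_bank <- function(x, ...) {
  cat(sprintf("<reference_bank> %d stimuli | %d harmonics | %d samples @ %g Hz\n",
              length(x$freqs), x$Nh, x$Ns, x$fs))
  invisible(x)
}

# Round-half-to-even sample index; base round() already implements IEC 60559
# banker's rounding, wrapped here so the windowing rule is named and testable.
round_sample <- function(x) as.integer(round(x))

#' Extract an analysis window from a raw trial
#'
#' Cuts the window `[latency_s, latency_s + window_s)` out of a raw
#' `[Nc x n_raw]` trial. Start sample is `round(latency_s * fs)` (0-based,
#' round-half-to-even) and the window holds `round(window_s * fs)` samples.
#'
#' @param raw numeric matrix `[Nc x n_raw]`.
#' @param fs sampling rate in Hz.
#' @param latency_s onset latency in seconds.
#' @param window_s window length in seconds.
#' @return numeric matrix `[Nc x Ns]`.
#' @export
extract_epoch <- function(raw, fs, latency_s, window_s) {
  if (!is.matrix(raw)) stop("`raw` must be a [Nc x n_raw] matrix")
  start <- round_sample(latency_s * fs)   # 0-based
  ns <- round_sample(window_s * fs)
  if (ns < 1L) stop("window_s too short: rounds to zero samples")
  n_raw <- ncol(raw)
  if (start < 0L) stop("latency_s must be non-negative")
  if (start + ns > n_raw)
    stop(sprintf("window end %d exceeds trial length %d samples", start + ns, n_raw))
  raw[, (start + 1L):(start + ns), drop = FALSE]
}

#' Re-window every trial of an epoch set
#'
#' Used by evaluation sweeps to realize shorter analysis windows `Tw` from
#' stored epochs (offset 0: stored epochs are already latency-aligned).
#'
#' @param x an `epoch_set`.
#' @param window_s new window length in seconds.
#' @param offset_s offset from the stored epoch start, seconds.
#' @return an `epoch_set` with `Ns = round(window_s * fs)`.
#' @export
rewindow_epochs <- function(x, window_s, offset_s = 0) {
  stopifnot(inherits(x, "epoch_set"))
  d <- epoch_dims(x)
  ns <- round_sample(window_s * x$fs)
  start <- round_sample(offset_s * x$fs)
  if (start + ns > d["Ns"])
    stop(sprintf("requested window of %d samples exceeds stored %d samples",
                 start + ns, d["Ns"]))
  data <- x$data[, , (start + 1L):(start + ns), drop = FALSE]
  epoch_set(data, x$fs, x$labels, x$blocks, x$freqs, x$channel_names, x$latency_s)
}

#' Restrict an epoch set to a channel prefix
#'
#' Channel-count sweeps use ordered prefixes of the configured channel list.
#'
#' @param x an `epoch_set`.
#' @param n_channels number of leading channels to keep.
#' @return an `epoch_set` with `Nc = n_channels`.
#' @export
channel_prefix <- function(x, n_channels) {
  stopifnot(inherits(x, "epoch_set"))
  d <- epoch_dims(x)
  if (n_channels < 1L || n_channels > d["Nc"])
    stop("n_channels out of range")
  epoch_set(x$data[, seq_len(n_channels), , drop = FALSE], x$fs, x$labels,
            x$blocks, x$freqs, x$channel_names[seq_len(n_channels)], x$latency_s)
}

#' Default occipital/parieto-occipital channel subset
#'
#' The nine-channel montage conventionally used for SSVEP decoding.
#' @return character vector of channel names.
#' @export
default_channels <- function() {
  c("Pz", "PO5", "PO3", "POz", "PO4", "PO6", "O1", "Oz", "O2")
}
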