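CONTAINER_VERSION <- "htrcca-container-1"

# Short FNV-1a hash of a serialized R object; used to stamp results with the
# exact configuration that produced them.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write an epoch set to the package container
#'
#' Versioned single-file container (RDS serialization) holding the trial
#' array, geometry, frequency table and a provenance block; round-trips
#' bit-exactly.
#'
#' @param x an `epoch_set`.
#' @param path output file path.
#' @param provenance optional named list (seed, config hash, notes).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path, provenance = list()) {
  stopifnot(inherits(x, "epoch_set"))
  obj <- list(version = CONTAINER_VERSION,
              data = x$data, fs = x$fs, labels = x$labels, blocks = x$blocks,
              freqs = x$freqs, channel_names = x$channel_names,
              latency_s = x$latency_s,
              provenance = c(provenance, list(hash = config_hash(x$data))))
  saveRDS(obj, path)
  invisible(path)
}

#' Read an epoch set from the package container
#'
#' @param path container file written by [write_epochs()].
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such container: %s", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop(sprintf("corrupt or truncated container: %s", path)))
  if (!identical(obj$version, CONTAINER_VERSION))
    stop(sprintf("unknown container version: %s", obj$version %||% "<missing>"))
  need <- c("data", "fs", "labels", "blocks", "freqs")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop(sprintf("container missing dataset(s): %s",
                                 paste(miss, collapse = ", ")))
  epoch_set(obj$data, obj$fs, obj$labels, obj$blocks, obj$freqs,
            obj$channel_names, obj$latency_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import a benchmark-layout SSVEP array
#'
#' Maps the `[channels x samples x targets x blocks]` array organization of
#' the public 40-target SSVEP recordings into an `epoch_set` (one trial per
#' block and stimulus). Epochs are assumed already windowed; pass
#' `latency_s` for bookkeeping only.
#'
#' @param arr numeric 4-d array `[Nc x Ns x Nf x B]`.
#' @param fs sampling rate in Hz.
#' @param freqs stimulus frequency table (length `Nf`).
#' @param channel_names optional channel labels.
#' @param latency_s latency already applied at extraction, seconds.
#' @return an `epoch_set`.
#' @export
import_benchmark_array <- function(arr, fs, freqs, channel_names = NULL,
                                   latency_s = 0) {
  if (!is.array(arr) || length(dim(arr)) != 4L)
    stop("expected a 4-d array [Nc x Ns x Nf x B]")
  d <- dim(arr)
  if (d[3L] != length(freqs))
    stop("third axis (targets) must match the frequency table length")
  perm <- aperm(arr, c(4L, 3L, 1L, 2L))   # [B x Nf x Nc x Ns]
  n_trials <- d[3L] * d[4L]
  data <- array(0, dim = c(n_trials, d[1L], d[2L]))
  labels <- integer(n_trials); blocks <- integer(n_trials)
  i <- 0L
  for (bl in seq_len(d[4L])) for (n in seq_len(d[3L])) {
    i <- i + 1L
    data[i, , ] <- perm[bl, n, , ]
    labels[i] <- n - 1L
    blocks[i] <- bl - 1L
  }
  epoch_set(data, fs, labels, blocks, freqs, channel_names, latency_s)
}

#' Read and validate a run configuration
#'
#' Single-document YAML with the experiment knobs (channels, window, latency,
#' harmonics, sub-bands, clustering, method, sweep grids). Unknown top-level
#' keys are rejected; missing keys take the defaults of the 40-target
#' paradigm (nine channels, `Nh = 5`, `Nb = 5`, latency 0.14 s).
#'
#' @param path YAML file path (`NULL` = all defaults).
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    channels = default_channels(), window_s = 1.0, latency_s = 0.14,
    Nh = 5L, Nb = 5L, method = "htrcca",
    clustering = list(h_range = 2:8, seed = 1L),
    gaze_shift_s = 0,
    sweep = list(Nt = NA, Tw = NULL, Nc = NULL, Nb = 5L))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    cfg <- utils::modifyList(defaults, user)
  }
  if (!cfg$method %in% c("cca", "trca", "etrca", "htrcca", "ehtrcca"))
    stop(sprintf("invalid method: %s", cfg$method))
  if (cfg$window_s <= 0 || cfg$latency_s < 0) stop("invalid window/latency")
  cfg$clustering$h_range <- as.integer(cfg$clustering$h_range)
  structure(c(cfg, list(hash = config_hash(cfg))), class = "run_config")
}

#' Write an evaluation result table as CSV
#'
#' One row per (cell, fold); deterministic byte output for a fixed input.
#'
#' @param tab data.frame from [sweep_eval()] or assembled fold rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
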