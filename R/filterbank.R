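#' Design the Chebyshev Type-I sub-band bank
#'
#' Sub-band `b` spans the `b`-th lower edge of the conventional SSVEP table
#' (passband/stopband lower edges `[6/4, 14/10, 22/16, 30/24, 38/32]` Hz) up
#' to a common 90 Hz passband / 100 Hz stopband upper edge, so that band `b`
#' keeps the stimulus harmonics from roughly `8b` Hz upward. Minimal filter
#' order is chosen per band for the design spec (`ripple_db` passband /
#' `atten_db` stopband); the realized passband ripple is `realized_ripple_db`,
#' kept small because the bank is applied forward-backward (doubling dB loss).
#'
#' @param fs sampling rate in Hz.
#' @param Nb number of sub-bands (1..5).
#' @param ripple_db passband ripple used for order selection, dB.
#' @param atten_db stopband attenuation, dB.
#' @param realized_ripple_db passband ripple of the realized filter, dB.
#' @return list of `subband_spec` objects (fields: `b`, edges in Hz, ripple,
#'   attenuation, filter order `n`, and `filt` = `signal::Arma` coefficients).
#' @export
design_subbands <- function(fs, Nb = 5L, ripple_db = 3, atten_db = 40,
                            realized_ripple_db = 0.5) {
  lower_pass <- c(6, 14, 22, 30, 38)
  lower_stop <- c(4, 10, 16, 24, 32)
  if (Nb < 1L || Nb > 5L) stop("Nb must lie in 1..5: only five sub-bands are defined")
  nyq <- fs / 2
  hi_pass <- 90; hi_stop <- 100
  if (nyq <= 100) {
    hi_pass <- 0.9 * nyq; hi_stop <- 0.95 * nyq
    warning(sprintf("fs/2 = %g Hz <= 100 Hz: upper band edges clipped to %g/%g Hz",
                    nyq, hi_pass, hi_stop))
  }
  lapply(seq_len(Nb), function(b) {
    wp <- c(lower_pass[b], hi_pass) / nyq
    ws <- c(lower_stop[b], hi_stop) / nyq
    ord <- signal::cheb1ord(wp, ws, Rp = ripple_db, Rs = atten_db)
    filt <- signal::cheby1(ord$n, Rp = realized_ripple_db, W = wp, type = "pass")
    structure(list(b = b,
                   passband_lo = lower_pass[b], stopband_lo = lower_stop[b],
                   passband_hi = hi_pass, stopband_hi = hi_stop,
                   passband_ripple = realized_ripple_db, stopband_atten = atten_db,
                   n = ord$n, filt = filt),
              class = "subband_spec")
  })
}

#' @export
print.subband_spec <- function(x, ...) {
  cat(sprintf("<subband_spec> b=%d | pass %g-%g Hz | stop %g/%g Hz | order %d\n",
              x$b, x$passband_lo, x$passband_hi, x$stopband_lo, x$stopband_hi, x$n))
  invisible(x)
}

# Zero-phase IIR filtering: odd-reflection pad by 3x the coefficient length,
# filter forward and backward, crop the padding.
filtfilt_reflect <- function(filt, x) {
  b <- filt$b; a <- filt$a
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad)
    stop(sprintf("input of %d samples too short for reflect padding of %d samples (filter transient)",
                 n, npad))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Apply the filter bank to one epoch
#'
#' Zero-phase (forward-backward, odd-reflection-padded) channel-wise filtering
#' of an epoch into `Nb` sub-band components.
#'
#' @param X numeric matrix `[Nc x Ns]`.
#' @param specs list of `subband_spec` from [design_subbands()].
#' @return `subband_stack`: list with `data` = array `[Nb x Nc x Ns]` and `specs`.
#' @export
apply_filter_bank <- function(X, specs) {
  if (!is.matrix(X)) stop("X must be a [Nc x Ns] matrix")
  nb <- length(specs)
  nc <- nrow(X); ns <- ncol(X)
  out <- array(0, dim = c(nb, nc, ns))
  for (b in seq_len(nb)) {
    for (ch in seq_len(nc)) {
      out[b, ch, ] <- filtfilt_reflect(specs[[b]]$filt, X[ch, ])
    }
  }
  structure(list(data = out, specs = specs), class = "subband_stack")
}

#' Sub-band weight
#'
#' Weight of sub-band `b` in the fused detection score:
#' `c_b = b^-1.25 + 0.25`, decreasing with band index so that bands carrying
#' the fundamental dominate those carrying only high harmonics.
#'
#' @param b sub-band index (integer >= 1, vectorized).
#' @return numeric weight(s).
#' @export
subband_weight <- function(b) {
  if (any(b < 1) || any(b != floor(b))) stop("b must be a positive integer")
  b^(-1.25) + 0.25
}

#' Fuse per-sub-band features into one score
#'
#' Weighted sum of squared per-band features:
#' `rho = sum_b c_b * r_b^2`, non-negative by construction.
#'
#' @param features numeric vector of per-band feature values `r_b`, band 1 first.
#' @return fused score (scalar >= 0).
#' @export
combine_subbands <- function(features) {
  if (!all(is.finite(features))) stop("features must be finite")
  sum(subband_weight(seq_along(features)) * features^2)
}
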