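#' Average training trials into a template
#'
#' @param trials numeric array `[Nt x Nc x Ns]`.
#' @return numeric matrix `[Nc x Ns]`, the element-wise trial mean.
#' @export
build_template <- function(trials) {
  if (!is.array(trials) || length(dim(trials)) != 3L || dim(trials)[1L] < 1L)
    stop("trials must be a non-empty [Nt x Nc x Ns] array")
  nt <- dim(trials)[1L]
  out <- trials[1L, , ]
  if (nt > 1L) for (i in 2L:nt) out <- out + trials[i, , ]
  out / nt
}

# Tile a matrix Nt times along the time axis.
tile_time <- function(M, Nt) {
  if (Nt == 1L) return(M)
  do.call(cbind, rep(list(M), Nt))
}

#' Template-vs-reference CCA filters (wa, wb)
#'
#' First canonical weight pair of CCA between the `Nt`-fold tiled template
#' `Kn = [Xbar ... Xbar]` and the tiled sine-cosine reference
#' `Yref = [Yn ... Yn]`. Tiling leaves the correlation structure unchanged,
#' so the result is invariant in `Nt`; the tiled form mirrors how the
#' trial-concatenation filters below are trained.
#'
#' @param template numeric matrix `[Nc x Ns]` (trial-averaged template).
#' @param Nt number of training trials represented by the template.
#' @param Yn reference matrix `[2*Nh x Ns]`.
#' @return list `(wa, wb)`: channel weights `[Nc]` and reference weights `[2*Nh]`.
#' @export
train_template_filters <- function(template, Nt, Yn) {
  if (ncol(template) != ncol(Yn)) stop("template and reference must share Ns")
  if (Nt < 1L) stop("Nt must be >= 1")
  if (all(template == template[1L])) stop("degenerate template: zero variance")
  fit <- cca(tile_time(template, Nt), tile_time(Yn, Nt))
  list(wa = fit$Wx[, 1L], wb = fit$Wy[, 1L])
}

#' Trial-concatenation CCA filters (wc, wd)
#'
#' First canonical pair of CCA between the time-concatenated training trials
#' `Xn = [Xn1 Xn2 ... XnNt]` and the equally tiled reference.
#'
#' @param trials numeric array `[Nt x Nc x Ns]`.
#' @param Yn reference matrix `[2*Nh x Ns]`.
#' @return list `(wc, wd)`.
#' @export
train_trial_filters <- function(trials, Yn) {
  if (!is.array(trials) || length(dim(trials)) != 3L) stop("trials must be [Nt x Nc x Ns]")
  nt <- dim(trials)[1L]
  Xn <- do.call(cbind, lapply(seq_len(nt), function(i) trials[i, , , drop = TRUE]))
  fit <- cca(Xn, tile_time(Yn, nt))
  list(wc = fit$Wx[, 1L], wd = fit$Wy[, 1L])
}

#' Task-related component analysis spatial filter (wt)
#'
#' Maximizes the inter-trial covariance of the projected component relative
#' to its total variance: `w = argmax w'Sw / w'Qw`, where `S` is the sum of
#' cross-trial covariances over trial pairs `i != j` and `Q` is the
#' covariance of all (per-channel mean-centered) trials pooled. Solved as a
#' symmetric-definite generalized eigenproblem via whitening of `Q` with a
#' relative ridge `1e-9 * trace(Q)/Nc`; the leading eigenvector is returned
#' unit-norm with the largest-magnitude entry positive.
#'
#' @param trials numeric array `[Nt x Nc x Ns]`, `Nt >= 2`.
#' @return numeric vector `wt` of length `Nc`.
#' @export
train_trca_filter <- function(trials) {
  if (!is.array(trials) || length(dim(trials)) != 3L) stop("trials must be [Nt x Nc x Ns]")
  nt <- dim(trials)[1L]
  nc <- dim(trials)[2L]
  if (nt < 2L) stop("TRCA needs Nt >= 2 trials (no inter-trial covariance otherwise)")
  centered <- lapply(seq_len(nt), function(i) {
    Xi <- trials[i, , , drop = TRUE]
    if (nc == 1L) Xi <- matrix(Xi, nrow = 1L)
    Xi - rowMeans(Xi)
  })
  S <- matrix(0, nc, nc)
  Q <- matrix(0, nc, nc)
  for (i in seq_len(nt)) {
    Q <- Q + tcrossprod(centered[[i]])
    for (j in seq_len(nt)) {
      if (i != j) S <- S + tcrossprod(centered[[i]], centered[[j]])
    }
  }
  if (nt >= 2L) {
    same <- all(vapply(2L:nt, function(i)
      isTRUE(all.equal(centered[[i]], centered[[1L]], tolerance = 1e-12)), logical(1L)))
    if (same) warning("identical trials: TRCA objective is degenerate (S proportional to Q)")
  }
  eps <- 1e-9 * sum(diag(Q)) / nc
  if (!is.finite(eps) || eps <= 0) {
    warning("singular total-covariance matrix: ridge-regularized solve")
    eps <- 1e-12
  }
  e <- eigen(Q + diag(eps, nc), symmetric = TRUE)
  vals <- pmax(e$values, eps)
  W <- e$vectors %*% (t(e$vectors) / sqrt(vals))   # Q^{-1/2}
  M <- W %*% ((S + t(S)) / 2) %*% W
  u <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  w <- as.vector(W %*% u)
  w <- w / sqrt(sum(w^2))
  fix_sign(w)
}

#' Concatenate per-stimulus TRCA filters
#'
#' Builds the joint spatial filter `W = [wt_1 ... wt_m]` over a set of
#' stimuli (the candidate set in stage 2, or all stimuli for the ensemble
#' recognizers), for one sub-band.
#'
#' @param bank a `model_bank` from [fit_model_bank()].
#' @param indices 0-based stimulus indices, order preserved.
#' @param b sub-band index (1-based).
#' @return numeric matrix `[Nc x length(indices)]`.
#' @export
concatenate_filters <- function(bank, indices, b = 1L) {
  stopifnot(inherits(bank, "model_bank"))
  if (length(indices) == 0L) stop("indices must be non-empty")
  if (any(indices < 0L) || any(indices >= bank$Nf))
    stop("stimulus index out of range 0..Nf-1")
  vapply(indices, function(n) bank$models[[n + 1L]][[b]]$wt,
         numeric(bank$Nc))
}

#' Train the full per-stimulus, per-sub-band model bank
#'
#' For every stimulus and sub-band: band-filter the training trials, average
#' them into a template, and train the five spatial filters (`wa`, `wb` from
#' template-vs-reference CCA; `wc`, `wd` from trial-concatenation CCA; `wt`
#' from TRCA). Deterministic given data and configuration.
#'
#' @param train an `epoch_set` of training trials.
#' @param refs a `reference_bank` with matching `Ns` and frequency table.
#' @param specs sub-band specs from [design_subbands()].
#' @return `model_bank`: `models[[n]][[b]]` holds the filters and template for
#'   stimulus `n` (1-based list index) and band `b`, plus geometry metadata.
#' @export
fit_model_bank <- function(train, refs, specs) {
  stopifnot(inherits(train, "epoch_set"), inherits(refs, "reference_bank"))
  d <- epoch_dims(train)
  nf <- length(train$freqs)
  nb <- length(specs)
  if (!isTRUE(all.equal(refs$freqs, train$freqs)))
    stop("reference bank frequency table does not match the epoch set")
  if (refs$Ns != d["Ns"]) stop("reference bank Ns does not match epochs")
  missing <- setdiff(seq_len(nf) - 1L, unique(train$labels))
  if (length(missing))
    stop(sprintf("stimuli missing from training data: %s",
                 paste(missing, collapse = ", ")))
  models <- vector("list", nf)
  for (n0 in seq_len(nf) - 1L) {
    idx <- which(train$labels == n0)
    nt <- length(idx)
    if (nt < 2L)
      stop(sprintf("stimulus %d has %d training trial(s); TRCA needs >= 2", n0, nt))
    # band-filter each training trial once
    banded <- lapply(idx, function(i)
      apply_filter_bank(train$data[i, , , drop = TRUE], specs)$data)
    Yn <- refs$Y[[n0 + 1L]]
    per_band <- vector("list", nb)
    for (b in seq_len(nb)) {
      trials_b <- array(0, dim = c(nt, d["Nc"], d["Ns"]))
      for (i in seq_len(nt)) trials_b[i, , ] <- banded[[i]][b, , ]
      template <- build_template(trials_b)
      tf <- train_template_filters(template, nt, Yn)
      cf <- train_trial_filters(trials_b, Yn)
      wt <- train_trca_filter(trials_b)
      per_band[[b]] <- list(wa = tf$wa, wb = tf$wb, wc = cf$wc, wd = cf$wd,
                            wt = wt, template = template,
                            n = n0, fn = train$freqs[n0 + 1L], b = b, Nt = nt)
    }
    models[[n0 + 1L]] <- per_band
  }
  structure(list(models = models, Nf = nf, Nb = nb,
                 Nc = unname(d["Nc"]), Ns = unname(d["Ns"]),
                 Nh = refs$Nh, fs = train$fs, freqs = train$freqs,
                 specs = specs, channel_names = train$channel_names),
            class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("<model_bank> %d stimuli x %d sub-bands | Nc=%d Ns=%d Nh=%d @ %g Hz\n",
              x$Nf, x$Nb, x$Nc, x$Ns, x$Nh, x$fs))
  invisible(x)
}
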