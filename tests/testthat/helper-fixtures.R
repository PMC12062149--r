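# Shared fixtures and independent oracles for the suite. Fixtures are
# simulated once per test run and cached; everything is seeded.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

fixture_suite <- function() cached("fixtures", suppressWarnings(make_fixture_suite(1L)))

# Trained bank + references for a fixture, training on all blocks but the last.
trained_setup <- function(name, Nb = 5L, Nh = 5L) {
  cached(paste0("setup_", name, "_", Nb, "_", Nh), {
    x <- fixture_suite()[[name]]
    d <- epoch_dims(x)
    specs <- design_subbands(x$fs, Nb)
    refs <- make_reference_bank(x$freqs, x$fs, d[["Ns"]], Nh)
    bmax <- max(x$blocks)
    train <- epoch_subset(x, which(x$blocks < bmax))
    test <- epoch_subset(x, which(x$blocks == bmax))
    bank <- suppressWarnings(fit_model_bank(train, refs, specs))
    list(x = x, train = train, test = test, bank = bank, refs = refs,
         specs = specs)
  })
}

# Independent CCA oracle: largest eigenvalue of Sxx^-1 Sxy Syy^-1 Syx on
# row-centered data, by direct (non-symmetric) eigendecomposition.
cca_eig_oracle <- function(X, Y) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  Sxx <- tcrossprod(Xc); Syy <- tcrossprod(Yc); Sxy <- tcrossprod(Xc, Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(Re(eigen(M)$values)))
}

# Definition-level Davies-Bouldin oracle: explicit double loop.
db_oracle <- function(points, labels) {
  labs <- unique(labels)
  h <- length(labs)
  cent <- lapply(labs, function(l) colMeans(points[labels == l, , drop = FALSE]))
  S <- sapply(seq_len(h), function(i) {
    P <- points[labels == labs[i], , drop = FALSE]
    mean(apply(P, 1L, function(p) sqrt(sum((p - cent[[i]])^2))))
  })
  total <- 0
  for (i in seq_len(h)) {
    best <- -Inf
    for (j in seq_len(h)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      r <- if (M == 0) Inf else (S[i] + S[j]) / M
      if (r > best) best <- r
    }
    total <- total + best
  }
  total / h
}

# Toy TRCA dataset: channel 1 carries a common 12 Hz sinusoid in all trials,
# channel 2 is independent white noise per trial.
trca_toy <- function(Nt = 10L, Ns = 250L, fs = 250, seed = 1L) {
  set.seed(seed)
  common <- sin(2 * pi * 12 * seq_len(Ns) / fs)
  trials <- array(0, dim = c(Nt, 2L, Ns))
  for (i in seq_len(Nt)) {
    trials[i, 1L, ] <- common + 0.1 * rnorm(Ns)
    trials[i, 2L, ] <- rnorm(Ns)
  }
  list(trials = trials, truth = common)
}

# Two/three well-separated 5-D Gaussian blobs.
make_blobs <- function(k, n_per = 12L, sep = 20, seed = 7L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rnorm(n_per * 5L, mean = j * sep, sd = 1), n_per, 5L)))
}
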