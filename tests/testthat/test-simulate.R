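test_that("the default simulation reproduces the benchmark geometry", {
  cfg <- sim_config(B = 4L, trial_s = 0.3, snr_db = Inf, seed = 2)
  x <- simulate_epochset(cfg, keep_components = FALSE)
  d <- epoch_dims(x)
  expect_identical(unname(d[["n_trials"]]), 160L)     # 4 blocks x 40 stimuli
  expect_equal(x$freqs, seq(8, 15.8, by = 0.2))
  expect_identical(length(unique(x$labels)), 40L)
  expect_identical(x$channel_names, default_channels())
  for (b in 0:3) expect_identical(sum(x$blocks == b), 40L)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(freqs = c(9, 12), Nc = 3L, B = 2L, trial_s = 0.4,
                    snr_db = -5, harmonics = 1 / (1:2), seed = 77)
  x1 <- simulate_epochset(cfg)
  x2 <- simulate_epochset(cfg)
  expect_identical(x1$data, x2$data)
  expect_identical(attr(x1, "components"), attr(x2, "components"))
})

test_that("noise-free trials are latency-aligned with their references", {
  fx <- fixture_suite()$noisefree8
  refs <- make_reference_bank(fx$freqs, fx$fs, epoch_dims(fx)[["Ns"]], 5)
  for (i in c(1L, 5L, 20L)) {
    rho <- max_canonical_correlation(fx$data[i, , ],
                                     refs$Y[[fx$labels[i] + 1L]])
    expect_gte(rho, 0.999)
  }
  # phase alignment: a trial channel correlates best with the zero-lag
  # reference built on the same one-based time grid
  cfg <- sim_config(freqs = 10, phases = 0, Nc = 2L, B = 1L, trial_s = 1,
                    snr_db = Inf, harmonics = 1, seed = 5)
  x <- simulate_epochset(cfg, keep_components = FALSE)
  v <- x$data[1, 1, ]
  ref <- sin(2 * pi * 10 * seq_len(250) / 250)
  lag_cor <- vapply(-5:5, function(l) {
    idx <- (1 + max(0, l)):(250 + min(0, l))
    pearson(v[idx], ref[idx - l])
  }, numeric(1))
  expect_identical(which.max(lag_cor), 6L)  # lag 0
})

test_that("realized SNR matches the target within half a decibel", {
  cfg <- sim_config(freqs = c(9, 11, 13, 15), Nc = 4L, B = 5L, trial_s = 1,
                    snr_db = -10, harmonics = 1 / (1:2), seed = 9)
  x <- simulate_epochset(cfg)
  snr <- realized_snr(x)
  expect_length(snr, 20L)
  expect_lt(abs(mean(snr) - (-10)), 0.5)
  clean_cfg <- sim_config(freqs = 10, Nc = 2L, B = 1L, trial_s = 0.5,
                          snr_db = Inf, harmonics = 1, seed = 10)
  expect_true(all(realized_snr(simulate_epochset(clean_cfg)) == Inf))
  x_nocomp <- simulate_epochset(cfg, keep_components = FALSE)
  expect_error(realized_snr(x_nocomp), "components")
})

test_that("simulated spectra peak at the stimulus frequency and harmonics", {
  cfg <- sim_config(freqs = 12, Nc = 3L, B = 1L, trial_s = 2, snr_db = 10,
                    harmonics = 1 / (1:2), seed = 12)
  x <- simulate_epochset(cfg, keep_components = FALSE)
  v <- x$data[1, 3, ]   # occipital channel
  n <- length(v)
  spec <- Mod(stats::fft(v))[2:(n / 2)]
  fgrid <- (1:(n / 2 - 1)) * x$fs / n
  in_band <- fgrid >= 6 & fgrid <= 40
  peak_f <- fgrid[in_band][which.max(spec[in_band])]
  expect_lt(abs(peak_f - 12), x$fs / n + 1e-9)  # within one frequency bin
})

test_that("same-stimulus trials share more structure than shuffled labels", {
  cfg <- sim_config(freqs = c(9, 13), Nc = 4L, B = 6L, trial_s = 0.6,
                    snr_db = 0, harmonics = 1, seed = 14)
  x <- simulate_epochset(cfg, keep_components = FALSE)
  trials_same <- x$data[x$labels == 0L, , , drop = FALSE]
  set.seed(15)
  mix <- sample(which(x$labels %in% c(0L, 1L)), 6)
  trials_mix <- x$data[mix, , , drop = FALSE]
  obj <- function(trials) {
    wt <- suppressWarnings(train_trca_filter(trials))
    nt <- dim(trials)[1]
    cs <- lapply(seq_len(nt), function(i) {
      Xi <- trials[i, , ]; Xi - rowMeans(Xi)
    })
    S <- 0; Q <- 0
    for (i in seq_len(nt)) {
      Q <- Q + as.numeric(t(wt) %*% tcrossprod(cs[[i]]) %*% wt)
      for (j in seq_len(nt)) if (i != j)
        S <- S + as.numeric(t(wt) %*% tcrossprod(cs[[i]], cs[[j]]) %*% wt)
    }
    S / Q
  }
  expect_gt(obj(trials_same), obj(trials_mix))
})

test_that("the fixture suite is deterministic and classifiable", {
  fx1 <- fixture_suite()
  fx2 <- suppressWarnings(make_fixture_suite(1L))
  expect_identical(fx1$noisefree8$data, fx2$noisefree8$data)
  expect_identical(fx1$noisy40$data, fx2$noisy40$data)
  expect_identical(length(unique(fx1$noisefree8$labels)), 8L)
  expect_identical(length(unique(fx1$noisefree40$labels)), 40L)
})
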