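test_that("templates are element-wise trial means", {
  tr <- array(0, dim = c(3, 2, 4))
  tr[1, , ] <- 1; tr[2, , ] <- 2; tr[3, , ] <- 3
  expect_true(all(build_template(tr) == 2))
  one <- array(rnorm(8), dim = c(1, 2, 4))
  expect_equal(build_template(one), one[1, , ])
  pm <- array(0, dim = c(2, 2, 4))
  pm[1, , ] <- 5; pm[2, , ] <- -5
  expect_true(all(build_template(pm) == 0))
  expect_error(build_template(array(0, dim = c(0, 2, 4))), "non-empty")
})

test_that("template-filter training is invariant to the tiling count", {
  set.seed(2)
  tmpl <- matrix(rnorm(4 * 120), 4, 120)
  Yn <- make_reference(10, 250, 120, 3)
  f1 <- train_template_filters(tmpl, 1L, Yn)
  f3 <- train_template_filters(tmpl, 3L, Yn)
  f5 <- train_template_filters(tmpl, 5L, Yn)
  expect_equal(f1$wa, f3$wa, tolerance = 1e-10)
  expect_equal(f1$wb, f3$wb, tolerance = 1e-10)
  expect_equal(f1$wa, f5$wa, tolerance = 1e-10)
  # equals the plain first canonical pair of template vs reference
  fit <- cca(tmpl, Yn)
  expect_equal(f1$wa, fit$Wx[, 1], tolerance = 1e-8)
  expect_error(train_template_filters(matrix(1, 3, 50), 1L,
                                      make_reference(10, 250, 50, 1)),
               "degenerate")
})

test_that("a noise-free mixed SSVEP template yields near-perfect projected correlation", {
  Ns <- 250; fs <- 250; fn <- 11
  t <- seq_len(Ns) / fs
  src <- rbind(sin(2 * pi * fn * t), cos(2 * pi * fn * t))
  set.seed(4)
  A <- matrix(rnorm(12), 6, 2)
  tmpl <- A %*% src
  Yn <- make_reference(fn, fs, Ns, 3)
  f <- train_template_filters(tmpl, 1L, Yn)
  expect_gte(pearson(as.vector(crossprod(tmpl, f$wa)),
                     as.vector(crossprod(Yn, f$wb))), 0.999)
})

test_that("trial-concatenation filters reduce to template filters for one trial", {
  set.seed(9)
  trial <- matrix(rnorm(5 * 100), 5, 100)
  Yn <- make_reference(9, 250, 100, 2)
  tf <- train_template_filters(trial, 1L, Yn)
  arr <- array(trial, dim = c(1, 5, 100))
  cf <- train_trial_filters(arr, Yn)
  expect_equal(cf$wc, tf$wa, tolerance = 1e-8)
  expect_equal(cf$wd, tf$wb, tolerance = 1e-8)
  # identical repeated trials tile away
  arr3 <- array(0, dim = c(3, 5, 100))
  for (i in 1:3) arr3[i, , ] <- trial
  cf3 <- train_trial_filters(arr3, Yn)
  expect_equal(cf3$wc, cf$wc, tolerance = 1e-8)
})

test_that("TRCA recovers the shared component in the 2-channel toy", {
  toy <- trca_toy(Nt = 10L, seed = 1L)
  wt <- train_trca_filter(toy$trials)
  cors <- vapply(1:10, function(i)
    abs(pearson(as.vector(crossprod(toy$trials[i, , ], wt)), toy$truth)),
    numeric(1))
  expect_gte(mean(cors), 0.95)
})

test_that("the TRCA component is invariant to invertible channel mixing", {
  toy <- trca_toy(Nt = 8L, seed = 2L)
  wt0 <- train_trca_filter(toy$trials)
  set.seed(3)
  A <- matrix(rnorm(4), 2, 2)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
  mixed <- toy$trials
  for (i in 1:8) mixed[i, , ] <- A %*% toy$trials[i, , ]
  wt1 <- train_trca_filter(mixed)
  c0 <- as.vector(crossprod(toy$trials[1, , ], wt0))
  c1 <- as.vector(crossprod(mixed[1, , ], wt1))
  expect_gte(abs(pearson(c0, c1)), 0.999)
})

test_that("TRCA maximizes its Rayleigh quotient over random directions", {
  toy <- trca_toy(Nt = 6L, Ns = 150L, seed = 5L)
  wt <- train_trca_filter(toy$trials)
  centered <- lapply(1:6, function(i) {
    Xi <- toy$trials[i, , ]; Xi - rowMeans(Xi)
  })
  S <- Reduce(`+`, lapply(1:6, function(i) Reduce(`+`, lapply(setdiff(1:6, i),
    function(j) tcrossprod(centered[[i]], centered[[j]])))))
  Q <- Reduce(`+`, lapply(centered, tcrossprod))
  rq <- function(w) as.numeric(t(w) %*% S %*% w / (t(w) %*% Q %*% w))
  set.seed(6)
  rand <- replicate(100, { v <- rnorm(2); rq(v / sqrt(sum(v^2))) })
  expect_true(all(rq(wt) >= rand - 1e-10))
})

test_that("degenerate TRCA inputs are flagged", {
  trial <- matrix(rnorm(3 * 80), 3, 80)
  same <- array(0, dim = c(2, 3, 80))
  same[1, , ] <- trial; same[2, , ] <- trial
  expect_warning(train_trca_filter(same), "degenerate")
  expect_error(train_trca_filter(array(rnorm(240), dim = c(1, 3, 80))), "Nt >= 2")
})

test_that("filter concatenation preserves order and validates indices", {
  st <- trained_setup("noisefree8", Nb = 2L, Nh = 3L)
  W <- concatenate_filters(st$bank, 0:7, 1L)
  expect_identical(dim(W), c(9L, 8L))
  expect_equal(W[, 3], st$bank$models[[3]][[1]]$wt)
  one <- concatenate_filters(st$bank, 4L, 2L)
  expect_equal(as.vector(one), st$bank$models[[5]][[2]]$wt)
  perm <- concatenate_filters(st$bank, c(5L, 0L, 2L), 1L)
  expect_equal(perm[, 1], W[, 6])
  expect_equal(perm[, 2], W[, 1])
  expect_error(concatenate_filters(st$bank, 42L, 1L), "out of range")
  expect_error(concatenate_filters(st$bank, integer(0), 1L), "non-empty")
})

test_that("the model bank covers the full stimulus-by-band grid deterministically", {
  st <- trained_setup("noisefree8", Nb = 2L, Nh = 3L)
  bank <- st$bank
  expect_identical(bank$Nf, 8L)
  expect_length(bank$models, 8L)
  expect_true(all(vapply(bank$models, length, integer(1)) == 2L))
  bank2 <- suppressWarnings(fit_model_bank(st$train, st$refs, st$specs))
  expect_identical(bank, bank2)
  # every model's wa-projected template tracks its wb-projected reference
  # (in magnitude: sign conventions are applied per filter; slightly below 1
  # only through band-filter edge transients)
  cors <- vapply(1:8, function(n) {
    m <- bank$models[[n]][[1]]
    pearson(as.vector(crossprod(m$template, m$wa)),
            as.vector(crossprod(st$refs$Y[[n]], m$wb)))
  }, numeric(1))
  expect_true(all(abs(cors) >= 0.99))
  broken <- epoch_subset(st$train, which(st$train$labels != 3L))
  expect_error(suppressWarnings(fit_model_bank(broken, st$refs, st$specs)),
               "missing")
})

test_that("all filters are invariant to global data rescaling up to sign convention", {
  toy <- trca_toy(Nt = 5L, seed = 8L)
  wt1 <- train_trca_filter(toy$trials)
  wt2 <- train_trca_filter(toy$trials * 37.5)
  expect_equal(wt1, wt2, tolerance = 1e-8)
  tmpl <- matrix(rnorm(3 * 100), 3, 100)
  Yn <- make_reference(12, 250, 100, 2)
  f1 <- train_template_filters(tmpl, 2L, Yn)
  f2 <- train_template_filters(tmpl * 0.001, 2L, Yn)
  expect_equal(f1$wa / sqrt(sum(f1$wa^2)), f2$wa / sqrt(sum(f2$wa^2)),
               tolerance = 1e-6)
})
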