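test_that("fused feature vectors are non-negative and peak at the true stimulus", {
  st <- trained_setup("noisefree8")
  X <- st$test$data[1, , ]
  truth <- st$test$labels[1]
  fv_true <- feature_vector(X, truth, st$bank, st$refs)
  expect_length(fv_true, 5L)
  expect_true(all(fv_true >= 0))
  # noise-free matched case: each fused component near its theoretical
  # maximum sum_b c_b (weights of the bands that carry signal dominate)
  expect_gte(fv_true[1], subband_weight(1) * 0.99)
  other <- setdiff(0:7, truth)[1]
  fv_other <- feature_vector(X, other, st$bank, st$refs)
  expect_gt(sum(fv_true), sum(fv_other))
})

test_that("with one sub-band the fused component is 1.25 times the squared correlation", {
  st <- trained_setup("noisefree8", Nb = 1L, Nh = 3L)
  X <- st$test$data[3, , ]
  n <- st$test$labels[3]
  fused <- feature_vector(X, n, st$bank, st$refs)
  stack <- apply_filter_bank(X, st$specs)
  m <- st$bank$models[[n + 1]][[1]]
  Xb <- stack$data[1, , ]
  r2 <- pearson(as.vector(crossprod(Xb, m$wa)),
                as.vector(crossprod(m$template, m$wa)))
  expect_equal(fused[2], 1.25 * r2^2, tolerance = 1e-10)
})

test_that("stage 1 keeps the true stimulus among the candidates on clean trials", {
  st <- trained_setup("noisefree8")
  for (i in c(1L, 4L, 8L)) {
    s1 <- suppressWarnings(stage1(st$test$data[i, , ], st$bank, st$refs, seed = 1))
    expect_identical(nrow(s1$features), 8L)
    expect_true(st$test$labels[i] %in% s1$candidates$indices)
  }
  # determinism
  a <- suppressWarnings(stage1(st$test$data[2, , ], st$bank, st$refs, seed = 3))
  b <- suppressWarnings(stage1(st$test$data[2, , ], st$bank, st$refs, seed = 3))
  expect_identical(a$candidates$indices, b$candidates$indices)
})

test_that("stage 2 sums features into T, adds D, and short-circuits singletons", {
  st <- trained_setup("noisefree8")
  X <- st$test$data[5, , ]
  s1 <- suppressWarnings(stage1(X, st$bank, st$refs, seed = 1))
  dec <- stage2(X, s1$candidates, s1$features, st$bank)
  expect_s3_class(dec, "decision")
  expect_true(dec$ft %in% s1$candidates$indices)
  expect_equal(dec$T, rowSums(s1$features)[s1$candidates$indices + 1L],
               tolerance = 1e-12)
  if (length(s1$candidates$indices) > 1L)
    expect_equal(dec$C, dec$T + dec$D, tolerance = 1e-12)
  lone <- structure(list(indices = 3L, h_selected = 2L,
                         cluster_means = c(`1` = 1)), class = "candidate_set")
  dec1 <- stage2(X, lone, s1$features, st$bank)
  expect_identical(dec1$ft, 3L)
})

test_that("decisions are invariant to positive rescaling of the test trial", {
  st <- trained_setup("noisefree8")
  X <- st$test$data[6, , ]
  d1 <- suppressWarnings(classify(X, st$bank, st$refs, seed = 2))
  d2 <- suppressWarnings(classify(X * 1e3, st$bank, st$refs, seed = 2))
  expect_identical(d1$ft, d2$ft)
  expect_equal(d1$C, d2$C, tolerance = 1e-6)
})

test_that("with two stimuli clustering degenerates to all-candidates", {
  fx <- fixture_suite()$noisefree8
  two <- epoch_subset(fx, which(fx$labels < 2L))
  two$freqs <- fx$freqs[1:2]
  d <- epoch_dims(two)
  specs <- design_subbands(two$fs, 2L)
  refs <- make_reference_bank(two$freqs, two$fs, d[["Ns"]], 3L)
  tr <- epoch_subset(two, which(two$blocks < 2L))
  te <- epoch_subset(two, which(two$blocks == 2L))
  bank <- suppressWarnings(fit_model_bank(tr, refs, specs))
  expect_warning(s1 <- stage1(te$data[1, , ], bank, refs), "fewer than 3")
  expect_identical(s1$candidates$indices, 0:1)
})

test_that("the baseline recognizers agree with their defining scores", {
  st <- trained_setup("noisefree8", Nb = 1L, Nh = 3L)
  X <- st$test$data[2, , ]
  # Nb = 1: TRCA decision equals argmax of the raw per-stimulus correlation
  stack <- apply_filter_bank(X, st$specs)
  raw <- vapply(1:8, function(n1) {
    m <- st$bank$models[[n1]][[1]]
    pearson(as.vector(crossprod(stack$data[1, , ], m$wt)),
            as.vector(crossprod(m$template, m$wt)))
  }, numeric(1))
  expect_identical(trca_classify(X, st$bank), which.max(raw) - 1L)
  # one-column ensemble reduces to the per-stimulus TRCA score
  n <- st$test$labels[2]
  W1 <- lapply(1L, function(b) concatenate_filters(st$bank, n, b))
  Xb <- stack$data[1, , ]
  m <- st$bank$models[[n + 1]][[1]]
  s_one <- matrix_correlation(crossprod(Xb, W1[[1]]),
                              crossprod(m$template, W1[[1]]))
  expect_equal(s_one, raw[n + 1], tolerance = 1e-12)
})

test_that("ensemble scores permute consistently with stimulus order", {
  st <- trained_setup("noisefree8", Nb = 2L, Nh = 3L)
  X <- st$test$data[4, , ]
  s_all <- vapply(0:7, function(n) ensemble_correlation(X, n, st$bank),
                  numeric(1))
  expect_identical(which.max(s_all) - 1L, st$test$labels[4])
  expect_identical(etrca_classify(X, st$bank), st$test$labels[4])
})

test_that("classify_epochs is deterministic and candidate-consistent", {
  st <- trained_setup("noisefree8")
  p1 <- suppressWarnings(classify_epochs(st$test, st$bank, st$refs, "htrcca", seed = 4))
  p2 <- suppressWarnings(classify_epochs(st$test, st$bank, st$refs, "htrcca", seed = 4))
  expect_identical(p1, p2)
  X <- st$test$data[7, , ]
  dec <- suppressWarnings(classify(X, st$bank, st$refs, seed = 4))
  m <- length(dec$candidates$indices)
  expect_length(dec$C, m)
  expect_length(dec$T, m)
  # non-candidate suppression: candidate rows out-score the rest on average
  s1 <- suppressWarnings(stage1(X, st$bank, st$refs, seed = 4))
  non <- setdiff(0:7, s1$candidates$indices)
  if (length(non) > 0)
    expect_gt(mean(s1$features[s1$candidates$indices + 1L, ]),
              mean(s1$features[non + 1L, ]))
})
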