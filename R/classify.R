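# Per-band five-feature vector for one stimulus, from a pre-banked epoch.
feature_vector_banded <- function(stack, n, bank, refs) {
  nb <- bank$Nb
  Yn <- refs$Y[[n + 1L]]
  raw <- matrix(0, nrow = nb, ncol = 5L)
  for (b in seq_len(nb)) {
    m <- bank$models[[n + 1L]][[b]]
    Xb <- stack$data[b, , , drop = TRUE]
    if (bank$Nc == 1L) Xb <- matrix(Xb, nrow = 1L)
    pX_a <- crossprod(Xb, m$wa)          # X_b' wa  [Ns]
    pX_c <- crossprod(Xb, m$wc)
    pT_a <- crossprod(m$template, m$wa)  # Xbar' wa
    pT_c <- crossprod(m$template, m$wc)
    pY_b <- crossprod(Yn, m$wb)          # Yn' wb
    pY_d <- crossprod(Yn, m$wd)
    raw[b, 1L] <- max_canonical_correlation(Xb, Yn)
    raw[b, 2L] <- pearson(pX_a, pT_a)
    raw[b, 3L] <- pearson(pX_a, pY_b)
    raw[b, 4L] <- pearson(pX_c, pY_d)
    raw[b, 5L] <- pearson(pX_c, pT_c)
  }
  fused <- vapply(1:5, function(s) combine_subbands(raw[, s]), numeric(1L))
  list(fused = fused, raw = raw)
}

#' Five-feature correlation vector for one stimulus
#'
#' Per sub-band `b`, computes (1) the maximal canonical correlation between
#' the banded test epoch and the stimulus reference, and (2-5) the Pearson
#' correlations between the `wa`/`wc`-projected test epoch and the equally
#' projected template (`wa`, `wc`) or reference (`wb`, `wd`); each component
#' is then fused across sub-bands by the weighted squared sum, so the
#' returned 5-vector is non-negative.
#'
#' @param X_test numeric matrix `[Nc x Ns]` (raw, unbanked epoch).
#' @param n 0-based stimulus index.
#' @param bank a `model_bank`.
#' @param refs the matching `reference_bank`.
#' @return numeric vector of 5 fused features.
#' @export
feature_vector <- function(X_test, n, bank, refs) {
  stack <- apply_filter_bank(X_test, bank$specs)
  feature_vector_banded(stack, n, bank, refs)$fused
}

#' Stage 1: feature matrix and candidate stimuli
#'
#' Computes the fused five-feature vector for every stimulus, then selects
#' the candidate set by clustering the feature rows (GMM + Davies-Bouldin
#' cluster-count selection, k-means++ partition, highest-mean cluster wins).
#' With fewer than three stimuli clustering is skipped and all stimuli are
#' candidates.
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param bank a `model_bank`.
#' @param refs the matching `reference_bank`.
#' @param h_range candidate cluster counts.
#' @param seed clustering seed.
#' @return list `(features, candidates)`: `[Nf x 5]` matrix, `candidate_set`.
#' @export
stage1 <- function(X_test, bank, refs, h_range = 2:8, seed = 1L) {
  stack <- apply_filter_bank(X_test, bank$specs)
  stage1_banded(stack, bank, refs, h_range, seed)
}

stage1_banded <- function(stack, bank, refs, h_range = 2:8, seed = 1L) {
  nf <- bank$Nf
  features <- t(vapply(seq_len(nf) - 1L, function(n)
    feature_vector_banded(stack, n, bank, refs)$fused, numeric(5L)))
  if (nf <= 2L) {
    warning("fewer than 3 stimuli: clustering skipped, all stimuli are candidates")
    cand <- structure(list(indices = seq_len(nf) - 1L, h_selected = 1L,
                           cluster_means = c(`1` = mean(features))),
                      class = "candidate_set")
    return(list(features = features, candidates = cand))
  }
  h <- select_cluster_count(features, h_range = h_range, seed = seed)
  labels <- cluster_features(features, h, seed = seed)
  list(features = features, candidates = pick_candidates(features, labels))
}

#' Stage 2: fuse CCA- and TRCA-derived scores over the candidates
#'
#' For each candidate `k`: `T_k` is the sum of its five fused features;
#' `D_k` is the matrix correlation between the test epoch and candidate
#' template, both projected through the concatenated TRCA filters of the
#' candidate stimuli (per sub-band, fused by the weighted squared sum);
#' `C_k = T_k + D_k` and the decision is `argmax_k C_k` (ties to the lowest
#' stimulus index). A singleton candidate set short-circuits to that
#' stimulus.
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param candidates a `candidate_set` from [stage1()].
#' @param features `[Nf x 5]` fused feature matrix from [stage1()].
#' @param bank a `model_bank`.
#' @param W optional override for the concatenated spatial filters: a list of
#'   `[Nc x m]` matrices, one per sub-band (used by the ensemble variant).
#' @return a `decision` (fields `ft`, `C`, `T`, `D`, `candidates`).
#' @export
stage2 <- function(X_test, candidates, features, bank, W = NULL) {
  stack <- apply_filter_bank(X_test, bank$specs)
  stage2_banded(stack, candidates, features, bank, W)
}

stage2_banded <- function(stack, candidates, features, bank, W = NULL) {
  idx <- candidates$indices
  m <- length(idx)
  if (m == 0L) stop("empty candidate set")
  T_vec <- rowSums(features)[idx + 1L]
  if (m == 1L) {
    return(structure(list(ft = idx, C = T_vec, T = T_vec, D = 0,
                          candidates = candidates), class = "decision"))
  }
  if (is.null(W))
    W <- lapply(seq_len(bank$Nb), function(b) concatenate_filters(bank, idx, b))
  D_vec <- vapply(seq_len(m), function(k) {
    per_band <- vapply(seq_len(bank$Nb), function(b) {
      Xb <- stack$data[b, , , drop = TRUE]
      if (bank$Nc == 1L) Xb <- matrix(Xb, nrow = 1L)
      tmpl <- bank$models[[idx[k] + 1L]][[b]]$template
      matrix_correlation(crossprod(Xb, W[[b]]), crossprod(tmpl, W[[b]]))
    }, numeric(1L))
    combine_subbands(per_band)
  }, numeric(1L))
  C_vec <- T_vec + D_vec
  structure(list(ft = idx[which.max(C_vec)], C = C_vec, T = T_vec, D = D_vec,
                 candidates = candidates), class = "decision")
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf("<decision> target stimulus %d | %d candidate(s) | C_max=%.4f\n",
              x$ft, length(x$candidates$indices), max(x$C)))
  invisible(x)
}

#' H-TRCCA recognition of a single test epoch
#'
#' Runs stage 1 (feature computation and clustering-based candidate
#' selection) then stage 2 (score fusion over the candidates).
#'
#' @inheritParams stage1
#' @return a `decision`; `$ft` is the predicted 0-based stimulus index.
#' @export
classify <- function(X_test, bank, refs, h_range = 2:8, seed = 1L) {
  stack <- apply_filter_bank(X_test, bank$specs)
  s1 <- stage1_banded(stack, bank, refs, h_range, seed)
  stage2_banded(stack, s1$candidates, s1$features, bank)
}

#' Ensemble H-TRCCA recognition of a single test epoch
#'
#' As [classify()], but stage 2 projects through the ensemble filter built
#' from the TRCA filters of *all* stimuli (not only the candidates), scoring
#' only the candidates.
#'
#' @inheritParams stage1
#' @return a `decision`.
#' @export
ehtrcca_classify <- function(X_test, bank, refs, h_range = 2:8, seed = 1L) {
  stack <- apply_filter_bank(X_test, bank$specs)
  s1 <- stage1_banded(stack, bank, refs, h_range, seed)
  W <- lapply(seq_len(bank$Nb), function(b)
    concatenate_filters(bank, seq_len(bank$Nf) - 1L, b))
  stage2_banded(stack, s1$candidates, s1$features, bank, W = W)
}

#' Calibration-free CCA recognition
#'
#' Scores each stimulus by the sub-band-fused maximal canonical correlation
#' between the banded epoch and the stimulus reference; returns the argmax.
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param refs a `reference_bank`.
#' @param specs sub-band specs from [design_subbands()].
#' @return predicted 0-based stimulus index.
#' @export
cca_classify <- function(X_test, refs, specs) {
  stack <- apply_filter_bank(X_test, specs)
  nb <- length(specs)
  scores <- vapply(seq_along(refs$Y), function(n1) {
    per_band <- vapply(seq_len(nb), function(b) {
      Xb <- stack$data[b, , , drop = TRUE]
      if (nrow(X_test) == 1L) Xb <- matrix(Xb, nrow = 1L)
      max_canonical_correlation(Xb, refs$Y[[n1]])
    }, numeric(1L))
    combine_subbands(per_band)
  }, numeric(1L))
  which.max(scores) - 1L
}

#' TRCA recognition
#'
#' Scores each stimulus by the sub-band-fused Pearson correlation between
#' the `wt`-projected test epoch and `wt`-projected template; argmax, ties
#' to the lowest index.
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param bank a `model_bank`.
#' @return predicted 0-based stimulus index.
#' @export
trca_classify <- function(X_test, bank) {
  stack <- apply_filter_bank(X_test, bank$specs)
  scores <- vapply(seq_len(bank$Nf), function(n1) {
    per_band <- vapply(seq_len(bank$Nb), function(b) {
      m <- bank$models[[n1]][[b]]
      Xb <- stack$data[b, , , drop = TRUE]
      if (bank$Nc == 1L) Xb <- matrix(Xb, nrow = 1L)
      pearson(crossprod(Xb, m$wt), crossprod(m$template, m$wt))
    }, numeric(1L))
    combine_subbands(per_band)
  }, numeric(1L))
  which.max(scores) - 1L
}

#' Ensemble-filter correlation score for one stimulus
#'
#' Projects the banded test epoch and the stimulus template through the
#' ensemble spatial filter `W = [wt_1 ... wt_Nf]` (all stimuli) and fuses
#' the per-band matrix correlations.
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param n 0-based stimulus index to score.
#' @param bank a `model_bank`.
#' @return fused ensemble score `S_n`.
#' @export
ensemble_correlation <- function(X_test, n, bank) {
  stack <- apply_filter_bank(X_test, bank$specs)
  W <- lapply(seq_len(bank$Nb), function(b)
    concatenate_filters(bank, seq_len(bank$Nf) - 1L, b))
  ensemble_correlation_banded(stack, n, bank, W)
}

ensemble_correlation_banded <- function(stack, n, bank, W) {
  per_band <- vapply(seq_len(bank$Nb), function(b) {
    Xb <- stack$data[b, , , drop = TRUE]
    if (bank$Nc == 1L) Xb <- matrix(Xb, nrow = 1L)
    tmpl <- bank$models[[n + 1L]][[b]]$template
    matrix_correlation(crossprod(Xb, W[[b]]), crossprod(tmpl, W[[b]]))
  }, numeric(1L))
  combine_subbands(per_band)
}

#' Ensemble TRCA recognition
#'
#' @param X_test numeric matrix `[Nc x Ns]`.
#' @param bank a `model_bank`.
#' @return predicted 0-based stimulus index.
#' @export
etrca_classify <- function(X_test, bank) {
  stack <- apply_filter_bank(X_test, bank$specs)
  W <- lapply(seq_len(bank$Nb), function(b)
    concatenate_filters(bank, seq_len(bank$Nf) - 1L, b))
  scores <- vapply(seq_len(bank$Nf) - 1L, function(n)
    ensemble_correlation_banded(stack, n, bank, W), numeric(1L))
  which.max(scores) - 1L
}

#' Classify every trial of an epoch set
#'
#' Applies one recognizer to each trial. `method` is one of `"cca"`,
#' `"trca"`, `"etrca"`, `"htrcca"`, `"ehtrcca"`.
#'
#' @param test an `epoch_set` of test trials.
#' @param bank a `model_bank` (ignored by `"cca"`).
#' @param refs a `reference_bank`.
#' @param method recognizer name.
#' @param h_range,seed clustering configuration for the hybrid recognizers.
#' @return integer vector of predicted 0-based stimulus indices.
#' @export
classify_epochs <- function(test, bank, refs, method = "htrcca",
                            h_range = 2:8, seed = 1L) {
  stopifnot(inherits(test, "epoch_set"))
  method <- match.arg(method, c("cca", "trca", "etrca", "htrcca", "ehtrcca"))
  d <- epoch_dims(test)
  vapply(seq_len(d["n_trials"]), function(i) {
    X <- test$data[i, , , drop = TRUE]
    if (d["Nc"] == 1L) X <- matrix(X, nrow = 1L)
    switch(method,
      cca = cca_classify(X, refs, bank$specs),
      trca = trca_classify(X, bank),
      etrca = etrca_classify(X, bank),
      htrcca = classify(X, bank, refs, h_range, seed)$ft,
      ehtrcca = ehtrcca_classify(X, bank, refs, h_range, seed)$ft)
  }, integer(1L))
}
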