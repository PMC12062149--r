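#' Classification accuracy
#'
#' @param predictions,truths equal-length vectors of stimulus indices.
#' @return fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("length mismatch in accuracy()")
  if (length(predictions) == 0L) stop("empty prediction vector")
  mean(predictions == truths)
}

#' Information transfer rate
#'
#' `ITR = [log2 Nf + P log2 P + (1-P) log2((1-P)/(Nf-1))] * 60 / (Tw + g)`
#' in bits/min, where `P` is accuracy, `Nf` the alphabet size, `Tw` the
#' selection (epoch) time in seconds and `g` an optional gaze-shift interval.
#' `P = 0` and `P = 1` are handled by continuity (`0 * log 0 := 0`); a
#' below-chance bracket is clipped to 0.
#'
#' @param P accuracy in `[0, 1]`.
#' @param Nf number of stimuli (>= 2).
#' @param Tw_s selection time per epoch, seconds.
#' @param gaze_shift_s additional gaze-shift time, seconds (default 0).
#' @return bits per minute.
#' @export
itr <- function(P, Nf, Tw_s, gaze_shift_s = 0) {
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (Nf < 2L) stop("Nf must be >= 2")
  if (Tw_s <= 0) stop("Tw_s must be positive")
  xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(Nf) + xlogx(P) + xlogx(1 - P) - (1 - P) * log2(Nf - 1)
  bits <- max(bits, 0)
  bits * 60 / (Tw_s + gaze_shift_s)
}

# Split an epoch set into (train, test) for one held-out block, optionally
# keeping only the first Nt training blocks.
lobo_split <- function(x, test_block, Nt = NULL) {
  train_blocks <- sort(setdiff(unique(x$blocks), test_block))
  if (!is.null(Nt)) {
    if (Nt > length(train_blocks))
      stop(sprintf("Nt = %d exceeds the %d available training blocks",
                   Nt, length(train_blocks)))
    train_blocks <- train_blocks[seq_len(Nt)]
  }
  list(train = epoch_subset(x, which(x$blocks %in% train_blocks)),
       test = epoch_subset(x, which(x$blocks == test_block)))
}

#' Leave-one-block-out cross-validated recognition
#'
#' Each of the `B` recording blocks serves once as the test set while the
#' remaining `B - 1` blocks train a fresh model bank. An optional `Nt`
#' restricts training to the first `Nt` training blocks of each fold
#' (deterministic), emulating reduced calibration data.
#'
#' @param x an `epoch_set` covering `B >= 2` blocks.
#' @param method recognizer name (see [classify_epochs()]).
#' @param Nh harmonics in the reference signals.
#' @param Nb number of sub-bands.
#' @param Nt optional number of training blocks per fold.
#' @param h_range,seed clustering configuration.
#' @param gaze_shift_s gaze-shift time added to `Tw` in the ITR.
#' @return `eval_result`: per-fold predictions/truths, per-fold and mean
#'   accuracy and ITR, and the sweep coordinates.
#' @export
leave_one_block_out <- function(x, method = "htrcca", Nh = 5L, Nb = 5L,
                                Nt = NULL, h_range = 2:8, seed = 1L,
                                gaze_shift_s = 0) {
  stopifnot(inherits(x, "epoch_set"))
  blocks <- sort(unique(x$blocks))
  B <- length(blocks)
  if (B < 2L) stop("leave-one-block-out needs at least 2 blocks")
  d <- epoch_dims(x)
  Tw <- d["Ns"] / x$fs
  specs <- design_subbands(x$fs, Nb)
  refs <- make_reference_bank(x$freqs, x$fs, d["Ns"], Nh)
  folds <- lapply(blocks, function(bl) {
    sp <- lobo_split(x, bl, Nt)
    bank <- fit_model_bank(sp$train, refs, specs)
    preds <- classify_epochs(sp$test, bank, refs, method, h_range, seed)
    list(block = bl, predictions = preds, truths = sp$test$labels,
         n_train_blocks = length(unique(sp$train$blocks)))
  })
  per_fold_acc <- vapply(folds, function(f) accuracy(f$predictions, f$truths),
                         numeric(1L))
  nf <- length(x$freqs)
  per_fold_itr <- vapply(per_fold_acc, itr, numeric(1L),
                         Nf = nf, Tw_s = Tw, gaze_shift_s = gaze_shift_s)
  structure(list(folds = folds, accuracy = per_fold_acc,
                 mean_accuracy = mean(per_fold_acc),
                 itr = per_fold_itr, mean_itr = mean(per_fold_itr),
                 method = method, B = B, Nf = nf, Nt = Nt, Tw = unname(Tw),
                 Nc = unname(d["Nc"]), Nb = Nb, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s | %d folds | mean accuracy %.1f%% | mean ITR %.2f bits/min\n",
              x$method, x$B, 100 * x$mean_accuracy, x$mean_itr))
  invisible(x)
}

#' Factorial evaluation sweep
#'
#' Evaluates every combination of method, training-block count `Nt`, window
#' length `Tw` (realized by re-windowing the stored epochs), channel-prefix
#' count `Nc` and sub-band count `Nb` with leave-one-block-out
#' cross-validation. Infeasible cells (e.g. `Nt > B - 1`) are skipped and
#' flagged in the returned table.
#'
#' @param x an `epoch_set`.
#' @param methods recognizer names.
#' @param Nt_grid training-block counts (`NA` = all available).
#' @param Tw_grid window lengths in seconds.
#' @param Nc_grid channel-prefix counts.
#' @param Nb_grid sub-band counts.
#' @param Nh,h_range,seed,gaze_shift_s as in [leave_one_block_out()].
#' @return data.frame, one row per (cell, fold), with columns method, Nt, Tw,
#'   Nc, Nb, seed, fold, accuracy, itr, feasible.
#' @export
sweep_eval <- function(x, methods = "htrcca", Nt_grid = NA, Tw_grid = NULL,
                       Nc_grid = NULL, Nb_grid = 5L, Nh = 5L, h_range = 2:8,
                       seed = 1L, gaze_shift_s = 0) {
  d <- epoch_dims(x)
  if (is.null(Tw_grid)) Tw_grid <- d["Ns"] / x$fs
  if (is.null(Nc_grid)) Nc_grid <- d["Nc"]
  grid <- expand.grid(method = methods, Nt = Nt_grid, Tw = Tw_grid,
                      Nc = Nc_grid, Nb = Nb_grid,
                      stringsAsFactors = FALSE)
  B <- length(unique(x$blocks))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    nt <- if (is.na(cell$Nt)) NULL else cell$Nt
    if (!is.null(nt) && nt > B - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = cell$method, Nt = cell$Nt, Tw = cell$Tw, Nc = cell$Nc,
        Nb = cell$Nb, seed = seed, fold = NA_integer_,
        accuracy = NA_real_, itr = NA_real_, feasible = FALSE)
      next
    }
    xs <- rewindow_epochs(channel_prefix(x, cell$Nc), cell$Tw)
    res <- leave_one_block_out(xs, method = cell$method, Nh = Nh,
                               Nb = cell$Nb, Nt = nt, h_range = h_range,
                               seed = seed, gaze_shift_s = gaze_shift_s)
    rows[[length(rows) + 1L]] <- data.frame(
      method = cell$method, Nt = cell$Nt, Tw = cell$Tw, Nc = cell$Nc,
      Nb = cell$Nb, seed = seed, fold = seq_len(res$B),
      accuracy = res$accuracy, itr = res$itr, feasible = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
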