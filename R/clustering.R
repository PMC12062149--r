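# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Davies-Bouldin cluster-validity index
#'
#' `DB = (1/h) * sum_i max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the mean
#' Euclidean distance of cluster `i`'s points to their centroid and `M_ij`
#' the distance between centroids `i` and `j`. Lower is better. Coincident
#' centroids contribute `+Inf` (with a warning).
#'
#' @param points numeric matrix `[N x d]`.
#' @param labels cluster assignment per row (any label type; >= 2 clusters).
#' @return scalar index.
#' @export
davies_bouldin <- function(points, labels) {
  if (!is.matrix(points)) points <- as.matrix(points)
  labs <- unique(labels)
  h <- length(labs)
  if (h < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  cent <- do.call(rbind, lapply(labs, function(l)
    colMeans(points[labels == l, , drop = FALSE])))
  S <- vapply(seq_len(h), function(i) {
    P <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((P - rep(cent[i, ], each = nrow(P)))^2)))
  }, numeric(1L))
  R <- numeric(h)
  for (i in seq_len(h)) {
    ratios <- vapply(setdiff(seq_len(h), i), function(j) {
      M <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (M == 0) {
        warning("coincident cluster centroids: infinite Davies-Bouldin contribution")
        return(Inf)
      }
      (S[i] + S[j]) / M
    }, numeric(1L))
    R[i] <- max(ratios)
  }
  mean(R)
}

#' Select the number of clusters via GMM + Davies-Bouldin
#'
#' For each candidate `h`, fits a full-covariance Gaussian mixture to the
#' feature rows, hard-assigns points to components, and scores the partition
#' with the Davies-Bouldin index; returns the `h` with the lowest index
#' (smallest `h` on ties). An `h` whose fit fails or collapses below two
#' non-empty clusters is skipped with a warning; if every `h` fails the
#' fallback is `h = 2`.
#'
#' @param points numeric matrix `[N x d]` of feature rows.
#' @param h_range integer candidates for the cluster count (default 2..8).
#' @param seed RNG seed for the fit.
#' @return selected cluster count `h`.
#' @export
select_cluster_count <- function(points, h_range = 2:8, seed = 1L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  h_range <- sort(unique(as.integer(h_range)))
  if (any(h_range < 2L)) stop("h_range must contain values >= 2")
  h_range <- h_range[h_range <= nrow(points)]
  # Mclust() resolves mclustBIC in the calling frame; bind it locally so the
  # fit works without mclust attached to the search path
  mclustBIC <- mclust::mclustBIC
  scores <- rep(NA_real_, length(h_range))
  for (k in seq_along(h_range)) {
    h <- h_range[k]
    cl <- local_seed(seed, tryCatch(
      suppressWarnings({
        fit <- mclust::Mclust(points, G = h, modelNames = "VVV", verbose = FALSE)
        if (is.null(fit)) NULL else fit$classification
      }),
      error = function(e) NULL))
    if (is.null(cl) || length(unique(cl)) < 2L || anyNA(cl)) {
      warning(sprintf("GMM fit failed or collapsed at h = %d; skipped", h))
      next
    }
    scores[k] <- suppressWarnings(davies_bouldin(points, cl))
  }
  if (all(is.na(scores))) {
    warning("no cluster count could be fit; falling back to h = 2")
    return(2L)
  }
  h_range[which.min(scores)]   # which.min takes the first (smallest h) on ties
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(points, h) {
  n <- nrow(points)
  centers <- integer(h)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((points - rep(points[centers[1L], ], each = n))^2)
  for (j in seq_len(h - 1L)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j + 1L] <- pick
    d2 <- pmin(d2, rowSums((points - rep(points[pick, ], each = n))^2))
  }
  points[centers, , drop = FALSE]
}

# Lloyd iterations with the documented empty-cluster rule: a centroid losing
# all its points is re-seeded at the point farthest from its nearest centroid.
lloyd_with_reseed <- function(points, centers, iter_max = 300L, tol = 1e-8) {
  n <- nrow(points); h <- nrow(centers)
  inertia_old <- Inf
  labels <- integer(n)
  for (it in seq_len(iter_max)) {
    d2 <- vapply(seq_len(h), function(j)
      rowSums((points - rep(centers[j, ], each = n))^2), numeric(n))
    if (n == 1L) d2 <- matrix(d2, nrow = 1L)
    labels <- max.col(-d2, ties.method = "first")
    nearest <- d2[cbind(seq_len(n), labels)]
    for (j in seq_len(h)) {
      if (!any(labels == j)) {
        warning("empty cluster during Lloyd update; centroid re-seeded at farthest point")
        far <- which.max(nearest)
        labels[far] <- j
        nearest[far] <- 0
      }
    }
    for (j in seq_len(h))
      centers[j, ] <- colMeans(points[labels == j, , drop = FALSE])
    inertia <- sum(vapply(seq_len(h), function(j) {
      P <- points[labels == j, , drop = FALSE]
      sum((P - rep(centers[j, ], each = nrow(P)))^2)
    }, numeric(1L)))
    if (abs(inertia_old - inertia) <= tol) break
    inertia_old <- inertia
  }
  labels
}

#' Cluster feature rows with k-means++
#'
#' k-means++ seeding followed by Lloyd iterations (convergence tolerance
#' `1e-8` on inertia, at most 300 iterations); deterministic given `seed`.
#' Lloyd runs through [stats::kmeans()]; the degenerate empty-cluster case
#' falls back to an in-package Lloyd loop that re-seeds the empty centroid
#' at the farthest point.
#'
#' @param points numeric matrix `[N x d]`.
#' @param h number of clusters (`h <= N`).
#' @param seed RNG seed for the seeding step.
#' @return integer cluster labels (1-based) per row.
#' @export
cluster_features <- function(points, h, seed = 1L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (h > nrow(points)) stop("h must not exceed the number of points")
  if (h == nrow(points)) return(seq_len(nrow(points)))
  local_seed(seed, {
    init <- kmeanspp_init(points, h)
    fit <- tryCatch(
      stats::kmeans(points, centers = init, iter.max = 300L, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) lloyd_with_reseed(points, init) else as.integer(fit$cluster)
  })
}

#' Pick the candidate stimuli from a clustering of feature rows
#'
#' Scores each cluster by the mean of all feature entries of its member rows
#' and returns the stimuli of the highest-mean cluster. Ties break to the
#' smaller cluster, then to the lower cluster label, so selection is
#' deterministic.
#'
#' @param points numeric matrix `[Nf x d]`, row `n+1` = stimulus `n` features.
#' @param labels cluster labels from [cluster_features()].
#' @return `candidate_set`: list with `indices` (0-based stimulus indices,
#'   sorted), `h_selected`, and per-cluster `cluster_means`.
#' @export
pick_candidates <- function(points, labels) {
  if (!is.matrix(points)) points <- as.matrix(points)
  labs <- sort(unique(labels))
  means <- vapply(labs, function(l) mean(points[labels == l, , drop = FALSE]),
                  numeric(1L))
  sizes <- vapply(labs, function(l) sum(labels == l), numeric(1L))
  ord <- order(-means, sizes, labs)
  win <- labs[ord[1L]]
  structure(list(indices = sort(which(labels == win) - 1L),
                 h_selected = length(labs),
                 cluster_means = stats::setNames(means, labs)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d of %d clusters won | %d candidates: %s\n",
              1L, x$h_selected, length(x$indices),
              paste(x$indices, collapse = " ")))
  invisible(x)
}
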