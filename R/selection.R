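#' @title Three-filter consensus feature selection
#'
#' @description Features are ranked independently by mRMR (greedy mutual
#' information difference), the chi-squared statistic, and ReliefF.  The
#' top 2/3 of each ranking are intersected to give the final feature
#' set.
#'
#' @name feature_selection
NULL

discretize_ew <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1L)
}

mi_disc <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log(p[idx] / (pa[idx[, 1]] * pb[idx[, 2]])))
}

new_ranked <- function(method, order, scores) {
  structure(list(method = method, order = order, scores = scores),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> method=%s, p=%d; top: %s\n", x$method,
              length(x$order), paste(head(x$order, 5), collapse = ", ")))
  invisible(x)
}

#' mRMR feature ranking (greedy MID criterion)
#'
#' First picks the feature with maximal mutual information with the
#' label; each later pick maximises `I(f; y) - mean_{s in S} I(f; s)`.
#' Mutual information is estimated on an equal-width discretization with
#' `bins` bins.  Ties are broken by original column order.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y class labels (factor or vector).
#' @param bins discretization bins (default 10).
#' @return object of class `ranked_features` (`order` best-first,
#'   `scores` = criterion value at selection time).
#' @export
mrmr_rank <- function(X, y, bins = 10) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("constant label vector", call. = FALSE)
  if (ncol(X) < 1) stop("no features", call. = FALSE)
  p <- ncol(X)
  D <- apply(X, 2, discretize_ew, bins = bins)
  rel <- vapply(seq_len(p), function(j) mi_disc(D[, j], y), numeric(1))
  selected <- integer(0)
  scores <- numeric(p)
  redsum <- rep(0, p)
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    crit <- if (step == 1) rel[remaining] else
      rel[remaining] - redsum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]
    scores[pick] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redsum[remaining] <- redsum[remaining] +
        vapply(remaining, function(j) mi_disc(D[, j], D[, pick]), numeric(1))
  }
  new_ranked("mrmr", colnames(X)[selected], setNames(scores, colnames(X)))
}

#' Chi-squared feature ranking
#'
#' Per-feature chi-squared statistic of the binned-feature-by-class
#' contingency table (no continuity correction), ranked descending.
#' Features landing in a single bin score 0.
#'
#' @inheritParams mrmr_rank
#' @return object of class `ranked_features`.
#' @export
chi2_rank <- function(X, y, bins = 10) {
  X <- as.matrix(X)
  sc <- vapply(seq_len(ncol(X)), function(j) {
    d <- discretize_ew(X[, j], bins)
    if (length(unique(d)) < 2) return(0)
    tab <- table(d, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }, numeric(1))
  ord <- order(-sc)  # stable: ties keep original order
  new_ranked("chi2", colnames(X)[ord], setNames(sc, colnames(X)))
}

#' ReliefF feature ranking
#'
#' Standard ReliefF with every sample as an anchor: for each anchor, the
#' k nearest hits and, per other class, the k nearest misses (weighted by
#' class priors) update the feature weights; features are
#' range-normalised and distances are Manhattan.  Deterministic given
#' the sample order.
#'
#' @inheritParams mrmr_rank
#' @param k_neighbors nearest hits/misses per class (default 10; shrunk
#'   with a warning when a class is too small).
#' @return object of class `ranked_features`.
#' @export
relieff_rank <- function(X, y, k_neighbors = 10) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("single class", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) {
    r <- max(v) - min(v); if (r == 0) 1 else r
  })
  Z <- sweep(X, 2, rng, "/")
  min_class <- min(table(y))
  k <- k_neighbors
  if (min_class - 1 < k) {
    k <- max(1L, min_class - 1L)
    warning("k_neighbors shrunk to ", k, " (smallest class has ",
            min_class, " samples)")
  }
  prior <- table(y) / n
  W <- rep(0, p)
  by_class <- split(seq_len(n), y)
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(Z, 2, Z[i, ], "-")))
    ci <- as.character(y[i])
    hits <- setdiff(by_class[[ci]], i)
    hits <- hits[order(d[hits], hits)][seq_len(min(k, length(hits)))]
    if (length(hits))
      W <- W - colSums(abs(Z[hits, , drop = FALSE] -
                             rep(Z[i, ], each = length(hits)))) /
        (n * length(hits))
    for (cc in setdiff(levels(y), ci)) {
      miss <- by_class[[cc]]
      if (length(miss) == 0) next
      miss <- miss[order(d[miss], miss)][seq_len(min(k, length(miss)))]
      wcl <- prior[[cc]] / (1 - prior[[ci]])
      W <- W + wcl * colSums(abs(Z[miss, , drop = FALSE] -
                                   rep(Z[i, ], each = length(miss)))) /
        (n * length(miss))
    }
  }
  ord <- order(-W)
  new_ranked("relieff", colnames(X)[ord], setNames(W, colnames(X)))
}

#' Consensus selection across the three rankings
#'
#' Keeps the top `ceiling(fraction * p)` features of each ranking and
#' returns their intersection.
#'
#' @param rankings list of three `ranked_features` over the same feature
#'   universe.
#' @param fraction fraction of features kept per method (default 2/3).
#' @return object of class `consensus_result`: list with `selected`
#'   (ordered as in the first ranking), `per_method_top`, `fraction`.
#'   Errors on an empty intersection.
#' @export
consensus_select <- function(rankings, fraction = 2 / 3) {
  stopifnot(length(rankings) >= 2)
  universes <- lapply(rankings, function(r) sort(r$order))
  for (u in universes[-1])
    if (!identical(u, universes[[1]]))
      stop("rankings cover different feature universes", call. = FALSE)
  p <- length(rankings[[1]]$order)
  m <- ceiling(fraction * p)
  tops <- lapply(rankings, function(r) head(r$order, m))
  names(tops) <- vapply(rankings, function(r) r$method, character(1))
  sel <- Reduce(intersect, tops)
  if (length(sel) == 0) stop("empty consensus intersection", call. = FALSE)
  sel <- rankings[[1]]$order[rankings[[1]]$order %in% sel]
  structure(list(selected = sel, per_method_top = tops, fraction = fraction),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d features selected (fraction %.3f)\n",
              length(x$selected), x$fraction))
  invisible(x)
}

#' Run the full three-filter consensus on a feature matrix
#' @inheritParams mrmr_rank
#' @param fraction per-method fraction (default 2/3).
#' @param bins discretization bins for mRMR and chi-squared.
#' @param k_neighbors ReliefF neighbours.
#' @return a `consensus_result`.
#' @export
select_features <- function(X, y, fraction = 2 / 3, bins = 10,
                            k_neighbors = 10) {
  consensus_select(list(mrmr_rank(X, y, bins), chi2_rank(X, y, bins),
                        relieff_rank(X, y, k_neighbors)), fraction)
}
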