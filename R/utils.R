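# Internal numerical helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian blur with replicated edges.  Kernel half-width is
# ceiling(3*sigma), truncated so it never exceeds the image extent.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  r <- min(ceiling(3 * sigma), h - 1L, w - 1L)
  if (r < 1L) return(m)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(x) {
    # x: matrix, convolve along rows (dim 1) with kernel k
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

# k-means with k-means++ initialisation and farthest-point re-seeding of
# empty clusters; Lloyd iterations, deterministic given the RNG state.
# nstart > 1 repeats the whole procedure and keeps the solution with the
# lowest within-cluster sum of squares (guards against local optima when
# a small tight cluster competes with broad illumination variation).
# x: numeric matrix (rows = points).  Returns list(cluster, centers, iter).
kmeans_lloyd <- function(x, k, iters = 100L, nstart = 1L) {
  if (nstart > 1L) {
    best <- NULL
    for (s in seq_len(nstart)) {
      cand <- kmeans_lloyd(x, k, iters)
      if (is.null(best) || cand$wcss < best$wcss) best <- cand
    }
    return(best)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("more clusters than points", call. = FALSE)
  sqd_to <- function(center) colSums((t(x) - center)^2)
  # k-means++ seeding
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- sqd_to(centers[1L, ])
  if (k > 1L) for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, sqd_to(centers[j, ]))
  }
  assign_pts <- function(centers) {
    d <- matrix(0, n, k)
    for (j in seq_len(k)) d[, j] <- sqd_to(centers[j, ])
    max.col(-d, ties.method = "first")
  }
  cl <- assign_pts(centers)
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(k)) {
      idx <- which(cl == j)
      if (length(idx) == 0L) {
        # re-seed an empty cluster from the farthest point
        dmin <- rep(Inf, n)
        for (jj in seq_len(k)) if (jj != j) dmin <- pmin(dmin, sqd_to(centers[jj, ]))
        centers[j, ] <- x[which.max(dmin), ]
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    new_cl <- assign_pts(centers)
    if (identical(new_cl, cl) || it >= iters) { cl <- new_cl; break }
    cl <- new_cl
  }
  list(cluster = cl, centers = centers, iter = it,
       wcss = sum((x - centers[cl, , drop = FALSE])^2))
}

# Draw a quadratic Bezier stroke into a logical matrix (used for hair
# strokes in the scene generator).
bezier_stroke <- function(h, w, p0, p1, p2, n = 400L) {
  t <- seq(0, 1, length.out = n)
  y <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  x <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  yi <- clamp(round(y), 1, h); xi <- clamp(round(x), 1, w)
  m <- matrix(FALSE, h, w)
  m[cbind(yi, xi)] <- TRUE
  m
}
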