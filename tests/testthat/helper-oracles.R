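# Brute-force oracles for the similarity metrics, written against the
# definitions directly (set enumeration, per-pixel refinement error,
# entropy of partition label vectors, exhaustive pair scans).  They are
# deliberately independent of the package implementations.

bf_dice <- function(a, b) {
  A <- which(a); B <- which(b)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

bf_gce <- function(a, b) {
  n <- length(a)
  region <- function(m, i) if (m[i]) which(m) else which(!m)
  e_dir <- function(p, q) {
    sum(vapply(seq_len(n), function(i) {
      rp <- region(p, i); rq <- region(q, i)
      length(setdiff(rp, rq)) / length(rp)
    }, numeric(1)))
  }
  min(e_dir(a, b), e_dir(b, a)) / n
}

bf_voi <- function(a, b) {
  n <- length(a)
  ent <- function(lbl) {
    p <- table(lbl) / n
    -sum(p * log2(p))
  }
  joint <- paste(as.integer(a), as.integer(b))
  hj <- ent(joint)
  # VI = 2 H(A,B) - H(A) - H(B)
  2 * hj - ent(as.integer(a)) - ent(as.integer(b))
}

bf_hd <- function(a, b) {
  A <- which(a, arr.ind = TRUE); B <- which(b, arr.ind = TRUE)
  d <- function(P, Q) {
    max(apply(P, 1, function(p) {
      min(sqrt((Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2))
    }))
  }
  max(d(A, B), d(B, A))
}

bf_ri <- function(a, b) {
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / tot
}

random_mask <- function(h, w, p = 0.5) {
  matrix(runif(h * w) < p, h, w)
}

# Analytic disk fixture: dark disk on a light background, plus its mask.
disk_image <- function(size = 96, r = 30, fg = c(150, 60, 50),
                       bg = c(220, 190, 170)) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  mask <- d <= r
  img <- array(0, c(size, size, 3))
  for (k in 1:3) img[, , k] <- ifelse(mask, fg[k], bg[k])
  list(image = img, mask = mask)
}

circle_mask <- function(size, r, cy = (size + 1) / 2, cx = (size + 1) / 2) {
  d <- sqrt(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+"))
  d <= r
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Planted 2-class feature data: `n` samples, `p` features, the first
# `n_informative` features shifted by `delta` in class 2.
planted_features <- function(n = 150, p = 50, n_informative = 5,
                             delta = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("a", "b"), length.out = n))
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    X[y == "b", seq_len(n_informative)] <-
      X[y == "b", seq_len(n_informative)] + delta
    list(X = X, y = y)
  })
}

# Well-separated Gaussian classes for classifier tests.
separable_classes <- function(n_per_class = 20, n_classes = 2, p = 2,
                              sep = 8, seed = 1) {
  withr::with_seed(seed, {
    X <- NULL; y <- c()
    for (k in seq_len(n_classes)) {
      Xk <- matrix(rnorm(n_per_class * p), n_per_class, p) + (k - 1) * sep
      X <- rbind(X, Xk)
      y <- c(y, rep(letters[k], n_per_class))
    }
    colnames(X) <- paste0("x", seq_len(p))
    list(X = X, y = factor(y))
  })
}

# Independent oracle for the greedy MID criterion: at every step evaluate
# I(f;y) - mean_{s in S} I(f;s) for all remaining features with a from-
# scratch MI estimator and pick the argmax.
oracle_mrmr_order <- function(X, y, bins = 10) {
  disc <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) rep(1L, length(x)) else
      pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1L)
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    s
  }
  D <- apply(X, 2, disc)
  p <- ncol(X)
  sel <- integer(0); rest <- seq_len(p)
  while (length(rest)) {
    crit <- vapply(rest, function(j) {
      rel <- mi(D[, j], y)
      if (!length(sel)) rel else
        rel - mean(vapply(sel, function(s) mi(D[, j], D[, s]), numeric(1)))
    }, numeric(1))
    pick <- rest[which.max(crit)]
    sel <- c(sel, pick); rest <- setdiff(rest, pick)
  }
  colnames(X)[sel]
}

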