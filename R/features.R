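#' @title Texture, colour and spectrum features
#'
#' @description All features are computed over the lesion (or patch) mask
#' only.  The pools are fixed and ordered: texture = GLCM (5) + GLRLM (7)
#' + intensity histogram (6) + semi-variogram (5) + uniform LBP (10) = 33
#' features with prefix `tex.`; colour = mean/sd of the 12 channels of
#' RGB, HSV, CIE-L*a*b* and YCbCr + skewness of a* and L* + erythema
#' index (mean a* - mean b*) = 27 features with prefix `col.`; spectrum =
#' Gabor bank (4 orientations x 3 frequencies x mean/sd = 24) + Zernike
#' magnitudes to radial order 8 (25) = 49 features with prefix `spec.`.
#'
#' @name feature_engine
NULL

moment_skewness <- function(x) {
  s <- sd(x) * sqrt((length(x) - 1) / length(x))
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

moment_kurtosis <- function(x) {
  s <- sd(x) * sqrt((length(x) - 1) / length(x))
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

quantize_gray <- function(gray, mask, levels) {
  v <- gray[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (hi == lo) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(levels, floor((gray[mask] - lo) / (hi - lo) * levels) + 1L)
  }
  q
}

glcm_offsets <- function(d) {
  list(deg0 = c(0L, d), deg45 = c(-d, d), deg90 = c(-d, 0L), deg135 = c(-d, -d))
}

#' Symmetric grey-level co-occurrence counts for one offset
#'
#' @param gray numeric intensity matrix.
#' @param mask logical matrix; only pixel pairs fully inside the mask are
#'   counted.
#' @param levels quantization levels (equal-width over the masked range).
#' @param offset integer `c(dr, dc)` displacement.
#' @return `levels x levels` matrix of unnormalised symmetric counts.
#' @export
glcm_counts <- function(gray, mask, levels = 32, offset = c(0L, 1L)) {
  q <- quantize_gray(gray, mask, levels)
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1L, 1L - dr):min(h, h - dr)
  c0 <- max(1L, 1L - dc):min(w, w - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  m <- matrix(0, levels, levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    m <- matrix(as.numeric(tab), levels, levels)
  }
  m + t(m)
}

glcm_stats <- function(p) {
  # p: normalised symmetric co-occurrence matrix
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (s_i * s_j > 0) sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else 0
  pe <- p[p > 0]
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    entropy = -sum(pe * log2(pe)))
}

#' GLCM texture statistics (angle-averaged)
#'
#' Contrast, correlation, energy, homogeneity and entropy of the
#' normalised symmetric co-occurrence matrix, averaged over the four
#' directions (0, 45, 90, 135 degrees) at each distance.
#'
#' @inheritParams glcm_counts
#' @param distances integer pixel displacements (default 1).
#' @return named numeric vector (`tex.glcm_*`).
#' @export
glcm_features <- function(gray, mask, levels = 32, distances = 1L) {
  if (sum(mask) < 2) stop("need at least two masked pixels", call. = FALSE)
  acc <- NULL
  n <- 0L
  for (d in distances) for (off in glcm_offsets(as.integer(d))) {
    cnt <- glcm_counts(gray, mask, levels, off)
    tot <- sum(cnt)
    if (tot == 0) next
    st <- glcm_stats(cnt / tot)
    acc <- if (is.null(acc)) st else acc + st
    n <- n + 1L
  }
  if (n == 0L) stop("mask admits no pixel pairs", call. = FALSE)
  out <- acc / n
  names(out) <- paste0("tex.glcm_", names(out))
  out
}

# maximal runs of equal values along one direction, mask-aware
mask_runs <- function(q, offset) {
  h <- nrow(q); w <- ncol(q)
  lines <- switch(paste(offset, collapse = ","),
    "0,1" = split(as.vector(t(q)), rep(seq_len(h), each = w)),
    "1,0" = split(as.vector(q), rep(seq_len(w), each = h)),
    "1,1" = split(as.vector(q), (col(q) - row(q))[seq_along(q)]),
    "-1,1" = split(as.vector(q), (col(q) + row(q))[seq_along(q)]),
    stop("bad offset"))
  vals <- integer(0); lens <- integer(0)
  for (v in lines) {
    seg_id <- cumsum(is.na(v))
    for (seg in split(v, seg_id)) {
      seg <- seg[!is.na(seg)]
      if (length(seg) == 0) next
      r <- rle(seg)
      vals <- c(vals, r$values); lens <- c(lens, r$lengths)
    }
  }
  list(values = vals, lengths = lens)
}

#' GLRLM texture statistics (direction-averaged)
#'
#' Run-length statistics over four directions: short/long-run emphasis
#' (SRE, LRE), grey-level and run-length non-uniformity (GLN, RLN), run
#' percentage (RP) and low/high grey-level run emphasis (LGRE, HGRE).
#'
#' @inheritParams glcm_counts
#' @return named numeric vector (`tex.glrlm_*`).
#' @export
glrlm_features <- function(gray, mask, levels = 32) {
  if (sum(mask) < 1) stop("empty mask", call. = FALSE)
  q <- quantize_gray(gray, mask, levels)
  npix <- sum(mask)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  acc <- NULL
  for (off in dirs) {
    rr <- mask_runs(q, off)
    g <- rr$values; r <- rr$lengths
    nr <- length(r)
    st <- c(sre = sum(1 / r^2) / nr,
            lre = sum(r^2) / nr,
            gln = sum(tapply(rep(1, nr), g, sum)^2) / nr,
            rln = sum(tapply(rep(1, nr), r, sum)^2) / nr,
            rp = nr / npix,
            lgre = sum(1 / g^2) / nr,
            hgre = sum(g^2) / nr)
    acc <- if (is.null(acc)) st else acc + st
  }
  out <- acc / length(dirs)
  names(out) <- paste0("tex.glrlm_", names(out))
  out
}

#' Intensity histogram statistics
#'
#' Mean, variance, skewness, kurtosis of the masked intensities plus
#' energy and entropy (bits) of their `bins`-bin histogram over
#' `[0, 255]`.
#'
#' @inheritParams glcm_counts
#' @param bins histogram bins (default 64).
#' @return named numeric vector (`tex.hist_*`).
#' @export
intensity_histogram_features <- function(gray, mask, bins = 64) {
  v <- gray[mask]
  if (length(v) == 0) stop("empty mask", call. = FALSE)
  b <- pmin(bins, floor(v / 256 * bins) + 1L)
  p <- tabulate(b, nbins = bins) / length(v)
  pe <- p[p > 0]
  c(tex.hist_mean = mean(v),
    tex.hist_var = mean((v - mean(v))^2),
    tex.hist_skewness = moment_skewness(v),
    tex.hist_kurtosis = moment_kurtosis(v),
    tex.hist_energy = sum(p^2),
    tex.hist_entropy = -sum(pe * log2(pe)))
}

#' Semi-variogram features
#'
#' `gamma(h) = sum (z(x) - z(x+h))^2 / (2 N(h))` over masked horizontal
#' and vertical pairs at each lag, plus the slope of `gamma` over
#' `log(h)`.
#'
#' @inheritParams glcm_counts
#' @param lags integer lags (default 1, 2, 4, 8).
#' @return named numeric vector (`tex.svar_*`).
#' @export
semivariogram_features <- function(gray, mask, lags = c(1, 2, 4, 8)) {
  if (sum(mask) < 2) stop("need at least two masked pixels", call. = FALSE)
  z <- gray
  z[!mask] <- NA
  gam <- vapply(lags, function(h) {
    diffs <- c()
    for (off in list(c(0L, h), c(h, 0L))) {
      a <- shift_crop(z, off)
      diffs <- c(diffs, (a$x - a$y)^2)
    }
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) == 0) return(NA_real_)
    sum(diffs) / (2 * length(diffs))
  }, numeric(1))
  if (anyNA(gam)) stop("some lags admit no masked pairs", call. = FALSE)
  slope <- unname(coef(lm(gam ~ log(lags)))[2])
  if (is.na(slope)) slope <- 0
  out <- c(gam, slope)
  names(out) <- c(paste0("tex.svar_lag", lags), "tex.svar_slope")
  out
}

shift_crop <- function(z, offset) {
  h <- nrow(z); w <- ncol(z)
  dr <- offset[1]; dc <- offset[2]
  if (h - dr < 1 || w - dc < 1)
    return(list(x = numeric(0), y = numeric(0)))
  r0 <- 1:(h - dr); c0 <- 1:(w - dc)
  list(x = z[r0, c0, drop = FALSE],
       y = z[r0 + dr, c0 + dc, drop = FALSE])
}

#' Uniform LBP histogram (P = 8, R = 1)
#'
#' The 8-neighbour sign pattern (`neighbour >= centre`) is mapped to the
#' uniform coding: patterns with at most two circular transitions are
#' binned by their number of set bits (0..8), all others share a
#' non-uniform bin; the normalised 10-bin histogram is returned.  Only
#' pixels whose full neighbourhood lies inside the mask contribute.
#'
#' @inheritParams glcm_counts
#' @return named numeric vector (`tex.lbp_*`), summing to 1.
#' @export
lbp_features <- function(gray, mask) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3 || w < 3) stop("image too small for LBP", call. = FALSE)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- gray[ri, ci, drop = FALSE]
  valid <- mask[ri, ci, drop = FALSE]
  bits <- vector("list", 8)
  for (p in seq_along(offs)) {
    o <- offs[[p]]
    nb <- gray[ri + o[1], ci + o[2], drop = FALSE]
    valid <- valid & mask[ri + o[1], ci + o[2], drop = FALSE]
    bits[[p]] <- nb >= ctr
  }
  if (!any(valid)) stop("mask admits no full LBP neighbourhoods", call. = FALSE)
  bmat <- vapply(bits, function(b) as.integer(b[valid]), integer(sum(valid)))
  bmat <- matrix(bmat, ncol = 8)
  ones <- rowSums(bmat)
  trans <- rowSums(bmat != bmat[, c(2:8, 1), drop = FALSE])
  bin <- ifelse(trans <= 2, ones + 1L, 10L)
  p <- tabulate(bin, nbins = 10) / length(bin)
  names(p) <- c(paste0("tex.lbp_u", 0:8), "tex.lbp_nonuniform")
  p
}

#' Texture feature group (33 features)
#' @inheritParams glcm_counts
#' @return named numeric vector of the full texture pool.
#' @export
texture_features <- function(gray, mask, levels = 32) {
  c(glcm_features(gray, mask, levels),
    glrlm_features(gray, mask, levels),
    intensity_histogram_features(gray, mask),
    semivariogram_features(gray, mask),
    lbp_features(gray, mask))
}

#' Colour feature group (27 features)
#'
#' Mean and standard deviation of each of the 12 channels of RGB, HSV,
#' CIE-L*a*b* and YCbCr over the mask, plus skewness of a* and L* and the
#' erythema index (mean a* - mean b*).
#'
#' @param img RGB array.
#' @param mask logical matrix.
#' @return named numeric vector (`col.*`).
#' @export
color_features <- function(img, mask) {
  assert_rgb_image(img); assert_mask(mask); assert_same_shape(img, mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  spaces <- list(rgb = img, hsv = rgb_to_hsv_img(img), lab = rgb_to_lab(img),
                 ycbcr = rgb_to_ycbcr(img))
  chans <- list(rgb = c("r", "g", "b"), hsv = c("h", "s", "v"),
                lab = c("l", "a", "b"), ycbcr = c("y", "cb", "cr"))
  out <- c()
  for (sp in names(spaces)) {
    for (k in 1:3) {
      v <- spaces[[sp]][, , k][mask]
      nm <- paste0("col.", sp, "_", chans[[sp]][k])
      out[paste0(nm, "_mean")] <- mean(v)
      out[paste0(nm, "_sd")] <- sd(v) * sqrt((length(v) - 1) / max(1, length(v)))
      if (length(v) == 1) out[paste0(nm, "_sd")] <- 0
    }
  }
  lab <- spaces$lab
  out["col.lab_a_skew"] <- moment_skewness(lab[, , 2][mask])
  out["col.lab_l_skew"] <- moment_skewness(lab[, , 1][mask])
  out["col.erythema_index"] <- mean(lab[, , 2][mask]) - mean(lab[, , 3][mask])
  out
}

gabor_kernel <- function(f, theta, gamma = 0.5) {
  sigma <- 0.56 / f
  half <- ceiling(2.5 * sigma)
  g <- expand.grid(y = -half:half, x = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + (gamma * yr)^2) / (2 * sigma^2))
  re <- matrix(env * cos(2 * pi * f * xr), 2 * half + 1)
  im <- matrix(env * sin(2 * pi * f * xr), 2 * half + 1)
  re <- re - mean(re)  # DC-free
  list(re = re, im = im)
}

conv2_replicate <- function(m, k) {
  kh <- (nrow(k) - 1L) %/% 2L; kw <- (ncol(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- m[clamp(seq_len(h + 2 * kh) - kh, 1L, h),
          clamp(seq_len(w + 2 * kw) - kw, 1L, w), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] == 0) next
    out <- out + k[i, j] * mp[i:(i + h - 1L), j:(j + w - 1L), drop = FALSE]
  }
  out
}

#' Gabor filter-bank features (24 features)
#'
#' Mean and standard deviation of the complex magnitude response per
#' orientation/frequency pair, over the mask.  Kernels are zero-mean;
#' pixels outside the mask are replaced by the masked mean intensity
#' before filtering to suppress boundary leakage.
#'
#' @inheritParams glcm_counts
#' @param orientations orientation angles in degrees.
#' @param frequencies spatial frequencies in cycles/pixel.
#' @return named numeric vector (`spec.gabor_*`).
#' @export
gabor_features <- function(gray, mask, orientations = c(0, 45, 90, 135),
                           frequencies = c(0.1, 0.2, 0.4)) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  gi <- gray / 255
  gi[!mask] <- mean(gi[mask])
  out <- c()
  for (f in frequencies) for (th in orientations) {
    k <- gabor_kernel(f, th * pi / 180)
    if (nrow(k$re) > nrow(gi) || ncol(k$re) > ncol(gi)) {
      # truncate oversized kernels on tiny inputs
      cut <- function(m) {
        hh <- min((nrow(m) - 1) %/% 2, (nrow(gi) - 1) %/% 2)
        ww <- min((ncol(m) - 1) %/% 2, (ncol(gi) - 1) %/% 2)
        c0 <- (nrow(m) + 1) %/% 2
        m[(c0 - hh):(c0 + hh), (c0 - ww):(c0 + ww), drop = FALSE]
      }
      k$re <- cut(k$re) - mean(cut(k$re)); k$im <- cut(k$im)
    }
    mag <- sqrt(conv2_replicate(gi, k$re)^2 + conv2_replicate(gi, k$im)^2)
    v <- mag[mask]
    nm <- sprintf("spec.gabor_t%d_f%g", th, f)
    out[paste0(nm, "_mean")] <- mean(v)
    out[paste0(nm, "_sd")] <- if (length(v) > 1) sd(v) else 0
  }
  out
}

zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) %/% 2
  out <- 0
  for (s in 0:s_max) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

#' Zernike moment magnitudes (25 features, radial order <= 8)
#'
#' Moments are computed on the unit disk spanned by the mask: centre at
#' the mask centroid, radius the maximal centroid-to-pixel distance.
#' Intensities are normalised by their masked mean, making the
#' magnitudes invariant to global intensity scaling; magnitudes are
#' rotation-invariant by construction.
#'
#' @inheritParams glcm_counts
#' @param order maximum radial order (default 8).
#' @return named numeric vector (`spec.zernike_n_m`).
#' @export
zernike_features <- function(gray, mask, order = 8) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask", call. = FALSE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  rr <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  R <- max(rr, 1)
  rho <- rr / R
  theta <- atan2(idx[, 1] - cy, idx[, 2] - cx)
  f <- gray[mask]
  f <- f / ifelse(mean(f) != 0, mean(f), 1)
  out <- c()
  for (n in 0:order) for (m in seq(n %% 2, n, by = 2)) {
    Rnm <- zernike_radial(n, m, rho)
    z <- sum(f * Rnm * exp(-1i * m * theta)) * (n + 1) / pi / R^2
    out[sprintf("spec.zernike_%d_%d", n, m)] <- Mod(z)
  }
  out
}

#' Spectrum feature group (49 features)
#' @inheritParams glcm_counts
#' @return named numeric vector of the full spectrum pool.
#' @export
spectrum_features <- function(gray, mask) {
  c(gabor_features(gray, mask), zernike_features(gray, mask))
}

#' Extract a named feature vector for one masked image
#'
#' @param img RGB array.
#' @param mask logical lesion/patch mask.
#' @param groups subset of `c("texture", "color", "spectrum")`.
#' @return named numeric vector in fixed group order
#'   (texture, color, spectrum), with attribute `group_index` mapping
#'   each group to its feature names.  Errors if any feature is
#'   non-finite.
#' @export
extract_all <- function(img, mask, groups = c("texture", "color", "spectrum")) {
  groups <- match.arg(groups, several.ok = TRUE)
  assert_rgb_image(img); assert_mask(mask); assert_same_shape(img, mask)
  if (!any(mask)) stop("empty mask: no pixels to extract from", call. = FALSE)
  gray <- rgb_to_gray(img)
  out <- c()
  gidx <- list()
  ordered <- intersect(c("texture", "color", "spectrum"), groups)
  for (g in ordered) {
    v <- switch(g,
      texture = texture_features(gray, mask),
      color = color_features(img, mask),
      spectrum = spectrum_features(gray, mask))
    gidx[[g]] <- names(v)
    out <- c(out, v)
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    stop("non-finite features: ", paste(bad, collapse = ", "), call. = FALSE)
  attr(out, "group_index") <- gidx
  out
}

#' Extract a feature matrix for a dataset manifest
#'
#' @param manifest tibble with columns `filename`, `mask_filename`,
#'   `label`, `is_patch` (as produced by [assemble_dataset()] /
#'   [patch_manifest()]).
#' @param root directory containing the files.
#' @param groups feature groups, see [extract_all()].
#' @return tibble: `filename`, `label`, `is_patch`, then one column per
#'   feature, with attribute `group_index`.  Rows whose extraction fails
#'   are dropped with a warning; rows with an empty mask (healthy-skin
#'   crops) are described by whole-crop statistics instead.
#' @export
extract_matrix <- function(manifest, root,
                           groups = c("texture", "color", "spectrum")) {
  rows <- vector("list", nrow(manifest))
  gidx <- NULL
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    fv <- tryCatch({
      img <- read_image(file.path(root, r$filename))
      mask <- read_mask(file.path(root, r$mask_filename))
      # healthy crops carry an empty lesion mask: describe the whole crop
      if (!any(mask)) mask <- matrix(TRUE, nrow(mask), ncol(mask))
      extract_all(img, mask, groups)
    }, error = function(e) {
      warning("feature extraction failed for ", r$filename, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(fv)) next
    if (is.null(gidx)) gidx <- attr(fv, "group_index")
    rows[[i]] <- tibble::tibble(filename = r$filename, label = r$label,
                                is_patch = r$is_patch,
                                !!!setNames(as.list(unname(fv)), names(fv)))
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  attr(out, "group_index") <- gidx
  out
}

#' Split a feature-matrix tibble into X and y
#' @param fm tibble from [extract_matrix()].
#' @return list with numeric matrix `X` (rownames = filenames) and factor
#'   `y` over [severity_levels()].
#' @export
feature_xy <- function(fm) {
  meta <- intersect(c("filename", "label", "is_patch"), names(fm))
  X <- as.matrix(fm[, setdiff(names(fm), meta), drop = FALSE])
  rownames(X) <- fm$filename
  lv <- intersect(severity_levels(), unique(as.character(fm$label)))
  if (length(lv) == 0) lv <- unique(as.character(fm$label))
  list(X = X, y = factor(as.character(fm$label), levels = lv))
}
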