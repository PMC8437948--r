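#' Parameters for SLIC-superpixel lesion segmentation
#'
#' SLIC clusters pixels in the 5-D space (L*, a*, b*, x, y).  The map is
#' then reduced to `n_centers` colour clusters by k-means on per-superpixel
#' mean Lab vectors, and a lesion-selection rule turns clusters into a
#' binary mask.
#'
#' @param n_superpixels target number of superpixels (default 700).
#' @param compactness spatial-vs-colour weight of the SLIC distance
#'   (default 10).
#' @param n_centers number of colour clusters for the secondary k-means
#'   (default 3: lesion / normal skin / other).
#' @param kmeans_iters iteration cap for the secondary k-means
#'   (default 500).
#' @param slic_iters SLIC assignment/update sweeps (default 10).
#' @param min_area connected components smaller than this many pixels are
#'   dropped from the final mask (default 25).
#' @param close_radius disc radius (pixels) of the morphological closing
#'   applied before hole filling; recovers boundary speckle lost to the
#'   colour clustering (default 3; 0 disables).
#' @param min_a_contrast minimum excess of the selected cluster's mean a*
#'   over the image median a* (Lab units) for the cluster to count as
#'   lesion; guards healthy images (default 5).
#' @param rule lesion-cluster selection rule, see
#'   [select_lesion_clusters()].
#' @param seed integer seed for the secondary k-means.
#' @return object of class `slic_params`.
#' @export
slic_params <- function(n_superpixels = 700, compactness = 10, n_centers = 3,
                        kmeans_iters = 500, slic_iters = 10, min_area = 25,
                        close_radius = 3, min_a_contrast = 5, rule = "max_a",
                        seed = 1L) {
  stopifnot(n_superpixels >= n_centers, n_centers >= 2, kmeans_iters >= 1,
            slic_iters >= 1)
  structure(list(n_superpixels = as.integer(n_superpixels),
                 compactness = compactness, n_centers = as.integer(n_centers),
                 kmeans_iters = as.integer(kmeans_iters),
                 slic_iters = as.integer(slic_iters),
                 min_area = as.integer(min_area),
                 close_radius = as.integer(close_radius),
                 min_a_contrast = min_a_contrast, rule = rule,
                 seed = as.integer(seed)),
            class = "slic_params")
}

#' SLIC superpixel map
#'
#' Local k-means in (L*, a*, b*, x, y) with combined distance
#' `d = d_lab + (compactness / S) * d_xy` (S = seed grid interval).
#' Seeds start on a regular grid, perturbed to the lowest-gradient pixel
#' in a 3x3 window; after the sweeps, connectivity is enforced by merging
#' orphan components into their largest neighbour.
#'
#' @param img RGB array.
#' @param params [slic_params()].
#' @return integer label matrix with labels `1..n`, attribute `n_labels`.
#' @export
slic_superpixels <- function(img, params = slic_params()) {
  assert_rgb_image(img)
  npix <- prod(dim(img)[1:2])
  if (params$n_superpixels > npix)
    stop("more superpixels than pixels", call. = FALSE)
  lab <- rgb_to_lab(img)
  raw <- slic_assign_cpp(lab[, , 1], lab[, , 2], lab[, , 3],
                         params$n_superpixels, params$compactness,
                         params$slic_iters)
  min_size <- max(4L, as.integer(npix / params$n_superpixels / 4))
  out <- slic_connectivity_cpp(raw, min_size)
  attr(out, "n_labels") <- max(out)
  out
}

#' Cluster superpixels by mean colour
#'
#' k-means (k-means++ initialisation, empty clusters re-seeded from the
#' farthest point) on the per-superpixel mean (L*, a*, b*) vectors.
#'
#' @param spx superpixel label matrix (1-based labels).
#' @param lab `H x W x 3` Lab array covering `spx`.
#' @param n_centers number of clusters.
#' @param iters iteration cap.
#' @param seed RNG seed.
#' @return integer matrix of per-pixel cluster ids `1..n_centers`, with
#'   attribute `superpixel_cluster` (cluster id per superpixel).
#' @export
cluster_superpixels <- function(spx, lab, n_centers = 3, iters = 500,
                                seed = 1L) {
  assert_same_shape(spx, lab)
  ns <- max(spx)
  if (n_centers > ns) stop("more centers than superpixels", call. = FALSE)
  f <- factor(as.vector(spx), levels = seq_len(ns))
  means <- cbind(tapply(as.vector(lab[, , 1]), f, mean),
                 tapply(as.vector(lab[, , 2]), f, mean),
                 tapply(as.vector(lab[, , 3]), f, mean))
  km <- withr::with_seed(seed, kmeans_lloyd(means, n_centers, iters,
                                            nstart = 8L))
  out <- matrix(km$cluster[spx], nrow(spx), ncol(spx))
  attr(out, "superpixel_cluster") <- km$cluster
  attr(out, "n_labels") <- n_centers
  out
}

#' Select lesion clusters from a cluster map
#'
#' The default rule `max_a` takes the cluster with maximum mean a*
#' (erythema is red); `a_above_median` takes every cluster whose mean a*
#' exceeds the image-wide median a*; `manual` takes explicit cluster ids.
#' `min_a_contrast` > 0 additionally requires the selected clusters to
#' exceed the image median a* by that many Lab units, so that images
#' without lesions yield an empty mask.
#'
#' @param clusters per-pixel cluster id matrix.
#' @param lab Lab array of the same shape.
#' @param rule `"max_a"`, `"a_above_median"` or `"manual"`.
#' @param ids cluster ids for `rule = "manual"`.
#' @param min_a_contrast Lab-units guard (default 0: pure rule).
#' @return logical lesion mask.
#' @export
select_lesion_clusters <- function(clusters, lab,
                                   rule = c("max_a", "a_above_median", "manual"),
                                   ids = NULL, min_a_contrast = 0) {
  rule <- match.arg(rule)
  a <- lab[, , 2]
  ks <- sort(unique(as.vector(clusters)))
  if (length(ks) < 2 && rule != "manual")
    stop("need at least two clusters", call. = FALSE)
  mean_a <- vapply(ks, function(k) mean(a[clusters == k]), numeric(1))
  med_a <- median(a)
  sel <- switch(rule,
    max_a = ks[which.max(mean_a)],
    a_above_median = ks[mean_a > med_a],
    manual = {
      if (is.null(ids)) stop("rule 'manual' needs `ids`", call. = FALSE)
      ids
    })
  if (min_a_contrast > 0 && rule != "manual")
    sel <- sel[mean_a[match(sel, ks)] - med_a >= min_a_contrast]
  matrix(clusters %in% sel, nrow(clusters), ncol(clusters))
}

clean_mask <- function(mask, min_area = 25, close_radius = 3) {
  if (!any(mask)) return(mask)
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, "disc")
    mask <- matrix(as.numeric(EBImage::closing(EBImage::Image(mask * 1),
                                               brush)) > 0.5,
                   nrow(mask), ncol(mask))
  }
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  filled <- matrix(as.logical(filled), nrow(mask), ncol(mask))
  cc <- EBImage::bwlabel(EBImage::Image(filled * 1))
  cc <- matrix(as.integer(cc), nrow(mask), ncol(mask))
  keep <- which(tabulate(cc[cc > 0]) >= min_area)
  matrix(cc %in% keep, nrow(mask), ncol(mask))
}

#' Automatic lesion segmentation by SLIC + local k-means
#'
#' Composition of [slic_superpixels()], [cluster_superpixels()] and
#' [select_lesion_clusters()], followed by morphological cleanup (hole
#' filling and removal of components below `min_area`).
#'
#' @inheritParams slic_superpixels
#' @return object of class `segmentation_result`: list with `mask`,
#'   `method = "slic"`, `superpixels`, `cluster_labels`.
#' @export
segment_slic <- function(img, params = slic_params()) {
  lab <- rgb_to_lab(img)
  spx <- slic_superpixels(img, params)
  cl <- cluster_superpixels(spx, lab, params$n_centers, params$kmeans_iters,
                            params$seed)
  mask <- select_lesion_clusters(cl, lab, rule = params$rule,
                                 min_a_contrast = params$min_a_contrast)
  mask <- clean_mask(mask, params$min_area, params$close_radius)
  structure(list(mask = mask, method = "slic", superpixels = spx,
                 cluster_labels = cl),
            class = "segmentation_result")
}

#' Parameters for the reaction-diffusion level-set segmentation
#'
#' @param dt1 time step of the evolution sub-step (default 1).
#' @param dt2 time step of the diffusion (regularisation) sub-step
#'   (default 0.001).
#' @param iterations number of alternating iterations (default 15).
#' @param smoothing_sigma Gaussian pre-smoothing of the intensity image,
#'   pixels (default 1.5).
#' @param init_mask non-empty logical matrix initialising the front.
#' @return object of class `lsm_params`.
#' @export
lsm_params <- function(init_mask, dt1 = 1, dt2 = 0.001, iterations = 15,
                       smoothing_sigma = 1.5) {
  stopifnot(dt1 > 0, dt2 >= 0, iterations >= 1)
  assert_mask(init_mask, "init_mask")
  if (!any(init_mask)) stop("init_mask must be non-empty", call. = FALSE)
  structure(list(dt1 = dt1, dt2 = dt2, iterations = as.integer(iterations),
                 smoothing_sigma = smoothing_sigma, init_mask = init_mask),
            class = "lsm_params")
}

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) + dr, 1L, h)
  ci <- clamp(seq_len(w) + dc, 1L, w)
  m[ri, ci, drop = FALSE]
}

laplacian4 <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

grad_mag <- function(m) {
  gx <- (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / 2
  gy <- (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / 2
  sqrt(gx^2 + gy^2)
}

#' Semi-automatic segmentation by a reaction-diffusion level set
#'
#' Two-phase level set: the field is initialised as a signed binary step
#' from `init_mask` (+1 inside, -1 outside).  Each iteration applies (a)
#' one explicit evolution step with step `dt1`: an edge-stopped region
#' force (signed pressure towards the Chan-Vese midpoint of the inside /
#' outside means) scaled by the local gradient magnitude of the field,
#' and (b) a diffusion sub-step `phi <- phi + dt2 * laplacian(phi)`.  The
#' field is clamped to `[-1, 1]` after each iteration for numerical
#' stability; the final mask is `{phi > 0}`.
#'
#' @param img RGB array.
#' @param params [lsm_params()] (must carry a non-empty `init_mask`).
#' @return object of class `segmentation_result` with `method = "lsm"`.
#' @export
segment_lsm <- function(img, params) {
  assert_rgb_image(img)
  stopifnot(inherits(params, "lsm_params"))
  gray <- rgb_to_gray(img) / 255
  if (!all(is.finite(gray))) stop("non-finite image", call. = FALSE)
  assert_same_shape(params$init_mask, gray)
  gs <- blur_gaussian(gray, params$smoothing_sigma)
  gm <- grad_mag(gs)
  gmx <- max(gm)
  g <- if (gmx > 0) 1 / (1 + (4 * gm / gmx)^2) else matrix(1, nrow(gm), ncol(gm))

  phi <- ifelse(params$init_mask, 1, -1)
  for (it in seq_len(params$iterations)) {
    inside <- phi > 0
    if (!any(inside) || all(inside)) break
    c1 <- mean(gs[inside]); c2 <- mean(gs[!inside])
    spf <- gs - (c1 + c2) / 2
    mx <- max(abs(spf))
    force <- if (mx > 1e-8) sign(c1 - c2) * spf / mx else 0 * spf
    phi <- phi + params$dt1 * g * force * grad_mag(phi)
    if (params$dt2 > 0) phi <- phi + params$dt2 * laplacian4(phi)
    phi <- clamp(phi, -1, 1)
  }
  structure(list(mask = phi > 0, method = "lsm", superpixels = NULL,
                 cluster_labels = NULL),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method=%s, %d x %d, lesion fraction %.3f\n",
              x$method, nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}
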