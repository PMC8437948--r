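#' Decompose a segmented lesion into erythema and scale patches
#'
#' Lesion pixels are converted to CIE-L*a*b* and clustered by k-means
#' (k-means++ initialisation, fixed seed).  Clusters are labelled by their
#' colour statistics: the cluster with maximum mean a* is erythema
#' (redness), the cluster with maximum mean L* among the remainder is
#' scale (whiteness); any leftover clusters are transitional tissue.
#' Patch images are the original RGB values on the component mask with
#' all other pixels zeroed (black background).
#'
#' @param img RGB array.
#' @param lesion non-empty logical lesion mask (`|lesion| >= k`).
#' @param k number of colour clusters (default 3:
#'   erythema / scale / transitional).
#' @param seed RNG seed for the clustering.
#' @param max_iter k-means iteration cap (default 300).
#' @return object of class `patch_set`: list with `erythema_image`,
#'   `scale_image` (RGB arrays, non-component pixels zeroed),
#'   `erythema_mask`, `scale_mask`, and `cluster_map` (0 outside the
#'   lesion, 1..k inside).
#' @export
decompose_lesion <- function(img, lesion, k = 3, seed = 1L, max_iter = 300L) {
  assert_rgb_image(img)
  assert_mask(lesion, "lesion")
  assert_same_shape(img, lesion)
  n <- sum(lesion)
  if (n < k) stop("lesion has fewer pixels than clusters", call. = FALSE)
  lab <- rgb_to_lab(img)
  pts <- cbind(lab[, , 1][lesion], lab[, , 2][lesion], lab[, , 3][lesion])
  if (nrow(unique(pts)) < k)
    stop("degenerate clustering: fewer than k distinct lesion colours; ",
         "lower k", call. = FALSE)
  km <- withr::with_seed(seed, kmeans_lloyd(pts, k, max_iter, nstart = 4L))
  cluster_map <- matrix(0L, nrow(img), ncol(img))
  cluster_map[lesion] <- km$cluster
  mean_a <- tapply(pts[, 2], km$cluster, mean)
  mean_l <- tapply(pts[, 1], km$cluster, mean)
  ery_id <- as.integer(names(which.max(mean_a)))
  rest <- setdiff(seq_len(k), ery_id)
  scale_id <- rest[which.max(mean_l[as.character(rest)])]
  ery_mask <- cluster_map == ery_id
  scale_mask <- cluster_map == scale_id
  masked_rgb <- function(m) {
    out <- img
    for (ch in 1:3) out[, , ch][!m] <- 0
    out
  }
  structure(list(erythema_image = masked_rgb(ery_mask),
                 scale_image = masked_rgb(scale_mask),
                 erythema_mask = ery_mask,
                 scale_mask = scale_mask,
                 cluster_map = cluster_map),
            class = "patch_set")
}

#' Write erythema/scale patch images for a set of scenes
#'
#' For every non-healthy scene the lesion is decomposed with
#' [decompose_lesion()] and two patch images are written
#' (`<stem>_erythema.png`, `<stem>_scale.png`), each carrying the parent
#' scene's severity scores.  Healthy scenes yield no patches.  No
#' augmentation is ever applied to patch images downstream.
#'
#' @param manifest scene manifest (columns `filename`, `erythema`,
#'   `scale`, `group`), as written by [generate_dataset()].
#' @param root directory holding the scene images and masks.
#' @param out_dir output directory for patch PNGs.
#' @param use_gt_mask if `TRUE` (default) the ground-truth lesion mask is
#'   used; otherwise the lesion is segmented with [segment_slic()].
#' @param k,seed passed to [decompose_lesion()].
#' @return tibble with columns `filename`, `erythema`, `scale`, `group`,
#'   `source`, `component`, `is_patch` (one row per written patch); rows
#'   whose decomposition fails are skipped with a warning.
#' @export
patch_manifest <- function(manifest, root, out_dir, use_gt_mask = TRUE,
                           k = 3, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    if (r$group == "healthy") next
    stem <- sub("\\.png$", "", r$filename)
    img <- read_image(file.path(root, r$filename))
    mask <- if (use_gt_mask) {
      read_mask(file.path(root, scene_mask_paths(r$filename)[["mask"]]))
    } else {
      segment_slic(img)$mask
    }
    ps <- tryCatch(decompose_lesion(img, mask, k = k, seed = seed),
                   error = function(e) {
                     warning("patch decomposition skipped for ", r$filename,
                             ": ", conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(ps)) next
    for (comp in c("erythema", "scale")) {
      fn <- sprintf("%s_%s.png", stem, comp)
      write_image(ps[[paste0(comp, "_image")]], file.path(out_dir, fn))
      write_mask(ps[[paste0(comp, "_mask")]],
                 file.path(out_dir, sprintf("%s_%s_mask.png", stem, comp)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        filename = fn, erythema = r$erythema, scale = r$scale,
        group = r$group, source = r$filename, component = comp, is_patch = 1L)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(filename = character(), erythema = integer(),
                   scale = integer(), group = character(),
                   source = character(), component = character(),
                   is_patch = integer())
  write.csv(out, file.path(out_dir, "patches.csv"), row.names = FALSE)
  attr(out, "root") <- out_dir
  out
}
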