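#' Dataset assembly specification
#'
#' Dataset A contains crops only; dataset B additionally contains 11
#' affine variants of every kept crop (three rotations, four horizontal
#' flips of identity and the rotations, and four scalings).  Patch
#' images, when included, are appended untransformed.
#'
#' @param mode `"A"` (crops only) or `"B"` (crops + affine variants).
#' @param include_patches append patch rows untransformed.
#' @param min_lesion_fraction crops (other than healthy-class crops) are
#'   kept only if lesion pixels / crop pixels >= this (default 0.01).
#' @param crop_rule_threshold aspect ratio at or above which an image is
#'   cropped into 6 parts instead of 4 (default 1.4).
#' @param scaling_factors four positive reals: uniform expansion,
#'   uniform reduction, x-stretch, y-stretch.
#' @param seed kept for interface symmetry; assembly is deterministic.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(mode = c("A", "B"), include_patches = FALSE,
                         min_lesion_fraction = 0.01,
                         crop_rule_threshold = 1.4,
                         scaling_factors = c(1.25, 0.8, 1.25, 1.25),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (any(scaling_factors <= 0)) stop("scaling factors must be > 0", call. = FALSE)
  stopifnot(length(scaling_factors) == 4)
  structure(list(mode = mode, include_patches = include_patches,
                 min_lesion_fraction = min_lesion_fraction,
                 crop_rule_threshold = crop_rule_threshold,
                 scaling_factors = scaling_factors, seed = as.integer(seed)),
            class = "dataset_spec")
}

tile_cuts <- function(n, k) floor(n * (0:k) / k)

#' Crop an image (and its mask) into 4 or 6 tiles
#'
#' Images whose aspect ratio (long/short side) is at least
#' `aspect_threshold` are cut into a 3x2 grid with the long axis split in
#' three; otherwise a 2x2 grid.  Tiles cover the image exactly.
#'
#' @param img RGB array.
#' @param mask logical matrix of the same shape.
#' @param aspect_threshold default 1.4.
#' @return list of tiles, each `list(image, mask, row, col)`.
#' @export
crop_image <- function(img, mask, aspect_threshold = 1.4) {
  assert_rgb_image(img); assert_mask(mask); assert_same_shape(img, mask)
  h <- nrow(mask); w <- ncol(mask)
  if (h < 2 || w < 2) stop("image too small to crop", call. = FALSE)
  aspect <- max(h, w) / min(h, w)
  if (aspect >= aspect_threshold) {
    nr <- if (h >= w) 3L else 2L
    nc <- if (h >= w) 2L else 3L
  } else {
    nr <- 2L; nc <- 2L
  }
  rc <- tile_cuts(h, nr); cc <- tile_cuts(w, nc)
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- (rc[i] + 1L):rc[i + 1L]
    ci <- (cc[j] + 1L):cc[j + 1L]
    out[[length(out) + 1L]] <- list(image = img[ri, ci, , drop = FALSE],
                                    mask = mask[ri, ci, drop = FALSE],
                                    row = i, col = j)
  }
  out
}

rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_mat <- function(m) m[, ncol(m):1, drop = FALSE]

apply_geom <- function(img, f) {
  chans <- lapply(1:3, function(k) f(img[, , k]))
  array(unlist(chans), dim = c(dim(chans[[1]]), 3L))
}

bilinear_resize <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  ys <- (seq_len(new_h) - 0.5) * h / new_h + 0.5
  xs <- (seq_len(new_w) - 0.5) * w / new_w + 0.5
  y0 <- clamp(floor(ys), 1, h); y1 <- clamp(y0 + 1, 1, h)
  x0 <- clamp(floor(xs), 1, w); x1 <- clamp(x0 + 1, 1, w)
  fy <- clamp(ys - y0, 0, 1); fx <- clamp(xs - x0, 0, 1)
  m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
    m[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
    m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
    m[y1, x1, drop = FALSE] * (fy %o% fx)
}

nearest_resize <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  yi <- clamp(ceiling((seq_len(new_h) - 0.5) * h / new_h), 1, h)
  xi <- clamp(ceiling((seq_len(new_w) - 0.5) * w / new_w), 1, w)
  m[yi, xi, drop = FALSE]
}

resize_pair <- function(img, mask, fy, fx) {
  nh <- max(2L, round(nrow(mask) * fy)); nw <- max(2L, round(ncol(mask) * fx))
  img2 <- apply_geom(img, function(m) bilinear_resize(m, nh, nw))
  img2 <- round(clamp(img2, 0, 255))
  list(image = img2, mask = nearest_resize(mask, nh, nw))
}

#' Affine augmentation variants of a crop
#'
#' Emits the 11 variants used for dataset B: rotations by 90/180/270
#' degrees, horizontal flips of the identity and of the three rotations,
#' and four scalings (uniform expansion, uniform reduction, horizontal
#' stretch, vertical stretch).  The identity itself is not emitted (the
#' original crop stays in the dataset).  Images are resampled bilinearly,
#' masks with nearest neighbour; rotations and flips are exact grid
#' isometries.
#'
#' @param img RGB array (a crop).
#' @param mask logical matrix.
#' @param factors four positive scaling factors (expansion, reduction,
#'   x-stretch, y-stretch).
#' @return named list of 11 `list(image, mask)` variants.
#' @export
affine_set <- function(img, mask, factors = c(1.25, 0.8, 1.25, 1.25)) {
  if (any(factors <= 0)) stop("scaling factors must be > 0", call. = FALSE)
  r1 <- function(m) rot90_mat(m)
  r2 <- function(m) rot90_mat(rot90_mat(m))
  r3 <- function(m) rot90_mat(rot90_mat(rot90_mat(m)))
  geo <- list(
    rot90 = r1, rot180 = r2, rot270 = r3,
    flip = flip_mat,
    flip_rot90 = function(m) flip_mat(r1(m)),
    flip_rot180 = function(m) flip_mat(r2(m)),
    flip_rot270 = function(m) flip_mat(r3(m))
  )
  out <- lapply(geo, function(f) list(image = apply_geom(img, f),
                                      mask = f(mask)))
  out$scale_up <- resize_pair(img, mask, factors[1], factors[1])
  out$scale_down <- resize_pair(img, mask, factors[2], factors[2])
  out$stretch_x <- resize_pair(img, mask, 1, factors[3])
  out$stretch_y <- resize_pair(img, mask, factors[4], 1)
  out
}

#' Filter crops by lesion content
#'
#' Keeps a crop iff its lesion fraction is at least `min_fraction`;
#' crops from healthy-class images are exempt (kept regardless), since an
#' empty mask is their expected state.
#'
#' @param pairs list of `list(image, mask, label, ...)` entries.
#' @param min_fraction default 0.01.
#' @return the kept subset of `pairs`.
#' @export
filter_lesion_content <- function(pairs, min_fraction = 0.01) {
  keep <- vapply(pairs, function(p) {
    identical(p$label, "healthy") || mean(p$mask) >= min_fraction
  }, logical(1))
  pairs[keep]
}

#' Assemble a classification dataset from a scene manifest
#'
#' Mode A: each scene is cropped ([crop_image()]) and crops are filtered
#' by lesion content.  Mode B: additionally every kept crop's 11 affine
#' variants ([affine_set()]) are generated and filtered.  Patch rows are
#' appended untransformed when `spec$include_patches` is `TRUE`.  Crops
#' and masks are written as PNGs; the returned manifest records
#' provenance (`source`, `transform`).
#'
#' @param manifest scene manifest from [generate_dataset()].
#' @param spec a [dataset_spec()].
#' @param root directory of the scene images.
#' @param out_dir output directory for the dataset images.
#' @param patches optional patch manifest from [patch_manifest()]
#'   (required if `spec$include_patches`).
#' @param patch_root directory of the patch images.
#' @return tibble with columns `filename`, `mask_filename`, `label`,
#'   `source`, `transform`, `is_patch`; attribute `root` = `out_dir`.
#' @export
assemble_dataset <- function(manifest, spec, root, out_dir,
                             patches = NULL, patch_root = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(img, mask, label, source, transform, stem) {
    fn <- paste0(stem, ".png"); mfn <- paste0(stem, "_mask.png")
    write_image(img, file.path(out_dir, fn))
    write_mask(mask, file.path(out_dir, mfn))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      filename = fn, mask_filename = mfn, label = label,
      source = source, transform = transform, is_patch = 0L)
  }
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    img <- read_image(file.path(root, r$filename))
    mask <- read_mask(file.path(root, scene_mask_paths(r$filename)[["mask"]]))
    stem0 <- sub("\\.png$", "", r$filename)
    crops <- crop_image(img, mask, spec$crop_rule_threshold)
    crops <- lapply(crops, function(cr) { cr$label <- as.character(r$group); cr })
    crops <- filter_lesion_content(crops, spec$min_lesion_fraction)
    for (cr in crops) {
      tag <- sprintf("crop(%d,%d)", cr$row, cr$col)
      stem <- sprintf("%s_r%dc%d", stem0, cr$row, cr$col)
      emit(cr$image, cr$mask, cr$label, r$filename, tag, stem)
      if (spec$mode == "B") {
        vars <- affine_set(cr$image, cr$mask, spec$scaling_factors)
        vars <- lapply(names(vars), function(nm) {
          v <- vars[[nm]]; v$label <- cr$label; v$name <- nm; v
        })
        vars <- filter_lesion_content(vars, spec$min_lesion_fraction)
        for (v in vars)
          emit(v$image, v$mask, v$label, r$filename,
               paste0(tag, "+", v$name), paste0(stem, "_", v$name))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (spec$include_patches) {
    if (is.null(patches) || is.null(patch_root))
      stop("include_patches requires `patches` and `patch_root`", call. = FALSE)
    for (i in seq_len(nrow(patches))) {
      pr <- patches[i, ]
      stem <- sub("\\.png$", "", pr$filename)
      file.copy(file.path(patch_root, pr$filename), file.path(out_dir, pr$filename),
                overwrite = TRUE)
      mfn <- paste0(stem, "_mask.png")
      file.copy(file.path(patch_root, mfn), file.path(out_dir, mfn),
                overwrite = TRUE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        filename = pr$filename, mask_filename = mfn,
        label = as.character(pr$group), source = pr$source,
        transform = "", is_patch = 1L))
    }
  }
  write.csv(out, file.path(out_dir, "dataset.csv"), row.names = FALSE)
  attr(out, "root") <- out_dir
  out
}
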