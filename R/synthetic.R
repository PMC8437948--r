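#' Parameters for the synthetic lesion-scene generator
#'
#' The generator emulates local psoriasis photographs: a skin-tone
#' background with a smooth shading ramp and hair-like strokes, plus 1-4
#' irregular lesion blobs.  Interior redness (a* shift) scales with the
#' erythema score and white-speckle coverage scales with the scaling
#' score, each graded 0-4 as in PASI-style clinical scoring.  Every scene
#' carries ground-truth lesion / erythema / scale masks.
#'
#' @param image_size height/width in pixels (length-1 or length-2).
#' @param skin_base_lab background skin tone as (L*, a*, b*).
#' @param n_lesions number of lesion blobs (0-4).  `NULL` (default) draws
#'   1-4 from the seed; forced to 0 for a healthy scene.  Must be 0 iff
#'   both scores are 0.
#' @param erythema_score,scale_score integer severity scores 0-4.
#' @param erythema_a_gain a* shift per erythema score unit (Lab units).
#' @param scale_coverage_gain fraction of lesion area covered by scale
#'   speckle per scaling score unit.
#' @param shadow_amplitude amplitude of the multiplicative shading ramp in
#'   L* units.
#' @param n_hairs number of dark hair strokes.
#' @param blur_sigma final Gaussian blur of the rendered image (pixels).
#' @param seed integer seed; the scene is fully reproducible from it.
#' @return an object of class `lesion_scene_params`.
#' @export
lesion_scene_params <- function(image_size = 512,
                                skin_base_lab = c(70, 12, 18),
                                n_lesions = NULL,
                                erythema_score = 2,
                                scale_score = 2,
                                erythema_a_gain = 8,
                                scale_coverage_gain = 0.12,
                                shadow_amplitude = 6,
                                n_hairs = 15,
                                blur_sigma = 0.8,
                                seed = 1L) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  stopifnot(all(image_size >= 32), length(skin_base_lab) == 3L)
  for (s in c(erythema_score, scale_score))
    if (!s %in% 0:4) stop("scores must be integers in 0..4", call. = FALSE)
  healthy <- erythema_score == 0 && scale_score == 0
  if (is.null(n_lesions)) {
    if (healthy) n_lesions <- 0L
  } else {
    if (!n_lesions %in% 0:4) stop("n_lesions must be in 0..4", call. = FALSE)
    if ((n_lesions == 0L) != healthy)
      stop("n_lesions must be 0 exactly for healthy scenes (both scores 0)",
           call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 skin_base_lab = as.numeric(skin_base_lab),
                 n_lesions = n_lesions,
                 erythema_score = as.integer(erythema_score),
                 scale_score = as.integer(scale_score),
                 erythema_a_gain = erythema_a_gain,
                 scale_coverage_gain = scale_coverage_gain,
                 shadow_amplitude = shadow_amplitude,
                 n_hairs = as.integer(n_hairs),
                 blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "lesion_scene_params")
}

#' Generate one synthetic lesion scene
#'
#' Lesion shapes are thresholded smoothed random fields (irregular,
#' ambiguous boundaries); the erythema falloff at the boundary widens as
#' the erythema score decreases, and scale speckle is a high-frequency
#' field thresholded inside the lesion at the requested coverage
#' quantile.  See [lesion_scene_params()] for the dials.
#'
#' @param params a [lesion_scene_params()] object.
#' @return an object of class `lesion_scene`: list with `image` (RGB
#'   array), `lesion_mask`, `erythema_mask`, `scale_mask` (logical
#'   matrices), the two scores, `severity_group`, and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "lesion_scene_params"))
  withr::with_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  n_lesions <- p$n_lesions
  if (is.null(n_lesions)) n_lesions <- sample(1:4, 1L)

  L <- matrix(p$skin_base_lab[1], h, w)
  A <- matrix(p$skin_base_lab[2], h, w)
  B <- matrix(p$skin_base_lab[3], h, w)
  # gentle base texture so healthy skin is not perfectly flat
  L <- L + blur_gaussian(matrix(rnorm(h * w, sd = 4), h, w), 3)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)

  lesion_mask <- matrix(FALSE, h, w)
  wmap <- matrix(0, h, w)          # erythema core weight
  fw <- 0.12 + 0.10 * (4 - p$erythema_score)  # falloff width: wider when mild
  if (n_lesions > 0) {
    for (i in seq_len(n_lesions)) {
      cy <- runif(1, 0.25, 0.75) * h
      cx <- runif(1, 0.25, 0.75) * w
      r <- runif(1, 0.10, 0.16) * min(h, w)
      z <- blur_gaussian(matrix(rnorm(h * w), h, w), r / 2)
      z <- (z - mean(z)) / sd(z)
      s <- sqrt(((rows - cy) / r)^2 + ((cols - cx) / r)^2)
      u <- 1 + 0.35 * z - s
      blob <- u > 0
      lesion_mask <- lesion_mask | blob
      wmap <- pmax(wmap, ifelse(blob, clamp(u / fw, 0, 1), 0))
    }
  }

  # erythema: a* shift with radial falloff; slightly darker where redder
  da <- p$erythema_score * p$erythema_a_gain * wmap
  A <- A + da
  L <- L - 0.06 * da
  erythema_mask <- (p$erythema_score > 0) & (wmap >= 0.5) & lesion_mask

  # scale: high-frequency speckle inside lesions, rendered near-white
  scale_mask <- matrix(FALSE, h, w)
  if (p$scale_score > 0 && any(lesion_mask)) {
    cov <- p$scale_score * p$scale_coverage_gain
    if (cov > 1) {
      warning("scale coverage > 1 after gain; clipped to 1")
      cov <- 1
    }
    hf <- blur_gaussian(matrix(rnorm(h * w), h, w), 1.2)
    thr <- quantile(hf[lesion_mask], 1 - cov, names = FALSE)
    scale_mask <- lesion_mask & (hf >= thr)
    L[scale_mask] <- 0.15 * L[scale_mask] + 0.85 * 93
    A[scale_mask] <- 0.15 * A[scale_mask] + 0.85 * 1
    B[scale_mask] <- 0.15 * B[scale_mask] + 0.85 * 3
  }
  erythema_mask <- erythema_mask & !scale_mask

  # multiplicative shading ramp in a random direction
  if (p$shadow_amplitude > 0) {
    th <- runif(1, 0, 2 * pi)
    g <- cos(th) * (rows - h / 2) / (h / 2) + sin(th) * (cols - w / 2) / (w / 2)
    g <- g / max(abs(g))
    L <- L * (1 + (p$shadow_amplitude / p$skin_base_lab[1]) * g)
  }

  # hair-like dark Bezier strokes
  if (p$n_hairs > 0) {
    for (i in seq_len(p$n_hairs)) {
      p0 <- c(runif(1, 1, h), runif(1, 1, w))
      p2 <- p0 + c(runif(1, -0.4, 0.4) * h, runif(1, -0.4, 0.4) * w)
      mid <- (p0 + p2) / 2 + c(runif(1, -0.1, 0.1) * h, runif(1, -0.1, 0.1) * w)
      stroke <- bezier_stroke(h, w, p0, mid, p2)
      L[stroke] <- L[stroke] * 0.45
      A[stroke] <- A[stroke] * 0.5
      B[stroke] <- B[stroke] * 0.5
    }
  }

  if (p$blur_sigma > 0) {
    L <- blur_gaussian(L, p$blur_sigma)
    A <- blur_gaussian(A, p$blur_sigma)
    B <- blur_gaussian(B, p$blur_sigma)
  }
  L <- clamp(L, 0, 100)

  img <- lab_to_rgb(array(c(L, A, B), dim = c(h, w, 3L)))
  structure(list(image = img,
                 lesion_mask = lesion_mask,
                 erythema_mask = erythema_mask,
                 scale_mask = scale_mask,
                 erythema_score = p$erythema_score,
                 scale_score = p$scale_score,
                 severity_group = as.character(
                   severity_group(p$erythema_score, p$scale_score)$group),
                 params = p),
            class = "lesion_scene")
}

#' Generate a balanced synthetic dataset on disk
#'
#' Writes `n_per_group` scenes for each of the five severity groups
#' (healthy, mild, moderate, severe, very severe), together with their
#' lesion / erythema / scale masks (`<stem>_mask.png`,
#' `<stem>_erythema.png`, `<stem>_scale.png`) and a CSV manifest with
#' header `filename,erythema,scale,group`.
#'
#' @param n_per_group scenes per severity group (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-scene seeds are drawn from it.
#' @param image_size passed to [lesion_scene_params()].
#' @return tibble manifest (also written to `manifest.csv`), invisibly
#'   carrying `out_dir` as attribute `root`.
#' @export
generate_dataset <- function(n_per_group, out_dir, seed = 1L, image_size = 512) {
  stopifnot(n_per_group >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- severity_levels()
  bands <- list(healthy = 0L, mild = 1:2, moderate = 3:4,
                severe = 5:6, very_severe = 7:8)
  rows <- list()
  withr::with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L,
                              5L * n_per_group)
    idx <- 0L
    for (g in groups) {
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1L
        total <- if (length(bands[[g]]) == 1L) bands[[g]] else sample(bands[[g]], 1L)
        e_lo <- max(0L, total - 4L); e_hi <- min(4L, total)
        e <- if (e_lo == e_hi) e_lo else sample(e_lo:e_hi, 1L)
        s <- total - e
        sc <- generate_scene(lesion_scene_params(
          image_size = image_size, erythema_score = e, scale_score = s,
          seed = scene_seeds[idx]))
        stem <- sprintf("scene_%03d", idx)
        write_image(sc$image, file.path(out_dir, paste0(stem, ".png")))
        write_mask(sc$lesion_mask, file.path(out_dir, paste0(stem, "_mask.png")))
        write_mask(sc$erythema_mask,
                   file.path(out_dir, paste0(stem, "_erythema.png")))
        write_mask(sc$scale_mask, file.path(out_dir, paste0(stem, "_scale.png")))
        rows[[idx]] <- tibble::tibble(filename = paste0(stem, ".png"),
                                      erythema = e, scale = s, group = g)
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "root") <- out_dir
  manifest
}

#' Companion mask paths for a scene image filename
#' @param filename scene image filename (e.g. `scene_001.png`).
#' @return named character vector with `mask`, `erythema`, `scale` paths.
#' @export
scene_mask_paths <- function(filename) {
  stem <- sub("\\.png$", "", filename)
  c(mask = paste0(stem, "_mask.png"),
    erythema = paste0(stem, "_erythema.png"),
    scale = paste0(stem, "_scale.png"))
}
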