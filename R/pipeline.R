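#' Pipeline configuration
#'
#' Nested list of per-stage parameters with a single global seed; can be
#' loaded from / written to YAML.  Unknown keys are rejected.
#'
#' @param seed global seed driving every stochastic stage.
#' @param out_root run directory.
#' @param simulate list: `n_per_group`, `image_size`.
#' @param segment list passed to [slic_params()].
#' @param patchify list: `k`, `use_gt_mask`.
#' @param augment list: `mode`, `include_patches`, `min_lesion_fraction`.
#' @param extract list: `groups`.
#' @param select list: `fraction`, `enabled`.
#' @param train list: `classifiers`, `k_folds`, `repeats`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_root = "run",
                            simulate = list(), segment = list(),
                            patchify = list(), augment = list(),
                            extract = list(), select = list(),
                            train = list()) {
  defaults <- list(
    simulate = list(n_per_group = 4, image_size = 256),
    segment = list(n_superpixels = 700, compactness = 10, n_centers = 3,
                   kmeans_iters = 500, min_area = 25, close_radius = 3,
                   min_a_contrast = 5, rule = "max_a"),
    patchify = list(k = 3, use_gt_mask = FALSE),
    augment = list(mode = "B", include_patches = FALSE,
                   min_lesion_fraction = 0.01),
    extract = list(groups = c("texture", "color")),
    select = list(fraction = 2 / 3, enabled = TRUE),
    train = list(classifiers = c("rf", "knn"), k_folds = 5, repeats = 10)
  )
  user <- list(simulate = simulate, segment = segment, patchify = patchify,
               augment = augment, extract = extract, select = select,
               train = train)
  for (sec in names(defaults)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop("unknown config keys in ", sec, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(c(list(seed = as.integer(seed), out_root = out_root), defaults),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), c("seed", "out_root", "simulate",
                                      "segment", "patchify", "augment",
                                      "extract", "select", "train"))]
  unknown <- setdiff(names(raw), names(args))
  if (length(unknown))
    stop("unknown config sections: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Validate a scene or dataset manifest against its files
#'
#' @param manifest tibble with at least `filename`; `label`/`group` and
#'   mask columns are checked when present.
#' @param root directory holding the files.
#' @return tibble of violations (`row`, `problem`); empty when clean.
#' @export
validate_manifest <- function(manifest, root) {
  probs <- list()
  note <- function(i, msg)
    probs[[length(probs) + 1L]] <<- tibble::tibble(row = i, problem = msg)
  lab_col <- intersect(c("group", "label"), names(manifest))[1]
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    fp <- file.path(root, r$filename)
    if (!file.exists(fp)) { note(i, paste0("missing file: ", r$filename)); next }
    if (!is.na(lab_col) && !as.character(r[[lab_col]]) %in% severity_levels())
      note(i, paste0("invalid label: ", as.character(r[[lab_col]])))
    mask_fn <- if ("mask_filename" %in% names(manifest)) r$mask_filename else
      scene_mask_paths(r$filename)[["mask"]]
    mp <- file.path(root, mask_fn)
    if (!file.exists(mp)) {
      note(i, paste0("missing mask: ", mask_fn))
    } else {
      img <- read_image(fp); mask <- read_mask(mp)
      if (!identical(dim(img)[1:2], dim(mask)))
        note(i, paste0("mask/image shape mismatch: ", r$filename))
    }
  }
  if (length(probs)) dplyr::bind_rows(probs) else
    tibble::tibble(row = integer(), problem = character())
}

#' Run the full assessment pipeline
#'
#' Chains simulate, segment, patchify, augment, extract, select and
#' train-eval into per-stage subdirectories under `config$out_root`,
#' writing a YAML run summary.  With `resume = TRUE`, stages whose
#' output manifest already exists are reloaded instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage outputs (default TRUE).
#' @return (invisibly) list with the stage outputs and the summary.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  root <- config$out_root
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)
  stage_dir <- function(s) { d <- file.path(root, s); dir.create(d, showWarnings = FALSE); d }

  # -- simulate
  d_sim <- stage_dir("scenes")
  man_path <- file.path(d_sim, "manifest.csv")
  scenes <- if (resume && file.exists(man_path)) {
    tibble::as_tibble(read.csv(man_path))
  } else {
    generate_dataset(config$simulate$n_per_group, d_sim, seed = config$seed,
                     image_size = config$simulate$image_size)
  }
  summary$scenes <- nrow(scenes)

  # -- segment + similarity vs ground truth
  d_seg <- stage_dir("segmentation")
  seg_path <- file.path(d_seg, "similarity.csv")
  sp <- do.call(slic_params, c(config$segment, list(seed = config$seed)))
  if (resume && file.exists(seg_path)) {
    seg <- tibble::as_tibble(read.csv(seg_path))
  } else {
    rows <- list()
    for (i in seq_len(nrow(scenes))) {
      r <- scenes[i, ]
      img <- read_image(file.path(d_sim, r$filename))
      gt <- read_mask(file.path(d_sim, scene_mask_paths(r$filename)[["mask"]]))
      res <- segment_slic(img, sp)
      write_mask(res$mask, file.path(d_seg, sub("\\.png$", "_pred.png", r$filename)))
      rep_ <- evaluate_segmentation(res$mask, gt)
      rows[[i]] <- tibble::tibble(filename = r$filename, group = r$group,
                                  dice = rep_$dice, gce = rep_$gce,
                                  voi = rep_$voi, hd = rep_$hd, ri = rep_$ri)
    }
    seg <- dplyr::bind_rows(rows)
    write.csv(seg, seg_path, row.names = FALSE)
  }
  lesional <- seg$group != "healthy"
  summary$segmentation <- list(
    n = nrow(seg),
    mean_dice_lesional = mean(seg$dice[lesional], na.rm = TRUE),
    mean_ri_lesional = mean(seg$ri[lesional], na.rm = TRUE))

  # -- patchify (from the predicted masks by default)
  d_patch <- stage_dir("patches")
  patch_path <- file.path(d_patch, "patches.csv")
  patches <- if (resume && file.exists(patch_path)) {
    tibble::as_tibble(read.csv(patch_path))
  } else {
    patch_manifest(scenes, d_sim, d_patch,
                   use_gt_mask = config$patchify$use_gt_mask,
                   k = config$patchify$k, seed = config$seed)
  }
  summary$patches <- nrow(patches)

  # -- augment
  d_aug <- stage_dir("dataset")
  aug_path <- file.path(d_aug, "dataset.csv")
  dspec <- dataset_spec(mode = config$augment$mode,
                        include_patches = config$augment$include_patches,
                        min_lesion_fraction = config$augment$min_lesion_fraction,
                        seed = config$seed)
  dataset <- if (resume && file.exists(aug_path)) {
    tibble::as_tibble(read.csv(aug_path))
  } else {
    assemble_dataset(scenes, dspec, d_sim, d_aug,
                     patches = patches, patch_root = d_patch)
  }
  summary$dataset <- nrow(dataset)

  # -- extract
  d_feat <- stage_dir("features")
  feat_path <- file.path(d_feat, "features.csv")
  features <- if (resume && file.exists(feat_path)) {
    tibble::as_tibble(read.csv(feat_path, check.names = FALSE))
  } else {
    fm <- extract_matrix(dataset, d_aug, groups = config$extract$groups)
    write.csv(fm, feat_path, row.names = FALSE)
    fm
  }
  summary$features <- ncol(features) - 3L

  # -- select
  xy <- feature_xy(features)
  sel_names <- colnames(xy$X)
  if (isTRUE(config$select$enabled)) {
    d_sel <- stage_dir("selection")
    sel <- select_features(xy$X, xy$y, fraction = config$select$fraction)
    writeLines(sel$selected, file.path(d_sel, "selected.txt"))
    sel_names <- sel$selected
  }
  summary$selected <- length(sel_names)

  # -- train-eval
  d_tr <- stage_dir("evaluation")
  cv <- cv_config(k_folds = config$train$k_folds,
                  repeats = config$train$repeats, seed = config$seed)
  reports <- list()
  for (clf in config$train$classifiers) {
    rep_ <- cross_validate(classifier_spec(clf, seed = config$seed),
                           xy$X[, sel_names, drop = FALSE], xy$y, cv)
    reports[[clf]] <- rep_
    write.csv(rep_$aggregate, file.path(d_tr, paste0(clf, "_aggregate.csv")),
              row.names = FALSE)
  }
  summary$evaluation <- lapply(reports, function(r)
    as.list(setNames(r$aggregate$mean, r$aggregate$metric)))
  yaml::write_yaml(summary, file.path(root, "run_summary.yaml"))
  invisible(list(scenes = scenes, segmentation = seg, patches = patches,
                 dataset = dataset, features = features,
                 selected = sel_names, reports = reports, summary = summary))
}
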