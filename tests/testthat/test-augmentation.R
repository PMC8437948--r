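make_img <- function(h, w, seed = 1) {
  withr::with_seed(seed, {
    array(as.double(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
  })
}

test_that("the crop rule yields 6 tiles for elongated and 4 for square images", {
  img6 <- make_img(300, 200); m6 <- matrix(TRUE, 300, 200)
  expect_length(crop_image(img6, m6), 6)
  img4 <- make_img(200, 200); m4 <- matrix(TRUE, 200, 200)
  expect_length(crop_image(img4, m4), 4)
  # wide images split the long axis in three as well
  imgw <- make_img(200, 300); mw <- matrix(TRUE, 200, 300)
  expect_length(crop_image(imgw, mw), 6)
})

test_that("crops tile the image exactly", {
  img <- make_img(37, 53); m <- matrix(FALSE, 37, 53); m[5:20, 7:40] <- TRUE
  crops <- crop_image(img, m)
  expect_equal(sum(vapply(crops, function(cr) length(cr$mask), numeric(1))),
               length(m))
  expect_equal(sort(unlist(lapply(crops, function(cr) as.vector(cr$image)))),
               sort(as.vector(img)))
  expect_equal(sum(vapply(crops, function(cr) sum(cr$mask), numeric(1))),
               sum(m))
})

test_that("rotations and flips are exact grid isometries", {
  img <- make_img(24, 16); m <- matrix(FALSE, 24, 16); m[3:10, 2:9] <- TRUE
  v <- affine_set(img, m)
  expect_length(v, 11)
  r <- psoriabench:::rot90_mat
  expect_identical(r(r(r(r(m)))), m)            # four rotations = identity
  expect_identical(psoriabench:::flip_mat(psoriabench:::flip_mat(m)), m)
  for (nm in c("rot90", "rot180", "rot270", "flip", "flip_rot90",
               "flip_rot180", "flip_rot270"))
    expect_equal(sum(v[[nm]]$mask), sum(m), info = nm)
  # scalings resize by the stated factors
  expect_equal(dim(v$scale_up$mask), round(dim(m) * 1.25))
  expect_equal(dim(v$scale_down$mask), round(dim(m) * 0.8))
  expect_equal(dim(v$stretch_x$mask), c(24, 20))
  expect_equal(dim(v$stretch_y$mask), c(30, 16))
  expect_error(affine_set(img, m, factors = c(-1, 1, 1, 1)), "> 0")
})

test_that("lesion-content filtering drops empty and tiny-lesion crops", {
  mk <- function(frac, label) {
    m <- matrix(FALSE, 20, 20)
    if (frac > 0) m[seq_len(max(1, round(frac * 400)))] <- TRUE
    list(image = make_img(20, 20), mask = m, label = label)
  }
  pairs <- list(mk(0, "mild"), mk(0.005, "moderate"), mk(0.5, "severe"),
                mk(1, "severe"), mk(0, "healthy"))
  kept <- filter_lesion_content(pairs)
  expect_length(kept, 3)  # the two lesion-rich crops + the healthy exemption
  labs <- vapply(kept, `[[`, character(1), "label")
  expect_true("healthy" %in% labs)
  expect_false(any(vapply(kept, function(p)
    p$label == "moderate", logical(1))))
})

local_scene_dir <- function(seed = 77) {
  tmp <- withr::local_tempdir(.local_envir = parent.frame())
  sc <- generate_scene(lesion_scene_params(image_size = 200,
                                           erythema_score = 4,
                                           scale_score = 0, n_lesions = 4,
                                           seed = seed))
  # force every quadrant to carry lesion so that no crop is filtered
  mask <- sc$lesion_mask
  for (ri in list(1:100, 101:200)) for (ci in list(1:100, 101:200)) {
    sub <- mask[ri, ci]
    if (mean(sub) < 0.05) {
      mask[ri[40:60], ci[40:60]] <- TRUE
    }
  }
  write_image(sc$image, file.path(tmp, "scene_001.png"))
  write_mask(mask, file.path(tmp, "scene_001_mask.png"))
  write_mask(sc$erythema_mask & mask, file.path(tmp, "scene_001_erythema.png"))
  write_mask(sc$scale_mask & mask, file.path(tmp, "scene_001_scale.png"))
  man <- tibble::tibble(filename = "scene_001.png", erythema = 4L,
                        scale = 0L, group = "moderate")
  list(root = tmp, manifest = man)
}

test_that("dataset A and B row counts follow the crop and x12 rules", {
  fx <- local_scene_dir()
  outA <- file.path(fx$root, "dsA"); outB <- file.path(fx$root, "dsB")
  dsA <- assemble_dataset(fx$manifest, dataset_spec("A"), fx$root, outA)
  expect_equal(nrow(dsA), 4)
  expect_true(all(dsA$is_patch == 0L))
  dsB <- assemble_dataset(fx$manifest, dataset_spec("B"), fx$root, outB)
  expect_equal(nrow(dsB), 48)  # 4 crops x (1 + 11 variants)
  expect_true(all(dsA$filename %in% dsB$filename))
  expect_true(all(file.exists(file.path(outB, dsB$filename))))
  expect_true(all(file.exists(file.path(outB, dsB$mask_filename))))
  # provenance: every variant row carries its transform chain
  expect_true(all(grepl("^crop\\(", dsB$transform)))
  expect_equal(sum(grepl("\\+", dsB$transform)), 44)
})

test_that("patch rows are appended untransformed and never augmented", {
  fx <- local_scene_dir(seed = 78)
  pm <- patch_manifest(fx$manifest, fx$root, file.path(fx$root, "patches"),
                       use_gt_mask = TRUE, seed = 1)
  expect_equal(nrow(pm), 2)
  out <- file.path(fx$root, "dsBp")
  ds <- assemble_dataset(fx$manifest, dataset_spec("B", include_patches = TRUE),
                         fx$root, out, patches = pm,
                         patch_root = file.path(fx$root, "patches"))
  expect_equal(nrow(ds), 48 + 2)
  patch_rows <- ds[ds$is_patch == 1L, ]
  expect_equal(nrow(patch_rows), 2)
  expect_true(all(patch_rows$transform == ""))
  expect_error(assemble_dataset(fx$manifest,
                                dataset_spec("B", include_patches = TRUE),
                                fx$root, out), "requires")
})

test_that("dataset assembly is deterministic", {
  fx <- local_scene_dir(seed = 79)
  d1 <- assemble_dataset(fx$manifest, dataset_spec("A"), fx$root,
                         file.path(fx$root, "d1"))
  d2 <- assemble_dataset(fx$manifest, dataset_spec("A"), fx$root,
                         file.path(fx$root, "d2"))
  attr(d1, "root") <- NULL; attr(d2, "root") <- NULL
  expect_identical(d1, d2)
  f1 <- file.path(fx$root, "d1", d1$filename[1])
  f2 <- file.path(fx$root, "d2", d2$filename[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
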