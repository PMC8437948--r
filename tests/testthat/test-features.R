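const_img <- function(v = 100, h = 12, w = 12) matrix(v, h, w)
full_mask <- function(h = 12, w = 12) matrix(TRUE, h, w)

test_that("GLCM counts match the hand-enumerated toy", {
  g <- rbind(c(0, 0, 1), c(0, 1, 1)) * 255
  cnt <- glcm_counts(g, matrix(TRUE, 2, 3), levels = 2, offset = c(0, 1))
  # 4 horizontal pairs: (0,0) once, (0,1) twice, (1,1) once; symmetrised
  expect_equal(cnt[1, 1], 2)
  expect_equal(cnt[2, 2], 2)
  expect_equal(cnt[1, 2] + cnt[2, 1], 4)
  expect_equal(cnt, t(cnt))
  expect_equal(sum(cnt), 8)
})

test_that("GLCM statistics behave on degenerate and extremal images", {
  v <- glcm_features(const_img(), full_mask())
  expect_equal(unname(v["tex.glcm_energy"]), 1)
  expect_equal(unname(v["tex.glcm_contrast"]), 0)
  expect_equal(unname(v["tex.glcm_homogeneity"]), 1)
  # checkerboard maximises horizontal-offset contrast over all 3x3
  # binary images (exhaustive scan; every pair there is a 0-1 pair)
  h_contrast <- function(m) {
    if (length(unique(as.vector(m))) == 1) return(0)
    cnt <- glcm_counts(m, full_mask(3, 3), levels = 2, offset = c(0, 1))
    p <- cnt / sum(cnt)
    i <- matrix(1:2, 2, 2); j <- t(i)
    sum((i - j)^2 * p)
  }
  combos <- expand.grid(rep(list(0:1), 9))
  contrast <- apply(combos, 1, function(bits)
    h_contrast(matrix(as.numeric(bits), 3, 3) * 255))
  checker <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3) * 255
  expect_equal(h_contrast(checker), max(contrast))
  expect_error(glcm_features(const_img(), matrix(FALSE, 12, 12)), "masked")
})

test_that("run-length extraction matches hand counts", {
  runs <- psoriabench:::mask_runs
  q <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  horiz <- runs(q, c(0L, 1L))
  expect_equal(sort(horiz$lengths), c(2, 2))
  expect_equal(sort(horiz$values), c(1, 2))
  # constant row of length n: a single run, LRE = n^2
  g <- matrix(50, 1, 8)
  v <- glrlm_features(g, matrix(TRUE, 1, 8))
  # horizontal: one run of 8 (LRE 64); the other 3 directions: 8 runs of 1
  expect_equal(unname(v["tex.glrlm_lre"]), (64 + 1 + 1 + 1) / 4)
  # strictly alternating row: all runs length 1 in every direction
  ga <- matrix(rep(c(0, 255), 4), 1, 8)
  va <- glrlm_features(ga, matrix(TRUE, 1, 8))
  expect_equal(unname(va["tex.glrlm_sre"]), 1)
  expect_equal(unname(va["tex.glrlm_rp"]), 1)
})

test_that("intensity histogram features match closed forms", {
  v <- intensity_histogram_features(const_img(), full_mask())
  expect_equal(unname(v["tex.hist_var"]), 0)
  expect_equal(unname(v["tex.hist_energy"]), 1)
  expect_equal(unname(v["tex.hist_entropy"]), 0)
  # symmetric two-point distribution: zero skewness
  g2 <- matrix(rep(c(0, 255), 32), 8, 8)
  v2 <- intensity_histogram_features(g2, full_mask(8, 8))
  expect_equal(unname(v2["tex.hist_skewness"]), 0)
  # uniform over the 64 bins: entropy = 6 bits
  g3 <- matrix(seq(0, 252, by = 4), 8, 8)
  v3 <- intensity_histogram_features(g3, full_mask(8, 8))
  expect_equal(unname(v3["tex.hist_entropy"]), 6)
})

test_that("semi-variogram matches the ramp closed form", {
  v0 <- semivariogram_features(const_img(), full_mask())
  expect_equal(unname(v0[paste0("tex.svar_lag", c(1, 2, 4, 8))]),
               rep(0, 4), ignore_attr = TRUE)
  ramp <- matrix(0:31, 1, 32, byrow = TRUE)
  v <- semivariogram_features(ramp, matrix(TRUE, 1, 32))
  for (h in c(1, 2, 4, 8))
    expect_equal(unname(v[paste0("tex.svar_lag", h)]), h^2 / 2)
})

test_that("uniform LBP histograms behave as specified", {
  v <- lbp_features(const_img(), full_mask())
  expect_equal(unname(v["tex.lbp_u8"]), 1)  # all-ones pattern only
  expect_equal(sum(v), 1)
  # centre smaller than all 8 neighbours: 8 set bits
  g <- matrix(10, 3, 3); g[2, 2] <- 5
  v2 <- lbp_features(g, full_mask(3, 3))
  expect_equal(unname(v2["tex.lbp_u8"]), 1)
  withr::with_seed(3, gr <- matrix(runif(400, 0, 255), 20, 20))
  expect_equal(sum(lbp_features(gr, full_mask(20, 20))), 1)
})

test_that("colour features track the pinned conversions", {
  img <- array(0, c(6, 6, 3)); img[, , 1] <- 255
  v <- color_features(img, full_mask(6, 6))
  sds <- v[grepl("_sd$", names(v))]
  expect_true(all(sds == 0))
  expect_equal(unname(v["col.lab_a_mean"]), 80.1, tolerance = 0.1)
  expect_equal(unname(v["col.lab_b_mean"]), 67.2, tolerance = 0.1)
  expect_equal(unname(v["col.erythema_index"]),
               unname(v["col.lab_a_mean"] - v["col.lab_b_mean"]))
  expect_equal(unname(v["col.hsv_h_mean"]), 0)
  expect_equal(unname(v["col.ycbcr_cr_mean"]), 255, tolerance = 0.01)
})

test_that("Gabor features are DC-free and orientation/frequency selective", {
  v <- gabor_features(const_img(200, 32, 32), full_mask(32, 32))
  expect_true(all(abs(v[grepl("_mean$", names(v))]) < 1e-6))
  # horizontal grating at f = 0.2 (varies along columns)
  x <- matrix(rep(seq_len(48), each = 48), 48, 48)
  grating <- 127.5 + 127.5 * sin(2 * pi * 0.2 * x)
  vg <- gabor_features(grating, full_mask(48, 48))
  means <- vg[grepl("_mean$", names(vg))]
  expect_equal(names(which.max(means)), "spec.gabor_t0_f0.2_mean")
  # magnitude features invariant under image negation
  vn <- gabor_features(255 - grating, full_mask(48, 48))
  expect_equal(unname(vn), unname(vg), tolerance = 1e-8)
})

test_that("Zernike magnitudes carry the promised invariances", {
  withr::with_seed(5, g <- matrix(runif(1600, 0, 255), 40, 40))
  mask <- circle_mask(40, 15)
  v1 <- zernike_features(g, mask)
  # 90 degree rotation of mask and content leaves magnitudes unchanged
  r <- psoriabench:::rot90_mat
  v2 <- zernike_features(r(g), r(mask))
  expect_equal(unname(v1), unname(v2), tolerance = 1e-6)
  # intensity scaling invariance (normalised by the masked mean)
  v3 <- zernike_features(g * 3, mask)
  expect_equal(unname(v1), unname(v3), tolerance = 1e-9)
  # constant disk: moments with m not divisible by 4 cancel exactly on
  # the 4-fold symmetric grid; the rest stay small discretization noise
  vd <- zernike_features(const_img(180, 40, 40), mask)
  m_of <- as.integer(sub(".*_", "", names(vd)))
  z00 <- unname(vd["spec.zernike_0_0"])
  expect_true(all(vd[m_of %% 4 != 0 & m_of != 0] < 1e-6 * z00))
  expect_true(all(vd[m_of != 0] < 0.05 * z00))
})

test_that("extraction is ordered, grouped, deterministic and finite", {
  sc <- generate_scene(lesion_scene_params(image_size = 128,
                                           erythema_score = 3,
                                           scale_score = 2, seed = 17))
  fv_t <- extract_all(sc$image, sc$lesion_mask, groups = "texture")
  fv_c <- extract_all(sc$image, sc$lesion_mask, groups = "color")
  fv_tc <- extract_all(sc$image, sc$lesion_mask, groups = c("texture", "color"))
  expect_identical(names(fv_tc), c(names(fv_t), names(fv_c)))
  expect_length(fv_t, 33)
  expect_length(fv_c, 27)
  fv_s <- extract_all(sc$image, sc$lesion_mask, groups = "spectrum")
  expect_length(fv_s, 49)
  expect_true(all(is.finite(c(fv_t, fv_c, fv_s))))
  expect_identical(extract_all(sc$image, sc$lesion_mask, "color"), fv_c)
  gi <- attr(fv_tc, "group_index")
  expect_identical(names(gi), c("texture", "color"))
  expect_error(extract_all(sc$image, matrix(FALSE, 128, 128)), "empty mask")
})

test_that("rotation-stable features move less than 1% under 90-degree rotation", {
  sc <- generate_scene(lesion_scene_params(image_size = 128,
                                           erythema_score = 3,
                                           scale_score = 2, seed = 23))
  g <- rgb_to_gray(sc$image); m <- sc$lesion_mask
  r <- psoriabench:::rot90_mat
  stable <- c(glcm_features(g, m), lbp_features(g, m), zernike_features(g, m))
  rotated <- c(glcm_features(r(g), r(m)), lbp_features(r(g), r(m)),
               zernike_features(r(g), r(m)))
  rel <- abs(rotated - stable) / pmax(abs(stable), 1e-6)
  expect_lt(max(rel), 0.01)
})

test_that("feature matrices extract from manifests and expose X/y", {
  tmp <- withr::local_tempdir()
  scenes <- generate_dataset(1, tmp, seed = 41, image_size = 96)
  ds <- assemble_dataset(scenes, dataset_spec("A"), tmp,
                         file.path(tmp, "ds"))
  fm <- extract_matrix(ds, file.path(tmp, "ds"), groups = "color")
  expect_true(all(c("filename", "label", "is_patch") %in% names(fm)))
  expect_equal(ncol(fm), 3 + 27)
  # healthy crops fall back to whole-crop statistics: no row is lost
  expect_equal(nrow(fm), nrow(ds))
  xy <- feature_xy(fm)
  expect_equal(nrow(xy$X), nrow(fm))
  expect_true(is.factor(xy$y))
})
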