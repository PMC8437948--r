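test_that("superpixels tessellate a constant image into near-equal cells", {
  img <- array(128, c(100, 100, 3))
  spx <- slic_superpixels(img, slic_params(n_superpixels = 25))
  sizes <- tabulate(spx)
  expect_equal(attr(spx, "n_labels"), 25)
  expect_lt(sd(sizes) / mean(sizes), 0.1)
})

test_that("superpixel maps are partitions with compact labels", {
  withr::with_seed(4, {
    img <- array(as.double(sample(0:255, 60 * 80 * 3, replace = TRUE)),
                 c(60, 80, 3))
  })
  spx <- slic_superpixels(img, slic_params(n_superpixels = 40))
  n <- attr(spx, "n_labels")
  expect_true(all(spx >= 1 & spx <= n))
  expect_setequal(unique(as.vector(spx)), seq_len(n))
  expect_error(slic_superpixels(img, slic_params(n_superpixels = 60 * 80 + 1)),
               "more superpixels")
})

test_that("superpixel count stays near the request on smooth scenes", {
  sc <- generate_scene(lesion_scene_params(image_size = 128,
                                           erythema_score = 3,
                                           scale_score = 1, seed = 2))
  spx <- slic_superpixels(sc$image, slic_params(n_superpixels = 100))
  expect_lt(abs(attr(spx, "n_labels") - 100) / 100, 0.15)
})

test_that("superpixel boundaries recall a disk boundary", {
  fx <- disk_image(size = 128, r = 30, fg = c(190, 60, 60),
                   bg = c(225, 200, 180))
  spx <- slic_superpixels(fx$image, slic_params(n_superpixels = 100))
  # true boundary: disk pixels with a 4-neighbour outside
  inner <- fx$mask
  sh <- psoriabench:::shift_mat
  nb_all <- sh(inner, 1, 0) & sh(inner, -1, 0) & sh(inner, 0, 1) &
    sh(inner, 0, -1)
  er <- inner & !nb_all
  spx_b <- spx != psoriabench:::shift_mat(spx, 0, 1) |
    spx != psoriabench:::shift_mat(spx, 1, 0)
  bp <- which(er, arr.ind = TRUE)
  sb <- which(spx_b, arr.ind = TRUE)
  mind <- apply(bp, 1, function(p)
    min(sqrt((sb[, 1] - p[1])^2 + (sb[, 2] - p[2])^2)))
  expect_gte(mean(mind <= 2), 0.95)
})

test_that("clustering superpixels recovers well-separated colours exactly", {
  # 3 colour bands at mutual Lab distance > 50
  img <- array(0, c(30, 90, 3))
  img[, 1:30, ] <- rep(c(200, 40, 40), each = 30 * 30)
  img[, 31:60, ] <- rep(c(40, 200, 40), each = 30 * 30)
  img[, 61:90, ] <- rep(c(40, 40, 200), each = 30 * 30)
  lab <- rgb_to_lab(img)
  spx <- slic_superpixels(img, slic_params(n_superpixels = 36))
  cl <- cluster_superpixels(spx, lab, n_centers = 3, seed = 5)
  # every band maps to exactly one cluster
  for (cols in list(1:30, 31:60, 61:90))
    expect_equal(length(unique(as.vector(cl[, cols]))), 1)
  expect_equal(length(unique(as.vector(cl))), 3)
  # converged assignment is a fixed point of further iterations
  cl2 <- cluster_superpixels(spx, lab, n_centers = 3, iters = 501, seed = 5)
  expect_identical(as.vector(cl), as.vector(cl2))
})

test_that("degenerate single-colour clustering does not crash", {
  img <- array(120, c(20, 20, 3))
  spx <- slic_superpixels(img, slic_params(n_superpixels = 9))
  cl <- cluster_superpixels(spx, rgb_to_lab(img), n_centers = 3, seed = 1)
  expect_equal(length(unique(as.vector(cl))), 1)  # one effective cluster
  expect_error(cluster_superpixels(spx, rgb_to_lab(img), n_centers = 100),
               "more centers")
})

test_that("lesion-cluster selection rules behave as specified", {
  # synthetic cluster map with controlled mean a*: a large skin cluster
  # (a* = 12) and two smaller red-ish clusters (35, 30)
  lab <- array(0, c(10, 30, 3))
  lab[, , 1] <- 60
  lab[, 1:20, 2] <- 12; lab[, 21:25, 2] <- 35; lab[, 26:30, 2] <- 30
  cl <- matrix(0L, 10, 30)
  cl[, 1:20] <- 1L; cl[, 21:25] <- 2L; cl[, 26:30] <- 3L
  m1 <- select_lesion_clusters(cl, lab, rule = "max_a")
  expect_identical(m1, cl == 2)
  m2 <- select_lesion_clusters(cl, lab, rule = "a_above_median")
  expect_identical(m2, matrix(cl %in% c(2, 3), 10, 30))
  m3 <- select_lesion_clusters(cl, lab, rule = "manual", ids = c(1, 3))
  expect_identical(m3, matrix(cl %in% c(1, 3), 10, 30))
  expect_error(select_lesion_clusters(cl, lab, rule = "nope"))
})

test_that("SLIC segmentation recovers a severe synthetic lesion", {
  sc <- generate_scene(lesion_scene_params(image_size = 192,
                                           erythema_score = 4,
                                           scale_score = 2, seed = 21))
  res <- segment_slic(sc$image)
  expect_gte(dice(res$mask, sc$lesion_mask), 0.85)
  res2 <- segment_slic(sc$image)
  expect_identical(res$mask, res2$mask)  # deterministic
})

test_that("healthy scenes segment to a near-empty mask", {
  sc <- generate_scene(lesion_scene_params(image_size = 192,
                                           erythema_score = 0,
                                           scale_score = 0, seed = 8))
  res <- segment_slic(sc$image)
  expect_lt(mean(res$mask), 0.02)
})

test_that("the level set grows an inner seed to a high-contrast disk", {
  fx <- disk_image(size = 96, r = 30)
  init <- circle_mask(96, 22)
  res <- segment_lsm(fx$image, lsm_params(init))
  expect_gte(dice(res$mask, fx$mask), 0.9)
  expect_identical(res$method, "lsm")
})

test_that("the level set is inert on a constant image", {
  img <- array(120, c(64, 64, 3))
  init <- circle_mask(64, 15)
  res <- segment_lsm(img, lsm_params(init))
  expect_lt(abs(sum(res$mask) - sum(init)) / sum(init), 0.05)
})

test_that("zero diffusion step reduces to pure evolution", {
  fx <- disk_image(size = 64, r = 20)
  init <- circle_mask(64, 14)
  m0 <- segment_lsm(fx$image, lsm_params(init, dt2 = 0))$mask
  m1 <- segment_lsm(fx$image, lsm_params(init, dt2 = 1e-300))$mask
  expect_identical(m0, m1)
  expect_error(lsm_params(matrix(FALSE, 4, 4)), "non-empty")
})
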