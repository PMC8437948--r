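test_that("mRMR demotes a duplicated feature below independent noise", {
  withr::with_seed(2, {
    y <- factor(rep(c("a", "b"), each = 30))
    f1 <- rnorm(60) + 4 * (y == "b")  # informative, spread over many bins
    X <- cbind(f1 = f1, f2 = f1, f3 = rnorm(60))
  })
  rk <- mrmr_rank(X, y)
  expect_identical(rk$order[1], "f1")
  expect_identical(rk$order[2], "f3")
  expect_identical(rk$order[3], "f2")  # the exact duplicate goes last
})

test_that("mRMR greedy matches the exhaustive criterion oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40; p <- sample(3:8, 1)
      y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("f", seq_len(p))))
      X[, 1] <- X[, 1] + as.integer(y)
    })
    expect_identical(mrmr_rank(X, y)$order, oracle_mrmr_order(X, y))
  }
})

test_that("a feature independent of everything ranks last", {
  withr::with_seed(9, {
    y <- factor(rep(c("a", "b"), each = 40))
    X <- cbind(s1 = as.integer(y) + rnorm(80, sd = 0.1),
               s2 = -as.integer(y) + rnorm(80, sd = 0.1),
               noise = rnorm(80))
  })
  rk <- mrmr_rank(X, y)
  expect_identical(rk$order[1], "s1")
  expect_identical(mrmr_rank(X[, 1, drop = FALSE], y)$order, "s1")
  expect_error(mrmr_rank(X, factor(rep("a", 80))), "constant label")
})

test_that("chi-squared scoring matches the perfect-table closed form", {
  withr::with_seed(1, {
    y <- factor(rep(c("a", "b"), each = 10))
    X <- cbind(flat = rep(1, 20),
               perfect = as.numeric(y == "b"),
               rand = rnorm(20))
  })
  rk <- chi2_rank(X, y)
  expect_equal(unname(rk$scores["flat"]), 0)
  expect_equal(unname(rk$scores["perfect"]), 20)  # chi2 = n for a perfect 2x2
  expect_identical(rk$order[1], "perfect")
  # joint row permutation leaves scores unchanged
  withr::with_seed(4, perm <- sample(20))
  rk2 <- chi2_rank(X[perm, ], y[perm])
  expect_equal(rk2$scores, rk$scores)
})

test_that("ReliefF weights separate signal from noise", {
  withr::with_seed(3, {
    y <- factor(rep(c("a", "b"), each = 30))
    X <- cbind(sep = ifelse(y == "a", 0, 5) + rnorm(60, sd = 0.3),
               flat = rep(2, 60),
               n1 = rnorm(60), n2 = rnorm(60))
  })
  rk <- relieff_rank(X, y)
  expect_equal(unname(rk$scores["flat"]), 0)
  expect_gt(unname(rk$scores["sep"]), 0)
  expect_identical(rk$order[1], "sep")
  noise_w <- c()
  for (seed in 1:10) {
    withr::with_seed(seed, {
      Xn <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
    })
    noise_w <- c(noise_w, relieff_rank(Xn, y)$scores)
  }
  expect_lt(abs(mean(noise_w)), 0.05)
  expect_error(relieff_rank(X, factor(rep("a", 60))), "single class")
  expect_warning(relieff_rank(X[c(1:3, 31:60), ], y[c(1:3, 31:60)]),
                 "shrunk")
})

test_that("consensus selection intersects the per-method top sets", {
  mk <- function(method, ord) {
    structure(list(method = method, order = ord,
                   scores = setNames(rev(seq_along(ord)), ord)),
              class = "ranked_features")
  }
  feats <- as.character(1:7)
  r1 <- mk("mrmr", c("1", "2", "3", "4", "5", "6", "7"))
  r2 <- mk("chi2", c("1", "2", "3", "5", "4", "6", "7"))
  r3 <- mk("relieff", c("1", "2", "6", "7", "3", "4", "5"))
  cs <- consensus_select(list(r1, r2, r3), fraction = 4 / 7)
  expect_setequal(cs$selected, c("1", "2"))  # {1234} & {1235} & {1267}
  # identical rankings: selected = the top set itself
  cs2 <- consensus_select(list(r1, r1, r1))
  expect_identical(cs2$selected, head(r1$order, ceiling(2 / 3 * 7)))
  # ceiling arithmetic: p = 9, fraction 2/3 -> 6 members per top set
  r9 <- mk("mrmr", as.character(1:9))
  cs3 <- consensus_select(list(r9, r9, r9))
  expect_length(cs3$per_method_top$mrmr, 6)
  # mismatched universes and empty intersections raise
  expect_error(consensus_select(list(r1, r9, r9)), "universes")
  ra <- mk("mrmr", as.character(1:4))
  rb <- mk("chi2", as.character(c(3, 4, 1, 2)))
  rc <- mk("relieff", as.character(c(2, 1, 4, 3)))
  expect_error(consensus_select(list(ra, rb, rc), fraction = 0.25), "empty")
})

test_that("selected sets shrink (or hold) as the fraction decreases", {
  dat <- planted_features(n = 80, p = 20, seed = 5)
  s_big <- select_features(dat$X, dat$y, fraction = 2 / 3)
  s_small <- select_features(dat$X, dat$y, fraction = 0.4)
  expect_lte(length(s_small$selected), length(s_big$selected))
  expect_lte(length(s_big$selected), ceiling(2 / 3 * 20))
})

test_that("planted informative features survive consensus selection", {
  hits <- 0
  for (seed in 1:5) {
    dat <- planted_features(n = 120, p = 30, n_informative = 5, seed = seed)
    sel <- select_features(dat$X, dat$y)$selected
    if (all(sprintf("f%02d", 1:5) %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("rankings and consensus expose tidy methods", {
  dat <- planted_features(n = 60, p = 10, seed = 2)
  rk <- chi2_rank(dat$X, dat$y)
  td <- tidy(rk)
  expect_identical(td$feature, rk$order)
  cs <- select_features(dat$X, dat$y)
  tc <- tidy(cs)
  expect_true(all(c("mrmr", "chi2", "relieff", "selected") %in% names(tc)))
})
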