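test_that("pointwise sign-flip p-values hit the resolution floor on pure signal", {
  scores <- matrix(1, 20, 5)
  p <- signflip_pointwise(scores, n_perm = 999, seed = 1)
  expect_equal(unname(p), rep(1 / 1000, 5))
})

test_that("pointwise p-values are uniform under the null", {
  set.seed(2)
  scores <- matrix(rnorm(12 * 300), 12, 300)
  p <- signflip_pointwise(scores, n_perm = 500, seed = 3)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))  # discrete p grid
  expect_gt(ks$p.value, 0.01)
})

test_that("Monte-Carlo p-values match exhaustive enumeration at 5 participants", {
  col <- c(0.62, -0.21, 1.13, -0.77, 0.34)  # no near-zero subset sums
  fl <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  exact <- mean(fl %*% col / 5 >= mean(col))
  mc <- signflip_pointwise(matrix(col, 5, 1), n_perm = 40000, seed = 4)
  expect_equal(unname(mc), exact, tolerance = 0.01)
})

test_that("cluster permutation recovers a planted window and only it", {
  set.seed(5)
  scores <- matrix(rnorm(14 * 60), 14, 60)
  scores[, 25:40] <- scores[, 25:40] + 1.1
  cr <- cluster_permutation(scores, n_perm = 1000, seed = 6)
  sig <- significant_clusters(cr)
  expect_equal(nrow(sig), 1)
  expect_lte(abs(sig$start - 25), 2)
  expect_lte(abs(sig$end - 40), 2)
  expect_lt(sig$p, 0.05)
})

test_that("negating the scores with the opposite tail mirrors the clusters", {
  set.seed(7)
  scores <- matrix(rnorm(10 * 40), 10, 40)
  scores[, 10:20] <- scores[, 10:20] + 1.5
  a <- cluster_permutation(scores, n_perm = 500, tail = "greater", seed = 8)
  b <- cluster_permutation(-scores, n_perm = 500, tail = "less", seed = 8)
  expect_equal(a$clusters$start, b$clusters$start)
  expect_equal(a$clusters$mass, -b$clusters$mass)
  expect_equal(a$clusters$p, b$clusters$p)
})

test_that("pure noise yields an empty cluster list most of the time", {
  set.seed(9)
  scores <- matrix(rnorm(10 * 30), 10, 30)
  cr <- cluster_permutation(scores, n_perm = 500, seed = 10)
  expect_true(nrow(significant_clusters(cr)) == 0)
})

test_that("two-sided clusters separate signs", {
  set.seed(11)
  scores <- matrix(rnorm(14 * 50, sd = .5), 14, 50)
  scores[, 5:15] <- scores[, 5:15] + 1.4
  scores[, 30:42] <- scores[, 30:42] - 1.4
  cr <- cluster_permutation(scores, n_perm = 1000, tail = "two.sided",
                            seed = 12)
  sig <- significant_clusters(cr)
  expect_equal(sort(sig$sign), c(-1, 1))
})

test_that("cross-correlation convention: negative peak lag means series 1 leads", {
  t <- seq(0, 5, by = .01)
  x <- exp(-((t - 2) / .3)^2)
  y <- exp(-((t - 2.25) / .3)^2)  # same bump 250 ms later
  cc <- crosscorr_lagged(x, y, max_lag_s = 1, sampling_rate = 100)
  expect_equal(cc$peak_lag, -0.25, tolerance = 1e-9)
  self <- crosscorr_lagged(x, x, max_lag_s = 1, sampling_rate = 100)
  expect_equal(self$peak_lag, 0)
  expect_equal(self$peak_coef, 1, tolerance = 1e-9)
  expect_error(crosscorr_lagged(rep(1, 10), rnorm(10), .1, 100), "constant")
})

test_that("the max-statistic threshold controls false positives on white noise", {
  set.seed(13)
  hits <- replicate(60, {
    x <- rnorm(80); y <- rnorm(80)
    r <- crosscorr_null_threshold(x, y, max_lag_s = .2, sampling_rate = 100,
                                  n_perm = 200)
    any(r$significant)
  })
  expect_lte(mean(hits), 0.15)  # ~5% nominal, 60-sim binomial slack
})

test_that("coupled series show a significant band at the true offset", {
  set.seed(14)
  t <- seq(0, 6, by = .01)
  base <- stats::filter(rnorm(length(t)), rep(1 / 8, 8), sides = 1)
  base[is.na(base)] <- 0
  x <- as.numeric(base) + rnorm(length(t), sd = .05)
  y <- c(rep(0, 10), utils::head(x, -10)) + rnorm(length(t), sd = .05)
  r <- crosscorr_null_threshold(x, y, max_lag_s = .3, sampling_rate = 100,
                                n_perm = 300, seed = 15)
  expect_true(any(r$significant))
  expect_equal(r$peak_lag, -0.1, tolerance = 0.02)
  expect_warning(crosscorr_null_threshold(x, y, .1, 100, n_perm = 1),
                 "degenerate")
})

test_that("bootstrap peak-lag CIs behave at the degenerate extremes", {
  t <- seq(0, 3, by = .02)
  tc <- sin(2 * pi * t / 1.5)
  one <- matrix(rep(tc, 3), 3, byrow = TRUE)  # one participant cloned
  bb <- bootstrap_peak_lag(one, one, max_lag_s = .5, sampling_rate = 50,
                           n_boot = 100, seed = 16)
  expect_equal(bb$ci[1], bb$ci[2])
  expect_equal(bb$peak_lag, 0)
  expect_error(bootstrap_peak_lag(one[1:2, ], one[1:2, ], .5, 50),
               "3 participants")
})

test_that("bootstrap peak-lag CI covers a planted offset", {
  set.seed(17)
  t <- seq(0, 3, by = .02)
  bump <- exp(-((t - 1.2) / .25)^2)
  P <- 12
  s1 <- t(replicate(P, bump + rnorm(length(t), sd = .15)))
  s2 <- t(replicate(P, c(rep(0, 5), utils::head(bump, -5)) +
                      rnorm(length(t), sd = .15)))  # +100 ms
  bb <- bootstrap_peak_lag(s1, s2, max_lag_s = .5, sampling_rate = 50,
                           n_boot = 300, seed = 18)
  expect_lte(bb$ci[1], -0.1)
  expect_gte(bb$ci[2], -0.1)
  expect_lt(diff(bb$ci), 0.3)
})

test_that("outlier-aware correlation excludes leverage points and reports them", {
  set.seed(19)
  x <- rnorm(29)
  y <- 2 * x + rnorm(29, sd = .01)
  r0 <- corr_with_outliers(x, y)
  expect_equal(r0$r, 1, tolerance = 1e-3)
  expect_length(r0$excluded, 0)
  x2 <- c(x, 10); y2 <- c(y, -20)  # one 10-SD leverage point
  r1 <- corr_with_outliers(x2, y2)
  expect_equal(r1$excluded, 30)
  expect_equal(r1$r, 1, tolerance = 1e-3)
  expect_error(corr_with_outliers(rnorm(4), rnorm(4)), "fewer than 5")
})

test_that("correlation p-values are calibrated for independent inputs", {
  set.seed(20)
  p <- replicate(100, corr_with_outliers(rnorm(20), rnorm(20))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("permutation machinery is reproducible and n_perm-stable", {
  set.seed(21)
  scores <- matrix(rnorm(10 * 30, mean = .2), 10, 30)
  p1 <- signflip_pointwise(scores, 2000, seed = 22)
  p2 <- signflip_pointwise(scores, 2000, seed = 22)
  expect_identical(p1, p2)
  p4 <- signflip_pointwise(scores, 4000, seed = 23)
  # doubling n_perm moves p by less than ~3 Monte-Carlo SEs
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_true(all(abs(p4 - p1) < 3 * se + 2e-3))
})
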