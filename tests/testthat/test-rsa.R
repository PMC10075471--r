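test_that("spatiotemporal patterns follow the documented layout", {
  tt <- toy_trials(pitch = c(1, 2, 3))
  dat <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  ep <- epoch_set(dat, seq(0, by = .01, length.out = 5), tt)
  X <- spatiotemporal_patterns(ep, 3, window_samples = 2)
  expect_equal(dim(X), c(3, 8))
  # sample-major: channels at t first, then channels at t-1
  expect_equal(X[2, ], c(dat[2, , 3], dat[2, , 2]))
  X1 <- spatiotemporal_patterns(ep, 3, window_samples = 1)
  expect_equal(X1, dat[, , 3])
  expect_error(spatiotemporal_patterns(ep, 1, 2), "out of range")
  # 64-channel, 2-sample windows give 128-value patterns
  ep64 <- epoch_set(array(0, c(2, 64, 3)), c(0, .01, .02),
                    toy_trials(pitch = c(1, 2)))
  expect_equal(ncol(spatiotemporal_patterns(ep64, 2, 2)), 128)
})

test_that("shrinkage covariance converges to the sample covariance for n >> p", {
  set.seed(20)
  X <- matrix(rnorm(4000 * 6), 4000, 6) %*% diag(c(3, 2, 1, 1, .5, .5))
  S_lw <- shrinkage_covariance(X)
  S_emp <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_lt(attr(S_lw, "gamma"), 0.02)
  rel <- norm(S_lw - S_emp, "F") / norm(S_emp, "F")
  expect_lt(rel, 0.05)
})

test_that("shrinkage guarantees positive definiteness in hard cases", {
  set.seed(21)
  # p > n
  X <- matrix(rnorm(10 * 40), 10, 40)
  S <- shrinkage_covariance(X)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  # a single repeated sample vector: scaled identity fallback
  X2 <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  S2 <- shrinkage_covariance(X2)
  expect_equal(S2 / S2[1, 1], diag(3), ignore_attr = TRUE)
})

test_that("cross-validated distances match a brute-force explicit inverse", {
  # 40 trials, 6 features, well-conditioned; shrinkage forced to 0 so the
  # chol path must equal solve()-based Mahalanobis on identical folds
  set.seed(22)
  n <- 40; p <- 6
  labels <- rep(c("a", "b"), each = n / 2)
  mu <- ifelse(labels == "a", 1.5, -1.5)
  X <- matrix(rnorm(n * p), n, p) + mu
  cfg <- decoding_config(n_folds = 4, n_reps = 1, balance = FALSE,
                         shrinkage = 0, seed = 99)
  D <- crossval_distances(X, labels, cfg)

  # independent oracle: replay the same fold assignment (same child RNG),
  # then compute distances with an explicit matrix inverse
  oracle <- {
    set.seed(cfg$seed)  # replay the fold assignment crossval_distances drew
    fold <- serialdep:::stratified_folds(labels, cfg$n_folds)
    Do <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
    for (k in 1:4) {
      tr <- which(fold != k); te <- which(fold == k)
      mus <- rbind(colMeans(X[tr, ][labels[tr] == "a", ]),
                   colMeans(X[tr, ][labels[tr] == "b", ]))
      resid <- X[tr, ] - mus[match(labels[tr], c("a", "b")), ]
      S <- crossprod(resid) / length(tr)
      Sinv <- solve(S)
      for (i in te) for (ci in 1:2) {
        v <- X[i, ] - mus[ci, ]
        Do[i, ci] <- sqrt(drop(t(v) %*% Sinv %*% v))
      }
    }
    Do
  }
  expect_lt(max(abs(D - oracle)), 1e-8)
})

test_that("well-separated clouds put every trial nearest its own template", {
  set.seed(23)
  labels <- rep(c("a", "b"), each = 24)
  X <- matrix(rnorm(48 * 8, sd = .3), 48, 8)
  X[labels == "a", 1] <- X[labels == "a", 1] + 5
  D <- crossval_distances(X, labels, decoding_config(n_folds = 4,
                                                     n_reps = 2, seed = 1))
  own <- D[cbind(1:48, match(labels, colnames(D)))]
  other <- D[cbind(1:48, 3 - match(labels, colnames(D)))]
  expect_true(all(other > own))
})

test_that("label shuffling destroys the decoding score", {
  set.seed(24)
  labels <- rep(as.character(1:4), each = 12)
  X <- matrix(rnorm(48 * 10), 48, 10) +
    outer(as.numeric(labels), rep(1, 10))
  cfg <- decoding_config(n_folds = 4, n_reps = 2, seed = 5)
  s_real <- distance_regression_score(crossval_distances(X, labels, cfg),
                                      labels)
  sh <- replicate(20, {
    lab2 <- sample(labels)
    distance_regression_score(crossval_distances(X, lab2, cfg), lab2)
  })
  expect_gt(s_real, 0.5)
  expect_lt(abs(mean(sh)), 0.15)
})

test_that("the regression score reduces to hand-computed slopes", {
  # binary feature: slope = other - same distance
  D <- rbind(c(1, 3), c(3, 1))
  colnames(D) <- c("x", "y")  # own-condition distance 1, other 3
  expect_equal(distance_regression_score(D, c("x", "y")), 2)
  # 5 conditions with hand-set distances: slope via closed-form OLS
  d5 <- matrix(5, 1, 5, dimnames = list(NULL, as.character(1:5)))
  d5[1, 2] <- 1  # own condition "2" closer
  # x = (1,0,1,1,1), y = (5,1,5,5,5): slope = mean(diff) - own = 5 - 1
  expect_equal(distance_regression_score(d5, "2"), 4)
})

test_that("confound regression removes the confound but keeps orthogonal signal", {
  set.seed(26)
  n <- 60
  conf <- rep(c("L", "R"), each = n / 2)
  target <- rep(c("a", "b"), times = n / 2)
  pat_conf <- c(rep(4, 5), rep(0, 5))
  pat_tgt <- c(rep(0, 5), rep(3, 5))  # orthogonal to the confound pattern
  X <- outer(ifelse(conf == "L", 1, -1), pat_conf) +
    outer(ifelse(target == "a", 1, -1), pat_tgt) +
    matrix(rnorm(n * 10, sd = .2), n, 10)
  R <- regress_out_condition(X, conf)
  # balanced design: confound condition means equalized exactly
  expect_lt(max(abs(colMeans(R[conf == "L", ]) -
                      colMeans(R[conf == "R", ]))), 1e-10)
  cfg <- decoding_config(n_folds = 4, n_reps = 2, seed = 2)
  s_conf <- distance_regression_score(crossval_distances(R, conf, cfg), conf)
  s_tgt <- distance_regression_score(crossval_distances(R, target, cfg),
                                     target)
  expect_lt(abs(s_conf), 0.3)
  expect_gt(s_tgt, 1)
  expect_warning(regress_out_condition(X, rep("L", n)), "single level")
})

test_that("display smoothing preserves constants and normalizes its kernel", {
  x <- rep(2.5, 40)
  expect_equal(smooth_for_display(x, sampling_rate = 100), x)
  # impulse response sums to ~1 on interior samples (kernel normalization)
  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smooth_for_display(imp, sampling_rate = 100)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_gt(sm[21], sm[20])  # peaked at the impulse
  # sub-2-sample windows are the identity
  expect_equal(smooth_for_display(imp, 10, window_ms = 100), imp)
})

test_that("rep-averaging reduces the variance of the decoding score", {
  set.seed(27)
  labels <- rep(c("a", "b"), each = 16)
  X <- matrix(rnorm(32 * 6), 32, 6) + outer(ifelse(labels == "a", .8, -.8),
                                            rep(1, 6))
  score_sd <- function(reps) {
    s <- vapply(1:12, function(i) {
      cfg <- decoding_config(n_folds = 4, n_reps = reps, seed = 1000 + i)
      distance_regression_score(crossval_distances(X, labels, cfg), labels)
    }, 0)
    stats::sd(s)
  }
  expect_gt(score_sd(1), score_sd(10))
})
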