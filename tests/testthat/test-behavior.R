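test_that("aggregate curves match hand tallies", {
  # 20 hand-built trials, one participant
  tt <- derive_history_columns(toy_trials(
    pitch  = c(1, 3, 3, 5, 2, 3, 4, 3, 1, 3, 3, 2, 5, 3, 3, 4, 3, 1, 3, 3),
    choice = c(0, 1, 0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 1, 1, 0, 0, 1, 1)),
    -1)
  cur <- aggregate_choice_curves(tt, "prev_choice")
  # hand count: trials with prev_choice = 1 and current pitch 3
  sel <- tt$prev_choice == 1 & tt$pitch_level == 3 & !is.na(tt$prev_choice)
  row <- cur[cur$cond == 1 & cur$pitch_level == 3, ]
  expect_equal(row$n, sum(sel))
  expect_equal(row$pct_high, mean(tt$choice[sel]))
  # degenerate: all-high choices give all-1 percents
  tt1 <- derive_history_columns(toy_trials(pitch = c(1, 2, 3, 4, 5),
                                           choice = rep(1, 5)), -1)
  cur1 <- aggregate_choice_curves(tt1, "prev_choice")
  expect_true(all(cur1$pct_high[cur1$n > 0] == 1))
})

test_that("an attractive choice-history effect separates the curves", {
  tt <- simulate_behavior(synth_behavior_config(
    n_participants = 6, n_trials = 500, gamma = c(0, 1.2, 0, 1.7),
    Sigma = diag(0.02, 4), seed = 14))
  cur <- aggregate_choice_curves(tt, "prev_choice")
  hi <- cur$pct_high[cur$cond == 1]
  lo <- cur$pct_high[cur$cond == 0]
  expect_true(all(hi > lo))  # prev-"high" curve sits above at every pitch
})

test_that("the pointwise logistic fit inverts the titration percents", {
  lev <- 1:5
  p <- c(.1, .3, .5, .7, .9)
  tot <- rep(4000, 5)
  set.seed(8)
  succ <- rbinom(5, tot, p)
  fit <- fit_pointwise_logistic(lev, succ, tot)
  expect_false(fit$separation)
  expect_equal(fit$inverse(0.5), 3, tolerance = 0.05)
  expect_equal(fit$inverse(p), lev, tolerance = 0.12)
  # flat data: slope ~ 0
  flat <- fit_pointwise_logistic(lev, rep(500, 5), rep(1000, 5))
  expect_lt(abs(flat$slope), 1e-8)
})

test_that("planted logistic parameters are recovered from Bernoulli draws", {
  set.seed(15)
  lev <- rep(1:5, each = 4000)
  x <- lev - 3
  p <- plogis(0.4 + 0.9 * x)
  y <- rbinom(length(x), 1, p)
  succ <- tapply(y, lev, sum)
  fit <- fit_pointwise_logistic((1:5) - 3, succ, rep(4000, 5))
  expect_equal(fit$slope, 0.9, tolerance = 0.05)
  expect_equal(fit$intercept, 0.4, tolerance = 0.05)
})

test_that("complete separation falls back to a penalized fit", {
  fit <- suppressWarnings(
    fit_pointwise_logistic(1:5, c(0, 0, 0, 20, 20), rep(20, 5)))
  expect_true(fit$separation)
  expect_true(is.finite(fit$slope) && abs(fit$slope) < 15)
})

test_that("distance-binned category bias equals hand arithmetic on a toy", {
  # two participants, fixed sequences; compute cells by hand afterwards
  set.seed(33)
  tt <- trial_table(data.frame(
    participant_id = rep(c("A", "B"), each = 40),
    trial_index = rep(1:40, 2),
    pitch_level = sample(1:5, 80, TRUE),
    choice = rbinom(80, 1, .5),
    motor_response = rbinom(80, 1, .5),
    reaction_time = .5))
  tt <- derive_history_columns(tt, -1)
  res <- category_bias_by_distance(tt, n_perm = 50, n_boot = 50, seed = 2)
  d <- tt[!is.na(tt$prev_choice), ]
  cell <- matrix(NA_real_, 5, 5)
  for (a in 1:5) for (b in 1:5) {
    hi <- d$choice[d$prev_pitch == a & d$pitch_level == b & d$prev_choice == 1]
    lo <- d$choice[d$prev_pitch == a & d$pitch_level == b & d$prev_choice == 0]
    if (length(hi) && length(lo)) cell[a, b] <- mean(hi) - mean(lo)
  }
  dist <- abs(outer(1:5, 1:5, `-`))
  hand <- sapply(0:4, function(k) mean(cell[dist == k], na.rm = TRUE))
  expect_equal(res$effect, hand)
})

test_that("history-independent choices give near-zero distance effects", {
  tt <- simulate_behavior(synth_behavior_config(
    n_participants = 6, n_trials = 800, gamma = c(0, 1.2, 0, 0),
    Sigma = diag(0.02, 4), seed = 19))
  res <- category_bias_by_distance(tt, n_perm = 200, n_boot = 100, seed = 5)
  expect_true(all(abs(res$effect) < 0.08))
  expect_true(all(res$p > 0.001))
})

test_that("a planted attractive bias decays with pitch distance", {
  tt <- simulate_behavior(synth_behavior_config(
    n_participants = 10, n_trials = 1500, gamma = c(0, 1.2, 0, 1.7),
    Sigma = diag(0.02, 4), seed = 27))
  res <- category_bias_by_distance(tt, n_perm = 100, n_boot = 100, seed = 6)
  expect_gt(res$effect[1], res$effect[3])
  expect_gt(res$effect[2], res$effect[4])
  expect_gt(res$effect[1], 0.1)
})

test_that("switch/stay rates are complementary and detect alternation", {
  tt <- toy_trials(pitch = rep(1:5, 4))
  tt$motor_response <- rep(c(0, 1), 10)  # strict alternation
  tt <- derive_history_columns(tt, -1)
  sw <- motor_switch_bias(tt)
  expect_equal(sw$rates$switch_rate, 1)
  expect_equal(sw$rates$switch_rate + sw$rates$stay_rate, 1)
  expect_null(sw$test)  # single participant: no group test
})

test_that("fair coin responses are null-calibrated for the switch test", {
  set.seed(61)
  rej <- replicate(60, {
    df <- do.call(rbind, lapply(1:6, function(i)
      data.frame(participant_id = sprintf("S%d", i), trial_index = 1:60,
                 pitch_level = sample(1:5, 60, TRUE),
                 choice = rbinom(60, 1, .5),
                 motor_response = rbinom(60, 1, .5),
                 reaction_time = .5)))
    tt <- derive_history_columns(trial_table(df), -1)
    sw <- motor_switch_bias(tt)
    sw$test$p.value < 0.05
  })
  # type-I near nominal: 95% binomial band for 60 sims at alpha = .05
  expect_lte(mean(rej), 0.15)
})
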