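#' Aggregate psychometric curves conditioned on trial history
#'
#' Pools trials across participants, drops rows with undefined history, and
#' tabulates the percentage of "high" choices for each current pitch level
#' within each level of the conditioning history feature (previous pitch or
#' previous choice).
#'
#' @param trials a [trial_table()] with history columns.
#' @param condition_on `"prev_pitch"` or `"prev_choice"`.
#' @return data.frame with columns `cond`, `pitch_level`, `n`, `n_high`,
#'   `pct_high` (NA and flagged when a cell is empty).
#' @export
aggregate_choice_curves <- function(trials,
                                    condition_on = c("prev_pitch",
                                                     "prev_choice")) {
  condition_on <- match.arg(condition_on)
  if (!condition_on %in% names(trials))
    stop("derive history columns first", call. = FALSE)
  d <- trials[!is.na(trials[[condition_on]]), , drop = FALSE]
  lev_cond <- sort(unique(d[[condition_on]]))
  grid <- expand.grid(cond = lev_cond, pitch_level = 1:5)
  grid$n <- mapply(function(cv, pl)
    sum(d[[condition_on]] == cv & d$pitch_level == pl), grid$cond,
    grid$pitch_level)
  grid$n_high <- mapply(function(cv, pl)
    sum(d$choice[d[[condition_on]] == cv & d$pitch_level == pl]), grid$cond,
    grid$pitch_level)
  grid$pct_high <- ifelse(grid$n > 0, grid$n_high / grid$n, NA_real_)
  if (anyNA(grid$pct_high))
    attr(grid, "empty_cells") <- grid[is.na(grid$pct_high), 1:2]
  grid[order(grid$cond, grid$pitch_level), ]
}

#' Binomial logistic fit of percent-"high" on pitch level
#'
#' Maximum-likelihood logistic regression of success counts on a stimulus
#' level covariate; used for psychometric curve overlays and for titration
#' (the inverse maps a target percent back to a level). Complete separation
#' is detected and handled by refitting with a Haldane-Anscombe continuity
#' correction (0.5 added to each cell), flagged in the result.
#'
#' @param levels numeric stimulus levels.
#' @param successes,totals per-level "high" counts and trial counts.
#' @return list with `intercept`, `slope`, `fitted` (per level),
#'   `inverse` (function percent -> level), `separation` flag.
#' @export
fit_pointwise_logistic <- function(levels, successes, totals) {
  stopifnot(length(levels) == length(successes),
            length(levels) == length(totals), all(totals > 0))
  fit_once <- function(s, t) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(cbind(s, t - s) ~ levels, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, sep = sep || abs(stats::coef(fit)[2]) > 15)
  }
  r <- fit_once(successes, totals)
  separation <- r$sep
  if (separation)
    r <- fit_once(successes + 0.5, totals + 1)
  cf <- as.numeric(stats::coef(r$fit))
  list(intercept = cf[1], slope = cf[2],
       fitted = unname(stats::fitted(r$fit)),
       inverse = function(p) (stats::qlogis(p) - cf[1]) / cf[2],
       separation = separation)
}

#' Category serial bias as a function of previous-current pitch distance
#'
#' For each of the 25 (previous pitch x current pitch) cells, computes the
#' difference in percent-"high" between trials preceded by a "high" versus a
#' "low" choice, then averages cells by absolute pitch distance (0..4).
#' Significance per distance comes from a trial-order permutation null
#' (orders shuffled within participant, history re-derived), and confidence
#' intervals from a trial-level bootstrap (trials resampled with their
#' attached history).
#'
#' @param trials a [trial_table()] with history columns.
#' @param n_perm,n_boot resampling sizes (study convention: 5000 each).
#' @param tail `"two.sided"` or `"greater"` (attraction-positive).
#' @param seed integer seed.
#' @return data.frame: `distance`, `effect`, `ci_lo`, `ci_hi`, `p`,
#'   `n_cells`.
#' @export
category_bias_by_distance <- function(trials, n_perm = 5000, n_boot = 5000,
                                      tail = c("two.sided", "greater"),
                                      seed = NULL) {
  tail <- match.arg(tail)
  d <- trials[!is.na(trials$prev_choice) & !is.na(trials$prev_pitch), ,
              drop = FALSE]
  eff_by_dist <- function(pp, cp, pc, ch) {
    cell <- matrix(NA_real_, 5, 5)
    for (a in 1:5) for (b in 1:5) {
      hi <- ch[pp == a & cp == b & pc == 1L]
      lo <- ch[pp == a & cp == b & pc == 0L]
      if (length(hi) && length(lo)) cell[a, b] <- mean(hi) - mean(lo)
    }
    dist <- abs(outer(1:5, 1:5, `-`))
    vapply(0:4, function(k) mean(cell[dist == k], na.rm = TRUE), 0)
  }
  obs <- eff_by_dist(d$prev_pitch, d$pitch_level, d$prev_choice, d$choice)
  n_cells <- vapply(0:4, function(k) sum(abs(outer(1:5, 1:5, `-`)) == k), 0L)

  with_seed(seed, {
    # permutation: shuffle trial order within participant, re-derive history
    pid <- d$participant_id
    perm_stats <- matrix(NA_real_, n_perm, 5)
    for (r in seq_len(n_perm)) {
      pp <- pc <- rep(NA_real_, nrow(d))
      for (g in split(seq_len(nrow(d)), pid)) {
        ord <- sample(g)
        pp[ord[-1]] <- d$pitch_level[ord[-length(ord)]]
        pc[ord[-1]] <- d$choice[ord[-length(ord)]]
      }
      ok <- !is.na(pp)
      perm_stats[r, ] <- eff_by_dist(pp[ok], d$pitch_level[ok], pc[ok],
                                     d$choice[ok])
    }
    p <- vapply(1:5, function(k) {
      nn <- perm_stats[is.finite(perm_stats[, k]), k]
      if (!length(nn) || !is.finite(obs[k])) return(NA_real_)
      if (tail == "greater") (1 + sum(nn >= obs[k])) / (length(nn) + 1)
      else (1 + sum(abs(nn) >= abs(obs[k]))) / (length(nn) + 1)
    }, 0)

    boot_stats <- matrix(NA_real_, n_boot, 5)
    for (r in seq_len(n_boot)) {
      idx <- unlist(lapply(split(seq_len(nrow(d)), pid), function(g)
        sample(g, replace = TRUE)), use.names = FALSE)
      boot_stats[r, ] <- eff_by_dist(d$prev_pitch[idx], d$pitch_level[idx],
                                     d$prev_choice[idx], d$choice[idx])
    }
    ci <- apply(boot_stats, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    data.frame(distance = 0:4, effect = obs, ci_lo = ci[1, ], ci_hi = ci[2, ],
               p = p, n_cells = n_cells)
  })
}

#' Motor switch/stay serial bias
#'
#' Per participant, the switch rate is the proportion of trials whose motor
#' response differs from the previous trial's; stay = 1 - switch by
#' construction. The group test is a paired t test of switch against stay
#' rates (equivalently, a one-sample t of switch - stay against 0).
#'
#' @param trials a [trial_table()] with `prev_motor` derived.
#' @return list with `rates` (per-participant data.frame) and `test`
#'   (htest, NULL with < 2 participants).
#' @export
motor_switch_bias <- function(trials) {
  if (!"prev_motor" %in% names(trials))
    stop("derive history columns first", call. = FALSE)
  d <- trials[!is.na(trials$prev_motor), , drop = FALSE]
  sw <- tapply(d$motor_response != d$prev_motor, d$participant_id, mean)
  rates <- data.frame(participant_id = names(sw),
                      switch_rate = as.numeric(sw),
                      stay_rate = 1 - as.numeric(sw))
  test <- if (nrow(rates) >= 2L)
    stats::t.test(rates$switch_rate - rates$stay_rate) else NULL
  list(rates = rates, test = test)
}
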