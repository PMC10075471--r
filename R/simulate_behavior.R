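#' Configuration for the behavioral generator
#'
#' Trials are generated from the mixed-effects logistic choice model used for
#' analysis: participant i's choice on trial j is Bernoulli with
#' logit p = b0i + b1i * pitch + b2i * prev_pitch + b3i * prev_choice, where
#' b_i = gamma + mu_i and mu_i ~ N(0, Sigma). Pitch levels 1..5 enter through
#' `pitch_coding` (centered equal-spaced scores by default) and the previous
#' choice is centered to -0.5/+0.5. The first trial of each participant uses
#' zero history terms (cold start); model fitting drops those rows.
#'
#' @param n_participants,n_trials design size (default 30 participants x
#'   2000 trials, the study's session size).
#' @param gamma length-4 fixed effects: intercept, current pitch,
#'   previous pitch, previous choice. Defaults plant the qualitative result
#'   pattern: repulsive pitch history (negative), attractive choice history
#'   (positive).
#' @param Sigma 4x4 random-effect covariance (symmetric PSD).
#' @param pitch_coding numeric scores for levels 1..5.
#' @param switch_prob probability that the motor response switches sides
#'   between consecutive trials when the tone carries no evidence; 0.5 means
#'   no planted motor bias. Implemented as a logit nudge qlogis(switch_prob)
#'   toward the switching response.
#' @param block_size trials per block; pitch levels are balanced and shuffled
#'   within blocks (must be a multiple of 5).
#' @param rt_meanlog,rt_sdlog lognormal reaction-time parameters (seconds).
#' @param seed integer seed; same seed gives a bitwise-identical table.
#' @export
synth_behavior_config <- function(n_participants = 30, n_trials = 2000,
                                  gamma = c(0, 1.2, -0.8, 1.7),
                                  Sigma = diag(c(0.3, 0.2, 0.2, 0.3)^2),
                                  pitch_coding = -2:2,
                                  switch_prob = 0.5,
                                  block_size = 100,
                                  rt_meanlog = log(0.5), rt_sdlog = 0.25,
                                  seed = NULL) {
  stopifnot(length(gamma) == 4, length(pitch_coding) == 5)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) ||
      min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("Sigma must be symmetric positive semidefinite", call. = FALSE)
  if (switch_prob < 0 || switch_prob > 1)
    stop("switch_prob must be in [0, 1]", call. = FALSE)
  if (block_size %% 5 != 0)
    stop("block_size must be a multiple of 5", call. = FALSE)
  if (n_trials %% block_size != 0)
    stop("n_trials must be a multiple of block_size", call. = FALSE)
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 gamma = as.numeric(gamma), Sigma = Sigma,
                 pitch_coding = as.numeric(pitch_coding),
                 switch_prob = switch_prob, block_size = block_size,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog, seed = seed),
            class = "synth_behavior_config")
}

# Draw from N(0, Sigma) via eigendecomposition (PSD-safe).
rmvn <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Simulate behavioral trial tables with planted serial bias
#'
#' @param cfg a [synth_behavior_config()].
#' @return a [trial_table()] with history columns derived and a
#'   `ground_truth` attribute (planted gamma, per-participant slopes).
#' @export
simulate_behavior <- function(cfg = synth_behavior_config()) {
  stopifnot(inherits(cfg, "synth_behavior_config"))
  with_seed(cfg$seed, {
    beta <- sweep(rmvn(cfg$n_participants, cfg$Sigma), 2, cfg$gamma, `+`)
    delta <- stats::qlogis(cfg$switch_prob)
    n_blocks <- cfg$n_trials %/% cfg$block_size
    res <- vector("list", cfg$n_participants)
    for (i in seq_len(cfg$n_participants)) {
      pitch <- unlist(lapply(seq_len(n_blocks), function(b)
        sample(rep(1:5, cfg$block_size / 5))))
      x <- cfg$pitch_coding[pitch]
      cue <- stats::rbinom(cfg$n_trials, 1L, 0.5)
      m_high <- ifelse(cue == 1L, 0L, 1L)  # hand pressed if choice = "high"
      choice <- integer(cfg$n_trials)
      motor <- integer(cfg$n_trials)
      xp <- 0; cp <- 0; pm <- NA_integer_
      for (j in seq_len(cfg$n_trials)) {
        s <- if (is.na(pm) || delta == 0) 0 else
          (m_high[j] != pm) - (m_high[j] == pm)  # +1 if "high" switches hand
        p <- stats::plogis(beta[i, 1] + beta[i, 2] * x[j] +
                           beta[i, 3] * xp + beta[i, 4] * cp + delta * s)
        choice[j] <- stats::rbinom(1L, 1L, p)
        motor[j] <- if (choice[j] == 1L) m_high[j] else 1L - m_high[j]
        xp <- x[j]; cp <- choice[j] - 0.5; pm <- motor[j]
      }
      res[[i]] <- data.frame(
        participant_id = sprintf("P%02d", i),
        block = rep(seq_len(n_blocks), each = cfg$block_size),
        trial_index = seq_len(cfg$n_trials),
        pitch_level = pitch, choice = choice, motor_response = motor,
        cue_mapping = cue,
        reaction_time = stats::rlnorm(cfg$n_trials, cfg$rt_meanlog,
                                      cfg$rt_sdlog),
        valid = TRUE)
    }
    tt <- trial_table(do.call(rbind, res))
    tt <- derive_history_columns(tt, -1L)
    tt <- derive_history_columns(tt, +1L)
    attr(tt, "ground_truth") <- list(gamma = cfg$gamma, Sigma = cfg$Sigma,
                                     beta = beta,
                                     switch_prob = cfg$switch_prob)
    tt
  })
}
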