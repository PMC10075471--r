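#' Condition templates: pseudo-orthogonal channel patterns
#'
#' Builds one unit-norm spatial pattern per condition by orthonormalizing a
#' seeded Gaussian random matrix (QR). With more conditions than channels the
#' surplus patterns are random unit vectors and separation degrades (warned).
#'
#' @param n_channels number of channels.
#' @param levels number of conditions (>= 2) or a vector of condition labels.
#' @param seed integer seed; same seed gives identical templates.
#' @return a `template_set`: list with `patterns` (channels x conditions,
#'   unit-norm columns) and `labels`.
#' @export
make_condition_templates <- function(n_channels, levels, seed = NULL) {
  labels <- if (length(levels) == 1L) seq_len(levels) else levels
  k <- length(labels)
  if (k < 2L) stop("need at least 2 condition levels", call. = FALSE)
  with_seed(seed, {
    if (k > n_channels) {
      warning("more conditions than channels; template separation degrades")
      m <- matrix(stats::rnorm(n_channels * k), n_channels, k)
      patterns <- sweep(m, 2, sqrt(colSums(m^2)), `/`)
    } else {
      m <- matrix(stats::rnorm(n_channels * k), n_channels, k)
      patterns <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
    }
    colnames(patterns) <- as.character(labels)
    structure(list(patterns = patterns, labels = labels),
              class = "template_set")
  })
}

# Smoothly ramped rectangular activation envelope on a time axis.
# onset/offset in seconds; cosine ramps of `ramp` seconds inside the window.
envelope_window <- function(times, onset, offset, ramp = 0.05) {
  e <- numeric(length(times))
  inside <- times >= onset & times <= offset
  e[inside] <- 1
  if (ramp > 0) {
    up <- inside & times < onset + ramp
    dn <- inside & times > offset - ramp
    e[up] <- 0.5 - 0.5 * cos(pi * (times[up] - onset) / ramp)
    e[dn] <- 0.5 - 0.5 * cos(pi * (offset - times[dn]) / ramp)
  }
  e
}

#' Configuration for the epoch generator
#'
#' Each trial's epoch is a sum over features (pitch, category choice, motor
#' response) of (i) the current condition's template, morphed a fraction
#' `shift_lambda` along the chord toward (positive) or away from (negative)
#' the previous trial's template, gated by a feature-specific activation
#' envelope; (ii) a reactivation of the previous trial's template with gain
#' `reactivation_gain` inside the reactivation window; plus (iii) spatially
#' correlated Gaussian noise, white in time. Pitch and category envelopes are
#' locked to the tone onset, the motor envelope to the response-cue onset,
#' mirroring the task structure.
#'
#' @param n_channels,sampling_rate array geometry (defaults 64 ch, 100 Hz).
#' @param t_start,t_end epoch window in seconds relative to noise onset.
#' @param tone_onset,cue_onset event times (seconds); defaults follow the
#'   first experiment's timing (tone 1 s after noise onset, cue at tone
#'   offset 0.25 s later).
#' @param windows named list per feature (`pitch`, `category`, `motor`) of
#'   `c(onset, offset)` in seconds. Defaults place pitch/category activation
#'   after the tone and motor activation after the cue.
#' @param amplitude named numeric: template amplitude at envelope peak
#'   (the SNR, since templates are unit-norm and `noise_sd` scales noise).
#' @param reactivation_gain named numeric >= 0: amplitude of the *previous*
#'   trial's template inside `react_windows` (default: the feature's own
#'   activation window, so reactivations co-occur with current encoding).
#' @param shift_lambda named numeric in (-1, 1): morph fraction along the
#'   chord from the current toward the previous template (negative values
#'   extrapolate away, i.e. repulsion).
#' @param react_windows optional named list overriding reactivation windows.
#' @param noise_sd per-channel noise SD; `noise_length` the exponential
#'   spatial-correlation length in channel index units.
#' @param seed integer seed (templates and noise both derive from it).
#' @export
synth_neural_config <- function(n_channels = 64, sampling_rate = 100,
                                t_start = 0, t_end = 2.25,
                                tone_onset = 1, cue_onset = 1.25,
                                windows = NULL,
                                amplitude = c(pitch = 1, category = 1,
                                              motor = 1),
                                reactivation_gain = c(pitch = 0,
                                                      category = 0,
                                                      motor = 0),
                                shift_lambda = c(pitch = 0, category = 0,
                                                 motor = 0),
                                react_windows = NULL,
                                noise_sd = 1, noise_length = 5,
                                seed = NULL) {
  if (is.null(windows))
    windows <- list(pitch = tone_onset + c(0.08, 1.14),
                    category = tone_onset + c(0.08, 0.93),
                    motor = cue_onset + c(0.04, 0.99))
  feats <- c("pitch", "category", "motor")
  amplitude <- amplitude[feats]; amplitude[is.na(amplitude)] <- 0
  reactivation_gain <- reactivation_gain[feats]
  reactivation_gain[is.na(reactivation_gain)] <- 0
  shift_lambda <- shift_lambda[feats]; shift_lambda[is.na(shift_lambda)] <- 0
  names(amplitude) <- names(reactivation_gain) <- names(shift_lambda) <- feats
  if (any(abs(shift_lambda) >= 1))
    stop("|shift_lambda| must be < 1", call. = FALSE)
  if (any(reactivation_gain < 0))
    stop("reactivation_gain must be >= 0", call. = FALSE)
  if (is.null(react_windows)) react_windows <- windows
  for (w in c(windows, react_windows))
    if (w[1] < t_start || w[2] > t_end)
      stop("activation window outside the epoch", call. = FALSE)
  structure(list(n_channels = n_channels, sampling_rate = sampling_rate,
                 t_start = t_start, t_end = t_end,
                 tone_onset = tone_onset, cue_onset = cue_onset,
                 windows = windows, react_windows = react_windows,
                 amplitude = amplitude,
                 reactivation_gain = reactivation_gain,
                 shift_lambda = shift_lambda,
                 noise_sd = noise_sd, noise_length = noise_length,
                 seed = seed),
            class = "synth_neural_config")
}

# Feature value columns in a trial table, per feature name.
feature_columns <- function() {
  list(pitch = c(cur = "pitch_level", prev = "prev_pitch"),
       category = c(cur = "choice", prev = "prev_choice"),
       motor = c(cur = "motor_response", prev = "prev_motor"))
}

#' Simulate epoched multichannel data with planted feature codes
#'
#' @param trials one participant's [trial_table()] rows, with history columns
#'   derived (see [derive_history_columns()]).
#' @param cfg a [synth_neural_config()].
#' @return an [epoch_set()] whose `templates` attribute holds the planted
#'   `template_set` per feature.
#' @export
simulate_epochs <- function(trials, cfg = synth_neural_config()) {
  stopifnot(inherits(cfg, "synth_neural_config"))
  if (length(unique(trials$participant_id)) != 1L)
    stop("simulate_epochs generates one participant at a time", call. = FALSE)
  if (!"prev_pitch" %in% names(trials))
    stop("derive history columns before simulating epochs", call. = FALSE)
  feats <- c("pitch", "category", "motor")
  n_levels <- c(pitch = 5L, category = 2L, motor = 2L)
  with_seed(cfg$seed, {
    # one orthonormal basis across all features so feature codes don't mix
    basis <- make_condition_templates(cfg$n_channels, sum(n_levels))
    ofs <- c(0L, cumsum(n_levels))[1:3]
    templates <- stats::setNames(lapply(seq_along(feats), function(k) {
      p <- basis$patterns[, ofs[k] + seq_len(n_levels[k]), drop = FALSE]
      lv <- if (feats[k] == "pitch") 1:5 else 0:1
      colnames(p) <- as.character(lv)
      structure(list(patterns = p, labels = lv), class = "template_set")
    }), feats)

    times <- seq(cfg$t_start, cfg$t_end, by = 1 / cfg$sampling_rate)
    ns <- length(times); nch <- cfg$n_channels; ntr <- nrow(trials)
    env <- lapply(feats, function(f)
      envelope_window(times, cfg$windows[[f]][1], cfg$windows[[f]][2]))
    renv <- lapply(feats, function(f)
      envelope_window(times, cfg$react_windows[[f]][1],
                      cfg$react_windows[[f]][2]))
    names(env) <- names(renv) <- feats

    C <- exp(-abs(outer(1:nch, 1:nch, `-`)) / cfg$noise_length)
    L <- t(chol(C))
    cols <- feature_columns()
    dat <- array(0, c(ntr, nch, ns))
    n_skipped_react <- 0L
    for (tr in seq_len(ntr)) {
      sig <- matrix(0, nch, ns)
      for (f in feats) {
        cur <- as.character(trials[[cols[[f]]["cur"]]][tr])
        prev <- trials[[cols[[f]]["prev"]]][tr]
        tpl <- templates[[f]]$patterns
        lam <- cfg$shift_lambda[[f]]
        pat <- tpl[, cur]
        # chord morph: positive lambda moves the pattern toward the
        # previous template, negative extrapolates away from it
        if (!is.na(prev) && lam != 0)
          pat <- (1 - lam) * pat + lam * tpl[, as.character(prev)]
        sig <- sig + cfg$amplitude[[f]] * pat %o% env[[f]]
        g <- cfg$reactivation_gain[[f]]
        if (g > 0) {
          if (is.na(prev)) n_skipped_react <- n_skipped_react + 1L
          else sig <- sig + g * tpl[, as.character(prev)] %o% renv[[f]]
        }
      }
      noise <- cfg$noise_sd * (L %*% matrix(stats::rnorm(nch * ns), nch, ns))
      dat[tr, , ] <- sig + noise
    }
    if (n_skipped_react > 0L)
      message(n_skipped_react,
              " feature reactivation(s) skipped (undefined history)")
    ep <- epoch_set(dat, times, trials,
                    events = c(tone_onset = cfg$tone_onset,
                               cue_onset = cfg$cue_onset))
    attr(ep, "templates") <- templates
    ep
  })
}

#' Simulate a full multi-participant experiment (behavior + epochs)
#'
#' Convenience wrapper: draws one behavioral table, then per participant an
#' epoch set from a participant-specific child seed. `neural_cfg` may be a
#' single config (shared planted parameters) or a list of per-participant
#' configs (e.g. heterogeneous shift strengths).
#'
#' @param behavior_cfg a [synth_behavior_config()].
#' @param neural_cfg a [synth_neural_config()] or list of them.
#' @return list with `trials` (combined table) and `epochs`
#'   (list of epoch_set, one per participant).
#' @export
simulate_experiment <- function(behavior_cfg, neural_cfg) {
  tt <- simulate_behavior(behavior_cfg)
  pids <- unique(tt$participant_id)
  per <- inherits(neural_cfg, "synth_neural_config")
  epochs <- lapply(seq_along(pids), function(i) {
    cfg <- if (per) neural_cfg else neural_cfg[[i]]
    cfg$seed <- child_seed(cfg$seed %||% behavior_cfg$seed, i)
    sub <- tt[tt$participant_id == pids[i], , drop = FALSE]
    class(sub) <- class(tt)
    simulate_epochs(sub, cfg)
  })
  names(epochs) <- pids
  list(trials = tt, epochs = epochs)
}
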