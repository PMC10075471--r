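# Shared builders for the test suite. Everything is generated in code; the
# sizes are deliberately small so the whole suite runs in minutes.

# A hand-written minimal trial table (one participant unless stated).
toy_trials <- function(pitch = c(2, 3, 5), choice = NULL,
                       pid = "P01") {
  n <- length(pitch)
  trial_table(data.frame(
    participant_id = pid,
    trial_index = seq_len(n),
    pitch_level = pitch,
    choice = choice %||% rep_len(c(0, 1), n),
    motor_response = rep_len(c(0, 1), n),
    cue_mapping = rep_len(c(1, 0), n),
    reaction_time = 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic experiment used by decoding/shift tests: compressed
# timing (tone 0.3 s, cue 0.55 s after noise onset), few channels.
quick_neural_cfg <- function(..., seed = 1) {
  args <- list(...)
  defaults <- list(
    n_channels = 16, sampling_rate = 50, t_start = 0, t_end = 1.2,
    tone_onset = 0.3, cue_onset = 0.55,
    windows = list(pitch = c(0.38, 1.10), category = c(0.38, 1.00),
                   motor = c(0.60, 1.10)),
    amplitude = c(pitch = 4, category = 4, motor = 4),
    noise_sd = 1, seed = seed)
  do.call(synth_neural_config, utils::modifyList(defaults, args))
}

quick_cfg <- function(...) {
  args <- utils::modifyList(list(n_folds = 4, n_reps = 2, seed = 7),
                            list(...))
  do.call(decoding_config, args)
}

# Epoch set with hand-placed constant patterns (no time structure):
# `patterns` is trials x channels; replicated at `ns` samples.
static_epochs <- function(patterns, trials, ns = 3, sr = 50) {
  dat <- array(0, c(nrow(patterns), ncol(patterns), ns))
  for (s in seq_len(ns)) dat[, , s] <- patterns
  epoch_set(dat, seq(0, by = 1 / sr, length.out = ns), trials)
}
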