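#' Construct and validate a trial table
#'
#' A trial table is the behavioral record of an auditory categorization
#' session: one row per trial, ordered within participant. The five pitch
#' levels (`pitch_level` 1..5) are the individually titrated probe tones
#' spanning the low/high category boundary; `choice` is the reported category
#' (1 = "high", 0 = "low"); `motor_response` is the hand used (0 = left,
#' 1 = right); `cue_mapping` records which side of the response cue showed
#' "high" (1 = left). History columns (`prev_*`, `next_*`) are derived with
#' [derive_history_columns()] and are `NA` at participant boundaries and
#' across removed trials.
#'
#' @param df data.frame with at least `participant_id`, `trial_index`,
#'   `pitch_level`, `choice`. Optional: `block`, `motor_response`,
#'   `cue_mapping`, `reaction_time`, `valid`.
#' @return a `trial_table` (a validated data.frame sorted by participant and
#'   trial index).
#' @export
trial_table <- function(df) {
  mandatory <- c("participant_id", "trial_index", "pitch_level", "choice")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("trial table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$participant_id <- as.character(df$participant_id)
  df$trial_index <- as.integer(df$trial_index)
  df$pitch_level <- as.integer(df$pitch_level)
  bad <- which(!df$pitch_level %in% 1:5)
  if (length(bad))
    stop("pitch_level outside 1..5 in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  for (col in c("choice", "motor_response", "cue_mapping")) {
    if (col %in% names(df)) {
      df[[col]] <- as.integer(df[[col]])
      bad <- which(!is.na(df[[col]]) & !df[[col]] %in% 0:1)
      if (length(bad))
        stop(sprintf("%s must be 0/1; offending row(s): %s", col,
                     paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
    }
  }
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df <- df[order(df$participant_id, df$trial_index), , drop = FALSE]
  dup <- stats::ave(df$trial_index, df$participant_id,
                    FUN = function(x) duplicated(x))
  if (any(dup == 1))
    stop("trial_index must be unique within participant", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read / write a trial table from delimited text
#'
#' Plain CSV/TSV with a mandatory header; the delimiter is sniffed from the
#' first line. Columns are validated by [trial_table()].
#'
#' @param path file path.
#' @return a `trial_table`.
#' @export
read_trial_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tt <- trial_table(df)
  message(sprintf("read %d trials / %d participant(s) from %s",
                  nrow(tt), length(unique(tt$participant_id)), path))
  tt
}

#' @rdname read_trial_table
#' @param trials a `trial_table`.
#' @param sep field delimiter (default tab).
#' @export
write_trial_table <- function(trials, path, sep = "\t") {
  utils::write.table(as.data.frame(trials), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive trial-history columns
#'
#' Adds the features of the trial at `trial_index + offset` within the same
#' participant (offset -1 gives `prev_*`, +1 gives `next_*`). Lookup is by
#' trial index, not row position, so a removed trial leaves `NA` in its
#' neighbours' history columns (chain-break semantics) rather than silently
#' pairing trials that were not consecutive in the session.
#'
#' @param trials a `trial_table`.
#' @param offset signed integer trial offset (default -1).
#' @param features columns to shift (default pitch, choice, motor).
#' @return the table with added/overwritten history columns.
#' @export
derive_history_columns <- function(trials, offset = -1L,
                                   features = c("pitch_level", "choice",
                                                "motor_response")) {
  stopifnot(is.data.frame(trials))
  offset <- as.integer(offset)
  if (offset == 0L) stop("offset must be nonzero", call. = FALSE)
  features <- intersect(features, names(trials))
  prefix <- if (offset < 0L) "prev" else "next"
  nice <- c(pitch_level = "pitch", choice = "choice",
            motor_response = "motor")
  counts <- table(trials$participant_id)
  if (length(counts) && abs(offset) >= max(counts))
    warning("`offset` exceeds every participant's trial count; ",
            "history columns are all NA")
  out <- trials
  for (f in features) {
    col <- paste0(prefix, "_", nice[[f]] %||% f)
    out[[col]] <- NA
    for (pid in names(counts)) {
      rows <- which(out$participant_id == pid)
      idx <- match(out$trial_index[rows] + offset, out$trial_index[rows])
      out[[col]][rows] <- out[[f]][rows][idx]
    }
  }
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Trial filtering specification
#'
#' @param rt_sd_threshold remove trials whose reaction time exceeds the
#'   participant mean by more than this many SDs (default 4; `Inf` disables).
#' @param exclude_prev_levels pitch levels of the *previous* trial whose
#'   followers are excluded from analysis (e.g. `c(1, 5)` to drop trials
#'   preceded by the unambiguous extreme pitches); these exclusions subset
#'   the analysis set but do not break their neighbours' history chains.
#' @param require_valid drop rows flagged invalid.
#' @export
filter_spec <- function(rt_sd_threshold = 4, exclude_prev_levels = integer(),
                        require_valid = TRUE) {
  if (!is.numeric(rt_sd_threshold) || length(rt_sd_threshold) != 1L ||
      is.na(rt_sd_threshold) || rt_sd_threshold <= 0)
    stop("`rt_sd_threshold` must be a positive scalar (Inf disables the rule)",
         call. = FALSE)
  structure(list(rt_sd_threshold = rt_sd_threshold,
                 exclude_prev_levels = as.integer(exclude_prev_levels),
                 require_valid = isTRUE(require_valid)),
            class = "filter_spec")
}

#' Apply trial filters (and subset linked epochs consistently)
#'
#' Reaction-time outliers (per participant, RT > mean + k*SD) and invalid
#' trials are removed first; history columns are then re-derived so removed
#' trials break the chain. The previous-pitch exclusion is applied last, as
#' an analysis subset: history columns of retained rows are kept as derived
#' from the full sequence.
#'
#' @param trials a `trial_table`.
#' @param epochs optional [epoch_set()] linked to `trials`; subset in step.
#' @param spec a [filter_spec()].
#' @return list with elements `trials`, `epochs` (NULL if none given) and
#'   `n_removed` (named counts per rule).
#' @export
apply_filters <- function(trials, epochs = NULL, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(trials))
  n_rt <- 0L; n_valid <- 0L
  if (spec$require_valid && "valid" %in% names(trials)) {
    n_valid <- sum(!trials$valid)
    keep <- keep & trials$valid
  }
  if (is.finite(spec$rt_sd_threshold) && "reaction_time" %in% names(trials)) {
    rt <- trials$reaction_time
    mu <- stats::ave(rt, trials$participant_id, FUN = mean)
    sdv <- stats::ave(rt, trials$participant_id, FUN = stats::sd)
    sdv[is.na(sdv)] <- 0  # single-trial participants: no RT rule
    out_rt <- !is.na(rt) & rt > mu + spec$rt_sd_threshold * sdv
    n_rt <- sum(out_rt & keep)
    keep <- keep & !out_rt
  }
  tt <- trials[keep, , drop = FALSE]
  class(tt) <- c("trial_table", "data.frame")
  tt <- derive_history_columns(tt, -1L)
  if (any(grepl("^next_", names(trials))))
    tt <- derive_history_columns(tt, +1L)
  n_prev <- 0L
  if (length(spec$exclude_prev_levels)) {
    drop_prev <- !is.na(tt$prev_pitch) &
      tt$prev_pitch %in% spec$exclude_prev_levels
    n_prev <- sum(drop_prev)
    tt <- tt[!drop_prev, , drop = FALSE]
    class(tt) <- c("trial_table", "data.frame")
  }
  empty <- setdiff(unique(trials$participant_id), unique(tt$participant_id))
  if (length(empty))
    warning("all trials removed for participant(s): ",
            paste(empty, collapse = ", "))
  ep <- NULL
  if (!is.null(epochs)) {
    sel <- match(interaction(tt$participant_id, tt$trial_index),
                 interaction(epochs$trials$participant_id,
                             epochs$trials$trial_index))
    if (anyNA(sel))
      stop("epochs do not cover all retained trials", call. = FALSE)
    ep <- subset_epochs(epochs, sel)
    ep$trials <- tt
  }
  list(trials = tt, epochs = ep,
       n_removed = c(invalid = n_valid, rt = n_rt, prev_level = n_prev))
}
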