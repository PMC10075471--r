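#' Epoched multichannel data container
#'
#' Holds one participant's preprocessed epochs as a trials x channels x
#' samples array with a uniform time axis (seconds, 0 = white-noise onset by
#' convention), channel labels, event annotations (e.g. tone and response-cue
#' onsets), and the linked trial metadata table (one row per epoch).
#'
#' @param data numeric array, trials x channels x samples, all finite.
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param trials a [trial_table()] with exactly one row per epoch.
#' @param channel_labels character vector (default "ch01".."chNN").
#' @param events named numeric vector of event onsets in seconds
#'   (e.g. `c(tone_onset = 1, cue_onset = 1.25)`).
#' @return an `epoch_set`.
#' @export
epoch_set <- function(data, times, trials, channel_labels = NULL,
                      events = numeric()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)",
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (length(times) != dim(data)[3L])
    stop("length(times) must equal the sample dimension", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0) || (length(dt) > 1L && max(abs(dt - dt[1L])) > 1e-9))
    stop("`times` must be strictly increasing and uniform", call. = FALSE)
  if (nrow(trials) != dim(data)[1L])
    stop("metadata rows (", nrow(trials), ") != number of epochs (",
         dim(data)[1L], ")", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  if (length(channel_labels) != dim(data)[2L])
    stop("channel_labels length mismatch", call. = FALSE)
  structure(list(data = data, times = as.numeric(times),
                 sampling_rate = 1 / dt[1L],
                 channel_labels = as.character(channel_labels),
                 events = events, trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %.6g Hz, t in [%.3g, %.3g] s\n",
    d[1L], d[2L], d[3L], x$sampling_rate, min(x$times), max(x$times)))
  if (length(x$events))
    cat("events:", paste(sprintf("%s=%.3gs", names(x$events), x$events),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset an epoch_set by trial
#'
#' @param epochs an `epoch_set`.
#' @param i integer or logical index over epochs.
#' @export
subset_epochs <- function(epochs, i) {
  out <- epochs
  out$data <- epochs$data[i, , , drop = FALSE]
  out$trials <- epochs$trials[i, , drop = FALSE]
  class(out$trials) <- class(epochs$trials)
  out
}

#' Save / load epochs as a raw array container with a JSON sidecar
#'
#' The canonical on-disk dialect is three files sharing a stem:
#' `<stem>.dat` (float64, little-endian, values in R column-major order over
#' the trials x channels x samples array, i.e. trial index fastest),
#' `<stem>.meta.json` (dimensions, sampling rate, time axis, channel labels,
#' events, byte order), and `<stem>.trials.tsv` (the linked trial table).
#'
#' @param epochs an [epoch_set()].
#' @param stem path stem (no extension).
#' @return `read_epochs` returns an `epoch_set`; `write_epochs` the stem.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  meta <- list(dims = dim(epochs$data),
               dim_order = c("trial", "channel", "sample"),
               storage = "float64-little-endian-column-major",
               sampling_rate = epochs$sampling_rate,
               times = epochs$times,
               channel_labels = epochs$channel_labels,
               events = as.list(epochs$events))
  jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_trial_table(epochs$trials, paste0(stem, ".trials.tsv"))
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n + 1L, size = 8L,
               endian = "little")
  if (length(x) != n)
    stop("epoch payload size (", length(x),
         ") does not match metadata dims (", n, ")", call. = FALSE)
  trials <- read_trial_table(paste0(stem, ".trials.tsv"))
  if (nrow(trials) != dims[1L])
    stop("trial metadata rows do not match epoch count", call. = FALSE)
  epoch_set(array(x, dims), as.numeric(meta$times), trials,
            channel_labels = meta$channel_labels,
            events = unlist(meta$events) %||% numeric())
}
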