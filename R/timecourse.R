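# Internal: cross-validated distance matrices at every valid timepoint.
# Returns list(times, t_idx, dist = list of trials x conditions matrices).
# Labels must be NA-free; patterns are optionally confound-residualized.
cv_distance_timecourse <- function(epochs, labels, cfg,
                                   confound_labels = NULL) {
  ns <- dim(epochs$data)[3L]
  t_idx <- seq.int(cfg$window_samples, ns)
  dist <- vector("list", length(t_idx))
  for (j in seq_along(t_idx)) {
    X <- spatiotemporal_patterns(epochs, t_idx[j], cfg$window_samples)
    if (!is.null(confound_labels))
      X <- regress_out_condition(X, confound_labels)
    cfg_t <- cfg
    cfg_t$seed <- child_seed(cfg$seed, j)
    dist[[j]] <- crossval_distances(X, labels, cfg_t)
  }
  list(times = epochs$times[t_idx], t_idx = t_idx, dist = dist)
}

new_timecourse <- function(times, score, feature, n_trials, what) {
  structure(list(feature = feature, times = times, score = score,
                 n_trials = n_trials),
            class = c(what, "feature_timecourse"))
}

#' @export
print.feature_timecourse <- function(x, ...) {
  cat(sprintf("<%s> feature '%s', %d timepoints (%.3g..%.3g s), n = %d\n",
              class(x)[1L], x$feature, length(x$times), min(x$times),
              max(x$times), x$n_trials))
  invisible(x)
}

#' Time-resolved feature decoding for one participant
#'
#' At each timepoint: spatiotemporal patterns -> optional confound
#' regression -> cross-validated Mahalanobis distances to condition
#' templates -> distance-on-dissimilarity regression score. Timepoints whose
#' window would start before the epoch are trimmed.
#'
#' @param epochs an [epoch_set()] (one participant).
#' @param labels condition label per trial (vector, or the name of a column
#'   of `epochs$trials`). Trials with `NA` labels are dropped.
#' @param cfg a [decoding_config()].
#' @param confound_labels optional confound condition per trial (vector or
#'   column name), regressed out of the patterns before decoding.
#' @return a `decoding_timecourse`: `times`, `score` (one value per
#'   timepoint), `feature`, `n_trials`.
#' @export
decode_timecourse <- function(epochs, labels, cfg = decoding_config(),
                              confound_labels = NULL) {
  feature <- if (is.character(labels) && length(labels) == 1L) labels
  else deparse(substitute(labels))[1L]
  labels <- resolve_labels(epochs, labels)
  confound_labels <- resolve_labels(epochs, confound_labels)
  keep <- !is.na(labels)
  ep <- subset_epochs(epochs, keep)
  lab <- labels[keep]
  conf <- if (!is.null(confound_labels)) confound_labels[keep]
  tc <- cv_distance_timecourse(ep, lab, cfg, conf)
  score <- vapply(tc$dist, distance_regression_score, 0, labels = lab)
  new_timecourse(tc$times, score, feature, sum(keep), "decoding_timecourse")
}

resolve_labels <- function(epochs, labels) {
  if (is.null(labels)) return(NULL)
  if (is.character(labels) && length(labels) == 1L) {
    if (!labels %in% names(epochs$trials))
      stop("no column '", labels, "' in the linked trial table",
           call. = FALSE)
    return(epochs$trials[[labels]])
  }
  if (length(labels) != dim(epochs$data)[1L])
    stop("labels length must match the number of epochs", call. = FALSE)
  labels
}

#' Conditional decoding: decode one feature while fixing another
#'
#' Splits trials into strata (e.g. the current pitch when decoding the
#' *previous* pitch), decodes the target within each stratum, and averages
#' the stratum timecourses without weighting. Strata in which some target
#' condition has fewer trials than folds are skipped (messaged); if every
#' stratum is skipped an error is raised.
#'
#' @param epochs an [epoch_set()].
#' @param target_labels target condition per trial (vector or column name).
#' @param strata_labels stratifying condition per trial (vector or column
#'   name).
#' @inheritParams decode_timecourse
#' @return a `decoding_timecourse` with attribute `"n_strata_used"`.
#' @export
conditional_decode_timecourse <- function(epochs, target_labels,
                                          strata_labels,
                                          cfg = decoding_config(),
                                          confound_labels = NULL) {
  feature <- if (is.character(target_labels) && length(target_labels) == 1L)
    target_labels else "target"
  target <- resolve_labels(epochs, target_labels)
  strata <- resolve_labels(epochs, strata_labels)
  confound <- resolve_labels(epochs, confound_labels)
  keep <- !is.na(target) & !is.na(strata)
  ep0 <- subset_epochs(epochs, keep)
  target <- target[keep]; strata <- strata[keep]
  if (!is.null(confound)) confound <- confound[keep]
  lv <- sort(unique(strata))
  curves <- list(); times <- NULL; used <- character()
  for (s in lv) {
    i <- which(strata == s)
    cnt <- table(target[i])
    if (length(cnt) < 2L || any(cnt < cfg$n_folds)) {
      message("stratum '", s, "' skipped (insufficient target trials)")
      next
    }
    ep <- subset_epochs(ep0, i)
    cfg_s <- cfg
    cfg_s$seed <- child_seed(cfg$seed, match(s, lv) * 131L)
    conf_s <- if (!is.null(confound)) confound[i]
    tc <- cv_distance_timecourse(ep, target[i], cfg_s, conf_s)
    curves[[as.character(s)]] <-
      vapply(tc$dist, distance_regression_score, 0, labels = target[i])
    times <- tc$times
    used <- c(used, as.character(s))
  }
  if (!length(curves))
    stop("all strata skipped; conditional decoding impossible",
         call. = FALSE)
  score <- rowMeans(do.call(cbind, curves))
  out <- new_timecourse(times, score, feature, length(target),
                        "decoding_timecourse")
  attr(out, "n_strata_used") <- length(used)
  attr(out, "strata_used") <- used
  out
}

#' Gaussian smoothing for display
#'
#' Gaussian-weighted moving average (window of `window_ms`, kernel truncated
#' and renormalized at the edges). Display only: inference always runs on
#' the raw timecourses.
#'
#' @param x numeric vector, or a `feature_timecourse` (smoothed in place).
#' @param sampling_rate Hz (taken from the time axis for timecourses).
#' @param window_ms full window width in ms (default 150).
#' @return same shape as `x`.
#' @export
smooth_for_display <- function(x, sampling_rate = NULL, window_ms = 150) {
  if (inherits(x, "feature_timecourse")) {
    sr <- 1 / diff(x$times[1:2])
    x$score <- smooth_for_display(x$score, sr, window_ms)
    return(x)
  }
  stopifnot(!is.null(sampling_rate))
  L <- round(window_ms / 1000 * sampling_rate)
  if (L < 2) return(x)
  half <- floor(L / 2)
  sigma <- L / 5  # window covers +-2.5 sd, the usual moving-window setting
  w <- stats::dnorm(-half:half, sd = sigma)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    wj <- w[j - i + half + 1L]
    out[i] <- sum(x[j] * wj) / sum(wj)
  }
  out
}

#' Stack per-participant timecourses into a matrix
#'
#' @param tcs list of `feature_timecourse` objects on identical time grids.
#' @return participants x time matrix with attribute `"times"`.
#' @export
timecourse_matrix <- function(tcs) {
  times <- tcs[[1L]]$times
  for (tc in tcs)
    if (length(tc$times) != length(times) ||
        max(abs(tc$times - times)) > 1e-9)
      stop("timecourses are not on a common time grid", call. = FALSE)
  m <- do.call(rbind, lapply(tcs, `[[`, "score"))
  rownames(m) <- names(tcs)
  attr(m, "times") <- times
  m
}
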