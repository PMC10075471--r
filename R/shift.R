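#' Representational shift of the current pitch by the previous pitch
#'
#' Quantifies, per timepoint, whether the neural representation of the
#' current pitch is displaced toward (positive) or away from (negative) the
#' previous trial's pitch. For each ordered pitch pair (a, b), a != b:
#' cross-validated templates are built for every pitch; for trials with
#' current a the signed distance difference D(b) - D(a) is averaged over
#' trials preceded by b (`M_diff`) and over trials preceded by a themselves
#' (`M_diff_baseline`); the pair's shift is `M_diff_baseline - M_diff`, so
#' an attraction toward b (smaller D(b)) gives positive values. The
#' participant's timecourse is the unweighted mean over all ordered pairs
#' with data (`pairs = "adjacent"` restricts to |a - b| = 1).
#'
#' @param epochs an [epoch_set()] (one participant).
#' @param current_pitch,prev_pitch level per trial (vector or column name;
#'   defaults to the `pitch_level` / `prev_pitch` metadata columns).
#' @param cfg a [decoding_config()]; the same fold machinery (and seed) as
#'   the decoder, so shift and decoding timecourses are comparable.
#' @param confound_labels optional confound (e.g. the motor response)
#'   regressed out of the patterns first.
#' @param pairs `"all"` ordered pairs or `"adjacent"` only.
#' @return a `shift_timecourse`: `times`, `score` (positive = attraction),
#'   `n_trials`, plus per-pair bookkeeping in attribute `"pairs"` (pair x
#'   time matrices of `M_diff`, `M_diff_baseline` and cell counts).
#' @export
pairwise_shift_pitch <- function(epochs, current_pitch = "pitch_level",
                                 prev_pitch = "prev_pitch",
                                 cfg = decoding_config(),
                                 confound_labels = NULL,
                                 pairs = c("all", "adjacent")) {
  pairs <- match.arg(pairs)
  cur <- resolve_labels(epochs, current_pitch)
  prev <- resolve_labels(epochs, prev_pitch)
  conf <- resolve_labels(epochs, confound_labels)
  keep <- !is.na(cur) & !is.na(prev)
  ep <- subset_epochs(epochs, keep)
  cur <- as.character(cur[keep]); prev <- as.character(prev[keep])
  if (!is.null(conf)) conf <- conf[keep]
  tc <- cv_distance_timecourse(ep, cur, cfg, conf)
  conds <- colnames(tc$dist[[1L]])
  pr <- expand.grid(a = conds, b = conds, stringsAsFactors = FALSE)
  pr <- pr[pr$a != pr$b, ]
  if (pairs == "adjacent")
    pr <- pr[abs(as.numeric(pr$a) - as.numeric(pr$b)) == 1, ]
  nt <- length(tc$times)
  m_diff <- m_base <- matrix(NA_real_, nrow(pr), nt)
  n_cell <- integer(nrow(pr))
  for (q in seq_len(nrow(pr))) {
    a <- pr$a[q]; b <- pr$b[q]
    sel <- which(cur == a & prev == b)
    bas <- which(cur == a & prev == a)
    n_cell[q] <- min(length(sel), length(bas))
    if (n_cell[q] == 0L) next
    for (j in seq_len(nt)) {
      D <- tc$dist[[j]]
      m_diff[q, j] <- mean(D[sel, b] - D[sel, a])
      m_base[q, j] <- mean(D[bas, b] - D[bas, a])
    }
  }
  ok <- n_cell > 0L
  if (!any(ok)) stop("every pitch pair has an empty cell", call. = FALSE)
  if (any(!ok))
    message(sum(!ok), " pitch pair(s) skipped (empty cell)")
  shift <- colMeans(m_base[ok, , drop = FALSE] -
                      m_diff[ok, , drop = FALSE])
  out <- new_timecourse(tc$times, shift, "pitch", length(cur),
                        "shift_timecourse")
  attr(out, "pairs") <- list(pairs = pr, n_cell = n_cell, m_diff = m_diff,
                             m_diff_baseline = m_base)
  out
}

#' Representational shift for a binary feature
#'
#' For category choice or motor response: cross-validated templates for the
#' two levels; per trial the signed distance difference is oriented so that
#' attraction toward the *previous* trial's level is positive (distance to
#' the other level minus distance to the previous level). The two
#' orientations (previous = first level, previous = second level) are
#' averaged, which cancels the current-encoding asymmetry. With
#' `control_strata` the analysis runs within each stratum (e.g. the response
#' cue identity) and averages across usable strata.
#'
#' @param epochs an [epoch_set()] (one participant).
#' @param current_binary,prev_binary binary condition per trial (vector or
#'   column name).
#' @param cfg a [decoding_config()].
#' @param control_strata optional stratifying labels.
#' @param confound_labels optional confound regressed out of the patterns.
#' @param feature name stored on the result.
#' @return a `shift_timecourse` with attribute `"components"` holding the
#'   two oriented means (`diff_prev_first`, `diff_prev_second`).
#' @export
binary_shift <- function(epochs, current_binary, prev_binary,
                         cfg = decoding_config(), control_strata = NULL,
                         confound_labels = NULL, feature = "binary") {
  cur <- resolve_labels(epochs, current_binary)
  prev <- resolve_labels(epochs, prev_binary)
  strata <- resolve_labels(epochs, control_strata)
  conf <- resolve_labels(epochs, confound_labels)
  keep <- !is.na(cur) & !is.na(prev)
  if (!is.null(strata)) keep <- keep & !is.na(strata)
  ep0 <- subset_epochs(epochs, keep)
  cur <- as.character(cur[keep]); prev <- as.character(prev[keep])
  if (!is.null(strata)) strata <- strata[keep]
  if (!is.null(conf)) conf <- conf[keep]
  lvls <- sort(unique(cur))
  if (length(lvls) != 2L)
    stop("current feature must have exactly 2 levels", call. = FALSE)
  if (!all(unique(prev) %in% lvls))
    stop("previous labels outside the current levels", call. = FALSE)

  one_stratum <- function(idx, sub_seed) {
    cnt <- table(cur[idx])
    if (length(cnt) < 2L || any(cnt < cfg$n_folds) ||
        length(unique(prev[idx])) < 2L) return(NULL)
    cfg_s <- cfg
    cfg_s$seed <- child_seed(cfg$seed, sub_seed)
    conf_s <- if (!is.null(conf)) conf[idx]
    tc <- cv_distance_timecourse(subset_epochs(ep0, idx), cur[idx], cfg_s,
                                 conf_s)
    p1 <- which(prev[idx] == lvls[1L])
    p2 <- which(prev[idx] == lvls[2L])
    d1 <- vapply(tc$dist, function(D)
      mean(D[p1, lvls[2L]] - D[p1, lvls[1L]]), 0)
    d2 <- vapply(tc$dist, function(D)
      mean(D[p2, lvls[1L]] - D[p2, lvls[2L]]), 0)
    list(times = tc$times, d1 = d1, d2 = d2)
  }

  if (is.null(strata)) {
    r <- one_stratum(seq_along(cur), 1L)
    if (is.null(r)) stop("a level has fewer trials than folds",
                         call. = FALSE)
    parts <- list(r)
  } else {
    lv <- sort(unique(strata))
    parts <- list()
    for (s in lv) {
      r <- one_stratum(which(strata == s), 977L + match(s, lv))
      if (is.null(r)) message("stratum '", s, "' skipped") else
        parts[[as.character(s)]] <- r
    }
    if (!length(parts)) stop("all control strata skipped", call. = FALSE)
  }
  d1 <- rowMeans(do.call(cbind, lapply(parts, `[[`, "d1")))
  d2 <- rowMeans(do.call(cbind, lapply(parts, `[[`, "d2")))
  out <- new_timecourse(parts[[1L]]$times, (d1 + d2) / 2, feature,
                        length(cur), "shift_timecourse")
  attr(out, "components") <- list(levels = lvls, diff_prev_first = d1,
                                  diff_prev_second = d2,
                                  n_strata_used = length(parts))
  out
}
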