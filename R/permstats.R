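# Sign-flip null: (n_perm + 1) x T matrix of permuted group means whose
# first row is the identity permutation (the observed means). Sharing one
# arithmetic path makes ties between observed and permuted values exact.
signflip_null <- function(scores, n_perm) {
  P <- nrow(scores)
  flips <- rbind(rep(1, P),
                 matrix(sample(c(-1, 1), n_perm * P, replace = TRUE),
                        n_perm, P))
  (flips %*% scores) / P
}

# Tie-safe pointwise p-values for every permutation row (including the
# observed first row) against the full null, per column.
pointwise_p_matrix <- function(null, tail) {
  N <- nrow(null)
  v <- switch(tail, two.sided = abs(null), less = -null, null)
  apply(v, 2, function(col) (N - rank(col, ties.method = "min") + 1) / N)
}

#' Pointwise sign-permutation test on participant timecourses
#'
#' Under the group-level null each participant's timecourse is symmetric
#' around zero, so signs are flipped with probability 1/2 and the permuted
#' group means form the null distribution. The observed statistic is counted
#' into the null, so p >= 1/(n_perm + 1).
#'
#' @param scores participants x time matrix (e.g. [timecourse_matrix()]).
#' @param n_perm number of sign flips.
#' @param tail `"greater"` (scores above zero), `"less"`, or `"two.sided"`.
#' @param seed integer seed.
#' @return numeric vector of p-values (one per timepoint).
#' @export
signflip_pointwise <- function(scores, n_perm = 10000,
                               tail = c("greater", "two.sided", "less"),
                               seed = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(scores), nrow(scores) >= 2L)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p resolution")
  with_seed(seed, {
    null <- signflip_null(scores, n_perm)
    pointwise_p_matrix(null, tail)[1L, ]
  })
}

# Maximal runs of TRUE in a logical vector -> list of index ranges.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

# Suprathreshold clusters of one permutation row: runs of pointwise
# p < alpha, split by the sign of the statistic under two-sided testing.
row_clusters <- function(p_row, v_row, alpha, tail) {
  runs <- if (tail == "two.sided")
    c(lapply(logical_runs(p_row < alpha & v_row > 0), c, +1L),
      lapply(logical_runs(p_row < alpha & v_row < 0), c, -1L))
  else lapply(logical_runs(p_row < alpha),
              c, if (tail == "less") -1L else +1L)
  runs
}

# Max |cluster mass| of one permutation row.
max_cluster_mass <- function(p_row, v_row, alpha, tail) {
  best <- 0
  for (rg in row_clusters(p_row, v_row, alpha, tail))
    best <- max(best, abs(sum(v_row[rg[1L]:rg[2L]])))
  best
}

#' Cluster-based sign-permutation test across time
#'
#' Clusters are maximal runs of timepoints whose group mean exceeds the
#' pointwise permutation critical value at `alpha_cluster`; the cluster
#' statistic is the summed group mean (mass). The corrected p-value of each
#' observed cluster is its mass's rank in the null distribution of
#' per-permutation maximal cluster masses (the same sign-flip draws used for
#' the pointwise thresholds).
#'
#' @inheritParams signflip_pointwise
#' @param alpha_cluster pointwise threshold defining clusters (default .05).
#' @param times optional time axis (seconds) used to report cluster extents.
#' @return a `cluster_result`: data.frame `clusters` (start/end index and
#'   seconds, mass, corrected p), `pointwise_p`, `null_max`, `n_perm`,
#'   `tail`, `alpha_cluster`.
#' @export
cluster_permutation <- function(scores, n_perm = 10000, alpha_cluster = 0.05,
                                tail = c("greater", "two.sided", "less"),
                                seed = NULL, times = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(scores), nrow(scores) >= 2L)
  if (is.null(times)) times <- attr(scores, "times") %||%
      seq_len(ncol(scores))
  with_seed(seed, {
    null <- signflip_null(scores, n_perm)
    pm <- pointwise_p_matrix(null, tail)
    obs <- null[1L, ]
    null_max <- vapply(seq_len(n_perm) + 1L, function(i)
      max_cluster_mass(pm[i, ], null[i, ], alpha_cluster, tail), 0)
    cl <- data.frame(start = integer(), end = integer(),
                     start_s = numeric(), end_s = numeric(),
                     sign = integer(), mass = numeric(), p = numeric())
    for (rg in row_clusters(pm[1L, ], obs, alpha_cluster, tail)) {
      mass <- sum(obs[rg[1L]:rg[2L]])
      cl <- rbind(cl, data.frame(
        start = rg[1L], end = rg[2L],
        start_s = times[rg[1L]], end_s = times[rg[2L]], sign = rg[3L],
        mass = mass,
        p = (1 + sum(null_max >= abs(mass))) / (n_perm + 1)))
    }
    cl <- cl[order(cl$start), , drop = FALSE]
    rownames(cl) <- NULL
    structure(list(clusters = cl, pointwise_p = pm[1L, ],
                   null_max = null_max, n_perm = n_perm, tail = tail,
                   alpha_cluster = alpha_cluster, times = times),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, n_perm = %d, alpha = %.3g\n", x$tail,
              x$n_perm, x$alpha_cluster))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE, digits = 3)
  else cat("no suprathreshold clusters\n")
  invisible(x)
}

#' Significant clusters of a cluster_result
#'
#' @param x a `cluster_result`.
#' @param alpha corrected significance level (default .05).
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cluster_result"))
  x$clusters[x$clusters$p < alpha, , drop = FALSE]
}

#' Normalized lagged cross-correlation of two timecourses
#'
#' Both series are demeaned over their full extent; the coefficient at lag L
#' is sum_t x(t) y(t - L) over the overlap, normalized by the product of the
#' full-series root energies, so a negative peak lag means the first series
#' leads the second.
#'
#' @param tc1,tc2 numeric vectors on the same uniform grid.
#' @param max_lag_s maximal lag in seconds.
#' @param sampling_rate grid rate in Hz.
#' @return list `lags` (seconds), `coef`, `peak_lag` (seconds),
#'   `peak_coef`.
#' @export
crosscorr_lagged <- function(tc1, tc2, max_lag_s, sampling_rate) {
  stopifnot(length(tc1) == length(tc2))
  x <- tc1 - mean(tc1); y <- tc2 - mean(tc2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: cross-correlation undefined", call. = FALSE)
  L <- round(max_lag_s * sampling_rate)
  n <- length(x)
  norm <- sqrt(sum(x^2) * sum(y^2))
  cc <- vapply(-L:L, function(l) {
    t1 <- max(1L, 1L + l):min(n, n + l)  # indices of x; y index = t - l
    sum(x[t1] * y[t1 - l]) / norm
  }, 0)
  lags <- (-L:L) / sampling_rate
  k <- which.max(cc)
  list(lags = lags, coef = cc, peak_lag = lags[k], peak_coef = cc[k])
}

#' Max-statistic permutation threshold for a cross-correlation
#'
#' Null: both group-mean series are independently shuffled across time, the
#' lagged cross-correlation recomputed, and its maximum over lags recorded;
#' the threshold is the 95th percentile of those maxima (corrected over
#' lags). Time shuffling destroys autocorrelation, so for strongly
#' autocorrelated series this null is anticonservative; interpret
#' accordingly.
#'
#' @inheritParams crosscorr_lagged
#' @param n_perm permutations.
#' @param level threshold quantile (default .95).
#' @param seed integer seed.
#' @return list `threshold`, `significant` (logical per lag), `lags`,
#'   `coef`, `null_max`.
#' @export
crosscorr_null_threshold <- function(tc1, tc2, max_lag_s, sampling_rate,
                                     n_perm = 10000, level = 0.95,
                                     seed = NULL) {
  if (n_perm < 2) warning("n_perm < 2: threshold is degenerate")
  obs <- crosscorr_lagged(tc1, tc2, max_lag_s, sampling_rate)
  with_seed(seed, {
    null_max <- vapply(seq_len(n_perm), function(i) {
      cc <- crosscorr_lagged(sample(tc1), sample(tc2), max_lag_s,
                             sampling_rate)
      max(cc$coef)
    }, 0)
    thr <- stats::quantile(null_max, level, names = FALSE)
    list(threshold = thr, significant = obs$coef > thr, lags = obs$lags,
         coef = obs$coef, peak_lag = obs$peak_lag, null_max = null_max)
  })
}

#' Bootstrap confidence interval for the cross-correlation peak lag
#'
#' Participants are resampled with replacement; for each resample the two
#' group-mean timecourses and their cross-correlation peak lag are
#' recomputed. The CI is the 2.5/97.5 percentile of the peak lags.
#'
#' @param scores1,scores2 participants x time matrices (same participants,
#'   same grid).
#' @inheritParams crosscorr_lagged
#' @param n_boot bootstrap resamples (study convention 5000).
#' @param seed integer seed.
#' @return list `peak_lag` (observed), `ci` (2-vector, seconds),
#'   `boot_lags`.
#' @export
bootstrap_peak_lag <- function(scores1, scores2, max_lag_s, sampling_rate,
                               n_boot = 5000, seed = NULL) {
  stopifnot(is.matrix(scores1), is.matrix(scores2),
            nrow(scores1) == nrow(scores2))
  P <- nrow(scores1)
  if (P < 3L) stop("need at least 3 participants to bootstrap",
                   call. = FALSE)
  obs <- crosscorr_lagged(colMeans(scores1), colMeans(scores2), max_lag_s,
                          sampling_rate)
  with_seed(seed, {
    lags <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(P, replace = TRUE)
      crosscorr_lagged(colMeans(scores1[i, , drop = FALSE]),
                       colMeans(scores2[i, , drop = FALSE]),
                       max_lag_s, sampling_rate)$peak_lag
    }, 0)
    list(peak_lag = obs$peak_lag,
         ci = stats::quantile(lags, c(0.025, 0.975), names = FALSE),
         boot_lags = lags)
  })
}

#' Pearson correlation with explicit outlier exclusion
#'
#' Excludes points lying more than `sd_threshold` SDs from the mean on
#' either axis, re-checks once on the remaining points, then reports the
#' Pearson correlation. Exclusions are returned, never silent.
#'
#' @param x,y paired per-participant values (names used as ids if present).
#' @param sd_threshold exclusion rule (default 3 SD).
#' @return list `r`, `p`, `n`, `excluded` (ids or indices), `test` (htest).
#' @export
corr_with_outliers <- function(x, y, sd_threshold = 3) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  ids <- names(x) %||% seq_along(x)
  keep <- rep(TRUE, length(x))
  for (pass in 1:2) {
    xs <- x[keep]; ys <- y[keep]
    out <- abs(x - mean(xs)) > sd_threshold * stats::sd(xs) |
      abs(y - mean(ys)) > sd_threshold * stats::sd(ys)
    if (!any(out & keep)) break
    keep <- keep & !out
  }
  if (sum(keep) < 5L)
    stop("fewer than 5 participants after outlier exclusion",
         call. = FALSE)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep),
       excluded = ids[!keep], test = ct)
}
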