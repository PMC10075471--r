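#' Decoding configuration
#'
#' @param window_samples samples pooled per timepoint (2 = the sample at t
#'   and the one before, i.e. a 20 ms window at 100 Hz).
#' @param n_folds cross-validation folds (study convention 8).
#' @param n_reps independent fold randomizations averaged (study
#'   convention 50).
#' @param balance subsample training trials to the minimum per-condition
#'   count so templates are unbiased.
#' @param shrinkage `"auto"` (analytic Ledoit-Wolf intensity), a fixed
#'   value in \[0, 1\] (0 = plain sample covariance), or `"identity"` to
#'   force the identity metric (distances become Euclidean; diagnostics).
#' @param seed integer seed controlling fold/subsample randomness.
#' @export
decoding_config <- function(window_samples = 2, n_folds = 8, n_reps = 50,
                            balance = TRUE, shrinkage = "auto",
                            seed = NULL) {
  stopifnot(window_samples >= 1, n_folds >= 2, n_reps >= 1)
  if (!identical(shrinkage, "auto") && !identical(shrinkage, "identity")) {
    stopifnot_scalar(shrinkage, "shrinkage")
    if (shrinkage < 0 || shrinkage > 1)
      stop("fixed shrinkage must be in [0, 1]", call. = FALSE)
  }
  structure(list(window_samples = as.integer(window_samples),
                 n_folds = as.integer(n_folds),
                 n_reps = as.integer(n_reps),
                 balance = isTRUE(balance), shrinkage = shrinkage,
                 seed = seed),
            class = "decoding_config")
}

#' Spatiotemporal pattern matrix at one timepoint
#'
#' Pools the channel vectors at samples t, t-1, ..., t-(window-1) into one
#' pattern per trial (sample-major column order: all channels at t first).
#'
#' @param epochs an [epoch_set()].
#' @param t_index sample index (1-based); must be >= `window_samples`.
#' @param window_samples window length in samples.
#' @return trials x (channels * window) matrix.
#' @export
spatiotemporal_patterns <- function(epochs, t_index, window_samples = 2) {
  ns <- dim(epochs$data)[3L]
  if (t_index < window_samples || t_index > ns)
    stop("t_index out of range for this window", call. = FALSE)
  do.call(cbind, lapply(seq_len(window_samples) - 1L, function(k)
    epochs$data[, , t_index - k]))
}

# Ledoit-Wolf analytic shrinkage toward the scaled identity, on pre-demeaned
# rows X (n x p). Returns list(sigma, gamma).
lw_shrink <- function(X) {
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  if (d2 < 1e-300) # degenerate: no scatter at all
    return(list(sigma = diag(max(m, 1e-12), p), gamma = 1))
  sq <- rowSums(X^2)
  # sum_k ||x_k x_k' - S||_F^2 = sum (x'x)^2 - 2 sum x'Sx + n ||S||_F^2
  xSx <- rowSums((X %*% S) * X)
  b2bar <- (sum(sq^2) - 2 * sum(xSx) + n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2bar, d2)
  gam <- b2 / d2
  list(sigma = gam * diag(m, p) + (1 - gam) * S, gamma = gam)
}

#' Shrinkage covariance estimate
#'
#' Convex combination of the sample covariance and a scaled identity with
#' the analytic Ledoit-Wolf intensity; always symmetric positive definite
#' for non-degenerate data, including p > n.
#'
#' @param X samples x features matrix (rows are observations; demeaned
#'   internally by the grand mean).
#' @param shrinkage `"auto"` or a fixed intensity in \[0, 1\].
#' @return covariance matrix with attribute `"gamma"` (intensity used).
#' @export
shrinkage_covariance <- function(X, shrinkage = "auto") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  if (identical(shrinkage, "auto")) {
    r <- lw_shrink(Xc)
    structure(r$sigma, gamma = r$gamma)
  } else {
    S <- crossprod(Xc) / nrow(Xc)
    m <- sum(diag(S)) / ncol(S)
    structure(shrinkage * diag(max(m, 1e-12), ncol(S)) +
                (1 - shrinkage) * S, gamma = shrinkage)
  }
}

#' Regress a confound out of multivariate patterns
#'
#' Removes per-feature condition means of the confound labels (OLS on dummy
#' codes), retaining the grand mean, so the confound's template no longer
#' separates the classes.
#'
#' @param patterns trials x features matrix.
#' @param confound_labels vector of confound conditions (one per trial).
#' @return residual matrix of the same shape.
#' @export
regress_out_condition <- function(patterns, confound_labels) {
  f <- factor(confound_labels)
  if (nlevels(f) < 2L) {
    warning("confound has a single level; patterns returned unchanged")
    return(patterns)
  }
  gm <- colMeans(patterns)
  for (lv in levels(f)) {
    i <- which(f == lv)
    patterns[i, ] <- sweep(patterns[i, , drop = FALSE], 2,
                           colMeans(patterns[i, , drop = FALSE]) - gm)
  }
  patterns
}

# Stratified fold assignment: within each condition, trials are randomly
# dealt across folds as evenly as possible, so every training partition
# keeps every condition (given >= n_folds trials per condition).
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    i <- which(labels == lv)
    fold[i] <- sample(rep(seq_len(n_folds), length.out = length(i)))
  }
  fold
}

#' Cross-validated Mahalanobis distances to condition templates
#'
#' Stratified k-fold cross-validation: in each fold, condition templates are
#' the means of a balanced subsample of the training trials, the covariance
#' is a shrinkage estimate from the same training trials (demeaned by
#' condition), and each held-out trial's Mahalanobis distance to every
#' template is computed. The whole procedure is repeated `n_reps` times with
#' fresh fold/subsample randomness and averaged.
#'
#' @param patterns trials x features matrix.
#' @param labels condition label per trial.
#' @param cfg a [decoding_config()].
#' @return trials x conditions matrix of averaged distances (columns named
#'   by condition, sorted).
#' @export
crossval_distances <- function(patterns, labels, cfg = decoding_config()) {
  labels <- as.character(labels)
  conds <- sort(unique(labels))
  if (length(conds) < 2L) stop("need >= 2 conditions", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < cfg$n_folds))
    stop("condition(s) with fewer trials than folds: ",
         paste(names(cnt)[cnt < cfg$n_folds], collapse = ", "),
         call. = FALSE)
  n <- nrow(patterns)
  with_seed(cfg$seed, {
    acc <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
    for (rep in seq_len(cfg$n_reps)) {
      fold <- stratified_folds(labels, cfg$n_folds)
      for (k in seq_len(cfg$n_folds)) {
        test <- which(fold == k)
        train <- which(fold != k)
        tl <- labels[train]
        if (cfg$balance) {
          m <- min(table(tl))
          train <- unlist(lapply(conds, function(cv) {
            i <- train[tl == cv]
            if (length(i) > m) sample(i, m) else i
          }), use.names = FALSE)
          tl <- labels[train]
        }
        Xtr <- patterns[train, , drop = FALSE]
        mus <- t(vapply(conds, function(cv)
          colMeans(Xtr[tl == cv, , drop = FALSE]), numeric(ncol(Xtr))))
        resid <- Xtr - mus[match(tl, conds), , drop = FALSE]
        S <- if (identical(cfg$shrinkage, "auto")) lw_shrink(resid)$sigma
        else if (identical(cfg$shrinkage, "identity")) diag(ncol(Xtr))
        else {
          S0 <- crossprod(resid) / nrow(resid)
          m0 <- sum(diag(S0)) / ncol(S0)
          cfg$shrinkage * diag(max(m0, 1e-12), ncol(S0)) +
            (1 - cfg$shrinkage) * S0
        }
        U <- tryCatch(chol(S), error = function(e)
          chol(S + diag(1e-8 * mean(diag(S)) + 1e-12, ncol(S))))
        Xte <- patterns[test, , drop = FALSE]
        for (ci in seq_along(conds)) {
          Z <- backsolve(U, t(Xte) - mus[ci, ], transpose = TRUE)
          acc[test, ci] <- acc[test, ci] + sqrt(colSums(Z^2))
        }
      }
    }
    acc / cfg$n_reps
  })
}

#' Distance-on-dissimilarity regression score
#'
#' Per trial, the OLS slope of its template distances on the dummy feature
#' dissimilarity (0 = own condition, 1 = other conditions); with a binary
#' feature this reduces to (other-condition - own-condition) distance. The
#' score is the mean slope across trials; positive values mean the feature
#' is encoded.
#'
#' @param distances trials x conditions matrix (as from
#'   [crossval_distances()]), columns named by condition.
#' @param labels condition label per trial.
#' @return scalar score.
#' @export
distance_regression_score <- function(distances, labels) {
  labels <- as.character(labels)
  own <- match(labels, colnames(distances))
  if (anyNA(own)) stop("labels not found among distance columns",
                       call. = FALSE)
  k <- ncol(distances)
  d_own <- distances[cbind(seq_len(nrow(distances)), own)]
  # OLS slope on binary x equals mean(other) - own
  mean((rowSums(distances) - d_own) / (k - 1) - d_own)
}
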