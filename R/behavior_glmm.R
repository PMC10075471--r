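#' Mixed-effects logistic serial-bias models
#'
#' Fits one of the four nested choice-history GLMMs. All models regress the
#' binary category choice on the current pitch; Model 2 adds the previous
#' pitch, Model 3 the previous choice, and Model 4 both. Every fixed effect
#' has a correlated per-participant random effect (random intercept + random
#' slopes), the structure of the full model
#' logit p_ij = b0i + b1i*pitch_ij + b2i*prev_pitch_ij + b3i*prev_choice_ij,
#' b_i ~ N(gamma, Sigma).
#'
#' Pitch levels enter through `pitch_coding` (centered equal-spaced scores
#' by default, reported with the fit) and the previous choice is centered to
#' -0.5/+0.5. Rows with undefined history are dropped for every model so
#' that AIC values are comparable across the ladder.
#'
#' @param trials a [trial_table()] with history columns.
#' @param model_id 1, 2, 3, or 4.
#' @param engine `"glmmTMB"` (default, fast Laplace) or `"glmer"` (lme4).
#' @param pitch_coding numeric scores for pitch levels 1..5.
#' @return a `glmm_fit`: list with `model_id`, `fixed_effects` (term,
#'   estimate, se, z, p, ci_lo, ci_hi), `random_cov`, `loglik`, `df`, `aic`,
#'   `n_obs`, `converged`, `pitch_coding` and the underlying `fit`.
#' @export
fit_serial_glmm <- function(trials, model_id,
                            engine = c("glmmTMB", "glmer"),
                            pitch_coding = -2:2) {
  stopifnot(model_id %in% 1:4)
  engine <- match.arg(engine)
  d <- glmm_frame(trials, pitch_coding)
  fx <- switch(model_id,
               "cur",
               c("cur", "prev_pitch_c"),
               c("cur", "prev_choice_c"),
               c("cur", "prev_pitch_c", "prev_choice_c"))
  rhs <- paste(fx, collapse = " + ")
  form <- stats::as.formula(sprintf(
    "choice ~ %s + (1 + %s | participant_id)", rhs, rhs))
  if (engine == "glmmTMB") {
    tmb_ok <- function(f) !is.null(f) && isTRUE(f$sdr$pdHess) &&
      is.finite(stats::logLik(f)) && isTRUE(f$fit$convergence == 0)
    fit <- tryCatch(suppressWarnings(
      glmmTMB::glmmTMB(form, data = d, family = stats::binomial())),
      error = function(e) NULL)
    # near-boundary random effects can defeat the default optimizer on
    # small data; retry with BFGS, then fall back to lme4's Laplace fit
    # (which reports boundary fits instead of refusing them)
    if (!tmb_ok(fit)) {
      refit <- tryCatch(suppressWarnings(glmmTMB::glmmTMB(
        form, data = d, family = stats::binomial(),
        control = glmmTMB::glmmTMBControl(
          optimizer = stats::optim, optArgs = list(method = "BFGS")))),
        error = function(e) NULL)
      if (tmb_ok(refit)) fit <- refit
      else {
        engine <- "glmer"
        message("glmmTMB did not produce a usable fit for model ",
                model_id, "; falling back to lme4::glmer")
      }
    }
  }
  if (engine == "glmmTMB") {
    est <- glmmTMB::fixef(fit)$cond
    vc <- stats::vcov(fit)$cond
    conv <- TRUE
    rc <- as.matrix(glmmTMB::VarCorr(fit)$cond$participant_id)
    singular <- any(attr(glmmTMB::VarCorr(fit)$cond$participant_id,
                         "stddev") < 1e-5)
  } else {
    fit <- suppressWarnings(
      lme4::glmer(form, data = d, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)))
    est <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    conv <- length(fit@optinfo$conv$lme4) == 0L
    rc <- as.matrix(lme4::VarCorr(fit)$participant_id)
    singular <- lme4::isSingular(fit)
  }
  if (!conv) warning("model ", model_id, " did not converge cleanly")
  if (singular)
    message("model ", model_id, ": near-singular random-effect covariance; ",
            "consider simplifying the random structure")
  se <- sqrt(diag(vc))
  z <- est / se
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  fixed <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se))
  structure(list(model_id = model_id, engine = engine, fixed_effects = fixed,
                 random_cov = rc, loglik = ll, df = k, aic = 2 * k - 2 * ll,
                 n_obs = nrow(d), converged = conv, singular = singular,
                 pitch_coding = pitch_coding, fit = fit),
            class = "glmm_fit")
}

# Model frame shared by all four models: centered codings, undefined-history
# rows dropped (history terms exist only from the second trial on).
glmm_frame <- function(trials, pitch_coding = -2:2) {
  stopifnot(length(pitch_coding) == 5)
  need <- c("prev_pitch", "prev_choice")
  if (!all(need %in% names(trials)))
    stop("derive history columns first", call. = FALSE)
  d <- trials[!is.na(trials$prev_pitch) & !is.na(trials$prev_choice), ,
              drop = FALSE]
  data.frame(participant_id = factor(d$participant_id),
             choice = d$choice,
             cur = pitch_coding[d$pitch_level],
             prev_pitch_c = pitch_coding[d$prev_pitch],
             prev_choice_c = d$prev_choice - 0.5)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> model %d (%s), n = %d, logLik = %.1f, AIC = %.1f\n",
              x$model_id, x$engine, x$n_obs, x$loglik, x$aic))
  print(x$fixed_effects, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare serial-bias models by AIC
#'
#' @param fits list of `glmm_fit` objects fitted on the same observations,
#'   including Model 1 (the no-history reference).
#' @return data.frame `model_id`, `aic`, `delta_aic` (vs Model 1), `winner`.
#' @export
compare_models <- function(fits) {
  stopifnot(all(vapply(fits, inherits, TRUE, "glmm_fit")))
  n <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n)) != 1L)
    stop("fits use different observation sets; AIC is not comparable",
         call. = FALSE)
  if (anyNA(vapply(fits, `[[`, 0, "aic")))
    stop("a fit has no valid likelihood (non-convergence); refit before ",
         "comparing", call. = FALSE)
  ids <- vapply(fits, `[[`, 0, "model_id")
  aic <- vapply(fits, `[[`, 0, "aic")
  ref <- which(ids == 1L)
  if (!length(ref)) stop("Model 1 (reference) missing", call. = FALSE)
  out <- data.frame(model_id = ids, aic = aic,
                    delta_aic = aic - aic[ref[1L]])
  out$winner <- out$aic == min(out$aic)
  out[order(out$model_id), ]
}

#' Per-participant serial-bias indices
#'
#' Pitch and category bias are the per-participant coefficients of previous
#' pitch and previous choice from the full model: either the conditional
#' modes of the random effects added to the fixed effects (BLUP, default) or
#' independent per-participant GLMs. Motor bias is switch rate - stay rate.
#'
#' @param trials a [trial_table()] with history columns.
#' @param method `"blup"` or `"glm"`.
#' @param fit4 optional pre-computed Model 4 `glmm_fit` (blup method).
#' @param pitch_coding passed to the fits.
#' @return a `bias_indices` data.frame: `participant_id`, `pitch_bias`,
#'   `category_bias`, `motor_bias`.
#' @export
bias_indices <- function(trials, method = c("blup", "glm"), fit4 = NULL,
                         pitch_coding = -2:2) {
  method <- match.arg(method)
  if (method == "blup") {
    if (is.null(fit4)) fit4 <- fit_serial_glmm(trials, 4,
                                               pitch_coding = pitch_coding)
    stopifnot(fit4$model_id == 4)
    cf <- if (fit4$engine == "glmmTMB")
      stats::coef(fit4$fit)$cond$participant_id
    else stats::coef(fit4$fit)$participant_id
    idx <- data.frame(participant_id = rownames(cf),
                      pitch_bias = cf[["prev_pitch_c"]],
                      category_bias = cf[["prev_choice_c"]])
  } else {
    d <- glmm_frame(trials, pitch_coding)
    per <- lapply(split(d, d$participant_id), function(g)
      stats::coef(stats::glm(choice ~ cur + prev_pitch_c + prev_choice_c,
                             data = g, family = stats::binomial())))
    idx <- data.frame(participant_id = names(per),
                      pitch_bias = vapply(per, `[[`, 0, "prev_pitch_c"),
                      category_bias = vapply(per, `[[`, 0, "prev_choice_c"))
  }
  sw <- motor_switch_bias(trials)$rates
  idx$motor_bias <- sw$switch_rate[match(idx$participant_id,
                                         sw$participant_id)] -
    sw$stay_rate[match(idx$participant_id, sw$participant_id)]
  rownames(idx) <- NULL
  class(idx) <- c("bias_indices", "data.frame")
  idx
}

#' Median-split participants into High- and Low-bias groups
#'
#' The split is on the signed bias in the feature's behavioral direction:
#' pitch bias is repulsive at the group level, so *more negative* previous-
#' pitch coefficients count as higher bias; category bias is attractive
#' (more positive = higher); motor bias is repulsive (larger switch - stay =
#' higher). Ties are broken deterministically by participant id; with an odd
#' number of participants the High group gets the extra member's complement
#' (sizes differ by at most one).
#'
#' @param indices a [bias_indices()] table.
#' @param feature `"pitch"`, `"category"` or `"motor"`.
#' @return data.frame `participant_id`, `score`, `group` ("high"/"low").
#' @export
split_bias_groups <- function(indices,
                              feature = c("pitch", "category", "motor")) {
  feature <- match.arg(feature)
  score <- switch(feature,
                  pitch = -indices$pitch_bias,
                  category = indices$category_bias,
                  motor = indices$motor_bias)
  ord <- order(-score, indices$participant_id)
  n_high <- floor(nrow(indices) / 2)
  group <- rep("low", nrow(indices))
  group[ord[seq_len(n_high)]] <- "high"
  data.frame(participant_id = indices$participant_id, score = score,
             group = group)
}
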