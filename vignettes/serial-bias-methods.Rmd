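---
title: "Measuring serial bias in behavior and neural representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring serial bias in behavior and neural representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a pitch categorization task, the decision on one trial is systematically
pulled around by what happened on the previous trial, even though trials are
statistically independent: the perceived pitch tends to be *repulsed* from
the preceding pitch, while the categorical choice is *attracted* to the
preceding choice, and the motor response shows a mild tendency to switch
hands. `serialdep` implements the analysis stack for quantifying these
serial biases jointly in behavior and in multichannel EEG epochs, together
with a synthetic-data generator that plants all of these effects with known
parameters, so that every stage of the pipeline can be validated by
parameter recovery rather than by eyeballing.

## The behavioral model

Choices are modeled with a mixed-effects logistic regression. For
participant $i$ on trial $j$, the probability of a "high" report is

$$\mathrm{logit}\, p_{ij} = \beta_{0i} + \beta_{1i}\,x_{ij}
  + \beta_{2i}\,x^{\mathrm{prev}}_{ij} + \beta_{3i}\,c^{\mathrm{prev}}_{ij},
  \qquad \beta_i = \gamma + \mu_i,\ \mu_i \sim N(0, \Sigma),$$

where $x$ is the current pitch level, $x^{\mathrm{prev}}$ the previous pitch
and $c^{\mathrm{prev}}$ the previous choice. Four nested models (intercept +
current pitch only; + previous pitch; + previous choice; + both) are
compared by AIC. A negative $\gamma_2$ is a repulsive stimulus history
effect; a positive $\gamma_3$ an attractive choice history effect.

Numeric codings are not part of the model family and must be fixed by
convention: pitch levels 1..5 enter as centered equal-spaced scores
$\{-2,\dots,2\}$ and the previous choice as $\pm 0.5$. Both are exposed
(`pitch_coding`) and reported with every fit; the generator uses the same
coding so planted and recovered coefficients live on one scale. The first
trial of each participant has no history; the generator gives it zero
history terms (a cold start), and the fitting front end drops
undefined-history rows — for **all four** models, so that their AICs are
computed on an identical observation set (`compare_models()` refuses
anything else).

Fits use `glmmTMB` by default (Laplace approximation; `lme4::glmer` is
available via `engine=`). On small or nearly singular problems the default
optimizer can fail with a non-positive-definite Hessian; the fitter retries
once with BFGS and otherwise reports non-convergence rather than guessing.
Per-participant bias indices are the conditional modes (BLUPs) of the
Model-4 random effects by default, with independent per-participant GLMs as
the alternative (`method = "glm"`); the motor bias is switch rate minus
stay rate, which is bounded in $[-1, 1]$ by construction.

## Time-resolved decoding

Neural information is quantified with cross-validated Mahalanobis-distance
RSA. At each timepoint the channel vectors in a short window (2 samples,
i.e. 20 ms at 100 Hz) are pooled into one pattern per trial. Within each of
8 stratified folds, condition templates are the means of a *balanced*
subsample of training trials (equal counts per condition, so templates are
unbiased), the noise covariance is estimated from the training trials after
removing their condition means, and each held-out trial's Mahalanobis
distance to every template is computed. The whole fold assignment is
redrawn `n_reps` times (50 by default) and distances averaged.

The covariance uses analytic Ledoit–Wolf shrinkage toward a scaled
identity: the intensity is chosen in closed form and the estimate is
positive definite even with more pattern dimensions than trials. Forcing
the intensity to 0 recovers the plain sample covariance (the test suite
checks this path against an explicit-inverse brute force to 1e-8);
`shrinkage = "identity"` forces the Euclidean metric, which is what makes
noise-free geometric oracles exact.

The decoding score is the per-trial OLS slope of template distances on a
dummy dissimilarity code (0 = own condition, 1 = other), averaged over
trials; for a binary feature this is simply (other − own) distance.
Positive scores mean the feature is encoded. Past- and future-trial
features are decoded *conditionally*: trials are split into strata defined
by the other feature (e.g. the current pitch when decoding the previous
pitch), the target is decoded within each stratum, and stratum timecourses
are averaged unweighted. Strata that cannot support the cross-validation
(fewer trials than folds in some condition) are skipped with a message; if
every stratum is skipped — as when the strata coincide with the target —
that is an error, not a silent answer. A confound (e.g. the motor response
when decoding pitch) can be regressed out of the patterns first, which
equalizes the confound's condition means exactly in balanced designs.

Group means may be smoothed for display with a Gaussian-weighted moving
average (150 ms window); inference always runs on raw timecourses.

## The representational shift statistic

Decoding tells us a feature is present; the shift statistic asks whether
the current trial's representation is *displaced* toward or away from the
previous trial's feature. For each ordered pitch pair $(a, b)$: build CV
templates; for trials with current pitch $a$, compute $D_1$ (distance to
template $a$) and $D_2$ (distance to template $b$); average $D_2 - D_1$
over trials preceded by $b$ (`M_diff`) and over trials preceded by $a$
(`M_diff_baseline`); the shift is `M_diff_baseline - M_diff`. Attraction
toward $b$ shrinks $D_2$, so positive values mean attraction — the sign
convention used throughout, for binary features too (where the two
orientations, previous = high and previous = low, are averaged). The
participant's timecourse averages all ordered pairs with data; an
adjacent-pairs-only variant is available (`pairs = "adjacent"`). The
statistic is in distance units and has no natural scale; only its sign and
relative magnitude are interpreted.

## What the generator plants (and what it does not)

`simulate_behavior()` draws per-participant coefficients from
$N(\gamma, \Sigma)$ and generates choices sequentially through the logistic
model, with pitch levels balanced and shuffled within blocks (100 trials,
20 per level, matching the task design), a random response-cue mapping each
trial, and an optional motor switch bias implemented as a logit nudge of
size $\mathrm{logit}(p_{\mathrm{switch}})$ toward the switching response.
Defaults are the study-scale conditions: 30 participants, 2000 trials,
$\gamma = (0, 1.2, -0.8, 1.7)$ — a repulsive pitch and attractive choice
history of roughly the size reported for this task family — and modest
random-effect SDs (0.2–0.3).

`simulate_epochs()` builds each epoch as a sum over features (pitch,
category, motor) of template × activation envelope, plus optional
reactivation of the *previous* trial's template, plus spatially correlated
Gaussian noise (exponential channel-distance kernel, white in time).
Templates are orthonormalized random channel patterns, drawn as one basis
across all features so feature codes do not mix. Pitch and category
envelopes are locked to the tone onset, the motor envelope to the
response-cue onset. Amplitudes are in units of noise SD at the envelope
peak (templates are unit-norm), so `amplitude = 4` means peak SNR 4.

The planted shift moves the current template a fraction $\lambda$ along
the chord to the previous template: $(1-\lambda)T_{\mathrm{cur}} +
\lambda T_{\mathrm{prev}}$. Positive $\lambda$ is attraction; negative
$\lambda$ extrapolates away (repulsion). We use the chord rather than a
norm-preserving morph deliberately: with a "shrink-toward" variant of the
form $(1-|\lambda|)T_{\mathrm{cur}} + \lambda T_{\mathrm{prev}}$, working
the distances through the symmetric two-template geometry shows the
baseline and shifted trials end up *equidistant* from both templates for
negative $\lambda$ — repulsion would be unmeasurable by construction. The
chord morph instead yields closed forms under the identity metric:
$\mathrm{Shift} = \lambda\sqrt{2}$ for pitch pairs and $\lambda/\sqrt{2}$
for binary features, both signs, which the test suite freezes as exact
oracles.

What the generator does **not** emulate: 1/f spectra, oscillations,
volume-conducted topographies from dipolar sources, artifacts, temporal
autocorrelation of noise, or drifting templates. Passing recovery tests
therefore demonstrates that the *analysis* is correct and calibrated under
the stated noise model, not that real EEG will show these effects at these
sizes.

## Group-level inference

Under the group null each participant's score timecourse is symmetric
around zero, so signs are flipped with probability 1/2; the permuted group
means form the null. Clusters are maximal runs of timepoints with pointwise
permutation $p$ below 0.05; the cluster statistic is the summed group mean
(mass), and the corrected $p$ is the cluster's mass rank in the null
distribution of per-permutation maximal masses. Two implementation details
matter:

* the identity permutation is included as the first sign-flip row, so the
  observed statistic and the null share one arithmetic path. Without this,
  the all-positive flip ties the observed mean at machine precision and
  quantile interpolation breaks the tie arbitrarily, producing spurious
  one-sample clusters (we observed exactly this at small participant
  counts);
* pointwise thresholds are rank-based (tie-safe), and two-sided clusters
  are split by sign so opposite-signed runs never merge and cancel.

Tail conventions follow the analysis: one-sided for decoding (information
cannot be negative in expectation), two-sided for whole-group shift
timecourses, one-sided in the direction of the group effect for High/Low
bias-group contrasts.

Cross-correlation between two group-mean timecourses is normalized by the
full-series energies after demeaning; a negative peak lag means the first
series leads. The permutation threshold shuffles both series across time
and keeps the maximum coefficient over lags (max-statistic correction).
Time shuffling destroys autocorrelation, so this null is anticonservative
for strongly autocorrelated series — it matches the common practice for
these analyses, and the documentation flags the caveat. Peak-lag confidence
intervals bootstrap participants (2.5/97.5 percentiles). Brain–behavior
correlations exclude points more than 3 SD from the mean on either axis
(re-checked once), and the exclusions are always reported; the rule is a
package default, exposed as an argument, since exclusion criteria in this
literature are rarely stated.

## Numerical and design choices

* **RT outlier rule**: reaction times above mean + 4 SD are removed *per
  participant* (thresholds in the task were individualized, so a pooled
  rule would mix scales). With constant RTs the SD is 0 and nothing is
  removed.
* **Chain-break semantics**: history lookup is by trial index, so a removed
  trial leaves `NA` in both neighbours' history columns instead of
  splicing non-consecutive trials together. The previous-pitch exclusion
  (e.g. dropping trials preceded by the unambiguous extreme pitches) is an
  analysis subset and keeps the retained rows' history intact.
* **Folds**: stratified by condition; a condition with fewer trials than
  folds is an error naming the condition. Balancing subsamples the
  training set to the minimum per-condition count.
* **Degenerate covariance**: if training residuals have no scatter the
  shrinkage estimate falls back to a scaled identity; Cholesky failures
  add a relative ridge of 1e-8.
* **Separation** in the aggregate logistic fit falls back to a
  Haldane–Anscombe continuity correction (+0.5 per cell), flagged.
* **Median splits** order by the signed bias in the group-level direction
  of each feature (more negative pitch coefficient = higher bias; more
  positive choice coefficient = higher; larger switch − stay = higher),
  with deterministic id tie-breaks; group sizes differ by at most one.

## Problem sizes used by the tests

The test suite and the acceptance script run everything at reduced
reference conditions chosen by us: behavioral recovery at 10 replicates of
20 participants × 800 trials (plus one full 30 × 2000 fit in the
acceptance script), type-I calibration at 60 nulls of 15 × 200, decoding
and shift recovery at 8 participants × 150–250 trials × 16 channels with a
compressed trial timeline (tone 0.3 s, cue 0.55 s, epochs of 1.2 s at
50–100 Hz), and cluster-FWER calibration over 80 label-shuffled
experiments. Thresholds keep the proportions of the full-scale criteria
(e.g. "all runs recover the sign", FWER within the 99% binomial band
around 5%). These sizes trade Monte-Carlo resolution for runtime, not
correctness: every check is a property of the algorithms, verified exactly
where a closed form exists.

## Known limitations

* The sign-flip test assumes per-participant symmetric null distributions;
  decoding scores are only approximately symmetric under the null.
* The sample-shuffle cross-correlation null is anticonservative for
  autocorrelated inputs (see above).
* The shift statistic inherits template contamination: with planted morph
  $\lambda$, CV templates themselves move by about $\lambda/2$ along the
  chord, which scales the statistic but does not change its sign — worth
  remembering when comparing magnitudes across designs with different
  cell compositions.
* The *binary* shift statistic conflates choice repetition with neural
  shift when behavior is strongly autocorrelated: if the previous choice
  predicts the current choice, trials preceded by "high" are closer to the
  "high" template simply because they tend to *be* "high" trials, which
  reads as attraction. The orientation averaging does not remove this, and
  at planted study sizes we measured offsets comparable to a morph of
  $\lambda \approx 0.2$. The pairwise pitch statistic conditions its
  baseline on the (current, previous) cell and is immune. Interpret binary
  shift timecourses jointly with the behavioral autocorrelation.
* The shift dose–response saturates at large $\lambda \times$ SNR: morphed
  and unmorphed trials form a mixture within each current condition, the
  covariance inflates along the chord, and whitening compresses exactly
  the direction the statistic measures. Monotonicity in $\lambda$ is a
  small-signal property.
* Wald z tests on GLMM fixed effects are mildly anticonservative at small
  participant counts; the calibration check bounds the inflation rather
  than pretending it away.
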