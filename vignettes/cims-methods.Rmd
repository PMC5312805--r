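---
title: "Causal inference in multisensory speech: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal inference in multisensory speech: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimspeech)
```

This vignette is the package's own account of the science it implements:
the observer model, the assumptions baked into it, the parameters that
matter, the calibration that produced the shipped defaults, and the places
where the design was genuinely open and a choice had to be made.

## The observer model

An audiovisual syllable has an auditory component and a visual component.
The observer represents both in a single two-dimensional space whose x-axis
carries auditory features and whose y-axis carries visual features (an
abstract internal space, in arbitrary "space units" — not physical stimulus
dimensions). Three syllable categories, "ba", "da" and "ga", are summarised
by prototype locations, a shared isotropic category covariance
$\Sigma_i = \sigma_c^2 I$ (different utterances scatter around the
prototype), and uniform category priors. "da" lies between "ba" and "ga" on
both axes — slightly closer to "ba" auditorily and to "ga" visually, which
is what makes the McGurk fusion geometry work.

One trial proceeds in five stages.

**Encoding.** Each modality is encoded independently with Gaussian noise:
$X_A \sim N(S_A, \Sigma_A)$, $X_V \sim N(S_V, \Sigma_V)$. A unisensory cue
carries some information about the other modality (hearing "ba" implies
closed lips), but less precisely: the cross-axis SD is `anisotropy` (1.5 by
default) times the own-axis SD, making $\Sigma_A$ and $\Sigma_V$
axis-swapped rotations of one another when $\sigma_a = \sigma_v$.

**Fusion (the $C=1$ representation).** Standard precision-weighted cue
combination: $\Sigma_{AV} = (\Sigma_A^{-1} + \Sigma_V^{-1})^{-1}$,
$X_{AV} = \Sigma_{AV}(\Sigma_A^{-1} X_A + \Sigma_V^{-1} X_V)$.

**Causal-structure likelihoods.** Under a common cause, one exemplar of
category $i$ drove both cues, so the fused representation is distributed as
$N(\mu_i, \Sigma_i + \Sigma_{AV})$; the $C=1$ likelihood is the
prior-weighted sum of these densities at $X_{AV}$. Under separate causes,
every ordered incongruent pair $(i, j)$ — category $i$ speaking to the ear,
category $j$ to the eye — is a hypothesis with equal prior $1/(L^2 - L)$.
The noise covariances are inflated by the hypothesised category scatter
($\Sigma_A' = \Sigma_A + \Sigma_i$, $\Sigma_V' = \Sigma_V + \Sigma_j$) and
the cues fused with the inflated precisions into a statistic $\mu_{C2}$
with covariance $\Sigma_{C2} = (\Sigma_A'^{-1} + \Sigma_V'^{-1})^{-1}$.

**Posterior and combination.** The log posterior ratio
$d = \log\frac{P(X_A, X_V \mid C=1)}{P(X_A, X_V \mid C=2)}
+ \log\frac{P(C=1)}{P(C=2)}$ becomes $p = P(C=1 \mid X_A, X_V)$ through the
logistic function. The final representation under the default
model-averaging strategy is $X_{CIMS} = p\,X_{AV} + (1-p)\,X_A$: when the
cues look like two talkers, perception falls back on the auditory cue,
because that is what people overwhelmingly report for unintegrated speech.

**Categorization.** The percept is the category maximising the Gaussian
density of the final representation with covariance
$\Sigma_i + \Sigma_{AV}$. Equal category covariances and priors make the
decision boundaries linear.

The forced-fusion baseline ("non-CIMS") takes $X_{AV}$ as final —
identically parameterised, so any behavioral dissociation between the two
models isolates the causal-inference step. It is exactly the
`prior_common = 1` special case, and the package tests that equivalence
bit-for-bit.

## Where the printed formula was ambiguous

The separate-cause likelihood is stated in the source as a bivariate normal
density $N_2(X_A, X_V;\, \mu_{C2}, \Sigma_{C2})$ — ambiguous, because
$\mu_{C2}$ is itself a function of $(X_A, X_V)$ and a two-dimensional
density cannot take a four-dimensional argument. We evaluate the
inflated-precision fusion **of the data** against the identically fused
**prototype pair**, with covariance $\Sigma_{C2}$:

$$P(X_A, X_V \mid S_i, S_j) =
N_2\!\big(\mu_{C2};\, \Sigma_{C2}(\Sigma_A'^{-1}\mu_i +
\Sigma_V'^{-1}\mu_j),\, \Sigma_{C2}\big).$$

This is not an arbitrary reading: under hypothesis $(i, j)$ the marginal
distribution of the statistic $\mu_{C2}$ is exactly that Gaussian (the
weights satisfy $W_A \Sigma_A' W_A^\top + W_V \Sigma_V' W_V^\top =
\Sigma_{C2}$), and it mirrors the $C=1$ rule, which likewise scores only the
integrated location rather than the joint cue vector — a simplification the
source itself notes. Because the category covariance already enters through
$\Sigma_A'$ and $\Sigma_V'$, it is **not** added a second time at
evaluation. The alternative joint-cue scoring
$N_2(X_A; \mu_i, \Sigma_A')\,N_2(X_V; \mu_j, \Sigma_V')$ is available for
sensitivity analysis via `model_config(..., c2_eval = "joint")`; it sharpens
the congruent/incongruent contrast but is not used by the defaults.

A second ambiguity — whether "the variance of the syllable category that
generated the exemplar" means the hypothesised or the true generating
category — is resolved toward the hypothesised category, since the true one
is unknowable to the observer.

A third: the source's methods and results sections disagree about which
axis is auditory. We follow the methods convention throughout (x =
auditory, y = visual) and treat the other passage as a typo; the model is
symmetric under relabelling, so nothing empirical hinges on it.

## Parameters, units, defaults

| parameter | meaning | default | why |
|---|---|---|---|
| prototypes | category locations (space units) | ba = (0,0), ga = (1,1), da = (0.347, 0.560) | gauge fixed at the corners; "da" calibrated |
| `category_sd` | within-category scatter per axis | 0.049 | calibrated |
| `sigma_a`, `sigma_v` | encoding noise SDs along the own axis | 0.126, 0.115 | calibrated |
| `anisotropy` | cross-axis SD multiplier | 1.5 | stated model constant |
| `prior_common` | $P(C = 1)$ | 0.5 | no prior bias toward one or two talkers |
| `n_trials` | Monte-Carlo trials per stimulus | 10,000 | matches the published simulation size |
| `strategy` | combination rule | `averaging` | the published model; `selection` (winner-take-all) and `matching` (probability matching) are provided as the standard alternatives discussed in the causal-inference literature |

The gauge ba = (0,0), ga = (1,1) removes the translation/scale
non-identifiability of an abstract space; only the "da" location, the
category SD and the noise SDs are scientifically meaningful degrees of
freedom.

## Calibration of the unpublished parameters

The source never printed prototype coordinates, the category SD, or the
noise SDs ("chose the values heuristically"). The shipped defaults are
therefore produced by `cims_calibrate()`: root-mean-square error between
model and observed proportions over all reported cells, minimised by a
coarse grid search (4 points per parameter) followed by Nelder–Mead
refinement started from the three best grid points, 2,000 evaluation trials
per stimulus, and a fixed evaluation seed so the optimizer sees a
deterministic surface (final reporting re-evaluates on fresh seeds). The
behavioral matrix it fits ships in `inst/extdata/behavior-reported.csv`:
the seven cells printed in the source text (McGurk 57% "ba" / 40% "da";
inverse-McGurk 96% "ga" / 2% "da"; congruent diagonals at the 97% mean
accuracy), all other cells explicitly missing rather than guessed from
color maps.

Seven observed cells cannot identify five parameters. Unconstrained, the
RMSE optimum drifts into a regime (strongly unequal noise SDs, "da" pulled
toward "ba") that fits the seven cells marginally better but destroys a
printed property of the model family: the forced-fusion baseline's
prediction of the fused percept on >99% of incongruent trials. Since the
parameters are shared between the two models, the calibrated defaults must
be consistent with the baseline's printed behavior too. `cims_calibrate()`
therefore penalises candidates whose `non_cims` variant drops below a 99%
"da" floor on either incongruent syllable type (`baseline_floor`,
disengageable with `NULL`). The constrained fit reaches RMSE 0.019 and
reproduces the McGurk "ba"/"da" split at the behavioral values.

One consequence is worth stating plainly: a model calibrated to the
*behavioral* proportions reproduces those proportions (57/43 for the McGurk
split), not the *heuristic-parameter model predictions* the source printed
(51/49). The two differ by about six percentage points because the source
did not fit its parameters to its own data. No parameter setting can
reproduce both at once; the package ships the calibrated (behavior-matching)
defaults and reports whatever they produce.

```{r calibration, eval = FALSE}
cal <- cims_calibrate(behavioral_fixture(), seed = 1)
glance(cal)
write_config(cal$fitted_config, "my-config.yaml")
```

## The synthetic behavioral generator

`simulate_subjects()` emulates the design of the source experiment — 60
subjects, all 9 audiovisual pairings of ba/da/ga, 10 repetitions,
three-alternative forced choice (the "da/tha" response option is mapped to
"da") — so that end-to-end workflows (generate, aggregate, calibrate,
compare) can run without any data download. Individual differences enter as
subject-level log-normal multipliers on the two noise SDs (median 1, sdlog
0.15 by default — a modest spread consistent with the well-documented
variability in McGurk susceptibility) and optionally a subject-level causal
prior on the logit scale; parameters are drawn once per subject and held
fixed across that subject's trials, matching a repeated-measures design.

What the generator does **not** emulate: response bias, lapses and
attention failures, learning or adaptation across trials, stimulus-level
(talker) variability, and online-panel exclusion artifacts. Passing
recovery tests on this generator therefore demonstrates that the
calibration machinery is self-consistent under the model's own assumptions,
not that the model family is identifiable from arbitrary real data.

Parameter recovery under the published design (60 × 9 × 10) recovers the
generating noise SDs to within a few percent (the test suite asserts 20%
relative error); the category SD is recovered far more loosely, as only a
few boundary-adjacent cells constrain it.

## Numerical choices

- All densities are evaluated in log-space with log-sum-exp pooling; a
  dedicated closed-form 2×2 Gaussian log-density (explicit determinant and
  precision) keeps the Monte-Carlo hot loop vectorised over trials.
- `prior_common` of exactly 0 or 1 short-circuits the posterior without
  evaluating likelihoods — the forced-fusion equivalence is exact, not
  approximate. If both causal likelihoods underflow even in log-space the
  trial errors rather than silently returning 0.5.
- Exact categorization ties (measure zero, but constructible) break
  deterministically by label order.
- Singular or non-positive-definite covariances raise a diagnostic error
  rather than propagating NaNs.
- One seeded generator drives a simulation run; within a run the stream
  order is fixed (auditory deviates, then visual, then the
  matching-strategy uniforms, when used). Grid simulations derive one
  sub-seed per stimulus from the master seed and the stimulus's position in
  the full label grid, so adding stimuli to a run never perturbs existing
  rows.
- A `zero_noise` flag implements the noiseless limit by pinning encodings
  to the prototypes while leaving the covariances used by fusion and
  inference untouched (the limit of the draws, not of the model).

## Problem sizes

Headline simulations use the published 10,000 trials per stimulus
(seconds). Calibration evaluates its objective with 2,000 trials per
stimulus — cell standard errors around one percentage point, well below the
structure in the loss surface — for roughly a two-minute calibration on one
CPU; unit tests use a few hundred trials where only structural properties
are asserted.

## Known limitations

- The representational space is 2-D with three categories; voice-onset
  time, temporal asynchrony and talker identity are outside the model.
- Percept probabilities are Monte-Carlo estimates; there is deliberately no
  analytic integration path to cross-check them beyond convergence tests.
- The calibration objective is RMSE on proportions because the packaged
  behavioral fixture has no counts for most cells; multinomial likelihood
  would need the full per-subject data.
- Congruent model-behavior correlations against the packaged fixture are
  undefined (the three reported congruent cells are all 0.97, so the
  behavioral vector has zero variance); correlations over the congruent
  subset require full-grid behavior such as the synthetic cohort's.
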