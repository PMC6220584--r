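---
title: "Estimating temporal weighting strategies from pulse-based motion discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporal weighting strategies from pulse-based motion discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsekernel)
```

## The problem

When an observer integrates a stream of sensory evidence into a binary
choice, not every moment of the stream counts equally. Reverse correlation
— regressing choices on the trial-to-trial fluctuations of each stimulus
epoch — recovers a *temporal weighting kernel* that makes this explicit.
Early-heavy kernels are commonly read as bounded accumulation (once an
internal bound is hit, later evidence is ignored); late-heavy kernels as
leaky integration (early evidence decays). Kernels can also simply track
the statistics of the stimulus itself when those are manipulated over time.

`pulsekernel` implements the full measurement chain for a pulsed motion
task, and — because the behavioral datasets this kind of analysis is run on
are rarely public — ships a generative stimulus simulator and a family of
ground-truth observers so that every estimator in the chain is validated by
parameter recovery on synthetic cohorts.

## The stimulus model

A trial is a sequence of `n_pulses` motion pulses (default 7, 150 ms each,
1050 ms total). The stimulus is physically a grid of `n_elements = 19`
Gabor patches; a pulse's signed strength is the proportion of elements
drifting coherently, with sign encoding direction. Strength on pulse `i` is
drawn as `X_i ~ N(mu_k(i), sigma)` with `sigma = 0.15`, where `k` indexes
the five generating distributions, `mu_k` in {-0.50, -0.10, 0, +0.10,
+0.50}. The observer is rewarded for reporting the sign of the *realized*
sum of the pulses, whatever distribution generated them.

Two modelling decisions are worth stating explicitly:

* **Quantization.** Because the stimulus is physically composed of 19
  discrete elements, strengths are quantized by rounding
  `strength * n_elements` to the nearest signed element count — half away
  from zero so that leftward and rightward strengths round symmetrically —
  and clipping to `+/- n_elements`. Realized strengths therefore live on
  the lattice `{-19..19}/19`. (The alternative reading, rounding to integer
  percent coherence, would decouple the stimulus from its physical element
  count.)
* **Temporal transition.** In the `late` condition the per-pulse mean rises
  from 0 at pulse 1 to `mu_k` at the final pulse following a logistic
  function `1 / (1 + exp(-(i - 4) / 0.3))`, affinely rescaled so the first
  and last pulses hit 0 and `mu_k` *exactly*; the rescaling is what lets a
  smooth curve honor both endpoint constraints. `early` is defined as the
  exact time reverse of `late`. A multiplicative-rate parameterization of
  the "slope 0.3" was rejected because it cannot reach `mu_k` by the final
  pulse. Zero-mean trials (`mu_k = 0`) have an all-zero mean profile in
  every condition, which is what makes them condition-invariant probes.

Sessions may include *frozen-seed* trials: a single pulse sequence,
rejection-sampled from the zero-mean distribution until its element counts
sum to exactly zero, repeated identically for a small fraction of trials
and rewarded at random. Non-frozen trials whose realized sum happens to be
exactly zero are also rewarded at random, by extension of the same rule.

```{r profiles}
cfg <- stimulus_config(condition = "late")
condition_profile(cfg, 0.10)
```

## Ground-truth observers

The observers are test instruments, not claims about any real subject:

* `linear_observer(kernel, bias, lapse)` is the exact generative inverse of
  the estimation model: P(rightward) =
  `lapse + (1 - 2 lapse) * plogis(kernel . pulses + bias)`. Any kernel
  recovered from its choices can be compared against `kernel` directly.
* `accumulator_observer(gain, bound, leak, noise_sd)` updates a scalar
  state once per pulse — decay by `1 - leak`, add `gain * pulse + noise` —
  and absorbs at `+/- bound` (later pulses then ignored; the absorbed sign
  is kept). The bound produces early weighting, the leak late weighting,
  and `bound = Inf, leak = 0, noise = 0` is the perfect integrator, whose
  choices equal the sign of the pulse sum.
* `extrema_observer()` reports the sign of the single strongest pulse
  (largest absolute element count, earliest pulse on ties) — the
  non-integrating strategy the consistency control is designed to detect.

The accumulator operates at pulse resolution (7 updates per trial) rather
than continuous time because the kernel is estimated at pulse resolution;
a finer-grained diffusion would be invisible to the analysis.

## Psychometric estimation

Choices are fit with the three-parameter logistic by maximum likelihood.
Net strengths are z-scored per subject across all of that subject's
sessions (population-SD convention) before fitting. The lapse `gamma` is
optimized on an unconstrained scale (`gamma = 0.5 * plogis(eta)`) because
unconstrained optimizers overshoot the `[0, 0.5)` box; a single symmetric
lapse is used for both response directions. Three deterministic starting
points are tried and the best likelihood kept. Standard errors come from
the inverse Hessian of the negative log-likelihood at the optimum,
evaluated in the natural parameterization (`pracma::hessian`); they can be
unavailable at the `gamma = 0` boundary or under separation, which the fit
flags rather than hides. The 75% threshold inverts the fitted function
including bias and lapse:
`alpha - (1/beta) log((0.25 - gamma) / (0.75 - gamma))`, undefined for
`gamma >= 0.25`. Thresholds are reported in the fitted x-units (z-scored
strength by default).

## Kernel estimation

The temporal weighting kernel maximizes the penalized Bernoulli log
posterior

```
L(w) = sum_i [ Y_i w'X_i - log(1 + exp(w'X_i)) ] - lambda ||w_pulse||^2
```

with the design `X` the pulse strengths augmented by a column of ones. Two
deliberate choices:

* **Penalty sign.** The penalty is *subtracted*, i.e. it is the standard
  Gaussian-prior (precision `2 lambda`) ridge term. An added penalty would
  be an anti-prior: the objective would lose concavity and the estimator
  would inflate rather than shrink weights. We read a printed `+` with an
  implicitly negative multiplier as equivalent to this form.
* **The bias is unpenalized.** Shrinking the intercept would bias the
  estimated choice bias toward zero for no statistical benefit; the
  evidence computation gives it an improper flat prior.

The optimizer is Newton's method with step halving on the (strictly
concave, for `lambda > 0`) objective, converging to gradient norms below
1e-9; tests verify agreement with an independent derivative-free optimizer
to 1e-4 per weight.

`lambda` is chosen by evidence optimization: the Laplace approximation to
the log marginal likelihood — log-likelihood at the MAP, plus the Gaussian
log prior, minus half the log determinant of the Hessian of the negative
log posterior — evaluated on a fixed grid of 25 log-spaced points in
`[1e-4, 1e4]`. The grid covers shrinkage from negligible to total at the
session sizes this analysis meets (hundreds to thousands of trials), and a
grid maximizer is deterministic given the data, which matters for
reproducible reports. Fitted kernels are normalized by their Euclidean norm
(bias excluded) before any comparison or summary.

Because logistic regression whitens the stimulus covariance, the kernel can
be estimated on *all* trials — including signal trials, where pulses are
correlated through the shared generating mean — not just the classical
zero-mean subset. `whitening_check()` verifies this on any cohort by
fitting both and correlating the two normalized kernels.

## Summaries, controls, QC

* `kernel_slope()` fits an OLS line to the normalized weights over pulse
  index; `kernel_energy()` is the sum of squared deviations of the weights
  from their mean. Both are invariant to positive rescaling of the raw
  weights because they are computed on normalized kernels.
* `group_statistics()` tests per-condition slopes against zero with the
  exact two-sided sign test (the conservative reading of a "sign test" on
  non-Gaussian slopes; the Wilcoxon signed-rank test is exposed as an
  option), compares condition means with one-way ANOVA, and condition
  variances with pairwise Bartlett tests.
* `consistency_analysis()` is the extrema-detection control: trials where
  the strongest pulse opposes the net direction ("inconsistent") are
  compared with difficulty-matched trials where it agrees. Matching is
  greedy nearest-neighbour on |net strength| without replacement with a
  maximum match distance of half a lattice step — simple, deterministic and
  auditable (matched row indices are returned). Accuracies carry exact
  Clopper-Pearson 95% CIs. A perfect integrator passes (equal accuracies);
  an extrema detector fails completely (0 vs 1 in the noise-free limit).
* `session_qc()` applies three inclusion rules: at least 250 completed
  trials; at least 85% accuracy on trials from the strongest-|mean|
  generating distributions; and a psychophysical threshold within 2
  *unscaled* median absolute deviations of the subject's median (no 1.4826
  consistency factor, since the rule is stated in raw MADs). Thresholds of
  all candidate sessions enter the MAD statistics before any exclusion, and
  subjects with fewer than 3 sessions skip the MAD rule with a warning.

## What the simulator does and does not emulate

The generator reproduces the pulse-level statistics of the task: the five
Gaussian generating distributions, the flat/early/late mean profiles,
element-count quantization, zero-mean trials, frozen-seed trials, and the
sign-of-sum reward rule. It does **not** render frames (no Gabor carrier
phase, contrast flicker, spatial layout), does not model fixation timing,
reaction times, reward history, motivation drift, or session-to-session
nonstationarity in the observer. Passing recovery tests therefore
demonstrate that the *estimators* are correct and well calibrated under the
task's generative statistics — they do not certify behavior on real data
with, e.g., sequential dependencies or nonstationary lapses, which should
be checked per dataset (the `continuous` dialect of `read_trial_table()`
accepts external, non-quantized trial tables).

## Numerical choices and validation sizes

Validation cohorts use 5,000 trials for kernel-shape recovery (five
ground-truth shapes: uniform, two linear ramps, a late hump with a
final-pulse dip, and a steep early profile; recovery criterion Pearson
r >= 0.95 between normalized estimated and true kernels — the uniform
shape, against which a correlation is undefined, is instead checked
pointwise to within 0.05 of `1/sqrt(7)`), and 10,000 trials for the
mechanism-signature and whitening checks. Shape-recovery cohorts are
zero-mean-only (the classical reverse-correlation design): every trial then
carries gradient information, whereas strong signal trials are decided
nearly deterministically and dilute recovery. The linear observers used for
recovery have kernel norm 10, i.e. a per-trial logit SD of about 1.5 on
zero-mean trials, comparable to a well-performing subject. The
leak-monotonicity property is checked on the grid `leak` in
{0, 0.25, 0.5}: beyond ~0.5 the mapping from leak to estimated slope
saturates and is no longer monotone, so larger leaks are not part of the
property.

Degenerate inputs are rejected loudly rather than silently repaired:
constant strengths cannot be z-scored, one-class choice vectors cannot be
fit, all-zero kernels cannot be normalized, `gamma >= 0.25` has no 75%
threshold, and off-lattice strengths fail table validation unless the
external-data dialect is requested.

## Limitations

The kernel model is linear-in-pulses through a sigmoid; real decision
processes contain nonlinearities this cannot express, and the estimated
kernel is an average over trials that may each have used a different
strategy. The evidence optimization uses a Laplace approximation and a
fixed grid rather than a continuous optimizer; at very small sessions
(fewer than ~10 trials per weight) the evidence curve can be flat and the
selected `lambda` correspondingly arbitrary, which is why the session QC
floor of 250 trials matters. The accumulator observers are discrete-time
and fixed-duration; reaction-time phenomena, collapsing bounds and urgency
signals are out of scope.
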