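---
title: "Methods: simulating and analyzing mouse-tracked food choice under nutrient warning labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing mouse-tracked food choice under nutrient warning labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nwlchoice)
```

## The paradigm

`nwlchoice` implements the computational chain of a two-alternative
food-choice experiment with front-of-package nutrient warning labels (NWL).
Participants, prompted into one of three eating contexts (*healthy*,
*typical*, *unrestricted*), click a start button and then choose one of two
food images shown in the upper screen corners, first for 90 pairs without
labels and then for the same 90 pairs with labels, under a 4-second
deadline. Each food carries 0–3 warning labels; the *healthy choice* is the
pair member with strictly fewer labels. The cursor path is recorded, and
two conflict measures are derived per trial: the area under the curve
(AUC) between the path and the direct start-to-choice line, and the
response time (RT). Because no raw data from such studies are assumed to
be available, the package ships a synthetic-data generator with known
ground truth, so every downstream stage — trajectory metrics, trial
filters, drift-diffusion fitting, Monte-Carlo parameter recovery, and the
behavioral estimates — is testable end to end.

## Stimulus inventories and constrained pair sequences

Each context uses its own image inventory (32/29/33 images for
healthy/typical/unrestricted, stratified over label counts as 8/6/8/10,
7/6/7/9 and 8/6/8/11; 94 images in total, never shared between contexts).
A context block consists of 15 pairs for each of the six unordered
label-count combinations (0v1, 0v2, 0v3, 1v2, 1v3, 2v3 — the source design
lists five and states "six possible combinations"; 1v3 is the only
remaining unordered pair and is included as the sixth). Sequences must
satisfy two further rules: any image skips at least two pairs before
reappearing, and no label count stays on the same screen side for more
than three consecutive pairs.

A naive shuffle-then-check generator is hopeless here: with ~31 images
filling 180 slots, a uniformly shuffled 90-pair sequence violates the
reuse-gap rule with probability essentially one (the per-pair collision
hazard is roughly 0.25, i.e. ~20 expected violations per shuffle).
`generate_pair_sequence()` therefore builds the sequence position by
position: a combination is drawn with probability proportional to its
remaining quota, images are drawn from the *least-used* eligible images of
each stratum (which keeps exposure even and the reuse gap easy to
satisfy), and the side assignment is chosen to respect the side-run rule;
if a position admits no legal placement the whole sequence restarts (up to
`max_retries`, default 1000 — in practice restarts are rare).
`validate_sequence()` is an independent scan of the finished sequence that
shares no state with the generator; the test suite audits 1000 generated
sequences against it.

## The synthetic study and its ground truth

`simulate_study()` draws, per participant: subjective health/like/want
ratings for every image (normal around label-count-indexed means, clamped
to the 0–100 visual-analogue scale; perceived healthiness decreases
monotonically with label count while liking and wanting are U-shaped,
lowest at 2 labels), Bernoulli image recognition (default 95%), the three
context blocks in random order, and per-trial choices and response times
from a drift-diffusion process.

Choices come from the four-parameter Wiener diffusion with unit diffusion
coefficient: boundary separation $\alpha$, non-decision time $\tau$ (s),
relative starting point (bias) $\beta$, and drift rate $\delta$ (evidence
/ s), with the healthy choice mapped to the upper boundary. The default
ground truth (`default_ddm_truth()`) assigns one parameter set per context
× label condition. Exact values are free parameters of the generator; they
were fixed once to mirror the qualitative structure and effect magnitudes
reported for this paradigm: the healthy context has the largest bias
(0.62) and drift (1.0) and the shortest non-decision time (0.30 s), the
unrestricted context the smallest bias (0.54) and drift (0.25) and the
longest non-decision time (0.36 s); showing labels multiplies drift by
~1.9 in the healthy and typical contexts and ~4.7 in the unrestricted
one, raises bias by 7.6%/6.9%/0%, and shortens non-decision time by
16.8%/9.6%/8.8% (healthy/typical/unrestricted). Between-participant
heterogeneity is one additive normal effect per parameter (SDs 0.10,
0.03 s, 0.04, 0.15), shared across that participant's conditions, clamped
to the valid region. Trials whose simulated response time exceeds the
deadline are kept with a `censored` flag — the quality-control policy,
not the generator, decides their fate (fitting excludes them with a
logged count).

Mouse paths live in a normalized frame: start button at the origin,
response targets at $(-1, 1.5)$ and $(1, 1.5)$, which makes the AUC
unit-free. A path is a quadratic Bézier from the start to the chosen
corner whose control point is pulled horizontally toward the *unchosen*
side in proportion to a per-trial conflict scalar, defined as one minus
the model probability of the chosen boundary — so choices made against
the drift curve more, and conditions with stronger drift produce
straighter healthy-choice paths. The cursor dwells exactly on the start
until a drawn initiation time, and white positional noise (SD 0.008) is
enveloped by $4s(1-s)$ along path progress $s$ so that jitter never
manufactures axis crossings at the start or the click. Sampling rates are
drawn per trial (default 60 ± 8 Hz, truncated at 20 Hz); the final sample
is the click, so the realized rate never exceeds the nominal one.

Four contaminant types can be injected at configurable per-trial rates,
each tagged in the trial table so filter recall is measurable: paths
resampled at 2–9 Hz; deterministic multi-crossing zigzag paths (at least
three axis crossings by construction, sampled densely enough that no
oscillation falls between samples); response-time outliers inflated to
87.5–98.75% of the deadline; and marking one image of a pair unrecognized
for that participant (which tags every trial showing that image).

What the generator does **not** emulate: trial-level coupling between
ratings and choices (ratings and choices are driven by the same label
counts but are otherwise independent), within-trial label reading,
sequential effects across trials, pixel quantization, or real image
content. Passing tests therefore demonstrate that the estimators recover
what this generative model encodes — not that the model captures every
property of human mouse-tracking data.

## Trajectory metrics

Paths are first made side-invariant: translated to start at the origin
and reflected horizontally when the right image was chosen (an
involution, so applying it twice is the identity). The AUC is the signed
area between the piecewise-linear path and the start-to-end chord,
computed by trapezoidal integration of the perpendicular deviation in the
rotated along/across-chord frame; deviation toward the unchosen side
counts positive. This equals the shoelace area of the closed polygon, the
oracle used in the tests, and scales as $c^2$ under coordinate scaling.
Signedness is a package choice (the convention of the mouse-tracking
literature; the absolute value is available via `signed = FALSE`).
Y-axis crossings are strict sign changes of the horizontal coordinate
about the start abscissa with exact zeros bridged. The initiation time is
the interval from the start press to the first sample displaced more than
0.02 normalized units from the origin (configurable; paths that never
move are flagged and given initiation time equal to the response time).
No spatial resampling or time-normalization is applied. The sampling rate
is $(n_{\mathrm{samples}}-1)/\mathrm{span}$.

## Trial quality control

`apply_trial_filters()` applies the standard exclusion rules in one
conjunctive pass: sampling resolution strictly below 10 Hz; initiation
time, AUC, or RT strictly above the participant's mean plus 3 SD;
three or more axis crossings; and fewer than two recognized images in
the pair. The outlier baselines are computed per participant over that
participant's resolution-passing trials across the whole session —
whole-session rather than per-context for stability (per-context is
available via `per_context = TRUE`), and in a single pass rather than
sequentially recomputing SDs after each rule, which keeps the report
order-independent. Participants with fewer than two usable trials keep
their trials with a warning. The report lists marginal per-rule counts
and fractions; a trial may trip several rules.

## Drift-diffusion likelihood, fitting and recovery

The Wiener first-passage density is evaluated with the classic dual-series
expansion: the small-time and large-time forms are both exact limits of
the same density, and for every evaluation the branch needing fewer terms
at absolute tolerance $10^{-10}$ is used. The upper-boundary density is
obtained by reflection ($\beta \to 1-\beta$, $\delta \to -\delta$). The
sampler is Euler–Maruyama (default step 1 ms) with the Brownian-bridge
within-step crossing probability, which removes the leading
$O(\sqrt{dt})$ boundary-detection bias; for constant drift the step
endpoints are exact, so the remaining bias is the double-crossing term
only. Tests check normalization against quadrature, the reflection
identity, the closed-form hit probability
$(1 - e^{-2\delta\alpha\beta})/(1 - e^{-2\delta\alpha})$, the closed-form
mean decision time at $\beta = 1/2$, and a Kolmogorov–Smirnov distance
below 0.01 between the density and $10^5$ simulated trials at
$dt = 10^{-4}$.

`fit_ddm()` maximizes the joint likelihood by Nelder–Mead simplex on a
scaled-logit-transformed space (bounds: $\alpha \in [0.1, 10]$, $\tau$
between 0 and the minimum observed RT, $\beta \in [0.01, 0.99]$,
$\delta \in [-10, 10]$), with five dispersed restarts whose starting
points are seeded from the choice fraction and jittered. Response times
at or below a candidate $\tau$ receive a guarded $-10^{10}$
log-likelihood so the simplex can traverse the region. One fit is
produced per participant × context × label condition, pooling label-count
combinations within the cell (the level at which parameters are
reported); cells below `min_trials` (default 20) are flagged, not
dropped.

The recovery study follows the Monte-Carlo logic of the paradigm: per
condition, the mean vector and covariance of the converged individual
fits define a multivariate normal (covariance clipped to positive
semi-definite if needed); 1000 parameter sets are drawn (invalid draws
clamped to the valid region, preserving the draw count, with a log);
128 response times are simulated per set and refitted with the same
settings; and individual parameters outside the central 95% of the
recovered marginals (type-7 empirical quantiles; "outside the 5%
quantile" read as total tail mass 0.05, two-sided, with one-sided
readings selectable) are flagged. The headline recovery correlation is
Pearson's r between the generating draws and their refits — the pairing
that actually measures whether estimation returns what generated the
data; the refit-vs-source pairing can be formed from the returned
matrices if wanted. The source text's "128 RT" per parameter set is kept
as the default `n_rt` but exposed as a parameter, since its origin
(plausibly the participant count) is not derivable from the design.

## Behavioral estimates and uncertainty

The analysis module computes healthy-choice probabilities (per context ×
label condition), decision paths (HH/HU/UH/UU across the two blocks of
the same pair, first letter = label-free choice), the reversal
probability $P(\mathrm{healthy\ with\ labels} \mid \mathrm{unhealthy\
without})$ — identically $|UH|/(|UH|+|UU|)$, an identity the tests assert
exactly — label-induced changes $\Delta = \mathrm{value}_{NWL} -
\mathrm{value}_{noNWL}$ in AUC and RT (negative = labels reduced
conflict or sped the choice), and the healthy-choice probability by
within-pair label difference (1–3). Pairs with either block filtered out
are dropped from paired analyses with a logged count.

Instead of wrapping a mixed-effects stack, all estimates are direct
pooled proportions/means with a participant-cluster percentile bootstrap
(default 2000 resamples, seeded): participants are the exchangeable
units, so resampling them respects the repeated-measures structure while
targeting the same marginal estimands; this substitution is recorded in
the output metadata. $\Delta$ summaries are baseline-adjusted by
regressing $\Delta$ on the grand-mean-centered baseline within each
context × path cell and evaluating at the grand mean, which removes the
regression-to-the-mean component; cells with a constant baseline fall
back to the unadjusted mean with a note. Cells whose bootstrap interval
excludes zero are flagged. Covariates (age, sex, BMI, ...) pass through
for external modelling but are not adjusted for in the headline
estimates.

## Numerical and design choices, problem sizes, limitations

Sizes used by the test and acceptance runs were chosen as the smallest
that make the stochastic checks stable: density/sampler agreement at
$10^5$ draws; recovery correlations over 100 conditions at 1000
trials each; exclusion-rate calibration with 50 source fits and 250
recovery refits at 350 trials; the constraint audit over 1000 seeds; and
a full 50-participant study (27,000 trials) for the end-to-end ordering
checks — with the configured ground truth the estimated healthy-choice
probability orders healthy > typical > unrestricted in both label
conditions and the reversal probability is maximal in the healthy
context.

Known limitations: reversal probabilities in the synthetic world are
higher than in real data because the two blocks of a pair are
conditionally independent given the condition parameters (real
participants are consistent within pairs, which no parameter here
controls); the diffusion coefficient is fixed at 1 (the convention of
standard Wiener-likelihood tools), so $\alpha$ and $\delta$ are in that
scale; censored trials contribute no likelihood (no deadline-truncation
correction); and hierarchical/Bayesian estimation and trial-level rating
regressors in the drift are out of scope.
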