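---
title: "The economics of cleaning gritty food: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The economics of cleaning gritty food: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gritclean)
```

## The problem

Sand on food surfaces is harder than tooth enamel; chewing it wears teeth.
Monkeys that receive provisioned food on beaches — such as the long-tailed
macaques of Koram Island, Thailand — can mitigate this cost by brushing
sand off with their hands (fast but sloppy) or carrying food to the ocean
and washing it (thorough but slow). Each behavior faces diminishing
returns: the first seconds of cleaning remove most of the sand, and every
further second removes less. `gritclean` models this trade-off, estimates
how efficient each behavior is from efficacy assays, predicts how long a
rate-maximizing forager *should* clean, and measures how far observed
animals overshoot that optimum.

## The model

We assume the fraction of sand removed after $t$ seconds of cleaning
saturates as

$$g(t) = \frac{t}{c + t},$$

where $c$ (seconds) is the **cleaning inefficiency**: the half-saturation
constant, i.e. the cleaning time needed to remove half the sand. Small
$c$ means an efficient behavior. The assumption is the usual
diminishing-returns one — removal is proportional to the sand remaining —
and matches assay data well over the few-second range that matters; we do
not claim validity in the extreme tail, where $g \to 1$ only
asymptotically.

Cleaning is not the only time cost. Before cleaning starts, the animal
spends a **handling time** $h$: a fixed assessment period (visual
fixation, reaching; set to 1 s) plus any pre-cleaning activity. For
brushing the pre-cleaning time is essentially nil; for washing it is the
walk to the water, which on Koram Island averages 22 s (SD 15 s, observed
range 5–78 s).

In the spirit of the marginal value theorem, the currency is the rate of
sand removal per unit of total time invested:

$$R(t) = \frac{g(t)}{h + t} = \frac{t}{(c + t)(h + t)}.$$

$R$ is unimodal with a single interior maximum. Setting $R'(t) = 0$
gives the **optimal cleaning time**

$$t^{*} = \sqrt{c\,h}, \qquad
  R(t^{*}) = \frac{1}{(\sqrt{c} + \sqrt{h})^{2}}.$$

A grid-search oracle in the test suite confirms the analytic maximizer
over a thousand random $(c, h)$ pairs. Cleaning past $t^*$ is
**overcleaning**: the ratio of observed cleaning durations to the
predicted $t^*$ quantifies it.

Because $R(t^*)$ depends on $c$ and $h$ only through
$\sqrt{c} + \sqrt{h}$, the locus of strategies with equal maximal rates
is the curve $\sqrt{c} + \sqrt{h} = \text{const}$
(`strategy_frontier()`). It separates the plane into region I
(strategies slower than the reference — the long-handling, efficient
oceanside-washing corner) and region II (faster — the short-handling,
inefficient immediate-brushing corner).

## Estimating the inefficiency

An efficacy assay reports, for one behavior, a cleaning time $t$ and the
mean fraction of sand it removed, $g$, with a replicate SD. Inverting the
saturating curve at that point gives the estimator

$$\hat c = t\,\frac{1 - g}{g},$$

undefined at $g = 0$ or $1$ (degenerate assays are rejected). Field
assays with cucumber slices give $t = 2.97$ s, $g = 0.75$ for brushing
($\hat c = 0.99$ s) and $t = 3.53$ s, $g = 0.93$ for washing
($\hat c \approx 0.27$ s): washing is the intrinsically efficient
behavior, before handling costs are charged.

Uncertainty is propagated by Monte Carlo: removal fractions are drawn
from a normal distribution with the assay mean and SD, truncated to
$(0.01, 0.99)$ so the inversion stays finite, and mapped through
$\hat c(g)$. The truncation bounds act only in pathological corners
(mass near 0 or 1); at the observed assay values fewer than a percent of
draws touch them. When a fit pools several assay points for one
behavior, per-point estimates are averaged and their Monte-Carlo draws
averaged elementwise, which is the Monte-Carlo distribution of the
averaged estimator. An alternative bootstrap sampler over raw replicate
values is available when replicate-level data exist.

## Monte-Carlo prediction of $t^*$

`propagate()` draws $(c_i, h_i)$ pairs, computes
$t_i^* = \sqrt{c_i h_i}$, and reports the mean, SD and the 5–95
percentile interval — percentile, not normal-theory, because the
distribution of $t^*$ is right-skewed and we make no distributional
claim. Default samplers:

* $c$: truncated normal (mean $\hat c$, SD from the assay inversion,
  lower bound 0.01 s). Truncation is by rejection; a rejection rate
  above 50% aborts with a configuration error, catching nonsensical
  sampler settings early.
* $h$: the 1 s assessment constant, plus (for washing) a travel time
  drawn from a truncated normal clipped to the observed 5–78 s range.

With 10,000+ draws these give $t^*_{\text{brushing}} \approx 0.98 \pm
0.20$ s and $t^*_{\text{washing}} \approx 2.6 \pm 0.9$ s. Note two
second-order effects worth knowing about: (i) by Jensen's inequality
(concavity of the square root) the Monte-Carlo mean sits slightly
*below* $\sqrt{\bar c \bar h}$ — `jensen_gap()` measures this, about
+0.02 s for brushing; (ii) clipping travel times at 5 s removes the left
tail and pushes the washing mean slightly *above* the point prediction
$\sqrt{0.27 \times 23} \approx 2.49$ s. Whether washing's handling time
should include the assessment second on top of travel is not
empirically resolvable at this precision; both conventions sit well
inside the Monte-Carlo interval, and the decomposition is configurable
in `strategy_params()`.

Determinism: every result records its seed and draw count, and the same
configuration reproduces bit-identical results.

## Overcleaning

`overcleaning_factor()` divides a central tendency of observed cleaning
durations by the predicted Monte-Carlo mean $t^*$. Three conventions are
deliberately exposed rather than hard-coded, because reporting practice
varies: the treatment conditioned on (default: the high-sand treatment,
where cleaning is reliably elicited), the center (default: mean), and
whether zero-duration bouts count (default: excluded — a bout with no
cleaning at all is evidence about the *decision* to clean, not about how
long cleaning is sustained once begun). Under these defaults, observed
high-treatment durations of ~3 s against predicted optima of ~1 s
(brushing) and ~2.6 s (washing) put the brushing factor well above the
washing factor, with both above 1 — brushing is the more flagrantly
overcleaned behavior, washing closer to rational.

## Bout pipeline

Field bout tables carry one row per food-handling event (from first
contact with a slice until the last piece enters the mouth):
identifiers, sex, ordinal dominance rank, sand treatment (closed
vocabulary `low`/`intermediate`/`high`; anything else fails fast),
brushing/washing/travel durations, slices consumed, and the trial's
participant count. Processing steps:

* `filter_trials()` drops trials with more than 3 participants
  (scramble competition suppresses cleaning and erases the individual
  variation of interest), logging the excluded count.
* `treatment_summaries()` reports median-with-SD per treatment and
  behavior. The pairing of a median with an SD is unusual but kept
  deliberately: these zero-heavy, right-skewed durations are best
  located by a median, while the SD conveys spread on the raw scale.
  Zeros are real observations and stay in.
* `energy_intake_rate()` converts slices to energy at 1.1 kcal x
  4.186 kJ/kcal per slice.
* `standardize_ranks()` merges both sexes into one dense ordinal
  ranking 1..n (1 = most dominant). The species' hierarchy is strictly
  linear, so tied raw ranks are treated as data errors, not broken
  arbitrarily.
* `model_ready_table()` emits exactly the columns a zero-inflated
  mixed-model fit consumes. Durations are recorded at 0.1 s video
  resolution but modeled as whole-second counts, so they are
  floor-rounded here (with a logged count); fitting the models
  themselves is out of scope — any GLMM package can take the table
  from this point.

## Particle morphometrics

Sand particles recovered from food surfaces are summarized by:

* **circularity** $4\pi A / P^2$, clipped to $[0,1]$ (digitized
  near-circles can exceed 1 by rounding); 1 for a circle, $\pi/4$ for a
  square. Raw polygon area and perimeter are used here, so concavity
  counts against circularity.
* **Feret (caliper) diameters**: the max Feret is the largest point-pair
  distance on the convex hull (exact); min and mean Feret come from a
  1-degree caliper sweep (180 directions) — a stated, reproducible
  discretization whose error on the mean width is far below measurement
  noise. Concave outlines are measured on their hull, which is what a
  physical caliper would do. Collinear point sets are rejected.
* **grittiness fraction**: the share of particles whose mean Feret
  diameter is below 25 µm, the approximate threshold of human oral grit
  detection — particles below it abrade enamel undetected.
* **size bins**: default edges 5, 15, 25, 50, 100, 150, 200, 400, 600,
  1000 µm (left-closed, right-open), overridable since standard
  contamination size classes are not published with explicit edges.
  Particles under the 5 µm imaging floor are excluded with a logged
  count.
* the **size–circularity trend**, an OLS slope used purely
  descriptively (larger particles are more angular, hence riskier to
  enamel).

Composition labels (e.g. quartz) are carried through as inputs; X-ray
classification of particles is instrumentation, not statistics, and is
out of scope.

## Synthetic data: what it emulates, and what not

The generators exist so every stage is testable end-to-end without any
field data, and each records its seed (per-stream substreams derive from
one global seed, so adding a stream never perturbs another).

`simulate_experiment()` emulates the feeding-trial design: ~100 trials,
24 individuals (8 male, 16 female) in a strict hierarchy, three sand
treatments, zero-inflated Poisson cleaning durations at 0.1 s
resolution whose means rise with sand load, washing gated by a
logit-quadratic propensity in standardized rank
(`plogis(4 - 9 r^2)`, $r \in [-1, 1]$): mid-ranked animals wash most and
the extremes essentially abstain, as observed in the field. Travel times
for washing bouts come from the truncated 22 ± 15 s distribution. The
treatment-level duration means and zero-inflation rates
(brushing λ = 0.3/1.8/3.5 s with zero inflation 0.80/0.35/0.10;
washing λ = 0.5/2.0/4.0 s with 0.90/0.15/0.05) are plausible
placeholders chosen once so that medians are treatment-ordered for both
behaviors — they are *not* fitted effect sizes, and tests against this
generator validate the pipeline's mechanics, not any field effect size.
A Conway–Maxwell-type underdispersion option is deliberately not
emulated; the ZIP law suffices for pipeline testing. The generator also
omits kinship, social networks, temporal autocorrelation and
individual-level random effects beyond rank — passing tests therefore
say nothing about those features of real data.

`simulate_assay()` adds truncated Gaussian noise (default SD 0.07) to
the saturating curve at chosen assay times; at SD ≥ 0.5 it warns that
the assay is uninformative.

`simulate_particles()` draws mean Feret diameters from a two-component
lognormal mixture (defaults: equal weights, medians 15 and 60 µm, log-SDs
0.45 and 0.8), placing about half the sample below the 25 µm threshold
with a realistic bimodal shape and upper tail. Each particle is a
64-vertex ellipse whose elongation is solved numerically (uniroot on the
discretized-ellipse circularity) so its measured circularity equals a
linear trend in size (default slope −0.001 µm⁻¹, intercept 0.9, noise SD
0.05, clipped to [0.05, 0.999]), and which is scaled so its mean caliper
width equals the drawn size — using Cauchy's formula that a convex
body's mean width is its perimeter over π. This makes the configured
trend exactly recoverable by the measurement pipeline. Real sand is
angular, not elliptical; the generator controls the circularity *value*,
not the outline's texture, so it cannot exercise concave-outline edge
cases (those are covered by direct geometric tests instead).

`recovery_harness()` closes the loop: simulate an assay, estimate
$\hat c$ and its 5–95% interval, repeat (default 100 replicates of 100
measurements at the brushing assay time, noise SD 0.07), and report
bias, RMSE and interval coverage. With the defaults, bias on $c$ is a
few thousandths of a second and coverage is within a few points of the
nominal 90%.

## Numerical choices and degenerate inputs

* $c \le 0$, $h \le 0$, $t < 0$ are domain errors naming the offending
  parameter; $0 < c < 10^{-9}$ is handled as the $c \to 0$ limit
  ($t^* \to 0$, max rate $\to 1/h$) with a warning rather than an error.
* Frontier grid values with $\sqrt{c} \ge \sqrt{c_\text{ref}} +
  \sqrt{h_\text{ref}}$ admit no positive $h$ and are omitted with a
  warning count.
* Monte-Carlo configurations require at least 1000 draws so percentile
  intervals are meaningful; results below report 10,000–20,000.
* Reports round seconds to two decimals; full precision is kept
  internally.
* Test problem sizes (chosen to probe each property at negligible cost):
  1000 random $(c,h)$ pairs for the optimizer oracle, 200 random convex
  polygons for the caliper oracle, 100 simulate–estimate replicates for
  recovery, 2000-draw Monte Carlo inside pipeline smoke tests.

## Known limitations

* The saturating-removal form is assumed, not selected from data; a
  different kinetic law (e.g. with a removable asymptote below 1) would
  shift $\hat c$ and $t^*$.
* $t^*$ maximizes the *rate of sand removal* only. It prices neither the
  energetic cost of travel nor the fitness value of tooth preservation,
  so deviations from $t^*$ are "suboptimal" strictly in this currency.
* The inefficiency estimator uses single-point inversion (averaged over
  points when several are given) rather than a nonlinear least-squares
  fit across times; with one or two assay points — the realistic case —
  the two coincide.
* Circularity is a 2-D projection proxy for sphericity; 3-D shape is out
  of scope.
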