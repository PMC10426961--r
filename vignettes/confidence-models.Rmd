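---
title: "Modelling category choice and confidence under sensory uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling category choice and confidence under sensory uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcat)
```

## The behavioural setting

`confcat` models two-alternative categorisation with confidence. On each
trial an observer sees (or hears) a stimulus whose single relevant attribute
— orientation in degrees, or pure-tone frequency in Hz — was drawn from one
of two Gaussian category distributions. The observer reports the category
(1 or 2) and a confidence rating from 1 to 4. Two category structures are
supported:

* **different means**: the categories share a standard deviation and differ
  in mean (visual ±4° with SD 5°; auditory 2300/3100 Hz with SD 475 Hz);
* **different SDs**: the categories share a mean and differ in spread
  (visual SDs 3° and 12° around 0°; auditory 125 and 500 Hz around
  2700 Hz), so category 1 occupies the centre of category 2's range and the
  optimal partition is a pair of boundaries.

Stimulus intensity (contrast or loudness) is manipulated over four levels,
which changes the reliability of the observer's measurement but not the
category structure. Before modelling, stimulus values are z-scored against
all presented values of the task–modality configuration, putting degrees
and hertz on one scale (`fit_standardizer()`).

Two stimulus-side transforms summarise the category structure: the evidence
that a value came from category 2 (its category-2 density over the summed
densities, `evidence_for_category2()`), and category diagnosticity (the
normalised density of the more probable category,
`category_diagnosticity()`). For a different-SDs pair the evidence never
reaches 0 — the narrow category sits inside the wide one — and its minimum,
attained at the shared mean, is $\sigma_1 / (\sigma_1 + \sigma_2) = 0.2$
for both the visual (3/15) and auditory (125/625) configurations.

## The observer models

All models share the same front end: the internal measurement $x$ of a
standardized stimulus $z$ is Gaussian, $x \sim N(z, \sigma_I^2)$, with one
noise SD per intensity level $I$, constrained non-increasing from the
weakest to the strongest intensity. A variant for visual data adds
orientation-dependent noise, $\sigma(I, s) = \gamma_I + \psi\,
\lvert\sin(\pi s / 90)\rvert$, a rectified two-cycle sinusoid peaking at
oblique orientations; it is parameterised in degrees (its 90° period is a
physical property of orientation) and divided by the configuration's
standardizer SD before use on the standardized axis. Whether that
conversion should instead happen inside the sinusoid is not determined by
the measurement model itself; we convert the result, which preserves the
period in physical degrees.

The models differ in how the measurement becomes a joint
category–confidence response. Eight *response regions* $r = 1..8$ encode
the response: regions 1–4 are category 1 with confidence 4 down to 1,
regions 5–8 category 2 with confidence 1 up to 4, ordered so neighbouring
regions differ by one confidence step and extreme category evidence earns
high confidence.

**Unscaled evidence strength (distance).** The observer compares $x$ with
fixed boundaries $b_r = k_r$ that ignore sensory uncertainty. In the
different-means task the seven cuts are $(-b_4, -b_3, -b_2, b_1, b_2, b_3,
b_4)$: a free category criterion $b_1$ (not pinned to 0 — fitted values sit
near but not at zero) plus three confidence boundaries mirrored about zero.
In the different-SDs task the cuts are symmetric half-widths $b_1 < \dots <
b_7$ about a centre fixed at the standardized category mean ($b_0 = 0$);
each response region is the union of two mirror-image intervals.

**Scaled evidence strength.** The same geometry, but each boundary moves
with the uncertainty estimate: $b_r(\sigma) = k_r + m_r\,\sigma^a$, with
$a = 1$ (linear), $a = 2$ (quadratic) or free (free-exponent, constrained
to $(1, 10]$ — the upper bound is a numerical-stability choice). The scales
$m_r$ are unconstrained in sign; instead of reparameterising them we reject
any parameter vector whose *realized* boundaries are not strictly ordered
at every fitted $\sigma$ (see Fitting).

**Bayesian (log posterior probability ratio).** The observer computes
$d = \log p(C\!=\!1 \mid x) - \log p(C\!=\!2 \mid x)$ and compares it with
seven free boundaries $k_1 > \dots > k_7$ in $d$ space. With equal priors
the closed forms are

$$d_{\text{dm}} = \frac{2 x \mu_1}{\sigma^2 + \sigma_1^2}, \qquad
  d_{\text{ds}} = \tfrac{1}{2}\log\frac{\sigma^2 + \sigma_2^2}
  {\sigma^2 + \sigma_1^2} - \frac{\sigma_2^2 - \sigma_1^2}
  {2(\sigma^2 + \sigma_1^2)(\sigma^2 + \sigma_2^2)}\,x^2 ,$$

both equal to the log ratio of the predictive densities (the package tests
this against direct density evaluation at $10^{-9}$). For the likelihood
the $d$-boundaries are converted to perceptual space by inverting these
forms at each fitted $\sigma$; in the different-SDs task a boundary with
$k_r$ above the maximum of $d$ (attained at $x = 0$) is unreachable and
yields an empty central region with zero probability mass — legal, and
protected from $-\infty$ by the likelihood floor. Three relaxations are
provided: *decision noise* (Gaussian noise of SD $\sigma_d$ on $d$),
*free category beliefs* (the observer's $\mu_1, \sigma_1$ or $\sigma_1,
\sigma_2$ fitted instead of veridical), and orientation-dependent noise.
Decision noise and ODN are not combined, matching the nine-model set the
package targets.

## Likelihood

The probability of each response is the measurement distribution's mass
over the realized region — a single interval (different means) or a union
of two mirror intervals (different SDs) — computed from differences of the
normal CDF, never by numerical integration. Each trial's observed-response
probability is floored at $10^{-12}$ before the log: the models have no
lapse process, and without a floor a single stray response at high
intensity would send the log-likelihood to $-\infty$. The floor is far
below any probability that influences model ranking on realistic data.

For decision noise the mass is marginalised by quadrature: 101 evenly
spaced draws spanning the 1st–99th percentiles of $N(k_r, \sigma_d^2)$ per
boundary, converted to perceptual space, with the 101 region-mass vectors
combined using the draws' normalised normal densities as weights.
Corresponding draws are paired across boundaries — the same quantile offset
is added to every $k_r$ — so boundary noise is perfectly correlated and the
drawn boundary sets stay ordered in $d$ space. Should a drawn set still
produce a negative region mass after conversion, that draw's masses are
clipped at zero and renormalised.

Two numerical facts about this quadrature are worth knowing. First, as the
draw count grows it converges to the *truncated* (1st–99th percentile)
marginalisation, not the full one: the span excludes 2% of the noise mass,
and re-normalising the density weights redistributes that mass
proportionally. The resulting bias in a region probability is roughly
$0.02\,\Delta$, where $\Delta$ is how much the region's probability in the
excluded tails differs from its central average; we measure up to
$\sim 0.006$ at $\sigma_d = 0.8$ and $\sim 4\times10^{-4}$ at $\sigma_d =
0.1$. Second, the synthetic-data generator draws decision noise from the
full normal distribution (as the behavioural model states), so
simulated frequencies converge to the exact marginalisation and differ from
the quadrature by exactly this truncation bias. The test suite's
generator-vs-likelihood comparison at $10^5$ draws resolves the bias for
the different-SDs decision-noise variant: that check fails at ~3.4 binomial
SEs, and we keep it failing rather than hide a real property of the
quadrature. Fits are unaffected in practice (the bias is smooth in
$\theta$ and small relative to likelihood differences between models).

Free-parameter counts follow from the blocks: 4 noise SDs (5 with ODN:
4 baselines + amplitude), plus 4 or 7 base positions, a scale per boundary
for the scaled families, one exponent if free, 7 $d$-space boundaries for
the Bayesian family, +1 decision noise, +2 free beliefs. Per dataset,
$\mathrm{AIC} = 2z - 2\log L$ and $\mathrm{BIC} = -2\log L + z\log n$;
group-level sums add AICs across participants, while the group BIC sums the
likelihood terms and applies one penalty $z_B \log n_B$ with the pooled
parameter and trial totals.

## Fitting

Maximum likelihood by bounded local optimization (`nlminb`) on a smooth
reparameterization: noise SDs as a positive value at the lowest-noise
intensity plus positive increments (enforcing monotonicity); base positions
as a first cut plus log-gaps (ordering in the $\sigma \to 0$ limit);
$a = 1 + 9\,\mathrm{logistic}(u)$; $\sigma_d$ on the log scale. Ordering of
the realized boundaries at each fitted $\sigma$ is then checked explicitly,
and violations are rejected through a penalty that grows with the violation
magnitude, steering the optimizer back rather than presenting a flat
cliff. Convergence tolerance is $10^{-6}$ on the objective; random
initialization draws noise SDs in $[0.2, 6]$ standardized units, boundary
bases and scales in the ranges fitted values occupy, exponents in
$(1.05, 3.5)$.

Because several models are nested, `fit_model()` runs a *warm-start
ladder* by default: the linear and quadratic optima seed the free-exponent
fit (at $a \to 1$ and $a = 2$ they are exact special cases), and the plain
Bayesian optimum seeds its decision-noise, free-prior and ODN variants.
This is purely an optimization aid — random starts are unchanged — and it
makes nested-model log-likelihood dominance hold numerically, not just in
expectation. Cross-modal fits share parameters across a visual and an
auditory dataset of the same task at three levels: everything shared
(`common`), noise SDs free per modality (`different_noise`; the exponent
stays shared with $k$ and $m$, grouped with the boundary block), or
everything free (`flexible`, computed exactly as the sum of the two
separate fits).

## The synthetic-data generator

`generate_design()` reproduces the session structure: blocks of 120 trials
balanced exactly — not in expectation — over 2 categories × 4 intensities
(15 trials per cell), stimulus values drawn from the generating category,
order shuffled, 6 blocks per session. `simulate_dataset()` standardizes
the session (empirically by default, matching how real sessions are
scored; a theoretical-moments policy is available for cross-session
reproducibility), draws one measurement per trial, and applies the model's
own decision rule. The generator and the likelihood are written
independently (simulation by comparison against realized boundaries or
$d$-boundaries; likelihood by CDF masses), which is the package's central
cross-check: simulated frequencies must converge to the analytic
probabilities for every variant.

`sample_generating_params()` draws observer parameters from documented
ranges resembling fitted human values: the noise SD at the strongest
intensity in 0.4–1.0 standardized units, growing by random factors to
roughly 1–6 at the weakest intensity (so the non-increasing-in-intensity
constraint holds by construction); boundary ladders spanning the fitted
range; $a \in (1.1, 2.5)$;
$\sigma_d \in (0.1, 0.8)$ ($\sigma_d$ is not reported in the source
material; this range makes decision noise comparable to one confidence
step in $d$ units); subjective beliefs within ±40% of truth. Draws are
verified against the realized-ordering constraint and redrawn if needed.

What the generator does *not* emulate: real participants' lapses,
sequential dependencies, response-time structure, learning across blocks,
and any mismatch between the assumed Gaussian measurement noise and actual
sensory encoding. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and the models are mutually discriminable
under their own assumptions — not that those assumptions hold for human
data.

The accuracy screen (`exclude_by_accuracy()`) applies a one-sided exact
binomial test of highest-intensity accuracy against chance at
$\alpha = 0.05$, with correctness judged against the most probable
generating category for the stimulus value; "significantly above chance"
implies the one-sided direction.

## Recovery studies and problem sizes

The recovery machinery (`model_recovery()`, `parameter_recovery()`)
simulates, refits and tabulates winners by AIC or BIC, with ties broken by
smaller parameter count and then model token. The package's standard
recovery configuration is the **different-SDs task**, matching where the
source analyses concentrated their recovery work, and the scales are
desk-sized: 20 datasets × 360 trials for the 4-model confusability matrix
(3 optimizer starts per fit plus the warm-start ladder) and 20 datasets ×
720 trials for linear-model parameter recovery (5 starts). At these sizes
the full suite runs in well under half an hour on one CPU; the original
scale (100 datasets × 720 trials, more starts) is reachable through the
function arguments.

The task choice matters scientifically: in the different-means task the
Bayesian observer's perceptual boundaries scale as $k_r(\sigma^2 +
\sigma_1^2) / 2\mu_1$ — a quadratic function of $\sigma$ — so a
free-exponent observer with $a \approx 2$ is genuinely mimicked by the
LPPR model, which then wins AIC with two fewer parameters. This
confusability is a property of the task geometry, not an estimation
failure (fitted log-likelihoods at the optimum exceed those at the
generating parameters). In the different-SDs task the two families place
boundaries with qualitatively different geometry and recover cleanly.

## Known limitations

* The decision-noise quadrature's percentile truncation biases region
  probabilities by up to ~0.006 at large $\sigma_d$ (discussed above).
* Orientation is treated as linear, not circular; appropriate only for
  small orientation ranges.
* Priors are fixed at 0.5/0.5 throughout (the designs sample categories
  equally); `prior1` exists on `category_pair` for generality but is not
  fitted.
* Exact ties of the evidence transform at 0.5 are labelled category 1 — a
  deterministic convention for a measure-zero event.
* No lapse process, non-Gaussian noise, response-time modelling, or
  hierarchical pooling across participants; fits are per participant.
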