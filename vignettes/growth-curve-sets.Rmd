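---
title: "Estimating growth curve sets from nonchronological data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating growth curve sets from nonchronological data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonchron)
```

## The problem

Many growth surveys record each individual only once: a stand age and a
mean tree height, a fish age (otolith rings) and a body length. Such
*nonchronological* data carry no per-individual growth history, yet the
collection of observed (age, size) points is shaped by the whole family
of growth curves in the population — the *growth curve set* — together
with the distribution of final sizes (*asymptotes*) across individuals.

If every individual follows the same standard curve scaled by its own
asymptote (an *anamorphic* set), classical guide-curve regression is
statistically consistent and nothing more is needed. But populations
often show orderly shape variation: individuals that end up small also
grow slowly, so curves differ even after dividing by the asymptote (a
*polymorphic* set). For that case `nonchron` implements a proper
likelihood, obtained by a change of variables from the asymptote
distribution to the observable size distribution at each age.

## The model

Sizes follow a Richards-type curve set
$$x = A\,\bigl[1 - e^{-k A^{l} t}\bigr]^{b},$$
where $A$ is the individual asymptote, $k > 0$ a rate (per year),
$b > 0$ a shape exponent, and $l$ couples the rate to the asymptote:
$l = 0$ is the anamorphic set, $l \neq 0$ a polymorphic set in which
curve shape varies smoothly with $A$. Asymptotes are random across
individuals, following either a lognormal distribution
$(\mu, \sigma)$ or a Stacy generalized gamma
$(\lambda, \psi, \tau)$, which contains the gamma ($\tau = 1$), the
Weibull ($\psi = 1$) and the lognormal ($\psi \to \infty$) as special
or limiting cases. Crossing the two curve families with the two
distributions gives the four instance models AL, AG, PL, PG with 4, 5,
5 and 6 free parameters.

Assuming individuals are sampled randomly from the curve set, the
log-likelihood of the data $\{(t_i, x_i)\}$ factorizes as
$$LL = \sum_i \ln p(t_i) + \sum_i \ln p(A_i)
  - \sum_i \ln \left.\frac{dx}{dA}\right|_{t_i, A_i},$$
where $A_i$ is the asymptote of the curve through $(t_i, x_i)$ and
$dx/dA$ is the Jacobian of the size-for-asymptote map at fixed age —
the factor that converts the asymptote density into the size density.
The age term is a model-independent constant and is excluded from every
reported NLL. Mass conservation ($p(x)\,dx = p(A)\,dA$) means the
implied size density at any age integrates to one and inherits the
asymptote distribution's quantiles through the monotone map
$A \mapsto x(A)$; both properties are verified by quadrature in the
test suite.

For fixed curve parameters $\theta = (k, b, l)$ the distribution
parameters enter only through $\sum_i \ln p(A_i)$, so they are profiled
out: each evaluation of the profile likelihood inverts all
observations to asymptotes, fits the distribution to $\{A_i\}$ by
maximum likelihood, and subtracts the log-Jacobians
(`profile_negloglik()`). The outer search over $\theta$ is global.

An exact consequence worth knowing: with the anamorphic set and a
lognormal asymptote distribution, the profile NLL reduces to
$\tfrac n2 \ln\hat\sigma^2 + \tfrac n2 + \tfrac n2 \ln 2\pi + \sum_i \ln x_i$
with $\hat\sigma^2$ the MLE variance of
$\ln x_i - \ln f(t_i;\theta)$ — i.e. AL estimation coincides with
nonweighted least squares after the log transform. The tests confirm
the fitted AL parameters against an independent log-least-squares
estimator.

## Numerical choices

**Reparameterized rate.** With large $|l|$ the natural rate $k$ spans
absurd ranges, so the search uses $k' = k\,a_{\mathrm{ref}}^{\,l}$ —
the effective rate of an individual at the reference asymptote
$a_{\mathrm{ref}}$ (default 25 size units, a rough average asymptote)
— and recovers $k = k'/a_{\mathrm{ref}}^{\,l}$ afterwards. Default
boxes: $k' \in [10^{-12}, 0.1]$ searched as $\log_{10} k'$ (the range
spans eleven decades), $b \in [0.01, 5]$, $l \in [-10, 10]$. Published
polymorphic point estimates quote $k'$ on this convention.

**Inversion.** Anamorphic sets invert in closed form. For $l > 0$ the
size is strictly increasing in $A$, and a vectorized safeguarded
Newton iteration (started from an anamorphic-style guess, clamped to
$[x, 10^{6}x]$) solves all observations simultaneously; any element
whose verified round-trip residual exceeds $10^{-8}x$ falls back to
bracketed Brent root finding on $[x, \max(2x, a_{\mathrm{ref}})]$ with
geometric bracket expansion. For $l < 0$ the map need not be monotone;
a 64-point scan detects multiple sign changes and raises an ambiguity
error rather than returning an arbitrary root. Saturation fractions
are computed through `expm1`/`log1p` so extreme rates neither
underflow nor lose precision.

**Inner generalized gamma MLE.** The scale has the closed-form profile
$\lambda^\tau = \sum_i A_i^\tau / (n\psi)$, leaving a 2-D Nelder-Mead
search over $(\ln\psi, \ln\tau)$ from four deterministic starts
(moment-matched gamma, Weibull, the lognormal ridge, a generic
interior point). The likelihood surface is ridged along the
$\psi \to \infty$ lognormal limit, so $\psi$ is capped at $10^{6}$ and
$\tau \in [0.1, 10]$; all log-densities go through `lgamma`. During
the outer search the inner fit is warm-started from the previous
evaluation (plus one safeguard start), which cuts nested-optimization
cost several-fold without changing converged values.

**Outer search.** Particle swarm optimization with constriction
defaults (40 particles, 300 iterations, inertia 0.729, cognitive =
social = 1.49445), velocity clamped to half the box width, reflection
at the bounds, and a final Nelder-Mead polish from the incumbent. A
candidate $\theta$ whose inversion fails or whose asymptotes are
degenerate (zero log-scale variance would make the likelihood
unbounded) receives an infinite-penalty sentinel — partial likelihoods
are not comparable, so one bad observation poisons the whole
candidate. Every fit is deterministic given its seed. The profile
surfaces of the 2-parameter anamorphic models are smooth enough that
much smaller swarms (around 16 particles, 40–60 iterations) reach the
same optimum as a multi-start simplex to $10^{-4}$ nats, and the
simulation experiments below use budgets of that size.

**Model comparison.** AIC $= 2\,\mathrm{NLL} + 2K$ with
$K = 4/5/5/6$; likelihood-ratio tests only between nested pairs
(AL–AG, AL–PL, AG–PG, PL–PG with 1 df; AL–PG with 2 df). AG and PL are
not nested and the test is refused for that pair. Some extra
parameters sit on boundary values under the null (e.g. the
$\psi \to \infty$ lognormal limit), where the plain $\chi^2$ reference
is only approximate; the plain reference is used regardless and the
caveat documented. Confidence intervals use the empirical bootstrap:
case resampling with replacement, 1,001 resamples by default, a full
refit per resample (seeded with the point estimate as one initial
particle), and percentile 2.5/97.5 endpoints. Percentile rather than
basic bootstrap intervals were chosen as the simplest reading of
"empirical bootstrap"; the per-replicate estimates are retained, so
other interval constructions can be derived from a `growth_boot`
object if wanted.

## The synthetic-data generator

`simulate_observations()` draws ages uniformly over the survey range,
asymptotes from the specified distribution, and computes sizes
*exactly* from the curve set — no residual noise term. This is the
statistical structure the likelihood assumes: all size variation at a
given age comes from the asymptote distribution, and observation error,
environmental covariates, random effects and mortality-biased sampling
are deliberately absent. Passing recovery tests therefore demonstrates
internal consistency of the estimator under its own assumptions, not
robustness to the measurement error or sampling bias present in real
surveys.

`reference_true_models()` provides the published point estimates for
cypress (*Chamaecyparis obtusa*) and larch (*Larix kaempferi*) mean
tree height (ages 11–110 and 11–118 years, heights in metres) as
ready-made generating truths.

`reproductivity_experiment()` repeats generate-and-refit many times and
compares, on a common age grid, the true growth curves at the 2.5th,
50th and 97.5th percentile asymptotes with the pointwise median and
2.5/97.5 percentile envelope of the estimated curves. Ages are redrawn
each replicate (the reference experiment does not fix an age design,
and the age density drops out of the likelihood regardless). The
reference experiment uses 1,001 replicates of $n = 100$ or 200; the
packaged experiments use about 100 replicates, which is enough to
resolve the qualitative behaviour: a proper (or compatible) estimator's
median curves overlap the truth and envelopes narrow as $n$ doubles,
while an anamorphic estimator fitted to polymorphic truth leaves the
true tail-percentile curves outside the envelopes at old ages no matter
how large $n$ grows — the estimated 2.5th percentile curve too low and
the 97.5th too high, the underdispersion signature that motivates the
polymorphic likelihood in the first place.

## Scales used by the packaged experiments

The parameter-recovery experiment (also run by
`scripts/acceptance.R`) uses 100 replicates of $n = 200$ from the
larch AL truth with 16-particle, 60-iteration swarms; the
misspecification experiment uses 101 replicates of $n = 200$ from the
cypress PG truth with an AG estimator and 16-particle, 40-iteration
swarms. These sizes resolve median parameter recovery to a few percent
and envelope coverage to within a few grid points while keeping a full
run in minutes on one core.

## Limitations

* Type B curve sets (common asymptote, varying shape) violate the
  method's assumptions and are not supported; nor are random mixtures
  of curves uncorrelated with the asymptote (use random-effects models
  there instead).
* Negative $l$ makes size non-monotone in the asymptote; inversion
  then refuses ambiguous observations rather than guessing, and fits
  with $l < 0$ deserve scrutiny.
* The $\chi^2$ reference for boundary-null likelihood-ratio tests is
  approximate, as noted above.
* Measurement error, covariates, random effects and mortality
  correction are out of scope; the likelihood would need extension
  before the method is applied where those dominate.
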