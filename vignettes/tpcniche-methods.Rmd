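---
title: "Methods: fundamental and realized thermal performance curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fundamental and realized thermal performance curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcniche)
```

`tpcniche` has two halves that meet in the middle: a mechanistic model of how
interspecific competition reshapes thermal performance curves (TPCs), and an
inference pipeline that estimates TPCs from binary breeding-trial records. A
third component, the synthetic-data generators, joins them: it produces data
with exactly the statistical structure the inference assumes, from known
ground truth, so the whole chain can be validated end to end. This vignette
documents the model, the estimators, the numerical choices, and the places
where a convention had to be chosen.

## The mechanistic model

### Fundamental curves

A species' fundamental TPC is a unimodal curve with three parameters, all in
°C: the optimum `t_opt`, the upper critical temperature `t_max`, and the
cold-limb shape `sigma_p`:

$$P(T) = \begin{cases}
\exp\{-\left((T - T_{opt})/(2\sigma_p)\right)^2\} & T \le T_{opt}\\
1 - \left((T - T_{opt})/(T_{opt} - T_{max})\right)^2 & T_{opt} < T \le T_{max}\\
0 & T > T_{max}.
\end{cases}$$

The Gaussian cold limb decays smoothly toward cold temperatures; the warm
limb is a parabola that hits zero exactly at `t_max`, beyond which
performance is identically zero — a hard upper critical temperature, the
standard asymmetric TPC shape for ectotherms. The curve is continuous at both
joins and peaks at exactly 1.

### Environmental weighting

Organisms at a site with mean temperature $T_{mean}$ do not experience a
single temperature. We take the encountered temperature to be Gaussian with
variance $V$ (°C²), i.i.d. across trials — no seasonal or diurnal
autocorrelation — and define the temperature-weighted performance

$$w(T_{mean}) = \int P(t)\, \mathcal{N}(t;\, T_{mean}, V)\, dt.$$

`weighted_performance()` evaluates this by adaptive quadrature
(`stats::integrate`) after standardising to $z = (t - T_{mean})/\sqrt{V}$,
integrating over $z \in [-10, 10]$ truncated at $t_{max}$ (lossless, since
$P \equiv 0$ above it) and split at the kink $t_{opt}$ so each piece is
smooth. The standardised scale matters: it keeps the integrand
well-conditioned down to vanishing variance, where $w \to P(T_{mean})$. The
absolute tolerance is 1e-8; the suite checks agreement with a
10⁶-slice midpoint-Riemann sum to 1e-6 and the degenerate-variance limit to
1e-3 away from the kinks.

### Realized curves

With two competitors, the focal species' realized TPC is its relative
performance $w_{focal}(T_{mean}) / w_{comp}(T_{mean})$. Two conventions were
open and are fixed as follows:

* **Undefined ratios.** Where the competitor's weighted performance falls
  below `eps_den = 1e-12` the ratio is `NA`, not a huge number: a 0/0 contest
  beyond both species' viable ranges is meaningless.
* **Width.** The realized width is the longest contiguous interval where the
  ratio stays ≥ 1 — where the focal species outperforms its competitor,
  the equal-performance line. Fundamental-curve width uses a level relative
  to the maximum (default half-max) via `curve_summary()`.

`realized_tpc()` tabulates the ratio on a grid (default 0.05 °C spacing from
`min(t_opt) − 4 max(sigma_p)` to `max(t_max)`), refines the argmax between
its bracketing grid neighbours with `stats::optimize()` to 1e-4 °C, and
locates the ratio = 1 boundaries with `stats::uniroot()` to the same
tolerance. A flat curve (range < 1e-9, e.g. identical competitors) has no
defined optimum.

Two model predictions follow and are verified across randomized
configurations in the suite: a cool specialist competing with a warmer,
broader generalist has its realized optimum shifted *below* its fundamental
optimum and its ratio ≥ 1 width squeezed below its fundamental half-max
width; mirrored (warm specialist, cool generalist) configurations shift the
optimum *up*. One asymmetry deserves note: in the mirrored case the width
comparison is not asserted, because under the ratio ≥ 1 convention the focal
species keeps outperforming a cold-shifted competitor all the way to the
temperatures where both die, so its "advantage region" is bounded by joint
extinction rather than by competitor dominance and need not be narrower than
the half-max width. The narrowing claim is a statement about the
configuration with a warm-shifted generalist, which is the empirical system's
geometry.

### The contest rule

The mechanistic generator turns the theory into binary outcomes: a beetle
group with cooperative boost $g \ge 1$ wins a carcass against blowflies with
probability $p = g\,w_{beetle} / (g\,w_{beetle} + w_{blowfly})$. This
proportional-contest form is a modelling choice (no contest function is
implied by the theory itself). Note a property that is easy to miss: $p$ is a
monotone transform of the ratio $w_{beetle}/w_{blowfly}$, so the *location*
of its maximum over $T_{mean}$ does not depend on $g$. What cooperation does
change is the level of $p$ everywhere and, in particular, the warm-side
temperature at which the beetles still break even ($p = 0.5$): larger groups
keep winning into warmer environments. The tests assert exactly these
properties, plus unimodality of $p$ for the documented default pair
(specialist 16/26/4 vs generalist 23/35/9, V = 4 °C²).

## The inference pipeline

### Models

Trial records are rows with a temperature, a binary outcome, plot and year
identifiers, and treatment labels. `tpc_model_spec()` describes the
regression: a quadratic-logit curve `logit p = β0 + β1 T + β2 T²`, optionally
per treatment arm (`treatment × {T, T²}` interactions), with optional
independent Gaussian random intercepts for plot and year — crossed, since
nothing ties a year effect to a plot. Fitting goes through `stats::glm`
(lab), `lme4::glmer` with the Laplace approximation (field), or `stats::lm`
(Gaussian responses such as body-minus-ambient temperature differences). The
suite checks the GLM against a brute-force grid-search likelihood
maximisation, the Laplace marginal log-likelihood against exact 1-D
integration on a two-plot toy (within 0.1), and the zero-variance reduction
of the GLMM to the GLM.

Records with a missing outcome (e.g. animals that died mid-trial) are
dropped before fitting, with a reported count. All-success or all-failure
data are refused. Separation is detected on the fitted linear predictor: if
$|\hat\eta|$ exceeds 25 logits anywhere in the data, the fitted probabilities
are pinned at 0/1 beyond anything binary data can support and the MLE has
diverged, so fitting stops with an explicit error. (A threshold on raw
coefficients would misfire: with temperatures around 15 °C a perfectly
healthy vertex parameterisation already puts the intercept near −40.)

### Optimum, breadth, tests, uncertainty

* **`t_optimal()`** is the vertex $-\beta_1/(2\beta_2)$ of the fitted
  quadratic; the logit link is monotone, so this is also the maximiser of
  the fitted probability. $\beta_2 \ge 0$ (no interior maximum) is an error,
  not a number. For interaction models, arm-specific coefficients are used.
* **`tpc_breadth()`** operationalises "distinguishable from zero": the
  pointwise $(1-\alpha)$ Wald band for the success probability is computed on
  the response scale by the delta method,
  $\hat p \pm z\,\hat p(1-\hat p)\,se(\hat\eta)$, and breadth is the maximal
  contiguous interval around the optimum where the band's lower limit stays
  positive, with boundaries bisected to 0.01 °C. The response scale is forced
  by the rule itself — a logit-scale band can never cross zero. The band is
  symmetric around the fitted curve by construction, and its lower limit
  *can* be negative; a band that never clears zero yields an empty breadth
  with a warning.
* **`lr_test()` / `temperature_lrt()` / `compare_tpcs()`**: model comparison
  is by likelihood ratio. The temperature effect is the 2-df test of
  {T, T²} against the intercept-only model; the treatment comparison is the
  2(L−1)-df test of the `treatment × {T, T²}` interactions against the
  treatment-main-effect model. Wald-style tables are deliberately not
  provided. The suite calibrates the 2-df test's size on 1000 null
  replicates (acceptance band 0.03–0.07 at α = 0.05) and its power on
  optimum shifts.
* **`bootstrap_summary()`**: `t_optimal` and breadth are nonlinear
  functionals of the fit, so their intervals come from a parametric
  bootstrap: simulate from the fitted model (redrawing random intercepts
  from their estimated variances when present), refit, take percentile
  intervals. The seed is mandatory and recorded; B ≥ 200. Replicates whose
  refit fails — separation or a sign-flipped curvature — are discarded, and
  more than 10% failures aborts with an instability error rather than
  returning an interval built on a biased subset. That error is informative:
  it flags datasets whose curvature is too weak to support a vertex summary
  at all.

## What the generators emulate — and what they do not

`simulate_lab()` reproduces a common-garden design: fixed chamber
temperatures 8, 10, 12, 16, 20, 22 °C, independent Bernoulli outcomes from a
logistic-quadratic TPC, one lab "plot". Defaults put ~120 trials across the
six chambers. The ground-truth parameterisation `coeffs_from_shape()` is
interpretable: an optimum, a peak success probability `p_max`, and the
halfwidth `h` at which success halves; defaults `p_max = 0.7`, `h = 4.7` °C
were back-computed once from peak lab success near 0.7 and near-zero success
at the 8 °C and 22 °C extremes, and `t_opt = 15.6` °C matches the lab
optimum the pipeline is asked to recover.

`simulate_field()` reproduces the elevational experiments: sites spaced
along an elevation range, site temperature set by a linear lapse of
−0.55 °C per 100 m anchored at 20 °C / 1600 m, per-trial day-to-day
temperature jitter (SD 1.5 °C — trials run on different days, and without
within-site variation temperature would be perfectly confounded with plot),
logit-scale random intercepts for plot (SD 0.5) and year (SD 0.3), and
treatment arms encoded as separate ground-truth curves so arms can shift
*and* reshape. The default design covers 1600–2800 m (site temperatures
13.4–20 °C); the validation studies of the two-arm field comparison pass the
full 673–3422 m experimental gradient (≈10–25 °C under the same lapse)
explicitly, because with arm optima at 15.6 and 13.1 °C the narrow default
range samples only the warm flank of each curve and the per-arm curvature —
hence the vertex — becomes weakly identified at a few hundred trials. That
weak identification is real, not numerical: on the narrow range the per-arm
optimum ordering is recovered in roughly nine of ten replicates rather than
nearly always, and bootstrap instability errors become common.

The generators are statistical emulators, not field mechanics: no carcass
contests between individual animals, no arrival-time dynamics, no weather
time series, no spatial covariance between nearby sites, and no
overdispersion beyond the plot/year intercepts. Passing tests therefore
certify the estimators under the model's own assumptions — they do not
certify that real field data meet those assumptions.

## Study sizes used by the validation suite

The suite's heavy studies are sized to be decisive yet quick: 20 random
parameter sets against the 10⁶-slice quadrature oracle; 20 randomized
competitor configurations for the directional predictions; 1000 null
replicates for test size; 200 replicates × B = 200 for bootstrap coverage of
the lab optimum (observed coverage is asserted within 0.90–0.99); and 100
replicates of the two-arm field experiment (37 sites × 5 replicates × 2
arms = 370 trials) for end-to-end recovery — the arm ordering must be right
in ≥ 95 of 100, and the truth must fall inside the per-arm bootstrap CI in
≥ 90% of the replicates with a stable bootstrap. Replicate-level fits in
these two large studies use the per-arm quadratic GLM rather than the GLMM:
with Gaussian random intercepts the marginal success curve keeps its vertex
at the same temperature (the intercepts shift the curve's height, not its
peak location), so the GLM vertex estimator is consistent for the arm
optimum at a fraction of the cost, and the GLMM's own accuracy is checked
separately against exact integration.

## Known limitations

* Breadth depends on sample size by construction — it is a statement about
  statistical distinguishability from zero, not a fixed physiological
  quantity; more data widen it toward the curve's support.
* The bootstrap percentile interval for `t_optimal` inherits the instability
  of ratio estimators when $\hat\beta_2 \approx 0$; the 10% failure guard
  turns that into an explicit error instead of a silent wild interval.
* Only two competitors, i.i.d. Gaussian temperatures, and logit-quadratic
  data curves are supported; the theory curves are not themselves
  logit-quadratic, so the empirical and mechanistic halves meet only through
  the simulated contest outcomes, not through shared parameters.
* Elevation and daily-minimum temperature are carried through the record
  schema but never modelled (they are collinear with mean temperature in
  the motivating design).
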