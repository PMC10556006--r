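---
title: "The maintenance-growth model: methods and design"
author: "mgmgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The maintenance-growth model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mgmgrowth)
```

## The model

`mgmgrowth` models the ontogenetic growth of an individual animal as the
net outcome of an energy balance. Ingested energy $S$ is assimilated with
efficiency $e$; the assimilated flux pays, in order, the metabolic costs of
feeding ($R_F$), maintenance ($R_M$) and tissue synthesis overhead
($R_G$), and whatever remains is bound in new tissue at the rate
$G = E_M(W)\,\mathrm{d}W/\mathrm{d}t$. Rearranging the balance
$eS = R_M + R_F + R_G + G$ gives the growth equation

$$\frac{\mathrm{d}W}{\mathrm{d}t}
  = \frac{e\,S(\varphi, W) - R_F(S) - R_M(\varphi, W)}{E_M(W) + E_S(W)},$$

with $W$ body mass (mg), $t$ age (days) and energies in J. The components
are:

* **Ingestion** $S(\varphi, W) = \varphi\, \alpha W^{\beta}$: an allometric
  maximum (ad libitum) ingestion rate scaled by the *relative food
  acquirement* $\varphi \in [0, 1]$, the realised fraction of the
  ad-libitum rate at the current size. An optional break mass $W'$ caps or
  holds the allometry in determinate growers that stop increasing intake
  near maturity.
* **Tissue energy density**
  $E_M(W) = (E_{CP} f_{CP} + E_L f_L)(1 - f_R) + E_{MR} f_R$: what one mg
  of new tissue is worth, from its carbohydrate/protein, lipid and
  reproductive make-up. $E_{CP} \approx 17$ and $E_L \approx 34$ J/mg are
  standard constants for animal tissue.
* **Growth overhead**
  $E_S(W) = [E_{SSD}(1 - f_G) + E_{SSG} f_G](1 - f_R) + E_{SR} f_R$: the
  metabolic cost of building one mg, distinguishing somatic cell division,
  somatic cell enlargement and reproductive synthesis. Moulting costs can
  be folded into the somatic overheads.
* **Feeding costs** $R_F = k_F S$ by default; any monotone increasing
  function of $S$ may be supplied.
* **Maintenance** $R_M$, the model's centrepiece, is split into a
  *non-negotiable* basal part proportional to tissue mass
  ($\gamma_{BS} W_S + \gamma_{BR} W_R$) and a *negotiable* "defence" part
  (immune function, buffering, non-essential activity) that makes up a
  fraction $\rho$ of total tissue maintenance:
  $$R_M(\varphi, W) =
    \frac{\gamma_{BS} W_S}{1 - a_{NS} W_S^{b_{NS}} \varphi^{\delta}} +
    \frac{\gamma_{BR} W_R}{1 - a_{NR} W_R^{b_{NR}} \varphi^{\delta}},
    \qquad W_S = (1 - p_R) W,\; W_R = p_R W.$$
  Under ad libitum feeding the defence fraction rises allometrically with
  tissue mass ($\rho_N = a_N W^{b_N}$, so $b_N > 0$ makes total maintenance
  hyperallometric); under restriction it is downregulated as
  $\varphi^{\delta}$, with $\delta$ controlling how readily defence is
  shed. The singular mass where $\rho \to 1$ is treated as an error, never
  clamped: terminated growth must emerge from the balance, not from a
  numerical guard.

With constant composition, one tissue ($p_R = 0$) and proportional feeding
costs the equation reduces to

$$\frac{\mathrm{d}W}{\mathrm{d}t} = \frac{1}{E_M + E_S}
  \left[(e - k_F)\varphi\alpha W^{\beta} -
  \frac{\gamma_B W}{1 - a_N W^{b_N} \varphi^{\delta}}\right],$$

and two further special cases anchor the package's comparisons:

* $b_N = 0$, fixed $\varphi$: a mechanistic von Bertalanffy equation
  $\mathrm{d}W/\mathrm{d}t = aW^{\beta} - bW$ with the closed-form
  Bernoulli solution used as an integration oracle
  (`vb_closed_form()`).
* $b_N = 1$, $\varphi = 1$: the four-parameter ad-libitum form
  $\mathrm{d}W/\mathrm{d}t = aW^{\beta} - cW/(1 - a_N W)$
  (`mgm33_params()`) used for fitting.

The comparator `gsgm_params()` implements the umbrella
supply-minus-expenditure power law
$\mathrm{d}W/\mathrm{d}t = aW^b - cW^d$ covering the classical mechanistic
growth models ($d = 1$ by default, the value those models share). Its key
structural limitation is exposed by `gsgm_omega_star()`: the ratio of the
mass at maximum growth rate to the ultimate mass is $(b/d)^{1/(d-b)}$,
whose supremum for $d = 1$ is $1/e \approx 0.368$. Growth-rate humps
peaking beyond 37% of the final mass — as insect data show — are therefore
out of the classical models' reach, while the defence-laden form
reproduces them.

## Default parameters

Defaults are the package's own calibration to a cricket-like determinate
grower; they are chosen once, on biological grounds, and all tests and
examples run from them.

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 4.5 | J mg$^{-\beta}$ d$^{-1}$ | sets the growth time scale: 95% of final size in ~100 d |
| `beta` | 0.75 | — | classical interspecific ingestion allometry |
| `e` | 0.7 | — | typical insect assimilation efficiency on mixed diets |
| `k_F` | 0.1 | — | feeding costs an order below assimilation |
| `f_CP`, `f_L` | 0.35, 0.03 | — | fresh-tissue composition giving $E_M \approx 7$ J/mg |
| `E_SSD`, `E_SSG`, `E_SR` | 2 | J/mg | synthesis overhead ~30% of bound energy |
| `gamma_B` | 0.33 | J mg$^{-1}$ d$^{-1}$ | balances supply at $W_U \approx 409$ mg |
| `a_N`, `b_N` | 0.0011, 1 | mg$^{-b_N}$, — | linear rise of the defence fraction, $\rho \approx 0.45$ at $W_U$ |
| `delta` | 1 | — | proportional defence downregulation |

Two consequences of this calibration matter:

* The growth-rate hump peaks at $\omega^* = W^*/W_U \approx 0.48$,
  comfortably above the $1/e$ ceiling of the classical models — the regime
  the model exists to describe.
* The ad-libitum defence fraction at the ultimate mass,
  $\rho_U = a_N W_U \approx 0.45$, lies below $1/(1+\delta)$. A short
  computation on the root condition
  $\varphi a W^{\beta-1}(1 - a_N W \varphi^{\delta}) = c$ shows that
  $\mathrm{d}W_U/\mathrm{d}\varphi > 0$ exactly when
  $\rho_U < 1/(1+\delta)$: below the threshold, food restriction shrinks
  the ultimate mass monotonically (smaller $W_{95}$, later $t_{95}$, the
  empirically common pattern); above it, downregulated defence frees more
  than the supply lost and the response reverses. The default sits in the
  monotone regime for $\delta \le 1$; `food_restriction_sweep()` makes the
  reversal reproducible by raising `delta`.

## Trajectories and summaries

`integrate_growth()` solves the ODE with `deSolve::lsoda` (rtol $10^{-9}$,
atol $10^{-12}$ mg), dense output at 1001 ages by default. Summaries
deliberately avoid discrete-grid artefacts: `ultimate_mass()` brackets and
root-finds the rate function's zero (relative tolerance $10^{-10}$),
`summarize_trajectory()` maximises the analytic rate over $(0, W_U)$ for
$\dot W_{max}$ and $W^*$, and inverts the dense mass-age solution with a
monotone (Hyman) cubic spline for ages at mass fractions, so `t95` is
accurate to about $10^{-6}$ relative at default resolution. The
dimensionless descriptors are $\omega^* = W^*/W_U$ and
$\Omega = \dot W_{max} / [(W_{95} - W_0)/t_{95}]$, the maximum over the
average life-time growth rate with "life time" operationalised as $t_{95}$
(the asymptote itself is never reached in finite time).

Inside solver trial steps the right-hand side is guarded (a step probing
beyond the singular mass reports a strong decline rather than an error);
user-facing evaluation is strict. `predict_masses()`, used by the fitting
objective, is strict throughout: a parameter set whose trajectory hits the
singularity or overflows is a failed integration and is penalised.

## Fitting: the inverse method

`fit_model()` estimates parameters by least squares between the model
trajectory (integrated from the first observed mass, which is treated as
known, not estimated) and averaged mass-at-age data. Fit quality is
reported as

$$GF = 1 - \sqrt{\textstyle\sum_i (O_i - E_i)^2} \big/
        \sqrt{\textstyle\sum_i (O_i - \bar O)^2},$$

one minus a ratio of root sums of squares — deliberately not $R^2$; a
perfect fit gives 1, predicting the observed mean gives 0.

The optimiser is multi-start Levenberg–Marquardt: a seeded Latin-hypercube
start set (scale parameters drawn log-uniformly), plus one data-informed
start in the spirit of self-starting nonlinear models (supply anchored on
the initial slope, expenditure on growth stalling at the largest observed
mass). Scale parameters are optimised on the log scale; the natural-scale
problem is so badly conditioned across the default bounds that LM stalls
in local minima even from good starts. On noiseless self-generated data
the four ad-libitum parameters are recovered to within optimizer
precision.

Two optional arguments matter for noisy data:

* `weights = "relative"` divides residuals by the observed masses — the
  variance-stabilised estimator when noise is multiplicative, which is how
  mass measurement error behaves. The default (`"none"`) is the plain
  least squares of the classical inverse method.
* `fixed` holds named parameters at known values. This exists because the
  four-parameter form is *sloppy*: a Fisher-information analysis at the
  default truth shows the expenditure normalisation $c$ and the defence
  normalisation $a_N$ are nearly collinear along the growth curve, with
  sampling deviations of $c$ above 50% at 5% measurement noise however
  the data are weighted. Recovery of $c$ from realistic noisy data is
  only meaningful conditional on $a_N$; with $a_N$ known, relative
  weighting and ~15 ages spanning the plateau, $a$ and $c$ come back
  within 10% in the large majority of replicates. This sloppiness is a
  genuine property of the model, worth knowing before fitting it to small
  noisy data sets — the original use case fit averaged (hence
  low-noise) curves.

## The cohort reduction pipeline

`average_cohort()` pools all individuals of a starting density (across
replicate cohorts — a pooled mean, not a mean of cohort means) at each
weighing age. `rates_from_differences()` turns each averaged series into
growth rates: forward difference ratios at interval midpoints, linearly
interpolated back to the observation ages, with nearest-midpoint values at
the two endpoints. `smooth_rate_curve()` fits a least-squares quadratic of
rate on mass whose vertex gives $(\dot W_{max}, W^*)$ (concave-up fits and
out-of-range vertices are flagged, not silently used), and
`smooth_growth_curve()` integrates the fitted quadratic from $W_0$ to give
a smooth mass-age curve, the implied $W_U$ (the quadratic's upper positive
root) and ages at mass fractions. `normalized_food_availability()` maps
starting densities to $\min[\log_{10} d] / \log_{10} d_i \in (0, 1]$, and
`maturation_summary()` averages maturation age and mass per density and
sex, never pooling sexes.

The quadratic is an approximation, and a biased one: the true rate curve
rises like $W^{\beta}$ at small mass, which no parabola follows, so the
vertex height overestimates the true maximum by about 3% when rates are
sampled densely. Two features of the emulated design pull the bias back
under 2%: weekly weighing (secant slopes under a concave hump
underestimate the peak, partially cancelling the quadratic's
overestimate) and an 18-week horizon that covers the plateau without
drowning the hump in plateau points. The pipeline identity check —
reduce noiseless synthetic cohorts, compare $(\dot W_{max}, W^*, W_U)$
against engine truth — holds to 2% under exactly those conditions, and
that is the honest scale of this estimator's accuracy; expect no better
on real weekly data.

## The synthetic cohort generator

`generate_cohort()` emulates a density-manipulation (self-thinning style)
growth experiment: starting densities $\{5, 10, 20, 40, 80\}$ share a
fixed ration, summarised by a monotone map from density to relative food
acquirement, defaulting to the normalised food availability
$\varphi(d) = \log_{10} 5 / \log_{10} d$ so the lowest density is ad
libitum. Hatchlings start at 0.67 mg and are weighed weekly for 18 weeks.
Stochastic structure: a lognormal individual scale factor (mean 1, cv 0.1)
multiplying the whole trajectory, lognormal measurement noise per weighing
(cv 0.05) — both multiplicative, keeping masses positive, which is why no
additive noise model is offered — optional exponential mortality thinning,
and a maturation event when an individual reaches 90% of the
density-specific asymptotic mass (age jittered by the individual cv).
Maturation-at-mass-fraction, rather than at an absolute threshold, is the
package's choice: with asymptotes spanning ~409 mg (ad libitum) down to
~72 mg (highest density), any fixed threshold would either exclude the
restricted densities from maturing or be biologically meaningless, whereas
emergence near the individual growth plateau reproduces the observed joint
pattern (later age, smaller size at maturation under crowding). An
absolute threshold remains available via `maturation_mass`.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: $\varphi$ is imposed per density, not emergent
from competition, so there is no interference, no size hierarchy and no
feedback between mortality and food share; weighing ages are exact (no
handling jitter); individual variation is a single multiplicative scale,
not variation in parameters; and the noiseless pipeline identity isolates
reduction bias, not sampling error.

## Numerical choices and test scales

* ODE: `lsoda`, rtol $10^{-9}$, atol $10^{-12}$ mg (fitting uses
  $10^{-8}$/$10^{-10}$ for speed); budget closure along trajectories is
  exact to floating point ($<10^{-8}$ relative by test, observed
  ~$10^{-16}$) because the growth equation is an algebraic rearrangement
  of the balance.
* Root finding and maximisation act on the analytic rate function, not on
  trajectory samples.
* The von Bertalanffy reduction is verified against the closed form to
  $10^{-6}$ relative over a 5-point parameter grid.
* The classical-regime ("$b_N = 0$") food-restriction invariance — ages at
  fixed mass fractions nearly independent of $\varphi$ — is checked at
  $\beta = 2/3$ (the canonical surface-limited-uptake exponent of that
  regime) and fractions $\{0.75, 0.9, 0.95\}$: the residual
  $\varphi$-dependence comes from the hatchling term
  $(W_0/W_U)^{1-\beta}$, which at $\beta = 0.75$ or at early fractions
  exceeds 5% even with no negotiable maintenance at all, so "roughly
  independent" is a late-fraction, $\beta = 2/3$ statement.
* Test problem sizes are chosen for sharpness per CPU-second: recovery
  studies use 15–21 ages and 6–16 optimizer starts; replicate counts are
  8 (unit suite) and 20 (end-to-end suite); sweeps use 6 values of
  $\varphi$ and 2 of $\delta$.

## Known limitations

* Temperature is outside the model; rates are for a fixed thermal
  environment.
* The supplied allometric hooks for composition and defence fractions are
  the simplest monotone forms; stage-structured (holometabolous) growth
  and post-maturation reproductive dynamics are not modelled —
  integration stops at the fixed point.
* The four-parameter ad-libitum form is sloppy in $(c, a_N)$ (see
  fitting); report conditional fits or profile the pair rather than
  quoting marginal uncertainties.
* The registry's comparator set covers the umbrella power-law family and
  the logistic; other literature models can be registered by the user but
  ship without defaults.
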