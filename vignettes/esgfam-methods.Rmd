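---
title: "The exponentiated sine-generated family: models, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The exponentiated sine-generated family: models, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esgfam)
```

## The model

Trigonometric distribution generators build new lifetime families by
composing a bounded transform with an arbitrary baseline CDF. The
sine-generated (SG) family maps a baseline CDF $G(x;\xi)$ to
$\sin\!\big(\tfrac{\pi}{2}G(x;\xi)\big)$, which is again a valid CDF but
with a reshaped hazard. **esgfam** implements the exponentiated extension,

$$F(x;\alpha,\xi) \;=\; \sin\!\Big(\frac{\pi}{2}\,G(x;\xi)\Big)^{\alpha},
\qquad \alpha > 0,$$

which adds a power parameter controlling tail weight and early-failure
behaviour: $\alpha = 1$ recovers the SG family, $\alpha > 1$ lowers the CDF
pointwise (stochastically larger lifetimes), $\alpha < 1$ raises it. The
density, survival and hazard functions follow in closed form, as does the
quantile function
$Q(p) = G^{-1}\big(\tfrac{2}{\pi}\arcsin p^{1/\alpha}\big)$, which the
package uses for inverse-CDF sampling.

The workhorse member is the **exponentiated sine-Weibull (ESW)**
distribution, obtained from the Weibull baseline
$G(x) = 1 - e^{-\lambda x^\beta}$. Note the parameterization: $\lambda$ is
a *rate on $x^\beta$*, not a scale on $x$; other Weibull conventions exist
and estimates are not comparable across them. The three parameters are

* $\alpha > 0$ — the power; with $\beta$ it controls the behaviour of the
  density at the origin ($f \sim x^{\alpha\beta - 1}$), so $\alpha\beta < 1$
  gives an unbounded density at 0 (reported as `Inf`, never an error);
* $\beta > 0$ — the Weibull shape; jointly with $\alpha$ it drives the
  hazard shape (monotone, bathtub or upside-down bathtub);
* $\lambda > 0$ — the rate-like scale, entering quantiles only through the
  factor $\lambda^{-1/\beta}$ (hence Bowley skewness and Moors kurtosis are
  $\lambda$-free).

Submodels arise by restriction: $\beta = 1$ is the exponentiated
sine-exponential (ESE), $\alpha = 1$ the sine-Weibull (SW), and dropping
the sine layer gives the plain Weibull; `esw_fit()` fits all four.

## Series expansions

Many quantities admit expansions in powers of $G$. The package implements
three building blocks, each as explicit coefficient tables
(`sine_power_series()`, `cosine_power_series()`, `desg_series_coefs()`)
plus an evaluator:

* integer powers of a power series by the classical recursion
  (`power_series_pow()`);
* $\sin((\pi/2)G)^w$ for noninteger $w$ by factoring out $G^w$ and
  binomially expanding the remaining entire series;
* $\cos((\pi/2)G)^\rho$ analogously around $\cos(0) = 1$.

The density then becomes a series of exponentiated-baseline densities,
which combined with the gamma-series integral $\psi$ (`esw_psi()`) yields
ESW moments in series form; the double sum is collapsed by grouping terms
with equal total index, so a truncation order $K$ costs only $K + 1$
evaluations of $\psi$.

**Validity region.** The binomial step needs the inner series to stay
inside the unit disc. Its magnitude is bounded by the alternating-series
constant $\sum_{n\ge1}(-1)^n(\pi/2)^{2n}/(2n+1)! = 2/\pi - 1 \approx
-0.363$, so convergence holds on all of $[0, 1)$ — but it slows severely
as $G \to 1$, where the cosine factor also vanishes. The package therefore
*certifies* truncated evaluations only for $G \in [0, 0.9]$ and refuses
outside (`eval_series()` raises rather than silently degrading). The
default truncation is $K = 25$ in each index, which meets a $10^{-6}$
agreement with direct evaluation across the certified region; $K$ is a
user-visible knob. Integer exponents bypass the expansion entirely (the
binomial terminates or the direct form is exact).

## Numerical choices

* **Quadrature.** All integrals go through R's adaptive Gauss–Kronrod
  integrator with relative tolerance $10^{-8}$–$10^{-10}$. Endpoint
  singularities (density at 0 when $\alpha\beta < 1$; the $u^{\alpha_1-1}$
  factor in the reliability integral) are integrable and handled by the
  open rules.
* **The $\psi$ series** is truncated when terms fall below $10^{-14}$; the
  terms decay polynomially (order $s^{-(1+\omega_3)-q}$), so a hard cap
  with a warning guards pathological inputs.
* **Optimization.** All likelihood fits are BFGS in log-parameter space
  (positivity by construction) with analytic gradients, deterministic
  multi-start (a fixed grid plus method-of-quantiles guesses, each with
  the power parameter replaced by its closed-form profile root
  $\hat\alpha(\xi) = -n/\sum\log\sin\frac{\pi}{2}G(x_i;\xi)$), and a
  final polish from the best start.
* **Observed information** is computed from fully analytic second
  derivatives of the ESW log-likelihood; the $\alpha,\alpha$ entry equals
  the closed form $n/\alpha^2$ exactly, and a Richardson-extrapolated
  jacobian of the analytic score is exposed as an independent
  verification route (`method = "score_jacobian"`). The matrix is
  symmetrized before inversion. This matters: the $\beta,\lambda$ block is
  stiff (the two parameters are strongly correlated), and one-shot
  numerical Hessians of the log-likelihood itself are unreliable here —
  which is also the likely origin of a defective published information
  matrix for one of the benchmark datasets, whose printed inverse is
  internally consistent but incompatible with the definition
  $I = -\partial^2 L/\partial\theta\partial\theta^T$ (its lead diagonal
  entry disagrees by an order of magnitude with both of our independent
  routes, while the same code reproduces the published matrix
  entry-for-entry on the second benchmark dataset). The package reports
  the definitional value.
* **Goodness of fit.** KS/AD/CvM are computed with estimated parameters
  plugged in, no Lilliefors-type correction; the KS p-value uses the
  asymptotic Kolmogorov limit of $\sqrt{n}D$ and is documented as
  asymptotic. CAIC is the small-sample corrected AIC,
  $\mathrm{AIC} + 2k(k+1)/(n-k-1)$.

## Bayesian estimation

Independent gamma priors on $(\alpha, \beta, \lambda)$ lead to
nonstandard full conditionals, sampled by random-walk
Metropolis–Hastings within a Gibbs sweep in the order $\alpha \to
\lambda \to \beta$. Design points:

* Default hyperparameters are shape 2, rate 1 for every parameter —
  unimodal priors with all hyperparameters above one, the regime in which
  this estimation scheme is well behaved. They are fully configurable via
  `esw_priors()`; no claim is made that they reproduce any published
  Bayes point estimates, whose hyperparameters are not recoverable.
* Proposal scales start at a quarter of the initial values and are tuned
  only during burn-in (default 30% of 3000 sweeps) toward an acceptance
  rate in (0.2, 0.5), then frozen so the retained chain is Markovian.
* Initialization is the MLE, falling back to prior means.
* The HPD interval is the shortest window of
  $\lceil(1-\epsilon)T\rceil$ consecutive order statistics (ceiling, so
  coverage is at least nominal; ties resolve to the lowest lower
  endpoint).
* Passing an empty sample runs the sampler on the bare priors — the test
  suite uses this to verify the kernels against the known gamma laws.

## Stress–strength reliability

For strength $X$ and stress $Y$, both ESW with a shared $\lambda$,
$R = P(Y < X)$ has the closed form $\alpha_1/(\alpha_1+\alpha_2)$ when
$\beta_1 = \beta_2$ (for any shared baseline, in fact), and otherwise
reduces by the substitution $u = \frac{\pi}{2}G_1(x)$ to a single
integral on $(0, \pi/2)$ evaluated by quadrature. The joint five-parameter
likelihood is maximized in log space; $\hat R$ is the plug-in value at the
MLE.

Bootstrap intervals follow the nonparametric case-resampling scheme with
the two samples resampled independently. Two conventions are implemented
exactly as specified for this analysis and deserve flags:

* the $\delta$ percentile of the replicate estimates is defined through
  the indicator equation, i.e. the smallest order statistic whose
  empirical CDF reaches $\delta$ (index $\lceil\delta B\rceil$, with a
  $10^{-9}$ slack so $\delta B$ cannot straddle an integer in floating
  point);
* the studentized (Bt) interval is centred at the replicate *mean*
  $\bar R^*$, not at $\hat R$ — this differs from the textbook
  bootstrap-t and is retained deliberately; endpoints are sorted so the
  interval is always proper.

Replicate fits that fail are retried on fresh resamples up to five times,
then dropped, and the effective $B$ is reported.

## The simulation harnesses and what they show

`simulate_mle_study()` and `simulate_ss_study()` regenerate the package's
own study conditions: inverse-CDF samples at fixed true parameters, fits
per replicate, and per-cell bias, MSE, SD, average interval length and
coverage. A master seed spawns one sub-seed per replicate, so any cell is
reproducible independently of loop organization; failed replicate fits
are dropped and counted (`n_fail`), keeping coverage denominators
explicit.

The generators emulate exactly the idealized conditions of a
Monte-Carlo design: i.i.d. draws from the true model, no censoring, no
measurement rounding, no covariates. Passing recovery and coverage tests
therefore demonstrates internal correctness of estimator and interval
code — not robustness to misspecification, censoring or dependence, which
real lifetime data routinely exhibit.

Problem sizes used by the shipped checks: recovery/coverage at $n = 300$
with 300–500 replicates; the reliability study cell at $n = m = 60$ with
1000 replicates; bootstrap coverage at $B = 200$ with 120 replicates.
These are the package's own verification scales, chosen so the whole
suite re-runs comfortably on one core; all counts are arguments, and the
full-scale designs (replicates and $B$ of 1000) run unchanged.

## Known limitations

* Series paths require noninteger exponents and the certified
  $G \le 0.9$ region; quadrature is always the production route.
* Wald intervals are on the natural scale, as in the source analysis;
  for small samples a log-scale or profile interval would cover better,
  and `esw_profile()` provides the profile curves.
* The exact mean-residual-life path refuses when the survival probability
  underflows below $10^{-12}$; use the incomplete-gamma asymptote there.
* KS p-values are asymptotic; with estimated parameters they are known to
  be conservative.
* Unequal-$\lambda$ stress–strength reliability is out of scope, as are
  competitor families used only for comparison tables in the source
  analysis, and alternative loss functions for the Bayes estimates.
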