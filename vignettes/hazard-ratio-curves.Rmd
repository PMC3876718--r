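---
title: "Smooth hazard-ratio curves: model, smoothing, selection, inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth hazard-ratio curves: model, smoothing, selection, inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrspline)
```

## The model and its assumptions

`hrspline` fits the additive Cox proportional hazards model

$$\alpha(t; Z) = \alpha_0(t)\exp\Big(\sum_{i=1}^q f_i(Z_i) +
\sum_{i=q+1}^p \beta_i Z_i\Big),$$

where the first $q$ continuous covariates act through unknown smooth
functions $f_i$ and the rest act linearly. Estimation is by the partial
likelihood, so the baseline hazard $\alpha_0$ is never estimated — and the
package deliberately offers no baseline or survival-function estimate. The
assumptions are the usual ones: proportional hazards (each covariate's
effect multiplies the hazard by a time-constant factor — checkable with
`ph_test()`), independent right censoring, and, when entry times are
supplied, left truncation that is independent given covariates. Risk sets
are $\{l : \text{entry}_l < t \le \text{exit}_l\}$; tied event times are
handled by Efron's correction (default) or Breslow's.

The scientific output is not the spline coefficients but the
**hazard-ratio curve** $\widehat{HR}(z, z_{ref}) =
\exp(\hat f(z) - \hat f(z_{ref}))$ against a reference value $z_{ref}$,
with pointwise limits
$\exp\big(\widehat{\ln HR} \pm z_{1-\alpha/2}\,\widehat{SE}\big)$, where
the variance comes from the sandwich covariance $V = H^{-1} I H^{-1}$
($I$ the observed information at the optimum, $H = I + P$ the penalized
Hessian). For a linear term the curve degenerates to the familiar straight
line $\hat\beta\,(z - z_{ref})$ with $SE = |z - z_{ref}|\,SE(\hat\beta)$,
so linear and smooth terms are reported through one interface.

A note on covariance ordering: $H^{-1} = V + H^{-1} P H^{-1}$, so the
sandwich is the *smallest* of the three natural covariances,
$V \preceq H^{-1} \preceq I^{-1}$ — the penalty buys variance at the price
of smoothing bias. The test suite asserts this ordering.

## Smoothers

**P-splines** (default): a cubic B-spline basis on equally spaced knots
spanning the observed covariate range, extended `degree` steps beyond each
boundary, with the discrete difference penalty $P = D^\top D$ of order 2
(null space = straight lines). The basis size is
$\max(\lceil 2.5\,\mathrm{df}\rceil + 3,\ \text{order} + 2)$, capped at 40
— rich enough that any requested effective df is attainable, small enough
that the information matrix stays well conditioned at moderate $n$.
Because the basis is a partition of unity and the partial likelihood is
invariant to constant shifts of the log hazard, the all-ones coefficient
direction is unidentifiable *and* penalty-free; the basis is therefore
reparameterized onto the orthogonal complement of that direction
(`constrain_identifiability()`). Hazard-ratio differences are invariant to
this choice. Evaluation outside the boundary knots clamps to the boundary
with a warning — a raw B-spline is zero out there, which would silently
zero the effect.

**Natural cubic splines**: integer df, `df` basis columns, boundary knots
at the covariate extremes and `df - 1` interior knots at equally spaced
(type-7) quantiles, linear extrapolation beyond the boundary (their
defining property). No penalty; complexity is controlled by df alone.

One wording in the source literature places default knots "at predefined
percentiles of the survival times". For a covariate basis this is almost
certainly a slip for percentiles of the covariate — quantiles of follow-up
time do not define a covariate basis — so covariate quantiles are the
default; the literal behaviour remains selectable via
`spline_term(..., knot_source = "survival_time")` and is documented as
rarely sensible.

## Smoothing as degrees of freedom

Users state smoothness as effective degrees of freedom
$\mathrm{df} = \mathrm{tr}(H^{-1} I)$ per term; the internal penalty
weight $\lambda$ is found by bisection on $\log_{10}\lambda \in [-12, 12]$
(df is continuous and monotone nonincreasing in $\lambda$), to a default
tolerance of $10^{-3}$. With several P-spline terms, each term's df
depends weakly on the others through the shared information matrix, so the
bisections repeat cyclically (up to 10 passes, joint tolerance 0.01).
Warm starts make each probe cost only a couple of Newton iterations. The
near-unpenalized bracket end is probed only when the bisection actually
walks there, because an effectively unpenalized rich basis on a modest
cohort can carry a monotone likelihood (divergent MLE).

## Newton–Raphson: numerical choices

* Step-halving (up to 20) on the penalized objective; gradient-direction
  fallback if the Hessian solve fails.
* Convergence: relative objective change $< 10^{-9}$ *and* flatness —
  either gradient max-norm $< 10^{-6}$ or squared Newton decrement
  $g^\top H^{-1} g < 10^{-9}(1 + |f|)$. The absolute gradient criterion
  alone is unattainable at extreme penalties ($\lambda = 10^{12}$ makes
  gradient rounding noise of order $\lambda\,\varepsilon\,\|\beta\|$), so
  the scale-invariant decrement is accepted as the alternative.
* Stall detection: three consecutive iterations with negligible decrement
  end the iteration — at the extreme-penalty noise floor the objective
  oscillates by ~$10^{-6}$ while no genuine ascent exists. Measured
  optimizer precision on well-conditioned problems is unaffected (score at
  the optimum $\sim 10^{-11}$).
* The linear predictor is declared overflowed beyond $|\eta| > 250$; such
  steps are rejected and halved.

## Model selection

Criterion scores use the maximized log partial likelihood and total df =
(smooth-term traces) + (number of linear coefficients):
$\mathrm{AIC} = -2\,\mathrm{LPL} + 2\,\mathrm{df}$;
$\mathrm{BIC} = -2\,\mathrm{LPL} + \ln(d)\,\mathrm{df}$ and
$\mathrm{AICc} = -2\,\mathrm{LPL} + 2d(\mathrm{df}+1)/(d - \mathrm{df} -
2)$ with $d$ the **event count**, not the record count — censored
observations carry little information, and using $n$ would over-penalize
lightly censored cohorts and under-penalize heavy ones. AICc is undefined
unless $d > \mathrm{df} + 2$ and the package refuses rather than
extrapolates. AIC tends to overfit; AICc and BIC read together are the
recommended practice.

`dfmacox_search()` selects df for several nonlinear terms jointly: per
round, each covariate contributes (interval minimum, midpoint, maximum);
all $3^q$ combinations are fitted (cached by df combination) and scored;
each interval is halved towards the winner's coordinate. Design choices
where the procedure was genuinely open:

* natural-spline midpoints round half-*down* (parsimony);
* when the midpoint wins, the kept half is the one containing the better
  endpoint, ties to the lower half;
* the reported answer is the best over the *entire* evaluated history, not
  the final round — it strictly dominates and costs nothing;
* P-spline minimum df defaults to 1.1 (the literature only requires
  "strictly greater than 1"); the per-covariate maximum defaults to the
  univariate AICc optimum (`default_max_df()`, a golden-section search on
  $\log\lambda$ — equivalent to a df search because df is monotone in
  $\lambda$ — stopped at df resolution 0.05).

**Known limitation, stated plainly.** Interval halving is *not* a valid
bracketing scheme for this problem: even a unimodal criterion surface can
have its minimizer discarded, because the kept half is decided by endpoint
scores and a df-1 endpoint that misses real curvature scores so badly that
the search always walks away from the low-df region where the minimum
often sits. On seeded n = 150 cohorts the search misses the exhaustive
integer-scan minimizer in a majority of AIC/AICc cases (BIC, whose optima
sit in flatter regions, fares better), and the corresponding acceptance
test is deliberately left failing as a faithful record of this property.
When $q$ is small enough, an exhaustive scan over integer df is cheap and
strictly better; the search's value is the multivariable case where
$3^q \times$ rounds is far below the full grid.

## The synthetic-data generator

`simulate_cohort()` draws event times by inverse transform from a Weibull
baseline (constant hazard by default — the method under test never touches
the baseline, a Weibull shape is provided purely to exercise non-exponential
time scales), with declared nonlinear log-hazard shapes: `linear`,
`quadratic`, `jshape` (a "linex" curve $s(e^{-u} + u - 1)$,
$u = (z - m)/w$: steep convex rise below the minimum, asymptotically
linear above — the shape of mortality against fasting glucose), `sigmoid`,
`zero`. Censoring is administrative, uniform, or exponential; optional
left truncation redraws records whose entry is not before their exit (the
count is reported). A single integer seed governs all draws in a fixed
order, so cohorts are bit-reproducible.

The shipped scenarios (`example_design()`) fix the stated world of the
test suite: `quadratic` (n-varying, ~70–75% events) for coverage and
bootstrap checks, `jshape` (minimum at 105, lognormal glucose around a
median of 110, ~60% events) for reference-selection behaviour, `linear`
(~30% censoring) for parameter recovery and null PH calibration. What the
generator does **not** emulate: covariate measurement error, time-varying
covariates or effects, competing risks, informative censoring, multi-state
structure. A green coverage or recovery test therefore certifies the
estimator under a correctly specified proportional-hazards world, nothing
more.

## Proportional-hazards diagnostic

`ph_test()` is the Grambsch–Therneau score test: unscaled Schoenfeld
residuals $s_k = x_{(k)} - \bar x(t_k)$ at each event, a centred time
transform $g$ (default $1 - \widehat{KM}(t^-)$, the recommended choice;
`identity` and `rank` are available), $u = \sum_k (g_k - \bar g) s_k$, and
$\chi^2 = d\, u^\top V u / \sum_k (g_k - \bar g)^2$ globally (block-
restricted for per-term rows), on the fit's effective df. For penalized
fits $V$ is the sandwich covariance; the classical theory is exact only in
the unpenalized case, and the simulation calibration (null rejection
2–9% at $\alpha = 0.05$, power > 80% against a sign-switching
time-varying coefficient) is part of the acceptance suite.

## Degenerate inputs and tie-breaks

* Reference selection at `prob = 0`/`1` searches the *observed* covariate
  values (data-anchored, reproducible), not a continuous grid.
* `pred_value` outside the observed range is clamped with a warning.
* The HR contrast at the reference point is set to exactly zero, so the
  reported log-HR and SE are identically 0 there rather than BLAS-rounding
  noise.
* Equal criterion scores in the df search resolve to the first (lowest-df)
  combination in evaluation order.
* Missing values: empty fields and `"NA"` are missing; any other
  non-numeric token in an otherwise numeric column is an error — silent
  coercion hides data bugs. Columns that are entirely non-numeric are
  treated as categorical and expanded to reference-coded indicators (first
  observed level is the reference).

## Scope

No baseline-hazard or survival estimation, no stratification, frailties,
robust/cluster variance, time-varying effects, simultaneous confidence
bands, or REML/CV smoothing selection. The bootstrap appears only as a
test oracle for the sandwich standard errors, never as a user-facing
interval method.
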