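# hrspline — smooth hazard-ratio curves for additive Cox models

Clinical survival analyses routinely force continuous predictors (glucose,
age, a tumour marker) into a log-linear Cox term, even when the underlying
risk relationship is U- or J-shaped. `hrspline` is for the analyst who wants
to *see* that relationship: it fits the additive Cox model

```
alpha(t; Z) = alpha0(t) * exp( sum_i f_i(Z_i) + sum_j beta_j Z_j )
```

where the `f_i` are penalized B-splines (P-splines) or natural cubic
splines, and reports each effect as a **hazard-ratio curve**

```
HR(z, z_ref) = exp( f(z) - f(z_ref) )
```

anchored at a reference value `z_ref` (chosen directly, or as the fitted
curve's minimum/maximum), with pointwise confidence limits.

## What it computes

* **Penalized partial likelihood.** Newton–Raphson maximization of
  `LPL(beta) - 0.5 * sum_j lambda_j beta_j' P_j beta_j`, with Efron or
  Breslow tie handling, delayed entry (counting-process rows), and the
  Eilers–Marx difference penalty `P = D'D` on adjacent B-spline
  coefficients.
* **Inference.** Pointwise limits from the sandwich covariance
  `V = H^-1 I H^-1` with `I` the observed information and `H = I + P`:
  `Var(ln HR(z, z_ref)) = c'Vc`, `c = b(z) - b(z_ref)`.
* **Smoothness as degrees of freedom.** The public smoothing parameter is
  the effective df `tr(H^-1 I)` per term; `lambda` is calibrated internally
  by bisection to hit the requested df.
* **Automatic multivariable df selection** (`dfmacox_search`): iterated
  interval-halving over df combinations of several nonlinear terms,
  minimizing AIC, corrected AIC (AICc, with the event count as sample
  size), or the event-count BIC.
* **Diagnostics.** Grambsch–Therneau proportional-hazards score test on
  scaled Schoenfeld residuals.
* **Synthetic cohorts.** An inverse-transform simulator with declared
  nonlinear log-hazard shapes (linear, quadratic, J-shape, sigmoid), so
  every estimation and selection path is testable without clinical data.

## Worked example

A 600-patient cohort with a J-shaped dependence of mortality on a
glucose-like covariate (true hazard minimum at 105 mg/dL), fitted with a
4-df P-spline:

```r
library(hrspline)
cohort <- simulate_cohort(example_design("jshape", n = 600, seed = 42))
fit <- fit_penalized_cox(cohort, spline_term("glucose", "penalized_bspline", df = 4))
fit
#> Additive Cox model (penalized partial likelihood)
#> n = 600, events = 443, ties = efron, iterations = 2
#> log partial likelihood = -2546.5115
#>
#> Terms:
#>   ps(glucose)      penalized_bspline  df =  4.000, lambda = 8.544
#>
#> Total df = 4.000  AIC = 5101.024  AICc = 5103.161  BIC = 5117.400
#>
#> Proportional hazards test (Grambsch-Therneau, km transform):
#>             chisq df     p
#> ps(glucose) 1.083  4 0.897
#> GLOBAL      1.083  4 0.897

ref <- select_reference(fit, "glucose", prob = 0)   # fitted hazard minimum
round(ref, 1)
#> [1] 113.4
round(predict_hr(fit, "glucose", c(70, 90, ref, 130, 180, 220),
                 pred_value = ref), 4)
#>      value log_hr      hr     se lower_hr upper_hr
#> 1  70.0000 1.0957  2.9913 0.1450   2.2511   3.9748
#> 2  90.0000 0.3668  1.4431 0.0726   1.2517   1.6637
#> 3 113.3857 0.0000  1.0000 0.0000   1.0000   1.0000
#> 4 130.0000 0.1904  1.2098 0.0545   1.0872   1.3461
#> 5 180.0000 1.8226  6.1877 0.1786   4.3605   8.7804
#> 6 220.0000 2.9155 18.4578 0.3658   9.0114  37.8070
```

Reading the table: relative to the fitted minimum-risk glucose value
(113.4 here — estimated from data whose true minimum is 105), a patient at
70 mg/dL carries about 3.0 times the hazard (95% CI 2.3–4.0), the curve is
nearly flat around the reference (HR 1.21 at 130), and risk climbs steeply
above 180 — the classic J shape. The HR at the reference is exactly 1 with
a zero-width interval by construction. `hr_curve()` gives the full curve;
`plot()`/`render_curve()` draw it with its confidence band and a rug of
observed values.

Degrees of freedom for several nonlinear terms are selected jointly with

```r
dfmacox_search(cohort, nl_covariates = "glucose", smoother = "natural_cubic",
               criterion = "AICc")
```

## Command line

Every step is scriptable via `exec/hrspline` (or `hrspline_cli()`):

```sh
hrspline simulate --scenario jshape --n 600 --seed 42 --out runs/sim
hrspline fit    --input runs/sim/cohort.csv --time-col entry_time \
                --time2-col exit_time --status-col status \
                --nl glucose --smoother pspline --df 4 --out runs/fit
hrspline select --input runs/sim/cohort.csv --time-col entry_time \
                --time2-col exit_time --status-col status \
                --nl glucose --smoother ns --criterion AICc --out runs/sel
hrspline hr     --input runs/sim/cohort.csv --time-col entry_time \
                --time2-col exit_time --status-col status --nl glucose \
                --smoother pspline --df 4 --covariate glucose --prob 0 \
                --out runs/hr
```

Outputs are CSV tables, JSON summaries, a merged `config.json` (every run
is reproducible from it), a structured `run.log`, and PNG/SVG/PDF figures.
Exit codes: 0 success, 2 validation error, 3 numerical failure.

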