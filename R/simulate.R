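# Survival-data simulator: right-censored (optionally left-truncated)
# cohorts with known additive log-hazard structure, by inverse-transform
# sampling.  The baseline hazard is Weibull (constant/exponential when
# shape = 1); proportional hazards holds under any baseline, so the method
# under test never depends on it.

eval_effect <- function(effect, z) {
  switch(effect$shape,
         zero = rep(0, length(z)),
         linear = effect$slope * z,
         quadratic = effect$curvature * (z - effect$center)^2,
         # J-shape: steep convex rise below the minimum, asymptotically
         # linear above it (a "linex" curve) — the familiar shape of e.g.
         # mortality risk against fasting glucose
         jshape = {
           u <- (z - effect$min_at) / effect$width
           effect$steepness * (exp(-u) + u - 1)
         },
         sigmoid = effect$height / (1 + exp(-(z - effect$center) / effect$scale)),
         hs_stop(sprintf("unknown effect shape '%s'", effect$shape)))
}

draw_covariate <- function(spec, n) {
  switch(spec$dist,
         uniform = runif(n, spec$min, spec$max),
         normal = rnorm(n, spec$mean, spec$sd),
         lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
         hs_stop(sprintf("unknown covariate distribution '%s'", spec$dist)))
}

draw_censoring <- function(spec, n) {
  switch(spec$type,
         none = rep(Inf, n),
         administrative = rep(spec$tau, n),
         uniform = runif(n, 0, spec$max),
         exponential = rexp(n, spec$rate),
         hs_stop(sprintf("unknown censoring type '%s'", spec$type)))
}

#' Describe a simulation scenario
#'
#' A fully explicit generative model of the additive Cox class: covariates
#' with declared distributions, named true effect functions on the log
#' hazard, a Weibull baseline hazard \eqn{\alpha_0(t) = \lambda k t^{k-1}}
#' (constant when `baseline_shape = 1`), an independent censoring mechanism,
#' and optionally a left-truncation (delayed entry) sampler.
#'
#' @param n cohort size.
#' @param covariates named list of samplers, e.g.
#'   `list(z = list(dist = "normal", mean = 0, sd = 1))`; distributions:
#'   `uniform(min, max)`, `normal(mean, sd)`, `lognormal(meanlog, sdlog)`.
#' @param effects named list of true effect functions on the log hazard;
#'   shapes: `linear(slope)`, `quadratic(center, curvature)`,
#'   `jshape(min_at, steepness, width)`, `sigmoid(center, scale, height)`,
#'   `zero`.
#' @param linear_effects named numeric vector of plain linear coefficients
#'   (shorthand for `linear` effects).
#' @param baseline_rate Weibull rate \eqn{\lambda > 0}.
#' @param baseline_shape Weibull shape \eqn{k > 0} (1 = exponential).
#' @param censoring list: `list(type = "administrative", tau = )`,
#'   `list(type = "uniform", max = )`, `list(type = "exponential", rate = )`,
#'   or `list(type = "none")`.
#' @param truncation optional entry-time sampler (same format as a covariate
#'   sampler); records with entry >= exit are redrawn.
#' @param seed integer seed making the cohort fully reproducible.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n, covariates, effects = list(),
                              linear_effects = NULL, baseline_rate = 0.1,
                              baseline_shape = 1,
                              censoring = list(type = "none"),
                              truncation = NULL, seed = 1L) {
  if (!is_scalar_number(n) || n < 2) hs_stop("n must be at least 2")
  if (!is_scalar_number(baseline_rate) || baseline_rate <= 0)
    hs_stop("baseline_rate must be positive")
  if (!is_scalar_number(baseline_shape) || baseline_shape <= 0)
    hs_stop("baseline_shape must be positive")
  if (!length(covariates) || is.null(names(covariates)))
    hs_stop("covariates must be a named list of samplers")
  for (nm in names(effects))
    if (!nm %in% names(covariates))
      hs_stop(sprintf("effect '%s' references an undeclared covariate", nm))
  for (nm in names(linear_effects))
    if (!nm %in% names(covariates))
      hs_stop(sprintf("linear effect '%s' references an undeclared covariate",
                      nm))
  structure(list(n = as.integer(n), covariates = covariates,
                 effects = effects,
                 linear_effects = linear_effects, baseline_rate = baseline_rate,
                 baseline_shape = baseline_shape, censoring = censoring,
                 truncation = truncation, seed = as.integer(seed)),
            class = "simulation_design")
}

design_eta <- function(design, covs) {
  eta <- rep(0, nrow(covs))
  for (nm in names(design$effects))
    eta <- eta + eval_effect(design$effects[[nm]], covs[[nm]])
  for (nm in names(design$linear_effects))
    eta <- eta + design$linear_effects[[nm]] * covs[[nm]]
  eta
}

#' Simulate a cohort from a design
#'
#' Event times are drawn by inverse transform from the Weibull
#' proportional-hazards model \eqn{S(t \mid z) = \exp(-\lambda t^k
#' e^{\eta(z)})}: with `E ~ Exp(1)`, `T = (E / (lambda * exp(eta)))^(1/k)`.
#' Exit time is `min(T, C)`, status is `T <= C`.  With truncation, records
#' whose entry time is not before their exit time are redrawn (the count is
#' reported via `message()`).  Bit-reproducible from `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return A [survival_dataset()].
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n <- design$n
  draw <- function(m) {
    covs <- as.data.frame(lapply(design$covariates, draw_covariate, n = m),
                          check.names = FALSE)
    eta <- design_eta(design, covs)
    E <- rexp(m)
    T <- (E / (design$baseline_rate * exp(eta)))^(1 / design$baseline_shape)
    C <- draw_censoring(design$censoring, m)
    entry <- if (!is.null(design$truncation))
      draw_covariate(design$truncation, m) else rep(0, m)
    data.frame(entry = entry, exit = pmin(T, C),
               status = as.numeric(T <= C), covs, check.names = FALSE)
  }
  out <- draw(n)
  redrawn <- 0L
  attempts <- 0L
  repeat {
    bad <- which(out$entry >= out$exit | out$exit <= 0)
    if (!length(bad)) break
    attempts <- attempts + length(bad)
    if (attempts > 10L * n)
      hs_stop_numeric("censoring/truncation too heavy: records cannot be drawn")
    redrawn <- redrawn + length(bad)
    out[bad, ] <- draw(length(bad))
  }
  if (redrawn > 0L)
    message(sprintf("%d truncated records redrawn", redrawn))
  if (sum(out$status) < 2L)
    hs_stop_numeric("censoring too heavy: fewer than 2 events")
  survival_dataset(exit_time = out$exit, status = out$status,
                   entry_time = if (!is.null(design$truncation)) out$entry,
                   covariates = out[, -(1:3), drop = FALSE])
}

#' True log hazard ratio of a design
#'
#' Ground truth \eqn{f(z) - f(z_{ref})} from the design's declared effect
#' function — the quantity [hr_curve()] estimates.
#'
#' @param design a [simulation_design()].
#' @param covariate covariate name with a declared effect.
#' @param z,z_ref evaluation and reference values.
#' @return Numeric vector `f(z) - f(z_ref)`.
#' @export
true_log_hr <- function(design, covariate, z, z_ref) {
  stopifnot(inherits(design, "simulation_design"))
  eff <- design$effects[[covariate]]
  if (is.null(eff)) {
    if (!covariate %in% names(design$linear_effects))
      hs_stop(sprintf("covariate '%s' has no declared effect", covariate))
    eff <- list(shape = "linear",
                slope = design$linear_effects[[covariate]])
  }
  eval_effect(eff, z) - eval_effect(eff, rep(z_ref, length(z)))
}

#' Shipped example designs
#'
#' Fixed simulation scenarios used throughout the package tests and
#' documentation:
#'
#' * `linear`: standard-normal covariate, slope 0.7, exponential baseline
#'   rate 0.5, uniform(0, 6) censoring (about 30 percent censored).
#' * `quadratic`: standard-normal covariate, log-hazard `0.5 * z^2`,
#'   baseline rate 0.2, uniform(0, 15) censoring (about 70 percent events).
#' * `jshape`: lognormal "fasting-glucose-like" covariate (median about
#'   110), J-shaped log hazard with minimum at 105 and unit steepness over
#'   a width of 30, baseline rate 0.1, administrative censoring at t = 10
#'   (about 60 percent events).
#' * `sigmoid`: standard-normal covariate, sharp sigmoid of height 2 and
#'   scale 0.3, baseline rate 0.3, uniform(0, 10) censoring.
#'
#' @param shape scenario name.
#' @param n cohort size.
#' @param seed integer seed.
#' @return A [simulation_design()].
#' @export
example_design <- function(shape = c("linear", "quadratic", "jshape",
                                     "sigmoid"),
                           n = 200L, seed = 1L) {
  shape <- match.arg(shape)
  switch(shape,
    linear = simulation_design(
      n = n, seed = seed,
      covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
      linear_effects = c(z = 0.7),
      baseline_rate = 0.5,
      censoring = list(type = "uniform", max = 6)),
    quadratic = simulation_design(
      n = n, seed = seed,
      covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
      effects = list(z = list(shape = "quadratic", center = 0,
                              curvature = 0.5)),
      baseline_rate = 0.2,
      censoring = list(type = "uniform", max = 15)),
    jshape = simulation_design(
      n = n, seed = seed,
      covariates = list(glucose = list(dist = "lognormal",
                                       meanlog = log(110), sdlog = 0.25)),
      effects = list(glucose = list(shape = "jshape", min_at = 105,
                                    steepness = 1, width = 30)),
      baseline_rate = 0.1,
      censoring = list(type = "administrative", tau = 10)),
    sigmoid = simulation_design(
      n = n, seed = seed,
      covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
      effects = list(z = list(shape = "sigmoid", center = 0, scale = 0.3,
                              height = 2)),
      baseline_rate = 0.3,
      censoring = list(type = "uniform", max = 10)))
}

#' Expected event fraction of a design
#'
#' Numerically integrates `P(T <= C)` over the covariate and censoring
#' distributions by plain Monte Carlo quadrature with `m` draws from the
#' design (independent of any simulated cohort's seed).  Used to check that
#' simulated cohorts match their design-implied censoring level.
#'
#' @param design a [simulation_design()].
#' @param m number of quadrature draws.
#' @param seed seed for the quadrature draws.
#' @return Expected fraction of records with an observed event.
#' @export
expected_event_fraction <- function(design, m = 20000L, seed = 99991L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  covs <- as.data.frame(lapply(design$covariates, draw_covariate, n = m),
                        check.names = FALSE)
  eta <- design_eta(design, covs)
  rate <- design$baseline_rate * exp(eta)
  C <- draw_censoring(design$censoring, m)
  # P(T <= C | z, C) = 1 - exp(-rate * C^shape)
  mean(1 - exp(-rate * pmin(C, 1e300)^design$baseline_shape))
}
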