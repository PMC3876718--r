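test_that("log partial likelihood matches closed forms on tiny cohorts", {
  # two records, exits (1, 2), both events, z = (1, 0):
  # LPL(beta) = beta - log(exp(beta) + 1)
  ds <- survival_dataset(exit_time = c(1, 2), status = c(1, 1),
                         covariates = data.frame(z = c(1, 0)))
  X <- matrix(ds$covariates$z)
  for (b in c(0, -1.3, 0.7))
    expect_equal(log_partial_likelihood(ds, X, b), b - log(exp(b) + 1))
  expect_equal(log_partial_likelihood(ds, X, 0), -log(2))

  # beta = 0, no ties: -sum over events of log |risk set|
  set.seed(7)
  ds2 <- make_cohort("linear", n = 30, seed = 7)
  X2 <- matrix(ds2$covariates$z)
  rs <- vapply(ds2$exit_time[ds2$status == 1],
               function(t) sum(ds2$exit_time >= t), numeric(1L))
  expect_equal(log_partial_likelihood(ds2, X2, 0), -sum(log(rs)))

  ds0 <- survival_dataset(exit_time = 1:3, status = c(0, 0, 0),
                          covariates = data.frame(z = 1:3))
  expect_error(log_partial_likelihood(ds0, matrix(1:3), 0),
               "partial likelihood undefined")
})

test_that("tied event times match hand-enumerated Breslow and Efron sums", {
  ds <- tied_cohort()
  X <- as.matrix(ds$covariates)
  for (b in c(0, 0.8, -0.4)) {
    for (tm in c("breslow", "efron")) {
      expect_equal(log_partial_likelihood(ds, X, b, ties_method = tm),
                   oracle_lpl(ds$entry_time, ds$exit_time, ds$status, X, b,
                              ties = tm),
                   tolerance = 1e-12)
    }
  }
  # and against survival's evaluation at fixed coefficients
  for (tm in c("breslow", "efron")) {
    cf <- survival::coxph(
      survival::Surv(ds$exit_time, ds$status) ~ x, data = ds$covariates,
      ties = tm, init = 0.8,
      control = survival::coxph.control(iter.max = 0))
    expect_equal(log_partial_likelihood(ds, X, 0.8, ties_method = tm),
                 cf$loglik[2], tolerance = 1e-10)
  }
})

test_that("fits agree with survival::coxph (linear, spline, delayed entry)", {
  ds <- make_cohort("linear", n = 250, seed = 8)
  f <- fit_penalized_cox(ds, linear_term("z"))
  cf <- survival::coxph(survival::Surv(ds$exit_time, ds$status) ~ z,
                        data = ds$covariates)
  expect_equal(unname(f$coefficients), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(f$lpl, cf$loglik[2], tolerance = 1e-9)
  expect_equal(f$covariance[1, 1], vcov(cf)[1, 1], tolerance = 1e-7)

  # natural-spline additive model
  f2 <- fit_penalized_cox(ds, list(spline_term("z", "natural_cubic", df = 3)))
  kn <- place_knots(ds$covariates$z, spline_term("z", "natural_cubic", df = 3))
  NB <- natural_cubic_basis(ds$covariates$z,
                            interior_knots = kn$interior_knots,
                            boundary_knots = kn$boundary_knots)
  cf2 <- survival::coxph(survival::Surv(ds$exit_time, ds$status) ~ NB)
  expect_equal(f2$lpl, cf2$loglik[2], tolerance = 1e-9)
  expect_equal(unname(f2$coefficients), unname(coef(cf2)), tolerance = 1e-6)

  # delayed entry
  dtr <- simulation_design(
    n = 250, seed = 9,
    covariates = list(z = list(dist = "normal", mean = 0, sd = 1)),
    linear_effects = c(z = 0.6), baseline_rate = 0.4,
    censoring = list(type = "uniform", max = 8),
    truncation = list(dist = "uniform", min = 0, max = 0.4))
  ds3 <- suppressMessages(simulate_cohort(dtr))
  f3 <- fit_penalized_cox(ds3, linear_term("z"))
  cf3 <- survival::coxph(
    survival::Surv(ds3$entry_time, ds3$exit_time, ds3$status) ~ z,
    data = ds3$covariates)
  expect_equal(unname(f3$coefficients), unname(coef(cf3)), tolerance = 1e-7)
  expect_equal(f3$lpl, cf3$loglik[2], tolerance = 1e-9)
})

test_that("Breslow and Efron coincide exactly without ties", {
  ds <- make_cohort("quadratic", n = 120, seed = 10)
  expect_equal(anyDuplicated(ds$exit_time[ds$status == 1]), 0L)
  fe <- fit_penalized_cox(ds, spline_term("z", "penalized_bspline", df = 3),
                          ties_method = "efron")
  fb <- fit_penalized_cox(ds, spline_term("z", "penalized_bspline", df = 3),
                          lambdas = unname(fe$lambdas),
                          ties_method = "breslow")
  expect_equal(fe$lpl, fb$lpl, tolerance = 1e-12)
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
  expect_equal(fe$covariance, fb$covariance, tolerance = 1e-8)
})

test_that("partial likelihood is invariant to covariate shifts", {
  ds <- make_cohort("quadratic", n = 150, seed = 11)
  f <- fit_penalized_cox(ds, spline_term("z", "penalized_bspline", df = 4))
  ds_shift <- survival_dataset(
    exit_time = ds$exit_time, status = ds$status,
    covariates = data.frame(z = ds$covariates$z + 100))
  f2 <- fit_penalized_cox(ds_shift,
                          spline_term("z", "penalized_bspline", df = 4),
                          lambdas = unname(f$lambdas))
  expect_equal(f$lpl, f2$lpl, tolerance = 1e-9)
  ref1 <- median(ds$covariates$z)
  c1 <- hr_curve(f, "z", ref1, grid = ref1 + c(-1, 0.5, 1))
  c2 <- hr_curve(f2, "z", ref1 + 100, grid = ref1 + 100 + c(-1, 0.5, 1))
  expect_equal(c1$log_hr, c2$log_hr, tolerance = 1e-9)
  expect_equal(c1$se, c2$se, tolerance = 1e-8)
})

test_that("covariance ordering: sandwich <= penalized inverse <= I^-1", {
  # H = I + P gives H^-1 = V + H^-1 P H^-1, so H^-1 - V is PSD (the sandwich
  # is the smallest of the three covariances, I^-1 the largest)
  ds <- make_cohort("quadratic", n = 200, seed = 12)
  f <- fit_penalized_cox(ds, list(spline_term("z", "penalized_bspline",
                                              df = 3.5)))
  expect_lt(max(abs(f$covariance - t(f$covariance))), 1e-12)
  expect_true(all(diag(f$covariance) >= 0))
  min_eig <- function(M) min(eigen((M + t(M)) / 2, symmetric = TRUE,
                                   only.values = TRUE)$values)
  expect_gt(min_eig(solve(f$hessian) - f$covariance), -1e-10)
  expect_gt(min_eig(solve(f$info) - solve(f$hessian)), -1e-10)
})

test_that("effective df: limits and lambda monotonicity; total-df identity", {
  ds <- make_cohort("quadratic", n = 200, seed = 13)
  term <- spline_term("z", "penalized_bspline", df = 4)
  f0 <- fit_penalized_cox(ds, list(term), lambdas = 0)
  expect_equal(unname(f0$df_per_term), ncol(f0$design), tolerance = 1e-8)
  expect_lt(max(abs(f0$covariance - solve(f0$info))), 1e-7)

  dfs <- vapply(10^seq(-4, 4, length.out = 10), function(l) {
    unname(fit_penalized_cox(ds, list(term), lambdas = l)$df_per_term)
  }, numeric(1L))
  expect_true(all(diff(dfs) <= 1e-8))
  expect_true(all(dfs <= ncol(f0$design) + 1e-6 & dfs >= 1 - 1e-6))

  # sum of block traces equals trace(H^-1 I); linear block trace ~ its count
  set.seed(977)
  dq <- survival_dataset(ds$exit_time, ds$status,
                         covariates = data.frame(z = ds$covariates$z,
                                                 u = rnorm(ds$n)))
  fm <- fit_penalized_cox(dq, list(spline_term("z", "penalized_bspline",
                                               df = 3),
                                   linear_term("u")))
  expect_equal(sum(fm$df_per_term),
               sum(diag(solve(fm$hessian, fm$info))), tolerance = 1e-10)
  expect_equal(sum(fm$df_per_term),
               unname(fm$df_per_term[1]) + 1, tolerance = 1e-6)
})

test_that("solve_lambda_for_df is self-consistent and range-checked", {
  ds <- make_cohort("quadratic", n = 200, seed = 14)
  terms <- list(spline_term("z", "penalized_bspline", df = 6))
  lam <- solve_lambda_for_df(ds, terms, 1, target_df = 3.3)
  refit <- fit_penalized_cox(ds, terms, lambdas = as.numeric(lam))
  expect_lt(abs(unname(refit$df_per_term) - 3.3), 1e-3)
  expect_error(solve_lambda_for_df(ds, terms, 1, target_df = 50),
               "outside attainable range")
})

test_that("non-convergence raises a numeric error carrying the last iterate", {
  ds <- make_cohort("quadratic", n = 100, seed = 15)
  err <- tryCatch(
    fit_penalized_cox(ds, spline_term("z", "penalized_bspline", df = 4),
                      lambdas = 1, max_iter = 1L, tol = 1e-14),
    error = function(e) e)
  expect_s3_class(err, "hrspline_numeric_error")
  expect_true(is.numeric(err$data$beta))
})

test_that("ph_test matches a direct-formula computation and validates", {
  ds <- make_cohort("linear", n = 150, seed = 16)
  fit <- fit_penalized_cox(ds, linear_term("z"))
  pt <- ph_test(fit, time_transform = "km")

  # brute force from the definitions: unscaled Schoenfeld residuals,
  # KM-transformed times, u = sum (g - gbar) s, chisq = d u' V u / sum gc^2
  X <- as.matrix(ds$covariates)
  beta <- fit$coefficients
  w <- exp(drop(X %*% beta))
  dts <- sort(ds$exit_time[ds$status == 1])
  s <- numeric(length(dts)); g <- numeric(length(dts))
  all_t <- sort(unique(ds$exit_time[ds$status == 1]))
  surv_at <- function(t) {        # left-continuous KM, plain loops
    sv <- 1
    for (u in all_t[all_t < t]) {
      du <- sum(ds$status == 1 & ds$exit_time == u)
      nu <- sum(ds$exit_time >= u)
      sv <- sv * (1 - du / nu)
    }
    sv
  }
  k <- 0
  for (t in dts) {
    k <- k + 1
    i <- which(ds$status == 1 & ds$exit_time == t)
    R <- which(ds$exit_time >= t)
    s[k] <- X[i, 1] - sum(X[R, 1] * w[R]) / sum(w[R])
    g[k] <- 1 - surv_at(t)
  }
  gc <- g - mean(g)
  u <- sum(gc * s)
  V <- fit$covariance[1, 1]
  chisq <- length(dts) * u^2 * V / sum(gc^2)
  expect_equal(pt$table["GLOBAL", "chisq"], chisq, tolerance = 1e-8)
  expect_true(all(pt$table$p >= 0 & pt$table$p <= 1))

  # 2 events with an interior maximum so the tiny fit converges
  ds_small <- survival_dataset(exit_time = 1:5, status = c(1, 1, 0, 0, 0),
                               covariates = data.frame(z = c(0, 1, -1, 2, -2)))
  fsmall <- fit_penalized_cox(ds_small, linear_term("z"))
  expect_error(ph_test(fsmall), "at least 3 events")
})

test_that("analytic derivatives match finite differences (spot check)", {
  ds <- make_cohort("quadratic", n = 60, seed = 17)
  X <- cbind(ds$covariates$z, ds$covariates$z^2)
  beta <- c(0.3, -0.2)
  dv <- cox_derivatives(ds, X, beta)
  fg <- num_grad(function(b) log_partial_likelihood(ds, X, b), beta)
  expect_lt(max(abs(dv$gradient - fg)) / max(1, max(abs(fg))), 1e-6)
})
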