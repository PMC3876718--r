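# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately brute force (explicit loops over risk sets, textbook
# recursions) so it shares no code path with the package internals.

# --- Cox partial likelihood by explicit risk-set enumeration ---------------

oracle_lpl <- function(entry, exit, status, X, beta, ties = "efron") {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  lpl <- 0
  for (t in sort(unique(exit[status == 1]))) {
    D <- which(status == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    d <- length(D)
    lpl <- lpl + sum(eta[D])
    if (ties == "breslow") {
      lpl <- lpl - d * log(sum(w[R]))
    } else {
      for (k in seq_len(d))
        lpl <- lpl - log(sum(w[R]) - (k - 1) / d * sum(w[D]))
    }
  }
  lpl
}

# Score (single covariate) by the same enumeration, Breslow ties.
oracle_score_1d <- function(entry, exit, status, x, beta) {
  w <- exp(beta * x)
  u <- 0
  for (t in sort(unique(exit[status == 1]))) {
    D <- which(status == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    u <- u + sum(x[D]) - length(D) * sum(x[R] * w[R]) / sum(w[R])
  }
  u
}

# Golden-section maximization of a 1-D function, followed by a few
# score-equation polish steps (the golden bracket alone cannot localize the
# maximum below the sqrt(machine-eps) flatness floor).
oracle_max_beta <- function(entry, exit, status, x, lo = -5, hi = 5) {
  f <- function(b) oracle_lpl(entry, exit, status, matrix(x), b,
                              ties = "breslow")
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > 1e-10) {
    if (f1 > f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - phi * (b - a); f1 <- f(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + phi * (b - a); f2 <- f(x2) }
  }
  beta <- (a + b) / 2
  for (i in 1:6) {
    u <- oracle_score_1d(entry, exit, status, x, beta)
    h <- 1e-6
    du <- (oracle_score_1d(entry, exit, status, x, beta + h) -
           oracle_score_1d(entry, exit, status, x, beta - h)) / (2 * h)
    beta <- beta - u / du
  }
  beta
}

# --- Cox-de Boor B-spline recursion ---------------------------------------

oracle_bspline <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B0 <- function(i, x) {
    # right-closed at the last interval so the boundary point is covered
    if (i == length(knots) - 1L)
      as.numeric(x >= knots[i] & x <= knots[i + 1L])
    else as.numeric(x >= knots[i] & x < knots[i + 1L])
  }
  Brec <- function(i, d, x) {
    if (d == 0L) return(B0(i, x))
    t1 <- knots[i + d] - knots[i]
    t2 <- knots[i + d + 1L] - knots[i + 1L]
    a <- if (t1 > 0) (x - knots[i]) / t1 * Brec(i, d - 1L, x) else 0
    b <- if (t2 > 0) (knots[i + d + 1L] - x) / t2 * Brec(i + 1L, d - 1L, x) else 0
    a + b
  }
  sapply(seq_len(nb), function(i) Brec(i, degree, x))
}

# --- Truncated-power natural cubic spline basis ---------------------------

oracle_natural_tp <- function(x, interior, boundary) {
  xi <- c(boundary[1L], interior, boundary[2L])
  K <- length(xi)
  dd <- function(j) {
    (pmax(x - xi[j], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[j])
  }
  cols <- cbind(1, x)
  for (j in seq_len(K - 2L)) cols <- cbind(cols, dd(j) - dd(K - 1L))
  cols
}

proj_matrix <- function(M) {
  q <- qr(M)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# --- finite differences ---------------------------------------------------

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}

num_jac <- function(g, x, h = 1e-5) {
  cols <- lapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (g(x + e) - g(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

# --- cohorts ---------------------------------------------------------------

make_cohort <- function(shape, n, seed) simulate_cohort(example_design(shape, n = n, seed = seed))

# Two nonlinear covariates (quadratic + sigmoid) for the multivariable
# df-search battery.
two_cov_design <- function(n, seed) simulation_design(
  n = n, seed = seed,
  covariates = list(z1 = list(dist = "normal", mean = 0, sd = 1),
                    z2 = list(dist = "normal", mean = 0, sd = 1)),
  effects = list(z1 = list(shape = "quadratic", center = 0, curvature = 0.5),
                 z2 = list(shape = "sigmoid", center = 0, scale = 0.3,
                           height = 2)),
  baseline_rate = 0.2, censoring = list(type = "uniform", max = 15))

# Cohort with a strongly time-varying coefficient: beta(t) switches from b1
# to b2 at time tau (piecewise-exponential inverse transform) -- the
# proportional-hazards alternative.
sim_tv_cohort <- function(n, seed, b1 = 1, b2 = -1, tau = 1.5, r0 = 0.5,
                          cens = 6) {
  set.seed(seed)
  z <- rnorm(n)
  E <- rexp(n)
  r1 <- r0 * exp(b1 * z); r2 <- r0 * exp(b2 * z)
  T <- ifelse(E < r1 * tau, E / r1, tau + (E - r1 * tau) / r2)
  C <- runif(n, 0, cens)
  survival_dataset(exit_time = pmin(T, C), status = as.numeric(T <= C),
                   covariates = data.frame(z = z))
}

# Small deterministic cohort with tied event times for tie-method tests.
tied_cohort <- function() {
  survival_dataset(exit_time = c(1, 2, 2, 3, 4, 5),
                   status = c(1, 1, 1, 0, 1, 0),
                   covariates = data.frame(x = c(0.5, 1, -1, 0, 2, -0.5)))
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Exhaustive integer-df scan for natural-spline model selection; returns the
# score matrix/array over the grid for all three criteria at once.
exhaustive_ns_scan <- function(dataset, covs, dfs = 1:20,
                               ties_method = "efron") {
  q <- length(covs)
  grid <- expand.grid(rep(list(dfs), q))
  out <- matrix(Inf, nrow(grid), 3L,
                dimnames = list(NULL, c("AIC", "AICc", "BIC")))
  for (r in seq_len(nrow(grid))) {
    terms <- lapply(seq_len(q), function(i)
      spline_term(covs[i], "natural_cubic", df = grid[r, i]))
    f <- tryCatch(fit_penalized_cox(dataset, terms, ties_method = ties_method),
                  error = function(e) NULL)
    if (!is.null(f))
      for (cr in colnames(out))
        out[r, cr] <- tryCatch(score_model(f, cr)$score,
                               error = function(e) Inf)
  }
  list(grid = grid, scores = out)
}
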