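test_that("knot placement follows the quantile / equal-spacing conventions", {
  sp3 <- spline_term("x", "natural_cubic", df = 3)
  kn <- place_knots(1:100, sp3)
  expect_equal(kn$interior_knots, c(34, 67))
  expect_equal(kn$boundary_knots, c(1, 100))

  sp1 <- spline_term("x", "natural_cubic", df = 1)
  expect_length(place_knots(1:100, sp1)$interior_knots, 0L)

  # df = 2 -> n_basis = ceiling(5) + 3 = 8, cubic: 4 equally spaced interior
  spp <- spline_term("x", "penalized_bspline", df = 2)
  knp <- place_knots(0:100, spp)
  expect_equal(knp$n_basis, 8L)
  expect_equal(knp$interior_knots, c(20, 40, 60, 80))
  expect_equal(diff(knp$all_knots), rep(20, length(knp$all_knots) - 1L))

  expect_error(place_knots(c(1:5, 1:5), sp3), "at least 10 distinct")
  sp19 <- spline_term("x", "natural_cubic", df = 19)
  expect_error(place_knots(rep(1:12, 4), sp19), "fewer distinct values")
})

test_that("B-spline basis: partition of unity, degree-0 indicators, clamping", {
  set.seed(1)
  spp <- spline_term("x", "penalized_bspline", df = 4)
  v <- runif(200, -3, 7)
  kn <- place_knots(v, spp)
  x <- runif(500, min(v), max(v))
  B <- bspline_basis(x, kn$all_knots, degree = kn$degree)
  expect_equal(ncol(B), kn$n_basis)
  expect_true(all(B >= 0))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)

  # degree 0 on knots {0,1,2}: indicator of the interval
  B0 <- bspline_basis(0.5, knots = c(0, 1, 2), degree = 0,
                      boundary_knots = c(0, 2))
  expect_equal(drop(B0), c(1, 0))

  expect_warning(Bc <- bspline_basis(max(v) + 1, kn$all_knots,
                                     degree = kn$degree), "clamped")
  expect_equal(drop(Bc),
               drop(bspline_basis(max(v), kn$all_knots, degree = kn$degree)))
  expect_error(bspline_basis(1, knots = c(0, 0, 0), degree = 1),
               "degenerate")
})

test_that("B-spline basis matches the Cox-de Boor recursion oracle", {
  for (degree in c(1L, 2L, 3L)) {
    kn <- seq(-4, 4, by = 0.5)
    x <- c(min(kn) + degree * 0.5,          # left boundary of the span
           seq(-1.9, 1.9, length.out = 7),
           max(kn) - degree * 0.5)          # right boundary of the span
    B <- splines::splineDesign(knots = kn, x = x, ord = degree + 1L)
    O <- oracle_bspline(x, kn, degree)
    expect_lt(max(abs(B - O)), 1e-12)
  }
})

test_that("natural cubic basis: linear tails, df=1 linearity, oracle span", {
  set.seed(2)
  x <- sort(runif(40, 0, 10))
  # df = 1 reduces to a column proportional to (centered) x
  b1 <- natural_cubic_basis(x, df = 1)
  fitcoef <- coef(lm(b1[, 1] ~ x))
  expect_lt(max(abs(b1[, 1] - (fitcoef[1] + fitcoef[2] * x))), 1e-12)

  # linearity beyond the boundary: second divided differences vanish
  kn <- place_knots(x, spline_term("x", "natural_cubic", df = 4))
  xe <- c(11, 12, 13, 14, -2, -1.5, -1, -0.5)
  Be <- natural_cubic_basis(xe, interior_knots = kn$interior_knots,
                            boundary_knots = kn$boundary_knots)
  for (j in seq_len(ncol(Be))) {
    right <- diff(diff(Be[1:4, j]))
    left <- diff(diff(Be[5:8, j]))
    expect_lt(max(abs(c(right, left))), 1e-10)
  }

  # df = 3 span equals the truncated-power natural-spline space
  kn3 <- place_knots(x, spline_term("x", "natural_cubic", df = 3))
  x20 <- seq(0.2, 9.8, length.out = 20)
  B <- natural_cubic_basis(x20, interior_knots = kn3$interior_knots,
                           boundary_knots = kn3$boundary_knots)
  O <- oracle_natural_tp(x20, kn3$interior_knots, kn3$boundary_knots)
  expect_lt(max(abs(proj_matrix(cbind(1, B)) - proj_matrix(O))), 1e-9)

  expect_error(spline_term("x", "natural_cubic", df = 0), "integer >= 1")
})

test_that("difference penalty matches its definition and null space", {
  p2 <- difference_penalty(4, 2)
  D <- rbind(c(1, -2, 1, 0), c(0, 1, -2, 1))
  expect_equal(p2$matrix, crossprod(D))
  expect_equal(p2$null_space_dim, 2L)
  expect_lt(max(abs(p2$matrix %*% cbind(rep(1, 4), 1:4))), 1e-12)

  p1 <- difference_penalty(3, 1)
  expect_equal(p1$matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  expect_error(difference_penalty(3, 2), "at least order")
})

test_that("identifiability constraint removes one column and preserves differences", {
  set.seed(4)
  spp <- spline_term("x", "penalized_bspline", df = 3)
  v <- rnorm(100)
  kn <- place_knots(v, spp)
  x <- seq(min(v), max(v), length.out = 25)
  B <- bspline_basis(x, kn$all_knots, degree = kn$degree)
  pen <- difference_penalty(kn$n_basis, 2)
  cs <- constrain_identifiability(B, pen)
  expect_equal(ncol(cs$basis), kn$n_basis - 1L)
  expect_equal(dim(cs$penalty), c(kn$n_basis - 1L, kn$n_basis - 1L))

  # f(z) - f(ref) invariant between parameterizations
  for (i in 1:5) {
    theta <- rnorm(kn$n_basis - 1L)
    beta <- cs$transform %*% theta
    f_con <- drop(cs$basis %*% theta)
    f_unc <- drop(B %*% beta)
    expect_lt(max(abs((f_con - f_con[1]) - (f_unc - f_unc[1]))), 1e-10)
  }
})

test_that("penalized Hessian on the constrained basis is nonsingular", {
  ds <- make_cohort("quadratic", n = 150, seed = 5)
  fit <- fit_penalized_cox(ds, spline_term("z", "penalized_bspline", df = 4))
  ev <- eigen(fit$hessian, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("basis evaluation is deterministic", {
  set.seed(6)
  v <- rnorm(50)
  kn <- place_knots(v, spline_term("x", "penalized_bspline", df = 4))
  x <- runif(20, min(v), max(v))
  expect_identical(bspline_basis(x, kn$all_knots, 3),
                   bspline_basis(x, kn$all_knots, 3))
  kn2 <- place_knots(v, spline_term("x", "natural_cubic", df = 4))
  expect_identical(
    natural_cubic_basis(x, interior_knots = kn2$interior_knots,
                        boundary_knots = kn2$boundary_knots),
    natural_cubic_basis(x, interior_knots = kn2$interior_knots,
                        boundary_knots = kn2$boundary_knots))
})

test_that("knot layouts round-trip through JSON", {
  set.seed(9)
  v <- rnorm(80)
  for (sp in list(spline_term("x", "penalized_bspline", df = 3.7),
                  spline_term("x", "natural_cubic", df = 4))) {
    kn <- place_knots(v, sp)
    p <- tempfile(fileext = ".json")
    write_knot_layout(kn, p)
    back <- read_knot_layout(p)
    expect_equal(back[sort(names(back))], kn[sort(names(kn))],
                 tolerance = 1e-15)
    if (!is.null(kn$all_knots))
      expect_equal(bspline_basis(v, back$all_knots, back$degree),
                   bspline_basis(v, kn$all_knots, kn$degree))
  }
})
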