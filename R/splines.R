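#' Declare a smooth model term
#'
#' Describes one nonlinear covariate effect: either a natural cubic spline
#' with integer degrees of freedom (`df` coefficients, knots at equally
#' spaced quantiles), or a penalized B-spline (P-spline: a rich cubic
#' B-spline basis on equally spaced knots whose coefficients are shrunk by an
#' order-`penalty_order` difference penalty until the effective degrees of
#' freedom hit `df`, which may be any real > 1).
#'
#' @param covariate covariate column name.
#' @param smoother `"penalized_bspline"` (default) or `"natural_cubic"`.
#' @param df target degrees of freedom: integer >= 1 for natural cubic
#'   splines, real > 1 for P-splines.
#' @param penalty_order order of the difference penalty (P-splines only),
#'   default 2 (null space = straight lines).
#' @param degree B-spline degree (P-splines only), default 3 (cubic).
#' @param knot_source `"covariate"` (default) places knots at quantiles of
#'   the covariate values; `"survival_time"` uses quantiles of the exit
#'   times instead (rarely sensible for a covariate basis; provided for
#'   compatibility with descriptions that state knots are placed at
#'   percentiles of the survival times).
#' @return An object of class `spline_term_spec`.
#' @export
spline_term <- function(covariate,
                        smoother = c("penalized_bspline", "natural_cubic"),
                        df = 4, penalty_order = 2L, degree = 3L,
                        knot_source = c("covariate", "survival_time")) {
  smoother <- match.arg(smoother)
  knot_source <- match.arg(knot_source)
  if (!is.character(covariate) || length(covariate) != 1L)
    hs_stop("covariate must be a single column name")
  if (!is_scalar_number(df)) hs_stop("df must be a finite number")
  if (smoother == "natural_cubic") {
    if (df < 1 || df != round(df))
      hs_stop("natural_cubic df must be an integer >= 1")
    df <- as.integer(df)
  } else {
    if (df <= 1) hs_stop("penalized_bspline df must be > 1")
    if (penalty_order < 1) hs_stop("penalty_order must be >= 1")
  }
  structure(list(covariate = covariate, smoother = smoother, df = df,
                 penalty_order = as.integer(penalty_order),
                 degree = as.integer(degree), knot_source = knot_source),
            class = c("spline_term_spec", "term_spec"))
}

#' Declare a linear (parametric) model term
#'
#' @param covariate covariate column name.
#' @return An object of class `linear_term_spec`.
#' @export
linear_term <- function(covariate) {
  if (!is.character(covariate) || length(covariate) != 1L)
    hs_stop("covariate must be a single column name")
  structure(list(covariate = covariate),
            class = c("linear_term_spec", "term_spec"))
}

#' @export
print.spline_term_spec <- function(x, ...) {
  cat(sprintf("spline term: %s (%s, df = %g)\n", x$covariate, x$smoother,
              x$df))
  invisible(x)
}

#' @export
print.linear_term_spec <- function(x, ...) {
  cat(sprintf("linear term: %s\n", x$covariate))
  invisible(x)
}

# Basis size heuristic for P-splines: rich enough that any requested
# effective df up to the target is attainable, capped at 40 columns.
pspline_n_basis <- function(df, penalty_order) {
  as.integer(min(max(ceiling(2.5 * df) + 3L, penalty_order + 2L), 40L))
}

#' Place spline knots for a term
#'
#' Natural cubic splines get boundary knots at the extremes of `values` and
#' `df - 1` interior knots at equally spaced quantiles (type-7).  P-splines
#' get equally spaced knots spanning `[min, max]`, extended `degree` steps
#' beyond each boundary (the usual equally-spaced B-spline convention), with
#' the interior count derived from the basis size.
#'
#' @param values numeric values from which the knot layout is derived
#'   (normally the covariate column; at least 10 distinct values required).
#' @param spec a [spline_term()] specification.
#' @return list with `interior_knots`, `boundary_knots`, and for P-splines
#'   `all_knots` (full extended vector), `n_basis`, `degree`.
#' @export
place_knots <- function(values, spec) {
  stopifnot(inherits(spec, "spline_term_spec"))
  values <- values[!is.na(values)]
  nd <- length(unique(values))
  if (nd < 10L) hs_stop("need at least 10 distinct values to place knots")
  bk <- range(values)
  if (spec$smoother == "natural_cubic") {
    df <- spec$df
    if (nd < df + 1L)
      hs_stop(sprintf("fewer distinct values (%d) than knots requested (%d)",
                      nd, df + 1L))
    ik <- if (df >= 2L)
      as.numeric(quantile(values, probs = seq_len(df - 1L) / df, names = FALSE))
    else numeric(0)
    if (any(ik <= bk[1L]) || any(ik >= bk[2L]) || is.unsorted(ik, strictly = TRUE))
      hs_stop("degenerate knot layout: interior knots must be strictly increasing inside the boundary")
    return(list(interior_knots = ik, boundary_knots = bk))
  }
  n_basis <- pspline_n_basis(spec$df, spec$penalty_order)
  degree <- spec$degree
  n_interior <- n_basis - degree - 1L
  if (n_interior < 0L) hs_stop("basis too small for the requested degree")
  if (nd < n_interior + 2L)
    hs_stop(sprintf("fewer distinct values (%d) than knots requested (%d)",
                    nd, n_interior + 2L))
  h <- diff(bk) / (n_interior + 1L)
  ik <- if (n_interior > 0L)
    seq(bk[1L] + h, by = h, length.out = n_interior) else numeric(0)
  # boundary values are kept exact so that covariate extremes never trip the
  # out-of-range clamp through rounding of the equally spaced sequence
  all_knots <- c(bk[1L] - rev(seq_len(degree)) * h, bk[1L], ik, bk[2L],
                 bk[2L] + seq_len(degree) * h)
  list(interior_knots = ik, boundary_knots = bk, all_knots = all_knots,
       n_basis = n_basis, degree = degree)
}

#' Evaluate a B-spline basis
#'
#' Cox-de Boor B-spline basis on a full (extended) knot vector.  Values
#' outside the boundary are clamped to it with a warning: a B-spline is zero
#' outside its knot span, which would silently annihilate the effect.
#'
#' @param x evaluation points.
#' @param knots full knot vector (see [place_knots()]), strictly covering the
#'   boundary `degree` steps on each side.
#' @param degree spline degree (default 3).
#' @param boundary_knots the interval on which the basis is a partition of
#'   unity; defaults to `knots[degree + 1]` and `knots[length(knots) - degree]`.
#' @return matrix with `length(knots) - degree - 1` columns; each row sums
#'   to 1 (partition of unity) and all entries are nonnegative.
#' @export
bspline_basis <- function(x, knots, degree = 3L, boundary_knots = NULL) {
  knots <- as.numeric(knots)
  if (is.unsorted(knots) || length(unique(knots)) < 2L)
    hs_stop("degenerate knot layout")
  if (length(knots) < 2L * (degree + 1L))
    hs_stop("degenerate knot layout: too few knots for the degree")
  if (is.null(boundary_knots))
    boundary_knots <- c(knots[degree + 1L], knots[length(knots) - degree])
  if (any(x < boundary_knots[1L] | x > boundary_knots[2L])) {
    warning("values outside the boundary knots were clamped to the boundary")
    x <- pmin(pmax(x, boundary_knots[1L]), boundary_knots[2L])
  }
  splines::splineDesign(knots = knots, x = x, ord = degree + 1L,
                        outer.ok = TRUE)
}

#' Evaluate a natural cubic spline basis
#'
#' `df` columns, linear beyond the boundary knots (evaluation outside the
#' boundary extrapolates linearly — the defining natural boundary
#' condition).  With `df = 1` the single column is linear in `x`.
#'
#' @param x evaluation points.
#' @param df integer degrees of freedom (>= 1); ignored when knots are given.
#' @param interior_knots,boundary_knots knot layout; when `NULL`, derived
#'   from `x` via [place_knots()].
#' @return matrix with `df` columns.
#' @export
natural_cubic_basis <- function(x, df = NULL, interior_knots = NULL,
                                boundary_knots = NULL) {
  if (is.null(boundary_knots)) {
    if (is.null(df)) hs_stop("give df or an explicit knot layout")
    kn <- place_knots(x, spline_term("x", "natural_cubic", df = df))
    interior_knots <- kn$interior_knots
    boundary_knots <- kn$boundary_knots
  }
  if (length(interior_knots) == 0L) {
    b <- splines::ns(x, knots = NULL, Boundary.knots = boundary_knots,
                     intercept = FALSE)
  } else {
    b <- splines::ns(x, knots = interior_knots,
                     Boundary.knots = boundary_knots, intercept = FALSE)
  }
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- NULL
  m
}

#' Difference penalty matrix
#'
#' Returns \eqn{D^T D} for the order-`order` difference operator `D`
#' (dimension `(n_basis - order) x n_basis`), the discrete roughness penalty
#' applied to adjacent B-spline coefficients.  Its null space has dimension
#' `order` (order 2: constants and linear sequences).
#'
#' @param n_basis number of basis coefficients (>= `order + 2`).
#' @param order difference order, default 2.
#' @return An object of class `penalty_matrix`: list with `order`, `matrix`,
#'   `null_space_dim`.
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  if (n_basis < order + 2L)
    hs_stop(sprintf("n_basis must be at least order + 2 (= %d)", order + 2L))
  D <- diff(diag(n_basis), differences = order)
  structure(list(order = as.integer(order), matrix = crossprod(D),
                 null_space_dim = as.integer(order)),
            class = "penalty_matrix")
}

#' Remove the unidentifiable constant direction from a B-spline basis
#'
#' The B-spline partition of unity makes the all-ones coefficient direction
#' invisible to the Cox partial likelihood (a constant added to the log
#' hazard cancels) and it also lies in the difference-penalty null space, so
#' the naive penalized Hessian is singular.  This reparameterizes the basis
#' onto the orthogonal complement of the ones direction.  Hazard-ratio
#' differences \eqn{\hat f(z) - \hat f(z_{ref})} are invariant to the choice
#' of constraint.
#'
#' @param basis B-spline basis matrix whose rows sum to a constant.
#' @param penalty optional [difference_penalty()] (or plain matrix) to
#'   transform alongside.
#' @return list with `basis` (one fewer column), `penalty` (transformed, or
#'   `NULL`), and `transform` — the `n_basis x (n_basis - 1)` matrix mapping
#'   constrained coefficients back to B-spline coefficients.
#' @export
constrain_identifiability <- function(basis, penalty = NULL) {
  K <- ncol(basis)
  Z <- constraint_transform(K)
  P <- NULL
  if (!is.null(penalty)) {
    pm <- if (inherits(penalty, "penalty_matrix")) penalty$matrix else penalty
    P <- crossprod(Z, pm %*% Z)
    P <- (P + t(P)) / 2
  }
  list(basis = basis %*% Z, penalty = P, transform = Z)
}

# Orthonormal basis of the complement of the all-ones direction in R^K.
constraint_transform <- function(K) {
  qr.Q(qr(matrix(1, K, 1L)), complete = TRUE)[, -1L, drop = FALSE]
}

#' Serialize a knot layout to JSON
#'
#' Knot layouts fully determine a spline basis, so storing them alongside a
#' fit makes the basis — and therefore the fitted curve — reproducible.
#'
#' @param layout a [place_knots()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knot_layout <- function(layout, path) {
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(layout, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a knot layout from JSON
#'
#' @param path file written by [write_knot_layout()].
#' @return The knot layout list.
#' @export
read_knot_layout <- function(path) {
  if (!file.exists(path)) hs_stop(sprintf("file not found: %s", path))
  lay <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("interior_knots", "boundary_knots", "all_knots"))
    if (!is.null(lay[[nm]])) lay[[nm]] <- as.numeric(lay[[nm]])
  if (!is.null(lay$n_basis)) lay$n_basis <- as.integer(lay$n_basis)
  if (!is.null(lay$degree)) lay$degree <- as.integer(lay$degree)
  lay
}
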