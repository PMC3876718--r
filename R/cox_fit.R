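# Term preparation and the penalized Newton-Raphson fitter.

term_label <- function(spec) {
  if (inherits(spec, "linear_term_spec")) spec$covariate
  else paste0(if (spec$smoother == "natural_cubic") "ns(" else "ps(",
              spec$covariate, ")")
}

# Resolve a term spec against a cohort: knot layout, (constrained) basis,
# penalty block, and a closure evaluating the basis at new covariate values.
prepare_term <- function(spec, dataset) {
  x <- dataset$covariates[[spec$covariate]]
  if (is.null(x))
    hs_stop(sprintf("covariate '%s' not found in dataset", spec$covariate))
  if (anyNA(x))
    hs_stop(sprintf("covariate '%s' has missing values; apply complete_case_filter first",
                    spec$covariate))
  if (inherits(spec, "linear_term_spec")) {
    return(list(spec = spec, kind = "linear", ncol = 1L,
                label = term_label(spec), penalty = NULL,
                basis = matrix(x, ncol = 1L),
                eval = function(z) matrix(z, ncol = 1L)))
  }
  knot_values <- if (spec$knot_source == "survival_time") dataset$exit_time else x
  kn <- place_knots(knot_values, spec)
  if (spec$smoother == "natural_cubic") {
    ev <- function(z) natural_cubic_basis(z, interior_knots = kn$interior_knots,
                                          boundary_knots = kn$boundary_knots)
    return(list(spec = spec, kind = "natural_cubic", ncol = spec$df,
                label = term_label(spec), penalty = NULL, knots = kn,
                basis = ev(x), eval = ev))
  }
  pen <- difference_penalty(kn$n_basis, spec$penalty_order)
  Z <- constraint_transform(kn$n_basis)
  P <- crossprod(Z, pen$matrix %*% Z)
  P <- (P + t(P)) / 2
  ev <- function(z) {
    b <- bspline_basis(z, knots = kn$all_knots, degree = kn$degree,
                       boundary_knots = kn$boundary_knots)
    b %*% Z
  }
  list(spec = spec, kind = "penalized_bspline", ncol = kn$n_basis - 1L,
       label = term_label(spec), penalty = P, knots = kn, transform = Z,
       basis = ev(x), eval = ev)
}

build_design <- function(dataset, terms) {
  if (inherits(terms, "term_spec")) terms <- list(terms)
  if (!length(terms)) hs_stop("at least one model term is required")
  prepared <- lapply(terms, prepare_term, dataset = dataset)
  ncols <- vapply(prepared, `[[`, integer(1L), "ncol")
  ends <- cumsum(ncols)
  blocks <- Map(function(e, k) seq.int(e - k + 1L, e), ends, ncols)
  X <- do.call(cbind, lapply(prepared, `[[`, "basis"))
  colnames(X) <- unlist(Map(function(pt, k)
    if (k == 1L && pt$kind == "linear") pt$label
    else paste0(pt$label, ".", seq_len(k)), prepared, ncols))
  labels <- vapply(prepared, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) hs_stop("duplicate model terms")
  smooth_idx <- which(vapply(prepared, function(pt)
    pt$kind == "penalized_bspline", logical(1L)))
  list(prepared = prepared, X = X, blocks = blocks, labels = labels,
       smooth_idx = smooth_idx, p = ncol(X))
}

# Block-diagonal lambda-weighted penalty for the whole coefficient vector.
assemble_penalty <- function(design, lambdas) {
  P <- matrix(0, design$p, design$p)
  for (k in seq_along(design$smooth_idx)) {
    j <- design$smooth_idx[k]
    b <- design$blocks[[j]]
    P[b, b] <- lambdas[k] * design$prepared[[j]]$penalty
  }
  P
}

# Core Newton-Raphson with step-halving on the penalized objective
# lpl(beta) - 0.5 * beta' P beta.  Falls back to a gradient step when the
# Hessian solve fails.  Returns the converged state or errors (carrying the
# last iterate) after max_iter steps.
newton_cox <- function(prep, Pl, init = NULL, tol = 1e-9, max_iter = 25L,
                       max_halvings = 20L, grad_tol = 1e-6) {
  p <- prep$p
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  ev <- cox_eval(prep, beta)
  if (!ev$ok) { beta <- rep(0, p); ev <- cox_eval(prep, beta) }
  if (!ev$ok) hs_stop_numeric("partial likelihood not evaluable at start")
  pen_obj <- function(b, lpl) lpl - 0.5 * sum(b * (Pl %*% b))
  f <- pen_obj(beta, ev$lpl)
  converged <- FALSE
  iter <- 0L
  rel <- Inf
  flat_streak <- 0L
  repeat {
    iter <- iter + 1L
    g <- ev$grad - drop(Pl %*% beta)
    H <- ev$info + Pl
    dir <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(dir) || any(!is.finite(dir))) dir <- g / max(1, sqrt(sum(g^2)))
    # Newton decrement^2: scale-invariant flatness measure; the absolute
    # gradient criterion is unattainable when an extreme penalty makes the
    # objective curvature of order lambda (gradient noise ~ lambda * eps).
    dec2 <- max(sum(g * dir), 0)
    flat <- max(abs(g)) < grad_tol || dec2 < 1e-9 * (1 + abs(f))
    # stalled at the floating-point noise floor: the predicted objective
    # gain has been negligible for three consecutive iterations, so the
    # remaining "progress" is rounding noise
    flat_streak <- if (dec2 < 1e-9 * (1 + abs(f))) flat_streak + 1L else 0L
    if ((rel < tol && flat) || flat_streak >= 3L) {
      converged <- TRUE; break
    }
    s <- 1
    new_beta <- beta; new_f <- f; improved <- FALSE
    for (h in seq_len(max_halvings)) {
      cand <- beta + s * dir
      ce <- cox_eval(prep, cand, derivs = FALSE)
      if (ce$ok) {
        cf <- pen_obj(cand, ce$lpl)
        if (is.finite(cf) && cf >= f - 1e-12) {
          new_beta <- cand; new_f <- cf; improved <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (improved) {
      new_ev <- cox_eval(prep, new_beta)
      if (!new_ev$ok) { improved <- FALSE; new_beta <- beta; new_f <- f }
    }
    if (improved) {
      rel <- abs(new_f - f) / (abs(f) + tol)
      beta <- new_beta; f <- new_f; ev <- new_ev
    } else {
      # no ascent possible: accept if the objective is already flat
      if (flat) { converged <- TRUE; break }
      rel <- 0
    }
    if (iter >= max_iter) break
  }
  if (!converged)
    hs_stop_numeric(sprintf("Newton-Raphson did not converge in %d iterations",
                            max_iter),
                    data = list(beta = beta, lpl = ev$lpl, iterations = iter))
  list(beta = beta, lpl = ev$lpl, grad = ev$grad, info = ev$info,
       iterations = iter)
}

#' Per-term effective degrees of freedom
#'
#' The effective degrees of freedom of a penalized fit is
#' \eqn{\mathrm{tr}(H^{-1} I)}; each term's share is the trace over its
#' coefficient block.  Unpenalized blocks contribute (essentially) their
#' column count; an order-2-penalized constrained P-spline block shrinks
#' towards 1 (the surviving linear direction) as the penalty grows.
#'
#' @param info observed information matrix `I`.
#' @param hessian penalized Hessian `H = I + P` (must be nonsingular).
#' @param term_blocks list of integer index vectors, one per term.
#' @return numeric vector of per-term effective df.
#' @export
effective_df <- function(info, hessian, term_blocks) {
  HI <- tryCatch(solve(hessian, info), error = function(e)
    hs_stop_numeric("singular penalized Hessian"))
  dg <- diag(HI)
  vapply(term_blocks, function(b) sum(dg[b]), numeric(1L))
}

fit_from_state <- function(dataset, design, prep, lambdas, st, ties_method) {
  Pl <- assemble_penalty(design, lambdas)
  I <- st$info
  H <- I + Pl
  Hi <- tryCatch(solve(H), error = function(e)
    hs_stop_numeric(paste0("singular penalized Hessian (terms: ",
                           paste(design$labels, collapse = ", "), ")")))
  V <- Hi %*% I %*% Hi
  V <- (V + t(V)) / 2
  dfs <- effective_df(I, H, design$blocks)
  names(dfs) <- design$labels
  coefficients <- setNames(st$beta, colnames(design$X))
  structure(list(terms = design$prepared, labels = design$labels,
                 blocks = design$blocks, coefficients = coefficients,
                 lpl = st$lpl, info = I, penalty = Pl, hessian = H,
                 covariance = V, df_per_term = dfs,
                 lambdas = setNames(lambdas,
                                    design$labels[design$smooth_idx]),
                 n = dataset$n, n_events = dataset$n_events,
                 ties_method = ties_method, converged = TRUE,
                 iterations = st$iterations,
                 dataset = dataset, design = design$X),
            class = "additive_cox_fit")
}

#' Fit an additive Cox model by penalized partial likelihood
#'
#' Maximizes \eqn{LPL(\beta) - \tfrac12 \sum_j \lambda_j \beta_j^T P_j
#' \beta_j} by Newton-Raphson with step-halving, where the sum runs over the
#' P-spline terms.  When `lambdas` is `NULL` (the default) and P-spline terms
#' are present, each term's penalty weight is calibrated so that its
#' effective degrees of freedom match the `df` declared in its
#' [spline_term()] (term-by-term bisection with cyclic passes when several
#' smooth terms interact).  Natural-spline and linear terms are never
#' penalized.
#'
#' @param dataset a [survival_dataset()] with no missing values in the used
#'   columns (see [complete_case_filter()]).
#' @param terms a list of [spline_term()] / [linear_term()] specifications
#'   (a single spec is accepted).
#' @param lambdas optional numeric vector of penalty weights, one per
#'   P-spline term in order; bypasses df calibration.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param tol relative convergence tolerance on the penalized objective.
#' @param max_iter maximum Newton steps.
#' @param df_tol tolerance for df calibration (per term).
#' @param init optional starting coefficient vector.
#' @return An object of class `additive_cox_fit` with elements including
#'   `coefficients`, `lpl`, `info` (observed information `I`), `penalty`
#'   (block-diagonal `P`), `hessian` (`H = I + P`), `covariance` (sandwich
#'   `H^-1 I H^-1`), `df_per_term`, `lambdas`, `n`, `n_events`, `converged`.
#' @export
fit_penalized_cox <- function(dataset, terms, lambdas = NULL,
                              ties_method = c("efron", "breslow"),
                              tol = 1e-9, max_iter = 25L, df_tol = 1e-3,
                              init = NULL) {
  stopifnot(inherits(dataset, "survival_dataset"))
  ties_method <- match.arg(ties_method)
  design <- build_design(dataset, terms)
  prep <- cox_prep(dataset$entry_time, dataset$exit_time, dataset$status,
                   design$X, ties_method)
  ns <- length(design$smooth_idx)
  if (is.null(lambdas)) {
    if (ns == 0L) lambdas <- numeric(0)
    else {
      cal <- calibrate_lambdas_core(prep, design, df_tol = df_tol,
                                    tol = tol, max_iter = max_iter,
                                    init = init)
      lambdas <- cal$lambdas
      init <- cal$beta
    }
  } else {
    if (length(lambdas) != ns)
      hs_stop(sprintf("expected %d lambdas (one per P-spline term), got %d",
                      ns, length(lambdas)))
    if (any(!is.finite(lambdas)) || any(lambdas < 0))
      hs_stop("lambdas must be finite and nonnegative")
  }
  Pl <- assemble_penalty(design, lambdas)
  st <- newton_cox(prep, Pl, init = init, tol = tol, max_iter = max_iter)
  fit_from_state(dataset, design, prep, lambdas, st, ties_method)
}

# Bisection on log10(lambda_j) over [-12, 12]: effective df of term j is
# continuous and monotone nonincreasing in lambda_j, so the target is
# bracketed whenever it lies in the attainable range (1, block size].
# The near-unpenalized bracket end is only probed when the bisection walks
# there: an effectively unpenalized rich basis can carry a monotone
# likelihood (divergent MLE), so probes use a generous iteration cap.
bisect_lambda <- function(prep, design, lambdas, j, target_df, tol = 1e-3,
                          beta0 = NULL, max_bisect = 60L) {
  sm <- design$smooth_idx[j]
  block <- design$blocks[[sm]]
  if (target_df > length(block) + tol)
    hs_stop(sprintf("target df %.3f outside attainable range (1, %d]",
                    target_df, length(block)))
  df_at <- function(loglam, init) {
    l2 <- lambdas; l2[j] <- 10^loglam
    Pl <- assemble_penalty(design, l2)
    st <- newton_cox(prep, Pl, init = init, tol = 1e-9, max_iter = 100L)
    H <- st$info + Pl
    list(df = effective_df(st$info, H, list(block)), beta = st$beta)
  }
  lo <- -12; hi <- 12
  beta <- beta0
  best <- NULL
  for (it in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    m <- df_at(mid, beta)
    beta <- m$beta
    if (is.null(best) || abs(m$df - target_df) < abs(best$df - target_df))
      best <- list(lambda = 10^mid, beta = beta, df = m$df)
    if (abs(m$df - target_df) <= tol)
      return(list(lambda = 10^mid, beta = beta, df = m$df))
    if (m$df > target_df) lo <- mid else hi <- mid
  }
  # bracket exhausted without reaching the target: the target lies outside
  # the df range attainable on [-12, 12]
  hs_stop(sprintf("target df %.3f outside attainable range [%.3f, %.3f]; nearest achieved %.3f",
                  target_df,
                  df_at(12, beta)$df, df_at(-12, beta)$df, best$df))
}

# Cyclic per-term calibration: each term's effective df depends weakly on the
# other terms' penalties through the shared information matrix, so single
# bisections are repeated (up to max_cycles passes) until every term is
# within tolerance.
calibrate_lambdas_core <- function(prep, design, df_tol = 1e-3, tol = 1e-9,
                                   max_iter = 25L, init = NULL,
                                   max_cycles = 10L) {
  ns <- length(design$smooth_idx)
  targets <- vapply(design$smooth_idx, function(i)
    design$prepared[[i]]$spec$df, numeric(1L))
  lambdas <- rep(1, ns)
  beta <- init
  cycle_tol <- if (ns == 1L) df_tol else max(df_tol, 0.01)
  for (cycle in seq_len(max_cycles)) {
    for (j in seq_len(ns)) {
      res <- bisect_lambda(prep, design, lambdas, j, targets[j],
                           tol = df_tol, beta0 = beta)
      lambdas[j] <- res$lambda
      beta <- res$beta
    }
    Pl <- assemble_penalty(design, lambdas)
    st <- newton_cox(prep, Pl, init = beta, tol = tol, max_iter = max_iter)
    beta <- st$beta
    dfs <- effective_df(st$info, st$info + Pl,
                        design$blocks[design$smooth_idx])
    if (max(abs(dfs - targets)) <= cycle_tol) break
  }
  list(lambdas = lambdas, beta = beta)
}

#' Solve the penalty weight that yields a target effective df
#'
#' Finds \eqn{\lambda} for one P-spline term such that the term's effective
#' degrees of freedom equal `target_df` within `tol`, by bisection on
#' \eqn{\log_{10}\lambda} over \eqn{[-12, 12]} with a full refit at every
#' probe.  Other P-spline terms are held at `lambdas` (default 0).
#'
#' @param dataset a [survival_dataset()].
#' @param terms model term list (see [fit_penalized_cox()]).
#' @param term_index index (within `terms`) of the P-spline term to
#'   calibrate.
#' @param target_df requested effective df, in `(1, constrained basis size]`.
#' @param tol df tolerance (default 1e-3).
#' @param lambdas penalty weights for the other P-spline terms.
#' @param ties_method tie handling.
#' @return The calibrated `lambda` (scalar), with attributes `df` (achieved)
#'   and `beta` (coefficients at the solution).
#' @export
solve_lambda_for_df <- function(dataset, terms, term_index, target_df,
                                tol = 1e-3, lambdas = NULL,
                                ties_method = c("efron", "breslow")) {
  stopifnot(inherits(dataset, "survival_dataset"))
  ties_method <- match.arg(ties_method)
  design <- build_design(dataset, terms)
  sm <- match(term_index, design$smooth_idx)
  if (is.na(sm))
    hs_stop("term_index does not refer to a P-spline term")
  if (is.null(lambdas)) lambdas <- rep(0, length(design$smooth_idx))
  prep <- cox_prep(dataset$entry_time, dataset$exit_time, dataset$status,
                   design$X, ties_method)
  res <- bisect_lambda(prep, design, lambdas, sm, target_df, tol = tol)
  structure(res$lambda, df = res$df, beta = res$beta)
}

#' @export
print.additive_cox_fit <- function(x, digits = 4, ...) {
  cat("Additive Cox model (penalized partial likelihood)\n")
  cat(sprintf("n = %d, events = %d, ties = %s, iterations = %d\n",
              x$n, x$n_events, x$ties_method, x$iterations))
  cat(sprintf("log partial likelihood = %.*f\n", digits, x$lpl))
  cat("\nTerms:\n")
  for (i in seq_along(x$labels)) {
    lab <- x$labels[i]
    df <- x$df_per_term[i]
    kind <- x$terms[[i]]$kind
    lam <- if (kind == "penalized_bspline")
      sprintf(", lambda = %.4g", x$lambdas[[lab]]) else ""
    cat(sprintf("  %-16s %-18s df = %6.3f%s\n", lab, kind, df, lam))
  }
  tdf <- model_total_df(x)
  cat(sprintf("\nTotal df = %.3f  AIC = %.3f", tdf, aic(x$lpl, tdf)))
  if (x$n_events > tdf + 2)
    cat(sprintf("  AICc = %.3f", aicc(x$lpl, tdf, x$n_events)))
  cat(sprintf("  BIC = %.3f\n", bic(x$lpl, tdf, x$n_events)))
  if (x$n_events >= 3) {
    pt <- tryCatch(ph_test(x), error = function(e) NULL)
    if (!is.null(pt)) {
      cat("\nProportional hazards test (Grambsch-Therneau, km transform):\n")
      print(pt$table, digits = digits)
    }
  }
  invisible(x)
}

#' @export
summary.additive_cox_fit <- function(object, ...) {
  list(coefficients = object$coefficients,
       df_per_term = object$df_per_term,
       lambdas = object$lambdas,
       lpl = object$lpl,
       total_df = model_total_df(object),
       n = object$n, n_events = object$n_events,
       ties_method = object$ties_method,
       converged = object$converged,
       iterations = object$iterations)
}
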