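# Penalized Cox partial-likelihood engine.
#
# Risk set at an event time t is {records with entry < t <= exit}.  All
# at-risk sums are computed as reverse cumulative sums over records sorted by
# exit time, minus the same sums over records whose entry time is >= t
# (delayed entry).  Efron's tie correction is handled by expanding each tied
# event time with d deaths into d rows with denominators
# S(t) - (k-1)/d * S_D(t); Breslow uses the same expansion with a zero
# fraction.  The observed information needs per-risk-set sums of
# w_i x_i x_i^T, carried as the n x p(p+1)/2 matrix of half-vectorized outer
# products, which is computed once per fit (it does not depend on beta).

vech_pairs <- function(p) {
  ip <- integer(0); jp <- integer(0)
  for (j in seq_len(p)) {
    ip <- c(ip, seq_len(j))
    jp <- c(jp, rep(j, j))
  }
  list(i = ip, j = jp)
}

unvech <- function(v, p, pairs) {
  m <- matrix(0, p, p)
  m[cbind(pairs$i, pairs$j)] <- v
  m[cbind(pairs$j, pairs$i)] <- v
  m
}

col_cumsum <- function(m) {
  if (ncol(m) == 1L) matrix(cumsum(m), ncol = 1L) else apply(m, 2L, cumsum)
}

cox_prep <- function(entry, exit, status, X, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  n <- length(exit)
  p <- ncol(X)
  if (sum(status) < 1) hs_stop("partial likelihood undefined: no events")
  pairs <- vech_pairs(p)
  Xp <- X[, pairs$i, drop = FALSE] * X[, pairs$j, drop = FALSE]

  ord_x <- order(exit)
  exit_s <- exit[ord_x]
  has_entry <- any(entry > 0)
  ord_e <- if (has_entry) order(entry) else NULL
  entry_s <- if (has_entry) entry[ord_e] else NULL

  di <- which(status == 1)
  ut <- sort(unique(exit[di]))
  gi <- match(exit[di], ut)            # death -> distinct-time group
  d <- tabulate(gi, nbins = length(ut))

  # number at risk by exit (>= t) and to-subtract by entry (>= t)
  c_t <- n - findInterval(ut, exit_s, left.open = TRUE)
  e_t <- if (has_entry) n - findInterval(ut, entry_s, left.open = TRUE)
         else integer(length(ut))

  eidx <- rep(seq_along(ut), d)        # expanded rows (one per death)
  frac <- if (ties == "efron")
    unlist(lapply(d, function(dd) (seq_len(dd) - 1) / dd), use.names = FALSE)
  else rep(0, sum(d))
  need_death_sums <- ties == "efron" && any(d > 1L)

  list(n = n, p = p, X = X, Xp = Xp, pairs = pairs,
       entry = entry, exit = exit, status = status, ties = ties,
       ord_x = ord_x, ord_e = ord_e, has_entry = has_entry,
       di = di, ut = ut, gi = gi, d = d, c_t = c_t, e_t = e_t,
       eidx = eidx, frac = frac, need_death_sums = need_death_sums,
       xsum_deaths = colSums(X[di, , drop = FALSE]),
       n_events = length(di))
}

# At-risk sums of the columns of M at every distinct event time.
risk_sums <- function(prep, M) {
  CSx <- col_cumsum(M[rev(prep$ord_x), , drop = FALSE])
  S <- CSx[prep$c_t, , drop = FALSE]
  if (prep$has_entry) {
    CSe <- col_cumsum(M[rev(prep$ord_e), , drop = FALSE])
    nz <- prep$e_t > 0L
    if (any(nz))
      S[nz, ] <- S[nz, , drop = FALSE] - CSe[prep$e_t[nz], , drop = FALSE]
  }
  S
}

# lpl and, when derivs = TRUE, gradient and observed information of the
# unpenalized log partial likelihood at beta.  Returns ok = FALSE when the
# linear predictor overflows (caller should shorten the step).
cox_eval <- function(prep, beta, derivs = TRUE) {
  eta <- drop(prep$X %*% beta)
  if (any(!is.finite(eta)) || max(abs(eta)) > 250)
    return(list(ok = FALSE))
  w <- exp(eta)
  p <- prep$p

  M <- if (derivs) cbind(w, prep$X * w, prep$Xp * w) else matrix(w, ncol = 1L)
  S <- risk_sums(prep, M)

  if (prep$need_death_sums) {
    Md <- M[prep$di, , drop = FALSE]
    Dm <- rowsum(Md, prep$gi, reorder = TRUE)
    Ex <- S[prep$eidx, , drop = FALSE] - prep$frac * Dm[prep$eidx, , drop = FALSE]
  } else {
    Ex <- S[prep$eidx, , drop = FALSE]
  }
  S0e <- Ex[, 1L]
  if (any(S0e <= 0) || any(!is.finite(S0e))) return(list(ok = FALSE))

  lpl <- sum(eta[prep$di]) - sum(log(S0e))
  if (!derivs) return(list(ok = TRUE, lpl = lpl))

  U <- Ex[, 1L + seq_len(p), drop = FALSE] / S0e
  grad <- prep$xsum_deaths - colSums(U)
  A <- colSums(Ex[, -seq_len(1L + p), drop = FALSE] / S0e)
  info <- unvech(A, p, prep$pairs) - crossprod(U)
  list(ok = TRUE, lpl = lpl, grad = grad, info = info)
}

#' Cox log partial likelihood
#'
#' Evaluates the log partial likelihood of a design matrix and coefficient
#' vector on a cohort, with risk sets `{entry < t <= exit}` at each event
#' time and Breslow or Efron handling of tied event times.
#'
#' @param dataset a [survival_dataset()].
#' @param design numeric design matrix, rows aligned with the records.
#' @param coefficients numeric coefficient vector.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @return The log partial likelihood (a scalar).
#' @export
log_partial_likelihood <- function(dataset, design, coefficients,
                                   ties_method = c("efron", "breslow")) {
  stopifnot(inherits(dataset, "survival_dataset"))
  design <- as.matrix(design)
  if (nrow(design) != dataset$n)
    hs_stop("design rows do not align with dataset records")
  if (ncol(design) != length(coefficients))
    hs_stop("coefficient length does not match design columns")
  prep <- cox_prep(dataset$entry_time, dataset$exit_time, dataset$status,
                   design, match.arg(ties_method))
  ev <- cox_eval(prep, as.numeric(coefficients), derivs = FALSE)
  if (!ev$ok) hs_stop_numeric("linear predictor overflow")
  ev$lpl
}

#' Partial-likelihood derivatives at arbitrary coefficients
#'
#' Evaluates the log partial likelihood together with its analytic gradient
#' and the observed information matrix (negative Hessian) at `coefficients`.
#' Mainly useful for diagnostics and for validating the fitting machinery
#' against finite differences.
#'
#' @inheritParams log_partial_likelihood
#' @return list with `lpl`, `gradient`, `information`.
#' @export
cox_derivatives <- function(dataset, design, coefficients,
                            ties_method = c("efron", "breslow")) {
  stopifnot(inherits(dataset, "survival_dataset"))
  design <- as.matrix(design)
  if (nrow(design) != dataset$n)
    hs_stop("design rows do not align with dataset records")
  prep <- cox_prep(dataset$entry_time, dataset$exit_time, dataset$status,
                   design, match.arg(ties_method))
  ev <- cox_eval(prep, as.numeric(coefficients), derivs = TRUE)
  if (!ev$ok) hs_stop_numeric("linear predictor overflow")
  list(lpl = ev$lpl, gradient = ev$grad, information = ev$info)
}
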