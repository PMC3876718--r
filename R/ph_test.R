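# Grambsch-Therneau proportional-hazards diagnostic on Schoenfeld residuals.

# Unscaled Schoenfeld residual for each death: x_(k) - S1(t_k)/S0(t_k),
# risk-set expectations evaluated at the fitted coefficients.
schoenfeld_residuals <- function(fit) {
  ds <- fit$dataset
  X <- fit$design
  prep <- cox_prep(ds$entry_time, ds$exit_time, ds$status, X,
                   fit$ties_method)
  eta <- drop(X %*% fit$coefficients)
  w <- exp(eta)
  M <- cbind(w, X * w)
  S <- risk_sums(prep, M)                    # distinct event times
  Xbar <- S[, -1L, drop = FALSE] / S[, 1L]
  di <- prep$di
  ord <- order(ds$exit_time[di])
  di <- di[ord]
  gi <- prep$gi[ord]
  resid <- X[di, , drop = FALSE] - Xbar[gi, , drop = FALSE]
  list(resid = resid, times = ds$exit_time[di], death_idx = di, prep = prep)
}

# Left-continuous Kaplan-Meier estimate (with delayed entry) evaluated just
# before each death time.
km_before <- function(prep, times) {
  ut <- prep$ut; d <- prep$d
  # number at risk at each distinct event time (counts, not weighted sums)
  n_at <- prep$c_t - prep$e_t
  surv <- cumprod(1 - d / n_at)
  # S(t-): product over event times strictly before t
  idx <- findInterval(times, ut, left.open = TRUE)
  ifelse(idx == 0L, 1, surv[pmax(idx, 1L)])
}

#' Proportional-hazards score test on scaled Schoenfeld residuals
#'
#' Tests, per model term and globally, whether the (scaled) Schoenfeld
#' residuals drift with a transform of event time — the Grambsch-Therneau
#' diagnostic for non-proportional hazards.  Writing \eqn{u = \sum_k (g_k -
#' \bar g)\, s_k} for the residual-weighted transform and \eqn{V} for the
#' fitted coefficient covariance, the global statistic is \eqn{d\, u^T V u /
#' \sum_k (g_k - \bar g)^2} on the model's total effective df, and a term's
#' statistic restricts \eqn{V u} to the term's block.
#'
#' @param fit an `additive_cox_fit`.
#' @param time_transform `"km"` (default; `1 -` left-continuous Kaplan-Meier
#'   at the event time, the Grambsch-Therneau recommendation), `"identity"`,
#'   or `"rank"`.
#' @return An object of class `ph_test_result`: a list with `table` (data
#'   frame of chisq, df, p per term plus a GLOBAL row) and `transform`.
#' @export
ph_test <- function(fit, time_transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "additive_cox_fit"))
  time_transform <- match.arg(time_transform)
  if (fit$n_events < 3) hs_stop("ph_test needs at least 3 events")
  sr <- schoenfeld_residuals(fit)
  d <- fit$n_events
  g <- switch(time_transform,
              km = 1 - km_before(sr$prep, sr$times),
              identity = sr$times,
              rank = rank(sr$times, ties.method = "average"))
  gc <- g - mean(g)
  sgc2 <- sum(gc^2)
  if (sgc2 <= 0) hs_stop_numeric("degenerate time transform (all equal)")
  u <- colSums(gc * sr$resid)
  V <- fit$covariance
  Vu <- drop(V %*% u)
  rows <- list()
  for (i in seq_along(fit$blocks)) {
    b <- fit$blocks[[i]]
    Vbb <- V[b, b, drop = FALSE]
    chisq <- d * drop(crossprod(Vu[b], solve(Vbb, Vu[b]))) / sgc2
    dfi <- max(fit$df_per_term[i], 1e-8)
    rows[[fit$labels[i]]] <- c(chisq = chisq, df = dfi,
                               p = pchisq(chisq, dfi, lower.tail = FALSE))
  }
  chisq_g <- d * drop(crossprod(u, Vu)) / sgc2
  df_g <- sum(vapply(seq_along(fit$blocks), function(i)
    fit$df_per_term[i], numeric(1L)))
  rows[["GLOBAL"]] <- c(chisq = chisq_g, df = df_g,
                        p = pchisq(chisq_g, df_g, lower.tail = FALSE))
  tab <- as.data.frame(do.call(rbind, rows))
  bad <- tab$p < 0 | tab$p > 1
  stopifnot(!any(bad))
  structure(list(table = tab, transform = time_transform),
            class = "ph_test_result")
}

#' @export
print.ph_test_result <- function(x, digits = 4, ...) {
  cat(sprintf("Proportional hazards test (transform = %s)\n", x$transform))
  print(x$table, digits = digits)
  invisible(x)
}
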