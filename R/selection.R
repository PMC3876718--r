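# Model-selection criteria for censored data and the multivariable
# degrees-of-freedom search.

#' Akaike information criterion for a Cox fit
#'
#' `-2 * lpl + 2 * total_df`.
#' @param lpl maximum log partial likelihood.
#' @param total_df total (effective) degrees of freedom.
#' @return The criterion score (smaller is better).
#' @export
aic <- function(lpl, total_df) -2 * lpl + 2 * total_df

#' Event-count Bayesian information criterion
#'
#' `-2 * lpl + log(n_events) * total_df`.  The penalty uses the number of
#' uncensored observations (events), not the sample size — the appropriate
#' effective sample size for censored data.
#' @inheritParams aic
#' @param n_events number of events (uncensored observations), >= 1.
#' @return The criterion score.
#' @export
bic <- function(lpl, total_df, n_events) {
  if (!is_scalar_number(n_events) || n_events < 1)
    hs_stop("bic requires n_events >= 1")
  -2 * lpl + log(n_events) * total_df
}

#' Corrected AIC for a Cox fit
#'
#' `-2 * lpl + 2 * n_events * (total_df + 1) / (n_events - (total_df + 2))`
#' — the small-sample correction with the sample size taken as the event
#' count.  Undefined unless `n_events > total_df + 2`.
#' @inheritParams bic
#' @return The criterion score.
#' @export
aicc <- function(lpl, total_df, n_events) {
  if (n_events <= total_df + 2)
    hs_stop("AICc undefined: n_events must exceed total_df + 2")
  -2 * lpl + 2 * n_events * (total_df + 1) / (n_events - (total_df + 2))
}

# Total df for criterion scoring: effective df of the smooth terms plus one
# per linear coefficient (natural-spline blocks are unpenalized, so their
# trace equals the column count up to numerical noise; counted via trace).
model_total_df <- function(fit) {
  td <- 0
  for (i in seq_along(fit$terms)) {
    td <- td + if (fit$terms[[i]]$kind == "linear") 1
    else if (fit$terms[[i]]$kind == "natural_cubic") fit$terms[[i]]$ncol
    else fit$df_per_term[i]
  }
  unname(td)
}

#' Score a fitted model under a selection criterion
#'
#' @param fit an `additive_cox_fit`.
#' @param criterion `"AIC"`, `"AICc"`, or `"BIC"`.
#' @return An object of class `criterion_score`: list with `criterion`,
#'   `score`, `lpl`, `total_df`, `n_events`.
#' @export
score_model <- function(fit, criterion = c("AICc", "AIC", "BIC")) {
  stopifnot(inherits(fit, "additive_cox_fit"))
  if (!is.character(criterion))
    hs_stop("unknown criterion")
  criterion <- match.arg(toupper(criterion[1L]), c("AICC", "AIC", "BIC"))
  criterion <- c(AICC = "AICc", AIC = "AIC", BIC = "BIC")[[criterion]]
  td <- model_total_df(fit)
  s <- switch(criterion,
              AIC = aic(fit$lpl, td),
              AICc = aicc(fit$lpl, td, fit$n_events),
              BIC = bic(fit$lpl, td, fit$n_events))
  structure(list(criterion = criterion, score = s, lpl = fit$lpl,
                 total_df = td, n_events = fit$n_events),
            class = "criterion_score")
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("%s = %.4f  (lpl = %.4f, df = %.3f, events = %d)\n",
              x$criterion, x$score, x$lpl, x$total_df, x$n_events))
  invisible(x)
}

#' Default maximum degrees of freedom for one covariate
#'
#' For P-splines, the df minimizing the corrected AIC in a univariate model
#' of the covariate alone, found by golden-section search on
#' \eqn{\log_{10}\lambda} (effective df is monotone in \eqn{\lambda}, so
#' this is a 1-D refinement search over df in `(1, 20]`; the search stops
#' when the df bracket is narrower than `df_tol`).  For natural cubic
#' splines the fixed default 20 is returned.
#'
#' @param dataset a [survival_dataset()].
#' @param covariate covariate name.
#' @param smoother `"penalized_bspline"` or `"natural_cubic"`.
#' @param criterion selection criterion (default `"AICc"`).
#' @param maxdf upper bound of the search (default 20).
#' @param df_tol df resolution of the search (default 0.05).
#' @param ties_method tie handling.
#' @return Scalar df.
#' @export
default_max_df <- function(dataset, covariate,
                           smoother = c("penalized_bspline", "natural_cubic"),
                           criterion = "AICc", maxdf = 20, df_tol = 0.05,
                           ties_method = "efron") {
  smoother <- match.arg(smoother)
  if (is.null(dataset$covariates[[covariate]]))
    hs_stop(sprintf("covariate '%s' not found", covariate))
  if (smoother == "natural_cubic") return(maxdf)
  spec <- spline_term(covariate, "penalized_bspline", df = maxdf)
  design <- build_design(dataset, list(spec))
  prep <- cox_prep(dataset$entry_time, dataset$exit_time, dataset$status,
                   design$X, ties_method)
  block <- design$blocks[[1L]]
  state <- new.env(parent = emptyenv())
  state$beta <- NULL
  eval_at <- function(loglam) {
    Pl <- assemble_penalty(design, 10^loglam)
    st <- newton_cox(prep, Pl, init = state$beta)
    state$beta <- st$beta
    H <- st$info + Pl
    df <- effective_df(st$info, H, list(block))
    sc <- switch(criterion,
                 AIC = aic(st$lpl, df),
                 AICc = aicc(st$lpl, df, dataset$n_events),
                 BIC = bic(st$lpl, df, dataset$n_events))
    list(score = sc, df = df)
  }
  # restrict the lambda range so that df stays within (1, maxdf]
  lo <- -12; hi <- 12
  cal <- tryCatch(bisect_lambda(prep, design, 0, 1L, maxdf, tol = 0.02),
                  error = function(e) NULL)
  if (!is.null(cal)) lo <- log10(cal$lambda)
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- eval_at(x1); f2 <- eval_at(x2)
  for (i in seq_len(80L)) {
    if (abs(f1$df - f2$df) < df_tol && (hi - lo) < 6) break
    if (f1$score < f2$score) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- eval_at(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- eval_at(x2)
    }
  }
  best <- if (f1$score <= f2$score) f1 else f2
  min(best$df, maxdf)
}

# Midpoint rounding for integer (natural-spline) df: ties go to the smaller
# value, favouring parsimony.
round_half_down <- function(x) ceiling(x - 0.5)

#' Multivariable degrees-of-freedom search
#'
#' Selects the degrees of freedom of several nonlinear covariate effects
#' jointly by iterated interval halving: each round, every nonlinear
#' covariate contributes the candidate values (minimum, midpoint, maximum)
#' of its current df interval; all combinations are fitted and scored under
#' the chosen criterion; each covariate's interval is then halved towards
#' the winning combination's coordinate.  After `ntimes` rounds the best df
#' combination over the whole evaluated history is returned, together with
#' its refitted model.  Natural-spline candidates are integers (midpoints
#' rounded half-down, favouring parsimony); duplicate combinations are
#' served from a cache.
#'
#' @param dataset a [survival_dataset()] (complete cases).
#' @param nl_covariates names of covariates entering nonlinearly.
#' @param other_covariates names of covariates entering linearly.
#' @param smoother `"natural_cubic"` or `"penalized_bspline"` for all
#'   nonlinear terms.
#' @param criterion `"AIC"`, `"AICc"`, or `"BIC"`.
#' @param mindf,maxdf per-covariate bounds (scalars are recycled).  Defaults:
#'   min 1 (natural) or 1.1 (P-spline); max 20 (natural) or the univariate
#'   AICc optimum via [default_max_df()] (P-spline).
#' @param ntimes number of halving rounds (default 5).
#' @param ties_method tie handling.
#' @return An object of class `df_search_result`: list with
#'   `df_per_covariate`, `best_fit`, `best_score` (a `criterion_score`),
#'   `history` (data frame of every evaluation), `ntimes_used`, `n_fits`.
#' @export
dfmacox_search <- function(dataset, nl_covariates,
                           other_covariates = character(0),
                           smoother = c("natural_cubic", "penalized_bspline"),
                           criterion = c("AICc", "AIC", "BIC"),
                           mindf = NULL, maxdf = NULL, ntimes = 5L,
                           ties_method = "efron") {
  stopifnot(inherits(dataset, "survival_dataset"))
  smoother <- match.arg(smoother)
  criterion <- match.arg(criterion)
  q <- length(nl_covariates)
  if (q == 0L) hs_stop("nl_covariates must be nonempty")
  natural <- smoother == "natural_cubic"
  if (is.null(mindf)) mindf <- if (natural) 1 else 1.1
  if (is.null(maxdf)) {
    maxdf <- if (natural) rep(20, q)
    else vapply(nl_covariates, function(cv)
      max(default_max_df(dataset, cv, "penalized_bspline",
                         criterion = "AICc", ties_method = ties_method),
          1.6), numeric(1L))
  }
  mindf <- rep_len(mindf, q); maxdf <- rep_len(maxdf, q)
  if (any(mindf > maxdf)) hs_stop("mindf must not exceed maxdf")
  if (natural && any(mindf != round(mindf) | maxdf != round(maxdf)))
    hs_stop("natural-spline df bounds must be integers")

  make_terms <- function(dfs) {
    tm <- lapply(seq_len(q), function(i) {
      if (natural) spline_term(nl_covariates[i], "natural_cubic",
                               df = dfs[i])
      else spline_term(nl_covariates[i], "penalized_bspline", df = dfs[i])
    })
    c(tm, lapply(other_covariates, linear_term))
  }

  cache <- new.env(parent = emptyenv())
  n_fits <- 0L
  evaluate <- function(dfs) {
    key <- paste(format(dfs, digits = 12), collapse = "|")
    if (!is.null(cache[[key]])) {
      out <- cache[[key]]; out$cached <- TRUE
      return(out)
    }
    out <- tryCatch({
      fit <- fit_penalized_cox(dataset, make_terms(dfs),
                               ties_method = ties_method)
      sc <- score_model(fit, criterion)
      list(score = sc$score, lpl = fit$lpl, total_df = sc$total_df,
           fit = fit, error = FALSE, cached = FALSE)
    }, error = function(e)
      list(score = Inf, lpl = NA_real_, total_df = NA_real_, fit = NULL,
           error = TRUE, cached = FALSE))
    n_fits <<- n_fits + 1L
    cache[[key]] <- out
    out
  }

  lo <- mindf; hi <- maxdf
  history <- list()
  best <- list(score = Inf, dfs = NULL)
  for (round_i in seq_len(ntimes)) {
    cand <- lapply(seq_len(q), function(i) {
      if (natural) sort(unique(c(lo[i], round_half_down((lo[i] + hi[i]) / 2),
                                 hi[i])))
      else sort(unique(c(lo[i], (lo[i] + hi[i]) / 2, hi[i])))
    })
    grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
    names(grid) <- nl_covariates
    scores <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      dfs <- as.numeric(grid[r, ])
      res <- evaluate(dfs)
      scores[r] <- res$score
      history[[length(history) + 1L]] <- data.frame(
        round = round_i, t(setNames(dfs, paste0("df_", nl_covariates))),
        lpl = res$lpl, total_df = res$total_df, score = res$score,
        cached = res$cached, error = res$error)
      if (is.finite(res$score) && res$score < best$score)
        best <- list(score = res$score, dfs = dfs)
    }
    if (all(!is.finite(scores)))
      hs_stop_numeric("all df combinations failed to fit")
    win <- as.numeric(grid[which.min(scores), ])
    # halve each covariate's interval towards the winning coordinate
    for (i in seq_len(q)) {
      ci <- cand[[i]]
      wi <- win[i]
      if (length(ci) == 1L) next
      if (length(ci) == 2L) { lo[i] <- wi; hi[i] <- wi; next }
      lov <- ci[1L]; midv <- ci[2L]; hiv <- ci[3L]
      if (wi == lov) {
        hi[i] <- midv
      } else if (wi == hiv) {
        lo[i] <- midv
      } else {
        # winner is the midpoint: keep the half containing the better
        # endpoint, ties towards the lower half
        s_lo <- endpoint_score(grid, scores, win, i, lov)
        s_hi <- endpoint_score(grid, scores, win, i, hiv)
        if (s_lo <= s_hi) { lo[i] <- lov; hi[i] <- midv }
        else { lo[i] <- midv; hi[i] <- hiv }
      }
    }
  }
  history <- do.call(rbind, history)
  best_res <- evaluate(best$dfs)   # cache hit
  best_fit <- best_res$fit
  stopifnot(abs(best$score - min(history$score, na.rm = TRUE)) < 1e-12)
  structure(list(
    df_per_covariate = setNames(best$dfs, nl_covariates),
    best_fit = best_fit,
    best_score = score_model(best_fit, criterion),
    history = history, ntimes_used = ntimes, n_fits = n_fits,
    criterion = criterion, smoother = smoother),
    class = "df_search_result")
}

# Score of the evaluated combination equal to `win` except that covariate i
# is set to the endpoint value v.
endpoint_score <- function(grid, scores, win, i, v) {
  probe <- win; probe[i] <- v
  for (r in seq_len(nrow(grid))) {
    if (all(abs(as.numeric(grid[r, ]) - probe) < 1e-12)) return(scores[r])
  }
  Inf
}

#' @export
print.df_search_result <- function(x, ...) {
  cat(sprintf("df search (%s, %s): %d fits, %d rounds\n", x$smoother,
              x$criterion, x$n_fits, x$ntimes_used))
  cat("selected df:\n")
  print(x$df_per_covariate)
  print(x$best_score)
  invisible(x)
}

#' Write a df-search history to CSV
#'
#' One row per evaluated df combination: per-covariate df, log partial
#' likelihood, total df, and criterion score.
#'
#' @param result a [dfmacox_search()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_search_history <- function(result, path) {
  stopifnot(inherits(result, "df_search_result"))
  utils::write.table(result$history, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
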