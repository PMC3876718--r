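# Smooth hazard-ratio curves relative to a reference covariate value,
# with pointwise confidence limits from the sandwich covariance.

find_term <- function(fit, covariate) {
  for (i in seq_along(fit$terms))
    if (fit$terms[[i]]$spec$covariate == covariate) return(i)
  hs_stop(sprintf("covariate '%s' is not a term of the fit", covariate))
}

# Fitted term contribution f_hat at arbitrary covariate values.
term_values <- function(fit, i, z) {
  b <- fit$terms[[i]]$eval(z)
  drop(b %*% fit$coefficients[fit$blocks[[i]]])
}

#' Choose the reference value for a hazard-ratio curve
#'
#' Either pass the value directly (`pred_value`, clamped to the observed
#' covariate range with a warning), or derive it from the fitted curve:
#' `prob = 0` returns the observed covariate value at which the fitted
#' effect is smallest (the hazard minimum), `prob = 1` the value where it is
#' largest, and any other `prob` in (0, 1) the corresponding quantile of the
#' observed covariate values.
#'
#' @param fit an `additive_cox_fit`.
#' @param covariate covariate name (a smooth or linear term of the fit).
#' @param prob reference selector in `[0, 1]` (exclusive with `pred_value`).
#' @param pred_value explicit reference value.
#' @return The reference value (scalar).
#' @export
select_reference <- function(fit, covariate, prob = NULL, pred_value = NULL) {
  stopifnot(inherits(fit, "additive_cox_fit"))
  if (is.null(prob) == is.null(pred_value))
    hs_stop("give exactly one of prob and pred_value")
  i <- find_term(fit, covariate)
  obs <- fit$dataset$covariates[[covariate]]
  if (!is.null(pred_value)) {
    rng <- range(obs)
    if (pred_value < rng[1L] || pred_value > rng[2L]) {
      warning("pred_value outside the observed covariate range; clamped")
      pred_value <- min(max(pred_value, rng[1L]), rng[2L])
    }
    return(pred_value)
  }
  if (!is_scalar_number(prob) || prob < 0 || prob > 1)
    hs_stop("prob must be in [0, 1]")
  if (prob == 0 || prob == 1) {
    f <- term_values(fit, i, obs)
    return(obs[if (prob == 0) which.min(f) else which.max(f)])
  }
  as.numeric(quantile(obs, probs = prob, names = FALSE))
}

#' Hazard-ratio curve with pointwise confidence limits
#'
#' For the chosen covariate, computes the log hazard ratio \eqn{\ln
#' HR(z, z_{ref}) = \hat f(z) - \hat f(z_{ref}) = c^T \hat\beta} with
#' \eqn{c = b(z) - b(z_{ref})} the basis difference on the term's block, its
#' standard error \eqn{\sqrt{c^T V c}} from the sandwich covariance
#' \eqn{V = H^{-1} I H^{-1}}, and symmetric normal-quantile confidence
#' limits on the log scale.
#'
#' @param fit an `additive_cox_fit`.
#' @param covariate covariate name.
#' @param reference reference covariate value (see [select_reference()]).
#' @param grid evaluation points: either a numeric vector or a single count
#'   (default 100 equally spaced points over the observed covariate range).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `hr_curve`: list with `covariate`,
#'   `reference`, `grid`, `log_hr`, `se`, `lower`, `upper`, `conf_level`,
#'   `scale` (`"log_hr"`), and `obs_values` (for rug plots).
#' @export
hr_curve <- function(fit, covariate, reference, grid = 100L,
                     conf_level = 0.95) {
  stopifnot(inherits(fit, "additive_cox_fit"))
  if (!fit$converged) hs_stop("fit did not converge")
  if (!is_scalar_number(conf_level) || conf_level <= 0 || conf_level >= 1)
    hs_stop("conf_level must be in (0, 1)")
  i <- find_term(fit, covariate)
  obs <- fit$dataset$covariates[[covariate]]
  if (length(grid) == 1L && grid == round(grid) && grid > 1)
    grid <- seq(min(obs), max(obs), length.out = as.integer(grid))
  grid <- as.numeric(grid)
  if (!length(grid)) hs_stop("empty evaluation grid")
  block <- fit$blocks[[i]]
  bg <- fit$terms[[i]]$eval(grid)
  br <- fit$terms[[i]]$eval(reference)
  C <- bg - matrix(br, nrow = length(grid), ncol = length(block),
                   byrow = TRUE)
  # the contrast at the reference itself is identically zero; enforce it so
  # log_hr = se = 0 holds exactly rather than to BLAS rounding
  C[grid == reference, ] <- 0
  log_hr <- drop(C %*% fit$coefficients[block])
  V <- fit$covariance[block, block, drop = FALSE]
  var <- rowSums((C %*% V) * C)
  se <- sqrt(pmax(var, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(covariate = covariate, reference = reference, grid = grid,
                 log_hr = log_hr, se = se,
                 lower = log_hr - zq * se, upper = log_hr + zq * se,
                 conf_level = conf_level, scale = "log_hr",
                 obs_values = obs),
            class = "hr_curve")
}

#' @export
as.data.frame.hr_curve <- function(x, ...) {
  data.frame(value = x$grid, log_hr = x$log_hr, hr = exp(x$log_hr),
             se = x$se, lower_hr = exp(x$lower), upper_hr = exp(x$upper))
}

#' @export
print.hr_curve <- function(x, ...) {
  cat(sprintf("hr_curve for %s, reference = %g, %d points, %.0f%% limits\n",
              x$covariate, x$reference, length(x$grid), 100 * x$conf_level))
  print(utils::head(as.data.frame(x)))
  if (length(x$grid) > 6L) cat("...\n")
  invisible(x)
}

#' Hazard-ratio predictions at chosen covariate values
#'
#' @param fit an `additive_cox_fit`.
#' @param covariate covariate name.
#' @param values covariate values at which to predict (nonempty).
#' @param pred_value,prob reference selector, passed to
#'   [select_reference()]; alternatively give `reference` directly.
#' @param reference explicit reference value (overrides the selectors).
#' @param conf_level confidence level.
#' @return data frame with columns `value`, `log_hr`, `hr`, `se`,
#'   `lower_hr`, `upper_hr`; the row at the reference value has `hr = 1`
#'   and a zero-width interval.
#' @export
predict_hr <- function(fit, covariate, values, pred_value = NULL,
                       prob = NULL, reference = NULL, conf_level = 0.95) {
  if (!length(values)) hs_stop("values must be nonempty")
  if (is.null(reference))
    reference <- select_reference(fit, covariate, prob = prob,
                                  pred_value = pred_value)
  curve <- hr_curve(fit, covariate, reference, grid = as.numeric(values),
                    conf_level = conf_level)
  out <- as.data.frame(curve)
  attr(out, "reference") <- reference
  out
}

#' Render a hazard-ratio curve to a figure file
#'
#' Writes the curve with its confidence band, a marker at the reference
#' value, and a rug of observed covariate values.  The device is chosen by
#' file extension: `.png`, `.svg`, or `.pdf`.
#'
#' @param curve an [hr_curve()].
#' @param file output path.
#' @param scale `"log_hr"` (default) or `"hr"`.
#' @param xlim optional x-axis restriction (the rendered grid is restricted
#'   accordingly).
#' @param xlab,ylab,main usual plot labels.
#' @param ref_label label printed at the reference marker.
#' @param width,height device size in inches.
#' @return `file`, invisibly.
#' @export
render_curve <- function(curve, file, scale = c("log_hr", "hr"),
                         xlim = NULL, xlab = NULL, ylab = NULL, main = "",
                         ref_label = "Ref.", width = 7, height = 5) {
  stopifnot(inherits(curve, "hr_curve"))
  scale <- match.arg(scale)
  ext <- tolower(tools::file_ext(file))
  dev <- switch(ext,
                png = function() grDevices::png(file, width = width * 96,
                                                height = height * 96),
                svg = function() grDevices::svg(file, width = width,
                                                height = height),
                pdf = function() grDevices::pdf(file, width = width,
                                                height = height),
                hs_stop(sprintf("unsupported figure extension '%s'", ext)))
  ok <- tryCatch({ dev(); TRUE }, error = function(e)
    hs_stop(sprintf("cannot open figure file '%s': %s", file,
                    conditionMessage(e))))
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(curve, scale = scale, xlim = xlim, xlab = xlab, ylab = ylab,
       main = main, ref_label = ref_label)
  invisible(file)
}

#' Plot a hazard-ratio curve
#'
#' @param x an [hr_curve()].
#' @param scale `"log_hr"` or `"hr"`.
#' @param xlim optional x-range restriction.
#' @param xlab,ylab,main plot labels.
#' @param ref_label label for the reference marker.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hr_curve <- function(x, scale = c("log_hr", "hr"), xlim = NULL,
                          xlab = NULL, ylab = NULL, main = "",
                          ref_label = "Ref.", ...) {
  scale <- match.arg(scale)
  keep <- if (is.null(xlim)) rep(TRUE, length(x$grid))
          else x$grid >= xlim[1L] & x$grid <= xlim[2L]
  if (!any(keep)) hs_stop("xlim excludes every grid point")
  g <- x$grid[keep]
  tf <- if (scale == "hr") exp else identity
  y <- tf(x$log_hr[keep]); loy <- tf(x$lower[keep]); upy <- tf(x$upper[keep])
  xlab <- xlab %||% x$covariate
  ylab <- ylab %||% if (scale == "hr") "Hazard ratio" else "Log hazard ratio"
  plot(g, y, type = "n", ylim = range(loy, upy), xlim = xlim,
       xlab = xlab, ylab = ylab, main = main, ...)
  polygon(c(g, rev(g)), c(loy, rev(upy)), border = NA,
          col = grDevices::adjustcolor("steelblue", 0.3))
  lines(g, y, lwd = 2, col = "steelblue4")
  abline(h = tf(0), lty = 3)
  rug(x$obs_values[x$obs_values >= min(g) & x$obs_values <= max(g)])
  ref_in <- x$reference >= min(g) && x$reference <= max(g)
  if (ref_in) {
    abline(v = x$reference, lty = 2, col = "grey40")
    points(x$reference, tf(0), pch = 19, col = "grey20")
    if (nzchar(ref_label))
      axis(3, at = x$reference, labels = ref_label, tick = FALSE,
           line = -1, cex.axis = 0.8)
  }
  invisible(x)
}
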