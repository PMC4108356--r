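#' @export
print.firefit <- function(x, digits = 4, ...) {
  cat("Discrete lognormal fire-interval model\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  cat("\nObservations: ", x$counts["complete"], " complete, ",
      x$counts["right_censored"], " right-censored, ",
      x$counts["left_censored"], " left-censored\n", sep = "")
  cat("Log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  cat("Median ", x$median, " yr, mode ", x$mode,
      " yr, hazard turning point ", x$turning_point, " yr\n", sep = "")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$degenerate)
    cat("WARNING: degenerate fit (sdlog at lower bound)\n")
  invisible(x)
}

#' @export
coef.firefit <- function(object, ...) object$coefficients

#' @export
vcov.firefit <- function(object, ...) object$vcov

#' @export
logLik.firefit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = sum(object$counts),
            class = "logLik")
}

#' Summary of a fitted fire-interval model
#'
#' Adds standard errors (from the inverse observed information) and normal
#' 95% confidence intervals to the parameter estimates, alongside the derived
#' fire-regime descriptors and the mean fire interval.
#'
#' @param object a [fire_fit()] result.
#' @param ... unused.
#' @export
summary.firefit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `2.5 %` = object$coefficients - 1.96 * se,
               `97.5 %` = object$coefficients + 1.96 * se)
  out <- list(coefficients = tab, counts = object$counts,
              loglik = object$loglik, median = object$median,
              mode = object$mode, turning_point = object$turning_point,
              mean_interval = fireint_mean(object$coefficients[["meanlog"]],
                                           object$coefficients[["sdlog"]]),
              converged = object$converged, degenerate = object$degenerate,
              call = object$call)
  class(out) <- "summary.firefit"
  out
}

#' @export
print.summary.firefit <- function(x, digits = 4, ...) {
  cat("Discrete lognormal fire-interval model\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  cat("\nObservations: ", x$counts["complete"], " complete, ",
      x$counts["right_censored"], " right-censored, ",
      x$counts["left_censored"], " left-censored\n", sep = "")
  cat("Log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  cat("Median ", x$median, " yr, mode ", x$mode,
      " yr, turning point ", x$turning_point, " yr, mean interval ",
      format(x$mean_interval, digits = digits), " yr\n", sep = "")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$degenerate) cat("WARNING: degenerate fit (sdlog at lower bound)\n")
  invisible(x)
}

#' Predicted interval, survival and hazard curves
#'
#' @param object a [fire_fit()] result.
#' @param t fuel ages (whole years) at which to evaluate; defaults to
#'   `1:t_max` of the fit.
#' @param type `"pmf"` for the interval distribution f(t), `"survival"` for
#'   A(t), or `"hazard"` for lambda(t).
#' @param ... unused.
#' @return A numeric vector of probabilities, one per element of `t`.
#' @export
predict.firefit <- function(object, t = seq_len(object$t_max),
                            type = c("pmf", "survival", "hazard"), ...) {
  type <- match.arg(type)
  ml <- object$coefficients[["meanlog"]]
  sl <- object$coefficients[["sdlog"]]
  switch(type,
         pmf = dfireint(t, ml, sl),
         survival = sfireint(t, ml, sl),
         hazard = hfireint(t, ml, sl))
}

#' Simulate complete fire intervals from a fitted model
#'
#' Draws `nsim` replicate samples of complete intervals, each of the same
#' size as the number of informative observations in the fitted sample.
#'
#' @param object a [fire_fit()] result.
#' @param nsim number of replicate samples.
#' @param seed optional RNG seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated intervals.
#' @export
simulate.firefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(object$counts)
  ml <- object$coefficients[["meanlog"]]
  sl <- object$coefficients[["sdlog"]]
  out <- as.data.frame(replicate(nsim, rfireint(n, ml, sl)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Cox-Snell residuals of a fitted fire-interval model
#'
#' The cumulative-hazard transform H(t) = -log A(t) evaluated at each
#' observation (at l - 1 for left-censored lower bounds l). If the model is
#' adequate the residuals of complete observations behave like a (discretized)
#' unit-exponential censored sample.
#'
#' @param object a [fire_fit()] result.
#' @param ... unused.
#' @return A numeric vector with a `status` attribute.
#' @export
residuals.firefit <- function(object, ...) {
  cnt <- object$data
  len <- rep(cnt$length, cnt$n)
  status <- rep(cnt$status, cnt$n)
  at <- ifelse(status == "left_censored", pmax(len - 1L, 0L), len)
  ml <- object$coefficients[["meanlog"]]
  sl <- object$coefficients[["sdlog"]]
  r <- -sfireint(at, ml, sl, log = TRUE)
  attr(r, "status") <- status
  r
}

#' Plot fitted fire-interval, survival and hazard curves
#'
#' Base-graphics panels of f(t), A(t) and lambda(t) for the fitted parameters.
#' The survival panel overlays the Kaplan-Meier estimate computed from the
#' complete and right-censored observations of the fitted sample.
#'
#' @param x a [fire_fit()] result.
#' @param t_max plotting horizon in years.
#' @param which subset of `1:3` selecting the pmf, survival and hazard panels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.firefit <- function(x, t_max = 20L, which = 1:3, ...) {
  tt <- seq_len(t_max)
  op <- par(mfrow = c(1, length(which)))
  on.exit(par(op))
  if (1 %in% which) {
    plot(tt, predict(x, tt, "pmf"), type = "h", lwd = 3,
         xlab = "fire interval t (yr)", ylab = "f(t)",
         main = "Fire interval distribution", ...)
  }
  if (2 %in% which) {
    plot(c(0, tt), sfireint(c(0, tt), x$coefficients[["meanlog"]],
                            x$coefficients[["sdlog"]]),
         type = "s", xlab = "time since fire t (yr)", ylab = "A(t)",
         main = "Survival distribution", ylim = c(0, 1), ...)
    cnt <- x$data
    cr <- cnt$status %in% c("complete", "right_censored")
    if (sum(cnt$n[cr & cnt$status == "complete"]) > 0) {
      len <- rep(cnt$length[cr], cnt$n[cr])
      ev <- rep(cnt$status[cr], cnt$n[cr]) == "complete"
      km <- survival::survfit(survival::Surv(len, ev) ~ 1)
      lines(km$time, km$surv, type = "s", lty = 2, col = "grey40")
      legend("topright", legend = c("model", "Kaplan-Meier"),
             lty = c(1, 2), col = c("black", "grey40"), bty = "n")
    }
  }
  if (3 %in% which) {
    plot(tt, predict(x, tt, "hazard"), type = "b", pch = 16,
         xlab = "fuel age t (yr)", ylab = expression(lambda(t)),
         main = "Hazard of burning", ...)
    abline(v = x$turning_point, lty = 3)
  }
  invisible(x)
}
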