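#' @export
print.expdecomp <- function(x, digits = 4, ...) {
  cat("Multiexponential decay decomposition\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("Components selected: %d   dispersion (normalized MSE): %.6g\n\n",
              x$n_components, x$dispersion))
  tab <- x$components
  tab$weight_pct <- round(tab$weight_pct)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summary of a decay decomposition
#'
#' @param object An `expdecomp` fit.
#' @param ... Unused.
#' @return An object of class `"summary.expdecomp"` with the component
#'   table, dispersion, stage trace and residual quartiles.
#' @export
summary.expdecomp <- function(object, ...) {
  structure(list(
    call = object$call,
    components = object$components,
    n_components = object$n_components,
    dispersion = object$dispersion,
    rmse_norm = sqrt(object$dispersion),
    stage_trace = object$stage_trace,
    resid_quartiles = stats::quantile(object$residuals),
    n_obs = length(object$residuals),
    scale = object$scale),
    class = "summary.expdecomp")
}

#' @export
print.summary.expdecomp <- function(x, digits = 4, ...) {
  cat("Multiexponential decay decomposition\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("%d observations, initial amplitude %.6g\n", x$n_obs, x$scale))
  cat(sprintf("Components selected: %d\n", x$n_components))
  cat(sprintf("Dispersion (normalized MSE): %.6g   normalized RMSE: %.6g\n\n",
              x$dispersion, x$rmse_norm))
  cat("Components (decrement descending):\n")
  print(format(x$components, digits = digits), row.names = FALSE)
  cat("\nStage trace (greedy component addition):\n")
  print(format(x$stage_trace, digits = digits), row.names = FALSE)
  cat("\nResiduals (original scale):\n")
  print(signif(x$resid_quartiles, digits))
  invisible(x)
}

#' @export
coef.expdecomp <- function(object, ...) {
  cbind(weight = object$components$weight,
        decrement = object$components$decrement)
}

#' Predict from a fitted decomposition
#'
#' @param object An `expdecomp` fit.
#' @param newdata Numeric vector of times (seconds), a `decay_signal`, or a
#'   data.frame with a `time` column. Defaults to the fitted grid.
#' @param ... Unused.
#' @return Predicted amplitudes on the original scale.
#' @export
predict.expdecomp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  times <- if (inherits(newdata, "decay_signal")) newdata$times
  else if (is.data.frame(newdata)) {
    if (!"time" %in% names(newdata))
      stop_input("`newdata` data.frame must have a `time` column")
    newdata$time
  } else as.numeric(newdata)
  predict(object$model, times)
}

#' @export
fitted.expdecomp <- function(object, ...) object$fitted

#' Residuals of a fitted decomposition
#'
#' @param object An `expdecomp` fit.
#' @param normalized If `TRUE`, residuals divided by the initial amplitude
#'   (the scale on which the dispersion is defined).
#' @param ... Unused.
#' @export
residuals.expdecomp <- function(object, normalized = FALSE, ...) {
  if (normalized) object$residuals / object$scale else object$residuals
}

#' Plot a decay decomposition
#'
#' Draws the measured signal, the fitted sum of exponentials and,
#' optionally, the individual components.
#'
#' @param x An `expdecomp` fit.
#' @param components Draw the individual exponential components (dashed).
#' @param log Axis specification passed to [graphics::plot()] (e.g. `"y"`).
#' @param ... Further graphical parameters.
#' @export
plot.expdecomp <- function(x, components = TRUE, log = "", ...) {
  s <- x$signal
  graphics::plot(s$times, s$amplitudes, pch = ".", col = "grey40",
                 xlab = "time (s)", ylab = "amplitude (a.u.)", log = log,
                 main = sprintf("%d-component exponential decomposition",
                                x$n_components), ...)
  graphics::lines(s$times, x$fitted, col = "red3", lwd = 2)
  if (components && x$n_components > 1L) {
    for (i in seq_len(x$n_components))
      graphics::lines(s$times,
                      x$components$weight[i] *
                        exp(-x$components$decrement[i] * s$times),
                      lty = 2, col = "steelblue")
  }
  graphics::legend("topright", bty = "n",
                   legend = c("signal", "fit",
                              if (components && x$n_components > 1L) "components"),
                   col = c("grey40", "red3",
                           if (components && x$n_components > 1L) "steelblue"),
                   lty = c(NA, 1, if (components && x$n_components > 1L) 2),
                   pch = c(20, NA, if (components && x$n_components > 1L) NA))
  invisible(x)
}

#' Simulate replicate signals from a fitted decomposition
#'
#' Draws new signals as the fitted curve plus i.i.d. Gaussian noise with
#' standard deviation equal to the fit's normalized RMSE times the initial
#' amplitude.
#'
#' @param object An `expdecomp` fit.
#' @param nsim Number of replicate signals.
#' @param seed Optional RNG seed, handled as in [stats::simulate()].
#' @param ... Unused.
#' @return A data.frame with `nsim` amplitude columns, one row per time
#'   point, with attribute `"seed"`.
#' @export
simulate.expdecomp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  if (is.null(seed)) {
    rng_state <- get(".Random.seed", envir = globalenv())
  } else {
    rng_state_old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rng_state_old, envir = globalenv()))
    set.seed(seed)
    rng_state <- get(".Random.seed", envir = globalenv())
  }
  m <- length(object$fitted)
  sdev <- sqrt(object$dispersion) * object$scale
  out <- as.data.frame(
    object$fitted + matrix(stats::rnorm(m * nsim, sd = sdev), m, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "seed") <- rng_state
  out
}
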