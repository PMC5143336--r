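#' Sampled decay signal
#'
#' Container for a kinetic curve sampled on a strictly increasing time grid:
#' typically the recovery of reaction-center absorption after switching off
#' actinic light, or a chlorophyll fluorescence induction decay. Times are in
#' seconds, amplitudes in arbitrary units.
#'
#' @param times Numeric vector of sampling times (seconds), strictly
#'   increasing, first time >= 0, all finite.
#' @param amplitudes Numeric vector of signal amplitudes (arbitrary units),
#'   same length as `times`, all finite.
#'
#' @return An object of class `"decay_signal"`: a list with elements
#'   `times` and `amplitudes`.
#' @examples
#' s <- decay_signal(times = seq(0, 1, by = 0.1),
#'                   amplitudes = exp(-3 * seq(0, 1, by = 0.1)))
#' s
#' @export
decay_signal <- function(times, amplitudes) {
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes))
    stop_input("`times` and `amplitudes` must have equal length")
  if (length(times) < 2L)
    stop_input("a decay signal needs at least 2 samples")
  if (anyNA(times) || any(!is.finite(times)))
    stop_input("`times` contains non-finite values")
  if (anyNA(amplitudes) || any(!is.finite(amplitudes)))
    stop_input("`amplitudes` contains non-finite values")
  if (any(diff(times) <= 0))
    stop_input("`times` must be strictly increasing")
  if (times[1L] < 0)
    stop_input("the first sampling time must be >= 0")
  structure(list(times = times, amplitudes = amplitudes),
            class = "decay_signal")
}

#' @export
print.decay_signal <- function(x, ...) {
  m <- length(x$times)
  cat(sprintf("Sampled decay signal: %d points, t in [%g, %g] s, A(t_1) = %g\n",
              m, x$times[1L], x$times[m], x$amplitudes[1L]))
  invisible(x)
}

#' @export
as.data.frame.decay_signal <- function(x, ...) {
  data.frame(time = x$times, amplitude = x$amplitudes)
}

# Coerce data.frame / matrix / list inputs to a decay_signal.
as_signal <- function(x) {
  if (inherits(x, "decay_signal")) return(x)
  if (is.data.frame(x) || is.matrix(x)) {
    if (ncol(x) < 2L)
      stop_input("a signal needs two columns: time and amplitude")
    return(decay_signal(x[, 1L], x[, 2L]))
  }
  if (is.list(x) && all(c("times", "amplitudes") %in% names(x)))
    return(decay_signal(x$times, x$amplitudes))
  stop_input("cannot interpret input as a decay signal")
}

# classed conditions so callers (and the CLI) can map errors to exit codes
stop_input <- function(msg, class = "expdecomp_input_error") {
  stop(errorCondition(msg, class = c(class, "expdecomp_error")))
}

stop_format <- function(msg) {
  stop_input(msg, class = "expdecomp_format_error")
}

stop_infeasible <- function(msg) {
  stop_input(msg, class = "expdecomp_infeasible_error")
}
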