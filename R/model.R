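#' Multiexponential decay model
#'
#' Parameter container for a decomposition
#' \eqn{A(t) = \sum_i a_i e^{-k_i t}} with the physical restriction
#' \eqn{a_i > 0}, \eqn{k_i > 0}. Components are stored sorted by decrement
#' descending (fastest first), the convention used throughout the package
#' and in the kinetics literature (\eqn{k_1 > k_2 > \dots > k_n}).
#'
#' @param weights Numeric vector of positive amplitudes (arbitrary units).
#' @param decrements Numeric vector of positive, pairwise distinct decay
#'   rates (s^-1), same length as `weights`. Both may be empty, giving the
#'   zero model.
#'
#' @return An object of class `"decay_model"`: list with `weights` and
#'   `decrements`, sorted by decreasing decrement.
#' @examples
#' m <- decay_model(weights = c(0.59, 0.29, 0.07),
#'                  decrements = c(400, 87, 11))
#' predict(m, c(0, 0.01, 0.1))
#' @export
decay_model <- function(weights = numeric(), decrements = numeric()) {
  weights <- as.numeric(weights)
  decrements <- as.numeric(decrements)
  if (length(weights) != length(decrements))
    stop_input("`weights` and `decrements` must have equal length")
  if (length(weights)) {
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop_input("all weights must be finite and > 0")
    if (any(!is.finite(decrements)) || any(decrements <= 0))
      stop_input("all decrements must be finite and > 0")
    if (anyDuplicated(decrements))
      stop_input("decrements must be pairwise distinct")
    ord <- order(decrements, decreasing = TRUE)
    weights <- weights[ord]
    decrements <- decrements[ord]
  }
  structure(list(weights = weights, decrements = decrements),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  n <- length(x$weights)
  if (n == 0L) {
    cat("Empty decay model (0 components)\n")
  } else {
    cat(sprintf("Decay model with %d component%s:\n", n, if (n > 1L) "s" else ""))
    print(data.frame(weight = x$weights, decrement = x$decrements),
          row.names = paste0("  ", seq_len(n)))
  }
  invisible(x)
}

#' Predict amplitudes from a decay model
#'
#' @param object A [decay_model()].
#' @param times Numeric vector of times (seconds), or a `decay_signal`.
#' @param ... Unused.
#' @return Numeric vector \eqn{\sum_i a_i e^{-k_i t}} at each time.
#' @export
predict.decay_model <- function(object, times, ...) {
  if (inherits(times, "decay_signal")) times <- times$times
  times <- as.numeric(times)
  if (length(object$weights) == 0L) return(numeric(length(times)))
  drop(exp(-outer(times, object$decrements)) %*% object$weights)
}

#' @export
coef.decay_model <- function(object, ...) {
  cbind(weight = object$weights, decrement = object$decrements)
}
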