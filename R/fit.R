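#' Decompose a decay curve into positive exponential components
#'
#' Fits a monotonically decaying kinetic curve as
#' \eqn{A(t) = \sum_{i=1}^n a_i e^{-k_i t}} with \eqn{a_i > 0},
#' \eqn{k_i > 0}, selecting the number of components automatically.
#'
#' The algorithm alternates two reciprocal steps. For a fixed set of
#' decrements the optimal weights are linear: the signal is projected onto
#' the exponential basis by solving the normal equations \eqn{Ga = \beta}
#' of the Gram matrix (see [project_weights()]), so weights are never
#' searched. Decrements are optimized by coordinate descent over a discrete
#' logarithmic candidate grid: each component's decrement in turn is swept
#' over the grid ([sweep_decrement()]) and cycles are repeated until the
#' dispersion — the mean squared residual of the peak-normalized curve —
#' stops changing ([refine_cycle()]). Because single-coordinate moves on a
#' coarse grid can stall inside the coupled decrement valley, every
#' accepted stage is then polished by the same cyclic sweeps on
#' progressively finer local grids (`refine_levels`), down to a decrement
#' resolution of about 0.01% with the defaults. Components are added
#' greedily ([add_component()]); a new component is kept only while it
#' lowers the dispersion by more than `improvement_tol` (relative) and all
#' weights stay positive, which fixes the model order. The fit is fully
#' deterministic given the signal and control settings.
#'
#' The signal is peak-normalized internally (divided by its first
#' amplitude, the maximum of a decaying curve); reported weights are given
#' on both the original and the normalized scale.
#'
#' @param x A `decay_signal`, a two-column data.frame/matrix
#'   (time, amplitude), a formula, or a numeric vector of times (see
#'   methods).
#' @param ... Passed on to methods.
#' @param control An [expdecomp_control()] list of optimizer settings.
#'
#' @return An object of class `"expdecomp"`, a list with components
#' \describe{
#'   \item{model}{the fitted [decay_model()] (original amplitude scale)}
#'   \item{components}{data.frame with `weight` (original units),
#'     `weight_norm` (fraction of the initial amplitude), `weight_pct`
#'     (percent of the summed weights) and `decrement` (s^-1), sorted by
#'     decreasing decrement}
#'   \item{dispersion}{mean squared residual of the normalized curve}
#'   \item{stage_trace}{data.frame of `(n_components, dispersion)` for each
#'     accepted stage (strictly decreasing dispersion)}
#'   \item{residuals, fitted}{on the original amplitude scale}
#'   \item{signal, scale, candidates, control, call}{inputs and settings}
#' }
#' @examples
#' sig <- generate_signal(signal_spec(weights = c(0.7, 0.3),
#'                                    decrements = c(50, 5),
#'                                    t_end = 0.5, dt = 0.001))
#' fit <- expdecomp(sig)
#' fit
#' coef(fit)
#' @seealso [decrement_grid()], [read_signal()], [generate_signal()]
#' @export
expdecomp <- function(x, ...) UseMethod("expdecomp")

#' @rdname expdecomp
#' @param times,amplitudes Numeric vectors (default method).
#' @export
expdecomp.default <- function(x, amplitudes = NULL, ...,
                              control = expdecomp_control()) {
  if (is.null(amplitudes))
    stop_input("supply a decay_signal, a two-column data.frame, or times and amplitudes")
  fit_decay(decay_signal(x, amplitudes), control, match.call())
}

#' @rdname expdecomp
#' @export
expdecomp.decay_signal <- function(x, ..., control = expdecomp_control()) {
  fit_decay(x, control, match.call())
}

#' @rdname expdecomp
#' @export
expdecomp.data.frame <- function(x, ..., control = expdecomp_control()) {
  fit_decay(as_signal(x), control, match.call())
}

#' @rdname expdecomp
#' @param formula A formula `amplitude ~ time`.
#' @param data A data.frame holding the formula's variables.
#' @export
expdecomp.formula <- function(formula, data = parent.frame(), ...,
                              control = expdecomp_control()) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop_input("the formula must have the form amplitude ~ time")
  fit_decay(decay_signal(mf[[2L]], mf[[1L]]), control, match.call())
}

# The greedy fit proper. Works on the raw amplitudes; the dispersion used
# everywhere already carries the peak normalization, so no explicit
# rescaling of the data is needed and weights come out in original units.
fit_decay <- function(signal, control, call = sys.call(-1L)) {
  stopifnot(inherits(control, "expdecomp_control"))
  m <- length(signal$times)
  if (m < 2L * control$max_components + 1L)
    stop_input(sprintf(
      "signal too short: %d samples, need at least 2*max_components+1 = %d",
      m, 2L * control$max_components + 1L))
  y <- signal$amplitudes
  if (y[m] > y[1L])
    warning("signal does not decay overall (last amplitude exceeds the first); the exponential-decay model may be inappropriate")

  candidates <- decrement_grid(signal, control)
  attr(candidates, "basis_cache") <- basis_cache(signal$times, candidates)

  model <- add_component(signal, decay_model(), candidates, control)
  if (!model_feasible(model) || length(model$decrements) == 0L)
    stop_infeasible("no feasible single-component model: no candidate decrement admits a positive weight")
  model <- polish_model(signal, model, control)
  d_cur <- decay_dispersion(signal, model)
  trace_n <- 1L
  trace_d <- d_cur
  improvement_tol <- if (is.null(control$improvement_tol)) 20 / m
  else control$improvement_tol

  while (length(model$decrements) < control$max_components) {
    if (d_cur <= control$dispersion_floor) break
    cand <- add_component(signal, model, candidates, control)
    if (!model_feasible(cand)) break
    cand <- polish_model(signal, cand, control)
    d_new <- decay_dispersion(signal, cand)
    if (!(d_new < d_cur * (1 - improvement_tol)))
      break
    model <- cand
    d_cur <- d_new
    trace_n <- c(trace_n, length(model$decrements))
    trace_d <- c(trace_d, d_cur)
  }

  fitted <- predict(model, signal$times)
  res <- y - fitted
  w <- model$weights
  out <- list(
    model = model,
    components = data.frame(
      weight = w,
      weight_norm = w / y[1L],
      weight_pct = 100 * w / sum(w),
      decrement = model$decrements),
    n_components = length(w),
    dispersion = d_cur,
    residuals = res,
    fitted = fitted,
    stage_trace = data.frame(n_components = trace_n, dispersion = trace_d),
    signal = signal,
    scale = y[1L],
    candidates = as.numeric(candidates),
    control = control,
    call = call)
  class(out) <- "expdecomp"
  out
}
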