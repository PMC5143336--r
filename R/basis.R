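#' Exponential basis on a time grid
#'
#' Evaluates the (generally non-orthogonal) system of decaying exponentials
#' \eqn{\varphi_i(t) = e^{-k_i t}} on a sampling grid. The decay rates
#' \eqn{k_i} ("decrements" in the kinetics literature of photoinduced
#' reactions) must be positive and pairwise distinct, otherwise the system
#' is linearly dependent.
#'
#' @param decrements Numeric vector of decay rates (s^-1), each > 0,
#'   pairwise distinct.
#' @param times Numeric vector of sampling times (seconds), strictly
#'   increasing, first time >= 0. A `decay_signal` may also be given, in
#'   which case its time grid is used.
#'
#' @return An object of class `"exp_basis"`: list with `decrements`,
#'   `times`, and `values`, where `values[i, j] = exp(-decrements[i] *
#'   times[j])` (one row per basis function).
#' @examples
#' b <- exp_basis(c(3, 0.4), seq(0, 5, length.out = 501))
#' dim(b$values)
#' @export
exp_basis <- function(decrements, times) {
  if (inherits(times, "decay_signal")) times <- times$times
  decrements <- as.numeric(decrements)
  times <- as.numeric(times)
  if (length(times) < 1L)
    stop_input("empty time grid")
  if (any(diff(times) <= 0))
    stop_input("`times` must be strictly increasing")
  if (times[1L] < 0)
    stop_input("the first sampling time must be >= 0")
  if (length(decrements) < 1L)
    stop_input("at least one decrement is required")
  if (any(!is.finite(decrements)) || any(decrements <= 0))
    stop_input("all decrements must be finite and > 0")
  if (anyDuplicated(decrements))
    stop_input("decrements must be pairwise distinct (duplicates give a linearly dependent basis)")
  structure(list(decrements = decrements, times = times,
                 values = exp(-outer(decrements, times))),
            class = "exp_basis")
}

#' Gram matrix of an exponential basis
#'
#' Forms the matrix of pairwise discrete inner products
#' \eqn{G_{ij} = \sum_m \varphi_i(t_m)\varphi_j(t_m)} together with the
#' projection vector \eqn{\beta_i = \sum_m x(t_m)\varphi_i(t_m)} when a
#' signal is supplied. The inner product is the plain dot product on the
#' sample grid (no quadrature weights), so solving \eqn{Ga=\beta} is exactly
#' discrete least squares on the grid. A 2-norm condition estimate is
#' attached; near-coincident decrements make `G` near-singular and are
#' detected through it.
#'
#' @param basis An [exp_basis()] object.
#' @param signal Optional `decay_signal` sampled on the same grid as the
#'   basis; if given, `beta` is computed.
#'
#' @return An object of class `"gram_matrix"`: list with `G` (n x n,
#'   symmetric), `beta` (length n, or `NULL`), and `condition` (2-norm
#'   condition estimate of `G`).
#' @export
gram_matrix <- function(basis, signal = NULL) {
  stopifnot(inherits(basis, "exp_basis"))
  Phi <- basis$values                       # n x m
  G <- tcrossprod(Phi)
  G <- (G + t(G)) / 2                       # exact symmetry
  beta <- NULL
  if (!is.null(signal)) {
    signal <- as_signal(signal)
    if (length(signal$times) != length(basis$times) ||
        any(signal$times != basis$times))
      stop_input("signal and basis must share the same time grid")
    beta <- drop(Phi %*% signal$amplitudes)
  }
  structure(list(G = G, beta = beta, condition = kappa(G, exact = TRUE)),
            class = "gram_matrix")
}

#' Reciprocal (biorthogonal) basis
#'
#' Computes \eqn{\Gamma = G^{-1}} and the reciprocal functions
#' \eqn{\theta_j = \sum_k \Gamma_{jk}\varphi_k}, which satisfy
#' \eqn{(\varphi_i, \theta_j) = \delta_{ij}}. Projecting a signal onto the
#' reciprocal basis yields the least-squares weights directly.
#'
#' @param gram A [gram_matrix()] object.
#' @param basis The [exp_basis()] the Gram matrix was built from.
#' @param condition_limit Condition estimate above which the basis is
#'   rejected as ill-conditioned (default `1e12`).
#'
#' @return An object of class `"reciprocal_basis"`: list with `gamma`
#'   (the inverse Gram matrix) and `theta` (matrix of reciprocal-function
#'   values, same layout as `basis$values`).
#' @export
reciprocal_basis <- function(gram, basis, condition_limit = 1e12) {
  stopifnot(inherits(gram, "gram_matrix"), inherits(basis, "exp_basis"))
  if (!is.finite(gram$condition) || gram$condition > condition_limit)
    stop_input(sprintf(
      "Gram matrix is ill-conditioned (condition estimate %.3g > %.3g)",
      gram$condition, condition_limit), class = "expdecomp_illconditioned_error")
  R <- tryCatch(chol(gram$G), error = function(e)
    stop_input("Gram matrix is not positive definite",
               class = "expdecomp_illconditioned_error"))
  gamma <- chol2inv(R)
  structure(list(gamma = gamma, theta = gamma %*% basis$values),
            class = "reciprocal_basis")
}

#' Project a signal onto an exponential basis
#'
#' Solves the normal equations \eqn{Ga=\beta} of the sampled signal against
#' the basis through a Cholesky factorization of the Gram matrix. The
#' result is the unconstrained least-squares weight vector: the residual is
#' orthogonal (discrete inner product) to every basis function. Signs are
#' unconstrained at this layer; positivity is enforced by the optimizer.
#'
#' @param signal A `decay_signal` (or two-column data.frame) on the same
#'   grid as the basis.
#' @param basis An [exp_basis()] object.
#' @param condition_limit Passed to [reciprocal_basis()].
#'
#' @return Numeric weight vector, one entry per basis function.
#' @examples
#' t <- seq(0, 5, length.out = 501)
#' s <- decay_signal(t, 2 * exp(-3 * t) + 0.5 * exp(-0.4 * t))
#' project_weights(s, exp_basis(c(3, 0.4), t))
#' @export
project_weights <- function(signal, basis, condition_limit = 1e12) {
  signal <- as_signal(signal)
  gram <- gram_matrix(basis, signal)
  if (!is.finite(gram$condition) || gram$condition > condition_limit)
    stop_input(sprintf(
      "Gram matrix is ill-conditioned (condition estimate %.3g > %.3g)",
      gram$condition, condition_limit), class = "expdecomp_illconditioned_error")
  R <- tryCatch(chol(gram$G), error = function(e)
    stop_input("Gram matrix is not positive definite",
               class = "expdecomp_illconditioned_error"))
  drop(backsolve(R, backsolve(R, gram$beta, transpose = TRUE)))
}

#' Dispersion of a decomposition
#'
#' The objective function of the decomposition: the mean squared residual
#' between the signal and the model prediction after peak normalization
#' (amplitudes divided by the amplitude at the first time point, which is
#' the maximum of a decaying curve). It is 0 exactly when the model
#' reproduces the signal, and for additive Gaussian noise of standard
#' deviation \eqn{\sigma} on the normalized scale the dispersion of the
#' true model approaches \eqn{\sigma^2}.
#'
#' @param signal A `decay_signal`.
#' @param model A [decay_model()] (possibly empty) with weights on the
#'   signal's original amplitude scale.
#'
#' @return A single nonnegative number.
#' @export
decay_dispersion <- function(signal, model) {
  signal <- as_signal(signal)
  pred <- predict(model, signal$times)
  mean(((signal$amplitudes - pred) / signal$amplitudes[1L])^2)
}
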