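#' Specification of a synthetic multiexponential decay
#'
#' Describes a forward-generated signal
#' \eqn{A(t_j) = \mathrm{scale}\sum_i a_i e^{-k_i t_j} + \varepsilon_j}
#' with \eqn{\varepsilon_j \sim N(0, (\mathrm{noise\_sd}\cdot
#' \mathrm{scale})^2)} i.i.d. Weights are fractions of the nominal initial
#' amplitude `scale`; they need not sum to 1.
#'
#' @param weights Positive component weights (fractions of `scale`).
#' @param decrements Positive, pairwise distinct decay rates (s^-1).
#' @param t_start,t_end Time range in seconds (`t_start` defaults to 0).
#' @param dt Sampling step in seconds, > 0.
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   `scale` (default 0, noiseless).
#' @param seed Integer RNG seed for reproducible noise, or `NULL`.
#' @param scale Nominal initial amplitude in arbitrary units (default 1).
#'
#' @return A list of class `"signal_spec"`.
#' @examples
#' signal_spec(weights = c(0.7, 0.3), decrements = c(50, 5),
#'             t_end = 0.5, dt = 0.001, noise_sd = 0.01, seed = 1)
#' @export
signal_spec <- function(weights, decrements, t_start = 0, t_end, dt,
                        noise_sd = 0, seed = NULL, scale = 1) {
  model <- decay_model(weights * scale, decrements)  # validates positivity
  if (!is.finite(dt) || dt <= 0)
    stop_input("`dt` must be > 0")
  if (!is.finite(t_end) || t_end <= t_start)
    stop_input("`t_end` must exceed `t_start`")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_input("`noise_sd` must be >= 0")
  if (!is.finite(scale) || scale <= 0)
    stop_input("`scale` must be > 0")
  structure(list(weights = model$weights / scale,
                 decrements = model$decrements,
                 t_start = t_start, t_end = t_end, dt = dt,
                 noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 scale = scale),
            class = "signal_spec")
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic decay spec: %d components, t in [%g, %g] s, dt = %g s,\n  noise sd = %g x scale, scale = %g, seed = %s\n",
    length(x$weights), x$t_start, x$t_end, x$dt, x$noise_sd, x$scale,
    if (is.null(x$seed)) "none" else x$seed))
  print(data.frame(weight = x$weights, decrement = x$decrements),
        row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic decay signal
#'
#' Evaluates the spec's multiexponential sum on its time grid and adds
#' reproducible Gaussian noise. The same spec and seed always yield the
#' identical signal; the caller's RNG state is left untouched.
#'
#' @param spec A [signal_spec()].
#' @param noise_sd,seed Optional overrides of the spec's values.
#' @return A [decay_signal()] with the spec attached as attribute
#'   `"spec"`.
#' @export
generate_signal <- function(spec, noise_sd = NULL, seed = NULL) {
  if (!inherits(spec, "signal_spec"))
    stop_input("`spec` must be a signal_spec")
  if (!is.null(noise_sd) || !is.null(seed))
    spec <- signal_spec(spec$weights, spec$decrements, spec$t_start,
                        spec$t_end, spec$dt,
                        noise_sd = if (is.null(noise_sd)) spec$noise_sd else noise_sd,
                        seed = if (is.null(seed)) spec$seed else seed,
                        scale = spec$scale)
  times <- seq(spec$t_start, spec$t_end, by = spec$dt)
  clean <- spec$scale *
    drop(exp(-outer(times, spec$decrements)) %*% spec$weights)
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
      stats::rnorm(length(times), sd = spec$noise_sd * spec$scale))
    amps <- clean + noise
  } else {
    amps <- clean
  }
  out <- decay_signal(times, amps)
  attr(out, "spec") <- spec
  out
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Published wheat-genotype fluorescence parameter sets
#'
#' Reference three-component decompositions of chlorophyll fluorescence
#' induction decays reported for leaves of four winter-wheat genotypes
#' (Pdl, Per, Ods, Dos), with electron transport blocked so the decay
#' reflects antenna energy transfer. Weights are the published percentage
#' contributions expressed as fractions of the initial amplitude (kept
#' verbatim; because of rounding in the source they do not sum exactly
#' to 1), decrements in s^-1. The default grid, t in [0, 0.5] s with
#' dt = 0.25 ms, resolves the fastest published rate (400 s^-1, lifetime
#' 2.5 ms) and covers more than five lifetimes of the slowest (5 s^-1).
#'
#' @param genotype One of `"Pdl"`, `"Per"`, `"Ods"`, `"Dos"`.
#' @return A noiseless [signal_spec()] with the genotype's parameters;
#'   pass `noise_sd`/`seed` overrides to [generate_signal()] to add noise.
#' @examples
#' wheat_genotype_spec("Pdl")$decrements   # 400 87 11
#' @export
wheat_genotype_spec <- function(genotype) {
  params <- list(
    Pdl = list(w = c(0.59, 0.29, 0.07), k = c(400, 87, 11)),
    Per = list(w = c(0.67, 0.23, 0.03), k = c(300, 57, 5)),
    Ods = list(w = c(0.67, 0.22, 0.04), k = c(300, 66, 12)),
    Dos = list(w = c(0.77, 0.22, 0.04), k = c(370, 71, 13)))
  if (length(genotype) != 1L || !genotype %in% names(params))
    stop_input(sprintf("unknown genotype %s: expected one of %s",
                       deparse(genotype),
                       paste(names(params), collapse = ", ")))
  p <- params[[genotype]]
  signal_spec(weights = p$w, decrements = p$k,
              t_start = 0, t_end = 0.5, dt = 0.00025)
}
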