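# Independent oracles and generators used across the suite.

# Brute-force least squares via QR on the design matrix (independent of the
# package's Gram/Cholesky path).
qr_weights <- function(times, amplitudes, decrements) {
  qr.solve(exp(-outer(times, decrements)), amplitudes)
}

# Dispersion of an arbitrary decrement set, computed from scratch with the
# QR oracle (no package optimizer code).
oracle_dispersion <- function(times, amplitudes, decrements) {
  Phi <- exp(-outer(times, decrements))
  a <- tryCatch(qr.solve(Phi, amplitudes), error = function(e) NULL)
  if (is.null(a) || any(!is.finite(a)) || any(a <= 0)) return(Inf)
  mean(((amplitudes - drop(Phi %*% a)) / amplitudes[1])^2)
}

# Exhaustive joint grid search over all n-subsets of the candidate array,
# with the positivity rule applied; returns the argmin decrements and the
# minimal dispersion.
joint_grid_oracle <- function(times, amplitudes, candidates, n) {
  combos <- utils::combn(sort(candidates), n)
  best_d <- Inf
  best_k <- NULL
  for (j in seq_len(ncol(combos))) {
    d <- oracle_dispersion(times, amplitudes, combos[, j])
    if (d < best_d) {
      best_d <- d
      best_k <- combos[, j]
    }
  }
  list(decrements = sort(best_k, decreasing = TRUE), dispersion = best_d)
}

# A random well-separated positive decomposition: adjacent decrement ratios
# >= 4.5, every weight >= 7% of the total.
random_sep_model <- function(n) {
  k1 <- 10^runif(1, 1, 2.5)
  ratios <- runif(max(0, n - 1), 4.5, 8)
  k <- k1 / cumprod(c(1, ratios))
  w <- runif(n, 0.15, 1)
  decay_model(w / sum(w), k)
}

# Sample a model on a grid resolving its fastest and slowest rates.
signal_from_model <- function(model, points = 400, noise_sd = 0) {
  k_fast <- max(model$decrements)
  k_slow <- min(model$decrements)
  times <- seq(0, 4 / k_slow, length.out = points)
  amps <- predict(model, times)
  if (noise_sd > 0) amps <- amps + rnorm(points, sd = noise_sd * amps[1])
  decay_signal(times, amps)
}

# A candidate grid guaranteed to contain the model's decrements exactly.
grid_including <- function(model, per_decade = 12) {
  k <- model$decrements
  base <- 10^seq(log10(min(k)) - 0.5, log10(max(k)) + 0.5,
                 by = 1 / per_decade)
  sort(unique(c(base, k)))
}
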