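coarse_control <- function(...) {
  expdecomp_control(refine_levels = 0, ...)
}

test_that("default decrement grid is derived from the sampling grid", {
  t <- seq(0, 1, by = 0.001)
  s <- decay_signal(t, exp(-5 * t))
  g <- decrement_grid(s)
  expect_equal(range(g), c(0.1, 2000))
  expect_true(all(diff(g) > 0))

  g1 <- decrement_grid(s, expdecomp_control(k_min = 1, k_max = 10,
                                            points_per_decade = 1))
  expect_equal(g1, c(1, 10))

  expect_error(decrement_grid(s, expdecomp_control(k_min = 5, k_max = 5)),
               "less than")
  expect_error(decay_signal(0, 1), "at least 2")
})

test_that("a sweep picks the zero-residual candidate and is idempotent", {
  t <- seq(0, 2, by = 0.01)
  s <- decay_signal(t, 3 * exp(-4 * t))
  cand <- 10^seq(-1, 2, by = 0.05)
  cand <- sort(unique(c(cand, 4)))        # true decrement on the grid
  start <- decay_model(1, 0.5)
  swept <- sweep_decrement(s, start, 1, cand)
  expect_equal(swept$decrements, 4)
  expect_equal(swept$weights, 3, tolerance = 1e-10)
  again <- sweep_decrement(s, swept, 1, cand)
  expect_equal(again$decrements, swept$decrements)
  expect_equal(again$weights, swept$weights)
  expect_error(sweep_decrement(s, start, 3, cand), "out of range")
})

test_that("a sweep agrees with exhaustive candidate evaluation", {
  set.seed(5)
  for (i in 1:10) {
    m <- random_sep_model(2)
    sig <- signal_from_model(m, noise_sd = 0.01)
    cand <- grid_including(m)
    # sweep the fast component with the slow one fixed at truth
    start <- decay_model(m$weights, m$decrements)
    swept <- sweep_decrement(sig, start, 1, cand)
    d_all <- vapply(cand, function(k) {
      if (k == m$decrements[2]) return(Inf)
      oracle_dispersion(sig$times, sig$amplitudes, c(k, m$decrements[2]))
    }, numeric(1))
    expect_equal(swept$decrements[1], cand[which.min(d_all)])
  }
})

test_that("cyclic refinement never increases dispersion and recovers on-grid truths", {
  set.seed(17)
  for (i in 1:25) {
    m <- random_sep_model(2)
    sig <- signal_from_model(m, noise_sd = 0.005)
    cand <- grid_including(m)
    start <- decay_model(rev(m$weights), m$decrements * c(1.6, 0.7))
    ctl <- coarse_control(max_sweeps = 1)
    d <- decay_dispersion(sig, start)
    model <- start
    for (cycle in 1:8) {
      model <- refine_cycle(sig, model, cand, ctl)
      d_new <- decay_dispersion(sig, model)
      expect_lte(d_new, d + 1e-15)
      d <- d_new
    }
  }

  # noiseless two-component signal with both decrements on the grid
  m <- decay_model(c(0.7, 0.3), c(40, 5))
  sig <- signal_from_model(m)
  cand <- grid_including(m)
  start <- decay_model(c(0.5, 0.5), c(60, 3))
  refined <- refine_cycle(sig, start, cand, coarse_control())
  expect_equal(refined$decrements, c(40, 5))
  expect_equal(refined$weights, c(0.7, 0.3), tolerance = 1e-8)

  # a model already at a coordinate-wise minimum returns unchanged
  again <- refine_cycle(sig, refined, cand, coarse_control())
  expect_equal(again$decrements, refined$decrements)
})

test_that("adding a component lowers dispersion when structure remains and respects the cap", {
  m <- decay_model(c(0.6, 0.4), c(50, 4))
  sig <- signal_from_model(m)
  cand <- grid_including(m)
  ctl <- coarse_control()
  one <- add_component(sig, decay_model(), cand, ctl)
  expect_equal(length(one$decrements), 1L)
  two <- add_component(sig, one, cand, ctl)
  expect_lt(decay_dispersion(sig, two), decay_dispersion(sig, one))
  expect_equal(two$decrements, c(50, 4))

  capped <- coarse_control(max_components = 1)
  expect_error(add_component(sig, one, cand, capped), "cap")
})

test_that("the full fit recovers noiseless signals and selects the true order", {
  # single exponential: n = 1, near-exact parameters after polishing
  t <- seq(0, 1, by = 0.002)
  s1 <- decay_signal(t, 2.5 * exp(-6 * t))
  f1 <- expdecomp(s1)
  expect_equal(f1$n_components, 1L)
  expect_equal(f1$components$decrement, 6, tolerance = 1e-3)
  expect_equal(f1$components$weight, 2.5, tolerance = 1e-3)

  # published wheat parameter sets, noiseless: n = 3 and close recovery
  for (g in c("Pdl", "Dos")) {
    spec <- wheat_genotype_spec(g)
    sig <- generate_signal(spec)
    f <- expdecomp(sig)
    expect_equal(f$n_components, 3L)
    expect_equal(f$components$decrement, spec$decrements, tolerance = 0.01)
    expect_equal(f$components$weight, spec$weights, tolerance = 0.01)
    # reported dispersion matches an independent recomputation
    expect_equal(f$dispersion, decay_dispersion(sig, f$model),
                 tolerance = 1e-12)
  }
})

test_that("the greedy fit matches or beats the exhaustive joint-grid search", {
  # noiseless problems with both decrements on the candidate grid: the
  # greedy fit must find the same (zero-residual) argmin pair as the
  # exhaustive search over all candidate pairs
  set.seed(61)
  for (i in 1:4) {
    ctl <- expdecomp_control(k_min = 1, k_max = 1000, max_components = 2)
    base <- 10^seq(0, 3, by = 1 / 50)
    idx <- sort(sample(seq_along(base), 2))
    while (base[idx[2]] / base[idx[1]] < 4.5)
      idx <- sort(sample(seq_along(base), 2))
    m <- decay_model(sort(runif(2, 0.3, 1), decreasing = TRUE),
                     base[rev(idx)])
    sig <- signal_from_model(m, points = 250)
    f <- expdecomp(sig, control = ctl)
    oracle <- joint_grid_oracle(sig$times, sig$amplitudes, f$candidates, 2)
    expect_equal(f$components$decrement, oracle$decrements,
                 tolerance = 1e-4)
    expect_lt(f$dispersion, 1e-15)
  }

  # with noise the two discrete optimizers can settle one grid cell apart,
  # but the fit must never end up above the exhaustive joint-grid minimum
  set.seed(23)
  for (i in 1:8) {
    m <- random_sep_model(2)
    sig <- signal_from_model(m, points = 250, noise_sd = 0.005)
    ctl <- expdecomp_control(points_per_decade = 12,
                             k_min = min(m$decrements) / 5,
                             k_max = max(m$decrements) * 5,
                             max_components = 2)
    f <- expdecomp(sig, control = ctl)
    oracle <- joint_grid_oracle(sig$times, sig$amplitudes, f$candidates, 2)
    expect_lte(f$dispersion, oracle$dispersion * (1 + 1e-9))
  }
})

test_that("every fitted model is strictly positive with a strictly decreasing stage trace", {
  set.seed(31)
  for (i in 1:12) {
    m <- random_sep_model(sample(1:3, 1))
    sig <- signal_from_model(m, points = 300, noise_sd = 0.01)
    f <- expdecomp(sig, control = expdecomp_control(points_per_decade = 20))
    expect_true(all(f$components$weight > 0))
    expect_true(all(f$components$decrement > 0))
    expect_true(all(diff(f$components$decrement) < 0))
    expect_true(all(diff(f$stage_trace$dispersion) < 0))
  }
})

test_that("noiseless separated components are recovered across 50 seeded draws", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(2:3, 1)
    m <- random_sep_model(n)
    sig <- signal_from_model(m, points = 600)
    f <- expdecomp(sig)
    expect_equal(f$n_components, n)
    expect_equal(f$components$decrement, m$decrements, tolerance = 0.02)
    expect_equal(f$components$weight, m$weights, tolerance = 0.01)
  }
})

test_that("the stopping rule selects the generating order under 1% noise across 50 seeded draws", {
  set.seed(202)
  correct <- 0L
  for (i in 1:50) {
    n <- sample(2:3, 1)
    m <- random_sep_model(n)
    sig <- signal_from_model(m, points = 600, noise_sd = 0.01)
    f <- expdecomp(sig)
    correct <- correct + (f$n_components == n)
  }
  expect_gte(correct, 45L)   # >= 90% of the draws
})

test_that("the polished fit agrees with a continuous Levenberg-Marquardt refit", {
  library(minpack.lm)
  lm_refit <- function(sig, start_w, start_k) {
    df <- as.data.frame(sig)
    fm <- nlsLM(amplitude ~ a1 * exp(-k1 * time) + a2 * exp(-k2 * time),
                data = df,
                start = list(a1 = start_w[1], k1 = start_k[1],
                             a2 = start_w[2], k2 = start_k[2]),
                control = nls.lm.control(maxiter = 200))
    coef(fm)[c("k1", "k2")]
  }
  set.seed(55)
  for (noise in c(0, 0.005)) {
    m <- decay_model(c(0.65, 0.35), c(120, 9))
    sig <- signal_from_model(m, points = 800, noise_sd = noise)
    f <- expdecomp(sig)
    k_lm <- lm_refit(sig, m$weights, m$decrements)
    expect_equal(f$components$decrement, unname(k_lm), tolerance = 1e-3)
  }
})

test_that("an all-negative signal has no feasible model and a short signal is rejected", {
  t <- seq(0, 1, by = 0.01)
  s <- decay_signal(t, -exp(-2 * t))
  suppressWarnings(
    expect_error(expdecomp(s), class = "expdecomp_infeasible_error"))

  short <- decay_signal(c(0, 1, 2), c(3, 2, 1))
  expect_error(expdecomp(short), "too short")
  expect_error(expdecomp_control(max_components = 8), "between 1 and 7")
  expect_error(expdecomp_control(max_components = 0), "between 1 and 7")
})
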