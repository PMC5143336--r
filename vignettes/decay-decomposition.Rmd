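---
title: "Decomposing decay kinetics into positive exponential components"
author: "expdecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing decay kinetics into positive exponential components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expdecomp)
```

## The model and its assumptions

A decaying kinetic record — reaction-center absorption recovery after a
light pulse, or chlorophyll fluorescence induction with electron transport
blocked — is modelled as a finite sum of monoexponential relaxations,

$$A(t) = \sum_{i=1}^{n} a_i e^{-k_i t}, \qquad a_i > 0, \; k_i > 0,$$

where each component is read as the relaxation of one conformational
state or antenna subpopulation. The assumptions this encodes:

* the signal decays to zero (no constant offset term — a dark baseline
  must be subtracted beforehand);
* all component amplitudes are positive (subpopulations add, they do not
  cancel), so the amplitude decreases monotonically in time;
* rates are real (no damped oscillations);
* the number of components is small — at most 7 here.

Fitting sums of exponentials is a classically ill-posed separable
nonlinear least-squares problem: nearby decrements produce nearly
collinear basis functions, and the residual surface along each decrement
is shallow. The method below is built around those facts.

## The two reciprocal steps

**Step 1 — weights by projection.** For a *fixed* decrement set, the
exponentials $\varphi_i(t) = e^{-k_i t}$ evaluated on the sampling grid
span a linear space, and the best approximation of the signal $x$ in that
space solves the normal equations of the Gram matrix,

$$G a = \beta, \qquad G_{ij} = (\varphi_i, \varphi_j), \quad
\beta_i = (x, \varphi_i).$$

Equivalently, with the reciprocal (biorthogonal) basis
$\theta_j = \sum_k \Gamma_{jk}\varphi_k$, $\Gamma = G^{-1}$, the weights
are direct projections $a_i = (x, \theta_i)$. The package solves
$Ga=\beta$ by a Cholesky factorization (mathematically identical to the
explicit inverse, numerically stabler); `reciprocal_basis()` exposes the
$\Gamma$/$\theta$ construction and its biorthogonality
$(\varphi_i,\theta_j)=\delta_{ij}$ for inspection. Weights are never part
of the nonlinear search.

The inner product is the plain discrete dot product on the sample grid —
no quadrature weights. The projection is then *exactly* discrete least
squares on the sampled data, which is what a fit to a sampled record
should minimize; on a uniform grid a trapezoid rule would differ only by
a constant factor that cancels in $Ga=\beta$. This also keeps the package
testable against an independent QR least-squares oracle to machine
precision.

**Step 2 — decrements by discrete coordinate descent.** Candidate
decrements form a log-spaced array. One component at a time, the
candidate minimizing the dispersion (all weights re-projected at each
trial) replaces the component's decrement; components are swept
cyclically until a full cycle no longer changes the dispersion. A new
component is introduced by sweeping its decrement with the existing ones
fixed, after which the full cycle revisits every component.

Two feasibility rules apply to every trial: a candidate set whose Gram
condition estimate exceeds `condition_limit` (default $10^{12}$) and a
projection with any non-positive weight are both treated as infinite
dispersion. This keeps the sweep total (no mid-sweep exceptions) and
enforces $a_i>0$ sharply while leaving the linear solve unconstrained.
Ties between candidates go to the smaller decrement (the scan is
ascending), and a candidate equal to another component's current
decrement is skipped — the basis would be singular. The component's
current decrement always competes in its own sweep, so a sweep can never
increase the dispersion; this makes the monotonicity of the whole
procedure unconditional.

## The objective

The *dispersion* is the mean squared residual of the peak-normalized
curve: amplitudes are referred to the first sample (the maximum of a
decaying record), so

$$D = \frac{1}{N}\sum_j \left(\frac{x(t_j) - A(t_j)}{x(t_1)}\right)^2 .$$

The normalization makes $D$ comparable across records in arbitrary units:
for additive noise of standard deviation $\sigma$ (as a fraction of the
initial amplitude) the dispersion of the true model converges to
$\sigma^2$. Whether such an objective is called MSE, RMSE or residual
variance changes nothing about the minimizer; the package reports $D$ and
`summary()` additionally prints $\sqrt{D}$.

## The candidate grid and the multiresolution polish

The default grid is logarithmic with 50 points per decade between
$k_{\min} = 0.1/(t_{\text{last}} - t_{\text{first}})$ (a component losing
only 10% over the record is indistinguishable from a baseline) and
$k_{\max} = 2/\min \Delta t$ (faster components have decayed within half
a sampling step). Log spacing matches the multi-decade spread of rates in
these systems; both bounds and the density are user-settable.

A 50/decade grid has a 4.7% step — too coarse on its own for the final
parameters, and single-coordinate moves on a coarse grid can stall at a
*coordinate-wise* minimum of the strongly coupled decrement valley (each
decrement conditionally optimal, a joint move still improving). After
every accepted stage the fit therefore re-runs the same cyclic sweeps on
local log-spaced grids centred on the current decrements, shrinking the
step by `refine_subdiv` (default 8) per level for `refine_levels`
(default 3) levels, down to ~0.01% resolution. The local grid is rebuilt
around the current position after every cycle, so the window *walks* with
the descent instead of pinning it to its initial neighbourhood; with a
static window the descent demonstrably sticks at the window edge. On
noiseless in-span test problems the polished fit agrees with an
independent continuous Levenberg–Marquardt refit
(`minpack.lm::nlsLM`) to well under 0.1%.

Setting `refine_levels = 0` recovers the pure single-grid algorithm; the
test suite uses that mode when comparing the discrete core against an
exhaustive joint-grid search. The comparison is deliberately phrased as
"never worse than brute force": cyclic one-coordinate descent terminates
at coordinate-wise minima which, on coarse grids, differ from the joint
argmin for a substantial fraction of random two-component problems (we
verified the end points are true conditional argmins with an independent
oracle). Exact argmin agreement is asserted only where the algorithm can
deliver it — noiseless problems with on-grid decrements at the default
density — while under noise the polished fit is required to match or beat
the exhaustive joint-grid minimum.

## Selecting the number of components

Components are added greedily and stage $n{+}1$ is kept only if

* its dispersion improves on stage $n$ by more than `improvement_tol`
  (relative), **and**
* stage $n$'s dispersion is still above `dispersion_floor`.

`improvement_tol` defaults to $20/N$ for a record of $N$ samples. A
spurious component fitting pure noise reduces the residual mean square by
roughly $\chi^2_2/N$ in relative terms; maximizing that harvest over the
whole candidate grid inflates it, and $20/N$ bounds the inflated tail
with a comfortable margin. Genuine kinetic components in this problem
family contribute relative improvements of 0.1–1 — two to three orders
above the threshold — so the rule is insensitive to its exact value
(anything within roughly a decade behaves identically). A fixed small
tolerance, by contrast, over-selects on short records.

`dispersion_floor` (default $10^{-8}$, i.e. an RMS residual of $10^{-4}$
of the peak) stops the greedy loop once the fit is exact to far beyond
any photometric measurement precision. It exists because the *relative*
rule degenerates on noiseless signals: once the residual is negligible, a
near-duplicate decrement pair can still cut it by orders of magnitude,
and without an absolute floor the fit would happily split true components
into pairs 0.01% apart.

The fit is fully deterministic given the signal and settings; the stage
trace `(n, dispersion)` is stored in the result so the greedy path can be
audited.

## The synthetic generator

`signal_spec()`/`generate_signal()` evaluate the forward model on a
uniform grid and add i.i.d. Gaussian noise with standard deviation given
as a fraction of the nominal initial amplitude — the simplest model
consistent with photometric detection noise, and the model against which
the recovery properties are defined. `wheat_genotype_spec()` provides the
published three-component parameter sets for the four winter-wheat
genotypes (Pdl, Per, Ods, Dos), with weights kept verbatim as printed
(they do not sum exactly to 1 because the source rounds to integer
percent; the parameter-table writer instead reports percents of the
summed weights, so its percent column differs from the published one by
that renormalization). Their default grid — 0 to 0.5 s every 0.25 ms —
resolves the fastest published rate (400 s⁻¹, lifetime 2.5 ms) and covers
more than five lifetimes of the slowest (5 s⁻¹).

What the generator does *not* emulate: the physics of fluorescence
induction (OJIP transients), photocycle saturation, multiplicative or
Poisson detection noise, baseline drift, and correlated noise. Passing
the recovery suites therefore demonstrates the estimator's behaviour
under clean additive-Gaussian conditions, not robustness to instrument
systematics; on real records the monotonicity check in `read_signal()`
and the residual structure in `plot(fit)` are the first diagnostics to
consult.

## Numerical choices and degenerate inputs

* Gram matrices are symmetrized exactly (`(G + t(G))/2`) and factorized
  by Cholesky; the condition estimate is the exact 2-norm ratio of
  singular values.
* Signals must have strictly increasing times, at least
  `2 * max_components + 1` samples at fit time, and finite values; an
  overall non-decaying signal triggers a warning (the model cannot
  represent it), and a signal with no feasible single-component fit (for
  example, a negative record) is an error, not a silent zero-component
  result.
* Refinement stops on relative dispersion change below `refine_tol`
  (default $10^{-8}$) or `max_sweeps` cycles (default 100); polish levels
  additionally stop when the decrements move by less than half a grid
  step.
* Reported weights are given in original amplitude units, as fractions of
  the initial amplitude, and as percents of the summed weights.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data built at test time: records of
150–2001 samples, one to three components separated by at least a factor
4.5 with every weight at least 7% of the total, noise between 0 and 1% of
the initial amplitude, and seeded draws throughout (50-draw recovery and
order-selection families, a 100-draw monotonicity family, 1000 random
bases for the projection oracle). These sizes keep the full suite at a
few minutes on one core while leaving each property's sampling error far
below its assertion margin.

## Known limitations

* Cyclic one-coordinate descent offers no global-optimality guarantee;
  the stage trace is recorded precisely so that the path can be
  inspected. The polish reliably reaches the continuous optimum when the
  base grid is fine enough to place the descent in the right valley —
  the default density is chosen for that — but drastically coarse grids
  can park the fit in a coordinate-wise minimum.
* Rates closer than about a factor 2 are near-degenerate at realistic
  noise levels; the conditioning guard rejects them rather than
  returning meaningless split components.
* No uncertainty estimates are produced for $(a_i, k_i)$; the dispersion
  and residuals are the only goodness measures.
* No baseline/offset term: records must decay toward zero, and
  preprocessing must remove any dark level.
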