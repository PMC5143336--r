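# expdecomp

Decomposition of monotonically decaying kinetic curves into a sum of
positive exponential components, with automatic selection of the number of
components.

## The problem

The basic reaction kinetics of biological macromolecules — the recovery of
reaction-center (RC) absorption in purple bacteria after switching off
actinic light, or the decay of chlorophyll fluorescence induction in
thylakoid grana with electron transport blocked — is multiexponential: the
measured curve is a superposition of monoexponential relaxations of
distinct conformational or antenna subsystems. Identifying those
components means fitting

    A(t) = sum_{i=1..n} a_i * exp(-k_i * t),    a_i > 0,  k_i > 0,

where the *decrements* k_i (rate constants, s⁻¹) and *weights* a_i are
unknown, and so is the number of components n. This is a notoriously
ill-conditioned separable nonlinear least-squares problem. The package is
aimed at biophysicists analyzing such records: it reads a two-column
(time, amplitude) text signal, decomposes it, and writes the fitted
parameter table and the approximation curve.

## The method

The fit alternates two reciprocal steps:

1. **Weights are linear.** For a fixed set of decrements, the exponentials
   φ_i(t) = exp(-k_i t) form a (non-orthogonal) basis on the sampling
   grid. The Gram matrix G of their pairwise inner products links the
   signal to the optimal weights through the normal equations `G a = β`,
   with β_i = (x, φ_i); equivalently the weights are the projections of
   the signal on the reciprocal (biorthogonal) basis θ_j defined by
   Γ G = I. Weights are therefore never searched.
2. **Decrements by discrete coordinate descent.** Candidate decrements
   form a logarithmic grid spanning every rate the sampling can resolve.
   One component's decrement at a time is swept over the grid (with all
   weights re-projected at every candidate), components are swept
   cyclically until the dispersion — the mean squared residual of the
   peak-normalized curve — stops changing, and each accepted stage is
   polished on progressively finer local grids. Candidates that give any
   non-positive weight or a near-singular Gram matrix are infeasible.

Components are added greedily: a new component is kept only while it
lowers the dispersion by a significant relative margin (default 20/N for N
samples) and the fit has not already reached the measurement-precision
floor. The selected order is the last accepted stage.

## Worked example

Generate a synthetic fluorescence-induction decay from the published Pdl
winter-wheat parameter set (weights 0.59/0.29/0.07 of the initial
amplitude, decrements 400/87/11 s⁻¹; 0–0.5 s sampled every 0.25 ms), add
0.5% Gaussian noise, and decompose it:

```r
library(expdecomp)
sig <- generate_signal(wheat_genotype_spec("Pdl"), noise_sd = 0.005, seed = 7)
fit <- expdecomp(sig, control = expdecomp_control(max_components = 3))
fit
#> Multiexponential decay decomposition
#> Call: expdecomp.decay_signal(x = sig, control = expdecomp_control(max_components = 3))
#>
#> Components selected: 3   dispersion (normalized MSE): 2.7082e-05
#>
#>   weight weight_norm weight_pct decrement
#>  0.59633     0.62024         63    388.88
#>  0.28190     0.29321         30     85.02
#>  0.06998     0.07279          7     11.07
```

The three generating decrements are recovered to within 2.8% (388.9 vs
400, 85.0 vs 87, 11.07 vs 11 s⁻¹) and the weights to within about 3% of
their true values; the dispersion 2.7e-05 is the squared noise level of
the record (normalized RMSE 0.0052 against the injected 0.005).
`summary(fit)` additionally prints the greedy stage trace — here
4.64e-04 → 5.23e-05 → 2.71e-05 for one, two and three components — whose
sharp drop and subsequent flattening is what fixes the model order.
`plot(fit)` overlays signal, fit and components; `write_parameters()` and
`write_approximation()` produce the two standard text outputs.

The same operations are available from a shell:

```sh
Rscript exec/expdecomp.R generate --genotype Pdl --noise-sd 0.005 --seed 7 --out pdl.txt
Rscript exec/expdecomp.R fit --input pdl.txt --max-components 3 --save-approx
```

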