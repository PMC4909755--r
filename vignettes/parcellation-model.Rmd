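---
title: "Methods: fragmentation models, mu inference and connectome scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmentation models, mu inference and connectome scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainparc)
```

## The fragmentation model

A brain is modelled as a set of parcellation units (PUs), each carrying
only a volume. Evolution proceeds by binary fragmentation: starting from a
single root region, at every step one current region is selected with
probability proportional to `volume^mu` (normalized over all current
regions, recomputed in full at every step) and split in two. Each split
conserves volume: with parent volume `v` and a noise draw
`r ~ Normal(1, noise_sd)`, the children get `v*r/2` and `v*(2-r)/2`. The
second child's volume is computed as `v - child1` so the sum is conserved
to machine precision, and a run's leaf volumes always sum to the root
volume within 1e-9 relative error.

Assumptions worth making explicit:

* **Binary splits only.** Multi-way branch points in real atlases are read
  as a series of binary splits at different times; the readers accept
  non-binary tables (and flag them) because all statistics use leaves only.
* **No growth between splits.** Volumes change only at split events; there
  is no spatial embedding, only sizes.
* **One RNG stream.** Leaf selection and split noise are drawn from a
  single seeded stream in a fixed order (selection first, then noise), so
  a run is bit-reproducible from its seed.

### Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `mu` | selection bias exponent (dimensionless) | — | the quantity under study; 0 = uniform model |
| `n_target` / `n_pu` | number of leaf regions; also the evolutionary time `t = N_PU` | — | set by the data being emulated (e.g. 91 macaque cortical areas) |
| `noise_sd` | sd of the multiplicative split noise | 0.10 | splits are near-equal with 10% dispersion, so leaf volumes are not exact powers of 1/2 |
| `root_volume` | initial volume, arbitrary units | 1 | all statistics use `ln v`, so units cancel |

The noise draw is re-drawn while `r <= 0.02` or `r >= 1.98`. The stated
noise model makes this a ~1e-22 event; truncation only guards pathological
user-set `noise_sd` (which is capped below 0.5) while guaranteeing positive
volumes. A single multiplier cannot both perturb each child and preserve
the sum exactly; here child 1 is multiplied by `r` and child 2 absorbs the
complement `2 - r`, which gives both children the stated dispersion around
`v/2` and exact conservation.

With `mu = 0` and no noise the process is the classical Yule (uniform
leaf-split) tree and leaf volumes are exact powers of 1/2; the test suite
checks the simulator's leaf-depth distribution against an independently
coded uniform-leaf oracle, and the compiled ensemble kernel against the
plain-R tree simulator, so the two routes to `sigma(ln v)` validate each
other.

## Size statistics

`fit_log_gaussian()` reports the sample mean and sd (n−1 denominator — the
convention choice is immaterial at these sample sizes) of `ln v`; all
dispersions are in natural-log units. `ks_lognormality()` tests `ln v`
against a normal with the fitted parameters. Because the parameters are
estimated from the same sample, the classical KS p-value is
anti-conservative (the Lilliefors situation); the classical value is the
default to match the convention of the volume-table analyses this package
emulates, and a parametric-bootstrap Lilliefors p-value (1000 resamples) is
available behind `lilliefors = TRUE`. Q-Q data use `(i - 0.5)/n` plotting
positions. `filter_volumes()` drops internal rows and zero-volume leaves
before any of this, since atlas hierarchies list branch points and
unannotated leaves.

## Inferring the bias exponent

At fixed `N_PU`, larger `mu` homogenizes sizes, so the within-run
`sigma(ln v)` decreases with `mu` on average. `sigma_envelope()` simulates
the full sampling distribution of `sigma` on a `mu` grid (defaults: grid
`[-0.8, 0.8]` in steps of 0.02, 1000 simulations per point, 5th/95th
percentile band — a 90% acceptance region) and `infer_mu_interval()`
returns the smallest and largest `mu` at which an observed `sigma` lies
inside the band, interpolating the crossed band linearly between grid
points. Numerical choices:

* **Interpolation, not grid snapping.** Reading the interval off the
  plotted band corresponds to linear interpolation of the quantile curves;
  grid snapping would quantize endpoints to the 0.02 step.
* **No monotonicity assumption.** The bands are monotone only on average;
  the crossing scan inspects every grid cell, so Monte-Carlo wiggles widen
  rather than truncate the interval. (An isotonic smoothing was considered
  and rejected as a silent data alteration.)
* **`NA` endpoints** flag an observed `sigma` outside the band everywhere
  on the grid, rather than clamping to the grid edge.

`estimate_mu()` packages this as a model fit: the point estimate is the
median-band crossing, the interval is the envelope inversion, and the
envelope can be precomputed and reused across fits at the same `N_PU`
(the coverage experiments in the test suite do exactly that). Simulation
coverage at `N_PU = 91` is checked at true `mu` of 0 and 0.2: the nominal
90% band is required to cover at least 85% of 100 repeats, the slack
allowing for Monte-Carlo error on both sides of the experiment.

## Connectome scaling

`outer_product_connectome()` builds `C_ij = f rho^2 v_i v_j / 2`. The
diagonal (within-region) block is excluded by default because
retrograde-tracing FLN matrices report extrinsic connections; with
`include_diagonal = TRUE` the full bookkeeping identity
`sum(C) = f N^2 / 2` (with `N = rho * sum(v)` neurons) holds exactly.
`normalize_fln()` divides rows by their sums (all-zero rows are left zero
and flagged). Exponent fits are OLS of `ln strength` on `ln volume`
restricted to strictly positive strengths — zeros are excluded, never
floored, because any floor would bias the slope. Pooled incoming fits
weight each point (not each target) equally. A fit is refused when the
volume spread `max/min` is below 1.001 (the slope would be numerically
meaningless) or fewer than 3 non-zero strengths remain. Natural logs are
used throughout; the slope is base-invariant and the intercept is reported
in natural-log units.

## Hebbian plasticity

The rule `dC/dt = eps1 f_i^alpha C^beta f_j^gamma - eps2 C` factorizes over
matrix entries. For `beta < 1` each entry is a one-dimensional flow with
the closed-form equilibrium implemented in `hebbian_fixed_point()`; the
positive branch attracts all positive initial conditions and `C = 0` is
itself a (repelling) solution for `beta > 0`, so exactly-zero entries are
held at zero during integration. For `beta >= 1` the roles reverse — the
closed form is repelling — so both the fixed point and the integrator
refuse that regime rather than return a state the dynamics would not
reach. `integrate_to_equilibrium()` uses an adaptive solver (lsoda) in
chunks of 50 decay timescales, stopping when
`max |dC/dt| / max C < tol` (default 1e-9); the contract is only the
equilibrium, not the trajectory, and the result is required to match the
closed form to 1e-6 relative error in the tests. The activity map defaults
to `f_i = v_i`; the proportionality constant is absorbed into `eps1` and
cannot affect the exponents `eta = gamma/(1-beta)`, `kappa =
alpha/(1-beta)`. The exponent identities constrain only these ratios; the
package deliberately never picks a canonical `(alpha, beta, gamma)` triple
for a given observed exponent.

## Synthetic data: what it emulates, and what it does not

The fixture generators produce (i) lognormal volume sets at species-scale
dispersions (default `sigma = 1.24`, the printed macaque cortex value, as
a realistic setting), (ii) atlas-style hierarchy tables from fragmentation
runs with a planted fraction of zero-volume leaves, and (iii) FLN matrices
with a planted power-law exponent, multiplicative lognormal scatter
(matching the log-log OLS error model) and missing-at-random zeros.
`noise_for_r_squared()` converts a target fit quality into a noise sd, so
recovery experiments can be run at the scatter level seen in tracing data
(r² ≈ 0.6).

Passing tests on these fixtures show that the estimators recover what the
generators plant under the stated noise models. They do not show that real
atlas trees are generated by volume-biased fragmentation, that tracing
zeros are missing at random, that neuron density is uniform across regions,
or that connection locality and distance effects are negligible — all of
which real data may violate.

## Problem sizes and determinism

The test suite and the acceptance script use ensembles of 100-300 runs for
means and monotonicity checks, 1000 simulations per grid point for the
full-scale envelope (81 grid points at 91 regions), and 10-area systems
for ODE-vs-closed-form agreement; these sizes hold Monte-Carlo error
comfortably below the tolerances asserted while keeping a full run fast on
a laptop. The ensemble kernel is compiled (Rcpp) and driven by R's RNG, so
`set.seed()` reproduces every result bit-for-bit; the plain-R tree
simulator is retained both as the readable reference implementation and as
the statistical cross-check of the kernel.

## Known limitations

* The envelope inversion is the acceptance-region construction, not a
  likelihood or posterior for `mu`; its coverage is exact only to
  Monte-Carlo accuracy and to the extent the model holds.
* `sigma(ln v)` at small `N_PU` has large run-to-run spread (sd ≈ 0.3 at
  100 regions), so a single realization's dispersion can sit well away
  from the ensemble mean; intervals, not point dispersions, are the
  meaningful output.
* Non-binary atlas hierarchies are accepted but their internal topology is
  ignored; only leaf volumes enter the statistics.
* The Hebbian module treats activities as fixed; co-evolution of activity
  and connectivity is out of scope.
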