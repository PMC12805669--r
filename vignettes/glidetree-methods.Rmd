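---
title: "Models and methods in glidetree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in glidetree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the probabilistic models, the inference machinery,
and the numerical and design decisions behind glidetree. It is the
reference for *why* the package computes what it computes; the README
shows *how* to run it.

## The joint posterior

All inference targets one density over the continuous parameters `z` of a
fixed rooted binary time tree with alignment `D`:

```
log p(z, D) = log L(D | tree, substitution, site rates, clock)
            + log p_coalescent(node heights | N(t))
            + log p_GMRF(gamma | kappa) + log p(kappa)
            + log p(substitution, site, clock parameters)
            [+ log p_bridge(eps | tau) + log p(tau^-alpha)]
            + sum of transform log-Jacobians.
```

The topology is data: it never changes, and tip dates (heights) are fixed.
Everything continuous is mapped to an unconstrained vector by smooth
bijections, so a single `joint_posterior` object serves variational
inference, HMC, and MAP.

### Tree likelihood

`tree_log_likelihood()` implements the pruning recursion over compressed
site patterns, with per-pattern max-renormalization at every internal node
(log scalers accumulated), so underflow cannot occur even for trees far
larger than the packaged scenarios. Branch lengths in expected
substitutions are `(parent height − child height) × clock rate × category
rate`, in units of substitutions/site; heights are in years before the
most recent sample. Ambiguous or missing states (`N`, `-`, `?`, any
non-ACGT symbol) are all-ones tip partials — fully missing data.

Transition probabilities `P(t) = exp(Qt)` come from an eigendecomposition
of the normalized rate matrix: reversible models through the symmetric
similarity transform `diag(sqrt(pi)) Q diag(1/sqrt(pi))` (real, stable),
nonreversible random-effects models through the general complex solver
with a degree-13 Padé scaling-and-squaring fallback whenever the
eigenvector basis is ill-conditioned. Rate matrices are always normalized
to one expected substitution per unit branch length, `-sum_i pi_i Q_ii = 1`.
The normalization is recomputed **after** applying random effects
`exp(eps_ij)`, so the effects change relative rates only and the clock
rate stays identifiable; tests therefore never depend on an absolute rate
scale.

### Gradients

The gradient of the log joint is analytic end to end:

- branch-length derivatives by the standard inside/outside (post-order /
  pre-order) pass, with the same per-pattern scalers carried through both
  passes;
- substitution-parameter derivatives through the eigendecomposition
  Fréchet formula `dP = E ((E^-1 dQ E) ∘ F(t)) E^-1` with divided
  differences `F_ij = (e^{λ_i t} − e^{λ_j t})/(λ_i − λ_j)` (the Padé
  block-matrix Fréchet derivative as fallback), including the
  normalization chain and the root-frequency term;
- the site-model shape through the chain rule over category rates. The
  Weibull model's shape derivative is closed-form (its inverse CDF is
  `scale · (−log(1−p))^{1/shape}`); the gamma quantile has no closed-form
  shape derivative, so that one primitive is differentiated by central
  differences of the discretization itself — everything downstream is
  analytic;
- coalescent, GMRF, bridge, and transform derivatives in closed form.

Central finite differences of the assembled log joint are the test oracle
for all of this (relative tolerance 1e-4 at random points), kept strictly
independent of the implementation.

### Node-height reparameterization

Internal heights are encoded as a root-height excess plus, per non-root
internal node, a ratio in (0,1) of its position between its lower bound
(oldest descendant tip, computed once since the topology is fixed) and its
parent's height. Ratios are logit-transformed and the excess
log-transformed on the unconstrained scale. The log-Jacobian of the decode
is `sum log(h_parent − lb_i)`; the package adds it (plus the scalar
transform terms) to the log joint, i.e. the density of heights is pulled
back to the ratio space — the convention that makes the unconstrained
density integrate to the same posterior.

### Coalescent models

The demographic grid holds `M+1` log population sizes at equidistant
heights `0 = x_0 < … < x_M = C` (cutoff `C` in years). The piecewise
linear ("skyglide") `N(t)` is continuous across cells; the
piecewise-constant ("skygrid") variant jumps at grid points — the package
tests document both behaviors explicitly, because that discontinuity is
exactly what makes gradient-based fitting of the skygrid fragile (the
`-log N(t_c)` term jumps whenever a node height crosses a grid boundary).
`∫ 1/N` is accumulated cell-by-cell in closed form; within a linear cell
with slope `b` the integral is `(log N(v) − log N(u))/b`, with a
constant-cell fallback when `|b| < 1e-12 · theta` to avoid catastrophic
cancellation (the fallback's derivative splits by the interval-mean
position, the exact zero-slope limit). Beyond the cutoff both kinds use
`theta_M`. The constant-population model is represented internally as a
one-segment grid with its two values tied to a single parameter.

Event bookkeeping sorts sampling before coalescence at tied heights,
which keeps at least two lineages at every coalescence. Intervals with one
lineage (possible under heterochronous sampling) contribute no intensity.

The GMRF smoothing prior is first-order and intrinsic in level:
`(M/2) log(kappa/2π) − (kappa/2) Σ (γ_{i+1} − γ_i)²`; the overall level is
informed by the coalescent likelihood alone. The hyperprior phrasing
common in the skygrid literature, "rate and scale 0.005", is
self-contradictory (rate = 1/scale);
the package uses the conventional reading shape = 0.005, rate = 0.005, and
both are configurable.

### Priors and transforms

Default block priors: Dirichlet(1) on frequency and GTR-rate simplices
(stick-breaking transform, Stan convention with the `log(1/(K−k))`
centering shift); LogNormal(1, 1.25) on kappa; LogNormal(0, 1) on the
site-model shape; LogNormal(log 1e-3, 1.5) on a free clock rate;
Gamma(shape, rate) on the GMRF precision. The bridge prior's global scale
is parameterized through `nu = tau^(-alpha)` with a Gamma(delta,
scale = theta_s) prior (defaults alpha 0.25, delta 1, scale 2), matching
the usual hyperprior statement directly; the per-effect density is the
original bridge `alpha/(2 tau Γ(1/alpha)) · exp(−|eps/tau|^alpha)` — its
exact normalization is verified by quadrature in the tests, and its
density at zero has the closed forms used by the Savage–Dickey machinery
(8 for a single effect and 0.5 for a difference of two effects at the
default hyperparameters). Fixed parameters (e.g. a fixed clock) never
enter the unconstrained vector.

## Inference engines

**Variational families.** Mean-field: independent Gaussians on the
unconstrained scale (parameters mu, log sigma). Full-rank: `N(mu, LL')`
with the Cholesky diagonal stored on the log scale. A full-rank family can
be initialized from a fitted mean-field one with zero off-diagonals, which
makes it exactly the mean-field distribution at the start — the stable way
to use it, since fresh full-rank fits need tiny steps (default learning
rates: 0.1 mean-field, 1e-5 full-rank).

**ELBO.** Estimated with the full Monte-Carlo entropy form
`log p(z) − log q(z)` (one sample per step by default) so the same
estimator serves both families; an analytic-entropy variant would differ
only in gradient variance. The gradient is pathwise through
`z = mu + sigma ⊙ eps` (or `mu + L eps`); the explicit `log q` terms
cancel for `mu` and contribute +1 on the log-scale coordinates.

**Forward KL / SNIS.** Each step draws `S` fresh samples (default 10) from
the current `q`, computes self-normalized weights with one log-sum-exp
shift, and reports `Σ w_s (log p̃_s − log q_s) − log[(1/S) Σ p̃_s/q_s]`
(the normalizing-constant estimate removed). The gradient
`−Σ w_s ∇_phi log q(z_s)` treats samples and weights as constants —
a call-counting test verifies the model gradient is *never* evaluated
under this objective, which is the point: it fits models whose density is
discontinuous in the parameters. The effective sample size `1/Σ w_s²` is
reported per batch. No replay buffer is kept.

**Optimizer.** Adam with the defaults above, plus Polyak–Ruppert averaging
of the variational parameters over the final 25% of iterations (50% in
the calibration studies). A constant-step stochastic optimizer has a
stationary distribution around the optimum whose spread and O(step-size)
bias the averaging removes; without it, single-sample fits wander a few
percent around the target indefinitely. Fits are deterministic given the
seed, and checkpoint rows (iteration, objective, parameter summaries) form
the trace.

**HMC.** Fixed 10 leapfrog steps; warmup adapts the step size by dual
averaging toward 0.8 acceptance and sets the diagonal mass from the second
half of warmup. The per-trajectory step size is jittered ±15%: a fixed
trajectory length on a near-Gaussian target can resonate (trajectories
close to full periods return near their start), and jitter breaks the
resonance. Trajectories with energy error above 1000, or any failed or
non-finite model evaluation, count as divergences and are rejected.
Post-warmup draws are mapped back to constrained space.

**MAP.** BFGS on the unconstrained vector with the analytic gradient,
restarted once from its own solution; reports the achieved log joint and
gradient norm. Note that the MAP of the *unconstrained* density includes
the Jacobian terms (it is the mode of the pulled-back density); a
flat-prior identity-transform block recovers a plain maximum-likelihood
estimate, which is how the closed-form JC69 distance check is built.

## Diagnostics

The coefficient-of-variation series follows the running-moment definition:
for variational checkpoints, `CV(t_i) = sqrt(mean(σ²_{1..i})) /
mean(μ_{1..i})`; for MCMC, cumulative sample sd over cumulative mean. The
reported curve is `(CV(t_i) − CV(t_M))²`, whose final entry is identically
zero. Savage–Dickey Bayes factors use `log BF10 = log prior(0) − log
posterior(0)` with either the exact Gaussian mean-field marginal (for a
difference of two effects: `N(m_a − m_b, sqrt(s_a² + s_b²))`, exact under
the mean-field family) or a Gaussian KDE over samples; positive values
favor the unrestricted (nonreversible) model.

## The synthetic-data module

The simulator is first-class, tested code. Coalescent trees are drawn by
time rescaling: with `k` lineages the waiting time solves
`C(k,2) ∫ 1/N = Exp(1)`, analytically for constant and exponential
demographies and by bisection to 1e-10 years for piecewise ones;
heterochronous tips interrupt the clock (valid by memorylessness) and join
at their heights. Sequences evolve root-to-tips from the stationary
distribution with per-site rate categories drawn uniformly. All
randomness flows from one seeded generator per run.

Scenario presets pin the study conditions at desk scale: `hcv_like`
(16 isochronous tips, 300 sites, GTR + gamma(4), clock fixed at 7.9e-4
substitutions/site/year, constant truth N = 50 years, skyglide grid
cutoff 150 / 6 segments), `sc2_like` (12 tips sampled over 0.2 years, HKY
with random effects under the bridge prior alpha 0.25 / delta 1 / scale 2,
clock fixed at 1e-3, a five-parameter skyglide grid with cutoff 0.3
years), three single-mechanism validation scenarios (constant N = 5,
exponential growth, bottleneck; 20 tips, 300 sites, JC69), and
`sharp_change` (15 tips sampled over 2 years, 200 sites, an abrupt
bottleneck from N = 4 to 0.3 between heights 1.5 and 2.5). Grid cutoffs
are set to bracket the expected tree depth of each scenario, and clock
rates to give 0.1–0.5 expected substitutions root-to-tip — enough signal
to identify heights without saturating.

What the simulator does *not* emulate: recombination, selection,
population structure, alignment error, and topology uncertainty (the tree
given to inference is the true simulated tree). Passing recovery tests
therefore demonstrates correctness of the inference machinery under the
model, not robustness to model misspecification on real data.

The root-height coverage study treats each seed as a full replicate —
fresh data set, fresh fit — because a 95%-interval property is a
calibration statement over data draws; conditioning on one simulated data
set would make the outcome a coin flip decided by that draw. Mean-field
intervals are mildly anticonservative (variance underestimation is the
known cost of the family), which is visible in per-replicate coverage
around 80–90% rather than 95%, and in the forward-KL intervals being
systematically wider than the ELBO ones on the same data.

## Numerical choices and problem sizes

- Pattern compression merges identical alignment columns; likelihoods are
  invariant by construction and tested to 1e-10.
- Partials are max-renormalized at every internal node (cheaper to do
  always than to test thresholds; the contract only requires rescaling
  below 1e-40).
- Eigendecomposition divided differences switch to the `t·e^{λt}` limit
  when `|λ_i − λ_j| < 1e-9`.
- Ties at equal event heights: sampling processed before coalescence.
- Degenerate height encodings (ratio at 0/1, child at parent height) are
  rejected with explicit errors; the decode is numerically safe into the
  `1 − 1e-12` limits.
- Validation problem sizes are chosen to make every statistical check
  sharp but cheap: exhaustive-enumeration oracles at ≤ 5 taxa, 10⁴
  simulator replicates for coalescent expectations, 10⁴-iteration
  variational fits at learning rate 0.02 with 50% averaging for the
  conjugate calibration (the constant-step bias at 0.1 would exceed the
  5% sd tolerance), 10⁴ HMC draws with batch-means standard errors, and
  five seed-indexed replicates per arm of the coverage study.

## Limitations

Fixed topology only; nucleotides only (no codon or amino-acid models); no
proportion-invariant category; strict clock only; no normalizing flows or
multi-sample bounds; the skygrid/skyglide grid is equidistant with a
user-chosen cutoff. Mean-field variational intervals underestimate
posterior spread, and SNIS estimates of KL(p‖q) carry finite-sample bias
whenever `q` is much narrower than `p` (heavy-tailed weights) — both are
properties of the methods, shared with their reference implementations,
and both are measured rather than hidden by the test suite.

## JSON configuration schema

```json
{
  "seed": 1,
  "iterations": 5000,
  "learning_rate": 0.1,
  "objective": "elbo | forward_kl",
  "family": "mean_field | full_rank",
  "samples_per_step": 1,
  "checkpoint_every": 1000,
  "model": {
    "substitution": {"name": "JC69 | HKY | GTR",
                      "random_effects": false,
                      "estimate_frequencies": true},
    "site":  {"name": "none | weibull | gamma", "categories": 4,
              "shape": 0.5, "fixed": false},
    "clock": {"rate": 7.9e-4, "fixed": true},
    "coalescent": {"name": "constant | skygrid | skyglide",
                   "grid": {"cutoff": 400, "segments": 75},
                   "gmrf": {"shape": 0.005, "rate": 0.005}},
    "bridge": {"alpha": 0.25, "delta": 1, "scale": 2}
  },
  "data": {"alignment": "aln.fasta", "tree": "tree.nwk",
            "dates": "dates.tsv", "dates_from_labels": false}
}
```

The schema is this package's own; it mirrors the block structure common to
phylodynamic configuration files without being byte-compatible with any
other tool's format. Dates may be embedded in taxon labels as
`name_YYYY` (split on the last underscore); an explicit table wins on
conflict. Heights in years before the most recent sample are the internal
time coordinate everywhere; calendar dates exist only at I/O boundaries.
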