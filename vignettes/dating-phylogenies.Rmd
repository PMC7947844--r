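---
title: "Dating phylogenies by log-transformed rate smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating phylogenies by log-transformed rate smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logdater)
```

## The model

A rooted phylogeny estimated from sequences carries branch lengths
$\hat b_i$ in expected substitutions per site. If node $i$ diverged at
time $t_i$ (time increasing toward the present), the duration of the edge
above it is $\tau_i = t_i - t_{par(i)}$, and under a molecular clock with
per-branch rates $\mu_i$ the expected length is $b_i = \mu_i \tau_i$.
Writing the rates as a global rate $\mu$ times per-branch multipliers,
$\nu_i = \mu \tau_i / \hat b_i$, converting the tree to time units means
estimating $x = [\nu_1, \dots, \nu_E, \mu]$.

Calibrations pin the times of $k \ge 2$ nodes (tip sampling dates,
internal ages, or both; at least two distinct values, else $\mu$ is not
identifiable). Each pair of calibrated nodes $(i, j)$ with most recent
common ancestor $m$ imposes the linear constraint
$$\mu\,(t_j - t_i) \;=\; \sum_{e \in P(m,j)} \nu_e \hat b_e \;-\;
  \sum_{e \in P(i,m)} \nu_e \hat b_e ,$$
and $k-1$ independent rows imply all $\binom{k}{2}$ of them. `logdater`
chains *consecutive* calibrations in preorder rather than subtracting one
fixed anchor from all others: the two constructions generate the same row
space, but chaining keeps shared path segments short, so the sparse
constraint matrix has $\Theta(n)$ nonzeros on caterpillar and balanced
trees and $O(n \log n)$ in general. Raw input lengths are used in the
constraints; the short-branch smoothing below enters only the objective
weights.

## Objectives

Four penalties on the multipliers are supported, all independent of $\mu$
(which enters only through the constraints):

* **LF** (Poisson model of observed substitution counts):
  $\sum_i \hat b_i (\nu_i - \log \nu_i)$ — convex;
* **LSD-style least squares** (Gaussian branch-error model):
  $\sum_i \hat b_i (1 - \nu_i)^2$ — convex;
* **LogDate**: $\sum_i \log^2 \nu_i$;
* **wLogDate** (default): $\sum_i \sqrt{\hat b_i + \tilde b}\,
  \log^2 \nu_i$.

The log transform enforces *symmetry of ratios*: multiplying a branch's
rate by $\nu$ costs exactly as much as dividing by $\nu$, whereas the
least-squares term $(1-\nu)^2$ penalizes $\nu = 4$ sixteen times more
than $\nu = 1/4$. `penalty_skewness()` reproduces the distributional
version of this argument: under a LogNormal relaxed clock compounded with
Gaussian branch error, the log penalty terms are markedly less skewed
than the least-squares terms.

Weighting counteracts the heteroskedastic *relative* error of estimated
branch lengths (variance $\approx 1/(\hat b_i s)$): short branches get
small weights and may deviate more in log space. The smoothing constant
$\tilde b = -\log(1-\alpha)/s$ (defaults $s = 1000$, $\alpha = 0.01$,
giving $1.005 \times 10^{-5}$) is the longest branch expected to produce
zero substitutions with probability at least $1-\alpha$; it floors the
weights because tree estimators report arbitrary tiny lengths for
zero-event branches. The published weight is typographically ambiguous
between $\hat b + \tilde b$ and $\sqrt{\hat b + \tilde b}$; both are
implemented (`weights = "linear"` / `"sqrt"`). On this package's own
simulation study the square-root variant is equal or better throughout,
so it is the default.

## Solving

The log objectives are nonconvex — the per-term Hessian
$2 w_i (1 - \log \nu_i)/\nu_i^2$ changes sign at $\nu_i = e$ — so the
solver searches from multiple feasible starts and keeps the best local
minimum:

1. **Constraint elimination.** A QR factorization of the (row-normalized)
   constraint matrix yields an orthonormal null-space basis $Z$; the
   search runs over $x = x_0 + Z y$, so every iterate satisfies the
   calibrations to machine precision. Rank detection uses a strict
   tolerance so that nearly parallel rows (e.g. sibling tips joined by
   near-zero branches) are never silently dropped.
2. **Feasible starts.** Root-to-tip regression of distance on calibration
   time gives $\mu$ and a root age; time is then distributed along each
   root-to-calibration path in proportion to branch length, processing
   calibrated nodes oldest first (which guarantees an attachment ancestor
   is never younger than the node being connected). Randomized starts
   first apply the same scaling to random clades in postorder. Calibration
   times are propagated across chains of zero-length edges before the
   walk, because $\tau = \nu \hat b / \mu$ forces $\tau = 0$ there; any
   residual inconsistency is removed by an exact orthogonal projection
   onto the constraint null space.
3. **Bounded minimization.** L-BFGS-B with the analytic gradient
   ($\partial/\partial\nu_i = 2 w_i \log \nu_i / \nu_i$ for the log
   schemes; the $\mu$ component is identically zero). Positivity
   ($\nu \ge 10^{-5}$, $\mu \ge 10^{-12}$) is enforced by a continuous
   clamped-objective-plus-quadratic penalty, which leaves the equality
   constraints untouched because the penalty gradient is applied inside
   the null space. A run counts as converged only if the optimizer
   reports success (or the reduced gradient is numerically zero), the
   relative constraint residual is below $10^{-8}$, and no coordinate
   sits materially below its bound.

On trees with five or fewer edges the selected optimum matches an
exhaustive Nelder–Mead search over the independent time
parametrization to three significant figures for all four objectives
(see `tests/testthat/test-acceptance.R`); on error-free strict-clock
input every objective recovers the true times and rate to solver
precision, with the log objectives at exactly zero.

Degenerate inputs worth knowing about: an edge of length zero between two
*differently* dated nodes makes the bounded problem infeasible (the data
claim time passed with zero substitutions on a branch whose multiplier
cannot stretch it); `date_tree()` then reports per-start diagnostics
rather than returning a silently infeasible tree. Exactly equal
calibration times, polytomies, and calibrations on internal nodes are all
handled natively.

## Confidence intervals

`confidence_intervals()` subsamples the calibration set without
replacement ($\lceil f k \rceil$ entries, default $f = 0.8$, a free
parameter the procedure's description leaves open), re-dates each of $N$
replicates (default 100), and reports per-node empirical quantiles
(type-7 linear interpolation between order statistics) at the requested
level. This is deliberately not a bootstrap — sampling times cannot be
resampled with replacement — and nodes pinned by a retained calibration
still vary across replicates in which that calibration is dropped.

## What the simulator emulates — and what it does not

`simulate_birth_death_tree()` grows a forward birth–death process
(defaults: birth 1, death 0.5 per lineage per unit time) and samples
either all lineages when the target count is first reached (ultrametric)
or a fixed number per regular epoch (periodic, heterochronous).
`draw_rates()` implements strict, i.i.d. LogNormal (mean 1, sd 0.4),
Gamma ($\alpha = \beta = 6.05$), Exponential, and autocorrelated clocks;
the autocorrelated model evolves log rates by Brownian motion with
variance $0.3 \times$ duration per edge, root rate 0.01, a $-v\tau/2$
mean correction so the rate process is a martingale, and branch rate
equal to the mean of its endpoint rates. Branch noise is Poisson
($\hat b = \mathrm{Pois}(s b)/s$), truncated Gaussian
($\max(0, N(b, \sqrt{b/s}))$), or the full sequence route: Jukes–Cantor
simulation with exact transition probabilities followed by
fixed-topology maximum-likelihood re-estimation (phangorn; the two
root-adjacent edges are unidentifiable under a reversible model and their
merged estimate is split in proportion to the input tree's lengths).

The generator is a stand-in for the published simulation protocols whose
exact tree sets are external: the birth–death parameters were fixed once
so that a 50-taxon tree's substitution scale matches the printed
identical-sequence collapse rate of the original data (about five tips
per 50-taxon replicate), and the autocorrelated-model parameterization
follows the stated Brownian reading of the autocorrelation parameter.
Following the published protocol, the study discards the rare tests in
which an objective fails outright (normalized RMSE above 1, i.e. an error
larger than the entire tree height — the failures are cleanly bimodal, so
the threshold is not delicate). Green tests therefore establish
correctness of the method and qualitative agreement of the simulation
study (wLogDate ≈ LF, both well below the
least-squares objective on heterochronous trees), not exact recovery of
numbers tied to the original tree sets: the re-simulated error means run
some 30–50% above the published ones, consistently for every method,
which points at residual differences in tree shape and height rather than
at the estimator.

## Numerical choices

* Feasibility tolerance $10^{-8}$ (relative, scaled by the largest
  constraint-term magnitude), objective-change tolerance $10^{-10}$,
  iteration cap 5000 — all user-adjustable through `solve_options()`.
* Reference calibration for time recovery: minimum time, ties broken by
  smallest node index (deterministic; mathematically immaterial).
* Ties for the oldest calibrated node in the start heuristic: smallest
  node index.
* Zero-length edges get $\tau = 0$ and multiplier 1 in starts; their
  columns are absent from the constraints.
* Calendar dates convert to decimal years as
  year $+$ (day-of-year $- 1$)/days-in-year, so January 1 is exactly the
  integer year.
* Seeds: every stochastic entry point takes one; child seeds derive from
  the master seed by fixed increments and stay below $2^{31}$.

## Known limitations

Calibrations are exact equalities; interval or distributional
calibrations (fossil-style min/max bounds) are out of scope, as is
searching for the root. Trees whose rates follow multimodal or
local-clock regimes violate the single-global-rate assumption and can
bias the root age. Relative node-age errors are reported against times
normalized to the unit interval and blow up for nodes arbitrarily close
to the root; that is a property of the metric, not of the estimate.
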