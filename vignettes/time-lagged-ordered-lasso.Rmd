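---
title: "Methods: time-lagged Ordered Lasso network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lagged Ordered Lasso network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagnet)
```

## The model and its assumptions

lagnet treats a gene regulatory network as a set of per-gene lagged linear
models. For target gene $i$ with expression $x_i(t)$ sampled every
$\Delta t$:

$$
\min_{w}\; \tfrac12\sum_t\Big(x_i(t) - \sum_{j=1}^{p}\sum_{k=1}^{l_{\max}}
w_{ji,k}\, x_j(t-k\Delta t)\Big)^2
+ \lambda \sum_{j,k} |w_{ji,k}|
\quad\text{s.t.}\quad |w_{ji,1}|\ge\cdots\ge|w_{ji,l_{\max}}|.
$$

Three assumptions are doing the work. *Linearity*: each gene responds
linearly to the lagged expression of its regulators — a deliberate
simplification that controls overfitting on short series, not a claim
about kinetics. *Sparsity*: the $\ell_1$ penalty encodes that most gene
pairs do not interact. *Temporal decay*: the monotone constraint encodes
that a regulator's influence through lag $k$ cannot exceed its influence
through lag $k-1$; the most recent past is most informative. The target's
own lags are always included as covariates, so cross-gene edges must earn
their coefficients on top of autoregressive self-memory.

An edge $j \to i$ is called when any $w_{ji,k}$ is non-zero; the
constraint makes the first-lag check sufficient. Without the constraint
the same pipeline is Lasso-Granger, and there every lag must be checked.

## Solving the constrained problem

The constraint region $\{|w_1|\ge\cdots\ge|w_{l_{\max}}|\}$ per block is a
union of sign cones, not a convex set. We solve by accelerated proximal
gradient in the original coefficient space, using the fact that the
proximal operator of "penalty + constraint" for one block is exact and
cheap:

* the optimal signs equal the signs of the gradient-step point, and
* the optimal magnitudes are the non-increasing isotonic regression
  (pool-adjacent-violators, via `stats::isoreg` on the negated vector) of
  the point's magnitudes shifted down by the penalty, clipped at zero.

Every iterate is therefore exactly feasible, and the returned coefficient
tensor always satisfies the magnitude ordering. We first implemented the
common alternative — splitting coefficients into positive and negative
parts, each monotone — and rejected it: its optimum can require both
parts of one coordinate to be simultaneously positive, which inflates the
effective penalty and can return tensors whose *magnitudes increase* with
lag. The direct formulation keeps the model's defining invariant by
construction.

The price of the direct formulation is non-convexity of the feasible set:
a cold start can settle in the wrong sign cone. Two mitigations are built
in. Cold fits run a second solve seeded from the unconstrained lasso
solution (which almost always identifies the right cone) and keep the
lower objective; path fits inherit the previous (larger-$\lambda$)
solution as a warm start, a continuation scheme that tracks the solution
path. On small problems where exhaustive search is feasible, the solver's
objective matches (or undercuts the grid resolution of) brute-force
constrained grid search; the test suite automates that comparison on 50
randomly drawn lagged problems with up to 3 predictors, 2 lags and 15
rows.

Step size is $1/L$ with $L$ the top eigenvalue of $X^\top X$; momentum is
discarded for any step that would increase the objective, so the recorded
objective history is non-increasing. Convergence is declared at a relative
objective change below $10^{-8}$, capped at 10\,000 iterations (a classed
error carrying the iterate and history is raised at the cap). A
coefficient counts as non-zero above $10^{-10}$ after back-scaling.

### Standardisation

The response and all columns are centred (an implicit intercept —
expression is not mean-zero) and each predictor's *whole lag block* is
scaled by one pooled standard deviation. Per-column scales would make the
monotone constraint act on a distorted scale and could break the
magnitude ordering after back-scaling; a single per-block scale keeps the
constraint meaningful while making one $\lambda$ comparable across genes
and series. At $l_{\max}=1$ this coincides with ordinary per-column
standardisation, which is why the one-lag fit agrees with glmnet to
$10^{-4}$ in the tests.

### Where the penalty path starts

`lambda_zero()` gives the exact smallest $\lambda$ with an all-zero
solution: the zero vector is optimal iff, per block, $\lambda$ dominates
every prefix mean of $|X^\top y|$ over the lag indices (prefix indicators
are the extreme rays of the monotone cone; within each sign cone the
problem is convex, so directional stationarity at zero is sufficient). No
bisection is needed; the property tests confirm the threshold by fitting
just above and just below it.

## The penalty path and merged-$\lambda$ scoring

Networks at a single $\lambda$ are useful, but the central object is
the *entry path*: a 100-point log-spaced grid shared across targets, from
the dataset-wide `lambda_zero` down to $10^{-4}$ of it, fitted
large-to-small with warm starts. Each ordered pair records the largest
grid $\lambda$ at which it is active. Because an edge may leave and
re-enter as $\lambda$ decreases, scoring uses the merged rule — an edge is
predicted at $\lambda$ if it entered at that value *or larger* — which
forces nested predicted sets and a monotone ROC. Entry values are resolved
on the grid; grid density is the resolution of the ranking. The AUC is
the Mann–Whitney probability with ties at half credit; pairs that never
enter share one bottom rank. Self-pairs are always in the design but
excluded from candidate sets and predicted networks by default
(`include_self` flips this): the validation truths score cross-gene
regulation only.

## Semi-supervised inference

A prior network $E$ splits the penalty: blocks with $(j,i)\in E$ pay
$\lambda_{\text{edge}}$, all others $\lambda_{\text{non-edge}}$. Equal
penalties reproduce the de novo fit exactly (the tests check this bit for
bit). For novel-edge screening the default is $\lambda_{\text{edge}}=0$:
prior edges are free, and `novel_edge_path()` sweeps
$\lambda_{\text{non-edge}}$ from a top value verified to activate no
prior non-edge (doubling until that holds) down the usual grid,
recording entries of non-prior pairs only. Anomalous-edge detection
(prior pairs fit to zero) requires $\lambda_{\text{edge}}>0$ and is
exposed through `fit_semisupervised()`. Joint tuning of the two penalties
is left to the user; nothing in the data decides it automatically.

## Baselines

*Pairwise Granger*: per ordered pair, restricted (own lags) vs full (own
plus driver lags) OLS with intercepts; lag windows are built per replicate
series and residual sums of squares pooled, with residual degrees of
freedom $n_{\text{rows}} - 2l_{\max} - 1$; $F$-test p-values are adjusted
by Benjamini–Hochberg (the FDR procedure is our choice), and $1-p$ is the
edge score for ROC construction (the ranking statistic is likewise our
choice). Zero residual degrees of freedom — the short-series failure mode
— raises an error rather than a silent NaN. *Lasso-Granger*: the de novo
pipeline with `monotone = FALSE`. At $l_{\max}=1$ the two lasso paths are
identical by construction, and the suite asserts exact equality of entry
values on every fixture.

## What the simulators emulate — and what they do not

`simulate_repressilator()` integrates the three-gene cyclic repressor
($\alpha = 4$, Hill coefficient $3$) with lsoda at rtol $10^{-8}$ / atol
$10^{-10}$, far below fitting tolerances; halving $\Delta t$ reproduces
shared samples to integrator precision. The default initial state
$(1, 1.2, 1.5)$ is deliberately asymmetric: on the manifold $x=y=z$ the
system collapses to a decaying fixed point and samples carry no network
signal. Samples are noiseless ODE output; no measurement noise is added.
$\Delta t$ near an integer multiple of the oscillation period makes the
samples nearly constant — a documented hazard, not a runtime check.

`sparse_var_model()`/`simulate_var()` generate the linear ground truth the
estimator assumes: a sparse VAR with Gaussian innovations, burn-in, and a
stationarity guard (companion spectral radius, error at $\ge 1$). The
defaults are a *weak-coupling regime*: every gene gets a first-lag
self-memory of 0.5 (mRNA persistence; it also keeps every trajectory
excited even without innovations) and cross-coefficients of magnitude
0.25–0.45, spectral radius capped at 0.95. This regime was chosen because
support recovery is only well posed under it: strongly coupled draws
frequently violate the lasso irrepresentable condition, in which case *no*
$\ell_1$ method recovers the support exactly — a property of the problem,
not the solver. Noiseless recovery fixtures additionally use replicate
series restarted from random states (10 series × 10 points): a single
noiseless trajectory collapses onto the dominant eigenmode and loses
excitation. The recovery test certifies identifiability first — it selects
the first seed whose realised design satisfies the irrepresentable
condition, a solver-independent check — and then asserts exact recovery at
$\lambda = 0.01\,\lambda_{\max}$.

Passing these tests therefore shows the estimator does what the theory
promises *within its model class*. Real expression data break the class
in ways the simulators deliberately do not emulate: nonlinear and
saturating kinetics, unobserved regulators, measurement noise correlated
with magnitude, and non-uniform sampling. Results on simulations bound
what is algorithmically achievable; they do not certify biological
accuracy.

## Numerical choices and degenerate inputs

* Active-coefficient tolerance $10^{-10}$ (after back-scaling);
  convergence $10^{-8}$ relative; 10 000-iteration cap.
* Ties at the tolerance boundary count as satisfying the constraint.
* AUC ties get half credit via midranks; the ROC curve is made
  deterministic by thresholding at the sorted unique scores.
* A constant target gene has `lambda_zero` 0 (with a warning) and an
  all-zero fit at any positive penalty.
* Degenerate precision/recall cases are returned with a `degenerate`
  flag, not raised: no predicted edges reports precision 1 by convention.
* An undefined AUC (empty truth, or truth equal to the whole candidate
  set) is an error, as is a truth edge outside the candidate set.
* `experiment_grid()` reports cells whose sampled series cannot support
  the requested lag as skipped rather than failing the sweep.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: repressilator series of 257
points (T $= 6\pi$, $\Delta t = 6\pi/256$ — and T $= 6\pi/4$,
$\Delta t = 6\pi/1024$ for the short-series case), 6-gene VAR fixtures
with up to 200 time points, 50 tiny solver-oracle problems, and 1 000
two-gene null replicates for the Granger size check. The estimator itself
has no such limits; cost grows with the number of genes times the grid
size, dominated by one proximal-gradient path per target.

## Known limitations

* The monotone constraint assumes influence starts at the immediately
  preceding sample; a regulator acting only at a longer delay is
  penalised toward zero. Subsampling, or relaxing to Lasso-Granger, are
  the available workarounds.
* The feasible set is non-convex; despite multi-start and continuation,
  global optimality is verified only empirically (and only on small
  problems).
* One $\lambda$ is shared across targets. Per-gene penalties and
  automatic selection heuristics (e.g. information criteria) are out of
  scope.
* Granger baselines assume enough time points for positive residual
  degrees of freedom and pool replicate series; no small-sample
  correction is applied beyond the exact F reference distribution.
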