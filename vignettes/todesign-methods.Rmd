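---
title: "Methods: the triple-outcome double-criterion two-dose design"
author: "todesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the triple-outcome double-criterion two-dose design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(todesign)
```

## The scientific problem

After a dose-escalation study has identified a safe dose range, sponsors
increasingly run a randomized two-dose expansion trial to decide which dose
to carry forward.  The practical question is rarely "which dose has the
higher response rate" alone: if the lower dose is *noninferior* in efficacy
it is usually preferable on tolerability, cost and long-term safety
grounds.  `todesign` implements a Bayesian two-stage design for this
setting, with three ingredients:

1. **A dynamic linear dose-response model.**  Responder counts are
   binomial, `y_j ~ Bin(n_j, p_j)`, and the probit-transformed rates
   `mu_j = probit(p_j)` follow a random walk across doses:
   `mu_1 ~ N(theta, sigma1^2)` and `mu_2 | mu_1 ~ N(mu_1, sigma2^2)`, with
   a half-Cauchy prior `sigma2 ~ HC(xi, tau)` on the step scale.  Small
   `sigma2` pools the two doses (borrowing strength); large `sigma2`
   decouples them.  The half-Cauchy lets the data decide adaptively, and
   no monotone dose-response shape is imposed.
2. **Dual-criterion monitoring.**  At the interim (after `m1` patients per
   arm) and at the final analysis (after `n`), a dose is dropped if its
   posterior probability of beating the historical control rate is small:
   `Pr(p_j > p0 | D_k) < a_k`.  A dropped arm enrolls no further patients
   but its data stay in the joint posterior.
3. **A triple-outcome comparison.**  If both doses survive, the design
   computes `PP_NI = Pr(p2 - p1 < delta1 | D)` and selects the higher
   dose when `PP_NI <= c1`, the lower dose when `PP_NI > c2`, and declares
   the comparison *inconclusive* in between, handing the choice to
   clinical judgment (PK/PD, tolerability, convenience).  Setting
   `c1 = c2` recovers a conventional two-outcome rule.

Truth-level optimality mirrors the decision rule: the lower dose is
optimal when it is non-futile and within `delta1` of the higher dose (or
the higher dose is futile); the higher dose is optimal when it is
non-futile and better by at least `delta2` (or the lower dose is futile);
between the margins the truth itself is ambiguous.

## Default parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `theta` | prior mean of `mu_1` | `probit(p0)` | centers the lowest dose at the historical control |
| `sigma1` | prior SD of `mu_1` | 3 | vague on the probit scale |
| `xi`, `tau` | half-Cauchy location/scale | 0, 1 | weakly-informative borrowing scale, a standard shrinkage choice for small hierarchical models |
| `delta1`, `delta2` | noninferiority / inferiority margins | 0.05, 0.20 | wider than confirmatory noninferiority margins on purpose: the design is exploratory |
| `wl` | inconclusive discount | 0.40 | an inconclusive trial is less costly than a wrong selection but not free |

`priorPESS()` audits the implied prior informativeness: the prior marginal
of `p_j` is moment-matched to a `Beta(a, b)` (so `a + b = m(1-m)/v - 1`)
and `a + b` is reported as a prior effective sample size.  `Phi(N(0,1))`
is exactly uniform, so `dlmHyper(0, sigma1 = 1)` returns exactly 2; the
package's default `sigma1 = 3` prior is *more* diffuse on the probit scale
but its `p`-scale marginal is U-shaped, which moment-matching reads as a
sub-uniform effective sample size (about 0.4 for the first dose and less
for the second, whose marginal inherits the Cauchy tails).  Any value
well below the per-stage sample size indicates a suitably vague prior;
values are reported to 2 decimals.

## Posterior computation

Calibration evaluates millions of decisions, so the default posterior
backend is a deterministic quadrature rather than MCMC:

* Both latent probits live on a shared lattice with spacing `h = 0.05`.
  The borrowing scale is integrated out analytically per lattice cell: the
  kernel of `d = mu2 - mu1` is averaged over each cell using a stratified
  grid of 64 half-Cauchy nodes (`u = v^3` substitution), so that very
  small scales — near-complete pooling — are resolved for any `tau`.
* Probabilities such as `Pr(p_1 > p0)` interpolate the threshold inside
  its lattice cell, making the error `O(h^2)` rather than `O(h)`.
* The Cauchy tails extend far beyond any feasible lattice, but there the
  response probability is saturated at 0 or 1; the lost mass is collected
  exactly into absorbing edge cells at `p = 0` and `p = 1`, keeping
  normalization and tail probabilities correct.
* `dlmPosterior(..., check = TRUE)` verifies convergence by halving `h`
  (and doubling the scale nodes) until successive summaries agree to
  `tol = 1e-3`, raising an explicit error if the tolerance is not met
  after the configured refinements — numerical failure is never silent.

A completely independent cross-check backend, a compiled random-walk
Metropolis-within-Gibbs sampler over `(mu1, mu2, v)` with the half-Cauchy
sampled through its bounded quantile coordinate `v`, is available via
`method = "mcmc"`; it is seeded and reproducible, reports batch-means
Monte Carlo standard errors, and agrees with the quadrature to about
`1e-3` at a few million iterations.  The test suite holds the two
backends to that agreement on a fixed battery of twenty outcome tables.

Two model-level findings surfaced by this engine are worth recording.
First, `Pr(p_1 > p0 | D)` is monotone in the dose's own responder count,
but *not* necessarily in the other dose's count: discordant data enlarge
the posterior borrowing scale and legitimately weaken pooling, so only
the own-count monotonicity is asserted as an invariant.  Second, the
model approaches independent per-dose analyses as `tau` grows, but
slowly: even at `tau = sigma1 = 50`, mutually consistent outcomes retain
a posterior weight on strong borrowing worth up to ~0.02 in exceedance
probability (the half-Cauchy's density near zero never vanishes, and
consistent data reward it).  The tests assert a verified 0.02 envelope at
`tau = 50` and that the deviation shrinks as `tau` grows, rather than an
idealized exact-independence limit.

## Operating characteristics: exact enumeration first

For two doses the entire outcome tree is enumerable: `(m1+1)^2` interim
cells times the conditional stage-2 binomial mass.  `exactOC()` therefore
computes decision probabilities, Go percentages, FWER/OMP, average sample
size, and the unconditional bias/MSE of the posterior-mean estimates with
no Monte Carlo error, by caching the posterior summary tables at the four
terminal size configurations `(m1, m1)`, `(n, n)`, `(n, m1)`, `(m1, n)`
and sandwiching indicator matrices between shifted-binomial transition
matrices.  `simulateOC()` is the Monte Carlo twin (vectorized table
lookups, bitwise reproducible given a seed) kept for reporting parity
with simulation-based practice; the suite checks the two agree within
three binomial standard errors on every entry.

Estimation summaries average over *all* replications, including trials
stopped at the interim (whose estimates come from the joint posterior at
the interim data), so bias and MSE are unconditional per scenario.

## Calibration

`calibrateDesign()` runs the two-step grid search:

* **Step 1** (`step1Search()`): for each candidate `n` in increasing
  order and each `(m1, lambda, a2)` on the grid, with the regularization
  `a1 = a2 (m1/n)^lambda` tying the interim cutoff to the information
  fraction, compute the exact FWER under the global null `(p0, p0)` and
  OMP under the global alternative `(pA, pA)`.  Keep FWER-admissible
  combinations, restrict to OMP within one percentage point of the
  admissible maximum, and minimize the global-null ASS.  Ties are broken
  deterministically: higher OMP, then smaller `m1`, then smaller `a2`,
  then smaller `lambda`.  The first `n` whose optimum reaches `beta1` is
  returned; otherwise an explicit infeasibility report with the best
  achieved OMP.
* **Step 2** (`step2Search()`): with the step-1 design fixed, the
  terminal probability mass attached to every attainable `PP_NI` value is
  computed once per alternative (`HA* = (pA, pA + delta1)`,
  `HA+ = (pA, pA + delta2)`); each cutoff pair `c1 <= c2` is then a pair
  of weighted tail sums.  Feasibility requires `MRID <= alpha2` and
  `SIR <= alpha3` (SIR averaged across the two alternatives); the
  feasible pair minimizing `WL = IDR + wl * SIR` wins, with ties resolved
  toward smaller SIR, then a narrower inconclusive zone, then smaller
  `c1`.

Default grids are `m1` from `n/3` to `2n/3`, `lambda` in 0.1–1.0 by 0.1,
`a2` in 0.50–0.99 by 0.01, and comparison cutoffs 0.05–0.95 by 0.05 —
granularities in line with Bayesian optimal phase II calibration
practice.  All grids are user-configurable, and the returned design
carries the full search trace.  Because the OC backend is exact, the
calibration is reproducible run-to-run with no simulation noise.  With
the default grids, the reference configuration (`p0 = 0.2`, `pA = 0.4`,
`alpha1 = 10%`, `beta1 = 95%`) calibrates in well under a minute.

Comparators: `simonTwoStage()` performs the exhaustive exact-binomial
search for the single-arm two-stage design minimizing the expected null
sample size, and `calibrateDreamm2()` reproduces the heuristic
beta-binomial two-outcome comparator (interim cutoff from a 5% early-stop
target under `pA`; final cutoff from a 10% FWER target — since the FWER
decreases in the cutoff, "controlling at 10%" selects the smallest
feasible cutoff; selection of the higher dose iff
`Pr(p2 > p1 | D) >= 0.6`).  The beta-binomial variant of the main design
(`model = "bb"`) runs the same two-step calibration with independent
conjugate posteriors.

## The joint toxicity-efficacy extension

With co-primary endpoints, each dose must be both effective
(`Pr(p_j > p0 | D) >= a_k`) and safe (`Pr(q_j < q0 | D) >= a_k`);
toxicity gets its own DLM anchored at `probit(q0)` with the same
construction rule as the efficacy model.  The comparison then acts on the
risk-benefit utility `u_j = p_j - rho q_j` through
`PP = Pr(u2 - u1 < delta1 | D)`, computed by convolving the posterior
distribution of the efficacy difference with that of the (independent)
toxicity difference; the difference distributions are binned at width
0.005 and the convolution is a single matrix product, so the full
`PP` table over all final outcome pairs is precomputable.  `rho = 0` is
special-cased to reduce *exactly* to the efficacy-only comparison.

Efficacy and toxicity outcomes are simulated independently within a
patient — the model deliberately carries no toxicity-efficacy
association, which mirrors the modeling choice that association terms do
not improve performance.  That independence is also what makes exact
joint operating characteristics tractable: conditional on the interim
continuation pattern, the efficacy path and the toxicity path never
interact, so every joint probability factors into per-endpoint terms
combined over the 4 x 4 interim flag patterns and final flag patterns
(`exactJointOC()`).  The Monte Carlo twin `simulateJointOC()` is retained
for estimation summaries and as a cross-check; the suite verifies the
two agree within Monte Carlo error.

`calibrateJoint()` re-runs the two-step search with the global null
`(p = p0, q = q0)`, the global alternative `(p = pA, q = qA)`, and step-2
alternatives with toxicity fixed at `qA`.  A vacuous toxicity alternative
(`qA >= q0`) is rejected up front as infeasible.

## What the generator emulates — and what it does not

Simulated trials draw exchangeable binomial outcomes at fixed true rates,
with equal randomization, a single interim after exactly `m1` evaluable
patients per active arm, and immediate outcome availability.  Real trials
add accrual dynamics, evaluation lag, dropout, and drifting patient mix;
none of these are modeled, so passing operating characteristics say
nothing about interim-timing robustness or partial-information monitoring.
Within-patient toxicity-efficacy correlation is likewise absent.  The
random-number convention is deliberately simple: all stage draws are
generated vectorized in a fixed order from one seed, which makes every
report bitwise reproducible from its manifest (configuration hash + seed)
at the cost of not being invariant to replication count.

## Numerical choices and limitations

* Lattice spacing 0.05 and 64 scale nodes give posterior probabilities
  accurate to roughly `1e-3`–`1e-4` (verified against refined grids and
  long MCMC); calibration cutoff grids are coarser than that, so grid
  decisions are insensitive to quadrature error except exactly at
  thresholds.
* Monitoring uses strict inequalities (`drop iff Pr < a_k`), comparison
  uses `PP <= c1` / `PP > c2`; boundary cases in the tests pin these
  conventions.  The toxicity monitoring threshold is likewise strict.
* Degenerate inputs: empty arms return the prior; `y = 0` or `y = n`
  route tail mass through the absorbing edge cells; a degenerate prior
  variance in `priorPESS()` yields PESS 0 with a warning rather than a
  negative shape.
* Test and example problem sizes are deliberately small (per-dose sizes
  8–12 for unit tests, the reference configuration `n ~ 29` for the
  acceptance checks, 10,000 replications for Monte Carlo comparisons) —
  large enough to exercise every code path while keeping the whole suite
  in the minutes range.
* Scope: two doses, two stages, equal randomization.  Three or more
  doses (which would need a monotone variant of the random walk and a
  combinatorial decision table) and response-adaptive randomization are
  out of scope.
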