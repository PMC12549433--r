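---
title: "WKB approximation of quasistationarity and extinction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WKB approximation of quasistationarity and extinction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qswkb)
```

## The model class

`qswkb` works with density-dependent Markov population processes: a family
of continuous-time chains $X^{(N)}(t)$ on $\mathbb{Z}_+^k$ (or on a finite
box $\{0 \le x_i \le N f_i\}$), indexed by a scale parameter $N$, with
transition rates

$$x \to x + \ell \quad\text{at rate}\quad N\,\beta_\ell(x/N),$$

for a finite symmetric jump set $\mathcal{L}$ ($\ell \in \mathcal{L}
\Rightarrow -\ell \in \mathcal{L}$, and $\mathcal{L}$ spans $\mathbb{R}^k$).
The origin is absorbing ($\beta_\ell(0) = 0$), every other state
communicates, and the scaled process follows the fluid limit
$\dot y = \sum_\ell \ell\,\beta_\ell(y)$, which is assumed to have an
unstable equilibrium at $0$ and a unique stable interior equilibrium $y^*$.
Such processes persist in a quasi-equilibrium for a long but finite time:
conditional on non-extinction they settle to the quasistationary
distribution (QSD) $u$, and the time from quasistationarity to extinction
is exponential with mean $\tau$.

The two quantities the package approximates, and checks exactly on
truncated chains, are $u$ and $\tau$.

## The WKB construction

The QSD is sought in the form

$$u_x \approx M_N \exp\bigl(-N V(y) - V_0(y)\bigr), \qquad y = x/N .$$

Substituting into the stationarity equation and collecting powers of $N$
gives a Hamilton-Jacobi equation for the action $V$ and a linear transport
equation for the correction $V_0$.  These can be solved *analytically*
exactly when asymptotic analogues of Kolmogorov's reversibility criterion
hold, order by order:

1. **Cycle condition** (leading order): for every integer combination
   $\sum_i a_i \ell_i = 0$ of jumps, the log rate-ratio sum
   $\sum_i a_i \ln(\beta_{-\ell_i}/\beta_{\ell_i})$ vanishes identically on
   the interior.  The package quantifies this over an integer basis of the
   cycle space of the jump set (computed by fraction-free elimination),
   which suffices by linearity of the log-sums.  Pure birth-death jump sets
   $\{\pm e_i\}$ have an empty cycle space; the condition is then vacuous.
2. **Irrotationality of $\theta$**: the solution $\theta(y)$ of
   $\ell^T\theta = \ln(\beta_{-\ell}/\beta_\ell)$ must have a symmetric
   Jacobian, so that $\theta = \partial V/\partial y$ for a scalar
   potential.
3. **Solvability and irrotationality of $\theta^0$**: the analogous system
   $\ell^T\theta^0 = \tfrac12 \ell^T \partial_y
   \ln(\beta_{-\ell}\beta_\ell)$ yields $V_0$.

When these hold:

* $V(y) = \int_\Gamma \theta \cdot dy'$ along any path from $y^*$
  (`potential()`, path independence is a tested invariant);
* $V_0$ telescopes along any jump decomposition of $y - y^*$
  (`correction()`; the value is independent of the decomposition but
  diverges on the boundary of the state space);
* $\Sigma = \partial\theta/\partial y|_{y^*}$ is the Hessian of $V$ at its
  minimum (`sigma_matrix()`), and $\Sigma^{-1}$ solves the Lyapunov
  equation $J\Sigma^{-1} + \Sigma^{-1}J^T + G = 0$ with $J$ the drift
  Jacobian and $G = \sum_\ell \beta_\ell(y^*)\,\ell\ell^T$;
* $M_N = \sqrt{\det\Sigma/(2\pi N)^k}$, and the Gaussian with mean $Ny^*$
  and variance $N\Sigma^{-1}$ (`gaussian_qsd()`) is the small-fluctuation
  limit that the WKB mass (`wkb_qsd()`) refines;
* $\ln\tau^{(N)}/N \to A = V(0)$ (`log_tau_leading()`).

For multitype birth-death processes with constant birth rows
($\partial\beta_{e_i}/\partial y_j$ at $0$ independent of $j$), the package
additionally computes the full Eyring-Kramers-type prefactor: the process
near the origin is approximated by a supercritical linear branching
process (`linearise_origin()`), whose balance equations have an explicit
solution $\tilde u_x$ up to a normaliser (`u_tilde()`); matching
$\tilde u$ against the WKB body fixes the normaliser and yields

$$\tau^{(N)} \sim \frac{1}{\Lambda D}, \qquad
  \sum_i \frac{b_{ii}}{D + d_i} = 1$$

(`tau_full()`, `solve_D()`).  The matching constant involves rate products
at the partial equilibria $(0,\dots,0,y^*_i,\dots,y^*_k)$; the formula is
written in a fixed coordinate order, and invariance under relabelling the
axes is a tested property rather than an assumption.

## Numerical choices

* **Quadrature.**  Path integrals of $\theta$ use adaptive Gauss-Kronrod
  (`stats::integrate`, absolute tolerance $10^{-12}$).  At a boundary
  endpoint (notably the origin, needed for $A = V(0)$) the integrand has
  an integrable logarithmic singularity; the quadrature nodes are interior,
  and the adaptive extrapolation resolves the singularity to the requested
  tolerance.  Grid evaluations (`potential_grid()`) exploit path
  independence: axis-aligned segments with fixed 24-point Gauss-Legendre
  rules and fully batched $\theta$ evaluations.
* **Overdetermined solves.**  One representative of each $\pm\ell$ pair is
  used (the mirrored equation is the negation of its partner); $\theta$ is
  the least-squares solution via a precomputed pseudo-inverse, and the
  plug-back residual is reported — it vanishes precisely when the cycle
  condition holds, which is itself a tested equivalence.
* **Derivatives.**  Built-in models carry hand-coded analytic rate
  gradients, so criteria checks and $\Sigma$ are exact up to rounding.
  User models default to Richardson-extrapolated central differences
  (step $10^{-6}(1+|y|)$, one-sided at the boundary).
* **Criteria sampling.**  Conditions quantified over the interior are
  checked on 64 Latin-hypercube points inset 1% from the boundary (box
  models) or spread over $[0, 2y^*]$ (unbounded models), with tolerance
  $10^{-8}$ for exact conditions and $10^{-6}$ for finite-difference
  symmetry checks.  `VACUOUS` is distinguished from `PASS` when the cycle
  space is empty.
* **Boundary layer.**  The WKB mass formula is refused within a cutoff of
  the boundary where $V_0$ diverges: $10/N$ for unbounded models, 10% of
  the shortest side (capped at $10/N$) for boxes.  With this cutoff the
  WKB mass over the interior lattice at $N = 100$ for the two-group model
  sums to $1.009$.
* **Near-origin weights.**  $\tilde u_x$ is evaluated in log space with
  log-gamma factorials; the difference of the two exponential products
  uses `log1p(-exp(.))`, so weights remain finite and positive far beyond
  the naive overflow range ($|x| \approx 50$).
* **Degenerate inputs.**  Subcritical parameters are rejected at model
  construction; the decay-constant bracket $(0, \sum_i b_{ii})$ is
  guaranteed by supercriticality; equilibrium search is damped Newton with
  a multi-scale multi-start fallback.

## The exact oracle

`build_truncated()` enumerates the transient class on a capped lattice
(finite boxes exactly; unbounded models truncated at
$\lceil 3 N y^* \rceil$ per coordinate with outward jumps clipped —
reflecting truncation, which preserves positivity; doubling the cap moves
the decay rate by less than $10^{-8}$ relative in the tested regimes).
`exact_qsd()` computes the positive left eigenvector of the sparse
sub-generator by shifted inverse power iteration on a sparse LU
factorisation.  Each solve is followed by one step of iterative
refinement: this preserves the componentwise relative accuracy of the
exponentially small tail entries, which a dense eigendecomposition loses,
and which the flux identity
$\tau = (N\sum_\ell u_{-\ell}\beta_\ell(-\ell/N))^{-1}$ — exact for the
truncated chain and cross-checked to $10^{-8}$ in `exact_tau()` — is
sensitive to.  Beyond $\tau \sim 10^9$ (e.g. very large $N$ at large
growth margins) double precision limits this consistency check; the
tested study designs stay well inside that range.

## Simulation and estimation protocol

`gillespie()` is an exact stochastic simulation on the same capped lattice
as the oracle, with all rates precomputed and the event loop in compiled
code; it draws from R's RNG, so runs are reproducible under `set.seed()`.
The estimation protocol (`sample_extinction_times()`) starts each run at
$\lceil N y^* \rceil$, discards and re-runs (with fresh randomness — reusing
randomness after conditioning on early extinction would bias the retained
sample) any run extinct before the burn-in $t_0$, and right-censors at
$t_{\max}$.  Since the time from quasistationarity to extinction is
exponential, `censored_exp_mle()` returns $\hat\tau = T/d$ (total observed
time over observed extinctions) with the $\chi^2$ pivot interval
$[2T/\chi^2_{1-\alpha/2}(2d+2),\, 2T/\chi^2_{\alpha/2}(2d)]$; a
Monte-Carlo calibration (10\,000 synthetic samples of size 100 with 30%
censoring) shows mean bias under 1% and 95% coverage $\approx 0.954$.

`empirical_qsd()` estimates the QSD as the normalised occupation measure:
time spent per state between $t_0$ and $\min(\text{extinction}, t_{\max})$,
summed over runs.  Runs that die after the burn-in contribute their alive
time; the stricter rule that only runs surviving to $t_{\max}$ contribute
is available via `alive_at_end_only = TRUE`, but discards most of the data
while estimating the same measure (started from the QSD, the expected
occupation of $x$ is $u_x \tau$ under either reading).

## Study conditions and what the tests show

The validation suite uses three standing configurations:

* **Two-group movement model** at $\mu = 2.9$, $\kappa = 0.1$,
  $\lambda_1 = 1$, $\lambda_2 = 2$, $\nu_1 = 2$, $\nu_2 = 1$ — the
  reference parameter set for which all closed forms (equilibrium
  $(1/3, 2/3)$, action, $\Sigma$, QSD mass, and the $\nu = 0$ extinction
  time) are reproduced by the generic machinery to $10^{-7}$ or better.
  The movement-balance condition $\lambda_1\nu_1 = \lambda_2\nu_2$ holds
  here; the criteria checks discriminate exactly across that boundary.
* **Linear-birth quadratic-death process**, $k = 1$, at $\lambda = 1.6$,
  $\mu = 1$, $\kappa = 1$ for the oracle-convergence and simulation
  studies over $N \in \{20, 40, 80\}$.  The growth margin
  $\lambda - \mu = 0.6$ is chosen so that the asymptotic regime is visible
  at these moderate $N$: both $|\tau_{\mathrm{WKB}}/\tau_{\mathrm{exact}}
  - 1|$ (a $1/N$ effect) and $|\ln\tau/N - A|$ (a $\ln N/N$ effect) are
  then monotone decreasing over the study range, which is the behaviour
  the approximations claim.  At much larger margins the $\ln N/N$ term
  changes sign inside the study range and the finite-$N$ error is
  non-monotone even though the same limits hold.  Worked examples that
  illustrate single formulas use $\lambda = 2$, $\mu = \kappa = 1$.
* **Simulation protocol** for that process at $N = 20$
  ($\tau_{\mathrm{exact}} \approx 28$): burn-in $t_0 = 5$ (several
  relaxation times of the fluid limit), horizon $t_{\max} = 2000 \gg \tau$
  so censoring is rare, 100 runs per estimate.  The paper-style protocol
  ($t_0 = 10$, $t_{\max} = 50\,000$) is used where the two-group model is
  simulated.

One empirical finding is worth recording: for the two-group model at
$N = 100$ the per-state argmax of the exact QSD is the boundary state
$(0,1)$, not the lattice point nearest $N y^*$ — the ridge of the
distribution gains per-state mass towards the origin even though the
two-dimensional body is centred at the equilibrium.  The occupation-measure
tests therefore check total-variation agreement with the exact QSD and the
location of the conditional mode given totals near $N$, both of which the
simulation reproduces.

What passing tests do and do not show: the synthetic models exercise
multi-type interactions, movement cycles, boundary behaviour and censored
estimation, but all have smooth polynomial-type rates, a single interior
equilibrium, and moderate dimension ($k \le 3$).  Real systems with
near-critical dynamics, multiple attractors, or rate functions violating
the one-sided differentiability at the origin are outside what the suite
demonstrates, and the asymptotic reversibility criteria themselves are
restrictive — most processes fail them, in which case the package reports
the failure rather than a (meaningless) analytic solution.

## Known limitations

* Existence of the QSD on unbounded state spaces (the limiting conditional
  distribution) is assumed, not verified; reports flag it as unchecked.
* The extinction-time prefactor is available only for multitype
  birth-death jump sets with constant birth rows; for general jump sets
  only the exponent $A$ is computed.
* Numerical solution of the Hamilton-Jacobi equation by characteristics
  for models failing the criteria is out of scope.
* The competition family is implemented for $k = 2$ only.

## A worked example

```{r example, eval = FALSE}
tg <- make_two_group(2.9, 0.1, 1, 2, 2, 1)
full_report(tg)              # which criteria hold, which results apply
log_tau_leading(tg)          # 0.016855: the exponent A = V(0,0)
sigma_matrix(tg)             # QSD curvature at N y*
tau_full(make_two_group(2.9, 0.1, 1, 2, 0, 0), 60)   # 47.9 (no movement)
exact_tau(build_truncated(tg, 60), tg)$tau           # 38.4 (exact, N = 60)
```
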