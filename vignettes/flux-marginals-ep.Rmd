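---
title: "Flux marginals by expectation propagation: model, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux marginals by expectation propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxep)
```

## The model

A metabolic network at steady state confines the flux vector $\nu \in
\mathbb{R}^N$ to the polytope $\{S\nu = b,\ \nu^{\inf} \le \nu \le
\nu^{\sup}\}$, with $S$ the $M \times N$ stoichiometric matrix and $b$ the
fixed intakes. With no further information every feasible point is an
equally viable phenotype, so the object of interest is the marginal density
of each flux under the uniform distribution on the polytope. `fluxep`
computes these marginals analytically through a Bayesian reformulation:

$$
P(\nu) \;\propto\; e^{-\tfrac{\beta}{2}\lVert S\nu - b\rVert^2}
\prod_{n=1}^{N} \psi_n(\nu_n),
\qquad
\psi_n = \mathbb{1}\!\left[\nu^{\inf}_n \le \nu_n \le \nu^{\sup}_n\right],
$$

where the Gaussian likelihood with inverse temperature $\beta$ penalises
mass-balance violations and the indicator priors enforce the box. As
$\beta \to \infty$ the density concentrates on the polytope.

Expectation propagation replaces each indicator by a Gaussian factor
$\phi_n(\nu_n; a_n, d_n)$. The full approximation $Q$ is then a
multivariate Gaussian with precision $\beta S^{\top}S + D$, $D =
\mathrm{diag}(1/d_n)$, and mean $\Sigma(\beta S^\top b + D a)$. For flux
$n$ the *tilted* distribution $Q^{(n)}$ keeps $\psi_n$ exact and
approximates the rest; its marginal in $\nu_n$ is the *cavity* Gaussian
(precision $1/s_c = 1/\Sigma_{nn} - 1/d_n$, mean $\mu_c = s_c(\mu_n/
\Sigma_{nn} - a_n/d_n)$) truncated to the box. Moment matching — requiring
the mean and variance of $Q$'s marginal to equal the tilted ones, which is
the zero-gradient condition of the local Kullback–Leibler divergence —
gives the update in natural parameters

$$
\frac{1}{d_n'} = \frac{1}{v_n} - \frac{1}{s_c},
\qquad
\frac{a_n'}{d_n'} = \frac{m_n}{v_n} - \frac{\mu_c}{s_c},
$$

with $(m_n, v_n)$ the truncated-Gaussian moments of the tilted marginal.
At the fixed point every flux's reported posterior is the truncated
Gaussian $\mathcal{TG}(\mu_c, s_c, \nu^{\inf}_n, \nu^{\sup}_n)$; fluxes
pinned by equal bounds are point masses. With the parallel schedule all
cavities are read off one shared $\Sigma$, so each sweep costs a single
symmetric factorisation, $\Theta(N^3)$; the sequential schedule
(re-factorising per flux, $\Theta(N^4)$) is retained as a cross-check.

Empirical knowledge about one flux — a measured growth-rate profile fitted
by a Gaussian, say — is imposed by *replacing* that flux's tilted moments
with the measured mean and variance in the update above
(`run_constrained_ep()`). At convergence the constrained flux's posterior
equals the measurement and all other fluxes have adjusted consistently.

## Parameters

| parameter  | default    | units     | role |
|------------|------------|-----------|------|
| `beta`     | `1e10`     | (internal units)$^{-2}$ | precision of the mass-balance likelihood; larger is closer to exact balance, but updates destabilise around `1e11`; drop to `1e9` if a large model will not converge |
| `tol`      | `1e-5`     | internal  | stop when $\varepsilon$, the largest per-flux change of tilted mean + second moment between sweeps, falls below it |
| `max_iter` | `2000`     | sweeps    | cap; non-convergence is a warning, not an error |
| `damp`     | `0.5`      | —         | fraction of old natural parameters retained per update |
| `d_min`, `d_max` | `1e-50`, `1e50` | internal$^2$ | clamp on factor variances: wide enough to represent nearly flat and nearly pinned factors without destroying conditioning |
| `schedule` | `parallel` | —         | parallel (deterministic, $\Theta(N^3)$) or sequential |

Internally every problem is rescaled so bounds and intakes lie in
$[-1, 1]$ (`to_polytope(rescale = TRUE)` divides $b$ and the bounds by
$\max(|\nu^{\inf}|, |\nu^{\sup}|, |b|)$ over finite entries). This makes
`tol` and the clamping range scale-free; all reported moments are mapped
back to native units. The convergence statistic $\varepsilon$ is evaluated
in the internal units for the same reason.

## Numerical design

**Truncated-Gaussian moments.** Every update calls the mean/variance of a
Gaussian truncated to an interval, frequently with both standardised
bounds far into one tail (a tight factor a long way from the cavity mean).
The textbook $\Phi$-difference expressions cancel catastrophically there —
at 40$\sigma$ the naive variance loses all significant digits. The kernel
(`trunc_moments()`) therefore dispatches on the configuration:

* *one finite bound*: the Gaussian hazard computed in log space via
  `pnorm(log.p = TRUE)`; beyond $6\sigma$ the mean offset is taken from
  the Laplace continued fraction of the Mills ratio,
  $c(a) = 1/(a + 2/(a + 3/(a + \cdots)))$, and the variance from
  $1 - a\,c - c^2$, which avoids the $\sim a^2$-ulp cancellation of
  $1 + a h - h^2$;
* *two finite bounds*: fixed 128-point Gauss–Legendre quadrature of the
  density *shifted to its maximum over the interval* and clipped where the
  relative density falls below $e^{-60}$. Accumulating the moments
  relative to the shift point keeps full relative precision for narrow
  intervals, deep-tail intervals, and the benign central cases alike; the
  clip bounds are evaluated in subtraction-free form so that standardised
  bounds of order $10^{10}$ remain exact.

The kernel is validated against an independent *adaptive* quadrature
oracle (`quadrature_moments()`, built on `integrate()`) over a grid of
offsets $-40\ldots40$ and widths $10^{-6}\ldots10^{6}$; the acceptance
script recomputes the worst relative error (order $10^{-14}$). A variance
floor (`1e-300`) prevents a hard zero from reaching the reciprocals in the
EP update. `erfcx()` is provided on the same log-space route because the
system `pracma::erfcx` overflows to `NaN` beyond $x \approx 27$.

**Linear algebra.** The precision matrix $\beta S^\top S + D$ has
condition number of order $\beta\max(d)$. It is factorised by Cholesky
with escalating diagonal jitter ($10^{-12}\,\mathrm{tr}/N$, tenfold, three
attempts) before singularity is declared, and the mean solve is polished
with two steps of iterative refinement — without them the baseline
comparisons carry $\sim 10^{-6}$ errors traceable purely to conditioning.

**Flat cavities.** A flux that appears in no constraint row (possible in
sparse random fixtures) has $\Sigma_{nn} = d_n$ exactly: the cavity
carries no information. Whenever the cavity precision is below $10^{-10}$
of the marginal precision the tilted marginal is taken to be exactly the
uniform density on the box — its correct limit — rather than a
numerically garbage reciprocal. Genuinely nonpositive *proposed*
precisions (a standard EP pathology) skip that flux's update for the sweep
and push $d_n$ toward `d_max`, with a logged counter.

**Damping.** Parallel EP without damping can oscillate when stoichiometric
rows are strongly correlated. The default retains half of the old natural
parameters (`damp = 0.5`). Heavier fixed damping is counterproductive: it
shrinks the per-sweep change that $\varepsilon$ measures by the same
factor, so runs can pass `tol` while still far from the moment-matching
fixed point (with `damp = 0.9` the observed fixed-point gap was an order
of magnitude above the tolerance). Instead, `run_ep()` escalates damping
*only on evidence of stagnation*: every 20 sweeps, if $\varepsilon$ has
not halved, `damp` moves halfway toward 0.95. The policy is deterministic
and recorded in the run report.

**Convergence flooring.** Because the reported means equal the Gaussian
means only up to the moment-matching gap (itself of order `tol`), the
mass-balance residual $\lVert S\hat\nu - b\rVert_\infty$ cannot fall below
that gap no matter how large $\beta$ is. The $\beta$-ladder experiment
($\beta \in \{10^4, 10^6, 10^8, 10^{10}\}$ on the diamond network) is
therefore run at `tol = 1e-9`, where the residual tracks $1/\beta$
cleanly and monotonically; at the default tolerance the floor near
$6\times10^{-6}$ masks the trend from $\beta = 10^6$ upwards.

## What the generators emulate

`make_random(M, N, density, seed, bound_width)` draws sparse integer
stoichiometries with entries in $\{-2,-1,1,2\}$ and guarantees a nonempty
polytope by construction ($b = S\nu_0$ for a random interior $\nu_0$,
kept as a certificate). Nonzero $b$ exercises the intake terms.
`correlated_rows = TRUE` appends rows duplicating existing supports —
the row-correlation structure (ATP/ADP-like shared metabolites) that
defeats tree-based message passing and motivates EP. The generators do
*not* mimic genome-scale degree distributions, compartments, or realistic
reversibility patterns, so passing tests demonstrate correctness of the
machinery at fixture scale, not biological fidelity on a particular
organism. The validation protocol — Pearson correlation of EP means and
variances against hit-and-run moments for growing $T$ — is run at
$M = 10$, $N = 20$, $T = 10^6$, $10^4$ recorded samples, on twenty seeded
fixtures: sizes chosen so the whole protocol completes in seconds while
the null space (dimension 10) is still nontrivial.

The hit-and-run oracle walks in the orthonormal null-space
parametrisation of $S\nu = b$ with uniform chord steps, started from the
polytope's certificate or a Chebyshev-centre LP, thinned at fixed stride
with no further burn-in discard (adequate at fixture dimensions; a
production sampler is explicitly out of scope). Linear programs
(Chebyshev centre, `fba_min_flux()`) go through `boot::simplex` with
variable shifting; infinite bounds enter the LP as a large finite box
($10^9$).

## Known limitations

* **Gaussian-family bias at extreme anticorrelation.** For the two-flux
  segment ($\nu_1 + \nu_2 = 1$, boxes $[0,1]$) the exact marginal is
  uniform with variance $1/12$. The EP fixed point can be solved by hand:
  symmetry forces $d_1 = d_2 = d$ with the tilted variance equal to
  $d/2$, whose solution $d \approx 0.128$ reports variance $\approx
  0.064$ — about 23% below truth. This deficit is intrinsic to
  approximating a box by a single Gaussian factor under a hard pairwise
  constraint; it shrinks rapidly with dimension (the simplex variances
  for $N = 3, 5, 10$ are recovered within a few percent) and is asserted
  as a characterisation test rather than hidden.
* Variance *correlations* across fluxes are only informative when the
  true variances are heterogeneous; on the diamond fixture (all
  variances nearly equal) the per-flux relative band is the meaningful
  check and the Pearson coefficient is noise.
* $\beta$ above $\sim 10^{11}$ destabilises the updates; the likelihood
  precision is a modelling knob, not a free accuracy dial, and no
  free-energy optimisation over $\beta$ is attempted.
* Marginals are reported flux-by-flux; joint credible sets and
  non-Gaussian factor families are out of scope.
* SBML support is read-only (Level 3 core + fbc bounds);
  gene–protein–reaction rules and compartment semantics are ignored.
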