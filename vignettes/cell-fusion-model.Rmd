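---
title: "Coevolution of cell size and binary cell fusion: model and methods"
author: "fusevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution of cell size and binary cell fusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusevol)
```

## The life cycle and its assumptions

`fusevol` models a haploid unicellular population through discrete growth
cycles. A cycle consists of:

1. **Fission.** The population has fixed total mass `E` (the carrying
   capacity is set in mass, not cell number). A genotype with daughter-cell
   mass $m_i$ and frequency $f_i$ releases $N_i(0) = f_i E / m_i$ daughter
   cells. Daughter mass is a *compound* trait — mature mass divided by
   $2^n$ for $n$ divisions — treated as one continuous evolvable quantity;
   the package never tracks mature mass and division count separately.
2. **Fusion window.** For a fixed time $T$, daughter cells fuse pairwise by
   mass action, cross-genotype pairs at the average of the two rates:
   $\dot N_i = -\sum_j \tfrac{\alpha_i+\alpha_j}{2} N_i N_j$. Same-genotype
   pair counts accumulate as $\dot F_{ii} = \alpha_i N_i^2/2$, so that
   per-genotype cell number $N_i + 2F_{ii} + \sum_{j\ne i} F_{ij}$ is
   conserved exactly; this is the unique bookkeeping consistent with the
   monomorphic closed form $N(T) = N_0/(1+\alpha N_0 T)$.
3. **Survival.** Unfused cells survive with the Vance probability
   $S(m;\beta) = e^{-\beta/m}$; a fused pair survives as one cell of mass
   $m_i + m_j$, discounted by $1-C$. The cost $C\in[0,1]$ collapses three
   biological mechanisms (fusion failure, hindered growth of the
   binucleate, failed segregation) that are algebraically equivalent at the
   frequency level, so a single multiplicative scalar suffices.
4. **Renormalisation.** The next cycle's frequency of genotype $i$ is
   proportional to
   $N_i(T)S(m_i) + (1-C)\big[2F_{ii}S(2m_i) + \sum_{j\ne i}F_{ij}S(m_i{+}m_j)\big]$.
   A same-genotype fused cell carries two $i$ nuclei and therefore counts
   twice. This convention is forced by two requirements: costless fusion
   between equal-mass genotypes must leave frequencies unchanged, and the
   resident's per-capita weight must reduce to
   $m + E\alpha T(1-C)e^{\beta/2m}$ (up to a factor), which is the
   denominator of the closed-form selection gradients below. If every
   $\alpha$ is zero the update collapses to pure fission–survival,
   $f_i' \propto f_i S(m_i)/m_i$.

Frequencies between mutation events evolve deterministically (an
infinite-population assumption): there is no demographic drift, and
genotypes vanish only by falling below a pruning threshold.

## Selection gradients and the trait flow

Under rare, small mutations the traits follow the gradient flow
$\dot m = H_m$, $\dot\alpha = H_\alpha$ with

$$H_m = -\frac{4m(m-\beta) + A\,(4m-\beta)}{4m^2\,(m+A)},
\qquad
H_\alpha = -\frac{m\,(1-X)\,\ln(1+E\alpha T/m)}{2\alpha\,(A+m)},$$

where $X = (1-C)e^{\beta/2m}$ and $A = E\alpha T X$. Three anchors pin the
algebra and are asserted in tests: $H_m(m,0) = (\beta-m)/m^2$ exactly;
$H_m \to -(4m-\beta)/4m^2$ as $\alpha\to\infty$; and the boundary limit
$H_\alpha(m,0) = -(1-X)\,ET/2m$, whose sign flips at the saddle mass
$m_s = -\beta/(2\ln(1-C))$. Because selection at $\alpha=0$ can point out
of the physical region, the flow clamps $\alpha$ at zero whenever
$H_\alpha(m,0)<0$.

The attractor structure as the cost rises: below $1-e^{-1/2}\approx 0.393$
only the obligate-fusion manifold $(\beta/4, \infty)$ attracts; between
that and $C_{\mathrm{Base}}(ET)$ an interior saddle at
$\big(m_s,\; 4m_s(\beta-m_s)/[ET(4m_s-\beta)]\big)$ renders $(\beta,0)$
stable and the outcome initial-condition dependent; between
$C_{\mathrm{Base}}$ and $1-e^{-2}\approx 0.865$ the zero-fusion basin
covers the whole axis (small-mass starts still show a transient rise in
fusion); above $1-e^{-2}$ zero fusion is the only outcome. The interior
saddle's fusion rate is *derived* by solving $H_m=0$ at $m_s$ rather than
transcribed, because its printed closed form is sign-ambiguous; positivity
exactly on the middle cost band is a test.

`c_base(ET)` solves, in $L = \ln(1-C)$ on $(-2, -\tfrac12)$,

$$8(1+2L)^2\big[5+L(5+2L)\big] - (ET)^2 (2+L)^4 \ln\!\Big(\frac{6}{2+L}-3\Big) = 0 .$$

$L=-\tfrac12$ is an exact but spurious root of this expression (both
factors vanish there), so the bracket's upper end is nudged inward before
`uniroot()` is applied at tolerance $10^{-14}$. The root rises from
$1-e^{-1/2}$ (ET $\to 0$) towards $1-e^{-2}$ (ET $\to\infty$); convergence
to the upper bound is slow (the relative gap is still $\sim 4\times10^{-3}$
at $ET=10^4$ and reaches $10^{-3}$ only near $ET\sim10^6$), so the
limit checks in the test suite probe $ET = 10^{-3}$ and $10^{7}$.

**Accuracy of the separatrix construction.** The critical cost above is
built from a *linearisation* of the saddle's stable manifold. Numerically,
the exact cost at which the zero-fusion basin reaches the origin is
slightly higher (0.838 vs 0.826 at $ET=100$; 0.737 vs 0.730 at $ET=10$),
and at `c_base` itself the nonlinear separatrix still intercepts the axis
at $\approx 0.23\beta$. The package therefore offers both the closed form
(`c_base()`) and numerical basin classification (`separatrix()`, grid
method), and the tests assert the construction at this, its actual,
accuracy.

## Numerical choices

* **Fusion kinetics.** A Dormand–Prince 5(4) adaptive Runge–Kutta kernel
  (C++, `src/`) with relative tolerance $10^{-10}$, absolute $10^{-12}$;
  Runge–Kutta steps preserve the linear cell-number invariant to machine
  precision. When all rates coincide (including the ubiquitous
  $\alpha\equiv 0$ case) the exact solution is used instead. The kernel is
  cross-checked in tests against the closed form and a brute-force Euler
  oracle.
* **Trait flow.** `deSolve::lsodar` with root functions. The clamped field
  is discontinuous across $\alpha=0$, which makes naive integration
  chatter on the boundary; the flow is therefore integrated in alternating
  phases — a 2-D interior phase ending when the trajectory lands on the
  boundary with inward selection, and a 1-D sliding phase along the axis
  ending at lift-off (the boundary gradient turning nonnegative). Because
  $e^{\beta/2m}$ makes speeds astronomical at tiny masses while only the
  trajectory geometry is meaningful, the field's magnitude is capped at
  $10^3$ (a pure time reparametrisation). Divergence to obligate fusion is
  declared at $\alpha > 10^3/ET$; fixed points at gradient norm
  $<10^{-8}$.
* **Gradient overflow.** For $m \lesssim \beta/1400$ the factor
  $e^{\beta/2m}$ overflows doubles; both gradients then switch to their
  exact large-$A$ limiting forms.
* **Mutation scheme.** Events arrive after geometric waiting times from a
  single clock at rate $\mu \times (\#\text{evolvable traits})$ with a
  uniform trait choice — the exact superposition of independent per-trait
  processes ("Gillespie" here means discrete geometric waiting over
  integer growth cycles, matching the discrete-generation model). Proposals
  below $\alpha = 0$ or the mass floor are discarded with the event
  consumed, which respects the boundary without biasing $\alpha$ upward by
  reflection. Proposals are snapped to the boundary within $10^{-9}$ of a
  step: without this, accumulated floating-point error in repeated $\pm
  \delta$ steps can strand a genotype permanently one step above
  $\alpha=0$ (we observed exactly this pathology: a population frozen at
  $\alpha = \delta_\alpha$ because every return proposal computed to
  $-3\times10^{-18}$).
* **Genotype bookkeeping.** Trait vectors equal to tolerance $10^{-12}$
  are merged; genotypes below the pruning threshold are removed each cycle;
  a hard cap of $10^3$ concurrent genotypes turns runaway diversity into a
  configuration error.

## Default parameters (the simulated conditions)

The simulation defaults are `E = 100`, `T = 1`, `mu = 0.01` per trait per
cycle, `delta_m = delta_alpha = 0.02`, pruning threshold $10^{-6}$, mass
floor $10^{-3}$, and mutant seeding frequency $\min(10^{-3}, f_i/2)$
transferred from the ancestor. `ET = 100` puts the system in the large-`ET`
regime where the closed-form thresholds apply to good approximation; the
step size 0.02 matches the granularity of the switching-environment
protocols (initial mass 1.16, harshness 0.5 and 2.2, occupancy 0.7, cost
0.6). Where the source protocols leave values unstated (they are supplied
in an appendix we do not reproduce), these defaults are the package's
choices, fixed once and logged in every run's configuration echo.

For fixed-environment coevolution scans (the four cost regimes) the
reference harshness is $\beta = 1$, making the attractors $(1, 0)$ and
$m = 1/4$, with starting masses 0.02, 0.5 and 1.75 spanning the basins.
The regime-representative costs used in tests are 0.2, 0.5, 0.84 and 0.9.
The test runs are scaled to $1.5\times10^5$–$3\times10^5$ cycles (the full
protocols run to $1.5\times10^6$); at these lengths every panel reaches
its qualitative endpoint, and the fusion-disabled optimum-mass recovery
lands within 1 % of $\beta$ after $2\times10^5$ cycles with a 50 %
burn-in.

## What the simulator does and does not emulate

The generator reproduces the model's own idealisations: infinite
population between mutation events (no drift), strictly binary fusion,
linked traits with no recombination, instantaneous and costless phenotypic
switching, and an environment that is either fixed, switched on schedule,
or a two-state telegraph with geometric residence times. Passing tests
therefore demonstrate internal consistency of simulation and theory — not
that real populations satisfy these idealisations. Features of real data
the generator does not emulate include finite-population drift and
fixation, de novo variation in switching/sensing machinery, multi-cell
fusions, and any genetic (recombination) benefit of sex.

One genuine finite-step effect is worth knowing about: with mutational
steps of 0.02, escape excursions from very small initial masses ride
*above* the deterministic separatrix (both traits climb at the
mutation-limited speed, not along the gradient-flow path), so the
stochastic basin boundary sits slightly above the deterministic one near
the critical cost. The cost-regime tests use costs with a margin above
`c_base` for exactly this reason.

## Stationarity and ESS estimation

`estimate_ess()` time-averages the frequency-weighted trait means over the
post-burn-in window (default burn-in 50 %) and flags non-stationarity when
the two halves of the window differ by more than 1.5 within-window
standard deviations — a deliberately blunt diagnostic that catches
sustained drift (a run still converging) while tolerating the
autocorrelated fluctuation of a mutation–selection cloud around its
equilibrium.

## Known limitations

* The adaptive-dynamics analysis of the threshold-linear survival family
  is limited to what its closed forms support (the cost ceiling
  `threshold_linear_max_cost()`, boundary gradient signs via the generic
  machinery); no interior fixed-point theory is exposed for it.
* `c_base()` inherits the linearisation error described above; treat it as
  an approximation with known sign (it underestimates the exact coverage
  threshold by $\sim 1$–2 % over the `ET` range tested).
* Evolutionary branching at high fusion rates (the route to anisogamy) is
  out of scope; the flow reports divergence to the obligate-fusion
  manifold and stops there.
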