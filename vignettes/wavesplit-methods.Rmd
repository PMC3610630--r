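---
title: "Methods: eco-evolutionary wave splitting in cooperator-defector range expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary wave splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavesplit)
```

## The model

`wavesplit` studies a one-dimensional range expansion of a population
carrying two alleles (or phenotypes): cooperators, which produce a shared
benefit, and defectors, which free-ride on it.  Two classical processes are
coupled:

* **Ecology.** Population density $n(x,t)$ spreads by migration (a
  diffusion term with constant $D$) and grows with a per-capita rate
  subject to an Allee effect,
  $$g(n, f) = g_0(f)\Bigl(1 - \frac{n}{K(f)}\Bigr)
              \Bigl(\frac{n}{K(f)} - \frac{n^*(f)}{K(f)}\Bigr),$$
  the standard cubic form with carrying capacity $K$ and Allee threshold
  $n^*$ (growth is negative below $n^*$ when $n^* > 0$).  Because the
  shared benefit is produced by cooperators, the growth parameters may
  depend on the defector frequency $f$; by default the Allee threshold
  rises linearly with $f$ — a population that is mostly defectors needs a
  higher density of residents to assemble enough cooperators.

* **Evolution.** The defector frequency $f(x,t)$ diffuses with the *same*
  $D$ (both processes are the same migration) and changes under linear
  frequency-dependent selection,
  $$\partial_t f \supset f(1-f)\,w(n,f), \qquad
    w(n, f) = s(n)\bigl(f^*(n) - f\bigr),$$
  the weak-selection limit of a snowdrift-type game with preferred
  (coexistence) defector frequency $f^*$.  Density dependence enters
  through $f^*(n)$: defectors are favored in crowded populations
  ($f^* = f_{high} > 0$ for $n > n_c$) and disfavored, possibly strongly
  ($f^* = f_{low} \le f_{high}$, allowed negative), below the critical
  density $n_c$.  The Heaviside step is right-continuous
  ($\Theta(0) = 1$) and may be smoothed over a density width
  `smooth_eps`.

In terms of the species densities $c = n(1-f)$ (cooperators) and
$d = n f$ (defectors) the coupled system is
$$\partial_t c = D\,\partial_x^2 c + c\,[g(n,f) - f\,w(n,f)], \qquad
  \partial_t d = D\,\partial_x^2 d + d\,[g(n,f) + (1-f)\,w(n,f)].$$
Rewriting in $(n, f)$ variables produces the same reaction terms plus the
gradient-coupling advection $2D\,(\partial_x \ln n)(\partial_x f)$ in the
$f$ equation: high-density regions send out more migrants, so migration
drags the composition of the dense side into the sparse side.  This term
is the engine of everything interesting that follows.  The two
formulations are exact algebraic transforms of one another; the package
integrates $(c,d)$ as the primary path because it needs no special
handling where $n \to 0$, and carries the $(n,f)$ solver purely as a
validation path (`run_wave(..., formulation = "nf")`).

Assumptions worth keeping in mind: migration is short-ranged and isotropic
(hence diffusion), both alleles disperse identically, there are no
mutational transitions between the alleles, selection is of the
negative-frequency-dependence type ($s \ge 0$, coexistence rather than
bistability), and the habitat is one-dimensional (front curvature and
transverse structure are out of scope).

## Closed forms

For parameters frozen at a fixed composition the model reduces to
single-field waves with known results, all exposed in the `analytic`
functions:

* **Expansion velocity** (`expansion_velocity`): for the cubic law the
  pushed-front velocity is exact,
  $$v_C = \sqrt{\tfrac{D g_0}{2}}\,\Bigl(1 - \frac{2 n^*}{K}\Bigr),$$
  valid for $n^*/K > -1/2$.  A front with $n^* = K/2$ stalls (the cubic
  is symmetric under $n \to K - n$), and a deeper Allee effect always
  slows the wave.  For $n^*/K \le -1/2$ the front is pulled and the
  package returns the linear-spreading velocity
  $2\sqrt{D g_0 |n^*|/K}$ with a regime flag; the two expressions join
  continuously at $n^*/K = -1/2$.

* **Front profile** (`front_profile`): in the pushed regime the comoving
  profile is exactly $n(\zeta) = K/(1 + e^{\zeta/w})$ with width
  $w = \sqrt{2D/g_0}$, centered here so that $n(0) = K/2$ — the same
  half-maximum convention the front tracker uses.

* **Invasion velocity** (`invasion_velocity`): rare defectors in a
  resident population at density $n$ grow at rate $s(n) f^*(n)$ and
  spread as a pulled (KPP) front with
  $v_D = 2\sqrt{D\, s(n)\, f^*(n)}$; if $f^*(n) \le 0$ they cannot invade.

* **Decoupled mixed wave** (`mixed_velocity_decoupled`): when selection is
  density-independent, $f = f^*$ is attracting everywhere, the
  composition freezes, and the mixed wave is a pure expansion with
  parameters evaluated at $f^*$ — hence never faster than the
  pure-cooperator wave, and splitting is impossible no matter the initial
  condition.

## The splitting criterion

When $v_C > v_D$ the mixed wave has two possible fates.  Either a steady
composition profile travels with the population front (a *mixed wave*), or
cooperators shed the defectors: the population wave runs ahead as pure
cooperators at $v_C$ while defectors follow as a slower invasion wave —
*wave splitting* — and the defector-free territory grows linearly.

The criterion is spectral.  In the frame comoving with the cooperator
front, rare defectors obey the linear operator
$$\mathcal{L}\,\phi = D\phi'' + \bigl(v_C + a(\zeta)\bigr)\phi'
   + s(n)f^*(n)\,\phi, \qquad a(\zeta) = 2D\,\frac{n'(\zeta)}{n(\zeta)} \le 0 .$$
Written conservatively, the gradient coupling contributes an effective
advection $-a \ge 0$ towards the tip and an effective growth
$-a' \ge 0$ that peaks exactly at the half-maximum point of the front
(`effective_terms`; on the exact profile these are
$\sqrt{2Dg_0}(1 - n/K)$ and $g_0 (n/K)(1-n/K)$).  The Liouville
substitution $\phi = \psi \exp[-\int (v_C + a)/(2D)\,d\zeta]$ makes the
operator self-adjoint,
$$\lambda\,\psi = D \psi'' - U(\zeta)\,\psi, \qquad
  U = \frac{(v_C + a)^2}{4D} + \frac{a'}{2} - s(n) f^*(n),$$
(`schroedinger_potential`).  The plateaus of $U$ encode the velocity
comparison: behind the front $U(-\infty) = (v_C^2 - v_D^2)/(4D)$, positive
exactly when the expansion outruns the invasion; ahead of the front $U$ is
positive when defectors are sufficiently disfavored at low density.  In
between, the $a'/2$ term digs a finite potential well centered on the
front.  A steady mixed wave exists precisely when this well supports a
bound state with $\lambda_{max} > 0$; `predict_splitting` therefore
reports `splits = (lambda_max <= 0)`, with the margin quoted in units of
$s$ so that parameter sweeps are comparable.  Multiplying the eigenvalue
equation by $\psi$ and integrating shows that a region of negative $U$ is
necessary (`necessary_condition`), and the discrete form of that identity
is checked to round-off.

**Exactly solvable case.** With frequency-independent ecology, constant
$s$ and $f^* = f_{high}$ above $n_c$, and defectors *non-viable* below
$n_c$ (an absorbing condition where the front density crosses $n_c$), the
marginal eigenproblem on the exact profile can be solved in closed form.
In the scaled variable $y = 1 - n/K \in (0,1)$ and with
$\beta = v_C/\sqrt{2Dg_0}$, $\beta_D = v_D/\sqrt{2Dg_0}$,
$$\psi(y) = y^{p} (1-y)^{q}\,
   {}_2F_1\bigl(p+q-1,\; p+q+2;\; 2p+1;\; y\bigr), \qquad
  p = \sqrt{\beta^2 - \beta_D^2},\;\; q = \sqrt{(1-\beta)^2 - \beta_D^2},$$
is the $\lambda = 0$ solution decaying into the bulk.  By Sturm
oscillation, the absorbing domain supports a $\lambda \ge 0$ bound state
iff the absorbing point $y_c = 1 - n_c/K$ lies beyond the first zero
$y_0$ of $\psi$; splitting therefore occurs exactly when
$n_c > K(1 - y_0)$ (`splitting_threshold_exact`).  As $v_D \to v_C$,
$p \to 0$ and $y_0 \to 0$: the critical density climbs towards $K$ and
splitting becomes impossible, while for $v_D \ge v_C$ no choice of $n_c$
splits the wave.  The Gauss hypergeometric function is evaluated by its
series with the Euler transformation near the unit argument (`hyp2f1`);
no installed routine provides it.  The package verifies this closed form
against the discretized operator: the two thresholds agree to $5\times
10^{-4}$ in $n_c$, and a PDE sweep brackets both.

In the general coupled model the front near the transition is populated
almost exclusively by cooperators, so the same predictor applies with the
growth parameters evaluated at $f = 0$; far from the transition the PDE
classifier (`classify_outcome`) is the arbiter.

## Numerical choices

* **Scheme.** Explicit forward-time centered-space (4-point stencil) on a
  cell-centered grid, reflecting ghost cells for no-flux boundaries.
  Stability requires $\Delta t \le \Delta x^2/(2D)$; `wave_grid` enforces
  it and defaults to 40% of the bound.  Default $\Delta x$ is one tenth of
  the front width $w$ — at that resolution measured wave speeds sit within
  about 0.04% of the closed forms, comfortably inside the 1% agreement the
  package's acceptance suite demands, and halving $\Delta x$ moves them by
  less than 0.5%.
* **Negative overshoot.** Values in $(-10^{-12} K, 0)$ are clipped to 0
  (round-off); anything more negative, or non-finite, aborts with a
  blow-up diagnostic rather than silently corrupting the run.
* **Front tracking.** The front is the rightmost half-bulk crossing,
  linearly interpolated; the bulk value is the mean over the leftmost 5%
  of occupied cells.  A profile everywhere below half-bulk yields an
  undefined-front signal (`NA`), not an error.
* **Velocities.** Least squares on the final third of the trace.  Pulled
  fronts converge from below like $1/t$; `estimate_velocity(pulled =
  TRUE)` adds $\log t$ and $t^{-1/2}$ regressors, which brings the
  invasion-wave estimate within 1% on a habitat of ~200 front widths.
* **Classification.** The velocity tie-break is $\epsilon_v = 3\times$
  the larger standard error of the two fits (scale-free; sharpens with
  run length).  Near the splitting threshold transients decay slowly, so
  "split" additionally requires the lag growth rate in the final third to
  be at least 60% of the mid-run rate — a decaying lag growth marks a
  still-equilibrating mixed wave, not a split.  A lag that grew beyond
  twice the front width and then shrank back is "transient".  Phase scans
  (`phase_scan`) rerun verdict-boundary neighbors with a doubled habitat
  and time budget before accepting the flip.
* **Eigen solver.** Symmetric tridiagonal discretization; the largest
  eigenvalue by Sturm-sequence bisection (robust, no dense algebra), the
  eigenfunction by shifted inverse iteration.  The domain is truncated at
  15 front widths on each side (the potential plateaus exponentially) with
  Dirichlet ends; for the absorbing case a node is placed exactly on the
  $n = n_c$ crossing so the cut converges at second order.  Eigenvalues
  are computed at two resolutions, Richardson-extrapolated, and the run
  aborts if the two estimates disagree beyond $10^{-3}\max(|\lambda|, s)$.
  A sharp selection step is smoothed over $0.5\%$ of $K$ for spectral work
  (a discontinuous potential slows convergence without changing
  bound-state existence); verdicts are checked stable as the smoothing
  shrinks.
* **The $(n,f)$ validation path** needs states bounded away from $n = 0$:
  the advection ratio $n'/n$ is an ill-conditioned $0/0$ in empty habitat
  (one more reason the species form is primary).  The equivalence test
  therefore compares the two solvers on a front-like state with a small
  density floor, where their difference contracts by the expected factor
  of 4 per halving of $\Delta x$.

## The individual-based model

The lattice simulator is the package's noise generator: sites of capacity
$N$, one possible migration event and one possible birth-or-death event
per site per time step (left-to-right sweep), $N$ steps per generation so
that each individual experiences on average one demographic event per
generation.  With local density $\rho = n/N$ and Allee fraction
$\rho^* = n^*(f)$,
$$P_{birth} = g_0 (1 + \rho^*) \rho^2, \qquad
  P_{death} = g_0 (\rho^3 + \rho^* \rho),$$
whose difference $g_0\rho(1-\rho)(\rho-\rho^*)$ per step reproduces the
cubic drift exactly (time in generations, capacity 1); the quadratic birth
term is the cooperative-group mechanism behind the Allee effect.  Deaths
remove a uniformly chosen resident (selectively neutral).  Births are
cooperators with the payoff-share probability
$(1-f)\pi_C / [(1-f)\pi_C + f\pi_D]$ built from the interaction matrix
$A_{CC} = A_{CD} = 1$, $A_{DC} = 1 + s f^*(\rho)$,
$A_{DD} = 1 - s(1 - f^*(\rho))$, so the defector-cooperator payoff gap is
$s(f^*(\rho) - f)$ — the lattice mirror of the selection law.  Migration
fires with probability $m\,n/N$ and moves one uniform resident to a
uniform neighbor (reflecting ends), giving per-generation fluxes $m n/2$
each way and the continuum limit $D = m/2$.  At capacity $N = 120$ the
measured pure-cooperator front speed is within ~5% of the matched PDE
value, closing the loop between the two engines.  Both probability laws
can be replaced by injected callables (the pure-R stepper honors them),
so alternative demographies drop in without code change.  In the far
above-capacity tail ($\rho \gtrsim 1.2$, reachable only by extreme
fluctuations) death takes priority when the two probabilities would
exceed one.

**Stochastic splitting.** When $v_C > v_D$ but the deterministic criterion
says "mixed", number fluctuations still split the wave: a rare fluctuation
opens a defector-free region at the front wider than the invasion-front
width, and since invasion is slower than expansion the gap then grows
deterministically.  `detect_stochastic_split` flags the earliest
generation at which the front lag exceeds three invasion-front widths and
stays there for a confirmation window; `splitting_time_experiment` reports
mean waiting times with the standard deviation of the mean,
right-censoring (never dropping) replicates that do not split.  Waiting
times grow steeply with $N$ and with $m$ — both enlarge the number of
organisms in the front region and hence suppress the fluctuations that
nucleate splitting.

## Study conditions (presets) and problem sizes

All PDE presets use nondimensional units $D = g_0 = K = 1$ (so lengths
are in units of $\sqrt{D/g_0}$ and times in $1/g_0$); the defaults were
fixed once, on the following grounds, and the tests and the acceptance
script run exactly these conditions:

* `mixed_wave` / `split_wave`: $n^*(f) = 0.2 + 0.3 f$ (strong Allee
  effect, worsened by defectors), $s = 0.1$, $f_{high} = 0.3$,
  $f_{low} = -1$, differing *only* in $n_c$ (0.2 vs 0.7).  Here
  $v_C = 0.424$, $v_D = 0.346$, and the spectral threshold sits at
  $n_c^* \approx 0.63$, so the pair straddles it.
* `transient_strip`: the same family at $n_c = 0.45$ (below threshold,
  $\lambda_{max} \approx +0.012$) started from a 25-unit engineered
  pure-cooperator strip: the strip lets cooperators bolt transiently, but
  any state with a nonzero projection on the positive mode is eventually
  recaptured — the textbook distinction between initial-condition
  engineering and a true instability.
* `slow_acceleration`: slow selection $s = 0.05 \ll g_0$, strong coupling
  $n^*(f) = 0.15 + 0.5f$, $f^*$ from 0.5 to $-0.5$ at $n_c = 0.3$,
  non-splitting.  The front composition creeps from the bulk value toward
  its low-density optimum and the front speed rises monotonically from
  0.162 to an asymptote of 0.171, well below the pure-cooperator 0.495.
* `special_case`: $n^* = 0.05$, $s = 0.05$, $f_{high} = 0.5$, defectors
  non-viable below $n_c$ — the exactly solvable family; its closed-form
  threshold is $n_c^{crit} = 0.0692$.
* `abm_stochastic`: $m = 0.5$, $g_0 = 0.2$, $s = 0.08$, $f_{high} = 0.3$,
  $f_{low} = -1$, $n_c = 0.35$, $N \sim 10$–$20$ on ~220 sites.  The
  matched continuum model has $v_C = 0.095 > v_D = 0.076$ per generation
  and a deterministic threshold near $n_c = 0.62$, so splitting at
  $n_c = 0.35$ is purely fluctuation-driven; small capacities keep mean
  waiting times at a few hundred generations so that tens of replicates
  are cheap.

Habitats of 200–450 front widths, grids of $\Delta x = 0.1$–$0.15\,w$ and
20 replicates per ABM point keep the full test suite in the few-minutes
range on a single core while leaving each measured quantity an order of
magnitude inside its tolerance; these sizes are the package's default
experimental design, and all of them scale up by changing one argument.

## What the generator does and does not emulate

The synthetic conditions exercise exactly the mechanisms the model is
about — Allee growth, density-gated selection, gradient-driven advection,
demographic noise — under controlled, reproducible parameters.  They do
not emulate environmental heterogeneity or temporal fluctuation,
long-range dispersal, mutation between the alleles, more than two types,
or two-dimensional front geometry.  A passing suite therefore certifies
the implementation of this model class, not the behavior of any
particular natural population; mapping a real system onto these laws (and
checking that its dispersal is genuinely short-ranged and its selection
genuinely frequency-linear) is the user's modeling step.

## Known limitations

* Near the splitting threshold the PDE classifier's resolution is set by
  how slowly transients decay ($\sim 1/|\lambda_{max}|$); verdicts within
  one scan step of the boundary should be settled with
  `predict_splitting`, which is sharp there.
* The exact threshold applies to the absorbing special case only; for
  finite $f_{low}$ the spectral threshold moves (the sub-$n_c$ region is
  a finite, penetrable barrier) and the absorbing limit is approached
  like the penetration length $\sqrt{D/(s|f_{low}|)}$.
* The eigen predictor linearizes about the pure-cooperator front; far
  from the transition in strongly coupled parameter regions the PDE
  classifier is the authority.
* The ABM's effective selection strength scales like
  $s\,g_0(1+\rho^*)\rho$ (selection acts through births), so ABM and PDE
  selection parameters correspond only after this mapping.
* Velocities of pulled fronts converge like $1/t$; without the
  extrapolating fit, finite-time estimates are biased low by several
  percent.
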