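---
title: "A spatial stochastic model of mitochondrial quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial stochastic model of mitochondrial quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mitonet` simulates a population of mitochondria inside a two-dimensional
square cell as hard disks of radius $r$ that move, collide, fuse, divide,
are degraded, and are replaced. The functional state of each mitochondrion
is condensed into a single *health* variable — a proxy for the
inner-membrane potential $\Delta\psi_m$ — represented as $N_{HU}$ binary
*health units* (HUs, e.g. undamaged mtDNA copies). Health is the fraction
of undamaged units, so it lives on the lattice
$\{0, 1/N_{HU}, \dots, 1\}$.

Six stochastic processes act on the population in discrete time steps of
$\Delta t$ (an event of rate $k$ fires within a step with probability
$1 - e^{-k \Delta t}$):

* **Damage.** Each healthy unit flips to the damaged state at rate
  $k_d$ per unit. Damaged units never recover, so an isolated population
  decays exponentially: $\bar h(t) = \bar h(0)\,e^{-k_d t}$.
* **Transport.** Unfused mitochondria perform a persistent random walk
  along an implicit, isotropic cytoskeletal network: a stationary
  mitochondrion binds a filament at rate $k_{on}$ with a uniformly random
  direction, moves at constant speed $v$, and unbinds at rate $k_{off}$,
  on hitting another mitochondrion (center distance $2r$), or at the cell
  wall. Fused mitochondria do not move.
* **Fusion.** Every touching pair (center distance $\le 2r +$ tol) whose
  members both have health at or above the fusion threshold $h_{fus}$
  fuses at rate $k_{fus}$, adding a bond to the fusion graph; repeated
  fusion builds networks of more than two mitochondria. The rate is scaled
  by $1$, $\alpha$, or $\beta$ ($\beta \le \alpha \le 1$) according to
  whether both, one, or neither partner was in motion in the transport
  sub-step in which the contact was evaluated.
* **Fission.** Each bond breaks independently at rate $k_{fis}$. At the
  moment of separation the two endpoint mitochondria exchange
  $n_{ex}$ randomly chosen health units — the model's mechanism for
  generating the post-fission health asymmetry that selective turnover
  exploits. The exchange conserves healthy units; exchanging $n$ and
  $N_{HU} - n$ units is statistically equivalent because the two partner
  identities can be swapped.
* **Autophagy.** Each *unfused* mitochondrion with health strictly below
  the threshold $h_{aut}$ is removed at rate $k_{aut}$; fused mitochondria
  are protected (the autophagosome size limit is taken to be a single
  mitochondrion).
* **Replication.** At most one event per cell per step: with total
  propensity $N k_{rep}\, g(N)$ a uniformly chosen mitochondrion is
  copied (identical health-unit vector) to a random non-overlapping
  position. The population-limiting factor
  $g(N) = 1 / (1 + e^{(N - N_0)/\sigma_N})$ is monotone non-increasing
  and vanishes for large $N$; it is isolated behind
  `replication_rate()` so alternative cutoffs with the same asymptotics
  can be swapped in.

Autophagy and replication can additionally be rate-capped: each process is
halted while more than `cap_autophagy` (respectively `cap_replication`)
events have occurred in the trailing 180-minute window, and resumes as
events age out of the window.

## Parameters

Defaults (see `mito_params()`) describe a 25 × 25 µm cell seeded with 150
mitochondria of radius 0.5 µm (filling fraction ≈ 0.19), 10 HUs per
mitochondrion of which 2 are exchanged at fission, thresholds
$h_{aut} = h_{fus} = 0.3$, rates $k_d = 5\times10^{-4}$,
$k_{fus} = k_{fis} = 0.1$, $k_{aut} = 3.33\times10^{-3}$,
$k_{rep} = 0.02$ (all min⁻¹), $v = 0.5$ µm/min, $\Delta t = 1$ min,
10000 simulated minutes, and 25-cell ensembles. Each HU starts healthy
with probability 1/2, so initial healths are Binomial($N_{HU}$, 1/2)
draws with mean 0.5.

Two transport constants are not direct observables and were calibrated:
`calibrate_transport()` grid-searches $(k_{on}, k_{off})$ against the
observed fusion accounting at default parameters — an overall fusion
frequency of ~168 events/hr with ~70/25/5% of events coming from
both-/one-/neither-moving contact pairs. The stored defaults
($k_{on} = 8$, $k_{off} = 0.002$ min⁻¹) are that search's optimum: they
reproduce the fusion frequency and the small neither-moving class well,
while the one-moving class saturates near 35% rather than 25% — fused
network members are never in motion, so every fusion that recruits a
network member is classified one-moving, and with roughly a fifth of the
population in networks at steady state this share cannot be pushed lower
by transport rates alone. `calibrate_transport()` reports achieved
observables and a convergence flag so users can re-calibrate under other
conditions.

The damage rate is interpreted per health unit (not per mitochondrion),
giving healthy units a mean lifetime of 2000 minutes — the reading
consistent with units losing function over days; the alternative
per-mitochondrion interpretation can be emulated by rescaling `k_damage`.

With the logistic population limit and $\sigma_N = 15$ the population
equilibrates where replication balances autophagy, at roughly
$N_0 + 3\sigma_N \approx 200$ rather than at $N_0$ itself; narrower
$\sigma_N$ pins the population closer to $N_0$ at the cost of a lower
fusion frequency (fewer contacts). This sensitivity is worth keeping in
mind when comparing scan positions quoted at the *nominal* filling
fraction, which is computed from the initial population.

## Numerical choices

* **Sub-step order.** Each step applies damage → transport → contact
  detection → fusion → fission → autophagy → replication, then advances
  the clock. With per-step probabilities ≲ 0.1 the ordering bias is
  second order in $\Delta t$. The order also makes same-step
  fuse-and-degrade coincidences impossible (asserted in the tests).
* **Movement.** Movers advance in random order within a step; earlier
  movers are obstacles for later ones. A mover truncated by contact or
  wall detaches from its filament (it may rebind the next step); the
  first-contact point is found by exact ray–disk intersection, and
  positions are clamped to $[r, L - r]^2$ against floating-point drift.
* **Contact tolerance.** Touching means center distance
  $\le 2r + $ `tol` with `tol` = 0.01 µm (2% of the radius), needed
  because contact-truncated movers stop at exactly $2r$.
* **Threshold conventions.** Autophagy eligibility is *strictly below*
  $h_{aut}$; fusion eligibility is *at or above* $h_{fus}$, so equal
  thresholds leave no dead zone on the health lattice.
* **Initialization.** Positions are uniform rejection samples with
  hard-disk exclusion. Above ~45% filling fraction rejection sampling
  jams (the random-sequential-addition limit for disks is ≈ 0.547), so
  dense initializations switch to a triangular lattice with the largest
  spacing that fits the population, each site jittered uniformly within
  its clearance. Replication placements that find no free position
  within the attempt budget are skipped and logged.
* **Density transition metric.** On the uneven density grid the
  "steepest rise" of fusion frequency is the largest difference quotient
  between consecutive grid points, attributed to the upper point
  (`density_transition()`).
* **Determinism.** All randomness — including inside the compiled core —
  is drawn from R's RNG. Per-cell seeds derive deterministically from a
  master seed, so ensembles reproduce bit-exactly and independently of
  execution order, and the R-level sub-step wrappers consume the stream
  exactly as the compiled whole-run loop (regression-tested).

## What the simulations do and do not emulate

The generator reproduces the study conditions the model was built for:
fixed-size circular mitochondria in an empty square cell, an isotropic
filament network, health as a single discrete variable, and constant
rates. It does not emulate explicit membrane-potential or ATP/ROS
biochemistry, size variation among mitochondria, multi-species content
exchange (complementarity), intracellular obstacles or 3D geometry, or
cell growth and division. Conclusions from passing tests therefore
concern the model's internal consistency and its characterized emergent
behavior — not quantitative agreement with any particular cell type.

Known behavioral notes, measured with this implementation at the
defaults: the fusion-frequency-vs-density curve rises smoothly (nearly
linearly) over 1–19% filling rather than switching sharply near 5%, so
the location of its steepest rise on a finite grid is noise-sensitive;
and mean steady-state health continues to gain ~20% between 5% and 55%
filling rather than saturating below 10%. Both are documented honestly by
the acceptance checks rather than hidden by loosened tolerances.

## Test and experiment scales

The unit suite runs tiny fixtures (20 mitochondria, 500 minutes, 3
cells) that preserve the dimensionless ratios of the defaults (filling
fraction, rate × $\Delta t$ products, $N_0$ = initial population). The
acceptance checks use 25 cells × 10000 min for the fusion accounting,
10 cells × 6000 min per point for the exchange scan, 6 cells × 10000 min
per point for the density scans, and 4 cells × 5000–6000 min per point
for the threshold, cap, and discreteness scans — ensemble sizes chosen
so each check resolves its effect well beyond its Monte-Carlo error.

## A worked example

```{r, eval = FALSE}
library(mitonet)

p <- mito_params()            # reference conditions
ens <- run_ensemble(p, n_cells = 25, master_seed = 1)
steady_state_summary(ens)     # health, population, fusion accounting

# exchange-count scan (scaled down)
sp <- experiment_preset("exchange-scan", n_cells = 10, t_sim = 6000)
res <- run_experiment(sp, master_seed = 1)
res$points[, c("n_exchange", "mean_health")]
```
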