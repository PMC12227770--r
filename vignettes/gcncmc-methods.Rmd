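---
title: "Grand canonical nonequilibrium candidate Monte Carlo on toy molecular systems"
author: "gcncmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grand canonical nonequilibrium candidate Monte Carlo on toy molecular systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcncmc)
```

## The method

Grand canonical Monte Carlo (GCMC) samples the $\mu VT$ ensemble by
attempting trial insertions and deletions of molecules in a region of
interest, so that the region stays in equilibrium with a notional reference
solution of fixed chemical potential. The control parameter is the
dimensionless Adams value $B$, which for a species with excess chemical
potential $\mu'_\mathrm{sol}$ at reference concentration $c$ is

$$B_\mathrm{eq}(c) \;=\; \beta\,\mu'_\mathrm{sol}
  \;+\; \ln\!\frac{V_\mathrm{GCMC}}{V(c)},
  \qquad V(c) = \frac{1}{c\,N_A},$$

with $V_\mathrm{GCMC}$ the region volume and $V(c)$ the average volume per
molecule in the reference solution. Raising $B$ (equivalently, the
reference concentration) drives insertions; lowering it drives deletions.

Instantaneous insertions of a molecule into a condensed environment are
almost always rejected: the new molecule overlaps whatever is already
there. Nonequilibrium candidate Monte Carlo (NCMC) replaces the
instantaneous switch by a gradual alchemical one. A "ghost" (fully
decoupled) molecule is placed at a uniform random position and orientation
in the region and its intermolecular interactions are switched on over
`nPert` perturbation steps, with `nProp` steps of thermostatted dynamics
between consecutive perturbations so the environment can relax; a deletion
runs the same schedule in reverse on a randomly chosen real molecule in the
region. The switching time is

$$\tau = (n_\mathrm{pert}+1)\, n_\mathrm{prop}\, \delta t ,$$

because every move starts and ends with a propagation block. The protocol
work is the sum of the fixed-configuration potential-energy changes across
the $\lambda$ jumps,

$$w(X\mid\Lambda_p) = \sum_{i} \big[\,U(x_i;\lambda_{i+1}) -
U(x_i;\lambda_i)\,\big],$$

and excludes the heat exchanged with the thermostat during relaxation.
The spherical-region acceptance probabilities are

$$P_\mathrm{insert}=\min\!\Big[1,\tfrac{1}{N_T}\,
  e^{B_\mathrm{eq}}\,e^{-\beta w}\Big], \qquad
  P_\mathrm{delete}=\min\!\Big[1, N_0\,
  e^{-B_\mathrm{eq}}\,e^{-\beta w}\Big],$$

where $N_0$ and $N_T$ count the molecules of the switched species inside
the region at the start and end of the move (the switched molecule counts
itself while its membership point -- the centre of geometry -- is inside).
If the switched molecule's membership point lies outside a spherical
region at the end of the move, the move is rejected automatically: the
reverse proposal could not be generated, so accepting would break detailed
balance. On rejection the pre-move configuration is restored and all
velocities are redrawn from the Maxwell-Boltzmann distribution, which is a
valid refreshment under Langevin dynamics and avoids momentum-reversal
bookkeeping.

Because the acceptance test depends on $B$, titrating $B$ over a scan of
chains traces out a binding curve. For a single-site binder the mean
occupancy follows a logistic in $B$,

$$N(B_\mathrm{eq}) = \frac{1}{1+\exp[k\,(B_{50}-B_\mathrm{eq})]},$$

whose midpoint $B_{50}$ maps to the dissociation constant through the same
Adams relation evaluated at $c=K_D$, and on to the standard binding free
energy $\Delta G^\circ = k_B T\,\ln(K_D/c^\circ)$. Per-repeat logistic
fits give per-repeat $K_D$ values; the mean and standard error of the mean
over repeats are reported, and the concentration-scale fit is an exact
reparameterisation of the $B$-scale fit (checked to $10^{-8}$ relative in
the tests).

## Toy systems instead of force fields

All sampling here runs on self-contained toy particle systems: single-site
molecules with optional Lennard-Jones parameters, cutoff-truncated
Coulomb, an optional constant same-species pair term, and external
gaussian binding wells standing in for protein pockets. This keeps every
ensemble property either analytic or computable by deterministic
quadrature, so the engine can be validated end to end:

* **Ideal gas** (`makeIdealGas`): the grand-canonical number distribution
  in the region is exactly Poisson with mean $e^B$.
* **Mean-field gas** (`makeMeanFieldGas`): a constant pair energy $u$ of
  infinite range gives enumerable weights
  $P(N)\propto e^{BN} e^{-\beta u N(N-1)/2}/N!$ -- the reference for the
  sampled state frequencies.
* **Single binding well** (`makeSingleWell`): one gaussian well,
  single occupancy enforced by a large constant pair repulsion, whole-box
  region. The configuration integral
  $z=\langle e^{-\beta U}\rangle_{V}$ is computed by grid quadrature, so
  $B_{50}=-\ln z$, $K_D$ and $\Delta G^\circ$ are known exactly and the
  occupancy is a unit-slope logistic in $B$ (a Langmuir two-state system).
* **Double well** (`makeDoubleWell`): two gaussian wells on the $x$ axis;
  the minor depth is solved numerically so the bound-state populations
  match a requested free-energy split (default $0.79\,k_BT$, i.e. 69:31).
  The truth block carries dihedral reference sites whose bins separate the
  two modes exactly along the dividing plane.

What the toys deliberately do not emulate: molecular detail (rotamers,
internal degrees of freedom, water networks), long-range electrostatics,
pressure coupling, and the force-field energetics of real ligands. Passing
tests therefore demonstrate the correctness of the sampling machinery and
estimators, not force-field accuracy on real systems.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| temperature | K | 298 | thermostat and all $\beta$ factors |
| cutoff | A | 12 | plain truncation, no switching function, no tail correction |
| friction | ps$^{-1}$ | 1 | Langevin BAOAB thermostat |
| time step | fs | 2 (4 in most toy runs) | toy masses of 40 amu tolerate 4 fs |
| `nPert`, `nProp` | -- | per protocol | switch length $\tau=(n_\mathrm{pert}+1)n_\mathrm{prop}\delta t$ |
| soft-core $\alpha$ | -- | 0.5 | Beutler-style 1-1-6 form |
| `stageSplit` | -- | 0.5 | fraction of the $\lambda$ path in the LJ stage |
| grid spacing | A | 0.5 | occupancy-grid voxel spacing |
| capture radius | A | 1.6 | voxel counted if a probe site is within this radius |
| equilibration | cycles | 200 | discarded before averaging |
| reject limit | moves | 200 | consecutive-rejection early stop |

The soft-core form is
$U = 4\varepsilon\lambda\big[(\alpha(1-\lambda)+(r/\sigma)^6)^{-2} -
(\alpha(1-\lambda)+(r/\sigma)^6)^{-1}\big]$: finite at $r=0$ for
$\lambda<1$ and exactly plain LJ at $\lambda=1$. On insertion the LJ stage
completes before electrostatics are scaled in (linearly, on the truncated
Coulomb term), so no bare charge is ever exposed without a steric
envelope; deletion reverses the order. Within each stage the $\lambda$
spacing is uniform, and the LJ stage takes
$\lceil \mathrm{stageSplit}\cdot n_\mathrm{pert}\rceil$ perturbations.

## Numerical choices and degenerate inputs

* Energies are capped per pair term at $10^8$ kcal/mol so overlapping
  fully-coupled sites give large but finite energies; non-finite forces
  abort propagation with a diagnostic.
* The constant same-species pair term is treated as structural and is
  *not* subject to the nonbonded cutoff; otherwise single-occupancy
  exclusion would silently vanish in boxes wider than the cutoff.
* Logistic fits use Levenberg-Marquardt least squares with $B_{50}$
  bounded inside the scanned range extended by one range width and $k>0$;
  $B_{50}$ is initialised at the interpolated first 0.5 crossing and $k$
  at 1. All-empty or all-saturated repeats are reported as failed and
  excluded rather than fitted.
* Deletions proposed with an empty region are recorded as skipped
  rejections and count toward the consecutive-rejection limit.
* Widom estimates with every trial overlapping report $+\infty$ with a
  warning; errors come from block averages over frames.
* Occupancy is the mean molecule count in the region (not capped at 1),
  so multi-molecule regions remain meaningful; the logistic is still
  fitted to that mean.

## Design choices where the design was open

* **Membership point.** A molecule belongs to the region if the centre of
  geometry of its sites is inside. This is unambiguous for multi-site
  species.
* **Velocities on rejection.** The restored pre-move state gets freshly
  resampled Maxwell-Boltzmann velocities rather than stored or reversed
  momenta; with a Langevin thermostat this preserves the target ensemble
  and simplifies bookkeeping.
* **Work convention.** Only the potential-energy changes imposed by the
  $\lambda$ jumps enter $w$; relaxation heat is excluded, and the
  bracketing propagation blocks sit outside the work sum.
* **Ghost pool.** Insertions draw from a pool of parked, fully decoupled
  molecules that grows on demand, so particle-array topology never
  changes mid-run.
* **Proposal/main-chain randomness.** The switch relaxation uses the same
  seeded stream as the main chain (one stream per chain); nothing in the
  acceptance requires a separate stream.
* **Single-well affinity convention.** The fixture's $K_D$ comes from the
  full single-molecule configuration integral over the GCMC region
  (background included). This makes the two-state enumeration exact and
  the fixture's zero-depth limit finite; it differs from a site-only
  (excess) convention in which $K_D$ would diverge as the well vanishes.
* **Mode-population chains** run at $B_{50}-1.5$ rather than $B_{50}$. In
  these toys the exchange bottleneck is deletion from an occupied well;
  slightly undersaturated chains produce more independent binding
  episodes per cycle, and the mode ratio conditional on being bound does
  not depend on $B$.
* **Clustering.** Pairwise-RMSD mode assignment uses average-linkage
  hierarchical clustering cut at the requested number of modes, with a
  classical-MDS two-component projection for plotting. Mode analyses are
  run on bound frames (within the capture radius of a well), since frames
  in the diffuse background belong to no mode.

## Problem sizes used for validation

The test suite and the acceptance script validate with: ideal-gas chains
of 2 x 10^4 moves at $B\in\{-1,0,\ln 5\}$ in both instantaneous and
nonequilibrium modes; a 12,000-cycle chain on the four-state mean-field
toy; a closed concentration loop on a 24 A box of weak LJ particles at
0.5 M (Widom estimate from 60 frames x 150 trials, then a 3,000-cycle
chain); a titration of the single-well toy over 12 B values x 4 repeats
of 1,800 cycles each; and a 6,000-cycle double-well chain for mode
populations. These
sizes put the stochastic checks comfortably inside their 2-3 standard
error bands while keeping a full run on a laptop-class single core in the
tens of minutes.

## Known limitations

* Rigid multi-site molecules are supported in the energy model and the
  writers, but the propagator treats sites independently; the shipped
  toys therefore use single-site species, and multi-site dynamics should
  be considered approximate.
* No Ewald electrostatics, switching functions, or dispersion tail
  corrections: energies are simple truncations by design.
* Equilibration is a fixed cycle count, not detected automatically; the
  consecutive-rejection limit is the only early-stopping heuristic.
  Titration chains start from an empty region: with dissipative short
  switches, deletion from an occupied well is the slow direction at every
  B, so empty starts equilibrate fastest; occupied starting states
  (`makeSingleWell()$stateBound`) carry transients that outlast the
  default equilibration window and should only be used with long chains.
* The titration error model propagates only the repeat scatter of
  $K_D$ and the supplied $\mu'$ uncertainty; with few repeats the
  standard error of the mean is itself noisy.

## A worked example

```{r example, eval = FALSE}
library(gcncmc)

## enumerated single-well system: truth known by quadrature
fx <- makeSingleWell(depth = 4, width = 1, boxEdge = 10)
fx$truth$b50   # half-occupancy Adams value
fx$truth$kd    # dissociation constant, mol/L
fx$truth$dg    # standard binding free energy, kcal/mol

## titrate 12 B values x 4 repeats and fit the logistic
bGrid <- fx$truth$b50 + seq(-2, 2, length.out = 12)
sched <- chainSchedule(1800, "ligand", mdStepsPerCycle = 2,
                       nEquil = 300, rejectLimit = 200, mdDtFs = 4)
tab <- runTitration(fx$state, fx$region, sched,
                    ncmcProtocol(4, 2, 4), bGrid, repeats = 4, seed = 1)
fit <- aggregateTitration(fitBScale(tab), fx$spec, tab)
fit
```
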