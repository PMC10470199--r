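---
title: "Methods: Monte Carlo–molecular dynamics of methylation-driven chromatin folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo-molecular dynamics of methylation-driven chromatin folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`polyfold` simulates a Polycomb-repressed chromatin locus as a coarse-grained
bead-spring polymer. One bead is one nucleosome of diameter $\sigma = 10$ nm;
the default chain has 360 beads (about 63 kb at 175 bp per nucleosome). The
middle third of the chain is the repressed locus: beads carrying the
H3K27me3 mark (`METH`), with a few Polycomb Response Elements (`PRE`)
embedded among them. The flanks are unmethylated (`UNMETH`).

The central biological question the model addresses is how a histone mark
that does *not* recruit PRC1 to genes (PRC1 binds stably only at PREs) can
still drive the folding of the methylated domain. The model's answer: a
PRE occupied by PRC1 acquires a weak, short-ranged attraction to every
methylated bead; transient PRE–nucleosome loops formed through this
attraction are sufficient to compact the locus, and they also cluster the
PREs themselves.

### Interactions

All quantities are in reduced units: $\sigma = 1$, $k_BT = 1$, bead mass
$m = 1$, time unit $\tau = 1$.

* **Bonds** — finitely extensible (FENE/Warner) springs,
  $V(r) = -\tfrac12 K_s R_0^2 \ln[1-(r/R_0)^2]$ with $K_s = 30\,k_BT$ and
  $R_0 = 1.5\sigma$, infinite beyond $R_0$. Together with the excluded
  volume this gives a mean bond length of $\approx 0.97\sigma$.
* **Bending** — $V(\theta) = K_\theta(1-\cos\theta)$ on successive bond
  vectors, $K_\theta = 3\,k_BT$, nominal persistence length
  $l_p = K_\theta\sigma/k_BT = 3\sigma$; the measured value in equilibrium
  is $\approx 2.7\sigma$ (the discrete chain with thermal fluctuations
  decorrelates slightly faster than the nominal value suggests).
* **Excluded volume** — WCA: Lennard-Jones truncated at its minimum
  $2^{1/6}\sigma$ and shifted up by $\epsilon_{ev} = 1\,k_BT$, applied to
  every non-attracting pair including bonded neighbours (Kremer–Grest
  convention).
* **Binding attraction** — Lennard-Jones of strength $\epsilon$ truncated
  at $r_{int} = 2.5\sigma$ and shifted to zero at the cutoff, applied
  *only* between PRC1-occupied PREs and methylated beads. An attracting
  pair interacts through this potential alone — its $r^{-12}$ core already
  provides the repulsion, so WCA is not double-counted. With
  $\epsilon = 0$ the pair falls back to plain WCA; this makes the zero-
  attraction negative control *exactly* equivalent to occupancy-free
  dynamics, which the tests assert bitwise.
* **Soft push-off** — $A(1+\cos(\pi r/r_c))$, $r_c = 2.5\sigma$, replaces
  the non-bonded terms during overlap removal, with $A$ ramped linearly
  from 0 to 40 $k_BT$.

### Dynamics

Beads follow the Langevin equation integrated with velocity Verlet: the
conservative force plus friction $-m\Gamma v$ ($\Gamma = 0.5\,\tau^{-1}$)
plus Gaussian noise of amplitude $\sqrt{2m\Gamma k_BT/\Delta t}$ per
component, recomputed at each force evaluation (the thermostat used by the
major MD engines). The step is $\Delta t = 0.012\tau$. Physical time
follows from the bead diffusion constant: $\tau = \sigma^2/D = 20\,\mu s$
for $D = 5\,\mu m^2/s$, so one step is 0.24 µs.

Two integrator properties anchor the test suite: with the thermostat off
and $\Gamma = 0$ the total energy is conserved to better than $10^{-3}$
relative over $10^4$ steps, and with it on the mean kinetic energy per
bead is $\tfrac32 k_BT$ within 5 %.

Periodic boundaries use the minimum-image convention inside the force loop
only; coordinates are kept unwrapped, and all observables (radius of
gyration, distance maps) are computed on unwrapped coordinates — at the
simulated density (volume fraction 0.026) the chain never spans the box.

Pair interactions are accelerated with a Verlet neighbour list (cutoff
plus a 0.3 $\sigma$ skin, rebuilt when any bead has moved half the skin,
with a conservative $O(N^2)$ rebuild — at $N \le 500$ a cell grid buys
nothing). The list is an optimisation only: tests assert force identity
with the all-pairs loop to $10^{-12}$.

All stochastic kernels draw from an embedded xoshiro256++ generator
(splitmix64-seeded, Marsaglia polar Gaussian), so a trajectory is bitwise
reproducible from its seed independent of the platform's C++ library. A
single user seed expands into independent child streams for placement,
push-off, equilibration, occupancy draws and each replicate.

## The MC–MD protocol

PRC1 is not simulated as particles. Instead, before each dynamics round
every PRE is independently set to the occupied state with probability
$p_b^{PRE}$ (`assign_prc1()`); the round then runs with occupied PREs
attracting methylated beads, and at its end the occupancy is cleared and
redrawn. One round represents the characteristic ~100 s chromatin
residence time of PRC1. Averages are taken over uncorrelated snapshots
*and* repeated occupancy draws at fixed $p_b^{PRE}$.

The occupancy probability connects to biochemistry through the binding
isotherm $p_b = c/(c + K_D)$: at the nuclear PRC1 concentration of
0.2 µM, half occupancy requires $K_D^{PRE} = 200$ nM and 95 % occupancy
$K_D^{PRE} \approx 10$ nM.

## Calibration of the attraction strength

The attraction $\epsilon$ is calibrated against the measured
PRC1–H3K27me3 dissociation constant ($\sim 5$ µM) along two independent
routes:

1. **Closed form** (`eps_from_kd()`): $K_D = c_0 e^{E_b/k_BT}$ with
   $E_b \approx -0.938\epsilon$ and the standard state
   $c_0 = 1/(N_A\sigma^3) \approx 1.66$ mM (one particle per bead
   volume). At $K_D = 5$ µM this gives $\epsilon = 6.20\,k_BT$.
2. **Many-particle simulation** (`binding_simulation()`): diffusing
   binder particles around one immobile site at 5 µM; the bound fraction
   (≥ 1 particle within $r_{int}$ of the site, no occupancy cap) crosses
   0.5 near $\epsilon \approx 3.9\,k_BT$. The two estimates differ
   because the simulation permits multiple simultaneous occupancy while
   the closed form forbids it; their mean, $5.07 \approx 5.1\,k_BT$, is
   the production value.

Two numerical conventions deserve a note, both selectable rather than
hidden. The well-depth coefficient 0.938 corresponds to evaluating the
well between $2^{1/6}\sigma$ and a 2.0 $\sigma$ cutoff; the exact value
for the 2.5 $\sigma$ dynamics cutoff is 0.9837. The calibration algebra
uses 0.938 by default so that the quoted calibration chain
($-0.938\epsilon \to 6.20 \to 5.07 \to 5.1$) is reproduced; `well_depth()`
exposes both. Similarly $c_0$ is computed exactly (1.6605 mM) but is often
quoted rounded as 1.67 mM; the difference moves $\epsilon(K_D = 5\,\mu M)$
by less than 0.01 $k_BT$.

"Bound" in the simulation is operationalised as centre-to-centre distance
$\le r_{int}$ — the only length scale the interaction defines. Samples
are taken at strides long compared to the site-occupancy correlation
time; the desk-scale default (2 500 steps at 40–50 particles) was chosen
from the measured residence times at $\epsilon \approx 4\,k_BT$.

## System preparation

`prepare_system()` chains four stages, each seeded independently:
random-walk placement at bond length 0.97 $\sigma$ in a box 4× the target
side (large enough that periodic images are irrelevant before
compression); soft push-off with the amplitude ramped 0→40 $k_BT$ over
1 000 steps (the ramp length is not critical; the stage ends with an
explicit no-overlap check on non-bonded pairs); geometric box compression
to the production density over 500 steps with affine position remapping;
and attraction-free equilibration. Equilibration convergence is
diagnosed from the stationarity of the locus radius of gyration
(half-series comparison against the between-sample spread — Rg samples
are autocorrelated, so a naive standard error would over-trigger).

## Observables

* Locus size: radius of gyration over the methylated interval (beads
  120–240 of the 360-mer), volume $V = \tfrac43\pi R_g^3$, reported
  relative to the mean volume $V_{ref}$ of a matching no-PRE chain.
* Pairwise-distance maps: trajectory means of all 3D distances; folded
  loci show reduced in-locus distances, and PRE pairs form
  "off-diagonal spots" below the background at the same linear
  separation (`pre_pair_vs_background()` quantifies exactly this
  contrast, restricted to non-PRE pairs at the same index separation).
* Per-PRE proximity curves with valley detection at other-PRE positions.
* Chain statistics: mean bond length, and persistence length from
  $l_p = -\langle b\rangle / \ln\langle\cos\theta\rangle$ (the estimator
  is a package choice; the adjacent-bond correlation is the quantity the
  bending potential controls directly).
* Replicate summaries: Student-t 95 % confidence intervals for means;
  boxplot statistics with the 1.5 IQR whisker/outlier rule. The control
  experiments divide each control replicate by a reference replicate with
  its own seed, so the interval reflects both uncertainties.

## The anchored-loop model of PRE clustering

A one-dimensional model explains why folding clusters PREs without any
direct PRE–PRE interaction. Each anchor throws loops whose lengths are
Gaussian around the anchor position ($\sigma_l$); only loops landing on
methylated ("sticky") chromatin persist, so an anchor with unmethylated
chromatin on one side draws from a half-Gaussian on the sticky side.
With anchors at 0 and 2, the mean absolute distance between loop
positions is $\bar\Delta = L - k\,\sigma_l\sqrt{2/\pi}$, $k$ = number of
inward-restricted anchors — exact in the no-sign-flip limit
$L \gg \sigma_l$, and the analytic oracle for the Monte Carlo sampler.
For $\sigma_l = 0.3$: 2.00, 1.76, 1.52 for $k = 0, 1, 2$. The reference
means match $\sigma_l = 0.3$ (a nominal 0.2 would give 1.84/1.68); the
package defaults to 0.3 and exposes the parameter. The practical
consequence: PREs near the *edges* of a methylated domain — the
arrangement found at the fly *inv-en* locus, reproducible with
`build_inv_en()` — cluster most strongly.

## Desk-scale study conditions

The full-scale conditions (360-mer, 150–400 replicates, $10^8$-step
cycles) are expressible through `experiment_plan()` but amount to days of
computing. The test suite and the worked examples instead use scaled-down
conditions chosen once as the package's desk-scale defaults:

* a 60-mer fixture (`make_fixture("chain60")`) with a 20-bead methylated
  core and two PREs, in a box preserving the production volume fraction
  0.026;
* $5 \times 10^4$-step equilibration, $8 \times 10^4$-step cycles, and
  6–10 replicates for the folding experiments;
* 40–50 binder particles at the 5 µM-equivalent concentration, 150
  samples × 2 replicates per $\epsilon$ for the binding calibration.

Scaled-down runs preserve the ordering of conditions (occupancy
monotonicity, controls at 1, PRE clustering below background) though
absolute ratios shift with locus size; the tests therefore assert
orderings, interval coverage and one-sided contrasts rather than the
full-scale ratio values.

## What the generator does and does not emulate

The synthetic systems capture the polymer physics the model is built on:
chain connectivity and stiffness, excluded volume, the three monomer
classes, stochastic occupancy, and density matched to the nucleosome
filling fraction of the fly nucleus (0.021–0.026). They do not emulate
replication fork passage (dilution is an instantaneous random
demethylation), nucleosome turnover, PRC1 self-interaction,
transcription, insulators, or hydrodynamic coupling — so passing tests
demonstrate the sufficiency of the modelled interactions inside this
model, not the absence of other mechanisms in vivo.

## Numerical choices and limitations

* Timestep 0.012 $\tau$ with $K_s = 30$ bonds is stable but stiff;
  undamped-energy checks use a halved step. Bond overextension or
  non-finite coordinates abort with the offending bead rather than
  propagating NaNs.
* The soft push-off has zero force at exactly $r = 0$; thermal noise
  breaks such coincidences in practice, and an explicit post-ramp check
  errors if any non-bonded pair remains closer than 0.95 $\sigma$.
* The duration of a "100 s" cycle in steps is a parameter
  (`cycle_steps`): commonly quoted step-count equivalences for it are mutually
  inconsistent at $\Delta t = 0.012\tau$, $\tau = 20$ µs, so the package
  treats $\Gamma$ and $\Delta t$ as primary and reports physical time as
  $\mathrm{steps} \times \Delta t \times \tau$.
* Dilution rounding is round-half-up of fraction × methylated count;
  occupancy and dilution draws are seed-deterministic and independent
  across PREs, cycles and replicates (chi-square tested).
* `find_crossing()` interpolates linearly between the first bracketing
  grid points; with a non-monotone (noisy) curve the first crossing is
  used.
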