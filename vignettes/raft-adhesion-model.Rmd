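---
title: "Modelling receptor-ligand binding and lipid-raft phase behaviour in cell-substrate adhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling receptor-ligand binding and lipid-raft phase behaviour in cell-substrate adhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

Cell adhesion is mediated by receptors that bind cognate ligands on an
apposing surface. In experiments the ligand-bearing surface is either a
supported lipid bilayer (laterally **mobile** ligands, mimicking
cell-cell adhesion) or a bare solid substrate (**immobile** ligands,
mimicking cell-matrix adhesion). Adhesion receptors additionally
partition into nanoscale liquid-ordered membrane domains — lipid rafts —
which themselves tend to coalesce. The question this package addresses
quantitatively is how ligand mobility and spatial distribution couple
receptor-ligand binding to raft coalescence: whether binding promotes or
hinders the homogeneous-to-phase-separated transition of the raft
component, and how raft clustering feeds back on the two-dimensional
binding constant

$$K = \frac{[RL]}{[R][L]},$$

with $[RL]$, $[R]$, $[L]$ the area concentrations of complexes, unbound
receptors and unbound ligands.

## The model

The cell membrane and the apposing surface are $L \times L$ square
lattices of patch size $a = 10$ nm (the exclusion size of an adhesion
protein); by default $L = 60$, i.e. a $600 \times 600\ \mathrm{nm}^2$
membrane with periodic boundaries. The configuration is

* a separation field $l_i \ge 0$ (nm) between apposed patches,
* receptor occupancies $m_i^+ \in \{0,1\}$ on the membrane,
* ligand occupancies $m_i^- \in \{0,1\}$ on the lower surface,
* raft occupancies $n_i^+ \in \{0,1\}$ on the membrane,

with at most one protein per patch and one raft per membrane patch. The
Hamiltonian has four terms (all energies in units of $k_BT$):

$$\mathcal{H}_{ad} = \underbrace{\frac{\kappa}{2a^2}\sum_i
  (\Delta_d l_i)^2}_{\text{bending}}
  \;\underbrace{- u_b \sum_i m_i^+ m_i^- \,
  \theta\!\left(\tfrac{l_b}{2} - |l_i - l_c|\right)}_{\text{binding}}
  \;\underbrace{- u_a \sum_i n_i^+ m_i^+}_{\text{raft-receptor}}
  \;\underbrace{- u \sum_{\langle ij\rangle} n_i^+
  n_j^+}_{\text{raft-raft}}$$

where $\Delta_d$ is the 5-point discrete Laplacian (the standard
discretization for this model family, adopted here as a documented
package choice), the binding
potential is a square well of depth $u_b$ and width $l_b$ centred on the
complex length $l_c$ with *strict* inequalities at the well edges
(a measure-zero convention), and the raft contact sum counts each
nearest-neighbour bond once (a fully covered lattice has energy
$-2uL^2$).

Default parameters: $\kappa = 10\,k_BT$, $a = 10$ nm,
$u_b \in \{4, 6\}\,k_BT$, $l_b = 1$ nm, $l_c = 15$ nm,
$u_a = 3\,k_BT$ (chosen so that the receptor concentration inside rafts
falls in the experimentally reported $10^3$–$10^4\ \mu m^{-2}$ window
for the studied receptor concentrations), and the raft-raft contact
energy $u$ is the main control parameter of the phase analysis.

## Monte Carlo scheme

`run_simulation()` performs Metropolis dynamics with three trial-move
types, interleaved at random within each cycle:

1. **height moves**: $l_i \to l_i + \delta$, $\delta \sim
   U(-s, s)$; any proposal with $l_i < 0$ is rejected outright
   (the substrate is impenetrable);
2. **protein hops** to one of the four neighbouring sites, rejected if
   the destination is occupied on the same surface; ligands hop only in
   the mobile-ligand scenario;
3. **raft hops** into raft-free membrane sites; receptors do *not*
   travel with rafts (hence a hop off a receptor-carrying raft patch
   costs $+u_a$).

Moves are accepted with probability $\min(1, e^{-\Delta H})$. The
default mix gives each membrane patch one height attempt and each
mobile protein and raft patch one hop attempt per cycle; equilibrium
observables are independent of these proportions (verified by test),
only the dynamics depend on them. One cycle maps to roughly 10 µs of
physical time (patch-scale protein diffusion at $D = 1\ \mu m^2/s$).

Numerical choices: the height step defaults to $s = 0.5$ nm — half the
binding-well width, so the well is resolved while height acceptance
stays moderate (~50–85 % in practice); no canonical step size exists
for this move type, so the default is a tunable package convention. Energies are maintained incrementally (O(1) per
move) and cross-checked against a full recompute at the end of every
run; the drift over $10^6$ moves is below $10^{-6}\,k_BT$. The engine
uses a splitmix64 generator seeded from the run configuration;
replicate $r$ uses `seed + r`, and initial placements use R's RNG with
the scenario seed, so every trajectory is bit-reproducible.

The separation field is initialized uniformly at $l_c$, so binding is
reachable without a vertical drift phase; compositions are placed at
random (equilibrium results do not depend on the initial placement,
which is also verified by test). No upper confinement wall is imposed:
in binder-free runs the in-plane raft sector decouples from the
membrane, and in adhered runs binding itself pins the membrane.

## Observables and phase analysis

* **Heat capacity per site** $C_V = (\langle H^2\rangle - \langle
  H\rangle^2)/(N k_B T^2)$, computed from the recorded total energies.
  The peak of $C_V(u)$ locates the finite-size transition between the
  homogeneous and phase-separated raft states. `locate_transition()`
  takes the grid argmax, refines it by a three-point quadratic fit
  (the peak-extraction rule is a package convention; reported
  transition points in this literature rarely state one), breaks exact ties
  toward lower $u$, and reports the replicate SD of the peak location.
  A boundary maximum raises an error rather than returning a value.
* **Binding constant** $K$: ratio of time averages,
  $\langle [RL]\rangle / (\langle[R]\rangle\langle[L]\rangle)$, in
  $\mu m^2$ — not the average of per-sample ratios; the
  equilibrium-constant definition applies to the averaged
  concentrations, and the ratio-of-averages has well-defined error
  propagation. Saturation (no free receptors or ligands on average) is
  reported as an error, never silently dropped.
* **Raft-partition statistics**: time-averaged receptor concentration
  inside raft patches; in the dilute non-interacting limit the in/out
  concentration ratio approaches $e^{u_a}$ ($\approx 20.1$ for
  $u_a = 3$), an exact two-state check.
* **Replicates**: independent runs aggregated as mean ± population SD
  (the "SD of the measurements" convention, denominator $n$);
  10 replicates at full fidelity, fewer in scaled-down presets.

Samples are recorded every `sample_interval` cycles (default 1000 at
full scale, chosen to decorrelate samples; scaled presets record more
densely because their runs are shorter).

In the rigid, binder-free limit the raft sector is exactly the 2D
square-lattice gas with conserved density, so the transition at
$x = 1/2$ must approach the exact critical coupling
$u_0^* = 2\ln(1+\sqrt2)\,k_BT \approx 1.763$; this is both an analytic
reference (`onsager_critical_coupling()`) and an end-to-end pipeline
test. Monte Carlo phase diagrams are reported normalized by this
$u_0^*$. Note that the $u^*/u_0^* \to 1$ limit at $c_R \to 0$ holds at
the critical composition $x = 1/2$; at the off-critical raft fractions
studied ($x = 0.1$–$0.3$) the binder-free intercept is the finite-size
binodal crossing, slightly above $u_0^*$. The hopping dynamics conserve
raft number, so small-lattice validation enumerates the fixed-$N$
ensemble ($\binom{16}{n}$ configurations on $4\times4$), not all
$2^{16}$ occupancy patterns.

## Mean-field theory

For mobile ligands the package provides a Bragg-Williams mean-field
counterpart. The raft sector contributes the regular-solution free
energy per site

$$f_0(\phi) = \frac{z}{2} u\, \phi(1-\phi) + \phi\ln\phi +
  (1-\phi)\ln(1-\phi), \qquad z = 4,$$

written in the symmetric form (equivalent to $-\frac{z}{2}u\phi^2$ up
to a linear term, which affects neither spinodal nor common tangent)
so that $f(\phi) = f(1-\phi)$ at $c_R = 0$ and the critical point is
exactly $u_0^* = 1\,k_BT$ at $\phi = 1/2$.

Binding enters through the **contact probability** $P_b$: the
equilibrium fraction of membrane patches whose separation lies inside
the binding well in the homogeneous reference system. Receptors are
treated grand-canonically: a receptor on a patch with local raft
density $\phi$ has statistical weight $A e^{u_a\phi}(1+b)$, where
$b = P_b\, \rho_L\, (e^{u_b}-1)$ is the binding excess weight
($\rho_L$ the per-patch ligand density) and the fugacity $A$ is fixed
so the homogeneous phase at the global raft fraction $x$ carries the
prescribed receptor density. The receptor contribution to the free
energy is the *excess over the binding-free reference*,

$$f_{bind}(\phi) = -\ln\frac{1 + A(1+b)e^{u_a\phi}}
  {1 + A e^{u_a\phi}}.$$

Two deliberate design points, made where the published algebra was not
available to us:

* Subtracting the binding-free reference makes the phase line collapse
  exactly onto the $c_R = 0$ line when $u_b \to 0$ or $P_b \to 0$: the
  mean-field theory isolates the effect *of binding* on the transition,
  rather than the (weaker) effect of bare receptor-raft partitioning.
* At dilute receptor occupancy $f_{bind}$ is concave in $\phi$, so
  binding lowers the transition — the mean-field image of the
  membrane-fluctuation-mediated attraction between complexes; near
  receptor saturation the curvature reverses, reproducing
  qualitatively the non-monotonic trend of the transition with $c_R$.

`solve_self_consistent()` finds coexisting densities by the
common-tangent construction (equal chemical potentials and tangent
intercepts, verified to $10^{-8}$): the spinodal is bracketed on a
$\phi$ grid and refined by root-finding on $f''$ (tolerance
$10^{-10}$ or better), the tangent slope by root-finding on the
grand-potential gap. For given $(x, c_R)$ the transition
$u_\mathrm{tr}$ is the smallest $u$ at which $x$ enters the
coexistence region, located by bisection to $10^{-7}\,k_BT$. Within
$\sim 10^{-6}$ of the critical point, where binodal and spinodal
merge, the spinodal bracket is used directly.

$P_b$ itself is measured by `estimate_contact_probability()`: a bare
fluctuating membrane initialized at $l_c$, with the centre-of-mass
drift relative to the initial mean removed before the well test. The
drift correction reflects that the unconstrained vertical zero mode of
the reference system has no counterpart in the adhered system, where
binding pins the mean separation; without it the estimate would decay
with run length. The estimate agrees with the closed-form Gaussian
prediction from the exact mode sum of the discrete bending Hamiltonian
(`contact_probability_theory()`). Because the membrane is tensionless,
the roughness grows as $L^2/\kappa$ and $P_b$ is lattice-size
dependent: the reference value belongs to the full $L = 60$ system
($P_b \approx 0.034$ for $\kappa = 10\,k_BT$), and scaled-down checks
use the matching theory value for their own $L$. No mean-field theory
is provided for immobile-ligand scenarios (a mean-field closure for
quenched ligand disorder would be a different theory), and `cmd_mf()` rejects them explicitly.

## Scenario generator

`scenario_config()` + `build_initial_state()` generate every studied
system; the generator *is* the data module of this analysis and its
defaults are the stated experimental conditions:

* **mobile**: ligands on random distinct patches, hops enabled;
  $c_L = 1000\ \mu m^{-2}$ for phase diagrams, $100\ \mu m^{-2}$ for
  binding-constant curves.
* **uniform**: immobile ligands on an exactly even square grid when
  the count is a perfect square whose root divides $L$ (the studied
  $c_L = 625\ \mu m^{-2}$ gives $225 = 15^2$ at spacing 4 on
  $L = 60$); otherwise a maximally even rounded grid. "Uniform" is not
  taken in its natural reading: the exact grid.
* **random**: immobile ligands on random distinct patches.
* **clustered**: rasterized disks of diameter $d_c$ — all offsets with
  $d_i^2 + d_j^2 \le (d_c/2a)^2$ — at random centres with pairwise
  periodic distance $\ge d_c$ (rejection sampling, capped at $10^5$
  tries). Ten 50 nm disks realize 210 ligands on the $0.36\ \mu m^2$
  membrane, i.e. $c_L \approx 583\ \mu m^{-2}$, matching the stated
  $\approx 580\ \mu m^{-2}$; cluster counts for other diameters are
  chosen to match the same total concentration (e.g. one 170 nm
  cluster).

Receptors are placed independently of rafts; the affinity $u_a$
enriches rafts dynamically. Requested concentrations are converted as
`round(c (La)^2/10^6)` and the realized values are logged with every
state.

What the generator does *not* emulate: polydisperse or non-circular
ligand clusters, receptor-raft co-localized initial conditions (an
option exists in nature but equilibrium results are initialization
independent), membrane tension, or flexible-protein conformations. A
green test therefore establishes correctness of the stated lattice
model, not fidelity to any particular experimental image beyond it.

## Scale presets and what green tests establish

Full fidelity ($L = 60$, $5\times10^7 + 5\times10^7$ cycles, 10
replicates) is cluster-scale. The `desk` preset ($10^5 + 10^5$ cycles)
and `test` preset ($10^4 + 10^4$) keep every code path exercised at
desk scale; tests that compare against exact enumeration, closed
forms, or equipartition are quantitative at any scale, while the
qualitative phase-behaviour checks (direction of the $u^*$ shift,
shape of $K(u)$) run on $L = 24$–$32$ lattices with a few replicates
and inherit finite-size and sampling noise. The transition-location
uncertainty at desk scale is $\sim 0.05$–$0.1\,k_BT$; effects smaller
than that (for example the fine structure of the non-monotonic
$u^*(c_R)$ maximum) are at the edge of desk resolution, and the
acceptance suite says so explicitly rather than over-claiming.

## Known limitations

* Local (single-site) moves only, for dynamic realism: no
  cluster algorithms, so critical slowing down limits desk-scale
  precision near $u^*$, and conserved raft dynamics coarsen slowly.
* The mean-field binding excess is a reconstruction calibrated to the
  stated anchors (critical point, direction of the shift, collapse
  without binding); its higher-order terms may differ from the
  unpublished original algebra.
* $C_V$ uses the plain variance of the recorded total energies; with
  a fluctuating membrane the bending background adds noise to the
  raft-transition peak, which is why rigid baselines are used where
  they are exactly equivalent (binder-free systems).
* No finite-size scaling or Binder-cumulant analysis: the finite-size
  CV peak is taken as the transition directly.
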