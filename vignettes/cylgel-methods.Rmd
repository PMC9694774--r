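---
title: "Swelling and collapse of charged cylindrical microgels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swelling and collapse of charged cylindrical microgels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cylgel simulates single cylindrical polyelectrolyte microgels — colloidal
cross-linked polymer networks that swell in good solvent and collapse when
the solvent quality declines — with a coarse-grained bead-spring model and
implicit-solvent Langevin (Brownian) dynamics, and measures how their
length, thickness, shape anisotropy and counterion distribution respond to
solvent quality. This vignette documents the model, the numerical choices,
the design decisions taken where the procedure was genuinely open, and what
the desk-scale defaults do and do not demonstrate.

## The coarse-grained model

All species — neutral monomers, charged monomers, and counterions — are
beads of diameter $\sigma$ and mass $m$; lengths, energies and times are
reported in the reduced units $\sigma$, $k_BT$, and
$\tau = \sigma\sqrt{m/k_BT}$.

**Excluded volume and solvent quality.** Every bead pair interacts through
a truncated Lennard-Jones potential
$U_{LJ}(r) = 4\varepsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right]$ for
$r \le r_{cut}$, zero beyond. Monomer–monomer pairs use the *solvent
quality parameter* $\varepsilon \in [0.01, 1.4]\,k_BT$ with
$r_{cut} = 2.5\sigma$: small $\varepsilon$ is a good (athermal-like)
solvent, large $\varepsilon$ a poor one, mimicking heating of a
thermoresponsive gel. Any pair involving a counterion uses
$\varepsilon = 1\,k_BT$ truncated at the minimum $r_{cut} = 2^{1/6}\sigma$,
i.e. purely repulsive excluded volume. Note a consequence used throughout:
because $\varepsilon$ scales the repulsive core together with the
attraction, beads interpenetrate substantially at $\varepsilon = 0.01$; the
good-solvent network is soft.

**Connectivity.** Bonded beads are joined by the finitely extensible
nonlinear elastic (FENE) spring
$U_{FENE}(r) = -\tfrac{k}{2} R_0^2 \ln\left[1 - (r/R_0)^2\right]$ with
$k = 30\,k_BT/\sigma^2$ and $R_0 = 1.5\sigma$, which diverges at $R_0$ and
prevents chain crossing in combination with the LJ core.

**Electrostatics.** Charged species ($+1e$ network groups, $-1e$
counterions) interact via the Coulomb potential with Bjerrum length
$l_B = 1\sigma$ (aqueous conditions). Three solvers are provided:

* `"ewald"` — classical Ewald summation (real + reciprocal space, tinfoil
  boundaries). The splitting parameter and k-space extent are derived from
  the configured relative accuracy (default $10^{-5}$). Used for energies
  and as the accurate force route on small systems.
* `"direct"` — a brute-force image-shell lattice sum (or plain pair sum for
  open boundaries). This is the independent oracle the Ewald solver is
  tested against; on zero-charge, zero-dipole configurations the lattice
  sum is absolutely convergent and boundary-condition independent, so the
  two must agree to the accuracy target.
* `"dsf"` — a shifted-force truncation at `coulomb_cutoff` (default
  $10\sigma$), the fast mode used in sweep dynamics. With the default
  damping `dsf_alpha = 0` this is the undamped Wolf-type form whose force
  errs from bare Coulomb by exactly $(r/r_c)^2$ inside the cutoff. We
  deliberately do not damp by default: the conventional damped form
  (`dsf_alpha` ≈ 0.2–0.3) is calibrated for dense homogeneous ionic
  systems, and in the dilute single-gel geometry its screening artificially
  suppresses counterion condensation onto the network — in pilot runs the
  localized fraction dropped by an order of magnitude. The mode is
  approximate by construction and labelled so; the accuracy-controlled
  solver is Ewald.

## Building cylindrical microgels

An ideal microgel is assembled from fully stretched subchains of $M$ beads
joined at tetrafunctional cross-links arranged as the diamond crystal
lattice. The conventional cubic cell carries 8 nodes and 16
nearest-neighbour bonds, so the bulk cross-link bead fraction is
$8/(8 + 16M) = 1/(2M+1)$ — about 5% for $M = 10$ and 2.5% for $M = 20$.
`crosslink_fraction_limit()` evaluates this by enumerating the periodic
cell with the same machinery that builds finite templates;
`crosslink_fraction()` on finite templates converges to it from above as
the boundary-to-volume ratio shrinks.

The as-built bond spacing of $0.97\sigma$ is the one free parameter of the
construction. It must be below $R_0$; we place it near the LJ minimum so
the preparation state is mechanically relaxed, and the cell edge follows as
$a = 4(M+1)\cdot 0.97/\sqrt{3}$.

A cylinder is inscribed into an $n_x \times n_y \times n_z$ template: the
axis is a straight, full-height column of cross-links nearest the
transverse centre, all beads strictly outside the radius are cut off, and
fragments disconnected from the axis-bearing component are dropped
(dangling stubs that remain bonded are kept — cutting removes beads, not
chains). The preparation-state geometry is recorded: contour length $L_0$,
radius $R_{0}$, and aspect ratio $A_0 = L_0/2R_0$; with the max-fit radius
$A_0 = (n_z - 1)/n_x$ exactly.

Charged groups are then assigned to `round(f N)` beads uniformly at random
(cross-links are eligible — the model does not distinguish), and one
counterion per charged group is placed uniformly in the periodic box,
avoiding core overlap ($< 0.9\sigma$) with the network and with other
counterions, so the system is exactly neutral.

**Box.** The automatic box is $3\times$ the cylinder diameter transverse
to the axis and $1.5 L_0 + 2\cdot 2R_0$ along it. This keeps the
solution-to-gel volume ratio of order $10^2$ (comparable dilution to the
reference cluster-scale setup) while leaving counterions close enough to
exchange with the gel within desk-scale run lengths; much larger boxes make
the counterion subsystem the slowest mode of the simulation without
changing the qualitative physics.

## Dynamics and the sweep protocol

The equations of motion are integrated with the BAOAB splitting of
Langevin dynamics at $k_BT = 1$, friction $\gamma = 1\,\tau^{-1}$ and time
step $\Delta t = 0.005\,\tau$ (one force evaluation per step; the
velocity-variance and tethered-bead position-variance targets are
reproduced exactly in the test suite). The friction only sets kinetics, not
equilibrium averages. An overdamped (inertialess) Brownian variant is
provided; its explicit step is stable only for
$\Delta t \lesssim 2\gamma/U''$, in practice $\Delta t \le 10^{-3}\tau$
against the FENE + LJ bond curvature.

Forces use Verlet pair lists built by cell binning (skins $0.7\sigma$ for
LJ, $1.4\sigma$ for electrostatics, rebuilt when any bead has moved half a
skin), which the tests require to agree with the all-pairs reference to
machine precision.

The solvent-quality sweep mirrors the annealing experiment: equilibrate at
$\varepsilon = 0.01$, then increase $\varepsilon$ stage by stage to 1.4,
keeping the total time (equilibration + statistics) identical per stage;
observables are averaged over frames recorded in each stage's statistics
window, with frame-to-frame block averaging providing the standard errors.

One numerically motivated refinement: each stage *ramps* $\varepsilon$
geometrically from the previous value over the first half of its
equilibration (20 sub-steps) instead of jumping. Because $\varepsilon$
scales the repulsive core, beads that interpenetrate at low $\varepsilon$
would see their overlap energy multiplied by the full $\varepsilon$ ratio
under an instantaneous quench, producing forces that can snap FENE bonds;
the gradual quench lets overlaps relax and leaves equilibrium averages
unaffected. A pair-force cap is additionally available (`cap`), off by
default, for deliberately overlapping relaxation pre-passes.

## Observables

* **Contour length** $L$: the sum of distances between neighbouring
  cross-links of the chain the cylinder axis passes through at
  preparation. It tracks the apparent cylinder length; for small floppy
  gels the transverse wander of the axis cross-links inflates it relative
  to the end-to-end extent (it is a path length), which is why desk-scale
  $L$ at good solvent can exceed $L_0$ even though the chains have
  contracted.
* **Thickness** $2R$: from the beads within a central slab of length
  $0.2L$ about the centre of mass along the principal axis, with the
  uniform-cylinder moment estimator $R = \sqrt{2\langle r_\perp^2\rangle}$
  (exact for a uniformly filled cylinder; a 95th-percentile radial-extent
  estimator is available as a robustness check).
* **Gyration-tensor shape metrics**: eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the gyration tensor give (i)
  the cylinder-calibrated aspect estimate
  $\hat A = \sqrt{12\lambda_1}/(4\sqrt{\lambda_3})$ — the length-to-diameter
  ratio of the moment-equivalent uniform cylinder, which agrees with
  $L/2R$ for long cylinders and evaluates to $\sqrt{3}/2$ for a sphere —
  and (ii) the raw ratio $\lambda_1/\lambda_3$, reported alongside because
  the two readings differ by a geometry factor ($\lambda_z/\lambda_x =
  4A^2/3$ for a uniform cylinder) and the literature plots either; and
  (iii) the normalized asphericity
  $\delta = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
  \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2 \in [0, 1]$,
  zero for spherically symmetric distributions, one for a thin rod, with
  $\delta > 0.6$ classified cylindrical and $\delta < 0.1$ spherical.
* **Counterion localization** $\beta$: the fraction of counterions inside
  the microgel. The criterion is not uniquely defined by the physics; the
  default counts a counterion as localized when its minimum-image distance
  to the nearest network bead is at most $2.5\sigma$ (the monomer
  attraction cutoff — a parameter-free tie to the force field), and a
  moment-equivalent cylindrical-envelope criterion is available. The
  uncompensated relative net charge follows as $Q/(Ne) = f(1-\beta)$.
* **Radial profiles**: each frame's gel is cut into axial segments of
  length $0.2L$; the two end segments are discarded and, for the inner
  segments, polymer / charged-group / counterion bead counts are
  histogrammed in annular bins about the axis (azimuthal averaging is
  implicit), converted to volume fractions with the bead volume
  $\pi\sigma^3/6$, and averaged over segments and frames. The tests verify
  the profile of a uniform synthetic cylinder is flat at its analytic
  volume fraction and that integrating $\phi$ over bin volumes returns the
  bead count exactly.

Shape measurements require unwrapped coordinates; the integrator keeps
them unwrapped internally, and `unwrap_frame()` reconstructs continuity
from bond connectivity for trajectories re-read from wrapped dump files.

## Synthetic fixtures as oracles

`uniform_cylinder_cloud()` and `uniform_sphere_cloud()` generate exactly
uniform clouds by rejection sampling with threaded seeds. Their closed-form
moments ($\lambda_{axis} = L^2/12$, $\lambda_\perp = R^2/4$ for the
cylinder; $\lambda = R^2/5$, $R_g^2 = 3R^2/5$ for the ball; $\delta =
0.759$ at $A = 4$) validate every shape observable without running
dynamics, and `ideal_microgel_frame()` exposes the as-built conformation as
the preparation-state reference. These fixtures emulate idealized mass
distributions only — they have no chain statistics, no periodic box, no
thermal roughness — so passing them certifies the estimators, not the
simulation.

## Desk-scale study conditions

The reference experiments run $N = 5\times10^4$–$10^5$ beads for $10^7$
steps with mesh Ewald electrostatics — a cluster workload. The package
reproduces the *mechanisms* at desk scale; the default demonstration
(`sweep_config()`) uses a $4\times4\times16$-cell, $M = 5$ template with a
one-cell-edge radius (about 4,200 network beads, $A_0 = 7.5$) and an
8-point $\varepsilon$ ramp of $\approx 10^5$ total steps, minutes on one
CPU. The acceptance checks use three still smaller geometries, chosen once
as the smallest systems in which the mechanisms are resolvable:

* a $2\times2\times13$, $M = 3$ cylinder ($A_0 = 6$, ~1,900 beads), neutral
  versus 25%-charged, for the length/thickness/aspect-ratio response. The
  charge fraction balances two desk-scale constraints: well below 25% the
  electrostatic elongation at good solvent is not resolvable above the
  block noise of so small a gel, while well above it the electrostatics
  still dominate at $\varepsilon = 1.4$ and the aspect-ratio maximum moves
  out of the studied range;
* a $2\times2\times4$, $M = 5$ cylinder ($A_0 = 1.5$, ~850 beads, weakly
  cross-linked) for the cylinder-to-sphere collapse, with the poor-solvent
  endpoint repeated for several equal-duration stages because the final
  coalescence into a globule is the slowest step;
* a $2\times2\times9$, $M = 3$ cylinder at $\varepsilon = 0.01$ with
  $f \in \{0.2, 0.35, 0.5\}$ (the upper half of the studied charge range,
  where the desk-scale gel's Donnan well is deep enough for localization
  to reach its saturating, sublinear regime), in a $36\times36\times112$
  box with an $8\sigma$ electrostatics cutoff, for counterion localization
  and radial profiles.

What desk scale does *not* show: quantitative agreement with cluster-scale
magnitudes. The counterion localization $\beta$ depends on the
solution-to-gel volume ratio and on how long distant counterions have had
to find the gel, so desk values sit well below the cluster-scale ones; the
contour length carries the path-inflation bias noted above; and thin
desk-scale cylinders resolve the peripheral structure of radial profiles
over a few bins only. The qualitative orderings — lengths decreasing with
$\varepsilon$, charged longer than neutral, thickness minima, the
electrostatic aspect-ratio maximum, $\beta$ rising sublinearly with $f$,
the peripheral electric double layer — are the desk-scale acceptance
surface.

## Known limitations

* Implicit solvent, no hydrodynamics, no added salt, monovalent ions only.
* The fast electrostatics mode truncates at $10\sigma$; interactions
  beyond that range (e.g. between well-separated released counterions)
  are neglected in dynamics. The Ewald solver is available where accuracy
  matters and is cross-checked against the direct lattice sum.
* Brownian (overdamped) mode needs a reduced time step (see above).
* The builder produces monodisperse subchains and a single cylinder per
  box; spherical or core–shell architectures are out of scope.
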