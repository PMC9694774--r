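# cylgel

Coarse-grained simulation and analysis of the swelling and collapse of
single **cylindrical polyelectrolyte microgels** — colloidal-scale
cross-linked polymer networks that swell in good solvent and collapse as
solvent quality declines (e.g. on heating a thermoresponsive gel). The
package is aimed at polymer/soft-matter simulators who want a reproducible,
desk-scale pipeline for the mechanism-level questions: how do charged
groups and their counterions change a cylindrical gel's length, thickness,
aspect ratio and shape as the monomer attraction grows, and how are
charges and counterions distributed radially?

## Model

All species are beads of diameter σ (mass m = 1, energies in kBT, time in
τ = σ√(m/kBT)):

* **Truncated Lennard-Jones** between all beads:
  `U(r) = 4ε[(σ/r)¹² − (σ/r)⁶]`, zero beyond the cutoff. Monomer–monomer
  pairs use the solvent-quality parameter ε ∈ [0.01, 1.4] kBT with cutoff
  2.5σ (larger ε = poorer solvent); pairs involving counterions use
  ε = 1 kBT cut at 2^{1/6}σ (pure excluded volume).
* **FENE bonds** along subchains:
  `U(r) = −(k/2)R₀² ln[1 − (r/R₀)²]`, k = 30 kBT/σ², R₀ = 1.5σ.
* **Coulomb electrostatics** at Bjerrum length lB = 1σ (aqueous
  conditions) between +1e charged monomers and −1e counterions: Ewald
  summation (configurable accuracy, default 1e-5) with a brute-force
  lattice-sum oracle, plus a fast shifted-force mode for sweep dynamics.

Microgels are built from fully stretched M-bead subchains joined at
tetrafunctional cross-links on a diamond lattice (bulk cross-link fraction
1/(2M+1): ≈5% for M = 10, ≈2.5% for M = 20), cut into a cylinder of aspect
ratio A₀ = L₀/2R₀, randomly charged at fraction f, and neutralized with
counterions in a periodic box. NVT Langevin (BAOAB) dynamics with
Δt = 0.005 τ anneals the gel at ε = 0.01 and sweeps ε upward with equal
time per stage, measuring contour length L, central-slab thickness 2R,
gyration-tensor aspect ratio and asphericity δ (δ > 0.6 cylindrical,
δ < 0.1 spherical), the localized-counterion fraction β, the net charge
fraction Q/(Ne) = f(1 − β), and cylindrical radial volume-fraction
profiles.

## Worked example

```r
library(cylgel)

# a small charged cylinder: 2x2x9 diamond cells, subchains of 3 beads,
# 10% charged groups, counterions added automatically
topo <- build_diamond_template(2, 2, 9, M = 3) |>
  inscribe_cylinder() |>                  # max-fit radius -> A0 = 4
  assign_charges(f = 0.1, seed = 1)
sys <- make_system(topo, seed = 2)

crosslink_fraction(topo)                  # 0.1565 (finite template, M = 3)
topo$A0                                   # 4

# sweep solvent quality; ~1 minute of desk time
cfg <- sweep_config(nx = 2, ny = 2, nz = 9, M = 3, f = 0.1, radius = "max-fit",
                    eps = c(0.01, 0.5, 1.0, 1.4),
                    equil_steps = 4000, stats_steps = 2000, seed = 1)
sw <- run_sweep(cfg)
tidy(sw)[, c("eps", "L", "D", "aspect_contour", "asphericity", "beta")]
autoplot(sw)
```

A run of the example printed:

```
# A tibble: 4 × 6
    eps     L     D aspect_contour asphericity   beta
  <dbl> <dbl> <dbl>          <dbl>       <dbl>  <dbl>
1  0.01  62.3  6.25           9.98       0.960 0.0189
2  0.5   60.0  6.40           9.39       0.955 0.0303
3  1     56.6  5.59          10.1        0.959 0.0341
4  1.4   54.8  5.25          10.4        0.958 0.0246
```

Reading it: the contour length L (σ units) shrinks monotonically as the
solvent worsens while the central-slab thickness 2R thins; the gel stays
firmly cylindrical (asphericity ≈ 0.96 > 0.6); and only a few percent of
the counterions sit inside this very small, strongly diluted gel at this
short demonstration length — the localized fraction grows with the charge
fraction and with equilibration time (the acceptance sweeps run an order
of magnitude longer). Standard errors (`se_L`, ...) come from block
averaging over the statistics frames.
`compare_sweeps()` overlays charged and neutral runs and flags the
electrostatic signature — an interior maximum of A(ε) — and
`radial_profiles()` / `autoplot()` show the polymer, charged-group and
counterion volume fractions versus radius, including the peripheral
electric double layer.

Interchange: `write_lammps_data()` / `read_lammps_data()` (full atom
style), `write_lammps_dump()` / `read_lammps_dump()` with
connectivity-based `unwrap_frame()`, `write_xyz()` / `read_xyz()`, and
`write_sweep_tables()` / `read_sweep_tables()` (CSV/JSON with an
MD5-checksummed run manifest, YAML configs).

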