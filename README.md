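# furanoseFF

Force-field parameterization tools for fluoro- and hydroxy-substituted
furanose rings.

Five-membered sugar rings live on a continuous pseudorotation cycle
described by a phase angle *P* and amplitude *τ<sub>m</sub>*, with the
endocyclic torsions following ν<sub>j</sub> = τ<sub>m</sub> cos(P + 144°(j−2)).
Generic additive force fields underestimate the energy barriers between
pucker states of fluorinated nucleoside sugars — the gauche preference of
vicinal electronegative substituents is not captured by default torsion
constants — so simulated rings interconvert too easily and can prefer the
wrong hemisphere. This package implements the standard refitting workflow
for people building Amber-style parameters for such systems:

* **Pseudorotation geometry** — phase/amplitude from endocyclic torsions
  or Cartesian coordinates, the exact inverse, and least-squares embedding
  of a molecular template at any target pucker
  (`phase_from_torsions()`, `torsions_from_phase()`, `embed_ring()`).
* **Conformer generation** — 18°-interval pseudorotation scans, seeded
  random pose ensembles with the ring frozen per window, Kabsch RMSD and
  greedy 1 Å culling (`scan_pseudorotation()`, `random_poses()`,
  `cull_by_rmsd()`).
* **MM energies** — the additive potential
  E = Σ K<sub>b</sub>(b−b₀)² + Σ K<sub>θ</sub>(θ−θ₀)² +
  Σ (A/r¹² − B/r⁶ + k<sub>C</sub> q<sub>i</sub>q<sub>j</sub>/r) +
  Σ Σ<sub>n=1..3</sub> V<sub>n</sub>[1 + cos(nφ − γ)],
  with per-term decomposition (`mm_energy()`, `batch_energies()`).
* **Torsion fitting** — linear least squares for the barrier
  coefficients V<sub>n</sub> of the seven fluoro/hydroxy dihedral classes
  (γ constrained to {0°, 180°} analytically, free offset per molecule),
  the 5 % iterative convergence rule, and an outer loop alternating with
  charge refitting (`fit_torsions()`, `iterate_fit()`).
* **ESP/IpolQ charges** — net-charge-constrained electrostatic-potential
  fitting on van-der-Waals shell grids and the implicitly polarized
  vacuum/solvated midpoint (`fit_esp_charges()`, `combine_ipolq()`).
* **Pucker analysis** — phase series, probability histograms, percent
  North (−90 ≤ P < 90), per-window energy-error statistics, and
  through-origin MM-vs-reference regression (`percent_north()`,
  `window_error_stats()`, `origin_regression()`).
* **Synthetic oracle** — hidden "true" parameter sets, reference energies
  and ESP grids so every fitting stage is testable by parameter recovery
  (`make_oracle()`, `reference_energies()`, `oracle_esp_grids()`).

File formats: SYBYL mol2 templates, Amber frcmod parameter files
(including negative-PN multi-term dihedrals), multi-model PDB and
multi-frame XYZ trajectories, tab-separated reference-energy tables and
whitespace ESP grids. A set of 24 synthetic fluoro/hydroxy furanose test
templates covering all seven fitted dihedral classes is built in code
(`furanose_templates()`).

## Worked example

Recover hidden torsion coefficients from synthetic reference energies
over a three-molecule pose ensemble:

```r
library(furanoseFF)

tpl <- furanose_template(3)
tpl
#> <molecular_template> T03: 22 atoms, 22 bonds, net charge +0 e
#>   ring (C1' C2' C3' C4' O4'): C1' C2' C3' C4' O4'

scan <- scan_pseudorotation(tpl, scan_spec(interval_deg = 18))
scan
#> <conformer_set> 20 frames of 22 atoms (template T03)
#>   provenance: scan
phase_series(scan, tpl$ring)$phase_deg[1:4]
#> [1]  0.000 18.000 36.005 53.999

mm_energy(tpl, frame_coords(scan, 1))
#> <energy_breakdown> total 540.4033 kcal/mol (bond 3.4763, angle 478.9619,
#>   vdw 7.5030, coulomb 35.5599, dihedral 14.9021)

tpls <- lapply(c(1, 3, 11), furanose_template)
oracle <- make_oracle(7, tpls, noise_sd = 0)   # hidden "true" coefficients
entries <- lapply(tpls, function(t) {
  fr <- random_poses(t, scan_spec(poses_per_window = 10, seed = 2))
  list(template = t, frames = fr,
       energies = reference_energies(t, fr, oracle)$energy)
})
fit <- fit_torsions(fit_problem(entries))
summary(fit)
#> Torsion coefficient fit over 600 frames
#>   SSE 1.1267e-24 kcal^2/mol^2, RMSE 4.333e-14 kcal/mol
#>   fitted-vs-reference (through origin): slope 1.0000, r^2 1.0000
#>
#> Fitted terms (Vn kcal/mol, gamma deg):
#>          key n        v gamma
#>  c3-c3-c3-oh 1 1.978373   180
#>  c3-c3-c3-oh 2 0.825604     0
#>  ...
#> Per-molecule offsets (kcal/mol):
#>     T01     T03     T11
#>  2.6539 -2.9623  1.8475
```

The scan's measured phases hit their 18°-grid targets to within 0.05°;
the noiseless fit reproduces the oracle's hidden V<sub>n</sub> and γ to
machine precision (SSE ~ 10⁻²⁴), and the per-molecule offsets absorb the
arbitrary energy zero of each reference surface. `coef()`, `residuals()`,
`predict()`, `plot()` and `simulate()` work on the fit object as on any
R model. Writing the result is one call:
`write_frcmod(update_dihedral_params(default_parameters(), fit$terms), "sugar_mod.frcmod")`.

A thin command-line wrapper with `scan` / `poses` / `cull` / `energy` /
`fit-torsions` / `fit-charges` / `analyze` subcommands is installed at
`system.file("scripts", "furanoseff", package = "furanoseFF")`.

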