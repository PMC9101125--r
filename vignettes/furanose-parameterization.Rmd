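---
title: "Parameterizing fluorinated furanose rings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing fluorinated furanose rings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furanoseFF)
```

## The problem

Five-membered sugar rings interconvert along a continuous puckering
coordinate. Additive force fields describe each conformation's energy as a
sum of bonded, nonbonded and torsional terms, but standard parameter sets
systematically underestimate the barriers between pucker states of
fluoro- and hydroxy-substituted furanoses: the gauche preference of
vicinal electronegative substituents is poorly captured by generic
torsion constants, so simulated rings are too floppy and can even prefer
the wrong hemisphere of pucker space. The remedy implemented here is to
refit the Fourier coefficients of the fluorine/hydroxyl dihedral classes
(and the partial charges) against per-conformation reference energies
sampled over the whole pucker cycle.

## Pseudorotation

Ring conformation is parameterized by the phase angle $P$ and amplitude
$\tau_m$. The five endocyclic torsions follow
$\nu_j = \tau_m \cos(P + 144^\circ (j-2))$, with $\nu_2$ the torsion about
the C2$'$–C3$'$ bond, so $\nu_2 = \tau_m\cos P$. Inversion uses
$\tan P = \frac{(\nu_4+\nu_1) - (\nu_3+\nu_0)}{2\nu_2(\sin 36^\circ + \sin 72^\circ)}$,
with the quadrant resolved by `atan2` and the amplitude recovered from
$\nu_2$ together with the sine combination (robust when $\cos P \to 0$).
The atom quadruple of each $\nu_j$ is fixed in code: positions
$(j\!-\!2, j\!-\!1, j, j\!+\!1)$ mod 5 of the ring order
C1$'$, C2$'$, C3$'$, C4$'$, O4$'$. `phase_from_torsions()` and
`torsions_from_phase()` are exact inverses; the test suite verifies the
round trip to $10^{-9}$ degrees over 1000 random states.

**Embedding.** `embed_ring()` places a template at a target $(P, \tau_m)$
by damped least squares (Levenberg–Marquardt via minpack.lm) over the 15
ring-atom coordinates. The residual vector stacks the five torsion
deviations (weight 1 per degree), bond-length deviations from the
template (weight 500 per Å — effectively pinned), and bond-angle
deviations (weight 0.02 per degree — nearly free). This reflects the
physics: a closed five-ring with fixed bond lengths has four internal
degrees of freedom, so the five-torsion cosine wave can only be matched
by letting angles relax slightly. Initialization is a planar pentagon
puckered along the ring normal with displacement amplitude
$0.0072\,\text{Å/deg} \times \tau_m$ (calibrated so $\tau_m \approx 35^\circ$
gives the ~0.25 Å apex displacement of real furanoses); up to five phase
offsets of the initial displacement wave are tried, keeping the best.
Failure to reach every torsion within 0.5° or any bond within 0.01 Å
raises an error. Measured phase error across all 480 scan windows is
below 0.05°. Exocyclic substituents are carried rigidly in the local
frame of their anchor ring atom (built from its two ring neighbours);
no exocyclic relaxation is attempted in the embedding step.

The default scan amplitude is 35°, a typical furanose value; it is a
`scan_spec()` parameter because the reference workflow does not fix it.

## Conformer generation

`scan_pseudorotation()` emits one frame per 18° window (20 per molecule;
480 over the 24-template set). `random_poses()` then perturbs only
exocyclic torsions — every rotatable bond whose far side contains no ring
atom — by uniform angles in ±30° (configurable), keeping the ring frozen
at the window geometry so pucker remains the controlled variable. With
124 poses per window this reproduces the 2480-frames-per-molecule,
59,520-frame ensemble of the full workflow. Generation is seeded and
bitwise reproducible.

Near-duplicate culling (`cull_by_rmsd()`) uses heavy-atom Kabsch RMSD
with a 1 Å threshold. The published rule ("remove anything within 1 Å of
any other structure") is order-ambiguous; we adopt greedy keep-first in
generation order, which is deterministic, idempotent, and guarantees the
output is pairwise separated by at least the threshold.

## The energy model

`mm_energy()` evaluates the additive potential
$$E = \sum_{\text{bonds}} K_b (b-b_0)^2 + \sum_{\text{angles}} K_\theta (\theta-\theta_0)^2
+ \sum_{i<j}\left(\frac{A_{ij}}{r_{ij}^{12}} - \frac{B_{ij}}{r_{ij}^{6}}
+ k_C\frac{q_i q_j}{r_{ij}}\right)
+ \sum_{\text{dihedrals}} \sum_{n=1}^{3} V_n\,[1 + \cos(n\phi - \gamma)]$$
with $k_C = 332.0522$ kcal·Å/(mol·e²), Lorentz–Berthelot combination
($R_{ij} = r^*_i + r^*_j$, $\varepsilon_{ij} = \sqrt{\varepsilon_i\varepsilon_j}$,
$A = \varepsilon R^{12}$, $B = 2\varepsilon R^{6}$), nonbonded pairs
restricted to atoms three or more bonds apart, 1–4 pairs divided by 1.2
(electrostatics) and 2.0 (van der Waals), and no cutoff — the molecules
are small. The dihedral coefficient is taken literally as $V_n$ (no
division by 2); the frcmod writer maps $V_n \leftrightarrow$ PK/IDIVF so
files remain Amber-conventional. Improper torsions are excluded: none of
the refitted classes are impropers and the templates define none. The
per-term decomposition (`bond`, `angle`, `vdw`, `coulomb`, `dihedral`)
always sums to `total` within $10^{-9}$.

## Torsion fitting

At fixed coordinates the dihedral sum is *linear* in the $V_n$, so the
"nonlinear least squares" of the reference workflow reduces to ordinary
least squares after linearization: one row per frame, one column per
(adjustable class, $n$) holding $\sum_{\text{matching torsions}} 1 + \cos n\phi$,
plus one indicator column per molecule. The response is the reference
energy minus the MM energy of everything except the adjustable classes.
Three design choices matter:

* **Per-molecule offsets are mandatory.** Reference (quantum-style) and
  MM energy zeros are incommensurate; without a free constant per
  molecule the problem is ill-posed. The synthetic oracle deliberately
  injects hidden per-molecule offsets so that a fitter lacking them
  fails recovery.
* **$\gamma$ by sign, not search.** A negative linear coefficient is
  reported as $(|V_n|, \gamma = 180^\circ)$ via
  $V_n[1+\cos(n\phi-180^\circ)] = V_n[1-\cos n\phi]$; the constant
  difference moves into the molecule offset. This is exactly equivalent
  to the discrete $\gamma \in \{0, 180\}$ search and deterministic. A
  coefficient of exactly zero is reported with $\gamma = 0$.
* **Equal frame weights.** No weighting is prescribed; all frames count
  equally. (Boltzmann weighting would bias the fit toward minima, the
  opposite of the barrier-correction goal.)

Bond, angle and Lennard-Jones constants and $\theta_0$ are never
refit. Rank deficiency triggers a flagged ridge fallback with a warning
naming the unidentifiable classes; it is not silent.

`fit_torsions()` returns a classed model object with `print`, `summary`,
`coef` (signed coefficients), `residuals`, `fitted`, `predict` (reference
energies for new frames of a fitted molecule), `plot` (residuals against
phase) and `simulate` methods.

**Identifiability.** Within a single molecule, classes whose member
torsions all sit on ring bonds (e.g. F–C2$'$–C3$'$–F) generate design
columns confined to the two-dimensional span of $\cos n\nu, \sin n\nu$
over the 20-window scan, because terminal F/O substituents are rigid
relative to the ring and pose randomization only turns exocyclic bonds.
Two or more such classes in one molecule are therefore confounded, and
even a lone one is ill-conditioned: its torsion traverses only a
±$\tau_m$ arc, over which $\cos\phi$, $\cos 2\phi$ and $\cos 3\phi$ are
nearly affinely dependent. The cure is the one the original workflow
uses: fit jointly across many molecules, where each class appears with
different constant offsets (different substitution patterns and
stereochemistry). As a design rule, every adjustable class should occur
in at least two molecules of the training set with distinct
stereochemistry. Even then there is an irreducible noise floor: with
reference noise of 0.5 kcal/mol the coefficient standard errors at the
full 59,520-frame ensemble are roughly 0.01–0.04 kcal/mol, so hidden
coefficients drawn near the bottom of the [0.05, 2] kcal/mol range
cannot be pinned down to 10 % relative accuracy by any estimator —
a limitation of the experiment, not of the solver. The acceptance suite
reports this quantity as measured.

**Convergence.** Two successive fits are converged when every $V_n$
changed by less than 5 % (relative, with a 0.01 kcal/mol floor guarding
near-zero values) and every $\gamma$ kept its value; the same 5 % rule
(floor 0.01 e) applies to charges. `iterate_fit()` alternates a charge
stage and the torsion fit until both rules pass, starting from the
supplied (GAFF-like) constants only on iteration 1. With an identity
charge stage and self-consistent references it converges at iteration 2:
the first fit, then an unchanged confirmation. The convergence is
declared per (class, $n$) term.

## Charge fitting

`fit_esp_charges()` minimizes the squared deviation between grid
potentials and the atom-centred point-charge potential, with the net
charge enforced exactly through a Lagrange multiplier and an optional
harmonic restraint toward prior charges (the iterative workflow passes
the previous iteration's set with weight $10^{-4}$ for stability).
Potentials are in kcal/(mol·e) with the same $k_C$ as the energy model,
so fitted charges are directly consistent with it. The implicitly
polarized set is the per-atom midpoint of the vacuum and solvated fits.
By the workflow's convention the *vacuum* set feeds the torsion-fitting
stage, while the midpoint set is the deliverable for simulation; both
are available. Symmetry equivalencing (e.g. methyl hydrogens) is not
applied — the reference procedure does not mention it. Charges are fit
jointly over concatenated grids when several conformers are supplied.

Shell grids are seeded uniform points kept between 1.4× and 2.0× the
van-der-Waals radii (never closer than 1 Å to any atom), with target
density in points/Å³ of the sampling box.

## The synthetic oracle

`make_oracle()` stands in for the quantum-chemistry stages: it hides
"true" torsion coefficients ($V_n$ uniform in [0.05, 2] kcal/mol,
$\gamma$ random in $\{0, 180\}$, $n = 1..3$) for the seven refittable
classes, per-molecule constant energy offsets (±5 kcal/mol), vacuum
charges (the template values), a zero-sum polarization perturbation
$\delta q$ (±0.05 e) for the solvated environment, and homoscedastic
Gaussian reference noise of configurable $\sigma$ (the reference
workflow gives no error model). Reference energies are always evaluated
against the oracle's frozen copies of the templates, so later charge
refits cannot contaminate the ground truth. Grids for both environments
share one point set; the midpoint rule then has the analytic answer
$q_\mathrm{vac} + \delta q / 2$.

What the oracle does *not* emulate: real electron correlation, the
actual magnitude and anisotropy of gauche/anomeric effects,
conformation-dependent polarization, or solvent structure. Passing
recovery tests therefore demonstrates that the fitting machinery is
correct and well-posed — not that the resulting constants are accurate
for real fluorosugars.

## Pucker analysis

`phase_series()` maps frames to $(P, \tau_m)$ with phases reported in
$(-180, 180]$; `percent_north()` integrates $-90 \le P < 90$ (a frame at
exactly $+90^\circ$ counts South — a deterministic tie rule; note that a
measured uniform scan has two windows sitting exactly on this divide, so
sub-0.1° numerical phase error decides their side). Histograms use
left-closed bins and normalize to 1. Energy-error statistics
($EE = E_\mathrm{MM} - E_\mathrm{ref}$) report per-window mean and
*population* standard deviation (n divisor) with ±σ and ±2σ envelopes.
The MM-versus-reference regression is through the origin:
slope $= \sum xy / \sum x^2$ and $r^2 = 1 - \sum(y-\hat y)^2/\sum y^2$
(uncentred convention — a centred $r^2$ would differ), applied after
per-molecule minimum alignment of both energy scales, since their zeros
are arbitrary.

## The template set

The 24 bundled test molecules are synthetic constructs built in code: a
tetrahydrofuran ring with a 1$'$-methoxy group, a 4$'$-hydroxymethyl arm
and all 6 × 4 combinations of {F, OH, gem-F$_2$, F/OH} substitution at
the 2$'$ and 3$'$ positions on either ring face, GAFF-typed (c3, os, oh,
ho, h1, f) with electronegativity-motivated charges balanced to zero at
mol2 precision (4 decimals). They cover all seven refitted dihedral
classes. The shipped starting parameters are GAFF-flavoured values for
these types; they are the package's defaults, not a published set.

## Problem sizes and determinism

The test suite uses reduced ensembles (4–12 poses per window, a handful
of templates) wherever exactness rather than statistics is asserted —
noiseless least squares recovers parameters to machine precision at any
ensemble size once the design has full rank. Statistical assertions
(noise variance, noisy recovery) use the full per-molecule ensemble of
124 poses × 20 windows. Every stochastic step takes an explicit integer
seed and restores the session RNG state afterwards.

## Known limitations

* Template geometries are idealized, not optimized structures; bond
  angles at the crude pentagon carry strain. This is immaterial for
  recovery tests (both sides of the comparison use the same geometry)
  but the bundled templates should not be mistaken for literature
  conformers.
* The embedding carries substituents rigidly; steric clashes after large
  pucker changes are resolved only by the ±30° pose randomization, not
  by minimization.
* Fitting assumes the adjustable classes are absent from the
  non-adjustable remainder (specific keys shadow wildcards); frcmod
  files with exotic wildcard patterns beyond `X-b-c-X` are not
  supported.
* Six-membered (Cremer–Pople) puckering, periodic boundary conditions,
  Ewald electrostatics and any actual MD are out of scope; trajectories
  are inputs.
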