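---
title: "Methods: coarse-grained adsorption free energies and kinetic corona prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained adsorption free energies and kinetic corona prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

When a nanoparticle (NP) is immersed in a biological medium, biomolecules
adsorb to its surface and form a corona that largely determines how the
particle is seen by cells. `coronaforge` predicts that corona in two stages.

**Stage 1 — orientation-resolved adsorption free energies.** A biomolecule
is represented as a rigid set of typed beads, one per residue (CA position,
three-letter code), each with a weight `alpha_i` read from the PDB occupancy
column and a charge from a residue table (ARG/LYS +1, ASP/GLU −1, HIS +0.1
at pH 7). The NP is one or more geometric beads (sphere, cylinder, cube,
tube) of a material. The interaction of a biomolecule bead with an NP bead
at surface-to-bead-center distance `d` is

U(d) = U_S(d) + U_H(d) + U_el(d) + U_x(d),

where

* `U_S` is a tabulated short-range potential — typically a potential of mean
  force (PMF) from atomistic simulation — remapped from the geometry it was
  produced for (a plane, or a cylinder of stated radius) to the actual NP
  geometry. The remapping factor is the ratio of `r^-6` integrals over the
  two NP volumes truncated at the production cutoff `r_c` around the bead
  center, the approximation being that the short-range potential is
  dominated by the dispersion term. For `d >= r_c` both truncated volumes
  vanish and the factor is 1 by continuity.
* `U_H` is the integrated van-der-Waals (Hamaker) attraction over the NP
  volume and the bead sphere, restricted to point pairs farther apart than
  `r_c` — the nearer pairs are already included in the PMF. For spheres the
  unrestricted part is the classic two-sphere closed form and the excluded
  near-pair part is integrated numerically through the pair-distance
  density; cylinders are numerical throughout; cubes use their bounding
  sphere. The construction is smooth at the separation where the exclusion
  region empties and reduces to the standard two-sphere expression in the
  far field.
* `U_el` is the linearized Debye–Hückel interaction of the point-charge
  bead with a surface held at potential `psi_0`: `q psi0 (R/(R+d)) e^{-kappa d}`
  for spheres, `q psi0 e^{-kappa d}` for planes (also used for cubes, whose
  edge lengths far exceed typical Debye lengths), and
  `q psi0 K0(kappa(R+d))/K0(kappa R)` for cylinders. These are the standard
  solutions for the boundary condition `psi(d=0) = psi0`; 1 e·mV =
  0.09649 kJ/mol.
* `U_x(h) = (0.1/h)^12 - 1` kBT for `h <= 0.1` nm (0 above) is a
  numerical-stability wall that keeps the Boltzmann factor finite when an
  orientation places a bead inside the NP; it is capped at 1e6 kBT so
  integrands underflow to zero rather than overflow.

For a whole biomolecule in one orientation the per-bead potentials are
summed. In the default *presummed* mode a single axial table `U_m(z)` per
bead type is built for the NP complex and read at the coordinate matching
the global symmetry (radial distance for spheres, axis distance for
cylinders, height for planes); beads that would overlap an NP bead add a
small penalty (5 kBT each, configurable — the choice only needs to
discourage unphysical overlaps in the presummed picture). For decorated NPs
(brushes), whose potential is not a function of one coordinate, the *full*
mode sums every bead–NP-bead pair at its true three-dimensional closest
approach; for a single spherical NP bead the two modes coincide.

The orientation `(phi, theta, omega)` is applied as `R_z(-phi)` then
`R_y(180° - theta)` (then optionally `R_z(omega)`), which maps the body
direction `(cos phi sin theta, sin phi sin theta, cos theta)` onto the
inward surface normal. The adsorption free energy of the orientation is the
Boltzmann-weighted integral over the approach coordinate `xi` (NP center to
biomolecule COM),

E = -kBT ln [ ∫ xi^a e^{-U(xi)/kBT} dxi / ∫ xi^a dxi ],

with `a` = 2, 1, 0 for spherical, cylindrical and planar coordinate
systems. The inner bound is the first bead–surface contact on approach
along the axis (or, in full-scan mode, the deepest COM position with no
bead inside the core bounding radius — relevant for concave molecules that
can straddle a small NP); the outer bound places the lowest bead 2 nm above
the outer bounding radius, far enough that all interactions are negligible.
The `(phi, theta)` sphere is divided into 5°×5° cells with 64 uniform
subsamples per cell by default; per-cell means (simple or
Boltzmann-weighted) and standard deviations are written to `.uam` maps at
the cells' left-hand edges, so postprocessing adds 2.5° before taking
`sin(theta)` weights.

**Stage 2 — competitive adsorption kinetics.** Each orientation cell of
each molecule becomes an adsorbate species with a hard-disk footprint
(maximum in-plane bead distance from the COM axis, floored at 0.1 nm so
point-like adsorbates keep a positive area), a `sin(theta)`-normalized
orientation weight `f_i`, an adsorption rate `k_a = f_i k_coll` built from
the Smoluchowski collision rate `4 pi (R + r_p) D c N_A` with
Stokes–Einstein diffusivity (water viscosity 0.89 mPa·s), and a desorption
rate fixed by detailed balance (below). A rejection-free kinetic Monte
Carlo then simulates adsorption and desorption: candidates are drawn
proportionally to `k_a`, placed uniformly on the surface, and accepted in
standard mode only if their disk overlaps no adsorbed disk (great-circle
metric on spheres, periodic Euclidean metric on planes, unrolled-surface
metric on cylinders). In displacement mode an arrival that overlaps
disks of total binding energy `E_over` is accepted with probability
`e^{-dE}/(1+e^{-dE})`, `dE = E_in - E_over`, evicting the overlapped disks;
an energy-neutral exchange is accepted exactly half the time, the limit
consistent with implicit water at reference energy zero. Desorption rates
are multiplied by the same no-overlap acceptance factor so each `k_a/k_d`
ratio is preserved. Steady-state mode rescales every `k_a` to a common
reference rate with `k_d` scaled identically, which accelerates convergence
without changing the stationary distribution of the reversible dynamics.

# Rate-constant convention and the mean-field baseline

The mean-field (competitive-Langmuir) baseline is

N_i = n_i (c_i/c0) e^{-E_i} / (1 + Σ_j (c_j/c0) e^{-E_j}),

with `n_i = A/(pi r_p,i^2)` disk-sized sites and `c0 = 1/(v_ref N_A)` for
the reference volume `v_ref = 1 nm^3` (`c0 ≈ 1.66 M`). We treat the
agreement between this closed form and the KMC stationary state as the
normative contract pinning the rate conventions: the desorption rate is
defined through `k_a/k_d = n_i (c_i/c0) e^{-E_i}`, which makes the
mean-field expression the exact stationary solution of the KMC's
low-coverage rate equation. The individual prefactors (collision rate,
reference volume) are documented conventions and can be overridden through
the species table. Consequences verified by the test suite: doubling a
concentration doubles `k_a` and leaves `k_d` unchanged; a near-point-like
species reaches the Langmuir mean within stochastic error; an irreversible
planar run reaches the random-sequential-adsorption jamming coverage
(≈ 0.547).

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| temperature | 300 | K | standard simulation temperature; kBT = 2.494 kJ/mol |
| Debye length | 1 | nm | physiological-strength electrolyte |
| PMF cutoff `r_c` | 1.0 | nm | typical LJ cutoff of PMF production runs |
| quadrature step | 0.05 | nm | comparable to PMF table resolution; halving it moves energies by < 0.01 kBT on fixtures |
| scan grid / subsamples | 5° / 64 | — | balances angular resolution against cost; coarser grids are exposed for quick runs |
| overlap penalty | 5 | kBT | "small" presum-mode penalty; any value large enough to disfavour overlaps works |
| wall cap | 1e6 | kBT | keeps integrands finite; `e^{-U}` underflows to 0 regardless |
| tube wall thickness | 0.34 | nm | graphene interlayer spacing, for hollow-cylinder volume integrals |
| KMC replicates | 5 | — | averages stochastic scatter in reported counts |
| `v_ref` | 1 | nm^3 | reference volume for the concentration scale |

Correction factors and Hamaker grids are cached per (geometry, radius,
cutoff) on distance grids of 0.005 nm and ~0.02 nm respectively with linear
interpolation, matching the resolution of the PMF tables themselves; the
sphere Hamaker value switches to the exact closed form as soon as the
exclusion region empties.

# Long-range parametrization

Hamaker constants can be supplied per material or derived:

* **Force-field route:** `A = pi^2 (eta/V_b)^2 Σ_lm 4 eps_lm sigma_lm^6`
  with Lorentz–Berthelot combination, packing fraction `eta = 0.64`
  (random close packing) for molecules and 1 for surface structures already
  in the solid phase, and `V_b` the convex-hull volume of the molecule's
  atom spheres (radius `sigma/2`, 512 surface samples per atom by default).
  For a three-site water model this yields ~6.7e-20 J, against ~6.8e-20 J
  computed by the same route upstream — the residual difference reflects
  the exact water parametrization, which is not pinned down by the method.
* **Lifshitz route:** `A = A(0) + A(nu>0)` with the entropic term from the
  static permittivity contrast and the dispersive term
  `(3h/4pi) ∫ D13 D23 dnu` over imaginary frequencies, using a
  single-oscillator dielectric model `eps(i nu) = 1 + (n^2-1)/(1+(nu/nu_e)^2)`
  or the free-electron `1 + (nu_p/nu)^2` for metals. With all-dielectric
  media sharing one absorption frequency the integral collapses to the
  visible-refractive-index closed form, which the quadrature reproduces to
  better than 0.5% — that identity also provides the numerical inversion
  used to assign an effective refractive index to a material from its
  force-field self-interaction constant.
* **Material pipeline:** beads are always dielectric (`eps0 = 1.3`,
  `nu_e = 3e15 Hz`); a surface is metallic when a strict majority of its
  atoms are highly polarizable (`eps > 12 kJ/mol`, assumed to be in the
  force-field energy unit) and quasi-neutral (`|q| < 0.5 e`), in which case
  it gets a nominal plasma frequency of 5e15 Hz; the medium is water
  (`n = 1.33`, `eps0 = 82`); the zero-frequency term (< 1 kBT) is
  neglected. The output is order-of-magnitude accurate, which is
  acceptable because the Hamaker term is a small correction to the PMF.

Bead radii come either from the convex-hull equal-volume sphere or from the
first repulsive-to-attractive zero crossing of the orientation-averaged LJ
self-interaction (232 deterministic rotations, bisection to 1e-4 nm).
The 3-D convex hull is built in-package by incremental insertion; against
an analytically known sphere the equal-volume radius is accurate to ~0.2%
at 1024 samples per atom.

# The synthetic material and toy biomolecules

Because real PMF libraries are external artifacts, the package generates
synthetic materials for development and testing: each bead type gets a 9-3
wall-well potential `U(d) = eps[(2/15)(sigma/d)^9 - (sigma/d)^3]` truncated
and shifted to zero at the cutoff, with well depths drawn from 2–10 kJ/mol
and `sigma` from 0.25–0.45 nm — the range spanned by residue–surface PMFs
on common inorganic materials — plus Hamaker constants uniform in
0.05–1 kJ/mol. Toy biomolecules are CA-only PDB files in helix
(alpha-helical CA geometry: 2.3 Å radius, 1.5 Å rise, 100° turn), line
(3.8 Å CA spacing) and ring layouts. Everything is deterministic per seed.

What the synthetic fixtures do *not* emulate: chemically correlated well
depths across residues, PMF fine structure (solvation oscillations,
barriers), conformational flexibility, or realistic protein shapes. Tests
passing on these fixtures therefore validate the machinery — geometry
remapping, integration, kinetics, bookkeeping — not the chemical accuracy
of any real material, which enters only through user-supplied PMF and
Hamaker libraries.

# Numerical choices and degenerate inputs

* Free-energy quadrature is trapezoidal; with `U = 0` the normalization is
  algebraically exact, so the zero-potential result is exactly 0.
* PMF interpolation is linear and exact at tabulated points; below the
  first point the last value is held (the wall dominates there), above the
  last point the potential is 0. A PMF whose final entry exceeds
  0.25 kJ/mol (~0.1 kBT) in magnitude triggers a far-field-decay warning,
  not an error.
* Core bounding radius with several equally-large beads: first index wins
  (documented tie-break). Bounding radii can be overridden for agglomerates.
* All-coincident atom sites fall back to the single-atom radius `sigma/2`;
  an LJ scan with no sign change is an error rather than a guess.
* Per-cell scan streams derive from the master seed by a fixed counter, so
  cell results are independent of evaluation order.
* The historical fixed-width PMF dialect is rejected with a clear message;
  only the comma-separated dialect is supported.
* Hamaker files store kJ/mol (PMF-consistent); `kJmol_to_J()` /
  `J_to_kJmol()` convert to the literature's J scale.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run on deliberately small
instances chosen to give clean statistics: orientation scans at 30–90°
cells with 2–8 subsamples, Monte-Carlo volume-integral oracles at 1.2e7
draws, 20 KMC replicates for the detailed-balance check, three 8e6-event
runs for the jamming limit, and a two-molecule end-to-end demonstration.
The defaults (5° cells, 64 subsamples) match production use.

# Known limitations

* Biomolecules are rigid; flexible or multimeric adsorbates need structure
  ensembles upstream.
* The PMF remapping assumes dispersion-dominated short-range interactions
  and distance-only PMFs.
* Mean first-passage times are not computed; the `.uam` column is -1.
* The electrostatic model is linearized and surface-potential based; for
  PMFs that already include charge effects the surface potential should be
  set to 0 to avoid double counting.
* The cube electrostatic/dispersion treatment is the bounding-sphere /
  planar approximation, appropriate while the Debye length is much smaller
  than the edge length.
* Cylinder KMC treats only the lateral surface (no end caps), matching the
  periodic simulation surface.
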