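---
title: "End-point binding free energies: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-point binding free energies: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endpointr)
```

## The end-point model

`endpointr` estimates host–guest binding free energies from snapshots of
equilibrium ensembles, without alchemical intermediates:

$$\Delta G_{bind} \approx \Delta E_{MM} + \Delta G_{polar} +
  \Delta G_{nonpolar} - T\Delta S.$$

Two sampling realizations are supported, and their difference is the point
of the package:

* **Single-trajectory** (`single_trajectory_estimate()`): only the bound
  complex is sampled. Host and guest terms are evaluated on coordinates
  sliced from the complex frames, so every internal energy (bonds, angles,
  torsions, intra-molecular nonbonded) cancels *exactly* and only
  inter-molecular vdW and electrostatics plus the solvation change
  survive. This is the popular, low-variance protocol.
* **Three-trajectory** (`three_trajectory_estimate()`): complex, free host
  and free guest are sampled independently, $\Delta G = \langle G
  \rangle_C - \langle G \rangle_H - \langle G \rangle_G$. Binding-induced
  reorganization (the `internal` component) now enters the estimate, and
  with it much larger fluctuations — for macrocyclic hosts with charged,
  rotatable rims the unbound-host polar terms can drift on any practical
  sampling timescale. `convergence_diagnostics()` exists to detect exactly
  that: a least-squares drift slope with a normal CI plus a block-averaged
  SEM curve; a series is flagged non-convergent when the slope CI excludes
  zero or the block SEM fails to plateau (largest-block SEM more than 3
  times the naive SEM — a deliberately permissive factor, since iid series
  keep the ratio near 1 while genuinely drifting series exceed it by
  orders of magnitude).

When the three unbound/bound ensembles are exact coordinate slices of one
another the two realizations coincide term by term; the test suite checks
this cancellation to 1e-8 kcal/mol, which is the strongest available
internal consistency check of the partitioned energy bookkeeping.

## Energy terms

**Gas phase.** AMBER functional forms throughout: $E = k(r-r_0)^2$ bonds
(no 1/2), $k(\theta-\theta_0)^2$ angles, $\sum_n (V_n/2)(1+\cos(n\phi -
\gamma))$ torsions (impropers use the same form), Lennard-Jones
$A/r^{12}-B/r^6$ under Lorentz–Berthelot combination from per-type
rmin/2 and epsilon, Coulomb with $k_e = 332.0637$ kcal Å mol$^{-1}$
e$^{-2}$. 1-2 and 1-3 pairs are excluded; 1-4 electrostatics and vdW are
divided by 1.2 and 2.0 (overridable by the parameter file). There is no
cutoff and no periodicity: these are post-processing energies of extracted
snapshots, where end-point re-scoring conventionally uses the full
pairwise sums (cutoffs and PME belong to the sampling engine, which is out
of scope here).

**Polar solvation.** The default is a generalized Born model of the OBC
type: Hawkins–Cramer–Truhlar pairwise descreening with screened,
offset-reduced intrinsic radii ($\rho_i - 0.09$ Å), rescaled through the
$\tanh(\alpha\Psi - \beta\Psi^2 + \gamma\Psi^3)$ polynomial with the
second coefficient set (1.0, 0.8, 4.85) and mbondi2-style intrinsic radii
stored as data on each atom kind. The pair energy uses the standard
$f_{GB} = \sqrt{r^2 + \alpha_i\alpha_j\exp(-r^2/4\alpha_i\alpha_j)}$ with
self terms and bonded pairs included. The exterior dielectric defaults to
78.5 (a common implicit-water value; configurable), salt screening
$\kappa$ defaults to 0.

A finite-difference linearized Poisson–Boltzmann solver
(`pb_energy_fd()`) is provided as an independent reference for the polar
term: successive over-relaxation (C++ kernel) on a two-dielectric map with
face dielectrics assigned by face midpoints inside the union of
`gb_radius` spheres, trilinear charge spreading, Debye–Hückel monopole
boundary values, and grid self-energy cancelled by subtracting a
uniform-dielectric solve of the same grid/charges. At 0.25 Å spacing and
10 Å padding the Born-ion error is ~1.5% and halving the spacing from
0.5 Å reduces the error roughly threefold. It is a reference
implementation — sphere-union boundary only, no nonlinear term, not tuned
for large solutes.

**Nonpolar solvation.** $\gamma \cdot SASA + \beta$ with Shrake–Rupley
SASA on a deterministic golden-spiral lattice (960 points/atom default,
probe 1.4 Å, atomic radii = LJ rmin/2). Defaults $\gamma = 0.0072$
kcal/mol/Å$^2$, $\beta = 0$; the PB-flavoured pair (0.00542, 0.92) can be
set on the model object.

**Entropy.** RRHO from normal-mode analysis of minimized snapshots:
L-BFGS with the analytic MM gradient plus a damped-Newton polish on the
finite-difference Hessian, then central-difference mass-weighted Hessian
(step 1e-4 Å), discarding the 6 smallest-|eigenvalue| modes by count (5
linear, 3 monatomic) — validated by the invariant that minimized nonlinear
toys show exactly six near-zero modes. Sackur–Tetrode translation,
classical rigid rotor, harmonic-oscillator vibrations at 300 K, 1 atm,
symmetry number 1. NMA runs on the gas-phase potential at
$\epsilon_{in}=1$; if a symmetric start relaxes onto a saddle the
imaginary mode is followed downhill deterministically. Snapshots are
chosen equally spaced (`floor(n/k)` stride), mirroring the fixed-interval
protocol of end-point practice; the estimators take entropy as an optional
precomputed term (`binding_entropy()`) because it is by far the most
expensive stage.

## The dielectric-constant scan and its decomposition

The interior dielectric $\epsilon_{in}$ scales every Coulomb term by
$1/\epsilon_{in}$ and the GB prefactor to $(1/\epsilon_{in} -
1/\epsilon_{out})$, with effective radii unchanged. `dielectric_scan()`
therefore never re-evaluates energies: Coulomb sums are stored at
$\epsilon = 1$ and rescaled exactly; the GB pair sum is stored
$\epsilon$-free. The scan is exact by linearity and is only defined for
the GB solvent (a PB scan would require one solve per $\epsilon$; it is
deliberately unimplemented and requested PB scans raise an error).
Entropy, vdW, internal and nonpolar terms are held fixed across the scan
(the entropy is not recomputed per dielectric).

`decompose_dielectric_response()` splits the $\epsilon$-dependent part
into three physically distinct rows: (1) bound-state inter-molecular
electrostatics, (2) the binding-induced change of intra-molecular
electrostatics — identically zero in the single-trajectory realization,
where sliced intra terms cancel — and (3) the binding-induced change of GB
polar solvation. The rows sum to the $\epsilon$-dependent part of the
estimate to 1e-9; whether the estimate rises or falls with
$\epsilon_{in}$ is decided by the sign of that total: a negative
$\epsilon$-dependent part (the typical opposite-charge host–guest
situation, where solvation screening dominates) is attenuated by
screening, so the net affinity increases monotonically.

## Quality metrics

`compute_metrics()` pairs calculated and experimental affinities by system
id: RMSE; mean signed error defined as mean(exp − calc), so that
*positive* MSE means overbinding — the sign convention was fixed by
recomputing both signs printed in the benchmark tables; Kendall τ-b
(tie-corrected, via `stats::cor`; the shipped three-trajectory tables
contain ties at printed precision); and Pearlman's predictive index with
pair weights equal to the *calculated* affinity gaps
$|\Delta G_{calc,j} - \Delta G_{calc,i}|$ — the convention verified to
reproduce all sixteen printed PI summary values, where experimental-gap
weights reproduce none of them.

## The synthetic host–guest generator

Real macrocycle trajectories are not shippable, so every stage is
exercised on seeded toys (`make_toy_hostguest()`, `make_ensemble()`) that
emulate the *structure* of the problem:

* a closed 12-bead ring (polygon angle 150°) with 6 pendant 2-bead tails
  whose terminal bead carries −1 e (a carboxylated rim), giving the host
  an integer net charge of −6 e, and a 4-bead zigzag guest with a +1 e
  head threaded through the cavity;
* made-up but plausible bead parameters (bond k = 300 kcal/mol/Å²,
  r0 = 1.5 Å, angle k = 50, LJ ε ≈ 0.1 kcal/mol, Fourier torsion triples
  on the tails);
* pseudo-dynamics as Gaussian jitter (0.03 Å default — enough to give
  nonzero fluctuation statistics without disturbing the geometry) plus a
  two-state tail-rotation switch (open ↔ rotated 90° out of the rim
  plane). A constant flip probability produces a bimodal tail-torsion
  population; a time-ramped closed-state schedule produces the systematic
  drift in the polar energetics that the diagnostics must flag.

What the toys deliberately do **not** emulate: solvent and counter-ion
coordination, realistic chemistry or force-field values, Boltzmann-
consistent state populations, and timescales. Passing tests therefore
demonstrate that the estimator algebra, the solvation models and the
diagnostics behave correctly — not that any particular real system is
predicted well. The published per-guest affinities of the WP6 benchmark
require hundreds of nanoseconds of explicit-solvent sampling and are out
of reach by construction; the reproducible surface is the quality-metric
summary rows recomputed from the printed per-guest columns (shipped as
CSV transcriptions under `inst/extdata/`) plus the analytic oracles.

## Numerical choices and degenerate inputs

* Dihedral gradients use the standard cross-product formulation with
  guards at $|n_1|^2, |n_2|^2 < 10^{-12}$; angle gradients guard the
  collinear $\sin\theta \to 0$ singularity. The analytic gradient is
  verified against central differences in the suite.
* The prmtop subset writes real fields at full double precision
  (`%FORMAT(3E24.16)`): 8-significant-digit fields measurably perturb
  hundred-kcal/mol Coulomb and angle sums, and the JSON/prmtop
  cross-format equivalence is held to 1e-6 kcal/mol.
* Zero interatomic distance between interacting atoms is an error, not an
  Inf; an empty torsion definition is a valid zero-energy term and
  round-trips through the prmtop format as a single zero-barrier entry so
  the 1-4 pair bookkeeping survives.
* Uncertainties are naive SEMs (sd/√n) per component, combined in
  quadrature across the three independent ensembles in the
  three-trajectory case; frames are treated as independent, so duplicating
  every frame shrinks the naive SEM by ~1/√2 (documented behaviour —
  use `uncertainty(..., method = "block")` for correlated series).
* Problem sizes used in the shipped tests and acceptance script — 28-atom
  toys, 50-frame ensembles, a 97³ PB grid for the Born ion, 10-snapshot
  entropy averages — were chosen as the smallest systems on which every
  invariant is sharp (cancellation at 1e-8, conservation at 1e-9);
  the estimator algebra is size-independent.

## Known limitations

PB: sphere-union dielectric boundary only (no SES), linearized equation,
single interior dielectric region, modest convergence for large solutes.
GB: no ALPB/neck corrections. Entropy: no quasi-harmonic or
interaction-entropy estimators, no anharmonicity. Trajectories: text
formats only (multi-model PDB, XYZ); binary MD formats are out of scope.
The CLI (`endpointr_cli()`, `exec/endpointr`) is a thin dispatcher over
these functions with JSON/CSV outputs and a provenance record per run.
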