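---
title: "Methods: screw-symmetry stacking for fibril ligand docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screw-symmetry stacking for fibril ligand docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symstack)
```

## The model

Amyloid fibrils such as tau filaments are helical polymers: consecutive
monomers are related by one screw operation, a twist of angle $\theta$
about the fibril axis combined with a rise $d$ along it (for AD tau,
$d \approx 4.7$ Å and $\theta \approx -1^\circ$). Ligands observed in
cryo-EM structures of these fibrils bind as *stacks* that repeat with the
same operator: each bound molecule touches the protein identically, and
most of its contacts are with its own symmetry mates.

`symstack` treats that symmetry as a hard constraint on docking output.
For a candidate pose $x$ (atom coordinates in the fibril frame) and the
fibril operator $T(x) = Rx + t$:

1. **Clash filter.** The image $T(x)$ is generated and the pose is
   discarded if any atom of $x$ comes within 2 Å of any atom of $T(x)$
   (`symmetry_clash_check()`). A pose that fails cannot tile into a stack.
2. **Stacking energy.** A pose that passes gains a ligand–ligand 12-6
   Lennard-Jones term $\sum_{ij} \varepsilon_{ij}[(r_{min,ij}/r_{ij})^{12}
   - 2(r_{min,ij}/r_{ij})^6]$ over pairs with one atom in $x$ and one in
   $T(x)$ (`pair_vdw_energy()`), added to externally supplied
   ligand–protein terms (`stack_score()`). Only the first pair is
   evaluated: by symmetry every interface in the stack is identical.
3. **Periodic context.** Deposited fibril structures are short (five
   monomers per protofilament for AD PHF tau); applying integer powers of
   $T$ and $T^{-1}$ blockwise extends them (5 monomers → 15 with one copy
   each way, `extend_fibril()`) so score grids computed downstream have no
   edge effects, and the heavy atoms of a ligand stack can be exported as
   pseudo-atoms that extend the low-dielectric boundary of
   electrostatics/desolvation grids (`boundary_pseudoatoms()`).
4. **Stack refinement.** A Metropolis Monte Carlo search over rigid
   placements of the monomer (`run_mc()`), with the symmetry re-imposed at
   every step, asks whether the docked stacking geometry is already near a
   minimum of a chosen energy backend.
5. **Screen evaluation.** Labelled score lists are summarized by the
   enrichment factor at a screened fraction and the adjusted logAUC
   (`ef_at_fraction()`, `adjusted_logauc()`).

## Deriving the operator

`derive_operator()` reconstructs $T$ from the deposited structure itself:
consecutive monomers of one protofilament are put in atom correspondence
through their identical residue sequences (alpha-carbons by default; a
flag adds N, C, O — which of these the original pipeline used is not
documented, so both are exposed and CA-only is the default), each pair is
superposed by the proper-rotation least-squares (Kabsch) fit, and the
per-pair transforms are averaged: rotations by the chordal mean (project
the elementwise mean onto SO(3) via SVD), translations arithmetically
after re-solving each pair against the mean rotation. Averaging over the
$n-1$ consecutive pairs suppresses per-monomer coordinate noise.

`decompose_screw()` reports the operator as screw parameters. Conventions
chosen once: the axis is oriented so the rise is non-negative (for a pure
rotation, so the twist is non-negative), the twist sign follows the
right-hand rule about that axis — this reproduces "4.7 Å rise, −1° twist"
as a signed pair — and the axis point is the perpendicular foot of the
axis nearest the origin. A rotation within 1e-12 of the identity takes
its axis from the translation; identity rotation *and* zero translation
is reported as a degenerate-operator error.

**Conditioning caveat.** When the twist is small, the rotation is nearly
the identity and the direction of its axis is the quotient of two small
quantities. With 0.1 Å coordinate noise, a 12-residue monomer lets the
derived axis wander by ~0.2 rad, biasing the recovered rise by up to
~0.2 Å; a realistic fibril-core monomer (~70 residues spread across the
cross-section, like tau's ordered core) pins the axis down and recovers
the rise to well within 0.05 Å. The noise-robustness tests therefore use
72-residue monomers; treat rises derived from very small fragments with
caution.

## Energies and the per-monomer formula

The vdW table ships as editable plain text
(`inst/extdata/vdw_params.txt`) with generic united-atom literature
values (one site per heavy atom, Lorentz–Berthelot combination:
arithmetic `rmin`, geometric `epsilon`). The published parameter set the
method's score grids use is not printed anywhere we can cite numerically,
so none of the package's tests depend on the shipped constants — they use
round-number fixture tables. No cutoff or softening is applied to the LJ
sum; whether the upstream engine applies one is unstated, so the default
is the bare sum.

For stack refinement the energy of one monomer inside the infinite stack
is estimated from the two nearest symmetry mates: with a backend total
energy $E$,

$$E_\mathrm{per-monomer} = \tfrac12\left[E(\mathrm{trimer}) -
3E(\mathrm{monomer})\right].$$

The central monomer owns two interfaces, each shared by two monomers of
the infinite stack, hence the factor $\tfrac12$; the small mate–mate
(±1) coupling stays inside the trimer term. Intramolecular contributions
cancel exactly, so the built-in LJ backend scores only inter-pose pairs
and treats a lone monomer as zero. The formula sits behind one function
(`per_monomer_energy()`) so an alternative partitioning can be swapped
in. External evaluators (e.g. a neural-network potential) plug in through
`command_backend()`: the geometry is written as XYZ, a user command runs,
and a single energy (kcal/mol or hartree) is read back; the package never
binds to any NN runtime.

## Monte Carlo choices

Moves are rigid only — the docking engine owns the conformation — and are
applied about the heavy-atom centroid. Translations are i.i.d. normal per
component; rotations realize an isotropic SO(3) perturbation as a uniform
random axis with angle $|N(0, \sigma_r^2)|$, an accepted small-angle
construction of that family. Acceptance is standard Metropolis
($\Delta E \le 0$ always, else $e^{-\Delta E/kT}$). Defaults — 1000
steps, $\sigma_t = 0.2$ Å, $\sigma_r = 2^\circ$, $kT = 0.593$ kcal/mol
(room temperature) — are not documented by the original method beyond the
step count; the widths were chosen small enough to keep acceptance
moderate on LJ landscapes and are all exposed as arguments. The result
reports the minimum over *every evaluated* configuration (start included,
rejected proposals included), so `best_energy <= start_energy` always
holds; a clash in the final best pose is flagged rather than forbidden,
since the energy already penalizes it. A fixed seed reproduces the
accepted-energy trace bit-exactly; the caller's RNG state is restored.

## Enrichment metrics

`adjusted_logauc()` integrates the fraction of actives found against
$\log_{10}$ of the screened *decoy* fraction over $[\lambda, 1]$ with
$\lambda = 0.001$, normalizes by $\log_{10}(1/\lambda)$, scales to
percent and subtracts the random-curve value 14.462, giving 85.538 for a
perfect ranking and ≈0 for a random one. The decoy-fraction x-axis is the
convention of the docking enrichment literature; because the source
material does not restate the formula, a `x_axis = "database"` switch is
provided. The ROC curve is piecewise-linear through the per-decoy points
and integrated with exact trapezoids on the log axis. Molecules the clash
filter prevented from scoring still occupy ranks: they are appended after
all scored molecules in input order and counted in the report.

## What the synthetic data does and does not establish

The generators state a fixed world:

* `make_helical_fibril()` — 5 monomers per protofilament, rise 4.7 Å,
  twist −1°, monomer = an idealized C-shaped CA arc (3.8 Å spacing,
  ±0.3 Å pleat) offset from the axis; optional second protofilament
  related by a 2-fold about the axis; optional Gaussian jitter.
* `make_planar_ligand()` — flat carbon rings with 1.39 Å aromatic bonds
  (the non-planar variant displaces one atom 1.5 Å, a bridged-bicyclic-
  like corner that the clash filter rejects as a stacker).
* `make_screen_set()` — 16 actives vs 800 decoys, Gaussian scores with a
  2 kcal/mol mean separation, the shape and rough difficulty of a
  retrospective fibril-ligand screen.

These emulate the *geometry and statistics the method assumes*, not real
data: no side chains, no sequence, no conformational strain in ligands,
no correlation structure between decoy properties and scores. A green
test establishes that the operators, filters, energies and metrics
compute what they claim on structures with exactly known ground truth —
not that the method reproduces any particular experimental pose, which
requires the external docking engine, grids, decoy sets and quantum
backend that are out of scope here.

## Known limitations

* A 2 Å centre-to-centre clash cutoff misses clashes of large-radius
  atoms (Br, I); the cutoff is exposed.
* Only single-screw symmetry is handled — no point-group or alternating
  (2:1) stack patterns.
* Only the nearest image is clash-checked and scored by default; ligands
  elongated along the axis should raise `images`.
* The LJ stacking term ignores electrostatics and π–π quadrupole effects;
  the external-backend contract exists precisely to rescore past that.
* PDB chain IDs limit one-character naming; very large extensions fall
  back to the generated two-character pool and are refused if exhausted.
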