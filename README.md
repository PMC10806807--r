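# symstack

Screw-symmetry stacking toolkit for ligand docking on helical protein
fibrils.

## The problem

Amyloid fibrils — tau filaments in Alzheimer's disease being the
motivating case — are helical polymers whose monomers are related by a
single screw operation: a rise *d* along the fibril axis plus a twist
*θ* about it (*d* ≈ 4.7 Å, *θ* ≈ −1° for AD tau). Ligands of these
fibrils, including the PET tracers used to image tangles, bind as
symmetric *stacks* that repeat with the fibril's own operator and
interact mostly with their own symmetry mates rather than with the
protein. Standard docking assumes 1:1 stoichiometry and knows nothing of
this; `symstack` supplies the symmetry machinery a fibril docking
workflow needs:

* **Operator derivation** — least-squares superposition of consecutive
  monomers, averaged along the protofilament, gives the affine operator
  `x ↦ Rx + t`; screw decomposition reports (axis, twist, rise).
* **Clash filter** — a pose is kept only if no atom of it comes within
  2 Å of any atom of its symmetry image, i.e. it can tile into a stack.
* **Stacking energy** — the ligand–ligand united-atom 12-6
  Lennard-Jones term `ε[(r_min/r)¹² − 2(r_min/r)⁶]` for the nearest
  image pair (every interface in the stack is identical by symmetry),
  added to externally computed ligand–protein scores.
* **Periodic extension** — grow a 5-monomer protofilament to 15 by
  applying the operator and its inverse blockwise, and export stack
  heavy atoms as dielectric-boundary pseudo-atoms for grid programs.
* **Stack refinement** — rigid-body Metropolis Monte Carlo on the
  monomer placement with symmetry re-imposed each step, under a
  pluggable per-monomer energy backend (built-in LJ, or any external
  command such as a neural-network potential).
* **Screen metrics** — enrichment factor at a fraction and adjusted
  logAUC (semilog early-recognition ROC area minus the random value
  14.462; perfect ranking scores 85.538).
* **Synthetic fixtures** — deterministic helical fibrils, planar
  ligands, and labelled screen lists, so everything is testable offline.

It is aimed at structure-based drug-design and methods people working on
fibril targets; it deliberately does **not** dock (pose generation,
protein grids, decoy generation and quantum rescoring belong to external
engines).

## Worked example

```r
library(symstack)

# a synthetic 5-monomer fibril with tau-like geometry, and its operator
fib <- make_helical_fibril(n_monomers = 5, rise = 4.7, twist = -1)
op  <- derive_operator(fib)
decompose_screw(op)
#> <screw_parameters> rise 4.7000 A, twist -1.0000 deg, axis [-0.000, -0.000, 1.000]

# a flat aromatic ring: can it stack with the fibril symmetry?
pose <- make_planar_ligand(id = "ring")
symmetry_clash_check(pose, op)
#> $passes
#> [1] TRUE
#> $min_distance
#> [1] 4.700063

# clash filter + ligand-ligand vdW stacking energy
tab <- read_vdw_table(system.file("extdata", "vdw_params.txt",
                                  package = "symstack"))
stack_score(pose, op, tab)
#> <stack_energy_report> ring: clash pass, min image distance 4.700 A,
#>   ligand-ligand vdW -1.462 kcal/mol

# rigid-body MC refinement of the stack (built-in LJ backend)
run_mc(pose, op, mc_config(n_steps = 200, seed = 42), table = tab)
#> <mc_result> start -1.4794 -> best -1.9757 kcal/mol (delta -0.4963),
#>   rmsd 6.689 A, acc 0.98 [builtin-LJ]

# periodic extension: 5 monomers -> 15
length(unique(extend_fibril(fib, op, 1, 1)$atoms$chain))
#> [1] 15

# enrichment metrics on a synthetic 16-active / 800-decoy screen
enrichment_report(make_screen_set(seed = 42))
#> <enrichment_report> adjusted logAUC 6.62, EF1% 6.25
#>   (16 actives, 800 decoys, 0 unscored)
```

The clash verdict says the ring tiles cleanly at the fibril repeat (its
nearest image sits 4.7 Å away, above the 2 Å cutoff); the negative vdW
energy is the favorable self-stacking added to the docking score; the MC
run slides the ring to a better-packed stack (energy down ~0.5 kcal/mol);
and the screen report shows modest early enrichment of the synthetic
actives (EF1% = 6.25: the top 1% holds ~6× the active density of the
whole list).

A command-line wrapper covers the same operations
(`exec/symstack <subcommand> --flags`, or `symstack(c(...))` from R):
`derive-operator`, `check`, `score`, `refine`, `extend`, `boundary`,
`enrich`, `fixtures`.

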