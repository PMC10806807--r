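# Deterministic synthetic-data generators: helical fibrils, planar ligands,
# labelled screen lists. These stand in for deposited cryo-EM structures and
# DUD-E-style screens so every module is testable offline; they emulate the
# geometry the method assumes (a screw-symmetric fibril, planar stackable
# ligands), not any particular protein fold or chemistry.

#' Generate a synthetic helical fibril
#'
#' Monomer 0 is an idealized beta-strand alpha-carbon trace (3.8 Angstrom
#' consecutive-CA spacing, pleated, offset from the fibril axis); monomer k
#' is exactly the k-th power of the screw operator built from `rise` and
#' `twist` about the z axis applied to the template, so
#' [derive_operator()] must recover `(rise, twist)` up to the requested
#' coordinate jitter. Defaults emulate the AD tau filament geometry:
#' 5 monomers per protofilament, 4.7 Angstrom rise, -1 degree twist.
#'
#' @param n_monomers monomers per protofilament (default 5).
#' @param rise screw rise in Angstrom (default 4.7).
#' @param twist screw twist in degrees (default -1).
#' @param residues_per_monomer CA count per monomer (default 8).
#' @param n_protofilaments 1 (default) or 2 (second protofilament rotated
#'   180 degrees about the axis, as in paired filaments).
#' @param backbone also place idealized N, C, O atoms around each CA.
#' @param jitter per-coordinate Gaussian noise s.d. in Angstrom (default 0,
#'   i.e. exact symmetry).
#' @param seed RNG seed for the jitter.
#' @return a `fibril_structure`.
#' @export
#' @examples
#' fib <- make_helical_fibril()
#' decompose_screw(derive_operator(fib))
make_helical_fibril <- function(n_monomers = 5L, rise = 4.7, twist = -1.0,
                                residues_per_monomer = 8L,
                                n_protofilaments = 1L, backbone = FALSE,
                                jitter = 0, seed = 1L) {
  stopifnot(n_monomers >= 1L, residues_per_monomer >= 3L,
            n_protofilaments %in% c(1L, 2L), jitter >= 0)
  i <- seq_len(residues_per_monomer) - 1L
  # C-shaped CA arc spanning 270 deg in the cross-section plane, offset
  # from the z axis: fibril monomers are flat and spread in 2D
  # perpendicular to the axis (the C-shaped fold of tau protofilaments).
  # Consecutive-CA spacing is 3.8 A (in-plane chord plus the +-0.3 A
  # pleat); the arc radius grows with the residue count.
  chord <- sqrt(3.8^2 - 0.6^2)
  dth <- (3 * pi / 2) / max(residues_per_monomer - 1L, 1L)
  arc_r <- chord / (2 * sin(dth / 2))
  th <- (i - (residues_per_monomer - 1L) / 2) * dth
  ca <- cbind(x = (arc_r + 2) + arc_r * cos(th),
              y = arc_r * sin(th),
              z = 0.3 * (-1)^i)
  template <- data.frame(resno = i + 1L, atom = "CA", element = "C",
                         x = ca[, 1], y = ca[, 2], z = ca[, 3])
  if (backbone) {
    extra <- do.call(rbind, lapply(seq_len(residues_per_monomer), function(r) {
      p <- ca[r, ]
      data.frame(resno = r,
                 atom = c("N", "C", "O"),
                 element = c("N", "C", "O"),
                 x = p[1] + c(-1.2, 1.2, 1.6),
                 y = p[2] + c(0.5, 0.5, 1.5),
                 z = p[3] + c(-0.4, 0.4, 0.4))
    }))
    template <- rbind(template, extra)
    template <- template[order(template$resno,
                               match(template$atom, c("N", "CA", "C", "O"))), ]
  }
  template$resname <- rep_len(c("ALA", "VAL", "GLY", "SER"),
                              residues_per_monomer)[template$resno]
  op <- screw_operator(c(0, 0, 1), twist_deg = twist, rise = rise)
  flip <- rotation_about_axis(c(0, 0, 1), pi) # C2 for the second protofilament
  pool <- chain_id_pool()
  atoms <- list()
  pfs <- list()
  idx <- 0L
  for (pf in seq_len(n_protofilaments)) {
    ids <- pool[idx + seq_len(n_monomers)]
    idx <- idx + n_monomers
    base <- as.matrix(template[c("x", "y", "z")])
    if (pf == 2L) base <- base %*% t(flip)
    for (m in seq_len(n_monomers)) {
      xyz <- apply_operator(operator_power(op, m - 1L), base)
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = ids[m], resno = template$resno, resname = template$resname,
        atom = template$atom, element = template$element,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
    pfs[[paste0("P", pf)]] <- ids
  }
  atoms <- do.call(rbind, atoms)
  if (jitter > 0) {
    withr_seed <- function(expr) { # local seed, restore caller RNG
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      expr
    }
    noise <- withr_seed(matrix(stats::rnorm(3L * nrow(atoms), 0, jitter),
                               ncol = 3L))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  fibril_structure(atoms, pfs)
}

hexagon_coords <- function(ring_size, bond = 1.39) {
  # regular polygon with the requested edge length, in the xy plane
  r <- bond / (2 * sin(pi / ring_size))
  th <- 2 * pi * (seq_len(ring_size) - 1L) / ring_size
  cbind(x = r * cos(th), y = r * sin(th), z = 0)
}

#' Generate a synthetic planar ligand
#'
#' Flat carbon ring systems with aromatic 1.39 Angstrom bond lengths, laid
#' side by side in the xy plane — the geometry of the planar aromatic
#' stackers that bind fibrils in symmetric stacks. The non-planar variant
#' pushes one atom out of plane (an sp3 corner), producing the kind of 3D
#' molecule the clash filter rejects.
#'
#' @param ring_sizes integer vector, one ring per entry (default 6).
#' @param planar if FALSE, displace one atom 0.8 Angstrom out of plane.
#' @param center place the centroid here (length-3, default origin).
#' @param id molecule id.
#' @return a `ligand_pose` (all carbon).
#' @export
make_planar_ligand <- function(ring_sizes = 6L, planar = TRUE,
                               center = c(0, 0, 0), id = "ligand") {
  stopifnot(all(ring_sizes >= 3L))
  offset <- 0
  coords <- list()
  for (rs in ring_sizes) {
    ring <- hexagon_coords(rs)
    ring[, 1] <- ring[, 1] + offset
    coords[[length(coords) + 1L]] <- ring
    offset <- offset + max(ring[, 1]) - min(ring[, 1]) + 1.45
  }
  xyz <- do.call(rbind, coords)
  if (!planar) xyz[1, 3] <- xyz[1, 3] + 1.5 # sp3 bridge-like corner
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  xyz <- sweep(xyz, 2L, as.numeric(center), "+")
  ligand_pose(id, data.frame(element = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Generate a synthetic labelled screen list
#'
#' Active and decoy scores are drawn from two Gaussians; the default class
#' sizes (16 actives, 800 decoys) mirror a retrospective fibril-ligand
#' enrichment screen, and the default 2 kcal/mol mean separation gives the
#' modest-but-real early enrichment typical of such screens.
#'
#' @param n_actives,n_decoys class sizes (defaults 16 and 800).
#' @param mu_active,sd_active active score distribution (kcal/mol; defaults
#'   -32, 2).
#' @param mu_decoy,sd_decoy decoy score distribution (defaults -30, 2).
#' @param seed RNG seed.
#' @return a `screen_records` data.frame with `n_actives + n_decoys` rows.
#' @export
make_screen_set <- function(n_actives = 16L, n_decoys = 800L,
                            mu_active = -32, sd_active = 2,
                            mu_decoy = -30, sd_decoy = 2, seed = 1L) {
  stopifnot(n_actives >= 1L, n_decoys >= 1L, sd_active >= 0, sd_decoy >= 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  screen_records(
    id = c(sprintf("active-%03d", seq_len(n_actives)),
           sprintf("decoy-%04d", seq_len(n_decoys))),
    score = c(stats::rnorm(n_actives, mu_active, sd_active),
              stats::rnorm(n_decoys, mu_decoy, sd_decoy)),
    label = c(rep("active", n_actives), rep("decoy", n_decoys)))
}
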