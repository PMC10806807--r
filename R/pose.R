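# Ligand poses: typed atom sets with coordinates in the fibril frame.

is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

#' Construct a ligand pose
#'
#' A pose is an ordered set of atoms with Cartesian coordinates in the
#' fibril frame, as produced by a docking engine. Conformation and
#' orientation are fixed; this toolkit only transforms poses rigidly.
#'
#' @param id molecule/pose identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `name` (atom name), `charge` (partial charge, e) and
#'   `vdw_type` (force-field atom type label).
#' @param bonds optional data.frame with columns `i`, `j` (1-based atom
#'   indices) and `order`.
#' @return An object of class `ligand_pose`.
#' @export
ligand_pose <- function(id, atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"name" %in% names(atoms)) {
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"vdw_type" %in% names(atoms)) atoms$vdw_type <- NA_character_
  atoms <- atoms[c("name", "element", "x", "y", "z", "charge", "vdw_type")]
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (nrow(atoms) == 0L || !all(is.finite(xyz))) {
    stop("pose must have at least one atom with finite coordinates",
         call. = FALSE)
  }
  if (!any(!is_hydrogen(atoms$element))) {
    stop("pose must contain at least one heavy atom", call. = FALSE)
  }
  if (anyDuplicated(xyz) > 0L) {
    stop("pose has two atoms with identical coordinates", call. = FALSE)
  }
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (!"order" %in% names(bonds)) bonds$order <- 1L
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s: %d atoms (%d heavy)\n", x$id,
              nrow(x$atoms), sum(!is_hydrogen(x$atoms$element))))
  invisible(x)
}

#' Coordinates of a pose
#' @param pose a `ligand_pose`.
#' @param heavy_only drop hydrogens.
#' @return n x 3 numeric matrix.
#' @export
pose_coords <- function(pose, heavy_only = FALSE) {
  at <- pose$atoms
  if (heavy_only) at <- at[!is_hydrogen(at$element), , drop = FALSE]
  as.matrix(at[c("x", "y", "z")])
}

set_pose_coords <- function(pose, xyz) {
  pose$atoms$x <- xyz[, 1]
  pose$atoms$y <- xyz[, 2]
  pose$atoms$z <- xyz[, 3]
  pose
}

#' Apply an operator to a ligand pose
#' @param op an `affine_operator`.
#' @param x a `ligand_pose`.
#' @param ... unused.
#' @export
apply_operator.ligand_pose <- function(op, x, ...) {
  set_pose_coords(x, apply_operator(op, pose_coords(x)))
}

#' Heavy-atom RMSD between two poses of the same molecule
#'
#' Computed in the fixed fibril frame with no superposition, as used for
#' comparing docked poses to experimental ones. Atoms are matched by order
#' (after dropping hydrogens when `heavy_only`) unless an explicit `mapping`
#' is given.
#'
#' @param pose_a,pose_b `ligand_pose` objects with the same atom count and
#'   ordering.
#' @param heavy_only use heavy atoms only (default TRUE).
#' @param mapping optional 2-column integer matrix of (index in a, index in
#'   b) atom pairs, applied before hydrogen filtering.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose_a, pose_b, heavy_only = TRUE, mapping = NULL) {
  a <- pose_a$atoms
  b <- pose_b$atoms
  if (!is.null(mapping)) {
    mapping <- as.matrix(mapping)
    a <- a[mapping[, 1], , drop = FALSE]
    b <- b[mapping[, 2], , drop = FALSE]
  }
  if (heavy_only) {
    ka <- !is_hydrogen(a$element)
    kb <- !is_hydrogen(b$element)
    if (is.null(mapping)) {
      a <- a[ka, , drop = FALSE]
      b <- b[kb, , drop = FALSE]
    } else if (!all(ka == kb)) {
      stop("mapped atoms mix hydrogens and heavy atoms", call. = FALSE)
    } else {
      a <- a[ka, , drop = FALSE]
      b <- b[ka, , drop = FALSE]
    }
  }
  if (nrow(a) != nrow(b)) {
    stop(sprintf(
      "cannot map atoms: %d vs %d atoms after filtering (elements a: %s; b: %s)",
      nrow(a), nrow(b), paste(a$element, collapse = ""),
      paste(b$element, collapse = "")), call. = FALSE)
  }
  if (!all(toupper(a$element) == toupper(b$element))) {
    bad <- which(toupper(a$element) != toupper(b$element))
    stop("element mismatch at mapped positions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(a[c("x", "y", "z")]) - as.matrix(b[c("x", "y", "z")])
  sqrt(mean(rowSums(d^2)))
}
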