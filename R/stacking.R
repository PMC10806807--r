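# Symmetry images of a pose: clash filter, stack building, stack geometry.

min_image_distance <- function(A, B) {
  # minimum Euclidean distance between two coordinate sets (n x 3, m x 3)
  d2 <- outer(A[, 1], B[, 1], "-")^2 +
    outer(A[, 2], B[, 2], "-")^2 +
    outer(A[, 3], B[, 3], "-")^2
  sqrt(min(d2))
}

select_clash_atoms <- function(pose, atom_selection) {
  xyz <- pose_coords(pose, heavy_only = (atom_selection == "heavy"))
  if (nrow(xyz) == 0L) {
    stop("no atoms left after '", atom_selection, "' selection",
         call. = FALSE)
  }
  xyz
}

#' Self-stacking clash filter
#'
#' Applies the fibril operator to the pose and checks whether any atom of
#' the original pose comes within `cutoff` of any atom of the image: such a
#' pose cannot form a symmetric stack and is discarded. The default 2
#' Angstrom centre-to-centre cutoff is the calibrated constant of the
#' method; `images > 1` extends the check to the k nearest images on each
#' side, which matters for ligands elongated along the fibril axis.
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param cutoff clash distance in Angstrom (default 2.0).
#' @param atom_selection `"all"` (default; the rule is "any atom") or
#'   `"heavy"` for hydrogen-free docking outputs.
#' @param images check images 1..k on each side (default 1; by screw
#'   symmetry the +k and -k images give identical distances, so only one
#'   side is computed).
#' @return list with `passes` (logical: min distance >= cutoff) and
#'   `min_distance` (Angstrom, over all checked images).
#' @export
#' @examples
#' ring <- make_planar_ligand()
#' symmetry_clash_check(ring, screw_operator(c(0, 0, 1), -1, 4.7))
symmetry_clash_check <- function(pose, op, cutoff = 2.0,
                                 atom_selection = c("all", "heavy"),
                                 images = 1L) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(op, "affine_operator"),
            cutoff > 0, images >= 1L)
  atom_selection <- match.arg(atom_selection)
  A <- select_clash_atoms(pose, atom_selection)
  mind <- Inf
  img <- A
  for (k in seq_len(images)) {
    img <- apply_operator(op, img)
    mind <- min(mind, min_image_distance(A, img))
  }
  list(passes = mind >= cutoff, min_distance = mind)
}

#' Build a symmetric stack of poses
#'
#' Element k of the stack is `operator_power(op, k)` applied to the pose for
#' k from `-n_down` to `+n_up`; the k = 0 element is the input pose itself,
#' unchanged. `n_up = n_down = 1` is the "two nearest symmetry mates"
#' trimer used for per-monomer stack energies.
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param n_up,n_down non-negative image counts.
#' @return list of `ligand_pose` objects in ascending k order; each carries
#'   its power as attribute `k`.
#' @export
build_stack <- function(pose, op, n_up = 1L, n_down = 1L) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(op, "affine_operator"),
            n_up >= 0L, n_down >= 0L)
  ks <- seq.int(-as.integer(n_down), as.integer(n_up))
  out <- lapply(ks, function(k) {
    p <- if (k == 0L) pose else apply_operator(operator_power(op, k), pose)
    attr(p, "k") <- k
    p
  })
  names(out) <- paste0("k", ks)
  out
}

fit_plane <- function(xyz) {
  # least-squares plane through points; returns unit normal + centroid
  stopifnot(nrow(xyz) >= 3L)
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2L, ctr))
  if (s$d[2] < 1e-8 * max(s$d[1], 1)) {
    stop("ring atoms are collinear or degenerate; cannot fit a plane",
         call. = FALSE)
  }
  list(normal = s$v[, 3], centroid = ctr)
}

#' Interplanar distance between a pose and its symmetry image
#'
#' Distance from the least-squares plane of the selected ring atoms in the
#' original pose to the centroid of the same atoms in the op-image. Stacked
#' aromatic systems in fibril complexes sit around 3.3-3.5 Angstrom apart,
#' the hallmark of quadrupole stacking.
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param ring_atoms integer indices of at least 3 non-collinear atoms.
#' @return unsigned distance in Angstrom.
#' @export
interplanar_distance <- function(pose, op, ring_atoms = NULL) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(op, "affine_operator"))
  if (is.null(ring_atoms)) ring_atoms <- seq_len(nrow(pose$atoms))
  xyz <- pose_coords(pose)[ring_atoms, , drop = FALSE]
  pl <- fit_plane(xyz)
  img_ctr <- colMeans(apply_operator(op, xyz))
  abs(sum(pl$normal * (img_ctr - pl$centroid)))
}
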