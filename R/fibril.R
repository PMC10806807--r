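# Fibril structures: containers, operator derivation, periodic extension.

#' Construct a fibril structure
#'
#' A fibril is a set of protein chains (monomers) grouped into
#' protofilaments, each protofilament being an ordered stack of monomers
#' related by the fibril's screw operator. Consecutive monomers within one
#' protofilament must share an identical residue sequence so that an atom
#' correspondence can be built.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer), `resname`,
#'   `atom` (atom name, e.g. "CA"), `element`, `x`, `y`, `z` (Angstrom).
#' @param protofilaments named list; each element is a character vector of
#'   chain IDs in stacking order. Defaults to a single protofilament holding
#'   all chains in order of first appearance.
#' @return An object of class `fibril_structure`.
#' @export
fibril_structure <- function(atoms, protofilaments = NULL) {
  required <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) == 0L) stop("fibril has no atoms", call. = FALSE)
  if (anyNA(atoms[c("x", "y", "z")]) ||
      !all(is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("fibril coordinates must be finite", call. = FALSE)
  }
  chains <- unique(atoms$chain)
  if (is.null(protofilaments)) {
    protofilaments <- list(P1 = chains)
  }
  bad <- setdiff(unlist(protofilaments), chains)
  if (length(bad)) {
    stop("protofilament assignment names unknown chains: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(protofilaments))) {
    names(protofilaments) <- paste0("P", seq_along(protofilaments))
  }
  structure(list(atoms = atoms, protofilaments = protofilaments),
            class = "fibril_structure")
}

#' @export
print.fibril_structure <- function(x, ...) {
  cat(sprintf("<fibril_structure> %d atoms, %d chains, %d protofilament(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              length(x$protofilaments)))
  for (nm in names(x$protofilaments)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$protofilaments[[nm]],
                                        collapse = " ")))
  }
  invisible(x)
}

monomer_atoms <- function(fibril, chain) {
  df <- fibril$atoms[fibril$atoms$chain == chain, , drop = FALSE]
  df[order(df$resno), , drop = FALSE]
}

residue_signature <- function(df) {
  res <- df[!duplicated(df$resno), c("resno", "resname")]
  res <- res[order(res$resno), ]
  paste(res$resname, collapse = "-")
}

# Matched coordinate matrices for a pair of monomers, using shared atom
# names restricted to `atom_set` ("CA" or the full backbone).
superposition_coords <- function(a, b, atom_set) {
  key_a <- paste(a$resno - min(a$resno), a$atom)
  key_b <- paste(b$resno - min(b$resno), b$atom)
  keep_a <- a$atom %in% atom_set
  keep_b <- b$atom %in% atom_set
  shared <- intersect(key_a[keep_a], key_b[keep_b])
  if (length(shared) < 3L) {
    stop("fewer than 3 shared superposition atoms between monomers",
         call. = FALSE)
  }
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  list(X = as.matrix(a[ia, c("x", "y", "z")]),
       Y = as.matrix(b[ib, c("x", "y", "z")]))
}

#' Derive the fibril screw operator from a protofilament
#'
#' Builds an atom correspondence between consecutive monomers of one
#' protofilament (alpha-carbons by default, optionally all backbone atoms),
#' computes the proper-rotation least-squares superposition for each
#' consecutive pair, and averages: rotations by the chordal mean (projection
#' of the elementwise mean to the nearest proper rotation), translations
#' arithmetically after re-solving each pair against the mean rotation.
#' Averaging over pairs suppresses per-monomer coordinate noise.
#'
#' @param fibril a `fibril_structure`.
#' @param protofilament protofilament label; default the first one.
#' @param atoms `"calpha"` (default) to superpose on CA atoms only, or
#'   `"backbone"` for N, CA, C, O.
#' @return The `affine_operator` mapping monomer i onto monomer i+1.
#' @export
#' @examples
#' fib <- make_helical_fibril(n_monomers = 4, rise = 4.7, twist = -1)
#' decompose_screw(derive_operator(fib))
derive_operator <- function(fibril, protofilament = NULL,
                            atoms = c("calpha", "backbone")) {
  stopifnot(inherits(fibril, "fibril_structure"))
  atoms <- match.arg(atoms)
  atom_set <- if (atoms == "calpha") "CA" else c("N", "CA", "C", "O")
  if (is.null(protofilament)) protofilament <- names(fibril$protofilaments)[1]
  chains <- fibril$protofilaments[[protofilament]]
  if (is.null(chains)) {
    stop("unknown protofilament: ", protofilament, call. = FALSE)
  }
  if (length(chains) < 2L) {
    stop("protofilament ", protofilament,
         " has fewer than 2 monomers; cannot derive an operator",
         call. = FALSE)
  }
  monomers <- lapply(chains, monomer_atoms, fibril = fibril)
  sigs <- vapply(monomers, residue_signature, "")
  for (i in seq_len(length(chains) - 1L)) {
    if (sigs[i] != sigs[i + 1L]) {
      stop(sprintf(
        "residue sequences differ between consecutive chains %s and %s",
        chains[i], chains[i + 1L]), call. = FALSE)
    }
  }
  pairs <- lapply(seq_len(length(chains) - 1L), function(i) {
    superposition_coords(monomers[[i]], monomers[[i + 1L]], atom_set)
  })
  fits <- lapply(pairs, function(p) kabsch_fit(p$X, p$Y))
  R_mean <- project_rotation(Reduce(`+`, lapply(fits, `[[`, "rotation")) /
                               length(fits))
  ts <- vapply(pairs, function(p) {
    colMeans(p$Y) - as.numeric(R_mean %*% colMeans(p$X))
  }, numeric(3))
  affine_operator(R_mean, rowMeans(matrix(ts, nrow = 3)))
}

# Mean superposition residual (RMSD, Angstrom) of op applied to monomer i
# versus monomer i+1, over all consecutive pairs of one protofilament.
operator_residual <- function(fibril, op, protofilament = NULL,
                              atoms = "calpha") {
  atom_set <- if (atoms == "calpha") "CA" else c("N", "CA", "C", "O")
  if (is.null(protofilament)) protofilament <- names(fibril$protofilaments)[1]
  chains <- fibril$protofilaments[[protofilament]]
  monomers <- lapply(chains, monomer_atoms, fibril = fibril)
  res <- vapply(seq_len(length(chains) - 1L), function(i) {
    p <- superposition_coords(monomers[[i]], monomers[[i + 1L]], atom_set)
    d <- apply_operator(op, p$X) - p$Y
    sqrt(mean(rowSums(d^2)))
  }, 0)
  mean(res)
}

#' Apply an operator to a whole fibril structure
#' @param op an `affine_operator`.
#' @param x a `fibril_structure`.
#' @param ... unused.
#' @export
apply_operator.fibril_structure <- function(op, x, ...) {
  xyz <- apply_operator(op, as.matrix(x$atoms[c("x", "y", "z")]))
  x$atoms$x <- xyz[, 1]
  x$atoms$y <- xyz[, 2]
  x$atoms$z <- xyz[, 3]
  x
}

chain_id_pool <- function() {
  one <- c(LETTERS, letters, as.character(0:9))
  c(one, as.vector(outer(one, one, paste0)))
}

#' Extend a fibril periodically by its screw operator
#'
#' Cryo-EM fibril depositions typically hold a handful of monomers per
#' protofilament (five for AD PHF tau), while the physical fibril is
#' hundreds of nanometres long; score grids built from the short structure
#' show edge effects. This copies each protofilament blockwise by powers of
#' the operator: a protofilament of n monomers gains `copies_up` whole-stack
#' copies above (powers +n, +2n, ...) and `copies_down` below, so the
#' deposited coordinates are preserved verbatim in the centre (5 monomers
#' with one copy each way gives 15).
#'
#' @param fibril a `fibril_structure`.
#' @param op the fibril `affine_operator` (monomer i to i+1).
#' @param copies_up,copies_down non-negative whole-stack copy counts.
#' @param residual_warn warn if the operator's superposition residual against
#'   the input exceeds this RMSD (Angstrom, default 1.0).
#' @return A `fibril_structure` (classed additionally `extended_fibril`) with
#'   fresh chain IDs; attribute `provenance` is a data.frame mapping each
#'   chain to its source chain and operator power.
#' @export
extend_fibril <- function(fibril, op, copies_up = 1L, copies_down = 1L,
                          residual_warn = 1.0) {
  stopifnot(inherits(fibril, "fibril_structure"),
            inherits(op, "affine_operator"))
  copies_up <- as.integer(copies_up)
  copies_down <- as.integer(copies_down)
  stopifnot(copies_up >= 0L, copies_down >= 0L)
  for (pf in names(fibril$protofilaments)) {
    if (length(fibril$protofilaments[[pf]]) >= 2L) {
      res <- operator_residual(fibril, op, pf)
      if (res > residual_warn) {
        warning(sprintf(
          "operator residual %.3f A on protofilament %s exceeds %.2f A",
          res, pf, residual_warn), call. = FALSE)
      }
    }
  }
  existing <- unique(fibril$atoms$chain)
  pool <- setdiff(chain_id_pool(), existing)
  prov <- data.frame(chain = existing, source_chain = existing,
                     power = 0L, stringsAsFactors = FALSE)
  blocks <- list(fibril$atoms)
  new_pf <- fibril$protofilaments
  next_id <- 1L
  take_ids <- function(k) {
    if (next_id + k - 1L > length(pool)) {
      stop("chain-ID namespace exhausted; too many copies requested",
           call. = FALSE)
    }
    ids <- pool[next_id:(next_id + k - 1L)]
    next_id <<- next_id + k
    ids
  }
  for (pf in names(fibril$protofilaments)) {
    chains <- fibril$protofilaments[[pf]]
    n <- length(chains)
    block <- fibril$atoms[fibril$atoms$chain %in% chains, , drop = FALSE]
    powers <- integer(0)
    if (copies_down > 0L) powers <- c(powers, -(copies_down:1) * n)
    if (copies_up > 0L) powers <- c(powers, (1:copies_up) * n)
    for (p in powers) {
      shifted <- block
      xyz <- apply_operator(operator_power(op, p),
                            as.matrix(block[c("x", "y", "z")]))
      shifted$x <- xyz[, 1]
      shifted$y <- xyz[, 2]
      shifted$z <- xyz[, 3]
      ids <- take_ids(n)
      shifted$chain <- ids[match(shifted$chain, chains)]
      blocks[[length(blocks) + 1L]] <- shifted
      prov <- rbind(prov, data.frame(chain = ids, source_chain = chains,
                                     power = p, stringsAsFactors = FALSE))
      if (p < 0L) {
        new_pf[[pf]] <- c(ids, new_pf[[pf]])
      } else {
        new_pf[[pf]] <- c(new_pf[[pf]], ids)
      }
    }
    # order negative blocks outermost-first was appended innermost-first:
    # fix stacking order to ascending power
    pf_prov <- prov[prov$chain %in% new_pf[[pf]] |
                      prov$chain %in% chains, , drop = FALSE]
    pf_prov <- pf_prov[pf_prov$chain %in% new_pf[[pf]], , drop = FALSE]
    ord <- order(pf_prov$power, match(pf_prov$source_chain, chains))
    new_pf[[pf]] <- pf_prov$chain[ord]
  }
  out <- fibril_structure(do.call(rbind, blocks), new_pf)
  attr(out, "provenance") <- prov
  class(out) <- c("extended_fibril", class(out))
  out
}

#' Export stack heavy atoms as dielectric-boundary pseudo-atoms
#'
#' A bound ligand stack displaces solvent; extending the low-dielectric
#' boundary of electrostatics/desolvation grids to the heavy-atom positions
#' of the stack mimics that effect. This returns the heavy atoms of the
#' built stack, each with a radius, ready to be written as `xyzr` or PDB
#' HETATM input for external grid programs (the grids themselves are out of
#' scope here).
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param n_up,n_down image counts above/below the input pose.
#' @param radius pseudo-atom radius in Angstrom (default 1.9).
#' @return data.frame with columns `x`, `y`, `z`, `radius`, `element`,
#'   `image` (the operator power the atom came from).
#' @export
boundary_pseudoatoms <- function(pose, op, n_up = 1L, n_down = 1L,
                                 radius = 1.9) {
  stack <- build_stack(pose, op, n_up = n_up, n_down = n_down)
  out <- lapply(stack, function(p) {
    at <- p$atoms[!is_hydrogen(p$atoms$element), , drop = FALSE]
    data.frame(x = at$x, y = at$y, z = at$z, radius = radius,
               element = at$element, image = attr(p, "k"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
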