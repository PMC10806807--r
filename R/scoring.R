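# United-atom Lennard-Jones stacking energy and pose ranking.

#' Construct a van der Waals parameter table
#'
#' Holds per-type well depths and minimum-distance radii for the 12-6
#' Lennard-Jones term, an element-to-default-type fallback map, and
#' Lorentz-Berthelot combination rules (arithmetic rmin, geometric
#' epsilon). The shipped table (`inst/extdata/vdw_params.txt`) carries
#' generic united-atom literature values; the table is plain text and meant
#' to be edited or replaced.
#'
#' @param types data.frame with columns `type`, `epsilon` (kcal/mol, >= 0)
#'   and `rmin_half` (Angstrom, > 0).
#' @param defaults named character vector mapping element symbols to type
#'   labels.
#' @return An object of class `vdw_table`.
#' @export
vdw_table <- function(types, defaults = NULL) {
  types <- as.data.frame(types)
  stopifnot(all(c("type", "epsilon", "rmin_half") %in% names(types)))
  types$type <- as.character(types$type)
  if (anyDuplicated(types$type)) {
    stop("duplicate vdW type labels in table", call. = FALSE)
  }
  if (any(types$epsilon < 0) || any(types$rmin_half <= 0)) {
    stop("vdW table requires epsilon >= 0 and rmin_half > 0", call. = FALSE)
  }
  if (is.null(defaults)) defaults <- character(0)
  bad <- setdiff(unname(defaults), types$type)
  if (length(bad)) {
    stop("default map points at unknown types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(defaults) <- toupper(names(defaults))
  structure(list(types = types, defaults = defaults,
                 rule = "lorentz-berthelot"),
            class = "vdw_table")
}

#' @export
print.vdw_table <- function(x, ...) {
  cat(sprintf("<vdw_table> %d types, %d element defaults (%s rules)\n",
              nrow(x$types), length(x$defaults), x$rule))
  invisible(x)
}

#' Read a vdW parameter table from plain text
#'
#' Whitespace-delimited columns `type epsilon rmin_half`; `#` starts a
#' comment; lines `default <element> <type>` populate the element fallback
#' map.
#'
#' @param path file path.
#' @return A `vdw_table`.
#' @export
read_vdw_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  is_def <- vapply(toks, function(t) tolower(t[1]) == "default", TRUE)
  defaults <- character(0)
  if (any(is_def)) {
    dd <- toks[is_def]
    if (any(lengths(dd) != 3L)) {
      stop("malformed 'default' line in ", path, call. = FALSE)
    }
    defaults <- vapply(dd, `[`, "", 3L)
    names(defaults) <- vapply(dd, `[`, "", 2L)
  }
  tt <- toks[!is_def]
  if (any(lengths(tt) != 3L)) {
    stop("malformed parameter line in ", path, call. = FALSE)
  }
  types <- data.frame(
    type = vapply(tt, `[`, "", 1L),
    epsilon = as.numeric(vapply(tt, `[`, "", 2L)),
    rmin_half = as.numeric(vapply(tt, `[`, "", 3L)),
    stringsAsFactors = FALSE)
  if (anyNA(types$epsilon) || anyNA(types$rmin_half)) {
    stop("non-numeric epsilon/rmin_half in ", path, call. = FALSE)
  }
  vdw_table(types, defaults)
}

#' Assign vdW types to a pose's atoms
#'
#' Explicit per-atom type labels already on the pose (e.g. read from MOL2)
#' are kept verbatim; untyped atoms fall back to the table's element
#' default. Every resulting type must be resolvable in the table.
#'
#' @param pose a `ligand_pose`.
#' @param table a `vdw_table`.
#' @return The pose with a fully populated `vdw_type` column.
#' @export
assign_vdw_types <- function(pose, table) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(table, "vdw_table"))
  ty <- pose$atoms$vdw_type
  untyped <- is.na(ty) | !nzchar(ty)
  if (any(untyped)) {
    el <- toupper(pose$atoms$element[untyped])
    mapped <- table$defaults[el]
    if (anyNA(mapped)) {
      bad <- unique(el[is.na(mapped)])
      stop("no default vdW type for element(s): ",
           paste(bad, collapse = ", "), " (atoms ",
           paste(pose$atoms$name[untyped][is.na(mapped)], collapse = ", "),
           ")", call. = FALSE)
    }
    ty[untyped] <- unname(mapped)
  }
  unknown <- setdiff(unique(ty), table$types$type)
  if (length(unknown)) {
    stop("vdW type(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pose$atoms$vdw_type <- ty
  pose
}

lookup_params <- function(types, table) {
  i <- match(types, table$types$type)
  if (anyNA(i)) {
    stop("vdW type(s) not in table: ",
         paste(unique(types[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  list(eps = table$types$epsilon[i], rh = table$types$rmin_half[i])
}

#' Inter-pose 12-6 Lennard-Jones energy
#'
#' Sum over all atom pairs (one atom from each pose) of
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with Lorentz-Berthelot
#' combination (`rmin_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i eps_j)`). This is the ligand-ligand self-stacking
#' term added to the docking score for poses that pass the clash filter.
#' No distance cutoff or softening is applied.
#'
#' @param pose_a,pose_b typed `ligand_pose` objects (see
#'   [assign_vdw_types()]).
#' @param table a `vdw_table`.
#' @return energy in kcal/mol (symmetric in its arguments).
#' @export
pair_vdw_energy <- function(pose_a, pose_b, table) {
  pa <- lookup_params(pose_a$atoms$vdw_type, table)
  pb <- lookup_params(pose_b$atoms$vdw_type, table)
  A <- pose_coords(pose_a)
  B <- pose_coords(pose_b)
  r2 <- outer(A[, 1], B[, 1], "-")^2 +
    outer(A[, 2], B[, 2], "-")^2 +
    outer(A[, 3], B[, 3], "-")^2
  if (any(r2 < 1e-24)) {
    stop("singular geometry: coincident atoms between the two poses",
         call. = FALSE)
  }
  eps <- outer(pa$eps, pb$eps, function(x, y) sqrt(x * y))
  rmin <- outer(pa$rh, pb$rh, "+")
  s6 <- (rmin^2 / r2)^3
  sum(eps * (s6^2 - 2 * s6))
}

#' Clash-filter + stacking-energy report for one pose
#'
#' Runs the symmetry clash check; poses that fail are reported but not
#' scored (the method discards them rather than penalizing them). Passing
#' poses get the ligand-ligand vdW energy of the nearest image pair (only
#' the first pair is evaluated: by symmetry every interface in the stack is
#' identical), summed up to the `images`-th image if requested, plus an
#' optional total combining externally computed ligand-protein terms.
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param table a `vdw_table`.
#' @param cutoff,atom_selection,images clash-filter settings, see
#'   [symmetry_clash_check()]; `images` also controls how many image pairs
#'   are summed into the energy.
#' @param protein_terms optional numeric vector of ligand-protein score
#'   components (kcal/mol) from an external docking engine.
#' @return list of class `stack_energy_report` with fields `id`,
#'   `passes_clash`, `min_image_distance`, `ligand_ligand_vdw` (NA when the
#'   clash filter fails), `total_score`, `backend`.
#' @export
stack_score <- function(pose, op, table, cutoff = 2.0,
                        atom_selection = "all", images = 1L,
                        protein_terms = NULL) {
  pose <- assign_vdw_types(pose, table)
  chk <- symmetry_clash_check(pose, op, cutoff = cutoff,
                              atom_selection = atom_selection,
                              images = images)
  rep <- list(id = pose$id, passes_clash = chk$passes,
              min_image_distance = chk$min_distance,
              ligand_ligand_vdw = NA_real_, total_score = NA_real_,
              has_protein_terms = !is.null(protein_terms),
              backend = "builtin-LJ")
  if (chk$passes) {
    e <- 0
    img <- pose
    for (k in seq_len(images)) {
      img <- apply_operator(op, img)
      e <- e + pair_vdw_energy(pose, img, table)
    }
    rep$ligand_ligand_vdw <- e
    rep$total_score <- e + sum(protein_terms %||% 0)
  }
  class(rep) <- "stack_energy_report"
  rep
}

#' @export
print.stack_energy_report <- function(x, ...) {
  cat(sprintf("<stack_energy_report> %s: clash %s, min image distance %.3f A",
              x$id, if (x$passes_clash) "pass" else "FAIL",
              x$min_image_distance))
  if (x$passes_clash) {
    cat(sprintf(", ligand-ligand vdW %.3f kcal/mol", x$ligand_ligand_vdw))
  }
  cat("\n")
  invisible(x)
}

#' Rank scored poses
#'
#' Ascending by total score (more negative is better); clash-failed poses
#' are excluded entirely; ties break stably by pose id. All reports must
#' have been scored with the same term set (either all or none carry
#' protein terms).
#'
#' @param reports list of `stack_energy_report` objects.
#' @return the passing reports, ordered best-first.
#' @export
rank_poses <- function(reports) {
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, TRUE, "stack_energy_report")))
  has_pt <- vapply(reports, `[[`, TRUE, "has_protein_terms")
  if (length(unique(has_pt)) > 1L) {
    stop("reports mix scored term sets (some with protein terms, some without)",
         call. = FALSE)
  }
  keep <- reports[vapply(reports, `[[`, TRUE, "passes_clash")]
  if (length(keep) == 0L) return(keep)
  sc <- vapply(keep, `[[`, 0, "total_score")
  ids <- vapply(keep, `[[`, "", "id")
  keep[order(sc, ids, method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
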