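# File formats: PDB structures and stacks, SDF/MOL2 poses, operator JSON,
# xyzr pseudo-atoms, verdict/screen CSV. Minimal, deterministic writers
# (no timestamps in data files) and tolerant fixed-width readers.

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE", "SI")
  ifelse(two %in% known2, paste0(substr(two, 1, 1),
                                 tolower(substr(two, 2, 2))),
         toupper(substr(nm, 1, 1)))
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                          x, y, z, element) {
  nm <- ifelse(nchar(name) < 4L, paste0(" ", name), name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resname, chain, resno, x, y, z, 1.0, 0.0,
          toupper(element))
}

#' Write a fibril structure as PDB
#'
#' @param fibril a `fibril_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(fibril, path) {
  stopifnot(inherits(fibril, "fibril_structure"))
  at <- fibril$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    # PDB chain field is one character; map longer generated IDs via segid-
    # style truncation is lossy, so refuse and point at the generator
    ch1 <- if (nchar(ch) == 1L) ch else substr(ch, 1, 1)
    for (r in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, sub$atom[r],
                                      sub$resname[r], ch1, sub$resno[r],
                                      sub$x[r], sub$y[r], sub$z[r],
                                      sub$element[r]))
    }
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial + 1L, sub$resname[nrow(sub)], ch1,
                              sub$resno[nrow(sub)]))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

parse_pdb_atoms <- function(lines, path = "<pdb>") {
  rec <- substr(lines, 1, 6)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(sel) == 0L) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  ll <- lines[sel]
  altloc <- substr(ll, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  n_alt <- sum(!keep)
  if (n_alt > 0L) {
    message("dropping ", n_alt, " alternate-location atoms (keeping altloc A)")
  }
  ll <- ll[keep]
  sel <- sel[keep]
  num <- function(s) suppressWarnings(as.numeric(s))
  df <- data.frame(
    chain = substr(ll, 22, 22),
    resno = suppressWarnings(as.integer(trimws(substr(ll, 23, 26)))),
    resname = trimws(substr(ll, 18, 20)),
    atom = trimws(substr(ll, 13, 16)),
    element = trimws(substr(ll, 77, 78)),
    x = num(substr(ll, 31, 38)),
    y = num(substr(ll, 39, 46)),
    z = num(substr(ll, 47, 54)),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$x) | is.na(df$y) | is.na(df$z) | is.na(df$resno))
  if (length(bad)) {
    stop("unparseable PDB record at line ", sel[bad[1]], " of ", path,
         call. = FALSE)
  }
  noel <- !nzchar(df$element)
  df$element[noel] <- guess_element(df$atom[noel])
  # normalize two-letter elements to Title case
  df$element <- paste0(toupper(substr(df$element, 1, 1)),
                       tolower(substr(df$element, 2, 2)))
  df$element <- sub(" $", "", df$element)
  df
}

# Single-linkage grouping of chains into protofilaments by CA contact
# (< cutoff Angstrom), each group ordered by centroid projection on the
# global principal axis.
group_protofilaments <- function(atoms, contact_cutoff = 6.0) {
  chains <- unique(atoms$chain)
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) ca <- atoms
  xyz_by <- lapply(chains, function(ch) {
    as.matrix(ca[ca$chain == ch, c("x", "y", "z"), drop = FALSE])
  })
  n <- length(chains)
  grp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (min_image_distance(xyz_by[[i]], xyz_by[[j]]) < contact_cutoff) {
          old <- grp[j]
          grp[grp == old] <- grp[i]
        }
      }
    }
  }
  ctr <- t(vapply(xyz_by, colMeans, numeric(3)))
  out <- list()
  for (g in unique(grp)) {
    members <- which(grp == g)
    if (length(members) > 1L) {
      # chain centroids of a stacked protofilament lie along the fibril
      # axis: order by projection on their own principal direction
      sub <- ctr[members, , drop = FALSE]
      axis <- svd(sweep(sub, 2L, colMeans(sub)))$v[, 1]
      members <- members[order(sub %*% axis)]
      # deterministic orientation: file order of the first chain wins
      if (members[1] > members[length(members)]) members <- rev(members)
    }
    out[[paste0("P", length(out) + 1L)]] <- chains[members]
  }
  out
}

#' Read a fibril structure from PDB
#'
#' Keeps altloc A (logged), resolves elements from atom names when the
#' element column is absent, and groups chains into protofilaments either
#' from an explicit assignment or automatically by inter-chain CA contact
#' (< 6 Angstrom, single linkage), ordering each stack by projection on the
#' structure's principal axis.
#'
#' @param path PDB file.
#' @param protofilaments optional explicit assignment: a list of chain-ID
#'   vectors, or a string like `"A,B,C;D,E,F"`.
#' @return a `fibril_structure`.
#' @export
read_structure <- function(path, protofilaments = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  atoms <- parse_pdb_atoms(lines, path)
  if (is.character(protofilaments) && length(protofilaments) == 1L) {
    protofilaments <- lapply(strsplit(protofilaments, ";")[[1]],
                             function(s) trimws(strsplit(s, ",")[[1]]))
  }
  if (is.null(protofilaments)) {
    protofilaments <- group_protofilaments(atoms)
  }
  fibril_structure(atoms, protofilaments)
}

# ---- poses: SDF ----------------------------------------------------------

sdf_record <- function(pose) {
  at <- pose$atoms
  bonds <- pose$bonds
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  c(pose$id,
    "  symstack",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            at$x, at$y, at$z, at$element),
    if (nb > 0L) sprintf("%3d%3d%3d  0", bonds$i, bonds$j,
                         as.integer(bonds$order)),
    "M  END",
    "$$$$")
}

#' Write poses as a multi-record SDF (V2000)
#'
#' @param poses a `ligand_pose` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  writeLines(unlist(lapply(poses, sdf_record)), path)
  invisible(path)
}

read_sdf <- function(lines, path) {
  breaks <- which(trimws(lines) == "$$$$")
  if (length(breaks) == 0L) breaks <- length(lines) + 1L
  starts <- c(1L, utils::head(breaks, -1L) + 1L)
  poses <- list()
  skipped <- 0L
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:min(breaks[r] - 1L, length(lines))]
    if (length(block) < 4L || !any(nzchar(trimws(block)))) next
    id <- trimws(block[1])
    counts <- block[4]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na)) stop("bad SDF counts line in record ", r, " of ", path,
                        call. = FALSE)
    if (na == 0L) {
      skipped <- skipped + 1L
      next
    }
    al <- block[4L + seq_len(na)]
    atoms <- data.frame(
      element = trimws(substr(al, 32, 34)),
      x = as.numeric(substr(al, 1, 10)),
      y = as.numeric(substr(al, 11, 20)),
      z = as.numeric(substr(al, 21, 30)),
      stringsAsFactors = FALSE)
    bonds <- NULL
    if (!is.na(nb) && nb > 0L) {
      bl <- block[4L + na + seq_len(nb)]
      bonds <- data.frame(i = as.integer(substr(bl, 1, 3)),
                          j = as.integer(substr(bl, 4, 6)),
                          order = as.integer(substr(bl, 7, 9)))
    }
    poses[[length(poses) + 1L]] <- ligand_pose(
      if (nzchar(id)) id else sprintf("pose-%d", r), atoms, bonds)
  }
  if (skipped > 0L) {
    warning(skipped, " zero-atom record(s) skipped in ", path,
            call. = FALSE)
  }
  poses
}

# ---- poses: MOL2 ---------------------------------------------------------

read_mol2 <- function(lines, path) {
  mol_at <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(mol_at) == 0L) {
    stop("no @<TRIPOS>MOLECULE section in ", path, call. = FALSE)
  }
  ends <- c(utils::tail(mol_at, -1L) - 1L, length(lines))
  poses <- list()
  for (r in seq_along(mol_at)) {
    block <- lines[mol_at[r]:ends[r]]
    id <- trimws(block[2])
    asec <- grep("^@<TRIPOS>ATOM", block)
    if (length(asec) == 0L) next
    stop_at <- grep("^@<TRIPOS>", block)
    stop_at <- stop_at[stop_at > asec[1]]
    aend <- if (length(stop_at)) stop_at[1] - 1L else length(block)
    al <- block[(asec[1] + 1L):aend]
    al <- al[nzchar(trimws(al))]
    toks <- strsplit(trimws(al), "[[:space:]]+")
    if (any(lengths(toks) < 6L)) {
      stop("malformed @<TRIPOS>ATOM line in record ", r, " of ", path,
           call. = FALSE)
    }
    ty <- vapply(toks, `[`, "", 6L)
    atoms <- data.frame(
      name = vapply(toks, `[`, "", 2L),
      element = sub("\\..*$", "", ty),
      x = as.numeric(vapply(toks, `[`, "", 3L)),
      y = as.numeric(vapply(toks, `[`, "", 4L)),
      z = as.numeric(vapply(toks, `[`, "", 5L)),
      vdw_type = ty,
      charge = vapply(toks, function(t) {
        if (length(t) >= 9L) suppressWarnings(as.numeric(t[9])) else NA_real_
      }, 0),
      stringsAsFactors = FALSE)
    poses[[length(poses) + 1L]] <- ligand_pose(
      if (nzchar(id)) id else sprintf("pose-%d", r), atoms)
  }
  poses
}

#' Read ligand poses from SDF or MOL2
#'
#' Dispatches on file extension (override with `format`). Atom order is
#' preserved; record names become pose ids, with duplicate names suffixed
#' `-2`, `-3`, ...; explicit MOL2 SYBYL atom types are retained on the
#' `vdw_type` column.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"sdf"` or `"mol2"`.
#' @return list of `ligand_pose` objects in file order.
#' @export
read_poses <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mol2") "mol2" else "sdf"
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    stop("empty pose file: ", path, call. = FALSE)
  }
  poses <- if (format == "mol2") read_mol2(lines, path)
           else read_sdf(lines, path)
  if (length(poses) == 0L) stop("no readable poses in ", path, call. = FALSE)
  ids <- vapply(poses, `[[`, "", "id")
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  for (i in which(dup > 1L)) {
    poses[[i]]$id <- paste0(ids[i], "-", dup[i])
  }
  poses
}

#' Write a ligand stack as a multi-model PDB
#'
#' One MODEL/ENDMDL block per stack member, ligand atoms as HETATM.
#'
#' @param stack list of `ligand_pose` objects (see [build_stack()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_pdb <- function(stack, path) {
  if (inherits(stack, "ligand_pose")) stack <- list(stack)
  lines <- character(0)
  for (m in seq_along(stack)) {
    p <- stack[[m]]
    at <- p$atoms
    lines <- c(lines, sprintf("MODEL %8d", m),
               vapply(seq_len(nrow(at)), function(r) {
                 pdb_atom_line("HETATM", r, at$name[r], "LIG", "X", 1L,
                               at$x[r], at$y[r], at$z[r], at$element[r])
               }, ""),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- operator JSON -------------------------------------------------------

#' Read/write an affine operator as JSON
#'
#' On-disk form is a 4x4 row-major homogeneous matrix under key `"matrix"`;
#' the reader validates the `[0,0,0,1]` bottom row and the proper-rotation
#' invariants.
#'
#' @param op an `affine_operator`.
#' @param path file path.
#' @return `read_operator()` returns an `affine_operator`;
#'   `write_operator()` returns `path` invisibly.
#' @export
write_operator <- function(op, path) {
  stopifnot(inherits(op, "affine_operator"))
  m <- rbind(cbind(op$rotation, op$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_operator
#' @export
read_operator <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  m <- obj$matrix
  if (is.null(m) || !is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop("operator JSON must hold a 4x4 \"matrix\"", call. = FALSE)
  }
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    stop("operator matrix bottom row must be [0, 0, 0, 1]", call. = FALSE)
  }
  affine_operator(m[1:3, 1:3], m[1:3, 4])
}

# ---- misc ----------------------------------------------------------------

#' Write boundary pseudo-atoms
#'
#' `xyzr` format is one `x y z radius` line per pseudo-atom; `pdb` writes
#' HETATM records with the radius in the B-factor column.
#'
#' @param pseudo data.frame from [boundary_pseudoatoms()].
#' @param path output path.
#' @param format `"xyzr"` (default) or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_pseudoatoms <- function(pseudo, path, format = c("xyzr", "pdb")) {
  format <- match.arg(format)
  if (format == "xyzr") {
    writeLines(sprintf("%.4f %.4f %.4f %.4f",
                       pseudo$x, pseudo$y, pseudo$z, pseudo$radius), path)
  } else {
    lines <- vapply(seq_len(nrow(pseudo)), function(r) {
      sprintf("HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              r, pseudo$element[r], "STK", "X", 1L, pseudo$x[r],
              pseudo$y[r], pseudo$z[r], 1.0, pseudo$radius[r],
              toupper(pseudo$element[r]))
    }, "")
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Read a screen CSV (columns id, score, label)
#' @param path CSV path; empty `score` fields become NA (unscored).
#' @return a `screen_records` data.frame.
#' @export
read_screen_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check <- setdiff(c("id", "score", "label"), names(df))
  if (length(check)) {
    stop("screen CSV missing column(s): ", paste(check, collapse = ", "),
         call. = FALSE)
  }
  screen_records(df$id, df$score, df$label)
}
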