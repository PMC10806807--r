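# Rigid-body Metropolis Monte Carlo refinement of the ligand stack under a
# pluggable per-monomer energy backend.

#' Monte Carlo configuration
#'
#' @param n_steps number of Metropolis steps (default 1000, as used for
#'   stack validation).
#' @param translation_sigma per-component s.d. of the multivariate-normal
#'   translation proposal (Angstrom, default 0.2).
#' @param rotation_sigma angular scale of the isotropic SO(3) rotation
#'   proposal (degrees, default 2).
#' @param kT Metropolis temperature (kcal/mol, default 0.593, room
#'   temperature).
#' @param seed integer RNG seed; identical seed + config + inputs give a
#'   bit-identical trace.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_steps = 1000L, translation_sigma = 0.2,
                      rotation_sigma = 2.0, kT = 0.593, seed = 1L) {
  stopifnot(n_steps >= 1L, translation_sigma >= 0, rotation_sigma >= 0,
            kT > 0)
  structure(list(n_steps = as.integer(n_steps),
                 translation_sigma = translation_sigma,
                 rotation_sigma = rotation_sigma,
                 kT = kT, seed = as.integer(seed)),
            class = "mc_config")
}

#' Built-in Lennard-Jones stack energy backend
#'
#' A backend is a function taking a list of `ligand_pose` objects (a stack
#' geometry, ascending k order) and returning one energy in kcal/mol. The
#' built-in backend sums the inter-pose 12-6 LJ energy over all pose pairs
#' and treats a single pose as zero energy (intramolecular terms cancel in
#' the per-monomer formula, so they are omitted). External quantum/NN
#' backends plug in through [command_backend()].
#'
#' @param table a `vdw_table` used for typing and the LJ sum.
#' @return a backend function with attribute `label = "builtin-LJ"`.
#' @export
lj_backend <- function(table) {
  f <- function(poses) {
    poses <- lapply(poses, assign_vdw_types, table = table)
    n <- length(poses)
    if (n < 2L) return(0)
    e <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        e <- e + pair_vdw_energy(poses[[i]], poses[[j]], table)
      }
    }
    e
  }
  attr(f, "label") <- "builtin-LJ"
  f
}

#' External-command energy backend
#'
#' Writes the query geometry (all poses concatenated) as an XYZ file to a
#' temporary path, substitutes that path for `{xyz}` in the command
#' template, runs it, and reads a single energy from the command's standard
#' output. This is the contract through which an ANI or QM evaluator plugs
#' in without binding the package to any NN runtime.
#'
#' @param template shell command containing the placeholder `{xyz}`.
#' @param unit `"kcal"` (default) or `"hartree"` (converted with
#'   627.509474 kcal/mol per hartree).
#' @return a backend function with attribute `label = "external-command"`.
#' @export
command_backend <- function(template, unit = c("kcal", "hartree")) {
  unit <- match.arg(unit)
  stopifnot(grepl("{xyz}", template, fixed = TRUE))
  f <- function(poses) {
    xyz <- tempfile(fileext = ".xyz")
    on.exit(unlink(xyz), add = TRUE)
    at <- do.call(rbind, lapply(poses, function(p) p$atoms))
    writeLines(c(
      as.character(nrow(at)),
      "symstack geometry",
      sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z)
    ), xyz)
    cmd <- gsub("{xyz}", shQuote(xyz), template, fixed = TRUE)
    out <- tryCatch(system(cmd, intern = TRUE),
                    warning = function(w) {
                      stop("backend command failed: ", cmd, " (",
                           conditionMessage(w), ")", call. = FALSE)
                    })
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
      stop("backend command exited with status ", status, ": ", cmd,
           "\noutput: ", paste(out, collapse = "\n"), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(out[length(out)]))
    if (length(val) != 1L || is.na(val)) {
      stop("backend reply is not a single number: ",
           paste(out, collapse = "\n"), call. = FALSE)
    }
    if (unit == "hartree") val * 627.509474 else val
  }
  attr(f, "label") <- "external-command"
  f
}

#' Per-monomer stack energy from a trimer
#'
#' Builds the two nearest symmetry mates (k = -1, 0, +1), evaluates the
#' backend on the trimer and on the lone monomer, and returns
#' `(E(trimer) - 3 E(monomer)) / 2`: the central monomer's two interface
#' energies, halved because each interface is shared by two monomers of the
#' infinite stack; the small mate-mate coupling is retained inside the
#' trimer energy. For short-ranged interactions this converges to the
#' infinite-stack per-monomer interaction energy.
#'
#' @param pose a `ligand_pose`.
#' @param op the fibril `affine_operator`.
#' @param backend a backend function (see [lj_backend()],
#'   [command_backend()]).
#' @return per-monomer interaction energy in kcal/mol.
#' @export
per_monomer_energy <- function(pose, op, backend) {
  stack <- build_stack(pose, op, n_up = 1L, n_down = 1L)
  (backend(stack) - 3 * backend(list(pose))) / 2
}

#' Propose a rigid move
#'
#' Translation components are i.i.d. normal(0, translation_sigma^2); the
#' rotation is an isotropic SO(3) perturbation realized as a uniform random
#' axis with angle |N(0, rotation_sigma^2)|. Draws always consume the same
#' number of random variates so traces stay reproducible. The move is
#' applied about the pose's heavy-atom centroid by [apply_move()].
#'
#' @param cfg an `mc_config` (uses the current RNG state).
#' @return list with `translation` (length 3, Angstrom) and `rotation`
#'   (3x3 matrix).
#' @export
propose_move <- function(cfg) {
  tr <- stats::rnorm(3L, 0, cfg$translation_sigma)
  ax <- stats::rnorm(3L)
  ang <- abs(stats::rnorm(1L, 0, cfg$rotation_sigma * pi / 180))
  n <- sqrt(sum(ax^2))
  if (n < 1e-12 || cfg$rotation_sigma == 0) {
    R <- diag(3)
  } else {
    R <- rotation_about_axis(ax / n, ang)
  }
  list(translation = tr, rotation = R)
}

#' @rdname propose_move
#' @param pose a `ligand_pose`.
#' @param move a move from `propose_move()`.
#' @export
apply_move <- function(pose, move) {
  ctr <- colMeans(pose_coords(pose, heavy_only = TRUE))
  xyz <- pose_coords(pose)
  xyz <- sweep(xyz, 2L, ctr)
  xyz <- xyz %*% t(move$rotation)
  xyz <- sweep(xyz, 2L, ctr + move$translation, "+")
  set_pose_coords(pose, xyz)
}

#' Metropolis-Hastings rigid-body stack refinement
#'
#' Starting from a docked pose that passes the clash filter, proposes rigid
#' moves (the internal conformation never changes), re-imposes the fibril
#' symmetry at every step by regenerating the two mates from the moved
#' monomer, evaluates the per-monomer energy under `backend`, and accepts
#' with the standard Metropolis rule (always if the energy drops, else with
#' probability `exp(-dE/kT)`). The minimum-energy configuration over every
#' evaluated state (start plus all proposals, accepted or not) is returned;
#' after the run it is compared to the start in energy and RMSD to judge
#' whether the docking-predicted stacking was already sensible. A clash in
#' a proposed state is allowed (the energy penalizes it), but the result
#' flags a clashing final best pose.
#'
#' @param pose a `ligand_pose` (should pass [symmetry_clash_check()]).
#' @param op the fibril `affine_operator`.
#' @param cfg an `mc_config`.
#' @param backend an energy backend (default built-in LJ requires `table`).
#' @param table `vdw_table` for the default backend.
#' @return list of class `mc_result`: `start_energy`, `best_energy`,
#'   `best_pose`, `accepted_energy_trace` (current energy after each step),
#'   `acceptance_rate`, `rmsd_to_start`, `delta_energy`,
#'   `best_pose_clashes`, `backend`.
#' @export
run_mc <- function(pose, op, cfg = mc_config(), backend = NULL,
                   table = NULL) {
  stopifnot(inherits(pose, "ligand_pose"), inherits(op, "affine_operator"),
            inherits(cfg, "mc_config"))
  if (is.null(backend)) {
    if (is.null(table)) {
      stop("supply `backend` or a `table` for the built-in LJ backend",
           call. = FALSE)
    }
    backend <- lj_backend(table)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(cfg$seed)

  energy_of <- function(p, step) {
    tryCatch(per_monomer_energy(p, op, backend), error = function(e) {
      stop("energy backend failed at step ", step, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  cur_pose <- pose
  cur_e <- energy_of(pose, 0L)
  start_e <- cur_e
  best_pose <- pose
  best_e <- cur_e
  trace <- numeric(cfg$n_steps)
  n_acc <- 0L
  for (s in seq_len(cfg$n_steps)) {
    move <- propose_move(cfg)
    cand <- apply_move(cur_pose, move)
    e <- energy_of(cand, s)
    if (e < best_e) {
      best_e <- e
      best_pose <- cand
    }
    dE <- e - cur_e
    u <- stats::runif(1L)
    if (dE <= 0 || u < exp(-dE / cfg$kT)) {
      cur_pose <- cand
      cur_e <- e
      n_acc <- n_acc + 1L
    }
    trace[s] <- cur_e
  }
  chk <- symmetry_clash_check(best_pose, op)
  out <- list(
    start_energy = start_e,
    best_energy = best_e,
    best_pose = best_pose,
    accepted_energy_trace = trace,
    acceptance_rate = n_acc / cfg$n_steps,
    rmsd_to_start = pose_rmsd(pose, best_pose),
    delta_energy = best_e - start_e,
    best_pose_clashes = !chk$passes,
    backend = attr(backend, "label") %||% "custom")
  class(out) <- "mc_result"
  out
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> start %.4f -> best %.4f kcal/mol (delta %.4f), rmsd %.3f A, acc %.2f [%s]\n",
    x$start_energy, x$best_energy, x$delta_energy, x$rmsd_to_start,
    x$acceptance_rate, x$backend))
  invisible(x)
}
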