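# Per-monomer toy backend used in several tests: quadratic in the central
# pose's centroid z, zero for a lone monomer. With the trimer formula this
# yields per-monomer energy (z - a)^2.
quad_backend <- function(a) {
  f <- function(poses) {
    if (length(poses) < 2L) return(0)
    central <- poses[[2L]]
    2 * (mean(central$atoms$z) - a)^2
  }
  attr(f, "label") <- "toy-quadratic"
  f
}

test_that("per_monomer_energy: limits, expansion oracle, mock backend", {
  tab <- fixture_table()
  pose <- typed_ring()
  far <- screw_operator(c(0, 0, 1), twist_deg = 0.5, rise = 500)
  expect_lt(abs(per_monomer_energy(pose, far, lj_backend(tab))), 1e-6)

  op <- screw_operator(c(0, 0, 1), twist_deg = -1, rise = 3.6)
  got <- per_monomer_energy(pose, op, lj_backend(tab))
  # independent expansion: nearest-pair energy plus half the mate-mate term
  up <- apply_operator(op, pose)
  down <- apply_operator(invert_operator(op), pose)
  expected <- bf_lj(pose, up, tab) + bf_lj(down, up, tab) / 2
  expect_equal(got, expected, tolerance = 1e-9)

  zero <- function(poses) 0
  expect_identical(per_monomer_energy(pose, op, zero), 0)
})

test_that("per-monomer energy is invariant under stack translation", {
  tab <- fixture_table()
  op <- screw_operator(c(0, 0, 1), twist_deg = 2, rise = 3.8)
  pose <- typed_ring(center = c(3, 0, 0))
  e0 <- per_monomer_energy(pose, op, lj_backend(tab))
  e1 <- per_monomer_energy(apply_operator(op, pose), op, lj_backend(tab))
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("propose_move: zero-width proposals are the identity move", {
  cfg <- mc_config(translation_sigma = 0, rotation_sigma = 0)
  set.seed(1)
  mv <- propose_move(cfg)
  expect_equal(mv$translation, c(0, 0, 0))
  expect_equal(mv$rotation, diag(3))
  pose <- make_planar_ligand()
  expect_equal(apply_move(pose, mv)$atoms, pose$atoms, tolerance = 1e-12)
})

test_that("propose_move sampling statistics match the stated distributions", {
  cfg <- mc_config(translation_sigma = 0.3, rotation_sigma = 5)
  set.seed(2024)
  n <- 1e5L
  tr <- matrix(0, n, 3)
  axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    mv <- propose_move(cfg)
    tr[i, ] <- mv$translation
    # recover the rotation axis from the skew part
    w <- c(mv$rotation[3, 2] - mv$rotation[2, 3],
           mv$rotation[1, 3] - mv$rotation[3, 1],
           mv$rotation[2, 1] - mv$rotation[1, 2])
    axes[i, ] <- w / max(sqrt(sum(w^2)), 1e-300)
  }
  se <- 0.3 / sqrt(n)
  expect_true(all(abs(colMeans(tr)) < 4 * se))
  expect_true(all(abs(apply(tr, 2, sd) - 0.3) / 0.3 < 0.02))

  # axis direction uniform on the sphere: octant occupancy uniform
  keep <- rowSums(axes^2) > 0.5
  oct <- (axes[keep, 1] > 0) + 2 * (axes[keep, 2] > 0) +
    4 * (axes[keep, 3] > 0)
  p <- suppressWarnings(stats::chisq.test(table(oct)))$p.value
  expect_gt(p, 1e-3)
  # and mean |z-component| of a uniform axis is 1/2
  expect_lt(abs(mean(abs(axes[keep, 3])) - 0.5), 0.01)
})

test_that("run_mc: zero-width proposals return the input untouched", {
  tab <- fixture_table()
  pose <- typed_ring()
  op <- affine_operator(diag(3), c(0, 0, 4.2))
  res <- run_mc(pose, op, mc_config(n_steps = 10, translation_sigma = 0,
                                    rotation_sigma = 0, seed = 9),
                table = tab)
  expect_equal(res$best_pose$atoms, pose$atoms, tolerance = 1e-12)
  expect_equal(res$delta_energy, 0)
  expect_equal(res$rmsd_to_start, 0)
})

test_that("run_mc finds the quadratic toy minimum", {
  pose <- make_planar_ligand() # centroid z = 0
  op <- affine_operator(diag(3), c(0, 0, 6))
  cfg <- mc_config(n_steps = 1000, translation_sigma = 0.2,
                   rotation_sigma = 0, kT = 0.593, seed = 17)
  res <- run_mc(pose, op, cfg, backend = quad_backend(0.7))
  best_z <- mean(res$best_pose$atoms$z)
  expect_lt(abs(best_z - 0.7), 3 * cfg$translation_sigma)
  expect_lte(res$best_energy, res$start_energy)
})

test_that("run_mc reaches the LJ scan optimum and is deterministic", {
  tab <- fixture_table()
  op <- screw_operator(c(0, 0, 1), twist_deg = 30, rise = 3.8)
  # 1D oracle: slide the ring radially, energy by independent double loops
  energy_at <- function(x0) {
    p <- typed_ring(center = c(x0, 0, 0))
    up <- apply_operator(op, p)
    down <- apply_operator(invert_operator(op), p)
    bf_lj(p, up, tab) + bf_lj(down, up, tab) / 2
  }
  xs <- seq(0.5, 12, by = 0.01)
  es <- vapply(xs, energy_at, 0)
  x_opt <- xs[which.min(es)]
  sep_of <- function(p) {
    c0 <- colMeans(pose_coords(p))
    sqrt(sum((apply_operator(op, c0) - c0)^2))
  }
  target_sep <- sep_of(typed_ring(center = c(x_opt, 0, 0)))

  start <- typed_ring(center = c(x_opt + 1, 0, 0))
  cfg <- mc_config(n_steps = 1000, translation_sigma = 0.1,
                   rotation_sigma = 0, seed = 21)
  res <- run_mc(start, op, cfg, table = tab)
  expect_lte(res$best_energy, res$start_energy)
  expect_lt(abs(sep_of(res$best_pose) - target_sep), 0.2)

  res2 <- run_mc(start, op, cfg, table = tab)
  expect_identical(res$accepted_energy_trace, res2$accepted_energy_trace)
  expect_identical(res$best_pose$atoms, res2$best_pose$atoms)
})

test_that("running minimum of the trace never undercuts best_energy", {
  tab <- fixture_table()
  pose <- typed_ring()
  op <- screw_operator(c(0, 0, 1), twist_deg = 10, rise = 4.0)
  res <- run_mc(pose, op, mc_config(n_steps = 200, seed = 4), table = tab)
  expect_lte(res$best_energy, min(res$accepted_energy_trace))
  expect_lte(res$best_energy, res$start_energy)
})

test_that("acceptance fraction follows kT limits", {
  pose <- make_planar_ligand()
  op <- affine_operator(diag(3), c(0, 0, 6))
  uphill <- function(poses) { # bowl centered on the start: all moves uphill
    if (length(poses) < 2L) return(0)
    ctr <- colMeans(pose_coords(poses[[2L]]))
    2 * sum(ctr^2)
  }
  hot <- run_mc(pose, op, mc_config(n_steps = 300, kT = 1e6, seed = 8),
                backend = uphill)
  expect_gt(hot$acceptance_rate, 0.95)
  cold <- run_mc(pose, op, mc_config(n_steps = 300, kT = 1e-6, seed = 8),
                 backend = uphill)
  expect_lt(cold$acceptance_rate, 0.05)
})

test_that("external command backend contract", {
  skip_on_os("windows")
  pose <- make_planar_ligand()
  op <- affine_operator(diag(3), c(0, 0, 6))

  zero_cmd <- command_backend("cat {xyz} > /dev/null; echo 0.0")
  expect_equal(per_monomer_energy(pose, op, zero_cmd), 0)

  kcal <- command_backend("cat {xyz} > /dev/null; echo -2.5")
  expect_equal(kcal(list(pose)), -2.5)
  hartree <- command_backend("cat {xyz} > /dev/null; echo -1.0",
                             unit = "hartree")
  expect_equal(hartree(list(pose)), -627.509474)

  bad <- command_backend("cat {xyz} > /dev/null; echo not-a-number")
  expect_error(bad(list(pose)), "not a single number")
  dies <- command_backend("cat {xyz} > /dev/null; exit 3")
  expect_error(dies(list(pose)), "backend")
  # run_mc reports the failing step
  expect_error(run_mc(pose, op, mc_config(n_steps = 2, seed = 1),
                      backend = dies), "step 0")
})
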