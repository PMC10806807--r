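test_that("clash check: identity operator always clashes at distance 0", {
  pose <- make_planar_ligand()
  chk <- symmetry_clash_check(pose, identity_operator())
  expect_false(chk$passes)
  expect_equal(chk$min_distance, 0)
})

test_that("clash check: flat ring under a pure 4.7 A rise passes", {
  pose <- make_planar_ligand()
  op <- affine_operator(diag(3), c(0, 0, 4.7))
  chk <- symmetry_clash_check(pose, op)
  expect_true(chk$passes)
  expect_equal(chk$min_distance, 4.7, tolerance = 1e-12)
})

test_that("clash check matches the brute-force double loop exactly", {
  set.seed(101)
  for (i in 1:200) {
    pose <- rand_pose(n = sample(3:10, 1))
    op <- rand_operator()
    chk <- symmetry_clash_check(pose, op, cutoff = 2.0)
    oracle <- bf_min_dist(pose_coords(pose),
                          apply_operator(op, pose_coords(pose)))
    expect_identical(chk$min_distance, oracle)
    expect_identical(chk$passes, oracle >= 2.0)
  }
})

test_that("clash result is identical for op and its inverse", {
  set.seed(5)
  for (i in 1:20) {
    pose <- rand_pose()
    op <- rand_operator()
    a <- symmetry_clash_check(pose, op)
    b <- symmetry_clash_check(pose, invert_operator(op))
    expect_equal(a$min_distance, b$min_distance, tolerance = 1e-9)
    expect_identical(a$passes, b$passes)
  }
})

test_that("clash verdict is invariant under stack translation of the pose", {
  set.seed(6)
  op <- screw_operator(c(0.2, 0.1, 1), twist_deg = 3, rise = 4.0)
  pose <- make_planar_ligand(center = c(5, 0, 0))
  base <- symmetry_clash_check(pose, op)
  for (k in c(-2L, 1L, 3L)) {
    moved <- apply_operator(operator_power(op, k), pose)
    chk <- symmetry_clash_check(moved, op)
    expect_identical(chk$passes, base$passes)
    expect_equal(chk$min_distance, base$min_distance, tolerance = 1e-9)
  }
})

test_that("multi-image check catches second-image contacts", {
  # ligand elongated along the axis: nearest image clears 2 A but the
  # second image interleaves
  pose <- ligand_pose("long", data.frame(
    element = "C", x = c(0, 0, 0), y = c(0, 0.1, 0.2), z = c(0, 4, 8)))
  op <- affine_operator(diag(3), c(1.5, 0, 3))
  one <- symmetry_clash_check(pose, op, images = 1)
  two <- symmetry_clash_check(pose, op, images = 2)
  expect_lte(two$min_distance, one$min_distance)
})

test_that("empty selection after atom filtering errors", {
  h <- data.frame(element = c("C", "H"), x = c(0, 1), y = 0, z = 0)
  pose <- ligand_pose("h", h)
  pose$atoms$element <- c("H", "H") # bypass constructor to force all-H
  expect_error(symmetry_clash_check(pose, identity_operator(),
                                    atom_selection = "heavy"),
               "no atoms left")
})

test_that("build_stack returns powers in order with a bit-identical center", {
  pose <- make_planar_ligand()
  op <- screw_operator(c(0, 0, 1), twist_deg = -1, rise = 4.7)
  expect_identical(build_stack(pose, op, 0, 0)[[1]]$atoms, pose$atoms)

  trimer <- build_stack(pose, op, 1, 1)
  expect_length(trimer, 3L)
  expect_identical(vapply(trimer, attr, 0L, "k"), c(k.1 = -1L, k0 = 0L,
                                                    k1 = 1L),
                   ignore_attr = TRUE)
  expect_identical(trimer[[2]]$atoms, pose$atoms)

  five <- build_stack(pose, op, 2, 2)
  expect_length(five, 5L)
  ctr <- t(vapply(five, function(p) colMeans(pose_coords(p)), numeric(3)))
  gaps <- sqrt(rowSums(diff(ctr)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
})

test_that("interplanar distance: constructed cases and screw invariance", {
  ring <- make_planar_ligand()
  up <- affine_operator(diag(3), c(0, 0, 3.4))
  expect_equal(interplanar_distance(ring, up), 3.4, tolerance = 1e-9)
  sideways <- affine_operator(diag(3), c(2.5, -1, 0))
  expect_equal(interplanar_distance(ring, sideways), 0, tolerance = 1e-9)

  op <- screw_operator(c(0, 0, 1), twist_deg = -1, rise = 3.4)
  d0 <- interplanar_distance(ring, op)
  d1 <- interplanar_distance(apply_operator(op, ring), op)
  expect_equal(d0, d1, tolerance = 1e-9)

  line <- ligand_pose("line", data.frame(element = "C", x = 0:3, y = 0,
                                         z = 0))
  expect_error(interplanar_distance(line, up), "collinear")
})

test_that("pose_rmsd: exact values, symmetry, and the direct formula", {
  pose <- make_planar_ligand()
  expect_equal(pose_rmsd(pose, pose), 0)
  shifted <- apply_operator(affine_operator(diag(3), c(1, 0, 0)), pose)
  expect_equal(pose_rmsd(pose, shifted), 1.0)

  set.seed(12)
  a <- rand_pose(10)
  b <- rand_pose(10)
  direct <- sqrt(mean(rowSums((pose_coords(a) - pose_coords(b))^2)))
  expect_equal(pose_rmsd(a, b), direct, tolerance = 1e-12)
  expect_equal(pose_rmsd(a, b), pose_rmsd(b, a))

  expect_error(pose_rmsd(a, rand_pose(7)), "cannot map")
})
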