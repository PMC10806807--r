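test_that("vdw_table validation and plain-text reading", {
  expect_error(vdw_table(data.frame(type = "A", epsilon = -1,
                                    rmin_half = 1)), "epsilon")
  expect_error(vdw_table(data.frame(type = c("A", "A"), epsilon = 1,
                                    rmin_half = 1)), "duplicate")

  path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "CX 0.1 1.7   # inline", "NX 0.2 2.0",
               "default C CX", "default N NX", ""), path)
  tab <- read_vdw_table(path)
  expect_equal(nrow(tab$types), 2L)
  expect_equal(unname(tab$defaults["C"]), "CX")

  writeLines(c("CX 0.1"), path)
  expect_error(read_vdw_table(path), "malformed")

  # the shipped table parses and covers common organic elements
  shipped <- read_vdw_table(system.file("extdata", "vdw_params.txt",
                                        package = "symstack"))
  expect_true(all(c("C", "N", "O", "S", "H") %in% names(shipped$defaults)))
})

test_that("assign_vdw_types: defaults, explicit overrides, errors", {
  tab <- fixture_table()
  pose <- make_planar_ligand()
  typed <- assign_vdw_types(pose, tab)
  expect_true(all(typed$atoms$vdw_type == "CX"))

  pose$atoms$vdw_type[1] <- "NX" # explicit label wins
  typed <- assign_vdw_types(pose, tab)
  expect_equal(typed$atoms$vdw_type[1], "NX")
  expect_true(all(typed$atoms$vdw_type[-1] == "CX"))

  sel <- ligand_pose("se", data.frame(element = c("C", "Se"),
                                      x = c(0, 2), y = 0, z = 0))
  expect_error(assign_vdw_types(sel, tab), "SE")
})

test_that("pair_vdw_energy: analytic two-atom cases", {
  tab <- fixture_table()
  mk <- function(x, type) {
    p <- ligand_pose(paste0("a", x),
                     data.frame(element = "C", x = x, y = 0, z = 0))
    p$atoms$vdw_type <- type
    p
  }
  # LJ minimum: r = rmin_ij = 1.7 + 1.7 -> energy exactly -eps = -0.1
  expect_equal(pair_vdw_energy(mk(0, "CX"), mk(3.4, "CX"), tab), -0.1,
               tolerance = 1e-12)
  # mixed pair: eps = sqrt(0.1*0.2), rmin = 3.7
  expect_equal(pair_vdw_energy(mk(0, "CX"), mk(3.7, "NX"), tab),
               -sqrt(0.02), tolerance = 1e-12)
  # asymptotic zero
  expect_lt(abs(pair_vdw_energy(mk(0, "CX"), mk(100, "CX"), tab)), 1e-6)
  # singular geometry
  expect_error(pair_vdw_energy(mk(0, "CX"), mk(0, "CX"), tab), "singular")
})

test_that("pair_vdw_energy equals the double-loop oracle and is symmetric", {
  tab <- fixture_table()
  set.seed(33)
  for (i in 1:20) {
    a <- rand_pose(6, id = "a")
    b <- rand_pose(6, id = "b")
    b <- set_shift(b, c(0, 0, 8)) # keep pairs non-singular
    a <- assign_vdw_types(a, tab)
    b <- assign_vdw_types(b, tab)
    a$atoms$vdw_type[1:3] <- "NX"
    e <- pair_vdw_energy(a, b, tab)
    expect_equal(e, bf_lj(a, b, tab), tolerance = 1e-9)
    expect_equal(e, pair_vdw_energy(b, a, tab), tolerance = 1e-12)
  }
})

test_that("stacking energy is translation- and rigid-motion-invariant", {
  tab <- fixture_table()
  op <- screw_operator(c(0, 0, 1), twist_deg = -1, rise = 3.6)
  pose <- typed_ring(center = c(4, 0, 0))
  e01 <- pair_vdw_energy(pose, apply_operator(op, pose), tab)
  p1 <- apply_operator(op, pose)
  p2 <- apply_operator(operator_power(op, 2), pose)
  expect_equal(e01, pair_vdw_energy(p1, p2, tab), tolerance = 1e-9)

  set.seed(44)
  g <- rand_operator()
  expect_equal(e01, pair_vdw_energy(apply_operator(g, pose),
                                    apply_operator(g, p1), tab),
               tolerance = 1e-9)
})

test_that("stack_score: clash gating, LJ optimum, additive identity", {
  tab <- fixture_table()
  pose <- make_planar_ligand()
  rep_fail <- stack_score(pose, identity_operator(), tab)
  expect_false(rep_fail$passes_clash)
  expect_true(is.na(rep_fail$ligand_ligand_vdw))

  # scan separations: the optimum of the 1D scan must give negative energy
  scan <- vapply(seq(3, 6, by = 0.01), function(d) {
    op <- affine_operator(diag(3), c(0, 0, d))
    pair_vdw_energy(typed_ring(), apply_operator(op, typed_ring()), tab)
  }, 0)
  d_opt <- seq(3, 6, by = 0.01)[which.min(scan)]
  op_opt <- affine_operator(diag(3), c(0, 0, d_opt))
  rep_opt <- stack_score(pose, op_opt, tab)
  expect_true(rep_opt$passes_clash)
  expect_lt(rep_opt$ligand_ligand_vdw, 0)
  expect_equal(rep_opt$ligand_ligand_vdw, min(scan), tolerance = 1e-9)

  rep0 <- stack_score(pose, op_opt, tab, protein_terms = 0)
  expect_identical(rep0$total_score, rep0$ligand_ligand_vdw)
  rep2 <- stack_score(pose, op_opt, tab, protein_terms = c(-3, -2))
  expect_equal(rep2$total_score, rep2$ligand_ligand_vdw - 5)
})

test_that("filter/geometry boundary consistency", {
  tab <- fixture_table()
  pose <- make_planar_ligand()
  # shrink the rise until the image crosses the 2 A cutoff
  passing <- symmetry_clash_check(pose,
                                  affine_operator(diag(3), c(0, 0, 2.5)))
  expect_true(passing$passes)
  failing <- symmetry_clash_check(pose,
                                  affine_operator(diag(3), c(0, 0, 1.9)))
  expect_false(failing$passes)
  expect_equal(failing$min_distance, 1.9, tolerance = 1e-12)
})

test_that("rank_poses orders, filters and validates", {
  tab <- fixture_table()
  mk_rep <- function(id, score, passes = TRUE, pt = FALSE) {
    structure(list(id = id, passes_clash = passes,
                   min_image_distance = 3, ligand_ligand_vdw = score,
                   total_score = score, has_protein_terms = pt,
                   backend = "builtin-LJ"),
              class = "stack_energy_report")
  }
  out <- rank_poses(list(mk_rep("a", -5), mk_rep("b", -7), mk_rep("c", -6)))
  expect_equal(vapply(out, `[[`, 0, "total_score"), c(-7, -6, -5))

  out <- rank_poses(list(mk_rep("clash", -99, passes = FALSE),
                         mk_rep("ok", -1)))
  expect_length(out, 1L)
  expect_equal(out[[1]]$id, "ok")

  expect_error(rank_poses(list(mk_rep("a", -1), mk_rep("b", -2, pt = TRUE))),
               "term sets")

  set.seed(55)
  sc <- round(stats::rnorm(100), 2)
  reps <- lapply(seq_along(sc), function(i) mk_rep(sprintf("p%03d", i),
                                                   sc[i]))
  got <- vapply(rank_poses(reps), `[[`, "", "id")
  ref <- sprintf("p%03d", order(sc, sprintf("p%03d", seq_along(sc))))
  expect_identical(got, ref)
})
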