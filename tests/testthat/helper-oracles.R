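# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, direct formulas) and never call the code paths they check.

rand_rotation <- function() {
  M <- matrix(stats::rnorm(9L), 3L)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rand_operator <- function(tmax = 6) {
  affine_operator(rand_rotation(), stats::runif(3L, -tmax, tmax))
}

rand_pose <- function(n = 8L, spread = 3, id = "rand") {
  xyz <- matrix(stats::rnorm(3L * n, 0, spread), ncol = 3L)
  ligand_pose(id, data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3]))
}

# all-pairs brute-force minimum distance (double loop)
bf_min_dist <- function(A, B) {
  m <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dx <- A[i, 1] - B[j, 1]
      dy <- A[i, 2] - B[j, 2]
      dz <- A[i, 3] - B[j, 3]
      m <- min(m, sqrt(dx * dx + dy * dy + dz * dz))
    }
  }
  m
}

# brute-force double-loop 12-6 LJ sum with Lorentz-Berthelot rules
bf_lj <- function(pose_a, pose_b, table) {
  pa <- pose_a$atoms
  pb <- pose_b$atoms
  look <- function(ty) {
    i <- match(ty, table$types$type)
    c(eps = table$types$epsilon[i], rh = table$types$rmin_half[i])
  }
  e <- 0
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      qa <- look(pa$vdw_type[i])
      qb <- look(pb$vdw_type[j])
      r <- sqrt((pa$x[i] - pb$x[j])^2 + (pa$y[i] - pb$y[j])^2 +
                  (pa$z[i] - pb$z[j])^2)
      rmin <- qa[["rh"]] + qb[["rh"]]
      eps <- sqrt(qa[["eps"]] * qb[["eps"]])
      e <- e + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  e
}

# round-number vdW fixture table: tests never depend on shipped constants
fixture_table <- function() {
  vdw_table(data.frame(type = c("CX", "NX"),
                       epsilon = c(0.1, 0.2),
                       rmin_half = c(1.7, 2.0)),
            defaults = c(C = "CX", N = "NX"))
}

set_shift <- function(pose, vec) {
  apply_operator(affine_operator(diag(3), vec), pose)
}

typed_ring <- function(center = c(0, 0, 0), id = "ring") {
  assign_vdw_types(make_planar_ligand(center = center, id = id),
                   fixture_table())
}
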