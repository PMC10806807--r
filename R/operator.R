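# Affine screw operators: construction, algebra, screw decomposition.

#' Construct an affine symmetry operator
#'
#' An affine operator represents the fibril's screw transformation acting on
#' 3D coordinates with the column-vector convention `x' = R x + t`: a proper
#' rotation followed by a translation. Consecutive monomers of a helical
#' fibril are related by one such operator (for AD PHF tau, a rise of about
#' 4.7 Angstrom along the fibril axis combined with a twist of about -1
#' degree about it).
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det = +1, both
#'   within 1e-6).
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class `affine_operator` with elements `rotation` and
#'   `translation`.
#' @seealso [screw_operator()], [decompose_screw()], [apply_operator()]
#' @export
#' @examples
#' op <- affine_operator(diag(3), c(0, 0, 4.7))
#' apply_operator(op, c(1, 0, 0))
affine_operator <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || anyNA(rotation)) {
    stop("`rotation` must be a finite 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L || anyNA(translation) ||
      any(!is.finite(translation))) {
    stop("`translation` must be a finite length-3 vector", call. = FALSE)
  }
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho > 1e-6) {
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", ortho),
         call. = FALSE)
  }
  d <- det(rotation)
  if (abs(d - 1) > 1e-6) {
    stop(sprintf("rotation must be proper (det = +1); got det = %.8f", d),
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "affine_operator")
}

#' @export
print.affine_operator <- function(x, ...) {
  cat("<affine_operator>\n")
  sp <- decompose_screw(x)
  cat(sprintf("  rise  %.4f A   twist %.4f deg\n", sp$rise, sp$twist_deg))
  cat(sprintf("  axis  [%.4f, %.4f, %.4f]\n",
              sp$axis[1], sp$axis[2], sp$axis[3]))
  invisible(x)
}

#' Identity operator
#' @return The identity `affine_operator` (no rotation, no translation).
#' @export
identity_operator <- function() affine_operator(diag(3), c(0, 0, 0))

#' Operator algebra: composition, inverse, integer powers
#'
#' `compose_operators(a, b)` returns the operator applying `b` first and then
#' `a` (`x -> a(b(x))`). `invert_operator(op)` returns the inverse screw step
#' (used, e.g., to grow a fibril in the opposite direction).
#' `operator_power(op, k)` is the k-fold composition for any integer k
#' (negative k uses the inverse; k = 0 is the identity).
#'
#' @param a,b,op `affine_operator` objects.
#' @param k integer power.
#' @return An `affine_operator`.
#' @export
compose_operators <- function(a, b) {
  stopifnot(inherits(a, "affine_operator"), inherits(b, "affine_operator"))
  affine_operator(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_operators
#' @export
invert_operator <- function(op) {
  stopifnot(inherits(op, "affine_operator"))
  Rt <- t(op$rotation)
  affine_operator(Rt, -as.numeric(Rt %*% op$translation))
}

#' @rdname compose_operators
#' @export
operator_power <- function(op, k) {
  stopifnot(inherits(op, "affine_operator"))
  k <- as.integer(k)
  if (k == 0L) return(identity_operator())
  base <- if (k < 0L) invert_operator(op) else op
  out <- base
  for (i in seq_len(abs(k) - 1L)) out <- compose_operators(base, out)
  out
}

#' Apply an affine operator to coordinates
#'
#' A rigid motion: all pairwise distances within the point set are preserved.
#'
#' @param op an `affine_operator`.
#' @param x coordinates: a length-3 vector, an n x 3 matrix, or an object
#'   with an `apply_operator` method (ligand poses, fibril structures).
#' @param ... passed to methods.
#' @return Transformed coordinates of the same shape/class as `x`.
#' @export
apply_operator <- function(op, x, ...) UseMethod("apply_operator", x)

#' @export
apply_operator.default <- function(op, x, ...) {
  stopifnot(inherits(op, "affine_operator"))
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    return(as.numeric(op$rotation %*% x) + op$translation)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  sweep(x %*% t(op$rotation), 2L, op$translation, "+")
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Build an operator from screw parameters
#'
#' @param axis unit 3-vector along the screw axis (normalized internally).
#' @param twist_deg signed rotation about `axis` in degrees (right-hand
#'   rule).
#' @param rise translation along `axis` in Angstrom.
#' @param axis_point a point on the screw axis (default origin).
#' @return An `affine_operator`.
#' @export
#' @examples
#' op <- screw_operator(c(0, 0, 1), twist_deg = -1, rise = 4.7)
#' decompose_screw(op)$rise
screw_operator <- function(axis, twist_deg, rise, axis_point = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("`axis` must be a nonzero vector", call. = FALSE)
  axis <- axis / n
  R <- rotation_about_axis(axis, twist_deg * pi / 180)
  t <- rise * axis + as.numeric((diag(3) - R) %*% as.numeric(axis_point))
  affine_operator(R, t)
}

#' Decompose an operator into screw parameters
#'
#' Every proper rigid motion is a screw: a rotation by `twist_deg` about an
#' axis through `axis_point` combined with a translation `rise` along that
#' axis. The axis is oriented so that `rise >= 0` (for a pure rotation,
#' so that `twist_deg >= 0`); the twist sign then follows the right-hand
#' rule, which reproduces the "4.7 Angstrom rise with ~ -1 degree twist"
#' description of AD tau filaments as a signed pair. `axis_point` is the
#' foot of the axis closest to the origin (perpendicular component only).
#'
#' @param op an `affine_operator`.
#' @return A list of class `screw_parameters`: `axis` (unit 3-vector),
#'   `twist_deg`, `rise` (Angstrom), `axis_point`.
#' @export
decompose_screw <- function(op) {
  stopifnot(inherits(op, "affine_operator"))
  R <- op$rotation
  t <- op$translation
  # axial vector of the skew part: w = sin(theta) * axis
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  cos_th <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  sin_abs <- sqrt(sum(w^2))

  if (sin_abs < 1e-12 && cos_th > 0) {
    # identity rotation: screw degenerates to a pure translation
    tn <- sqrt(sum(t^2))
    if (tn < 1e-12) {
      stop("degenerate operator: identity rotation and zero translation",
           call. = FALSE)
    }
    out <- list(axis = t / tn, twist_deg = 0, rise = tn,
                axis_point = c(0, 0, 0))
    class(out) <- "screw_parameters"
    return(out)
  }

  if (sin_abs < 1e-8) {
    # angle near pi: recover axis from the symmetric part, R + I = 2 a a'
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    axis <- M[, j] / sqrt(sum(M[, j]^2))
  } else {
    axis <- w / sin_abs
  }
  twist <- atan2(sum(axis * w), cos_th) # signed about `axis`
  rise <- sum(t * axis)
  if (rise < 0 || (abs(rise) < 1e-12 && twist < 0)) {
    axis <- -axis
    twist <- -twist
    rise <- -rise
  }
  # in-plane fixed point: (I - R) p = t_perp with p restricted to axis-perp
  t_perp <- t - rise * axis
  if (abs(twist) < 1e-12) {
    axis_point <- c(0, 0, 0)
  } else {
    A <- diag(3) - R + outer(axis, axis)
    axis_point <- as.numeric(solve(A, t_perp))
  }
  out <- list(axis = axis, twist_deg = twist * 180 / pi, rise = rise,
              axis_point = axis_point)
  class(out) <- "screw_parameters"
  out
}

#' @export
print.screw_parameters <- function(x, ...) {
  cat(sprintf("<screw_parameters> rise %.4f A, twist %.4f deg, axis [%.3f, %.3f, %.3f]\n",
              x$rise, x$twist_deg, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# Project an arbitrary 3x3 matrix to the nearest proper rotation (chordal /
# Frobenius sense) via SVD.
project_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Optimal proper-rotation least-squares superposition mapping X onto Y
# (both n x 3): returns R, t with Y ~ R X + t (Kabsch).
kabsch_fit <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3L)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = cy - as.numeric(R %*% cx))
}
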