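#' @importFrom stats sd setNames
#' @importFrom utils head tail
NULL

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from an axis and angle
#'
#' Rodrigues' formula. The axis need not be normalized.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle rotation angle in radians.
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  # uniform over SO(3) via QR of a Gaussian matrix, sign-fixed
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  unit(v)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric length-3 vector (Angstrom).
#' @return An object of class `pv_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation is improper (det < 0)", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "pv_transform")
}

#' @export
print.pv_transform <- function(x, ...) {
  cat("<pv_transform>\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates or structures
#'
#' @param x an n x 3 coordinate matrix, a `pv_protein`, `pv_ligand`, or
#'   `pv_complex`.
#' @param tf a `pv_transform`.
#' @return The transformed object, same class as `x`.
#' @export
apply_transform <- function(x, tf) UseMethod("apply_transform")

#' @export
apply_transform.matrix <- function(x, tf) {
  stopifnot(inherits(tf, "pv_transform"), ncol(x) == 3)
  sweep(x %*% t(tf$rotation), 2, tf$translation, "+")
}

#' @export
apply_transform.data.frame <- function(x, tf) {
  xyz <- apply_transform(as.matrix(x[, c("x", "y", "z")]), tf)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

transform_to_json <- function(tf) {
  jsonlite::toJSON(list(rotation = as.vector(t(tf$rotation)),
                        translation = tf$translation),
                   digits = NA, auto_unbox = FALSE)
}

transform_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) least-squares deviation between two paired point sets. A
#' reflection is never returned: the smallest singular direction is flipped
#' when needed, so `det(R) = +1` always.
#'
#' @param mobile_coords,ref_coords n x 3 matrices of paired points, n >= 3.
#' @param weights optional non-negative weights of length n.
#' @return A list with `transform` (a [rigid_transform()] taking mobile onto
#'   reference) and `fit_rmsd`, the post-fit RMSD in Angstrom.
#' @export
kabsch <- function(mobile_coords, ref_coords, weights = NULL) {
  A <- as.matrix(mobile_coords); B <- as.matrix(ref_coords)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("point sets must be equal-sized n x 3 matrices", call. = FALSE)
  n <- nrow(A)
  if (n < 3) stop_degenerate("need at least 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ca <- colSums(A * w); cb <- colSums(B * w)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0 * w) %*% B0
  sv <- svd(H)
  # rank-deficient (collinear/coincident) point sets have no unique rotation
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop_degenerate("point configuration is rank-deficient (collinear points)")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cb - as.vector(R %*% ca)
  tf <- rigid_transform(R, t_)
  fitted <- apply_transform(A, tf)
  list(transform = tf,
       fit_rmsd = sqrt(sum(w * rowSums((fitted - B)^2))))
}

stop_degenerate <- function(msg) {
  rlang::abort(msg, class = "poseval_degenerate_alignment")
}

#' Least-squares plane fit
#'
#' @param coords n x 3 matrix, n >= 3.
#' @return list with `normal` (unit), `centroid`, and `max_residual`, the
#'   largest absolute out-of-plane distance in Angstrom.
#' @keywords internal
fit_plane <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  sv <- svd(X)
  normal <- sv$v[, 3]
  list(normal = unit(normal), centroid = ctr,
       max_residual = max(abs(X %*% normal)))
}

# NeRF-style internal-coordinate placement: position a new atom at given
# bond length from a, bond angle (deg) at a w.r.t. b, and dihedral (deg)
# w.r.t. the b-c reference.
place_atom <- function(a, b, c_, dist, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- unit(a - b)
  n <- unit(vcross(b - c_, bc))
  m <- vcross(n, bc)
  d <- c(-dist * cos(ang),
         dist * sin(ang) * cos(dih),
         dist * sin(ang) * sin(dih))
  a + d[1] * bc + d[2] * m + d[3] * n
}

# Build coordinates from a Z-matrix table: columns name, element,
# ref1/ref2/ref3 (indices), dist, angle, dihedral. First three rows use the
# degenerate conventions (origin; +x axis; xy-plane).
build_zmat <- function(z) {
  n <- nrow(z)
  xyz <- matrix(0, n, 3)
  if (n >= 2) xyz[2, ] <- c(z$dist[2], 0, 0)
  if (n >= 3) {
    # angle measured at ref1 between ref2 and the new atom; placed in xy-plane
    ang <- z$angle[3] * pi / 180
    a <- xyz[z$ref1[3], ]; b <- xyz[z$ref2[3], ]
    u <- unit(b - a)
    perp <- c(-u[2], u[1], 0)
    if (vnorm(perp) < 1e-9) perp <- c(0, 1, 0)
    xyz[3, ] <- a + z$dist[3] * (cos(ang) * u + sin(ang) * unit(perp))
  }
  if (n >= 4) {
    for (i in 4:n) {
      xyz[i, ] <- place_atom(xyz[z$ref1[i], ], xyz[z$ref2[i], ],
                             xyz[z$ref3[i], ], z$dist[i], z$angle[i],
                             z$dihedral[i])
    }
  }
  xyz
}

angle_deg <- function(a, b, c_) {
  u <- unit(a - b); v <- unit(c_ - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}
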