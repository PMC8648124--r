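# Rigid-body geometry: transforms, least-squares superposition, internal
# coordinate atom placement. All coordinates are in Angstrom; points are rows
# of n x 3 matrices.

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop("expected a finite 3-vector")
  x
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#'
#' @param u,v Numeric 3-vectors.
#' @return Angle in radians, in `[0, pi]`.
#' @export
vector_angle <- function(u, v) {
  cu <- unit(u); cv <- unit(v)
  acos(max(-1, min(1, sum(cu * cv))))
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Signed dihedral in radians, in `(-pi, pi]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- vec3(p2) - vec3(p1)
  b2 <- vec3(p3) - vec3(p2)
  b3 <- vec3(p4) - vec3(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame construction: given three reference
#' points `a`, `b`, `c`, returns the point `d` with bond length `|c-d|`,
#' bond angle `b-c-d` and torsion `a-b-c-d` as requested.
#'
#' @param a,b,c Reference points (3-vectors, Angstrom).
#' @param bond Bond length `c`--`d` in Angstrom.
#' @param angle Bond angle `b`--`c`--`d` in radians.
#' @param torsion Torsion `a`--`b`--`c`--`d` in radians.
#' @return The placed point as a 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  a <- vec3(a); b <- vec3(b); c <- vec3(c)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), -sin(angle) * sin(torsion))
  c(c + m %*% d2)
}

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 proper rotation matrix (determinant +1).
#' @param translation Numeric 3-vector (Angstrom).
#' @return An object of class `"RigidTransform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- vec3(translation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (determinant +1); reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.2f deg, translation %.3f A\n",
              ang, vnorm(x$translation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tf A [rigid_transform()].
#' @param coords A 3-vector or an n x 3 matrix of points.
#' @return Transformed coordinates with the same shape.
#' @export
transform_coords <- function(tf, coords) {
  stopifnot(inherits(tf, "RigidTransform"))
  if (is.null(dim(coords)))
    return(c(tf$rotation %*% vec3(coords)) + tf$translation)
  t(tf$rotation %*% t(coords) + tf$translation)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  c(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -c(rt %*% tf$translation))
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) via random unit quaternion. Uses the current RNG state.
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(c(q, 0)[1:4])
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform (proper rotation, no reflection) minimizing the
#' root mean squared deviation between `transform_coords(tf, mobile)` and
#' `target` under the given one-to-one correspondence of rows.
#'
#' @param mobile,target n x 3 coordinate matrices with corresponding rows,
#'   n >= 3, not all collinear.
#' @return A list with elements `transform` (a [rigid_transform()]) and
#'   `rmsd` (the minimized RMSD in Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(target))
    stop("mobile and target must have the same number of points")
  if (nrow(mobile) < 3L)
    stop("superposition requires at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  # collinearity: rank of centered point clouds must be >= 2 on one side
  if (max(svd(p)$d[2], svd(q)$d[2]) < 1e-8 * max(1, svd(p)$d[1]))
    stop("degenerate geometry: points are collinear")
  h <- crossprod(p, q)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tf <- rigid_transform(r, ct - c(r %*% cm))
  moved <- transform_coords(tf, mobile)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = tf, rmsd = rmsd)
}

#' Ideal C-beta position from backbone atoms
#'
#' Constructs the position a C-beta atom would occupy for an L-amino acid with
#' ideal tetrahedral geometry (bond CA-CB 1.521 A, angle N-CA-CB 110.4
#' degrees), given the backbone N, CA and C positions. Used for glycine and
#' for residues whose C-beta is missing; deterministic and SE(3)-equivariant.
#'
#' @param n,ca,c Backbone atom coordinates (3-vectors, Angstrom).
#' @return The ideal C-beta position as a 3-vector.
#' @export
ideal_cb <- function(n, ca, c) {
  place_atom(c, n, ca,
             bond = 1.521,
             angle = 110.4 * pi / 180,
             torsion = 122.55 * pi / 180)
}
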