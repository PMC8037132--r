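# Elementary geometry: centres of mass, gyration radii, dihedrals,
# quaternion algebra and Kabsch superposition.

#' Centre of mass
#'
#' @param coords n x 3 matrix, nm
#' @param masses per-bead masses (any consistent unit); equal by default
#' @return 3-vector, nm
#' @export
com <- function(coords, masses = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1) stop("need at least one bead")
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n)
  if (any(masses < 0)) stop("masses must be non-negative")
  m <- sum(masses)
  if (m <= 0) stop("total mass must be positive")
  drop(crossprod(masses, coords)) / m
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{COM}|^2 / \sum_i m_i}}.
#'
#' @inheritParams com
#' @return Rg in Angstrom (coordinates are taken in nm)
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- matrix(coords, ncol = 3)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  cm <- com(coords, masses)
  d2 <- rowSums(sweep(coords, 2, cm)^2)
  nm_to_ang(sqrt(sum(masses * d2) / sum(masses)))
}

#' End-to-end distance of a peptide frame
#'
#' Distance between the designated N-terminal site (`NT` of residue 1)
#' and C-terminal site (`CT` of the last residue).
#'
#' @param beads a peptide bead table (one frame)
#' @return distance in Angstrom
#' @export
end_to_end <- function(beads) {
  i_nt <- which(beads$name == "NT")[1]
  i_ct <- which(beads$name == "CT")
  i_ct <- i_ct[length(i_ct)]
  if (is.na(i_nt) || length(i_ct) == 0 || is.na(i_ct))
    stop("terminal sites NT/CT not found")
  p <- bead_coords(beads)
  nm_to_ang(sqrt(sum((p[i_nt, ] - p[i_ct, ])^2)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention via atan2 of the plane normals: trans is +/- pi,
#' cis is 0; mirroring the points negates the angle.
#'
#' @param p1,p2,p3,p4 3-vectors
#' @return angle in radians, in (-pi, pi]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("collinear points: dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- quaternions (w, x, y, z) ---------------------------------------------

#' Quaternion product q1 (x) q2
#' @param q1,q2 length-4 numeric vectors (w, x, y, z)
#' @return the composed quaternion
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]; w2 <- q2[1]; v2 <- q2[2:4]
  c(w1 * w2 - sum(v1 * v2),
    w1 * v2 + w2 * v1 + .cross3(v1, v2))
}

#' Quaternion from a rotation vector
#'
#' Axis = direction of `omega`, angle = |omega| (radians).
#' @param omega rotation vector, rad
#' @return unit quaternion
#' @export
quat_from_rotvec <- function(omega) {
  theta <- sqrt(sum(omega^2))
  if (theta < 1e-14) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * omega / theta)
}

#' Rotate points by a unit quaternion
#' @param q unit quaternion (w, x, y, z)
#' @param pts n x 3 matrix
#' @return rotated n x 3 matrix
#' @export
quat_rotate <- function(q, pts) {
  pts <- matrix(pts, ncol = 3)
  R <- quat_to_matrix(q)
  pts %*% t(R)
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion
#' @return 3 x 3 rotation matrix
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Random uniform unit quaternion
#' @return unit quaternion drawn uniformly over SO(3)
#' @export
quat_random <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

## ---- RMSD / superposition --------------------------------------------------

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE`, the optimal least-squares rigid-body fit
#' (Kabsch algorithm, proper rotation enforced) is applied before the
#' deviation is computed; without, the raw site-by-site RMSD is returned.
#'
#' @param frame_A,frame_B n x 3 coordinate matrices, nm
#' @param superpose logical
#' @return RMSD in Angstrom
#' @export
rmsd <- function(frame_A, frame_B, superpose = TRUE) {
  A <- matrix(frame_A, ncol = 3); B <- matrix(frame_B, ncol = 3)
  if (nrow(A) != nrow(B)) stop("frames have mismatched bead counts")
  if (superpose) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    R <- kabsch_rotation(A, B)
    B <- B %*% t(R)
  }
  nm_to_ang(sqrt(mean(rowSums((A - B)^2))))
}

#' Optimal rotation aligning B onto A (Kabsch)
#'
#' Both point sets must already be centred. Returns the proper rotation R
#' minimizing |A - B R^T|^2.
#'
#' @param A,B centred n x 3 matrices
#' @return 3 x 3 rotation matrix
#' @export
kabsch_rotation <- function(A, B) {
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}
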