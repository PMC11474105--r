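#' Backbone frames from N, CA, C coordinates
#'
#' Builds one rigid frame per residue by Gram-Schmidt orthogonalisation of the
#' local backbone geometry: the x-axis points along CA->C, the y-axis is the
#' component of CA->N orthogonal to it, and z completes a right-handed set.
#' The translation is the CA position. Frames are equivariant: building frames
#' from a rigidly transformed structure equals composing the transform with
#' the original frames.
#'
#' @param record an `fv_structure` with backbone atoms, or a list with `n x 3`
#'   matrices `N`, `CA`, `C`.
#' @return a `rigid` with one frame per residue.
#' @export
frames_from_backbone <- function(record) {
  if (inherits(record, "fv_structure")) {
    Nm <- atom_coords(record, "N"); CAm <- atom_coords(record, "CA")
    Cm <- atom_coords(record, "C")
  } else {
    Nm <- record$N; CAm <- record$CA; Cm <- record$C
  }
  n <- nrow(CAm)
  R <- array(0, c(3, 3, n))
  for (k in seq_len(n)) {
    v1 <- Cm[k, ] - CAm[k, ]
    v2 <- Nm[k, ] - CAm[k, ]
    n1 <- sqrt(sum(v1^2))
    if (!is.finite(n1) || n1 < 1e-8) stop("degenerate geometry at residue ", k)
    e1 <- v1 / n1
    u2 <- v2 - sum(v2 * e1) * e1
    n2 <- sqrt(sum(u2^2))
    if (!is.finite(n2) || n2 < 1e-8) {
      stop("degenerate geometry at residue ", k, ": N, CA, C are collinear")
    }
    e2 <- u2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    R[, , k] <- cbind(e1, e2, e3)
  }
  structure(list(R = R, t = CAm), class = "rigid")
}

#' Optimal superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation + translation minimising the (weighted) RMSD
#' between `mobile` and `target`, by SVD of the weighted covariance with the
#' usual determinant correction that excludes reflections.
#'
#' @param mobile,target `m x 3` matrices of corresponding points (m >= 3,
#'   not all collinear).
#' @param weights optional non-negative weights, one per point.
#' @return a list with `transform` (a single-frame `rigid` mapping mobile onto
#'   target) and `rmsd` (the minimised weighted RMSD, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) stop("point sets differ in size")
  m <- nrow(mobile)
  if (m < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0)) stop("invalid weights")
  W <- sum(weights)
  if (W <= 0) stop("weights sum to zero")
  w <- weights / W
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ct - as.vector(R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - B)^2)))
  list(transform = rigid(R, t), rmsd = rmsd)
}

#' Signed dihedral angle of four points
#'
#' Standard convention: cis (syn-periplanar) is 0, trans (anti-periplanar) is
#' pi; the result lies in (-pi, pi] and changes sign under mirror reflection.
#'
#' @param p1,p2,p3,p4 3-vectors (Angstrom).
#' @return angle in radians.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-16 || sum(b2^2) < 1e-16 || sum(b3^2) < 1e-16) {
    stop("degenerate geometry: coincident consecutive points")
  }
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("degenerate geometry: collinear points")
  }
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  # (-pi, pi]: fold the branch point -pi onto +pi
  if (ang <= -pi + 1e-15) ang <- pi
  ang
}

#' Place a point from internal coordinates (NERF)
#'
#' Natural-extension-reference-frame placement: given three previously placed
#' atoms `a-b-c`, returns the position `d` at the stated bond length from `c`,
#' bond angle `b-c-d`, and torsion `a-b-c-d`.
#'
#' @param a,b,c 3-vectors.
#' @param length bond length c-d (Angstrom).
#' @param angle bond angle b-c-d (radians).
#' @param torsion dihedral a-b-c-d (radians).
#' @return the 3-vector `d`.
#' @keywords internal
nerf_place <- function(a, b, c, length, angle, torsion) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate geometry: collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(angle),
          length * sin(angle) * cos(torsion),
          -length * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
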