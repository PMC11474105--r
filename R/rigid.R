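#' Rigid transforms (rotation + translation)
#'
#' A `rigid` object stores `n` rigid-body transforms as a `3 x 3 x n` array of
#' proper rotation matrices and an `n x 3` matrix of translations in Angstrom.
#' Rigids are the currency for per-residue backbone frames and for global
#' superpositions: applying a rigid maps local coordinates into global space
#' via `y = R x + t`.
#'
#' @param rotation a `3 x 3` matrix, or a `3 x 3 x n` array of rotation
#'   matrices. Each must be orthonormal with determinant +1 (tolerance 1e-6).
#' @param translation a 3-vector or an `n x 3` matrix of translations (Angstrom).
#' @return an object of class `rigid`.
#' @examples
#' r <- rigid_identity(1)
#' p <- matrix(rnorm(30), 10, 3)
#' all.equal(rigid_apply(r, p), p)
#' @export
rigid <- function(rotation, translation) {
  if (is.matrix(rotation)) rotation <- array(rotation, c(3, 3, 1))
  if (is.null(dim(translation))) translation <- matrix(translation, 1, 3)
  stopifnot(length(dim(rotation)) == 3L, dim(rotation)[1:2] == c(3L, 3L),
            ncol(translation) == 3L, dim(rotation)[3] == nrow(translation))
  for (k in seq_len(dim(rotation)[3])) {
    R <- rotation[, , k]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
      stop("invalid frame: rotation ", k,
           " is not a proper orthonormal rotation (det=+1) within 1e-6")
    }
  }
  structure(list(R = rotation, t = translation), class = "rigid")
}

#' @rdname rigid
#' @param n number of identity frames.
#' @export
rigid_identity <- function(n = 1L) {
  structure(list(R = array(diag(3), c(3, 3, n)),
                 t = matrix(0, n, 3)), class = "rigid")
}

#' @export
length.rigid <- function(x) dim(x$R)[3]

#' @export
print.rigid <- function(x, ...) {
  cat("<rigid> ", length(x), " frame(s)\n", sep = "")
  invisible(x)
}

#' @export
`[.rigid` <- function(x, i) {
  structure(list(R = x$R[, , i, drop = FALSE],
                 t = x$t[i, , drop = FALSE]), class = "rigid")
}

check_rigid <- function(a) {
  if (!inherits(a, "rigid")) stop("expected a 'rigid' object")
  # re-validate: objects may have been constructed internally
  for (k in seq_len(length(a))) {
    R <- a$R[, , k]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
      stop("invalid frame at index ", k)
    }
  }
  invisible(a)
}

#' Compose two rigid transforms
#'
#' `rigid_compose(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`: `(a o b)(x) = a(b(x))`. Both arguments must hold the same
#' number of frames (or one of them a single frame, which is recycled).
#'
#' @param a,b `rigid` objects.
#' @return a `rigid` object.
#' @export
rigid_compose <- function(a, b) {
  check_rigid(a); check_rigid(b)
  na <- length(a); nb <- length(b)
  n <- max(na, nb)
  if (!(na %in% c(1L, n)) || !(nb %in% c(1L, n))) {
    stop("frame counts are incompatible: ", na, " vs ", nb)
  }
  R <- array(0, c(3, 3, n)); t <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    Ra <- a$R[, , min(k, na)]; Rb <- b$R[, , min(k, nb)]
    ta <- a$t[min(k, na), ];   tb <- b$t[min(k, nb), ]
    R[, , k] <- Ra %*% Rb
    t[k, ] <- as.vector(Ra %*% tb) + ta
  }
  structure(list(R = R, t = t), class = "rigid")
}

#' Invert a rigid transform
#'
#' @param a a `rigid` object.
#' @return the inverse transform: `rigid_apply(rigid_invert(a), rigid_apply(a, x)) = x`.
#' @export
rigid_invert <- function(a) {
  check_rigid(a)
  n <- length(a)
  R <- array(0, c(3, 3, n)); t <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    Rt <- t(a$R[, , k])
    R[, , k] <- Rt
    t[k, ] <- -as.vector(Rt %*% a$t[k, ])
  }
  structure(list(R = R, t = t), class = "rigid")
}

#' Apply a rigid transform to points
#'
#' With a single frame, all rows of `points` are transformed by it. With `n`
#' frames and an `n x 3` point matrix, row `i` is transformed by frame `i`.
#'
#' @param a a `rigid` object.
#' @param points an `m x 3` matrix (a bare 3-vector is accepted).
#' @return a matrix of transformed points, same shape as `points`.
#' @export
rigid_apply <- function(a, points) {
  check_rigid(a)
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1, 3)
  stopifnot(ncol(points) == 3L)
  n <- length(a)
  if (n == 1L) {
    out <- points %*% t(a$R[, , 1]) +
      matrix(a$t[1, ], nrow(points), 3, byrow = TRUE)
  } else {
    if (nrow(points) != n) stop("need one point per frame (or a single frame)")
    out <- matrix(0, n, 3)
    for (k in seq_len(n)) out[k, ] <- as.vector(a$R[, , k] %*% points[k, ]) + a$t[k, ]
  }
  if (vec) out[1, ] else out
}

#' Rotation from a fixed-first-component quaternion
#'
#' Maps three unconstrained reals `(b, c, d)` to a rotation by normalising the
#' quaternion `(1, b, c, d)` and converting it to a matrix. This is the
#' parametrisation of the backbone update layer: the network emits `(b, c, d)`
#' and a translation per residue, and the zero vector maps to the identity.
#'
#' @param b,c,d numeric vectors (recycled to common length).
#' @param translation optional `n x 3` translation (defaults to zero).
#' @return a `rigid` object with one frame per element of `b`.
#' @export
quaternion_from_bcd <- function(b, c, d, translation = NULL) {
  n <- max(length(b), length(c), length(d))
  b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (is.null(translation)) translation <- matrix(0, n, 3)
  if (is.null(dim(translation))) translation <- matrix(translation, n, 3, byrow = TRUE)
  a <- 1
  s <- a^2 + b^2 + c^2 + d^2
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- (a^2 + b^2 - c^2 - d^2) / s
  R[1, 2, ] <- 2 * (b * c - a * d) / s
  R[1, 3, ] <- 2 * (b * d + a * c) / s
  R[2, 1, ] <- 2 * (b * c + a * d) / s
  R[2, 2, ] <- (a^2 - b^2 + c^2 - d^2) / s
  R[2, 3, ] <- 2 * (c * d - a * b) / s
  R[3, 1, ] <- 2 * (b * d - a * c) / s
  R[3, 2, ] <- 2 * (c * d + a * b) / s
  R[3, 3, ] <- (a^2 - b^2 - c^2 + d^2) / s
  structure(list(R = R, t = translation), class = "rigid")
}
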