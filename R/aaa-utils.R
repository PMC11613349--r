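# Low-level 3D vector helpers shared by the builder, torsion driver and scans.
# All angles at this level are in degrees unless a name says otherwise.

`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the half-open interval [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in degrees.
#' @keywords internal
wrap180 <- function(x) ((x + 180) %% 360) - 180

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector has no direction", call. = FALSE)
  a / n
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking from `b` to `c`, the angle is positive when
#' `d` is rotated clockwise relative to `a`.  Invariant under reversal of
#' the atom sequence.
#'
#' @param a,b,c,d numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees in [-180, 180).
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  wrap180(rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2))))
}

#' Bond angle a-b-c in degrees
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Place atom X bonded to `a` such that |X-a| = r, angle(X,a,b) = theta and
# dihedral(X,a,b,c) = tau (degrees).  Standard internal-coordinate (NeRF)
# construction.
place_atom <- function(a, b, c, r, theta, tau) {
  th <- deg2rad(theta); ta <- deg2rad(tau)
  e1 <- vunit(a - b)                      # b -> a
  n <- vunit(vcross(b - c, e1))
  e2 <- vcross(n, e1)
  a + r * (-cos(th) * e1 + sin(th) * (cos(ta) * e2 + sin(ta) * n))
}

# Rotate rows `idx` of coordinate matrix X about the axis through point `p`
# with unit direction `k` by `delta` degrees (right-hand rule about k).
rotate_about_axis <- function(X, idx, p, k, delta) {
  th <- deg2rad(delta)
  v <- sweep(X[idx, , drop = FALSE], 2L, p)
  kv <- drop(v %*% k)
  vpar <- outer(kv, k)
  vperp <- v - vpar
  w <- cbind(k[2L] * vperp[, 3L] - k[3L] * vperp[, 2L],
             k[3L] * vperp[, 1L] - k[1L] * vperp[, 3L],
             k[1L] * vperp[, 2L] - k[2L] * vperp[, 1L])
  X[idx, ] <- sweep(vpar + cos(th) * vperp + sin(th) * w, 2L, p, `+`)
  X
}

# Positions of atoms `idx` rotated about axis (p, k) for a whole vector of
# angles at once.  Returns an array (length(idx), 3, length(deltas)).
rotate_positions_multi <- function(X, idx, p, k, deltas) {
  th <- deg2rad(deltas)
  v <- sweep(X[idx, , drop = FALSE], 2L, p)
  kv <- drop(v %*% k)
  vpar <- outer(kv, k)
  vperp <- v - vpar
  w <- cbind(k[2L] * vperp[, 3L] - k[3L] * vperp[, 2L],
             k[3L] * vperp[, 1L] - k[1L] * vperp[, 3L],
             k[1L] * vperp[, 2L] - k[2L] * vperp[, 1L])
  m <- length(idx); n <- length(th)
  out <- array(0, dim = c(m, 3L, n))
  ct <- cos(th); st <- sin(th)
  for (d in 1:3) {
    out[, d, ] <- p[d] + vpar[, d] + outer(vperp[, d], ct) + outer(w[, d], st)
  }
  out
}
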