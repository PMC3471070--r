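# Vectorized eigendecomposition of many symmetric 3x3 tensors, used for the
# ground-truth tensors of the phantom and for the fitted diffusion tensors.

#' Eigenvalues of symmetric 3x3 tensors (vectorized)
#'
#' Trigonometric closed form; returns eigenvalues sorted descending.
#'
#' @param xx,yy,zz,xy,xz,yz numeric vectors of tensor components.
#' @return n x 3 matrix with columns lambda1 >= lambda2 >= lambda3.
#' @keywords internal
eigvals_sym3 <- function(xx, yy, zz, xy, xz, yz) {
  n <- length(xx)
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx[nz] - q[nz]) / p[nz]; byy <- (yy[nz] - q[nz]) / p[nz]
    bzz <- (zz[nz] - q[nz]) / p[nz]
    bxy <- xy[nz] / p[nz]; bxz <- xz[nz] / p[nz]; byz <- yz[nz] / p[nz]
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    l3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

# Unit eigenvector for a given eigenvalue of each symmetric 3x3 tensor, via
# the cross product of two rows of (A - lambda I); the most numerically
# independent row pair is chosen.  Degenerate (isotropic) tensors fall back
# to +x.  Returns an n x 3 matrix.
eigvec_sym3 <- function(xx, yy, zz, xy, xz, yz, lambda) {
  r1 <- cbind(xx - lambda, xy, xz)
  r2 <- cbind(xy, yy - lambda, yz)
  r3 <- cbind(xz, yz, zz - lambda)
  cr <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  c12 <- cr(r1, r2); c13 <- cr(r1, r3); c23 <- cr(r2, r3)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- pmax(n12, n13, n23)
  v <- c12
  use13 <- n13 == best; v[use13, ] <- c13[use13, , drop = FALSE]
  use23 <- n23 == best; v[use23, ] <- c23[use23, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  bad <- !is.finite(nrm) | nrm < 1e-30
  v[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
  nrm[bad] <- 1
  v / nrm
}
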