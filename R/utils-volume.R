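# Small 3D-volume helpers shared across modules.  All voxel coordinates are
# 0-based and the grid is axis-aligned with isotropic 1-unit voxels; a NIfTI
# affine only enters at the I/O boundary.

#' Voxel-center coordinate matrix for a grid
#'
#' @param dims integer vector of length 3.
#' @return an n-voxel x 3 matrix of 0-based voxel-center coordinates, in
#'   column-major (linear index) order.
#' @keywords internal
vox_coords <- function(dims) {
  stopifnot(length(dims) == 3L)
  cbind(
    rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
    rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  )
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that library code does not
#' disturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a base seed
#'
#' Deterministic, stays below 2^31 - 1.
#' @keywords internal
derive_seed <- function(base, ...) {
  ks <- c(base, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483629
  as.integer(s) + 1L
}

# shift an array by an integer offset, zero-filling
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      if (o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      if (-o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation with a 6- or 26-neighbourhood
#' @keywords internal
dilate_mask <- function(mask, connectivity = 6L) {
  m <- array(as.numeric(mask), dim(mask))
  offs <- neighbourhood_offsets(connectivity)
  acc <- m
  for (i in seq_len(nrow(offs))) acc <- acc + shift_array(m, offs[i, ])
  acc > 0
}

neighbourhood_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  dimnames(offs) <- NULL
  offs
}

#' 3x3x3 box smoothing of a volume (zero-padded borders, normalized weights)
#' @keywords internal
box_smooth <- function(a) {
  d <- dim(a)
  num <- array(0, d)
  den <- array(0, d)
  ones <- array(1, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(offs))) {
    num <- num + shift_array(a, offs[i, ])
    den <- den + shift_array(ones, offs[i, ])
  }
  num / den
}

#' Trilinear interpolation of a 3D volume at continuous 0-based points
#'
#' Points outside the grid are clamped to the boundary.
#' @param vol 3D array.
#' @param pts n x 3 matrix of 0-based coordinates.
#' @keywords internal
trilinear <- function(vol, pts) {
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- vol[idx(x0, y0, z0)];     v100 <- vol[idx(x0 + 1, y0, z0)]
  v010 <- vol[idx(x0, y0 + 1, z0)]; v110 <- vol[idx(x0 + 1, y0 + 1, z0)]
  v001 <- vol[idx(x0, y0, z0 + 1)]; v101 <- vol[idx(x0 + 1, y0, z0 + 1)]
  v011 <- vol[idx(x0, y0 + 1, z0 + 1)]; v111 <- vol[idx(x0 + 1, y0 + 1, z0 + 1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Connected components of a binary volume
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array of component labels (0 = background).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- neighbourhood_offsets(connectivity)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (cur - 1L) %/% (d[1] * d[2])
      r <- (cur - 1L) %% (d[1] * d[2])
      j <- r %/% d[1]
      i <- r %% d[1]
      ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- k + offs[, 3]
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      nidx <- 1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok])
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      lab[nidx] <- nxt
      queue <- c(queue, nidx)
    }
  }
  lab
}

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}.
#' @param a,b logical arrays of identical dimension.
#' @return scalar in [0, 1]; \code{NaN} when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
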