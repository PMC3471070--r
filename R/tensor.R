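# Diffusion tensor fitting by log-linear least squares, and FA/MD maps.

#' Scalar map container
#'
#' @param values 3D array; undefined voxels are NA (flagged, never silently
#'   zero).
#' @param kind "FA" or "dispersion" (dimensionless) or "MD" (mm^2/s).
#' @export
scalar_map <- function(values, kind = c("FA", "MD", "dispersion")) {
  kind <- match.arg(kind)
  structure(list(values = values, kind = kind,
                 units = if (kind == "MD") "mm^2/s" else "1"),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<scalar_map ", x$kind, "> ", paste(dim(x$values), collapse = "x"),
      " grid, defined ", length(v), " voxels, range [",
      format(min(v)), ", ", format(max(v)), "]\n", sep = "")
  invisible(x)
}

# design matrix of the log-linear tensor model:
# log S = -b g'Dg + log S0, unknowns (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz,logS0)
tensor_design <- function(scheme) {
  b <- scheme$bvals
  g <- t(scheme$bvecs)
  cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3], 1)
}

#' Fit the diffusion tensor voxelwise
#'
#' Log-linear least squares of \eqn{\log S = -b g' D g + \log S_0} per
#' masked voxel, with signals clamped at \code{1e-6 * S0} before the log.
#' Eigenvalues are sorted descending; negative eigenvalues are clamped to 0
#' and flagged.
#'
#' @param dwi a \code{dwi_volume} (>= 7 volumes: 6 non-collinear directions
#'   + 1 b=0).
#' @param mask logical 3D array (default: all voxels).
#' @return a \code{tensor_field}: list(dims, mask, idx, evals (n x 3),
#'   e1, e2 (n x 3 unit eigenvectors), md, neg_clamped, s0).
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  dims <- dim(dwi$signal)[1:3]
  nvol <- dim(dwi$signal)[4]
  if (nvol < 7L) stop("tensor fitting needs >= 7 volumes, got ", nvol,
                      call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask)
  X <- tensor_design(dwi$scheme)
  qx <- qr(X)
  if (qx$rank < 7L) {
    stop("rank-deficient tensor design (rank ", qx$rank, " < 7): the scheme ",
         "needs >= 6 non-collinear non-zero-b directions plus b=0",
         call. = FALSE)
  }
  sig <- matrix(dwi$signal, prod(dims), nvol)[idx, , drop = FALSE]
  b0 <- dwi$scheme$bvals == 0
  s0 <- rowMeans(sig[, b0, drop = FALSE])
  s0 <- pmax(s0, .Machine$double.eps)
  floor_ <- 1e-6 * s0
  logs <- log(pmax(sig, floor_))
  beta <- qr.coef(qx, t(logs))                       # 7 x n
  ev <- eigvals_sym3(beta[1, ], beta[2, ], beta[3, ],
                     beta[4, ], beta[5, ], beta[6, ])
  e1 <- eigvec_sym3(beta[1, ], beta[2, ], beta[3, ],
                    beta[4, ], beta[5, ], beta[6, ], ev[, 1])
  e2 <- eigvec_sym3(beta[1, ], beta[2, ], beta[3, ],
                    beta[4, ], beta[5, ], beta[6, ], ev[, 2])
  # enforce e2 orthogonal to e1 (degenerate eigenvalues give unstable e2)
  dp <- rowSums(e1 * e2)
  e2 <- e2 - e1 * dp
  n2 <- sqrt(rowSums(e2^2))
  bad <- n2 < 1e-6
  if (any(bad)) {
    # any perpendicular direction will do
    alt <- cbind(-e1[bad, 2], e1[bad, 1], rep(0, sum(bad)))
    altn <- sqrt(rowSums(alt^2))
    alt[altn < 1e-6, ] <- rep(c(0, 1, 0), each = sum(altn < 1e-6))
    e2[bad, ] <- alt / pmax(sqrt(rowSums(alt^2)), 1e-12)
    n2[bad] <- 1
  }
  e2 <- e2 / n2
  neg <- ev[, 3] < 0
  ev_cl <- pmax(ev, 0)
  structure(list(dims = dims, mask = mask, idx = idx, evals = ev_cl,
                 evals_raw = ev, e1 = e1, e2 = e2,
                 neg_clamped = neg, s0 = exp(beta[7, ])),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$dims, collapse = "x"), " grid, ",
      length(x$idx), " fitted voxels, ", sum(x$neg_clamped),
      " with clamped negative eigenvalues\n", sep = "")
  invisible(x)
}

#' FA and MD maps from a fitted tensor field
#'
#' \deqn{FA = \sqrt{3/2} \sqrt{\sum_i (\lambda_i - \bar\lambda)^2} /
#'   \sqrt{\sum_i \lambda_i^2}, \qquad MD = \bar\lambda.}
#' FA is flagged undefined (NA) where \eqn{\sum \lambda_i^2 = 0}.
#'
#' @param tensors a \code{tensor_field}.
#' @return list(fa = \code{\link{scalar_map}}, md = \code{\link{scalar_map}}).
#' @export
fa_md <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_field"))
  fa_vals <- fa_from_eigvals(tensors$evals)
  md_vals <- rowMeans(tensors$evals)
  fa <- array(NA_real_, tensors$dims)
  md <- array(NA_real_, tensors$dims)
  fa[tensors$idx] <- fa_vals
  md[tensors$idx] <- md_vals
  list(fa = scalar_map(fa, "FA"), md = scalar_map(md, "MD"))
}
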