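# Two-fiber ball-and-stick fitting with residual-bootstrap orientation
# samples (the tracking PDF), and the dyadic-tensor dispersion measure.

#' Orientation-sample container
#'
#' Per masked voxel and fiber population, a fixed number of sampled unit
#' directions with volume fractions -- the probability density the tracker
#' draws from.
#'
#' @param dims grid shape.
#' @param index integer 3D array mapping voxels to sample rows (NA outside
#'   the fitted mask).
#' @param v1,v2 sample direction arrays (n_rows x n_samples x 3).
#' @param f1,f2 sampled volume fractions (n_rows x n_samples).
#' @param has2 logical per row: second population supported (point-estimate
#'   fraction at least the support threshold).
#' @param point list of point estimates (v1, v2, f1, f2, d, s0, converged).
#' @param n_samples samples per voxel.
#' @param rng_seed seed used for the bootstrap.
#' @export
orientation_samples <- function(dims, index, v1, f1, v2 = NULL, f2 = NULL,
                                has2 = NULL, point = NULL, n_samples = dim(v1)[2],
                                rng_seed = NA_integer_) {
  nrows <- dim(v1)[1]
  if (is.null(v2)) v2 <- array(0, dim(v1))
  if (is.null(f2)) f2 <- array(0, dim(f1))
  if (is.null(has2)) has2 <- rep(FALSE, nrows)
  structure(list(dims = as.integer(dims), index = index, n_samples = n_samples,
                 v1 = v1, f1 = f1, v2 = v2, f2 = f2, has2 = has2,
                 point = point, rng_seed = rng_seed),
            class = "orientation_samples")
}

#' @export
print.orientation_samples <- function(x, ...) {
  cat("<orientation_samples> ", paste(x$dims, collapse = "x"), " grid, ",
      dim(x$v1)[1], " voxels x ", x$n_samples, " samples, ",
      sum(x$has2), " with a supported second fiber\n", sep = "")
  invisible(x)
}

#' Fit the ball-and-stick model with bootstrap orientation uncertainty
#'
#' Point estimates per masked voxel come from nonlinear least squares of the
#' ball-and-stick signal (stick directions and the shared diffusivity by
#' Nelder-Mead, compartment fractions profiled out by non-negative least
#' squares, initialized from the tensor fit with a crossing-aware second
#' start).  Orientation/fraction samples are generated by residual
#' bootstrap: the fit is repeated \code{n_samples} times on the fitted
#' signal plus resampled residuals.  The second fiber is used for tracking
#' only when its point-estimate fraction reaches \code{f2_threshold}
#' (dominant-fiber fallback).  Deterministic given \code{rng_seed}.
#'
#' @param dwi a \code{dwi_volume}.
#' @param mask logical 3D array of voxels to fit.
#' @param n_fibers 1 or 2 (default 2, the maximum considered per voxel).
#' @param n_samples bootstrap samples per voxel (>= 50).
#' @param rng_seed integer seed.
#' @param f2_threshold support threshold for the second fiber (default 0.05).
#' @param maxit_point,maxit_boot iteration caps for the point fit
#'   (Nelder-Mead + LM polish) and the bootstrap refits (warm-started
#'   Levenberg-Marquardt).
#' @return an \code{\link{orientation_samples}} object.  Voxels where the
#'   fit failed fall back to the tensor-derived direction and are flagged in
#'   \code{point$converged}.
#' @export
fit_ball_and_stick <- function(dwi, mask, n_fibers = 2L, n_samples = 50L,
                               rng_seed = 1L, f2_threshold = 0.05,
                               maxit_point = 250L, maxit_boot = 25L) {
  stopifnot(inherits(dwi, "dwi_volume"), n_fibers %in% 1:2, n_samples >= 50L)
  dims <- dim(dwi$signal)[1:3]
  stopifnot(identical(as.integer(dim(mask)), as.integer(dims)))
  tf <- fit_tensor(dwi, mask)
  idx <- tf$idx
  nmask <- length(idx)
  if (nmask == 0L) stop("empty fitting mask", call. = FALSE)
  sig <- matrix(dwi$signal, prod(dims), dim(dwi$signal)[4])[idx, , drop = FALSE]
  init_d <- pmin(pmax(tf$evals[, 1], 1e-5), 1e-2)
  fit <- cpp_fit_ball_stick(sig, dwi$scheme$bvals, dwi$scheme$bvecs,
                            tf$e1, tf$e2, init_d,
                            as.integer(n_fibers), as.integer(n_samples),
                            as.integer(rng_seed), as.integer(maxit_point),
                            as.integer(maxit_boot))
  index <- array(NA_integer_, dims)
  index[idx] <- seq_len(nmask)
  has2 <- n_fibers == 2L & fit$f2 >= f2_threshold
  orientation_samples(
    dims = dims, index = index,
    v1 = array(fit$boot_v1, c(nmask, n_samples, 3)), f1 = fit$boot_f1,
    v2 = array(fit$boot_v2, c(nmask, n_samples, 3)), f2 = fit$boot_f2,
    has2 = as.logical(has2),
    point = list(v1 = fit$v1, v2 = fit$v2, f1 = fit$f1, f2 = fit$f2,
                 d = fit$d, s0 = fit$s0, converged = fit$converged),
    n_samples = n_samples, rng_seed = rng_seed
  )
}

#' Noise-free orientation samples from phantom ground truth
#'
#' Builds a degenerate sample set (every sample equal to the true fiber
#' direction) for voxels carrying fibers; useful for exercising the tracker
#' independently of model fitting.
#'
#' @param field a \code{\link{fiber_field}}.
#' @param n_samples samples per voxel (replicated).
#' @param extra_mask optional logical array of additional voxels (e.g. seed
#'   spheres) to include with their -- possibly zero -- fractions.
#' @export
true_orientation_samples <- function(field, n_samples = 50L, extra_mask = NULL) {
  dims <- field$dims
  mask <- field$f1 > 0 | field$f2 > 0
  if (!is.null(extra_mask)) mask <- mask | extra_mask
  idx <- which(mask)
  nmask <- length(idx)
  nvox <- prod(dims)
  v1p <- cbind(field$v1[idx], field$v1[idx + nvox], field$v1[idx + 2 * nvox])
  v2p <- cbind(field$v2[idx], field$v2[idx + nvox], field$v2[idx + 2 * nvox])
  # degenerate voxels (no fiber) get +x so the sample set stays unit-norm
  deg <- rowSums(v1p^2) == 0
  v1p[deg, 1] <- 1
  deg2 <- rowSums(v2p^2) == 0
  v2p[deg2, 1] <- 1
  index <- array(NA_integer_, dims)
  index[idx] <- seq_len(nmask)
  rep_dirs <- function(vp) {
    out <- array(0, c(nmask, n_samples, 3))
    for (c in 1:3) out[, , c] <- matrix(vp[, c], nmask, n_samples)
    out
  }
  orientation_samples(
    dims = dims, index = index,
    v1 = rep_dirs(v1p), f1 = matrix(field$f1[idx], nmask, n_samples),
    v2 = rep_dirs(v2p), f2 = matrix(field$f2[idx], nmask, n_samples),
    has2 = field$f2[idx] >= 0.05,
    point = list(v1 = v1p, v2 = v2p, f1 = field$f1[idx], f2 = field$f2[idx],
                 d = field$d[idx], s0 = field$S0[idx],
                 converged = rep(TRUE, nmask)),
    n_samples = n_samples
  )
}

#' Orientation dispersion map
#'
#' Dispersion per voxel is \eqn{1 - \mu_1}, with \eqn{\mu_1} the principal
#' eigenvalue of the mean dyadic tensor \eqn{(1/N) \sum_s v_s v_s'} of the
#' direction samples: 0 for perfectly concentrated samples, 2/3 for a
#' uniform distribution on the sphere.
#'
#' @param samples an \code{\link{orientation_samples}} object.
#' @param fiber_index 1 or 2.
#' @return a \code{\link{scalar_map}} (kind "dispersion"); NA outside the
#'   fitted mask and where the requested fiber is unsupported.
#' @export
dispersion_map <- function(samples, fiber_index = 1L) {
  stopifnot(inherits(samples, "orientation_samples"), fiber_index %in% 1:2)
  v <- if (fiber_index == 1L) samples$v1 else samples$v2
  comp <- function(c) matrix(v[, , c], nrow = dim(v)[1])
  vx <- comp(1); vy <- comp(2); vz <- comp(3)
  txx <- rowMeans(vx^2); tyy <- rowMeans(vy^2); tzz <- rowMeans(vz^2)
  txy <- rowMeans(vx * vy); txz <- rowMeans(vx * vz); tyz <- rowMeans(vy * vz)
  mu1 <- eigvals_sym3(txx, tyy, tzz, txy, txz, tyz)[, 1]
  disp <- 1 - mu1
  if (fiber_index == 2L) disp[!samples$has2] <- NA_real_
  vol <- array(NA_real_, samples$dims)
  vol[!is.na(samples$index)] <- disp[samples$index[!is.na(samples$index)]]
  scalar_map(vol, "dispersion")
}
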