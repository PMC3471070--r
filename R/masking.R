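# Tract-center masking: a simplified TBSS-style white-matter skeleton
# (local FA maxima along the perpendicular-to-tract direction), used purely
# as a sampling mask, plus CSF/GM exclusion -- the three masking
# configurations: none, skeleton, skeleton+gm+csf.

# central-difference gradient and Hessian stacks of a 3D array
fa_derivatives <- function(a) {
  sh <- function(off) shift_array(a, off)
  gx <- (sh(c(-1, 0, 0)) - sh(c(1, 0, 0))) / 2
  gy <- (sh(c(0, -1, 0)) - sh(c(0, 1, 0))) / 2
  gz <- (sh(c(0, 0, -1)) - sh(c(0, 0, 1))) / 2
  hxx <- sh(c(-1, 0, 0)) - 2 * a + sh(c(1, 0, 0))
  hyy <- sh(c(0, -1, 0)) - 2 * a + sh(c(0, 1, 0))
  hzz <- sh(c(0, 0, -1)) - 2 * a + sh(c(0, 0, 1))
  hxy <- (sh(c(-1, -1, 0)) + sh(c(1, 1, 0)) - sh(c(-1, 1, 0)) - sh(c(1, -1, 0))) / 4
  hxz <- (sh(c(-1, 0, -1)) + sh(c(1, 0, 1)) - sh(c(-1, 0, 1)) - sh(c(1, 0, -1))) / 4
  hyz <- (sh(c(0, -1, -1)) + sh(c(0, 1, 1)) - sh(c(0, -1, 1)) - sh(c(0, 1, -1))) / 4
  list(gx = gx, gy = gy, gz = gz, hxx = hxx, hyy = hyy, hzz = hzz,
       hxy = hxy, hxz = hxz, hyz = hyz)
}

#' TBSS-style white-matter skeleton
#'
#' Keeps voxels with FA at or above \code{fa_floor} that are local FA maxima
#' along the perpendicular-to-tract search direction: the FA gradient where
#' it is informative, otherwise (ridge interiors, where the gradient
#' vanishes) the most concave principal direction of the local FA Hessian.
#' FA is compared against trilinear samples one voxel away on both sides.
#' The result is a thin sheet/curve set marking tract centers; it is used
#' only as a mask, never for projection.
#'
#' @param mean_fa cohort mean FA in the common grid (\code{scalar_map} or 3D
#'   array; NAs treated as 0).
#' @param fa_floor minimum FA (default 0.2, the TBSS convention).
#' @return logical 3D array; empty (with a warning) when no voxel reaches
#'   the floor.
#' @export
skeletonize <- function(mean_fa, fa_floor = 0.2) {
  fa <- if (inherits(mean_fa, "scalar_map")) mean_fa$values else mean_fa
  fa[is.na(fa)] <- 0
  dims <- dim(fa)
  cand <- which(fa >= fa_floor)
  out <- array(FALSE, dims)
  if (!length(cand)) {
    warning("all voxels below fa_floor = ", fa_floor, "; empty skeleton")
    return(out)
  }
  dv <- fa_derivatives(fa)
  g <- cbind(dv$gx[cand], dv$gy[cand], dv$gz[cand])
  gn <- sqrt(rowSums(g^2))
  use_hess <- gn < 1e-3
  n <- g / pmax(gn, 1e-12)
  if (any(use_hess)) {
    i <- cand[use_hess]
    ev <- eigvals_sym3(dv$hxx[i], dv$hyy[i], dv$hzz[i],
                       dv$hxy[i], dv$hxz[i], dv$hyz[i])
    vec <- eigvec_sym3(dv$hxx[i], dv$hyy[i], dv$hzz[i],
                       dv$hxy[i], dv$hxz[i], dv$hyz[i], ev[, 3])
    n[use_hess, ] <- vec
  }
  vc <- vox_coords(dims)[cand, , drop = FALSE]
  up <- trilinear(fa, vc + n)
  dn <- trilinear(fa, vc - n)
  keep <- fa[cand] >= up - 1e-9 & fa[cand] >= dn - 1e-9
  out[cand[keep]] <- TRUE
  out
}

#' Sampling mask for one tract under a masking configuration
#'
#' \itemize{
#'   \item \code{"none"}: the template mask itself;
#'   \item \code{"skeleton"}: template intersected with the skeleton;
#'   \item \code{"skeleton+gm+csf"}: template and skeleton, minus the CSF
#'     and grey-matter (seed/target ROI) masks.
#' }
#'
#' @param template a \code{tract_template}.
#' @param skeleton logical skeleton volume (required unless config "none").
#' @param csf,gm logical exclusion volumes (required for the full config).
#' @param config_label one of the three configurations.
#' @return a \code{sampling_mask}: list(mask, config_label, tract_id).
#' @export
make_sampling_mask <- function(template, skeleton = NULL, csf = NULL,
                               gm = NULL,
                               config_label = c("none", "skeleton",
                                                "skeleton+gm+csf")) {
  config_label <- match.arg(config_label)
  stopifnot(inherits(template, "tract_template"))
  mask <- template$mask
  if (config_label != "none") {
    stopifnot(!is.null(skeleton), identical(dim(skeleton), dim(mask)))
    mask <- mask & skeleton
  }
  if (config_label == "skeleton+gm+csf") {
    stopifnot(!is.null(csf), !is.null(gm))
    mask <- mask & !csf & !gm
  }
  if (!any(mask)) {
    stop("empty sampling mask for tract '", template$tract_id,
         "' under config '", config_label, "'", call. = FALSE)
  }
  structure(list(mask = mask, config_label = config_label,
                 tract_id = template$tract_id),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat("<sampling_mask '", x$tract_id, "', ", x$config_label, "> ",
      sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}
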