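# Synthetic diffusion phantom: curved anisotropic tract bundles in an
# isotropic background, imaged with a single-shell ball-and-stick forward
# model, Rician noise, per-subject spatial jitter (a stand-in for residual
# registration error) and graded injury with ground-truth masks.
#
# Conventions: axis-aligned grid, isotropic 1-unit voxels, identity affine,
# 0-based voxel coordinates throughout.

#' Curve specification for a tract bundle
#'
#' Control points are interpolated with a natural cubic spline against
#' chord-length parameterization and sampled densely; tangents come from
#' finite differences of the dense polyline.
#'
#' @param control_points k x 3 matrix of 0-based voxel coordinates (k >= 2).
#' @param radius tube radius in voxels (>= 1).
#' @param name tract identifier.
#' @return a \code{tract_curve}: list(points, tangents, radius, name) with
#'   \code{points} the dense polyline (m x 3) and \code{tangents} unit
#'   tangent vectors (m x 3).
#' @export
tract_curve <- function(control_points, radius, name = "tract") {
  cp <- as.matrix(control_points)
  stopifnot(ncol(cp) == 3L, nrow(cp) >= 2L, radius >= 1)
  seg <- sqrt(rowSums(diff(cp)^2))
  t0 <- c(0, cumsum(seg))
  m <- max(64L, ceiling(sum(seg) * 8))
  tt <- seq(0, sum(seg), length.out = m)
  pts <- sapply(1:3, function(j) {
    if (nrow(cp) == 2L) {
      cp[1, j] + (cp[2, j] - cp[1, j]) * tt / sum(seg)
    } else {
      stats::spline(t0, cp[, j], xout = tt, method = "natural")$y
    }
  })
  tang <- rbind(pts[2, ] - pts[1, ],
                (pts[3:m, ] - pts[1:(m - 2), ]) / 2,
                pts[m, ] - pts[m - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = pts, tangents = tang, radius = radius, name = name),
            class = "tract_curve")
}

#' Construct an empty (purely isotropic) fiber field
#'
#' @param dims grid shape (3 integers).
#' @param d isotropic diffusivity in mm^2/s (stored per voxel; default
#'   1.7e-3, the stick diffusivity of deep white matter).
#' @param S0 non-diffusion-weighted signal (arbitrary units, default 100).
#' @return a \code{fiber_field}: per-voxel volume fractions \code{f1},
#'   \code{f2}, unit directions \code{v1}, \code{v2} (x,y,z,3 arrays),
#'   diffusivity \code{d} and \code{S0}.
#' @export
fiber_field <- function(dims, d = 1.7e-3, S0 = 100) {
  stopifnot(length(dims) == 3L, d > 0)
  structure(list(
    dims = as.integer(dims),
    f1 = array(0, dims), f2 = array(0, dims),
    v1 = array(0, c(dims, 3)), v2 = array(0, c(dims, 3)),
    d = array(d, dims), S0 = array(S0, dims)
  ), class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat("<fiber_field> ", paste(x$dims, collapse = "x"), " grid, ",
      sum(x$f1 > 0), " anisotropic voxels\n", sep = "")
  invisible(x)
}

# minimum distance from every voxel center to a dense polyline, measured
# against the polyline *segments* (not just the vertices, so voxels at
# exactly the tube radius are classified correctly), with the index of the
# nearest segment's start point; chunked to bound memory
curve_distance <- function(dims, pts) {
  vc <- vox_coords(dims)
  n <- nrow(vc)
  best <- rep(Inf, n)
  arg <- rep(1L, n)
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]
    d <- pts[i + 1L, ] - p0
    len2 <- sum(d^2)
    if (len2 == 0) next
    t <- ((vc[, 1] - p0[1]) * d[1] + (vc[, 2] - p0[2]) * d[2] +
            (vc[, 3] - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (vc[, 1] - p0[1] - t * d[1])^2 + (vc[, 2] - p0[2] - t * d[2])^2 +
      (vc[, 3] - p0[3] - t * d[3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    arg[upd] <- i
  }
  list(dist = sqrt(best), nearest = arg)
}

#' Add a tract bundle to a fiber field
#'
#' Voxels within \code{curve$radius} of the curve receive a fiber population
#' tangent to the curve.  The anisotropic volume fraction falls off
#' parabolically towards the tube surface
#' (\code{f = fiber_fraction * (1 - 0.5 (r/R)^2)}), giving the radially
#' decaying FA profile of a real tract's partial-volume edge.  Where a voxel
#' already carries a population, the new one is stored as the second
#' population (crossing bundle); total fraction is capped at 1.
#'
#' @param field a \code{\link{fiber_field}} (default: new empty field).
#' @param curve a \code{\link{tract_curve}}; must lie inside the grid.
#' @param dims grid shape, used when \code{field} is NULL.
#' @param fiber_fraction peak anisotropic volume fraction (default 0.7).
#' @param profile \code{"parabolic"} (default) or \code{"flat"}.
#' @param d,S0 passed to \code{\link{fiber_field}} when creating a new field.
#' @return list(field = fiber_field, tract_mask = logical array).
#' @export
make_tract_field <- function(curve, dims = c(40L, 40L, 40L), field = NULL,
                             fiber_fraction = 0.7, profile = c("parabolic", "flat"),
                             d = 1.7e-3, S0 = 100) {
  profile <- match.arg(profile)
  if (is.null(field)) field <- fiber_field(dims, d = d, S0 = S0)
  dims <- field$dims
  pts <- curve$points
  if (any(pts < 0) || any(sweep(pts, 2, dims - 1, ">"))) {
    stop("geometry error: curve exits the grid (extent ",
         paste(dims, collapse = "x"), ")", call. = FALSE)
  }
  cd <- curve_distance(dims, pts)
  inside <- cd$dist <= curve$radius
  frac <- if (profile == "parabolic") {
    fiber_fraction * (1 - 0.5 * (cd$dist / curve$radius)^2)
  } else {
    rep(fiber_fraction, length(cd$dist))
  }
  tang <- curve$tangents[cd$nearest, , drop = FALSE]
  idx <- which(inside)
  occupied <- field$f1[idx] > 0
  i1 <- idx[!occupied]
  field <- set_population(field, i1, pmin(frac[i1], 1),
                          tang[i1, , drop = FALSE], 1L)
  i2 <- idx[occupied]
  if (length(i2)) {
    cap <- pmax(0, 1 - field$f1[i2])
    field <- set_population(field, i2, pmin(frac[i2], cap),
                            tang[i2, , drop = FALSE], 2L)
  }
  mask <- array(FALSE, dims)
  mask[idx] <- TRUE
  list(field = field, tract_mask = mask)
}

# assign fraction/direction for population slot (1 or 2) at linear indices
set_population <- function(field, lin_idx, frac, dirs, slot) {
  if (!length(lin_idx)) return(field)
  nvox <- prod(field$dims)
  fkey <- if (slot == 1L) "f1" else "f2"
  vkey <- if (slot == 1L) "v1" else "v2"
  fa <- field[[fkey]]; fa[lin_idx] <- pmin(frac, 1)
  field[[fkey]] <- fa
  va <- field[[vkey]]
  for (k in 1:3) va[lin_idx + (k - 1) * nvox] <- dirs[, k]
  field[[vkey]] <- va
  field
}

# per-voxel ground-truth diffusion tensor of the compartment mixture:
# D = d * [(1 - f1 - f2) I + f1 v1 v1' + f2 v2 v2']
field_tensor <- function(field) {
  nvox <- prod(field$dims)
  f1 <- as.numeric(field$f1); f2 <- as.numeric(field$f2)
  d <- as.numeric(field$d)
  v1 <- matrix(field$v1, nvox, 3); v2 <- matrix(field$v2, nvox, 3)
  iso <- 1 - f1 - f2
  list(
    xx = d * (iso + f1 * v1[, 1]^2 + f2 * v2[, 1]^2),
    yy = d * (iso + f1 * v1[, 2]^2 + f2 * v2[, 2]^2),
    zz = d * (iso + f1 * v1[, 3]^2 + f2 * v2[, 3]^2),
    xy = d * (f1 * v1[, 1] * v1[, 2] + f2 * v2[, 1] * v2[, 2]),
    xz = d * (f1 * v1[, 1] * v1[, 3] + f2 * v2[, 1] * v2[, 3]),
    yz = d * (f1 * v1[, 2] * v1[, 3] + f2 * v2[, 2] * v2[, 3])
  )
}

fa_from_eigvals <- function(ev) {
  mn <- rowMeans(ev)
  num <- (ev[, 1] - mn)^2 + (ev[, 2] - mn)^2 + (ev[, 3] - mn)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- NA_real_
  pmin(fa, 1)
}

#' Ground-truth FA and MD volumes of a fiber field
#'
#' Evaluates the closed-form tensor of the mixed ball/stick compartments and
#' returns its fractional anisotropy and mean diffusivity per voxel.
#'
#' @param field a \code{\link{fiber_field}}.
#' @return list(fa = 3D array, md = 3D array in mm^2/s).
#' @export
field_truth_maps <- function(field) {
  tc <- field_tensor(field)
  ev <- eigvals_sym3(tc$xx, tc$yy, tc$zz, tc$xy, tc$xz, tc$yz)
  list(fa = array(fa_from_eigvals(ev), field$dims),
       md = array(rowMeans(ev), field$dims))
}

#' Phantom ground truth container
#' @param tract_masks named list of logical arrays (one per tract).
#' @param damage_mask logical array (all-FALSE when undamaged).
#' @param field fiber field from which true FA/MD are evaluated.
#' @param severity damage severity in [0, 1].
#' @return a \code{phantom_truth} list with tract_masks, damage_mask,
#'   true_fa, true_md and damage_severity.
#' @export
phantom_truth <- function(tract_masks, damage_mask, field, severity = 0) {
  tm <- field_truth_maps(field)
  structure(list(tract_masks = tract_masks, damage_mask = damage_mask,
                 true_fa = tm$fa, true_md = tm$md,
                 damage_severity = severity),
            class = "phantom_truth")
}

#' Inject graded damage into a fiber field
#'
#' Within \code{region}, the anisotropic volume fractions are scaled by
#' \code{(1 - severity)} and the isotropic diffusivity is elevated by the
#' fixed factor \code{(1 + severity)}, so true FA decreases and true MD
#' increases monotonically with severity (the diffusion signature of
#' traumatic axonal injury).  \code{severity = 1} leaves the region purely
#' isotropic.
#'
#' When \code{rng_seed} is given, damage additionally disorders the fiber
#' orientations: each damaged voxel's stick directions are blended with an
#' independent random unit vector with weight \code{severity} and
#' renormalized.  Per-voxel rotations leave the closed-form true FA/MD
#' untouched (they are rotation invariant), but the loss of voxel-to-voxel
#' coherence is what actually disrupts streamline propagation through the
#' lesion -- axonal injury misaligns fibers, it does not merely dilute
#' them.  Deterministic given the seed.
#'
#' @param field a \code{\link{fiber_field}}.
#' @param truth a \code{\link{phantom_truth}} to update (or NULL).
#' @param severity scalar in [0, 1].
#' @param region logical array, same grid as the field.
#' @param rng_seed integer seed for the orientation-incoherence draw; NULL
#'   (default) keeps directions coherent (pure compartment mixing).
#' @return list(field, truth) with truth's damage mask/severity and true
#'   FA/MD refreshed.
#' @export
inject_damage <- function(field, truth, severity, region, rng_seed = NULL) {
  stopifnot(severity >= 0, severity <= 1)
  if (!identical(dim(region), dim(field$f1))) {
    stop("damage region grid ", paste(dim(region), collapse = "x"),
         " does not match field grid ", paste(field$dims, collapse = "x"),
         call. = FALSE)
  }
  idx <- which(region)
  field$f1[idx] <- field$f1[idx] * (1 - severity)
  field$f2[idx] <- field$f2[idx] * (1 - severity)
  field$d[idx] <- field$d[idx] * (1 + severity)
  if (!is.null(rng_seed) && severity > 0 && length(idx)) {
    nvox <- prod(field$dims)
    perturb <- function(varr, seed) {
      v <- cbind(varr[idx], varr[idx + nvox], varr[idx + 2 * nvox])
      keep <- rowSums(v^2) > 0
      if (!any(keep)) return(varr)
      u <- with_seed(seed, matrix(rnorm(3 * sum(keep)), ncol = 3))
      u <- u / sqrt(rowSums(u^2))
      w <- (1 - severity) * v[keep, , drop = FALSE] + severity * u
      nw <- sqrt(rowSums(w^2))
      small <- nw < 1e-6                  # near-cancellation: keep random dir
      w[small, ] <- u[small, , drop = FALSE]
      w <- w / pmax(sqrt(rowSums(w^2)), 1e-12)
      ii <- idx[keep]
      for (k in 1:3) varr[ii + (k - 1) * nvox] <- w[, k]
      varr
    }
    field$v1 <- perturb(field$v1, derive_seed(rng_seed, 1L))
    field$v2 <- perturb(field$v2, derive_seed(rng_seed, 2L))
  }
  if (!is.null(truth)) {
    tm <- field_truth_maps(field)
    truth$true_fa <- tm$fa
    truth$true_md <- tm$md
    truth$damage_mask <- array(as.logical(region), field$dims)
    truth$damage_severity <- severity
  }
  list(field = field, truth = truth)
}

#' Simulate a diffusion-weighted acquisition of a fiber field
#'
#' Noiseless ball-and-stick signal per voxel and volume:
#' \deqn{S = S0 [(1 - \sum f_j) e^{-b d} + \sum_j f_j e^{-b d (g \cdot v_j)^2}]}
#' With \code{model = "tensor"} the mono-exponential signal of the
#' closed-form compartment tensor is generated instead (\eqn{S = S0
#' e^{-b g' D g}}); this is the signal a diffusion-tensor fit inverts
#' exactly, used for model-recovery validation.  Rician noise is the
#' magnitude of a complex Gaussian perturbation with standard deviation
#' \code{noise_sigma} (in S0 units; SNR = S0 / sigma).
#'
#' @param field a \code{\link{fiber_field}}.
#' @param scheme an \code{\link{acq_scheme}}.
#' @param noise_sigma Rician sigma (>= 0, same units as S0).
#' @param rng_seed integer; required when noise_sigma > 0.
#' @param model \code{"ball_and_stick"} (default) or \code{"tensor"}.
#' @return a \code{dwi_volume}: list(signal = 4D array, scheme, voxel_size).
#' @export
simulate_dwi <- function(field, scheme, noise_sigma = 0, rng_seed = NULL,
                         model = c("ball_and_stick", "tensor")) {
  model <- match.arg(model)
  stopifnot(inherits(scheme, "acq_scheme"), noise_sigma >= 0)
  dims <- field$dims
  nvox <- prod(dims)
  nvol <- n_volumes(scheme)
  S0 <- as.numeric(field$S0)
  d <- as.numeric(field$d)
  sig <- matrix(0, nvox, nvol)
  if (model == "ball_and_stick") {
    f1 <- as.numeric(field$f1); f2 <- as.numeric(field$f2)
    v1 <- matrix(field$v1, nvox, 3); v2 <- matrix(field$v2, nvox, 3)
    iso <- 1 - f1 - f2
    for (k in seq_len(nvol)) {
      b <- scheme$bvals[k]; g <- scheme$bvecs[, k]
      e_iso <- exp(-b * d)
      c1 <- (v1 %*% g)[, 1]; c2 <- (v2 %*% g)[, 1]
      sig[, k] <- S0 * (iso * e_iso + f1 * exp(-b * d * c1^2) +
                          f2 * exp(-b * d * c2^2))
    }
  } else {
    tc <- field_tensor(field)
    for (k in seq_len(nvol)) {
      b <- scheme$bvals[k]; g <- scheme$bvecs[, k]
      quad <- tc$xx * g[1]^2 + tc$yy * g[2]^2 + tc$zz * g[3]^2 +
        2 * (tc$xy * g[1] * g[2] + tc$xz * g[1] * g[3] + tc$yz * g[2] * g[3])
      sig[, k] <- S0 * exp(-b * quad)
    }
  }
  if (noise_sigma > 0) {
    if (is.null(rng_seed)) stop("rng_seed required when noise_sigma > 0",
                                call. = FALSE)
    sig <- with_seed(rng_seed, {
      n1 <- matrix(rnorm(nvox * nvol, sd = noise_sigma), nvox, nvol)
      n2 <- matrix(rnorm(nvox * nvol, sd = noise_sigma), nvox, nvol)
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  structure(list(signal = array(sig, c(dims, nvol)), scheme = scheme,
                 voxel_size = c(1, 1, 1)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_volume> ", paste(d[1:3], collapse = "x"), " grid, ", d[4],
      " volumes\n", sep = "")
  invisible(x)
}

#' Smooth band-limited displacement field
#'
#' Gaussian displacements on a coarse control grid, trilinearly upsampled to
#' the full grid and rescaled so the maximum absolute component equals
#' \code{jitter_voxels}.  Stands in for residual misregistration after
#' nonlinear normalization.
#'
#' @param dims grid shape.
#' @param jitter_voxels max-norm bound in voxels (>= 0; 0 gives a zero field).
#' @param rng_seed integer seed.
#' @param n_coarse control points per axis (default 4).
#' @return 4D array (dims x 3) of per-voxel displacements.
#' @export
jitter_field <- function(dims, jitter_voxels, rng_seed, n_coarse = 4L) {
  stopifnot(jitter_voxels >= 0)
  disp <- array(0, c(dims, 3))
  if (jitter_voxels == 0) return(disp)
  coarse <- with_seed(rng_seed, array(rnorm(n_coarse^3 * 3), c(rep(n_coarse, 3), 3)))
  vc <- vox_coords(dims)
  # map full-grid coords into coarse-grid coords
  sc <- (n_coarse - 1) / (dims - 1)
  pts <- sweep(vc, 2, sc, "*")
  for (k in 1:3) {
    disp[, , , k] <- array(trilinear(coarse[, , , k], pts), dims)
  }
  mx <- max(abs(disp))
  if (mx > 0) disp <- disp * (jitter_voxels / mx)
  disp
}

#' Nearest-neighbour resampling of a volume through a displacement field
#'
#' \code{out[x] = vol[round(x + disp[x])]}; samples falling outside the grid
#' give \code{fill}.
#'
#' @param vol 3D array.
#' @param disp 4D displacement array (dims x 3).
#' @param fill value for out-of-grid samples (default 0).
#' @export
nn_resample <- function(vol, disp, fill = 0) {
  dims <- dim(vol)
  if (!identical(as.integer(dim(disp)), as.integer(c(dims, 3L)))) {
    stop("displacement grid ", paste(dim(disp), collapse = "x"),
         " does not match volume grid ", paste(dims, collapse = "x"),
         call. = FALSE)
  }
  vc <- vox_coords(dims)
  src <- round(vc + matrix(disp, prod(dims), 3))
  ok <- src[, 1] >= 0 & src[, 1] < dims[1] &
    src[, 2] >= 0 & src[, 2] < dims[2] &
    src[, 3] >= 0 & src[, 3] < dims[3]
  out <- rep(fill, prod(dims))
  lin <- 1 + src[ok, 1] + dims[1] * (src[ok, 2] + dims[2] * src[ok, 3])
  out[ok] <- vol[lin]
  array(out, dims)
}

# warp every per-voxel array of a field/mask set into subject space:
# subject(x) = base(round(x - u(x)))
warp_field <- function(field, disp) {
  pull <- -disp
  out <- field
  out$f1 <- nn_resample(field$f1, pull)
  out$f2 <- nn_resample(field$f2, pull)
  out$d <- nn_resample(field$d, pull, fill = field$d[1])
  out$S0 <- nn_resample(field$S0, pull, fill = field$S0[1])
  for (k in 1:3) {
    out$v1[, , , k] <- nn_resample(field$v1[, , , k], pull)
    out$v2[, , , k] <- nn_resample(field$v2[, , , k], pull)
  }
  out
}

warp_mask <- function(mask, disp) {
  nn_resample(array(as.numeric(mask), dim(mask)), -disp) > 0.5
}

sphere_mask <- function(dims, center, radius) {
  vc <- vox_coords(dims)
  d2 <- (vc[, 1] - center[1])^2 + (vc[, 2] - center[2])^2 +
    (vc[, 3] - center[3])^2
  array(d2 <= radius^2, dims)
}

#' Default two-bundle phantom geometry
#'
#' Two mirrored quarter-circle arcs (left/right hemisphere analogues) in the
#' x-z plane of a cubic grid, an exclusion slab between them (midline
#' analogue), a CSF rim around each tube, and spherical seed/target regions
#' at the arc ends.  Focal damage regions sit at each arc midpoint.
#'
#' @param dims grid shape (default 40^3); all geometry scales with the
#'   smallest grid extent, so scaled-down grids stay valid.
#' @param radius tube radius in voxels (default ~7.5% of the grid, 3 at
#'   40^3).
#' @param n_tracts 1 or 2 (default 2: left/right hemisphere analogues with
#'   a midline exclusion slab between them).
#' @return list of per-tract geometry (curve, seed/target centers, damage
#'   center) plus the exclusion slab definition.
#' @export
default_geometry <- function(dims = c(40L, 40L, 40L),
                             radius = max(2, round(0.075 * min(dims))),
                             n_tracts = 2L) {
  stopifnot(n_tracts %in% 1:2)
  n <- min(dims) - 1
  c1 <- 0.2 * n
  R <- 0.55 * n
  arc <- function(y, name) {
    th <- seq(0, pi / 2, length.out = 9)
    cp <- cbind(c1 + R * cos(th), y, c1 + R * sin(th))
    # the lesion center sits on the tube surface at the arc midpoint
    # (offset radially outward): small lesions damage a crescent of the
    # cross-section that streamlines can deflect around, the mechanism
    # behind individual tractography's damage underestimation
    out45 <- c(cos(pi / 4), 0, sin(pi / 4))
    list(curve = tract_curve(cp, radius, name = name),
         seed_center = cp[1, ], target_center = cp[9, ],
         damage_center = cp[5, ] + radius * out45)
  }
  ys <- if (n_tracts == 2L) round(c(1 / 3, 0.692) * n) else round(0.5 * n)
  tracts <- lapply(seq_len(n_tracts), function(i) {
    arc(ys[i], paste0("tract", i))
  })
  names(tracts) <- vapply(tracts, function(t) t$curve$name, "")
  excl_y <- if (n_tracts == 2L) {
    round(c(0.475, 0.525) * n)
  } else {
    round(c(0.875, 0.925) * n)
  }
  list(tracts = tracts, dims = as.integer(dims),
       exclusion_y = excl_y, roi_radius = 2.5, damage_radius = radius)
}

# build base field, masks and ROIs for a geometry set
build_base_phantom <- function(geometry, fiber_fraction = 0.7, d = 1.7e-3,
                               S0 = 100) {
  dims <- geometry$dims
  field <- fiber_field(dims, d = d, S0 = S0)
  tract_masks <- list()
  for (tr in geometry$tracts) {
    res <- make_tract_field(tr$curve, field = field,
                            fiber_fraction = fiber_fraction)
    field <- res$field
    tract_masks[[tr$curve$name]] <- res$tract_mask
  }
  all_tract <- Reduce(`|`, tract_masks)
  # CSF rim: shell one voxel thick around each tube
  rim <- dilate_mask(dilate_mask(all_tract, 6L), 6L) & !all_tract
  exclusion <- array(FALSE, dims)
  ey <- geometry$exclusion_y
  exclusion[, (ey[1] + 1):(ey[2] + 1), ] <- TRUE
  rois <- lapply(geometry$tracts, function(tr) {
    seed <- sphere_mask(dims, tr$seed_center, geometry$roi_radius)
    target <- sphere_mask(dims, tr$target_center, geometry$roi_radius)
    list(seed = seed, target = target)
  })
  gm <- Reduce(`|`, lapply(rois, function(r) r$seed | r$target))
  damage_regions <- lapply(geometry$tracts, function(tr) {
    sphere_mask(dims, tr$damage_center, geometry$damage_radius) & all_tract
  })
  list(field = field, tract_masks = tract_masks, csf = rim,
       exclusion = exclusion, rois = rois, gm = gm,
       damage_regions = damage_regions)
}

#' Cohort specification for the phantom generator
#'
#' Defaults are the stated desk-scale world: 10 template controls, 8
#' patients with graded severities 0.1-0.8, 32-direction b=1000 scheme + 4
#' b=0, SNR 20 (sigma = S0/20), jitter bounded at 1 voxel.
#'
#' @param n_controls template controls (>= 2).
#' @param n_patients number of patients.
#' @param n_holdout_controls additional controls not used for the template.
#' @param damage_severities one scalar in [0, 1] per patient.
#' @param jitter_voxels max-norm bound (voxels) of the total per-subject
#'   displacement.
#' @param residual_fraction fraction of the jitter bound that registration
#'   does NOT recover (default 0.5): the subject warp is the sum of a
#'   recoverable field (whose known inverse is used to resample into the
#'   common grid) and an independent residual field bounded by
#'   \code{residual_fraction * jitter_voxels} that persists in common
#'   space -- the misregistration that skeleton/CSF masking is meant to
#'   absorb.
#' @param noise_sigma Rician sigma in S0 units.
#' @param rng_seed integer master seed.
#' @param damage_mode \code{"focal"} (severity-scaled ball at the tract
#'   midpoint surface) or \code{"diffuse"} (the whole tract).
#' @export
cohort_spec <- function(n_controls = 10L, n_patients = 8L,
                        n_holdout_controls = 0L,
                        damage_severities = seq(0.1, 0.8, by = 0.1),
                        jitter_voxels = 1, residual_fraction = 0.5,
                        noise_sigma = 5, rng_seed = 42L,
                        damage_mode = c("focal", "diffuse")) {
  damage_mode <- match.arg(damage_mode)
  stopifnot(residual_fraction >= 0, residual_fraction <= 1)
  if (n_controls < 2L) stop("n_controls must be >= 2", call. = FALSE)
  if (length(damage_severities) != n_patients) {
    stop("need one damage severity per patient (", n_patients, "), got ",
         length(damage_severities), call. = FALSE)
  }
  stopifnot(all(damage_severities >= 0 & damage_severities <= 1),
            jitter_voxels >= 0, noise_sigma >= 0)
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 n_holdout_controls = as.integer(n_holdout_controls),
                 damage_severities = as.numeric(damage_severities),
                 jitter_voxels = jitter_voxels,
                 residual_fraction = residual_fraction,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed), damage_mode = damage_mode),
            class = "cohort_spec")
}

#' Generate a synthetic multi-subject cohort
#'
#' Each subject is the base geometry warped by a smooth random displacement
#' bounded by \code{jitter_voxels}; patients additionally receive
#' \code{\link{inject_damage}} at their listed severity (applied to both
#' bundles).  Fully reproducible from \code{rng_seed}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param geometry a geometry set from \code{\link{default_geometry}}.
#' @param scheme an \code{\link{acq_scheme}} (default
#'   \code{make_scheme()}).
#' @return a \code{phantom_cohort}: list(subjects, geometry, scheme, spec,
#'   base).  Each subject carries id, role ("control", "holdout" or
#'   "patient"), severity, dwi, truth, rois (per tract seed/target plus
#'   shared exclusion/csf/gm) and the jitter displacement \code{disp}.
#' @export
make_cohort <- function(spec, geometry = default_geometry(),
                        scheme = make_scheme()) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- build_base_phantom(geometry)
  roles <- c(rep("control", spec$n_controls),
             rep("holdout", spec$n_holdout_controls),
             rep("patient", spec$n_patients))
  sev <- c(rep(0, spec$n_controls + spec$n_holdout_controls),
           spec$damage_severities)
  subjects <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    sseed <- derive_seed(spec$rng_seed, i)
    resid_bound <- spec$residual_fraction * spec$jitter_voxels
    reg_bound <- spec$jitter_voxels - resid_bound
    u_reg <- jitter_field(geometry$dims, reg_bound,
                          rng_seed = derive_seed(sseed, 1L))
    u_res <- jitter_field(geometry$dims, resid_bound,
                          rng_seed = derive_seed(sseed, 6L))
    disp_total <- u_reg + u_res
    fld <- if (spec$jitter_voxels > 0) warp_field(base$field, disp_total) else base$field
    wmask <- function(m) if (spec$jitter_voxels > 0) warp_mask(m, disp_total) else m
    tract_masks <- lapply(base$tract_masks, wmask)
    damage_mask <- array(FALSE, geometry$dims)
    if (roles[i] == "patient" && sev[i] > 0) {
      region <- if (spec$damage_mode == "focal") {
        # the lesion ball sits on the tube surface and its radius grows as
        # damage_radius * (1 + 0.6 severity): extent as well as intensity
        # scale with the severity grade (what drives graded abnormal-voxel
        # percentages), while an intact corridor of >= 1.2 voxels always
        # survives on the far side of the tube, which is what lets
        # streamlines deflect around the lesion instead of every survivor
        # being forced through it
        r_s <- geometry$damage_radius * (1 + 0.6 * sev[i])
        all_tract <- Reduce(`|`, base$tract_masks)
        ball <- Reduce(`|`, lapply(geometry$tracts, function(tr) {
          sphere_mask(geometry$dims, tr$damage_center, r_s)
        }))
        wmask(ball & all_tract)
      } else {
        Reduce(`|`, tract_masks)
      }
      dmg <- inject_damage(fld, NULL, sev[i], region,
                           rng_seed = derive_seed(sseed, 5L))
      fld <- dmg$field
      damage_mask <- region
    }
    truth <- phantom_truth(tract_masks, damage_mask, fld, sev[i])
    dwi <- simulate_dwi(fld, scheme, noise_sigma = spec$noise_sigma,
                        rng_seed = derive_seed(sseed, 2L))
    rois <- lapply(base$rois, function(r) {
      list(seed = wmask(r$seed), target = wmask(r$target))
    })
    subjects[[i]] <- list(
      id = sprintf("%s%02d", substr(roles[i], 1, 1), i),
      role = roles[i], severity = sev[i], dwi = dwi, truth = truth,
      rois = rois, exclusion = wmask(base$exclusion),
      csf = wmask(base$csf), gm = wmask(base$gm),
      disp = u_reg, disp_total = disp_total
    )
  }
  structure(list(subjects = subjects, geometry = geometry, scheme = scheme,
                 spec = spec, base = base),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  roles <- vapply(x$subjects, `[[`, "", "role")
  cat("<phantom_cohort> ", sum(roles == "control"), " controls, ",
      sum(roles == "holdout"), " held-out controls, ",
      sum(roles == "patient"), " patients on ",
      paste(x$geometry$dims, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Write one cohort subject to disk
#'
#' Emits NIfTI volumes (DWI, truth masks), FSL bval/bvec tables and is used
#' by the pipeline's manifest writer.
#' @param subject one element of a cohort's \code{subjects} list.
#' @param scheme the cohort's acquisition scheme.
#' @param dir output directory (created).
#' @return invisibly, the vector of files written.
#' @export
write_subject <- function(subject, scheme, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    dwi = file.path(dir, "dwi.nii.gz"),
    bval = file.path(dir, "dwi.bval"),
    bvec = file.path(dir, "dwi.bvec"),
    damage = file.path(dir, "truth_damage.nii.gz")
  )
  write_nifti(subject$dwi$signal, paths["dwi"])
  write_bvalbvec(scheme, paths["bval"], paths["bvec"])
  write_nifti(subject$truth$damage_mask, paths["damage"])
  for (tn in names(subject$truth$tract_masks)) {
    p <- file.path(dir, paste0("truth_", tn, ".nii.gz"))
    write_nifti(subject$truth$tract_masks[[tn]], p)
    paths[paste0("truth_", tn)] <- p
  }
  invisible(paths)
}
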