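# Probabilistic streamline tractography: seed-to-target with exclusion
# masking, producing streamline-count-normalized connectivity maps.

#' ROI set for tractography
#'
#' @param seed logical seed volume.
#' @param targets named list of logical target volumes (or a single array,
#'   named "target").
#' @param exclusion logical avoid volume (streamlines entering it are
#'   discarded entirely); default none.
#' @param csf,gm optional tissue masks carried along for masking configs.
#' @export
roi_set <- function(seed, targets, exclusion = NULL, csf = NULL, gm = NULL) {
  if (is.array(targets)) targets <- list(target = targets)
  dims <- dim(seed)
  if (is.null(exclusion)) exclusion <- array(FALSE, dims)
  for (m in c(targets, list(exclusion))) {
    if (!identical(dim(m), dims)) stop("ROI grids differ", call. = FALSE)
  }
  if (any(seed & exclusion)) stop("seed and exclusion masks overlap",
                                  call. = FALSE)
  structure(list(seed = seed, targets = targets, exclusion = exclusion,
                 csf = csf, gm = gm), class = "roi_set")
}

#' Tracking configuration
#'
#' @param n_samples_per_seed_voxel streamlines per seed voxel (desk-scale
#'   default 500; the acquisition-scale value is 5000).
#' @param curvature_threshold minimum cosine between consecutive steps
#'   (default 0.2).
#' @param step_size step length in voxels (default 0.5).
#' @param max_steps per-leg step cap (default 2000).
#' @param rng_seed integer seed.
#' @export
tracking_config <- function(n_samples_per_seed_voxel = 500L,
                            curvature_threshold = 0.2, step_size = 0.5,
                            max_steps = 2000L, rng_seed = 1L) {
  stopifnot(n_samples_per_seed_voxel >= 1L,
            curvature_threshold >= -1, curvature_threshold <= 1,
            step_size > 0, max_steps >= 1L)
  structure(list(n_samples_per_seed_voxel = as.integer(n_samples_per_seed_voxel),
                 curvature_threshold = curvature_threshold,
                 step_size = step_size, max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

#' Probabilistic tractography from seed to target
#'
#' For every seed voxel, \code{n_samples_per_seed_voxel} streamlines are
#' propagated bidirectionally from the voxel center, drawing one orientation
#' sample per step (between two fiber populations, the one most aligned with
#' the previous step is taken, sign flips allowed).  Steps whose cosine with
#' the previous direction does not exceed the curvature threshold terminate
#' the streamline; entering the exclusion mask discards it entirely.  Counts
#' accumulate per voxel over streamlines that reached the target (once per
#' streamline per voxel) and are normalized by the total number of generated
#' streamlines.
#'
#' @param samples an \code{\link{orientation_samples}} object.
#' @param rois a \code{\link{roi_set}}.
#' @param target_name which target to track to (default first).
#' @param config a \code{\link{tracking_config}}.
#' @param tract_id label stored on the output.
#' @return a \code{connectivity_map}: list(counts, normalized,
#'   total_streamlines, n_reached, tract_id, config).
#' @export
track <- function(samples, rois, target_name = names(rois$targets)[1],
                  config = tracking_config(), tract_id = target_name) {
  stopifnot(inherits(samples, "orientation_samples"),
            inherits(rois, "roi_set"), inherits(config, "tracking_config"))
  target <- rois$targets[[target_name]]
  if (is.null(target)) stop("no target named '", target_name, "'", call. = FALSE)
  seed_idx <- which(rois$seed)
  if (!length(seed_idx)) stop("empty seed mask", call. = FALSE)
  if (any(rois$seed & target)) stop("target overlaps seed mask", call. = FALSE)
  idx0 <- samples$index
  idx0[is.na(idx0)] <- 0L
  res <- cpp_track(samples$dims, as.integer(idx0) - 1L,
                   as.numeric(samples$v1), as.numeric(samples$v2),
                   samples$has2, as.integer(seed_idx) - 1L,
                   as.logical(target), as.logical(rois$exclusion),
                   as.integer(samples$n_samples),
                   config$n_samples_per_seed_voxel,
                   config$curvature_threshold, config$step_size,
                   config$max_steps, config$rng_seed)
  counts <- array(res$counts, samples$dims)
  structure(list(counts = counts, normalized = counts / res$total,
                 total_streamlines = res$total, n_reached = res$n_reached,
                 tract_id = tract_id, config = config),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("<connectivity_map '", x$tract_id, "'> ", x$n_reached, "/",
      x$total_streamlines, " streamlines reached the target; ",
      sum(x$counts > 0), " visited voxels\n", sep = "")
  invisible(x)
}

#' Fraction of streamlines that reached the target
#'
#' @param map a \code{connectivity_map}.
#' @return scalar in [0, 1].
#' @export
tract_success_rate <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  map$n_reached / map$total_streamlines
}
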