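# Mean tract templates: average control connectivity maps in the common
# grid, threshold at a percentile of the nonzero mean values, binarize;
# plus volume-matched binarization of individual maps.

#' Resample a connectivity map (or volume) into the common grid
#'
#' Values are moved by nearest-neighbour interpolation (no new values
#' created).  In phantom mode the subject-to-common warp is the subject's
#' known jitter displacement field.
#'
#' @param map a \code{connectivity_map} or a plain 3D array.
#' @param displacement 4D array (dims x 3): common-space coordinate x reads
#'   the subject volume at \code{round(x + displacement[x])}.
#' @return object of the same type, resampled.
#' @export
resample_to_common <- function(map, displacement) {
  if (inherits(map, "connectivity_map")) {
    out <- map
    out$counts <- nn_resample(map$counts, displacement)
    out$normalized <- nn_resample(map$normalized, displacement)
    return(out)
  }
  if (inherits(map, "scalar_map")) {
    return(scalar_map(nn_resample(map$values, displacement, fill = NA_real_),
                      map$kind))
  }
  nn_resample(map, displacement)
}

# percentile of v by linear interpolation between order statistics
# (quantile type 7); factored out so tests can oracle it by brute force
percentile_threshold <- function(v, percentile) {
  unname(quantile(v, percentile / 100, type = 7, names = FALSE))
}

#' Build a binary mean tract template
#'
#' Normalized control connectivity maps (already in the common grid) are
#' averaged voxelwise; the threshold is the given percentile of the mean
#' values over voxels with mean > 0 (set \code{include_zeros = TRUE} to use
#' the all-voxel distribution); voxels strictly exceeding the threshold form
#' the binarized template.
#'
#' @param maps list of >= 2 \code{connectivity_map}s (or 3D arrays) on one
#'   grid.
#' @param percentile threshold percentile (default 95).
#' @param include_zeros include zero-background voxels in the percentile
#'   distribution (default FALSE: on mostly-empty grids the nonzero support
#'   is the meaningful distribution).
#' @param tract_id label; taken from the first map when available.
#' @return a \code{tract_template}: list(mask, tract_id, n_subjects,
#'   percentile, threshold, mean_map, provenance).
#' @export
build_template <- function(maps, percentile = 95, include_zeros = FALSE,
                           tract_id = NULL, provenance = NULL) {
  stopifnot(length(maps) >= 2L, percentile > 0, percentile < 100)
  vols <- lapply(maps, function(m) {
    if (inherits(m, "connectivity_map")) m$normalized else m
  })
  dims <- dim(vols[[1]])
  for (v in vols) {
    if (!identical(dim(v), dims)) stop("template input grids differ",
                                       call. = FALSE)
  }
  if (is.null(tract_id) && inherits(maps[[1]], "connectivity_map")) {
    tract_id <- maps[[1]]$tract_id
  }
  mean_map <- Reduce(`+`, vols) / length(vols)
  pool <- if (include_zeros) as.numeric(mean_map) else mean_map[mean_map > 0]
  if (!length(pool)) stop("empty nonzero support: no voxel has positive mean ",
                          "connectivity", call. = FALSE)
  thr <- percentile_threshold(pool, percentile)
  mask <- mean_map > thr
  if (!any(mask)) stop("template mask is empty after thresholding",
                       call. = FALSE)
  structure(list(mask = mask, tract_id = tract_id %||% "tract",
                 n_subjects = length(maps), percentile = percentile,
                 threshold = thr, mean_map = mean_map,
                 provenance = provenance),
            class = "tract_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tract_template <- function(x, ...) {
  cat("<tract_template '", x$tract_id, "'> ", sum(x$mask), " voxels (",
      x$n_subjects, " subjects, ", x$percentile, "th percentile)\n", sep = "")
  invisible(x)
}

#' Volume-matched binarization of an individual connectivity map
#'
#' Returns the V voxels of highest normalized connectivity, where V is the
#' template's voxel count, so the individual tract is volume-equivalent to
#' the template.  Ties at the cut are broken deterministically (value
#' descending, then linear voxel index ascending).  When the map has fewer
#' than V nonzero voxels, all of them are returned and a shortfall is
#' flagged.
#'
#' @param map a \code{connectivity_map} (or plain 3D array of nonnegative
#'   values).
#' @param template a \code{tract_template}.
#' @return logical array with attribute \code{shortfall} (0 when the full
#'   volume was matched).
#' @export
volume_matched_binarize <- function(map, template) {
  vals <- if (inherits(map, "connectivity_map")) map$normalized else map
  stopifnot(inherits(template, "tract_template"),
            identical(dim(vals), dim(template$mask)))
  V <- sum(template$mask)
  nz <- which(vals > 0)
  if (!length(nz)) stop("empty connectivity map: no nonzero voxels",
                        call. = FALSE)
  out <- array(FALSE, dim(vals))
  if (length(nz) >= V) {
    ord <- nz[order(-vals[nz], nz)]
    out[ord[seq_len(V)]] <- TRUE
    shortfall <- 0L
  } else {
    out[nz] <- TRUE
    shortfall <- V - length(nz)
    warning("volume-matched binarization shortfall: only ", length(nz),
            " nonzero voxels for a template of ", V)
  }
  attr(out, "shortfall") <- shortfall
  out
}
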