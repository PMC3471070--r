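# On-disk container for orientation samples: one raw little-endian float64
# array file holding the sample blocks back to back, a JSON sidecar with
# shapes/offsets/seed, and the voxel->row index as NIfTI.

#' Write / read an orientation-sample container
#'
#' \code{<prefix>.bin} stores, in order, the flattened \code{v1}
#' (rows x samples x 3), \code{f1} (rows x samples), \code{v2}, \code{f2}
#' and the point-estimate matrix (rows x 12: v1, v2, f1, f2, d, s0,
#' converged) as little-endian float64.  \code{<prefix>.json} records the
#' shapes, voxel count, sample count and bootstrap seed;
#' \code{<prefix>_index.nii.gz} maps voxels to sample rows (0 = outside).
#'
#' @param samples an \code{\link{orientation_samples}} object.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_orientation_samples <- function(samples, prefix) {
  stopifnot(inherits(samples, "orientation_samples"))
  nrows <- dim(samples$v1)[1]
  ns <- samples$n_samples
  pt <- samples$point
  point_mat <- cbind(pt$v1, pt$v2, pt$f1, pt$f2, pt$d, pt$s0,
                     as.numeric(pt$converged))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (block in list(samples$v1, samples$f1, samples$v2, samples$f2,
                     point_mat)) {
    writeBin(as.numeric(block), con, size = 8, endian = "little")
  }
  idx <- samples$index
  idx[is.na(idx)] <- 0L
  write_nifti(array(as.numeric(idx), samples$dims),
              paste0(prefix, "_index.nii.gz"), datatype = "int32")
  jsonlite::write_json(
    list(n_rows = nrows, n_samples = ns, dims = samples$dims,
         has2 = as.logical(samples$has2), rng_seed = samples$rng_seed,
         blocks = c("v1", "f1", "v2", "f2", "point"),
         point_cols = c("v1x", "v1y", "v1z", "v2x", "v2y", "v2z",
                        "f1", "f2", "d", "s0", "converged")),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_orientation_samples
#' @export
read_orientation_samples <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nrows <- meta$n_rows
  ns <- meta$n_samples
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  grab <- function(n) {
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(x) < n) stop("truncated sample container: ", prefix,
                            call. = FALSE)
    x
  }
  v1 <- array(grab(nrows * ns * 3), c(nrows, ns, 3))
  f1 <- matrix(grab(nrows * ns), nrows, ns)
  v2 <- array(grab(nrows * ns * 3), c(nrows, ns, 3))
  f2 <- matrix(grab(nrows * ns), nrows, ns)
  pm <- matrix(grab(nrows * 11), nrows, 11)
  idx_img <- read_nifti(paste0(prefix, "_index.nii.gz"))
  index <- array(as.integer(round(idx_img$data)), meta$dims)
  index[index == 0L] <- NA_integer_
  orientation_samples(
    dims = meta$dims, index = index, v1 = v1, f1 = f1, v2 = v2, f2 = f2,
    has2 = meta$has2,
    point = list(v1 = pm[, 1:3, drop = FALSE], v2 = pm[, 4:6, drop = FALSE],
                 f1 = pm[, 7], f2 = pm[, 8], d = pm[, 9], s0 = pm[, 10],
                 converged = pm[, 11] > 0.5),
    n_samples = ns, rng_seed = meta$rng_seed)
}
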