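# Shared fixture builders: everything is generated in code at test time.

# single-shell scheme reused across tests
test_scheme <- function() make_scheme(n_dirs = 32L, n_b0 = 4L, bval = 1000)

# straight tube along +x in a small grid; flat or parabolic fiber profile
straight_tube <- function(dims = c(24L, 11L, 11L), radius = 2,
                          fiber_fraction = 0.7, profile = "flat") {
  yc <- (dims[2] - 1) / 2
  zc <- (dims[3] - 1) / 2
  cp <- cbind(c(2, dims[1] - 3), yc, zc)
  curve <- tract_curve(cp, radius, name = "tube")
  make_tract_field(curve, dims = dims, fiber_fraction = fiber_fraction,
                   profile = profile)
}

# seed/target balls at the tube ends (for tracking tests); pass the tube's
# tract mask to confine them to the bundle (the success-rate-1 contract
# needs every seed voxel to carry fibers)
tube_rois <- function(dims = c(24L, 11L, 11L), radius = 2.5,
                      tract_mask = NULL) {
  yc <- (dims[2] - 1) / 2
  zc <- (dims[3] - 1) / 2
  sphere <- function(center) {
    g <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                     z = seq_len(dims[3]) - 1)
    out <- array((g$x - center[1])^2 + (g$y - center[2])^2 +
                   (g$z - center[3])^2 <= radius^2, dims)
    if (!is.null(tract_mask)) out <- out & tract_mask
    out
  }
  list(seed = sphere(c(2, yc, zc)), target = sphere(c(dims[1] - 3, yc, zc)))
}

# brute-force distance from voxel centers to a segment (independent oracle)
segment_distance_count <- function(dims, p0, p1, radius) {
  g <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                             z = seq_len(dims[3]) - 1))
  d <- p1 - p0
  len2 <- sum(d^2)
  t <- pmin(pmax(((g[, 1] - p0[1]) * d[1] + (g[, 2] - p0[2]) * d[2] +
                    (g[, 3] - p0[3]) * d[3]) / len2, 0), 1)
  px <- p0[1] + t * d[1]; py <- p0[2] + t * d[2]; pz <- p0[3] + t * d[3]
  sum(sqrt((g[, 1] - px)^2 + (g[, 2] - py)^2 + (g[, 3] - pz)^2) <= radius)
}
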