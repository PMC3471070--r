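# Phantom generator: geometry, damage injection, forward model, cohorts.

test_that("straight tube carries the axis tangent everywhere in-tract", {
  tube <- straight_tube()
  idx <- which(tube$tract_mask)
  nvox <- prod(dim(tube$tract_mask))
  v <- cbind(tube$field$v1[idx], tube$field$v1[idx + nvox],
             tube$field$v1[idx + 2 * nvox])
  expect_true(all(abs(v[, 1] - 1) < 1e-12))
  expect_true(all(abs(v[, 2:3]) < 1e-12))
  # outside voxels are purely isotropic
  expect_true(all(tube$field$f1[-idx] == 0))
})

test_that("circular-arc tangents turn exactly with the arc angle", {
  # dense control points on a circle; central differences on a circle give
  # the exact tangent direction, so tangent(theta) is perpendicular to the
  # radius at theta: phi(tangent) - theta is constant along the arc.  Two
  # tangents 90 degrees of arc apart are then perpendicular to the same
  # accuracy, without needing polyline nodes at exactly 0 and 90 degrees.
  th <- seq(-0.2, pi / 2 + 0.2, length.out = 241)
  cp <- cbind(24 + 18 * cos(th), 10, 24 + 18 * sin(th))
  curve <- tract_curve(cp, radius = 2)
  ang <- atan2(curve$points[, 3] - 24, curve$points[, 1] - 24)
  phi <- atan2(curve$tangents[, 3], curve$tangents[, 1])
  m <- nrow(curve$points)
  interior <- 30:(m - 30)     # clear of the natural-spline boundary layer
  off <- (phi - ang)[interior]
  ref <- off[length(off) %/% 2]
  dev <- ((off - ref + pi) %% (2 * pi)) - pi      # wrap to (-pi, pi]
  expect_lt(max(abs(dev)), 1e-6)
  expect_true(all(abs(sqrt(rowSums(curve$tangents^2)) - 1) < 1e-12))
})

test_that("tract mask equals brute-force point-to-segment distance test", {
  dims <- c(36L, 9L, 9L)
  tube <- straight_tube(dims = dims, radius = 2)
  oracle <- segment_distance_count(dims, c(2, 4, 4), c(dims[1] - 3, 4, 4), 2)
  expect_identical(sum(tube$tract_mask), oracle)
})

test_that("curves exiting the grid are rejected with a geometry error", {
  cp <- cbind(c(-2, 30), 5, 5)
  expect_error(make_tract_field(tract_curve(cp, 2), dims = c(20L, 11L, 11L)),
               "geometry error")
})

test_that("damage injection: zero identity, full isotropy, monotone FA/MD", {
  tube <- straight_tube(profile = "flat")
  truth0 <- phantom_truth(list(tube = tube$tract_mask),
                          array(FALSE, dim(tube$tract_mask)), tube$field)
  region <- tube$tract_mask
  idx <- which(region)

  z <- inject_damage(tube$field, truth0, 0, region)
  expect_identical(z$field$f1, tube$field$f1)
  expect_equal(z$truth$true_fa, truth0$true_fa)
  expect_equal(z$truth$true_md, truth0$true_md)
  expect_true(all(z$truth$damage_mask == region))

  full <- inject_damage(tube$field, truth0, 1, region)
  expect_true(all(full$field$f1[idx] == 0))
  expect_true(all(full$truth$true_fa[idx] == 0))

  fas <- mds <- numeric(3)
  for (i in seq_along(c(0.2, 0.5, 0.8))) {
    s <- c(0.2, 0.5, 0.8)[i]
    r <- inject_damage(tube$field, truth0, s, region)
    fas[i] <- mean(r$truth$true_fa[idx])
    mds[i] <- mean(r$truth$true_md[idx])
  }
  expect_true(all(diff(fas) < 0))
  expect_true(all(diff(mds) > 0))
  # voxelwise monotonicity, not just means
  r2 <- inject_damage(tube$field, truth0, 0.5, region)
  r8 <- inject_damage(tube$field, truth0, 0.8, region)
  expect_true(all(r8$truth$true_fa[idx] <= r2$truth$true_fa[idx]))
  expect_true(all(r8$truth$true_md[idx] >= r2$truth$true_md[idx]))

  bad <- array(TRUE, c(3, 3, 3))
  expect_error(inject_damage(tube$field, truth0, 0.5, bad), "does not match")
})

test_that("ball-and-stick forward signal matches the closed form", {
  dims <- c(3L, 3L, 3L)
  f <- fiber_field(dims, d = 1.7e-3, S0 = 100)
  f$f1[] <- 1
  f$v1[, , , 1] <- 1
  sch <- acq_scheme(c(0, 1000, 1000),
                    cbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  dwi <- simulate_dwi(f, sch)
  expect_equal(unique(as.numeric(dwi$signal[, , , 1])), 100)    # b = 0
  expect_equal(unique(as.numeric(dwi$signal[, , , 2])), 100)    # g  |  v
  expect_equal(unique(as.numeric(dwi$signal[, , , 3])),
               100 * exp(-1.7), tolerance = 1e-12)              # g || v
  iso <- fiber_field(dims, d = 0.7e-3, S0 = 100)
  dwi2 <- simulate_dwi(iso, sch)
  expect_equal(as.numeric(dwi2$signal[, , , 2:3]),
               rep(100 * exp(-0.7), 2 * prod(dims)), tolerance = 1e-12)
})

test_that("Rician noise is seed-deterministic and vanishes as sigma -> 0", {
  tube <- straight_tube(dims = c(10L, 7L, 7L))
  sch <- test_scheme()
  a <- simulate_dwi(tube$field, sch, noise_sigma = 5, rng_seed = 9)
  b <- simulate_dwi(tube$field, sch, noise_sigma = 5, rng_seed = 9)
  c <- simulate_dwi(tube$field, sch, noise_sigma = 5, rng_seed = 10)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  clean <- simulate_dwi(tube$field, sch)
  tiny <- simulate_dwi(tube$field, sch, noise_sigma = 1e-7, rng_seed = 1)
  expect_lt(max(abs(tiny$signal - clean$signal)), 1e-5)
  expect_error(simulate_dwi(tube$field, sch, noise_sigma = 1), "rng_seed")
})

test_that("jitter fields are bounded, band-limited and deterministic", {
  disp <- jitter_field(c(16L, 16L, 16L), 1.5, rng_seed = 4)
  expect_equal(max(abs(disp)), 1.5)
  expect_identical(disp, jitter_field(c(16L, 16L, 16L), 1.5, rng_seed = 4))
  expect_true(all(jitter_field(c(8L, 8L, 8L), 0, rng_seed = 1) == 0))
  # band-limited: the per-voxel increment along any axis is bounded by
  # 2 * bound / control-point spacing (spacing 5 voxels here)
  d1 <- disp[, , , 1]
  expect_lte(max(abs(d1[2:16, , ] - d1[1:15, , ])), 2 * 1.5 / 5 + 1e-9)
  expect_lte(max(abs(d1[, 2:16, ] - d1[, 1:15, ])), 2 * 1.5 / 5 + 1e-9)
})

test_that("cohorts are reproducible and degrade with severity", {
  geo <- default_geometry(c(24L, 24L, 24L), n_tracts = 1L)
  spec0 <- cohort_spec(n_controls = 2L, n_patients = 2L,
                       damage_severities = c(0.1, 0.6), jitter_voxels = 0,
                       noise_sigma = 0, rng_seed = 5L)
  sch <- make_scheme(8L, 1L)
  coh <- make_cohort(spec0, geo, sch)
  # no stochastic elements: control volumes are identical
  expect_identical(coh$subjects[[1]]$dwi$signal, coh$subjects[[2]]$dwi$signal)
  # same spec, same seed: identical outputs
  coh2 <- make_cohort(spec0, geo, sch)
  expect_identical(lapply(coh$subjects, `[[`, "dwi"),
                   lapply(coh2$subjects, `[[`, "dwi"))
  # severity ordering of in-region ground truth
  p1 <- coh$subjects[[3]]; p2 <- coh$subjects[[4]]
  expect_equal(p1$severity, 0.1)
  expect_lt(mean(p2$truth$true_fa[p2$truth$damage_mask]),
            mean(p1$truth$true_fa[p1$truth$damage_mask]))
  expect_error(cohort_spec(n_controls = 1L), "n_controls")
  expect_error(cohort_spec(n_patients = 3L, damage_severities = c(0.5, 0.5)),
               "one damage severity per patient")
})

test_that("cohort subjects serialize to NIfTI + bval/bvec on disk", {
  geo <- default_geometry(c(20L, 20L, 20L), n_tracts = 1L)
  spec0 <- cohort_spec(n_controls = 2L, n_patients = 0L,
                       damage_severities = numeric(), jitter_voxels = 0.5,
                       noise_sigma = 2, rng_seed = 3L)
  sch <- make_scheme(8L, 1L)
  coh <- make_cohort(spec0, geo, sch)
  dir <- tempfile()
  paths <- write_subject(coh$subjects[[1]], sch, dir)
  expect_true(all(file.exists(paths)))
  back <- read_nifti(paths[["dwi"]])
  expect_equal(dim(back$data), dim(coh$subjects[[1]]$dwi$signal))
  expect_equal(as.numeric(back$data),
               as.numeric(coh$subjects[[1]]$dwi$signal))
  unlink(dir, recursive = TRUE)
})
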