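# Streamline propagation, curvature threshold, exclusion semantics.

test_that("a noiseless straight tube tracks seed-to-target perfectly", {
  dims <- c(24L, 11L, 11L)
  tube <- straight_tube(dims = dims, radius = 2, profile = "flat")
  rois <- tube_rois(dims, tract_mask = tube$tract_mask)
  smp <- true_orientation_samples(tube$field,
                                  extra_mask = rois$seed | rois$target)
  rs <- roi_set(rois$seed, list(target = rois$target))
  cm <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 50L,
                                                rng_seed = 5))
  expect_equal(tract_success_rate(cm), 1.0)
  # every spine voxel (the tube axis) up to the target entry face has
  # positive normalized connectivity (legs terminate on entering the target)
  spine <- cbind(3:(dims[1] - 5), 5, 5)
  lin <- 1 + spine[, 1] + dims[1] * (spine[, 2] + dims[2] * spine[, 3])
  expect_true(all(cm$normalized[lin] > 0))
  expect_equal(cm$total_streamlines, sum(rois$seed) * 50)
})

test_that("an exclusion slab crossing the tube discards every streamline", {
  dims <- c(24L, 11L, 11L)
  tube <- straight_tube(dims = dims, radius = 2, profile = "flat")
  rois <- tube_rois(dims)
  excl <- array(FALSE, dims)
  excl[12:13, , ] <- TRUE
  smp <- true_orientation_samples(tube$field,
                                  extra_mask = rois$seed | rois$target)
  rs <- roi_set(rois$seed, list(target = rois$target), exclusion = excl)
  cm <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 20L,
                                                rng_seed = 5))
  expect_equal(tract_success_rate(cm), 0)
  expect_true(all(cm$counts == 0))
})

test_that("steps breaking the 0.2 curvature threshold end the streamline", {
  # previous direction +x, all candidate samples +y: cos = 0 < 0.2 for both
  # signs, so walks die after one voxel and never reach the target
  dims <- c(15L, 7L, 7L)
  f <- fiber_field(dims)
  f$f1[] <- 0.8
  f$v1[, , , 2] <- 1                     # everything points +y
  f$v1[1:3, , , 2] <- 0
  f$v1[1:3, , , 1] <- 1                  # except the seed end: +x
  seed <- array(FALSE, dims); seed[2, 4, 4] <- TRUE
  target <- array(FALSE, dims); target[13:14, , ] <- TRUE
  smp <- true_orientation_samples(f)
  rs <- roi_set(seed, list(target = target))
  cm <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 30L,
                                                curvature_threshold = 0.2,
                                                rng_seed = 2))
  expect_equal(tract_success_rate(cm), 0)
  # with the threshold relaxed below -1 even orthogonal turns are allowed;
  # walks then wander off +y and still fail, but some voxels get visited:
  # instead verify that a straight field under the same config succeeds
  f2 <- fiber_field(dims); f2$f1[] <- 0.8; f2$v1[, , , 1] <- 1
  cm2 <- track(true_orientation_samples(f2), rs,
               config = tracking_config(n_samples_per_seed_voxel = 30L,
                                        rng_seed = 2))
  expect_equal(tract_success_rate(cm2), 1)
})

test_that("counts are conserved and normalization stays in [0, 1]", {
  dims <- c(24L, 11L, 11L)
  tube <- straight_tube(dims = dims, radius = 2)
  rois <- tube_rois(dims)
  dwi <- simulate_dwi(tube$field, test_scheme(), noise_sigma = 5, rng_seed = 31)
  mask <- tube$tract_mask | rois$seed | rois$target
  smp <- fit_ball_and_stick(dwi, mask, rng_seed = 32)
  rs <- roi_set(rois$seed, list(target = rois$target))
  cm <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 100L,
                                                rng_seed = 33))
  expect_true(all(cm$counts <= cm$total_streamlines))
  expect_true(all(cm$normalized >= 0 & cm$normalized <= 1))
  expect_equal(cm$normalized, cm$counts / cm$total_streamlines)
  # determinism
  cm2 <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 100L,
                                                 rng_seed = 33))
  expect_identical(cm$counts, cm2$counts)
  cm3 <- track(smp, rs, config = tracking_config(n_samples_per_seed_voxel = 100L,
                                                 rng_seed = 34))
  expect_false(identical(cm$counts, cm3$counts))
})

test_that("degenerate ROI configurations are rejected", {
  dims <- c(10L, 5L, 5L)
  tube <- straight_tube(dims = dims, radius = 1.5)
  smp <- true_orientation_samples(tube$field)
  empty <- array(FALSE, dims)
  ball <- array(FALSE, dims); ball[2:3, 2:3, 2:3] <- TRUE
  expect_error(track(smp, roi_set(empty, list(target = ball))), "empty seed")
  expect_error(track(smp, roi_set(ball, list(target = ball))),
               "overlaps seed")
  expect_error(roi_set(ball, list(target = empty), exclusion = ball),
               "overlap")
})
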