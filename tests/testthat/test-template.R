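# Template averaging, percentile thresholding, volume-matched binarization,
# nearest-neighbour resampling.

test_that("nearest-neighbour resampling: identity, integer shift, NN sets", {
  with_seed <- tractem:::with_seed
  vol <- with_seed(1, array(as.numeric(sample(0:9, 10^3, TRUE)), c(10, 10, 10)))
  zero <- array(0, c(10, 10, 10, 3))
  expect_identical(nn_resample(vol, zero), vol)
  # pure integer translation: values move exactly, unique set preserved
  shift <- zero; shift[, , , 1] <- 2
  out <- nn_resample(vol, shift)
  expect_identical(out[1:8, , ], vol[3:10, , ])
  expect_true(all(out[9:10, , ] == 0))
  # half-voxel shift: output values are a subset of input values
  half <- zero; half[, , , 2] <- 0.5
  out2 <- nn_resample(vol, half)
  expect_true(all(unique(as.numeric(out2)) %in% c(0, unique(as.numeric(vol)))))
  expect_error(nn_resample(vol, zero[, , 1:5, ]), "does not match")
})

test_that("resample_to_common preserves connectivity-map structure", {
  cm <- structure(list(counts = array(as.numeric(1:27), c(3, 3, 3)),
                       normalized = array((1:27) / 27, c(3, 3, 3)),
                       total_streamlines = 27, n_reached = 5,
                       tract_id = "t", config = NULL),
                  class = "connectivity_map")
  out <- resample_to_common(cm, array(0, c(3, 3, 3, 3)))
  expect_identical(out$counts, cm$counts)
  expect_identical(out$tract_id, "t")
})

test_that("percentile thresholding matches a brute-force sort oracle", {
  with_seed <- tractem:::with_seed
  for (seed in 1:5) {
    maps <- with_seed(seed, lapply(1:3, function(i) {
      m <- array(0, c(8, 8, 8))
      m[sample(512, 120)] <- runif(120)
      m
    }))
    tpl <- build_template(maps, percentile = 95)
    mean_map <- (maps[[1]] + maps[[2]] + maps[[3]]) / 3
    nz <- sort(mean_map[mean_map > 0])
    # type-7 linear interpolation between order statistics, by hand
    h <- (length(nz) - 1) * 0.95
    thr_oracle <- nz[floor(h) + 1] +
      (h - floor(h)) * (nz[min(floor(h) + 2, length(nz))] - nz[floor(h) + 1])
    expect_equal(tpl$threshold, thr_oracle)
    expect_identical(tpl$mask, mean_map > thr_oracle)
  }
})

test_that("100 distinct mean values leave exactly 5 survivors at p95", {
  m <- array(0, c(10, 10, 10))
  m[1:100] <- (1:100) / 100
  tpl <- build_template(list(m, m), percentile = 95)
  expect_identical(sum(tpl$mask), 5L)                    # values 96..100
  expect_identical(which(tpl$mask), 96:100)
  # identical input maps equal the single-map thresholding
  tpl4 <- build_template(list(m, m, m, m), percentile = 95)
  expect_identical(tpl4$mask, tpl$mask)
})

test_that("disjoint tract supports pool into a union-support percentile", {
  a <- array(0, c(6, 6, 6)); a[1:40] <- runif(40) + 0.5
  b <- array(0, c(6, 6, 6)); b[101:140] <- runif(40) + 0.5
  tpl <- build_template(list(a, b), percentile = 95)
  mean_map <- (a + b) / 2
  support <- mean_map > 0
  expect_identical(sum(support), 80L)
  expect_equal(tpl$threshold,
               unname(quantile(mean_map[support], 0.95, type = 7)))
  expect_error(build_template(list(a * 0, b * 0)), "empty nonzero support")
})

test_that("volume-matched binarization returns exactly V top voxels", {
  with_seed <- tractem:::with_seed
  vals <- with_seed(3, {
    m <- array(0, c(10, 10, 10))
    m[sample(1000, 200)] <- runif(200)
    m
  })
  tpl <- structure(list(mask = array(c(rep(TRUE, 50), rep(FALSE, 950)),
                                     c(10, 10, 10)), tract_id = "t"),
                   class = "tract_template")
  out <- volume_matched_binarize(vals, tpl)
  expect_identical(sum(out), 50L)
  expect_identical(attr(out, "shortfall"), 0L)
  # those 50 are the top-50 by value
  expect_gte(min(vals[out]), max(vals[vals > 0 & !out]))
  # self-consistency: binarizing the template's own mean map gives its mask
  maps <- with_seed(4, lapply(1:2, function(i) {
    m <- array(0, c(10, 10, 10)); m[sample(1000, 300)] <- runif(300); m
  }))
  tpl2 <- build_template(maps, percentile = 95)
  mean_map <- (maps[[1]] + maps[[2]]) / 2
  out2 <- volume_matched_binarize(mean_map, tpl2)
  expect_identical(which(out2), which(tpl2$mask))
  # shortfall: 30 nonzero voxels for a 50-voxel template
  small <- array(0, c(10, 10, 10)); small[1:30] <- runif(30)
  expect_warning(out3 <- volume_matched_binarize(small, tpl), "shortfall")
  expect_identical(sum(out3), 30L)
  expect_identical(attr(out3, "shortfall"), 20L)
  expect_error(volume_matched_binarize(small * 0, tpl), "empty connectivity")
})

test_that("ties at the cut break deterministically by linear index", {
  vals <- array(0, c(4, 4, 1))
  vals[1:8] <- c(0.9, 0.5, 0.5, 0.5, 0.5, 0.2, 0.1, 0.05)
  tpl <- structure(list(mask = array(c(rep(TRUE, 3), rep(FALSE, 13)),
                                     c(4, 4, 1)), tract_id = "t"),
                   class = "tract_template")
  out <- volume_matched_binarize(vals, tpl)
  expect_identical(which(out), c(1L, 2L, 3L))   # first tied indices win
})

test_that("templates from disjoint jittered cohorts overlap well (Dice)", {
  # two independent 5-subject cohorts, tracked on ground-truth orientations
  geo <- default_geometry(c(28L, 28L, 28L), n_tracts = 1L)
  base <- tractem:::build_base_phantom(geo)
  make_maps <- function(seed0) {
    lapply(1:5, function(i) {
      disp <- jitter_field(geo$dims, 1, rng_seed = seed0 + i)
      fld <- tractem:::warp_field(base$field, disp)
      rois <- lapply(base$rois[[1]], tractem:::warp_mask, disp = disp)
      smp <- true_orientation_samples(fld, extra_mask = rois$seed | rois$target)
      cm <- track(smp, roi_set(rois$seed, list(target = rois$target)),
                  config = tracking_config(n_samples_per_seed_voxel = 100L,
                                           rng_seed = seed0 + 50 + i))
      resample_to_common(cm, disp)
    })
  }
  t1 <- build_template(make_maps(1000))
  t2 <- build_template(make_maps(2000))
  expect_gt(dice(t1$mask, t2$mask), 0.7)
})
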