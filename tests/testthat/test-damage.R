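# Control statistics, Z-score outlier counting, cohort assessment.

mask3 <- function(dims, n) {
  m <- array(FALSE, dims); m[seq_len(n)] <- TRUE; m
}

test_that("control mean/SD use the n-1 denominator and flag zero SD", {
  dims <- c(4L, 4L, 4L)
  a <- array(1, dims); b <- array(3, dims)
  st <- control_stats(list(a, b), mask3(dims, 10))
  expect_equal(unique(st$mean[1:10]), 2)
  expect_equal(unique(st$sd[1:10]), sqrt(2))
  expect_true(all(st$valid[1:10]))
  expect_warning(st2 <- control_stats(list(a, a), mask3(dims, 10)),
                 "zero SD|undefined Z")
  expect_false(any(st2$valid))
  expect_error(percent_abnormal(a, st2, "MD"), "no valid voxels")
})

test_that("voxelwise control means concentrate as expected at n = 10", {
  with_seed <- tractem:::with_seed
  dims <- c(20L, 20L, 20L)
  maps <- with_seed(21, lapply(1:10, function(i) array(rnorm(prod(dims)), dims)))
  st <- control_stats(maps, array(TRUE, dims))
  # sd of the voxelwise mean is 1/sqrt(10) = 0.316; essentially all voxel
  # means should fall within 3 standard errors
  cover <- mean(abs(st$mean) <= 3 / sqrt(10))
  expect_gt(cover, 0.99)
})

test_that("Z-score arithmetic and percentages count as specified", {
  dims <- c(10L, 1L, 1L)
  m <- mask3(dims, 10)
  # two controls chosen so mean = 0.8e-3 and sd = 0.05e-3 exactly
  delta <- 0.05e-3 / sqrt(2)
  a <- array(0.8e-3 + delta, dims); b <- array(0.8e-3 - delta, dims)
  st <- control_stats(list(a, b), m)
  expect_equal(unique(st$sd[1:10]), 0.05e-3)
  patient <- array(0.8e-3, dims)
  patient[1:2] <- 1.0e-3                       # Z = 4 at two voxels
  res <- percent_abnormal(patient, st, "MD", z_threshold = 3)
  expect_equal(res$n_voxels, 10L)
  expect_equal(res$n_abnormal, 2L)
  expect_equal(res$pct_abnormal, 20)
  # patient identical to the control mean: 0% for both metrics
  base <- array(0.8e-3, dims)
  expect_equal(percent_abnormal(base, st, "MD")$pct_abnormal, 0)
  expect_equal(percent_abnormal(base, st, "FA")$pct_abnormal, 0)
  # FA directionality: only *low* FA counts unless two_sided
  hi <- array(0.8e-3 + 10 * 0.05e-3, dims)
  expect_equal(percent_abnormal(hi, st, "FA")$pct_abnormal, 0)
  expect_equal(percent_abnormal(hi, st, "FA", two_sided = TRUE)$pct_abnormal,
               100)
  lo <- array(0.8e-3 - 10 * 0.05e-3, dims)
  expect_equal(percent_abnormal(lo, st, "FA")$pct_abnormal, 100)
})

test_that("assess_cohort pairs methods, flags absent tracts, is exact", {
  with_seed <- tractem:::with_seed
  dims <- c(8L, 8L, 8L)
  smask <- structure(list(mask = mask3(dims, 200), config_label = "none",
                          tract_id = "t1"), class = "sampling_mask")
  maps <- with_seed(22, {
    out <- list()
    for (sid in c("c1", "c2", "c3", "c4", "p1")) {
      out[[sid]] <- list(
        fa = scalar_map(array(0.5 + 0.02 * rnorm(prod(dims)), dims), "FA"),
        md = scalar_map(array(8e-4 + 2e-5 * rnorm(prod(dims)), dims), "MD"))
    }
    out
  })
  regions <- list(t1 = list(c1 = mask3(dims, 150), c2 = mask3(dims, 150),
                            c3 = mask3(dims, 150), c4 = mask3(dims, 150),
                            p1 = NULL))
  rep <- assess_cohort(maps, c("c1", "c2", "c3", "c4"),
                       list(t1 = smask), regions)
  expect_s3_class(rep, "damage_report")
  expect_identical(nrow(rep), 10L)             # 5 subjects x 2 methods
  p1_ind <- rep[rep$subject_id == "p1" & rep$method == "individual", ]
  expect_true(p1_ind$absent)                   # flagged, not skipped
  # healthy cohort: small abnormal percentages (with only 4 controls the
  # plug-in Z > 3 rule has a ~4% false-positive rate from t-tail inflation)
  expect_true(all(rep$pct_abnormal_md[!rep$absent] < 8))
  # determinism
  rep2 <- assess_cohort(maps, c("c1", "c2", "c3", "c4"),
                        list(t1 = smask), regions)
  expect_identical(rep, rep2)
})

test_that("compare_methods: discrepancies, degenerate and unpaired cases", {
  mk_report <- function(tmpl, ind, subjects = paste0("p", seq_along(tmpl))) {
    rbind(
      data.frame(subject_id = subjects, tract_id = "t1", method = "template",
                 pct_abnormal_md = tmpl, pct_abnormal_fa = 0, n_voxels = 100L,
                 mean_fa = 0.5, mean_md = 8e-4, absent = FALSE),
      data.frame(subject_id = subjects, tract_id = "t1", method = "individual",
                 pct_abnormal_md = ind, pct_abnormal_fa = 0, n_voxels = 100L,
                 mean_fa = 0.5, mean_md = 8e-4, absent = FALSE))
  }
  # template >= individual with damage-graded growth
  tmpl <- c(1, 5, 12, 25, 40, 55)
  ind <- c(1, 4, 8, 15, 22, 30)
  cmp <- compare_methods(mk_report(tmpl, ind))
  expect_equal(cmp$pairs$discrepancy, tmpl - ind)
  expect_gt(cmp$rho, 0.9)
  expect_lt(cmp$p, 0.05)
  # identical estimates: all-zero discrepancies are flagged, not an error
  cmp0 <- compare_methods(mk_report(tmpl, tmpl))
  expect_true(cmp0$degenerate)
  expect_true(is.na(cmp0$rho))
  # two subjects only: refuses the correlation, still emits discrepancies
  cmp2 <- compare_methods(mk_report(c(1, 2), c(0, 1)))
  expect_true(cmp2$degenerate)
  expect_identical(nrow(cmp2$pairs), 2L)
  # unpaired entries are an error listing the offenders
  bad <- mk_report(tmpl, ind)
  bad <- bad[!(bad$subject_id == "p3" & bad$method == "individual"), ]
  expect_error(compare_methods(bad), "unpaired.*p3/t1")
})

test_that("patients separate from held-out controls (rank-sum, scaled down)", {
  # scaled-down grid (28^3), 8 held-out controls vs 8 patients sev >= 0.4
  # in the diffuse (whole-tract) damage mode, tracked on ground-truth
  # orientations: the property isolates the Z-score machinery from fitting
  # cost and from lesion-placement specifics
  geo <- default_geometry(c(28L, 28L, 28L), n_tracts = 1L)
  base <- tractem:::build_base_phantom(geo)
  sch <- make_scheme()
  sev <- c(rep(0, 18), seq(0.4, 0.75, length.out = 8))
  maps <- list(); conns <- list()
  for (i in seq_along(sev)) {
    disp <- jitter_field(geo$dims, 1, rng_seed = 3000 + i)
    fld <- tractem:::warp_field(base$field, disp)
    if (sev[i] > 0) {
      region <- tractem:::warp_mask(base$tract_masks[[1]], disp)
      fld <- inject_damage(fld, NULL, sev[i], region,
                           rng_seed = 3300 + i)$field
    }
    dwi <- simulate_dwi(fld, sch, noise_sigma = 5, rng_seed = 3100 + i)
    m <- fa_md(fit_tensor(dwi))
    sid <- sprintf("s%02d", i)
    maps[[sid]] <- list(fa = resample_to_common(m$fa, disp),
                        md = resample_to_common(m$md, disp))
    if (i <= 10) {
      smp <- true_orientation_samples(fld)
      rois <- lapply(base$rois[[1]], tractem:::warp_mask, disp = disp)
      cm <- track(smp, roi_set(rois$seed, list(target = rois$target)),
                  config = tracking_config(n_samples_per_seed_voxel = 100L,
                                           rng_seed = 3200 + i))
      conns[[sid]] <- resample_to_common(cm, disp)
    }
  }
  control_ids <- sprintf("s%02d", 1:10)
  holdout_ids <- sprintf("s%02d", 11:18)
  patient_ids <- sprintf("s%02d", 19:26)
  tpl <- build_template(conns[control_ids], tract_id = "t1")
  smask <- make_sampling_mask(tpl, config_label = "none")
  rep <- assess_cohort(maps, control_ids, list(t1 = smask))
  pct <- function(ids) {
    rep$pct_abnormal_md[rep$subject_id %in% ids & rep$method == "template"]
  }
  rs <- wilcoxon_rank_sum(pct(patient_ids), pct(holdout_ids),
                          alternative = "greater")
  expect_lt(rs$p, 0.05)
})
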