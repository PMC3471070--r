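# End-to-end workflow: phantom -> fit -> track -> template -> mask ->
# assess, with JSON configuration, per-stage seeds and a checksummed
# manifest of written artifacts.

#' Workflow configuration
#'
#' Collects every stage's parameters with the desk-scale defaults; all
#' randomness derives from \code{rng_seed}.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @param grid_dims common grid shape.
#' @param n_tracts number of bundles (1 or 2).
#' @param n_dirs,n_b0,bval acquisition scheme parameters.
#' @param tracking a \code{\link{tracking_config}}.
#' @param n_fibers,n_boot_samples ball-and-stick settings.
#' @param fa_mask_threshold smoothed-FA threshold defining the fitting mask
#'   (seed/target ROIs are always included).
#' @param template_percentile template threshold percentile (default 95).
#' @param masking_config sampling-mask configuration.
#' @param z_threshold,two_sided outlier rule.
#' @param rng_seed master seed (overrides the cohort spec's seed).
#' @param out_dir optional output directory; NULL keeps everything in
#'   memory.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            grid_dims = c(40L, 40L, 40L), n_tracts = 2L,
                            n_dirs = 32L, n_b0 = 4L, bval = 1000,
                            tracking = tracking_config(),
                            n_fibers = 2L, n_boot_samples = 50L,
                            fa_mask_threshold = 0.2,
                            template_percentile = 95,
                            masking_config = "skeleton+gm+csf",
                            z_threshold = 3, two_sided = FALSE,
                            rng_seed = NULL, out_dir = NULL) {
  if (!is.null(rng_seed)) cohort$rng_seed <- as.integer(rng_seed)
  structure(list(cohort = cohort, grid_dims = as.integer(grid_dims),
                 n_tracts = as.integer(n_tracts), n_dirs = as.integer(n_dirs),
                 n_b0 = as.integer(n_b0), bval = bval, tracking = tracking,
                 n_fibers = as.integer(n_fibers),
                 n_boot_samples = as.integer(n_boot_samples),
                 fa_mask_threshold = fa_mask_threshold,
                 template_percentile = template_percentile,
                 masking_config = masking_config, z_threshold = z_threshold,
                 two_sided = two_sided, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$tracking <- unclass(x$tracking)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- do.call(cohort_spec, as.list(x$cohort))
  tc <- do.call(tracking_config, x$tracking)
  args <- x[!(names(x) %in% c("cohort", "tracking"))]
  args$out_dir <- if (is.null(x$out_dir)) NULL else x$out_dir
  do.call(pipeline_config, c(list(cohort = cs, tracking = tc), args))
}

#' Data-driven model-fitting mask from an FA map
#'
#' Voxels with smoothed FA above the threshold, restricted to connected
#' components touching a seed/target ROI (dropping isolated noise blobs),
#' then morphologically closed so that low-FA pockets *inside* a bundle --
#' severely damaged tissue -- stay inside the mask: excluding them would
#' bias every lesion-sensitive quantity (dispersion, tracking) by ignoring
#' exactly the voxels that matter.
#'
#' @param fa_values 3D FA array (NAs treated as 0).
#' @param rois logical array of seed/target voxels (always included).
#' @param threshold smoothed-FA threshold (default 0.2).
#' @param close_iter closing radius in 6-neighbourhood dilation/erosion
#'   iterations (default 4, comfortably above the desk-scale tube radius).
#' @return logical 3D array.
#' @export
fit_mask_from_fa <- function(fa_values, rois, threshold = 0.2,
                             close_iter = 4L) {
  fa0 <- fa_values
  fa0[is.na(fa0)] <- 0
  dims <- dim(fa0)
  mask <- box_smooth(fa0) > threshold
  lab <- connected_components(mask, 26L)
  keep <- setdiff(unique(lab[rois & mask]), 0L)
  mask <- array(lab %in% keep, dims)
  grown <- mask
  for (i in seq_len(close_iter)) grown <- dilate_mask(grown, 6L)
  for (i in seq_len(close_iter)) grown <- !dilate_mask(!grown, 6L)
  (mask | grown) | rois
}

# fit + track one subject; returns common-grid maps and per-tract results
process_subject <- function(subject, scheme, geometry, config, seed) {
  dwi <- subject$dwi
  dims <- dim(dwi$signal)[1:3]
  tf <- fit_tensor(dwi)
  maps <- fa_md(tf)
  rois_all <- array(FALSE, dims)
  for (r in subject$rois) rois_all <- rois_all | r$seed | r$target
  fit_mask <- fit_mask_from_fa(maps$fa$values, rois_all,
                               config$fa_mask_threshold)
  samples <- fit_ball_and_stick(dwi, fit_mask, n_fibers = config$n_fibers,
                                n_samples = config$n_boot_samples,
                                rng_seed = derive_seed(seed, 3L))
  disp <- subject$disp
  tracts <- list()
  for (tn in names(subject$rois)) {
    rois <- roi_set(subject$rois[[tn]]$seed,
                    list(target = subject$rois[[tn]]$target),
                    exclusion = subject$exclusion,
                    csf = subject$csf, gm = subject$gm)
    cfg <- config$tracking
    cfg$rng_seed <- derive_seed(seed, 4L, match(tn, names(subject$rois)))
    cmap <- track(samples, rois, config = cfg, tract_id = tn)
    tracts[[tn]] <- list(
      map = cmap,
      map_common = resample_to_common(cmap, disp),
      success_rate = tract_success_rate(cmap)
    )
  }
  disp1 <- dispersion_map(samples, 1L)
  list(
    id = subject$id, role = subject$role, severity = subject$severity,
    fa = maps$fa, md = maps$md,
    fa_common = resample_to_common(maps$fa, disp),
    md_common = resample_to_common(maps$md, disp),
    dispersion = disp1,
    dispersion_common = resample_to_common(disp1, disp),
    tracts = tracts
  )
}

#' Run the full template-and-assessment workflow
#'
#' Generates (or accepts) a phantom cohort, fits tensors and the
#' ball-and-stick model per subject, tracks each tract, builds mean tract
#' templates from the controls, derives the skeleton and sampling masks,
#' computes volume-matched individual tracts, and assesses damage with both
#' methods.  Deterministic given the configuration; when \code{out_dir} is
#' set, all artifacts are written with a checksummed JSON manifest.
#'
#' @param config a \code{\link{pipeline_config}} or path to a JSON config.
#' @param cohort optional pre-built \code{phantom_cohort} (else generated
#'   from the config).
#' @param progress print per-stage timing to stderr.
#' @return a \code{pipeline_result} list: subjects (per-subject maps,
#'   connectivity, success rates), templates, skeleton, sampling_masks,
#'   reports (\code{damage_report}), comparison
#'   (\code{\link{compare_methods}} on the patients), config, manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         progress = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) {
    say("[%s] %5.1fs %s", format(Sys.time(), "%H:%M:%S"),
        as.numeric(difftime(Sys.time(), t0, units = "secs")), what)
  }
  seed <- config$cohort$rng_seed
  geometry <- default_geometry(config$grid_dims, n_tracts = config$n_tracts)
  scheme <- make_scheme(config$n_dirs, config$n_b0, config$bval)
  if (is.null(cohort)) {
    stage("phantom: generating cohort")
    cohort <- make_cohort(config$cohort, geometry, scheme)
  }
  subjects <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    stage(sprintf("fit+track subject %s (%s)", sub$id, sub$role))
    subjects[[sub$id]] <- process_subject(sub, scheme, geometry, config,
                                          derive_seed(seed, 100L, i))
    cohort$subjects[[i]]$dwi <- NULL     # free the 4D signal
  }
  roles <- vapply(subjects, `[[`, "", "role")
  control_ids <- names(subjects)[roles == "control"]
  tract_names <- names(geometry$tracts)

  stage("template: averaging control connectivity")
  templates <- list()
  for (tn in tract_names) {
    maps <- lapply(subjects[control_ids],
                   function(s) s$tracts[[tn]]$map_common)
    templates[[tn]] <- build_template(maps, config$template_percentile,
                                      tract_id = tn,
                                      provenance = control_ids)
  }

  stage("masking: skeleton from control mean FA")
  fa_stack <- lapply(subjects[control_ids], function(s) {
    v <- s$fa_common$values
    v[is.na(v)] <- 0
    v
  })
  mean_fa <- Reduce(`+`, fa_stack) / length(fa_stack)
  skeleton <- skeletonize(mean_fa)
  csf <- cohort$base$csf
  gm <- cohort$base$gm
  sampling_masks <- lapply(templates, function(tpl) {
    make_sampling_mask(tpl, skeleton, csf, gm, config$masking_config)
  })

  stage("assess: volume-matched binarization + Z scoring")
  individual_regions <- list()
  for (tn in tract_names) {
    individual_regions[[tn]] <- lapply(subjects, function(s) {
      m <- s$tracts[[tn]]$map_common
      if (sum(m$normalized > 0) == 0) return(NULL)
      volume_matched_binarize(m, templates[[tn]])
    })
  }
  maps <- lapply(subjects, function(s) list(fa = s$fa_common, md = s$md_common))
  reports <- assess_cohort(maps, control_ids, sampling_masks,
                           individual_regions,
                           z_threshold = config$z_threshold,
                           two_sided = config$two_sided)
  reports$role <- roles[reports$subject_id]
  reports$severity <- vapply(subjects, `[[`, 0, "severity")[reports$subject_id]
  pat <- reports[reports$role == "patient", ]
  comparison <- if (nrow(pat)) {
    compare_methods(pat, rng_seed = derive_seed(seed, 5L))
  } else NULL

  result <- structure(list(subjects = subjects, templates = templates,
                           skeleton = skeleton,
                           sampling_masks = sampling_masks,
                           reports = reports, comparison = comparison,
                           config = config, cohort = cohort),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    stage("write: artifacts + manifest")
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  stage("done")
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$subjects), " subjects, ",
      length(x$templates), " tract template(s)\n", sep = "")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

# write NIfTI/CSV/JSON artifacts and a manifest with md5 checksums
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(path) files <<- c(files, path)
  for (tn in names(result$templates)) {
    p <- file.path(out_dir, paste0("template_", tn, ".nii.gz"))
    write_nifti(result$templates[[tn]]$mask, p); put(p)
    pj <- file.path(out_dir, paste0("template_", tn, ".json"))
    tpl <- result$templates[[tn]]
    jsonlite::write_json(list(tract_id = tpl$tract_id,
                              n_subjects = tpl$n_subjects,
                              percentile = tpl$percentile,
                              threshold = tpl$threshold,
                              provenance = tpl$provenance),
                         pj, auto_unbox = TRUE, digits = NA)
    put(pj)
  }
  p <- file.path(out_dir, "skeleton.nii.gz")
  write_nifti(result$skeleton, p); put(p)
  for (tn in names(result$sampling_masks)) {
    sm <- result$sampling_masks[[tn]]
    p <- file.path(out_dir, paste0("sampling_mask_", tn, ".nii.gz"))
    write_nifti(sm$mask, p); put(p)
    pj <- file.path(out_dir, paste0("sampling_mask_", tn, ".json"))
    jsonlite::write_json(list(tract_id = sm$tract_id,
                              config_label = sm$config_label),
                         pj, auto_unbox = TRUE)
    put(pj)
  }
  p <- file.path(out_dir, "damage_report.csv")
  utils::write.csv(result$reports, p, row.names = FALSE); put(p)
  if (!is.null(result$comparison)) {
    p <- file.path(out_dir, "method_comparison.json")
    cmp <- result$comparison
    jsonlite::write_json(list(metric = cmp$metric, rho = cmp$rho, p = cmp$p,
                              p_approx = cmp$p_approx,
                              signed_rank = cmp$signed_rank,
                              degenerate = cmp$degenerate),
                         p, auto_unbox = TRUE, digits = NA)
    put(p)
    p2 <- file.path(out_dir, "method_pairs.csv")
    utils::write.csv(cmp$pairs, p2, row.names = FALSE); put(p2)
  }
  seeds <- list(master = result$config$cohort$rng_seed,
                tracking = result$config$tracking$rng_seed)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}
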