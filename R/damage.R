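# Voxelwise Z-score damage assessment against a control cohort, for the
# template and individual-tractography sampling methods, and the
# method-comparison statistics.

#' Voxelwise control mean and SD within a sampling mask
#'
#' @param control_maps list of \code{scalar_map}s (or 3D arrays) on the
#'   common grid, one per control subject (>= 2).
#' @param mask a \code{sampling_mask} or logical array.
#' @return a \code{cohort_stats}: list(mean, sd (3D arrays), n_controls,
#'   mask, valid).  Voxels where any control is undefined, or where the SD
#'   is zero (Z undefined), are flagged invalid and excluded from counts
#'   with a warning.
#' @export
control_stats <- function(control_maps, mask) {
  stopifnot(length(control_maps) >= 2L)
  m <- if (inherits(mask, "sampling_mask")) mask$mask else mask
  vols <- lapply(control_maps, function(x) {
    if (inherits(x, "scalar_map")) x$values else x
  })
  dims <- dim(vols[[1]])
  idx <- which(m)
  vals <- vapply(vols, function(v) v[idx], numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx))
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, sd)              # denominator n - 1
  valid_v <- !is.na(mu) & !is.na(sdv) & sdv > 0
  if (any(!valid_v)) {
    warning(sum(!valid_v), " voxel(s) with undefined Z (missing controls or ",
            "zero SD) excluded from abnormality counts")
  }
  mean_vol <- array(NA_real_, dims); mean_vol[idx] <- mu
  sd_vol <- array(NA_real_, dims); sd_vol[idx] <- sdv
  valid <- array(FALSE, dims); valid[idx] <- valid_v
  structure(list(mean = mean_vol, sd = sd_vol,
                 n_controls = length(control_maps), mask = mask,
                 valid = valid),
            class = "cohort_stats")
}

#' Percentage of abnormal voxels for one patient map
#'
#' Z = (patient - control mean) / control SD per valid masked voxel.  A
#' voxel is abnormal when Z exceeds \code{z_threshold} for MD, or falls
#' below \code{-z_threshold} for FA (axonal injury elevates diffusivity and
#' lowers anisotropy); \code{two_sided = TRUE} restores the symmetric
#' |Z| > threshold rule.
#'
#' @param patient a \code{scalar_map} (or 3D array) on the common grid.
#' @param stats a \code{\link{control_stats}} result for the same metric.
#' @param metric "MD" or "FA".
#' @param z_threshold default 3.
#' @param region optional extra logical array to intersect with the stats
#'   mask (the individual method's own tract).
#' @param two_sided use |Z| > threshold for both metrics.
#' @return list(pct_abnormal, n_voxels, n_abnormal, mean_value, metric).
#' @export
percent_abnormal <- function(patient, stats, metric = c("MD", "FA"),
                             z_threshold = 3, region = NULL,
                             two_sided = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(stats, "cohort_stats"))
  vals <- if (inherits(patient, "scalar_map")) patient$values else patient
  sel <- stats$valid
  if (!is.null(region)) sel <- sel & region
  sel <- sel & !is.na(vals)
  idx <- which(sel)
  if (!length(idx)) stop("no valid voxels to sample", call. = FALSE)
  z <- (vals[idx] - stats$mean[idx]) / stats$sd[idx]
  abnormal <- if (two_sided) {
    abs(z) > z_threshold
  } else if (metric == "MD") {
    z > z_threshold
  } else {
    z < -z_threshold
  }
  list(pct_abnormal = 100 * mean(abnormal), n_voxels = length(idx),
       n_abnormal = sum(abnormal), mean_value = mean(vals[idx]),
       metric = metric)
}

#' Assess a cohort: template vs individual tract sampling
#'
#' For every subject, tract and method, computes the percentage of abnormal
#' voxels (MD and FA) against control statistics built from
#' \code{control_ids}' maps within the tract's sampling mask.  The template
#' method samples the sampling mask itself; the individual method samples
#' the subject's own (volume-matched) tract intersected with the same mask,
#' so the comparison isolates tract-location differences.
#'
#' @param maps named list (subject id) of lists with \code{fa} and \code{md}
#'   \code{scalar_map}s in the common grid.
#' @param control_ids subject ids forming the control reference (>= 2).
#' @param sampling_masks named list (tract id) of \code{sampling_mask}s.
#' @param individual_regions nested named list
#'   \code{[[tract id]][[subject id]]} of logical arrays (a subject's own
#'   binarized tract); subjects with a missing/empty tract get a flagged
#'   absent row, never a silent skip.  NULL disables the individual method.
#' @param min_coverage individual-method reliability floor (default 0.25):
#'   when a subject's tract covers fewer valid sampling-mask voxels than
#'   this fraction of the template's count, the entry is flagged absent --
#'   the tract was reconstructed away from the template's location
#'   (tractography "failed almost completely") and a percentage estimated
#'   from the remaining handful of voxels is meaningless.
#' @param z_threshold,two_sided passed to \code{\link{percent_abnormal}}.
#' @return a \code{damage_report} data.frame: one row per subject x tract x
#'   method with pct_abnormal_md / pct_abnormal_fa / n_voxels / mean_fa /
#'   mean_md / absent.
#' @export
assess_cohort <- function(maps, control_ids, sampling_masks,
                          individual_regions = NULL, min_coverage = 0.25,
                          z_threshold = 3, two_sided = FALSE) {
  stopifnot(length(control_ids) >= 2L, all(control_ids %in% names(maps)))
  rows <- list()
  for (tract in names(sampling_masks)) {
    smask <- sampling_masks[[tract]]
    st_md <- control_stats(lapply(maps[control_ids], `[[`, "md"), smask)
    st_fa <- control_stats(lapply(maps[control_ids], `[[`, "fa"), smask)
    n_template <- sum(st_md$valid)
    for (sid in names(maps)) {
      methods <- "template"
      if (!is.null(individual_regions)) methods <- c(methods, "individual")
      for (method in methods) {
        region <- NULL
        absent <- FALSE
        if (method == "individual") {
          region <- individual_regions[[tract]][[sid]]
          n_cov <- if (is.null(region)) 0L else sum(region & st_md$valid)
          if (n_cov < ceiling(min_coverage * n_template)) {
            absent <- TRUE
          }
        }
        if (absent) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, tract_id = tract, method = method,
            pct_abnormal_md = NA_real_, pct_abnormal_fa = NA_real_,
            n_voxels = 0L, mean_fa = NA_real_, mean_md = NA_real_,
            absent = TRUE, stringsAsFactors = FALSE)
          next
        }
        md <- percent_abnormal(maps[[sid]]$md, st_md, "MD", z_threshold,
                               region, two_sided)
        fa <- percent_abnormal(maps[[sid]]$fa, st_fa, "FA", z_threshold,
                               region, two_sided)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, tract_id = tract, method = method,
          pct_abnormal_md = md$pct_abnormal, pct_abnormal_fa = fa$pct_abnormal,
          n_voxels = md$n_voxels, mean_fa = fa$mean_value,
          mean_md = md$mean_value, absent = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("damage_report", class(out))
  out
}

#' Compare template and individual damage estimates
#'
#' Pairs template/individual report rows per subject x tract, computes the
#' discrepancy (template % - individual %), the Spearman correlation between
#' the template estimate and the discrepancy (the underestimation-grows-
#' with-damage signature), and a paired Wilcoxon signed-rank test for the
#' overall method effect.  Per-tract correlations are reported with raw and
#' Holm-adjusted permutation p-values when at least 3 pairs exist.
#'
#' @param reports a \code{damage_report} (output of
#'   \code{\link{assess_cohort}}), typically restricted to patients.
#' @param metric "md" (default) or "fa".
#' @param rng_seed seed for permutation p-values.
#' @param absent_as_zero treat an absent individual-method entry (the
#'   subject's tractography produced no sampleable tract) as 0 percent
#'   abnormal -- failed tractography detects no damage, the extreme of the
#'   underestimation this comparison measures (default TRUE).  Pairs
#'   affected are flagged in \code{pairs$individual_absent}.
#' @return a \code{method_comparison}: list(pairs, rho, p, p_approx,
#'   signed_rank, per_tract, degenerate).
#' @export
compare_methods <- function(reports, metric = c("md", "fa"), rng_seed = 1L,
                            absent_as_zero = TRUE) {
  metric <- match.arg(metric)
  col <- paste0("pct_abnormal_", metric)
  ind_absent <- reports$method == "individual" & reports$absent
  if (absent_as_zero && any(ind_absent)) {
    reports[ind_absent, c("pct_abnormal_md", "pct_abnormal_fa")] <- 0
    reports$absent[ind_absent] <- FALSE
  }
  tpl <- reports[reports$method == "template" & !reports$absent, ]
  ind <- reports[reports$method == "individual" & !reports$absent, ]
  key <- function(d) paste(d$subject_id, d$tract_id, sep = "/")
  common <- intersect(key(tpl), key(ind))
  unpaired <- setdiff(union(key(tpl), key(ind)), common)
  if (length(unpaired)) {
    stop("unpaired template/individual entries: ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  }
  tpl <- tpl[match(common, key(tpl)), ]
  ind <- ind[match(common, key(ind)), ]
  pairs <- data.frame(subject_id = tpl$subject_id, tract_id = tpl$tract_id,
                      template = tpl[[col]], individual = ind[[col]],
                      individual_absent = ind$n_voxels == 0L,
                      stringsAsFactors = FALSE)
  pairs$discrepancy <- pairs$template - pairs$individual
  degenerate <- nrow(pairs) < 3L ||
    length(unique(pairs$template)) < 2L ||
    length(unique(pairs$discrepancy)) < 2L
  if (degenerate) {
    sp <- list(rho = NA_real_, p = NA_real_, p_approx = NA_real_)
  } else {
    sp <- spearman(pairs$template, pairs$discrepancy, rng_seed = rng_seed)
  }
  sr <- wilcoxon_signed_rank(pairs$template, pairs$individual)
  per_tract <- NULL
  for (tract in unique(pairs$tract_id)) {
    pp <- pairs[pairs$tract_id == tract, ]
    if (nrow(pp) >= 3L && length(unique(pp$template)) > 1L &&
        length(unique(pp$discrepancy)) > 1L) {
      s <- spearman(pp$template, pp$discrepancy, rng_seed = rng_seed)
      per_tract <- rbind(per_tract, data.frame(
        tract_id = tract, n = nrow(pp), rho = s$rho, p = s$p,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(per_tract)) per_tract$p_holm <- holm_adjust(per_tract$p)
  structure(list(pairs = pairs, rho = sp$rho, p = sp$p,
                 p_approx = sp$p_approx, signed_rank = sr,
                 per_tract = per_tract, degenerate = degenerate,
                 metric = metric),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison ", toupper(x$metric), "> ", nrow(x$pairs),
      " subject-tract pairs\n", sep = "")
  if (x$degenerate) {
    cat("  correlation degenerate (constant or < 3 pairs)\n")
  } else {
    cat(sprintf("  Spearman(template %%, discrepancy): rho = %.3f, p = %.4g\n",
                x$rho, x$p))
  }
  cat(sprintf("  paired signed-rank (template vs individual): V = %g, p = %.4g\n",
              x$signed_rank$statistic, x$signed_rank$p))
  invisible(x)
}
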