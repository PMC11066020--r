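# End-to-end orchestration: cohort -> per-subject ROI and metrics ->
# pooled thresholds and ROC threshold sweep -> group comparison. Failures
# are isolated per subject (skip and record); the run is a pure function of
# (config, cohort seed).

#' Pipeline configuration
#'
#' @param fluid A [fluid_properties()].
#' @param shear_threshold Low-shear threshold, 1/s (default 10, the
#'   coagulation-linked value).
#' @param velocity_candidates Low-velocity threshold sweep, cm/s (default
#'   0.5, 1, 2, 3, 5, 7.5, 10).
#' @param velocity_threshold Working low-velocity threshold, cm/s
#'   (default 3).
#' @param osi_top_pct Pooled upper-percentile for the high-OSI threshold
#'   (default 1).
#' @param roi_multiplier ROI downstream extent in CCA diameters
#'   (default 1.5).
#' @param presence_floor Stasis presence floor, % of ROI volume
#'   (default 0.1).
#' @param probe_fraction WSS probe depth as a fraction of local radius
#'   (default 0.1).
#' @param adjust Pairwise p-value adjustment for group tables (`"none"` or
#'   `"bonferroni"`).
#' @param centerline_source `"extract"` (march the cross-section centroids;
#'   falls back to generator metadata on failure, recorded in the manifest)
#'   or `"metadata"` (use the generator's exact centerline).
#' @param wall_metrics Compute WSS/OSI wall metrics (default TRUE; the
#'   volumetric stasis metrics alone are much cheaper).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fluid = fluid_properties(),
                            shear_threshold = 10,
                            velocity_candidates = c(0.5, 1, 2, 3, 5, 7.5, 10),
                            velocity_threshold = 3,
                            osi_top_pct = 1,
                            roi_multiplier = 1.5,
                            presence_floor = 0.1,
                            probe_fraction = 0.1,
                            adjust = c("none", "bonferroni"),
                            centerline_source = c("extract", "metadata"),
                            wall_metrics = TRUE) {
  stopifnot(shear_threshold > 0, all(velocity_candidates > 0),
            velocity_threshold > 0, roi_multiplier > 0,
            osi_top_pct > 0, osi_top_pct < 100)
  structure(list(fluid = fluid, shear_threshold = shear_threshold,
                 velocity_candidates = velocity_candidates,
                 velocity_threshold = velocity_threshold,
                 osi_top_pct = osi_top_pct, roi_multiplier = roi_multiplier,
                 presence_floor = presence_floor,
                 probe_fraction = probe_fraction,
                 adjust = match.arg(adjust),
                 centerline_source = match.arg(centerline_source),
                 wall_metrics = isTRUE(wall_metrics)),
            class = "pipeline_config")
}

# locate the lesion (narrowest lumen past the bifurcation) on a centerline;
# for unnarrowed geometries, the bifurcation itself
find_lesion_arclength <- function(cl, mesh) {
  bi <- cl$bifurcation_index
  if (is.na(bi) && !is.null(mesh$metadata$apex_arclength)) {
    s_bif <- mesh$metadata$apex_arclength
  } else if (!is.na(bi)) {
    s_bif <- cl$arclengths[bi]
  } else {
    s_bif <- cl$arclengths[1L]  # unbranched lumen: whole profile
  }
  n <- length(cl$arclengths)
  post <- which(cl$arclengths >= s_bif + 0.5 * cl$radii[1L])
  post <- setdiff(post, c(n - 1L, n))  # outlet-edge stations are unreliable
  if (length(post) < 3L) return(s_bif)
  r_post <- cl$radii[post]
  if (min(r_post) < 0.95 * stats::median(r_post)) {
    cl$arclengths[post[which.min(r_post)]]
  } else {
    s_bif
  }
}

#' Per-subject biomarker evaluation
#'
#' Builds the bulb ROI and computes the volumetric metrics (low-velocity
#' volume at the working threshold and at every sweep candidate, stasis)
#' and, when enabled, the wall metrics (time-averaged shear rate field,
#' OSI field, low-shear area).
#'
#' @param subject A cohort entry (`vitals`, `mesh`, `field`) or an
#'   equivalent list.
#' @param config A [pipeline_config()].
#' @return A list: `summary` (one-row data frame), `curve`, `osi_field`,
#'   `shear_field`, `roi`, `centerline_used`.
#' @export
evaluate_subject <- function(subject, config = pipeline_config()) {
  mesh <- subject$mesh; field <- subject$field
  cl_used <- "extract"
  cl <- if (config$centerline_source == "metadata") {
    cl_used <- "metadata"
    metadata_centerline(mesh)
  } else {
    tryCatch(extract_centerline(mesh), error = function(e) {
      cl_used <<- "metadata_fallback"
      metadata_centerline(mesh)
    })
  }
  D <- cca_diameter(cl)
  lesion_s <- find_lesion_arclength(cl, mesh)
  roi <- clip_bulb_roi(mesh, cl, lesion_s, D,
                       extent_multiplier = config$roi_multiplier)
  # volumetric metrics: one speed matrix, all thresholds
  vols <- tet_volumes(mesh)[roi$cells]
  sp <- cell_speed_matrix(field, mesh, roi$cells)
  pct_at <- function(thr) 100 * as.vector((sp < thr) %*% vols) / sum(vols)
  curve <- structure(data.frame(
    frame_times = field$frame_times,
    low_velocity_volume_pct = pct_at(config$velocity_threshold)),
    class = c("volume_fraction_curve", "data.frame"))
  sweep_means <- vapply(config$velocity_candidates, function(th) mean(pct_at(th)), 0)
  names(sweep_means) <- paste0("lv_", config$velocity_candidates)
  osi_field <- shear_field <- NULL
  low_shear <- NA_real_
  if (config$wall_metrics) {
    wss <- compute_wss(field, mesh, config$fluid,
                       probe_fraction = config$probe_fraction)
    shear_field <- shear_rate(wss, config$fluid)
    osi_field <- osi(wss)
    low_shear <- low_shear_area_pct(shear_field, roi, config$shear_threshold)
  }
  summary <- data.frame(
    subject_id = subject$vitals$subject_id,
    group = subject$vitals$group_label,
    event = subject$vitals$event_label,
    low_shear_area_pct = low_shear,
    high_osi_area_pct = NA_real_,  # needs the pooled threshold, filled later
    low_velocity_volume_pct = mean(curve$low_velocity_volume_pct),
    stasis_pct = stasis_pct(curve, config$presence_floor),
    stringsAsFactors = FALSE)
  summary <- cbind(summary, as.data.frame(as.list(sweep_means)))
  list(summary = summary, curve = curve, osi_field = osi_field,
       shear_field = shear_field, roi = roi, centerline_used = cl_used)
}

#' Run the full cohort pipeline
#'
#' Synthesizes (or accepts) a cohort, evaluates every subject, derives the
#' pooled OSI/shear thresholds, fills in the high-OSI areas, runs the
#' low-velocity threshold sweep and the group comparison, and optionally
#' writes the report bundle.
#'
#' @param cohort A [make_cohort()] result or a [cohort_spec()] (which is
#'   generated first).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report bundle
#'   (per-subject metrics CSV, ROC JSON, group-table CSV, manifest JSON).
#' @return A list of class `pipeline_result`: `subjects` (per-subject
#'   summary data frame), `sweep` (a `threshold_sweep`), `tables` (group
#'   comparisons per metric), `osi_threshold`, `low_shear_pooled_1pct`,
#'   `failures`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  if (inherits(cohort, "cohort_spec")) cohort <- make_cohort(cohort)
  stopifnot(inherits(cohort, "cohort") || is.list(cohort))
  results <- list(); failures <- list(); cl_sources <- character()
  for (s in cohort) {
    id <- s$vitals$subject_id
    r <- tryCatch(evaluate_subject(s, config), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[id]] <- conditionMessage(r)
    } else {
      results[[id]] <- r
      cl_sources[id] <- r$centerline_used
    }
  }
  if (!length(results)) stop("every subject failed", call. = FALSE)
  subjects <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(subjects) <- NULL
  osi_threshold <- NA_real_; shear_low_pooled <- NA_real_
  if (config$wall_metrics) {
    osi_threshold <- pooled_percentile_threshold(
      lapply(results, `[[`, "osi_field"), "upper", config$osi_top_pct)
    shear_low_pooled <- pooled_percentile_threshold(
      lapply(results, `[[`, "shear_field"), "lower", 1)
    subjects$high_osi_area_pct <- vapply(names(results), function(id) {
      high_osi_area_pct(results[[id]]$osi_field, results[[id]]$roi, osi_threshold)
    }, 0)
  }
  sweep_cols <- paste0("lv_", config$velocity_candidates)
  sweep <- threshold_sweep(subjects[, sweep_cols, drop = FALSE],
                           subjects$event, config$velocity_candidates)
  metric_cols <- c("low_shear_area_pct", "high_osi_area_pct",
                   "low_velocity_volume_pct", "stasis_pct")
  metric_cols <- metric_cols[vapply(metric_cols, function(m)
    !all(is.na(subjects[[m]])), TRUE)]
  tables <- group_summary_table(subjects, metrics = metric_cols,
                                adjust = config$adjust)
  manifest <- list(n_subjects = nrow(subjects),
                   n_failures = length(failures),
                   failures = failures,
                   centerline_sources = table(cl_sources),
                   seed = attr(cohort, "seed"),
                   config = config[setdiff(names(config), "fluid")])
  out <- structure(list(subjects = subjects, sweep = sweep, tables = tables,
                        osi_threshold = osi_threshold,
                        low_shear_pooled_1pct = shear_low_pooled,
                        failures = failures, manifest = manifest,
                        curves = lapply(results, `[[`, "curve")),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subjects (%d failures)\n",
              nrow(x$subjects), length(x$failures)))
  cat(sprintf("  best low-velocity threshold: %g cm/s (AUC %.3f)\n",
              x$sweep$best_threshold, x$sweep$best_auc))
  if (!is.na(x$osi_threshold))
    cat(sprintf("  pooled top-1%% OSI threshold: %.3f; pooled low-1%% shear: %.3g 1/s\n",
                x$osi_threshold, x$low_shear_pooled_1pct))
  for (m in names(x$tables)) {
    tb <- x$tables[[m]]
    if (inherits(tb, "group_comparison"))
      cat(sprintf("  %s: %s (KW p = %.3g)\n", m,
                  paste(sprintf("%s %.2f+-%.2f", tb$groups$group,
                                tb$groups$mean, tb$groups$sd), collapse = ", "),
                  tb$p_value))
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$subjects, file.path(dir, "subject_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(best_threshold_cm_s = result$sweep$best_threshold,
         best_auc = result$sweep$best_auc,
         candidates = lapply(result$sweep$results, function(r)
           list(auc = r$auc, gini = r$gini))),
    file.path(dir, "roc.json"), auto_unbox = TRUE, digits = NA)
  # Table-2-shaped CSV: per metric, group mean +- SD and pairwise p
  rows <- lapply(names(result$tables), function(m) {
    tb <- result$tables[[m]]
    if (!inherits(tb, "group_comparison")) return(NULL)
    data.frame(metric = m,
               group = tb$groups$group, n = tb$groups$n,
               mean = tb$groups$mean, sd = tb$groups$sd,
               kw_p = tb$p_value)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "group_table.csv"),
                   row.names = FALSE)
  fc <- attr(result$tables, "full_cycle_stasis")
  manifest <- result$manifest
  manifest$full_cycle_stasis <- as.list(fc)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
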