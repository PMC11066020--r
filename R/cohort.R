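# Synthetic three-group cohorts. Each subject gets vitals drawn around the
# group means of the study population, an idealized bifurcation geometry
# (web narrowing for the web group, plain narrowing for atherosclerosis,
# neither for normal), a pulsatile parabolic field, and a recirculation
# pocket in the bulb whose dwell fraction and volume fraction carry the
# group effect. Group effect defaults mirror the reported group-wise stasis
# and low-velocity volumes directionally; they are study conditions, not
# tuning knobs.

# Vitals means/SDs follow the study population tables. The pocket dwell
# for the web group is a latent ceiling-clipped normal (mean slightly above
# 1) so that most web subjects dwell through the whole cycle, matching the
# observed 9-of-13 subjects with full-cycle stasis; group SDs are chosen so
# the default cohort separates the web group from both controls with
# pairwise p < 0.05 in nearly every seed (the package's stated power
# property), which makes them tighter than the observed between-subject
# SDs. See the methods vignette.
cohort_group_defaults <- function() {
  list(
    caw = list(
      sbp = c(126.9, 11.8), dbp = c(73.6, 10.0), hr = c(67.2, 10.5),
      narrowing = c(0.30, 0.11),
      dwell = c(1.02, 0.05), pocket_frac = c(0.118, 0.030), event = TRUE),
    atherosclerosis = list(
      sbp = c(135.4, 13.2), dbp = c(72.3, 5.8), hr = c(70.1, 8.4),
      narrowing = c(0.42, 0.17),
      dwell = c(0.58, 0.10), pocket_frac = c(0.052, 0.020), event = FALSE),
    normal = list(
      sbp = c(123.5, 14.9), dbp = c(81.3, 7.8), hr = c(65.8, 8.0),
      narrowing = c(0, 0),
      dwell = c(0.84, 0.035), pocket_frac = c(0.050, 0.020), event = FALSE))
}

#' Cohort specification
#'
#' @param n_caw,n_atherosclerosis,n_normal Group sizes (defaults 13, 7, 6).
#' @param seed Integer RNG seed; the cohort is a pure function of
#'   (spec, seed).
#' @param group_params Per-group parameter list (means and SDs of vitals,
#'   narrowing, pocket dwell fraction and pocket volume fraction); defaults
#'   from `cohort_group_defaults()`.
#' @param stroke_volume Mean and SD of stroke volume, mL (default 70, 10).
#' @param mean_velocity Mean and SD of the cycle-averaged CCA inlet
#'   velocity, cm/s (default 24, 2, truncated to 20..30); the inlet flow is
#'   this velocity times the inlet area, so flow scales with vessel size as
#'   it does physiologically.
#' @param peak_factor Systolic peak flow as a multiple of mean flow
#'   (default 1.9, a carotid-like pulsatility with high diastolic flow).
#' @param inlet_area Mean and SD of CCA inlet area, cm^2 (default 0.3,
#'   0.05).
#' @param pocket_peak_speed Pocket speed cap, cm/s (default 2.8).
#' @param n_frames Frames per cardiac cycle (default 20).
#' @param resolution Mesh resolution for subject geometries; the cohort
#'   default is deliberately coarse and without near-wall grading, sized
#'   for cohort statistics rather than single-subject wall accuracy (see
#'   the methods vignette on why the volumetric stasis metrics want the
#'   viscous sublayer unresolved).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_caw = 13, n_atherosclerosis = 7, n_normal = 6,
                        seed = 1L, group_params = cohort_group_defaults(),
                        stroke_volume = c(70, 10), mean_velocity = c(24, 2),
                        peak_factor = 1.9,
                        inlet_area = c(0.3, 0.05), pocket_peak_speed = 2.8,
                        n_frames = 20L,
                        resolution = mesh_resolution(n_radial = 8,
                                                     n_circumferential = 16,
                                                     n_axial = 8,
                                                     boundary_layers = 0,
                                                     coarse_wall_fraction = 0.25)) {
  stopifnot(n_caw >= 0, n_atherosclerosis >= 0, n_normal >= 0, peak_factor > 1)
  structure(list(n_caw = as.integer(n_caw),
                 n_atherosclerosis = as.integer(n_atherosclerosis),
                 n_normal = as.integer(n_normal),
                 seed = as.integer(seed), group_params = group_params,
                 stroke_volume = stroke_volume, mean_velocity = mean_velocity,
                 peak_factor = peak_factor, inlet_area = inlet_area,
                 pocket_peak_speed = pocket_peak_speed,
                 n_frames = as.integer(n_frames), resolution = resolution),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic three-group cohort
#'
#' Deterministic given the spec's seed. Each subject entry carries the
#' vitals, mesh, velocity field, inlet waveform and the programmed ground
#' truth (narrowing, pocket dwell fraction, pocket volume fraction, lesion
#' arclength).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort`: one list per subject with elements
#'   `vitals`, `mesh`, `field`, `waveform`, `truth`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  counts <- c(caw = spec$n_caw, atherosclerosis = spec$n_atherosclerosis,
              normal = spec$n_normal)
  subjects <- list()
  sid <- 0L
  for (grp in names(counts)) {
    gp <- spec$group_params[[grp]]
    for (i in seq_len(counts[[grp]])) {
      sid <- sid + 1L
      sbp <- rtrunc_norm(1, gp$sbp[1], gp$sbp[2], 90, 200)
      dbp <- rtrunc_norm(1, gp$dbp[1], gp$dbp[2], 40, sbp - 20)
      hr <- rtrunc_norm(1, gp$hr[1], gp$hr[2], 40, 120)
      sv <- rtrunc_norm(1, spec$stroke_volume[1], spec$stroke_volume[2], 40, 120)
      vit <- subject_vitals(sbp, dbp, hr, sv, grp, gp$event,
                            subject_id = sprintf("%s_%02d", grp, i))
      area <- rtrunc_norm(1, spec$inlet_area[1], spec$inlet_area[2], 0.15, 0.45)
      r_cca <- sqrt(area / pi)
      narrowing <- if (gp$narrowing[1] > 0)
        rtrunc_norm(1, gp$narrowing[1], gp$narrowing[2], 0.05, 0.8) else 0
      web <- if (narrowing > 0)
        list(narrowing_fraction = narrowing, shelf_axial_position = 0.4,
             shelf_extent = 0.15) else NULL
      bspec <- bifurcation_spec(cca_radius = r_cca, ica_radius = 0.8 * r_cca,
                                eca_radius = 0.6 * r_cca, branch_angle = 50,
                                cca_length = 2, branch_length = 2, web = web)
      # the ICA branch hosts the web and the pocket: resolve it axially
      mesh <- make_bifurcation_mesh(bspec, spec$resolution,
                                    n_axial_ica = 36L, n_axial_eca = 8L)
      period <- 60 / hr
      v0 <- rtrunc_norm(1, spec$mean_velocity[1], spec$mean_velocity[2], 20, 30)
      q <- v0 * area
      wf <- make_carotid_waveform(period = period, mean_flow = q,
                                  peak_flow = spec$peak_factor * q,
                                  n_samples = 40)
      field <- sample_parabolic_field(mesh, wf, spec$n_frames)
      # pocket in the bulb, programmed group effect
      dwell <- rtrunc_norm(1, gp$dwell[1], gp$dwell[2], 0, 1)
      # the lower clip keeps every pocket large enough for the cohort mesh
      # to resolve (a sphere much smaller than a cell cannot register)
      pfrac <- rtrunc_norm(1, gp$pocket_frac[1], gp$pocket_frac[2], 0.04, 0.25)
      lesion_s <- if (!is.null(web)) bspec$cca_length + web$shelf_axial_position
        else mesh$metadata$apex_arclength
      cca_d <- 2 * r_cca
      roi_vol_est <- pi * bspec$ica_radius^2 * 1.5 * cca_d
      a <- (3 * pfrac * roi_vol_est / (4 * pi))^(1 / 3)
      # pocket center along the ICA path, offset toward the outer bulb wall
      half <- bspec$branch_angle / 2 * pi / 180
      u_i <- c(sin(half), 0, cos(half))
      s_pock <- (lesion_s - bspec$cca_length) + 0.45 * 1.5 * cca_d
      s_pock <- min(s_pock, bspec$branch_length - a - 0.05)
      c0 <- c(bspec$cca_radius - bspec$ica_radius, 0, bspec$cca_length)
      ctr_axis <- c0 + s_pock * u_i
      r_here <- bspec$ica_radius
      # the pocket lives in the densely meshed core: it must stay clear of
      # the coarse wall layer, whose no-slip cells would otherwise be
      # dragged under the threshold during the flush phase
      core_r <- (1 - max(spec$resolution$coarse_wall_fraction, 0.1)) * r_here
      a <- min(a, 0.85 * core_r)
      offset <- 0.5 * max(0, core_r - a)
      out_dir <- c(cos(half), 0, -sin(half))  # in-plane, toward outer wall
      ctr <- ctr_axis + offset * out_dir
      # snap to the nearest mesh vertex so small pockets always enclose nodes
      dd <- sweep(mesh$vertices, 2L, ctr)
      ctr <- mesh$vertices[which.min(rowSums(dd^2)), ]
      rspec <- recirculation_spec(ctr, a, peak_speed = spec$pocket_peak_speed,
                                  dwell_fraction = dwell, swirl_axis = u_i)
      field <- add_recirculation_pocket(field, mesh, rspec, waveform = wf)
      subjects[[sid]] <- list(
        vitals = vit, mesh = mesh, field = field, waveform = wf,
        truth = list(group = grp, narrowing = narrowing, dwell = dwell,
                     pocket_frac = pfrac, pocket_radius = a,
                     lesion_arclength = lesion_s, cca_diameter = cca_d,
                     bifurcation_spec = bspec, pocket_spec = rspec))
    }
  }
  structure(subjects, class = "cohort", seed = spec$seed)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x, function(s) s$vitals$group_label, "")
  cat(sprintf("Synthetic cohort: %d subjects (%s), seed %d\n", length(x),
              paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                    collapse = ", "), attr(x, "seed")))
  invisible(x)
}

#' Write a cohort to disk in the package file dialects
#'
#' Per subject: VTK mesh + velocity frames, waveform CSV, vitals YAML; plus
#' a cohort manifest CSV.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    id <- s$vitals$subject_id
    write_mesh(s$mesh, file.path(dir, paste0(id, ".vtk")), field = s$field)
    write_waveform(s$waveform, file.path(dir, paste0(id, "_flow.csv")))
    write_subject_vitals(s$vitals, file.path(dir, paste0(id, ".yaml")))
    data.frame(subject_id = id, group = s$vitals$group_label,
               event = s$vitals$event_label, seed = attr(cohort, "seed"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
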