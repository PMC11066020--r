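test_that("carotid waveform hits its mean and peak and stays positive", {
  for (prm in list(c(0.9, 6, 18), c(0.8, 4, 9), c(0.9, 6, 6.01))) {
    wf <- make_carotid_waveform(prm[1], prm[2], prm[3], 40)
    expect_equal(waveform_mean_flow(wf), prm[2], tolerance = 0.005)
    expect_equal(max(wf$flows), prm[3], tolerance = 0.005)
    expect_gt(min(wf$flows), 0)
    expect_equal(wf$period, prm[1])
  }
  expect_error(make_carotid_waveform(0.9, 6, 5), "exceed")
})

test_that("tube mesh volume and inlet area match the analytic cylinder", {
  m <- fx_tube()
  expect_equal(mesh_volume(m), pi * 0.09 * 3, tolerance = 0.02)
  ia <- sum(surface_areas(m$boundary)[m$boundary$labels == "inlet"])
  expect_equal(ia, pi * 0.09, tolerance = 0.02)
  oa <- sum(surface_areas(m$boundary)[m$boundary$labels == "outlet_ica"])
  expect_equal(oa, ia, tolerance = 1e-9)
})

test_that("refinement halves the tube volume error or better", {
  err0 <- abs(mesh_volume(fx_tube()) / (pi * 0.09 * 3) - 1)
  m1 <- make_tube_mesh(0.3, 3, refine_resolution(mesh_resolution()))
  err1 <- abs(mesh_volume(m1) / (pi * 0.09 * 3) - 1)
  expect_lt(err1, err0 / 2)
})

test_that("parabolic field conserves flux and satisfies no-slip", {
  m <- fx_tube()
  wf <- make_carotid_waveform(0.9, 6, 18, 40)
  f <- sample_parabolic_field(m, wf, 20)
  surf <- m$boundary
  inl <- which(surf$labels == "inlet")
  tri <- surf$triangles[inl, ]
  ar <- surface_areas(surf)[inl]
  nrm <- surf$normals[inl, ]
  vmap <- m$boundary_map
  Qf <- waveform_function(wf)
  for (k in c(1L, 4L, 11L)) {
    vm <- (f$values[[k]][vmap[tri[, 1]], ] + f$values[[k]][vmap[tri[, 2]], ] +
             f$values[[k]][vmap[tri[, 3]], ]) / 3
    flux <- -sum(rowSums(vm * nrm) * ar)
    expect_equal(flux, Qf(f$frame_times[k]), tolerance = 0.02)
  }
  wallv <- unique(as.vector(surf$triangles[surf$labels == "wall", ]))
  speeds <- sqrt(rowSums(f$values[[1]][vmap[wallv], ]^2))
  expect_equal(max(speeds), 0)
})

test_that("centerline vertex carries the peak parabolic speed 2Q/(pi R^2)", {
  m <- fx_tube()
  wf <- make_carotid_waveform(0.9, 6, 18, 40)
  f <- sample_parabolic_field(m, wf, 20)
  k <- which.max(waveform_function(wf)(f$frame_times))
  axis_pts <- which(m$metadata$vertex$rho == 0)
  sp <- sqrt(rowSums(f$values[[k]][axis_pts, ]^2))
  Qk <- waveform_function(wf)(f$frame_times[k])
  expect_equal(max(sp), 2 * Qk / (pi * 0.3^2), tolerance = 1e-9)
})

test_that("bifurcation mesh has labeled branches and the requested radii", {
  bs <- bifurcation_spec()
  m <- make_bifurcation_mesh(bs, mesh_resolution(n_radial = 6,
                                                 n_circumferential = 16,
                                                 n_axial = 12,
                                                 boundary_layers = 0))
  expect_setequal(unique(m$boundary$labels),
                  c("wall", "inlet", "outlet_ica", "outlet_eca"))
  # no-web ICA keeps its nominal radius along the whole branch
  md <- m$metadata$centerline
  post <- md$arclengths > bs$cca_length
  expect_equal(min(md$radii[post]), bs$ica_radius, tolerance = 1e-9)
  # Murray split over outlet diameters (exponent 2.1)
  expect_equal(unname(m$metadata$flux_fractions[c("ica", "eca")]),
               unname(murray_fractions(2 * c(0.24, 0.18))), tolerance = 1e-12)
})

test_that("web narrowing reduces the minimum ICA lumen as constructed", {
  bs <- bifurcation_spec(web = list(narrowing_fraction = 0.3,
                                    shelf_axial_position = 0.8,
                                    shelf_extent = 0.15))
  m <- make_bifurcation_mesh(bs, mesh_resolution(n_radial = 6,
                                                 n_circumferential = 16,
                                                 n_axial = 12,
                                                 boundary_layers = 0),
                             n_axial_ica = 30)
  md <- m$metadata$centerline
  expect_equal(min(md$radii), 0.24 * 0.7, tolerance = 0.01)
  expect_error(bifurcation_spec(web = list(narrowing_fraction = 1.2,
                                           shelf_axial_position = 0.5)),
               "narrowing_fraction")
  expect_error(bifurcation_spec(web = list(narrowing_fraction = 0.3,
                                           shelf_axial_position = 5)),
               "outside")
})

test_that("dwell frame rounding is nearest with ties toward more frames", {
  expect_equal(dwell_frame_count(0.3, 20), 6L)
  expect_equal(dwell_frame_count(0.325, 20), 7L)  # 6.5 -> 7
  expect_equal(dwell_frame_count(0, 20), 0L)
  expect_equal(dwell_frame_count(1, 20), 20L)
})

test_that("pocket speeds respect the cap during dwell and exceed it in flush", {
  m <- fx_tube()
  wf <- fx_steady_waveform(30 * pi * 0.09)
  f0 <- sample_parabolic_field(m, wf, 20)
  rs <- recirculation_spec(c(0, 0, 1.5), 0.15, peak_speed = 2.8,
                           dwell_fraction = 0.3)
  f <- add_recirculation_pocket(f0, m, rs, waveform = wf)
  pv <- attr(f, "pocket_vertices")
  below <- vapply(seq_len(20), function(k)
    max(sqrt(rowSums(f$values[[k]][pv, , drop = FALSE]^2))) < 2.8, TRUE)
  expect_equal(sum(below), 6L)
  # dwell_fraction 1: capped at every frame
  f1 <- add_recirculation_pocket(f0, m, recirculation_spec(c(0, 0, 1.5), 0.15,
                                                           dwell_fraction = 1),
                                 waveform = wf)
  below1 <- vapply(seq_len(20), function(k)
    max(sqrt(rowSums(f1$values[[k]][pv, , drop = FALSE]^2))) < 2.8, TRUE)
  expect_true(all(below1))
  # field untouched outside the pocket
  out <- setdiff(seq_len(nrow(m$vertices)), pv)
  expect_identical(f$values[[1]][out, ], f0$values[[1]][out, ])
  # sphere outside the lumen is rejected
  expect_error(add_recirculation_pocket(f0, m,
                                        recirculation_spec(c(5, 5, 5), 0.1)),
               "outside")
})

test_that("cohorts are reproducible and have the requested group structure", {
  cs <- cohort_spec(n_caw = 2, n_atherosclerosis = 2, n_normal = 2, seed = 5)
  c1 <- make_cohort(cs)
  c2 <- make_cohort(cs)
  expect_length(c1, 6)
  expect_identical(lapply(c1, function(s) s$field$values),
                   lapply(c2, function(s) s$field$values))
  expect_identical(vapply(c1, function(s) s$vitals$group_label, ""),
                   rep(c("caw", "atherosclerosis", "normal"), each = 2))
  expect_true(all(vapply(c1[1:2], function(s) s$vitals$event_label, TRUE)))
  expect_false(any(vapply(c1[3:6], function(s) s$vitals$event_label, TRUE)))
  # different seed changes the draw
  c3 <- make_cohort(cohort_spec(2, 2, 2, seed = 6))
  expect_false(identical(c1[[1]]$vitals$systolic, c3[[1]]$vitals$systolic))
})

test_that("cohort files are written in the package dialects with a manifest", {
  cs <- cohort_spec(n_caw = 1, n_atherosclerosis = 0, n_normal = 1, seed = 2)
  coh <- make_cohort(cs)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rt <- read_mesh_vtk(file.path(dir, paste0(coh[[1]]$vitals$subject_id, ".vtk")))
  expect_equal(nrow(rt$mesh$vertices), nrow(coh[[1]]$mesh$vertices))
  expect_equal(length(rt$field$values), 20)
})
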