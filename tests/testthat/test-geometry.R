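test_that("straight-tube centerline recovers the axis and radius", {
  cl <- fx_tube_centerline()
  expect_lt(max(sqrt(rowSums(cl$points[, 1:2, drop = FALSE]^2))), 0.02)
  expect_equal(cl$radii, rep(cl$radii[1], length(cl$radii)))
  expect_equal(cl$radii[1], 0.3, tolerance = 0.01 / 0.3)
  expect_equal(max(cl$arclengths), 3, tolerance = 0.02)
  expect_true(is.na(cl$bifurcation_index))
})

test_that("bent-tube centerline arclength matches the analytic arc", {
  Rc <- 1.5; r <- 0.25
  th <- seq(0, pi / 2, length.out = 25)
  centers <- cbind(Rc * sin(th), 0, Rc * (1 - cos(th)))
  axes <- cbind(cos(th), 0, sin(th))
  res <- mesh_resolution(n_radial = 6, n_circumferential = 16, n_axial = 24,
                         boundary_layers = 0)
  seg <- bulbflow:::gc_segment(centers, axes, rep(r, 25), Rc * th, res, "trunk")
  mesh <- bulbflow:::assemble_mesh(
    list(seg),
    list(list(seg = 1, which = "first", label = "inlet", outward = -axes[1, ]),
         list(seg = 1, which = "last", label = "outlet_ica", outward = axes[25, ])),
    list(kind = "bent"))
  cl <- extract_centerline(mesh)
  expect_equal(max(cl$arclengths), Rc * pi / 2, tolerance = 0.02)
  expect_equal(median(cl$radii), r, tolerance = 0.02)
})

test_that("bifurcation is detected near the constructed apex on the ICA path", {
  bs <- bifurcation_spec()
  m <- make_bifurcation_mesh(bs, mesh_resolution(n_radial = 6,
                                                 n_circumferential = 16,
                                                 n_axial = 16,
                                                 boundary_layers = 0))
  cl <- extract_centerline(m, target = "outlet_ica")
  expect_false(is.na(cl$bifurcation_index))
  s_bif <- cl$arclengths[cl$bifurcation_index]
  # within two radius-steps of the constructed apex
  expect_lt(abs(s_bif - m$metadata$apex_arclength), 2 * 0.25 * bs$cca_radius + 0.05)
  # the march ends at the ICA outlet, not the ECA
  endp <- cl$points[nrow(cl$points), ]
  expect_gt(endp[1], 0.5)  # ICA tilts toward +x
})

test_that("cca_diameter is the doubled median inlet radius, robust to outliers", {
  cl <- fx_tube_centerline()
  expect_equal(cca_diameter(cl), 0.6, tolerance = 0.01)
  s <- seq(0, 2, by = 0.05)
  r <- rep(sqrt(0.3 / pi), length(s))
  cl2 <- centerline(cbind(0, 0, s), r, s)
  expect_equal(cca_diameter(cl2), 2 * sqrt(0.3 / pi), tolerance = 1e-12)
  r_out <- r; r_out[3] <- 5 * r[3]  # single outlier station inside the window
  cl3 <- centerline(cbind(0, 0, s), r_out, s)
  expect_equal(cca_diameter(cl3), cca_diameter(cl2))
})

test_that("percent narrowing reproduces constructed lesions (ECST-style)", {
  s <- seq(0, 4, by = 0.05)
  mk <- function(frac, R = 0.24) centerline(
    cbind(0, 0, s), R * (1 - frac * exp(-((s - 2) / 0.15)^2)), s)
  expect_equal(percent_narrowing(mk(0.30)), 30, tolerance = 2)
  expect_equal(percent_narrowing(mk(0.42, R = 0.3)), 42, tolerance = 2)
  expect_equal(percent_narrowing(centerline(cbind(0, 0, s),
                                            rep(0.24, length(s)), s)), 0)
  # profile too short to place reference windows
  s2 <- seq(0, 0.4, by = 0.05)
  cl2 <- centerline(cbind(0, 0, s2),
                    0.24 * (1 - 0.3 * exp(-((s2 - 0.2) / 0.05)^2)), s2)
  expect_error(percent_narrowing(cl2), "insufficient")
})

test_that("extracted narrowing of a meshed web tracks the built geometry", {
  bs <- bifurcation_spec(web = list(narrowing_fraction = 0.3,
                                    shelf_axial_position = 0.8,
                                    shelf_extent = 0.3))
  m <- make_bifurcation_mesh(bs, mesh_resolution(n_radial = 6,
                                                 n_circumferential = 16,
                                                 n_axial = 16,
                                                 boundary_layers = 0),
                             n_axial_ica = 30)
  cl <- extract_centerline(m, target = "outlet_ica")
  built <- 100 * (1 - min(m$metadata$centerline$radii) / bs$ica_radius)
  got <- percent_narrowing(cl)
  expect_gt(got, 10)               # a web is clearly detected ...
  expect_lt(abs(got - built), 10)  # ... near the built degree (slab-smeared)
})

test_that("bulb ROI spans exactly 1.5 CCA diameters with analytic volume", {
  m <- fx_tube()
  cl <- fx_tube_centerline()
  roi <- clip_bulb_roi(m, cl, 1.0, 0.6)
  expect_equal(roi$end_arclength - roi$start_arclength, 0.9, tolerance = 1e-9)
  expect_equal(roi$roi_volume, pi * 0.09 * 0.9, tolerance = 0.05)
  expect_equal(roi$roi_surface_area, 2 * pi * 0.3 * 0.9, tolerance = 0.05)
  expect_false(roi$truncated)
  # membership is monotone: a longer span contains every member of a shorter
  roi2 <- clip_bulb_roi(m, cl, 1.0, 0.8)
  expect_true(all(roi$cells %in% roi2$cells))
  expect_true(all(roi$wall_faces %in% roi2$wall_faces))
  # spans beyond the mesh record a truncation flag, not an error
  roi3 <- clip_bulb_roi(m, cl, 2.5, 0.6)
  expect_true(roi3$truncated)
  expect_error(clip_bulb_roi(m, cl, 50, 0.6), "empty ROI")
})

test_that("ROI export writes a JSON summary and member lists", {
  m <- fx_tube()
  roi <- clip_bulb_roi(m, fx_tube_centerline(), 1.0, 0.6)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, tmp)
  j <- jsonlite::read_json(tmp)
  expect_equal(j$volume_cm3, roi$roi_volume)
  expect_equal(j$n_cells, length(roi$cells))
  expect_true(file.exists(paste0(tmp, ".members.csv")))
})
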