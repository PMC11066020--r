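test_that("pressure conversions use the standard constant and round-trip", {
  expect_equal(mmHg_to_cgs(1), 1333.22)
  expect_equal(mmHg_to_cgs(0), 0)
  expect_equal(mmHg_to_cgs(91.4), 121856.3, tolerance = 0.1 / 121856.3)
  p <- c(0.001, 1, 80, 120.7, 250)
  expect_equal(cgs_to_mmHg(mmHg_to_cgs(p)), p, tolerance = 1e-12)
})

test_that("fluid properties validate physical ranges", {
  f <- fluid_properties()
  expect_equal(f$viscosity, 0.04)
  expect_equal(f$density, 1.06)
  expect_error(fluid_properties(viscosity = 0), "viscosity")
  expect_error(fluid_properties(density = -1), "density")
})

test_that("waveform CSV round-trips and shifts times to zero", {
  tt <- seq(0.1, 0.95, length.out = 20)
  q <- 6 + 5 * sin(seq(0, 2 * pi, length.out = 20))
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = tt, flow_mL_s = q), tmp, row.names = FALSE)
  wf <- read_waveform(tmp, period = 0.9)
  expect_length(wf$times, 20)
  expect_equal(wf$times[1], 0)
  expect_equal(wf$flows, q)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, tmp2)
  wf2 <- read_waveform(tmp2, period = 0.9)
  expect_equal(wf2$times, wf$times, tolerance = 1e-9)
  expect_equal(wf2$flows, wf$flows, tolerance = 1e-9)
})

test_that("waveform reader rejects malformed inputs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = c(0, 0.1, 0.1, 0.3, 0.4),
                              flow_mL_s = rep(5, 5)), tmp, row.names = FALSE)
  expect_error(read_waveform(tmp, 0.9), "increasing")
  utils::write.csv(data.frame(time_s = c(0, 0.1), flow_mL_s = c(5, 5)),
                   tmp, row.names = FALSE)
  expect_error(read_waveform(tmp, 0.9), "4 rows")
  utils::write.csv(data.frame(a = 1:5, b = 1:5), tmp, row.names = FALSE)
  expect_error(read_waveform(tmp, 0.9), "column")
})

test_that("subject vitals YAML round-trips and validates", {
  v <- subject_vitals(126.9, 73.6, 67.2, 70, "caw", TRUE, "s01")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_subject_vitals(v, tmp)
  v2 <- read_subject_vitals(tmp)
  expect_equal(v2[c("systolic", "diastolic", "heart_rate", "stroke_volume",
                    "group_label", "event_label")],
               v[c("systolic", "diastolic", "heart_rate", "stroke_volume",
                   "group_label", "event_label")])
  expect_error(subject_vitals(70, 80, 60, 70, "normal"), "systolic")
  expect_error(subject_vitals(120, 80, -5, 70, "normal"), "heart_rate")
})

test_that("mesh + field VTK round-trip is lossless to 9 significant digits", {
  m <- fx_tube_coarse()
  wf <- fx_steady_waveform(4)
  fld <- sample_parabolic_field(m, wf, 8)
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, tmp, field = fld)
  rt <- read_mesh_vtk(tmp)
  expect_equal(nrow(rt$mesh$vertices), nrow(m$vertices))
  expect_equal(nrow(rt$mesh$tetrahedra), nrow(m$tetrahedra))
  expect_equal(nrow(rt$mesh$boundary$triangles), nrow(m$boundary$triangles))
  expect_equal(sort(table(rt$mesh$boundary$labels)),
               sort(table(m$boundary$labels)))
  expect_lt(max(abs(rt$mesh$vertices - m$vertices)), 1e-9 * max(abs(m$vertices)) * 10)
  expect_equal(length(rt$field$values), 8)
  expect_lt(max(abs(rt$field$values[[5]] - fld$values[[5]])),
            1e-9 * max(abs(fld$values[[5]])) * 10)
  expect_equal(rt$field$period, fld$period)
  # second write reproduces counts exactly (idempotent round trip)
  tmp2 <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(rt$mesh, tmp2, field = rt$field)
  rt2 <- read_mesh_vtk(tmp2)
  expect_equal(rt2$mesh$tetrahedra, rt$mesh$tetrahedra)
})

test_that("mesh reader rejects unsupported cells and malformed files", {
  m <- fx_tube_coarse()
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, tmp)
  lines <- readLines(tmp)
  # turn one tetrahedron into a pyramid (VTK cell type 14)
  i <- grep("^CELL_TYPES", lines) + 1L
  lines[i] <- "14"
  tmp2 <- withr::local_tempfile(fileext = ".vtk")
  writeLines(lines, tmp2)
  expect_error(read_mesh(tmp2), "unsupported cell type")
  # corrupt a coordinate token
  lines <- readLines(tmp)
  j <- grep("^POINTS", lines) + 3L
  lines[j] <- sub("^[-0-9.eE+]+", "bogus", lines[j])
  writeLines(lines, tmp2)
  expect_error(read_mesh(tmp2), "parse error at line")
  # not a VTK file at all
  writeLines(c("hello", "world"), tmp2)
  expect_error(read_mesh(tmp2), "line 1")
})

test_that("random header corruptions are always rejected, never mis-read", {
  m <- fx_tube_coarse()
  tmp <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(m, tmp)
  base <- readLines(tmp)
  set.seed(404)
  hdr <- grep("^(POINTS|CELLS|CELL_TYPES|CELL_DATA|DATASET)", base)
  for (k in 1:10) {
    lines <- base
    i <- sample(hdr, 1L)
    lines[i] <- paste(sample(strsplit(lines[i], " ")[[1]]), collapse = "x")
    tmp2 <- tempfile(fileext = ".vtk")
    writeLines(lines, tmp2)
    expect_error(read_mesh(tmp2))
    unlink(tmp2)
  }
})

test_that("STL surfaces round-trip with labels via the sidecar", {
  s <- fx_tube_coarse()$boundary
  tmp <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, tmp)
  s2 <- read_stl(tmp)
  expect_equal(nrow(s2$triangles), nrow(s$triangles))
  expect_equal(s2$labels, s$labels)
  expect_equal(nrow(s2$vertices), nrow(s$vertices))
  expect_lt(max(abs(sort(s2$vertices[, 3]) - sort(s$vertices[, 3]))), 1e-9)
})

test_that("surface and volume mesh constructors enforce invariants", {
  expect_error(surface_mesh(matrix(0, 3, 3), matrix(c(1, 2, 4), 1), "wall"),
               "out of range")
  expect_error(surface_mesh(diag(3), matrix(1:3, 1), "lumen"), "unknown boundary")
  # degenerate tetrahedron (coplanar) is rejected
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  s <- surface_mesh(v[1:3, ], matrix(1:3, 1), "wall")
  expect_error(volume_mesh(v, matrix(1:4, 1), s), "degenerate")
})

test_that("generated tetrahedra are positively oriented and map injective", {
  m <- fx_tube_coarse()
  sv <- bulbflow:::tet_signed_volumes(m$vertices, m$tetrahedra)
  expect_true(all(sv > 0))
  expect_false(anyDuplicated(m$boundary_map) > 0)
  expect_lt(max(abs(m$boundary$vertices - m$vertices[m$boundary_map, ])), 1e-12)
})
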