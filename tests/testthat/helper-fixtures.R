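# Shared fixtures, built lazily and cached for the session.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# default-resolution tube (R = 0.3 cm, L = 3 cm)
fx_tube <- function() fx_cached("tube", function() make_tube_mesh(0.3, 3))

# coarse tube for cheap structural tests
fx_tube_coarse <- function() fx_cached("tube_coarse", function()
  make_tube_mesh(0.25, 1.5, mesh_resolution(n_radial = 4, n_circumferential = 8,
                                            n_axial = 6, boundary_layers = 0)))

# steady waveform with flow Q (mL/s)
fx_steady_waveform <- function(Q, period = 0.9, n = 20) {
  flow_waveform(period * (seq_len(n) - 1L) / n, rep(Q, n), period)
}

# steady Poiseuille field on a mesh at mean speed vbar through radius R
fx_steady_field <- function(mesh, vbar, R) {
  sample_parabolic_field(mesh, fx_steady_waveform(vbar * pi * R^2), 20)
}

fx_tube_centerline <- function() fx_cached("tube_cl", function()
  extract_centerline(fx_tube()))

# wall shear series from a function tau(t) returning one 3-vector,
# replicated over `nf` faces with unit areas
fx_series_from_fun <- function(tau_fun, n_frames = 64, period = 1, nf = 3) {
  tt <- period * (seq_len(n_frames) - 1L) / n_frames
  tau <- lapply(tt, function(t) matrix(rep(tau_fun(t), each = nf), nf, 3L))
  wall_shear_series(tau, areas = rep(1, nf), frame_times = tt, period = period)
}

# minimal ROI over explicit faces/cells (for metric-rule tests)
fx_fake_roi <- function(wall_faces, cells = integer(), volume = 1) {
  structure(list(start_arclength = 0, end_arclength = 1,
                 wall_faces = wall_faces, cells = cells,
                 roi_surface_area = NA_real_, roi_volume = volume,
                 truncated = FALSE),
            class = "bulb_roi")
}

# wall scalar field over unit-area faces
fx_scalar_field <- function(values, areas = rep(1, length(values))) {
  structure(list(values = values, areas = areas,
                 faces = seq_along(values), valid = rep(TRUE, length(values)),
                 quantity = "test"),
            class = "wall_scalar_field")
}
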