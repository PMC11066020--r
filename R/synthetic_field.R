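# Analytic pulsatile velocity fields. Instead of solving Navier-Stokes, the
# generator prescribes a fully developed parabolic (Poiseuille) profile
# modulated by the inlet waveform, which gives exact oracles for flux, wall
# shear and low-velocity fractions. A kinematic "recirculation pocket" can
# then be stamped into the field to provide programmable ground truth for
# stasis: inside a sphere the velocity is replaced by a slow swirl for a
# prescribed fraction of the cycle (the dwell) and by a fast axial flush for
# the rest.

#' Sample a pulsatile parabolic velocity field on a generated mesh
#'
#' At every frame t the axial velocity is
#' v(r, t) = 2 Q_seg(t) / (pi R^2) (1 - (r/R)^2) along the local segment
#' axis, with R the local lumen radius and Q_seg the waveform flow times the
#' segment's Murray flux fraction (1 in the trunk). No-slip holds exactly at
#' wall vertices. Frames are uniform on [0, T).
#'
#' @param mesh A [volume_mesh()] produced by [make_tube_mesh()] or
#'   [make_bifurcation_mesh()] (generator axis metadata required).
#' @param waveform A [flow_waveform()].
#' @param n_frames Number of frames per cycle (default 20).
#' @return A [velocity_field()].
#' @export
sample_parabolic_field <- function(mesh, waveform, n_frames = 20) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(waveform, "flow_waveform"))
  md <- mesh$metadata
  if (is.null(md) || is.null(md$vertex))
    stop("mesh has no axis metadata; parabolic sampling needs a generated mesh (unsupported geometry)",
         call. = FALSE)
  vm <- md$vertex
  Qfun <- waveform_function(waveform)
  period <- waveform$period
  tt <- period * (seq_len(n_frames) - 1L) / n_frames
  frac <- md$flux_fractions[vm$region]
  shape <- frac * 2 / (pi * vm$R_local^2) * (1 - vm$rho^2)
  ax <- cbind(vm$ax, vm$ay, vm$az)
  values <- lapply(tt, function(t) ax * (Qfun(t) * shape))
  velocity_field(tt, values, period)
}

#' Specification of a kinematic recirculation pocket
#'
#' @param pocket_center Sphere center, cm (length-3).
#' @param pocket_radius Sphere radius, cm.
#' @param peak_speed Speed cap, cm/s: during dwell frames the pocket speed
#'   stays strictly below this value (low, typically < 3 cm/s).
#' @param dwell_fraction Fraction of the cycle (0..1) during which the
#'   pocket dwells below `peak_speed`.
#' @param swirl_axis Axis of the swirl, default +z.
#' @param dwell_scale Dwell swirl maximum as a fraction of `peak_speed`
#'   (default 0.95).
#' @param flush_factor Flush speed as a multiple of `peak_speed`
#'   (default 4): outside the dwell frames the pocket is flushed by a
#'   uniform axial velocity of `flush_factor * peak_speed`.
#' @return A list of class `recirculation_spec`.
#' @export
recirculation_spec <- function(pocket_center, pocket_radius, peak_speed = 2.8,
                               dwell_fraction = 1, swirl_axis = c(0, 0, 1),
                               dwell_scale = 0.95, flush_factor = 4) {
  stopifnot(length(pocket_center) == 3L, pocket_radius > 0, peak_speed >= 0,
            dwell_fraction >= 0, dwell_fraction <= 1,
            dwell_scale > 0, dwell_scale < 1, flush_factor > 1)
  structure(list(pocket_center = as.numeric(pocket_center),
                 pocket_radius = pocket_radius, peak_speed = peak_speed,
                 dwell_fraction = dwell_fraction,
                 swirl_axis = swirl_axis / sqrt(sum(swirl_axis^2)),
                 dwell_scale = dwell_scale, flush_factor = flush_factor),
            class = "recirculation_spec")
}

#' Number of dwell frames for a dwell fraction
#'
#' Nearest-integer rounding with ties toward more frames.
#' @param dwell_fraction Fraction in 0..1.
#' @param n_frames Total frames.
#' @return Integer frame count.
#' @export
dwell_frame_count <- function(dwell_fraction, n_frames) {
  as.integer(floor(dwell_fraction * n_frames + 0.5))
}

#' Stamp a recirculation pocket into a velocity field
#'
#' Inside the pocket sphere the velocity is replaced frame-wise. During the
#' dwell frames (the `round(dwell_fraction * n_frames)` frames of lowest
#' waveform flow; ties toward more frames) the pocket carries a solid-body
#' swirl about `swirl_axis` whose maximum speed is
#' `dwell_scale * peak_speed` (< `peak_speed`). During the remaining frames
#' the pocket is flushed by a uniform axial velocity of
#' `flush_factor * peak_speed`, with the swirl sense reversed so near-wall
#' shear alternates direction over the cycle. Outside the sphere the field
#' is untouched.
#'
#' @param field A [velocity_field()].
#' @param mesh The [volume_mesh()] the field lives on.
#' @param spec A [recirculation_spec()]; the sphere must lie inside the mesh.
#' @param waveform Optional [flow_waveform()] used to pick the dwell frames
#'   (lowest-flow frames); if omitted the first frames of the cycle dwell.
#' @return A [velocity_field()] with the pocket stamped in.
#' @export
add_recirculation_pocket <- function(field, mesh, spec, waveform = NULL) {
  stopifnot(inherits(field, "velocity_field"), inherits(mesh, "volume_mesh"),
            inherits(spec, "recirculation_spec"))
  d <- sweep(mesh$vertices, 2L, spec$pocket_center)
  inside <- which(rowSums(d^2) < spec$pocket_radius^2)
  if (length(inside) < 4L)
    stop("pocket sphere lies outside the mesh (no vertices inside)", call. = FALSE)
  # reject spheres protruding beyond the lumen: every corner of the sphere's
  # bounding box should be near some mesh vertex
  rng <- apply(mesh$vertices, 2L, range)
  lo <- spec$pocket_center - spec$pocket_radius
  hi <- spec$pocket_center + spec$pocket_radius
  if (any(lo < rng[1L, ] - 1e-9) || any(hi > rng[2L, ] + 1e-9))
    stop("pocket sphere extends beyond the mesh bounding box", call. = FALSE)
  n_frames <- length(field$frame_times)
  n_dwell <- dwell_frame_count(spec$dwell_fraction, n_frames)
  if (!is.null(waveform)) {
    q <- waveform_function(waveform)(field$frame_times)
    dwell_frames <- order(q)[seq_len(n_dwell)]
  } else {
    dwell_frames <- seq_len(n_dwell)
  }
  w <- spec$swirl_axis
  rvec <- d[inside, , drop = FALSE]
  # swirl direction: w x r; the speed profile is a rotation-like band
  # (0.8 + 0.2 r_perp/a) so every point in the pocket moves at 80-100% of
  # the dwell speed — a slow core would smear the pocket's signature across
  # lower thresholds
  swirl <- cbind(w[2] * rvec[, 3] - w[3] * rvec[, 2],
                 w[3] * rvec[, 1] - w[1] * rvec[, 3],
                 w[1] * rvec[, 2] - w[2] * rvec[, 1])
  rp <- sqrt(rowSums(swirl^2))  # |w x r| = in-plane distance from the axis
  e1 <- c(w[2] - w[3], w[3] - w[1], w[1] - w[2])  # any direction not || w
  e1 <- e1 - sum(e1 * w) * w; e1 <- e1 / sqrt(sum(e1^2))
  dir <- swirl / pmax(rp, 1e-12)
  on_axis <- rp < 1e-9
  if (any(on_axis)) dir[on_axis, ] <- matrix(e1, sum(on_axis), 3L, byrow = TRUE)
  profile <- 0.8 + 0.2 * rp / spec$pocket_radius
  values <- field$values
  for (k in seq_len(n_frames)) {
    if (k %in% dwell_frames) {
      values[[k]][inside, ] <- dir * (spec$dwell_scale * spec$peak_speed * profile)
    } else {
      flush <- matrix(spec$flush_factor * spec$peak_speed * w,
                      length(inside), 3L, byrow = TRUE)
      values[[k]][inside, ] <- flush -
        dir * (0.05 * spec$flush_factor * spec$peak_speed * profile)
    }
  }
  out <- velocity_field(field$frame_times, values, field$period)
  attr(out, "pocket_vertices") <- inside
  out
}
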