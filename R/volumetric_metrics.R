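# Low-velocity volume and flow stasis. A tetrahedron counts as low-velocity
# in a frame when its cell speed (the mean of its four vertex speeds) is
# strictly below the threshold; the low-velocity volume percentage is the
# counted volume over the ROI volume. Stasis is the percentage of frames in
# which a low-velocity region is present, where "present" means the
# low-velocity volume exceeds a small presence floor (a literal > 0 rule is
# available by setting the floor to 0, but is sensitive to mesh noise).

# cell speeds for all frames: n_frames x n_cells matrix (mean vertex speed)
cell_speed_matrix <- function(field, mesh, cells = NULL) {
  t4 <- mesh$tetrahedra
  if (!is.null(cells)) t4 <- t4[cells, , drop = FALSE]
  sp <- field_speeds(field)  # frames x vertices
  (sp[, t4[, 1L], drop = FALSE] + sp[, t4[, 2L], drop = FALSE] +
     sp[, t4[, 3L], drop = FALSE] + sp[, t4[, 4L], drop = FALSE]) / 4
}

#' Low-velocity volume percentage in one frame
#'
#' @param field A [velocity_field()].
#' @param mesh The [volume_mesh()] the field lives on.
#' @param roi A [bulb_roi()] whose cells index the mesh tetrahedra.
#' @param threshold Speed threshold, cm/s (strict `<`).
#' @param frame Frame index (1-based).
#' @return Percentage of ROI volume below the threshold, 0..100.
#' @export
low_velocity_volume_pct <- function(field, mesh, roi, threshold, frame = 1L) {
  curve <- volume_fraction_curve(field, mesh, roi, threshold)
  curve$low_velocity_volume_pct[frame]
}

#' Low-velocity volume curve over the cardiac cycle
#'
#' [low_velocity_volume_pct()] evaluated at every frame.
#'
#' @inheritParams low_velocity_volume_pct
#' @return A data frame of class `volume_fraction_curve` with columns
#'   `frame_times` (s) and `low_velocity_volume_pct` (%).
#' @export
volume_fraction_curve <- function(field, mesh, roi, threshold) {
  stopifnot(inherits(field, "velocity_field"), inherits(mesh, "volume_mesh"),
            inherits(roi, "bulb_roi"), threshold >= 0)
  if (!length(roi$cells)) stop("empty ROI (no cells)", call. = FALSE)
  if (max(roi$cells) > nrow(mesh$tetrahedra))
    stop("ROI cells are not a subset of the mesh cells", call. = FALSE)
  vols <- tet_volumes(mesh)[roi$cells]
  sp <- cell_speed_matrix(field, mesh, roi$cells)  # frames x cells
  low <- sp < threshold
  pct <- 100 * as.vector(low %*% vols) / sum(vols)
  structure(data.frame(frame_times = field$frame_times,
                       low_velocity_volume_pct = pct),
            class = c("volume_fraction_curve", "data.frame"))
}

#' Flow stasis percentage of the cardiac cycle
#'
#' 100 x (number of frames whose low-velocity volume exceeds the presence
#' floor) / (number of frames).
#'
#' @param curve A [volume_fraction_curve()].
#' @param presence_floor Minimum low-velocity volume percentage for a frame
#'   to count as exposed (default 0.1% of ROI volume; 0 reproduces the
#'   literal any-low-velocity rule).
#' @return Stasis percentage, 0..100.
#' @export
stasis_pct <- function(curve, presence_floor = 0.1) {
  stopifnot(inherits(curve, "volume_fraction_curve"), nrow(curve) > 0)
  100 * sum(curve$low_velocity_volume_pct > presence_floor) / nrow(curve)
}

#' Time-averaged low-velocity volume percentage
#'
#' Mean of the volume-fraction curve over the cycle (equals the periodic
#' time average because frames are uniform).
#' @param curve A [volume_fraction_curve()].
#' @return Percentage, 0..100.
#' @export
mean_low_velocity_pct <- function(curve) {
  stopifnot(inherits(curve, "volume_fraction_curve"))
  mean(curve$low_velocity_volume_pct)
}
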