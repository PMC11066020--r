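# The bulb region of interest: the segment of the trunk-to-ICA path running
# from the narrowest point of the lumen (or the bifurcation, for normal
# geometries) to 1.5 CCA diameters downstream — the region where flow
# separation and stasis downstream of a web are expected.

#' Clip the bulb region of interest
#'
#' Membership is by projected arclength: a wall face or tetrahedron belongs
#' to the ROI when its centroid's nearest centerline station (on the
#' trunk-to-ICA path, within a transverse distance of
#' `max_radial_factor x local radius`) has arclength inside
#' `[lesion_arclength, lesion_arclength + 1.5 cca_diameter]`.
#'
#' @param mesh A [volume_mesh()].
#' @param cl A [centerline()] along the trunk-to-ICA path.
#' @param lesion_arclength Arclength (cm) of the narrowest lumen point; for
#'   normal geometries, of the bifurcation.
#' @param cca_diameter CCA diameter, cm (see [cca_diameter()]).
#' @param extent_multiplier Downstream extent in CCA diameters (default 1.5).
#' @param max_radial_factor Transverse gate in local radii (default 1.3),
#'   excluding cells that belong to the other branch.
#' @return An object of class `bulb_roi` with the member wall-face and cell
#'   index sets, the arclength span, surface area and volume. If the span
#'   extends past the end of the centerline a truncation flag is recorded
#'   (not fatal).
#' @export
clip_bulb_roi <- function(mesh, cl, lesion_arclength, cca_diameter,
                          extent_multiplier = 1.5, max_radial_factor = 1.3) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(cl, "centerline"),
            cca_diameter > 0)
  s0 <- lesion_arclength
  s1 <- lesion_arclength + extent_multiplier * cca_diameter
  truncated <- s1 > max(cl$arclengths) + 1e-9
  project <- function(pts) {
    # nearest centerline station per point (vectorized over stations)
    n <- nrow(pts)
    best_d2 <- rep(Inf, n); best_i <- rep(1L, n)
    for (i in seq_len(nrow(cl$points))) {
      d2 <- (pts[, 1] - cl$points[i, 1])^2 + (pts[, 2] - cl$points[i, 2])^2 +
        (pts[, 3] - cl$points[i, 3])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]; best_i[upd] <- i
    }
    list(s = cl$arclengths[best_i], r = sqrt(best_d2),
         rloc = cl$radii[best_i])
  }
  tc <- tet_centroids(mesh)
  pv <- project(tc)
  cells <- which(pv$s >= s0 & pv$s <= s1 & pv$r <= max_radial_factor * pv$rloc)
  wall <- which(mesh$boundary$labels == "wall")
  wc <- surface_centroids(mesh$boundary)[wall, , drop = FALSE]
  pw <- project(wc)
  wsel <- pw$s >= s0 & pw$s <= s1 & pw$r <= (max_radial_factor + 0.3) * pw$rloc
  faces <- wall[wsel]
  if (!length(cells) || !length(faces))
    stop("empty ROI: no cells or wall faces in the requested span", call. = FALSE)
  areas <- surface_areas(mesh$boundary)
  structure(list(start_arclength = s0, end_arclength = s1,
                 wall_faces = faces, cells = cells,
                 roi_surface_area = sum(areas[faces]),
                 roi_volume = sum(tet_volumes(mesh)[cells]),
                 truncated = truncated),
            class = "bulb_roi")
}

#' @export
print.bulb_roi <- function(x, ...) {
  cat(sprintf("Bulb ROI: s in [%.3g, %.3g] cm, %d wall faces (%.3g cm^2), %d cells (%.3g cm^3)%s\n",
              x$start_arclength, x$end_arclength, length(x$wall_faces),
              x$roi_surface_area, length(x$cells), x$roi_volume,
              if (x$truncated) " [truncated at mesh end]" else ""))
  invisible(x)
}

#' Export an ROI summary to JSON (+ member index CSV)
#'
#' @param roi A [bulb_roi()].
#' @param path JSON output path; member face/cell indices go to
#'   `<path>.members.csv`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "bulb_roi"))
  jsonlite::write_json(list(start_arclength_cm = roi$start_arclength,
                            end_arclength_cm = roi$end_arclength,
                            surface_area_cm2 = roi$roi_surface_area,
                            volume_cm3 = roi$roi_volume,
                            n_wall_faces = length(roi$wall_faces),
                            n_cells = length(roi$cells),
                            truncated = roi$truncated),
                       path, auto_unbox = TRUE, digits = NA)
  n <- max(length(roi$wall_faces), length(roi$cells))
  utils::write.csv(data.frame(
    wall_face = c(roi$wall_faces, rep(NA, n - length(roi$wall_faces))),
    cell = c(roi$cells, rep(NA, n - length(roi$cells)))),
    paste0(path, ".members.csv"), row.names = FALSE)
  invisible(path)
}
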