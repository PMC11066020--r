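# Mesh containers. A volume mesh is a tetrahedral lumen discretization; its
# boundary is a labeled triangulated surface (wall / inlet / outlet-ICA /
# outlet-ECA) whose vertices are a subset of the volume vertices.

BOUNDARY_LABELS <- c("wall", "inlet", "outlet_ica", "outlet_eca")

#' Construct a labeled surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates, cm.
#' @param triangles m x 3 integer matrix of vertex indices (1-based).
#' @param labels Character vector of length m; each one of `"wall"`,
#'   `"inlet"`, `"outlet_ica"`, `"outlet_eca"`.
#' @param normals Optional m x 3 matrix of outward (lumen-exterior) unit
#'   normals; computed from vertex winding if omitted.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, labels, normals = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3", call. = FALSE)
  if (ncol(triangles) != 3L) stop("`triangles` must be m x 3", call. = FALSE)
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(triangles))
    stop("`labels` must have one entry per triangle", call. = FALSE)
  bad <- setdiff(unique(labels), BOUNDARY_LABELS)
  if (length(bad))
    stop("unknown boundary labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(normals)) {
    normals <- triangle_normals(vertices, triangles)
  } else {
    normals <- as.matrix(normals); storage.mode(normals) <- "double"
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("`normals` must be unit length within 1e-6", call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$triangles),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Construct a tetrahedral volume mesh with labeled boundary
#'
#' Tetrahedra are reordered if necessary so every signed volume is positive.
#' The boundary-to-volume vertex index map is taken as given when supplied,
#' otherwise built by exact coordinate matching within 1e-9 cm.
#'
#' @param vertices N x 3 matrix of coordinates, cm.
#' @param tetrahedra M x 4 integer matrix of vertex indices.
#' @param boundary A [surface_mesh()] whose vertices all coincide with volume
#'   vertices.
#' @param boundary_map Optional integer vector: volume index of each boundary
#'   vertex. Must be injective.
#' @param metadata Optional list of generator metadata (axis frames, radii);
#'   carried along, never required.
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(vertices, tetrahedra, boundary, boundary_map = NULL,
                        metadata = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  tetrahedra <- as.matrix(tetrahedra); storage.mode(tetrahedra) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be N x 3", call. = FALSE)
  if (ncol(tetrahedra) != 4L) stop("`tetrahedra` must be M x 4", call. = FALSE)
  if (min(tetrahedra) < 1L || max(tetrahedra) > nrow(vertices))
    stop("tetrahedron indices out of range", call. = FALSE)
  stopifnot(inherits(boundary, "surface_mesh"))
  # enforce positive orientation by swapping the last two vertices where needed
  sv <- tet_signed_volumes(vertices, tetrahedra)
  neg <- which(sv < 0)
  if (length(neg)) {
    tmp <- tetrahedra[neg, 3L]
    tetrahedra[neg, 3L] <- tetrahedra[neg, 4L]
    tetrahedra[neg, 4L] <- tmp
  }
  if (any(tet_signed_volumes(vertices, tetrahedra) <= 0))
    stop("degenerate tetrahedra (zero volume) present", call. = FALSE)
  if (is.null(boundary_map)) {
    boundary_map <- match_vertices(boundary$vertices, vertices, tol = 1e-9)
  }
  boundary_map <- as.integer(boundary_map)
  if (anyNA(boundary_map))
    stop("boundary vertex has no matching volume vertex (topology error)", call. = FALSE)
  if (anyDuplicated(boundary_map))
    stop("boundary index map is not injective", call. = FALSE)
  structure(list(vertices = vertices, tetrahedra = tetrahedra,
                 boundary = boundary, boundary_map = boundary_map,
                 metadata = metadata),
            class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("Volume mesh: %d vertices, %d tetrahedra, %d boundary triangles\n",
              nrow(x$vertices), nrow(x$tetrahedra), nrow(x$boundary$triangles)))
  invisible(x)
}

# match each row of `a` to a row of `b` within absolute tolerance `tol`
# (per coordinate). Returns NA where no match. Uses rounded-key hashing, with
# neighbor keys to absorb round-off at bin edges.
match_vertices <- function(a, b, tol = 1e-9) {
  key <- function(m, shift = 0) {
    apply(round(m / tol + shift), 1L, paste, collapse = ",")
  }
  kb <- key(b)
  idx <- match(key(a), kb)
  miss <- which(is.na(idx))
  for (i in miss) {
    d <- abs(b[, 1] - a[i, 1]) < tol & abs(b[, 2] - a[i, 2]) < tol &
      abs(b[, 3] - a[i, 3]) < tol
    j <- which(d)
    if (length(j) >= 1L) idx[i] <- j[1L]
  }
  idx
}

## ---- geometric primitives -------------------------------------------------

#' Signed volumes of tetrahedra
#' @param vertices N x 3 coordinate matrix.
#' @param tets M x 4 index matrix.
#' @return Numeric vector of signed volumes, cm^3.
#' @keywords internal
tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1L], , drop = FALSE]
  b <- vertices[tets[, 2L], , drop = FALSE] - a
  c <- vertices[tets[, 3L], , drop = FALSE] - a
  d <- vertices[tets[, 4L], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
     b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
     b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Tetrahedron volumes of a mesh
#' @param mesh A [volume_mesh()].
#' @return Positive volumes, cm^3, one per tetrahedron.
#' @export
tet_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "volume_mesh"))
  abs(tet_signed_volumes(mesh$vertices, mesh$tetrahedra))
}

#' Tetrahedron centroids of a mesh
#' @param mesh A [volume_mesh()].
#' @return M x 3 matrix of centroids.
#' @export
tet_centroids <- function(mesh) {
  stopifnot(inherits(mesh, "volume_mesh"))
  (mesh$vertices[mesh$tetrahedra[, 1L], , drop = FALSE] +
     mesh$vertices[mesh$tetrahedra[, 2L], , drop = FALSE] +
     mesh$vertices[mesh$tetrahedra[, 3L], , drop = FALSE] +
     mesh$vertices[mesh$tetrahedra[, 4L], , drop = FALSE]) / 4
}

triangle_cross <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  u <- vertices[triangles[, 2L], , drop = FALSE] - a
  v <- vertices[triangles[, 3L], , drop = FALSE] - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Triangle areas
#' @param vertices n x 3 coordinates.
#' @param triangles m x 3 indices.
#' @return Areas, cm^2.
#' @keywords internal
triangle_areas <- function(vertices, triangles) {
  cr <- triangle_cross(vertices, triangles)
  sqrt(rowSums(cr^2)) / 2
}

#' Unit normals from triangle winding
#' @keywords internal
triangle_normals <- function(vertices, triangles) {
  cr <- triangle_cross(vertices, triangles)
  n <- sqrt(rowSums(cr^2))
  if (any(n == 0)) stop("degenerate triangle (zero area)", call. = FALSE)
  cr / n
}

#' Areas of a surface mesh's triangles
#' @param surf A [surface_mesh()].
#' @return Areas, cm^2.
#' @export
surface_areas <- function(surf) {
  stopifnot(inherits(surf, "surface_mesh"))
  triangle_areas(surf$vertices, surf$triangles)
}

#' Triangle centroids of a surface mesh
#' @param surf A [surface_mesh()].
#' @return m x 3 matrix.
#' @export
surface_centroids <- function(surf) {
  stopifnot(inherits(surf, "surface_mesh"))
  (surf$vertices[surf$triangles[, 1L], , drop = FALSE] +
     surf$vertices[surf$triangles[, 2L], , drop = FALSE] +
     surf$vertices[surf$triangles[, 3L], , drop = FALSE]) / 3
}

#' Total mesh volume
#' @param mesh A [volume_mesh()].
#' @return Volume, cm^3.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

## ---- velocity fields ------------------------------------------------------

#' Construct a velocity field over one cardiac cycle
#'
#' @param frame_times Frame times in seconds: at least 8 frames, first at 0,
#'   uniformly spaced, covering exactly one period (frame k at (k-1) T / n).
#' @param values List with one N x 3 matrix per frame (cm/s), N the number of
#'   volume-mesh vertices.
#' @param period Cardiac period, s.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(frame_times, values, period) {
  frame_times <- as.numeric(frame_times)
  n <- length(frame_times)
  if (n < 8L) stop("need at least 8 frames", call. = FALSE)
  if (abs(frame_times[1L]) > 1e-12) stop("first frame time must be 0", call. = FALSE)
  dt <- diff(frame_times)
  if (any(abs(dt - dt[1L]) > 1e-9))
    stop("frame spacing must be uniform within 1e-9", call. = FALSE)
  if (abs(frame_times[n] + dt[1L] - period) > 1e-9)
    stop("frames must cover exactly one period (n uniform frames on [0, T))",
         call. = FALSE)
  if (!is.list(values) || length(values) != n)
    stop("`values` must be a list with one matrix per frame", call. = FALSE)
  values <- lapply(values, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    if (ncol(m) != 3L) stop("each frame must be N x 3", call. = FALSE)
    m
  })
  nv <- vapply(values, nrow, 1L)
  if (any(nv != nv[1L])) stop("all frames must have the same vertex count", call. = FALSE)
  structure(list(frame_times = frame_times, values = values, period = period),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d frames x %d vertices, period %.3g s\n",
              length(x$frame_times), nrow(x$values[[1L]]), x$period))
  invisible(x)
}

#' Per-vertex speed matrix of a field
#' @param field A [velocity_field()].
#' @return n_frames x N matrix of speeds, cm/s.
#' @export
field_speeds <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  t(vapply(field$values, function(m) sqrt(rowSums(m^2)),
           numeric(nrow(field$values[[1L]]))))
}
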