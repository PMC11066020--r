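# Idealized lumen geometries with analytic ground truth: straight tubes
# (stand-in for the CCA) and Y-bifurcations with an optional web-like focal
# narrowing in the proximal ICA. Meshes are structured generalized cylinders:
# each axial station carries a triangulated disk (center node + concentric
# rings); disk triangles are extruded into prisms and each prism split into
# three tetrahedra. Radial node spacing optionally includes geometrically
# graded boundary layers near the wall, where velocity gradients are
# steepest. Generator metadata (station centers, axes, radii, per-vertex
# normalized radius) rides along on the mesh and supplies exact oracles for
# the parabolic velocity sampler and the wall-shear probes.

#' Mesh resolution settings
#'
#' @param n_radial Number of radial rings (>= 4).
#' @param n_circumferential Nodes per ring (>= 8).
#' @param n_axial Axial layers for a tube; bifurcation segments scale this by
#'   their length.
#' @param boundary_layers Number of geometrically graded near-wall layers
#'   (0 disables grading; the `n_radial` rings are then uniform).
#' @param bl_ratio Geometric size ratio between successive boundary layers
#'   (< 1 refines toward the wall).
#' @param bl_thickness Total boundary-layer thickness as a fraction of the
#'   local radius.
#' @param coarse_wall_fraction If positive, use the opposite grading: a
#'   dense uniform core out to `1 - coarse_wall_fraction` of the radius and
#'   a single coarse wall layer. This deliberately leaves the viscous
#'   sublayer unresolved — the regime in which voxel-style low-velocity
#'   thresholding sees the bulk flow rather than the no-slip layer — while
#'   resolving interior structures such as recirculation pockets.
#'   Mutually exclusive with `boundary_layers`.
#' @return A list of class `mesh_resolution`.
#' @export
mesh_resolution <- function(n_radial = 9, n_circumferential = 28, n_axial = 24,
                            boundary_layers = 3, bl_ratio = 0.8,
                            bl_thickness = 0.10, coarse_wall_fraction = 0) {
  stopifnot(n_radial >= 4, n_circumferential >= 8, n_axial >= 4,
            boundary_layers >= 0, boundary_layers < n_radial,
            bl_ratio > 0, bl_ratio <= 1, bl_thickness > 0, bl_thickness < 1,
            coarse_wall_fraction >= 0, coarse_wall_fraction < 1)
  if (coarse_wall_fraction > 0 && boundary_layers > 0)
    stop("`coarse_wall_fraction` and `boundary_layers` are mutually exclusive",
         call. = FALSE)
  structure(list(n_radial = as.integer(n_radial),
                 n_circumferential = as.integer(n_circumferential),
                 n_axial = as.integer(n_axial),
                 boundary_layers = as.integer(boundary_layers),
                 bl_ratio = bl_ratio, bl_thickness = bl_thickness,
                 coarse_wall_fraction = coarse_wall_fraction),
            class = "mesh_resolution")
}

#' Double a mesh resolution (for convergence studies)
#'
#' Doubles every count, including the number of graded boundary layers, so
#' that the near-wall spacing genuinely shrinks under refinement.
#' @param res A [mesh_resolution()].
#' @return A refined [mesh_resolution()].
#' @export
refine_resolution <- function(res) {
  mesh_resolution(n_radial = 2L * res$n_radial,
                  n_circumferential = 2L * res$n_circumferential,
                  n_axial = 2L * res$n_axial,
                  boundary_layers = 2L * res$boundary_layers,
                  bl_ratio = res$bl_ratio, bl_thickness = res$bl_thickness,
                  coarse_wall_fraction = res$coarse_wall_fraction)
}

# radial node positions rho_1..rho_n on (0, 1], last exactly 1
radial_nodes <- function(res) {
  n <- res$n_radial
  nbl <- res$boundary_layers
  cwf <- if (is.null(res$coarse_wall_fraction)) 0 else res$coarse_wall_fraction
  if (cwf > 0) return(c(seq_len(n - 1L) / (n - 1L) * (1 - cwf), 1))
  if (nbl == 0L) return(seq_len(n) / n)
  t <- res$bl_thickness
  core <- seq_len(n - nbl) / (n - nbl) * (1 - t)
  w <- res$bl_ratio^(seq_len(nbl) - 1L)  # layer sizes shrink toward the wall
  sizes <- t * w / sum(w)
  c(core, (1 - t) + cumsum(sizes))
}

# triangulated unit disk: center node + n_r rings of n_c nodes each
disk_template <- function(res) {
  nr <- res$n_radial; nc <- res$n_circumferential
  rho <- radial_nodes(res)
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  pts <- rbind(c(0, 0),
               cbind(rep(rho, each = nc) * cos(rep(theta, nr)),
                     rep(rho, each = nc) * sin(rep(theta, nr))))
  rho_pt <- c(0, rep(rho, each = nc))
  ring_idx <- function(j, k) 1L + (j - 1L) * nc + ((k - 1L) %% nc) + 1L
  tris <- vector("list", nr)
  k <- seq_len(nc)
  tris[[1L]] <- cbind(1L, ring_idx(1L, k), ring_idx(1L, k + 1L))
  for (j in seq_len(nr - 1L)) {
    a <- ring_idx(j, k); b <- ring_idx(j, k + 1L)
    cc <- ring_idx(j + 1L, k + 1L); d <- ring_idx(j + 1L, k)
    tris[[j + 1L]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  list(pts = pts, rho = rho_pt, tris = do.call(rbind, tris),
       outer_ring = ring_idx(nr, k), n_pts = 1L + nr * nc)
}

# flip triangle winding so winding normals align with reference directions
orient_faces <- function(vertices, tris, ref) {
  nrm <- triangle_normals(vertices, tris)
  flip <- rowSums(nrm * ref) < 0
  if (any(flip)) {
    tmp <- tris[flip, 2L]
    tris[flip, 2L] <- tris[flip, 3L]
    tris[flip, 3L] <- tmp
    nrm[flip, ] <- -nrm[flip, ]
  }
  list(tris = tris, normals = nrm)
}

# One generalized-cylinder segment along a (straight or mildly curved) path.
# centers/axes: n_s x 3; radii, arclengths: length n_s. Returns local-index
# vertices, tets, wall triangles with per-face metadata, cap triangles, and
# per-vertex metadata (region, rho, R_local, s, axis, station center).
gc_segment <- function(centers, axes, radii, arclengths, res, region) {
  dk <- disk_template(res)
  ns <- nrow(centers)
  u0 <- colMeans(axes); u0 <- u0 / sqrt(sum(u0^2))
  ref <- if (abs(u0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u0) * u0; e1 <- e1 / sqrt(sum(e1^2))
  npts <- dk$n_pts
  verts <- matrix(0, ns * npts, 3L)
  meta <- data.frame(region = rep(region, ns * npts),
                     rho = rep(dk$rho, ns),
                     R_local = rep(radii, each = npts),
                     s = rep(arclengths, each = npts),
                     ax = 0, ay = 0, az = 0, cx = 0, cy = 0, cz = 0)
  for (i in seq_len(ns)) {
    u <- axes[i, ]
    e1i <- e1 - sum(e1 * u) * u; e1i <- e1i / sqrt(sum(e1i^2))
    e2i <- c(u[2] * e1i[3] - u[3] * e1i[2],
             u[3] * e1i[1] - u[1] * e1i[3],
             u[1] * e1i[2] - u[2] * e1i[1])
    rows <- (i - 1L) * npts + seq_len(npts)
    verts[rows, ] <- rep(centers[i, ], each = npts) +
      radii[i] * (outer(dk$pts[, 1], e1i) + outer(dk$pts[, 2], e2i))
    meta$ax[rows] <- u[1]; meta$ay[rows] <- u[2]; meta$az[rows] <- u[3]
    meta$cx[rows] <- centers[i, 1]; meta$cy[rows] <- centers[i, 2]
    meta$cz[rows] <- centers[i, 3]
  }
  tet_list <- vector("list", ns - 1L)
  for (i in seq_len(ns - 1L)) {
    off0 <- (i - 1L) * npts; off1 <- i * npts
    a <- dk$tris[, 1L] + off0; b <- dk$tris[, 2L] + off0; cc <- dk$tris[, 3L] + off0
    A <- dk$tris[, 1L] + off1; B <- dk$tris[, 2L] + off1; C <- dk$tris[, 3L] + off1
    tet_list[[i]] <- rbind(cbind(a, b, cc, A), cbind(b, cc, A, B), cbind(cc, A, B, C))
  }
  nc <- res$n_circumferential
  wall_list <- vector("list", ns - 1L)
  wm_list <- vector("list", ns - 1L)
  k <- seq_len(nc); kk <- k %% nc + 1L
  for (i in seq_len(ns - 1L)) {
    w0 <- dk$outer_ring + (i - 1L) * npts
    w1 <- dk$outer_ring + i * npts
    wall_list[[i]] <- rbind(cbind(w0[k], w0[kk], w1[kk]),
                            cbind(w0[k], w1[kk], w1[k]))
    wm_list[[i]] <- data.frame(
      s = rep((arclengths[i] + arclengths[i + 1L]) / 2, 2L * nc),
      R_local = rep((radii[i] + radii[i + 1L]) / 2, 2L * nc),
      region = rep(region, 2L * nc))
  }
  list(vertices = verts, tets = do.call(rbind, tet_list), meta = meta,
       wall_tris = do.call(rbind, wall_list), wall_meta = do.call(rbind, wm_list),
       cap_first = dk$tris, cap_last = dk$tris + (ns - 1L) * npts,
       axis_first = axes[1L, ], axis_last = axes[ns, ])
}

# Assemble segments into a volume_mesh. `caps` entries: list(seg = segment
# index, which = "first"|"last", label, outward = 3-vector).
assemble_mesh <- function(segs, caps, metadata) {
  offs <- cumsum(c(0L, vapply(segs, function(s) nrow(s$vertices), 1L)))
  verts <- do.call(rbind, lapply(segs, `[[`, "vertices"))
  tets <- do.call(rbind, lapply(seq_along(segs), function(i) segs[[i]]$tets + offs[i]))
  meta <- do.call(rbind, lapply(segs, `[[`, "meta"))
  wall_tris <- do.call(rbind, lapply(seq_along(segs), function(i)
    segs[[i]]$wall_tris + offs[i]))
  wall_meta <- do.call(rbind, lapply(segs, `[[`, "wall_meta"))
  # outward direction for a wall face: its centroid minus the station center
  # of its first vertex, with the axial component removed
  v1 <- wall_tris[, 1L]
  cen <- (verts[wall_tris[, 1L], , drop = FALSE] +
            verts[wall_tris[, 2L], , drop = FALSE] +
            verts[wall_tris[, 3L], , drop = FALSE]) / 3
  ax <- cbind(meta$ax[v1], meta$ay[v1], meta$az[v1])
  d <- cen - cbind(meta$cx[v1], meta$cy[v1], meta$cz[v1])
  d <- d - rowSums(d * ax) * ax
  ref_dirs <- d / sqrt(rowSums(d^2))
  all_tris <- wall_tris
  labels <- rep("wall", nrow(wall_tris))
  for (cp in caps) {
    tri <- if (cp$which == "first") segs[[cp$seg]]$cap_first else segs[[cp$seg]]$cap_last
    tri <- tri + offs[cp$seg]
    all_tris <- rbind(all_tris, tri)
    labels <- c(labels, rep(cp$label, nrow(tri)))
    ref_dirs <- rbind(ref_dirs, matrix(cp$outward, nrow(tri), 3L, byrow = TRUE))
    wall_meta <- rbind(wall_meta,
                       data.frame(s = rep(NA_real_, nrow(tri)),
                                  R_local = rep(NA_real_, nrow(tri)),
                                  region = rep(NA_character_, nrow(tri))))
  }
  bidx <- sort(unique(as.vector(all_tris)))
  remap <- integer(nrow(verts)); remap[bidx] <- seq_along(bidx)
  local_tris <- matrix(remap[all_tris], ncol = 3L)
  o <- orient_faces(verts[bidx, , drop = FALSE], local_tris, ref_dirs)
  surf <- surface_mesh(verts[bidx, , drop = FALSE], o$tris, labels, o$normals)
  metadata$vertex <- meta
  metadata$face <- wall_meta
  volume_mesh(verts, tets, surf, boundary_map = bidx, metadata = metadata)
}

#' Generate a straight tube mesh
#'
#' Cylinder of the given radius and length, aligned with +z, inlet at z = 0.
#' Boundary labels: lateral surface `wall`, z = 0 cap `inlet`, far cap
#' `outlet_ica`.
#'
#' @param radius Tube radius, cm.
#' @param length Tube length, cm.
#' @param resolution A [mesh_resolution()].
#' @return A [volume_mesh()] carrying generator metadata (per-vertex
#'   normalized radius, station radius and axis) used by
#'   [sample_parabolic_field()].
#' @export
make_tube_mesh <- function(radius = 0.3, length = 3,
                           resolution = mesh_resolution()) {
  stopifnot(radius > 0, length > 0)
  res <- resolution
  ns <- res$n_axial + 1L
  z <- length * (seq_len(ns) - 1L) / (ns - 1L)
  centers <- cbind(0, 0, z)
  axes <- matrix(rep(c(0, 0, 1), each = ns), ncol = 3L)
  seg <- gc_segment(centers, axes, rep(radius, ns), z, res, "trunk")
  metadata <- list(kind = "tube", radius = radius, length = length,
                   resolution = res, flux_fractions = c(trunk = 1),
                   centerline = list(points = centers, radii = rep(radius, ns),
                                     arclengths = z, bifurcation_index = NA_integer_))
  assemble_mesh(list(seg),
                list(list(seg = 1L, which = "first", label = "inlet",
                          outward = c(0, 0, -1)),
                     list(seg = 1L, which = "last", label = "outlet_ica",
                          outward = c(0, 0, 1))),
                metadata)
}

#' Specification of an idealized carotid bifurcation
#'
#' @param cca_radius,ica_radius,eca_radius Branch radii, cm.
#' @param branch_angle Total opening angle between ICA and ECA, degrees
#'   (0 < angle < 90).
#' @param cca_length,branch_length Segment lengths, cm.
#' @param web Optional web-like narrowing in the proximal ICA:
#'   `list(narrowing_fraction, shelf_axial_position, shelf_extent)` with
#'   `narrowing_fraction` in (0, 1), `shelf_axial_position` the distance
#'   (cm) from the bifurcation along the ICA, and `shelf_extent` the
#'   Gaussian axial half-width of the narrowing (cm, default 0.15).
#' @return A list of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(cca_radius = 0.3, ica_radius = 0.24,
                             eca_radius = 0.18, branch_angle = 50,
                             cca_length = 2, branch_length = 2, web = NULL) {
  stopifnot(cca_radius > 0, ica_radius > 0, eca_radius > 0,
            branch_angle > 0, branch_angle < 90,
            cca_length > 0, branch_length > 0)
  if (!is.null(web)) {
    stopifnot(is.list(web), !is.null(web$narrowing_fraction),
              !is.null(web$shelf_axial_position))
    if (web$narrowing_fraction <= 0 || web$narrowing_fraction >= 1)
      stop("web narrowing_fraction must lie in (0, 1)", call. = FALSE)
    if (web$shelf_axial_position <= 0 || web$shelf_axial_position >= branch_length)
      stop("web shelf_axial_position lies outside the ICA branch", call. = FALSE)
    if (is.null(web$shelf_extent)) web$shelf_extent <- 0.15
  }
  structure(list(cca_radius = cca_radius, ica_radius = ica_radius,
                 eca_radius = eca_radius, branch_angle = branch_angle,
                 cca_length = cca_length, branch_length = branch_length,
                 web = web),
            class = "bifurcation_spec")
}

#' Murray's-law outflow fractions
#'
#' Flow fractions f_i = d_i^k / sum(d_j^k) for outlet diameters d and Murray
#' exponent k (default 2.1).
#'
#' @param diameters Outlet diameters, cm.
#' @param exponent Murray exponent.
#' @return Fractions summing to 1.
#' @export
murray_fractions <- function(diameters, exponent = 2.1) {
  if (any(diameters <= 0)) stop("diameters must be positive", call. = FALSE)
  w <- diameters^exponent
  w / sum(w)
}

#' Generate an idealized carotid bifurcation mesh
#'
#' A straight CCA trunk along +z splits at z = cca_length into ICA and ECA
#' branches tilted by half the branch angle each, meshed as generalized
#' cylinders. The branch tubes start side by side inside the trunk cross
#' section (internally tangent to it) and diverge; the flow-divider apex of
#' the constructed geometry is where the two branch cross sections become
#' disjoint (stored in the metadata as `apex_arclength` along the trunk-ICA
#' path). An optional web narrows the ICA radius by `narrowing_fraction`
#' around `shelf_axial_position`.
#'
#' Boundary labels: `wall`, `inlet` (z = 0), `outlet_ica`, `outlet_eca`.
#'
#' @param spec A [bifurcation_spec()].
#' @param resolution A [mesh_resolution()]; `n_axial` applies to the trunk
#'   and is scaled by length for the branches.
#' @param n_axial_ica,n_axial_eca Optional explicit axial layer counts for
#'   the branches (e.g. to resolve a web or a recirculation pocket in the
#'   ICA without refining the whole mesh).
#' @return A [volume_mesh()] with generator metadata (centerline stations of
#'   the trunk-ICA path, apex arclength, Murray flux fractions, web info).
#' @export
make_bifurcation_mesh <- function(spec, resolution = mesh_resolution(),
                                  n_axial_ica = NULL, n_axial_eca = NULL) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  res <- resolution
  half <- spec$branch_angle / 2 * pi / 180
  L <- spec$cca_length; Lb <- spec$branch_length
  # trunk
  ns_t <- res$n_axial + 1L
  zt <- L * (seq_len(ns_t) - 1L) / (ns_t - 1L)
  seg_t <- gc_segment(cbind(0, 0, zt),
                      matrix(rep(c(0, 0, 1), each = ns_t), ncol = 3L),
                      rep(spec$cca_radius, ns_t), zt, res, "trunk")
  # branches: internally tangent to the trunk circle at the junction
  u_i <- c(sin(half), 0, cos(half))
  u_e <- c(-sin(half), 0, cos(half))
  c0_i <- c(spec$cca_radius - spec$ica_radius, 0, L)
  c0_e <- c(-(spec$cca_radius - spec$eca_radius), 0, L)
  ns_def <- max(4L, ceiling(res$n_axial * Lb / L))
  ns_i <- (if (is.null(n_axial_ica)) ns_def else max(4L, n_axial_ica)) + 1L
  ns_e <- (if (is.null(n_axial_eca)) ns_def else max(4L, n_axial_eca)) + 1L
  sb <- Lb * (seq_len(ns_i) - 1L) / (ns_i - 1L)
  se <- Lb * (seq_len(ns_e) - 1L) / (ns_e - 1L)
  r_ica <- rep(spec$ica_radius, ns_i)
  if (!is.null(spec$web)) {
    w <- spec$web
    r_ica <- spec$ica_radius *
      (1 - w$narrowing_fraction * exp(-((sb - w$shelf_axial_position) / w$shelf_extent)^2))
  }
  seg_i <- gc_segment(t(c0_i + outer(u_i, sb)),
                      matrix(rep(u_i, each = ns_i), ncol = 3L),
                      r_ica, L + sb, res, "ica")
  seg_e <- gc_segment(t(c0_e + outer(u_e, se)),
                      matrix(rep(u_e, each = ns_e), ncol = 3L),
                      rep(spec$eca_radius, ns_e), L + se, res, "eca")
  # Murray split over outlet diameters
  fr <- murray_fractions(2 * c(spec$ica_radius, spec$eca_radius))
  # apex: axial distance past the junction at which the branch circles in a
  # z-plane become disjoint (center gap exceeds the radius sum)
  gap0 <- (spec$cca_radius - spec$ica_radius) + (spec$cca_radius - spec$eca_radius)
  dz_apex <- max(0, (spec$ica_radius + spec$eca_radius - gap0) / (2 * tan(half)))
  apex_arclength <- L + dz_apex / cos(half)
  cl_pts <- rbind(cbind(0, 0, zt), t(c0_i + outer(u_i, sb)))
  cl_r <- c(rep(spec$cca_radius, ns_t), r_ica)
  cl_s <- c(zt, L + sb)
  metadata <- list(kind = "bifurcation", spec = spec, resolution = res,
                   flux_fractions = c(trunk = 1, ica = fr[1L], eca = fr[2L]),
                   apex_arclength = apex_arclength,
                   centerline = list(points = cl_pts, radii = cl_r,
                                     arclengths = cl_s,
                                     bifurcation_index = ns_t))
  assemble_mesh(list(seg_t, seg_i, seg_e),
                list(list(seg = 1L, which = "first", label = "inlet",
                          outward = c(0, 0, -1)),
                     list(seg = 2L, which = "last", label = "outlet_ica",
                          outward = u_i),
                     list(seg = 3L, which = "last", label = "outlet_eca",
                          outward = u_e)),
                metadata)
}
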