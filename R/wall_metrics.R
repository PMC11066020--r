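# Near-wall hemodynamic indices. WSS is estimated by normal-offset probing:
# the velocity is interpolated a small distance inside the lumen along each
# wall face's inward normal and the tangential component divided by the
# offset gives the shear. The default estimator samples at delta/2 and
# delta and combines them one-sidedly to second order, which is exact for
# the parabolic profiles of the synthetic generator; the plain single-probe
# first-order variant is available for comparison.

# per-tet barycentric precomputation: inverse edge matrices as three row
# vectors, so weights for a point come from three dot products
tet_bary_setup <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tetrahedra
  a <- v[t4[, 1L], , drop = FALSE]
  e1 <- v[t4[, 2L], , drop = FALSE] - a
  e2 <- v[t4[, 3L], , drop = FALSE] - a
  e3 <- v[t4[, 4L], , drop = FALSE] - a
  cr23 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
                e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
                e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  cr31 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
                e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
                e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  cr12 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  det <- rowSums(e1 * cr23)
  list(a = a, g1 = cr23 / det, g2 = cr31 / det, g3 = cr12 / det)
}

# vertex -> incident tets
vertex_tet_map <- function(mesh) {
  M <- nrow(mesh$tetrahedra)
  split(rep(seq_len(M), 4L), as.vector(mesh$tetrahedra))
}

# locate one point among candidate tets; returns list(tet, w = length-4
# weights) for the best candidate (largest minimum barycentric coordinate),
# or NULL when even the best is badly outside
locate_point <- function(p, cand, setup, slack = 0.05) {
  d <- sweep(setup$a[cand, , drop = FALSE], 2L, p, function(a, b) b - a)
  l1 <- rowSums(setup$g1[cand, , drop = FALSE] * d)
  l2 <- rowSums(setup$g2[cand, , drop = FALSE] * d)
  l3 <- rowSums(setup$g3[cand, , drop = FALSE] * d)
  l0 <- 1 - l1 - l2 - l3
  minb <- pmin(l0, l1, l2, l3)
  i <- which.max(minb)
  if (minb[i] < -slack) return(NULL)
  w <- pmax(c(l0[i], l1[i], l2[i], l3[i]), 0)
  list(tet = cand[i], w = w / sum(w))
}

#' Compute wall shear stress series by normal-offset probing
#'
#' For each wall face the velocity is interpolated at
#' `delta = probe_fraction x local_radius` along the inward normal from the
#' face centroid; the tangential component over delta (times the viscosity)
#' gives the WSS vector. `method = "second_order"` (default) probes at
#' delta/2 and delta and uses the one-sided second-order difference
#' mu (4 v(d/2) - v(d)) / d, exact for quadratic near-wall profiles;
#' `method = "single"` uses mu v(d)/d. Faces whose probe point cannot be
#' located in the lumen are flagged invalid and excluded from area
#' statistics.
#'
#' @param field A [velocity_field()].
#' @param mesh The [volume_mesh()] the field lives on.
#' @param fluid A [fluid_properties()].
#' @param probe_fraction Probe depth as a fraction of the local radius
#'   (default 0.1).
#' @param method `"second_order"` or `"single"`.
#' @param local_radius Optional per-wall-face local radii, cm; defaults to
#'   generator metadata, else to distances from a `centerline` argument.
#' @param cl Optional [centerline()] used to derive local radii when the
#'   mesh has no generator metadata.
#' @return An object of class `wall_shear_series`: per-frame list of
#'   face x 3 WSS vectors (dyn/cm^2), face areas, face indices (into the
#'   boundary triangles), validity flags.
#' @export
compute_wss <- function(field, mesh, fluid = fluid_properties(),
                        probe_fraction = 0.1,
                        method = c("second_order", "single"),
                        local_radius = NULL, cl = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(field, "velocity_field"), inherits(mesh, "volume_mesh"))
  surf <- mesh$boundary
  wall <- which(surf$labels == "wall")
  nf <- length(wall)
  if (!nf) stop("mesh has no wall faces", call. = FALSE)
  if (is.null(local_radius)) {
    if (!is.null(mesh$metadata$face)) {
      local_radius <- mesh$metadata$face$R_local[wall]
    } else if (!is.null(cl)) {
      wc <- surface_centroids(surf)[wall, , drop = FALSE]
      local_radius <- vapply(seq_len(nf), function(i) {
        d2 <- rowSums(sweep(cl$points, 2L, wc[i, ])^2)
        cl$radii[which.min(d2)]
      }, 0)
    } else {
      stop("no local radius available: supply `local_radius` or `cl`", call. = FALSE)
    }
  }
  stopifnot(length(local_radius) == nf, all(local_radius > 0))
  cent <- surface_centroids(surf)[wall, , drop = FALSE]
  n_in <- -surf$normals[wall, , drop = FALSE]
  delta <- probe_fraction * local_radius
  setup <- tet_bary_setup(mesh)
  v2t <- vertex_tet_map(mesh)
  bmap <- mesh$boundary_map
  tets <- mesh$tetrahedra
  # probe locations: (delta) and, for the second-order method, (delta/2)
  probes <- if (method == "second_order") list(0.5, 1) else list(1)
  loc <- vector("list", length(probes))
  valid <- rep(TRUE, nf)
  for (j in seq_along(probes)) {
    loc[[j]] <- vector("list", nf)
    last_tet <- NULL  # warm start: consecutive wall faces are neighbors
    for (i in seq_len(nf)) {
      if (!valid[i]) next
      p <- cent[i, ] + probes[[j]] * delta[i] * n_in[i, ]
      fverts <- bmap[surf$triangles[wall[i], ]]
      seed <- as.character(fverts)
      if (!is.null(last_tet)) seed <- c(seed, as.character(tets[last_tet, ]))
      cand <- unique(unlist(v2t[seed], use.names = FALSE))
      hit <- locate_point(p, cand, setup)
      tries <- 0L
      while (is.null(hit) && tries < 12L) {  # expand ring by ring
        tries <- tries + 1L
        ring <- unique(as.vector(tets[cand, ]))
        cand_new <- unique(unlist(v2t[as.character(ring)], use.names = FALSE))
        if (length(cand_new) == length(cand)) break
        cand <- cand_new
        hit <- locate_point(p, cand, setup)
      }
      if (is.null(hit)) valid[i] <- FALSE else {
        loc[[j]][[i]] <- hit
        last_tet <- hit$tet
      }
    }
  }
  areas <- surface_areas(surf)[wall]
  mu <- fluid$viscosity
  interp <- function(vals, hits) {
    out <- matrix(NA_real_, nf, 3L)
    for (i in seq_len(nf)) {
      h <- hits[[i]]
      if (is.null(h)) next
      idx <- tets[h$tet, ]
      out[i, ] <- h$w %*% vals[idx, , drop = FALSE]
    }
    out
  }
  tau <- lapply(field$values, function(vals) {
    if (method == "second_order") {
      vh <- interp(vals, loc[[1L]])
      vd <- interp(vals, loc[[2L]])
      grad <- (4 * vh - vd) / delta
    } else {
      grad <- interp(vals, loc[[1L]]) / delta
    }
    tang <- grad - rowSums(grad * n_in) * n_in
    mu * tang
  })
  structure(list(tau = tau, areas = areas, faces = wall, valid = valid,
                 frame_times = field$frame_times, period = field$period),
            class = "wall_shear_series")
}

#' Construct a wall shear series directly
#'
#' For WSS data obtained outside [compute_wss()] (e.g. solver output): one
#' faces x 3 matrix of WSS vectors per frame, uniform frames over one
#' period.
#'
#' @param tau List of faces x 3 matrices (dyn/cm^2), one per frame.
#' @param areas Face areas, cm^2.
#' @param frame_times Frame times, s (uniform, starting at 0).
#' @param period Cardiac period, s.
#' @param faces Face indices (default sequential).
#' @return A `wall_shear_series`.
#' @export
wall_shear_series <- function(tau, areas, frame_times, period,
                              faces = seq_along(areas)) {
  stopifnot(is.list(tau), length(tau) == length(frame_times))
  tau <- lapply(tau, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3L, nrow(m) == length(areas))
    m
  })
  structure(list(tau = tau, areas = areas, faces = faces,
                 valid = rep(TRUE, length(areas)),
                 frame_times = frame_times, period = period),
            class = "wall_shear_series")
}

#' @export
print.wall_shear_series <- function(x, ...) {
  cat(sprintf("Wall shear series: %d faces x %d frames (%d valid faces)\n",
              length(x$faces), length(x$tau), sum(x$valid)))
  invisible(x)
}

wall_scalar_field <- function(values, wss, quantity) {
  structure(list(values = values, areas = wss$areas, faces = wss$faces,
                 valid = wss$valid, quantity = quantity),
            class = "wall_scalar_field")
}

#' @export
print.wall_scalar_field <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("Wall scalar field (%s): %d faces, range [%.3g, %.3g]\n",
              x$quantity, length(x$values), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

# periodic time average over uniform frames: for frames sampled uniformly on
# [0, T) the wrap-around trapezoidal rule reduces to the plain frame mean
periodic_mean <- function(mat) colMeans(mat)

tau_magnitudes <- function(wss) {
  m <- vapply(wss$tau, function(m) sqrt(rowSums(m^2)),
              numeric(length(wss$faces)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-face series
  m
}

#' Time-averaged wall shear stress
#'
#' Mean of |tau(t)| over one period (periodic trapezoidal rule on the
#' uniform frames).
#' @param wss A `wall_shear_series` from [compute_wss()].
#' @return A `wall_scalar_field` (dyn/cm^2).
#' @export
tawss <- function(wss) {
  stopifnot(inherits(wss, "wall_shear_series"))
  if (length(wss$tau) < 2L) stop("need at least 2 frames", call. = FALSE)
  mag <- tau_magnitudes(wss)           # faces x frames
  wall_scalar_field(rowMeans(mag), wss, "tawss")
}

#' Oscillatory shear index
#'
#' OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt), in [0, 0.5]:
#' 0 for unidirectional shear, 0.5 for full reversal. A face with
#' identically zero shear (0/0) is defined as 0.
#'
#' @param wss A `wall_shear_series` from [compute_wss()].
#' @return A `wall_scalar_field` (dimensionless).
#' @export
osi <- function(wss) {
  stopifnot(inherits(wss, "wall_shear_series"))
  if (length(wss$tau) < 2L) stop("need at least 2 frames", call. = FALSE)
  nfc <- length(wss$faces)
  sum_vec <- matrix(0, nfc, 3L)
  for (m in wss$tau) sum_vec <- sum_vec + m
  num <- sqrt(rowSums((sum_vec / length(wss$tau))^2))
  den <- rowMeans(tau_magnitudes(wss))
  v <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  wall_scalar_field(pmin(pmax(v, 0), 0.5), wss, "osi")
}

#' Wall shear rate
#'
#' Shear rate gamma = |WSS| / mu (1/s). Given a shear series the
#' time-averaged magnitude is used; given a `wall_scalar_field` (e.g. a
#' TAWSS field) its values are divided by the viscosity.
#'
#' @param wss A `wall_shear_series` or `wall_scalar_field`.
#' @param fluid A [fluid_properties()].
#' @return A `wall_scalar_field` (1/s).
#' @export
shear_rate <- function(wss, fluid = fluid_properties()) {
  if (inherits(wss, "wall_scalar_field"))
    return(wall_scalar_field(wss$values / fluid$viscosity, wss, "shear_rate"))
  stopifnot(inherits(wss, "wall_shear_series"))
  wall_scalar_field(rowMeans(tau_magnitudes(wss)) / fluid$viscosity,
                    wss, "shear_rate")
}

#' Relative residence time
#'
#' RRT = 1 / ((1 - 2 OSI) TAWSS), cm^2/dyn: a near-wall residence
#' surrogate that grows with both low and oscillatory shear. Faces with
#' OSI = 0.5 or TAWSS = 0 are unbounded and marked `NA` (excluded from
#' statistics).
#'
#' @param tawss_field TAWSS `wall_scalar_field`.
#' @param osi_field OSI `wall_scalar_field` on the same faces.
#' @return A `wall_scalar_field` (cm^2/dyn) with `NA` sentinels.
#' @export
rrt <- function(tawss_field, osi_field) {
  stopifnot(inherits(tawss_field, "wall_scalar_field"),
            inherits(osi_field, "wall_scalar_field"),
            identical(tawss_field$faces, osi_field$faces))
  den <- (1 - 2 * osi_field$values) * tawss_field$values
  v <- ifelse(den > 1e-12, 1 / den, NA_real_)
  wall_scalar_field(v, tawss_field, "rrt")
}

area_pct <- function(scalar, roi, member) {
  stopifnot(inherits(scalar, "wall_scalar_field"), inherits(roi, "bulb_roi"))
  sel <- match(roi$wall_faces, scalar$faces)
  if (anyNA(sel))
    stop("ROI wall faces are not a subset of the metric faces", call. = FALSE)
  ok <- scalar$valid[sel] & !is.na(scalar$values[sel])
  sel <- sel[ok]
  if (!length(sel)) stop("empty ROI after excluding flagged faces", call. = FALSE)
  a <- scalar$areas[sel]
  100 * sum(a[member(scalar$values[sel])]) / sum(a)
}

#' Low-shear area percentage inside the ROI
#'
#' Area-weighted percentage of ROI wall surface with shear rate strictly
#' below the threshold (default 10 1/s, the coagulation-linked value).
#'
#' @param shear A shear-rate `wall_scalar_field` (1/s).
#' @param roi A [bulb_roi()].
#' @param threshold Shear-rate threshold, 1/s.
#' @return Percentage in 0..100.
#' @export
low_shear_area_pct <- function(shear, roi, threshold = 10) {
  area_pct(shear, roi, function(v) v < threshold)
}

#' High-OSI area percentage inside the ROI
#'
#' Area-weighted percentage of ROI wall surface with OSI strictly above the
#' threshold (typically the pooled top-1% value across subjects).
#'
#' @param osi_field An OSI `wall_scalar_field`.
#' @param roi A [bulb_roi()].
#' @param threshold OSI threshold in (0, 0.5).
#' @return Percentage in 0..100.
#' @export
high_osi_area_pct <- function(osi_field, roi, threshold) {
  area_pct(osi_field, roi, function(v) v > threshold)
}

#' Export per-face wall metrics as CSV
#'
#' @param path Output CSV path.
#' @param tawss_field,osi_field,shear_field,rrt_field Matching
#'   `wall_scalar_field`s.
#' @return `path`, invisibly.
#' @export
write_wall_metrics <- function(path, tawss_field, osi_field, shear_field,
                               rrt_field) {
  utils::write.csv(data.frame(face_id = tawss_field$faces,
                              area_cm2 = tawss_field$areas,
                              tawss = tawss_field$values,
                              osi = osi_field$values,
                              shear_rate_mean = shear_field$values,
                              rrt = rrt_field$values,
                              valid = tawss_field$valid),
                   path, row.names = FALSE)
  invisible(path)
}
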