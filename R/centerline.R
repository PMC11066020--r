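# Centerline extraction by cross-section-centroid marching: starting from
# the inlet, planes advance along the running tangent in steps of a quarter
# local radius; at each station the lumen cross section is estimated from
# the tetrahedra cut by a thin slab around the plane. The equivalent radius
# is sqrt(area/pi). The bifurcation is detected where the cross section
# splits into two separated components (2-means split test); the march then
# follows the component heading toward the requested target outlet.

#' Centerline of a lumen mesh
#'
#' @param points n x 3 matrix of centerline points, cm.
#' @param radii Local equivalent radii, cm (> 0).
#' @param arclengths Cumulative arclength, cm, strictly increasing from 0.
#' @param bifurcation_index Index of the first station past the branch
#'   point, or `NA` for unbranched lumens.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, radii, arclengths, bifurcation_index = NA_integer_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, length(radii) == nrow(points),
            length(arclengths) == nrow(points))
  if (any(radii <= 0)) stop("local radii must be positive", call. = FALSE)
  if (any(diff(arclengths) <= 0))
    stop("arclength must be strictly increasing", call. = FALSE)
  structure(list(points = points, radii = as.numeric(radii),
                 arclengths = as.numeric(arclengths),
                 bifurcation_index = bifurcation_index),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("Centerline: %d stations, length %.3g cm%s\n",
              nrow(x$points), max(x$arclengths),
              if (is.na(x$bifurcation_index)) "" else
                sprintf(", bifurcation at station %d (s = %.3g cm)",
                        x$bifurcation_index,
                        x$arclengths[x$bifurcation_index])))
  invisible(x)
}

# Cross-section estimate in a slab around the plane through p with normal
# `tangent`. Each tetrahedron overlapping the slab contributes its volume
# scaled by the overlapped fraction of its axial extent, which makes the
# area estimate (= slab volume / slab thickness) insensitive to where the
# slab boundaries cut through cell layers. Returns centroid, area, and a
# split flag from a deterministic 2-means test (clusters separated by more
# than the sum of their equivalent radii = two distinct lumens); on a split
# the cluster kept is the one toward `steer` (else nearest `predicted`).
section_in_slab <- function(cen, vol, pz_lo, pz_hi, p, tangent, h,
                            predicted, r_prev, steer = NULL) {
  z0 <- sum(p * tangent)
  lo <- z0 - h; hi <- z0 + h
  sel <- which(pz_hi > lo & pz_lo < hi)
  if (!length(sel)) return(NULL)
  ext <- pz_hi[sel] - pz_lo[sel]
  over_lo <- pmax(pz_lo[sel], lo); over_hi <- pmin(pz_hi[sel], hi)
  w <- vol[sel] * (over_hi - over_lo) / pmax(ext, 1e-12)
  pts <- cen[sel, , drop = FALSE]
  # axial coordinate of a contribution = midpoint of its overlapped extent
  # (cells larger than the slab would otherwise quantize the centroid)
  zadj <- (over_lo + over_hi) / 2 - as.vector(pts %*% tangent)
  pts <- pts + zadj %o% tangent
  # gate to the neighborhood of the predicted point
  d2 <- (pts[, 1] - predicted[1])^2 + (pts[, 2] - predicted[2])^2 +
    (pts[, 3] - predicted[3])^2
  near <- d2 <= (3 * r_prev)^2
  if (!any(near)) return(NULL)
  pts <- pts[near, , drop = FALSE]; w <- w[near]
  split <- FALSE
  keep <- seq_along(w)
  if (length(w) >= 10L) {
    # deterministic 2-means: seed with the two extreme points along the
    # leading in-plane spread direction
    q <- sweep(pts, 2L, colMeans(pts))
    q <- q - (q %*% tangent) %*% t(tangent)
    cv <- crossprod(q * sqrt(w / sum(w)))
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    proj <- as.vector(q %*% ev)
    seeds <- pts[c(which.min(proj), which.max(proj)), , drop = FALSE]
    km <- tryCatch(suppressWarnings(stats::kmeans(pts, centers = seeds)),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size >= 4L)) {
      a1 <- sum(w[km$cluster == 1L]) / (2 * h)
      a2 <- sum(w[km$cluster == 2L]) / (2 * h)
      r1 <- sqrt(max(a1, 0) / pi); r2 <- sqrt(max(a2, 0) / pi)
      dcc <- sqrt(sum((km$centers[1L, ] - km$centers[2L, ])^2))
      if (min(a1, a2) > 0.15 * max(a1, a2) && dcc > 1.05 * (r1 + r2)) {
        split <- TRUE
        if (!is.null(steer)) {
          sc <- c(sum((km$centers[1L, ] - predicted) * steer),
                  sum((km$centers[2L, ] - predicted) * steer))
          pick <- which.max(sc)
        } else {
          pick <- which.min(c(sum((km$centers[1L, ] - predicted)^2),
                              sum((km$centers[2L, ] - predicted)^2)))
        }
        keep <- which(km$cluster == pick)
      }
    }
  }
  pts <- pts[keep, , drop = FALSE]; w <- w[keep]
  area <- sum(w) / (2 * h)
  centroid <- colSums(pts * w) / sum(w)
  list(centroid = centroid, area = area, split = split)
}

#' Extract a centerline by cross-section-centroid marching
#'
#' @param mesh A [volume_mesh()] with one inlet and at least one outlet.
#' @param target Outlet label to march toward after the bifurcation
#'   (default `"outlet_ica"`; ignored for unbranched meshes).
#' @param step_fraction Step length as a fraction of the local radius
#'   (default 0.25).
#' @param max_steps Safety bound on the number of stations.
#' @return A [centerline()] along the inlet-to-target path. Fails with a
#'   topology error when the lumen ahead of a station is empty before any
#'   outlet is reached.
#' @export
extract_centerline <- function(mesh, target = "outlet_ica",
                               step_fraction = 0.25, max_steps = 400L) {
  stopifnot(inherits(mesh, "volume_mesh"))
  surf <- mesh$boundary
  if (!any(surf$labels == "inlet")) stop("mesh has no inlet surface", call. = FALSE)
  cen <- tet_centroids(mesh)
  vol <- tet_volumes(mesh)
  # inlet centroid and inward tangent (mean inward normal)
  inl <- surf$labels == "inlet"
  ia <- triangle_areas(surf$vertices, surf$triangles[inl, , drop = FALSE])
  ic <- (surf$vertices[surf$triangles[inl, 1L], , drop = FALSE] +
           surf$vertices[surf$triangles[inl, 2L], , drop = FALSE] +
           surf$vertices[surf$triangles[inl, 3L], , drop = FALSE]) / 3
  p <- colSums(ic * ia) / sum(ia)
  tangent <- -colSums(surf$normals[inl, , drop = FALSE] * ia)
  tangent <- tangent / sqrt(sum(tangent^2))
  r0 <- sqrt(sum(ia) / pi)
  # outlet planes terminate the march; the target outlet centroid steers the
  # branch choice past the bifurcation
  steer_to <- NULL
  outlets <- list()
  for (lab in intersect(c("outlet_ica", "outlet_eca"), unique(surf$labels))) {
    tl <- surf$labels == lab
    ta <- triangle_areas(surf$vertices, surf$triangles[tl, , drop = FALSE])
    tc <- (surf$vertices[surf$triangles[tl, 1L], , drop = FALSE] +
             surf$vertices[surf$triangles[tl, 2L], , drop = FALSE] +
             surf$vertices[surf$triangles[tl, 3L], , drop = FALSE]) / 3
    ctr <- colSums(tc * ta) / sum(ta)
    nrm <- colSums(surf$normals[tl, , drop = FALSE] * ta)
    nrm <- nrm / sqrt(sum(nrm^2))
    outlets[[lab]] <- list(center = ctr, normal = nrm, radius = sqrt(sum(ta) / pi))
    if (lab == target) steer_to <- ctr
  }
  pts <- matrix(p, 1L, 3L)
  radii <- r0
  arcs <- 0
  bif_index <- NA_integer_
  r <- r0
  # mean cell scale sets the slab half-thickness floor
  cell_h <- stats::median(vol)^(1 / 3)
  v <- mesh$vertices; t4 <- mesh$tetrahedra
  for (k in seq_len(max_steps)) {
    step <- step_fraction * r
    h <- max(step, cell_h)
    p_new <- p + step * tangent
    steer <- if (!is.null(steer_to)) {
      sd <- steer_to - p; sd / sqrt(sum(sd^2))
    } else NULL
    # per-tet axial extents along the current tangent
    pz <- as.vector(v %*% tangent)
    z1 <- pz[t4[, 1L]]; z2 <- pz[t4[, 2L]]; z3 <- pz[t4[, 3L]]; z4 <- pz[t4[, 4L]]
    pz_lo <- pmin(z1, z2, z3, z4); pz_hi <- pmax(z1, z2, z3, z4)
    sec <- section_in_slab(cen, vol, pz_lo, pz_hi, p_new, tangent, h,
                           p_new, r, steer)
    if (is.null(sec)) {
      if (k <= 2L)
        stop("centerline extraction failed at the inlet (disconnected lumen?)",
             call. = FALSE)
      break  # marched out of the mesh: the outlet has been reached
    }
    # clamp the in-plane jump to half a radius to reject far-field leakage
    d_in <- sec$centroid - p_new
    d_in <- d_in - sum(d_in * tangent) * tangent
    if (sqrt(sum(d_in^2)) > 0.5 * r) d_in <- d_in * (0.5 * r / sqrt(sum(d_in^2)))
    p_next <- p_new + d_in
    # stop on crossing an outlet plane (within its face disc); the final
    # station is the march point projected onto the outlet plane
    done <- FALSE
    for (o in outlets) {
      if (sum((p_next - o$center) * o$normal) > -0.5 * step &&
          sqrt(sum((p_next - o$center)^2)) < 3 * o$radius) {
        tn <- sum(tangent * o$normal)
        if (tn > 0.1) {
          p_end <- p_next + tangent * (sum((o$center - p_next) * o$normal) / tn)
          gap <- sqrt(sum((p_end - pts[nrow(pts), ])^2))
          if (gap > 1e-6) {
            pts <- rbind(pts, p_end)
            arcs <- c(arcs, arcs[length(arcs)] + gap)
            radii <- c(radii, r)
          }
        }
        done <- TRUE
        break
      }
    }
    if (done) break
    # stop on stalled or reversed advance (the outlet face pulls the
    # centroid backward once the slab leaves the lumen)
    advance <- sum((sec$centroid - p) * tangent)
    if (advance < 0.4 * step) break
    if (sec$area < 0.05 * pi * r^2) break
    if (sec$split && is.na(bif_index)) bif_index <- length(radii) + 1L
    t_new <- (p_next - p) / sqrt(sum((p_next - p)^2))
    tangent <- tangent + t_new  # smoothed running tangent
    tangent <- tangent / sqrt(sum(tangent^2))
    arcs <- c(arcs, arcs[length(arcs)] + sqrt(sum((p_next - p)^2)))
    pts <- rbind(pts, p_next)
    r <- sqrt(sec$area / pi)
    radii <- c(radii, r)
    p <- p_next
  }
  if (nrow(pts) < 4L)
    stop("centerline extraction failed: fewer than 4 stations recovered (last good arclength ",
         signif(max(arcs), 4), " cm)", call. = FALSE)
  # single-station spikes (e.g. the transient at the branch split) are
  # artifacts of the slab estimator; a 3-point running median removes them
  radii <- stats::runmed(radii, 3L, endrule = "keep")
  # the final slab straddles the outlet and under-reports the area
  n <- length(radii)
  if (n > 5L && radii[n] < 0.9 * radii[n - 1L]) {
    pts <- pts[-n, , drop = FALSE]; radii <- radii[-n]; arcs <- arcs[-n]
  }
  centerline(pts, radii, arcs, bif_index)
}

#' Centerline from generator metadata
#'
#' For meshes built by the synthetic generator, returns the exact
#' construction centerline (trunk-to-ICA path) without extraction.
#' @param mesh A generated [volume_mesh()].
#' @return A [centerline()].
#' @export
metadata_centerline <- function(mesh) {
  stopifnot(inherits(mesh, "volume_mesh"))
  cl <- mesh$metadata$centerline
  if (is.null(cl)) stop("mesh carries no generator centerline", call. = FALSE)
  centerline(cl$points, cl$radii, cl$arclengths, cl$bifurcation_index)
}

#' Common carotid diameter from the inlet end of a centerline
#'
#' Twice the median local radius over the first `inlet_offset` of arclength
#' (median for robustness to single-station outliers).
#'
#' @param cl A [centerline()].
#' @param inlet_offset Arclength window from the inlet, cm (default 0.5).
#' @return Diameter, cm.
#' @export
cca_diameter <- function(cl, inlet_offset = 0.5) {
  stopifnot(inherits(cl, "centerline"))
  sel <- cl$arclengths <= inlet_offset
  if (!any(sel)) sel <- 1L
  2 * stats::median(cl$radii[sel])
}

#' Percent luminal narrowing (ECST-style)
#'
#' 100 (1 - d_min / d_ref): d_min is the minimum lumen diameter along the
#' profile; d_ref is the estimated normal diameter at the lesion site,
#' obtained by linearly interpolating between the median diameters of a
#' proximal and a distal window (each window spans twice the local radius,
#' separated from the lesion by the same margin).
#'
#' @param cl A [centerline()] covering the lesion and adjacent normal
#'   segments.
#' @return Percentage narrowing (0 for a uniform lumen).
#' @export
percent_narrowing <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  s <- cl$arclengths
  d <- 2 * cl$radii
  if (min(d) >= 0.999 * stats::median(d)) return(0)  # no discernible lesion
  i_min <- which.min(d)
  s_min <- s[i_min]
  w <- 2 * cl$radii[i_min]
  if (s_min - 2 * w < min(s) || s_min + 2 * w > max(s))
    stop("insufficient extent: profile must cover 2 windows on each side of the lesion",
         call. = FALSE)
  prox <- s >= s_min - 2 * w & s <= s_min - w
  dist <- s >= s_min + w & s <= s_min + 2 * w
  if (!any(prox) || !any(dist))
    stop("insufficient extent: empty reference window", call. = FALSE)
  d_p <- stats::median(d[prox]); s_p <- mean(s[prox])
  d_d <- stats::median(d[dist]); s_d <- mean(s[dist])
  d_ref <- d_p + (d_d - d_p) * (s_min - s_p) / (s_d - s_p)
  100 * max(0, 1 - d[i_min] / d_ref)
}
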