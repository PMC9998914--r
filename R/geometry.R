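# Star-convex geometry: boundary-distance extraction, polyhedron
# rasterization, IoU, the ray-count reconstruction study, and the empirical
# anisotropy estimate.

# logical inside-test for fractional 0-based (z,y,x) positions (n x 3):
# a position samples the voxel whose center is nearest (rounding)
inside_mask <- function(mask, pts) {
  d <- dim(mask)
  ind <- round(pts) + 1
  ok <- ind[, 1] >= 1 & ind[, 1] <= d[1] &
        ind[, 2] >= 1 & ind[, 2] <= d[2] &
        ind[, 3] >= 1 & ind[, 3] <= d[3]
  res <- logical(nrow(pts))
  if (any(ok)) res[ok] <- mask[ind[ok, , drop = FALSE]]
  res
}

#' Boundary distances along a ray set
#'
#' From a center voxel inside an instance, marches outward along every ray in
#' steps of `step` voxels until the sampled voxel leaves the instance, then
#' refines each boundary crossing by bisection to within `step/16`. This is
#' the exact-geometry counterpart of the per-pixel radial distances a
#' star-convex segmentation model predicts.
#'
#' @param mask logical 3D array (or label volume; any non-zero voxel is
#'   inside).
#' @param center 0-based `(z, y, x)` voxel inside the instance.
#' @param rays a [fibonacci_rays()] set (or a ray count).
#' @param step march step in voxels (> 0; default 0.5, well below the
#'   >= 20-voxel scale of a seed).
#' @return Numeric vector of crossing distances, one per ray.
#' @export
boundary_distances <- function(mask, center, rays, step = 0.5) {
  mask <- vol_data(mask) > 0
  rays <- as_ray_set(rays)
  if (step <= 0) stopf("step must be > 0")
  center <- as.numeric(center)
  if (!inside_mask(mask, matrix(center, 1L)))
    stopf("center (%g, %g, %g) is not inside the instance",
          center[1], center[2], center[3])
  drop(boundary_march_cpp(as.logical(mask), dim(mask),
                          matrix(center, 1L, 3L), rays$directions, step))
}

# batch variant: one row of distances per center
boundary_distances_batch <- function(mask, centers, rays, step = 0.5) {
  mask <- vol_data(mask) > 0
  boundary_march_cpp(as.logical(mask), dim(mask),
                     matrix(as.numeric(centers), ncol = 3L),
                     rays$directions, step)
}

# rasterize to a bounding-box voxel set (internal work-horse)
rasterize_vs <- function(instance, rays, shape) {
  rays <- as_ray_set(rays)
  if (rays$n < 4L) stopf("rasterization requires at least 4 rays")
  center <- instance$center
  if (any(center < 0) || any(center > dim_or(shape) - 1))
    stopf("instance center lies outside the volume")
  dists <- instance$dists
  rmax <- max(dists)
  if (rmax == 0) {  # all-zero distances: exactly the center voxel
    m <- array(TRUE, c(1L, 1L, 1L))
    return(voxel_set(round(center), m))
  }
  tri <- ray_triangulation(rays)
  dirs <- rays$directions
  minv <- matrix(NA_real_, nrow(tri), 9L)
  keep <- rep(TRUE, nrow(tri))
  for (j in seq_len(nrow(tri))) {
    M <- t(dirs[tri[j, ], , drop = FALSE])  # columns = unit directions
    inv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(inv)) keep[j] <- FALSE else minv[j, ] <- as.vector(inv)
  }
  fdist <- cbind(dists[tri[, 1]], dists[tri[, 2]], dists[tri[, 3]])
  minv <- minv[keep, , drop = FALSE]
  fdist <- fdist[keep, , drop = FALSE]
  if (nrow(minv) == 0L) stopf("degenerate ray triangulation")
  shp <- dim_or(shape)
  origin <- pmax(floor(center - rmax), 0)
  top <- pmin(ceiling(center + rmax), shp - 1)
  bdim <- as.integer(top - origin + 1)
  m <- array(rasterize_star_cpp(center, minv, fdist, as.integer(origin),
                                bdim, rmax),
             dim = bdim)
  voxel_set(origin, m)
}

dim_or <- function(shape) {
  if (is.array(shape)) dim(shape) else as.numeric(shape)
}

#' Rasterize a star-convex polyhedron into a voxel mask
#'
#' A voxel `v` is inside iff `|v - center| <= r(u)` where `u` is the direction
#' of `v - center` and `r` interpolates the per-ray boundary distances over
#' the spherical triangulation of the ray directions (piecewise-planar
#' polyhedron surface through the boundary points `d_i * u_i`). The all-zero
#' distance vector rasterizes, by convention, to exactly the center voxel.
#'
#' @param instance a [star_instance()].
#' @param rays the matching [fibonacci_rays()] set.
#' @param shape volume shape `(Z, Y, X)` to rasterize into (clips the
#'   polyhedron at the volume bounds).
#' @return Logical array of dimension `shape`.
#' @export
rasterize <- function(instance, rays, shape) {
  shp <- as.integer(dim_or(shape))
  vs <- rasterize_vs(instance, rays, shp)
  out <- array(FALSE, shp)
  vs_paint(out, vs, TRUE)
}

#' Intersection-over-union of two voxel masks
#'
#' @param a,b logical (or 0/positive) arrays of identical shape.
#' @return `|a & b| / |a | b|`; two empty masks give 0 by convention.
#' @export
mask_iou <- function(a, b) {
  a <- vol_data(a) > 0
  b <- vol_data(b) > 0
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  sum(a & b) / uni
}

# coordinates (0-based, n x 3) of every voxel of each instance,
# as a named list keyed by label
instance_coords <- function(labels) {
  arr <- vol_data(labels)
  idx <- which(arr > 0L)
  if (length(idx) == 0L) return(list())
  vals <- arr[idx]
  coords <- arrayInd(idx, dim(arr)) - 1L
  lapply(split(seq_along(idx), vals), function(i) coords[i, , drop = FALSE])
}

# interior voxel nearest the centroid (the centroid itself may fall outside
# a concave instance)
interior_center <- function(coords) {
  cen <- colMeans(coords)
  d2 <- (coords[, 1] - cen[1])^2 + (coords[, 2] - cen[2])^2 +
        (coords[, 3] - cen[3])^2
  as.numeric(coords[which.min(d2), ])
}

#' Star-convex reconstruction accuracy versus ray count
#'
#' For every instance: take the interior voxel nearest the centroid as the
#' reconstruction center, extract boundary distances along the ray set,
#' rasterize the polyhedron and score it by IoU against the original mask.
#' Reports the mean IoU per ray count — the study that decides how many rays
#' a star-convex representation of the objects needs.
#'
#' @param labels a [label_volume()] with at least one instance.
#' @param ray_counts ray counts to evaluate (default `8, 16, 32, 64, 96, 128`).
#' @param anisotropy per-axis factors passed to [fibonacci_rays()].
#' @param step march step for [boundary_distances()].
#' @return Data frame with columns `ray_count`, `mean_iou`, `n_instances`.
#' @export
reconstruction_accuracy <- function(labels, ray_counts = c(8, 16, 32, 64, 96, 128),
                                    anisotropy = c(1, 1, 1), step = 0.5) {
  coords <- instance_coords(labels)
  if (length(coords) == 0L) stopf("label volume contains no instances")
  arr <- vol_data(labels)
  ious <- matrix(NA_real_, length(coords), length(ray_counts))
  for (i in seq_along(coords)) {
    co <- coords[[i]]
    lab <- as.integer(names(coords)[i])
    lo <- pmax(apply(co, 2, min) - 3L, 0)
    hi <- pmin(apply(co, 2, max) + 3L, dim(arr) - 1L)
    sub <- arr[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
               drop = FALSE] == lab
    center <- interior_center(co) - lo
    for (j in seq_along(ray_counts)) {
      rays <- fibonacci_rays(ray_counts[j], anisotropy)
      d <- boundary_distances(sub, center, rays, step = step)
      rec <- rasterize(star_instance(center, d), rays, dim(sub))
      ious[i, j] <- mask_iou(rec, sub)
    }
  }
  data.frame(ray_count = as.integer(ray_counts),
             mean_iou = colMeans(ious),
             n_instances = length(coords))
}

#' Empirical per-axis anisotropy of labelled instances
#'
#' Median bounding-box extent of all instances along each axis; the factor
#' for an axis is the largest median extent divided by that axis's median, so
#' the longest axis gets exactly 1 and shorter axes get factors > 1.
#'
#' @param labels a [label_volume()] or a list of them.
#' @return Named numeric `(z, y, x)` of class `anisotropy_estimate`.
#' @examples
#' # instances with median extents (32, 31, 29) give (1, 32/31, 32/29)
#' @export
empirical_anisotropy <- function(labels) {
  if (!is.list(labels) || !is.null(dim(labels))) labels <- list(labels)
  ext <- do.call(rbind, lapply(labels, function(lv) {
    co <- instance_coords(lv)
    if (length(co) == 0L) return(NULL)
    t(vapply(co, function(cc) apply(cc, 2, max) - apply(cc, 2, min) + 1,
             numeric(3)))
  }))
  if (is.null(ext) || nrow(ext) == 0L) stopf("no instances found")
  med <- apply(ext, 2, median)
  est <- max(med) / med
  structure(stats::setNames(est, c("z", "y", "x")),
            class = "anisotropy_estimate")
}

#' @export
print.anisotropy_estimate <- function(x, ...) {
  cat(sprintf("<anisotropy_estimate> Z = %.15g, Y = %.15g, X = %.15g\n",
              x[1], x[2], x[3]))
  invisible(x)
}
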