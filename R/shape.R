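# Per-instance location and size/shape measurements.
#
# Conventions: 0-based voxel coordinates; bounding boxes half-open [min, max)
# per axis, so (max - min) along the three axes multiplies to the bounding-box
# volume and matches the reported per-axis minima/maxima.

#' Sphericity from volume and surface area
#'
#' Ratio of the surface area of a sphere with the instance's volume to the
#' instance's mesh surface area: `pi^(1/3) * (6 V)^(2/3) / A`.
#'
#' @param volume instance volume in voxels.
#' @param surface_area mesh surface area in voxel^2.
#' @return Sphericity (1 for a perfect sphere, < 1 otherwise).
#' @examples
#' sphericity(23237, 4440.313)
#' @export
sphericity <- function(volume, surface_area) {
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Equivalent diameter from volume
#'
#' Diameter of the sphere with the same volume: `(6 V / pi)^(1/3)`.
#'
#' @param volume instance volume in voxels.
#' @return Equivalent diameter in voxels.
#' @examples
#' equivalent_diameter(19451)
#' @export
equivalent_diameter <- function(volume) {
  (6 * volume / pi)^(1 / 3)
}

# convex-hull voxel count: voxels of the instance bounding box whose centers
# lie inside (or on) the hull of the instance's boundary-voxel centers
convex_volume_count <- function(coords, sub) {
  if (nrow(coords) < 4L) return(nrow(coords))
  d <- dim(sub)
  # boundary voxels: any of the 6 face neighbours outside the instance
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sub
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  bidx <- which(sub & !inner)
  bpts <- arrayInd(bidx, d) - 1L
  hull <- convex_hull3_cpp(bpts * 1.0)
  if (nrow(hull$facets) == 0L) return(sum(sub))  # flat/degenerate instance
  inside <- in_hull_grid_cpp(c(0L, 0L, 0L), as.integer(d),
                             hull$normals, hull$offsets, 1e-7)
  sum(inside)
}

#' Measure location and shape of every instance
#'
#' For each labelled instance: bounding box (0-based, half-open) and centroid
#' per axis; voxel-count volume; bounding-box volume and `extent`
#' (volume / bbox volume); convex-hull voxel count and `solidity`
#' (volume / convex volume); equivalent spherical diameter; mesh surface area
#' ([surface_area_mesh()]) and sphericity; major/minor axis lengths of the
#' ellipsoid with the same second central moments (`2 * sqrt(5 * lambda)` for
#' the largest/smallest eigenvalue of the voxel-coordinate covariance).
#' The valve columns are left unset; [assign_valves()] fills them.
#'
#' @param labels a [label_volume()].
#' @return Data frame with one row per instance (empty for an empty volume).
#' @export
measure_instances <- function(labels) {
  coords <- instance_coords(labels)
  arr <- vol_data(labels)
  rows <- lapply(names(coords), function(lab) {
    co <- coords[[lab]]
    lo <- apply(co, 2, min)
    hi <- apply(co, 2, max) + 1L  # half-open
    cen <- colMeans(co)
    vol <- nrow(co)
    bvol <- prod(hi - lo)
    sub <- arr[(lo[1]:(hi[1] - 1)) + 1L, (lo[2]:(hi[2] - 1)) + 1L,
               (lo[3]:(hi[3] - 1)) + 1L, drop = FALSE] == as.integer(lab)
    sa <- surface_area_mesh(sub)
    cvol <- convex_volume_count(sweep(co, 2L, lo), sub)
    cc <- sweep(co, 2L, cen)
    ev <- if (vol > 1L) eigen(crossprod(cc) / vol, symmetric = TRUE,
                              only.values = TRUE)$values
          else c(0, 0, 0)
    ev <- pmax(ev, 0)
    data.frame(
      seed_id = as.integer(lab),
      z_min = lo[1], y_min = lo[2], x_min = lo[3],
      z_max = hi[1], y_max = hi[2], x_max = hi[3],
      z_centroid = cen[1], y_centroid = cen[2], x_centroid = cen[3],
      volume = vol, bbox_volume = bvol,
      sphericity = sphericity(vol, sa), surface_area = sa,
      convex_volume = cvol,
      equivalent_diameter = equivalent_diameter(vol),
      extent = vol / bvol,
      major_axis_length = 2 * sqrt(5 * ev[1]),
      minor_axis_length = 2 * sqrt(5 * ev[3]),
      solidity = vol / cvol,
      valve = NA_integer_, sequence_in_valve = NA_integer_,
      spacing_to_previous = NA_real_)
  })
  if (!length(rows)) {
    sch <- seed_table_schema()$internal
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(sch)),
                                         sch))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the image of one detected seed
#'
#' Crops the intensity volume to the instance's bounding box with every voxel
#' outside the instance zeroed, and extracts the three orthogonal mid-slices
#' through the centroid voxel: trans-axial XY (fixed Z), YZ (fixed X) and XZ
#' (fixed Y).
#'
#' @param image the [image_volume()] the labels were derived from.
#' @param labels the matching [label_volume()].
#' @param seed_id label of the instance to export.
#' @return List with `crop` (masked 3D sub-volume, dimensions = bbox extents),
#'   `slice_xy`, `slice_yz`, `slice_xz` (2D matrices) and `bbox`.
#' @export
export_instance_images <- function(image, labels, seed_id) {
  img <- vol_data(image)
  arr <- vol_data(labels)
  if (!identical(dim(img), dim(arr))) stopf("image and label shapes differ")
  idx <- which(arr == as.integer(seed_id))
  if (!length(idx)) stopf("no instance with label %s", seed_id)
  co <- arrayInd(idx, dim(arr)) - 1L
  lo <- apply(co, 2, min)
  hi <- apply(co, 2, max) + 1L
  cen <- round(colMeans(co))
  crop <- img[(lo[1]:(hi[1] - 1)) + 1L, (lo[2]:(hi[2] - 1)) + 1L,
              (lo[3]:(hi[3] - 1)) + 1L, drop = FALSE]
  m <- arr[(lo[1]:(hi[1] - 1)) + 1L, (lo[2]:(hi[2] - 1)) + 1L,
           (lo[3]:(hi[3] - 1)) + 1L, drop = FALSE] == as.integer(seed_id)
  crop[!m] <- 0
  ci <- pmin(pmax(cen - lo, 0), dim(crop) - 1L) + 1L
  list(crop = crop,
       slice_xy = crop[ci[1], , ],
       slice_yz = crop[, , ci[3]],
       slice_xz = crop[, ci[2], ],
       bbox = list(min = lo, max = hi))
}
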