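#' Fibonacci ray set
#'
#' Generates `n` unit direction vectors from the golden-angle spherical
#' lattice: for `k = 0..n-1`, `z_k = 1 - 2(k + 0.5)/n` and azimuth
#' `theta_k = k * pi * (3 - sqrt(5))`. The lattice is approximately equal-area
#' on the sphere, which makes the per-ray boundary distances of a star-convex
#' body roughly equally informative in every direction.
#'
#' With a non-trivial `anisotropy`, each lattice vector is divided
#' component-wise by the per-axis factors and renormalised. This moves rays
#' away from axes with larger factors (the axes along which objects are
#' shorter), so that an ellipsoid with those axis ratios is evenly covered by
#' the warped set.
#'
#' @param n ray count (>= 1; rasterization additionally needs >= 4).
#' @param anisotropy three positive per-axis scale factors `(Z, Y, X)`, e.g.
#'   from [empirical_anisotropy()].
#' @return A `ray_set`: list with `n`, the `n x 3` matrix `directions` of unit
#'   `(Z, Y, X)` vectors, and `anisotropy`.
#' @examples
#' r <- fibonacci_rays(96)
#' range(sqrt(rowSums(r$directions^2)))  # all 1
#' @export
fibonacci_rays <- function(n, anisotropy = c(1, 1, 1)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stopf("n must be a positive integer")
  if (length(anisotropy) != 3L || any(!is.finite(anisotropy)) ||
      any(anisotropy <= 0))
    stopf("anisotropy must be 3 positive factors (Z, Y, X)")
  n <- as.integer(n)
  k <- seq_len(n) - 1L
  zc <- 1 - 2 * (k + 0.5) / n
  theta <- k * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - zc^2))
  dirs <- cbind(z = zc, y = rho * sin(theta), x = rho * cos(theta))
  if (any(anisotropy != 1)) {
    dirs <- sweep(dirs, 2L, anisotropy, "/")
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  structure(list(n = n, directions = dirs,
                 anisotropy = as.numeric(anisotropy)),
            class = "ray_set")
}

#' @export
print.ray_set <- function(x, ...) {
  cat(sprintf("<ray_set> %d Fibonacci rays, anisotropy (%.6g, %.6g, %.6g)\n",
              x$n, x$anisotropy[1], x$anisotropy[2], x$anisotropy[3]))
  invisible(x)
}

as_ray_set <- function(rays) {
  if (inherits(rays, "ray_set")) return(rays)
  if (is.numeric(rays) && length(rays) == 1L) return(fibonacci_rays(rays))
  stopf("rays must be a ray_set or a ray count")
}

# spherical triangulation of the ray directions = convex hull facets;
# every direction of a Fibonacci set is extreme, so the triangulation
# covers the sphere
ray_triangulation <- function(rays) {
  hull <- convex_hull3_cpp(rays$directions)
  if (nrow(hull$facets) == 0L)
    stopf("ray triangulation requires at least 4 non-coplanar rays")
  hull$facets
}

#' Star-convex instance
#'
#' One detected or reconstructed object: a center voxel plus the radial
#' distance from the center to the object boundary along each ray of an
#' associated [fibonacci_rays()] set, and a confidence score.
#'
#' @param center 0-based voxel coordinate `(z, y, x)`.
#' @param dists non-negative boundary distances (voxels), one per ray.
#' @param score confidence in `[0, 1]`.
#' @return A `star_instance` list.
#' @export
star_instance <- function(center, dists, score = 1) {
  if (length(center) != 3L || any(!is.finite(center)))
    stopf("center must be a finite (z, y, x) coordinate")
  if (any(!is.finite(dists)) || any(dists < 0))
    stopf("distances must be finite and non-negative")
  check_scalar01(score, "score")
  structure(list(center = as.numeric(center), dists = as.numeric(dists),
                 score = as.numeric(score)),
            class = "star_instance")
}

#' @export
print.star_instance <- function(x, ...) {
  cat(sprintf(
    "<star_instance> center (%g, %g, %g), %d rays, score %.3f, mean dist %.2f\n",
    x$center[1], x$center[2], x$center[3], length(x$dists), x$score,
    mean(x$dists)))
  invisible(x)
}
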