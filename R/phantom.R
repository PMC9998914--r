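# Synthetic pod phantom.
#
# Emulates the structure of a micro-CT scan of a dried seed pod: the pod's
# long axis runs along Z, each trans-axial slice shows an elliptical pod wall
# shell, and the seeds sit in two rows (valves) on either side of a smooth
# pseudoseptum curve in the Z-X plane. Seeds are star-convex bodies: a base
# ellipsoid radius modulated by a smooth low-order directional series with
# bounded amplitude, which keeps every body star-convex about its center by
# construction. Intensities are composited (seed > wall > background) with
# additive Gaussian noise, the CT-like degradation that matters for the
# threshold/distance-transform detector. Everything is deterministic under a
# fixed RNG seed.

#' Phantom configuration
#'
#' Defaults describe a pod scaled down from full scan size (256 x 128 x 128
#' rather than up to 1397 x 512 x 512) with the seed scale preserved: base
#' radii 10-18 voxels give per-axis extents of roughly 20-36 voxels.
#'
#' @param shape volume shape `(Z, Y, X)`.
#' @param n_seeds number of seeds to place.
#' @param radius_range min/max base seed radius (voxels).
#' @param axis_scale_range per-seed Y/X axis scale range relative to Z
#'   (values <= 1 make Z the long axis on average).
#' @param perturbation amplitude cap of the smooth directional radius
#'   modulation, as a fraction of the ellipsoid radius (< 1 keeps radii
#'   positive, hence bodies star-convex).
#' @param valve_offset_range min/max lateral (X) offset of seed centers from
#'   the pseudoseptum curve (voxels).
#' @param septum_amplitude maximum deviation of the pseudoseptum curve from
#'   the pod midline (voxels); the curve is a random cubic in Z.
#' @param flip_prob probability that a seed breaks the alternating valve
#'   pattern and lands on the same side as its predecessor.
#' @param wall_thickness pod wall shell thickness (voxels).
#' @param cavity_semiaxes `(Y, X)` semi-axes of the pod cavity ellipse.
#' @param intensities named levels `background`, `wall`, `seed` in `[0, 1]`.
#' @param noise_sd additive Gaussian noise SD (seed-background contrast 0.75
#'   over noise 0.05 is a signal-to-noise ratio of 15).
#' @param clearance minimum surface gap enforced between seeds and between
#'   seed and wall (voxels).
#' @param seed RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(256L, 128L, 128L), n_seeds = 7L,
                           radius_range = c(10, 18),
                           axis_scale_range = c(0.85, 1),
                           perturbation = 0.15,
                           valve_offset_range = c(9, 15),
                           septum_amplitude = 4, flip_prob = 0.1,
                           wall_thickness = 3,
                           cavity_semiaxes = c(40, 48),
                           intensities = c(background = 0.1, wall = 0.45,
                                           seed = 0.85),
                           noise_sd = 0.05, clearance = 3, seed = 1L) {
  if (n_seeds < 1L) stopf("n_seeds must be >= 1")
  if (perturbation < 0 || perturbation >= 1)
    stopf("perturbation must be in [0, 1)")
  if (diff(radius_range) < 0 || radius_range[1] <= 0)
    stopf("invalid radius_range")
  if (!all(c("background", "wall", "seed") %in% names(intensities)))
    stopf("intensities needs levels background, wall, seed")
  structure(list(shape = as.integer(shape), n_seeds = as.integer(n_seeds),
                 radius_range = radius_range,
                 axis_scale_range = axis_scale_range,
                 perturbation = perturbation,
                 valve_offset_range = valve_offset_range,
                 septum_amplitude = septum_amplitude, flip_prob = flip_prob,
                 wall_thickness = wall_thickness,
                 cavity_semiaxes = cavity_semiaxes,
                 intensities = intensities, noise_sd = noise_sd,
                 clearance = clearance, seed = as.integer(seed)),
            class = "phantom_config")
}

# smooth directional radius modulation: p(u) = sum_j c_j (u . w_j)^(d_j),
# |p| <= amplitude since sum |c_j| = amplitude and |u . w_j| <= 1
sample_perturbation <- function(amplitude) {
  w <- matrix(rnorm(12), 4L, 3L)
  w <- w / sqrt(rowSums(w^2))
  cc <- runif(4L, -1, 1)
  s <- sum(abs(cc))
  cc <- if (s > 0) cc / s * amplitude else rep(0, 4L)
  dg <- c(1, 2, 2, 3)
  list(w = w, c = cc, d = dg)
}

# radius along unit directions U (m x 3) for one seed
seed_radius <- function(U, radii, pert) {
  rell <- 1 / sqrt((U[, 1] / radii[1])^2 + (U[, 2] / radii[2])^2 +
                   (U[, 3] / radii[3])^2)
  p <- rep(0, nrow(U))
  for (j in seq_along(pert$c)) {
    p <- p + pert$c[j] * (U %*% pert$w[j, ])^pert$d[j]
  }
  rell * (1 + p)
}

# rasterize one seed body into a voxel set centered at `center`
rasterize_seed <- function(center, radii, pert, shape, rmax) {
  lo <- pmax(floor(center - rmax - 1), 0)
  hi <- pmin(ceiling(center + rmax + 1), shape - 1)
  bdim <- as.integer(hi - lo + 1)
  gz <- (lo[1]:hi[1]) - center[1]
  gy <- (lo[2]:hi[2]) - center[2]
  gx <- (lo[3]:hi[3]) - center[3]
  U <- cbind(rep(gz, times = bdim[2] * bdim[3]),
             rep(rep(gy, each = bdim[1]), times = bdim[3]),
             rep(gx, each = bdim[1] * bdim[2]))
  rho <- sqrt(rowSums(U^2))
  inside <- rho < 1e-9
  nz <- which(!inside & rho <= rmax + 1)
  if (length(nz)) {
    r <- seed_radius(U[nz, , drop = FALSE] / rho[nz], radii, pert)
    inside[nz] <- rho[nz] <= r
  }
  voxel_set(lo, array(inside, bdim))
}

# sample a full arrangement (no rasterization); NULL if infeasible
sample_arrangement <- function(cfg) {
  shp <- cfg$shape
  y0 <- (shp[2] - 1) / 2
  x0 <- (shp[3] - 1) / 2
  n <- cfg$n_seeds
  # pseudoseptum: random cubic in normalized z, scaled to the amplitude
  a <- runif(3, -1, 1)
  septum <- function(z) {
    u <- z / max(shp[1] - 1, 1) - 0.5
    q <- a[1] * u + a[2] * u^2 + a[3] * u^3
    qn <- max(abs(a[1] * 0.5 + a[2] * 0.25 + a[3] * 0.125),
              abs(-a[1] * 0.5 + a[2] * 0.25 - a[3] * 0.125), abs(q), 1e-9)
    x0 + cfg$septum_amplitude * q / qn
  }
  rmax_cap <- cfg$radius_range[2] * (1 + cfg$perturbation)
  margin <- rmax_cap + cfg$clearance
  usable <- shp[1] - 1 - 2 * margin
  if (usable < 0) return(NULL)
  zs <- if (n == 1L) margin + usable / 2 else
    margin + usable * (seq_len(n) - 1) / (n - 1)
  zs <- zs + runif(n, -0.25, 0.25) * if (n > 1L) usable / (n - 1) else 0
  zs <- pmin(pmax(zs, margin), shp[1] - 1 - margin)
  side <- integer(n)
  side[1] <- sample(c(1L, 2L), 1L)
  if (n > 1L) for (i in 2:n) {
    side[i] <- if (runif(1) < cfg$flip_prob) side[i - 1L] else 3L - side[i - 1L]
  }
  r_base <- runif(n, cfg$radius_range[1], cfg$radius_range[2])
  scl <- cbind(1, runif(n, cfg$axis_scale_range[1], cfg$axis_scale_range[2]),
               runif(n, cfg$axis_scale_range[1], cfg$axis_scale_range[2]))
  radii <- r_base * scl
  rmax <- apply(radii, 1, max) * (1 + cfg$perturbation)
  off <- runif(n, cfg$valve_offset_range[1], cfg$valve_offset_range[2])
  xs <- septum(zs) + ifelse(side == 1L, off, -off)
  ys <- y0 + runif(n, -3, 3)
  centers <- cbind(zs, ys, xs)
  # pairwise non-overlap: center distance > sum of max radii + clearance
  if (n > 1L) {
    D <- as.matrix(stats::dist(centers))
    need <- outer(rmax, rmax, "+") + cfg$clearance
    diag(D) <- Inf
    if (any(D <= need)) return(NULL)
  }
  # containment in the pod cavity with clearance to the wall
  ry <- cfg$cavity_semiaxes[1]
  rx <- cfg$cavity_semiaxes[2]
  e <- ((xs - x0) / (rx - rmax - cfg$clearance))^2 +
       ((ys - y0) / (ry - rmax - cfg$clearance))^2
  if (any(!is.finite(e)) || any(e > 1)) return(NULL)
  list(centers = centers, radii = radii, rmax = rmax, side = side,
       septum = septum, y0 = y0, x0 = x0)
}

#' Generate a synthetic pod volume with ground truth
#'
#' Places `n_seeds` star-convex seed bodies alternately (with occasional
#' flips) on either side of a smooth pseudoseptum curve at jittered Z
#' positions, enforcing pairwise non-overlap (center distance greater than
#' the sum of maximal radii plus the clearance) with bounded retries;
#' composites background, pod wall shell and seed intensities; adds Gaussian
#' noise (clipped to `[0, 1]`).
#'
#' @param cfg a [phantom_config()].
#' @return List of class `pod_phantom`: `image` ([image_volume()]), `labels`
#'   ([label_volume()]) and `truth` (data frame: `seed_id`, centroids, `valve`,
#'   `sequence_in_valve`, base `radius`, `rmax`).
#' @export
generate_pod <- function(cfg = phantom_config()) {
  with_rng(cfg$seed, {
    arrangement <- NULL
    for (try in seq_len(200L)) {
      arrangement <- sample_arrangement(cfg)
      if (!is.null(arrangement)) break
    }
    if (is.null(arrangement))
      stopf("cannot place %d seeds without overlap in a %s volume",
            cfg$n_seeds, paste(cfg$shape, collapse = "x"))
    ar <- arrangement
    shp <- cfg$shape
    n <- cfg$n_seeds
    perts <- lapply(seq_len(n), function(i) sample_perturbation(cfg$perturbation))
    lab <- array(0L, shp)
    for (i in seq_len(n)) {
      vs <- rasterize_seed(ar$centers[i, ], ar$radii[i, ], perts[[i]], shp,
                           ar$rmax[i])
      lab <- vs_paint(lab, vs, i, overwrite = FALSE)
    }
    img <- array(cfg$intensities[["background"]], shp)
    # pod wall: elliptical shell, constant along Z
    yy <- matrix((seq_len(shp[2]) - 1 - ar$y0), shp[2], shp[3])
    xx <- matrix((seq_len(shp[3]) - 1 - ar$x0), shp[2], shp[3], byrow = TRUE)
    s <- sqrt((xx / cfg$cavity_semiaxes[2])^2 + (yy / cfg$cavity_semiaxes[1])^2)
    wall2d <- s >= 1 & s <= 1 + cfg$wall_thickness / min(cfg$cavity_semiaxes)
    wall3d <- aperm(array(wall2d, c(shp[2], shp[3], shp[1])), c(3, 1, 2))
    img[wall3d] <- cfg$intensities[["wall"]]
    img[lab > 0L] <- cfg$intensities[["seed"]]
    img <- img + rnorm(length(img), 0, cfg$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    img <- array(img, shp)
    # truth from the painted labels (centroids of actual voxels)
    meas <- instance_coords(lab)
    cen <- t(vapply(meas, colMeans, numeric(3)))
    truth <- data.frame(seed_id = as.integer(names(meas)),
                        z_centroid = cen[, 1], y_centroid = cen[, 2],
                        x_centroid = cen[, 3],
                        valve = ar$side[as.integer(names(meas))],
                        radius = signif(apply(ar$radii, 1, function(r)
                          r[1])[as.integer(names(meas))], 6),
                        rmax = ar$rmax[as.integer(names(meas))])
    truth <- truth[order(truth$seed_id), , drop = FALSE]
    truth$sequence_in_valve <- NA_integer_
    for (v in c(1L, 2L)) {
      iv <- which(truth$valve == v)
      iv <- iv[order(truth$z_centroid[iv])]
      truth$sequence_in_valve[iv] <- seq_along(iv)
    }
    structure(list(image = image_volume(img), labels = label_volume(lab),
                   truth = truth, config = cfg),
              class = "pod_phantom")
  })
}

#' @export
print.pod_phantom <- function(x, ...) {
  cat(sprintf("<pod_phantom> %s volume, %d seed(s), noise SD %.3g\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$truth),
              x$config$noise_sd))
  invisible(x)
}

#' Generate standalone star-convex seed masks
#'
#' Produces `n` isolated seed bodies (one small label volume each) with the
#' same radius/perturbation model as [generate_pod()] — the inputs of the
#' ray-count reconstruction study, without the cost of full pod volumes.
#'
#' @param n number of seeds.
#' @param cfg a [phantom_config()] (radius, axis-scale and perturbation
#'   fields are used).
#' @param seed RNG seed (defaults to the config's).
#' @return List of [label_volume()]s, each with a single instance labelled 1.
#' @export
generate_seed_masks <- function(n, cfg = phantom_config(), seed = cfg$seed) {
  with_rng(seed, {
    lapply(seq_len(n), function(i) {
      r_base <- runif(1, cfg$radius_range[1], cfg$radius_range[2])
      radii <- r_base * c(1, runif(2, cfg$axis_scale_range[1],
                                   cfg$axis_scale_range[2]))
      pert <- sample_perturbation(cfg$perturbation)
      rmax <- max(radii) * (1 + cfg$perturbation)
      side <- as.integer(2 * ceiling(rmax) + 5)
      shp <- c(side, side, side)
      ctr <- (shp - 1) / 2
      vs <- rasterize_seed(ctr, radii, pert, shp, rmax)
      lab <- array(0L, shp)
      label_volume(vs_paint(lab, vs, 1L))
    })
  })
}

#' Generate a multi-pod study with manifest
#'
#' Samples a per-pod seed count, derives a per-pod RNG seed from the master
#' seed, generates each phantom and writes its image TIFF, label TIFF and
#' truth CSV under `out_dir`, plus a `manifest.csv` listing pod id, seed
#' count, file paths and per-pod seed. The Z extent grows automatically with
#' the seed count so any count in the observed 1-34 range fits.
#'
#' @param n_pods number of pods.
#' @param out_dir output directory (created if needed).
#' @param n_seeds_range inclusive range the per-pod seed count is drawn from.
#' @param seed master RNG seed.
#' @param ... overrides passed to [phantom_config()] for every pod.
#' @return The manifest data frame, invisibly.
#' @export
generate_study <- function(n_pods, out_dir, n_seeds_range = c(1L, 12L),
                           seed = 1L, ...) {
  if (n_pods < 1L) stopf("n_pods must be >= 1")
  if (n_seeds_range[1] < 1L || diff(n_seeds_range) < 0)
    stopf("invalid n_seeds_range")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_cfg <- phantom_config(...)
  rows <- with_rng(seed, {
    vals <- n_seeds_range[1]:n_seeds_range[2]
    counts <- vals[sample.int(length(vals), n_pods, replace = TRUE)]
    seeds <- sample.int(.Machine$integer.max - 1L, n_pods)
    lapply(seq_len(n_pods), function(i) {
      cfg <- base_cfg
      cfg$n_seeds <- counts[i]
      cfg$seed <- seeds[i]
      need_z <- ceiling(2 * (cfg$radius_range[2] * (1 + cfg$perturbation) +
                             cfg$clearance) * (counts[i] + 1))
      cfg$shape[1] <- max(cfg$shape[1], need_z)
      pod <- generate_pod(cfg)
      id <- sprintf("pod%03d", i)
      paths <- file.path(out_dir, paste0(id, c("_image.tif", "_labels.tif",
                                               "_truth.csv")))
      write_volume(pod$image, paths[1])
      write_volume(pod$labels, paths[2])
      write.csv(pod$truth, paths[3], row.names = FALSE)
      data.frame(pod_id = id, n_seeds = counts[i], image = paths[1],
                 labels = paths[2], truth = paths[3], seed = seeds[i])
    })
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
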