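test_that("Fibonacci rays are unit, well spread, and warp with anisotropy", {
  # single ray is a unit vector
  r1 <- fibonacci_rays(1)
  expect_equal(sum(r1$directions^2), 1, tolerance = 1e-12)

  r <- fibonacci_rays(96)
  expect_equal(nrow(r$directions), 96L)
  expect_true(all(abs(sqrt(rowSums(r$directions^2)) - 1) < 1e-9))
  # minimum pairwise angle exceeds half the equal-area packing angle
  G <- r$directions %*% t(r$directions)
  diag(G) <- -1
  min_angle <- acos(max(G[upper.tri(G)]))
  expect_gt(min_angle, 0.5 * sqrt(4 * pi / 96))

  # anisotropy warping keeps count and unit norms, and concentrates rays
  # away from the short (largest-factor) X axis
  aniso <- c(1, 1.032258064516129, 1.103448275862069)
  rw <- fibonacci_rays(64, aniso)
  iso <- fibonacci_rays(64)
  expect_equal(nrow(rw$directions), 64L)
  expect_true(all(abs(sqrt(rowSums(rw$directions^2)) - 1) < 1e-9))
  expect_lt(mean(abs(rw$directions[, 3])), mean(abs(iso$directions[, 3])))
  expect_false(any(duplicated(round(rw$directions, 9))))

  expect_error(fibonacci_rays(0), "positive")
  expect_error(fibonacci_rays(8, c(1, 0, 1)), "positive")
})

test_that("boundary distances recover analytic radii", {
  rays <- fibonacci_rays(96)
  ball <- make_ball(10)
  ctr <- rep((dim(ball)[1] - 1) / 2, 3)
  d <- boundary_distances(ball, ctr, rays)
  expect_true(all(abs(d - 10) <= 0.75))

  # axis-aligned ellipsoid, ray along +X
  ell <- make_ellipsoid(c(8, 12, 16))
  ctr <- (dim(ell) - 1) / 2
  rs <- fibonacci_rays(6)
  rs$directions[1, ] <- c(0, 0, 1)
  dx <- boundary_distances(ell, ctr, rs)[1]
  expect_lt(abs(dx - 16), 0.75)

  # 1-voxel instance: every distance below one voxel
  one <- array(0L, c(3, 3, 3))
  one[2, 2, 2] <- 1L
  expect_true(all(boundary_distances(one, c(1, 1, 1), rays) < 1))

  expect_error(boundary_distances(ball, c(0, 0, 0), rays), "not inside")
  expect_error(boundary_distances(ball, ctr, rays, step = 0), "step")
})

test_that("rasterization reproduces analytic bodies", {
  rays <- fibonacci_rays(96)
  # constant distances give a ball of the right volume
  m <- rasterize(star_instance(c(16, 16, 16), rep(10, 96)), rays,
                 c(33, 33, 33))
  expect_lt(abs(sum(m) / (4 / 3 * pi * 1000) - 1), 0.05)

  # all-zero distances: exactly the center voxel
  m0 <- rasterize(star_instance(c(5, 5, 5), rep(0, 96)), rays, c(11, 11, 11))
  expect_equal(sum(m0), 1L)
  expect_true(m0[6, 6, 6])

  # extracted ellipsoid distances reconstruct with IoU >= 0.9
  ell <- make_ellipsoid(c(8, 12, 16))
  ctr <- (dim(ell) - 1) / 2
  d <- boundary_distances(ell, ctr, rays)
  rec <- rasterize(star_instance(ctr, d), rays, dim(ell))
  expect_gte(mask_iou(rec, ell), 0.9)

  expect_error(rasterize(star_instance(c(1, 1, 1), rep(1, 3)),
                         fibonacci_rays(3), c(5, 5, 5)), "4 rays")
})

test_that("mask IoU follows set arithmetic and its conventions", {
  a <- make_ball(6)
  expect_equal(mask_iou(a, a), 1)
  b <- array(0L, dim(a))
  b[1, 1, 1] <- 1L
  expect_equal(mask_iou(a, b), 0)
  expect_equal(mask_iou(b * 0L, b * 0L), 0)  # both empty: 0 by convention

  # 2x2x2 cube against itself shifted by 1 along Z: 4 / 12 by enumeration
  cu <- array(0L, c(5, 4, 4))
  cu[2:3, 2:3, 2:3] <- 1L
  sh <- array(0L, c(5, 4, 4))
  sh[3:4, 2:3, 2:3] <- 1L
  expect_equal(mask_iou(cu, sh), 1 / 3)

  # symmetry and range on random masks
  set.seed(7)
  for (i in 1:5) {
    x <- array(sample(0:1, 60, TRUE), c(3, 4, 5))
    y <- array(sample(0:1, 60, TRUE), c(3, 4, 5))
    expect_identical(mask_iou(x, y), mask_iou(y, x))
    expect_gte(mask_iou(x, y), 0)
    expect_lte(mask_iou(x, y), 1)
    if (any(x > 0)) expect_equal(mask_iou(x, x), 1)
  }
  expect_error(mask_iou(a, array(0L, c(2, 2, 2))), "differ")
})

test_that("reconstruction accuracy improves with ray count", {
  seeds <- generate_seed_masks(8, phantom_config(seed = 21L))
  # merge into one padded volume per seed via the study helper
  tab <- lapply(seeds, reconstruction_accuracy, ray_counts = c(8, 32, 96))
  mean_iou <- Reduce(`+`, lapply(tab, function(t) t$mean_iou)) / length(tab)
  expect_true(all(diff(mean_iou) > -0.01))
  expect_gt(mean_iou[2], 0.8)   # 32 rays
  expect_gt(mean_iou[3], 0.9)   # 96 rays
  expect_error(reconstruction_accuracy(label_volume(array(0L, c(4, 4, 4)))),
               "no instances")
})

test_that("128-ray reconstruction of axis-aligned ellipsoids reaches 0.93", {
  rays <- fibonacci_rays(128)
  for (semi in list(c(10, 12, 15), c(9, 9, 16), c(14, 11, 10))) {
    ell <- make_ellipsoid(semi)
    ctr <- (dim(ell) - 1) / 2
    d <- boundary_distances(ell, ctr, rays)
    rec <- rasterize(star_instance(ctr, d), rays, dim(ell))
    expect_gte(mask_iou(rec, ell), 0.93)
  }
})

test_that("empirical anisotropy matches median extents and symmetry", {
  # a ball is isotropic
  expect_equal(as.numeric(empirical_anisotropy(label_volume(make_ball(8)))),
               c(1, 1, 1))

  # boxes with median extents (32, 31, 29) give the (1, 32/31, 32/29) factors
  shape <- c(40L, 40L, 40L)
  boxes <- list(make_box(c(32, 31, 29), shape),
                make_box(c(30, 31, 27), shape),
                make_box(c(34, 33, 29), shape))
  est <- empirical_anisotropy(lapply(boxes, label_volume))
  expect_equal(as.numeric(est), c(1, 32 / 31, 32 / 29), tolerance = 1e-12)
  expect_equal(unname(est["x"]), 1.103448275862069, tolerance = 1e-15)

  # permuting axes permutes the factors identically
  perm <- lapply(boxes, function(b) label_volume(aperm(b, c(2, 3, 1))))
  est_p <- empirical_anisotropy(perm)
  expect_equal(as.numeric(est_p), as.numeric(est)[c(2, 3, 1)],
               tolerance = 1e-12)

  expect_error(empirical_anisotropy(label_volume(array(0L, c(3, 3, 3)))),
               "no instances")
})
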