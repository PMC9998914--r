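test_that("lowess reproduces lines and resists outliers", {
  # collinear points: local linear fit is exact for any span
  x <- seq(0, 10, length.out = 15)
  y <- 2 * x + 1
  for (f in c(0.3, 2 / 3, 1)) {
    expect_lt(max(abs(lowess_fit(x, y, f = f)$fitted - y)), 1e-9)
  }

  # single point returns its own value
  expect_equal(lowess_fit(3, 7, f = 1)$fitted, 7)
  # two points return the interpolating line's values
  expect_equal(lowess_fit(c(0, 2), c(1, 5))$fitted, c(1, 5))

  # a gross outlier barely moves the robust fit
  set.seed(8)
  x <- sort(runif(20, 0, 2 * pi))
  y <- sin(x)
  y_out <- y
  io <- 10
  y_out[io] <- y[io] + 10
  clean <- lowess_fit(x, y, f = 0.5, iters = 3)$fitted
  dirty <- lowess_fit(x, y_out, f = 0.5, iters = 3)$fitted
  expect_lt(abs(dirty[io] - clean[io]), 0.2)

  expect_error(lowess_fit(1:3, 1:2), "lengths differ")
  expect_error(lowess_fit(1:3, 1:3, f = 0), "\\(0, 1\\]")
  expect_error(lowess_fit(c(2, 1), c(1, 2)), "sorted")
})

test_that("lowess agrees with the direct local-fit oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    x <- sort(runif(n, 0, 10))
    y <- sin(x) + rnorm(n, 0, 0.25)
    if (rep %% 2 == 0) y[sample(n, 1)] <- y[sample(n, 1)] + 6
    for (f in c(0.5, 2 / 3, 1)) {
      got <- lowess_fit(x, y, f = f, iters = 3)$fitted
      expect_lt(max(abs(got - lowess_oracle(x, y, f = f, iters = 3))), 1e-8)
    }
  }
})

test_that("valve assignment splits alternating seeds and sequences them", {
  # 8 seeds alternating +/- 5 voxels around x = 230
  z <- seq(20, 230, length.out = 8)
  x <- 230 + rep(c(5, -5), 4)
  recs <- data.frame(seed_id = 1:8, z_centroid = z, x_centroid = x)
  out <- assign_valves(recs)
  expect_equal(out$valve, rep(c(1L, 2L), 4))
  expect_equal(out$sequence_in_valve[out$valve == 1L], 1:4)
  expect_equal(out$sequence_in_valve[out$valve == 2L], 1:4)
  # spacings: one fewer than the valve's seed count, all positive
  expect_equal(sum(is.na(out$spacing_to_previous)), 2L)
  expect_true(all(out$spacing_to_previous[!is.na(out$spacing_to_previous)] > 0))

  # single seed: tie-break residual 0 -> valve 1, sequence 1, no spacing
  one <- assign_valves(data.frame(seed_id = 1L, z_centroid = 50,
                                  x_centroid = 230))
  expect_equal(one$valve, 1L)
  expect_equal(one$sequence_in_valve, 1L)
  expect_true(is.na(one$spacing_to_previous))
  expect_equal(one$residual, 0)

  expect_error(assign_valves(recs[0, ]), "no seeds")
})

test_that("valve assignment is translation-invariant and flips with X", {
  set.seed(4)
  z <- sort(runif(9, 0, 300))
  x <- 100 + 3 * sin(z / 80) + rep_len(c(8, -8), 9) + rnorm(9)
  recs <- data.frame(seed_id = 1:9, z_centroid = z, x_centroid = x)
  base <- assign_valves(recs)
  shifted <- recs
  shifted$z_centroid <- shifted$z_centroid + 40
  shifted$x_centroid <- shifted$x_centroid + 17
  expect_equal(assign_valves(shifted)$valve, base$valve)
  mirrored <- recs
  mirrored$x_centroid <- -mirrored$x_centroid
  mv <- assign_valves(mirrored)$valve
  expect_true(all(mv != base$valve | base$residual == 0))
  # every seed lands in exactly one valve
  expect_equal(sum(base$valve == 1L) + sum(base$valve == 2L), 9L)
})

test_that("valve accuracy is permutation-invariant and matches fractions", {
  truth <- data.frame(seed_id = 1:10, valve = rep(c(1L, 2L), 5))
  expect_equal(valve_accuracy(truth, truth), 1)
  flipped <- truth
  flipped$valve <- 3L - flipped$valve
  expect_equal(valve_accuracy(flipped, truth), 1)

  # 198 of 209 correct gives 94.74% at two decimals
  big <- data.frame(seed_id = 1:209, valve = rep_len(c(1L, 2L), 209))
  wrong <- big
  wrong$valve[1:11] <- 3L - wrong$valve[1:11]
  expect_equal(round(100 * valve_accuracy(wrong, big), 2), 94.74)

  expect_error(valve_accuracy(truth[1:5, ], truth), "same seed ids")
})
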