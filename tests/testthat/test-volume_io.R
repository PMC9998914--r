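test_that("TIFF stacks round-trip losslessly in both directions", {
  td <- withr::local_tempdir()

  # all-zero image stack keeps shape and values
  v <- image_volume(array(0, c(3, 4, 4)))
  p <- file.path(td, "zeros.tif")
  write_volume(v, p)
  r <- read_volume(p)
  expect_s3_class(r, "image_volume")
  expect_equal(dim(r), c(3L, 4L, 4L))
  expect_true(all(r == 0))

  # integer labels: bit-identical round trip
  lab <- label_volume(array(sample(0:9, 5 * 6 * 7, replace = TRUE),
                            c(5, 6, 7)))
  pl <- file.path(td, "lab.tif")
  write_volume(lab, pl)
  rl <- read_volume(pl, type = "label")
  expect_identical(unclass(rl) + 0L, unclass(lab) + 0L)

  # float intensities: lossless at float32 precision
  img <- image_volume(array(runif(4 * 5 * 6), c(4, 5, 6)))
  pf <- file.path(td, "img.tif")
  write_volume(img, pf)
  rf <- read_volume(pf)
  expect_lt(max(abs(rf - img)), 1e-6)

  # a float stack refuses to load as labels
  expect_error(read_volume(pf, type = "label"), "float")
  expect_error(read_volume(file.path(td, "absent.tif")), "cannot read")
})

test_that("phantom volume shape matches its generator configuration", {
  pod <- generate_pod(phantom_config(shape = c(64L, 128L, 128L),
                                     n_seeds = 1L, seed = 11L))
  expect_equal(dim(pod$image), c(64L, 128L, 128L))
  expect_equal(dim(pod$labels), c(64L, 128L, 128L))
})

test_that("seed table CSV has the fixed schema and round-trips", {
  td <- withr::local_tempdir()
  p <- file.path(td, "seeds.csv")

  # empty records: header only
  empty <- measure_instances(label_volume(array(0L, c(2, 2, 2))))
  write_seed_table(empty, p)
  lines <- readLines(p)
  expect_length(lines, 1L)
  expect_match(lines, "^\"Seed ID Number\",\"Z-axis minimum\"")

  # a Table-style row reproduces its cells verbatim, bbox half-open:
  # (387-354) x (293-258) x (257-221) voxels = 41580
  rec <- empty[0, ]
  rec[1, c("seed_id", "z_min", "y_min", "x_min", "z_max", "y_max", "x_max")] <-
    c(1, 354, 258, 221, 387, 293, 257)
  rec$volume <- 23237
  rec$bbox_volume <- (387 - 354) * (293 - 258) * (257 - 221)
  expect_equal(rec$bbox_volume, 41580)
  write_seed_table(rec, p)
  back <- read_seed_table(p)
  expect_equal(back$volume, 23237)
  expect_equal(back$bbox_volume, 41580)

  # numeric columns survive a round trip to 6 significant digits
  pod <- generate_pod(phantom_config(shape = c(64L, 96L, 96L), n_seeds = 2L,
                                     radius_range = c(8, 10), seed = 5L))
  recs <- assign_valves(measure_instances(pod$labels))
  write_seed_table(recs, p)
  back <- read_seed_table(p)
  for (col in c("z_centroid", "sphericity", "surface_area", "solidity")) {
    expect_equal(back[[col]], signif(recs[[col]], 7), tolerance = 1e-6)
  }
  expect_equal(back$valve, recs$valve)
})

test_that("pipeline configuration validates and reads key=value files", {
  expect_error(pipeline_config(score_threshold = 1.2), "\\[0, 1\\]")
  expect_error(pipeline_config(n_rays = 3), ">= 4")
  expect_error(pipeline_config(anisotropy = c(1.1, 1.2, 1.3)), "min exactly 1")
  td <- withr::local_tempdir()
  p <- file.path(td, "run.cfg")
  writeLines(c("# run settings", "score_threshold = 0.25",
               "anisotropy = 1,1.032258064516129,1.103448275862069",
               "n_rays = 64"), p)
  cfg <- read_pipeline_config(p)
  expect_equal(cfg$score_threshold, 0.25)
  expect_equal(cfg$n_rays, 64L)
  # explicit arguments override the file
  cfg2 <- read_pipeline_config(p, score_threshold = 0.5)
  expect_equal(cfg2$score_threshold, 0.5)
  writeLines("not_a_key = 1", p)
  expect_error(read_pipeline_config(p), "unknown config key")
})
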