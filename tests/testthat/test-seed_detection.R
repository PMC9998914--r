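test_that("candidate proposal finds bright bodies and ignores empty volumes", {
  cfg <- detection_config(rays = fibonacci_rays(48))

  zeros <- image_volume(array(0, c(16, 16, 16)))
  expect_equal(length(propose_candidates(zeros, cfg)), 0L)

  # one bright ball: a candidate at the centroid with score 1
  arr <- array(0.1, c(31, 31, 31))
  arr[make_ball(9, pad = 6) > 0] <- 0.9
  cands <- propose_candidates(image_volume(arr), cfg)
  expect_gte(length(cands), 1L)
  top <- cands$centers[1, ]
  expect_lte(sqrt(sum((top - 15)^2)), 2)
  expect_equal(cands$scores[1], 1)

  # two disjoint balls: candidates in both components
  arr2 <- array(0.1, c(26, 26, 52))
  b <- make_ball(7, pad = 5)
  arr2[, , 1:25][b[1:25, 1:25, ] > 0] <- 0.9
  arr2[, , 27:51][b[1:25, 1:25, ] > 0] <- 0.9
  c2 <- propose_candidates(image_volume(arr2), cfg)
  expect_gte(length(c2), 2L)
  expect_true(any(c2$centers[, 3] < 26) && any(c2$centers[, 3] >= 26))
})

test_that("non-maximum suppression keeps the right candidates", {
  rays <- fibonacci_rays(48)
  shape <- c(40, 40, 80)
  dup <- candidate_set(rbind(c(20, 20, 20), c(20, 20, 20)),
                       rbind(rep(8, 48), rep(8, 48)), c(0.9, 0.8),
                       shape, rays)
  kept <- non_max_suppression(dup, 0.4)
  expect_equal(length(kept), 1L)
  expect_equal(kept$scores, 0.9)

  far <- candidate_set(rbind(c(20, 20, 15), c(20, 20, 60)),
                       rbind(rep(8, 48), rep(8, 48)), c(0.9, 0.8),
                       shape, rays)
  expect_equal(length(non_max_suppression(far, 0)), 2L)

  # chain A-B 0.6, B-C 0.6, A-C 0 with scores A > B > C at threshold 0.4:
  # A suppresses B; C survives because it never overlaps A
  iou <- matrix(0, 3, 3)
  iou[1, 2] <- iou[2, 1] <- 0.6
  iou[2, 3] <- iou[3, 2] <- 0.6
  expect_equal(starpod:::nms_keep_order(iou, 1:3, 0.4), c(1L, 3L))
})

test_that("NMS keep-sets match brute-force enumeration over subsets", {
  set.seed(5)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    iou <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      v <- runif(1) * rbinom(1, 1, 0.5)
      iou[i, j] <- iou[j, i] <- v
    }
    ord <- sample(k)
    thr <- runif(1)
    got <- sort(starpod:::nms_keep_order(iou, ord, thr))
    expect_equal(got, enumerate_nms_keep(iou, ord, thr))
  }
})

test_that("kept candidates never overlap beyond the NMS threshold", {
  pod <- generate_pod(phantom_config(shape = c(160L, 96L, 96L), n_seeds = 4L,
                                     seed = 23L))
  cfg <- detection_config(rays = fibonacci_rays(48))
  cands <- propose_candidates(pod$image, cfg)
  cands <- starpod:::subset_candidates(cands, which(cands$scores >= 0.3))
  kept <- non_max_suppression(cands, 0.4)
  masks <- starpod:::candidate_masks(kept)
  if (length(masks) > 1L) {
    for (i in seq_len(length(masks) - 1L)) for (j in (i + 1L):length(masks)) {
      expect_lte(starpod:::vs_iou(masks[[i]], masks[[j]]), 0.4)
    }
  }
  expect_lte(length(kept), length(cands))
})

test_that("detection recovers well-separated seeds exactly", {
  cfg <- detection_config()
  pod <- generate_pod(phantom_config(shape = c(448L, 128L, 128L),
                                     n_seeds = 12L, seed = 2L))
  pred <- detect(pod$image, cfg)
  expect_equal(n_instances(pred), 12L)
  m <- match_instances(pod$labels, pred, 0.5)
  expect_equal(unname(detection_metrics(m)[["f1"]]), 1)

  # labels are 1..k and every instance is at least min_volume voxels
  ids <- instance_ids(pred)
  expect_equal(ids, seq_along(ids))
  expect_true(all(tabulate(pred[pred > 0L]) >= cfg$min_volume))

  # degenerate inputs
  expect_equal(n_instances(detect(image_volume(array(0, c(12, 12, 12))),
                                  cfg)), 0L)
  sat <- detection_config(score_threshold = 1)
  pred_sat <- detect(pod$image, sat)
  cands <- propose_candidates(pod$image, sat)
  expect_lte(n_instances(pred_sat), sum(cands$scores == 1))
})

test_that("threshold optimization removes injected duplicates", {
  pod <- generate_pod(phantom_config(shape = c(160L, 96L, 96L), n_seeds = 4L,
                                     seed = 29L))
  cfg <- detection_config(rays = fibonacci_rays(48))
  cands <- propose_candidates(pod$image, cfg)
  cands <- starpod:::subset_candidates(cands, which(cands$scores >= 0.3))
  # inject near-duplicates of every candidate with slightly lower scores
  dup <- candidate_set(rbind(cands$centers, cands$centers + c(1, 0, 0)),
                       rbind(cands$dists, cands$dists),
                       c(cands$scores, pmax(cands$scores - 0.05, 0)),
                       cands$shape, cands$rays)
  best <- optimize_thresholds(list(dup), list(pod$labels),
                              score_grid = c(0.2, 0.5),
                              nms_grid = c(0.4, 1), min_volume = 300L)
  expect_lt(best[["nms_threshold"]], 1)
  expect_equal(best[["objective"]], 1)
  # deterministic: same inputs, same answer
  best2 <- optimize_thresholds(list(dup), list(pod$labels),
                               score_grid = c(0.2, 0.5),
                               nms_grid = c(0.4, 1), min_volume = 300L)
  expect_identical(best, best2)
})

test_that("external labels import relabels by first appearance", {
  td <- withr::local_tempdir()
  arr <- array(0L, c(6, 5, 5))
  arr[2, 2, 2] <- 3L
  arr[5, 3, 3] <- 7L
  p <- file.path(td, "ext.tif")
  write_volume(label_volume(arr), p)
  imp <- import_external_labels(p)
  expect_equal(instance_ids(imp), c(1L, 2L))
  expect_equal(imp[2, 2, 2], 1L)
  expect_equal(imp[5, 3, 3], 2L)

  # ground-truth labels are unchanged when already 1..k
  pod <- generate_pod(phantom_config(shape = c(96L, 96L, 96L), n_seeds = 2L,
                                     seed = 3L))
  pg <- file.path(td, "gt.tif")
  write_volume(pod$labels, pg)
  expect_identical(unclass(import_external_labels(pg)) + 0L,
                   unclass(pod$labels) + 0L)

  # empty volume stays empty
  pe <- file.path(td, "empty.tif")
  write_volume(label_volume(array(0L, c(4, 4, 4))), pe)
  expect_equal(n_instances(import_external_labels(pe)), 0L)
})
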