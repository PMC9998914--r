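test_that("matching handles identity, empties and the counting identities", {
  pod <- generate_pod(phantom_config(shape = c(160L, 96L, 96L), n_seeds = 5L,
                                     radius_range = c(8, 12), seed = 13L))
  m <- match_instances(pod$labels, pod$labels, 0.5)
  expect_equal(nrow(m$matches), 5L)
  expect_true(all(m$matches$iou == 1))
  expect_equal(detection_metrics(m),
               c(precision = 1, recall = 1, f1 = 1))

  empty <- label_volume(array(0L, dim(pod$labels)))
  m0 <- match_instances(pod$labels, empty, 0.5)
  expect_equal(nrow(m0$matches), 0L)
  expect_equal(m0$n_true, 5L)
  expect_equal(detection_metrics(m0), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(segmentation_scores(m0),
               c(mean_matched_score = 0, mean_true_score = 0,
                 panoptic_quality = 0))

  expect_error(match_instances(pod$labels,
                               label_volume(array(0L, c(2, 2, 2))), 0.5),
               "differ")
})

test_that("optimal assignment picks the larger-total pairing", {
  # IoU grid (g1,p1)=0.6, (g1,p2)=0.5, (g2,p2)=0.55: the assignment
  # (g1,p1)+(g2,p2) totals 1.15 and must beat (g1,p2) alone
  iou <- rbind(c(0.6, 0.5), c(0, 0.55))
  got <- starpod:::match_from_iou(iou, c(1L, 2L), c(1L, 2L), 0.5)
  expect_equal(got$gt, c(1L, 2L))
  expect_equal(got$pred, c(1L, 2L))
  oracle <- enumerate_best_assignment(iou, 0.5)
  expect_equal(sum(got$iou), oracle$total)
})

test_that("matching agrees with exhaustive assignment enumeration", {
  set.seed(31)
  for (rep in 1:30) {
    G <- sample(1:5, 1)
    P <- sample(1:5, 1)
    iou <- matrix(runif(G * P) * rbinom(G * P, 1, 0.6), G, P)
    tau <- sample(c(0.1, 0.3, 0.5), 1)
    got <- starpod:::match_from_iou(iou, seq_len(G), seq_len(P), tau)
    oracle <- enumerate_best_assignment(iou, tau)
    expect_equal(sum(got$iou), oracle$total, tolerance = 1e-9)
    expect_true(!anyDuplicated(got$gt) && !anyDuplicated(got$pred))
    expect_true(all(got$iou >= tau))
  }
})

test_that("detection metrics reproduce the printed worked examples", {
  mk <- function(tp, fp, fn, mean_iou) {
    match_result(tp + fn, tp + fp,
                 data.frame(gt = seq_len(tp), pred = seq_len(tp),
                            iou = rep(mean_iou, tp)), 0.1)
  }
  # validation counts at tau <= 0.8: 39 TP, 0 FP, 3 FN
  m <- mk(39, 0, 3, 0.900)
  dm <- detection_metrics(m)
  expect_equal(round(unname(dm), 3), c(1.000, 0.929, 0.963))
  ss <- segmentation_scores(m)
  expect_equal(round(unname(ss), 3), c(0.900, 0.836, 0.867))

  # tau = 0.9 column: 25 TP, 14 FP, 17 FN, mean matched 0.912
  m9 <- mk(25, 14, 17, 0.912)
  expect_equal(round(unname(detection_metrics(m9)), 3),
               c(0.641, 0.595, 0.617))
  expect_equal(round(unname(segmentation_scores(m9)), 3),
               c(0.912, 0.543, 0.563))

  # test-set totals: 207 TP, 1 FP, 2 FN as percentages to 2 decimals
  mt <- mk(207, 1, 2, 0.9)
  expect_equal(round(100 * unname(detection_metrics(mt)), 2),
               c(99.52, 99.04, 99.28))

  # perfect prediction scores (1, 1, 1)
  expect_equal(unname(segmentation_scores(mk(5, 0, 0, 1))), c(1, 1, 1))
})

test_that("threshold sweep is monotone and self-consistent", {
  pod <- generate_pod(phantom_config(shape = c(160L, 96L, 96L), n_seeds = 4L,
                                     radius_range = c(8, 12), seed = 17L))
  pred <- detect(pod$image, detection_config())
  rep <- evaluate_over_taus(pod$labels, pred, seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(rep$tp) <= 0))
  expect_true(all(rep$tp + rep$fn == rep$n_true))
  expect_true(all(rep$tp + rep$fp == rep$n_pred))
  # PQ and mean-true identities hold exactly
  expect_equal(rep$panoptic_quality,
               rep$mean_matched_score * rep$tp /
                 pmax(rep$tp + rep$fp / 2 + rep$fn / 2, 1e-12))
  expect_equal(rep$mean_true_score,
               rep$mean_matched_score * rep$tp / rep$n_true)

  # identical volumes: F1 = 1 everywhere; empty prediction: all zero
  self <- evaluate_over_taus(pod$labels, pod$labels, seq(0.1, 0.9, by = 0.1))
  expect_true(all(self$f1 == 1))
  none <- evaluate_over_taus(pod$labels,
                             label_volume(array(0L, dim(pod$labels))),
                             seq(0.1, 0.9, by = 0.1))
  expect_true(all(none$precision == 0 & none$recall == 0 & none$f1 == 0))
})
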