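# Training-free star-convex instance detection.
#
# The pipeline mirrors a star-convex segmentation network's candidate ->
# score-filter -> non-maximum-suppression -> label stages, but derives its
# candidates deterministically from classical image operations: binarize,
# Euclidean distance transform, distance-transform local maxima as candidate
# centers, exact per-ray boundary distances on the binary mask. Downstream
# evaluation/measurement/valve stages are detector-agnostic: label volumes
# produced by any external model enter through import_external_labels().

#' Detection configuration
#'
#' @param threshold `"otsu"` (volume-wide Otsu on a 256-bin histogram) or a
#'   fixed intensity threshold in `[0, 1]`.
#' @param score_threshold minimum candidate confidence kept before NMS.
#' @param nms_threshold maximum pairwise polyhedron IoU tolerated between
#'   kept candidates. Note the direction: a *higher* value prunes *less* (a
#'   candidate is suppressed when its overlap with a kept one exceeds the
#'   threshold).
#' @param rays [fibonacci_rays()] set used for candidate polyhedra.
#' @param min_volume smallest rasterized instance (voxels) kept.
#' @param step march step for [boundary_distances()].
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold = "otsu", score_threshold = 0.3,
                             nms_threshold = 0.4, rays = fibonacci_rays(96),
                             min_volume = 500L, step = 0.5) {
  check_scalar01(score_threshold, "score_threshold")
  check_scalar01(nms_threshold, "nms_threshold")
  if (is.numeric(threshold)) check_scalar01(threshold, "threshold")
  else if (!identical(threshold, "otsu"))
    stopf("threshold must be 'otsu' or a fixed value in [0, 1]")
  rays <- as_ray_set(rays)
  if (min_volume < 1) stopf("min_volume must be >= 1")
  structure(list(threshold = threshold, score_threshold = score_threshold,
                 nms_threshold = nms_threshold, rays = rays,
                 min_volume = as.integer(min_volume), step = step),
            class = "detection_config")
}

#' Candidate set
#'
#' Star-convex candidates proposed for one volume: centers (0-based, one row
#' per candidate), per-ray boundary distances, confidence scores in `[0, 1]`
#' and the source volume shape.
#'
#' @param centers k x 3 integer matrix of `(z, y, x)` centers.
#' @param dists k x n matrix of per-ray distances.
#' @param scores length-k confidences in `[0, 1]`.
#' @param shape source volume shape `(Z, Y, X)`.
#' @param rays the [fibonacci_rays()] set the distances refer to.
#' @return A `candidate_set`.
#' @export
candidate_set <- function(centers, dists, scores, shape, rays) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  if (length(scores) != nrow(centers))
    stopf("one score per candidate required")
  if (length(scores) && (min(scores) < 0 || max(scores) > 1))
    stopf("scores must be in [0, 1]")
  if (length(scores) && (any(centers < 0) ||
                         any(sweep(centers, 2L, shape, ">="))))
    stopf("candidate centers must lie inside the volume")
  structure(list(centers = centers,
                 dists = matrix(as.numeric(dists), nrow = nrow(centers)),
                 scores = as.numeric(scores),
                 shape = as.integer(shape), rays = rays),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidate(s), %d rays, volume %s\n",
              nrow(x$centers), x$rays$n, paste(x$shape, collapse = "x")))
  invisible(x)
}

#' @export
length.candidate_set <- function(x) nrow(x$centers)

subset_candidates <- function(cands, idx) {
  candidate_set(cands$centers[idx, , drop = FALSE],
                cands$dists[idx, , drop = FALSE],
                cands$scores[idx], cands$shape, cands$rays)
}

# descending score, ties by lexicographic center order
candidate_order <- function(cands) {
  order(-cands$scores, cands$centers[, 1], cands$centers[, 2],
        cands$centers[, 3])
}

#' Propose star-convex candidates from an intensity volume
#'
#' Binarizes the volume with the configured threshold, computes the interior
#' Euclidean distance transform, and turns every local maximum of the
#' distance transform (26-connectivity, plateaus merged to their central
#' voxel) into a candidate: the center's per-ray boundary distances are
#' extracted from the binary mask, and the confidence score is the center's
#' distance-transform value normalised by the volume-wide maximum (deep
#' interior points of large bodies score high; shallow ridges of thin
#' structures score low).
#'
#' @param image an [image_volume()].
#' @param cfg a [detection_config()].
#' @return A [candidate_set()] (empty when thresholding leaves no foreground).
#' @export
propose_candidates <- function(image, cfg = detection_config()) {
  arr <- vol_data(image)
  thr <- if (is.numeric(cfg$threshold)) cfg$threshold else otsu_threshold(arr)
  fg <- arr > thr
  rays <- cfg$rays
  empty <- candidate_set(matrix(numeric(0), 0, 3), matrix(numeric(0), 0, rays$n),
                         numeric(0), dim(arr), rays)
  if (!any(fg)) return(empty)
  dt <- sqrt(edt_squared_cpp(as.logical(fg), dim(arr)))
  mx <- local_maxima_cpp(dt, dim(arr))
  if (nrow(mx$centers) == 0L) return(empty)
  scores <- mx$values / max(mx$values)
  fg <- array(fg, dim(arr))
  dists <- boundary_distances_batch(fg, mx$centers, rays, step = cfg$step)
  cands <- candidate_set(mx$centers, dists, scores, dim(arr), rays)
  subset_candidates(cands, candidate_order(cands))
}

# rasterized voxel sets for every candidate (bounding-box representation)
candidate_masks <- function(cands) {
  lapply(seq_len(nrow(cands$centers)), function(i) {
    rasterize_vs(star_instance(cands$centers[i, ], cands$dists[i, ],
                               cands$scores[i]),
                 cands$rays, cands$shape)
  })
}

# greedy keep-set over a pairwise IoU matrix, in descending-score order
# (vis is the visiting order; returns indices kept, in that order)
nms_keep_order <- function(iou, vis, nms_threshold) {
  kept <- integer(0)
  for (i in vis) {
    if (all(iou[i, kept] <= nms_threshold)) kept <- c(kept, i)
  }
  kept
}

#' Non-maximum suppression of overlapping candidates
#'
#' Visits candidates in descending confidence (ties broken by lexicographic
#' center order) and keeps a candidate only if its rasterized-polyhedron IoU
#' with every already-kept candidate is at most `nms_threshold`. Scores are
#' passed through unchanged.
#'
#' @param cands a [candidate_set()].
#' @param nms_threshold overlap tolerance in `[0, 1]`.
#' @return The surviving [candidate_set()], in descending-score order.
#' @export
non_max_suppression <- function(cands, nms_threshold) {
  check_scalar01(nms_threshold, "nms_threshold")
  k <- nrow(cands$centers)
  if (k <= 1L) return(cands)
  vis <- candidate_order(cands)
  masks <- candidate_masks(cands)
  kept <- integer(0)
  for (i in vis) {
    ok <- TRUE
    for (j in kept) {
      if (vs_iou(masks[[i]], masks[[j]]) > nms_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  subset_candidates(cands, kept)
}

# paint surviving candidates (descending score) into a label volume;
# overlapping voxels go to the higher-scoring (lower-label) instance,
# then sub-min_volume instances are dropped and labels renumbered 1..k
labels_from_masks <- function(masks, shape, min_volume) {
  lab <- array(0L, shape)
  for (i in rev(seq_along(masks))) lab <- vs_paint(lab, masks[[i]], i)
  if (length(masks)) {
    sizes <- tabulate(lab[lab > 0L], length(masks))
    keep <- which(sizes >= min_volume)
    relab <- integer(length(masks))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  label_volume(lab)
}

#' Detect star-convex instances in an intensity volume
#'
#' Full detection: [propose_candidates()], drop candidates below
#' `score_threshold`, [non_max_suppression()], rasterize the survivors into a
#' label volume with labels `1..k` in descending-score order (overlapping
#' voxels go to the higher-scoring instance), and drop instances smaller than
#' `min_volume` voxels.
#'
#' @param image an [image_volume()].
#' @param cfg a [detection_config()].
#' @return A [label_volume()] (possibly empty).
#' @export
detect <- function(image, cfg = detection_config()) {
  cands <- propose_candidates(image, cfg)
  keep <- cands$scores >= cfg$score_threshold
  cands <- subset_candidates(cands, which(keep))
  cands <- non_max_suppression(cands, cfg$nms_threshold)
  masks <- candidate_masks(cands)
  labels_from_masks(masks, cands$shape, cfg$min_volume)
}

#' Optimize score and NMS thresholds on validation volumes
#'
#' Exhaustive grid search: for every `(score_threshold, nms_threshold)` pair
#' the candidates of each validation volume are filtered, suppressed,
#' rasterized to labels and scored by the mean F1 over the IoU-threshold
#' grid `taus`; the objective is averaged over volumes. Ties break toward
#' the smaller `nms_threshold`, then the smaller `score_threshold`.
#' Candidate polyhedra and their pairwise IoUs are computed once per volume,
#' so the grid search itself is cheap and fully deterministic.
#'
#' @param cands_list list of [candidate_set()]s (one per validation volume,
#'   from [propose_candidates()]).
#' @param gt_list list of matching ground-truth [label_volume()]s.
#' @param score_grid,nms_grid threshold grids to search.
#' @param taus evaluation IoU thresholds averaged in the objective.
#' @param min_volume smallest instance kept, as in [detect()].
#' @return Named numeric: `score_threshold`, `nms_threshold`, `objective`.
#' @export
optimize_thresholds <- function(cands_list, gt_list,
                                score_grid = seq(0.1, 0.9, by = 0.1),
                                nms_grid = seq(0.1, 0.9, by = 0.1),
                                taus = seq(0.1, 0.8, by = 0.1),
                                min_volume = 500L) {
  if (!length(cands_list) || length(cands_list) != length(gt_list))
    stopf("need one candidate set per ground-truth volume")
  if (!length(score_grid) || !length(nms_grid)) stopf("empty threshold grid")
  prep <- lapply(seq_along(cands_list), function(v) {
    cands <- cands_list[[v]]
    masks <- candidate_masks(cands)
    k <- length(masks)
    iou <- matrix(0, k, k)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        iou[i, j] <- iou[j, i] <- vs_iou(masks[[i]], masks[[j]])
      }
    }
    list(cands = cands, masks = masks, iou = iou)
  })
  best <- c(score_threshold = NA_real_, nms_threshold = NA_real_,
            objective = -Inf)
  for (nms in sort(nms_grid)) {
    for (sc in sort(score_grid)) {
      obj <- mean(vapply(seq_along(prep), function(v) {
        p <- prep[[v]]
        idx <- which(p$cands$scores >= sc)
        vis <- idx[order(-p$cands$scores[idx], p$cands$centers[idx, 1],
                         p$cands$centers[idx, 2], p$cands$centers[idx, 3])]
        kept <- nms_keep_order(p$iou, vis, nms)
        lab <- labels_from_masks(p$masks[kept], p$cands$shape, min_volume)
        mean(evaluate_over_taus(gt_list[[v]], lab, taus)$f1)
      }, numeric(1)))
      if (obj > best[["objective"]] + 1e-12) {
        best <- c(score_threshold = sc, nms_threshold = nms, objective = obj)
      }
    }
  }
  best
}

#' Import an externally produced label volume
#'
#' Adapter so the output of any external instance-segmentation model (e.g. a
#' trained star-convex network) can enter the evaluation, measurement and
#' valve-sorting stages: reads an integer TIFF stack and renumbers the labels
#' to `1..k` in order of first appearance (array scan order, Z fastest).
#'
#' @param path integer TIFF stack path.
#' @return A [label_volume()].
#' @export
import_external_labels <- function(path) {
  vol <- read_volume(path, type = "label")
  arr <- vol_data(vol)
  pos <- arr > 0L
  ids <- unique(arr[pos])
  arr[pos] <- match(arr[pos], ids)
  label_volume(arr)
}
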