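# Instance-level evaluation: one-to-one IoU matching of predicted vs
# ground-truth instances and the derived detection/segmentation metrics.

# joint label statistics: sizes of every gt/pred instance and the dense IoU
# matrix computed from the joint histogram of co-occurring labels
label_overlap_stats <- function(gt, pred) {
  g <- vol_data(gt)
  p <- vol_data(pred)
  if (!identical(dim(g), dim(p))) stopf("volume shapes differ")
  gids <- sort(unique(g[g > 0L]))
  pids <- sort(unique(p[p > 0L]))
  gsz <- if (length(gids)) tabulate(match(g, gids), length(gids)) else integer()
  psz <- if (length(pids)) tabulate(match(p, pids), length(pids)) else integer()
  iou <- matrix(0, length(gids), length(pids),
                dimnames = list(gids, pids))
  both <- which(g > 0L & p > 0L)
  if (length(both) && length(gids) && length(pids)) {
    gi <- match(g[both], gids)
    pi <- match(p[both], pids)
    key <- (gi - 1L) * length(pids) + pi
    inter <- tabulate(key, length(gids) * length(pids))
    inter <- matrix(inter, length(gids), length(pids), byrow = TRUE)
    iou <- inter / (outer(gsz, psz, "+") - inter)
  }
  list(gt_ids = gids, pred_ids = pids, gt_sizes = gsz, pred_sizes = psz,
       iou = iou)
}

# optimal one-to-one assignment on an IoU matrix, restricted to pairs with
# IoU >= tau (and strictly positive overlap); maximises total matched IoU
match_from_iou <- function(iou, gt_ids, pred_ids, tau) {
  elig <- iou >= tau & iou > 0
  if (!any(elig)) {
    return(data.frame(gt = integer(), pred = integer(), iou = numeric()))
  }
  benefit <- iou * elig
  if (nrow(benefit) <= ncol(benefit)) {
    sol <- clue::solve_LSAP(benefit, maximum = TRUE)
    pairs <- cbind(seq_len(nrow(benefit)), as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(benefit), maximum = TRUE)
    pairs <- cbind(as.integer(sol), seq_len(ncol(benefit)))
  }
  keep <- elig[pairs]
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(gt = gt_ids[pairs[, 1]], pred = pred_ids[pairs[, 2]],
                    iou = iou[pairs])
  out[order(out$gt, out$pred), , drop = FALSE]
}

#' Construct a match result
#'
#' Container for the outcome of one-to-one instance matching at an IoU
#' threshold `tau`: `TP = nrow(matches)`, `FN = n_true - TP`,
#' `FP = n_pred - TP`.
#'
#' @param n_true number of ground-truth instances.
#' @param n_pred number of predicted instances.
#' @param matches data frame with columns `gt`, `pred`, `iou` (each label in
#'   at most one pair, all `iou >= tau`).
#' @param tau IoU threshold in `[0, 1]`.
#' @return A `match_result`.
#' @export
match_result <- function(n_true, n_pred, matches, tau) {
  check_scalar01(tau, "tau")
  if (!all(c("gt", "pred", "iou") %in% names(matches)))
    stopf("matches needs columns gt, pred, iou")
  if (anyDuplicated(matches$gt) || anyDuplicated(matches$pred))
    stopf("each label may appear in at most one match")
  if (nrow(matches) > min(n_true, n_pred))
    stopf("more matches than instances")
  if (nrow(matches) && any(matches$iou < tau - 1e-12))
    stopf("matched IoU below tau")
  structure(list(n_true = as.integer(n_true), n_pred = as.integer(n_pred),
                 matches = matches, tau = tau),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  tp <- nrow(x$matches)
  cat(sprintf(
    "<match_result> tau = %.2f: TP %d, FP %d, FN %d (of %d true / %d pred)\n",
    x$tau, tp, x$n_pred - tp, x$n_true - tp, x$n_true, x$n_pred))
  invisible(x)
}

#' Match predicted to ground-truth instances at an IoU threshold
#'
#' Computes the IoU matrix from the joint label histogram of the two volumes
#' and selects the one-to-one assignment maximising total IoU among pairs
#' with `IoU >= tau` (Hungarian assignment; for `tau >= 0.5` at most one
#' prediction can pass the threshold per ground-truth instance, so greedy and
#' optimal matching coincide). Pairs with zero overlap are never matched,
#' whatever `tau`.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param tau IoU threshold in `[0, 1]`.
#' @return A [match_result()].
#' @export
match_instances <- function(gt, pred, tau) {
  check_scalar01(tau, "tau")
  st <- label_overlap_stats(gt, pred)
  matches <- match_from_iou(st$iou, st$gt_ids, st$pred_ids, tau)
  match_result(length(st$gt_ids), length(st$pred_ids), matches, tau)
}

#' Detection metrics from a match result
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `f1 = 2PR/(P+R)`; any 0/0 is defined as 0.
#'
#' @param m a [match_result()].
#' @return Named numeric: `precision`, `recall`, `f1`.
#' @export
detection_metrics <- function(m) {
  stopifnot(inherits(m, "match_result"))
  tp <- nrow(m$matches)
  fp <- m$n_pred - tp
  fn <- m$n_true - tp
  ratio0 <- function(a, b) if (b == 0) 0 else a / b
  precision <- ratio0(tp, tp + fp)
  recall <- ratio0(tp, tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Segmentation quality scores from a match result
#'
#' `mean_matched_score` is the mean IoU over matched (true-positive) pairs;
#' `mean_true_score` normalises the summed matched IoU by the number of
#' ground-truth instances; `panoptic_quality` divides it by
#' `TP + FP/2 + FN/2`. Degenerate 0/0 cases are 0.
#'
#' @param m a [match_result()].
#' @return Named numeric: `mean_matched_score`, `mean_true_score`,
#'   `panoptic_quality`.
#' @export
segmentation_scores <- function(m) {
  stopifnot(inherits(m, "match_result"))
  tp <- nrow(m$matches)
  fp <- m$n_pred - tp
  fn <- m$n_true - tp
  s <- sum(m$matches$iou)
  c(mean_matched_score = if (tp == 0) 0 else s / tp,
    mean_true_score = if (m$n_true == 0) 0 else s / m$n_true,
    panoptic_quality = if (tp + fp / 2 + fn / 2 == 0) 0 else
      s / (tp + fp / 2 + fn / 2))
}

#' Evaluate detection and segmentation across IoU thresholds
#'
#' One metrics row per `tau`, mirroring an accuracy table for automated
#' detection and segmentation: counts (TP/FP/FN), precision, recall, F1, mean
#' matched/true score and panoptic quality. The label overlap statistics are
#' computed once; only the assignment is redone per threshold. TP is
#' non-increasing in `tau`.
#'
#' @param gt,pred [label_volume()]s of identical shape.
#' @param taus IoU thresholds in `[0, 1]`.
#' @return Data frame of class `metrics_report`.
#' @export
evaluate_over_taus <- function(gt, pred, taus = seq(0.1, 0.9, by = 0.1)) {
  vapply(taus, check_scalar01, numeric(1), "tau")
  st <- label_overlap_stats(gt, pred)
  rows <- lapply(taus, function(tau) {
    matches <- match_from_iou(st$iou, st$gt_ids, st$pred_ids, tau)
    m <- match_result(length(st$gt_ids), length(st$pred_ids), matches, tau)
    tp <- nrow(matches)
    dm <- detection_metrics(m)
    ss <- segmentation_scores(m)
    data.frame(tau = tau, n_true = m$n_true, n_pred = m$n_pred,
               tp = tp, fp = m$n_pred - tp, fn = m$n_true - tp,
               precision = dm[["precision"]], recall = dm[["recall"]],
               f1 = dm[["f1"]],
               mean_matched_score = ss[["mean_matched_score"]],
               mean_true_score = ss[["mean_true_score"]],
               panoptic_quality = ss[["panoptic_quality"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
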