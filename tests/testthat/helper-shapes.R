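# fixture builders (all generated in code; 0-based centers)

make_ball <- function(radius, pad = 3L, center = NULL, value = 1L) {
  side <- 2L * (radius + pad) + 1L
  if (is.null(center)) center <- rep((side - 1) / 2, 3)
  arr <- array(0L, rep(side, 3L))
  for (z in seq_len(side)) for (y in seq_len(side)) {
    arr[z, y, ] <- value * as.integer(
      (z - 1 - center[1])^2 + (y - 1 - center[2])^2 +
        ((seq_len(side) - 1) - center[3])^2 <= radius^2)
  }
  arr
}

make_ellipsoid <- function(semi, pad = 3L) {
  side <- 2L * (ceiling(semi) + pad) + 1L
  ctr <- (side - 1) / 2
  arr <- array(0L, side)
  for (z in seq_len(side[1])) for (y in seq_len(side[2])) {
    arr[z, y, ] <- as.integer(
      ((z - 1 - ctr[1]) / semi[1])^2 + ((y - 1 - ctr[2]) / semi[2])^2 +
        (((seq_len(side[3]) - 1) - ctr[3]) / semi[3])^2 <= 1)
  }
  arr
}

make_box <- function(extents, shape, origin = c(2L, 2L, 2L), value = 1L) {
  arr <- array(0L, shape)
  arr[origin[1]:(origin[1] + extents[1] - 1L),
      origin[2]:(origin[2] + extents[2] - 1L),
      origin[3]:(origin[3] + extents[3] - 1L)] <- value
  arr
}

# exhaustive one-to-one assignment oracle: maximum total IoU among pairs with
# IoU >= tau (and > 0), by enumeration over all injective partial matchings
enumerate_best_assignment <- function(iou, tau) {
  G <- nrow(iou)
  P <- ncol(iou)
  best <- list(total = 0, pairs = matrix(integer(), 0, 2))
  recurse <- function(g, used, pairs, total) {
    if (g > G) {
      if (total > best$total + 1e-12) {
        best <<- list(total = total, pairs = pairs)
      }
      return()
    }
    recurse(g + 1L, used, pairs, total)  # g unmatched
    for (p in seq_len(P)) {
      if (!used[p] && iou[g, p] >= tau && iou[g, p] > 0) {
        used2 <- used
        used2[p] <- TRUE
        recurse(g + 1L, used2, rbind(pairs, c(g, p)), total + iou[g, p])
      }
    }
  }
  recurse(1L, rep(FALSE, P), matrix(integer(), 0, 2), 0)
  best
}

# declarative NMS oracle: enumerate all subsets of candidates and return the
# one where, visiting in the given priority order, each candidate is kept
# exactly when its IoU with every higher-priority kept candidate is <= thr
enumerate_nms_keep <- function(iou, order, thr) {
  k <- length(order)
  for (bits in 0:(2^k - 1)) {
    members <- order[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
    ok <- TRUE
    for (pos in seq_len(k)) {
      i <- order[pos]
      higher <- intersect(order[seq_len(pos - 1L)], members)
      should_keep <- all(iou[i, higher] <= thr)
      if (should_keep != (i %in% members)) { ok <- FALSE; break }
    }
    if (ok) return(sort(members))
  }
  stop("no consistent keep set found")
}
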