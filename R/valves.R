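# Sorting seeds into pod valves.
#
# Seeds of a pod sit in two longitudinal chambers (valves) on either side of
# the pseudoseptum. In the long-axis cross-section (the Z-X plane: Z runs
# beak-to-pedicel along the slice axis, X across the valves) the pseudoseptum
# is approximated by a lowess curve through the seed centroids; the sign of a
# seed's X-residual from the curve decides its valve.

#' Locally weighted scatterplot smoothing (lowess)
#'
#' Cleveland's lowess: for each `x_i`, a weighted local linear fit over the
#' nearest `ceiling(f * n)` neighbours with tricube distance weights, followed
#' by robustifying passes that downweight large residuals with bisquare
#' weights. One point returns `y`; two points return the interpolating line.
#'
#' @param x sorted (non-decreasing) abscissae.
#' @param y ordinates, same length as `x`.
#' @param f smoother span: fraction of points influencing each local fit,
#'   in `(0, 1]`.
#' @param iters number of robustifying iterations (default 3).
#' @return A `lowess_fit`: list with `x`, `y`, `f`, `iters` and `fitted`
#'   values at each `x`.
#' @export
lowess_fit <- function(x, y, f = 2 / 3, iters = 3L) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 1L) stopf("at least one point is required")
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stopf("f must be in (0, 1]")
  if (is.unsorted(x)) stopf("x must be sorted non-decreasing")
  fitted <- if (length(x) == 1L) {
    y
  } else {
    stats::lowess(x, y, f = f, iter = iters, delta = 0)$y
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), f = f,
                 iters = as.integer(iters), fitted = as.numeric(fitted)),
            class = "lowess_fit")
}

#' @export
print.lowess_fit <- function(x, ...) {
  cat(sprintf("<lowess_fit> n = %d, f = %.4g, %d robustness iteration(s)\n",
              length(x$x), x$f, x$iters))
  invisible(x)
}

#' Assign seeds of one pod to valves
#'
#' Fits a lowess curve to the seed centroids in the `(Z, X)` plane (`x` = Z
#' centroid along the pod axis, `y` = X centroid across the valves) as a
#' reconstruction of the pod pseudoseptum. Seeds above the curve (positive
#' X-residual) are valve 1, seeds below valve 2; a residual of exactly zero
#' goes to valve 1 (deterministic tie-break). The smoother span is 1 for pods
#' with 5 seeds or fewer and 2/3 (the lowess default) otherwise, unless
#' overridden. Within each valve, seeds are sequenced by ascending Z
#' (beak to pedicel) and the spacing to the previous same-valve seed is the
#' Euclidean distance between consecutive centroids in the `(Z, X)` plane.
#'
#' @param records per-seed table with columns `seed_id`, `z_centroid`,
#'   `x_centroid` (e.g. from [measure_instances()] or a phantom truth table).
#' @param f optional smoother span override in `(0, 1]`.
#' @param iters robustifying iterations for the lowess fit.
#' @return `records` with columns `valve`, `sequence_in_valve`,
#'   `spacing_to_previous` and `residual` filled in (input row order kept).
#' @export
assign_valves <- function(records, f = NULL, iters = 3L) {
  need <- c("seed_id", "z_centroid", "x_centroid")
  if (!all(need %in% names(records)))
    stopf("records needs columns %s", paste(need, collapse = ", "))
  n <- nrow(records)
  if (n < 1L) stopf("no seeds to assign")
  span <- f %||% (if (n <= 5L) 1 else 2 / 3)
  ord <- order(records$z_centroid, records$x_centroid, records$seed_id)
  z <- records$z_centroid[ord]
  xx <- records$x_centroid[ord]
  fit <- lowess_fit(z, xx, f = span, iters = iters)
  res <- xx - fit$fitted
  valve <- ifelse(res >= 0, 1L, 2L)
  seqv <- integer(n)
  spac <- rep(NA_real_, n)
  for (v in c(1L, 2L)) {
    iv <- which(valve == v)  # already in ascending-z order
    seqv[iv] <- seq_along(iv)
    if (length(iv) > 1L) {
      spac[iv[-1L]] <- sqrt(diff(z[iv])^2 + diff(xx[iv])^2)
    }
  }
  out <- records
  out$valve <- out$sequence_in_valve <- NA_integer_
  out$spacing_to_previous <- out$residual <- NA_real_
  out$valve[ord] <- valve
  out$sequence_in_valve[ord] <- seqv
  out$spacing_to_previous[ord] <- spac
  out$residual[ord] <- res
  out
}

#' Valve assignment accuracy against ground truth
#'
#' Fraction of seeds assigned to the correct valve, maximised over the two
#' valve-label permutations: which physical side is "valve 1" depends only on
#' scan orientation, so the numbering is arbitrary up to a swap.
#'
#' @param assignment data frame with `seed_id` and `valve` (from
#'   [assign_valves()]).
#' @param truth data frame with `seed_id` and `valve` (ground truth).
#' @return Fraction correct in `[0, 1]`.
#' @export
valve_accuracy <- function(assignment, truth) {
  if (!setequal(assignment$seed_id, truth$seed_id) ||
      nrow(assignment) != nrow(truth))
    stopf("assignment and truth must cover the same seed ids")
  a <- assignment$valve[order(assignment$seed_id)]
  t <- truth$valve[order(truth$seed_id)]
  max(mean(a == t), mean((3L - a) == t))
}
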