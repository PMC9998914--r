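# Independent reimplementation of Cleveland's lowess (the oracle):
# per-point weighted local linear fits with tricube weights over the
# ceil(f*n) nearest neighbours, plus bisquare robustness iterations.
lowess_oracle <- function(x, y, f = 2/3, iters = 3L) {
  n <- length(x)
  if (n == 1L) return(y)
  ns <- min(n, max(2L, floor(f * n + 1e-7)))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (pass in seq_len(iters + 1L)) {
    use_rw <- pass > 1L
    nleft <- 1L
    for (i in seq_len(n)) {
      while (nleft + ns - 1L < n &&
             x[i] - x[nleft] > x[nleft + ns] - x[i]) nleft <- nleft + 1L
      nright <- nleft + ns - 1L
      h <- max(x[i] - x[nleft], x[nright] - x[i])
      h9 <- 0.999 * h
      h1 <- 0.001 * h
      # scan right past nright to pick up ties (as the reference does)
      w <- numeric(n)
      for (j in nleft:n) {
        r <- abs(x[j] - x[i])
        if (r <= h9) {
          w[j] <- if (r <= h1) 1 else (1 - (r / h)^3)^3
          if (use_rw) w[j] <- w[j] * rw[j]
        } else if (x[j] > x[i]) break
      }
      a <- sum(w)
      if (a <= 0) { fit[i] <- y[i]; next }
      w <- w / a
      if (h > 0) {
        aw <- sum(w * x)
        cc <- sum(w * (x - aw)^2)
        if (sqrt(cc) > 0.001 * (x[n] - x[1])) {
          b <- (x[i] - aw) / cc
          w <- w * (b * (x - aw) + 1)
        }
      }
      fit[i] <- sum(w * y)
    }
    if (pass <= iters) {
      res <- abs(y - fit)
      m1 <- n %/% 2L + 1L
      cmad <- if (n %% 2L == 0L) {
        3 * (sort(res, partial = c(m1 - 1L, m1))[m1 - 1L] +
             sort(res, partial = c(m1 - 1L, m1))[m1])
      } else 6 * sort(res, partial = m1)[m1]
      if (cmad < 1e-7 * sum(abs(y - fit)) / n) break
      c9 <- 0.999 * cmad
      c1 <- 0.001 * cmad
      rw <- ifelse(res <= c1, 1,
                   ifelse(res <= c9, (1 - (res / cmad)^2)^2, 0))
    }
  }
  fit
}
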