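# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream, restoring the caller's state
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# strip volume classes down to a plain array
vol_data <- function(x) {
  if (is.list(x) && !is.null(x$data)) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    stopf("expected a 3D array (Z, Y, X)")
  x
}

check_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("%s must be a single value in [0, 1]", name)
  x
}

# ---- axis-aligned voxel sets (mask + 0-based origin), used internally for
# ---- candidate polyhedra so NMS never materialises full volumes

voxel_set <- function(origin, mask) {
  list(origin = as.integer(origin), dim = dim(mask), mask = mask,
       count = sum(mask))
}

# IoU of two voxel sets; intersects bounding boxes first
vs_iou <- function(a, b) {
  if (a$count == 0L && b$count == 0L) return(0)
  lo <- pmax(a$origin, b$origin)
  hi <- pmin(a$origin + a$dim, b$origin + b$dim)
  if (any(hi <= lo)) return(0)
  ia <- lapply(1:3, function(k) (lo[k] - a$origin[k] + 1L):(hi[k] - a$origin[k]))
  ib <- lapply(1:3, function(k) (lo[k] - b$origin[k] + 1L):(hi[k] - b$origin[k]))
  inter <- sum(a$mask[ia[[1]], ia[[2]], ia[[3]], drop = FALSE] &
               b$mask[ib[[1]], ib[[2]], ib[[3]], drop = FALSE])
  inter / (a$count + b$count - inter)
}

# paint a voxel set into an integer volume with a given label,
# without overwriting non-zero voxels when overwrite = FALSE
vs_paint <- function(vol, vs, label, overwrite = TRUE) {
  idx <- lapply(1:3, function(k) (vs$origin[k] + 1L):(vs$origin[k] + vs$dim[k]))
  sub <- vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sel <- vs$mask
  if (!overwrite) sel <- sel & sub == 0L
  sub[sel] <- label
  vol[idx[[1]], idx[[2]], idx[[3]]] <- sub
  vol
}

# volume-wide Otsu threshold on a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}
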