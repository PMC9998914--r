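#' Grayscale image volume
#'
#' A 3D grayscale intensity volume in `(Z, Y, X)` axis order: the first array
#' index is the slice (Z) axis, matching a multi-page TIFF stack read one
#' trans-axial slice per page. Intensities are kept in `[0, 1]` (the native
#' scale of normalised micro-CT reconstructions and of float TIFF storage).
#'
#' @param data 3D numeric array `(Z, Y, X)` with finite values.
#' @param voxel_size physical edge length of a voxel per axis (arbitrary
#'   units); a single value is recycled to all three axes.
#' @return An `image_volume`: the array with class and `voxel_size` attributes.
#' @examples
#' v <- image_volume(array(0, c(3, 4, 4)))
#' dim(v)
#' @export
image_volume <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stopf("image data must be a 3D array with all dimensions >= 1")
  if (!all(is.finite(data))) stopf("image intensities must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  structure(data, voxel_size = voxel_size,
            class = c("image_volume", class(array())))
}

#' Instance label volume
#'
#' A 3D integer volume in `(Z, Y, X)` axis order where 0 is background and
#' each positive value identifies one instance (one seed). Label values need
#' not be contiguous.
#'
#' @param data 3D array of non-negative integers `(Z, Y, X)`.
#' @return A `label_volume` (integer array with class attribute).
#' @examples
#' lv <- label_volume(array(0L, c(2, 2, 2)))
#' n_instances(lv)
#' @export
label_volume <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stopf("label data must be a 3D array with all dimensions >= 1")
  if (any(data < 0) || any(data != round(data)))
    stopf("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  structure(data, class = c("label_volume", class(array())))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume> %d x %d x %d (Z,Y,X), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d (Z,Y,X), %d instance(s)\n",
              d[1], d[2], d[3], n_instances(x)))
  invisible(x)
}

#' Number of instances in a label volume
#' @param labels a `label_volume` or integer array.
#' @return Count of distinct positive labels.
#' @export
n_instances <- function(labels) {
  x <- vol_data(labels)
  length(unique(x[x > 0L]))
}

#' Instance label values
#' @param labels a `label_volume` or integer array.
#' @return Sorted vector of distinct positive labels.
#' @export
instance_ids <- function(labels) {
  x <- vol_data(labels)
  sort(unique(x[x > 0L]))
}
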