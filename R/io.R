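# Reading/writing TIFF stacks and the per-seed CSV report.
#
# Conventions fixed across the package: axis order (Z, Y, X) with the slice
# index first; voxel coordinates 0-based; bounding boxes half-open [min, max).

#' Read a volume from a multi-page TIFF stack
#'
#' Each TIFF page is one trans-axial (Y, X) slice; pages are stacked along Z.
#' Integer-typed TIFFs (8/16-bit) can be loaded as label volumes; float TIFFs
#' are always grayscale image volumes.
#'
#' @param path TIFF file path.
#' @param type `"auto"` (label if integer-typed, image otherwise), `"image"`,
#'   or `"label"`.
#' @param voxel_size voxel edge length passed to [image_volume()].
#' @return An [image_volume()] or [label_volume()] with shape
#'   `(n_pages, H, W)`.
#' @export
read_volume <- function(path, type = c("auto", "image", "label"),
                        voxel_size = 1) {
  type <- match.arg(type)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stopf("cannot read TIFF '%s': %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("TIFF pages in '%s' have inconsistent shapes", path)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 32L
  arr <- aperm(simplify2array(lapply(pages, function(p) {
    attributes(p)[setdiff(names(attributes(p)), "dim")] <- NULL
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    p
  })), c(3, 1, 2))
  # 8/16-bit samples are integers stored scaled to [0, 1]; 32-bit is float
  integral <- bps <= 16L
  if (integral) arr <- round(arr * (2^bps - 1))
  if (type == "label" || (type == "auto" && integral)) {
    if (!integral)
      stopf("'%s' stores float data and cannot be read as labels", path)
    label_volume(arr)
  } else {
    if (integral) arr <- arr / max(1, max(arr))  # grayscale ints -> [0, 1]
    image_volume(arr, voxel_size = voxel_size)
  }
}

#' Write a volume to a multi-page TIFF stack
#'
#' Label volumes are stored as 16-bit integer TIFFs (losslessly, labels up to
#' 65535); image volumes as 32-bit float TIFFs. Image intensities must lie in
#' `[0, 1]` (float TIFF storage outside that range is undefined in libtiff).
#'
#' @param x an [image_volume()], [label_volume()] or plain 3D array
#'   (integer-typed arrays are written as labels).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- vol_data(x)
  is_label <- inherits(x, "label_volume") ||
    (!inherits(x, "image_volume") && is.integer(arr))
  nz <- dim(arr)[1]
  if (is_label) {
    if (max(arr) > 65535L)
      stopf("label values above 65535 cannot be stored as 16-bit TIFF")
    pages <- lapply(seq_len(nz), function(z) arr[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    if (min(arr) < 0 || max(arr) > 1)
      stopf("image intensities must be in [0, 1] for float TIFF storage")
    pages <- lapply(seq_len(nz), function(z) arr[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

# CSV column schema: Table-1 location block, Table-2 shape block, valve block.
seed_table_schema <- function() {
  data.frame(
    internal = c("seed_id",
                 "z_min", "y_min", "x_min", "z_max", "y_max", "x_max",
                 "z_centroid", "y_centroid", "x_centroid",
                 "volume", "bbox_volume", "sphericity", "surface_area",
                 "convex_volume", "equivalent_diameter", "extent",
                 "major_axis_length", "minor_axis_length", "solidity",
                 "valve", "sequence_in_valve", "spacing_to_previous"),
    csv = c("Seed ID Number",
            "Z-axis minimum", "Y-axis minimum", "X-axis minimum",
            "Z-axis maximum", "Y-axis maximum", "X-axis maximum",
            "Z-axis centroid", "Y-axis centroid", "X-axis centroid",
            "Volume", "Bounding box volume", "Sphericity", "Surface area",
            "Convex volume", "Equivalent diameter", "Extent",
            "Major axis length", "Minor axis length", "Solidity",
            "valve", "sequence_in_valve", "spacing_to_previous"),
    stringsAsFactors = FALSE)
}

#' Write a per-seed report table to CSV
#'
#' Columns are fixed: the location block (seed id, per-axis bounding-box
#' minima/maxima and centroids), the size/shape block (volume through
#' solidity) and the valve block (`valve`, `sequence_in_valve`,
#' `spacing_to_previous`). Bounding boxes are 0-based half-open, so
#' `(max - min)` along each axis multiplies to the bounding-box volume.
#' An empty table writes the header only.
#'
#' @param records data frame as returned by [measure_instances()] (optionally
#'   augmented by [assign_valves()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_seed_table <- function(records, path) {
  sch <- seed_table_schema()
  out <- as.data.frame(matrix(NA, nrow = nrow(records),
                              ncol = nrow(sch)))
  names(out) <- sch$csv
  for (i in seq_len(nrow(sch))) {
    if (sch$internal[i] %in% names(records))
      out[[i]] <- records[[sch$internal[i]]]
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-seed report table written by [write_seed_table()]
#' @param path CSV path.
#' @return Data frame with the package's internal column names.
#' @export
read_seed_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE)
  sch <- seed_table_schema()
  miss <- setdiff(sch$csv, names(raw))
  if (length(miss))
    stopf("seed table '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  out <- raw[, sch$csv, drop = FALSE]
  names(out) <- sch$internal
  out
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the full pipeline. Detection score and
#' NMS thresholds live in `[0, 1]`; the ray count must be at least 4 (a
#' star-convex polyhedron needs a triangulated direction set); anisotropy
#' factors are >= 1 with the minimum exactly 1 (the longest-axis factor).
#'
#' @param threshold intensity threshold: `"otsu"` or a fixed numeric value.
#' @param score_threshold minimum detection confidence kept, in `[0, 1]`.
#' @param nms_threshold maximum pairwise IoU tolerated between kept
#'   detections, in `[0, 1]`.
#' @param taus IoU thresholds used by evaluation reports.
#' @param n_rays number of Fibonacci rays (>= 4).
#' @param anisotropy three per-axis factors `(Z, Y, X)`, each >= 1, min == 1.
#' @param lowess_f smoother span override for valve sorting (`NULL` = the
#'   automatic rule: 1 for pods with <= 5 seeds, 2/3 otherwise).
#' @param min_volume smallest instance volume (voxels) kept by detection.
#' @param seed RNG seed used by simulation steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = "otsu", score_threshold = 0.3,
                            nms_threshold = 0.4,
                            taus = seq(0.1, 0.9, by = 0.1),
                            n_rays = 96L, anisotropy = c(1, 1, 1),
                            lowess_f = NULL, min_volume = 500L, seed = 1L) {
  check_scalar01(score_threshold, "score_threshold")
  check_scalar01(nms_threshold, "nms_threshold")
  if (is.numeric(threshold)) check_scalar01(threshold, "threshold")
  else if (!identical(threshold, "otsu"))
    stopf("threshold must be 'otsu' or a value in [0, 1]")
  if (!is.numeric(n_rays) || n_rays < 4) stopf("n_rays must be >= 4")
  if (length(anisotropy) != 3L || any(anisotropy < 1) ||
      abs(min(anisotropy) - 1) > 1e-12)
    stopf("anisotropy must be 3 factors >= 1 with min exactly 1")
  if (!is.null(lowess_f)) {
    if (lowess_f <= 0 || lowess_f > 1) stopf("lowess_f must be in (0, 1]")
  }
  structure(list(threshold = threshold, score_threshold = score_threshold,
                 nms_threshold = nms_threshold, taus = taus,
                 n_rays = as.integer(n_rays), anisotropy = anisotropy,
                 lowess_f = lowess_f, min_volume = as.integer(min_volume),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value text file
#'
#' Lines are `key = value`; `#` starts a comment. Recognised keys match the
#' arguments of [pipeline_config()]; `taus` and `anisotropy` take
#' comma-separated values. Unknown keys are an error. Values given here are
#' overridden by any explicitly supplied arguments in `...` (the CLI passes
#' its flags that way).
#'
#' @param path config file path.
#' @param ... overrides, as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(pipeline_config))
  if (length(unk <- setdiff(keys, known)))
    stopf("unknown config key(s): %s", paste(unk, collapse = ", "))
  parse_val <- function(key, v) {
    if (key == "threshold" && v == "otsu") return("otsu")
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (any(is.na(num))) stopf("cannot parse config value '%s' for %s", v, key)
    num
  }
  args <- stats::setNames(mapply(parse_val, keys, vals, SIMPLIFY = FALSE), keys)
  args[names(list(...))] <- list(...)
  do.call(pipeline_config, args)
}
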