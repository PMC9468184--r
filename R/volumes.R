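#' Construct a 3D volume stack
#'
#' A `volume_stack` holds a 3D grid of finite scalars (classifier
#' probabilities in \[0, 1\] or raw intensities) together with the physical
#' voxel spacing.  Storage order is `(z, y, x)` -- one matrix slice per
#' z-plane -- while all reported physical coordinates are `(x, y, z)` in
#' micrometres.
#'
#' @param values numeric 3D array, indexed `[z, y, x]`.
#' @param spacing numeric length-3 vector `(sx, sy, sz)`, micrometres per
#'   voxel along x, y and z.  All components must be positive.
#' @return an object of class `volume_stack` with elements `values` and
#'   `spacing`.
#' @examples
#' v <- volume_stack(array(0.7, c(4, 4, 4)), spacing = c(6.45, 6.45, 10))
#' dim(v$values)
#' @export
volume_stack <- function(values, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop_bad("`values` must be a 3D array (z, y, x)")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_bad("`values` must be numeric and finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_bad("`spacing` must be 3 positive numbers (sx, sy, sz)")
  structure(list(values = values, spacing = spacing), class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_stack: %d x %d x %d voxels (z, y, x), spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an integer label volume
#'
#' Region annotations on the same `(z, y, x)` grid as an associated
#' [volume_stack()], e.g. atlas areas.  Label 0 is reserved for "unlabeled".
#'
#' @param labels integer 3D array of non-negative region ids, `[z, y, x]`.
#' @param label_names optional named character vector mapping id to region
#'   name, e.g. `c("1" = "isocortex")`.
#' @param spacing voxel spacing `(sx, sy, sz)` in micrometres.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, label_names = NULL, spacing = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop_bad("`labels` must be a 3D array (z, y, x)")
  if (any(labels < 0) || any(labels != round(labels)))
    stop_bad("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_bad("`spacing` must be 3 positive numbers")
  structure(list(labels = labels, label_names = label_names,
                 spacing = spacing), class = "label_volume")
}

#' Construct a 3D point cloud
#'
#' @param coords numeric N x 3 matrix of `(x, y, z)` coordinates in
#'   micrometres.
#' @param region_id optional integer vector of per-point region labels
#'   (length N).
#' @param channel free-text tag naming the signal channel (e.g. `"aSMA"`).
#' @return an object of class `point_cloud` with elements `coords`,
#'   `region_id`, `channel`, and point count `n`.
#' @examples
#' pc <- point_cloud(cbind(runif(5), runif(5), runif(5)), channel = "Prox1")
#' pc$n
#' @export
point_cloud <- function(coords, region_id = NULL, channel = "") {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0, 3)
  if (ncol(coords) != 3L) stop_bad("`coords` must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop_bad("coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(region_id)) {
    region_id <- as.integer(region_id)
    if (length(region_id) != nrow(coords))
      stop_bad("`region_id` must have one entry per point")
  }
  structure(list(coords = coords, region_id = region_id,
                 channel = as.character(channel)[1], n = nrow(coords)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, channel '%s'%s\n", x$n, x$channel,
              if (is.null(x$region_id)) "" else ", region labels attached"))
  invisible(x)
}

#' Read a classified volume from disk
#'
#' Reads a multi-page TIFF (one page per z-plane; 8/16-bit or float) or a
#' long-format CSV/TSV voxel table with columns `z,y,x,value` (0-based
#' indices) into a [volume_stack()].  Voxel spacing is not stored in either
#' format; supply it via `spacing` or a default of 1 um per axis is used with
#' a warning.
#'
#' @param path file to read (`.tif`/`.tiff` or `.csv`/`.tsv`).
#' @param spacing voxel spacing `(sx, sy, sz)` in micrometres, or `NULL` to
#'   default to `c(1, 1, 1)` with a warning.
#' @return a [volume_stack()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  if (is.null(spacing)) {
    warning("no voxel spacing supplied; defaulting to (1, 1, 1) um",
            call. = FALSE)
    spacing <- c(1, 1, 1)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L)
      stop_bad("ragged TIFF: pages have differing shapes")
    d <- dims[[1]]
    if (length(d) != 2L)
      stop_bad("expected single-channel (grayscale) TIFF pages")
    # readTIFF returns row = y, col = x; stack pages along z
    arr <- array(0, c(length(pages), d[1], d[2]))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    volume_stack(arr, spacing)
  } else if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep)
    need <- c("z", "y", "x", "value")
    if (!all(need %in% names(df)))
      stop_bad("voxel table must have columns z,y,x,value")
    if (!all(vapply(df[need], is.numeric, TRUE)))
      stop_bad("non-numeric data in voxel table")
    dz <- max(df$z) + 1L; dy <- max(df$y) + 1L; dx <- max(df$x) + 1L
    arr <- array(0, c(dz, dy, dx))
    arr[cbind(df$z + 1L, df$y + 1L, df$x + 1L)] <- df$value
    volume_stack(arr, spacing)
  } else {
    stop_bad("unsupported volume format: .", ext)
  }
}

#' Write a volume stack to disk
#'
#' Writes one float TIFF page per z-plane (`.tif`) or a long-format CSV voxel
#' table (`.csv`).  `read_volume(write_volume(v, path))` is value-identical
#' for float data.
#'
#' @param vol a [volume_stack()].
#' @param path output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_stack"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(vol$values)[1]),
                    function(k) vol$values[k, , , drop = TRUE])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "csv") {
    d <- dim(vol$values)
    idx <- which(array(TRUE, d), arr.ind = TRUE)
    df <- data.frame(z = idx[, 1] - 1L, y = idx[, 2] - 1L, x = idx[, 3] - 1L,
                     value = as.vector(vol$values))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop_bad("unsupported volume format: .", ext)
  }
  invisible(path)
}

#' Threshold a volume into a point cloud
#'
#' Emits one point per voxel whose value is at least `threshold`, placed at
#' the voxel centre: physical coordinate = (0-based index + 0.5) x spacing.
#' An empty cloud is a valid result.
#'
#' @param vol a [volume_stack()].
#' @param threshold finite scalar cutoff applied as `value >= threshold`.
#'   Default 0.5, the midpoint of a two-class probability map.
#' @param channel channel tag propagated to the cloud.
#' @return a [point_cloud()] in micrometre coordinates.
#' @examples
#' v <- volume_stack(array(c(0.9, rep(0.1, 7)), c(2, 2, 2)))
#' threshold_to_points(v, 0.5)$n
#' @export
threshold_to_points <- function(vol, threshold = 0.5, channel = "") {
  stopifnot(inherits(vol, "volume_stack"))
  if (!is.finite(threshold)) stop_bad("`threshold` must be finite")
  idx <- which(vol$values >= threshold, arr.ind = TRUE)  # (z, y, x) indices
  sp <- vol$spacing
  coords <- cbind(x = (idx[, 3] - 0.5) * sp[1],
                  y = (idx[, 2] - 0.5) * sp[2],
                  z = (idx[, 1] - 0.5) * sp[3])
  point_cloud(coords, channel = channel)
}

#' Attach region labels to a point cloud
#'
#' Maps every point into the label grid by flooring `coordinate / spacing`
#' and copies the region id found there; points on label 0 keep id 0.  A
#' point outside the grid is an error naming the point index.
#'
#' @param cloud a [point_cloud()] in micrometres.
#' @param labels a [label_volume()] aligned to the same physical frame.
#' @return the cloud with `region_id` populated.
#' @export
attach_region_labels <- function(cloud, labels) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(labels, "label_volume"))
  if (cloud$n == 0L) { cloud$region_id <- integer(0); return(cloud) }
  sp <- labels$spacing
  ix <- floor(cloud$coords[, "x"] / sp[1])
  iy <- floor(cloud$coords[, "y"] / sp[2])
  iz <- floor(cloud$coords[, "z"] / sp[3])
  d <- dim(labels$labels)  # (z, y, x)
  bad <- which(ix < 0 | ix >= d[3] | iy < 0 | iy >= d[2] |
                 iz < 0 | iz >= d[1])
  if (length(bad))
    stop_bad("point ", bad[1], " falls outside the label grid")
  cloud$region_id <- as.integer(labels$labels[cbind(iz + 1, iy + 1, ix + 1)])
  cloud
}

#' Voxel count and physical volume of a cloud or volume mask
#'
#' For a point cloud each point is one voxel; for a volume stack voxels are
#' counted at `value >= threshold`.  Physical volume is
#' `count * sx * sy * sz`.
#'
#' @param x a [point_cloud()] or [volume_stack()].
#' @param spacing voxel spacing in micrometres; required for a point cloud,
#'   taken from the volume otherwise.
#' @param threshold cutoff used when `x` is a volume stack.
#' @return a list with `voxel_count` and `physical_volume` (um^3).
#' @examples
#' volume_metric(point_cloud(matrix(runif(300), 100, 3)),
#'               spacing = c(10, 10, 10))
#' @export
volume_metric <- function(x, spacing = NULL, threshold = 0.5) {
  if (inherits(x, "volume_stack")) {
    n <- sum(x$values >= threshold)
    spacing <- x$spacing
  } else if (inherits(x, "point_cloud")) {
    if (is.null(spacing)) stop_bad("`spacing` is required for a point cloud")
    n <- x$n
  } else stop_bad("`x` must be a point_cloud or volume_stack")
  list(voxel_count = as.integer(n),
       physical_volume = n * prod(as.numeric(spacing)))
}

#' Uniform random subsample of a point cloud
#'
#' Draws a uniform subset without replacement of size `min(n, n_max)`;
#' deterministic for a fixed seed.  Region labels follow their points.
#'
#' @param cloud a [point_cloud()].
#' @param n_max maximum number of points to keep.
#' @param seed integer seed.
#' @return a [point_cloud()].
#' @export
subsample_points <- function(cloud, n_max, seed = 0L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_max < 0) stop_bad("`n_max` must be >= 0")
  if (cloud$n <= n_max) return(cloud)
  keep <- with_seed(seed, sort(sample.int(cloud$n, n_max)))
  point_cloud(cloud$coords[keep, , drop = FALSE],
              region_id = cloud$region_id[keep], channel = cloud$channel)
}

#' Read / write point clouds as CSV
#'
#' Columns are `x_um,y_um,z_um,region_id,channel`; `region_id` may be empty.
#'
#' @param path CSV file.
#' @return [read_point_cloud()] returns a [point_cloud()].
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop_bad("point cloud CSV must have columns x_um,y_um,z_um")
  rid <- if ("region_id" %in% names(df) && !all(is.na(df$region_id)))
    df$region_id else NULL
  ch <- if ("channel" %in% names(df) && nrow(df)) as.character(df$channel[1])
    else ""
  point_cloud(as.matrix(df[need]), region_id = rid, channel = ch)
}

#' @param cloud a [point_cloud()].
#' @rdname read_point_cloud
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  df <- if (cloud$n == 0L)
    data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
               region_id = integer(0), channel = character(0))
  else
    data.frame(x_um = cloud$coords[, "x"], y_um = cloud$coords[, "y"],
               z_um = cloud$coords[, "z"],
               region_id = if (is.null(cloud$region_id)) NA_integer_
                 else cloud$region_id,
               channel = cloud$channel)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
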