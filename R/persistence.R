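#' Construct a persistence diagram
#'
#' A multiset of topological features, each a `(dim, birth, death)` triple in
#' ball-radius units (micrometres).  Dimension 0 features are connected
#' components, dimension 1 loops, dimension 2 voids.  Pairs are kept sorted
#' by `(dim, birth, death)`; a capped infinite feature carries
#' `is_capped = TRUE`.
#'
#' @param pairs data frame with numeric columns `dim`, `birth`, `death` and
#'   optionally logical `is_capped`.
#' @param meta list of provenance fields (`n_points`, `max_dim`,
#'   `max_radius`, `channel`, ...).
#' @return an object of class `persistence_diagram`.
#' @export
persistence_diagram <- function(pairs, meta = list()) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L)
    pairs <- data.frame(dim = integer(0), birth = numeric(0),
                        death = numeric(0), is_capped = logical(0))
  if (!all(c("dim", "birth", "death") %in% names(pairs)))
    stop_bad("`pairs` needs columns dim, birth, death")
  if (is.null(pairs$is_capped)) pairs$is_capped <- FALSE
  if (any(pairs$birth < 0)) stop_bad("birth radii must be >= 0")
  if (any(pairs$death < pairs$birth)) stop_bad("death must be >= birth")
  if (!all(pairs$dim %in% 0:2)) stop_bad("dimensions must be in {0, 1, 2}")
  ord <- order(pairs$dim, pairs$birth, pairs$death)
  pairs <- pairs[ord, c("dim", "birth", "death", "is_capped")]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, meta = meta), class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  tab <- table(factor(x$pairs$dim, levels = 0:2))
  cat(sprintf("persistence_diagram: %d features (H0: %d, H1: %d, H2: %d)\n",
              nrow(x$pairs), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Vietoris-Rips persistent homology of a point cloud
#'
#' Grows a ball of radius `r` around every point and tracks the homology of
#' the resulting Vietoris-Rips complex as `r` increases: two balls of radius
#' `r` intersect when the points are at most `2r` apart, so an edge between
#' points at Euclidean distance `d` enters the filtration at radius `d / 2`.
#' All birth/death values are reported on this ball-radius scale.  Features
#' alive at `max_radius` (the single essential connected component, and any
#' cycle still open there) are recorded with `death = max_radius` and
#' `is_capped = TRUE`.
#'
#' Clouds larger than `n_max` points are uniformly subsampled first (seeded),
#' since the complex grows as `n^(max_dim + 2)`.
#'
#' @param cloud a [point_cloud()] with at least one point.
#' @param max_dim largest homology dimension, 0, 1 or 2 (default 2: report
#'   components, loops and voids).
#' @param max_radius filtration ceiling in micrometres; default half the
#'   bounding-box diagonal of the (subsampled) cloud.
#' @param n_max subsample cap before the Rips construction (default 1500).
#' @param seed seed for the subsample draw.
#' @return a [persistence_diagram()].
#' @examples
#' sq <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
#' rips_persistence(sq, max_dim = 1)$pairs
#' @export
rips_persistence <- function(cloud, max_dim = 2, max_radius = NULL,
                             n_max = 1500, seed = 0L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$n < 1L) stop_bad("cannot compute persistence of an empty cloud")
  if (!max_dim %in% 0:2)
    stop_bad("`max_dim` must be 0, 1 or 2 (higher dimensions unsupported)")
  cloud <- subsample_points(cloud, n_max, seed)
  dmat <- as.matrix(dist(cloud$coords))
  if (is.null(max_radius)) {
    rng <- apply(cloud$coords, 2, range)
    max_radius <- sqrt(sum((rng[2, ] - rng[1, ])^2)) / 2
    if (max_radius <= 0) max_radius <- 1
  }
  if (max_radius <= 0) stop_bad("`max_radius` must be positive")
  raw <- rips_pairs_cpp(dmat, as.integer(max_dim), 2 * max_radius)
  pairs <- data.frame(dim = as.integer(raw[, "dim"]),
                      birth = raw[, "birth"] / 2,
                      death = raw[, "death"] / 2)
  pairs$is_capped <- !is.finite(pairs$death)
  pairs$death[pairs$is_capped] <- max_radius
  pairs <- pairs[pairs$death > pairs$birth | pairs$is_capped, , drop = FALSE]
  persistence_diagram(pairs,
                      meta = list(n_points = cloud$n, max_dim = max_dim,
                                  max_radius = max_radius,
                                  channel = cloud$channel))
}

#' Filter a persistence diagram by dimension and lifetime
#'
#' Keeps features of homology dimension `dim` whose persistence
#' `death - birth` is at least `min_persistence`.
#'
#' @param pd a [persistence_diagram()].
#' @param dim homology dimension to keep.
#' @param min_persistence non-negative lifetime cutoff in micrometres.
#' @return a [persistence_diagram()].
#' @export
filter_diagram <- function(pd, dim, min_persistence = 0) {
  stopifnot(inherits(pd, "persistence_diagram"))
  if (min_persistence < 0) stop_bad("`min_persistence` must be >= 0")
  keep <- pd$pairs$dim == dim &
    (pd$pairs$death - pd$pairs$birth) >= min_persistence
  persistence_diagram(pd$pairs[keep, , drop = FALSE], meta = pd$meta)
}

#' Read / write persistence diagrams as CSV
#'
#' Columns `dim,birth_um,death_um`; an uncapped infinite death serialises as
#' `inf`.  The round-trip is lossless.
#'
#' @param path CSV file.
#' @return [read_diagram()] returns a [persistence_diagram()].
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(dim = "integer",
                                             birth_um = "character",
                                             death_um = "character"))
  if (!all(c("dim", "birth_um", "death_um") %in% names(df)))
    stop_bad("diagram CSV must have columns dim,birth_um,death_um")
  birth <- suppressWarnings(as.numeric(df$birth_um))
  death <- suppressWarnings(ifelse(tolower(df$death_um) == "inf", Inf,
                                   as.numeric(df$death_um)))
  bad <- which(is.na(birth) | is.na(death) | death < birth)
  if (length(bad))
    stop_bad("malformed diagram row at line ", bad[1] + 1L)
  capped <- if ("is_capped" %in% names(df)) as.logical(df$is_capped)
    else rep(FALSE, nrow(df))
  persistence_diagram(data.frame(dim = df$dim, birth = birth, death = death,
                                 is_capped = capped))
}

#' @param pd a [persistence_diagram()].
#' @rdname read_diagram
#' @export
write_diagram <- function(pd, path) {
  stopifnot(inherits(pd, "persistence_diagram"))
  df <- data.frame(dim = pd$pairs$dim,
                   birth_um = format(pd$pairs$birth, digits = 17),
                   death_um = ifelse(is.finite(pd$pairs$death),
                                     format(pd$pairs$death, digits = 17),
                                     "inf"),
                   is_capped = pd$pairs$is_capped)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
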