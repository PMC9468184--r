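#' Tube phantom: points scattered in a cylinder
#'
#' Emulates a thresholded straight vessel segment: a Poisson number of
#' points (`density` per micrometre of centreline) placed uniformly along
#' the axis and uniformly over the circular cross-section, plus optional
#' isotropic Gaussian jitter.
#'
#' @param length centreline length in micrometres.
#' @param radius tube radius in micrometres.
#' @param density expected points per micrometre of centreline.
#' @param jitter_sd isotropic Gaussian jitter SD in micrometres.
#' @param seed integer seed (deterministic per seed).
#' @param origin length-3 start of the centreline.
#' @param direction length-3 axis direction (normalised internally).
#' @return a [point_cloud()].
#' @export
tube_phantom <- function(length = 1000, radius = 10, density = 0.5,
                         jitter_sd = 0, seed = 0L, origin = c(0, 0, 0),
                         direction = c(1, 0, 0)) {
  if (density <= 0 || radius <= 0 || length <= 0)
    stop_bad("length, radius and density must be positive")
  if (jitter_sd < 0) stop_bad("`jitter_sd` must be >= 0")
  with_seed(seed, {
    n <- rpois(1, density * length)
    pts <- segment_points(n, origin, origin + direction /
                            sqrt(sum(direction^2)) * length, radius)
    if (jitter_sd > 0) pts <- pts + rnorm(length(pts), 0, jitter_sd)
    point_cloud(pts, channel = "tube")
  })
}

# n points uniform in a cylinder around segment p0 -> p1
segment_points <- function(n, p0, p1, radius) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  e1 <- axis / len
  # any unit vector not parallel to e1
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  t <- runif(n, 0, len)
  rr <- radius * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  sweep(outer(t, e1) + outer(rr * cos(ang), e2) + outer(rr * sin(ang), e3),
        2, p0, "+")
}

#' Ring phantom: evenly spaced points on a circle
#'
#' Ground truth for a loop (dimension-1) feature: `n` points at evenly
#' spaced angles on a circle of radius `radius` in the z = 0 plane, plus
#' optional Gaussian jitter.  With zero jitter the Rips loop of the phantom
#' is known in closed form: birth `radius * sin(pi / n)`, death
#' `radius * sqrt(3) / 2`.
#'
#' @param radius circle radius in micrometres.
#' @param n number of points.
#' @param jitter_sd isotropic Gaussian jitter SD in micrometres.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return a [point_cloud()].
#' @export
ring_phantom <- function(radius = 100, n = 12, jitter_sd = 0, seed = 0L) {
  if (radius <= 0 || n < 3) stop_bad("need radius > 0 and n >= 3")
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (jitter_sd > 0)
    pts <- pts + with_seed(seed, matrix(rnorm(3 * n, 0, jitter_sd), n, 3))
  point_cloud(pts, channel = "ring")
}

#' Shell phantom: points on a sphere surface
#'
#' Ground truth for a void (dimension-2) feature: `n` points uniform on the
#' sphere of radius `radius`, plus optional radial Gaussian jitter.
#'
#' @inheritParams ring_phantom
#' @export
shell_phantom <- function(radius = 100, n = 500, jitter_sd = 0, seed = 0L) {
  if (radius <= 0 || n < 4) stop_bad("need radius > 0 and n >= 4")
  with_seed(seed, {
    g <- matrix(rnorm(3 * n), n, 3)
    g <- g / sqrt(rowSums(g^2))
    r <- radius + if (jitter_sd > 0) rnorm(n, 0, jitter_sd) else 0
    point_cloud(g * r, channel = "shell")
  })
}

#' Branching-tree phantom: a bifurcating vessel surrogate
#'
#' A recursive bifurcating centreline with a point-sampled tube around every
#' branch.  Depth `d` yields `2^(d+1) - 1` branch segments, each child
#' rotated by `angle` from its parent's direction and shortened by
#' `shrink`.
#'
#' @param depth bifurcation depth (0 = a single tube).
#' @param length root branch length in micrometres.
#' @param radius tube radius in micrometres.
#' @param density expected points per micrometre of centreline.
#' @param angle child branch half-angle in radians.
#' @param shrink child length multiplier per generation.
#' @param seed integer seed.
#' @return a [point_cloud()] with attribute `n_segments`.
#' @export
tree_phantom <- function(depth = 3, length = 400, radius = 8, density = 0.5,
                         angle = pi / 5, shrink = 0.7, seed = 0L) {
  if (depth < 0) stop_bad("`depth` must be >= 0")
  segs <- list()
  grow <- function(p0, dir, len, d) {
    p1 <- p0 + dir * len
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1)
    if (d == 0) return(invisible())
    # branch in the plane spanned by dir and a perpendicular that rotates
    # with depth so the tree fills 3D
    ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- ref - sum(ref * dir) * dir
    perp <- perp / sqrt(sum(perp^2))
    for (s in c(-1, 1)) {
      child <- cos(angle) * dir + s * sin(angle) * perp
      child <- child / sqrt(sum(child^2))
      grow(p1, child, len * shrink, d - 1)
    }
  }
  grow(c(0, 0, 0), c(1, 0, 0), length, depth)
  with_seed(seed, {
    pts <- do.call(rbind, lapply(segs, function(sg) {
      len <- sqrt(sum((sg$p1 - sg$p0)^2))
      segment_points(rpois(1, density * len), sg$p0, sg$p1, radius)
    }))
    if (is.null(pts)) pts <- matrix(numeric(0), 0, 3)
    out <- point_cloud(pts, channel = "tree")
    attr(out, "n_segments") <- length(segs)
    out
  })
}

#' Degrade a phantom by deleting contiguous clumps of points
#'
#' Emulates structurally damaged vessels: spatially contiguous runs of
#' points are removed around randomly chosen centres (each clump = the
#' centre's nearest neighbours within `clump_scale` micrometres) until
#' exactly `round(drop_fraction * n)` points are gone.  Deterministic per
#' seed.
#'
#' @param cloud a [point_cloud()].
#' @param drop_fraction fraction of points to remove, in `[0, 1]`.
#' @param clump_scale clump radius in micrometres.
#' @param seed integer seed.
#' @return a [point_cloud()].
#' @export
degrade_phantom <- function(cloud, drop_fraction, clump_scale = 50,
                            seed = 0L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (drop_fraction < 0 || drop_fraction > 1)
    stop_bad("`drop_fraction` must be in [0, 1]")
  target <- round(drop_fraction * cloud$n)
  if (target == 0L) return(cloud)
  with_seed(seed, {
    alive <- rep(TRUE, cloud$n)
    removed <- 0L
    X <- cloud$coords
    while (removed < target) {
      centre <- sample(which(alive), 1)
      d <- sqrt(colSums((t(X) - X[centre, ])^2))
      clump <- which(alive & d <= clump_scale)
      clump <- clump[order(d[clump])]
      clump <- head(clump, target - removed)
      alive[clump] <- FALSE
      removed <- removed + length(clump)
    }
    point_cloud(X[alive, , drop = FALSE], region_id = cloud$region_id[alive],
                channel = cloud$channel)
  })
}

#' Rasterise a point cloud back to a volume stack
#'
#' Bins points into voxels of the given spacing (counts per voxel), the
#' inverse of [threshold_to_points()] up to voxel-centre quantisation.
#'
#' @param cloud a [point_cloud()].
#' @param spacing voxel spacing `(sx, sy, sz)` in micrometres.
#' @return a [volume_stack()] of per-voxel counts.
#' @export
rasterize_cloud <- function(cloud, spacing = c(1, 1, 1)) {
  stopifnot(inherits(cloud, "point_cloud"))
  spacing <- as.numeric(spacing)
  if (cloud$n == 0L) return(volume_stack(array(0, c(1, 1, 1)), spacing))
  ix <- floor(cloud$coords[, "x"] / spacing[1])
  iy <- floor(cloud$coords[, "y"] / spacing[2])
  iz <- floor(cloud$coords[, "z"] / spacing[3])
  if (any(ix < 0 | iy < 0 | iz < 0))
    stop_bad("cloud has negative coordinates; shift it before rasterising")
  arr <- array(0, c(max(iz) + 1, max(iy) + 1, max(ix) + 1))
  for (k in seq_len(cloud$n))
    arr[iz[k] + 1, iy[k] + 1, ix[k] + 1] <-
      arr[iz[k] + 1, iy[k] + 1, ix[k] + 1] + 1
  volume_stack(arr, spacing)
}
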