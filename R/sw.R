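#' Configuration for Sliced Wasserstein comparisons
#'
#' @param n_slices number of equally spaced projection angles discretising
#'   `(-pi/2, pi/2]`.  Default 50; the approximation error decreases
#'   monotonically in the slice count.
#' @param sigma kernel scale, in diagram units (micrometres).  Default 1.
#' @param dims_used homology dimensions entering a comparison; default
#'   `c(1, 2)` (loops and voids; components are computed but excluded by
#'   default).
#' @param dim_aggregation how per-dimension distances combine; only
#'   `"sum"` is provided.
#' @return a list of class `sw_config`.
#' @export
sw_config <- function(n_slices = 50L, sigma = 1, dims_used = c(1, 2),
                      dim_aggregation = "sum") {
  if (n_slices < 1) stop_bad("`n_slices` must be >= 1")
  if (sigma <= 0) stop_bad("`sigma` must be positive")
  if (!all(dims_used %in% 0:2)) stop_bad("`dims_used` must be within 0:2")
  dim_aggregation <- match.arg(dim_aggregation, "sum")
  structure(list(n_slices = as.integer(n_slices), sigma = sigma,
                 dims_used = sort(unique(as.integer(dims_used))),
                 dim_aggregation = dim_aggregation), class = "sw_config")
}

# (birth, death) rows of one homology dimension, finite pairs enforced
.diagram_points <- function(dg, dim) {
  if (inherits(dg, "persistence_diagram")) {
    p <- dg$pairs[dg$pairs$dim == dim, , drop = FALSE]
    if (any(!is.finite(p$death) & !p$is_capped))
      stop_bad("diagram contains uncapped infinite features; cap or filter first")
    cbind(p$birth, p$death)
  } else {
    p <- as.matrix(dg)
    if (length(p) == 0L) return(matrix(numeric(0), 0, 2))
    if (ncol(p) != 2L) stop_bad("raw diagram must be an n x 2 matrix")
    if (any(!is.finite(p))) stop_bad("raw diagram must contain finite pairs")
    p
  }
}

# Sliced Wasserstein distance between two finite planar point multisets,
# each augmented with the other's diagonal projections.  The 1D Wasserstein
# distance along each slice is exact: both sides have equal mass after
# augmentation, so it is the L1 distance between sorted projections.
.sw_one <- function(p1, p2, n_slices) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 + n2 == 0L) return(0)
  theta <- -pi / 2 + pi * (seq_len(n_slices) - 0.5) / n_slices
  ct <- cos(theta); st <- sin(theta)
  d1 <- (p1[, 1] + p1[, 2]) / 2  # diagonal projections (d, d)
  d2 <- (p2[, 1] + p2[, 2]) / 2
  tot <- 0
  for (m in seq_len(n_slices)) {
    a <- c(p1[, 1] * ct[m] + p1[, 2] * st[m], d2 * (ct[m] + st[m]))
    b <- c(p2[, 1] * ct[m] + p2[, 2] * st[m], d1 * (ct[m] + st[m]))
    tot <- tot + sum(abs(sort(a) - sort(b)))
  }
  tot / n_slices
}

#' Sliced Wasserstein distance between persistence diagrams
#'
#' Averages, over `n_slices` directions through the origin, the exact
#' 1-Wasserstein distance between the two diagrams projected onto each
#' direction, after augmenting each diagram with the orthogonal projection of
#' the other onto the diagonal (which equalises masses).  With
#' [persistence_diagram()] inputs the per-dimension distances over
#' `cfg$dims_used` are summed; a raw two-column `(birth, death)` matrix is
#' compared as a single diagram.
#'
#' @param dg1,dg2 [persistence_diagram()] objects, or n x 2 matrices of
#'   finite `(birth, death)` pairs.
#' @param cfg an [sw_config()].
#' @return a non-negative scalar; 0 for two empty diagrams.
#' @examples
#' sw_distance(rbind(c(0, 1)), matrix(numeric(0), 0, 2),
#'             sw_config(n_slices = 1e4))  # ~ sqrt(2) / pi
#' @export
sw_distance <- function(dg1, dg2, cfg = sw_config()) {
  stopifnot(inherits(cfg, "sw_config"))
  if (inherits(dg1, "persistence_diagram") ||
      inherits(dg2, "persistence_diagram")) {
    sum(vapply(cfg$dims_used, function(d) {
      .sw_one(.diagram_points(dg1, d), .diagram_points(dg2, d),
              cfg$n_slices)
    }, numeric(1)))
  } else {
    .sw_one(.diagram_points(dg1, NA), .diagram_points(dg2, NA), cfg$n_slices)
  }
}

#' Sliced Wasserstein kernel between persistence diagrams
#'
#' `exp(-SW(dg1, dg2) / (2 sigma^2))`.  The exponent uses the distance
#' itself, not its square, so the kernel lies in `(0, 1]` and equals 1
#' exactly for identical diagrams.
#'
#' @inheritParams sw_distance
#' @return a scalar in `(0, 1]`.
#' @export
sw_kernel <- function(dg1, dg2, cfg = sw_config()) {
  exp(-sw_distance(dg1, dg2, cfg) / (2 * cfg$sigma^2))
}

#' Pairwise Sliced Wasserstein distance matrix
#'
#' @param diagrams named list of two or more [persistence_diagram()] objects
#'   (or raw two-column matrices).
#' @param cfg an [sw_config()].
#' @return a symmetric matrix with zero diagonal, dimnames from the list
#'   names.
#' @export
pairwise_distance_matrix <- function(diagrams, cfg = sw_config()) {
  k <- length(diagrams)
  if (k < 2L) stop_bad("need at least 2 diagrams")
  labels <- names(diagrams)
  if (is.null(labels)) labels <- paste0("dg", seq_len(k))
  dm <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dm[i, j] <- dm[j, i] <- sw_distance(diagrams[[i]], diagrams[[j]], cfg)
  }
  dm
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-centre the squared distances and embed on the top
#' eigenvectors.  The embedding is deterministic up to rigid motion and
#' reflection.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param out_dim embedding dimension, less than `nrow(dm)`.
#' @return a list with `coords` (n x out_dim matrix, rownames from `dm`) and
#'   `eig` (the full eigenvalue spectrum of the centred matrix).
#' @export
mds_embed <- function(dm, out_dim = 2L) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8 ||
      any(abs(diag(dm)) > 1e-12) || any(dm < 0))
    stop_bad("`dm` must be a symmetric non-negative matrix with zero diagonal")
  if (out_dim >= nrow(dm))
    stop_bad("`out_dim` must be smaller than the number of objects")
  # cmdscale warns when fewer than k eigenvalues are positive (e.g. a zero
  # matrix); the spectrum is returned for inspection instead
  fit <- suppressWarnings(stats::cmdscale(dm, k = out_dim, eig = TRUE))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < out_dim) {
    # degenerate input (e.g. all-zero distances): embed at the origin
    coords <- matrix(0, nrow(dm), out_dim)
  }
  rownames(coords) <- rownames(dm)
  list(coords = coords, eig = fit$eig)
}
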