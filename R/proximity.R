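#' Nearest-neighbour distances from one point set to another
#'
#' For every source point, the Euclidean distance to its nearest target
#' point, e.g. from tumour voxels to lymphatic-vessel voxels.  The result is
#' independent of point order and asymmetric in general: swapping source and
#' target changes the distribution.
#'
#' @param source,target [point_cloud()]s in the same micrometre frame;
#'   `target` must be non-empty.
#' @return numeric vector of length `source$n`.
#' @examples
#' s <- point_cloud(rbind(c(0, 0, 0)))
#' t <- point_cloud(rbind(c(3, 4, 0), c(10, 0, 0)))
#' nn_distances(s, t)  # 5
#' @export
nn_distances <- function(source, target) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (target$n == 0L) stop_bad("`target` must be non-empty")
  if (source$n == 0L) return(numeric(0))
  nn_dist_cpp(source$coords, target$coords)
}

#' Tukey five-number summary of a distance distribution
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `quantile` type 7), whiskers at the most extreme values within
#' `1.5 * IQR` of the hinges, and the values beyond the fences as outliers.
#'
#' @param distances non-empty numeric vector (um).
#' @return a list of class `distance_summary` with `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `outliers`, `n`.
#' @examples
#' summarize_distances(1:9)
#' @export
summarize_distances <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0L || any(!is.finite(distances)))
    stop_bad("`distances` must be non-empty and finite")
  q <- unname(stats::quantile(distances, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- distances >= lo_fence & distances <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(distances[inside]),
                 whisker_hi = max(distances[inside]),
                 outliers = sort(distances[!inside]),
                 n = length(distances)), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("distance_summary (n = %d): median %.3g, hinges [%.3g, %.3g], whiskers [%.3g, %.3g], %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
              length(x$outliers)))
  invisible(x)
}
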