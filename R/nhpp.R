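#' NHPP parameters: strength and per-axis concentration
#'
#' The point-process intensity is a sum of separable logistic kernels, one
#' per observed point.  `a` scales the kernel (its total mass over space is
#' `a^3`, since `a` multiplies each of the three axis factors); `b[i]` is the
#' concentration along axis `i` in 1/um -- the larger `b[i]`, the more
#' tightly the kernel concentrates, so `1/b[i]` measures directional spread
#' (directionality) along that axis.
#'
#' @param a positive strength parameter.
#' @param b positive length-3 vector `(b_x, b_y, b_z)` in 1/um.
#' @return a list of class `nhpp_params`.
#' @export
nhpp_params <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop_bad("`a` must be a positive scalar")
  if (length(b) != 3L || any(!is.finite(b)) || any(b <= 0))
    stop_bad("`b` must be 3 positive numbers (b_x, b_y, b_z)")
  structure(list(a = a, b = b), class = "nhpp_params")
}

#' @export
print.nhpp_params <- function(x, ...) {
  cat(sprintf("nhpp_params: a = %.4g, b = (%.4g, %.4g, %.4g) /um, total kernel mass a^3 = %.4g\n",
              x$a, x$b[1], x$b[2], x$b[3], x$a^3))
  invisible(x)
}

#' Rectangular observation domain
#'
#' @param lo,hi per-axis bounds in micrometres, `hi > lo` componentwise.
#' @return a list of class `domain_box`.
#' @export
domain_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi <= lo))
    stop_bad("`lo` and `hi` must be length-3 with hi > lo on each axis")
  structure(list(lo = lo, hi = hi), class = "domain_box")
}

#' Bounding box of a point cloud as a domain
#'
#' @param cloud a [point_cloud()].
#' @param pad symmetric padding in micrometres added to every face.
#' @return a [domain_box()].
#' @export
bounding_box <- function(cloud, pad = 0) {
  stopifnot(inherits(cloud, "point_cloud"), cloud$n > 0)
  rng <- apply(cloud$coords, 2, range)
  domain_box(rng[1, ] - pad, rng[2, ] + pad)
}

#' Logistic kernel of the NHPP
#'
#' Evaluates `g(u) = prod_i a * b_i / (exp(b_i u_i) + 2 + exp(-b_i u_i))`,
#' computed through the numerically stable one-exponential form of each
#' factor.  At the origin each factor is `a * b_i / 4`.
#'
#' @param u numeric length-3 offset in micrometres, or an n x 3 matrix of
#'   offsets.
#' @param p an [nhpp_params()].
#' @return kernel value(s).
#' @examples
#' nhpp_kernel(c(0, 0, 0), nhpp_params(1, c(1, 1, 1)))  # 1/64
#' @export
nhpp_kernel <- function(u, p) {
  stopifnot(inherits(p, "nhpp_params"))
  u <- if (is.matrix(u)) u else matrix(u, 1)
  if (ncol(u) != 3L) stop_bad("`u` must have 3 columns")
  out <- rep(1, nrow(u))
  for (i in 1:3) {
    t <- abs(p$b[i] * u[, i])
    e <- exp(pmin(t, 1400))
    f <- p$a * p$b[i] / (e + 2 + 1 / e)
    f[t > 1400] <- 0
    out <- out * f
  }
  out
}

#' Leave-one-out intensity of the fitted NHPP
#'
#' `lambda(u) = sum_j g(u - x_j)` over all data points except, when `u` is a
#' data point itself, that point (exclusion is by index, so duplicated
#' coordinates are allowed).
#'
#' @param u length-3 location or n x 3 matrix of locations (um).
#' @param points a [point_cloud()].
#' @param p an [nhpp_params()].
#' @param exclude_index optional index of the data point to leave out.
#' @return intensity value(s).
#' @export
nhpp_intensity <- function(u, points, p, exclude_index = NULL) {
  stopifnot(inherits(points, "point_cloud"), inherits(p, "nhpp_params"))
  X <- points$coords
  if (!is.null(exclude_index)) X <- X[-exclude_index, , drop = FALSE]
  if (nrow(X) == 0L) stop_bad("no points left after exclusion")
  u <- if (is.matrix(u)) u else matrix(u, 1)
  nhpp_lambda_at_cpp(u, X, p$a, p$b)
}

# closed-form integral of lambda over the box: each kernel contributes
# a^3 * prod_i [F_{b_i}(hi_i - x_i) - F_{b_i}(lo_i - x_i)], F the logistic CDF
nhpp_box_integral <- function(points, p, box) {
  nhpp_box_mass_cpp(points$coords, p$a, p$b, box$lo, box$hi)
}

#' Log-likelihood of the NHPP
#'
#' `sum_j log lambda(x_j) - integral_box lambda(u) du`, with leave-one-out
#' intensities at the data points and the domain integral in closed form via
#' logistic CDFs.  Returns `-Inf` (with a warning naming the first offending
#' point) if any leave-one-out intensity underflows to zero.
#'
#' @param points a [point_cloud()] with at least 2 points.
#' @param p an [nhpp_params()].
#' @param box a [domain_box()].
#' @return a scalar log-likelihood.
#' @export
nhpp_loglik <- function(points, p, box) {
  stopifnot(inherits(points, "point_cloud"), inherits(p, "nhpp_params"),
            inherits(box, "domain_box"))
  if (points$n < 2L)
    stop_bad("need at least 2 points (leave-one-out intensity of a single point is 0)")
  ll <- nhpp_loglik_cpp(points$coords, p$a, p$b, box$lo, box$hi)
  if (!is.finite(ll)) {
    lam <- nhpp_lambda_points_cpp(points$coords, p$a, p$b)
    warning("leave-one-out intensity is zero at point ", which(lam <= 0)[1],
            "; returning -Inf", call. = FALSE)
  }
  ll
}

#' Maximum-likelihood fit of the NHPP parameters
#'
#' Maximises [nhpp_loglik()] with seeded multi-start Nelder-Mead simplex
#' search over log-transformed concentrations (positivity by construction).
#' Because the intensity scales as `a^3`, the strength maximising the
#' likelihood at fixed `b` has the closed form `a^3 = n / K1(b)`, `K1` the
#' in-box kernel mass at unit strength; the simplex therefore searches the
#' 3D profile likelihood over `log b` and `a` is recovered exactly.  Start 1
#' initialises `b_i` from the per-axis spread of nearest-neighbour offsets;
#' the remaining starts are random log-scale perturbations of it.  For large
#' clouds the multi-start exploration runs on a uniform subsample of
#' `explore_n` points (each likelihood evaluation is quadratic in the point
#' count) and the best start is then refined on the full data with a tight
#' simplex.
#'
#' @param points a [point_cloud()] with at least 2 points.
#' @param box a [domain_box()]; default the bounding box.
#' @param init optional [nhpp_params()] used as start 1.
#' @param n_starts number of simplex starts (default 5).
#' @param seed seed for start perturbations and the exploration subsample.
#' @param explore_n subsample size for the exploration stage (default 500).
#' @param maxit simplex iteration cap per start.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return a list of class `nhpp_fit` with `params` ([nhpp_params()]),
#'   `loglik`, `converged`, `n_points`, and `starts` (per-start optima and
#'   log-likelihoods, a dispersion diagnostic).
#' @export
nhpp_fit <- function(points, box = NULL, init = NULL, n_starts = 5L,
                     seed = 0L, explore_n = 500L, maxit = 1000L,
                     reltol = 1e-8) {
  stopifnot(inherits(points, "point_cloud"))
  if (points$n < 2L) stop_bad("need at least 2 points to fit")
  if (is.null(box)) box <- bounding_box(points, pad = 0)
  X <- points$coords

  # negative profile log-likelihood over log(b); a^3 = n / K1(b)
  neg_profile <- function(logb, XX) {
    parts <- nhpp_profile_parts_cpp(XX, exp(logb), box$lo, box$hi)
    if (!is.finite(parts$sum_log_S) || parts$K1 <= 0) return(1e300)
    n <- nrow(XX)
    -(parts$sum_log_S + n * log(n / parts$K1) - n)
  }
  a_hat <- function(logb, XX) {
    parts <- nhpp_profile_parts_cpp(XX, exp(logb), box$lo, box$hi)
    (nrow(XX) / parts$K1)^(1 / 3)
  }

  if (is.null(init)) {
    # nearest-neighbour per-axis offsets set the concentration scale
    sub <- if (nrow(X) > 500) X[with_seed(seed, sample.int(nrow(X), 500)), ,
                                drop = FALSE] else X
    nn <- apply(as.matrix(dist(sub)) + diag(Inf, nrow(sub)), 1, which.min)
    spread <- pmax(apply(abs(sub - sub[nn, , drop = FALSE]), 2, mean), 1e-6)
    init <- nhpp_params(1, 1 / spread)
  }
  b0 <- log(init$b)

  Xe <- if (nrow(X) > explore_n)
    X[with_seed(seed, sort(sample.int(nrow(X), explore_n))), , drop = FALSE]
  else X

  starts <- with_seed(seed + 1L, {
    s <- list(b0)
    if (n_starts > 1)
      for (k in 2:n_starts) s[[k]] <- b0 + runif(3, -1, 1)
    s
  })

  runs <- lapply(starts, function(s) {
    stats::optim(s, neg_profile, XX = Xe, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]

  if (nrow(Xe) < nrow(X)) {
    best <- stats::optim(best$par, neg_profile, XX = X,
                         method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol,
                                        parscale = rep(0.1, 3)))
  }
  b_est <- exp(best$par)
  est <- nhpp_params(a_hat(best$par, X), b_est)
  start_tab <- data.frame(
    a = vapply(runs, function(r) a_hat(r$par, Xe), numeric(1)),
    bx = vapply(runs, function(r) exp(r$par[1]), numeric(1)),
    by = vapply(runs, function(r) exp(r$par[2]), numeric(1)),
    bz = vapply(runs, function(r) exp(r$par[3]), numeric(1)),
    neg_profile = vals)
  structure(list(params = est,
                 loglik = nhpp_loglik_cpp(X, est$a, est$b, box$lo, box$hi),
                 converged = best$convergence == 0L,
                 n_points = nrow(X), box = box, starts = start_tab),
            class = "nhpp_fit")
}

#' @export
print.nhpp_fit <- function(x, ...) {
  cat(sprintf("nhpp_fit on %d points, log-likelihood %.2f%s\n", x$n_points,
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Simulate a clustered point pattern consistent with the NHPP kernel
#'
#' A Neyman-Scott-style cluster process: `n_centers` cluster centres uniform
#' in the box, a Poisson(`a^3`) number of points per centre (the kernel's
#' total mass), and per-axis offsets drawn from the logistic distribution
#' with scale `1/b_i` (inverse-CDF `x = log(u/(1-u)) / b_i`).  Points
#' falling outside the box are discarded and the retention fraction
#' reported.
#'
#' @param n_centers number of cluster centres (>= 1).
#' @param p an [nhpp_params()].
#' @param box a [domain_box()].
#' @param seed integer seed; the draw is deterministic per seed.
#' @param channel channel tag for the output cloud.
#' @return a [point_cloud()] with attributes `retention` (kept / generated),
#'   `centers` (the cluster centres) and `center_id` (per kept point, the
#'   index of its centre) for diagnostics.
#' @export
nhpp_simulate <- function(n_centers, p, box, seed = 0L, channel = "sim") {
  stopifnot(inherits(p, "nhpp_params"), inherits(box, "domain_box"))
  if (n_centers < 1) stop_bad("`n_centers` must be >= 1")
  with_seed(seed, {
    ctr <- cbind(runif(n_centers, box$lo[1], box$hi[1]),
                 runif(n_centers, box$lo[2], box$hi[2]),
                 runif(n_centers, box$lo[3], box$hi[3]))
    m <- rpois(n_centers, p$a^3)
    total <- sum(m)
    if (total == 0L) {
      out <- point_cloud(matrix(numeric(0), 0, 3), channel = channel)
      attr(out, "retention") <- NA_real_
      return(out)
    }
    cid <- rep(seq_len(n_centers), m)
    X <- ctr[cid, , drop = FALSE] +
      cbind(rlogis(total, 0, 1 / p$b[1]), rlogis(total, 0, 1 / p$b[2]),
            rlogis(total, 0, 1 / p$b[3]))
    keep <- X[, 1] >= box$lo[1] & X[, 1] <= box$hi[1] &
      X[, 2] >= box$lo[2] & X[, 2] <= box$hi[2] &
      X[, 3] >= box$lo[3] & X[, 3] <= box$hi[3]
    out <- point_cloud(X[keep, , drop = FALSE], channel = channel)
    attr(out, "retention") <- sum(keep) / total
    attr(out, "centers") <- ctr
    attr(out, "center_id") <- cid[keep]
    out
  })
}

#' Fit the NHPP block-wise for two channels
#'
#' Tiles the box with cubic blocks of edge `block_edge` and fits the NHPP
#' independently per channel in every block holding at least `min_points`
#' points of each channel.  Blocks below the threshold are kept but flagged
#' unevaluable.  Each block's region id is the majority region label of the
#' points it contains (0 when labels are absent).
#'
#' @param cloud_a,cloud_b [point_cloud()]s for the two channels (A is the
#'   numerator channel in downstream fold changes).
#' @param box a [domain_box()]; default the joint bounding box.
#' @param block_edge cubic block edge in micrometres (default 500).
#' @param min_points minimum points per channel per block (default 50).
#' @param ... passed to [nhpp_fit()].
#' @return a list of class `block_grid` with the box, `block_edge`, and a
#'   data frame `blocks` (block index and bounds, per-channel point counts,
#'   fitted parameters `a_A, bx_A, ..., bz_B`, `region_id`, `evaluable`).
#' @export
fit_blocks <- function(cloud_a, cloud_b, box = NULL, block_edge = 500,
                       min_points = 50L, ...) {
  stopifnot(inherits(cloud_a, "point_cloud"), inherits(cloud_b, "point_cloud"))
  if (block_edge <= 0) stop_bad("`block_edge` must be positive")
  if (is.null(box)) {
    all_pts <- point_cloud(rbind(cloud_a$coords, cloud_b$coords))
    box <- bounding_box(all_pts)
  }
  nb <- pmax(1L, ceiling((box$hi - box$lo) / block_edge))
  grid <- expand.grid(ix = seq_len(nb[1]), iy = seq_len(nb[2]),
                      iz = seq_len(nb[3]))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    lo <- box$lo + (unlist(grid[g, ]) - 1) * block_edge
    hi <- pmin(lo + block_edge, box$hi)
    sub_box <- domain_box(lo, hi)
    in_block <- function(cl) {
      X <- cl$coords
      keep <- X[, 1] >= lo[1] & X[, 1] < hi[1] + (grid[g, 1] == nb[1]) * 1e-9 &
        X[, 2] >= lo[2] & X[, 2] < hi[2] + (grid[g, 2] == nb[2]) * 1e-9 &
        X[, 3] >= lo[3] & X[, 3] < hi[3] + (grid[g, 3] == nb[3]) * 1e-9
      point_cloud(X[keep, , drop = FALSE],
                  region_id = cl$region_id[keep], channel = cl$channel)
    }
    pa <- in_block(cloud_a); pb <- in_block(cloud_b)
    region <- {
      ids <- c(pa$region_id, pb$region_id)
      if (length(ids) == 0L) 0L
      else as.integer(names(which.max(table(ids))))
    }
    row <- data.frame(block = g, x_lo = lo[1], y_lo = lo[2], z_lo = lo[3],
                      n_A = pa$n, n_B = pb$n, region_id = region,
                      evaluable = pa$n >= min_points && pb$n >= min_points,
                      a_A = NA_real_, bx_A = NA_real_, by_A = NA_real_,
                      bz_A = NA_real_, a_B = NA_real_, bx_B = NA_real_,
                      by_B = NA_real_, bz_B = NA_real_)
    if (row$evaluable) {
      fa <- nhpp_fit(pa, box = sub_box, ...)
      fb <- nhpp_fit(pb, box = sub_box, ...)
      row[c("a_A", "bx_A", "by_A", "bz_A")] <- c(fa$params$a, fa$params$b)
      row[c("a_B", "bx_B", "by_B", "bz_B")] <- c(fb$params$a, fb$params$b)
    }
    rows[[g]] <- row
  }
  structure(list(box = box, block_edge = block_edge,
                 blocks = do.call(rbind, rows)), class = "block_grid")
}

#' Flag blocks whose fitted parameter changed by a fold threshold
#'
#' For strength the tested ratio is `a_A / a_B`; for the directionality
#' parameters it is the ratio of reciprocals `(1/b_A) / (1/b_B)`.  With the
#' default one-sided convention a block is "changed" when the ratio is at
#' least `fold` (channel A increased relative to B); `two_sided = TRUE`
#' flags `|log2 ratio| >= log2(fold)` instead.
#'
#' @param grid a `block_grid` from [fit_blocks()].
#' @param param one of `"a"`, `"inv_b_x"`, `"inv_b_y"`, `"inv_b_z"`.
#' @param fold fold-change threshold (default 2).
#' @param two_sided flag changes in either direction.
#' @return a logical vector over evaluable blocks (names = block indices).
#' @export
extract_changed_blocks <- function(grid, param = c("a", "inv_b_x", "inv_b_y",
                                                   "inv_b_z"),
                                   fold = 2, two_sided = FALSE) {
  stopifnot(inherits(grid, "block_grid"))
  param <- match.arg(param)
  bl <- grid$blocks[grid$blocks$evaluable, , drop = FALSE]
  cols <- switch(param, a = c("a_A", "a_B"), inv_b_x = c("bx_A", "bx_B"),
                 inv_b_y = c("by_A", "by_B"), inv_b_z = c("bz_A", "bz_B"))
  va <- bl[[cols[1]]]; vb <- bl[[cols[2]]]
  if (any(va <= 0 | vb <= 0, na.rm = TRUE))
    stop_bad("non-positive fitted parameter encountered")
  ratio <- if (param == "a") va / vb else (1 / va) / (1 / vb)
  changed <- if (two_sided) abs(log2(ratio)) >= log2(fold)
  else ratio >= fold
  names(changed) <- bl$block
  changed
}

#' Fisher's exact test for regional concentration of changed blocks
#'
#' Builds the 2x2 table of changed/unchanged blocks inside and outside an
#' area and computes the exact two-sided p-value (sum of hypergeometric
#' probabilities not exceeding that of the observed table).  If changed
#' blocks scatter at random the in-area fraction matches the overall one; a
#' small p-value flags concentration of change in the area.
#'
#' @param changed logical vector per evaluable block.
#' @param in_area logical vector of the same length: block lies in the area.
#' @return a list with `table` (2x2 matrix: rows changed/unchanged, columns
#'   in-area/elsewhere) and `p_value`.  Degenerate margins give p = 1.
#' @export
fisher_region_test <- function(changed, in_area) {
  if (length(changed) != length(in_area))
    stop_bad("`changed` and `in_area` must have equal length")
  A <- sum(changed & in_area); B <- sum(changed & !in_area)
  C <- sum(!changed & in_area); D <- sum(!changed & !in_area)
  tab <- matrix(c(A, C, B, D), 2, 2,
                dimnames = list(c("changed", "unchanged"),
                                c("in_area", "elsewhere")))
  p <- if (sum(tab) == 0L) 1 else stats::fisher.test(tab)$p.value
  list(table = tab, p_value = min(p, 1))
}
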