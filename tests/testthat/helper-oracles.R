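# Independent oracles used to validate the package implementations.
# These deliberately use naive textbook algorithms, separate from the
# package's code paths.

# Brute-force Vietoris-Rips persistence over Z/2: enumerate every simplex up
# to dim maxdim + 1, sort by (diameter, dim, lex), build the dense boundary
# matrix and reduce it column by column with plain Gaussian-style xor steps.
# Returns (dim, birth, death) on the ball-RADIUS scale, death = Inf for
# essential classes, zero-persistence pairs dropped.
rips_oracle <- function(coords, maxdim = 2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  simp <- list()
  for (d in 0:(maxdim + 1)) {
    if (d + 1 > n) break
    cm <- utils::combn(n, d + 1)
    for (c in seq_len(ncol(cm))) {
      v <- cm[, c]
      diam <- if (d == 0) 0 else max(D[v, v])
      simp[[length(simp) + 1L]] <- list(v = v, dim = d, diam = diam)
    }
  }
  key <- function(v) paste(v, collapse = "-")
  diams <- vapply(simp, `[[`, numeric(1), "diam")
  dims <- vapply(simp, `[[`, numeric(1), "dim")
  lex <- vapply(simp, function(s) paste(sprintf("%04d", s$v), collapse = ""),
                character(1))
  ord <- order(diams, dims, lex)
  simp <- simp[ord]
  m <- length(simp)
  idx <- structure(seq_len(m),
                   names = vapply(simp, function(s) key(s$v), character(1)))
  # dense boundary matrix over Z/2
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0) next
    for (drop in seq_along(s$v)) B[idx[[key(s$v[-drop])]], j] <- TRUE
  }
  low <- function(col) if (any(col)) max(which(col)) else 0L
  pivot_owner <- integer(m)  # row -> column
  pair_of <- integer(m)      # column -> pivot row
  for (j in seq_len(m)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L || pivot_owner[l] == 0L) break
      B[, j] <- xor(B[, j], B[, pivot_owner[l]])
    }
    l <- low(B[, j])
    if (l > 0L) { pivot_owner[l] <- j; pair_of[j] <- l }
  }
  out <- data.frame(dim = numeric(0), birth = numeric(0), death = numeric(0))
  for (j in seq_len(m)) {
    if (pair_of[j] > 0L) {
      r <- pair_of[j]
      if (simp[[j]]$diam > simp[[r]]$diam)
        out <- rbind(out, data.frame(dim = simp[[r]]$dim,
                                     birth = simp[[r]]$diam / 2,
                                     death = simp[[j]]$diam / 2))
    } else if (pivot_owner[j] == 0L && simp[[j]]$dim <= maxdim) {
      out <- rbind(out, data.frame(dim = simp[[j]]$dim,
                                   birth = simp[[j]]$diam / 2, death = Inf))
    }
  }
  out[order(out$dim, out$birth, out$death), , drop = FALSE]
}

# canonicalise a diagram data frame for exact comparison
canon_pairs <- function(df, digits = 9) {
  df <- data.frame(dim = df$dim, birth = round(df$birth, digits),
                   death = round(df$death, digits))
  df <- df[order(df$dim, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Sliced Wasserstein by adaptive quadrature over the angle: the 1D
# Wasserstein at each angle is computed by sorting, the angular average by
# stats::integrate.
sw_quad_oracle <- function(p1, p2, rel.tol = 1e-7) {
  w1 <- function(theta) {
    vapply(theta, function(th) {
      a <- c(p1[, 1] * cos(th) + p1[, 2] * sin(th),
             (p2[, 1] + p2[, 2]) / 2 * (cos(th) + sin(th)))
      b <- c(p2[, 1] * cos(th) + p2[, 2] * sin(th),
             (p1[, 1] + p1[, 2]) / 2 * (cos(th) + sin(th)))
      sum(abs(sort(a) - sort(b)))
    }, numeric(1))
  }
  stats::integrate(w1, -pi / 2, pi / 2, rel.tol = rel.tol,
                   subdivisions = 2000L, stop.on.error = FALSE)$value / pi
}

# Fisher's exact two-sided p by full hypergeometric enumeration
fisher_enum_oracle <- function(A, B, C, D) {
  n <- A + B + C + D
  r1 <- A + B          # changed blocks
  c1 <- A + C          # in-area blocks
  if (n == 0L) return(1)
  xs <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(A, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(N * M) nearest-neighbour distances
nn_brute_oracle <- function(src, tgt) {
  apply(src, 1, function(p) sqrt(min(colSums((t(tgt) - p)^2))))
}

# 1D quadrature of one logistic-kernel axis factor over (lo, hi)
axis_factor_quad <- function(a, b, centre, lo, hi) {
  stats::integrate(function(t) a * b / (exp(b * (t - centre)) + 2 +
                                          exp(-b * (t - centre))),
                   lo, hi, rel.tol = 1e-11)$value
}

# quadrature oracle for the box integral of lambda
box_integral_quad <- function(points, p, box) {
  sum(apply(points$coords, 1, function(x)
    prod(vapply(1:3, function(i)
      axis_factor_quad(p$a, p$b[i], x[i], box$lo[i], box$hi[i]),
      numeric(1)))))
}

# random small persistence-diagram point set (birth < death)
random_diagram_points <- function(n, scale = 1) {
  b <- runif(n, 0, scale)
  cbind(b, b + runif(n, 0, scale))
}
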