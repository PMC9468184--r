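test_that("logistic kernel evaluates the closed forms stably", {
  expect_equal(nhpp_kernel(c(0, 0, 0), nhpp_params(1, c(1, 1, 1))), 1 / 64)
  expect_equal(nhpp_kernel(c(0, 0, 0), nhpp_params(2, c(1, 2, 4))), 1)
  # huge offsets underflow to zero instead of NaN
  expect_equal(nhpp_kernel(c(1e6, 0, 0), nhpp_params(1, c(1, 1, 1))), 0)
  expect_true(is.finite(nhpp_kernel(c(500, -500, 500),
                                    nhpp_params(1, c(0.5, 0.5, 0.5)))))
})

test_that("kernel mass equals a^3 by separable quadrature", {
  set.seed(17)
  for (rep in 1:6) {
    p <- nhpp_params(runif(1, 0.5, 3), runif(3, 0.02, 2))
    mass <- prod(vapply(1:3, function(i)
      axis_factor_quad(p$a, p$b[i], 0, -Inf, Inf), numeric(1)))
    expect_equal(mass, p$a^3, tolerance = 1e-6)
  }
})

test_that("intensity is a leave-one-out kernel sum with the right geometry", {
  p <- nhpp_params(1.3, c(0.2, 0.3, 0.4))
  delta <- c(3, -2, 1)
  two <- point_cloud(rbind(c(0, 0, 0), delta))
  lam1 <- nhpp_intensity(c(0, 0, 0), two, p, exclude_index = 1)
  expect_equal(lam1, nhpp_kernel(delta, p))

  # decay far from all points
  cl <- point_cloud(matrix(runif(60, 0, 10), 20, 3))
  far <- c(10 + 50 / min(p$b), 0, 0)
  expect_lt(nhpp_intensity(far, cl, p),
            1e-10 * cl$n * nhpp_kernel(c(0, 0, 0), p))

  # translation invariance
  shift <- c(11, -7, 3)
  cl2 <- point_cloud(sweep(cl$coords, 2, shift, "+"))
  u <- c(4, 5, 6)
  expect_equal(nhpp_intensity(u + shift, cl2, p),
               nhpp_intensity(u, cl, p), tolerance = 1e-12)
})

test_that("closed-form box integral matches adaptive quadrature", {
  set.seed(23)
  for (rep in 1:5) {
    p <- nhpp_params(runif(1, 0.5, 2), runif(3, 0.05, 1))
    pts <- point_cloud(matrix(runif(12, 0, 40), 4, 3))
    box <- domain_box(runif(3, -10, 0), runif(3, 40, 60))
    expect_equal(vasctda:::nhpp_box_integral(pts, p, box),
                 box_integral_quad(pts, p, box), tolerance = 1e-6)
  }
})

test_that("box integral has the a^3 scaling and the whole-space limit", {
  p <- nhpp_params(1.8, c(0.3, 0.2, 0.5))
  pts <- point_cloud(matrix(runif(15, 0, 20), 5, 3))
  huge <- domain_box(rep(-1e5, 3), rep(1e5, 3))
  expect_equal(vasctda:::nhpp_box_integral(pts, p, huge), pts$n * p$a^3,
               tolerance = 1e-9)
  box <- domain_box(c(0, 0, 0), c(20, 20, 20))
  half <- nhpp_params(p$a / 2, p$b)
  expect_equal(vasctda:::nhpp_box_integral(pts, half, box),
               vasctda:::nhpp_box_integral(pts, p, box) / 8,
               tolerance = 1e-12)
})

test_that("log-likelihood combines point terms and the domain integral", {
  p <- nhpp_params(1.2, c(0.4, 0.4, 0.4))
  pts <- point_cloud(rbind(c(1, 1, 1), c(2, 1, 1), c(1, 3, 2)))
  box <- domain_box(c(0, 0, 0), c(5, 5, 5))
  lam <- vapply(1:3, function(j)
    nhpp_intensity(pts$coords[j, ], pts, p, exclude_index = j), numeric(1))
  expect_equal(nhpp_loglik(pts, p, box),
               sum(log(lam)) - vasctda:::nhpp_box_integral(pts, p, box),
               tolerance = 1e-12)
  expect_error(nhpp_loglik(point_cloud(rbind(c(0, 0, 0))), p, box),
               "at least 2")
  # isolated points underflow the leave-one-out intensity: -Inf sentinel
  sparse <- point_cloud(rbind(c(0, 0, 0), c(1e5, 1e5, 1e5)))
  expect_warning(ll <- nhpp_loglik(sparse, p,
                                   domain_box(c(0, 0, 0), rep(2e5, 3))),
                 "point 1")
  expect_identical(ll, -Inf)
})

test_that("simulation has the documented count, spread and determinism", {
  box <- domain_box(c(0, 0, 0), c(1000, 1000, 1000))
  # b so large that edge losses are negligible: E[N] = n_centers * a^3
  cl <- nhpp_simulate(100, nhpp_params(1, c(5, 5, 5)), box, seed = 7)
  expect_lt(abs(cl$n - 100), 3 * sqrt(100))
  expect_gt(attr(cl, "retention"), 0.99)

  cl2 <- nhpp_simulate(100, nhpp_params(1, c(5, 5, 5)), box, seed = 7)
  expect_identical(cl$coords, cl2$coords)

  # per-axis offsets have logistic variance pi^2 / (3 b^2)
  p <- nhpp_params(3, c(0.1, 0.2, 0.4))
  big <- domain_box(rep(-1e4, 3), rep(1e4, 3))
  sim <- nhpp_simulate(4000, p, big, seed = 1)
  expect_gt(sim$n, 1e5)
  off <- sim$coords - attr(sim, "centers")[attr(sim, "center_id"), ]
  for (i in 1:3)
    expect_equal(var(off[, i]), pi^2 / (3 * p$b[i]^2), tolerance = 0.05)
})

test_that("fit recovers concentrations and prefers the optimum to the truth", {
  box <- domain_box(c(0, 0, 0), c(500, 500, 500))
  p <- nhpp_params(1.5, c(0.05, 0.05, 0.2))
  cl <- nhpp_simulate(660, p, box, seed = 42)
  fit <- nhpp_fit(cl, box, seed = 42)
  expect_true(fit$converged)
  expect_gt(fit$params$b[3] / fit$params$b[1], 1)  # anisotropy ordering
  expect_lt(abs(fit$params$b[3] - p$b[3]) / p$b[3], 0.35)
  expect_gte(fit$loglik, nhpp_loglik(cl, p, box) - 1e-6)
  # isotropic data: x and y concentrations agree within 25 %
  iso <- nhpp_simulate(400, nhpp_params(1.5, c(0.1, 0.1, 0.1)),
                       domain_box(c(0, 0, 0), c(300, 300, 300)), seed = 1)
  fi <- nhpp_fit(iso, domain_box(c(0, 0, 0), c(300, 300, 300)), seed = 1)
  expect_lt(abs(fi$params$b[1] - fi$params$b[2]) / fi$params$b[1], 0.25)
})

test_that("stretching a cloud along an axis lowers that concentration", {
  box <- domain_box(c(0, 0, 0), c(300, 300, 300))
  base <- nhpp_simulate(300, nhpp_params(1.5, c(0.1, 0.1, 0.1)), box,
                        seed = 31)
  prev <- Inf
  for (stretch in c(2, 4)) {
    st <- point_cloud(base$coords %*% diag(c(stretch, 1, 1)))
    fs <- nhpp_fit(st, domain_box(c(0, 0, 0), c(300 * stretch, 300, 300)),
                   seed = 31)
    expect_lt(fs$params$b[1], fs$params$b[2])
    expect_lt(fs$params$b[1], fs$params$b[3])
    expect_lt(fs$params$b[1], prev)
    prev <- fs$params$b[1]
  }
})

test_that("fold-change extraction uses reciprocals for directionality", {
  mk_grid <- function(a_A, a_B, bx_A, bx_B) {
    blocks <- data.frame(block = 1:2, x_lo = 0, y_lo = 0, z_lo = 0,
                         n_A = 100, n_B = 100, region_id = 1:2,
                         evaluable = TRUE,
                         a_A = a_A, bx_A = bx_A, by_A = 1, bz_A = 1,
                         a_B = a_B, bx_B = bx_B, by_B = 1, bz_B = 1)
    structure(list(box = domain_box(c(0, 0, 0), c(1, 1, 1)),
                   block_edge = 1, blocks = blocks), class = "block_grid")
  }
  g <- mk_grid(a_A = c(3, 1.9), a_B = c(1, 1), bx_A = c(0.5, 1),
               bx_B = c(2, 1))
  expect_identical(unname(extract_changed_blocks(g, "a")), c(TRUE, FALSE))
  # 1/b ratio = (1/0.5)/(1/2) = 4 -> changed
  expect_identical(unname(extract_changed_blocks(g, "inv_b_x")),
                   c(TRUE, FALSE))
  # two-sided flags decreases too
  g2 <- mk_grid(a_A = c(0.25, 1), a_B = c(1, 1), bx_A = c(1, 1),
                bx_B = c(1, 1))
  expect_identical(unname(extract_changed_blocks(g2, "a")), c(FALSE, FALSE))
  expect_identical(unname(extract_changed_blocks(g2, "a", two_sided = TRUE)),
                   c(TRUE, FALSE))
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  ft <- fisher_region_test(rep(c(TRUE, FALSE), c(9, 11)),
                           c(rep(TRUE, 8), FALSE, TRUE, TRUE, rep(FALSE, 9)))
  expect_equal(unname(as.vector(ft$table)), c(8, 2, 1, 9))
  expect_equal(ft$p_value, 920 / 167960, tolerance = 1e-12)

  # exhaustive check over all tables with total <= 12 (acceptance widens this)
  for (n in 0:12) for (A in 0:n) for (B in 0:(n - A)) for (C in 0:(n - A - B)) {
    D <- n - A - B - C
    ch <- rep(c(TRUE, FALSE), c(A + B, C + D))
    ar <- c(rep(TRUE, A), rep(FALSE, B), rep(TRUE, C), rep(FALSE, D))
    expect_equal(fisher_region_test(ch, ar)$p_value,
                 fisher_enum_oracle(A, B, C, D), tolerance = 1e-9)
  }

  expect_equal(fisher_region_test(rep(FALSE, 10),
                                  rep(c(TRUE, FALSE), 5))$p_value, 1)
  # symmetry under simultaneous row and column swap
  p1 <- fisher_region_test(rep(c(TRUE, FALSE), c(5, 7)),
                           rep(c(TRUE, FALSE), 6))$p_value
  p2 <- fisher_region_test(rep(c(FALSE, TRUE), c(5, 7)),
                           rep(c(FALSE, TRUE), 6))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(fisher_region_test(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("block fitting tiles the box and respects the point threshold", {
  box <- domain_box(c(0, 0, 0), c(200, 200, 200))
  p <- nhpp_params(1.5, c(0.1, 0.1, 0.1))
  a <- nhpp_simulate(80, p, box, seed = 1)
  b <- nhpp_simulate(80, p, box, seed = 2)

  whole <- fit_blocks(a, b, box, block_edge = 200, min_points = 50,
                      n_starts = 2)
  expect_equal(nrow(whole$blocks), 1)
  expect_true(whole$blocks$evaluable)
  direct <- nhpp_fit(a, box, n_starts = 2)
  expect_equal(whole$blocks$a_A, direct$params$a, tolerance = 1e-6)

  none <- fit_blocks(a, b, box, block_edge = 200, min_points = 1e6)
  expect_false(any(none$blocks$evaluable))

  tiled <- fit_blocks(subsample_points(a, 30, 1), subsample_points(b, 30, 1),
                      box, block_edge = 100, min_points = 1e6)
  expect_equal(nrow(tiled$blocks), 8)
  expect_equal(sum(rep(100^3, 8)), prod(box$hi - box$lo))
  # every point lands in exactly one block
  expect_equal(sum(tiled$blocks$n_A), 30)
})
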