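test_that("TIFF and CSV volume round-trips are value-identical", {
  v <- volume_stack(array(runif(4 * 2 * 2), c(4, 2, 2)), spacing = c(1, 1, 1))
  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, tf)
  v2 <- read_volume(tf, spacing = c(1, 1, 1))
  expect_equal(dim(v2$values), c(4, 2, 2))
  expect_equal(v2$values, v$values, tolerance = 1e-7)

  zeros <- volume_stack(array(0, c(4, 2, 2)))
  write_volume(zeros, tf)
  expect_equal(read_volume(tf, spacing = c(1, 1, 1))$values, zeros$values)

  cf <- withr::local_tempfile(fileext = ".csv")
  u <- volume_stack(array(0.7, c(10, 10, 10)))
  write_volume(u, cf)
  u2 <- read_volume(cf, spacing = c(1, 1, 1))
  expect_equal(range(u2$values), c(0.7, 0.7))
  expect_identical(u2$values, u$values)
})

test_that("read_volume defaults spacing with a warning and rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".tif")
  write_volume(volume_stack(array(0.5, c(2, 2, 2))), tf)
  expect_warning(read_volume(tf), "spacing")
  expect_error(read_volume("no/such/file.tif"), "not found")
  cf <- withr::local_tempfile(fileext = ".csv")
  writeLines("z,y,x,value\n0,0,0,apple", cf)
  expect_error(read_volume(cf, spacing = c(1, 1, 1)), "non-numeric")
})

test_that("thresholding counts voxels at the cutoff and is monotone", {
  vals <- array(0.1, c(2, 2, 2))
  vals[c(1, 4, 7)] <- 0.9
  v <- volume_stack(vals)
  expect_equal(threshold_to_points(v, 0.5)$n, 3)
  expect_equal(threshold_to_points(v, 0)$n, 8)

  u <- volume_stack(array(0.7, c(10, 10, 10)))
  expect_equal(threshold_to_points(u, 0.5)$n, 1000)
  expect_equal(threshold_to_points(u, 0.9)$n, 0)

  # monotone: higher threshold keeps a subset
  set.seed(42)
  w <- volume_stack(array(runif(125), c(5, 5, 5)))
  for (pair in list(c(0.2, 0.6), c(0.5, 0.9))) {
    lo <- threshold_to_points(w, pair[1])$coords
    hi <- threshold_to_points(w, pair[2])$coords
    expect_true(all(apply(hi, 1, function(p)
      any(colSums(abs(t(lo) - p)) < 1e-12))))
  }
})

test_that("voxel-centre coordinates round-trip through the index grid", {
  sp <- c(6.45, 6.45, 10)
  v <- volume_stack(array(1, c(3, 4, 5)), spacing = sp)
  cl <- threshold_to_points(v, 0.5)
  idx <- floor(sweep(cl$coords, 2, sp, "/"))  # back to 0-based indices
  expect_true(all(idx[, 1] %in% 0:4 & idx[, 2] %in% 0:3 & idx[, 3] %in% 0:2))
  expect_equal(nrow(unique(idx)), 60)
  # centre placement: first voxel centre is spacing / 2
  expect_true(any(apply(cl$coords, 1, function(p)
    isTRUE(all.equal(unname(p), sp / 2)))))
})

test_that("region labels attach by floor(coord / spacing) with bounds checks", {
  lv <- label_volume(array(7L, c(3, 3, 3)), spacing = c(1, 1, 1))
  cl <- point_cloud(rbind(c(1.5, 1.5, 1.5)))
  expect_identical(attach_region_labels(cl, lv)$region_id, 7L)

  split <- array(3L, c(2, 2, 4))
  split[, , 3:4] <- 5L  # x >= 2 um gets label 5
  lv2 <- label_volume(split, spacing = c(1, 1, 1))
  cl2 <- point_cloud(rbind(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5)))
  expect_identical(attach_region_labels(cl2, lv2)$region_id, c(3L, 5L))

  cl3 <- point_cloud(rbind(c(10, 0.5, 0.5)))
  expect_error(attach_region_labels(cl3, lv2), "point 1")
})

test_that("volume metric multiplies counts by voxel volume and is additive", {
  cl <- point_cloud(matrix(runif(300), 100, 3))
  m <- volume_metric(cl, spacing = c(10, 10, 10))
  expect_identical(m$voxel_count, 100L)
  expect_equal(m$physical_volume, 1e5)

  empty <- point_cloud(matrix(numeric(0), 0, 3))
  m0 <- volume_metric(empty, spacing = c(1, 1, 1))
  expect_identical(m0$voxel_count, 0L)
  expect_equal(m0$physical_volume, 0)

  m3 <- volume_metric(point_cloud(matrix(runif(9), 3, 3)),
                      spacing = c(6.45, 6.45, 10))
  expect_equal(m3$physical_volume, 3 * 6.45 * 6.45 * 10)

  a <- point_cloud(matrix(runif(30), 10, 3))
  b <- point_cloud(matrix(runif(60) + 5, 20, 3))
  both <- point_cloud(rbind(a$coords, b$coords))
  expect_equal(volume_metric(both, spacing = c(2, 3, 4))$physical_volume,
               volume_metric(a, spacing = c(2, 3, 4))$physical_volume +
                 volume_metric(b, spacing = c(2, 3, 4))$physical_volume)
})

test_that("subsampling is deterministic, size-capped and a subset", {
  cl <- point_cloud(matrix(runif(3000), 1000, 3))
  expect_identical(subsample_points(cl, 1000, seed = 1), cl)
  s1 <- subsample_points(cl, 100, seed = 5)
  s2 <- subsample_points(cl, 100, seed = 5)
  expect_identical(s1$coords, s2$coords)
  expect_equal(s1$n, 100)
  key <- function(m) apply(m, 1, paste, collapse = "|")
  expect_true(all(key(s1$coords) %in% key(cl$coords)))
})

test_that("point cloud CSV round-trips with labels and channel", {
  cl <- point_cloud(matrix(runif(30), 10, 3), region_id = rep(1:2, 5),
                    channel = "VEcad")
  f <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(cl, f)
  cl2 <- read_point_cloud(f)
  expect_equal(cl2$coords, cl$coords, ignore_attr = TRUE)
  expect_identical(cl2$region_id, cl$region_id)
  expect_identical(cl2$channel, "VEcad")

  empty <- point_cloud(matrix(numeric(0), 0, 3))
  write_point_cloud(empty, f)
  expect_equal(read_point_cloud(f)$n, 0)
})
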