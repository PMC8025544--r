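test_that("image_volume validates its inputs", {
  expect_s3_class(image_volume(array(0, c(2, 3, 4)), c(1, 1, 2)),
                  "image_volume")
  expect_error(image_volume(array(0, c(2, 3)), c(1, 1, 1)))
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)))
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 0, 1)))
})

test_that("voxel centres and axis coordinates agree with the affine", {
  v <- image_volume(array(0, c(3, 4, 5)), c(2, 1, 3), origin = c(-1, 5, 2))
  ax <- sctval:::axis_coords(v)
  expect_equal(ax[[1]], -1 + (0:2) * 2)
  expect_equal(ax[[3]], 2 + (0:4) * 3)
  ctr <- sctval:::voxel_centers(v)
  expect_equal(nrow(ctr), 3 * 4 * 5)
  # column-major: first index varies fastest
  expect_equal(ctr[2, ], c(-1 + 2, 5, 2))
  expect_equal(ctr[3 * 4 * 5, ], c(-1 + 4, 5 + 3, 2 + 12))
})

test_that("threshold_mask implements lower <= HU < upper with exclusion", {
  v <- tiny_vol(array(c(-1000, 249, 250, 251, 1000, 40, 250, -900),
                      c(2, 2, 2)))
  m <- threshold_mask(v, mask_rule(250))
  expect_equal(sum(m$values), 4L)  # 250, 251, 1000, 250
  m2 <- threshold_mask(v, mask_rule(250, 1000))   # upper exclusive
  expect_equal(sum(m2$values), 3L)
  excl <- binary_mask(array(v$values >= 1000, c(2, 2, 2)), v$spacing,
                      v$origin)
  m3 <- threshold_mask(v, mask_rule(250, exclusion = excl))
  expect_equal(sum(m3$values), 3L)
  # monotone: loosening the lower bound never removes voxels
  m_loose <- threshold_mask(v, mask_rule(0))
  expect_true(all(m_loose$values[m$values]))
})

test_that("dilate_mask respects the physical radius and anisotropy", {
  arr <- array(FALSE, c(11, 11, 11))
  arr[6, 6, 6] <- TRUE
  m <- binary_mask(arr, c(1, 1, 1), origin = c(-5, -5, -5))
  d <- dilate_mask(m, 2)
  ctr <- sctval:::voxel_centers(m)
  expect_equal(as.logical(d$values), rowSums(ctr^2) <= 4)
  # anisotropic spacing: 2 mm radius reaches 2 voxels along x (1 mm) but
  # only 1 along z (2 mm)
  ma <- binary_mask(arr, c(1, 1, 2), origin = c(0, 0, 0))
  da <- dilate_mask(ma, 2)
  expect_true(da$values[4, 6, 6])
  expect_false(da$values[3, 6, 6])
  expect_true(da$values[6, 6, 7])
  expect_false(da$values[6, 6, 8])
  # dilation is extensive and monotone in the radius
  expect_true(all(d$values[m$values]))
  expect_true(all(dilate_mask(m, 3)$values[d$values]))
})

test_that("sphere_mask matches the analytic ball volume", {
  like <- image_volume(array(0, c(40, 40, 40)), c(1, 1, 1),
                       origin = c(-19.5, -19.5, -19.5))
  s <- sphere_mask(like, c(0, 0, 0), 10)
  vol_cc <- sum(s$values) * prod(like$spacing) / 1000
  expect_lt(abs(vol_cc - 4 / 3 * pi * 1000 / 1000) / (4 / 3 * pi), 0.01)
})

test_that("NIfTI round-trip preserves geometry and values", {
  set.seed(7)
  v <- image_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1.5, 2, 2.5),
                    origin = c(-3, 4, -7.5))
  p <- tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  r <- read_volume(p)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-5)
  expect_equal(r$values, v$values, tolerance = 1e-6)  # float32 storage
  m <- binary_mask(array(v$values > 0, dim(v$values)), v$spacing, v$origin)
  pm <- tempfile(fileext = ".nii.gz")
  write_volume(m, pm)
  rm_ <- read_mask(pm)
  expect_identical(rm_$values, m$values)
  unlink(c(p, pm))
})

test_that("resample_volume is exact for identity and integer-voxel shifts", {
  set.seed(1)
  v <- image_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), c(2, 2, 2))
  expect_equal(resample_volume(v)$values, v$values, tolerance = 1e-12)
  # shift by exactly one voxel along x: values move, border takes fill
  sh <- resample_volume(v, rigid_transform(tx = 2), fill = 0)
  expect_equal(sh$values[2:6, , ], v$values[1:5, , ], tolerance = 1e-12)
  expect_true(all(sh$values[1, , ] == 0))
  # HU default fill is -1000
  sh2 <- resample_volume(v, rigid_transform(tx = 2))
  expect_true(all(sh2$values[1, , ] == -1000))
})

test_that("resampling a mask stays boolean and nearest-neighbour", {
  arr <- array(FALSE, c(6, 6, 6)); arr[3, 3, 3] <- TRUE
  m <- binary_mask(arr, c(1, 1, 1))
  r <- resample_volume(m, rigid_transform(tx = 0.4))
  expect_s3_class(r, "binary_mask")
  expect_true(is.logical(r$values))
  expect_equal(sum(r$values), 1L)
  expect_true(r$values[3, 3, 3])
})

test_that("resample against an independent R interpolation oracle", {
  set.seed(42)
  v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(2, 2, 2),
                    origin = c(-7, -7, -7))
  tf <- rigid_transform(0.7, -1.2, 0.4, 4, -3, 7, center = c(1, 0, -2))
  out <- resample_volume(v, tf, fill = 0)
  ctr <- sctval:::voxel_centers(v)
  src <- transform_points(transform_inverse(tf), ctr)
  expect_equal(as.numeric(out$values), interp_r(v, src, fill = 0),
               tolerance = 1e-10)
})
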