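test_that("rotation matrices are orthonormal with det 1", {
  set.seed(2)
  for (i in 1:10) {
    a <- runif(3, -180, 180)
    R <- sctval:::rot_matrix(a[1], a[2], a[3])
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("angle decomposition inverts the rotation construction", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3, -89, 89)  # away from gimbal lock
    R <- sctval:::rot_matrix(a[1], a[2], a[3])
    expect_equal(sctval:::rot_angles(R), a, tolerance = 1e-10)
  }
})

test_that("angles are wrapped to (-180, 180]", {
  tf <- rigid_transform(rx = 270, ry = -180, rz = 540)
  expect_equal(tf$rx, -90)
  expect_equal(tf$ry, 180)
  expect_equal(tf$rz, 180)
})

test_that("inverse and composition behave as maps on points", {
  set.seed(4)
  pts <- matrix(runif(30, -50, 50), ncol = 3)
  a <- rigid_transform(1, -2, 3, 10, -20, 30, center = c(5, -5, 0))
  b <- rigid_transform(-4, 0.5, 2, -5, 15, -25, center = c(5, -5, 0))
  # inverse undoes the map
  expect_equal(transform_points(transform_inverse(a),
                                transform_points(a, pts)),
               pts, tolerance = 1e-10)
  # compose(a, b) applies b first
  expect_equal(transform_points(transform_compose(a, b), pts),
               transform_points(a, transform_points(b, pts)),
               tolerance = 1e-10)
  # centre mismatch is an error
  expect_error(transform_compose(a, rigid_transform(center = c(0, 0, 1))),
               "centre")
})

test_that("transform_with_center preserves the map exactly", {
  set.seed(5)
  pts <- matrix(runif(30, -50, 50), ncol = 3)
  a <- rigid_transform(1, -2, 3, 10, -20, 30, center = c(5, -5, 0))
  a2 <- transform_with_center(a, c(-12, 7, 3))
  expect_equal(a2$center, c(-12, 7, 3))
  expect_equal(transform_points(a2, pts), transform_points(a, pts),
               tolerance = 1e-10)
  expect_equal(c(a2$rx, a2$ry, a2$rz), c(a$rx, a$ry, a$rz))
})

test_that("registration_delta is antisymmetric and identity-consistent", {
  a <- rigid_transform(1, 2, 3, 4, 5, 6, center = c(1, 1, 1))
  b <- rigid_transform(0.5, -1, 2, -3, 2, 1, center = c(1, 1, 1))
  d_ab <- registration_delta(a, b)
  d_ba <- registration_delta(b, a)
  expect_equal(d_ab$delta, -d_ba$delta)
  expect_equal(unname(registration_delta(a, a)$delta), rep(0, 6))
  # composed form agrees with the map a o b^-1 on points
  pts <- matrix(c(10, -5, 2, 0, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(transform_points(d_ab$composed, pts),
               transform_points(a, transform_points(transform_inverse(b),
                                                    pts)),
               tolerance = 1e-10)
  expect_error(registration_delta(a, rigid_transform(center = c(0, 0, 0))),
               "centre")
})

test_that("transform JSON round-trip is lossless", {
  tf <- rigid_transform(0.123456789, -2, 3, 4.987654321, -5, 6,
                        center = c(1.5, -2.5, 3.5))
  p <- tempfile(fileext = ".json")
  r <- read_transform(write_transform(tf, p))
  expect_equal(transform_params(r), transform_params(tf), tolerance = 1e-12)
  expect_equal(r$center, tf$center)
  unlink(p)
})
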