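test_that("mae_me matches hand-computed values and sign convention", {
  ct <- tiny_vol(array(c(100, 200, 300, 400, 0, 0, 0, 0), c(2, 2, 2)))
  sct <- tiny_vol(array(c(90, 220, 300, 360, 5, -5, 0, 0), c(2, 2, 2)))
  m <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)),
                   c(1, 1, 1))
  r <- mae_me(ct, sct, m)
  expect_equal(r$mae, mean(c(10, 20, 0, 40)))
  expect_equal(r$me, mean(c(-10, 20, 0, -40)))
  expect_equal(r$n_voxels, 4L)
  expect_error(mae_me(ct, sct, binary_mask(array(FALSE, c(2, 2, 2)),
                                           c(1, 1, 1))), "empty")
})

test_that("MAE >= |ME| always (triangle inequality)", {
  set.seed(11)
  for (i in 1:10) {
    ct <- tiny_vol(array(rnorm(27, 0, 100), c(3, 3, 3)))
    sct <- tiny_vol(array(ct$values + rnorm(27, -20, 50), c(3, 3, 3)))
    m <- binary_mask(array(runif(27) < 0.7, c(3, 3, 3)), c(1, 1, 1))
    if (!any(m$values)) next
    r <- mae_me(ct, sct, m)
    expect_gte(r$mae, abs(r$me))
  }
})

test_that("dice matches hand counts, is symmetric, handles empties", {
  a <- binary_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)),
                   c(1, 1, 1))
  b <- binary_mask(array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1)),
                   c(1, 1, 1))
  expect_equal(dice(a, b)$dsc, 2 * 1 / (2 + 2))
  expect_equal(dice(a, b)$dsc, dice(b, a)$dsc)
  expect_equal(dice(a, a)$dsc, 1)
  e <- binary_mask(array(FALSE, c(2, 2, 1)), c(1, 1, 1))
  expect_equal(dice(a, e)$dsc, 0)
  expect_warning(r <- dice(e, e), "empty")
  expect_equal(r$dsc, 1)
  expect_true(r$both_empty)
})

test_that("region_suite uses the body intersection and 250 HU bone", {
  ph <- shared_phantom()
  rs <- region_suite(ph$ct, ph$ct, ph$labels$body, ph$labels$body,
                     ph$labels$brain)
  expect_equal(rs$metrics$mae, rep(0, 3))
  expect_equal(rs$metrics$me, rep(0, 3))
  expect_equal(rs$bone_overlap$dsc, 1)
  expect_setequal(rs$metrics$region, c("body", "brain", "bone"))
  # bone row counts CT voxels at >= 250 HU
  expect_equal(rs$metrics$n_voxels[rs$metrics$region == "bone"],
               sum(ph$ct$values >= 250))
  # shrinking one body contour shrinks the intersection region
  half <- ph$labels$body
  half$values[, , 1:10] <- FALSE
  rs2 <- region_suite(ph$ct, ph$ct, ph$labels$body, half, ph$labels$brain)
  expect_lt(rs2$metrics$n_voxels[rs2$metrics$region == "body"],
            rs$metrics$n_voxels[rs$metrics$region == "body"])
})

test_that("jaw exclusion removes voxels from the bone region only", {
  ph <- shared_phantom()
  excl <- binary_mask(array(FALSE, dim(ph$ct)), ph$ct$spacing, ph$ct$origin)
  excl$values[, , 1:20] <- TRUE
  rs <- region_suite(ph$ct, ph$ct, ph$labels$body, ph$labels$body,
                     ph$labels$brain, jaw_exclusion = excl)
  rs0 <- region_suite(ph$ct, ph$ct, ph$labels$body, ph$labels$body,
                      ph$labels$brain)
  n_bone <- function(x) x$metrics$n_voxels[x$metrics$region == "bone"]
  expect_lt(n_bone(rs), n_bone(rs0))
  expect_equal(rs$metrics$n_voxels[rs$metrics$region == "body"],
               rs0$metrics$n_voxels[rs0$metrics$region == "body"])
})

test_that("the resection VOI is slice-restricted and 10 mm dilated", {
  ph <- shared_phantom()
  # synthetic "resection": a small ball inside the skull shell
  res <- sphere_mask(ph$ct, skull_surface_point(ph$spec, c(0, 1, 0)), 5)
  res$values <- res$values & ph$labels$bone$values
  res <- binary_mask(res$values, res$spacing, res$origin)
  out <- resection_voi_suite(ph$ct, ph$ct, res)
  # VOI contains the dilated region on its slices and nothing elsewhere
  dil <- dilate_mask(res, 10)
  slices <- apply(dil$values, 3, any)
  expect_true(all(out$voi$values[dil$values]))
  expect_false(any(out$voi$values[, , !slices]))
  # identity comparison: zero error, DSC 1
  expect_equal(out$metrics$mae, 0)
  expect_equal(out$bone_overlap$dsc, 1)
  expect_error(resection_voi_suite(ph$ct, ph$ct,
                                   binary_mask(array(FALSE, dim(ph$ct)),
                                               ph$ct$spacing,
                                               ph$ct$origin)),
               "empty")
})
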