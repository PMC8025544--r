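test_that("phantom generation is deterministic and labelled consistently", {
  ph <- shared_phantom()
  ph2 <- generate_head_phantom(phantom_spec())
  expect_identical(ph$ct$values, ph2$ct$values)
  # air / brain+resection / bone / scalp partition the grid
  n <- sum(ph$labels$air$values) + sum(ph$labels$brain$values) +
    sum(ph$labels$resection$values) + sum(ph$labels$bone$values) +
    sum(ph$labels$scalp$values)
  expect_equal(n, prod(dim(ph$ct)))
  # body excludes outside air but contains the internal cavity
  expect_true(all(ph$labels$body$values[ph$labels$bone$values]))
  expect_true(all(ph$labels$body$values[ph$labels$air_cavity$values]))
  # HU means land near the class means (texture noise is zero-mean)
  expect_lt(abs(mean(ph$ct$values[ph$labels$bone$values]) - 1000), 10)
  expect_lt(abs(mean(ph$ct$values[ph$labels$brain$values]) - 40), 2)
})

test_that("resections carve bone to soft tissue on the skull surface", {
  spec <- phantom_spec(resections = list(
    list(center = skull_surface_point(phantom_spec(), c(0, 0, 1)),
         diameter = 20)))
  ph <- generate_head_phantom(spec)
  expect_gt(sum(ph$labels$resection$values), 0)
  # resected voxels are not bone and read soft-tissue HU
  expect_false(any(ph$labels$resection$values & ph$labels$bone$values))
  expect_lt(max(ph$ct$values[ph$labels$resection$values]), 250)
  # off-surface resection centres are rejected
  expect_error(generate_head_phantom(phantom_spec(resections = list(
    list(center = c(0, 0, 0), diameter = 10)))), "surface")
})

test_that("zero perturbation reproduces the CT exactly", {
  ph <- shared_phantom()
  pert <- perturbation_spec(bias = c(air = 0, brain = 0, bone = 0,
                                     scalp = 0),
                            noise_sd = c(air = 0, brain = 0, bone = 0,
                                         scalp = 0))
  sct <- derive_sct(ph, pert)
  expect_equal(sct$values, ph$ct$values, tolerance = 1e-12)
})

test_that("per-class bias is recovered by the mean error", {
  ph <- shared_phantom()
  pert <- perturbation_spec(bias = c(air = 0, brain = 5, bone = -40,
                                     scalp = 0),
                            noise_sd = c(air = 0, brain = 0, bone = 0,
                                         scalp = 0))
  sct <- derive_sct(ph, pert)
  d_bone <- sct$values[ph$labels$bone$values] -
    ph$ct$values[ph$labels$bone$values]
  d_brain <- sct$values[ph$labels$brain$values] -
    ph$ct$values[ph$labels$brain$values]
  expect_equal(unique(round(d_bone, 9)), -40)
  expect_equal(unique(round(d_brain, 9)), 5)
})

test_that("bone thickening near resections adds sCT bone outside CT bone", {
  spec <- phantom_spec(resections = list(
    list(center = skull_surface_point(phantom_spec(), c(0, -1, 0.2)),
         diameter = 20)))
  ph <- generate_head_phantom(spec)
  pert <- perturbation_spec(noise_sd = c(air = 0, brain = 0, bone = 0,
                                         scalp = 0),
                            bone_thickening_near_resection = 3)
  sct <- derive_sct(ph, pert)
  bone_ct <- threshold_mask(ph$ct, mask_rule(250))
  bone_sct <- threshold_mask(sct, mask_rule(250))
  extra <- bone_sct$values & !bone_ct$values
  expect_gt(sum(extra), 0)
  # the extra bone sits near the resection
  near <- dilate_mask(ph$labels$resection, 25)
  expect_true(all(near$values[extra]))
})

test_that("with_seed is deterministic and leaves the global RNG alone", {
  set.seed(123)
  plain <- runif(5)
  set.seed(123)
  x <- sctval:::with_seed(1, rnorm(3))
  expect_equal(runif(5), plain)   # outer stream unaffected
  expect_equal(x, sctval:::with_seed(1, rnorm(3)))
  expect_false(isTRUE(all.equal(x, sctval:::with_seed(2, rnorm(3)))))
})
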