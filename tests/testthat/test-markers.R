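# marker phantom analysis and the ZTE couch-detection check

test_that("the default template is the customary ~1200-marker lattice", {
  tpl <- marker_template()
  expect_equal(nrow(tpl), 1200)
  expect_equal(unname(colMeans(tpl)), c(0, 0, 0))
  d <- as.matrix(dist(tpl[1:30, ]))
  diag(d) <- Inf
  expect_equal(min(d), 20)   # lattice pitch
})

test_that("zero-field markers are recovered at the template positions", {
  tpl <- marker_template(n = c(6, 5, 5), pitch = 20)
  phm <- generate_marker_phantom(tpl, distortion_field = NULL,
                                 noise_sd = 0.02, seed = 61)
  det <- detect_markers(phm$image)
  expect_equal(nrow(det), nrow(tpl))
  an <- match_and_summarize(det, tpl, radial_limit = 1000)
  expect_equal(an$n_unmatched, 0)
  expect_lt(an$max_abs, 0.1)   # centroid noise only
  expect_lt(an$mean_abs, 0.05)
})

test_that("a known constant shift is recovered", {
  tpl <- marker_template(n = c(6, 5, 5), pitch = 20)
  shift <- c(0.8, -0.5, 0.3)
  fld <- function(p) matrix(shift, nrow(p), 3, byrow = TRUE)
  phm <- generate_marker_phantom(tpl, distortion_field = fld,
                                 noise_sd = 0.02, seed = 62)
  an <- match_and_summarize(detect_markers(phm$image), tpl,
                            radial_limit = 1000)
  mean_d <- colMeans(as.matrix(an$pairs[, c("dx", "dy", "dz")]))
  expect_equal(unname(mean_d), shift, tolerance = 0.05)
  expect_lt(abs(an$mean_abs - sqrt(sum(shift^2))), 0.1)
})

test_that("the radial limit restricts the summary statistics", {
  tpl <- marker_template(n = c(6, 5, 5), pitch = 20)
  # distortion grows with radius: outer markers move 1 mm, inner none
  fld <- function(p) {
    r <- sqrt(rowSums(p^2))
    sweep(p, 1, ifelse(r > 0, pmin(r / 50, 1) / pmax(r, 1e-9), 0), "*")
  }
  phm <- generate_marker_phantom(tpl, distortion_field = fld,
                                 noise_sd = 0.01, seed = 63)
  det <- detect_markers(phm$image)
  inner <- match_and_summarize(det, tpl, radial_limit = 30)
  outer <- match_and_summarize(det, tpl, radial_limit = 1000)
  expect_lt(inner$mean_abs, outer$mean_abs)
  # the pairs table itself keeps all matches; only the summaries restrict
  expect_equal(nrow(inner$pairs), nrow(outer$pairs))
})

test_that("detect_markers handles blank images and weak components", {
  blank <- image_volume(array(0, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(nrow(detect_markers(blank, threshold = 0.5)), 0)
  # a single bright voxel is dropped by min_voxels
  one <- blank; one$values[5, 5, 5] <- 1
  expect_equal(nrow(detect_markers(one, threshold = 0.5, min_voxels = 4)),
               0)
  expect_equal(nrow(detect_markers(one, threshold = 0.5, min_voxels = 1)),
               1)
})

test_that("the couch top is found at the configured position", {
  ph <- shared_phantom()
  zte <- generate_zte_couch_image(ph, couch_y_top = 96, snr = 5,
                                  seed = 64)$image
  res <- detect_couch_top(zte)
  expect_true(res$found)
  expect_lt(abs(res$y_mm - 96), max(zte$spacing))
  expect_gte(res$support, 0.5)
})

test_that("no couch means no detection", {
  ph <- shared_phantom()
  zte <- generate_zte_couch_image(ph, couch_y_top = 96, snr = 5,
                                  seed = 65)$image
  # strip the couch rows, keep the noise floor
  cut <- which(sctval:::axis_coords(zte)[[2]] > 90)
  zte$values[, cut, ] <- abs(rnorm(length(zte$values[, cut, ]), 0, 0.12))
  res <- detect_couch_top(zte)
  expect_false(res$found)
})
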