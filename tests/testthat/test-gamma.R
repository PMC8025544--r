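mk_dose <- function(vals, spacing = c(3, 3, 3))
  image_volume(array(vals, c(9, 9, 9)), spacing, unit = "Gy")

test_that("identical doses give gamma 0 and pass rate 100", {
  set.seed(41)
  d <- mk_dose(runif(729, 0, 30))
  g <- gamma_3d(d, d, gamma_criteria(3, 3), prescription = 30)
  expect_equal(g$pass_rate, 100)
  expect_equal(max(g$gamma$values[g$eval_mask$values]), 0)
  # cutoff: only voxels >= 15% of prescription are evaluated
  expect_equal(g$n_evaluated, sum(d$values >= 0.15 * 30))
})

test_that("a uniform dose offset below tolerance passes, above fails", {
  d <- mk_dose(rep(30, 729))
  up <- mk_dose(rep(30 + 0.02 * 30, 729))   # 2% of prescription
  g <- gamma_3d(d, up, gamma_criteria(3, 3), prescription = 30)
  expect_equal(g$pass_rate, 100)
  # 3.5% offset exceeds 3%/3mm everywhere (uniform, so DTA cannot help)
  up2 <- mk_dose(rep(30 + 0.035 * 30, 729))
  g2 <- gamma_3d(d, up2, gamma_criteria(3, 3), prescription = 30)
  expect_equal(g2$pass_rate, 0)
  expect_equal(unique(round(g2$gamma$values[g2$eval_mask$values], 9)),
               round(0.035 / 0.03, 9))
})

test_that("optimized gamma agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:3) {
    ref <- mk_dose(pmax(0, 20 + 6 * rnorm(729)))
    evl <- mk_dose(pmax(0, ref$values + rnorm(729, 0, 1.5)))
    g <- gamma_3d(ref, evl, gamma_criteria(3, 3), prescription = 20)
    o <- gamma_brute(ref, evl, 3, 3, 15, prescription = 20)
    sel <- g$eval_mask$values
    expect_equal(as.logical(sel), as.logical(o$eval_mask))
    expect_lt(max(abs(g$gamma$values[sel] - o$gamma[sel])), 1e-6)
  }
})

test_that("pass rate is monotone when criteria loosen", {
  set.seed(43)
  ref <- mk_dose(pmax(0, 20 + 5 * rnorm(729)))
  evl <- mk_dose(pmax(0, ref$values + rnorm(729, 0, 1)))
  p <- vapply(list(gamma_criteria(1, 1), gamma_criteria(2, 2),
                   gamma_criteria(3, 3)),
              function(cr) gamma_3d(ref, evl, cr,
                                    prescription = 20)$pass_rate,
              numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("restriction masks and normalization modes behave", {
  set.seed(44)
  ref <- mk_dose(pmax(0, 20 + 5 * rnorm(729)))
  evl <- mk_dose(pmax(0, ref$values + rnorm(729, 0, 1)))
  m <- binary_mask(array(rep(c(TRUE, FALSE), length.out = 729), c(9, 9, 9)),
                   ref$spacing)
  g <- gamma_3d(ref, evl, gamma_criteria(2, 2), prescription = 20,
                restriction = m)
  expect_true(all(is.na(g$gamma$values[!m$values])))
  expect_equal(g$n_evaluated, sum(m$values & ref$values >= 3))
  # global-max normalization needs no prescription
  gm <- gamma_3d(ref, evl, gamma_criteria(2, 2,
                                          normalization = "global-max"))
  expect_equal(gm$norm_dose, max(ref$values))
  expect_error(gamma_3d(ref, evl, gamma_criteria(2, 2)), "> 0")
})

test_that("criteria validation rejects nonsense", {
  expect_error(gamma_criteria(0, 3))
  expect_error(gamma_criteria(3, 0))
  expect_error(gamma_criteria(3, 3, cutoff = 100))
  expect_error(gamma_criteria(3, 3, cutoff = -1))
})
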