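test_that("the default case table describes the 20-case cohort", {
  tb <- default_case_table()
  expect_equal(nrow(tb), 20)
  expect_equal(sum(tb$resected), 14)
  expect_true(all(tb$prescription >= 24 & tb$prescription <= 60))
  expect_true(all(tb$ptv_cc >= 2 & tb$ptv_cc <= 448))
  expect_true(all(is.na(tb$resection_d[!tb$resected])))
  expect_true(all(tb$resection_d[tb$resected] %in% c(10, 20, 30)))
})

test_that("case simulation is deterministic and reproducible", {
  spec <- cohort_spec(seed = 7)
  a <- simulate_case(spec, 2, with_dose = FALSE, with_b0 = FALSE)
  b <- simulate_case(spec, 2, with_dose = FALSE, with_b0 = FALSE)
  expect_identical(a$phantom$ct$values, b$phantom$ct$values)
  expect_identical(a$sct$values, b$sct$values)
  # different case index, different phantom
  c3 <- simulate_case(spec, 3, with_dose = FALSE, with_b0 = FALSE)
  expect_false(identical(a$phantom$ct$values, c3$phantom$ct$values))
})

test_that("simulated PTVs approximate the tabulated volumes", {
  spec <- cohort_spec(seed = 7)
  for (i in c(3, 10)) {   # small PTVs keep this cheap
    cs <- simulate_case(spec, i, with_dose = FALSE, with_b0 = FALSE)
    cc <- sum(cs$ptv$values) * prod(cs$ptv$spacing) / 1000
    expect_lt(abs(cc - spec$cases$ptv_cc[i]) /
                max(spec$cases$ptv_cc[i], 5), 0.35)
    expect_true(all(cs$phantom$labels$body$values[cs$ptv$values]))
  }
})

test_that("resected cases carry a resection, intact cases do not", {
  spec <- cohort_spec(seed = 7)
  rs <- simulate_case(spec, 2, with_dose = FALSE, with_b0 = FALSE)
  expect_gt(sum(rs$phantom$labels$resection$values), 0)
  intact <- which(!spec$cases$resected)[1]
  ni <- simulate_case(spec, intact, with_dose = FALSE, with_b0 = FALSE)
  expect_equal(sum(ni$phantom$labels$resection$values), 0)
})

test_that("a small pipeline run has the expected structure", {
  spec <- cohort_spec(seed = 11)
  rep <- run_pipeline(spec, cases = c(3, 10),
                      registration_cases = integer(0), progress = FALSE)
  expect_s3_class(rep$hu, "tbl_df")
  expect_setequal(unique(rep$hu$region), c("body", "brain", "bone"))
  expect_equal(sort(unique(rep$hu$case)), c(3, 10))
  expect_setequal(unique(rep$gamma$criteria),
                  c("3%/3mm", "2%/2mm", "1%/1mm"))
  expect_true(all(rep$gamma$pass_rate >= 0 & rep$gamma$pass_rate <= 100))
  expect_true(all(c("mae_body", "me_bone", "dsc_bone") %in%
                    names(rep$summary)))
  expect_null(rep$reg_delta)
  # resected case 3 has a VOI row, intact case 10 does not
  expect_equal(rep$voi$case, 3)
  # bone underestimation shows up with the default -40 HU bias
  expect_lt(rep$summary$me_bone$mean, -20)
  expect_s3_class(rep$tests$resected_vs_not, "rank_sum_result")
})

test_that("report writing produces the CSV set and manifest", {
  spec <- cohort_spec(seed = 11)
  rep <- run_pipeline(spec, cases = c(3, 10),
                      registration_cases = integer(0), progress = FALSE)
  dir <- file.path(tempdir(), "sctval-report-test")
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "hu_metrics.csv")))
  expect_true(file.exists(file.path(dir, "gamma_pass_rates.csv")))
  expect_true(file.exists(file.path(dir, "cohort_summary.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  hu <- read.csv(file.path(dir, "hu_metrics.csv"))
  expect_equal(nrow(hu), nrow(rep$hu))
  unlink(dir, recursive = TRUE)
})
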