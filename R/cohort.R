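# Cohort simulation and end-to-end pipeline orchestration. The default
# cohort mirrors the clinical population the toolkit is meant to validate
# against: 20 cases, 14 with skull-bone resection, prescriptions 24-60 Gy,
# PTV volumes 2-448 cc, seven cases flagged as having targets in complex
# regions. Everything is a pure function of (spec, seed).

# per-case table of the default cohort (prescription Gy, PTV cc, resection
# max diameter mm, complex-region flag)
default_case_table <- function() {
  tibble::tibble(
    case = 1:20,
    prescription = c(25, 34, 30, 30, 40.05, 40.05, 40.05, 30, 30, 30,
                     60, 34, 24, 60, 60, 60, 30, 25, 30, 30),
    ptv_cc = c(31, 408, 5, 10, 181, 448, 186, 21, 41, 2,
               439, 314, 63, 179, 168, 430, 16, 318, 21, 25),
    resected = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                 TRUE, FALSE),
    resection_d = c(NA, 10, 10, 10, 10, 10, 10, 20, NA, NA,
                    10, 10, NA, 10, 10, 30, NA, 10, 10, NA),
    complex = c(1:20) %in% c(2, 6, 8, 11, 14, 16, 18)
  )
}

#' Cohort simulation specification
#'
#' @param cases per-case tibble (columns case, prescription, ptv_cc,
#'   resected, resection_d, complex); the default reproduces the standard
#'   20-case population (14 resected).
#' @param seed master seed; all per-case seeds derive from it.
#' @param bone_bias configured sCT bone HU bias (negative: bone
#'   underestimation).
#' @param bone_noise_sd sCT bone noise SD, HU.
#' @param brain_noise_sd sCT brain/soft-tissue noise SD, HU.
#' @param thickening_mm sCT bone-thickening ring width near resections, mm.
#' @param grid_dim,grid_spacing phantom grid.
#' @param b0_background,b0_cavity B0-map amplitudes, Hz.
#' @param cbct_noise_sd additive HU noise of the simulated setup CBCT.
#' @param cbct_offset true rigid offset applied to the simulated CBCT
#'   (a [rigid_transform()]).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(cases = default_case_table(), seed = 42L,
                        bone_bias = -40, bone_noise_sd = 200,
                        brain_noise_sd = 12, thickening_mm = 2,
                        grid_dim = c(64, 80, 64), grid_spacing = c(3, 3, 3),
                        b0_background = 60, b0_cavity = 600,
                        cbct_noise_sd = 40,
                        cbct_offset = rigid_transform(2, -1.5, 1, 0.8,
                                                      -0.5, 1.2)) {
  structure(list(cases = cases, seed = seed, bone_bias = bone_bias,
                 bone_noise_sd = bone_noise_sd,
                 brain_noise_sd = brain_noise_sd,
                 thickening_mm = thickening_mm, grid_dim = grid_dim,
                 grid_spacing = grid_spacing, b0_background = b0_background,
                 b0_cavity = b0_cavity, cbct_noise_sd = cbct_noise_sd,
                 cbct_offset = cbct_offset),
            class = "cohort_spec")
}

# deterministic per-case seed, kept well below 2^31
case_seed <- function(spec, i, salt = 0L) {
  (as.integer(spec$seed) %% 100000L) * 10000L + i * 10L + salt
}

#' Simulate one cohort case
#'
#' Generates the head phantom (with the case's resections), the perturbed
#' sCT, the B0 map, the PTV mask and the dose grids on CT and sCT.
#'
#' @param spec a [cohort_spec()].
#' @param i case index (row of `spec$cases`).
#' @param with_dose,with_b0 switch heavier products off when not needed.
#' @return A `cohort_case` list: `case` (row), `phantom`, `sct`, `ptv`,
#'   `dose_ct`, `dose_sct`, `b0`, `dose_spec`.
#' @export
simulate_case <- function(spec, i, with_dose = TRUE, with_b0 = TRUE) {
  row <- spec$cases[i, ]
  sd_i <- case_seed(spec, i)
  jit <- with_seed(sd_i + 1L, stats::runif(3, -0.04, 0.04))
  radii <- c(72, 88, 80) * (1 + jit)
  ps <- phantom_spec(head_radii = radii, grid_dim = spec$grid_dim,
                     grid_spacing = spec$grid_spacing, seed = sd_i + 2L)
  if (isTRUE(row$resected)) {
    dir <- with_seed(sd_i + 3L, {
      u <- stats::rnorm(3)
      u[3] <- -abs(u[3]) * 0.8   # keep defects cranial
      u / sqrt(sum(u^2))
    })
    ps$resections <- list(list(center = skull_surface_point(ps, dir),
                               diameter = row$resection_d))
  }
  phantom <- generate_head_phantom(ps)

  pert <- perturbation_spec(
    bias = c(air = 0, brain = 1, bone = spec$bone_bias, scalp = 2),
    noise_sd = c(air = 2, brain = spec$brain_noise_sd,
                 bone = spec$bone_noise_sd, scalp = 20),
    bone_thickening_near_resection =
      if (isTRUE(row$resected)) spec$thickening_mm else 0,
    seed = sd_i + 4L)
  sct <- derive_sct(phantom, pert)

  # PTV: sphere of the tabulated volume placed inside the brain
  r_ptv <- (3 * row$ptv_cc * 1000 / (4 * pi))^(1 / 3)
  r_brain <- radii - ps$scalp_thickness - ps$skull_thickness
  room <- pmax(r_brain - r_ptv - 3, 0)
  off <- with_seed(sd_i + 5L, stats::runif(3, -1, 1) * room * 0.5)
  ctr <- voxel_centers(phantom$ct)
  dd <- (ctr[, 1] - off[1])^2 + (ctr[, 2] - off[2])^2 +
    (ctr[, 3] - off[3])^2
  ptv <- binary_mask(array(dd <= r_ptv^2, dim(phantom$ct$values)),
                     phantom$ct$spacing, phantom$ct$origin)

  dspec <- NULL; dose_ct <- NULL; dose_sct <- NULL
  if (with_dose) {
    dspec <- dose_spec(row$prescription, ptv)
    dose_ct <- generate_dose(phantom$ct, dspec)
    dose_sct <- generate_dose(sct, dspec)
  }
  b0 <- if (with_b0)
    generate_b0_map(phantom, spec$b0_background, spec$b0_cavity,
                    seed = sd_i + 6L) else NULL

  structure(list(case = row, phantom = phantom, sct = sct, ptv = ptv,
                 dose_ct = dose_ct, dose_sct = dose_sct, b0 = b0,
                 dose_spec = dspec),
            class = "cohort_case")
}

#' Write a simulated cohort to NIfTI files
#'
#' Per-case volumes (ct, sct, dose_ct, dose_sct, b0, ptv and label masks)
#' plus a JSON manifest with seeds and case parameters.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @param cases case indices; default all.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(spec, dir, cases = seq_len(nrow(spec$cases))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in cases) {
    cs <- simulate_case(spec, i)
    cd <- file.path(dir, sprintf("case%02d", i))
    dir.create(cd, showWarnings = FALSE)
    write_volume(cs$phantom$ct, file.path(cd, "ct.nii.gz"))
    write_volume(cs$sct, file.path(cd, "sct.nii.gz"))
    write_volume(cs$dose_ct, file.path(cd, "dose_ct.nii.gz"))
    write_volume(cs$dose_sct, file.path(cd, "dose_sct.nii.gz"))
    write_volume(cs$b0, file.path(cd, "b0.nii.gz"))
    write_volume(cs$ptv, file.path(cd, "ptv.nii.gz"))
    for (nm in names(cs$phantom$labels))
      write_volume(cs$phantom$labels[[nm]],
                   file.path(cd, paste0("label_", nm, ".nii.gz")))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = spec$seed, cases = spec$cases[cases, ],
         bone_bias = spec$bone_bias, grid_dim = spec$grid_dim,
         grid_spacing = spec$grid_spacing,
         version = as.character(utils::packageVersion("sctval"))),
    manifest, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Run the full validation pipeline on a simulated cohort
#'
#' Per case: HU region metrics and bone overlap, the post-surgical VOI
#' sub-analysis, B0-derived distortion statistics, DVH endpoint differences
#' and 3D global gamma at 3%/3mm, 2%/2mm and 1%/1mm (15% cut-off; 1%/1mm
#' also restricted to the PTV), and setup-verification registration deltas
#' against a simulated CBCT. Cohort summaries and the rank-sum subgroup
#' comparisons close the report.
#'
#' @param spec a [cohort_spec()].
#' @param cases case indices to run; default all.
#' @param registration_cases subset of `cases` on which the (more costly)
#'   CBCT registration analysis runs; default all of `cases`.
#' @param gamma_criteria list of [gamma_criteria()] for the full-grid
#'   analysis; `NULL` means 3%/3mm, 2%/2mm and 1%/1mm.
#' @param progress print per-case timing to stderr.
#' @return A `pipeline_report` list of tibbles: `hu`, `overlap`, `voi`,
#'   `distortion`, `dvh`, `gamma`, `reg_delta`, plus `summary` (named list
#'   of cohort summaries), `tests` (rank-sum results) and `manifest`.
#' @export
run_pipeline <- function(spec, cases = seq_len(nrow(spec$cases)),
                         registration_cases = cases,
                         gamma_criteria = NULL,
                         progress = TRUE) {
  if (is.null(gamma_criteria))
    gamma_criteria <- list(sctval::gamma_criteria(3, 3),
                           sctval::gamma_criteria(2, 2),
                           sctval::gamma_criteria(1, 1))
  hu <- list(); overlap <- list(); voi <- list(); dist <- list()
  dvh <- list(); gam <- list(); regd <- list()
  for (i in cases) {
    t0 <- Sys.time()
    cs <- simulate_case(spec, i)
    ph <- cs$phantom
    rs <- region_suite(ph$ct, cs$sct, ph$labels$body, ph$labels$body,
                       ph$labels$brain)
    hu[[length(hu) + 1]] <- tibble::tibble(case = i, rs$metrics)
    overlap[[length(overlap) + 1]] <-
      tibble::tibble(case = i, rs$bone_overlap)
    if (isTRUE(cs$case$resected)) {
      vs <- resection_voi_suite(ph$ct, cs$sct, ph$labels$resection)
      voi[[length(voi) + 1]] <- tibble::tibble(
        case = i, vs$metrics[, c("mae", "me", "n_voxels")],
        dsc_voi = vs$bone_overlap$dsc, dsc_skull = rs$bone_overlap$dsc)
    }
    dmap <- b0_to_distortion(cs$b0)
    masks <- list(
      brain = ph$labels$brain,
      bone = threshold_mask(ph$ct, mask_rule(BONE_HU_THRESHOLD)),
      air = binary_mask(ph$ct$values < -900 & ph$labels$body$values,
                        ph$ct$spacing, ph$ct$origin))
    dist[[length(dist) + 1]] <-
      tibble::tibble(case = i, region_distortion_stats(dmap, masks))

    dvh_ct <- compute_dvh(cs$dose_ct, cs$ptv, cs$case$prescription)
    dvh_sct <- compute_dvh(cs$dose_sct, cs$ptv, cs$case$prescription)
    dvh[[length(dvh) + 1]] <-
      tibble::tibble(case = i, dvh_difference(dvh_sct, dvh_ct))
    for (gc in gamma_criteria) {
      gr <- gamma_3d(cs$dose_ct, cs$dose_sct, gc,
                     prescription = cs$case$prescription)
      gam[[length(gam) + 1]] <- tibble::tibble(
        case = i, criteria = sprintf("%g%%/%gmm", gc$dose_tol, gc$dta),
        restricted = "full", pass_rate = gr$pass_rate,
        n_evaluated = gr$n_evaluated)
    }
    gptv <- gamma_3d(cs$dose_ct, cs$dose_sct, gamma_criteria[[
      length(gamma_criteria)]], prescription = cs$case$prescription,
      restriction = cs$ptv)
    gam[[length(gam) + 1]] <- tibble::tibble(
      case = i, criteria = sprintf("%g%%/%gmm",
                                   gamma_criteria[[length(gamma_criteria)]]$dose_tol,
                                   gamma_criteria[[length(gamma_criteria)]]$dta),
      restricted = "PTV", pass_rate = gptv$pass_rate,
      n_evaluated = gptv$n_evaluated)

    if (i %in% registration_cases) {
      cbct <- simulate_cbct(cs, spec)
      box <- head_box(ph$ct)
      # the two registrations must share a rotation centre so their
      # parameter-wise deltas are comparable
      cen <- windowed_centroid(ph$ct, mask_rule(200, 1700), box)
      rspec <- registration_spec(window = mask_rule(200, 1700),
                                 box = box, center = cen)
      r_ct <- rigid_register(ph$ct, cbct, rspec)
      r_sct <- rigid_register(cs$sct, cbct, rspec)
      if (r_ct$status == "converged" && r_sct$status == "converged") {
        dl <- registration_delta(r_sct$transform, r_ct$transform)
        regd[[length(regd) + 1]] <- tibble::tibble(
          case = i, parameter = names(dl$delta), delta = unname(dl$delta),
          unit = c(rep("mm", 3), rep("deg", 3)))
      } else {
        warning("registration failed for case ", i, "; case skipped in ",
                "setup-verification analysis")
      }
    }
    if (progress)
      message(sprintf("case %02d done in %.1f s", i,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  hu <- do.call(rbind, hu); overlap <- do.call(rbind, overlap)
  voi <- if (length(voi)) do.call(rbind, voi) else NULL
  dist <- do.call(rbind, dist); dvh <- do.call(rbind, dvh)
  gam <- do.call(rbind, gam)
  regd <- if (length(regd)) do.call(rbind, regd) else NULL

  summary <- list()
  for (rg in unique(hu$region)) {
    summary[[paste0("mae_", rg)]] <-
      summarize_cohort(hu$mae[hu$region == rg])
    summary[[paste0("me_", rg)]] <- summarize_cohort(hu$me[hu$region == rg])
  }
  summary$dsc_bone <- summarize_cohort(overlap$dsc)
  for (cr in unique(gam$criteria)) {
    for (rk in unique(gam$restricted[gam$criteria == cr])) {
      summary[[paste0("gamma_", cr, "_", rk)]] <-
        summarize_cohort(gam$pass_rate[gam$criteria == cr &
                                         gam$restricted == rk])
    }
  }
  for (ep in unique(dvh$endpoint))
    summary[[paste0("dvh_", ep)]] <-
      summarize_cohort(dvh$diff_pct[dvh$endpoint == ep])

  tests <- list()
  tab <- spec$cases[cases, ]
  dmean <- dvh$diff_pct[dvh$endpoint == "Dmean"]
  names(dmean) <- dvh$case[dvh$endpoint == "Dmean"]
  grp <- function(flag) dmean[as.character(tab$case[flag])]
  if (any(tab$resected) && any(!tab$resected))
    tests$resected_vs_not <- rank_sum_test(grp(tab$resected),
                                           grp(!tab$resected))
  if (any(tab$complex) && any(!tab$complex))
    tests$complex_vs_not <- rank_sum_test(grp(tab$complex),
                                          grp(!tab$complex))

  structure(list(hu = hu, overlap = overlap, voi = voi, distortion = dist,
                 dvh = dvh, gamma = gam, reg_delta = regd,
                 summary = summary, tests = tests,
                 manifest = list(seed = spec$seed, cases = tab,
                                 bone_bias = spec$bone_bias)),
            class = "pipeline_report")
}

# simulated setup CBCT: the CT moved by the spec's true offset plus noise
simulate_cbct <- function(cs, spec) {
  i <- cs$case$case
  tf <- spec$cbct_offset
  tf$center <- c(0, 0, 0)
  moved <- resample_volume(cs$phantom$ct, tf, target = cs$phantom$ct)
  noisy <- moved$values +
    with_seed(case_seed(spec, i, 7L),
              array(stats::rnorm(length(moved$values), 0,
                                 spec$cbct_noise_sd), dim(moved$values)))
  image_volume(noisy, moved$spacing, moved$origin, unit = "HU")
}

#' Write a pipeline report to CSV/JSON files
#'
#' One CSV per table, a summary CSV shaped mean/SD/range per metric, and a
#' JSON manifest (seeds, case table, package version).
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) if (!is.null(df))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  wr(report$hu, "hu_metrics")
  wr(report$overlap, "bone_overlap")
  wr(report$voi, "voi_metrics")
  wr(report$distortion, "distortion")
  wr(report$dvh, "dvh_differences")
  wr(report$gamma, "gamma_pass_rates")
  wr(report$reg_delta, "registration_deltas")
  sm <- do.call(rbind, lapply(names(report$summary), function(nm)
    tibble::tibble(metric = nm, report$summary[[nm]])))
  wr(sm, "cohort_summary")
  tst <- do.call(rbind, lapply(names(report$tests), function(nm)
    tibble::tibble(comparison = nm, tidy(report$tests[[nm]]))))
  wr(tst, "rank_sum_tests")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d cases\n", length(unique(x$hu$case))))
  for (nm in c("mae_body", "me_bone", "dsc_bone")) {
    s <- x$summary[[nm]]
    if (!is.null(s))
      cat(sprintf("  %-10s %.2f +/- %.2f [%.2f, %.2f]\n", nm, s$mean, s$sd,
                  s$min, s$max))
  }
  invisible(x)
}
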