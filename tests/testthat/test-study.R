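# Study orchestration: configuration round-trip, end-to-end determinism,
# artifact manifest, plots.

test_that("the YAML configuration round-trips exactly", {
  cfg <- run_config(seed = 11, flow_lpm = c(15, 30), n_stations = 41,
                    cohort = cohort_spec(n_subjects = 4, seed = 11))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  got <- read_config(path)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(got, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_equal(got$seed, cfg$seed)
  expect_equal(got$cohort$n_subjects, 4)
})

test_that("run_study produces every panel and is reproducible under a seed", {
  cfg <- run_config(seed = 5, cohort = cohort_spec(n_subjects = 5, seed = 5))
  r1 <- run_study(cfg, quiet = TRUE)
  r2 <- run_study(cfg, quiet = TRUE)
  expect_identical(r1$cohort$table, r2$cohort$table)
  expect_identical(tidy(r1), tidy(r2))
  needed <- c("SA_cm2", "CV_cm3", "SAVR_per_cm", "SAVR_middle_per_cm",
              "R_total_15_Pa_s_ml", "R_total_30_Pa_s_ml",
              "R_anterior_15_Pa_s_ml", "R_posterior_30_Pa_s_ml")
  expect_true(all(needed %in% tidy(r1)$metric))

  cfg2 <- run_config(seed = 6, cohort = cohort_spec(n_subjects = 5, seed = 6))
  r3 <- run_study(cfg2, quiet = TRUE)
  expect_identical(names(r3$cohort$table), names(r1$cohort$table))
  expect_false(identical(r3$cohort$table$value_normal,
                         r1$cohort$table$value_normal))
})

test_that("written artifacts are listed in the manifest with stable hashes", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- run_config(seed = 9, cohort = cohort_spec(n_subjects = 3, seed = 9))
  cfg$out_dir <- out1
  m1 <- run_study(cfg, quiet = TRUE)$manifest
  cfg$out_dir <- out2
  m2 <- run_study(cfg, quiet = TRUE)$manifest
  expect_true(all(c("cohort_metrics.csv", "comparison.json") %in% m1$file))
  expect_true(file.exists(file.path(out1, "manifest.csv")))
  ## cohort table hashes identical across reruns (config file differs in
  ## its out_dir line)
  h1 <- m1$md5[m1$file == "cohort_metrics.csv"]
  h2 <- m2$md5[m2$file == "cohort_metrics.csv"]
  expect_identical(h1, h2)
})

test_that("stage failures abort with the stage name", {
  cfg <- run_config(seed = 1, cohort = cohort_spec(n_subjects = 3, seed = 1))
  cfg$cohort$n_subjects <- -1
  expect_error(run_study(cfg, quiet = TRUE), "simulate")
})

test_that("result types have autoplot methods", {
  tube <- make_tube(6, 50, n_rings = 11)
  cl <- extract_centerline(tube, n_stations = 8)
  prof <- profile_geometry(tube, cl, n_stations = 9)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15))
  rp <- resistance_profile(fld, prof)
  expect_s3_class(ggplot2::autoplot(rp), "ggplot")
  sc <- three_duct_scene()
  pt <- regional_partition(sc$field, sc$sections, sc$landmarks)
  expect_s3_class(ggplot2::autoplot(pt), "ggplot")
  co <- generate_cohort(cohort_spec(n_subjects = 4, seed = 2))
  cc <- compare_cohort(co$table)
  expect_s3_class(ggplot2::autoplot(cc), "ggplot")
})

test_that("flow-field CSV tables round-trip", {
  tube <- make_tube(6, 30, n_rings = 7)
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15), n_radial = 4,
                              n_azimuthal = 12)
  stem <- file.path(withr::local_tempdir(), "field")
  write_field_csv(fld, stem)
  got <- read_field_csv(stem)
  expect_equal(got$Q, fld$Q)
  expect_equal(nrow(got$points), nrow(fld$points))
  expect_equal(sum(got$wall$area_m2), sum(fld$wall$area_m2), tolerance = 1e-9)
})
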