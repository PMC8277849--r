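# Cohort generation: determinism, null behaviour, effect direction,
# closed-form vs mesh-pipeline agreement.

test_that("the same master seed reproduces the metric tables bit-identically", {
  a <- generate_cohort(cohort_spec(seed = 42))
  b <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(a$table, b$table)
  c2 <- generate_cohort(cohort_spec(seed = 43))
  expect_false(identical(a$table$value_normal, c2$table$value_normal))
  expect_identical(names(a$table), names(c2$table))
})

test_that("a null cohort has near-zero median paired differences across seeds", {
  null_spec <- cohort_spec(effect_ratio = 1, effect_cv = 0,
                           resistance_effect = 1, noise_cv = 0.03)
  meds <- vapply(1:40, function(s) {
    cs <- null_spec
    cs$seed <- 1000 + s
    tb <- generate_cohort(cs, metrics = "R_total_15")$table
    median(tb$value_normal - tb$value_decongested)
  }, numeric(1))
  typical <- median(abs(meds))
  expect_lt(abs(median(meds)), 3 * typical + 1e-12)
  expect_gt(mean(meds > 0), 0.2)
  expect_gt(mean(meds < 0), 0.2)
})

test_that("the programmed decongestion effect lowers resistance in every subject", {
  co <- generate_cohort(cohort_spec(seed = 7))
  tb <- co$table[co$table$metric == "R_total_15_Pa_s_ml", ]
  expect_true(all(tb$value_decongested < tb$value_normal))
  ## and raises plateau CSA by the programmed ~34.8%
  csa <- co$table[co$table$metric == "CSA_plateau_cm2", ]
  expect_equal(median(csa$value_decongested / csa$value_normal), 1.348,
               tolerance = 0.05)
})

test_that("closed-form and mesh-pipeline engines agree on one subject", {
  spec <- phantom_spec(n_rings = 101, ring_vertices = 48)
  ma <- nasoair:::phantom_metrics_analytic(spec, congestion = 1,
                                           flow_lpm = 15, regional = FALSE)
  mm <- nasoair:::phantom_metrics_mesh(spec, congestion = 1, flow_lpm = 15,
                                       n_stations = 26, regional = FALSE)
  ## volumes and plateau CSA agree tightly; wall areas differ by the mesh's
  ## real slant/junction area, resistance by the discrete d_h profile
  expect_equal(mm$CV_cm3, ma$CV_cm3, tolerance = 0.01)
  expect_equal(mm$CSA_plateau_cm2, ma$CSA_plateau_cm2, tolerance = 0.02)
  expect_equal(mm$SA_cm2, ma$SA_cm2, tolerance = 0.08)
  expect_equal(mm$SAVR_per_cm, ma$SAVR_per_cm, tolerance = 0.08)
  expect_equal(mm$R_total_15_Pa_s_ml, ma$R_total_15_Pa_s_ml, tolerance = 0.10)
})

test_that("cohort comparison reports every panel of the study design", {
  co <- generate_cohort(cohort_spec(seed = 3))
  cc <- compare_cohort(co$table)
  metrics <- tidy(cc)$metric
  expect_true(all(c(
    "SA_cm2", "CV_cm3", "SAVR_per_cm",
    "SAVR_superior_per_cm", "SAVR_middle_per_cm", "SAVR_inferior_per_cm",
    "R_total_15_Pa_s_ml", "R_total_30_Pa_s_ml",
    "R_anterior_15_Pa_s_ml", "R_posterior_15_Pa_s_ml"
  ) %in% metrics))
  g <- glance(cc)
  expect_equal(g$n_metrics, length(metrics))
})

test_that("unpaired subjects are reported by name", {
  co <- generate_cohort(cohort_spec(seed = 3))
  tb <- co$table
  tb$value_decongested[tb$subject == "S03"][1] <- NA
  expect_error(compare_cohort(tb), "S03")
})

test_that("Holm adjustment is available but off by default", {
  co <- generate_cohort(cohort_spec(seed = 3))
  plain <- compare_cohort(co$table)
  holm <- compare_cohort(co$table, adjust = "holm")
  expect_equal(tidy(plain)$p_value, tidy(holm)$p_value)
  expect_true(all(tidy(holm)$p_adjusted >= tidy(holm)$p_value - 1e-15))
})
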