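# Cavity metrics: SA, CV, SAVR, regional clipping, conservation.

test_that("a circular tube has SAVR = 4/d", {
  m <- cavity_metrics(make_tube(6, 50))
  expect_equal(m$SAVR_per_m, 4 / 0.006, tolerance = 1e-3)
  expect_equal(m$SA_m2, pi * 0.006 * 0.05, tolerance = 1e-3)
  expect_equal(m$CV_m3, pi * 0.003^2 * 0.05, tolerance = 1e-3)
})

ph <- make_phantom(phantom_spec(n_rings = 81, ring_vertices = 32))
ph_cl <- extract_centerline(ph, n_stations = 30)
ph_lmk <- place_landmarks(ph_cl, surface = ph)

test_that("vertical thirds conserve SA and CV to 0.1%", {
  m <- cavity_metrics(ph, c("whole", "superior", "middle", "inferior"),
                      landmarks = ph_lmk, centerline = ph_cl)
  whole <- m[m$region == "whole", ]
  parts <- m[m$region != "whole", ]
  expect_equal(sum(parts$SA_m2), whole$SA_m2, tolerance = 1e-3)
  expect_equal(sum(parts$CV_m3), whole$CV_m3, tolerance = 1e-3)
  expect_true(all(m$SAVR_per_m > 0))
})

test_that("anterior and posterior segments partition the pre-PS volume", {
  m <- cavity_metrics(ph, c("anterior", "posterior"),
                      landmarks = ph_lmk, centerline = ph_cl)
  expect_true(all(m$CV_m3 > 0))
  expect_true(all(m$SA_m2 > 0))
  ## anterior (nostril..1V) is shorter than posterior (1V..PS)
  expect_lt(m$CV_m3[m$region == "anterior"], m$CV_m3[m$region == "posterior"])
})

test_that("integrated per-station area matches the divergence-theorem volume", {
  prof <- profile_geometry(ph, ph_cl, n_stations = 101)
  L <- max(ph_cl$s) * 1e-3
  cv_int <- nasoair:::trapz(prof$s_norm * L, prof$area_m2)
  cv_div <- cavity_metrics(ph)$CV_m3
  expect_equal(cv_int, cv_div, tolerance = 0.01)
})

test_that("decongestion lowers SAVR at constant-order surface area", {
  spec <- phantom_spec(n_rings = 81, ring_vertices = 32)
  m1 <- cavity_metrics(make_phantom(spec, congestion = 1))
  m0 <- cavity_metrics(make_phantom(spec, congestion = 0))
  expect_lt(m0$SAVR_per_m, m1$SAVR_per_m)
  expect_gt(m0$CV_m3, m1$CV_m3)
  ## the mucosal area changes far less than the volume
  expect_lt(abs(m0$SA_m2 / m1$SA_m2 - 1), 0.05)
})

test_that("SAVR scales as 1/k under uniform scaling", {
  tube <- make_tube(8, 40)
  big <- airway_surface(tube$vertices * 2, tube$faces, tube$face_label)
  m1 <- cavity_metrics(tube)
  m2 <- cavity_metrics(big)
  expect_equal(m2$SAVR_per_m / m1$SAVR_per_m, 0.5, tolerance = 1e-9)
})

test_that("metrics JSON is written", {
  m <- cavity_metrics(make_tube(6, 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(m, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$SAVR_per_m, m$SAVR_per_m)
})
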