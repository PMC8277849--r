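# Phantom generator: programmed profiles, perimeter preservation,
# determinism, analytic fields.

spec_small <- phantom_spec(n_rings = 81, ring_vertices = 32)

test_that("the emitted mesh realizes the programmed CSA profile", {
  ph <- make_phantom(spec_small)
  cl <- extract_centerline(ph, n_stations = 30)
  prof <- profile_geometry(ph, cl, n_stations = 41)
  truth <- phantom_profile(ph)
  a_t <- approx(truth$s_norm, truth$area_m2, prof$s_norm)$y
  expect_lt(max(abs(prof$area_m2 / a_t - 1)), 0.02)
})

test_that("plateau area morphs with congestion while perimeter is preserved", {
  p1 <- phantom_profile(make_phantom(spec_small, congestion = 1))
  p0 <- phantom_profile(make_phantom(spec_small, congestion = 0))
  sel <- p1$s_norm >= 0.45 & p1$s_norm <= 0.70
  area_ratio <- mean(p0$area_m2[sel]) / mean(p1$area_m2[sel])
  expect_equal(area_ratio, 3.8 / 2.8, tolerance = 0.02)
  per_change <- abs(p0$perimeter_m[sel] / p1$perimeter_m[sel] - 1)
  expect_lt(max(per_change), 0.05)
})

test_that("intermediate congestion interpolates the plateau area", {
  p_half <- phantom_profile(make_phantom(spec_small, congestion = 0.5))
  p1 <- phantom_profile(make_phantom(spec_small, congestion = 1))
  p0 <- phantom_profile(make_phantom(spec_small, congestion = 0))
  sel <- p1$s_norm >= 0.5 & p1$s_norm <= 0.65
  expect_equal(mean(p_half$area_m2[sel]),
               (mean(p1$area_m2[sel]) + mean(p0$area_m2[sel])) / 2,
               tolerance = 0.01)
})

test_that("the same spec yields a bit-identical mesh", {
  a <- make_phantom(spec_small)
  b <- make_phantom(spec_small)
  expect_identical(digest::digest(a$vertices), digest::digest(b$vertices))
  expect_identical(digest::digest(a$faces), digest::digest(b$faces))
})

test_that("analytic fields are flux-consistent and WSS is uniform on a tube", {
  tube <- make_tube(6, 50, n_rings = 21)
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15))
  cl <- extract_centerline(tube, n_stations = 8)
  prof <- profile_geometry(tube, cl, n_stations = 11)
  rp <- resistance_profile(fld, prof)
  rho_q <- fld$props$rho * fld$Q
  expect_lt(max(abs(rp$mdot_kg_s / rho_q - 1)), 0.01)
  ## WSS uniform along a uniform tube
  expect_lt(diff(range(fld$wall$wss)) / mean(fld$wall$wss), 0.02)
  ## wall patch areas integrate to the lateral surface
  expect_equal(sum(fld$wall$area_m2), pi * 0.006 * 0.05, tolerance = 0.01)
})

test_that("phantom flux is conserved through valve, passages and merge", {
  ph <- make_phantom(phantom_spec(n_rings = 81))   # full contour resolution
  cl <- extract_centerline(ph, n_stations = 20)
  prof <- profile_geometry(ph, cl, n_stations = 21)   # aligned with rings
  fld <- assign_analytic_flow(ph, Q = flow_rate_lpm(15))
  rp <- resistance_profile(fld, prof)
  rho_q <- fld$props$rho * fld$Q
  expect_lt(max(abs(rp$mdot_kg_s / rho_q - 1)), 0.01)
})

test_that("foreign meshes are rejected by the analytic field generator", {
  tube <- make_tube(6, 50, n_rings = 5)
  stripped <- airway_surface(tube$vertices, tube$faces, tube$face_label)
  expect_error(assign_analytic_flow(stripped, Q = 1e-4), "parameterization")
})

test_that("infeasible profiles are rejected", {
  expect_error(phantom_spec(valve_csa_cm2 = -1), "positive")
  expect_error(make_tube(function(s) ifelse(s > 0.5, -1, 5), 10), "radius")
})
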