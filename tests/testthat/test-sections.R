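# Cross-section slicing: areas, perimeters, hydraulic diameter, loop counts.

cyl <- make_tube(20, 100, n_rings = 11, ring_vertices = 256)
cyl_cl <- extract_centerline(cyl, n_stations = 10)

test_that("slicing a cylinder recovers the circle formulas", {
  cs <- slice_cross_section(cyl, cyl_cl, 0.5)
  expect_equal(cs$A, pi * 1e-4, tolerance = 2e-4)
  expect_equal(cs$P, 2 * pi * 1e-2, tolerance = 2e-4)
  expect_equal(cs$d_h, 0.02, tolerance = 2e-4)
  expect_length(cs$loops, 1)
})

test_that("an elliptical duct matches the quadrature oracle for the perimeter", {
  ec <- make_ellipse_cylinder(a_mm = 10, b_mm = 5, length_mm = 40)
  cl <- extract_centerline(ec, n_stations = 8)
  cs <- slice_cross_section(ec, cl, 0.5)
  p_oracle <- integrate(function(t) sqrt((10 * sin(t))^2 + (5 * cos(t))^2),
                        0, 2 * pi, rel.tol = 1e-10)$value * 1e-3
  expect_equal(cs$A, pi * 5e-5, tolerance = 5e-3)
  expect_equal(cs$P, p_oracle, tolerance = 5e-3)
  expect_equal(cs$d_h, 4 * cs$A / cs$P, tolerance = 1e-12)
})

test_that("both passages of the phantom are summed bilaterally", {
  ph <- make_phantom(phantom_spec(n_rings = 81, ring_vertices = 32))
  cl <- extract_centerline(ph, n_stations = 30)
  cs <- slice_cross_section(ph, cl, 0.5)
  expect_length(cs$loops, 2)
  expect_equal(cs$A, sum(cs$loop_area_m2), tolerance = 1e-12)
  expect_equal(cs$P, sum(cs$loop_perimeter_m), tolerance = 1e-12)
  ## the two passages are mirror images: equal areas
  expect_equal(cs$loop_area_m2[1], cs$loop_area_m2[2], tolerance = 1e-6)
})

test_that("d_h = 4A/P holds exactly at every station of the profile", {
  prof <- profile_geometry(cyl, cyl_cl, n_stations = 25)
  expect_equal(prof$dh_m, 4 * prof$area_m2 / prof$perimeter_m,
               tolerance = 1e-14)
})

test_that("a uniform tube has a constant profile and n_stations = 2 returns the ends", {
  prof <- profile_geometry(cyl, cyl_cl, n_stations = 25)
  expect_lt(diff(range(prof$area_m2)) / mean(prof$area_m2), 0.005)
  ends <- profile_geometry(cyl, cyl_cl, n_stations = 2)
  expect_equal(nrow(ends), 2)
  expect_equal(ends$s_norm, c(0, 1))
  expect_equal(ends$area_m2, rep(pi * 1e-4, 2), tolerance = 1e-3)
})

test_that("stations outside [0, 1] are rejected", {
  expect_error(slice_cross_section(cyl, cyl_cl, 1.2), "0, 1")
})

test_that("the profile CSV round-trips", {
  prof <- profile_geometry(cyl, cyl_cl, n_stations = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  got <- read_profile_csv(path)
  expect_equal(got$area_m2, prof$area_m2)
  expect_equal(got$n_loops, prof$n_loops)
})

test_that("scaling covariance: A ~ k^2, P ~ k under uniform scaling", {
  k <- 1.7
  big <- airway_surface(cyl$vertices * k, cyl$faces, cyl$face_label)
  cl_big <- extract_centerline(big, n_stations = 10)
  cs1 <- slice_cross_section(cyl, cyl_cl, 0.5)
  cs2 <- slice_cross_section(big, cl_big, 0.5)
  expect_equal(cs2$A / cs1$A, k^2, tolerance = 1e-6)
  expect_equal(cs2$P / cs1$P, k, tolerance = 1e-6)
})
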