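# Flow post-processing: plane integrals, Reynolds, bilateral weighting,
# resistance, regional partitioning.

props <- fluid_properties()

test_that("plane mass flow integrates uniform, parabolic and reversed profiles", {
  cs <- manual_circle_section(10, 20)
  f_uni <- manual_disk_field(10, 20, u_mean = 1, profile = "uniform")
  expect_equal(plane_mass_flow(f_uni, cs), 1.204 * pi * 1e-4, tolerance = 0.01)

  f_poi <- manual_disk_field(10, 20, u_mean = 1, profile = "poiseuille")
  expect_equal(plane_mass_flow(f_poi, cs), 1.204 * pi * 1e-4, tolerance = 0.01)

  f_rev <- f_poi
  f_rev$points$ux <- -f_rev$points$ux
  expect_equal(plane_mass_flow(f_rev, cs), -plane_mass_flow(f_poi, cs),
               tolerance = 1e-12)
})

test_that("plane-averaged total pressure handles static, uniform and parabolic fields", {
  cs <- manual_circle_section(10, 20)
  still <- manual_disk_field(10, 20, u_mean = 0, p = 5, profile = "uniform",
                             Q = 1e-4)
  expect_equal(plane_avg_total_pressure(still, cs), 5, tolerance = 1e-9)

  uni <- manual_disk_field(10, 20, u_mean = 2, profile = "uniform")
  expect_equal(plane_avg_total_pressure(uni, cs), 0.5 * 1.204 * 4,
               tolerance = 0.02)

  ## area mean of (1/2) rho u^2 for a parabolic profile is (2/3) rho u_mean^2
  poi <- manual_disk_field(10, 20, u_mean = 2, profile = "poiseuille")
  expect_equal(plane_avg_total_pressure(poi, cs), (2 / 3) * 1.204 * 4,
               tolerance = 0.02)
})

test_that("a plane with no nearby samples errors", {
  cs <- manual_circle_section(10, 500)
  f <- manual_disk_field(10, 20, u_mean = 1)
  f$points <- f$points[1:4, ]
  expect_error(plane_mass_flow(f, cs), "not covered")
})

test_that("Reynolds number follows Re = 4 rho Q / (mu P)", {
  pr <- fluid_properties(rho = 1.2, mu = 1.8e-5)
  expect_equal(reynolds_number(2.5e-4, 0.08, pr), 833.3, tolerance = 1e-3)
  expect_equal(reynolds_number(2.5e-4, 0.16, pr),
               reynolds_number(2.5e-4, 0.08, pr) / 2)
  ## algebraic identity with rho * (Q/A) * d_h / mu for any area
  for (a in c(1e-4, 3e-4)) {
    d_h <- 4 * a / 0.08
    expect_equal(reynolds_number(2.5e-4, 0.08, pr),
                 pr$rho * (2.5e-4 / a) * d_h / pr$mu, tolerance = 1e-12)
  }
  expect_error(reynolds_number(1e-4, 0), "positive")
})

test_that("bilateral weighting is the mass-flow-weighted mean", {
  expect_equal(bilateral_weighted(2, 4, 1, 1), 3)
  expect_equal(bilateral_weighted(7, 4, 2, 0), 7)
  expect_equal(bilateral_weighted(10, 4, 2, 1), 8)
  expect_error(bilateral_weighted(1, 2, 0, 0), "zero total mass flow")
})

test_that("straight-tube resistance matches Hagen-Poiseuille within 2%", {
  tube <- make_tube(6, 50, n_rings = 21)
  cl <- extract_centerline(tube, n_stations = 8)
  prof <- profile_geometry(tube, cl, n_stations = 11)
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15), props = props)
  rp <- resistance_profile(fld, prof)
  r_hp <- 128 * props$mu * 0.05 / (pi * 0.006^4) * 1e-6
  expect_equal(rp$Rcum_Pa_s_per_ml[nrow(rp)], r_hp, tolerance = 0.02)
  expect_equal(rp$Rcum_Pa_s_per_ml[1], 0)
  expect_true(all(diff(rp$Rcum_Pa_s_per_ml) > -1e-9))
  ## prefix-sum identity
  expect_equal(rp$Rcum_Pa_s_per_ml, cumsum(rp$dR_Pa_s_per_ml), tolerance = 1e-14)
})

test_that("two tubes in series add their Poiseuille resistances within 3%", {
  d1 <- 8
  d2 <- 5
  tube <- make_tube(function(s) ifelse(s < 0.5, d1, d2), 60, n_rings = 121)
  cl <- extract_centerline(tube, n_stations = 10)
  prof <- profile_geometry(tube, cl, n_stations = 13)
  ## low flow rate: viscous resistance is Q-independent and the dynamic
  ## (Bernoulli) exchange at the step stays small next to it
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(1), props = props)
  rp <- resistance_profile(fld, prof)
  r_sum <- (128 * props$mu * 0.03 / (pi * (d1 * 1e-3)^4) +
            128 * props$mu * 0.03 / (pi * (d2 * 1e-3)^4)) * 1e-6
  expect_equal(rp$Rcum_Pa_s_per_ml[nrow(rp)], r_sum, tolerance = 0.03)
})

test_that("identical plane pressures give zero incremental resistance", {
  cs1 <- manual_circle_section(10, 10, s_norm = 0.2)
  cs2 <- manual_circle_section(10, 20, s_norm = 0.5)
  cs3 <- manual_circle_section(10, 30, s_norm = 0.8)
  pts <- do.call(rbind, lapply(c(10, 20, 30), function(x) {
    f <- manual_disk_field(10, x, u_mean = 0, p = 7, Q = 1e-4)
    f$points
  }))
  fld <- flow_field(pts, wall = data.frame(), Q = 1e-4, props = props)
  rp <- resistance_profile(fld, list(cs1, cs2, cs3))
  expect_equal(rp$dR_Pa_s_per_ml, rep(0, 3), tolerance = 1e-12)
  expect_equal(rp$Rcum_Pa_s_per_ml, rep(0, 3), tolerance = 1e-12)
})

test_that("a superposed uniform dynamic-pressure drop is captured exactly", {
  ## two planes, static p = 0, uniform speeds u1 and u2: the total-pressure
  ## drop must be (1/2) rho (u1^2 - u2^2)
  u1 <- 3
  u2 <- 1
  q_nom <- 1e-4
  cs1 <- manual_circle_section(10, 10, s_norm = 0)
  cs2 <- manual_circle_section(10, 20, s_norm = 1)
  pts <- rbind(
    manual_disk_field(10, 10, u_mean = u1, Q = q_nom)$points,
    manual_disk_field(10, 20, u_mean = u2, Q = q_nom)$points
  )
  fld <- flow_field(pts, wall = data.frame(), Q = q_nom, props = props)
  rp <- resistance_profile(fld, list(cs1, cs2))
  dp_expected <- 0.5 * props$rho * (u1^2 - u2^2)
  expect_equal(rp$Rcum_Pa_s_per_ml[2] * 1e6 * q_nom, dp_expected,
               tolerance = 0.03)
})

test_that("anterior/posterior split obeys the prefix-sum identity", {
  tube <- make_tube(6, 50, n_rings = 21)
  cl <- extract_centerline(tube, n_stations = 8)
  prof <- profile_geometry(tube, cl, n_stations = 11)
  fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15), props = props)
  rp <- resistance_profile(fld, prof)
  lmk <- place_landmarks(cl)
  ap <- anterior_posterior_resistance(rp, lmk)
  expect_true(all(ap$R_Pa_s_per_ml >= 0))
  ## anterior + posterior + remainder = total
  rc <- function(sn) approx(rp$s_norm, rp$Rcum_Pa_s_per_ml, sn)$y
  remainder <- rc(1) - rc(0.72)
  expect_equal(sum(ap$R_Pa_s_per_ml) + remainder, rp$Rcum_Pa_s_per_ml[nrow(rp)],
               tolerance = 1e-9)
  ## uniform tube: segment losses are proportional to length
  expect_equal(ap$R_Pa_s_per_ml[1] / ap$R_Pa_s_per_ml[2],
               0.32 / (0.72 - 0.32), tolerance = 0.03)
})

test_that("regional partition recovers a programmed three-way split", {
  sc <- three_duct_scene(split = c(0.2, 0.4, 0.4))
  rp <- regional_partition(sc$field, sc$sections, sc$landmarks)
  expect_equal(rp$frac_flow_superior, rep(0.2, 3), tolerance = 0.02)
  expect_equal(rp$frac_flow_middle, rep(0.4, 3), tolerance = 0.02)
  expect_equal(rp$frac_flow_inferior, rep(0.4, 3), tolerance = 0.02)
  ## normalization at every station
  sums_flow <- rp$frac_flow_superior + rp$frac_flow_middle + rp$frac_flow_inferior
  sums_wss <- rp$frac_wss_superior + rp$frac_wss_middle + rp$frac_wss_inferior
  expect_equal(sums_flow, rep(1, 3), tolerance = 1e-6)
  expect_equal(sums_wss, rep(1, 3), tolerance = 1e-6)
})

test_that("a duct entirely below 1H is all inferior", {
  sc <- three_duct_scene()
  lmk <- sc$landmarks
  lmk$plane_1H$origin <- c(0, 0, 50)
  lmk$plane_2H$origin <- c(0, 0, 60)
  rp <- regional_partition(sc$field, sc$sections, lmk)
  expect_equal(rp$frac_flow_inferior, rep(1, 3), tolerance = 1e-9)
  expect_equal(rp$frac_flow_superior, rep(0, 3), tolerance = 1e-9)
})

test_that("partition fractions are invariant under rigid rotation of the scene", {
  sc <- three_duct_scene(split = c(0.25, 0.35, 0.4))
  rp0 <- regional_partition(sc$field, sc$sections, sc$landmarks)
  ## rotate everything by 30 degrees about x
  th <- pi / 6
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
                3, byrow = TRUE)
  rot_pts <- function(m) t(rot %*% t(m))
  fld <- sc$field
  pc <- rot_pts(cbind(fld$points$x, fld$points$y, fld$points$z))
  fld$points$x <- pc[, 1]
  fld$points$y <- pc[, 2]
  fld$points$z <- pc[, 3]
  uc <- rot_pts(cbind(fld$points$ux, fld$points$uy, fld$points$uz))
  fld$points$ux <- uc[, 1]
  fld$points$uy <- uc[, 2]
  fld$points$uz <- uc[, 3]
  wc <- rot_pts(cbind(fld$wall$x, fld$wall$y, fld$wall$z))
  fld$wall$x <- wc[, 1]
  fld$wall$y <- wc[, 2]
  fld$wall$z <- wc[, 3]
  sections <- lapply(sc$sections, function(cs) {
    cs$loops <- lapply(cs$loops, rot_pts)
    cs$origin <- as.numeric(rot %*% cs$origin)
    cs$normal <- as.numeric(rot %*% cs$normal)
    cs$loop_centroid <- rot_pts(cs$loop_centroid)
    cs
  })
  lmk <- sc$landmarks
  lmk$plane_1H <- list(origin = as.numeric(rot %*% lmk$plane_1H$origin),
                       normal = as.numeric(rot %*% lmk$plane_1H$normal))
  lmk$plane_2H <- list(origin = as.numeric(rot %*% lmk$plane_2H$origin),
                       normal = as.numeric(rot %*% lmk$plane_2H$normal))
  rp1 <- regional_partition(fld, sections, lmk)
  expect_equal(rp1$frac_flow_superior, rp0$frac_flow_superior, tolerance = 1e-6)
  expect_equal(rp1$frac_wss_middle, rp0$frac_wss_middle, tolerance = 1e-6)
})

test_that("the flow summary CSV joins profile and partition", {
  sc <- three_duct_scene()
  rp <- resistance_profile(sc$field, sc$sections)
  pt <- regional_partition(sc$field, sc$sections, sc$landmarks)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(rp, path, partition = pt)
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("Rcum_Pa_s_per_ml", "frac_flow_superior") %in% names(got)))
  expect_equal(nrow(got), 3)
})
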