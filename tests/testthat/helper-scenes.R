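# Geometric fixtures and hand-built flow scenes used across the tests.
# Everything is generated in code; nothing is read from disk.

# quarter-torus tube: centerline a quarter circle of radius R_mm in the
# x-y plane, circular section of radius r_mm
make_quarter_torus <- function(R_mm = 40, r_mm = 8, n_rings = 81, v = 48) {
  phi <- seq(0, pi / 2, length.out = n_rings)
  th <- seq(0, 2 * pi, length.out = v + 1)[-(v + 1)]
  verts <- do.call(rbind, lapply(phi, function(ph) {
    ctr <- c(R_mm * cos(ph), R_mm * sin(ph), 0)
    e_r <- c(cos(ph), sin(ph), 0)   # radial (in-plane) direction
    e_z <- c(0, 0, 1)
    # ring basis (e_z, e_r) is right-handed about the direction of travel
    t(sapply(th, function(t) ctr + r_mm * (cos(t) * e_z + sin(t) * e_r)))
  }))
  tris <- list()
  for (i in seq_len(n_rings - 1)) {
    a0 <- (i - 1) * v
    b0 <- i * v
    j <- seq_len(v)
    jn <- c(2:v, 1)
    tris[[2 * i - 1]] <- cbind(a0 + j, a0 + jn, b0 + j)
    tris[[2 * i]] <- cbind(a0 + jn, b0 + jn, b0 + j)
  }
  cin <- nrow(verts) + 1L
  cout <- nrow(verts) + 2L
  verts <- rbind(verts, c(R_mm, 0, 0), c(0, R_mm, 0))
  j <- seq_len(v)
  jn <- c(2:v, 1)
  tris[[length(tris) + 1]] <- cbind(rep(cin, v), jn, j)
  tris[[length(tris) + 1]] <- cbind(rep(cout, v), (n_rings - 1) * v + j,
                                    (n_rings - 1) * v + jn)
  tris <- do.call(rbind, tris)
  lab <- rep("wall", nrow(tris))
  lab[(nrow(tris) - 2 * v + 1):(nrow(tris) - v)] <- "inlet"
  lab[(nrow(tris) - v + 1):nrow(tris)] <- "outlet"
  airway_surface(verts, tris, lab)
}

# elliptical cylinder along x with semi-axes a_mm (y) and b_mm (z)
make_ellipse_cylinder <- function(a_mm = 10, b_mm = 5, length_mm = 40,
                                  n_rings = 11, v = 256) {
  make_tube(
    diameter_mm = 1, length_mm = length_mm, n_rings = n_rings,
    ring_vertices = v
  ) |> (function(tmpl) {
    # rebuild with elliptical rings by scaling the template's unit circle
    verts <- tmpl$vertices
    r <- sqrt(verts[, 2]^2 + verts[, 3]^2)
    scale_pts <- r > 0
    verts[scale_pts, 2] <- verts[scale_pts, 2] / 0.5 * a_mm
    verts[scale_pts, 3] <- verts[scale_pts, 3] / 0.5 * b_mm
    airway_surface(verts, tmpl$faces, tmpl$face_label)
  })()
}

# hand-built circular cross-section at axial position x_mm (normal +x)
manual_circle_section <- function(r_mm, x_mm, v = 256, center_yz = c(0, 0),
                                  s_norm = 0.5) {
  th <- seq(0, 2 * pi, length.out = v + 1)[-(v + 1)]
  loop <- cbind(x_mm, center_yz[1] + r_mm * cos(th), center_yz[2] + r_mm * sin(th))
  a <- pi * r_mm^2 * 1e-6 * (sin(2 * pi / v) * v / (2 * pi))  # polygon area
  a_poly <- 0.5 * v * r_mm^2 * sin(2 * pi / v) * 1e-6
  p_poly <- v * 2 * r_mm * sin(pi / v) * 1e-3
  structure(list(
    s_norm = s_norm, origin = c(x_mm, center_yz), normal = c(1, 0, 0),
    loops = list(loop), loop_area_m2 = a_poly, loop_perimeter_m = p_poly,
    loop_centroid = matrix(c(x_mm, center_yz), 1),
    A = a_poly, P = p_poly, d_h = 4 * a_poly / p_poly,
    centroid = c(x_mm, center_yz)
  ), class = "cross_section")
}

# flow field sampled on one disk: parabolic or uniform axial profile
manual_disk_field <- function(r_mm, x_mm, u_mean, p = 0, profile = "uniform",
                              Q = NULL, props = fluid_properties(),
                              center_yz = c(0, 0), nt = 20, nv = 64) {
  tlev <- c(0, seq_len(nt) / (nt + 1), 1)
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  pts <- do.call(rbind, lapply(tlev, function(t) {
    u <- switch(profile,
      uniform = u_mean,                      # plug profile (slips at the wall)
      poiseuille = 2 * u_mean * (1 - t^2)
    )
    data.frame(
      x = x_mm, y = center_yz[1] + t * r_mm * cos(th),
      z = center_yz[2] + t * r_mm * sin(th),
      ux = u, uy = 0, uz = 0, p = p
    )
  }))
  if (is.null(Q)) Q <- u_mean * pi * (r_mm * 1e-3)^2
  flow_field(pts, wall = data.frame(), Q = Q, props = props)
}

# three stacked ducts with a programmed flow split: returns the scene
# (field + sections + landmarks) used to check regional partitioning
three_duct_scene <- function(split = c(0.2, 0.4, 0.4), r_mm = 4,
                             gap_mm = 12, Q = flow_rate_lpm(15),
                             props = fluid_properties()) {
  z0 <- c(gap_mm, 0, -gap_mm)   # superior, middle, inferior duct centers
  a_m2 <- pi * (r_mm * 1e-3)^2
  stations <- c(0.25, 0.5, 0.75)
  x_mm <- stations * 40
  sections <- lapply(seq_along(stations), function(si) {
    th <- seq(0, 2 * pi, length.out = 97)[-97]
    loops <- lapply(z0, function(z) {
      cbind(x_mm[si], r_mm * cos(th), z + r_mm * sin(th))
    })
    a_poly <- 0.5 * 96 * r_mm^2 * sin(2 * pi / 96) * 1e-6
    p_poly <- 96 * 2 * r_mm * sin(pi / 96) * 1e-3
    structure(list(
      s_norm = stations[si], origin = c(x_mm[si], 0, 0), normal = c(1, 0, 0),
      loops = loops,
      loop_area_m2 = rep(a_poly, 3), loop_perimeter_m = rep(p_poly, 3),
      loop_centroid = cbind(x_mm[si], 0, z0),
      A = 3 * a_poly, P = 3 * p_poly, d_h = 4 * a_poly / p_poly,
      centroid = c(x_mm[si], 0, 0)
    ), class = "cross_section")
  })
  pts <- list()
  wall <- list()
  for (xi in seq(0, 40, by = 2.5)) {
    for (di in 1:3) {
      u_mean <- split[di] * Q / a_m2
      f <- manual_disk_field(r_mm, xi, u_mean, profile = "poiseuille",
                             center_yz = c(0, z0[di]), Q = Q, props = props)
      fp <- f$points
      fp$s_norm <- xi / 40
      pts[[length(pts) + 1]] <- fp
      tau <- 8 * props$mu * u_mean / (2 * r_mm * 1e-3)
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      wall[[length(wall) + 1]] <- data.frame(
        x = xi + 1.25, y = r_mm * cos(th), z = z0[di] + r_mm * sin(th),
        wss = tau, area_m2 = (2 * pi * r_mm * 1e-3 / 32) * 2.5e-3,
        s_norm = (xi + 1.25) / 40
      )
    }
  }
  field <- flow_field(do.call(rbind, pts), do.call(rbind, wall),
                      Q = Q, props = props)
  landmarks <- structure(list(
    fractions = c(Nos = 0, NV = 0.12, AS = 0.18, V1 = 0.32, V2 = 0.45,
                  V3 = 0.58, PS = 0.72, Naso = 1),
    plane_1H = list(origin = c(0, 0, -gap_mm / 2), normal = c(0, 0, 1)),
    plane_2H = list(origin = c(0, 0, gap_mm / 2), normal = c(0, 0, 1)),
    vertical_axis = c(0, 0, 1)
  ), class = "landmark_set")
  list(field = field, sections = sections, landmarks = landmarks,
       split = split)
}

# brute-force exact two-sided signed-rank p-value by enumerating all 2^n
# sign assignments (oracle for the convolution implementation), n <= 12
enumerate_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- sum(r)
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-12)
  p_ge <- mean(ws >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
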