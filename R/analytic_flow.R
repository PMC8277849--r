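#' Attach an analytic laminar flow field to a phantom
#'
#' Constructs a fully-developed (Poiseuille-like) laminar flow field matched
#' to a phantom's known section parameterization, standing in for an external
#' CFD solution. Per station, each passage loop carries an axial velocity
#' profile `u = 2*u_mean*(1 - t^2)` (t the scaled distance from the loop
#' centroid to its boundary) scaled so the plane flux equals the passage flow
#' rate; the flow split between the two passages is proportional to their
#' series laminar conductance (d_h^4 weighting). Static pressure integrates
#' the local laminar gradient `-128*mu*Q_loop/(pi*d_h^4)` along the
#' centerline, and wall shear stress is the parabolic-profile wall gradient
#' `8*mu*u_mean/d_h` of the local hydraulic diameter. The field is
#' flux-consistent across stations by construction.
#'
#' @param surface A phantom from [make_phantom()] or [make_tube()]. Foreign
#'   meshes (no section parameterization) are rejected; import an externally
#'   computed field with [flow_field()] instead.
#' @param Q Volumetric flow rate (m^3/s); see [flow_rate_lpm()].
#' @param props A [fluid_properties()].
#' @param n_radial Radial sample levels per loop (plus centroid and wall).
#' @param n_azimuthal Azimuthal samples per radial level and wall band.
#' @return A [flow_field()] whose `points`/`wall` tables carry `s_norm`.
#' @examples
#' tube <- make_tube(6, 50)
#' fld <- assign_analytic_flow(tube, Q = flow_rate_lpm(15))
#' fld
#' @export
assign_analytic_flow <- function(surface, Q, props = fluid_properties(),
                                 n_radial = 16, n_azimuthal = 64) {
  ph <- attr(surface, "phantom")
  if (is.null(ph)) {
    abort(paste(
      "this surface has no section parameterization; analytic fields can only",
      "be built for phantoms. For real geometries, import an externally",
      "computed field with flow_field()."
    ))
  }
  rings <- ph$sections$rings
  n <- length(rings)
  mu <- props$mu
  rho <- props$rho
  length_m <- (rings[[n]]$x - rings[[1]]$x) * MM

  ## per-ring, per-loop geometric quantities (SI)
  geo <- lapply(rings, function(r) {
    lapply(r$loops, function(lp) {
      a <- lp$area_mm2 * MM2
      p <- lp$perimeter_mm * MM
      list(passage = lp$passage, center = lp$center, polygon = lp$polygon,
           A = a, P = p, d_h = 4 * a / p)
    })
  })
  s <- vapply(rings, `[[`, numeric(1), "s_norm")
  x_m <- vapply(rings, `[[`, numeric(1), "x") * MM

  ## flow split between passages: proportional to series laminar conductance
  passage_R <- function(tag) {
    grad <- vapply(seq_len(n), function(i) {
      lp <- geo_find(geo[[i]], tag)
      if (is.null(lp)) NA_real_ else 128 * mu / (pi * lp$d_h^4)
    }, numeric(1))
    ok <- which(!is.na(grad))
    if (length(ok) < 2) return(NA_real_)
    trapz(x_m[ok], grad[ok])
  }
  r_l <- passage_R("L")
  r_r <- passage_R("R")
  q_of <- c(S = Q,
            L = if (is.na(r_l)) 0 else Q * (1 / r_l) / (1 / r_l + 1 / r_r),
            R = if (is.na(r_r)) 0 else Q * (1 / r_r) / (1 / r_l + 1 / r_r))

  ## pressure march: integrate the local gradient along each passage path
  grad <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("S", "L", "R")))
  for (i in seq_len(n)) {
    for (lp in geo[[i]]) {
      grad[i, lp$passage] <- 128 * mu * q_of[[lp$passage]] / (pi * lp$d_h^4)
    }
  }
  ## plane-mean dynamic pressure of the parabolic profile, (2/3)*rho*u_mean^2
  ## per loop; the static pressure includes the Bernoulli exchange so that
  ## the plane-averaged total pressure decays by the viscous loss alone
  dyn <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("S", "L", "R")))
  for (i in seq_len(n)) {
    for (lp in geo[[i]]) {
      dyn[i, lp$passage] <- (2 / 3) * rho * (q_of[[lp$passage]] / lp$A)^2
    }
  }
  pres <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("S", "L", "R")))
  pres[1, names(which(!is.na(grad[1, ])))] <- 0
  for (i in 2:n) {
    dx <- x_m[i] - x_m[i - 1]
    for (tag in c("S", "L", "R")) {
      if (is.na(grad[i, tag])) next
      if (!is.na(pres[i - 1, tag])) {
        pres[i, tag] <- pres[i - 1, tag] -
          dx * (grad[i, tag] + grad[i - 1, tag]) / 2 -
          (dyn[i, tag] - dyn[i - 1, tag])
      } else if (tag %in% c("L", "R") && !is.na(pres[i - 1, "S"])) {
        ## split: passages start from the vestibule pressure
        pres[i, tag] <- pres[i - 1, "S"] -
          dx * (grad[i, tag] + grad[i - 1, "S"]) / 2 -
          (dyn[i, tag] - dyn[i - 1, "S"])
      } else if (tag == "S" && !is.na(pres[i - 1, "L"])) {
        ## merge: mass-flow-weighted junction pressure of the two passages
        pj <- (q_of[["L"]] * pres[i - 1, "L"] + q_of[["R"]] * pres[i - 1, "R"]) /
          (q_of[["L"]] + q_of[["R"]])
        gj <- (q_of[["L"]] * grad[i - 1, "L"] + q_of[["R"]] * grad[i - 1, "R"]) /
          (q_of[["L"]] + q_of[["R"]])
        dj <- (q_of[["L"]] * dyn[i - 1, "L"] + q_of[["R"]] * dyn[i - 1, "R"]) /
          (q_of[["L"]] + q_of[["R"]])
        pres[i, tag] <- pj - dx * (grad[i, tag] + gj) / 2 -
          (dyn[i, tag] - dj)
      }
    }
  }

  ## lumen samples: uniform radial levels plus the centroid and, on the wall
  ## itself, the full boundary polygon and its edge midpoints at zero
  ## velocity (resolving the no-slip layer for the interpolation)
  tlev <- c(0, seq_len(n_radial) / (n_radial + 1))
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- lapply(geo[[i]], function(lp) {
      u_mean <- q_of[[lp$passage]] / lp$A
      poly <- subsample_polygon(lp$polygon, n_azimuthal)
      ctr <- lp$center
      jb <- c(2:nrow(lp$polygon), 1)
      bnd_y <- c(lp$polygon[, 1], (lp$polygon[, 1] + lp$polygon[jb, 1]) / 2)
      bnd_z <- c(lp$polygon[, 2], (lp$polygon[, 2] + lp$polygon[jb, 2]) / 2)
      yy <- c(outer(poly[, 1] - ctr[1], tlev, function(d, t) ctr[1] + t * d),
              bnd_y)
      zz <- c(outer(poly[, 2] - ctr[2], tlev, function(d, t) ctr[2] + t * d),
              bnd_z)
      tt <- c(rep(tlev, each = nrow(poly)), rep(1, length(bnd_y)))
      tibble(
        x = rings[[i]]$x, y = yy, z = zz,
        ux = 2 * u_mean * (1 - tt^2), uy = 0, uz = 0,
        p = pres[i, lp$passage], s_norm = s[i]
      )
    })
    pts[[i]] <- dplyr::bind_rows(rows)
  }
  pts <- dplyr::distinct(dplyr::bind_rows(pts), .data$x, .data$y, .data$z,
                         .keep_all = TRUE)

  ## wall samples: per inter-ring band and loop, patches along the boundary
  wal <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    dx_mm <- rings[[i + 1]]$x - rings[[i]]$x
    if (dx_mm <= 0) next
    rows <- lapply(geo[[i]], function(lp) {
      lp2 <- geo_find(geo[[i + 1]], lp$passage)
      tau1 <- 8 * mu * (q_of[[lp$passage]] / lp$A) / lp$d_h
      tau2 <- if (is.null(lp2)) tau1 else 8 * mu * (q_of[[lp$passage]] / lp2$A) / lp2$d_h
      poly <- subsample_polygon(lp$polygon, n_azimuthal)
      jn <- c(2:nrow(poly), 1)
      seg_len <- sqrt((poly[jn, 1] - poly[, 1])^2 + (poly[jn, 2] - poly[, 2])^2)
      ## correct patch area so bands sum exactly to the loop band P * dx
      seg_len <- seg_len * lp$P / (sum(seg_len) * MM)
      tibble(
        x = rings[[i]]$x + dx_mm / 2,
        y = (poly[, 1] + poly[jn, 1]) / 2,
        z = (poly[, 2] + poly[jn, 2]) / 2,
        wss = (tau1 + tau2) / 2,
        area_m2 = seg_len * MM * dx_mm * MM,
        s_norm = (s[i] + s[i + 1]) / 2
      )
    })
    wal[[i]] <- dplyr::bind_rows(rows)
  }

  flow_field(pts, dplyr::bind_rows(wal), Q = Q, props = props)
}

## find loop record by passage tag
geo_find <- function(loops, tag) {
  for (lp in loops) if (lp$passage == tag) return(lp)
  NULL
}

## take every k-th vertex of a polygon so ~n remain
subsample_polygon <- function(poly, n) {
  v <- nrow(poly)
  if (v <= n) return(poly)
  poly[unique(round(seq(1, v, length.out = n + 1)[-(n + 1)])), , drop = FALSE]
}
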