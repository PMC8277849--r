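## Plane integration machinery: each cross-section loop is fan-triangulated
## about its centroid, each fan triangle is subdivided once (4 congruent
## sub-triangles, spreading nodes radially), and the field is evaluated at
## the three edge-midpoint quadrature nodes of every sub-triangle (degree-2
## exact) by inverse-distance interpolation from the 8 nearest samples.

## quadrature nodes and weights (areas, m^2) for one loop
loop_quadrature <- function(loop, centroid) {
  v <- nrow(loop)
  j <- c(2:v, 1)
  a <- loop
  b <- loop[j, , drop = FALSE]
  cx <- matrix(centroid, v, 3, byrow = TRUE)
  m1 <- (cx + a) / 2
  m2 <- (cx + b) / 2
  m3 <- (a + b) / 2
  p1 <- rbind(cx, m1, m2, m1)
  p2 <- rbind(m1, a, m3, m3)
  p3 <- rbind(m2, m3, b, m2)
  e1 <- p2 - p1
  e2 <- p3 - p1
  nvec <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  tri_area <- sqrt(rowSums(nvec^2)) / 2 * MM2   # m^2 (positive areas)
  nodes <- rbind((p1 + p2) / 2, (p2 + p3) / 2, (p3 + p1) / 2)
  weights <- rep(tri_area / 3, 3)
  list(nodes = nodes, weights = weights)
}

## inverse-distance (power 2) interpolation of field point columns at nodes
idw_field <- function(field, nodes, origin, normal, k = 8) {
  fp <- field$points
  ax <- abs((fp$x - origin[1]) * normal[1] + (fp$y - origin[2]) * normal[2] +
            (fp$z - origin[3]) * normal[3])
  ## candidate slab: widen until enough samples are available
  h <- 1
  repeat {
    cand <- which(ax <= h)
    if (length(cand) >= max(4 * k, 64) || h > 1e4) break
    h <- h * 2
  }
  if (length(cand) < k) abort("the plane is not covered by field samples")
  cx <- fp$x[cand]
  cy <- fp$y[cand]
  cz <- fp$z[cand]
  m <- nrow(nodes)
  out <- matrix(0, m, 4, dimnames = list(NULL, c("ux", "uy", "uz", "p")))
  vals <- cbind(fp$ux[cand], fp$uy[cand], fp$uz[cand], fp$p[cand])
  chunk <- max(16L, floor(4e6 / length(cand)))
  for (lo in seq(1, m, by = chunk)) {
    hi <- min(lo + chunk - 1, m)
    idx <- lo:hi
    nb <- length(idx)
    d2 <- outer(nodes[idx, 1], cx, `-`)^2 +
          outer(nodes[idx, 2], cy, `-`)^2 +
          outer(nodes[idx, 3], cz, `-`)^2
    ## k nearest neighbours by repeated max.col on the negated distances
    num <- matrix(0, nb, 4)
    den <- numeric(nb)
    rows <- seq_len(nb)
    for (kk in seq_len(k)) {
      jmin <- max.col(-d2, ties.method = "first")
      sel <- cbind(rows, jmin)
      w <- 1 / pmax(d2[sel], 1e-24)
      num <- num + vals[jmin, , drop = FALSE] * w
      den <- den + w
      d2[sel] <- Inf
    }
    out[idx, ] <- num / den
  }
  out
}

## One quadrature + interpolation pass over all loops of a section,
## returning every plane integral the pipeline needs.
plane_flow_eval <- function(field, cs) {
  rho <- field$props$rho
  mdot <- 0
  pt_area_num <- 0
  pt_mass_num <- 0
  area <- 0
  flux <- 0
  for (li in seq_along(cs$loops)) {
    q <- loop_quadrature(cs$loops[[li]], cs$loop_centroid[li, ])
    f <- idw_field(field, q$nodes, cs$origin, cs$normal)
    un <- f[, "ux"] * cs$normal[1] + f[, "uy"] * cs$normal[2] +
          f[, "uz"] * cs$normal[3]
    pt <- f[, "p"] + 0.5 * rho * (f[, "ux"]^2 + f[, "uy"]^2 + f[, "uz"]^2)
    mdot <- mdot + rho * sum(un * q$weights)
    pt_area_num <- pt_area_num + sum(pt * q$weights)
    pt_mass_num <- pt_mass_num + sum(pt * un * q$weights)
    area <- area + sum(q$weights)
    flux <- flux + sum(un * q$weights)
  }
  list(
    mdot = mdot,
    pt_area = pt_area_num / area,
    pt_mass = if (flux != 0) pt_mass_num / flux else NA_real_
  )
}

#' Plane mass flow
#'
#' Integrates the normal mass flux `rho * (u . n)` of a sampled flow field
#' over all loops of a cross-section; the plane normal is the local
#' centerline tangent stored in the section.
#'
#' @param field A [flow_field()].
#' @param cs A [slice_cross_section()] result.
#' @return Mass flow in kg/s (signed: positive along the centerline tangent).
#' @export
plane_mass_flow <- function(field, cs) {
  plane_flow_eval(field, cs)$mdot
}

#' Plane-averaged total pressure
#'
#' Surface-averaged total pressure `p + rho*|u|^2/2` over all loops of a
#' cross-section. Area weighting is the default; mass-flow weighting
#' (weighting each quadrature node by its normal mass flux) is available as
#' an option.
#'
#' @inheritParams plane_mass_flow
#' @param mass_weighted Use mass-flow weighting instead of area weighting.
#' @return Mean total pressure (Pa).
#' @export
plane_avg_total_pressure <- function(field, cs, mass_weighted = FALSE) {
  ev <- plane_flow_eval(field, cs)
  if (mass_weighted) ev$pt_mass else ev$pt_area
}

#' Reynolds number from flow rate and perimeter
#'
#' `Re = 4*rho*Q / (mu*P)`: the hydraulic-diameter Reynolds number of a duct
#' section, which for fixed flow rate depends only on the section perimeter.
#'
#' @param Q Volumetric flow rate (m^3/s).
#' @param P Section perimeter (m), positive.
#' @param props A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(flow_rate_lpm(15), P = 0.08)
#' @export
reynolds_number <- function(Q, P, props = fluid_properties()) {
  if (any(P <= 0)) abort("perimeter must be positive")
  4 * props$rho * Q / (props$mu * P)
}

#' Bilateral mass-flow-weighted summary
#'
#' Combines a per-side flow quantity into a bilateral value using mass-flow
#' weighting: `(mdot_l*phi_l + mdot_r*phi_r) / (mdot_l + mdot_r)`. With one
#' side carrying no flow this degenerates to the other side's value.
#'
#' @param phi_left,phi_right Per-side values of the quantity.
#' @param mdot_left,mdot_right Per-side mass flows (kg/s).
#' @return The weighted bilateral value.
#' @examples
#' bilateral_weighted(10, 4, 2, 1)  # 8
#' @export
bilateral_weighted <- function(phi_left, phi_right, mdot_left, mdot_right) {
  tot <- mdot_left + mdot_right
  if (any(tot == 0)) abort("zero total mass flow")
  (mdot_left * phi_left + mdot_right * phi_right) / tot
}

#' Trans-nasal resistance profile
#'
#' Per-station plane summaries and the incremental/cumulative resistance:
#' the drop in surface-averaged total pressure between consecutive planes
#' divided by the volumetric flow rate. Cumulative resistance is the prefix
#' sum of the increments from the first (nostril) plane.
#'
#' @param field A [flow_field()].
#' @param sections List of [slice_cross_section()] objects ordered by
#'   station, or a [profile_geometry()] tibble.
#' @param mass_weighted Passed to [plane_avg_total_pressure()].
#' @return A `resistance_profile` tibble with columns `s_norm`,
#'   `mdot_kg_s`, `pt_mean_Pa`, `Re`, `dR_Pa_s_per_ml`, `Rcum_Pa_s_per_ml`.
#'   Resistances are in Pa.s/ml (1 Pa.s/m^3 = 1e-6 Pa.s/ml).
#' @export
resistance_profile <- function(field, sections, mass_weighted = FALSE) {
  if (inherits(sections, "geometry_profile")) sections <- profile_sections(sections)
  if (length(sections) < 2) abort("need at least 2 sections")
  if (field$Q <= 0) abort("zero flow rate")
  sn <- vapply(sections, `[[`, numeric(1), "s_norm")
  evs <- lapply(sections, function(cs) plane_flow_eval(field, cs))
  mdot <- vapply(evs, `[[`, numeric(1), "mdot")
  pt <- vapply(evs, `[[`, numeric(1), if (mass_weighted) "pt_mass" else "pt_area")
  re <- vapply(sections, function(cs) {
    reynolds_number(field$Q, cs$P, field$props)
  }, numeric(1))
  dr <- c(0, -diff(pt) / field$Q) * 1e-6   # Pa.s/m^3 -> Pa.s/ml
  out <- tibble(
    s_norm = sn, mdot_kg_s = mdot, pt_mean_Pa = pt, Re = re,
    dR_Pa_s_per_ml = dr, Rcum_Pa_s_per_ml = cumsum(dr)
  )
  class(out) <- c("resistance_profile", class(out))
  out
}

#' Anterior/posterior resistance split
#'
#' Splits cumulative resistance at the anatomical landmark planes: the
#' anterior segment runs from the nostril to plane 1V, the posterior from 1V
#' to the posterior septum (PS). Cumulative resistance is linearly
#' interpolated between stations.
#'
#' @param profile A [resistance_profile()] tibble.
#' @param landmarks A [place_landmarks()] result.
#' @return A tibble with columns `segment` (`anterior`, `posterior`),
#'   `R_Pa_s_per_ml`.
#' @export
anterior_posterior_resistance <- function(profile, landmarks) {
  fr <- landmarks$fractions
  rc <- function(sn) {
    approx(profile$s_norm, profile$Rcum_Pa_s_per_ml, sn, rule = 2)$y
  }
  tibble(
    segment = c("anterior", "posterior"),
    R_Pa_s_per_ml = c(rc(fr[["V1"]]) - rc(fr[["Nos"]]),
                      rc(fr[["PS"]]) - rc(fr[["V1"]]))
  )
}

#' Superior/middle/inferior flow and WSS partitioning
#'
#' Per station, the fraction of plane mass flow passing through the
#' superior, middle and inferior vertical regions (delimited by the 1H and
#' 2H planes), and the fraction of integrated wall shear stress loading
#' (`sum(WSS * patch area)`) carried by each region over the wall band
#' between consecutive stations. A band's WSS fractions are reported at its
#' upstream station; the last station repeats the final band.
#'
#' @param field A [flow_field()] whose wall table carries patch areas. Wall
#'   patches are assigned to inter-station bands by their `s_norm` if
#'   present, otherwise by nearest-point projection onto `centerline`.
#' @param sections List of [slice_cross_section()] objects or a
#'   [profile_geometry()] tibble.
#' @param landmarks A [place_landmarks()] result with 1H/2H planes set.
#' @param centerline Optional [extract_centerline()] result, used to project
#'   wall patches when the field does not carry `s_norm`.
#' @return A `regional_partition` tibble: `s_norm`, `frac_flow_superior`,
#'   `frac_flow_middle`, `frac_flow_inferior`, `frac_wss_superior`,
#'   `frac_wss_middle`, `frac_wss_inferior`.
#' @export
regional_partition <- function(field, sections, landmarks, centerline = NULL) {
  if (inherits(sections, "geometry_profile")) sections <- profile_sections(sections)
  if (is.null(landmarks$plane_1H)) abort("`landmarks` must carry 1H/2H planes")
  p1 <- landmarks$plane_1H
  p2 <- landmarks$plane_2H
  region_of <- function(pts) {
    d1 <- (pts[, 1] - p1$origin[1]) * p1$normal[1] +
          (pts[, 2] - p1$origin[2]) * p1$normal[2] +
          (pts[, 3] - p1$origin[3]) * p1$normal[3]
    d2 <- (pts[, 1] - p2$origin[1]) * p2$normal[1] +
          (pts[, 2] - p2$origin[2]) * p2$normal[2] +
          (pts[, 3] - p2$origin[3]) * p2$normal[3]
    ifelse(d2 > 0, "superior", ifelse(d1 > 0, "middle", "inferior"))
  }

  sn <- vapply(sections, `[[`, numeric(1), "s_norm")
  n <- length(sn)
  flow_fr <- matrix(0, n, 3, dimnames = list(NULL, c("superior", "middle", "inferior")))
  for (i in seq_len(n)) {
    cs <- sections[[i]]
    flux <- c(superior = 0, middle = 0, inferior = 0)
    for (li in seq_along(cs$loops)) {
      q <- loop_quadrature(cs$loops[[li]], cs$loop_centroid[li, ])
      f <- idw_field(field, q$nodes, cs$origin, cs$normal)
      un <- f[, "ux"] * cs$normal[1] + f[, "uy"] * cs$normal[2] +
            f[, "uz"] * cs$normal[3]
      reg <- region_of(q$nodes)
      for (r in names(flux)) {
        flux[r] <- flux[r] + sum(un[reg == r] * q$weights[reg == r])
      }
    }
    tot <- sum(flux)
    if (tot == 0) abort(sprintf("zero total flux at station s_norm = %.3f", sn[i]))
    flow_fr[i, ] <- flux / tot
  }

  wall <- field$wall
  if (nrow(wall) == 0) abort("field has no wall samples")
  if (!"s_norm" %in% names(wall)) {
    if (is.null(centerline)) {
      abort("wall samples carry no `s_norm`; supply `centerline` for projection")
    }
    wall$s_norm <- project_s_norm(cbind(wall$x, wall$y, wall$z), centerline)
  }
  band <- findInterval(wall$s_norm, sn, rightmost.closed = TRUE)
  band <- pmin(pmax(band, 1L), n - 1L)
  wreg <- region_of(cbind(wall$x, wall$y, wall$z))
  load <- wall$wss * wall$area_m2
  wss_fr <- matrix(0, n, 3, dimnames = list(NULL, c("superior", "middle", "inferior")))
  for (k in seq_len(n - 1)) {
    inb <- band == k
    tot <- sum(load[inb])
    if (tot == 0) {
      wss_fr[k, ] <- NA_real_
    } else {
      for (r in colnames(wss_fr)) {
        wss_fr[k, r] <- sum(load[inb & wreg == r]) / tot
      }
    }
  }
  wss_fr[n, ] <- wss_fr[n - 1, ]

  out <- tibble(
    s_norm = sn,
    frac_flow_superior = flow_fr[, "superior"],
    frac_flow_middle = flow_fr[, "middle"],
    frac_flow_inferior = flow_fr[, "inferior"],
    frac_wss_superior = wss_fr[, "superior"],
    frac_wss_middle = wss_fr[, "middle"],
    frac_wss_inferior = wss_fr[, "inferior"]
  )
  class(out) <- c("regional_partition", class(out))
  out
}

## Internal: normalized centerline distance of the nearest centerline point
project_s_norm <- function(pts, centerline) {
  cp <- centerline$points
  sn <- centerline$s_norm
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (cp[, 1] - pts[i, 1])^2 + (cp[, 2] - pts[i, 2])^2 +
          (cp[, 3] - pts[i, 3])^2
    sn[which.min(d2)]
  }, numeric(1))
}

#' Write a station-wise flow summary as CSV
#'
#' Joins a [resistance_profile()] and (optionally) a [regional_partition()]
#' on `s_norm` and writes one row per station.
#'
#' @param profile A [resistance_profile()].
#' @param path Output CSV path.
#' @param partition Optional [regional_partition()].
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(profile, path, partition = NULL) {
  out <- profile
  if (!is.null(partition)) {
    out <- dplyr::left_join(out, partition, by = "s_norm")
  }
  readr::write_csv(out, path)
  invisible(path)
}
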