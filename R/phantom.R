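#' Phantom specification
#'
#' Parameters of the synthetic nasal airway phantom: a short single vestibule
#' duct that splits into two parallel passages (left/right), which run through
#' a nasal-valve constriction and a multi-lobed turbinate region and merge
#' again posterior to the posterior-septum fraction into a single nasopharynx
#' duct. The bilateral cross-sectional area follows a piecewise profile
#' through nostril, valve, anterior septum, turbinate plateau and nasopharynx
#' control values; the decongestion state interpolates the plateau between
#' the normal (congested) and decongested areas while the passage perimeter
#' is held nearly constant by shallowing the turbinate clefts.
#'
#' Default control values emulate a healthy adult cohort mean: centerline
#' length 113 mm, landmark fractions NV 0.12 / AS 0.18 / 1V 0.32 / 2V 0.45 /
#' 3V 0.58 / PS 0.72, turbinate-plateau CSA 2.8 cm^2 in the normal state and
#' 3.8 cm^2 decongested (a 35.7% increase).
#'
#' @param length_mm Total centerline length (mm).
#' @param landmarks Named fractions `NV, AS, V1, V2, V3, PS`.
#' @param nostril_csa_cm2,valve_csa_cm2 Bilateral CSA at the nostril and at
#'   the nasal-valve constriction (cm^2).
#' @param as_csa_cm2 Bilateral CSA at the anterior septum, common to both
#'   states (the decongestion morph acts only between AS and PS).
#' @param plateau_csa_normal_cm2,plateau_csa_decongested_cm2 Bilateral
#'   turbinate-plateau CSA (cm^2) for the congested (c = 1) and decongested
#'   (c = 0) states.
#' @param v1_csa_normal_cm2,v1_csa_decongested_cm2 Bilateral CSA at plane 1V.
#' @param postmerge_csa_cm2,naso_csa_cm2 Bilateral CSA just after the passage
#'   merge and at the nasopharynx outlet.
#' @param congestion Congestion factor c in `[0, 1]`: 1 = normal (congested),
#'   0 = fully decongested.
#' @param n_lobes Turbinate lobes (cosine clefts) per passage contour.
#' @param lobe_depth Relative cleft depth of the normal-state contour.
#' @param split_frac Fraction at which the vestibule splits into two passages.
#' @param n_rings Number of axial rings discretizing the phantom.
#' @param ring_vertices Vertices per passage contour (single-duct rings use
#'   twice this).
#' @param seed Optional integer recorded in the spec (the phantom build
#'   itself is deterministic; randomness enters only at cohort level).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(length_mm = 113,
                         landmarks = c(NV = 0.12, AS = 0.18, V1 = 0.32,
                                       V2 = 0.45, V3 = 0.58, PS = 0.72),
                         nostril_csa_cm2 = 1.5,
                         valve_csa_cm2 = 1.0,
                         as_csa_cm2 = 2.2,
                         plateau_csa_normal_cm2 = 2.8,
                         plateau_csa_decongested_cm2 = 3.8,
                         v1_csa_normal_cm2 = 2.8,
                         v1_csa_decongested_cm2 = 3.3,
                         postmerge_csa_cm2 = 4.5,
                         naso_csa_cm2 = 3.5,
                         congestion = 1,
                         n_lobes = 4,
                         lobe_depth = 0.35,
                         split_frac = 0.05,
                         n_rings = 161,
                         ring_vertices = 64,
                         seed = NULL) {
  spec <- as.list(environment())
  areas <- c(nostril_csa_cm2, valve_csa_cm2, as_csa_cm2,
             plateau_csa_normal_cm2, plateau_csa_decongested_cm2,
             postmerge_csa_cm2, naso_csa_cm2)
  if (any(areas <= 0)) abort("all CSA control values must be positive")
  if (congestion < 0 || congestion > 1) abort("`congestion` must lie in [0, 1]")
  if (any(diff(landmarks) < 0) || landmarks[["NV"]] <= split_frac) {
    abort("landmark fractions must be ordered and lie beyond `split_frac`")
  }
  if (ring_vertices %% 4 != 0) abort("`ring_vertices` must be a multiple of 4")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> L = %g mm, plateau %g -> %g cm^2, c = %g, %d rings\n",
    x$length_mm, x$plateau_csa_normal_cm2, x$plateau_csa_decongested_cm2,
    x$congestion, x$n_rings
  ))
  invisible(x)
}

## ---- contour primitives ----

## perimeter (mm) of r(theta) = r0 * (1 + eps*cos(k*theta))
lobed_perimeter <- function(r0, eps, k, nq = 256) {
  th <- seq(0, 2 * pi, length.out = nq + 1)[-(nq + 1)]
  g <- 1 + eps * cos(k * th)
  gp <- -eps * k * sin(k * th)
  r0 * sum(sqrt(g^2 + gp^2)) * (2 * pi / nq)
}

## r0 that gives continuous area A (mm^2) at cleft depth eps
lobed_r0 <- function(area_mm2, eps) sqrt(area_mm2 / (pi * (1 + eps^2 / 2)))

## cleft depth that preserves perimeter p_ref at area `area_mm2`; returns 0
## (perimeter then exceeds preservation) when even a circle is too long
solve_cleft_depth <- function(area_mm2, p_ref_mm, k, eps_hi = 0.9) {
  f <- function(eps) lobed_perimeter(lobed_r0(area_mm2, eps), eps, k) - p_ref_mm
  f0 <- f(0)
  if (f0 >= 0) return(0)
  if (f(eps_hi) < 0) abort("infeasible contour: cannot reach the target perimeter")
  uniroot(f, c(0, eps_hi), tol = 1e-8)$root
}

## polygon (V x 2, CCW in (y, z)) of a lobed contour about `center`
lobed_polygon <- function(center, r0, eps, k, v, phase = 0) {
  th <- seq(0, 2 * pi, length.out = v + 1)[-(v + 1)]
  r <- r0 * (1 + eps * cos(k * th + phase))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

## polygon of an ellipse with semi-axes a (y) and b (z)
ellipse_polygon <- function(center, a, b, v) {
  th <- seq(0, 2 * pi, length.out = v + 1)[-(v + 1)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

## shoelace area (positive for CCW) and perimeter of a 2D polygon
poly2_area <- function(p) {
  j <- c(2:nrow(p), 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}
poly2_perimeter <- function(p) {
  j <- c(2:nrow(p), 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

## ---- area profile ----

## bilateral CSA profile (mm^2) as a function of s_norm for congestion c
phantom_area_fun <- function(spec) {
  lm <- spec$landmarks
  mid <- (lm[["V1"]] + lm[["PS"]]) / 2
  s_ctrl <- c(0, lm[["NV"]], lm[["AS"]], lm[["V1"]],
              lm[["V1"]] + 0.10, mid, lm[["PS"]] - 0.10, lm[["PS"]],
              lm[["PS"]] + 0.06, (lm[["PS"]] + 1) / 2 + 0.05, 1)
  a_n <- c(spec$nostril_csa_cm2, spec$valve_csa_cm2, spec$as_csa_cm2,
           spec$v1_csa_normal_cm2, rep(spec$plateau_csa_normal_cm2, 4),
           spec$postmerge_csa_cm2, spec$postmerge_csa_cm2 * 0.9,
           spec$naso_csa_cm2) * 100
  a_d <- c(spec$nostril_csa_cm2, spec$valve_csa_cm2, spec$as_csa_cm2,
           spec$v1_csa_decongested_cm2, spec$plateau_csa_decongested_cm2 * 0.98,
           rep(spec$plateau_csa_decongested_cm2, 3),
           spec$postmerge_csa_cm2, spec$postmerge_csa_cm2 * 0.9,
           spec$naso_csa_cm2) * 100
  f_n <- splinefun(s_ctrl, a_n, method = "monoH.FC")
  f_d <- splinefun(s_ctrl, a_d, method = "monoH.FC")
  function(s, c) c * f_n(s) + (1 - c) * f_d(s)
}

## turbinate-cleft ramp: 0 before AS, smoothstep to 1 by 1V, 1 until PS
cleft_ramp <- function(s, lm) {
  t <- (s - lm[["AS"]]) / (lm[["V1"]] - lm[["AS"]])
  t <- pmin(pmax(t, 0), 1)
  ifelse(s >= lm[["PS"]], 0, t * t * (3 - 2 * t))
}

## ---- per-station section parameterization ----

## Tabulates, for each axial ring station and each loop, the analytic contour
## parameters and the discretized polygon. This table is the generator's
## ground truth ("programmed profile") and the parameterization consumed by
## assign_analytic_flow().
phantom_sections <- function(spec, congestion = NULL, stations = NULL) {
  c_state <- congestion %||% spec$congestion
  lm <- spec$landmarks
  area_fun <- phantom_area_fun(spec)
  k <- spec$n_lobes
  v <- spec$ring_vertices
  if (is.null(stations)) stations <- seq(0, 1, length.out = spec$n_rings)
  split_f <- spec$split_frac
  merge_f <- lm[["PS"]]

  ## passage max radius over both extreme states fixes the lateral offset
  probe <- seq(split_f, merge_f, length.out = 41)
  rmax <- 0
  for (cc in c(0, 1)) {
    for (s in probe) {
      pars <- passage_params(spec, area_fun, s, cc)
      rmax <- max(rmax, pars$r0 * (1 + abs(pars$eps)))
    }
  }
  y_off <- rmax + 0.8

  rings <- lapply(stations, function(s) {
    x <- s * spec$length_mm
    if (s <= split_f || s >= merge_f) {
      a_tot <- area_fun(s, c_state)
      gam <- single_aspect(spec, area_fun, s, y_off)
      b <- sqrt(a_tot / (pi * gam))
      a <- gam * b
      poly <- ellipse_polygon(c(0, 0), a, b, 2 * v)
      loops <- list(list(
        passage = "S", center = c(0, 0), kind = "ellipse", a = a, b = b,
        eps = 0, polygon = poly,
        area_mm2 = poly2_area(poly), perimeter_mm = poly2_perimeter(poly)
      ))
    } else {
      pars <- passage_params(spec, area_fun, s, c_state)
      mk <- function(side) {
        ctr <- c(side * y_off, 0)
        poly <- lobed_polygon(ctr, pars$r0, pars$eps, k, v,
                              phase = pi / (2 * k))
        if (side < 0) {  # mirror the right passage, restore CCW order
          poly[, 1] <- 2 * ctr[1] - poly[, 1]
          poly <- poly[c(1, nrow(poly):2), ]
        }
        list(
          passage = if (side > 0) "L" else "R", center = ctr, kind = "lobed",
          r0 = pars$r0, eps = pars$eps, polygon = poly,
          area_mm2 = poly2_area(poly), perimeter_mm = poly2_perimeter(poly)
        )
      }
      loops <- list(mk(+1), mk(-1))
    }
    list(s_norm = s, x = x, type = if (length(loops) == 1) "single" else "bilateral",
         loops = loops)
  })
  list(rings = rings, y_off = y_off, stations = stations,
       congestion = c_state, split_frac = split_f, merge_frac = merge_f)
}

## contour parameters (r0, eps) of one passage at station s for congestion c:
## the normal state (c = 1) fixes the reference perimeter; other states match
## it by adjusting cleft depth at the state's area
passage_params <- function(spec, area_fun, s, c_state) {
  lm <- spec$landmarks
  k <- spec$n_lobes
  a_pass_n <- area_fun(s, 1) / 2
  eps_n <- spec$lobe_depth * cleft_ramp(s, lm)
  a_pass <- area_fun(s, c_state) / 2
  if (eps_n == 0 || abs(a_pass - a_pass_n) < 1e-12) {
    return(list(r0 = lobed_r0(a_pass, eps_n), eps = eps_n))
  }
  p_ref <- lobed_perimeter(lobed_r0(a_pass_n, eps_n), eps_n, k)
  eps <- solve_cleft_depth(a_pass, p_ref, k)
  list(r0 = lobed_r0(a_pass, eps), eps = eps)
}

## aspect ratio of single-duct (vestibule / nasopharynx) elliptical rings:
## circular away from the junctions, widening so the ellipse spans both
## passages where the duct meets the split/merge
single_aspect <- function(spec, area_fun, s, y_off) {
  lm <- spec$landmarks
  split_f <- spec$split_frac
  merge_f <- lm[["PS"]]
  ramp_len <- 0.05
  gamma_at <- function(s_j) {
    a_tot <- area_fun(s_j, 1)
    r_child <- sqrt(a_tot / (2 * pi))
    a_semi <- y_off + r_child + 0.5
    max(1, pi * a_semi^2 / a_tot)
  }
  if (s <= split_f) {
    t <- s / split_f
    1 + (gamma_at(split_f) - 1) * t^2
  } else {
    t <- 1 - min((s - merge_f) / ramp_len, 1)
    1 + (gamma_at(merge_f) - 1) * t^2
  }
}

## ---- mesh assembly ----

#' Generate a nasal airway phantom surface
#'
#' Builds the watertight, labeled triangle mesh realizing a [phantom_spec()]
#' at a given congestion state. The returned surface carries its section
#' parameterization (the programmed area/perimeter profile and per-loop
#' contour parameters) as attribute `"phantom"`, which
#' [assign_analytic_flow()] uses to construct a matched laminar flow field
#' and which [phantom_profile()] exposes as the generator's ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param congestion Optional override of `spec$congestion` (1 normal,
#'   0 decongested).
#' @return An [airway_surface()] with attribute `"phantom"`.
#' @examples
#' ph <- make_phantom(phantom_spec(n_rings = 81, ring_vertices = 32))
#' ph
#' @export
make_phantom <- function(spec, congestion = NULL) {
  sect <- phantom_sections(spec, congestion)
  rings <- sect$rings
  n <- length(rings)

  mb <- new.env(parent = emptyenv())
  mb$verts <- list()
  mb$nv <- 0L
  mb$tris <- list()
  add_verts <- function(m3) {
    ids <- mb$nv + seq_len(nrow(m3))
    mb$verts[[length(mb$verts) + 1]] <- m3
    mb$nv <- mb$nv + nrow(m3)
    ids
  }
  add_ring <- function(poly2, x) {
    add_verts(cbind(x, poly2[, 1], poly2[, 2]))
  }
  add_tris <- function(m) {
    mb$tris[[length(mb$tris) + 1]] <- m
  }

  ring_ids <- vector("list", n)   # per ring: list of index vectors per loop
  for (i in seq_len(n)) {
    ring_ids[[i]] <- lapply(rings[[i]]$loops, function(lp) {
      add_ring(lp$polygon, rings[[i]]$x)
    })
  }

  strip <- function(idsA, idsB) {
    va <- length(idsA)
    j <- seq_len(va)
    jn <- c(2:va, 1)
    add_tris(cbind(idsA[j], idsA[jn], idsB[j]))
    add_tris(cbind(idsA[jn], idsB[jn], idsB[j]))
  }

  ## The split/merge transition is nearly axially degenerate: the
  ## pair-of-pants sheet spans 0.05 mm just inside the single-duct side, so
  ## cross-sectional cuts at ring stations (and any realistic station grid)
  ## never land inside the (otherwise ill-defined) transition.
  delta <- 0.05

  junction <- function(i_parent, i_children, at_split) {
    pr <- rings[[i_parent]]
    x_j <- pr$x + if (at_split) delta else -delta
    ## children contours just inside the bilateral region (area continuous
    ## with the parent up to the area profile's local slope)
    s_j <- if (at_split) sect$split_frac + 1e-9 else sect$merge_frac - 1e-9
    ch <- phantom_sections(spec, sect$congestion, stations = s_j)$rings[[1]]
    if (ch$type != "bilateral") {
      ch <- rings[[i_children]]  # defensive; should not happen
    }
    idsL <- add_ring(ch$loops[[1]]$polygon, x_j)
    idsR <- add_ring(ch$loops[[2]]$polygon, x_j)
    tris <- split_stitch(
      parent_ids = ring_ids[[i_parent]][[1]],
      parent_poly = pr$loops[[1]]$polygon,
      child_ids = list(idsL, idsR),
      child_polys = list(ch$loops[[1]]$polygon, ch$loops[[2]]$polygon),
      child_centers = list(ch$loops[[1]]$center, ch$loops[[2]]$center),
      ## the septum trailing edge sits on the children's plane so that a cut
      ## exactly at the parent ring remains a single clean loop
      add_chord_vertex = function(p2) {
        add_verts(matrix(c(x_j, p2[1], p2[2]), 1))
      }
    )
    if (!at_split) tris <- tris[, c(1, 3, 2), drop = FALSE]
    add_tris(tris)
    ## connect junction children to the adjacent bilateral ring
    if (at_split) {
      strip(idsL, ring_ids[[i_children]][[1]])
      strip(idsR, ring_ids[[i_children]][[2]])
    } else {
      strip(ring_ids[[i_children]][[1]], idsL)
      strip(ring_ids[[i_children]][[2]], idsR)
    }
  }

  for (i in seq_len(n - 1)) {
    a <- rings[[i]]
    b <- rings[[i + 1]]
    if (a$type == "single" && b$type == "single") {
      strip(ring_ids[[i]][[1]], ring_ids[[i + 1]][[1]])
    } else if (a$type == "bilateral" && b$type == "bilateral") {
      strip(ring_ids[[i]][[1]], ring_ids[[i + 1]][[1]])
      strip(ring_ids[[i]][[2]], ring_ids[[i + 1]][[2]])
    } else if (a$type == "single") {
      junction(i, i + 1, at_split = TRUE)
    } else {
      junction(i + 1, i, at_split = FALSE)
    }
  }

  ## caps: triangle fans, inward winding at the inlet, outward at the outlet
  cap_fan <- function(ids, poly2, x, inlet) {
    ctr_id <- add_verts(matrix(c(x, mean(poly2[, 1]), mean(poly2[, 2])), 1))
    vtx <- length(ids)
    j <- seq_len(vtx)
    jn <- c(2:vtx, 1)
    if (inlet) {
      add_tris(cbind(rep(ctr_id, vtx), ids[jn], ids[j]))
    } else {
      add_tris(cbind(rep(ctr_id, vtx), ids[j], ids[jn]))
    }
    vtx
  }
  n_in <- cap_fan(ring_ids[[1]][[1]], rings[[1]]$loops[[1]]$polygon,
                  rings[[1]]$x, inlet = TRUE)
  n_out <- cap_fan(ring_ids[[n]][[1]], rings[[n]]$loops[[1]]$polygon,
                   rings[[n]]$x, inlet = FALSE)

  verts <- do.call(rbind, mb$verts)
  tris <- do.call(rbind, mb$tris)
  nf <- nrow(tris)
  lab <- rep("wall", nf)
  ## caps were added last: n_in then n_out fan triangles
  lab[(nf - n_out + 1):nf] <- "outlet"
  lab[(nf - n_out - n_in + 1):(nf - n_out)] <- "inlet"

  surf <- airway_surface(verts, tris, lab)
  attr(surf, "phantom") <- list(spec = spec, sections = sect)
  surf
}

## Pair-of-pants stitch between a single parent ring and two child rings.
## The septum's trailing edge is a vertical chord across the parent plane;
## each chord edge is shared (in opposite directions) by the left and right
## sheets, closing the surface with a zero-thickness fold.
split_stitch <- function(parent_ids, parent_poly, child_ids, child_polys,
                         child_centers, add_chord_vertex, n_chord = 7) {
  vs <- length(parent_ids)
  j_top <- vs / 4 + 1        # polygon starts at theta = 0; top at pi/2
  j_bot <- 3 * vs / 4 + 1
  z_top <- parent_poly[j_top, 2]
  z_bot <- parent_poly[j_bot, 2]
  tt <- seq_len(n_chord) / (n_chord + 1)
  chord_pts <- cbind(0, z_top + tt * (z_bot - z_top))   # top -> bottom
  chord_ids <- vapply(seq_len(n_chord), function(l) {
    add_chord_vertex(chord_pts[l, ])
  }, integer(1))

  idx_right <- c(j_top:j_bot)                        # +y .. through -y side?
  idx_left <- c(j_bot:vs, 1:j_top)                   # bottom -> +y -> top
  ## parent polygon is CCW starting at theta = 0 (+y axis); theta increases
  ## through top (pi/2), -y (pi), bottom (3pi/2). So j_top..j_bot covers the
  ## -y (right) side and j_bot..j_top the +y (left) side.
  loop_right <- rbind(
    parent_poly[idx_right, , drop = FALSE],
    chord_pts[n_chord:1, , drop = FALSE]             # bottom -> top at y = 0
  )
  ids_right <- c(parent_ids[idx_right], chord_ids[n_chord:1])
  loop_left <- rbind(
    parent_poly[idx_left, , drop = FALSE],
    chord_pts                                        # top -> bottom
  )
  ids_left <- c(parent_ids[idx_left], chord_ids)

  tl <- zip_loops(loop_left, ids_left, child_polys[[1]], child_ids[[1]],
                  child_centers[[1]])
  tr <- zip_loops(loop_right, ids_right, child_polys[[2]], child_ids[[2]],
                  child_centers[[2]])
  rbind(tl, tr)
}

## Triangulate between two CCW loops (in the (y, z) plane at nearby axial
## positions) by merging on angular parameter about `center`. Produces
## triangles wound like an axial strip from loop A to loop B.
zip_loops <- function(polyA, idsA, polyB, idsB, center) {
  angA <- atan2(polyA[, 2] - center[2], polyA[, 1] - center[1])
  angB <- atan2(polyB[, 2] - center[2], polyB[, 1] - center[1])
  ## rotate B to start at the angle closest to A's start
  rot <- which.min((angB - angA[1]) %% (2 * pi))
  ordB <- c(rot:length(idsB), seq_len(rot - 1))
  polyB <- polyB[ordB, , drop = FALSE]
  idsB <- idsB[ordB]
  angB <- angB[ordB]
  ## unwrap both angle sequences to be increasing from angA[1]
  unwrap <- function(a, a0) {
    rel <- (a - a0) %% (2 * pi)
    for (i in seq_along(rel)[-1]) {
      while (rel[i] < rel[i - 1] - pi) rel[i] <- rel[i] + 2 * pi
    }
    rel
  }
  ua <- unwrap(angA, angA[1])
  ub <- unwrap(angB, angA[1])
  na <- length(ua)
  nb <- length(ub)
  tris <- matrix(0L, na + nb, 3)
  cnt <- 0L
  i <- 1L
  j <- 1L
  nexta <- function(i) if (i == na) 1L else i + 1L
  nextb <- function(j) if (j == nb) 1L else j + 1L
  ua_ext <- c(ua, ua[1] + 2 * pi)
  ub_ext <- c(ub, ub[1] + 2 * pi)
  while (i <= na || j <= nb) {
    adv_a <- if (i > na) FALSE else if (j > nb) TRUE else ua_ext[i + 1] <= ub_ext[j + 1]
    cnt <- cnt + 1L
    if (adv_a) {
      tris[cnt, ] <- c(idsA[i], idsA[nexta(i)], idsB[if (j > nb) 1L else j])
      i <- i + 1L
    } else {
      tris[cnt, ] <- c(idsA[if (i > na) 1L else i], idsB[nextb(j)], idsB[j])
      j <- j + 1L
    }
  }
  tris[seq_len(cnt), , drop = FALSE]
}

#' Programmed geometry profile of a phantom
#'
#' Returns the generator's ground-truth section table: for every axial ring,
#' the discretized bilateral area, perimeter and hydraulic diameter the mesh
#' was built to realize. Slicing the emitted mesh with [profile_geometry()]
#' recovers this profile (round-trip consistency).
#'
#' @param surface A phantom produced by [make_phantom()].
#' @return A tibble with `s_norm`, `area_m2`, `perimeter_m`, `dh_m`,
#'   `n_loops`.
#' @export
phantom_profile <- function(surface) {
  ph <- attr(surface, "phantom")
  if (is.null(ph)) abort("not a phantom: no section parameterization attached")
  rings <- ph$sections$rings
  ## the passage split/merge is an axial step: add the bilateral sections an
  ## infinitesimal distance inside the junctions so interpolation of the
  ## profile is piecewise-correct across the topology change
  sf <- ph$sections$split_frac
  mf <- ph$sections$merge_frac
  if (!is.null(sf) && is.finite(sf)) {
    extra <- phantom_sections(ph$spec, ph$sections$congestion,
                              stations = c(sf + 1e-9, mf - 1e-9))$rings
    rings <- c(rings, extra)
  }
  rows <- lapply(rings, function(r) {
    a <- sum(vapply(r$loops, `[[`, numeric(1), "area_mm2")) * MM2
    p <- sum(vapply(r$loops, `[[`, numeric(1), "perimeter_mm")) * MM
    tibble(s_norm = r$s_norm, area_m2 = a, perimeter_m = p,
           dh_m = 4 * a / p, n_loops = length(r$loops))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$s_norm)
}

#' Generate a straight tube phantom
#'
#' A circular (optionally varying-radius) straight duct along +x with labeled
#' caps and the section parameterization needed by [assign_analytic_flow()].
#' Used for oracle checks against closed-form laminar (Hagen-Poiseuille)
#' results.
#'
#' @param diameter_mm Tube diameter (mm), or a function of `s_norm` in
#'   `[0, 1]` returning the local diameter.
#' @param length_mm Tube length (mm).
#' @param n_rings Axial rings.
#' @param ring_vertices Vertices per ring.
#' @return An [airway_surface()] with attribute `"phantom"`.
#' @examples
#' tube <- make_tube(6, 50)
#' cavity_metrics(tube)
#' @export
make_tube <- function(diameter_mm, length_mm, n_rings = 41,
                      ring_vertices = 96) {
  dfun <- if (is.function(diameter_mm)) diameter_mm else function(s) diameter_mm
  stations <- seq(0, 1, length.out = n_rings)
  rings <- lapply(stations, function(s) {
    r <- dfun(s) / 2
    if (r <= 0) abort("infeasible profile: non-positive radius")
    poly <- ellipse_polygon(c(0, 0), r, r, ring_vertices)
    list(s_norm = s, x = s * length_mm, type = "single",
         loops = list(list(
           passage = "S", center = c(0, 0), kind = "ellipse", a = r, b = r,
           eps = 0, polygon = poly, area_mm2 = poly2_area(poly),
           perimeter_mm = poly2_perimeter(poly)
         )))
  })
  nvr <- ring_vertices
  verts <- do.call(rbind, lapply(rings, function(r) {
    cbind(r$x, r$loops[[1]]$polygon[, 1], r$loops[[1]]$polygon[, 2])
  }))
  tris <- list()
  for (i in seq_len(n_rings - 1)) {
    a0 <- (i - 1) * nvr
    b0 <- i * nvr
    j <- seq_len(nvr)
    jn <- c(2:nvr, 1)
    tris[[2 * i - 1]] <- cbind(a0 + j, a0 + jn, b0 + j)
    tris[[2 * i]] <- cbind(a0 + jn, b0 + jn, b0 + j)
  }
  cin <- nrow(verts) + 1L
  cout <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(length_mm, 0, 0))
  j <- seq_len(nvr)
  jn <- c(2:nvr, 1)
  tris[[length(tris) + 1]] <- cbind(rep(cin, nvr), jn, j)
  tris[[length(tris) + 1]] <- cbind(rep(cout, nvr),
                                    (n_rings - 1) * nvr + j,
                                    (n_rings - 1) * nvr + jn)
  tris <- do.call(rbind, tris)
  lab <- rep("wall", nrow(tris))
  lab[(nrow(tris) - 2 * nvr + 1):(nrow(tris) - nvr)] <- "inlet"
  lab[(nrow(tris) - nvr + 1):nrow(tris)] <- "outlet"
  surf <- airway_surface(verts, tris, lab)
  attr(surf, "phantom") <- list(
    spec = list(length_mm = length_mm, kind = "tube"),
    sections = list(rings = rings, stations = stations, y_off = 0,
                    congestion = NA_real_, split_frac = NA_real_,
                    merge_frac = NA_real_)
  )
  surf
}
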