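#' Cohort specification
#'
#' Parameters of a paired (normal vs decongested) synthetic cohort. Each
#' subject is a [phantom_spec()] whose caliber, valve size, length and
#' decongestion response are multiplicative lognormal perturbations of the
#' cohort means; measurement noise is multiplicative lognormal on the
#' reported metrics. The decongestion effect on the turbinate-plateau CSA
#' defaults to a ratio of 1.348 (a 34.8% increase).
#'
#' @param n_subjects Number of paired subjects (default 10).
#' @param csa_cv Coefficient of variation of the subject caliber factor
#'   (scales all CSA control values).
#' @param valve_cv Additional CV of the nasal-valve CSA.
#' @param length_cv CV of the centerline length.
#' @param effect_ratio Cohort-mean decongested/normal plateau CSA ratio
#'   (1 = null cohort).
#' @param effect_cv Subject-level CV of the decongestion ratio.
#' @param noise_cv Measurement noise CV applied to every reported metric.
#' @param resistance_effect Optional programmed decongested/normal ratio for
#'   the resistance metrics; when set, the decongested resistances are the
#'   normal values scaled by this ratio (with measurement noise), giving
#'   direct control of the effect size (e.g. `0.5` for a 50% reduction).
#'   When `NULL` (default) resistances follow from the subject geometries.
#' @param flow_lpm Flow-rate presets (L/min) at which resistances are
#'   reported.
#' @param seed Master seed; the cohort is fully reproducible given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, csa_cv = 0.15, valve_cv = 0.15,
                        length_cv = 0.07, effect_ratio = 1.348,
                        effect_cv = 0.05, noise_cv = 0.03,
                        resistance_effect = NULL, flow_lpm = c(15, 30),
                        seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be at least 2")
  if (effect_ratio <= 0) abort("`effect_ratio` must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, effect ratio %.3f, noise CV %.2g, seed %d\n",
    x$n_subjects, x$effect_ratio, x$noise_cv, as.integer(x$seed)
  ))
  invisible(x)
}

## lognormal factor with unit median and coefficient of variation cv
rln <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

## Draw the per-subject phantom specs (normal and decongested states share
## one anatomy; the state differs only in the congestion morph targets).
sample_subject_specs <- function(cspec) {
  n <- cspec$n_subjects
  caliber <- rln(n, cspec$csa_cv)
  valve <- rln(n, cspec$valve_cv)
  len <- rln(n, cspec$length_cv)
  eff <- cspec$effect_ratio * rln(n, cspec$effect_cv)
  base <- phantom_spec()
  lapply(seq_len(n), function(i) {
    plateau_n <- base$plateau_csa_normal_cm2 * caliber[i]
    v1_n <- base$v1_csa_normal_cm2 * caliber[i]
    phantom_spec(
      length_mm = base$length_mm * len[i],
      nostril_csa_cm2 = base$nostril_csa_cm2 * caliber[i],
      valve_csa_cm2 = base$valve_csa_cm2 * caliber[i] * valve[i],
      as_csa_cm2 = base$as_csa_cm2 * caliber[i],
      plateau_csa_normal_cm2 = plateau_n,
      plateau_csa_decongested_cm2 = plateau_n * eff[i],
      v1_csa_normal_cm2 = v1_n,
      v1_csa_decongested_cm2 = v1_n * (1 + 0.5 * (eff[i] - 1)),
      postmerge_csa_cm2 = base$postmerge_csa_cm2 * caliber[i],
      naso_csa_cm2 = base$naso_csa_cm2 * caliber[i]
    )
  })
}

## ---- analytic (closed-form) metric engine ----

## memoized shape function g(eps) = Perimeter / sqrt(area) of the unit lobed
## contour; monotone increasing, used to invert the perimeter-preservation
## condition without per-station root finding
cleft_shape_env <- new.env(parent = emptyenv())
cleft_shape_table <- function(k) {
  key <- as.character(k)
  tab <- cleft_shape_env[[key]]
  if (is.null(tab)) {
    eps <- seq(0, 0.9, by = 0.005)
    g <- vapply(eps, function(e) {
      lobed_perimeter(1, e, k, nq = 128) / sqrt(pi * (1 + e^2 / 2))
    }, numeric(1))
    tab <- list(eps = eps, g = g)
    cleft_shape_env[[key]] <- tab
  }
  tab
}

## cleft depth preserving the normal-state perimeter at a new area
cleft_depth_preserving <- function(eps_n, area_ratio, k) {
  tab <- cleft_shape_table(k)
  g_n <- approx(tab$eps, tab$g, eps_n, rule = 2)$y
  g_target <- g_n / sqrt(area_ratio)
  pmax(0, approx(tab$g, tab$eps, pmin(pmax(g_target, tab$g[1]), max(tab$g)),
                 rule = 2)$y)
}

## ellipse perimeter (quadrature)
ellipse_perimeter <- function(a, b, nq = 128) {
  th <- seq(0, 2 * pi, length.out = nq + 1)[-(nq + 1)]
  sum(sqrt((a * sin(th))^2 + (b * cos(th))^2)) * (2 * pi / nq)
}

## memoized ellipse shape function h(gamma) = Perimeter / sqrt(area) of an
## ellipse with aspect ratio gamma
ellipse_shape_table <- function() {
  tab <- cleft_shape_env[["ellipse"]]
  if (is.null(tab)) {
    gam <- c(seq(1, 5, by = 0.05), seq(5.2, 60, by = 0.2))
    h <- vapply(gam, function(g) {
      ellipse_perimeter(sqrt(g / pi), sqrt(1 / (pi * g)))
    }, numeric(1))
    tab <- list(gamma = gam, h = h)
    cleft_shape_env[["ellipse"]] <- tab
  }
  tab
}

## Station table of the analytic phantom sections: bilateral A (m^2),
## P (m), per-passage d_h (m), for congestion state c. Fully vectorized via
## the memoized shape functions (P = sqrt(A) * shape(eps or gamma)).
analytic_station_table <- function(spec, congestion, n_stations = 61) {
  s <- seq(0, 1, length.out = n_stations)
  area_fun <- phantom_area_fun(spec)
  lm <- spec$landmarks
  k <- spec$n_lobes
  a_tot <- area_fun(s, congestion)            # mm^2 bilateral
  a_tot_n <- area_fun(s, 1)
  bilat <- s > spec$split_frac & s < lm[["PS"]]
  eps_n <- spec$lobe_depth * cleft_ramp(s, lm)
  gtab <- cleft_shape_table(k)
  etab <- ellipse_shape_table()
  ## bilateral: cleft depth adjusts to preserve the normal-state perimeter
  ## where feasible (clamped at a circular contour otherwise), and the state
  ## perimeter follows from the state's area and cleft depth
  eps_c <- cleft_depth_preserving(eps_n, (a_tot / 2) / (a_tot_n / 2), k)
  g_c <- approx(gtab$eps, gtab$g, eps_c, rule = 2)$y
  p_pass <- sqrt(a_tot / 2) * g_c
  ## single duct: elliptical with the junction-widening aspect ramp
  y_off <- analytic_y_off(spec)
  p_tot <- 2 * p_pass
  for (i in which(!bilat)) {
    gam <- single_aspect(spec, area_fun, s[i], y_off)
    h <- approx(etab$gamma, etab$h, min(gam, max(etab$gamma)), rule = 2)$y
    p_tot[i] <- sqrt(a_tot[i]) * h
    eps_c[i] <- 0
  }
  n_loops <- ifelse(bilat, 2, 1)
  a_m2 <- a_tot * MM2
  p_m <- p_tot * MM
  tibble(
    s_norm = s, bilateral = bilat, n_loops = n_loops,
    area_m2 = a_m2, perimeter_m = p_m, dh_m = 4 * a_m2 / p_m,
    ## per-loop hydraulic diameter drives the laminar gradient
    dh_loop_m = 4 * (a_m2 / n_loops) / (p_m / n_loops),
    eps = eps_c
  )
}

## lateral passage offset used by the analytic ellipse aspect (memoized on
## the spec's plateau geometry; matches phantom_sections() closely enough
## for the vestibule perimeter, which the resistance barely sees)
analytic_y_off <- function(spec) {
  a_plateau <- max(spec$plateau_csa_normal_cm2,
                   spec$plateau_csa_decongested_cm2) * 100 / 2
  r0 <- lobed_r0(a_plateau, spec$lobe_depth)
  r0 * (1 + spec$lobe_depth) + 0.8
}

## Analytic whole-cavity and regional metrics for one subject state.
## Returns a named list of metric values in reporting units.
phantom_metrics_analytic <- function(spec, congestion, flow_lpm = c(15, 30),
                                     props = fluid_properties(),
                                     n_stations = 61, regional = TRUE) {
  st <- analytic_station_table(spec, congestion, n_stations)
  L <- spec$length_mm * MM
  x <- st$s_norm * L
  lm <- spec$landmarks
  sa <- trapz(x, st$perimeter_m)
  cv <- trapz(x, st$area_m2)
  out <- list(
    SA_cm2 = sa * 1e4, CV_cm3 = cv * 1e6, SAVR_per_cm = (sa / cv) / 100,
    CSA_plateau_cm2 = mean(st$area_m2[st$s_norm >= 0.45 & st$s_norm <= 0.70]) * 1e4
  )

  mu <- props$mu
  for (lpm in flow_lpm) {
    q <- flow_rate_lpm(lpm)
    q_loop <- q / st$n_loops
    grad <- 128 * mu * q_loop / (pi * st$dh_loop_m^4)   # Pa/m
    ## total-pressure loss is the viscous loss alone: the Bernoulli exchange
    ## between static and dynamic pressure cancels in the plane-mean total
    rseg <- function(s_lo, s_hi) {
      sel <- st$s_norm >= s_lo - 1e-9 & st$s_norm <= s_hi + 1e-9
      trapz(x[sel], grad[sel]) / q * 1e-6                # Pa.s/ml
    }
    tag <- as.character(lpm)
    out[[paste0("R_total_", tag, "_Pa_s_ml")]] <- rseg(0, 1)
    out[[paste0("R_anterior_", tag, "_Pa_s_ml")]] <- rseg(0, lm[["V1"]])
    out[[paste0("R_posterior_", tag, "_Pa_s_ml")]] <- rseg(lm[["V1"]], lm[["PS"]])
  }

  if (regional) {
    reg <- analytic_regional_savr(spec, congestion, st)
    out <- c(out, reg)
  }
  out
}

## Regional (superior/middle/inferior) SA, CV and SAVR by clipping the
## analytic contours at the equal-thirds horizontal planes of the turbinate
## region's vertical extent.
analytic_regional_savr <- function(spec, congestion, st) {
  lm <- spec$landmarks
  k <- spec$n_lobes
  area_fun <- phantom_area_fun(spec)
  turb <- st$s_norm >= lm[["V1"]] & st$s_norm <= lm[["PS"]]
  zmax <- 0
  polys <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    if (st$bilateral[i]) {
      a_pass <- st$area_m2[i] / 2 / MM2
      r0 <- lobed_r0(a_pass, st$eps[i])
      poly <- lobed_polygon(c(0, 0), r0, st$eps[i], k, 64, phase = pi / (2 * k))
    } else {
      gam <- single_aspect(spec, area_fun, st$s_norm[i], analytic_y_off(spec))
      a_tot <- st$area_m2[i] / MM2
      b <- sqrt(a_tot / (pi * gam))
      poly <- ellipse_polygon(c(0, 0), gam * b, b, 64)
    }
    polys[[i]] <- poly
    if (turb[i]) zmax <- max(zmax, max(abs(poly[, 2])))
  }
  z1 <- -zmax / 3
  z2 <- zmax / 3
  L <- spec$length_mm * MM
  x <- st$s_norm * L
  bands <- list(superior = c(z2, Inf), middle = c(z1, z2), inferior = c(-Inf, z1))
  out <- list()
  for (rn in names(bands)) {
    zb <- bands[[rn]]
    a_band <- numeric(nrow(st))
    p_band <- numeric(nrow(st))
    for (i in seq_len(nrow(st))) {
      m <- if (st$bilateral[i]) 2 else 1   # bilateral loops are mirror images
      cb <- clip_band_2d(polys[[i]], zb[1], zb[2])
      a_band[i] <- m * cb$area * MM2
      p_band[i] <- m * cb$wall_len * MM
    }
    sa <- trapz(x, p_band)
    cv <- trapz(x, a_band)
    out[[paste0("SAVR_", rn, "_per_cm")]] <- if (cv > 0) (sa / cv) / 100 else NA_real_
    out[[paste0("SA_", rn, "_cm2")]] <- sa * 1e4
    out[[paste0("CV_", rn, "_cm3")]] <- cv * 1e6
  }
  out
}

## Clip a 2D polygon to the horizontal band z in [z_lo, z_hi]; returns the
## clipped area and the length of the original boundary inside the band
## (the mucosal wall; clip chords are not wall).
clip_band_2d <- function(poly, z_lo, z_hi) {
  clipped <- sh_clip(poly, z_lo, keep_above = TRUE)
  if (!is.null(clipped)) clipped <- sh_clip(clipped, z_hi, keep_above = FALSE)
  area <- if (is.null(clipped) || nrow(clipped) < 3) 0 else abs(poly2_area(clipped))
  j <- c(2:nrow(poly), 1)
  zm <- (poly[, 2] + poly[j, 2]) / 2
  seg <- sqrt((poly[j, 1] - poly[, 1])^2 + (poly[j, 2] - poly[, 2])^2)
  list(area = area, wall_len = sum(seg[zm >= z_lo & zm < z_hi]))
}

## Sutherland-Hodgman clip of a polygon against a horizontal line
sh_clip <- function(poly, z0, keep_above) {
  if (!is.finite(z0)) return(poly)
  n <- nrow(poly)
  inside <- if (keep_above) poly[, 2] >= z0 else poly[, 2] <= z0
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  out <- matrix(0, 2 * n, 2)
  cnt <- 0
  for (i in seq_len(n)) {
    jn <- if (i == n) 1 else i + 1
    a <- poly[i, ]
    b <- poly[jn, ]
    if (inside[i]) {
      cnt <- cnt + 1
      out[cnt, ] <- a
    }
    if (inside[i] != inside[jn]) {
      t <- (z0 - a[2]) / (b[2] - a[2])
      cnt <- cnt + 1
      out[cnt, ] <- a + t * (b - a)
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

## ---- mesh-pipeline metric engine ----

## The same metrics, measured by running the full geometric/flow pipeline on
## the emitted mesh. Used to validate the analytic engine and for demo runs.
phantom_metrics_mesh <- function(spec, congestion, flow_lpm = c(15, 30),
                                 props = fluid_properties(),
                                 n_stations = 41, regional = TRUE) {
  surf <- make_phantom(spec, congestion)
  cl <- extract_centerline(surf, n_stations = 40)
  lmk <- place_landmarks(cl, fractions = spec$landmarks, surface = surf)
  prof <- profile_geometry(surf, cl, n_stations = n_stations)
  regions <- c("whole", if (regional) c("superior", "middle", "inferior"))
  met <- cavity_metrics(surf, regions, landmarks = lmk, centerline = cl)
  whole <- met[met$region == "whole", ]
  sel <- prof$s_norm >= 0.45 & prof$s_norm <= 0.70
  out <- list(
    SA_cm2 = whole$SA_m2 * 1e4, CV_cm3 = whole$CV_m3 * 1e6,
    SAVR_per_cm = whole$SAVR_per_m / 100,
    CSA_plateau_cm2 = mean(prof$area_m2[sel]) * 1e4
  )
  if (regional) {
    for (rn in c("superior", "middle", "inferior")) {
      r <- met[met$region == rn, ]
      out[[paste0("SAVR_", rn, "_per_cm")]] <- r$SAVR_per_m / 100
      out[[paste0("SA_", rn, "_cm2")]] <- r$SA_m2 * 1e4
      out[[paste0("CV_", rn, "_cm3")]] <- r$CV_m3 * 1e6
    }
  }
  for (lpm in flow_lpm) {
    fld <- assign_analytic_flow(surf, Q = flow_rate_lpm(lpm), props = props)
    rp <- resistance_profile(fld, prof)
    ap <- anterior_posterior_resistance(rp, lmk)
    tag <- as.character(lpm)
    out[[paste0("R_total_", tag, "_Pa_s_ml")]] <-
      rp$Rcum_Pa_s_per_ml[nrow(rp)]
    out[[paste0("R_anterior_", tag, "_Pa_s_ml")]] <-
      ap$R_Pa_s_per_ml[ap$segment == "anterior"]
    out[[paste0("R_posterior_", tag, "_Pa_s_ml")]] <-
      ap$R_Pa_s_per_ml[ap$segment == "posterior"]
  }
  out
}

metric_units <- function(metric) {
  dplyr::case_when(
    grepl("^SA_", metric) ~ "cm^2",
    grepl("^CV_", metric) ~ "cm^3",
    grepl("^SAVR", metric) ~ "cm^-1",
    grepl("^CSA", metric) ~ "cm^2",
    grepl("^R_", metric) ~ "Pa.s/ml",
    TRUE ~ ""
  )
}

#' Generate a paired synthetic cohort
#'
#' Draws `n_subjects` subject anatomies from a [cohort_spec()], evaluates
#' each in the normal (congested, c = 1) and decongested (c = 0) states, and
#' tabulates the paired metrics that feed [compare_cohort()]: SA, CV, SAVR
#' (whole cavity and vertical regions), plateau CSA, and total /
#' anterior / posterior resistance at each flow-rate preset.
#'
#' Metrics are evaluated from the subjects' closed-form section profiles
#' (the same parameterization the mesh generator discretizes); with
#' `meshes = TRUE` they are instead measured by emitting each phantom mesh
#' and running the full slicing/flow pipeline, which is slower but
#' validates the closed-form path.
#'
#' @param cspec A [cohort_spec()].
#' @param meshes Use the mesh pipeline instead of the closed-form engine.
#' @param metrics Optional character vector restricting which metrics are
#'   computed (prefix match), e.g. `"R_total_15"`; `NULL` computes all.
#' @param n_stations Stations per subject state.
#' @return A `cohort` object: list with `table` (tibble: `subject`,
#'   `metric`, `units`, `value_normal`, `value_decongested`),
#'   `subject_specs`, and `spec`.
#' @export
generate_cohort <- function(cspec, meshes = FALSE, metrics = NULL,
                            n_stations = if (meshes) 41 else 61) {
  withr::local_seed(as.integer(cspec$seed))
  specs <- sample_subject_specs(cspec)
  regional <- is.null(metrics) || any(grepl("^(SAVR_s|SAVR_m|SAVR_i|SA_|CV_)", metrics))
  engine <- if (meshes) phantom_metrics_mesh else phantom_metrics_analytic
  rows <- vector("list", cspec$n_subjects)
  for (i in seq_len(cspec$n_subjects)) {
    m_n <- engine(specs[[i]], congestion = 1, flow_lpm = cspec$flow_lpm,
                  n_stations = n_stations, regional = regional)
    m_d <- engine(specs[[i]], congestion = 0, flow_lpm = cspec$flow_lpm,
                  n_stations = n_stations, regional = regional)
    nm <- names(m_n)
    if (!is.null(metrics)) {
      keep <- Reduce(`|`, lapply(metrics, function(p) startsWith(nm, p)))
      nm <- nm[keep]
    }
    v_n <- unlist(m_n[nm])
    v_d <- unlist(m_d[nm])
    ## programmed resistance effect overrides the geometric one
    if (!is.null(cspec$resistance_effect)) {
      is_r <- startsWith(nm, "R_")
      v_d[is_r] <- v_n[is_r] * cspec$resistance_effect
    }
    ## multiplicative lognormal measurement noise, independent per state
    v_n <- v_n * rln(length(v_n), cspec$noise_cv)
    v_d <- v_d * rln(length(v_d), cspec$noise_cv)
    rows[[i]] <- tibble(
      subject = sprintf("S%02d", i), metric = nm, units = metric_units(nm),
      value_normal = unname(v_n), value_decongested = unname(v_d)
    )
  }
  structure(
    list(table = dplyr::bind_rows(rows), subject_specs = specs, spec = cspec),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects x %d metrics (seed %d)\n",
    x$spec$n_subjects, length(unique(x$table$metric)), as.integer(x$spec$seed)
  ))
  invisible(x)
}

#' Monte-Carlo replication of the cohort pipeline
#'
#' Repeats cohort generation and the paired Wilcoxon test of one metric over
#' many master seeds, returning the per-replicate p-value. Used to calibrate
#' the type-I error of the full pipeline under a null cohort
#' (`effect_ratio = 1`, `resistance_effect = 1`) and its power under a
#' programmed effect.
#'
#' @param cspec A [cohort_spec()]; its `seed` seeds the replicate-seed draw.
#' @param metric Metric name to test (exact match).
#' @param n_rep Number of replicates.
#' @return A tibble with `replicate`, `seed`, `p_value`.
#' @export
replicate_cohort_test <- function(cspec, metric = "R_total_15_Pa_s_ml",
                                  n_rep = 200) {
  withr::local_seed(as.integer(cspec$seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  res <- vapply(seq_len(n_rep), function(i) {
    cs <- cspec
    cs$seed <- seeds[i]
    co <- generate_cohort(cs, metrics = metric)
    tb <- co$table[co$table$metric == metric, ]
    wilcoxon_signed_rank(tb$value_normal, tb$value_decongested)$p_value
  }, numeric(1))
  tibble(replicate = seq_len(n_rep), seed = seeds, p_value = res)
}
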