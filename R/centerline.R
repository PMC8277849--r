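#' Extract the airway centerline
#'
#' Marches a polyline from the inlet-cap centroid to the outlet-cap centroid
#' by iterated slicing: planes normal to the current polyline are cut through
#' the lumen, each station point is replaced by the area-weighted centroid of
#' the intersection loops, and the procedure repeats until the largest station
#' displacement falls below `tol_mm` (default 0.1 mm) or `max_iter` passes.
#'
#' @param surface An [airway_surface()].
#' @param n_stations Number of interior stations used during marching.
#' @param tol_mm Convergence tolerance on station displacement (mm).
#' @param max_iter Maximum number of slice-centroid passes.
#' @return A `centerline`: list with `points` (mm, ordered inlet to outlet),
#'   `s` (arc length, mm) and `s_norm` (normalized distance in `[0, 1]`).
#' @examples
#' tube <- make_tube(diameter_mm = 6, length_mm = 50)
#' cl <- extract_centerline(tube, n_stations = 20)
#' range(cl$s)
#' @export
extract_centerline <- function(surface, n_stations = 60, tol_mm = 0.1,
                               max_iter = 10) {
  stopifnot(n_stations >= 2)
  v <- surface$vertices
  f <- surface$faces
  p_in <- faces_centroid(v, f[surface$face_label == "inlet", , drop = FALSE])
  p_out <- faces_centroid(v, f[surface$face_label == "outlet", , drop = FALSE])

  tt <- seq(0, 1, length.out = n_stations + 2)[2:(n_stations + 1)]
  pts <- rbind(p_in, t(sapply(tt, function(t) p_in + t * (p_out - p_in))), p_out)
  rownames(pts) <- NULL

  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    tang <- polyline_tangents(pts)
    newpts <- pts
    for (k in 2:(nrow(pts) - 1)) {
      loops <- slice_mesh(v, f, pts[k, ], tang[k, ])
      if (length(loops) == 0) {
        abort(sprintf(
          "empty lumen intersection at station %.3f during centerline extraction",
          (k - 1) / (nrow(pts) - 1)
        ))
      }
      props <- lapply(loops, polygon_props, origin = pts[k, ], normal = tang[k, ])
      areas <- vapply(props, `[[`, numeric(1), "area")
      cents <- t(vapply(props, `[[`, numeric(3), "centroid"))
      newpts[k, ] <- colSums(cents * areas) / sum(areas)
    }
    ## stabilize the march: light smoothing of the interior points, then
    ## uniform arc-length resampling (endpoints stay at the cap centroids)
    newpts <- resample_polyline(smooth_polyline(newpts), nrow(pts))
    delta <- max(sqrt(rowSums((newpts - pts)^2)))
    pts <- newpts
    if (delta < tol_mm) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "centerline extraction did not converge below %.3g mm in %d iterations",
      tol_mm, max_iter
    ))
  }
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (any(diff(s) <= 0)) abort("degenerate centerline: arc length not increasing")
  structure(
    list(points = pts, s = s, s_norm = s / s[length(s)]),
    class = "centerline"
  )
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf(
    "<centerline> %d points, arc length %.1f mm\n",
    nrow(x$points), x$s[length(x$s)]
  ))
  invisible(x)
}

## Internal: (1, 2, 1)/4 smoothing of interior polyline points
smooth_polyline <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  out <- pts
  out[2:(n - 1), ] <- (pts[1:(n - 2), ] + 2 * pts[2:(n - 1), ] + pts[3:n, ]) / 4
  out
}

## Internal: resample a polyline to n points uniform in arc length
resample_polyline <- function(pts, n) {
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (s[length(s)] <= 0) return(pts)
  si <- seq(0, s[length(s)], length.out = n)
  cbind(
    approx(s, pts[, 1], si)$y,
    approx(s, pts[, 2], si)$y,
    approx(s, pts[, 3], si)$y
  )
}

## Internal: unit tangents along a polyline (central differences)
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tang / sqrt(rowSums(tang^2))
}

## Internal: point and unit tangent at normalized distance s_norm
centerline_at <- function(centerline, s_norm) {
  sn <- centerline$s_norm
  pts <- centerline$points
  point <- c(
    approx(sn, pts[, 1], s_norm, rule = 2)$y,
    approx(sn, pts[, 2], s_norm, rule = 2)$y,
    approx(sn, pts[, 3], s_norm, rule = 2)$y
  )
  tang <- polyline_tangents(pts)
  tv <- c(
    approx(sn, tang[, 1], s_norm, rule = 2)$y,
    approx(sn, tang[, 2], s_norm, rule = 2)$y,
    approx(sn, tang[, 3], s_norm, rule = 2)$y
  )
  list(point = point, tangent = unitize(tv))
}

#' Place anatomical landmarks on a centerline
#'
#' Anatomical landmark planes are located as fractions of normalized
#' centerline distance. The defaults are cohort-mean fractions: nasal valve
#' (NV) 0.12, anterior septum (AS) 0.18, vertical thirds of the septal region
#' (1V, 2V, 3V) at 0.32, 0.45, 0.58, posterior septum (PS) 0.72, with the
#' nostril (Nos) and nasopharynx (Naso) pinned to 0 and 1. The horizontal
#' divider planes 1H and 2H split the lumen's vertical extent over the
#' turbinate region (1V to PS) into equal thirds unless given explicitly.
#'
#' @param centerline A [extract_centerline()] result.
#' @param fractions Named numeric vector of landmark fractions; any subset of
#'   `NV, AS, V1, V2, V3, PS` may be overridden. Must be non-decreasing.
#' @param surface Optional [airway_surface()] used to locate the default
#'   1H/2H planes from the lumen's vertical extent in the turbinate region.
#' @param plane_1H,plane_2H Optional explicit planes, each a list with
#'   `origin` and `normal` (mm); `plane_1H` must lie below `plane_2H` along
#'   the vertical axis.
#' @param vertical_axis Unit vector of the anatomical vertical (default +z).
#' @return A `landmark_set`: list of `fractions` (named, including `Nos` and
#'   `Naso`), `plane_1H`, `plane_2H`.
#' @export
place_landmarks <- function(centerline, fractions = NULL, surface = NULL,
                            plane_1H = NULL, plane_2H = NULL,
                            vertical_axis = c(0, 0, 1)) {
  fr <- c(NV = 0.12, AS = 0.18, V1 = 0.32, V2 = 0.45, V3 = 0.58, PS = 0.72)
  if (!is.null(fractions)) {
    unknown <- setdiff(names(fractions), names(fr))
    if (length(unknown) > 0) {
      abort(sprintf("unknown landmark name(s): %s", paste(unknown, collapse = ", ")))
    }
    fr[names(fractions)] <- fractions
  }
  fr <- c(Nos = 0, fr, Naso = 1)
  if (any(diff(fr) < 0)) {
    abort("landmark fractions must be ordered Nos <= NV <= AS <= 1V <= 2V <= 3V <= PS <= Naso")
  }
  if (any(fr < 0 | fr > 1)) abort("landmark fractions must lie in [0, 1]")

  if (is.null(plane_1H) != is.null(plane_2H)) {
    abort("either give both `plane_1H` and `plane_2H` or neither")
  }
  if (is.null(plane_1H) && !is.null(surface)) {
    zr <- turbinate_vertical_extent(surface, centerline, fr[["V1"]], fr[["PS"]],
                                    vertical_axis)
    zl <- zr[1] + diff(zr) / 3
    zu <- zr[1] + 2 * diff(zr) / 3
    mid <- centerline_at(centerline, (fr[["V1"]] + fr[["PS"]]) / 2)$point
    o1 <- mid + (zl - sum(mid * vertical_axis)) * vertical_axis
    o2 <- mid + (zu - sum(mid * vertical_axis)) * vertical_axis
    plane_1H <- list(origin = o1, normal = vertical_axis)
    plane_2H <- list(origin = o2, normal = vertical_axis)
  }
  if (!is.null(plane_1H)) {
    h1 <- sum(plane_1H$origin * vertical_axis)
    h2 <- sum(plane_2H$origin * vertical_axis)
    if (h1 >= h2) abort("plane 1H must lie strictly below plane 2H")
  }
  structure(
    list(fractions = fr, plane_1H = plane_1H, plane_2H = plane_2H,
         vertical_axis = unitize(vertical_axis)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n  fractions:",
      paste(sprintf("%s=%.3g", names(x$fractions), x$fractions), collapse = " "),
      "\n")
  cat(sprintf("  1H/2H planes: %s\n",
              if (is.null(x$plane_1H)) "not set" else "set"))
  invisible(x)
}

## Internal: vertical (along axis) extent of the lumen between two stations
turbinate_vertical_extent <- function(surface, centerline, f_lo, f_hi,
                                      vertical_axis, n_probe = 9) {
  zr <- c(Inf, -Inf)
  for (sn in seq(f_lo, f_hi, length.out = n_probe)) {
    at <- centerline_at(centerline, sn)
    loops <- slice_mesh(surface$vertices, surface$faces, at$point, at$tangent)
    for (lp in loops) {
      z <- lp %*% vertical_axis
      zr[1] <- min(zr[1], min(z))
      zr[2] <- max(zr[2], max(z))
    }
  }
  if (!is.finite(zr[1]) || zr[2] <= zr[1]) {
    abort("could not measure the lumen's vertical extent in the turbinate region")
  }
  zr
}
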