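#' Slice one cross-section
#'
#' Cuts the lumen with a plane through the centerline point at normalized
#' distance `s_norm`, normal to the local centerline tangent. All intersection
#' loops are retained and summed bilaterally: the section area `A`, perimeter
#' `P` and hydraulic diameter `d_h = 4A/P` cover every passage the plane
#' crosses (left plus right, and any turbinate lobes).
#'
#' @param surface An [airway_surface()].
#' @param centerline A [extract_centerline()] result for the same surface.
#' @param s_norm Station in `[0, 1]`.
#' @param end_offset Optional inward nudge (fraction of length) applied to
#'   the end stations. The default 0 cuts exactly at the cap planes, which
#'   the slicer handles by its vertex perturbation; a small positive value
#'   can help with caps that are oblique to the centerline tangent.
#' @return A `cross_section`: list with `s_norm`, `origin`, `normal` (the
#'   cutting plane, mm), `loops` (list of k x 3 point matrices, mm),
#'   per-loop areas/perimeters/centroids, and summed `A` (m^2), `P` (m),
#'   `d_h` (m) and area-weighted `centroid` (mm).
#' @examples
#' tube <- make_tube(diameter_mm = 20, length_mm = 100)
#' cl <- extract_centerline(tube, n_stations = 10)
#' cs <- slice_cross_section(tube, cl, 0.5)
#' c(cs$A, cs$P, cs$d_h)
#' @export
slice_cross_section <- function(surface, centerline, s_norm, end_offset = 0) {
  if (s_norm < 0 || s_norm > 1) abort("`s_norm` must lie in [0, 1]")
  s_cut <- min(max(s_norm, end_offset), 1 - end_offset)
  at <- centerline_at(centerline, s_cut)
  origin <- at$point
  ## end planes move 1e-6 mm into the lumen so the cut is never on the
  ## empty side of a cap; the offset is far below discretization error
  if (s_cut < 1e-9) origin <- origin + 1e-6 * at$tangent
  if (s_cut > 1 - 1e-9) origin <- origin - 1e-6 * at$tangent
  loops <- slice_mesh(surface$vertices, surface$faces, origin, at$tangent)
  if (length(loops) == 0) {
    abort(sprintf("empty lumen intersection at station s_norm = %.4f", s_norm))
  }
  props <- lapply(loops, polygon_props, origin = origin, normal = at$tangent)
  areas_mm2 <- vapply(props, `[[`, numeric(1), "area")
  pers_mm <- vapply(props, `[[`, numeric(1), "perimeter")
  cents <- t(vapply(props, `[[`, numeric(3), "centroid"))
  A <- sum(areas_mm2) * MM2
  P <- sum(pers_mm) * MM
  structure(
    list(
      s_norm = s_norm,
      origin = origin,
      normal = at$tangent,
      loops = loops,
      loop_area_m2 = areas_mm2 * MM2,
      loop_perimeter_m = pers_mm * MM,
      loop_centroid = cents,
      A = A,
      P = P,
      d_h = 4 * A / P,
      centroid = colSums(cents * areas_mm2) / sum(areas_mm2)
    ),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> s_norm = %.3f: %d loop(s), A = %.3f cm^2, P = %.2f cm, d_h = %.2f mm\n",
    x$s_norm, length(x$loops), x$A * 1e4, x$P * 1e2, x$d_h * 1e3
  ))
  invisible(x)
}

#' Profile geometry along the airway
#'
#' Slices `n_stations` cross-sections uniformly spaced in normalized
#' centerline distance and tabulates the cross-sectional area, perimeter and
#' hydraulic diameter profile that drives all downstream resistance and
#' partition analyses.
#'
#' @inheritParams slice_cross_section
#' @param n_stations Number of stations uniform in `s_norm` (default 100).
#' @return A tibble with columns `s_norm`, `area_m2`, `perimeter_m`, `dh_m`,
#'   `n_loops`, carrying the list of `cross_section` objects in the
#'   `"sections"` attribute.
#' @examples
#' tube <- make_tube(diameter_mm = 6, length_mm = 50)
#' cl <- extract_centerline(tube, n_stations = 10)
#' prof <- profile_geometry(tube, cl, n_stations = 11)
#' head(prof)
#' @export
profile_geometry <- function(surface, centerline, n_stations = 100) {
  stopifnot(n_stations >= 2)
  stations <- seq(0, 1, length.out = n_stations)
  sections <- lapply(stations, function(sn) {
    slice_cross_section(surface, centerline, sn)
  })
  out <- tibble(
    s_norm = stations,
    area_m2 = vapply(sections, `[[`, numeric(1), "A"),
    perimeter_m = vapply(sections, `[[`, numeric(1), "P"),
    dh_m = vapply(sections, `[[`, numeric(1), "d_h"),
    n_loops = vapply(sections, function(s) length(s$loops), integer(1))
  )
  attr(out, "sections") <- sections
  class(out) <- c("geometry_profile", class(out))
  out
}

#' Retrieve the cross-section objects behind a geometry profile
#'
#' @param profile A [profile_geometry()] tibble.
#' @return The list of `cross_section` objects.
#' @export
profile_sections <- function(profile) {
  s <- attr(profile, "sections")
  if (is.null(s)) abort("`profile` does not carry cross-section objects")
  s
}

#' Write / read a geometry profile as CSV
#'
#' Columns: `s_norm`, `area_m2`, `perimeter_m`, `dh_m`, `n_loops`.
#'
#' @param profile A [profile_geometry()] tibble.
#' @param path Output CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(
    profile[, c("s_norm", "area_m2", "perimeter_m", "dh_m", "n_loops")], path
  )
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
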