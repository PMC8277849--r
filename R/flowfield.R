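#' Flow field container
#'
#' Velocity and static-pressure samples in the lumen plus wall shear stress
#' samples on the wall, together with the nominal volumetric flow rate and
#' fluid properties. Coordinates are in mm; velocity in m/s, pressure and WSS
#' in Pa, patch areas in m^2.
#'
#' @param points Tibble/data frame with columns `x, y, z, ux, uy, uz, p`
#'   (optionally `s_norm`).
#' @param wall Tibble/data frame with columns `x, y, z, wss, area_m2`
#'   (optionally `s_norm`).
#' @param Q Nominal volumetric flow rate (m^3/s), positive.
#' @param props A [fluid_properties()].
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(points, wall, Q, props = fluid_properties()) {
  points <- as_tibble(points)
  wall <- as_tibble(wall)
  need_p <- c("x", "y", "z", "ux", "uy", "uz", "p")
  if (!all(need_p %in% names(points))) {
    abort(sprintf("`points` must have columns %s", paste(need_p, collapse = ", ")))
  }
  need_w <- c("x", "y", "z", "wss", "area_m2")
  if (nrow(wall) > 0 && !all(need_w %in% names(wall))) {
    abort(sprintf("`wall` must have columns %s", paste(need_w, collapse = ", ")))
  }
  if (!is.numeric(Q) || length(Q) != 1 || Q <= 0) abort("`Q` must be a single positive flow rate (m^3/s)")
  if (nrow(wall) > 0 && any(wall$wss < 0)) abort("WSS magnitudes must be non-negative")
  if (!inherits(props, "fluid_properties")) abort("`props` must be a fluid_properties()")
  structure(list(points = points, wall = wall, Q = Q, props = props),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d lumen samples, %d wall samples, Q = %.3g m^3/s (%.1f L/min)\n",
    nrow(x$points), nrow(x$wall), x$Q, x$Q * 6e4
  ))
  invisible(x)
}

#' Write / read a flow field as CSV tables
#'
#' The field is stored as `<stem>_points.csv`, `<stem>_wall.csv` and
#' `<stem>_meta.json` (flow rate and fluid properties).
#'
#' @param field A [flow_field()].
#' @param stem Path stem (no extension).
#' @return `stem` (write) or a [flow_field()] (read).
#' @export
write_field_csv <- function(field, stem) {
  readr::write_csv(field$points, paste0(stem, "_points.csv"))
  readr::write_csv(field$wall, paste0(stem, "_wall.csv"))
  jsonlite::write_json(
    list(Q = field$Q, rho = field$props$rho, mu = field$props$mu),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  flow_field(
    readr::read_csv(paste0(stem, "_points.csv"), show_col_types = FALSE),
    readr::read_csv(paste0(stem, "_wall.csv"), show_col_types = FALSE),
    Q = meta$Q, props = fluid_properties(meta$rho, meta$mu)
  )
}
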