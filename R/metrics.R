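## Half-space clipping of a labeled triangle soup.
##
## Keeps the side where the signed distance to the plane is negative.
## Crossing triangles are split; the new vertices are cached per mesh edge so
## the seam is shared exactly. The open seam polygon(s), needed to close the
## region for volume integration, are the slice loops of the input mesh.
clip_mesh <- function(vertices, faces, face_label, origin, normal) {
  normal <- unitize(normal)
  d <- plane_distances(vertices, origin, normal)
  pos1 <- d[faces[, 1]] > 0
  pos2 <- d[faces[, 2]] > 0
  pos3 <- d[faces[, 3]] > 0
  npos <- pos1 + pos2 + pos3
  keep_whole <- which(npos == 0)
  crossing <- which(npos == 1 | npos == 2)

  cap_loops <- slice_mesh(vertices, faces, origin, normal, allow_open = TRUE)

  new_v <- list()
  new_f <- list()
  new_lab <- character(0)
  vcount <- nrow(vertices)
  cache <- new.env(parent = emptyenv())
  cut_point <- function(a, b) {
    key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    id <- cache[[key]]
    if (is.null(id)) {
      t <- d[a] / (d[a] - d[b])
      vcount <<- vcount + 1L
      new_v[[length(new_v) + 1]] <<- vertices[a, ] + t * (vertices[b, ] - vertices[a, ])
      id <- vcount
      cache[[key]] <- id
    }
    id
  }
  for (i in crossing) {
    fc <- faces[i, ]
    pos <- d[fc] > 0
    if (sum(pos) == 2) {
      apex <- which(!pos)                      # kept vertex
      a <- fc[apex]
      b <- fc[if (apex == 3) 1 else apex + 1]
      cc <- fc[if (apex == 1) 3 else apex - 1]
      new_f[[length(new_f) + 1]] <- c(a, cut_point(a, b), cut_point(cc, a))
      new_lab <- c(new_lab, face_label[i])
    } else {
      apex <- which(pos)                       # removed vertex
      a <- fc[apex]
      b <- fc[if (apex == 3) 1 else apex + 1]
      cc <- fc[if (apex == 1) 3 else apex - 1]
      ab <- cut_point(a, b)
      ca <- cut_point(cc, a)
      new_f[[length(new_f) + 1]] <- c(ab, b, cc)
      new_f[[length(new_f) + 1]] <- c(ab, cc, ca)
      new_lab <- c(new_lab, face_label[i], face_label[i])
    }
  }
  verts <- rbind(vertices, do.call(rbind, new_v))
  fcs <- rbind(faces[keep_whole, , drop = FALSE], do.call(rbind, new_f))
  labs <- c(face_label[keep_whole], new_lab)
  if (nrow(fcs) == 0) abort("clip produced an empty region")
  list(
    vertices = verts, faces = fcs, face_label = labs,
    ## caps close the region at this plane; outward normal is +normal
    caps = list(list(loops = cap_loops, origin = origin, normal = normal))
  )
}

## Internal: volume (mm^3) of a clipped region: open triangle soup plus
## planar cap polygons. Divergence theorem with F = x/3; each planar cap
## contributes (centroid . n_out) * area / 3.
clipped_volume_mm3 <- function(region) {
  vol <- mesh_volume_mm3(region$vertices, region$faces)
  for (cap in region$caps) {
    for (lp in cap$loops) {
      pr <- polygon_props(lp, cap$origin, cap$normal)
      vol <- vol + sum(pr$centroid * cap$normal) * pr$area / 3
    }
  }
  vol
}

#' Cavity metrics: surface area, volume and SAVR
#'
#' Measures the mucosal (wall) surface area SA, the enclosed lumen volume CV
#' and their ratio SAVR = SA/CV for the whole cavity or an anatomical region.
#' Wall area excludes the inlet/outlet caps and any clip faces, matching the
#' convention that the cavity is bounded by the nostril and nasopharynx
#' planes. Vertical regions are obtained by clipping at the horizontal
#' divider planes 1H and 2H; `anterior` is bounded by the nostril and the 1V
#' plane, `posterior` by the 1V and PS planes.
#'
#' @param surface An [airway_surface()].
#' @param region One or more of `"whole"`, `"superior"`, `"middle"`,
#'   `"inferior"`, `"anterior"`, `"posterior"`.
#' @param landmarks A [place_landmarks()] result; needed (with 1H/2H planes
#'   set) for vertical regions, and (with a `centerline`) for
#'   anterior/posterior.
#' @param centerline Needed for `anterior`/`posterior` regions.
#' @return A tibble with one row per region: `region`, `SA_m2`, `CV_m3`,
#'   `SAVR_per_m`.
#' @examples
#' tube <- make_tube(diameter_mm = 6, length_mm = 50)
#' cavity_metrics(tube)  # SAVR of a circular tube is 4/d
#' @export
cavity_metrics <- function(surface, region = "whole", landmarks = NULL,
                           centerline = NULL) {
  rows <- lapply(region, function(r) {
    cavity_metrics_one(surface, r, landmarks, centerline)
  })
  dplyr::bind_rows(rows)
}

cavity_metrics_one <- function(surface, region, landmarks, centerline) {
  region <- match.arg(region,
    c("whole", "superior", "middle", "inferior", "anterior", "posterior"))
  v <- surface$vertices
  f <- surface$faces
  lab <- surface$face_label

  need_h <- region %in% c("superior", "middle", "inferior")
  need_v <- region %in% c("anterior", "posterior")
  if (need_h && (is.null(landmarks) || is.null(landmarks$plane_1H))) {
    abort("vertical regions need `landmarks` with 1H/2H planes set")
  }
  if (need_v && (is.null(landmarks) || is.null(centerline))) {
    abort("anterior/posterior regions need `landmarks` and `centerline`")
  }

  if (region == "whole") {
    sa <- sum(face_areas_mm2(v, f[lab == "wall", , drop = FALSE]))
    cv <- mesh_volume_mm3(v, f)
  } else {
    planes <- list()
    if (region == "superior") {
      p <- landmarks$plane_2H
      planes <- list(list(origin = p$origin, normal = -unitize(p$normal)))
    } else if (region == "inferior") {
      p <- landmarks$plane_1H
      planes <- list(list(origin = p$origin, normal = unitize(p$normal)))
    } else if (region == "middle") {
      p1 <- landmarks$plane_1H
      p2 <- landmarks$plane_2H
      planes <- list(
        list(origin = p1$origin, normal = -unitize(p1$normal)),
        list(origin = p2$origin, normal = unitize(p2$normal))
      )
    } else {
      cut_at <- function(frac) {
        at <- centerline_at(centerline, frac)
        list(origin = at$point, normal = at$tangent)
      }
      fr <- landmarks$fractions
      if (region == "anterior") {
        planes <- list(cut_at(fr[["V1"]]))
      } else {
        p1 <- cut_at(fr[["V1"]])
        planes <- list(
          list(origin = p1$origin, normal = -p1$normal),
          cut_at(fr[["PS"]])
        )
      }
    }
    reg <- list(vertices = v, faces = f, face_label = lab, caps = list())
    caps_acc <- list()
    for (pl in planes) {
      reg2 <- clip_mesh(reg$vertices, reg$faces, reg$face_label,
                        pl$origin, pl$normal)
      caps_acc <- c(caps_acc, reg2$caps)
      reg <- reg2
    }
    reg$caps <- caps_acc
    if (!any(reg$face_label == "wall")) abort("clip produced an empty region")
    sa <- sum(face_areas_mm2(
      reg$vertices, reg$faces[reg$face_label == "wall", , drop = FALSE]))
    cv <- clipped_volume_mm3(reg)
  }
  if (sa <= 0 || cv <= 0) abort("clip produced an empty region")
  tibble(
    region = region,
    SA_m2 = sa * MM2,
    CV_m3 = cv * MM3,
    SAVR_per_m = (sa * MM2) / (cv * MM3)
  )
}

#' Write cavity metrics as JSON
#'
#' @param metrics A [cavity_metrics()] tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
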