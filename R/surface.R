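#' Airway surface mesh
#'
#' Construct a labeled airway surface: a closed triangulated lumen wall with
#' designated inlet (nostril) and outlet (nasopharynx) caps. Coordinates are
#' in millimetres.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param face_label Character vector of length m with values `"wall"`,
#'   `"inlet"` or `"outlet"`.
#' @param validate Check watertightness and label invariants (default TRUE).
#' @return An object of class `airway_surface`.
#' @export
airway_surface <- function(vertices, faces, face_label, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) abort("`vertices` must be an n x 3 matrix")
  if (length(face_label) != nrow(faces)) {
    abort("`face_label` must have one entry per face")
  }
  if (!all(face_label %in% c("wall", "inlet", "outlet"))) {
    abort("face labels must be 'wall', 'inlet' or 'outlet'")
  }
  x <- structure(
    list(vertices = vertices, faces = faces, face_label = as.character(face_label)),
    class = "airway_surface"
  )
  if (validate) validate_airway_surface(x)
  x
}

#' Validate an airway surface
#'
#' Checks that the mesh (wall plus caps) is closed -- every edge shared by
#' exactly two faces with opposite orientation -- that each of the inlet and
#' outlet caps is a single connected planar patch, and that face winding is
#' globally consistent (positive enclosed volume).
#'
#' @param x An `airway_surface`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_airway_surface <- function(x) {
  f <- x$faces
  if (any(f < 1L) || any(f > nrow(x$vertices))) abort("face index out of range")
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2]
  if (length(bad) > 0) {
    abort(sprintf(
      "mesh is not watertight: %d edge(s) not shared by exactly 2 faces (first: vertices %s)",
      length(bad), bad[1]
    ))
  }
  ## orientation consistency: each undirected edge must appear once per direction
  dirkey <- paste(he[, 1], he[, 2])
  if (any(table(dirkey) > 1)) {
    abort("mesh face winding is inconsistent (repeated directed edge)")
  }
  for (lab in c("inlet", "outlet")) {
    idx <- which(x$face_label == lab)
    if (length(idx) == 0) abort(sprintf("no faces labeled '%s'", lab))
    if (!faces_connected(f[idx, , drop = FALSE])) {
      abort(sprintf("'%s' cap is not a single connected patch", lab))
    }
    if (!faces_coplanar(x$vertices, f[idx, , drop = FALSE])) {
      abort(sprintf("'%s' cap is not planar", lab))
    }
  }
  if (mesh_volume_mm3(x$vertices, f) <= 0) {
    abort("mesh is inside-out (non-positive enclosed volume)")
  }
  invisible(x)
}

## Internal: are faces edge-connected?
faces_connected <- function(faces) {
  nf <- nrow(faces)
  if (nf <= 1) return(TRUE)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(
    cbind(seq_len(nf), ekey(faces[, 1], faces[, 2])),
    cbind(seq_len(nf), ekey(faces[, 2], faces[, 3])),
    cbind(seq_len(nf), ekey(faces[, 3], faces[, 1]))
  )
  by_edge <- split(as.integer(edges[, 1]), edges[, 2])
  adj <- vector("list", nf)
  for (fs in by_edge) {
    if (length(fs) > 1) {
      for (a in fs) adj[[a]] <- c(adj[[a]], setdiff(fs, a))
    }
  }
  seen <- logical(nf)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    nb <- adj[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

## Internal: are faces coplanar within tolerance (mm)?
faces_coplanar <- function(vertices, faces, tol = 1e-3) {
  vid <- unique(as.vector(faces))
  pts <- vertices[vid, , drop = FALSE]
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  # smallest singular value measures out-of-plane extent
  length(s$d) < 3 || s$d[3] <= tol * max(s$d[1], 1)
}

## Internal: signed volume (mm^3) of a closed mesh via divergence theorem
mesh_volume_mm3 <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  sum(
    v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
    v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  ) / 6
}

## Internal: per-face areas (mm^2) and centroids
face_areas_mm2 <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

## Internal: area-weighted centroid (mm) of a set of faces
faces_centroid <- function(vertices, faces) {
  a <- face_areas_mm2(vertices, faces)
  ctr <- (vertices[faces[, 1], , drop = FALSE] +
          vertices[faces[, 2], , drop = FALSE] +
          vertices[faces[, 3], , drop = FALSE]) / 3
  colSums(ctr * a) / sum(a)
}

#' @export
print.airway_surface <- function(x, ...) {
  cat(sprintf(
    "<airway_surface> %d vertices, %d faces (wall %d, inlet %d, outlet %d)\n",
    nrow(x$vertices), nrow(x$faces),
    sum(x$face_label == "wall"), sum(x$face_label == "inlet"),
    sum(x$face_label == "outlet")
  ))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf(
    "  bounding box [mm]: x %.1f..%.1f, y %.1f..%.1f, z %.1f..%.1f\n",
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

#' Load an airway surface from file
#'
#' Reads an STL (ASCII or binary) or legacy-ASCII VTK polydata file. If the
#' file carries a `cap_label` cell field (0 wall, 1 inlet, 2 outlet) it is
#' used directly; otherwise caps are inferred as the two largest connected
#' planar face patches, the one with the smaller centroid coordinate along
#' the mesh's longest axis becoming the inlet.
#'
#' @param path Path to an `.stl`, `.vtk` file.
#' @param inlet Optional point (mm, length-3); the inferred cap nearest to it
#'   becomes the inlet. Overrides the longest-axis heuristic.
#' @return An [airway_surface()].
#' @export
load_surface <- function(path, inlet = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    m <- read_stl(path)
    infer_caps(m$vertices, m$faces, inlet = inlet)
  } else if (ext == "vtk") {
    m <- read_vtk_polydata(path)
    if (!is.null(m$cap_label)) {
      lab <- c("wall", "inlet", "outlet")[m$cap_label + 1L]
      airway_surface(m$vertices, m$faces, lab)
    } else {
      infer_caps(m$vertices, m$faces, inlet = inlet)
    }
  } else {
    abort(sprintf("unsupported mesh format '.%s' (use .stl or .vtk)", ext))
  }
}

## Internal: infer inlet/outlet caps from planar patches of an unlabeled mesh
infer_caps <- function(vertices, faces, inlet = NULL, angle_tol_deg = 1) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  normals <- cbind(nx, ny, nz) / pmax(nn, 1e-30)
  areas <- nn / 2
  nf <- nrow(faces)

  ## union coplanar-and-adjacent faces into patches
  ekey <- paste(pmin(faces[, 1], faces[, 2]), pmax(faces[, 1], faces[, 2]))
  ekey <- cbind(ekey,
                paste(pmin(faces[, 2], faces[, 3]), pmax(faces[, 2], faces[, 3])),
                paste(pmin(faces[, 3], faces[, 1]), pmax(faces[, 3], faces[, 1])))
  parent <- seq_len(nf)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cthr <- cos(angle_tol_deg * pi / 180)
  by_edge <- split(rep(seq_len(nf), 3), as.vector(ekey))
  for (fs in by_edge) {
    if (length(fs) == 2) {
      if (sum(normals[fs[1], ] * normals[fs[2], ]) >= cthr) {
        parent[findp(fs[1])] <- findp(fs[2])
      }
    }
  }
  comp <- vapply(seq_len(nf), findp, integer(1))
  patch_area <- tapply(areas, comp, sum)
  patch_n <- tapply(rep(1L, nf), comp, sum)
  ## caps: the two largest planar patches of at least 4 faces
  big <- patch_n >= 4
  patch_area <- patch_area[big]
  ord <- order(patch_area, decreasing = TRUE)
  planar <- vapply(as.integer(names(patch_area)[ord]), function(p) {
    faces_coplanar(vertices, faces[comp == p, , drop = FALSE], tol = 1e-2)
  }, logical(1))
  cap_ids <- as.integer(names(patch_area)[ord][planar])[1:2]
  cap_ids <- cap_ids[!is.na(cap_ids)]
  if (length(cap_ids) < 2) {
    abort(sprintf("expected 2 cap patches, found %d", length(cap_ids)))
  }
  c1 <- faces_centroid(vertices, faces[comp == cap_ids[1], , drop = FALSE])
  c2 <- faces_centroid(vertices, faces[comp == cap_ids[2], , drop = FALSE])
  if (!is.null(inlet)) {
    d1 <- sum((c1 - inlet)^2)
    first_is_inlet <- d1 <= sum((c2 - inlet)^2)
  } else {
    ax <- which.max(apply(vertices, 2, function(u) diff(range(u))))
    first_is_inlet <- c1[ax] <= c2[ax]
  }
  lab <- rep("wall", nf)
  lab[comp == cap_ids[if (first_is_inlet) 1 else 2]] <- "inlet"
  lab[comp == cap_ids[if (first_is_inlet) 2 else 1]] <- "outlet"
  airway_surface(vertices, faces, lab)
}

#' Write an airway surface to file
#'
#' `.stl` writes ASCII STL (labels are not representable in STL); `.vtk`
#' writes legacy-ASCII VTK polydata with a `cap_label` cell field
#' (0 wall, 1 inlet, 2 outlet) so labels round-trip.
#'
#' @param x An `airway_surface`.
#' @param path Output path ending in `.stl` or `.vtk`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    write_stl(x$vertices, x$faces, path)
  } else if (ext == "vtk") {
    lab <- match(x$face_label, c("wall", "inlet", "outlet")) - 1L
    write_vtk_polydata(x$vertices, x$faces, path, cap_label = lab)
  } else {
    abort(sprintf("unsupported mesh format '.%s' (use .stl or .vtk)", ext))
  }
  invisible(path)
}

## ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri_guess <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.info(path)$size
  is_binary <- length(ntri_guess) == 1 && !is.na(ntri_guess) &&
    fsize == 84 + 50 * as.numeric(ntri_guess)
  if (is_binary) {
    tri <- matrix(0, ntri_guess * 3, 3)
    for (i in seq_len(ntri_guess)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    if (is.null(nums) || nrow(nums) %% 3 != 0) abort("malformed ASCII STL")
    tri <- nums
  }
  ## weld duplicate vertices exactly (phantom writers emit identical coords)
  key <- apply(tri, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl <- function(vertices, faces, path) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  lines <- c(
    "solid nasoair",
    as.vector(rbind(
      paste0("facet normal ", fmt(n)),
      "outer loop",
      paste0("vertex ", fmt(v1)),
      paste0("vertex ", fmt(v2)),
      paste0("vertex ", fmt(v3)),
      "endloop",
      "endfacet"
    )),
    "endsolid nasoair"
  )
  writeLines(lines, path)
  invisible(path)
}

## ---- legacy VTK polydata (ASCII) ----

write_vtk_polydata <- function(vertices, faces, path, cap_label = NULL) {
  n <- nrow(vertices)
  m <- nrow(faces)
  lines <- c(
    "# vtk DataFile Version 3.0",
    "nasoair surface", "ASCII", "DATASET POLYDATA",
    sprintf("POINTS %d double", n),
    sprintf("%.17g %.17g %.17g", vertices[, 1], vertices[, 2], vertices[, 3]),
    sprintf("POLYGONS %d %d", m, 4 * m),
    sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L)
  )
  if (!is.null(cap_label)) {
    lines <- c(
      lines,
      sprintf("CELL_DATA %d", m),
      "SCALARS cap_label int 1",
      "LOOKUP_TABLE default",
      sprintf("%d", cap_label)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

read_vtk_polydata <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (length(ip) != 1) abort("not a legacy VTK polydata file (no POINTS)")
  n <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  pts <- scan(text = txt[(ip + 1):(ip + n)], quiet = TRUE)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", txt)
  if (length(ig) != 1) abort("no POLYGONS section")
  m <- as.integer(strsplit(txt[ig], "\\s+")[[1]][2])
  polys <- scan(text = txt[(ig + 1):(ig + m)], quiet = TRUE)
  polys <- matrix(polys, ncol = 4, byrow = TRUE)
  if (any(polys[, 1] != 3)) abort("only triangle polydata is supported")
  faces <- polys[, 2:4, drop = FALSE] + 1L
  cap_label <- NULL
  il <- grep("^SCALARS cap_label", txt)
  if (length(il) == 1) {
    cap_label <- as.integer(scan(text = txt[(il + 2):(il + 1 + m)], quiet = TRUE))
  }
  list(vertices = vertices, faces = faces, cap_label = cap_label)
}
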