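test_that("a capped cylinder STL round-trips with caps inferred from planar patches", {
  tube <- make_tube(12, 60, n_rings = 9, ring_vertices = 48)
  path <- withr::local_tempfile(fileext = ".stl")
  write_surface(tube, path)
  got <- load_surface(path)
  expect_s3_class(got, "airway_surface")
  expect_equal(sum(got$face_label == "inlet"), 48)
  expect_equal(sum(got$face_label == "outlet"), 48)
  ## inlet is the cap with the smaller coordinate along the long axis
  cin <- nasoair:::faces_centroid(got$vertices,
                                  got$faces[got$face_label == "inlet", ])
  cout <- nasoair:::faces_centroid(got$vertices,
                                   got$faces[got$face_label == "outlet", ])
  expect_lt(cin[1], cout[1])
  ## same enclosed volume as the source mesh
  expect_equal(nasoair:::mesh_volume_mm3(got$vertices, got$faces),
               nasoair:::mesh_volume_mm3(tube$vertices, tube$faces),
               tolerance = 1e-12)
})

test_that("VTK polydata round-trips vertices, faces and labels bit-identically", {
  ph <- make_phantom(phantom_spec(n_rings = 41, ring_vertices = 16))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_surface(ph, path)
  got <- load_surface(path)
  expect_identical(unname(got$vertices), unname(ph$vertices))
  expect_identical(unname(got$faces), unname(ph$faces))
  expect_identical(got$face_label, ph$face_label)
})

test_that("binary STL is read back to the same geometry", {
  tube <- make_tube(8, 30, n_rings = 5, ring_vertices = 24)
  path <- withr::local_tempfile(fileext = ".stl")
  ## write little-endian binary STL by hand
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(tube$faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tube$faces))) {
    tri <- tube$vertices[tube$faces[i, ], ]
    writeBin(c(0, 0, 0, t(tri)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  close(con)
  got <- load_surface(path)
  expect_equal(nrow(got$faces), nrow(tube$faces))
  expect_equal(nasoair:::mesh_volume_mm3(got$vertices, got$faces),
               nasoair:::mesh_volume_mm3(tube$vertices, tube$faces),
               tolerance = 1e-5)
})

test_that("a sphere (no planar caps) is rejected with the cap count", {
  ## lat-long sphere, coarse enough that no 4 faces are coplanar
  nth <- 16
  nph <- 9
  ph <- seq(0, pi, length.out = nph)
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  verts <- rbind(
    c(0, 0, 10),
    do.call(rbind, lapply(ph[2:(nph - 1)], function(p) {
      t(sapply(th, function(t) 10 * c(sin(p) * cos(t), sin(p) * sin(t), cos(p))))
    })),
    c(0, 0, -10)
  )
  tris <- list()
  idx <- function(i, j) 1 + (i - 1) * nth + ((j - 1) %% nth) + 1
  for (j in seq_len(nth)) tris[[length(tris) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in seq_len(nph - 3)) {
    for (j in seq_len(nth)) {
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      tris[[length(tris) + 1]] <- c(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1))
    }
  }
  south <- nrow(verts)
  for (j in seq_len(nth)) {
    tris[[length(tris) + 1]] <- c(south, idx(nph - 2, j + 1), idx(nph - 2, j))
  }
  tris <- do.call(rbind, tris)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl_mesh <- nasoair:::write_stl
  write_stl_mesh(verts, tris, path)
  expect_error(load_surface(path), "expected 2 cap patches, found 0")
})

test_that("open meshes and inconsistent winding are rejected", {
  tube <- make_tube(10, 40, n_rings = 5, ring_vertices = 24)
  open_faces <- tube$faces[-1, ]
  expect_error(
    airway_surface(tube$vertices, open_faces, tube$face_label[-1]),
    "not watertight"
  )
  flipped <- tube$faces
  flipped[1, ] <- flipped[1, c(1, 3, 2)]
  expect_error(
    airway_surface(tube$vertices, flipped, tube$face_label),
    "winding"
  )
})
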