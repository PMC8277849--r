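## Plane/mesh intersection primitives.
##
## All slicing is done with indexed edge intersections: the two endpoints of
## every crossing segment are keyed by the mesh edge they lie on, so chaining
## segments into closed loops is exact (no coordinate matching tolerances).

## Internal: signed distances of vertices to a plane, with degeneracy nudge.
## Vertices closer than `eps` (mm) are pushed to the positive side so that no
## vertex lies exactly on the plane.
plane_distances <- function(vertices, origin, normal, eps = 1e-9) {
  d <- (vertices[, 1] - origin[1]) * normal[1] +
       (vertices[, 2] - origin[2]) * normal[2] +
       (vertices[, 3] - origin[3]) * normal[3]
  d[abs(d) < eps] <- eps
  d
}

## Internal: intersect a triangle soup with a plane.
## Returns a list of closed loops, each an ordered k x 3 matrix of points (mm),
## oriented counter-clockwise about `normal`.
slice_mesh <- function(vertices, faces, origin, normal, allow_open = FALSE) {
  normal <- unitize(normal)
  d <- plane_distances(vertices, origin, normal)
  s1 <- d[faces[, 1]] > 0
  s2 <- d[faces[, 2]] > 0
  s3 <- d[faces[, 3]] > 0
  cross_f <- which((s1 | s2 | s3) & !(s1 & s2 & s3))
  if (length(cross_f) == 0) return(list())

  ## for each crossing face, the two crossed edges (as ordered vertex pairs)
  segs_from <- character(0)
  segs_to <- character(0)
  pt_of <- new.env(parent = emptyenv())
  edge_point <- function(a, b) {
    key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    if (is.null(pt_of[[key]])) {
      t <- d[a] / (d[a] - d[b])
      pt_of[[key]] <- vertices[a, ] + t * (vertices[b, ] - vertices[a, ])
    }
    key
  }
  from <- character(length(cross_f))
  to <- character(length(cross_f))
  for (i in seq_along(cross_f)) {
    fc <- faces[cross_f[i], ]
    sg <- d[fc] > 0
    ## rotate so that exactly one vertex is on the minority side
    if (sum(sg) == 1) {
      apex <- which(sg)
      ## apex above: segment runs (apex->next) to (apex->prev), oriented so the
      ## positive side is to the left, giving CCW loops about `normal`
      a <- fc[apex]
      b <- fc[if (apex == 3) 1 else apex + 1]
      cvx <- fc[if (apex == 1) 3 else apex - 1]
      from[i] <- edge_point(a, b)
      to[i] <- edge_point(cvx, a)
    } else {
      apex <- which(!sg)
      a <- fc[apex]
      b <- fc[if (apex == 3) 1 else apex + 1]
      cvx <- fc[if (apex == 1) 3 else apex - 1]
      from[i] <- edge_point(cvx, a)
      to[i] <- edge_point(a, b)
    }
  }

  ## chain segments into loops: each intersection point (edge key) is entered
  ## and left exactly once on a watertight mesh
  nxt <- setNames(to, from)
  loops <- list()
  visited <- new.env(parent = emptyenv())
  for (start in from) {
    if (!is.null(visited[[start]])) next
    chain <- character(0)
    cur <- start
    closed <- FALSE
    repeat {
      visited[[cur]] <- TRUE
      chain <- c(chain, cur)
      nx <- unname(nxt[cur])
      if (is.na(nx)) {
        if (allow_open) break
        abort("open intersection polyline: the mesh has a boundary crossing the plane")
      }
      if (nx == start) {
        closed <- TRUE
        break
      }
      if (!is.null(visited[[nx]])) break  # defensive: should not happen
      cur <- nx
    }
    if (!closed && !allow_open) {
      abort("open intersection polyline: the mesh has a boundary crossing the plane")
    }
    if (closed && length(chain) >= 3) {
      pts <- do.call(rbind, lapply(chain, function(k) pt_of[[k]]))
      loops[[length(loops) + 1]] <- pts
    }
  }
  loops
}

## Internal: planar polygon properties for a 3D loop lying in a plane.
## Returns area (mm^2, positive), perimeter (mm), area centroid (mm, 3D) and
## the signed area about `normal`.
polygon_props <- function(loop, origin, normal) {
  b <- plane_basis(normal)
  rel <- sweep(loop, 2, origin)
  u <- rel %*% b$e1
  v <- rel %*% b$e2
  n <- length(u)
  j <- c(2:n, 1)
  cr <- u * v[j] - u[j] * v
  a_signed <- sum(cr) / 2
  cu <- sum((u + u[j]) * cr) / (6 * a_signed)
  cv <- sum((v + v[j]) * cr) / (6 * a_signed)
  per <- sum(sqrt(diff(c(u, u[1]))^2 + diff(c(v, v[1]))^2))
  centroid <- origin + cu * b$e1 + cv * b$e2
  list(
    area = abs(a_signed), signed_area = a_signed,
    perimeter = per, centroid = as.numeric(centroid)
  )
}
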