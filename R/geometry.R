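# Rigid transforms, triangle meshes and distance primitives shared by the
# segmentation, registration and morphometry layers. All coordinates are in mm;
# the physical axes are (x = depth within slice, y = lateral within slice,
# z = along the slice stack).

#' Rigid transform in 3-D
#'
#' A proper rigid-body transform `p -> R p + t` with an optional RMS residual
#' (populated by [align_series()]).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation_mm length-3 numeric translation in mm.
#' @param rms_residual_mm non-negative fit residual, if known.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0),
                            rms_residual_mm = NA_real_) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation_mm) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm),
                 rms_residual_mm = rms_residual_mm),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric matrix with 3 columns (or a length-3 vector).
#' @return Transformed points, same shape as the input.
#' @export
rt_apply <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3L) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation_mm, nrow(p), 3L, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation_mm),
                  transform$rms_residual_mm)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return `rigid_transform` equivalent to `p -> a(b(p))`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation_mm) + a$translation_mm)
}

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z" (depth, lateral, slice axes).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("z", "x", "y"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  m <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c2, -s2), c(0, s2, c2)),
    y = rbind(c(c2, 0, s2), c(0, 1, 0), c(-s2, 0, c2)),
    z = rbind(c(c2, -s2, 0), c(s2, c2, 0), c(0, 0, 1)))
  unname(m)
}

#' Triangle mesh container
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param closed logical; `TRUE` for watertight meshes (depot surfaces),
#'   `FALSE` for open sheets (tissue boundaries).
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, closed = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L)
  if (nrow(faces) == 0L) stop("degenerate mesh: no triangles")
  structure(list(vertices = vertices, faces = faces, closed = closed),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces, %s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$closed) "closed" else "open sheet"))
  invisible(x)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a closed [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  # signed tetrahedron volumes against the origin
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6)
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Distance from a single point to a segment set, vectorised over segments.
#' @noRd
.point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  ap <- matrix(p, nrow(a), 3L, byrow = TRUE) - a
  t0 <- rowSums(ap * ab) / pmax(rowSums(ab * ab), .Machine$double.eps)
  t0 <- pmin(pmax(t0, 0), 1)
  d <- ap - ab * t0
  rowSums(d * d)
}

#' Minimum distance from one point to a set of triangles
#'
#' Exact Euclidean point-to-triangle distance: the in-plane projection when it
#' falls inside the triangle, otherwise the nearest point on the three edges.
#'
#' @param p length-3 point (mm).
#' @param v0,v1,v2 m x 3 matrices of triangle vertices.
#' @return Minimum distance in mm over all triangles.
#' @export
point_triangles_distance <- function(p, v0, v1, v2) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- nx^2 + ny^2 + nz^2
  w <- matrix(p, nrow(v0), 3L, byrow = TRUE) - v0
  # barycentric coordinates of the in-plane projection
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  dw1 <- rowSums(w * e1); dw2 <- rowSums(w * e2)
  den <- d11 * d22 - d12^2
  ok <- den > .Machine$double.eps & nn > .Machine$double.eps
  u <- ifelse(ok, (d22 * dw1 - d12 * dw2) / den, -1)
  v <- ifelse(ok, (d11 * dw2 - d12 * dw1) / den, -1)
  inside <- ok & u >= 0 & v >= 0 & (u + v) <= 1
  dist_n <- (w[, 1] * nx + w[, 2] * ny + w[, 3] * nz)^2 / pmax(nn, .Machine$double.eps)
  d2 <- pmin(.point_segment_dist2(p, v0, v1),
             .point_segment_dist2(p, v1, v2),
             .point_segment_dist2(p, v2, v0))
  d2[inside] <- pmin(d2[inside], dist_n[inside])
  sqrt(min(d2))
}

#' Minimum distance from a point to a mesh
#' @param p length-3 point (mm).
#' @param mesh a [surface_mesh()].
#' @return Distance in mm.
#' @export
min_dist_point_mesh <- function(p, mesh) {
  f <- mesh$faces; v <- mesh$vertices
  point_triangles_distance(p, v[f[, 1L], , drop = FALSE],
                           v[f[, 2L], , drop = FALSE],
                           v[f[, 3L], , drop = FALSE])
}

# Index and exact distance of the query point closest to a mesh. Vertex-cloud
# distances bound the exact ones within the longest mesh edge, so exact
# point-triangle tests run only on candidates that could still win.
#' @noRd
.closest_point_to_mesh <- function(points, mesh, chunk = 2000L) {
  pv <- mesh$vertices
  f <- mesh$faces
  n <- nrow(points)
  dvv <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(rowSums(points[idx, , drop = FALSE]^2), rowSums(pv^2), "+") -
      2 * points[idx, , drop = FALSE] %*% t(pv)
    dvv[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  emax <- sqrt(max(rowSums((pv[f[, 1L], ] - pv[f[, 2L], ])^2),
                   rowSums((pv[f[, 2L], ] - pv[f[, 3L], ])^2),
                   rowSums((pv[f[, 3L], ] - pv[f[, 1L], ])^2)))
  cen <- (pv[f[, 1L], , drop = FALSE] + pv[f[, 2L], , drop = FALSE] +
          pv[f[, 3L], , drop = FALSE]) / 3
  ord <- order(dvv)
  best <- Inf; best_i <- ord[1L]
  for (i in ord) {
    if (dvv[i] - emax > best) break
    p <- points[i, ]
    cd2 <- (cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 + (cen[, 3] - p[3])^2
    keep <- cd2 <= (min(dvv[i], best) + emax)^2
    if (!any(keep)) next
    d <- point_triangles_distance(p, pv[f[keep, 1L], , drop = FALSE],
                                  pv[f[keep, 2L], , drop = FALSE],
                                  pv[f[keep, 3L], , drop = FALSE])
    if (d < best) { best <- d; best_i <- i }
  }
  list(index = best_i, distance = best)
}

# Minimum over many query points of the distance to a mesh, with vertex-cloud
# pruning so that exact point-triangle tests only run on candidate pairs.
#' @noRd
.min_dist_points_mesh <- function(points, mesh, chunk = 2000L) {
  pv <- mesh$vertices
  n <- nrow(points)
  dvv <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    d2 <- outer(rowSums(points[idx, , drop = FALSE]^2), rowSums(pv^2), "+") -
      2 * points[idx, , drop = FALSE] %*% t(pv)
    dvv[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  best_vv <- min(dvv)
  # longest mesh edge bounds how much a triangle interior can undercut vertices
  f <- mesh$faces
  emax <- sqrt(max(rowSums((pv[f[, 1L], ] - pv[f[, 2L], ])^2),
                   rowSums((pv[f[, 2L], ] - pv[f[, 3L], ])^2),
                   rowSums((pv[f[, 3L], ] - pv[f[, 1L], ])^2)))
  cand <- which(dvv <= best_vv + emax)
  cen <- (pv[f[, 1L], , drop = FALSE] + pv[f[, 2L], , drop = FALSE] +
          pv[f[, 3L], , drop = FALSE]) / 3
  best <- best_vv
  for (i in cand) {
    p <- points[i, ]
    cd2 <- (cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 + (cen[, 3] - p[3])^2
    keep <- cd2 <= (best + emax)^2
    if (!any(keep)) next
    d <- point_triangles_distance(p, pv[f[keep, 1L], , drop = FALSE],
                                  pv[f[keep, 2L], , drop = FALSE],
                                  pv[f[keep, 3L], , drop = FALSE])
    if (d < best) best <- d
  }
  best
}

#' Closed voxel-face mesh of a binary mask
#'
#' Emits the boundary faces of the voxelised region (two triangles per exposed
#' voxel face), so the enclosed mesh volume equals the mask voxel volume
#' exactly.
#'
#' @param mask logical 3-D array.
#' @param spacing_mm voxel spacing `(depth, lateral, slice)` in mm.
#' @param origin_mm physical coordinate of the array corner (mm).
#' @return A closed [surface_mesh()].
#' @export
mask_to_mesh <- function(mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  d <- dim(mask)
  if (!any(mask)) stop("degenerate mesh: empty mask")
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  quads <- list(); qi <- 0L
  # face corner offsets (in voxel-corner units) for each of the 6 directions
  face_def <- list(
    list(sh = c(-1L, 0L, 0L), c = rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(0,0,1))),
    list(sh = c( 1L, 0L, 0L), c = rbind(c(1,0,0), c(1,0,1), c(1,1,1), c(1,1,0))),
    list(sh = c(0L, -1L, 0L), c = rbind(c(0,0,0), c(0,0,1), c(1,0,1), c(1,0,0))),
    list(sh = c(0L,  1L, 0L), c = rbind(c(0,1,0), c(1,1,0), c(1,1,1), c(0,1,1))),
    list(sh = c(0L, 0L, -1L), c = rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))),
    list(sh = c(0L, 0L,  1L), c = rbind(c(0,0,1), c(0,1,1), c(1,1,1), c(1,0,1))))
  idx <- which(pad, arr.ind = TRUE)
  for (fd in face_def) {
    nb <- pad[cbind(idx[, 1] + fd$sh[1], idx[, 2] + fd$sh[2], idx[, 3] + fd$sh[3])]
    expos <- idx[!nb, , drop = FALSE]
    if (nrow(expos) == 0L) next
    base <- expos - 2L  # 0-based voxel corner in the unpadded grid
    for (ci in 1:4) {
      qi <- qi + 1L
      quads[[qi]] <- base + matrix(fd$c[ci, ], nrow(base), 3L, byrow = TRUE)
    }
  }
  if (qi == 0L) stop("degenerate mesh: empty mask")
  nq <- nrow(quads[[1]])
  ngroups <- qi / 4L
  corner <- do.call(rbind, quads)
  # physical coordinates of voxel corners
  vert_all <- sweep(sweep(corner, 2L, spacing_mm, "*"), 2L, origin_mm, "+")
  key <- paste(corner[, 1], corner[, 2], corner[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- vert_all[uk, , drop = FALSE]
  faces <- NULL
  off <- 0L
  for (g in seq_len(ngroups)) {
    n <- nrow(quads[[(g - 1L) * 4L + 1L]])
    i1 <- vid[off + seq_len(n)]
    i2 <- vid[off + n + seq_len(n)]
    i3 <- vid[off + 2L * n + seq_len(n)]
    i4 <- vid[off + 3L * n + seq_len(n)]
    faces <- rbind(faces, cbind(i1, i2, i3), cbind(i1, i3, i4))
    off <- off + 4L * n
  }
  surface_mesh(vertices, faces, closed = TRUE)
}

#' Triangulated sheet from a boundary height field
#'
#' @param depth_mm matrix of boundary depths (mm) over the `(lateral, slice)`
#'   grid.
#' @param y_mm,z_mm physical coordinates of the grid rows/columns (mm).
#' @param valid optional logical matrix; triangles with any invalid corner are
#'   dropped.
#' @return An open [surface_mesh()].
#' @export
height_field_mesh <- function(depth_mm, y_mm, z_mm, valid = NULL) {
  ny <- nrow(depth_mm); nz <- ncol(depth_mm)
  if (is.null(valid)) valid <- !is.na(depth_mm)
  verts <- cbind(as.numeric(depth_mm),
                 rep(y_mm, times = nz),
                 rep(z_mm, each = ny))
  id <- function(j, k) (k - 1L) * ny + j
  j <- rep(seq_len(ny - 1L), times = nz - 1L)
  k <- rep(seq_len(nz - 1L), each = ny - 1L)
  ok <- valid[cbind(j, k)] & valid[cbind(j + 1L, k)] &
        valid[cbind(j, k + 1L)] & valid[cbind(j + 1L, k + 1L)]
  j <- j[ok]; k <- k[ok]
  faces <- rbind(cbind(id(j, k), id(j + 1L, k), id(j + 1L, k + 1L)),
                 cbind(id(j, k), id(j + 1L, k + 1L), id(j, k + 1L)))
  verts[!is.finite(verts)] <- 0
  surface_mesh(verts, faces, closed = FALSE)
}

#' Parametric ellipsoid mesh
#'
#' UV-sphere triangulation scaled to the given semi-axes; used as an analytic
#' fixture for projection and distance checks.
#'
#' @param center length-3 center (mm).
#' @param semiaxes length-3 semi-axes along (x, y, z) (mm).
#' @param n_u,n_v azimuthal and polar resolution.
#' @return A closed [surface_mesh()].
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), semiaxes = c(1, 1, 1),
                           n_u = 48L, n_v = 24L) {
  th <- seq(0, pi, length.out = n_v + 1L)[2:n_v]          # polar, poles apart
  ph <- seq(0, 2 * pi, length.out = n_u + 1L)[seq_len(n_u)]
  grid <- expand.grid(ph = ph, th = th)
  ring <- cbind(cos(grid$th),
                sin(grid$th) * cos(grid$ph),
                sin(grid$th) * sin(grid$ph))
  verts <- rbind(c(1, 0, 0), ring, c(-1, 0, 0))
  verts <- sweep(sweep(verts, 2L, semiaxes, "*"), 2L, center, "+")
  idx <- function(i, j) 1L + (i - 1L) * n_u + ((j - 1L) %% n_u) + 1L
  faces <- NULL
  for (j in seq_len(n_u)) {  # polar caps
    faces <- rbind(faces,
                   c(1L, idx(1L, j), idx(1L, j + 1L)),
                   c(nrow(verts), idx(n_v - 1L, j + 1L), idx(n_v - 1L, j)))
  }
  for (i in seq_len(n_v - 2L)) {
    for (j in seq_len(n_u)) {
      faces <- rbind(faces,
                     c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                     c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
  }
  surface_mesh(verts, faces, closed = TRUE)
}

# Pixel-center coverage rasterisation of projected 2-D triangles.
# Returns a logical matrix over the bounding grid plus the grid metadata.
#' @noRd
.rasterize_triangles <- function(tri_list, res) {
  allv <- do.call(rbind, tri_list)
  x0 <- min(allv[, 1]) - res; y0 <- min(allv[, 2]) - res
  nx <- ceiling((max(allv[, 1]) - x0) / res) + 2L
  ny <- ceiling((max(allv[, 2]) - y0) / res) + 2L
  img <- matrix(FALSE, nx, ny)
  for (tri in tri_list) {
    a <- tri[1, ]; b <- tri[2, ]; c3 <- tri[3, ]
    i1 <- max(1L, floor((min(tri[, 1]) - x0) / res)):min(nx, ceiling((max(tri[, 1]) - x0) / res) + 1L)
    j1 <- max(1L, floor((min(tri[, 2]) - y0) / res)):min(ny, ceiling((max(tri[, 2]) - y0) / res) + 1L)
    if (!length(i1) || !length(j1)) next
    px <- x0 + (rep(i1, times = length(j1)) - 0.5) * res
    py <- y0 + (rep(j1, each = length(i1)) - 0.5) * res
    d <- (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1])
    if (abs(d) < .Machine$double.eps) next
    u <- ((px - a[1]) * (c3[2] - a[2]) - (py - a[2]) * (c3[1] - a[1])) / d
    v <- ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) / d
  inside <- u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9
    if (any(inside)) {
      ii <- rep(i1, times = length(j1))[inside]
      jj <- rep(j1, each = length(i1))[inside]
      img[cbind(ii, jj)] <- TRUE
    }
  }
  list(mask = img, res = res, x0 = x0, y0 = y0)
}

# Maximal caliper width of a 2-D point set and the orthogonal extent.
#' @noRd
.principal_caliper <- function(pts) {
  if (nrow(pts) < 2L) return(c(0, 0, 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(rowSums(hp^2), rowSums(hp^2), "+") - 2 * hp %*% t(hp)
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  p1 <- hp[ij[1L], ]; p2 <- hp[ij[2L], ]
  width <- sqrt(max(d2[ij[1L], ij[2L]], 0))
  dir <- if (width > 0) (p2 - p1) / width else c(1, 0)
  perp <- c(-dir[2], dir[1])
  proj <- hp %*% perp
  c(width, max(proj) - min(proj), atan2(dir[2], dir[1]))
}
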