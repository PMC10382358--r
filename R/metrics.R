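# Depot and tissue morphometrics: depot volume, minimum 3-D distances to the
# tissue boundaries, depth from skin, orthographic projection with principal
# axes, subcutaneous thickness maps, reference-point thickness tracking, and
# heatmap rendering.

#' Depot volume in mL
#'
#' Voxel count times voxel volume, converted to mL (1 mL = 1000 mm^3).
#'
#' @param seg a `depot_segmentation` or a logical mask array.
#' @param spacing_mm voxel spacing; taken from `seg` when it is a
#'   segmentation object.
#' @return Volume in mL.
#' @export
depot_volume <- function(seg, spacing_mm = NULL) {
  if (inherits(seg, "depot_segmentation")) {
    spacing_mm <- seg$spacing_mm
    seg <- seg$mask
  }
  if (is.null(spacing_mm)) stop("spacing_mm required for a bare mask")
  sum(seg) * prod(spacing_mm) / 1000
}

#' Minimum 3-D distance between the depot surface and a tissue boundary
#'
#' Minimum Euclidean point-to-triangle distance over all depot mesh vertices
#' against the boundary sheet; 0 when the depot crosses the boundary.
#'
#' @param depot_mesh a closed [surface_mesh()] of the depot.
#' @param boundary a [boundary_surface()] or an open [surface_mesh()].
#' @return Distance in mm.
#' @export
min_distance <- function(depot_mesh, boundary) {
  if (is.null(depot_mesh) || nrow(depot_mesh$vertices) == 0L) {
    stop("empty depot mesh")
  }
  if (inherits(boundary, "boundary_surface")) {
    # crossing test via the height field: mixed signs of (vertex depth - sheet)
    v <- depot_mesh$vertices
    hs <- .interp_height(boundary, v[, 2], v[, 3])
    s <- v[, 1] - hs
    if (any(s > 0) && any(s < 0)) return(0)
    mesh <- boundary$mesh
  } else {
    mesh <- boundary
  }
  .min_dist_points_mesh(depot_mesh$vertices, mesh)
}

# Bilinear interpolation of a boundary height field at arbitrary (y, z).
#' @noRd
.interp_height <- function(bs, y, z) {
  ym <- bs$y_mm; zm <- bs$z_mm
  dy <- if (length(ym) > 1L) ym[2] - ym[1] else 1
  dz <- if (length(zm) > 1L) zm[2] - zm[1] else 1
  fj <- pmin(pmax((y - ym[1]) / dy, 0), length(ym) - 1L)
  fk <- pmin(pmax((z - zm[1]) / dz, 0), length(zm) - 1L)
  j0 <- pmin(floor(fj) + 1L, length(ym) - 1L); j0 <- pmax(j0, 1L)
  k0 <- pmin(floor(fk) + 1L, length(zm) - 1L); k0 <- pmax(k0, 1L)
  tj <- fj - (j0 - 1L); tk <- fk - (k0 - 1L)
  j1 <- pmin(j0 + 1L, length(ym)); k1 <- pmin(k0 + 1L, length(zm))
  bs$depth_mm[cbind(j0, k0)] * (1 - tj) * (1 - tk) +
    bs$depth_mm[cbind(j1, k0)] * tj * (1 - tk) +
    bs$depth_mm[cbind(j0, k1)] * (1 - tj) * tk +
    bs$depth_mm[cbind(j1, k1)] * tj * tk
}

#' Depot depth from the skin surface
#'
#' Depth from the ID/SC interface plus the estimated dermis thickness (the
#' skin surface itself is invisible in the sequence).
#'
#' @param min_dist_to_id_sc_mm depot top distance from the ID/SC interface.
#' @param dermal_thickness_mm estimated dermis thickness.
#' @return Depth from skin in mm.
#' @export
depth_from_skin <- function(min_dist_to_id_sc_mm, dermal_thickness_mm) {
  stopifnot(min_dist_to_id_sc_mm >= 0, dermal_thickness_mm >= 0)
  min_dist_to_id_sc_mm + dermal_thickness_mm
}

#' Orthographic depot projection and principal axes
#'
#' Fits the local skin plane (least squares through the ID/SC surface over
#' the depot footprint), rotates the depot so that plane becomes the X-Y
#' plane, rasterises the orthographic footprint and measures its area; the
#' first principal axis is the maximal caliper width of the footprint, the
#' second the orthogonal extent, and `z_extent_mm` the extent along the plane
#' normal.
#'
#' @param depot_mesh closed depot [surface_mesh()].
#' @param id_sc the ID/SC [boundary_surface()] (or `NULL` to project along
#'   the depth axis).
#' @param raster_res_mm footprint rasterisation resolution.
#' @return List with `projected_area_cm2`, `principal_x_mm`,
#'   `principal_y_mm`, `z_extent_mm`.
#' @export
project_and_axes <- function(depot_mesh, id_sc = NULL, raster_res_mm = 0.3) {
  v <- depot_mesh$vertices
  if (is.null(id_sc)) {
    normal <- c(1, 0, 0)
  } else {
    yr <- range(v[, 2]); zr <- range(v[, 3])
    sel <- which(id_sc$y_mm >= yr[1] - 5 & id_sc$y_mm <= yr[2] + 5)
    selk <- which(id_sc$z_mm >= zr[1] - 5 & id_sc$z_mm <= zr[2] + 5)
    if (length(sel) < 2L || length(selk) < 2L) {
      sel <- seq_along(id_sc$y_mm); selk <- seq_along(id_sc$z_mm)
    }
    yy <- rep(id_sc$y_mm[sel], times = length(selk))
    zz <- rep(id_sc$z_mm[selk], each = length(sel))
    dd <- as.numeric(id_sc$depth_mm[sel, selk])
    ok <- as.logical(id_sc$valid[sel, selk])
    fit <- stats::lm.fit(cbind(1, yy[ok], zz[ok]), dd[ok])
    b <- fit$coefficients
    normal <- c(1, -b[2], -b[3])
    normal <- normal / sqrt(sum(normal^2))
  }
  # orthonormal in-plane basis
  u2 <- c(0, 1, 0) - sum(normal * c(0, 1, 0)) * normal
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(normal[2] * u2[3] - normal[3] * u2[2],
          normal[3] * u2[1] - normal[1] * u2[3],
          normal[1] * u2[2] - normal[2] * u2[1])
  p2 <- cbind(v %*% u2, v %*% u3)
  zext <- diff(range(v %*% normal))
  if (zext < 1e-6) warning("degenerate (flat) depot")
  f <- depot_mesh$faces
  tris <- lapply(seq_len(nrow(f)), function(i) p2[f[i, ], , drop = FALSE])
  ras <- .rasterize_triangles(tris, raster_res_mm)
  area_cm2 <- sum(ras$mask) * raster_res_mm^2 / 100
  cal <- .principal_caliper(p2)
  list(projected_area_cm2 = area_cm2,
       principal_x_mm = max(cal[1], cal[2]),
       principal_y_mm = min(cal[1], cal[2]),
       z_extent_mm = zext)
}

#' Subcutaneous thickness map between the tissue boundaries
#'
#' Per skin-plane column, the minimum 3-D distance from the SC/IM point to the
#' ID/SC sheet (not merely the vertical gap), searched over a local window;
#' with summary statistics and a percent-frequency histogram.
#'
#' @param id_sc,sc_im [boundary_surface()]s on a shared grid.
#' @param window_mm `(lateral, slice)` half-width of the minimum-distance
#'   search window.
#' @param bin_mm histogram bin width.
#' @param roi_mask optional logical matrix restricting the summarised region.
#' @return Object of class `thickness_map` with `thickness_mm`, `valid`,
#'   `stats` (mean/median/sd/min/max), `histogram` (data frame of bin mids
#'   and percent frequencies summing to 100).
#' @export
thickness_map <- function(id_sc, sc_im, window_mm = c(10, 8), bin_mm = 1,
                          roi_mask = NULL) {
  if (!identical(dim(id_sc$depth_mm), dim(sc_im$depth_mm))) {
    stop("boundary surfaces must share a grid")
  }
  valid <- id_sc$valid & sc_im$valid
  if (!any(valid)) stop("boundary surfaces have disjoint valid regions")
  ny <- nrow(valid); nz <- ncol(valid)
  dy <- if (ny > 1L) id_sc$y_mm[2] - id_sc$y_mm[1] else 1
  dz <- if (nz > 1L) id_sc$z_mm[2] - id_sc$z_mm[1] else 1
  oy <- -round(window_mm[1] / dy):round(window_mm[1] / dy)
  oz <- -round(window_mm[2] / dz):round(window_mm[2] / dz)
  best <- matrix(Inf, ny, nz)
  im <- sc_im$depth_mm
  id <- id_sc$depth_mm
  for (a in oy) {
    js <- seq_len(ny)
    jt <- js + a
    okj <- jt >= 1L & jt <= ny
    for (b in oz) {
      ks <- seq_len(nz)
      kt <- ks + b
      okk <- kt >= 1L & kt <= nz
      if (!any(okj) || !any(okk)) next
      diffd <- im[js[okj], ks[okk], drop = FALSE] -
        id[jt[okj], kt[okk], drop = FALSE]
      cand <- sqrt(diffd^2 + (a * dy)^2 + (b * dz)^2)
      cur <- best[js[okj], ks[okk], drop = FALSE]
      best[js[okj], ks[okk]] <- pmin(cur, cand)
    }
  }
  best[!valid] <- NA
  sel <- valid & (if (is.null(roi_mask)) TRUE else roi_mask)
  vals <- best[sel]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid thickness values in the requested region")
  breaks <- seq(0, max(vals) + bin_mm, by = bin_mm)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(list(thickness_mm = best, valid = valid,
                 y_mm = id_sc$y_mm, z_mm = id_sc$z_mm,
                 stats = c(mean = mean(vals), median = stats::median(vals),
                           sd = stats::sd(vals), min = min(vals), max = max(vals)),
                 histogram = data.frame(bin_mid_mm = h$mids,
                                        percent = 100 * h$counts / length(vals))),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map %dx%d: mean %.1f mm (sd %.1f, range %.1f-%.1f)>\n",
              nrow(x$thickness_mm), ncol(x$thickness_mm),
              x$stats[["mean"]], x$stats[["sd"]], x$stats[["min"]], x$stats[["max"]]))
  invisible(x)
}

#' Track SC thickness at the deepest-depot reference point across a series
#'
#' The reference point is the SC/IM surface point closest to the depot at the
#' largest-volume stage; it is mapped through each stage's rigid alignment
#' transform and the stage thickness is the minimum 3-D distance from that
#' point to the stage's ID/SC sheet. Percent change is reported relative to
#' the cannula-placement (insertion) stage; pre-cannulation and post-removal
#' stages carry absolute values only.
#'
#' @param stage_data named list (one entry per stage) of lists with elements
#'   `id_sc`, `sc_im` ([boundary_surface()]s) and `transform` (a
#'   [rigid_transform()] mapping the stage frame into the common frame;
#'   identity if omitted).
#' @param depot_mesh depot [surface_mesh()] at the largest stage (in that
#'   stage's frame).
#' @param largest_stage stage label of the maximum-volume scan.
#' @param baseline_stage stage used as the percent-change baseline.
#' @return Object of class `series_thickness_track`: `reference_point_mm`
#'   (common frame) and a data frame `stages` with `thickness_mm` and
#'   `pct_change`.
#' @export
track_reference_thickness <- function(stage_data, depot_mesh, largest_stage,
                                      baseline_stage = "insertion") {
  if (!largest_stage %in% names(stage_data)) {
    stop("largest-volume stage missing from stage_data")
  }
  ld <- stage_data[[largest_stage]]
  im <- ld$sc_im
  jj <- which(im$valid, arr.ind = TRUE)
  pts <- cbind(im$depth_mm[jj], im$y_mm[jj[, 1]], im$z_mm[jj[, 2]])
  cp <- .closest_point_to_mesh(pts, depot_mesh)
  ref_local <- pts[cp$index, ]
  # de-noise the selected depth: the argmin over thousands of columns prefers
  # shallow extraction noise, so take the local median of the height field
  jk <- jj[cp$index, ]
  nbr_j <- max(1L, jk[1] - 2L):min(nrow(im$depth_mm), jk[1] + 2L)
  nbr_k <- max(1L, jk[2] - 1L):min(ncol(im$depth_mm), jk[2] + 1L)
  nbh <- im$depth_mm[nbr_j, nbr_k][im$valid[nbr_j, nbr_k]]
  if (length(nbh) >= 3L) ref_local[1] <- stats::median(nbh)
  tf_l <- stage_data[[largest_stage]]$transform %||% rigid_transform()
  ref_common <- rt_apply(tf_l, ref_local)

  stages <- names(stage_data)
  th <- vapply(stages, function(st) {
    sd0 <- stage_data[[st]]
    tf <- sd0$transform %||% rigid_transform()
    p_st <- rt_apply(rt_invert(tf), ref_common)
    min_dist_point_mesh(p_st, sd0$id_sc$mesh)
  }, numeric(1))
  base <- if (baseline_stage %in% stages) th[[baseline_stage]] else NA_real_
  pct <- if (is.na(base)) rep(NA_real_, length(th)) else 100 * (th - base) / base
  pct[stages %in% c("naive", "post_removal")] <- NA_real_
  structure(list(reference_point_mm = ref_common,
                 baseline_stage = baseline_stage,
                 stages = data.frame(stage = stages, thickness_mm = as.numeric(th),
                                     pct_change = as.numeric(pct),
                                     row.names = NULL)),
            class = "series_thickness_track")
}

#' @export
print.series_thickness_track <- function(x, ...) {
  cat("<series_thickness_track>\n")
  print(x$stages, digits = 3)
  invisible(x)
}

#' Render a thickness map as a skin-surface heatmap
#'
#' Top-down PNG, shallow thickness in blue warming to dark red, with a fixed
#' color scale (pass the same `range` for every stage of a site).
#'
#' @param tmap a [thickness_map()].
#' @param path output PNG path.
#' @param range color scale bounds in mm; defaults to the map's own range.
#' @return `path` invisibly, with the used scale bounds as attribute
#'   `"range"`.
#' @export
render_heatmap <- function(tmap, path, range = NULL) {
  vals <- tmap$thickness_mm
  if (is.null(range)) {
    range <- range(vals[tmap$valid], finite = TRUE)
  }
  ramp <- grDevices::colorRamp(c("#00008B", "#0000FF", "#00BFFF", "#00FF7F",
                                 "#FFFF00", "#FF8C00", "#FF0000", "#8B0000"))
  span <- max(range[2] - range[1], 1e-9)
  u <- pmin(pmax((vals - range[1]) / span, 0), 1)
  rgb <- ramp(as.numeric(u)) / 255
  ny <- nrow(vals); nz <- ncol(vals)
  img <- array(0.8, c(nz, ny, 3L))  # rows = slice axis, cols = lateral
  for (ch in 1:3) {
    m <- matrix(rgb[, ch], ny, nz)
    m[!tmap$valid] <- 0.8
    img[, , ch] <- t(m)[nz:1, , drop = FALSE]
  }
  png::writePNG(img, path)
  out <- path
  attr(out, "range") <- range
  invisible(out)
}
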