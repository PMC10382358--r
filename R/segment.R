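# Depot segmentation and tissue-boundary extraction: tissue-class estimation,
# ROI extraction, fiducial detection, histogram threshold selection, 3-D
# connected components, and per-column boundary parsing into height fields.

#' Estimate tissue intensity classes
#'
#' Clusters voxel intensities into background / muscle / SC-fat classes with
#' k-means (deterministic quantile initialisation) and assigns a fourth
#' "bright" class (depot, fiducial oil — free fluid on T2-FSE) above
#' `sc_fat + 0.5 (sc_fat - muscle)`. Assumes the T2-FSE ordering
#' background < muscle < fat < fluid.
#'
#' @param volume a [voxel_volume()] (ideally bias-corrected).
#' @param sample_size number of voxels sampled for clustering.
#' @return A list with `class` (integer array: 1 background, 2 muscle,
#'   3 SC fat, 4 bright) and `centers` (named class-center intensities).
#' @export
classify_tissue <- function(volume, sample_size = 30000L) {
  x <- as.numeric(volume$intensities)
  idx <- if (length(x) > sample_size) {
    round(seq(1L, length(x), length.out = sample_size))  # deterministic stratified take
  } else seq_along(x)
  sx <- x[idx]
  init <- matrix(stats::quantile(sx, c(0.08, 0.5, 0.82), names = FALSE), ncol = 1L)
  if (length(unique(init)) < 3L) stop("intensity histogram is degenerate (constant image)")
  km <- stats::kmeans(matrix(sx, ncol = 1L), centers = init, iter.max = 50L)
  cen <- sort(as.numeric(km$centers))
  bright_thr <- cen[3] + 0.5 * (cen[3] - cen[2])
  # nearest-center assignment, then the bright override
  b12 <- (cen[1] + cen[2]) / 2
  b23 <- (cen[2] + cen[3]) / 2
  cls <- 1L + (x >= b12) + (x >= b23) + (x >= bright_thr)
  # report class LEVELS as within-class medians: robust to the partial-volume
  # tails that drag k-means centers (the fat class contains fat/fluid mixes),
  # and the sub-voxel boundary estimator depends on unbiased levels
  med <- function(k) {
    v <- sx[cls[idx] == k]
    if (length(v) >= 20L) stats::median(v) else cen[min(k, 3L)]
  }
  list(class = array(as.integer(cls), dim(volume$intensities)),
       centers = c(background = med(1L), muscle = med(2L), sc_fat = med(3L),
                   bright = if (any(cls == 4L)) med(4L) else bright_thr))
}

#' 3-D connected components (26-neighbourhood)
#'
#' Labels each slice with [EBImage::bwlabel()] and merges labels across
#' adjacent slices (all nine in-plane offsets, i.e. 26-connectivity across the
#' stack) with a union-find pass.
#'
#' @param mask logical 3-D array.
#' @return Integer array of compact component labels (0 = background).
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(mask[, , k] * 1L)
    lk <- matrix(as.integer(lk), d[1], d[2])
    n_k <- max(lk, 0L)
    nz <- lk > 0L
    lk[nz] <- lk[nz] + offset
    offset <- offset + n_k
    lab[, , k] <- lk
  }
  if (offset == 0L) return(lab)
  edges <- vector("list", 9L * (d[3] - 1L)); ei <- 0L
  for (k in seq_len(d[3] - 1L)) {
    a <- lab[, , k]; b <- lab[, , k + 1L]
    for (di in -1:1) for (dj in -1:1) {
      ia <- seq_len(d[1]); ja <- seq_len(d[2])
      ib <- ia + di; jb <- ja + dj
      sel_a <- ia[ib >= 1L & ib <= d[1]]; sel_b <- sel_a + di
      sej_a <- ja[jb >= 1L & jb <= d[2]]; sej_b <- sej_a + dj
      aa <- a[sel_a, sej_a]; bb <- b[sel_b, sej_b]
      both <- aa > 0L & bb > 0L
      if (any(both)) {
        ei <- ei + 1L
        edges[[ei]] <- unique(cbind(aa[both], bb[both]))
      }
    }
  }
  if (ei > 0L) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges[seq_len(ei)]),
                                     directed = FALSE)
    if (igraph::vcount(g) < offset) {
      g <- igraph::add_vertices(g, offset - igraph::vcount(g))
    }
    membership <- as.integer(igraph::components(g)$membership)[seq_len(offset)]
  } else {
    membership <- seq_len(offset)
  }
  compact <- match(membership, unique(membership))
  nz <- lab > 0L
  lab[nz] <- compact[lab[nz]]
  lab
}

#' Detect fish-oil fiducial capsules
#'
#' Bright connected components whose volume is consistent with a capsule and
#' whose immediate neighbourhood is predominantly background (capsules float
#' above the skin, separated from tissue by the invisible dermis gap).
#'
#' @param volume a [voxel_volume()].
#' @param classes optional result of [classify_tissue()] (recomputed if
#'   missing).
#' @param volume_range_mL admissible capsule volume range.
#' @param min_shell_background minimum fraction of the one-voxel shell around
#'   a component that is background or sub-muscle-intensity (air and oil/air
#'   partial-volume voxels; tissue-embedded bright blobs fail this).
#' @return Object of class `fiducial_set`: list of capsules with
#'   `oil_centroid_mm`, `oil_lower_depth_mm`, `approx_radius_mm`.
#' @export
detect_fiducials <- function(volume, classes = NULL,
                             volume_range_mL = c(0.05, 1.5),
                             min_shell_background = 0.5) {
  if (is.null(classes)) classes <- classify_tissue(volume)
  cls <- classes$class
  bright <- cls == 4L
  lab <- label_components_3d(bright)
  n <- max(lab)
  if (n == 0L) stop("no fiducial capsules detected")
  vox <- voxel_size_mm3(volume)
  d <- dim(lab)
  caps <- list()
  vols_found <- numeric(0)
  lin_all <- which(lab > 0L)
  idx_by_comp <- split(lin_all, lab[lin_all])
  for (comp in seq_len(n)) {
    lin <- idx_by_comp[[as.character(comp)]]
    if (is.null(lin)) next
    v_mL <- length(lin) * vox / 1000
    if (v_mL < volume_range_mL[1] || v_mL > volume_range_mL[2]) next
    idx <- arrayInd(lin, d)
    # one-voxel 6-neighbour shell
    shell_cls <- integer(0)
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- sweep(idx, 2L, sh, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      out <- lab[nb] != comp
      shell_cls <- c(shell_cls, cls[nb[out, , drop = FALSE]])
    }
    # capsules float in air: their shell is background plus oil/air
    # partial-volume voxels (which fall into the low intensity bands); a
    # depot's shell is subcutaneous fat
    if (length(shell_cls) && mean(shell_cls <= 2L) < min_shell_background) next
    cen_vox <- colMeans(idx)
    cen <- volume$origin_mm + (cen_vox - 0.5) * volume$spacing_mm
    # oil lower surface from a sphere fit: slab averaging erodes the shallow
    # bottom sliver, so estimate the radius from per-slice chord areas
    # (R^2 = r_k^2 + dz_k^2) instead of the deepest detected voxel
    cnt_k <- tabulate(idx[, 3], nbins = d[3])
    ks <- which(cnt_k >= 0.3 * max(cnt_k))
    r_k <- sqrt(cnt_k[ks] * volume$spacing_mm[1] * volume$spacing_mm[2] / pi)
    dz_k <- volume$origin_mm[3] + (ks - 0.5) * volume$spacing_mm[3] - cen[3]
    r_sph <- stats::median(sqrt(r_k^2 + dz_k^2))
    caps[[length(caps) + 1L]] <- list(
      oil_centroid_mm = as.numeric(cen),
      oil_lower_depth_mm = cen[1] + r_sph,
      approx_radius_mm = r_sph)
    vols_found <- c(vols_found, v_mL)
  }
  if (!length(caps)) stop("no fiducial capsules detected")
  if (length(vols_found) > 1L && max(vols_found) > 2 * stats::median(vols_found)) {
    warning("possible merged fiducial capsules: one blob is much larger than the rest")
  }
  structure(list(capsules = caps), class = "fiducial_set")
}

#' Centroid matrix of a fiducial set
#' @param fiducials a `fiducial_set`.
#' @return n x 3 matrix of oil centroids (mm).
#' @export
fiducial_centroids <- function(fiducials) {
  do.call(rbind, lapply(fiducials$capsules, function(c3) c3$oil_centroid_mm))
}

#' Extract the region of interest around the injection site
#'
#' Crops the lateral and slice axes to `half_extent_mm` around the fiducial
#' centroid (the full depth column is kept); the origin is updated so physical
#' coordinates are preserved.
#'
#' @param volume a [voxel_volume()].
#' @param fiducials a `fiducial_set` bracketing the site.
#' @param half_extent_mm half-width of the ROI in the lateral and slice
#'   directions (scalar or length-2).
#' @return The cropped [voxel_volume()].
#' @export
extract_roi <- function(volume, fiducials, half_extent_mm = 48) {
  cen <- colMeans(fiducial_centroids(fiducials))
  d <- dim(volume$intensities)
  ext_hi <- volume$origin_mm + d * volume$spacing_mm
  if (any(cen < volume$origin_mm) || any(cen > ext_hi)) {
    stop("fiducial centroid lies outside the volume")
  }
  he <- rep_len(half_extent_mm, 2L)
  co <- .axis_coords(volume)
  jj <- which(co[[2]] >= cen[2] - he[1] & co[[2]] <= cen[2] + he[1])
  kk <- which(co[[3]] >= cen[3] - he[2] & co[[3]] <= cen[3] + he[2])
  if (!length(jj) || !length(kk)) stop("empty ROI")
  if (jj[1] == 1L || jj[length(jj)] == d[2] || kk[1] == 1L || kk[length(kk)] == d[3]) {
    if (he[1] < (d[2] * volume$spacing_mm[2]) / 2 ||
        he[2] < (d[3] * volume$spacing_mm[3]) / 2) {
      warning("ROI clipped by the volume edge")
    }
  }
  voxel_volume(volume$intensities[, jj, kk, drop = FALSE], volume$spacing_mm,
               origin_mm = volume$origin_mm +
                 c(0, (jj[1] - 1L) * volume$spacing_mm[2],
                   (kk[1] - 1L) * volume$spacing_mm[3]),
               stage = volume$stage, site = volume$site)
}

# ---- threshold selection ---------------------------------------------------

#' Otsu threshold on an integer histogram
#'
#' Exhaustive maximisation of the between-class variance over all split
#' points.
#'
#' @param values sorted unique bin values.
#' @param counts bin counts.
#' @return Threshold placed halfway between the optimal split bin and the
#'   next; voxels strictly above the threshold form the bright class.
#' @export
otsu_threshold <- function(values, counts) {
  stopifnot(length(values) == length(counts), length(values) >= 2L)
  w <- counts / sum(counts)
  mu <- values
  W1 <- cumsum(w)
  M1 <- cumsum(w * mu)
  MT <- M1[length(M1)]
  W2 <- 1 - W1
  valid <- W1 > 0 & W2 > 0
  m1 <- M1 / W1
  m2 <- (MT - M1) / W2
  bc <- W1 * W2 * (m1 - m2)^2
  bc[!valid] <- -Inf
  i <- which.max(bc[-length(bc)])
  (values[i] + values[i + 1L]) / 2
}

#' Select the depot segmentation threshold from the ROI histogram
#'
#' The depot is brighter than the surrounding SC fat, so the target is the
#' grayscale cut between the SC-fat mode and the depot mode. `mask` restricts
#' the histogram (the pipeline passes the SC layer so that air and muscle do
#' not dominate).
#'
#' @param roi a [voxel_volume()].
#' @param method `"otsu"` (default), `"valley"` (minimum between the two
#'   dominant histogram modes) or `"fixed"`.
#' @param fixed_value threshold for `method = "fixed"`.
#' @param mask optional logical array restricting the histogram.
#' @param bin_width histogram bin width in intensity units.
#' @return The selected grayscale threshold.
#' @export
select_threshold <- function(roi, method = c("otsu", "valley", "fixed"),
                             fixed_value = NULL, mask = NULL, bin_width = 1) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed method needs fixed_value")
    return(fixed_value)
  }
  x <- if (is.null(mask)) as.numeric(roi$intensities) else roi$intensities[mask]
  b <- round(x / bin_width)
  tab <- table(b)
  values <- as.numeric(names(tab)) * bin_width
  counts <- as.numeric(tab)
  if (length(values) < 2L) {
    stop("histogram is unimodal/degenerate: no depot appears to be present")
  }
  if (method == "otsu") return(otsu_threshold(values, counts))
  # valley: smooth the histogram, find the minimum between the two top modes
  full <- numeric(max(b) - min(b) + 1L)
  full[b - min(b) + 1L] <- 0
  for (i in seq_along(values)) full[round(values[i] / bin_width) - min(b) + 1L] <- counts[i]
  ker <- stats::dnorm(-7:7, sd = 2.5)
  sm <- as.numeric(stats::filter(full, ker / sum(ker), sides = 2))
  sm[is.na(sm)] <- 0
  pk <- which(diff(sign(diff(sm))) == -2) + 1L
  if (length(pk) < 2L) {
    stop("histogram is unimodal: no depot appears to be present")
  }
  pk <- pk[order(sm[pk], decreasing = TRUE)[1:2]]
  pk <- sort(pk)
  valley <- pk[1] + which.min(sm[pk[1]:pk[2]]) - 1L
  (valley - 1L + min(b)) * bin_width
}

# ---- depot segmentation ----------------------------------------------------

#' Segment the injected depot
#'
#' Thresholds the ROI, cleans the mask with an in-plane morphological opening
#' (structuring element specified in mm), labels 3-D components and keeps the
#' component intersecting a cylinder around the cannula axis (largest wins on
#' ties). Voxels above the skin (fiducial oil) are excluded via `sc_band`
#' when provided, otherwise by dropping components whose shell is mostly
#' background.
#'
#' @param roi a [voxel_volume()].
#' @param threshold grayscale threshold from [select_threshold()].
#' @param cannula_axis_yz cannula axis position `(lateral, slice)` in mm.
#' @param sc_band optional logical array marking the SC layer.
#' @param opening_radius_mm radius of the in-plane opening element.
#' @param cylinder_radius_mm capture radius around the cannula axis.
#' @return Object of class `depot_segmentation` with fields `mask`,
#'   `threshold_used`, `component_id`, `backfilled`, `void_filled_voxels`,
#'   `mesh`, `spacing_mm`, `origin_mm`.
#' @export
segment_depot <- function(roi, threshold, cannula_axis_yz, sc_band = NULL,
                          opening_radius_mm = 0.6, cylinder_radius_mm = 10) {
  arr <- roi$intensities
  mask <- arr >= threshold
  if (!is.null(sc_band)) mask <- mask & sc_band
  r_vox <- max(1L, round(opening_radius_mm / roi$spacing_mm[1]))
  brush <- EBImage::makeBrush(2L * r_vox + 1L, shape = "disc")
  for (k in seq_len(dim(mask)[3])) {
    mk <- EBImage::opening(mask[, , k] * 1L, brush)
    mask[, , k] <- mk > 0
  }
  lab <- label_components_3d(mask)
  n <- max(lab)
  empty <- function(reason) {
    warning("empty depot segmentation: ", reason)
    structure(list(mask = array(FALSE, dim(arr)), threshold_used = threshold,
                   component_id = NA_integer_, backfilled = FALSE,
                   void_filled_voxels = 0L, mesh = NULL,
                   spacing_mm = roi$spacing_mm, origin_mm = roi$origin_mm),
              class = "depot_segmentation")
  }
  if (n == 0L) return(empty("no voxels above threshold"))
  co <- .axis_coords(roi)
  inside_cyl <- outer((co[[2]] - cannula_axis_yz[1])^2,
                      (co[[3]] - cannula_axis_yz[2])^2, "+") <= cylinder_radius_mm^2
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  touches <- integer(0)
  for (comp in seq_len(n)) {
    ksl <- which(apply(lab == comp, 3L, any))
    hit <- FALSE
    for (k in ksl) {
      if (any((lab[, , k] == comp) & matrix(inside_cyl[, k], dim(arr)[1],
                                            dim(arr)[2], byrow = TRUE))) {
        hit <- TRUE; break
      }
    }
    if (hit) touches <- c(touches, comp)
  }
  cand <- if (length(touches)) touches else {
    # nearest component to the axis as fallback
    dmin <- vapply(seq_len(n), function(comp) {
      idx <- which(lab == comp, arr.ind = TRUE)
      min((co[[2]][idx[, 2]] - cannula_axis_yz[1])^2 +
          (co[[3]][idx[, 3]] - cannula_axis_yz[2])^2)
    }, numeric(1))
    which.min(dmin)
  }
  comp <- cand[which.max(sizes[cand])]
  dm <- lab == comp
  if (is.null(sc_band)) {
    # above-skin exclusion: capsules are enclosed by background
    idx <- which(dm, arr.ind = TRUE)
    d <- dim(dm)
    shell_bg <- 0; shell_n <- 0
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))) {
      nb <- sweep(idx, 2L, sh, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
      nb <- nb[ok, , drop = FALSE]
      out <- !dm[nb]
      shell_n <- shell_n + sum(out)
      shell_bg <- shell_bg + sum(arr[nb[out, , drop = FALSE]] < threshold / 4)
    }
    if (shell_n > 0 && shell_bg / shell_n > 0.8) {
      return(empty("only above-skin (capsule-like) components found"))
    }
  }
  if (sum(dm) < 10L) return(empty("component too small"))
  mesh <- mask_to_mesh(dm, roi$spacing_mm, roi$origin_mm)
  structure(list(mask = dm, threshold_used = threshold, component_id = comp,
                 backfilled = FALSE, void_filled_voxels = 0L, mesh = mesh,
                 spacing_mm = roi$spacing_mm, origin_mm = roi$origin_mm),
            class = "depot_segmentation")
}

#' @export
print.depot_segmentation <- function(x, ...) {
  cat(sprintf("<depot_segmentation: %d voxels (%.2f mL), threshold %.1f%s>\n",
              sum(x$mask), sum(x$mask) * prod(x$spacing_mm) / 1000,
              x$threshold_used, if (x$backfilled) ", backfilled" else ""))
  invisible(x)
}

# ---- boundary surfaces -----------------------------------------------------

#' Boundary surface container
#' @param kind `"ID_SC"` or `"SC_IM"`.
#' @param depth_mm matrix of boundary depths over the (lateral, slice) grid.
#' @param valid logical matrix of columns where the boundary was found.
#' @param y_mm,z_mm physical grid coordinates.
#' @return Object of class `boundary_surface` (with a triangulated `mesh`).
#' @export
boundary_surface <- function(kind = c("ID_SC", "SC_IM"), depth_mm, valid,
                             y_mm, z_mm) {
  kind <- match.arg(kind)
  structure(list(kind = kind, depth_mm = depth_mm, valid = valid,
                 y_mm = y_mm, z_mm = z_mm,
                 mesh = height_field_mesh(depth_mm, y_mm, z_mm)),
            class = "boundary_surface")
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat(sprintf("<boundary_surface %s: %dx%d columns, %.0f%% valid>\n",
              x$kind, nrow(x$depth_mm), ncol(x$depth_mm), 100 * mean(x$valid)))
  invisible(x)
}

#' Extract the ID/SC and SC/IM boundary surfaces
#'
#' Parses each skin-plane column of the classified volume: the SC/IM boundary
#' is the entry into the contiguous deep muscle block; the ID/SC boundary is
#' the first fat/bright voxel above it that is not separated from it by a
#' background gap of at least `min_gap_mm` (which excludes the floating
#' fiducial capsules above the invisible dermis). Depot voxels count as SC
#' continuation, so columns through the depot do not drop out. Boundary depths
#' are refined to sub-voxel precision by linear intensity interpolation,
#' median-filtered, and invalid columns are filled from their neighbours
#' (flagged in `valid`).
#'
#' @param volume a bias-corrected [voxel_volume()].
#' @param classes optional [classify_tissue()] result.
#' @param void_mask optional logical array of cannula-void voxels; the ID/SC
#'   boundary in any column touched by the void is marked invalid and filled
#'   from its neighbours (the void obliterates the local boundary signal).
#' @param min_gap_mm background gap length that separates distinct structures.
#' @param median_window odd window size of the height-field median filter.
#' @param subvoxel logical; refine boundary depths by intensity interpolation.
#' @return List with `id_sc` and `sc_im` [boundary_surface()]s.
#' @export
extract_boundaries <- function(volume, classes = NULL, void_mask = NULL,
                               min_gap_mm = 1.2, median_window = 3L,
                               subvoxel = TRUE) {
  if (is.null(classes)) classes <- classify_tissue(volume)
  cls <- classes$class
  arr <- volume$intensities
  d <- dim(cls)
  dx <- volume$spacing_mm[1]
  gap_vox <- max(1L, ceiling(min_gap_mm / dx))
  cen <- classes$centers
  n_col <- d[2] * d[3]
  id_idx <- matrix(NA_real_, d[2], d[3])
  im_idx <- matrix(NA_real_, d[2], d[3])
  win <- 5L
  for (jk in seq_len(n_col)) {
    j <- ((jk - 1L) %% d[2]) + 1L
    k <- ((jk - 1L) %/% d[2]) + 1L
    v <- cls[, j, k]
    musc <- v == 2L
    cs <- c(0L, cumsum(musc))
    wlen <- pmin(win, d[1] - seq_len(d[1]) + 1L)
    frac <- (cs[pmin(seq_len(d[1]) + win, d[1] + 1L)] - cs[seq_len(d[1])]) / wlen
    m_cand <- which(frac >= 0.8 & musc)
    if (!length(m_cand)) next
    m <- m_cand[1L]
    if (m <= 1L) next
    above <- v[seq_len(m - 1L)]
    tissue <- above == 3L | above == 4L
    if (!any(tissue)) next
    # partial-volume voxels at interface edges fall into the muscle intensity
    # band; above the muscle block they are gap, not tissue
    bg_rle <- rle(above == 1L | above == 2L)
    ends <- cumsum(bg_rle$lengths)
    starts <- ends - bg_rle$lengths + 1L
    long_bg <- which(bg_rle$values & bg_rle$lengths >= gap_vox)
    lo <- if (length(long_bg)) ends[long_bg[length(long_bg)]] + 1L else 1L
    t_idx <- which(tissue & seq_len(m - 1L) >= lo)
    if (!length(t_idx)) next
    id_idx[j, k] <- t_idx[1L]
    im_idx[j, k] <- m
  }

  ok_pair <- !is.na(id_idx) & !is.na(im_idx) & id_idx < im_idx
  id_idx[!ok_pair] <- NA_real_
  im_idx[is.na(im_idx)] <- NA_real_
  if (!is.null(void_mask) && any(void_mask)) {
    id_idx[apply(void_mask, c(2L, 3L), any)] <- NA_real_
  }
  # Sub-voxel boundary depth from the partial-volume fraction of the single
  # mixed voxel at the interface: for a box-averaged voxel of extent dx whose
  # value is a convex mix of the two adjacent tissue levels, the interface
  # position follows exactly from the mixing fraction. This stays accurate
  # even when a second interface (e.g. the depot just below the ID/SC
  # boundary) sits one voxel away, where a two-point intensity interpolation
  # would be biased.
  depth_of <- function(idx_mat, upper_level, lower_level) {
    depth <- volume$origin_mm[1] + (idx_mat - 1) * dx  # voxel top face fallback
    if (subvoxel) {
      span <- lower_level - upper_level
      eps <- 0.12 * abs(span)
      sel <- which(!is.na(idx_mat) & idx_mat > 1)
      for (p in sel) {
        j <- ((p - 1L) %% d[2]) + 1L
        k <- ((p - 1L) %/% d[2]) + 1L
        i <- idx_mat[j, k]
        c1 <- arr[i, j, k]; c0 <- arr[i - 1L, j, k]
        # fraction of a voxel occupied by the lower (deeper) tissue
        frac <- function(v) min(max((v - upper_level) / span, 0), 1)
        if ((c0 - upper_level) / span > eps / abs(span) &&
            (lower_level - c0) / span > eps / abs(span)) {
          b <- (i - 1.5) * dx + dx / 2 - dx * frac(c0)
        } else if ((lower_level - c1) / span > eps / abs(span)) {
          b <- (i - 0.5) * dx + dx / 2 - dx * frac(c1)
        } else {
          b <- (i - 1) * dx  # clean edge between two pure voxels
        }
        depth[j, k] <- volume$origin_mm[1] + b
      }
    }
    depth
  }
  id_depth <- depth_of(id_idx, cen[["background"]], cen[["sc_fat"]])
  im_depth <- depth_of(im_idx, cen[["sc_fat"]], cen[["muscle"]])
  # all smoothing is lateral within each slice so that per-slice structure
  # (the breathing stair-step) is preserved for realignment
  reject <- function(m, window = 21L, thresh = 2) {
    ref <- .lateral_filter(m, window, stats::median)
    bad <- !is.na(m) & !is.na(ref) & abs(m - ref) > thresh
    m[bad] <- NA
    m
  }
  id_depth <- reject(id_depth)
  im_depth <- reject(im_depth)
  id_valid <- !is.na(id_depth)
  im_valid <- !is.na(im_depth)
  id_depth <- .lateral_filter(id_depth, median_window, stats::median)
  im_depth <- .lateral_filter(im_depth, median_window, stats::median)
  if (subvoxel) {  # light lateral averaging to tame voxel-quantisation jitter
    id_depth <- .lateral_filter(id_depth, 5L, mean)
    im_depth <- .lateral_filter(im_depth, 5L, mean)
  }
  id_depth <- .fill_invalid(id_depth)
  im_depth <- .fill_invalid(im_depth)
  bad <- which(id_depth >= im_depth)
  if (length(bad)) { id_valid[bad] <- FALSE; im_valid[bad] <- FALSE }
  co <- .axis_coords(volume)
  list(id_sc = boundary_surface("ID_SC", id_depth, id_valid, co[[2]], co[[3]]),
       sc_im = boundary_surface("SC_IM", im_depth, im_valid, co[[2]], co[[3]]))
}

# NA-aware filter along the lateral (first) dimension only.
#' @noRd
.lateral_filter <- function(m, window = 3L, fun = stats::median) {
  if (window < 2L) return(m)
  h <- window %/% 2L
  d <- dim(m)
  stack <- array(NA_real_, c(d[1], d[2], 2L * h + 1L))
  for (s in seq_len(2L * h + 1L)) {
    src_i <- pmin(pmax(seq_len(d[1]) + s - h - 1L, 1L), d[1])
    stack[, , s] <- m[src_i, ]
  }
  out <- apply(stack, c(1L, 2L), fun, na.rm = TRUE)
  out[is.nan(out)] <- NA
  out
}

# Fill NA columns from the mean of valid neighbours, iteratively.
#' @noRd
.fill_invalid <- function(m) {
  for (it in 1:200) {
    na <- is.na(m)
    if (!any(na)) break
    d <- dim(m)
    acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      src_i <- pmin(pmax(seq_len(d[1]) + sh[1], 1L), d[1])
      src_j <- pmin(pmax(seq_len(d[2]) + sh[2], 1L), d[2])
      nb <- m[src_i, src_j]
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    fill <- na & cnt > 0
    m[fill] <- acc[fill] / cnt[fill]
  }
  m
}

#' SC-layer membership mask between two boundary surfaces
#'
#' @param volume a [voxel_volume()] sharing the boundary grid.
#' @param id_sc,sc_im [boundary_surface()]s.
#' @param margin_mm band margin subtracted inside each boundary.
#' @return Logical array: voxel centers between the two surfaces.
#' @export
sc_band_mask <- function(volume, id_sc, sc_im, margin_mm = 0) {
  d <- dim(volume$intensities)
  x <- .axis_coords(volume)[[1]]
  band <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    lo <- matrix(id_sc$depth_mm[, k] + margin_mm, d[1], d[2], byrow = TRUE)
    hi <- matrix(sc_im$depth_mm[, k] - margin_mm, d[1], d[2], byrow = TRUE)
    xs <- matrix(x, d[1], d[2])
    band[, , k] <- xs >= lo & xs <= hi
  }
  band
}
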