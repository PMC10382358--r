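# Artifact corrections and inter-scan alignment: dermal-gap arithmetic,
# metal-void detection and backfill, attenuation (bias-field) correction,
# breathing slice-to-slice realignment, and least-squares rigid series
# alignment (orthogonal Procrustes on fiducials + ICP refinement on the ID
# surface).

#' Estimate dermis thickness from the fiducial gap
#'
#' The dermis is invisible in the sequence and appears as a gap between the
#' imaged fish-oil and the ID/SC interface; its thickness is the mean gap
#' width minus the capsule wall thickness (an empirical caliper value).
#'
#' @param fiducials a `fiducial_set`.
#' @param id_sc the ID/SC [boundary_surface()].
#' @param capsule_wall_mm capsule shell thickness (mm), default 0.5.
#' @param max_offset_mm a capsule must sit within this lateral distance of a
#'   valid boundary column to be used.
#' @return Estimated dermis thickness (mm), clamped at 0 with a warning if
#'   the wall exceeds the gap.
#' @export
estimate_dermal_thickness <- function(fiducials, id_sc, capsule_wall_mm = 0.5,
                                      max_offset_mm = 6) {
  stopifnot(capsule_wall_mm >= 0)
  gaps <- numeric(0)
  for (cp in fiducials$capsules) {
    j <- which.min(abs(id_sc$y_mm - cp$oil_centroid_mm[2]))
    k <- which.min(abs(id_sc$z_mm - cp$oil_centroid_mm[3]))
    off <- sqrt((id_sc$y_mm[j] - cp$oil_centroid_mm[2])^2 +
                (id_sc$z_mm[k] - cp$oil_centroid_mm[3])^2)
    if (off > max_offset_mm || !id_sc$valid[j, k]) next
    gaps <- c(gaps, id_sc$depth_mm[j, k] - cp$oil_lower_depth_mm)
  }
  if (!length(gaps)) stop("no fiducial capsule sits above a valid boundary column")
  est <- mean(gaps) - capsule_wall_mm
  if (est < 0) {
    warning("capsule wall thickness exceeds the measured gap; clamping dermis to 0")
    est <- 0
  }
  est
}

#' Detect the metal-cannula signal void
#'
#' Background-intensity voxels lying inside the SC layer (between the
#' extracted ID/SC and SC/IM boundaries) within a cylinder about the cannula
#' axis. The ID/SC field is neighbour-filled across the void itself, so the
#' void interior — which obliterates the local boundary signal — is still
#' bracketed.
#'
#' @param volume a [voxel_volume()].
#' @param axis_yz cannula axis `(lateral, slice)` position in mm.
#' @param id_sc,sc_im extracted [boundary_surface()]s.
#' @param classes optional [classify_tissue()] result.
#' @param radius_max_mm search radius around the axis.
#' @param margin_mm band margin inside each boundary.
#' @return Logical array of void voxels.
#' @export
detect_void <- function(volume, axis_yz, id_sc, sc_im, classes = NULL,
                        radius_max_mm = 6, margin_mm = 0.3) {
  if (is.null(classes)) classes <- classify_tissue(volume)
  cls <- classes$class
  d <- dim(cls)
  co <- .axis_coords(volume)
  out <- array(FALSE, d)
  jj <- which(abs(co[[2]] - axis_yz[1]) <= radius_max_mm)
  kk <- which(abs(co[[3]] - axis_yz[2]) <= radius_max_mm)
  for (k in kk) for (j in jj) {
    if ((co[[2]][j] - axis_yz[1])^2 + (co[[3]][k] - axis_yz[2])^2 > radius_max_mm^2) next
    ii <- which(co[[1]] >= id_sc$depth_mm[j, k] + margin_mm &
                co[[1]] <= sc_im$depth_mm[j, k] - margin_mm)
    if (!length(ii)) next
    out[ii[cls[ii, j, k] == 1L], j, k] <- TRUE
  }
  out
}

#' Backfill the cannula void from the post-removal segmentation
#'
#' Voxels inside the void adopt the occupancy of the (rigidly aligned)
#' post-removal depot segmentation; no voxel outside the void is modified.
#'
#' @param seg target [segment_depot()] result.
#' @param void_mask logical array of void voxels in the target frame.
#' @param reference_seg post-removal `depot_segmentation`.
#' @param transform [rigid_transform()] mapping the reference frame into the
#'   target frame.
#' @return The updated `depot_segmentation` (flag `backfilled`,
#'   `void_filled_voxels` recorded, mesh recomputed).
#' @export
backfill_void <- function(seg, void_mask, reference_seg, transform = rigid_transform()) {
  if (!any(void_mask)) return(seg)
  if (!any(reference_seg$mask)) {
    warning("reference depot is empty; nothing to backfill")
    return(seg)
  }
  idx <- which(void_mask, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 0.5, 2L, seg$spacing_mm, "*"), 2L, seg$origin_mm, "+")
  pref <- rt_apply(rt_invert(transform), pts)
  vref <- sweep(sweep(pref, 2L, reference_seg$origin_mm, "-"), 2L,
                reference_seg$spacing_mm, "/") + 0.5
  vref <- round(vref)
  dref <- dim(reference_seg$mask)
  ok <- vref[, 1] >= 1 & vref[, 1] <= dref[1] & vref[, 2] >= 1 &
    vref[, 2] <= dref[2] & vref[, 3] >= 1 & vref[, 3] <= dref[3]
  occ <- rep(FALSE, nrow(idx))
  occ[ok] <- reference_seg$mask[vref[ok, , drop = FALSE]]
  before <- seg$mask[idx]
  seg$mask[idx] <- occ
  seg$void_filled_voxels <- sum(occ & !before)
  seg$backfilled <- TRUE
  seg$mesh <- if (any(seg$mask)) {
    mask_to_mesh(seg$mask, seg$spacing_mm, seg$origin_mm)
  } else NULL
  seg
}

#' Correct the low-order attenuation (bias) field
#'
#' Fits a low-order polynomial in the scaled spatial coordinates to the log
#' intensities of a single tissue class (by default the largest non-background
#' class), normalises the fitted field to mean one over the fit voxels, and
#' divides it out.
#'
#' @param roi a [voxel_volume()].
#' @param order polynomial order (1, 2 or 3).
#' @param mask optional logical array of voxels to fit on (overrides the
#'   automatic class selection).
#' @return The corrected [voxel_volume()]; a constant image is returned
#'   unchanged with a message.
#' @export
bias_correct <- function(roi, order = 2L, mask = NULL) {
  stopifnot(order %in% 1:3)
  arr <- roi$intensities
  if (stats::sd(arr) < 1e-12) {
    message("constant image: bias fit is singular, returning input unchanged")
    return(roi)
  }
  if (is.null(mask)) {
    cl <- tryCatch(classify_tissue(roi), error = function(e) NULL)
    if (is.null(cl)) {
      message("degenerate histogram: returning input unchanged")
      return(roi)
    }
    counts <- tabulate(cl$class[cl$class >= 2L] - 1L, nbins = 3L)
    pick <- which.max(counts) + 1L
    mask <- cl$class == pick
  }
  idx <- which(mask)
  if (length(idx) < 50L) {
    message("too few fit voxels: returning input unchanged")
    return(roi)
  }
  if (length(idx) > 40000L) idx <- idx[round(seq(1L, length(idx), length.out = 40000L))]
  d <- dim(arr)
  ai <- arrayInd(idx, d)
  co <- .axis_coords(roi)
  u <- cbind((co[[1]][ai[, 1]] - mean(co[[1]])) / (diff(range(co[[1]])) / 2),
             (co[[2]][ai[, 2]] - mean(co[[2]])) / (diff(range(co[[2]])) / 2),
             (co[[3]][ai[, 3]] - mean(co[[3]])) / (max(diff(range(co[[3]])), 1) / 2))
  X <- .poly_design(u, order)
  y <- log(pmax(arr[idx], 1e-6))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the field over the full grid
  ug <- list((co[[1]] - mean(co[[1]])) / (diff(range(co[[1]])) / 2),
             (co[[2]] - mean(co[[2]])) / (diff(range(co[[2]])) / 2),
             (co[[3]] - mean(co[[3]])) / (max(diff(range(co[[3]])), 1) / 2))
  Ug <- cbind(rep(ug[[1]], times = d[2] * d[3]),
              rep(rep(ug[[2]], each = d[1]), times = d[3]),
              rep(ug[[3]], each = d[1] * d[2]))
  field <- exp(.poly_design(Ug, order) %*% beta)
  # remove the constant component: normalise to mean 1 over the fit voxels
  field <- field / mean(field[idx])
  out <- arr / array(field, d)
  voxel_volume(pmax(out, 0), roi$spacing_mm, roi$origin_mm,
               stage = roi$stage, site = roi$site)
}

# Polynomial design matrix, all monomials with total degree <= order.
#' @noRd
.poly_design <- function(u, order) {
  cols <- list(rep(1, nrow(u)))
  for (p1 in 0:order) for (p2 in 0:(order - p1)) for (p3 in 0:(order - p1 - p2)) {
    if (p1 + p2 + p3 == 0) next
    cols[[length(cols) + 1L]] <- u[, 1]^p1 * u[, 2]^p2 * u[, 3]^p3
  }
  do.call(cbind, cols)
}

#' Slice-to-slice realignment of the breathing stair-step
#'
#' Estimates, per axial slice, the in-plane (depth, lateral) translation that
#' minimises the squared mismatch of its boundary contours against the
#' running average of the neighbouring slices, under a zero-net-mean-shift
#' constraint, and applies the correction to both surfaces (and optionally the
#' intensity volume). Damped fixed-point iteration; idempotent once converged.
#'
#' @param id_sc,sc_im the extracted [boundary_surface()]s.
#' @param volume optional [voxel_volume()] to correct alongside the surfaces.
#' @param max_iter,damp iteration controls.
#' @param lateral logical; also search for lateral shifts (+-4 voxels).
#' @param tol convergence tolerance on the shift update (mm).
#' @return List with `shift_mm` (n_slices x 2 matrix of applied corrections,
#'   approximately the negated breathing schedule), corrected `id_sc`,
#'   `sc_im` and `volume`.
#' @export
realign_slices <- function(id_sc, sc_im, volume = NULL, max_iter = 15L,
                           damp = 0.6, lateral = TRUE, tol = 0.01) {
  d_id <- id_sc$depth_mm
  d_im <- sc_im$depth_mm
  ny <- nrow(d_id); nz <- ncol(d_id)
  dy <- if (ny > 1L) id_sc$y_mm[2] - id_sc$y_mm[1] else 1
  total <- matrix(0, nz, 2L)
  lat_range <- if (lateral) -4:4 else 0L

  shift_contour <- function(m, s_vox) {
    if (s_vox == 0) return(m)
    j0 <- seq_len(ny) + s_vox
    jl <- floor(j0); fj <- j0 - jl
    gl <- pmin(pmax(jl, 1L), ny); gh <- pmin(pmax(jl + 1L, 1L), ny)
    m[gl, , drop = FALSE] * (1 - fj) + m[gh, , drop = FALSE] * fj
  }

  for (it in seq_len(max_iter)) {
    upd <- matrix(0, nz, 2L)
    for (k in seq_len(nz)) {
      nbr <- setdiff(c(k - 1L, k + 1L), c(0L, nz + 1L))
      ref_id <- rowMeans(d_id[, nbr, drop = FALSE])
      ref_im <- rowMeans(d_im[, nbr, drop = FALSE])
      best <- c(Inf, 0, 0)
      for (s in lat_range) {
        cid <- shift_contour(d_id[, k, drop = FALSE], s)
        cim <- shift_contour(d_im[, k, drop = FALSE], s)
        # median: a handful of locally corrupted columns (cannula void) must
        # not masquerade as a whole-slice shift
        dk <- stats::median(c(cid - ref_id, cim - ref_im))
        ss <- sum((cid - ref_id - dk)^2) + sum((cim - ref_im - dk)^2)
        if (ss < best[1]) best <- c(ss, dk, s)
      }
      # parabolic refinement of the lateral shift around the best integer
      s0 <- best[3]
      if (lateral && s0 > min(lat_range) && s0 < max(lat_range)) {
        ssd_at <- function(s) {
          cid <- shift_contour(d_id[, k, drop = FALSE], s)
          cim <- shift_contour(d_im[, k, drop = FALSE], s)
          dk <- stats::median(c(cid - ref_id, cim - ref_im))
          sum((cid - ref_id - dk)^2) + sum((cim - ref_im - dk)^2)
        }
        f0 <- best[1]; fm <- ssd_at(s0 - 1); fp <- ssd_at(s0 + 1)
        den <- fm - 2 * f0 + fp
        if (den > 1e-12) s0 <- s0 + 0.5 * (fm - fp) / den
      }
      upd[k, ] <- c(best[2], s0 * dy)
    }
    upd <- damp * sweep(upd, 2L, colMeans(upd))
    if (max(abs(upd)) < tol) break
    for (k in seq_len(nz)) {
      d_id[, k] <- shift_contour(d_id[, k, drop = FALSE], upd[k, 2] / dy) - upd[k, 1]
      d_im[, k] <- shift_contour(d_im[, k, drop = FALSE], upd[k, 2] / dy) - upd[k, 1]
    }
    total <- total - upd  # correction applied = negative of estimated displacement
  }
  total <- sweep(total, 2L, colMeans(total))

  out_vol <- volume
  if (!is.null(volume) && any(total != 0)) {
    arr <- volume$intensities
    fill <- as.numeric(stats::quantile(arr, 0.02))
    for (k in seq_len(dim(arr)[3])) {
      if (all(abs(total[k, ]) < 1e-9)) next
      arr[, , k] <- .shift_slice(arr[, , k], total[k, ] / volume$spacing_mm[1:2], fill)
    }
    out_vol <- voxel_volume(arr, volume$spacing_mm, volume$origin_mm,
                            stage = volume$stage, site = volume$site)
  }
  list(shift_mm = total,
       id_sc = boundary_surface("ID_SC", d_id, id_sc$valid, id_sc$y_mm, id_sc$z_mm),
       sc_im = boundary_surface("SC_IM", d_im, sc_im$valid, sc_im$y_mm, sc_im$z_mm),
       volume = out_vol)
}

# Kabsch / orthogonal Procrustes: rigid fit mapping P onto Q.
#' @noRd
.kabsch <- function(P, Q) {
  pb <- colMeans(P); qb <- colMeans(Q)
  H <- t(sweep(P, 2L, pb)) %*% sweep(Q, 2L, qb)
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  t3 <- qb - as.numeric(R %*% pb)
  rigid_transform(R, t3)
}

#' Least-squares rigid alignment of one scan to a reference
#'
#' Closed-form orthogonal Procrustes on matched fiducial centroids (matched by
#' angular order around their centroid), refined on a tissue surface in one of
#' two ways: `"depth_offset"` (default) corrects the depth translation by the
#' median height residual against the reference surface — when given the
#' SC/IM (muscle) surface, which does not deform with injection, this
#' prevents the anatomical SC expansion from leaking into the rigid fit;
#' `"icp"` runs iterative-closest-point on surface samples with the fiducials
#' heavily weighted (they anchor the in-plane translation that a nearly flat
#' surface cannot constrain).
#'
#' @param moving_fiducials,reference_fiducials `fiducial_set`s of the moving
#'   and reference scans.
#' @param moving_surface,reference_surface optional [boundary_surface()]s for
#'   refinement.
#' @param method surface refinement: `"depth_offset"` or `"icp"`.
#' @param icp_iterations number of ICP iterations.
#' @param fiducial_weight replication weight of fiducial pairs vs surface
#'   samples in the ICP fit.
#' @return [rigid_transform()] mapping moving coordinates into the reference
#'   frame; `rms_residual_mm` holds the final matched-pair RMS and attribute
#'   `rms_history` the per-iteration values.
#' @export
align_series <- function(moving_fiducials, reference_fiducials,
                         moving_surface = NULL, reference_surface = NULL,
                         method = c("depth_offset", "icp"),
                         icp_iterations = 8L, fiducial_weight = 200L) {
  method <- match.arg(method)
  P <- fiducial_centroids(moving_fiducials)
  Q <- fiducial_centroids(reference_fiducials)
  if (nrow(P) != nrow(Q)) stop("fiducial sets differ in capsule count")
  if (nrow(P) < 3L) stop("need at least 3 fiducial correspondences")
  ordang <- function(M) {
    c0 <- colMeans(M)
    order(atan2(M[, 3] - c0[3], M[, 2] - c0[2]))
  }
  P <- P[ordang(P), , drop = FALSE]
  Q <- Q[ordang(Q), , drop = FALSE]
  if (qr(sweep(P, 2L, colMeans(P)))$rank < 2L) {
    stop("fiducial correspondences are collinear")
  }
  tf <- .kabsch(P, Q)
  res <- sqrt(mean(rowSums((rt_apply(tf, P) - Q)^2)))
  history <- res

  samp_pts <- function(bs, step = 3L) {
    jj <- seq(1L, nrow(bs$depth_mm), by = step)
    kk <- seq_len(ncol(bs$depth_mm))
    pts <- cbind(as.numeric(bs$depth_mm[jj, kk]),
                 rep(bs$y_mm[jj], times = length(kk)),
                 rep(bs$z_mm[kk], each = length(jj)))
    pts[as.logical(bs$valid[jj, kk]), , drop = FALSE]
  }
  if (!is.null(moving_surface) && !is.null(reference_surface) &&
      method == "depth_offset") {
    Pm <- samp_pts(moving_surface, step = 2L)
    Pt <- rt_apply(tf, Pm)
    href <- .interp_height(reference_surface, Pt[, 2], Pt[, 3])
    resid <- href - Pt[, 1]
    resid <- resid[is.finite(resid)]
    if (length(resid) >= 10L) {
      tf$translation_mm[1] <- tf$translation_mm[1] + stats::median(resid)
      Pt2 <- rt_apply(tf, Pm)
      res <- sqrt(mean((.interp_height(reference_surface, Pt2[, 2], Pt2[, 3]) -
                          Pt2[, 1])^2, na.rm = TRUE))
      history <- c(history, res)
    }
  } else if (!is.null(moving_surface) && !is.null(reference_surface) &&
             icp_iterations > 0L) {
    Pm <- samp_pts(moving_surface)
    Qs <- samp_pts(reference_surface, step = 1L)
    if (nrow(Pm) >= 10L && nrow(Qs) >= 10L) {
      Q2 <- rowSums(Qs^2)
      for (it in seq_len(icp_iterations)) {
        Pt <- rt_apply(tf, Pm)
        nn <- integer(nrow(Pt))
        for (i0 in seq(1L, nrow(Pt), by = 1500L)) {
          ii <- i0:min(i0 + 1499L, nrow(Pt))
          d2 <- outer(rowSums(Pt[ii, , drop = FALSE]^2), Q2, "+") -
            2 * Pt[ii, , drop = FALSE] %*% t(Qs)
          nn[ii] <- max.col(-d2, ties.method = "first")
        }
        Pfit <- rbind(Pm[rep(seq_len(nrow(Pm)), 1L), , drop = FALSE],
                      P[rep(seq_len(nrow(P)), fiducial_weight), , drop = FALSE])
        Qfit <- rbind(Qs[nn, , drop = FALSE],
                      Q[rep(seq_len(nrow(Q)), fiducial_weight), , drop = FALSE])
        tf_new <- .kabsch(Pfit, Qfit)
        res_new <- sqrt(mean(rowSums((rt_apply(tf_new, Pfit) - Qfit)^2)))
        history <- c(history, res_new)
        tf <- tf_new
        res <- res_new
      }
    }
  }
  tf$rms_residual_mm <- res
  attr(tf, "rms_history") <- history
  tf
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of equal dimension.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
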