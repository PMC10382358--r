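# Synthetic LVSC injection-series phantom with exact ground truth.
#
# The phantom reproduces the study conditions of an incremental subcutaneous
# saline injection series imaged with a T2-FSE-like sequence: axial slices at
# 4 mm pitch (3 mm slabs + 1 mm skip), 0.6 mm in-plane resolution, a ~10.8 cm
# stack, fish-oil fiducial capsules floating above an invisible dermis gap,
# visible ID/SC and SC/IM boundaries, a bright conforming depot, and the four
# documented artifacts (dermis gap, metal-cannula void, attenuation bias,
# breathing stair-step).
#
# Geometry model: the SC/IM interface is fixed across stages; injections lift
# the ID/SC interface (and skin) by a Gaussian bump whose apex equals the
# requested per-stage thickness increment and whose integral equals the
# injected volume, so SC-layer volume increase matches depot volume.  The
# depot itself is an oblate lobulated blob sitting just above the SC/IM
# interface; its voxelised volume is solved to the target by bisection.

#' Reference site conditions for the LVSC study phantom
#'
#' Site-level mean subcutaneous thicknesses (mm) at cannula placement and at
#' the maximum cumulative volume, mean percent changes per stage, and the
#' cumulative injection volumes administered per site. These are the study
#' conditions the phantom generator emulates.
#'
#' @return A named list with one entry per site (`abdomen`, `thigh`, `arm`).
#' @export
lvsc_site_reference <- function() {
  list(
    abdomen = list(baseline_mm = 19.0, final_mm = 20.3,
                   pct_change = c(0.7, 4.5, 5.2), volumes_mL = c(2, 5, 10)),
    thigh = list(baseline_mm = 10.2, final_mm = 14.3,
                 pct_change = c(11.2, 21.3, 28.5), volumes_mL = c(2, 5, 10)),
    arm = list(baseline_mm = 8.8, final_mm = 9.9,
               pct_change = c(5.9, 12.2), volumes_mL = c(2, 5)))
}

#' @noRd
.site_defaults <- function(site) {
  switch(site,
    abdomen = list(lateral_extent_mm = 160, depth_extent_mm = 64,
                   sc_im_base_mm = 36, breathing_amp_mm = 1.5),
    thigh = list(lateral_extent_mm = 120, depth_extent_mm = 52,
                 sc_im_base_mm = 27, breathing_amp_mm = 0),
    arm = list(lateral_extent_mm = 100, depth_extent_mm = 48,
               sc_im_base_mm = 25, breathing_amp_mm = 0))
}

#' Phantom specification
#'
#' Parameters controlling the synthetic injection-series generator. Defaults
#' reproduce the imaging protocol (0.6 mm in-plane, 3 mm slices with 1 mm
#' skip, 10.8 cm stack) and per-site anatomy; thickness targets default to the
#' per-site reference conditions (see [lvsc_site_reference()]).
#'
#' @param site injection site: `"abdomen"`, `"thigh"` or `"arm"`.
#' @param depot_volumes_mL strictly increasing cumulative volumes; subset of
#'   `c(2, 5, 10)` mapping to stages `v2`, `v5`, `v10`.
#' @param baseline_thickness_mm SC thickness (mm) at the cannula position
#'   before injection (the `naive`/`insertion` apex thickness).
#' @param stage_apex_thickness_mm named or positional vector of SC thickness
#'   at the cannula position for each injected stage; default
#'   `baseline * (1 + stage_pct/100)`.
#' @param stage_pct per-stage percent change in apex thickness (used when
#'   `stage_apex_thickness_mm` is not given).
#' @param in_plane_res_mm,slice_pitch_mm,slice_thickness_mm,stack_extent_mm
#'   acquisition geometry (mm).
#' @param lateral_extent_mm,depth_extent_mm in-plane field of view (mm);
#'   site-dependent defaults.
#' @param dermis_thickness_mm dermis thickness (invisible in the sequence).
#' @param sc_im_base_mm depth of the muscle interface at the stack center.
#' @param intensity_levels named levels for `background`, `dermis`, `muscle`,
#'   `sc_fat`, `depot`, `oil`; depot must exceed sc_fat.
#' @param noise_sigma additive noise SD; `noise_model` is `"gaussian"` or
#'   `"rician"`.
#' @param bias_field_amplitude relative amplitude of the multiplicative
#'   low-order attenuation field.
#' @param breathing_shift_mm per-slice in-plane shift: `NULL`/0 for none, a
#'   scalar amplitude for an alternating depth-axis stair-step, or an
#'   `n_slices x 2` matrix of (depth, lateral) shifts in mm.
#' @param void_radius_mm radius of the metal-cannula signal void.
#' @param capsule_wall_mm,capsule_oil_radius_mm fiducial capsule geometry.
#' @param fiducial_offsets_mm 2-column matrix of capsule (lateral, slice)
#'   offsets from the cannula position.
#' @param depot_eccentricity in-plane/depth semi-axis ratio of the depot.
#' @param depot_lobularity amplitude scale of the seeded lobular perturbation.
#' @param reposition_translation_mm,reposition_angle_deg amplitude of the
#'   rigid subject-repositioning offsets applied to the `naive` and
#'   `post_removal` scans.
#' @param seed integer seed controlling every random element.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(site = c("thigh", "abdomen", "arm"),
                         depot_volumes_mL = NULL,
                         baseline_thickness_mm = NULL,
                         stage_apex_thickness_mm = NULL,
                         stage_pct = NULL,
                         in_plane_res_mm = 0.6,
                         slice_pitch_mm = 4,
                         slice_thickness_mm = 3,
                         stack_extent_mm = 108,
                         lateral_extent_mm = NULL,
                         depth_extent_mm = NULL,
                         dermis_thickness_mm = 1.8,
                         sc_im_base_mm = NULL,
                         intensity_levels = c(background = 10, dermis = 10,
                                              muscle = 60, sc_fat = 110,
                                              depot = 190, oil = 235),
                         noise_sigma = 4,
                         noise_model = c("gaussian", "rician"),
                         bias_field_amplitude = 0.15,
                         breathing_shift_mm = NULL,
                         void_radius_mm = 3,
                         capsule_wall_mm = 0.5,
                         capsule_oil_radius_mm = 4.5,
                         fiducial_offsets_mm = cbind(c(-28, 28, -28, 28),
                                                     c(-22, -22, 22, 22)),
                         depot_eccentricity = 2.5,
                         depot_lobularity = 0.07,
                         reposition_translation_mm = 1.5,
                         reposition_angle_deg = 1.5,
                         seed = 1L) {
  site <- match.arg(site)
  ref <- lvsc_site_reference()[[site]]
  sd0 <- .site_defaults(site)
  if (is.null(depot_volumes_mL)) depot_volumes_mL <- ref$volumes_mL
  if (is.null(baseline_thickness_mm)) baseline_thickness_mm <- ref$baseline_mm
  if (is.null(stage_pct)) stage_pct <- ref$pct_change[seq_along(depot_volumes_mL)]
  if (is.null(lateral_extent_mm)) lateral_extent_mm <- sd0$lateral_extent_mm
  if (is.null(depth_extent_mm)) depth_extent_mm <- sd0$depth_extent_mm
  if (is.null(sc_im_base_mm)) sc_im_base_mm <- sd0$sc_im_base_mm
  if (is.null(breathing_shift_mm)) breathing_shift_mm <- sd0$breathing_amp_mm
  if (is.null(stage_apex_thickness_mm)) {
    if (length(stage_pct) != length(depot_volumes_mL)) {
      stop("stage_pct must have one entry per injected volume")
    }
    stage_apex_thickness_mm <- baseline_thickness_mm * (1 + stage_pct / 100)
  }
  if (!all(depot_volumes_mL %in% c(2, 5, 10)) ||
      any(diff(depot_volumes_mL) <= 0)) {
    stop("depot_volumes_mL must be strictly increasing and drawn from 2, 5, 10 mL")
  }
  if (length(stage_apex_thickness_mm) != length(depot_volumes_mL)) {
    stop("stage_apex_thickness_mm must have one entry per injected volume")
  }
  if (slice_pitch_mm < slice_thickness_mm) {
    stop("slice pitch must be at least the slice thickness")
  }
  if (intensity_levels[["depot"]] <= intensity_levels[["sc_fat"]]) {
    stop("depot intensity must be strictly greater than SC fat intensity")
  }
  if (baseline_thickness_mm <= 0 || dermis_thickness_mm <= 0 ||
      any(stage_apex_thickness_mm <= 0)) {
    stop("thicknesses must be strictly positive")
  }
  if (any(diff(c(baseline_thickness_mm, stage_apex_thickness_mm)) < 0)) {
    stop("apex thickness must be non-decreasing across stages")
  }
  spec <- list(site = site, depot_volumes_mL = depot_volumes_mL,
               baseline_thickness_mm = baseline_thickness_mm,
               stage_apex_thickness_mm = as.numeric(stage_apex_thickness_mm),
               in_plane_res_mm = in_plane_res_mm,
               slice_pitch_mm = slice_pitch_mm,
               slice_thickness_mm = slice_thickness_mm,
               stack_extent_mm = stack_extent_mm,
               lateral_extent_mm = lateral_extent_mm,
               depth_extent_mm = depth_extent_mm,
               dermis_thickness_mm = dermis_thickness_mm,
               sc_im_base_mm = sc_im_base_mm,
               intensity_levels = intensity_levels,
               noise_sigma = noise_sigma,
               noise_model = match.arg(noise_model),
               bias_field_amplitude = bias_field_amplitude,
               breathing_shift_mm = breathing_shift_mm,
               void_radius_mm = void_radius_mm,
               capsule_wall_mm = capsule_wall_mm,
               capsule_oil_radius_mm = capsule_oil_radius_mm,
               fiducial_offsets_mm = fiducial_offsets_mm,
               depot_eccentricity = depot_eccentricity,
               depot_lobularity = depot_lobularity,
               reposition_translation_mm = reposition_translation_mm,
               reposition_angle_deg = reposition_angle_deg,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Study-condition phantom presets
#'
#' Builds a [phantom_spec()] whose per-stage ground-truth apex thicknesses are
#' set from the per-site reference conditions. The `"absolute"` variant pins
#' the final stage to the site's reported post-injection mean thickness (with
#' intermediate stages scaled by the mean percent changes); the `"ratio"`
#' variant sets every stage to `baseline * (1 + pct/100)`.
#'
#' @param site injection site.
#' @param variant `"absolute"` or `"ratio"` (see Details).
#' @param seed integer seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
lvsc_study_spec <- function(site = c("thigh", "abdomen", "arm"),
                            variant = c("absolute", "ratio"), seed = 1L, ...) {
  site <- match.arg(site)
  variant <- match.arg(variant)
  ref <- lvsc_site_reference()[[site]]
  apex <- ref$baseline_mm * (1 + ref$pct_change / 100)
  if (variant == "absolute") apex[length(apex)] <- ref$final_mm
  phantom_spec(site = site, depot_volumes_mL = ref$volumes_mL,
               baseline_thickness_mm = ref$baseline_mm,
               stage_apex_thickness_mm = apex, seed = seed, ...)
}

#' Stages present in a phantom series
#' @param spec a [phantom_spec()].
#' @return Character vector of stage labels in acquisition order.
#' @export
phantom_stages <- function(spec) {
  c("naive", "insertion", paste0("v", spec$depot_volumes_mL), "post_removal")
}

# ---- derived deterministic parameters --------------------------------------

#' @noRd
.phantom_grid <- function(spec) {
  d1 <- round(spec$depth_extent_mm / spec$in_plane_res_mm)
  d2 <- round(spec$lateral_extent_mm / spec$in_plane_res_mm)
  d3 <- round(spec$stack_extent_mm / spec$slice_pitch_mm)
  sp <- c(spec$in_plane_res_mm, spec$in_plane_res_mm, spec$slice_pitch_mm)
  list(dim = c(d1, d2, d3), spacing = sp,
       x = (seq_len(d1) - 0.5) * sp[1],
       y = (seq_len(d2) - 0.5) * sp[2],
       z = (seq_len(d3) - 0.5) * sp[3],
       yc = d2 * sp[2] / 2, zc = d3 * sp[3] / 2)
}

# Smooth anatomical profiles (reference frame). `y`, `z` may be vectors or
# conformable arrays.
# Muscle interface: zero slope at the cannula position and receding (deeper)
# away from it, so the depot's closest approach to muscle is well-conditioned
# at the apex.
#' @noRd
.profile_sc_im <- function(spec, g, y, z) {
  spec$sc_im_base_mm +
    1.2 * (1 - cos(2 * pi * (y - g$yc) / 90)) +
    0.8 * (1 - cos(2 * pi * (z - g$zc) / 140))
}

#' @noRd
.profile_t0 <- function(spec, g, y, z) {
  spec$baseline_thickness_mm +
    0.8 * (cos(2 * pi * (y - g$yc) / 110) * cos(2 * pi * (z - g$zc) / 150) - 1)
}

#' @noRd
.stage_tag <- function(stage) match(stage, STAGE_LEVELS)

# All seeded/derived generator parameters: per-stage bump widths solved so SC
# expansion volume equals depot volume, depot shape and radial scale solved to
# the target voxel volume, fiducial layout, repositioning transforms, and the
# breathing schedule.
#' @noRd
.phantom_params <- function(spec) {
  g <- .phantom_grid(spec)
  stages <- phantom_stages(spec)
  n_inj <- length(spec$depot_volumes_mL)
  inj_stages <- paste0("v", spec$depot_volumes_mL)

  rng <- local({
    set.seed(spec$seed)
    list(lob_amp = stats::runif(3, c(0.5, 0.5, 0.3), 1) * spec$depot_lobularity *
           c(1, 1, 0.6),
         lob_phase = stats::runif(3, 0, 2 * pi),
         t_naive = stats::runif(3, -1, 1) * spec$reposition_translation_mm * c(1, 1, 0.4),
         a_naive = stats::runif(1, -1, 1) * spec$reposition_angle_deg,
         t_post = stats::runif(3, -1, 1) * spec$reposition_translation_mm * c(1, 1, 0.4),
         a_post = stats::runif(1, -1, 1) * spec$reposition_angle_deg)
  })

  # apex increment and bump width per stage
  dA <- g$spacing[2] * g$spacing[3]
  yy <- matrix(g$y, g$dim[2], g$dim[3])
  zz <- matrix(g$z, g$dim[2], g$dim[3], byrow = TRUE)
  r2 <- (yy - g$yc)^2 + (zz - g$zc)^2
  apex_inc <- spec$stage_apex_thickness_mm - spec$baseline_thickness_mm
  sigma <- numeric(n_inj)
  for (i in seq_len(n_inj)) {
    v_mm3 <- spec$depot_volumes_mL[i] * 1000
    a_i <- apex_inc[i]
    if (a_i <= 0) {
      if (v_mm3 > 0) stop("infeasible geometry: injected volume with no SC expansion")
      sigma[i] <- 1
      next
    }
    f <- function(s) a_i * sum(exp(-r2 / (2 * s^2))) * dA - v_mm3
    if (f(3000) < 0) {
      stop(sprintf(paste0("infeasible geometry: %.1f mL cannot be accommodated by a ",
                          "%.2f mm apex expansion within the field of view"),
                   spec$depot_volumes_mL[i], a_i))
    }
    sigma[i] <- stats::uniroot(f, c(1, 3000), tol = 1e-4)$root
  }

  # depot ellipsoid per injected stage
  top_margin <- 1.2; bottom_gap <- 1.2
  sc_im_apex <- .profile_sc_im(spec, g, g$yc, g$zc)
  depot <- vector("list", n_inj)
  names(depot) <- inj_stages
  for (i in seq_len(n_inj)) {
    v_mm3 <- spec$depot_volumes_mL[i] * 1000
    apex_t <- spec$stage_apex_thickness_mm[i]
    room <- apex_t - top_margin - bottom_gap
    if (room < 2) stop("infeasible geometry: SC layer too thin for the requested depot")
    c_s <- min(room / 2, (3 * v_mm3 / (4 * pi * spec$depot_eccentricity^2))^(1 / 3))
    ab <- 3 * v_mm3 / (4 * pi * c_s)
    a_s <- sqrt(ab)
    if (a_s * (1 + 2 * spec$depot_lobularity) > spec$lateral_extent_mm / 2 - 8 ||
        a_s * (1 + 2 * spec$depot_lobularity) > spec$stack_extent_mm / 2 - 8) {
      stop("infeasible geometry: depot footprint exceeds the field of view")
    }
    depot[[i]] <- list(center = c(sc_im_apex - bottom_gap - c_s, g$yc, g$zc),
                       semiaxes = c(c_s, a_s, a_s), scale = 1,
                       volume_mm3 = v_mm3)
  }

  # fiducial capsule (lateral, slice) positions
  fid_yz <- cbind(g$yc + spec$fiducial_offsets_mm[, 1],
                  g$zc + spec$fiducial_offsets_mm[, 2])

  tf_for <- function(t3, ang) {
    ctr <- c(spec$depth_extent_mm / 2, g$yc, g$zc)
    R <- rotation_about_axis("z", ang)
    rigid_transform(R, ctr - as.numeric(R %*% ctr) + t3)
  }
  transforms <- stats::setNames(rep(list(rigid_transform()), length(stages)), stages)
  transforms[["naive"]] <- tf_for(rng$t_naive, rng$a_naive)
  transforms[["post_removal"]] <- tf_for(rng$t_post, rng$a_post)

  # breathing schedule (depth, lateral) per slice
  bs <- spec$breathing_shift_mm
  if (is.null(bs) || (length(bs) == 1L && bs == 0)) {
    sched <- matrix(0, g$dim[3], 2L)
  } else if (length(bs) == 1L) {
    sched <- cbind(bs * rep_len(c(1, -1), g$dim[3]), 0)
  } else {
    sched <- as.matrix(bs)
    if (nrow(sched) != g$dim[3] || ncol(sched) != 2L) {
      stop("breathing_shift_mm matrix must be n_slices x 2")
    }
  }
  sched <- sweep(sched, 2L, colMeans(sched))  # zero net drift

  par <- list(grid = g, stages = stages, inj_stages = inj_stages,
              apex_inc = apex_inc, sigma = sigma, depot = depot,
              top_margin = top_margin, bottom_gap = bottom_gap,
              lob_amp = rng$lob_amp, lob_phase = rng$lob_phase,
              fid_yz = fid_yz, transforms = transforms, breathing = sched)

  # solve the depot radial scale against the voxel grid (identity frame)
  for (i in seq_len(n_inj)) {
    st <- inj_stages[i]
    target <- depot[[i]]$volume_mm3
    vox <- prod(g$spacing)
    count_for <- function(s) {
      par$depot[[i]]$scale <<- s
      sum(.depot_indicator_grid(spec, par, st)) * vox
    }
    lo <- 0.7; hi <- 1.35
    if (count_for(hi) < target) {
      stop("infeasible geometry: depot volume cannot fit between the tissue boundaries")
    }
    for (it in 1:36) {
      mid <- (lo + hi) / 2
      if (count_for(mid) < target) lo <- mid else hi <- mid
    }
    par$depot[[i]]$scale <- hi
    par$depot[[i]]$voxel_mm3 <- count_for(hi)
  }
  par
}

# Depot membership for stage `stage` evaluated at reference-frame coordinates.
#' @noRd
.depot_inside <- function(spec, par, stage, x, y, z) {
  dp <- par$depot[[stage]]
  if (is.null(dp)) return(rep_len(FALSE, length(x)))
  g <- par$grid
  u1 <- (x - dp$center[1]) / dp$semiaxes[1]
  u2 <- (y - dp$center[2]) / dp$semiaxes[2]
  u3 <- (z - dp$center[3]) / dp$semiaxes[3]
  rho <- sqrt(u1^2 + u2^2 + u3^2)
  rho[rho == 0] <- 1e-9
  th <- acos(pmin(pmax(u1 / rho, -1), 1))
  ph <- atan2(u3, u2)
  f <- 1 + par$lob_amp[1] * sin(th)^2 * sin(2 * ph + par$lob_phase[1]) +
    par$lob_amp[2] * sin(th)^2 * cos(3 * ph + par$lob_phase[2]) +
    par$lob_amp[3] * cos(2 * th + par$lob_phase[3])
  inside <- rho <= dp$scale * f
  if (!any(inside)) return(inside)
  # clip to the SC layer with small safety margins
  sc_im <- .profile_sc_im(spec, g, y, z)
  t0 <- .profile_t0(spec, g, y, z)
  bump <- .stage_bump(spec, par, stage, y, z)
  id_sc <- sc_im - t0 - bump
  inside & (x >= id_sc + 0.6) & (x <= sc_im - 0.8)
}

#' @noRd
.stage_bump <- function(spec, par, stage, y, z) {
  i <- match(stage, par$inj_stages)
  if (is.na(i)) {
    if (stage == "post_removal") i <- length(par$inj_stages) else return(0 * y)
  }
  g <- par$grid
  par$apex_inc[i] * exp(-((y - g$yc)^2 + (z - g$zc)^2) / (2 * par$sigma[i]^2))
}

# Depot indicator on the voxel grid (identity frame, voxel centers); used by
# the volume solver and for ground-truth masks.
#' @noRd
.depot_indicator_grid <- function(spec, par, stage) {
  dp <- par$depot[[stage]]
  g <- par$grid
  ax <- dp$semiaxes * dp$scale * (1 + 2 * spec$depot_lobularity)
  i_rng <- which(g$x >= dp$center[1] - ax[1] & g$x <= dp$center[1] + ax[1])
  j_rng <- which(g$y >= dp$center[2] - ax[2] & g$y <= dp$center[2] + ax[2])
  k_rng <- which(g$z >= dp$center[3] - ax[3] & g$z <= dp$center[3] + ax[3])
  out <- array(FALSE, g$dim)
  if (!length(i_rng) || !length(j_rng) || !length(k_rng)) return(out)
  nx <- length(i_rng); ny <- length(j_rng); nz <- length(k_rng)
  X <- array(g$x[i_rng], c(nx, ny, nz))
  Y <- array(rep(g$y[j_rng], each = nx), c(nx, ny, nz))
  Z <- array(rep(g$z[k_rng], each = nx * ny), c(nx, ny, nz))
  out[i_rng, j_rng, k_rng] <- .depot_inside(spec, par, stage, X, Y, Z)
  out
}

# Depot stage used for imaging at a given acquisition stage (post-removal
# retains the maximum-volume depot; the cannula stages before injection have
# none).
#' @noRd
.imaged_depot_stage <- function(par, stage) {
  if (stage %in% par$inj_stages) return(stage)
  if (stage == "post_removal") return(par$inj_stages[length(par$inj_stages)])
  NA_character_
}

# ---- stage generation ------------------------------------------------------

#' Generate one clean (artifact-free) phantom stage
#'
#' Returns the noiseless, artifact-free volume for one acquisition stage plus
#' its ground-truth slice. The `naive` and `post_removal` stages are rendered
#' in a slightly repositioned frame (rigid offset recorded in the truth).
#'
#' @param spec a [phantom_spec()].
#' @param stage one of the labels from [phantom_stages()].
#' @param params optional precomputed parameter set (internal reuse).
#' @return A list with elements `volume` (a [voxel_volume()]) and `truth`
#'   (the per-stage ground-truth list).
#' @export
generate_stage <- function(spec, stage, params = NULL) {
  stage <- match.arg(stage, phantom_stages(spec))
  par <- params %||% .phantom_params(spec)
  g <- par$grid
  lev <- spec$intensity_levels
  tf <- par$transforms[[stage]]
  inv <- rt_invert(tf)
  dstage <- .imaged_depot_stage(par, stage)
  bump_stage <- if (stage %in% c(par$inj_stages, "post_removal")) {
    if (stage == "post_removal") par$inj_stages[length(par$inj_stages)] else stage
  } else NA_character_

  # fiducial capsule centers in the reference frame (resting on the skin)
  caps <- .capsule_centers(spec, par, bump_stage)

  d <- g$dim
  X0 <- matrix(g$x, d[1], d[2])
  Y0 <- matrix(g$y, d[1], d[2], byrow = TRUE)
  # partial-volume model: average 5 sub-samples across the voxel depth extent
  # and 3 across the central 3 mm of each 4 mm slab
  sub_x <- c(-2, -1, 0, 1, 2) / 5 * g$spacing[1]
  sub_z <- c(-1, 0, 1) * spec$slice_thickness_mm / 3
  arr <- array(0, d)
  labels <- array(0L, d)
  for (k in seq_len(d[3])) {
    acc <- matrix(0, d[1], d[2])
    for (sz in sub_z) {
      zk <- g$z[k] + sz
      for (sx in sub_x) {
        # image -> reference coordinates
        Xs <- X0 + sx
        Xr <- inv$rotation[1, 1] * Xs + inv$rotation[1, 2] * Y0 +
          inv$rotation[1, 3] * zk + inv$translation_mm[1]
        Yr <- inv$rotation[2, 1] * Xs + inv$rotation[2, 2] * Y0 +
          inv$rotation[2, 3] * zk + inv$translation_mm[2]
        Zr <- inv$rotation[3, 1] * Xs + inv$rotation[3, 2] * Y0 +
          inv$rotation[3, 3] * zk + inv$translation_mm[3]
        lab <- .scene_labels(spec, par, bump_stage, dstage, caps, Xr, Yr, Zr)
        acc <- acc + lev[c("background", "dermis", "muscle", "sc_fat",
                           "depot", "oil")][lab + 1L]
        if (sz == 0 && sx == 0) labels[, , k] <- lab
      }
    }
    arr[, , k] <- acc / (length(sub_z) * length(sub_x))
  }

  vol <- voxel_volume(arr, g$spacing, origin_mm = c(0, 0, 0),
                      stage = stage, site = spec$site)
  yy <- matrix(g$y, d[2], d[3])
  zz <- matrix(g$z, d[2], d[3], byrow = TRUE)
  sc_im <- .profile_sc_im(spec, g, yy, zz)
  t0 <- .profile_t0(spec, g, yy, zz)
  bump <- if (is.na(bump_stage)) 0 * yy else .stage_bump(spec, par, bump_stage, yy, zz)
  apex_idx <- match(stage, par$inj_stages)
  apex_t <- if (stage %in% par$inj_stages) {
    spec$stage_apex_thickness_mm[apex_idx]
  } else if (stage == "post_removal") {
    spec$stage_apex_thickness_mm[length(spec$stage_apex_thickness_mm)]
  } else spec$baseline_thickness_mm

  truth <- list(stage = stage,
                labels = labels,
                depot_mask = labels == 4L,
                true_depot_volume_mL = if (is.na(dstage)) 0 else
                  par$depot[[dstage]]$voxel_mm3 / 1000,
                target_depot_volume_mL = if (is.na(dstage)) 0 else
                  par$depot[[dstage]]$volume_mm3 / 1000,
                id_sc_depth = sc_im - t0 - bump,
                sc_im_depth = sc_im,
                thickness_map = t0 + bump,
                apex_thickness_mm = apex_t,
                dermis_thickness_mm = spec$dermis_thickness_mm,
                transform = par$transforms[[stage]],
                fiducials = .capsule_truth(spec, par, caps, tf),
                void_mask = NULL,
                applied_slice_shifts = matrix(0, d[3], 2L))
  list(volume = vol, truth = truth)
}

# Capsule centers (reference frame): resting on the stage's skin surface.
#' @noRd
.capsule_centers <- function(spec, par, bump_stage) {
  g <- par$grid
  yz <- par$fid_yz
  sc_im <- .profile_sc_im(spec, g, yz[, 1], yz[, 2])
  t0 <- .profile_t0(spec, g, yz[, 1], yz[, 2])
  bump <- if (is.na(bump_stage)) 0 else .stage_bump(spec, par, bump_stage, yz[, 1], yz[, 2])
  skin <- sc_im - t0 - bump - spec$dermis_thickness_mm
  r_out <- spec$capsule_oil_radius_mm + spec$capsule_wall_mm
  cbind(skin - r_out, yz[, 1], yz[, 2])
}

#' @noRd
.capsule_truth <- function(spec, par, caps, tf) {
  img <- rt_apply(tf, caps)
  lapply(seq_len(nrow(caps)), function(i) {
    list(oil_centroid_mm = as.numeric(img[i, ]),
         oil_lower_depth_mm = img[i, 1] + spec$capsule_oil_radius_mm,
         approx_radius_mm = spec$capsule_oil_radius_mm)
  })
}

# Label code at reference-frame coordinates:
# 0 bg, 1 dermis, 2 muscle, 3 sc fat, 4 depot, 5 oil.
#' @noRd
.scene_labels <- function(spec, par, bump_stage, dstage, caps, Xr, Yr, Zr) {
  g <- par$grid
  sc_im <- .profile_sc_im(spec, g, Yr, Zr)
  t0 <- .profile_t0(spec, g, Yr, Zr)
  bump <- if (is.na(bump_stage)) 0 else .stage_bump(spec, par, bump_stage, Yr, Zr)
  id_sc <- sc_im - t0 - bump
  skin <- id_sc - spec$dermis_thickness_mm
  lab <- matrix(0L, nrow(Xr), ncol(Xr))
  lab[Xr >= skin & Xr < id_sc] <- 1L
  lab[Xr >= id_sc & Xr < sc_im] <- 3L
  lab[Xr >= sc_im] <- 2L
  if (!is.na(dstage)) {
    inside <- .depot_inside(spec, par, dstage, Xr, Yr, Zr)
    lab[inside] <- 4L
  }
  r_oil2 <- spec$capsule_oil_radius_mm^2
  for (i in seq_len(nrow(caps))) {
    d2 <- (Xr - caps[i, 1])^2 + (Yr - caps[i, 2])^2 + (Zr - caps[i, 3])^2
    lab[d2 <= r_oil2] <- 5L
  }
  lab
}

# ---- artifacts -------------------------------------------------------------

#' Apply imaging artifacts to a clean phantom stage
#'
#' Applies, in order: the per-slice breathing stair-step (bilinear in-plane
#' resampling), the metal-cannula signal void (only while the cannula is in
#' situ, i.e. not for `naive`/`post_removal`), the multiplicative low-order
#' attenuation field, and additive noise. Applied shifts and the void mask are
#' recorded in the returned truth.
#'
#' @param volume clean stage volume from [generate_stage()].
#' @param spec the [phantom_spec()].
#' @param stage stage label.
#' @param truth per-stage truth list from [generate_stage()] (updated and
#'   returned).
#' @param params optional precomputed parameter set.
#' @return List with elements `volume` and `truth`.
#' @export
apply_artifacts <- function(volume, spec, stage, truth = NULL, params = NULL) {
  stage <- match.arg(stage, phantom_stages(spec))
  par <- params %||% .phantom_params(spec)
  g <- par$grid
  lev <- spec$intensity_levels
  arr <- volume$intensities
  d <- dim(arr)
  sched <- par$breathing
  shifts_applied <- matrix(0, d[3], 2L)

  if (any(sched != 0)) {
    for (k in seq_len(d[3])) {
      s <- sched[k, ]
      if (all(s == 0)) next
      arr[, , k] <- .shift_slice(arr[, , k], s / g$spacing[1:2], lev[["background"]])
      shifts_applied[k, ] <- s
      if (!is.null(truth) && any(truth$depot_mask[, , k])) {
        truth$depot_mask[, , k] <- .shift_slice_nn(truth$depot_mask[, , k],
                                                   round(s / g$spacing[1:2]))
      }
    }
  }

  void_mask <- array(FALSE, d)
  cann_in_situ <- stage %in% c("insertion", par$inj_stages)
  if (cann_in_situ && spec$void_radius_mm > 0) {
    sc_im_apex <- .profile_sc_im(spec, g, g$yc, g$zc)
    t0_apex <- spec$baseline_thickness_mm
    bump_stage <- if (stage %in% par$inj_stages) stage else NA_character_
    apex_t <- if (is.na(bump_stage)) t0_apex else
      spec$stage_apex_thickness_mm[match(bump_stage, par$inj_stages)]
    id_sc_apex <- sc_im_apex - apex_t
    skin_apex <- id_sc_apex - spec$dermis_thickness_mm
    x_lo <- skin_apex - 2
    x_hi <- min(id_sc_apex + 9, sc_im_apex - 1.5)
    for (k in seq_len(d[3])) {
      dz <- g$z[k] - g$zc
      if (abs(dz) > spec$void_radius_mm) next
      ry <- sqrt(spec$void_radius_mm^2 - dz^2)
      yc_k <- g$yc + shifts_applied[k, 2]
      jj <- which(abs(g$y - yc_k) <= ry)
      ii <- which(g$x >= x_lo + shifts_applied[k, 1] &
                  g$x <= x_hi + shifts_applied[k, 1])
      if (length(jj) && length(ii)) {
        arr[ii, jj, k] <- lev[["background"]]
        void_mask[ii, jj, k] <- TRUE
      }
    }
  }

  if (spec$bias_field_amplitude > 0) {
    ux <- (g$x - spec$depth_extent_mm / 2) / (spec$depth_extent_mm / 2)
    uy <- (g$y - g$yc) / (spec$lateral_extent_mm / 2)
    B <- 1 + spec$bias_field_amplitude * outer(0 * ux, uy, "+") +
      0.3 * spec$bias_field_amplitude * outer(ux, uy)
    arr <- arr * as.numeric(B)  # field is slice-independent; recycles over k
  }

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed + 7919L * .stage_tag(stage))
    if (spec$noise_model == "rician") {
      n1 <- array(stats::rnorm(length(arr), 0, spec$noise_sigma), d)
      n2 <- array(stats::rnorm(length(arr), 0, spec$noise_sigma), d)
      arr <- sqrt((arr + n1)^2 + n2^2)
    } else {
      arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sigma), d)
    }
    arr[arr < 0] <- 0
  }

  out <- voxel_volume(arr, volume$spacing_mm, volume$origin_mm,
                      stage = stage, site = spec$site)
  if (!is.null(truth)) {
    truth$void_mask <- void_mask
    truth$applied_slice_shifts <- shifts_applied
  }
  list(volume = out, truth = truth)
}

# Bilinear in-plane shift of one slice by (di, dj) voxels; image content moves
# by +shift, vacated edges take the fill value.
#' @noRd
.shift_slice <- function(m, shift_vox, fill) {
  d <- dim(m)
  i0 <- seq_len(d[1]) - shift_vox[1]
  j0 <- seq_len(d[2]) - shift_vox[2]
  il <- floor(i0); jl <- floor(j0)
  fi <- i0 - il; fj <- j0 - jl
  gi <- function(ii) pmin(pmax(ii, 1L), d[1])
  gj <- function(jj) pmin(pmax(jj, 1L), d[2])
  w <- m[gi(il), gj(jl)] * outer(1 - fi, 1 - fj) +
    m[gi(il + 1L), gj(jl)] * outer(fi, 1 - fj) +
    m[gi(il), gj(jl + 1L)] * outer(1 - fi, fj) +
    m[gi(il + 1L), gj(jl + 1L)] * outer(fi, fj)
  bad_i <- i0 < 1 | i0 > d[1]
  bad_j <- j0 < 1 | j0 > d[2]
  w[bad_i, ] <- fill
  w[, bad_j] <- fill
  w
}

#' @noRd
.shift_slice_nn <- function(m, shift_vox) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  i0 <- seq_len(d[1]) - shift_vox[1]
  j0 <- seq_len(d[2]) - shift_vox[2]
  oki <- i0 >= 1 & i0 <= d[1]; okj <- j0 >= 1 & j0 <= d[2]
  out[oki, okj] <- m[i0[oki], j0[okj]]
  out
}

# ---- series ----------------------------------------------------------------

#' Generate a complete phantom injection series with ground truth
#'
#' Produces one artifact-bearing volume per acquisition stage (`naive`,
#' `insertion`, one stage per cumulative volume, `post_removal`) together with
#' the complete ground truth: depot and void masks, boundary height fields,
#' per-stage thickness maps, fiducial positions, applied slice shifts and the
#' rigid repositioning transforms.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `series` (a [scan_series()]) and `truth`
#'   (a `phantom_truth` object).
#' @export
generate_series <- function(spec) {
  par <- .phantom_params(spec)
  g <- par$grid
  stages <- par$stages
  vols <- list(); truths <- list()
  for (st in stages) {
    gs <- generate_stage(spec, st, params = par)
    aa <- apply_artifacts(gs$volume, spec, st, truth = gs$truth, params = par)
    gs$truth$labels <- NULL  # bulky; masks and surfaces carry the truth
    aa$truth$labels <- NULL
    vols[[st]] <- aa$volume
    truths[[st]] <- aa$truth
  }
  truth <- structure(list(site = spec$site, seed = spec$seed,
                          spacing_mm = g$spacing,
                          y_mm = g$y, z_mm = g$z,
                          cannula_yz_mm = c(g$yc, g$zc),
                          dermis_thickness_mm = spec$dermis_thickness_mm,
                          capsule_wall_mm = spec$capsule_wall_mm,
                          baseline_thickness_mm = spec$baseline_thickness_mm,
                          stage_apex_thickness_mm = spec$stage_apex_thickness_mm,
                          stages = truths),
                     class = "phantom_truth")
  tfs <- lapply(truths, function(t) t$transform)
  fids <- lapply(truths, function(t) t$fiducials)
  list(series = scan_series(vols, spec$site, transforms = tfs, fiducials = fids),
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth %s: %d stages, baseline %.1f mm>\n",
              x$site, length(x$stages), x$baseline_thickness_mm))
  invisible(x)
}
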