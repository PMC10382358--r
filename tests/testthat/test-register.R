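# Artifact corrections and rigid series alignment.

test_that("dermal thickness is the fiducial gap minus the capsule wall", {
  id_sc <- flat_surface("ID_SC", 12)
  fid <- make_fiducials(rbind(c(5, 10, 10), c(5, 30, 30)), lower = c(10, 10))
  expect_equal(estimate_dermal_thickness(fid, id_sc, capsule_wall_mm = 0.5), 1.5)
  # wall equal to the gap clamps to zero with a warning
  fid2 <- make_fiducials(rbind(c(5, 10, 10), c(5, 30, 30)), lower = c(11.5, 11.5))
  expect_warning(d0 <- estimate_dermal_thickness(fid2, id_sc, 0.6), "clamp")
  expect_equal(d0, 0)
  # capsule far from any valid column errors
  fid3 <- make_fiducials(rbind(c(5, 200, 200)), lower = 10)
  expect_error(estimate_dermal_thickness(fid3, id_sc, 0.5), "no fiducial")
})

test_that("dermal estimate recovers the phantom truth within 0.5 mm", {
  res <- small_processed()
  spec <- small_spec()
  for (st in c("naive", "insertion", "v5")) {
    expect_lt(abs(res$stages[[st]]$dermal_mm - spec$dermis_thickness_mm), 0.5)
  }
})

test_that("backfill with an empty void is the identity", {
  res <- small_processed()
  seg <- res$stages$v5$seg
  out <- backfill_void(seg, array(FALSE, dim(seg$mask)),
                       res$stages$post_removal$seg)
  expect_identical(out$mask, seg$mask)
  expect_identical(out$void_filled_voxels, seg$void_filled_voxels)
})

test_that("backfill never modifies voxels outside the void mask", {
  res <- small_processed()
  seg <- res$stages$v5$seg
  void <- res$stages$v5$void
  out <- backfill_void(seg, void, res$stages$post_removal$seg,
                       transform = rigid_transform())
  expect_identical(out$mask[!void], seg$mask[!void])
  expect_true(out$backfilled)
})

test_that("backfill strictly improves the Dice against the truth", {
  gen <- small_series()
  res <- small_processed()
  p <- res$stages$v5
  tru <- crop_truth_to_roi(gen$truth$stages$v5$depot_mask, p$roi,
                           gen$series$volumes$v5)
  # re-segment without backfill for the pre-correction mask
  band <- sc_band_mask(p$roi, p$id_sc, p$sc_im)
  raw <- segment_depot(p$roi, p$seg$threshold_used, p$axis, sc_band = band)
  tf <- rt_compose(rt_invert(res$transforms$v5), res$transforms$post_removal)
  bf <- backfill_void(raw, p$void, res$stages$post_removal$seg, transform = tf)
  expect_gt(bf$void_filled_voxels, 0)
  expect_gt(dice_coefficient(bf$mask, tru), dice_coefficient(raw$mask, tru))
})

test_that("bias correction leaves a flat image unchanged", {
  set.seed(5)
  arr <- array(100, c(12, 12, 6))
  v <- voxel_volume(arr, c(1, 1, 4))
  out <- bias_correct(v, order = 2, mask = array(TRUE, dim(arr)))
  expect_lt(max(abs(out$intensities - arr) / arr), 1e-6)
  # constant image short-circuits with a message
  expect_message(bias_correct(v, order = 1), "constant|unchanged")
})

test_that("bias correction halves the SC-fat coefficient of variation", {
  spec <- small_spec(bias_field_amplitude = 0.2, noise_sigma = 2)
  par <- .phantom_params(spec)
  gs <- generate_stage(spec, "naive", params = par)
  aa <- apply_artifacts(gs$volume, spec, "naive", truth = gs$truth, params = par)
  # interior fat only: interface voxels are partial-volume mixtures whose
  # spread is not attenuation
  fat <- gs$truth$labels == 3L
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1), c(0, 0, -1))) {
    d <- dim(fat)
    shifted <- gs$truth$labels[pmin(pmax(seq_len(d[1]) + sh[1], 1), d[1]),
                               pmin(pmax(seq_len(d[2]) + sh[2], 1), d[2]),
                               pmin(pmax(seq_len(d[3]) + sh[3], 1), d[3])] == 3L
    fat <- fat & shifted
  }
  cov_pre <- sd(aa$volume$intensities[fat]) / mean(aa$volume$intensities[fat])
  corr <- bias_correct(aa$volume, order = 2)
  cov_post <- sd(corr$intensities[fat]) / mean(corr$intensities[fat])
  expect_gt(cov_pre / cov_post, 2)
})

test_that("two blobs across bright/dark halves equalise after correction", {
  set.seed(9)
  arr <- array(0, c(20, 60, 8))
  arr[6:15, 8:20, 3:6] <- 100
  arr[6:15, 40:52, 3:6] <- 100
  bias <- 1 + 0.25 * (rep(seq_len(60), each = 20) - 30.5) / 30
  for (k in 1:8) arr[, , k] <- arr[, , k] * matrix(bias, 20, 60)
  v <- voxel_volume(arr, c(1, 1, 4))
  blobs <- array(FALSE, dim(arr))
  blobs[6:15, 8:20, 3:6] <- TRUE; blobs[6:15, 40:52, 3:6] <- TRUE
  out <- bias_correct(v, order = 1, mask = blobs)
  m1 <- mean(out$intensities[6:15, 8:20, 3:6])
  m2 <- mean(out$intensities[6:15, 40:52, 3:6])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("realignment is a near no-op on an artifact-free phantom", {
  res <- small_processed()
  p <- res$stages$naive
  ra <- realign_slices(p$id_sc, p$sc_im)
  expect_lt(max(abs(ra$shift_mm)), 0.5 * small_spec()$in_plane_res_mm)
})

test_that("alternating stair-step shifts are recovered and corrected", {
  spec <- small_spec(breathing_shift_mm = 2, noise_sigma = 2)
  par <- .phantom_params(spec)
  gs <- generate_stage(spec, "naive", params = par)
  aa <- apply_artifacts(gs$volume, spec, "naive", truth = gs$truth, params = par)
  bd <- extract_boundaries(aa$volume)
  ra <- realign_slices(bd$id_sc, bd$sc_im, volume = aa$volume)
  applied <- aa$truth$applied_slice_shifts
  err <- ra$shift_mm + applied  # correction should negate the schedule
  expect_lt(sqrt(mean(err^2)), 0.5)
  # idempotence: a second pass finds (almost) nothing left
  ra2 <- realign_slices(ra$id_sc, ra$sc_im)
  expect_lt(max(abs(ra2$shift_mm)), 0.25)
  # post-correction thickness error strictly below pre-correction
  tru <- crop_field_to_surface(
    gs$truth$sc_im_depth, bd$sc_im, list(y_mm = .phantom_grid(spec)$y,
                                         z_mm = .phantom_grid(spec)$z)) -
    crop_field_to_surface(gs$truth$id_sc_depth, bd$id_sc,
                          list(y_mm = .phantom_grid(spec)$y,
                               z_mm = .phantom_grid(spec)$z))
  rmse <- function(b) sqrt(mean(((b$sc_im$depth_mm - b$id_sc$depth_mm) - tru)^2))
  expect_lt(rmse(ra), rmse(bd))
})

test_that("self-alignment is the identity with near-zero residual", {
  res <- small_processed()
  fid <- res$stages$naive$fiducials
  tf <- align_series(fid, fid, res$stages$naive$sc_im, res$stages$naive$sc_im)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-6)
  expect_lt(max(abs(tf$translation_mm)), 1e-6)
  expect_lt(tf$rms_residual_mm, 0.3)
})

test_that("known rigid offsets between stages are recovered", {
  # pure translation on synthetic fiducial sets
  set.seed(11)
  P <- cbind(runif(4, 5, 10), c(10, 50, 10, 50), c(10, 10, 40, 40))
  shift <- c(1.5, -2.0, 0.8)
  Q <- sweep(P, 2, shift, "+")
  tf <- align_series(make_fiducials(P), make_fiducials(Q))
  expect_lt(max(abs(tf$translation_mm - shift)), 1e-9)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  # pure rotation about the slice axis
  ang <- 5
  R <- rotation_about_axis("z", ang)
  ctr <- colMeans(P)
  Q2 <- sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, "+")
  tf2 <- align_series(make_fiducials(P), make_fiducials(Q2))
  got <- atan2(tf2$rotation[2, 1], tf2$rotation[1, 1]) * 180 / pi
  expect_lt(abs(got - ang), 0.5)
})

test_that("phantom repositioning transforms are recovered within 0.3 mm", {
  gen <- small_series()
  res <- small_processed()
  # post_removal is the reference; naive's truth transform maps anatomy ->
  # naive image, so naive -> post_removal = T_post o T_naive^-1
  tru <- rt_compose(gen$truth$stages$post_removal$transform,
                    rt_invert(gen$truth$stages$naive$transform))
  got <- res$transforms$naive
  expect_lt(max(abs(got$translation_mm - tru$translation_mm)), 0.3)
  expect_lt(max(abs(got$rotation - tru$rotation)), 0.01)
})

test_that("transform composition with its inverse is the identity", {
  tf <- rigid_transform(rotation_about_axis("z", 17), c(3, -2, 1))
  comp <- rt_compose(tf, rt_invert(tf))
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_lt(max(abs(comp$translation_mm)), 1e-12)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(rt_apply(rt_invert(tf), rt_apply(tf, p)), p, tolerance = 1e-12)
})

test_that("ICP residual decreases monotonically over iterations", {
  res <- small_processed()
  tf <- align_series(res$stages$naive$fiducials,
                     res$stages$post_removal$fiducials,
                     res$stages$naive$id_sc, res$stages$post_removal$id_sc,
                     method = "icp", icp_iterations = 6)
  h <- attr(tf, "rms_history")
  expect_gt(length(h), 3)
  expect_true(all(diff(h[-1]) <= 1e-6))
})
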