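# Phantom generator: geometry, ground truth, artifacts, determinism.

test_that("naive stage has the expected tissue classes and no depot", {
  spec <- small_spec(noise_sigma = 0, bias_field_amplitude = 0)
  gs <- generate_stage(spec, "naive")
  expect_false(any(gs$truth$depot_mask))
  expect_identical(sort(unique(as.integer(gs$truth$labels))),
                   c(0L, 1L, 2L, 3L, 5L))  # bg, dermis, muscle, fat, oil
  lev <- spec$intensity_levels
  # pure-region voxels carry exactly the configured levels
  arr <- gs$volume$intensities
  expect_true(any(arr == lev[["sc_fat"]]))
  expect_true(any(arr == lev[["muscle"]]))
  expect_true(any(arr == lev[["oil"]]))
  expect_false(any(arr == lev[["depot"]] & gs$truth$labels == 4L))
})

test_that("depot mask voxel volume matches the target injection volume", {
  gen <- small_series()
  vox <- prod(gen$truth$spacing_mm)
  for (st in c("v2", "v5")) {
    target <- gen$truth$stages[[st]]$target_depot_volume_mL * 1000
    got <- sum(gen$truth$stages[[st]]$depot_mask) * vox
    expect_lt(abs(got - target), 2 * vox)
  }
})

test_that("identical spec and seed give bit-identical output", {
  spec <- small_spec()
  a <- generate_stage(spec, "v2")
  b <- generate_stage(spec, "v2")
  expect_identical(a$volume$intensities, b$volume$intensities)
  s1 <- generate_series(spec)
  s2 <- generate_series(spec)
  expect_identical(s1$series$volumes$v5$intensities,
                   s2$series$volumes$v5$intensities)
  expect_identical(s1$truth$stages$v5$depot_mask, s2$truth$stages$v5$depot_mask)
})

test_that("SC-layer volume increase matches the injected volume (conservation)", {
  gen <- small_series()
  tr <- gen$truth
  dA <- tr$spacing_mm[2] * tr$spacing_mm[3]
  base <- tr$stages$naive$thickness_map
  for (st in c("v2", "v5")) {
    v_inj <- tr$stages[[st]]$target_depot_volume_mL * 1000
    dV <- sum(tr$stages[[st]]$thickness_map - base) * dA
    expect_lt(abs(dV - v_inj) / v_inj, 0.10)
  }
})

test_that("true thickness at the apex is non-decreasing across stages", {
  gen <- small_series()
  apex <- vapply(gen$truth$stages, function(s) s$apex_thickness_mm, numeric(1))
  ord <- c("naive", "insertion", "v2", "v5", "post_removal")
  expect_true(all(diff(apex[ord]) >= 0))
  # and the thickness maps agree at the cannula position (the nearest grid
  # column sits within half a voxel of the true apex)
  jc <- which.min(abs(gen$truth$y_mm - gen$truth$cannula_yz_mm[1]))
  kc <- which.min(abs(gen$truth$z_mm - gen$truth$cannula_yz_mm[2]))
  for (st in names(gen$truth$stages)) {
    expect_equal(gen$truth$stages[[st]]$thickness_map[jc, kc],
                 gen$truth$stages[[st]]$apex_thickness_mm, tolerance = 0.005)
  }
})

test_that("site protocols produce the documented stage sequences", {
  arm <- phantom_spec("arm", seed = 3L)
  expect_identical(phantom_stages(arm),
                   c("naive", "insertion", "v2", "v5", "post_removal"))
  abd <- phantom_spec("abdomen", seed = 3L)
  expect_identical(phantom_stages(abd),
                   c("naive", "insertion", "v2", "v5", "v10", "post_removal"))
})

test_that("impossible depot geometry raises an infeasible-geometry error", {
  expect_error(
    .phantom_params(phantom_spec("thigh", depot_volumes_mL = 10,
                                 baseline_thickness_mm = 4,
                                 stage_pct = 1,
                                 lateral_extent_mm = 60,
                                 stack_extent_mm = 48,
                                 depth_extent_mm = 40,
                                 sc_im_base_mm = 20, seed = 1L)),
    "infeasible|accommodat")
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec("thigh", intensity_levels = c(
    background = 10, dermis = 10, muscle = 60, sc_fat = 110,
    depot = 100, oil = 235)), "depot intensity")
  expect_error(phantom_spec("thigh", slice_pitch_mm = 2, slice_thickness_mm = 3),
               "pitch")
  expect_error(phantom_spec("thigh", depot_volumes_mL = c(5, 2)), "increasing")
})

test_that("artifact-free spec passes volumes through unchanged", {
  spec <- small_spec(noise_sigma = 0, bias_field_amplitude = 0,
                     void_radius_mm = 0)
  gs <- generate_stage(spec, "v2")
  aa <- apply_artifacts(gs$volume, spec, "v2", truth = gs$truth)
  expect_identical(aa$volume$intensities, gs$volume$intensities)
  expect_false(any(aa$truth$void_mask))
})

test_that("void voxel count approximates the analytic cylinder volume", {
  spec <- small_spec(noise_sigma = 0, bias_field_amplitude = 0)
  par <- .phantom_params(spec)
  gs <- generate_stage(spec, "v2", params = par)
  aa <- apply_artifacts(gs$volume, spec, "v2", truth = gs$truth, params = par)
  vm <- aa$truth$void_mask
  expect_gt(sum(vm), 0)
  # cylinder height from the applied depth window
  idx <- which(vm, arr.ind = TRUE)
  h <- (diff(range(idx[, 1])) + 1) * spec$in_plane_res_mm
  analytic <- pi * spec$void_radius_mm^2 * h
  got <- sum(vm) * prod(gs$volume$spacing_mm)
  # the 4 mm slice pitch is coarse against the 3 mm radius: compare to the
  # cylinder volume discretised at the slice centers (chord widths), and only
  # loosely to the continuous volume
  g <- .phantom_grid(spec)
  dz <- g$z - g$zc
  chord <- 2 * sqrt(pmax(spec$void_radius_mm^2 - dz^2, 0))
  disc <- sum(chord) * spec$slice_pitch_mm * h
  expect_lt(abs(got - disc) / disc, 0.10)
  expect_lt(abs(got - analytic) / analytic, 0.45)
  # all altered voxels include the void mask
  expect_true(all(aa$volume$intensities[vm] == spec$intensity_levels[["background"]]))
})

test_that("no void is applied after cannula removal", {
  spec <- small_spec()
  par <- .phantom_params(spec)
  for (st in c("naive", "post_removal")) {
    gs <- generate_stage(spec, st, params = par)
    aa <- apply_artifacts(gs$volume, spec, st, truth = gs$truth, params = par)
    expect_false(any(aa$truth$void_mask), info = st)
  }
  gs <- generate_stage(spec, "insertion", params = par)
  aa <- apply_artifacts(gs$volume, spec, "insertion", truth = gs$truth, params = par)
  expect_true(any(aa$truth$void_mask))
})

test_that("naive truth thickness equals the baseline profile", {
  gen <- small_series()
  tr <- gen$truth
  spec <- small_spec()
  g <- .phantom_grid(spec)
  yy <- matrix(g$y, g$dim[2], g$dim[3])
  zz <- matrix(g$z, g$dim[2], g$dim[3], byrow = TRUE)
  expect_equal(tr$stages$naive$thickness_map, .profile_t0(spec, g, yy, zz),
               tolerance = 1e-10)
})
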