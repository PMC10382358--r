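# Threshold selection, fiducial detection, ROI, depot segmentation and
# boundary extraction.

test_that("otsu matches the exhaustive within-class-variance oracle", {
  set.seed(101)
  for (case in 1:25) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    x <- c(round(rnorm(n1, sample(40:90, 1), sample(3:15, 1))),
           round(rnorm(n2, sample(120:220, 1), sample(3:20, 1))))
    tab <- table(x)
    values <- as.numeric(names(tab)); counts <- as.numeric(tab)
    expect_equal(otsu_threshold(values, counts), otsu_oracle(values, counts))
  }
})

test_that("otsu separates a balanced two-Gaussian histogram near the midpoint", {
  set.seed(7)
  x <- round(c(rnorm(20000, 100, 10), rnorm(20000, 200, 10)))
  tab <- table(x)
  thr <- otsu_threshold(as.numeric(names(tab)), as.numeric(tab))
  expect_gt(thr, 130)
  expect_lt(thr, 170)
})

test_that("select_threshold honours method contracts", {
  v <- voxel_volume(array(100, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(select_threshold(v, "fixed", fixed_value = 150), 150)
  expect_error(select_threshold(v, "valley"), "unimodal|degenerate")
  set.seed(1)
  v2 <- voxel_volume(array(c(rnorm(500, 100, 8), rnorm(500, 200, 8)),
                           c(10, 10, 10)), c(1, 1, 1))
  thr <- select_threshold(v2, "valley")
  expect_gt(thr, 120); expect_lt(thr, 180)
})

test_that("fiducial capsules are detected at their true positions", {
  gen <- small_series()
  vol <- gen$series$volumes$naive
  fid <- detect_fiducials(vol)
  expect_length(fid$capsules, 4L)
  got <- fiducial_centroids(fid)
  tru <- do.call(rbind, lapply(gen$truth$stages$naive$fiducials,
                               function(x) x$oil_centroid_mm))
  got <- got[order(got[, 2], got[, 3]), ]
  tru <- tru[order(tru[, 2], tru[, 3]), ]
  err <- abs(got - tru)
  expect_lt(max(err[, 1]), vol$spacing_mm[1])
  expect_lt(max(err[, 2]), vol$spacing_mm[2])
  expect_lt(max(err[, 3]), vol$spacing_mm[3])
  # oil lower surface consistent with the truth within half a voxel
  low_got <- sort(vapply(fid$capsules, function(c3) c3$oil_lower_depth_mm, 1))
  low_tru <- sort(vapply(gen$truth$stages$naive$fiducials,
                         function(x) x$oil_lower_depth_mm, 1))
  expect_lt(max(abs(low_got - low_tru)), 0.5)
})

test_that("a volume without capsules raises an error", {
  set.seed(2)
  arr <- array(rnorm(20 * 20 * 6, 60, 4), c(20, 20, 6))
  arr[1:6, , ] <- abs(rnorm(6 * 20 * 6, 10, 2))
  arr[14:20, , ] <- rnorm(7 * 20 * 6, 110, 4)
  v <- voxel_volume(pmax(arr, 0), c(1, 1, 4))
  expect_error(detect_fiducials(v), "no fiducial")
})

test_that("ROI extraction clamps, centers and validates", {
  gen <- small_series()
  vol <- gen$series$volumes$naive
  fid <- detect_fiducials(vol)
  # half-extent beyond the volume: ROI is the full volume (with a clip warning
  # suppressed since the request exceeds the FOV)
  roi_full <- extract_roi(vol, fid, half_extent_mm = 1000)
  expect_identical(dim(roi_full$intensities), dim(vol$intensities))
  roi <- extract_roi(vol, fid, half_extent_mm = 20)
  cen_f <- colMeans(fiducial_centroids(fid))
  co <- .axis_coords(roi)
  roi_cen <- c(mean(range(co[[2]])), mean(range(co[[3]])))
  expect_lt(abs(roi_cen[1] - cen_f[2]), vol$spacing_mm[2])
  expect_lt(abs(roi_cen[2] - cen_f[3]), vol$spacing_mm[3])
  out_fid <- make_fiducials(rbind(c(5, -40, 10), c(5, -42, 30), c(5, -44, 50)))
  expect_error(extract_roi(vol, out_fid, 20), "outside")
})

test_that("depot segmentation recovers the truth mask (Dice >= 0.90)", {
  gen <- small_series()
  res <- small_processed()
  for (st in c("v2", "v5")) {
    seg <- res$stages[[st]]$seg
    tru <- crop_truth_to_roi(gen$truth$stages[[st]]$depot_mask,
                             res$stages[[st]]$roi, gen$series$volumes[[st]])
    expect_gte(dice_coefficient(seg$mask, tru), 0.90)
  }
})

test_that("naive stage yields an empty mask as a negative control", {
  gen <- small_series()
  res <- small_processed()
  vol <- res$stages$naive$roi
  band <- sc_band_mask(vol, res$stages$naive$id_sc, res$stages$naive$sc_im)
  expect_warning(
    seg <- segment_depot(vol, 170, res$stages$naive$axis, sc_band = band),
    "empty depot")
  expect_false(any(seg$mask))
  expect_equal(depot_volume(seg), 0)
})

test_that("only the component touching the cannula axis is kept", {
  # bright blobs embedded in a fat-like background (a blob floating in air
  # would be rejected as capsule-like by the above-skin heuristic)
  arr <- array(100, c(20, 40, 6))
  arr[8:12, 5:10, 2:4] <- 200    # far blob
  arr[8:12, 25:32, 2:4] <- 200   # blob at the axis
  v <- voxel_volume(arr, c(1, 1, 4))
  seg <- segment_depot(v, 150, cannula_axis_yz = c(28, 12),
                       cylinder_radius_mm = 5)
  idx <- which(seg$mask, arr.ind = TRUE)
  expect_true(all(idx[, 2] >= 25))
  expect_equal(sum(seg$mask), 5L * 8L * 3L)
})

test_that("depot mask stays strictly below the skin (above-skin exclusion)", {
  res <- small_processed()
  for (st in c("v2", "v5")) {
    seg <- res$stages[[st]]$seg
    idsc <- res$stages[[st]]$id_sc
    idx <- which(seg$mask, arr.ind = TRUE)
    co <- .axis_coords(res$stages[[st]]$roi)
    depths <- co[[1]][idx[, 1]]
    floor_d <- idsc$depth_mm[cbind(idx[, 2], idx[, 3])]
    expect_true(all(depths > floor_d - res$stages[[st]]$roi$spacing_mm[1]))
  }
})

test_that("flat synthetic layers give flat boundary fields at the right gap", {
  arr <- array(10, c(50, 30, 8))
  arr[21:40, , ] <- 110   # SC fat: depth 20-40 mm
  arr[41:50, , ] <- 60    # muscle below 40 mm
  set.seed(3)
  arr <- pmax(arr + rnorm(length(arr), 0, 2), 0)
  v <- voxel_volume(arr, c(1, 1, 4))
  bd <- extract_boundaries(v, min_gap_mm = 3)
  expect_true(all(bd$id_sc$valid))
  expect_lt(max(abs(bd$id_sc$depth_mm - 20)), 1)
  expect_lt(max(abs(bd$sc_im$depth_mm - 40)), 1)
  gap <- bd$sc_im$depth_mm - bd$id_sc$depth_mm
  expect_lt(max(abs(gap - 20)), 1.5)
})

test_that("extracted boundaries track the phantom truth (RMSE < 1 voxel)", {
  gen <- small_series()
  res <- small_processed()
  for (st in c("naive", "v5")) {
    p <- res$stages[[st]]
    tru_im <- crop_field_to_surface(gen$truth$stages[[st]]$sc_im_depth,
                                    p$sc_im, gen$truth)
    tru_id <- crop_field_to_surface(gen$truth$stages[[st]]$id_sc_depth,
                                    p$id_sc, gen$truth)
    expect_lt(sqrt(mean((p$sc_im$depth_mm - tru_im)^2)), 0.6)
    expect_lt(sqrt(mean((p$id_sc$depth_mm - tru_id)^2)), 0.6)
  }
})

test_that("columns under the depot keep a continuous boundary", {
  res <- small_processed()
  p <- res$stages$v5$seg
  foot <- apply(p$mask, c(2, 3), any)
  idsc <- res$stages$v5$id_sc
  # every footprint column has a finite bridged boundary value
  expect_true(all(is.finite(idsc$depth_mm[foot])))
  expect_true(all(is.finite(res$stages$v5$sc_im$depth_mm[foot])))
  # and the SC/IM boundary under the depot remains directly measured
  expect_gt(mean(res$stages$v5$sc_im$valid[foot]), 0.95)
})

test_that("label_components_3d merges across slices with 26-connectivity", {
  m <- array(FALSE, c(4, 4, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # diagonal neighbour across slices: same component
  m[4, 4, 3] <- TRUE   # separate
  lab <- label_components_3d(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[4, 4, 3] != lab[1, 1, 1])
})
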