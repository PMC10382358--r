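# Depot and tissue morphometrics.

test_that("depot volume converts voxels to mL and is additive", {
  mask <- array(FALSE, c(10, 10, 10)); mask[1:10, 1:10, 1:10] <- TRUE
  expect_equal(depot_volume(mask, c(1, 1, 1)), 1)
  expect_equal(depot_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
  a <- array(FALSE, c(8, 8, 4)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(8, 8, 4)); b[6:8, , ] <- TRUE
  sp <- c(0.6, 0.6, 4)
  expect_equal(depot_volume(a | b, sp), depot_volume(a, sp) + depot_volume(b, sp))
})

test_that("sphere below a flat sheet is at the analytic distance", {
  sph <- ellipsoid_mesh(center = c(22, 20, 20), semiaxes = c(5, 5, 5),
                        n_u = 48, n_v = 32)
  sheet <- flat_surface("ID_SC", 10)
  expect_equal(min_distance(sph, sheet), 7, tolerance = 0.05)
  # depot crossing the sheet reports zero
  sph2 <- ellipsoid_mesh(center = c(11, 20, 20), semiaxes = c(5, 5, 5))
  expect_equal(min_distance(sph2, sheet), 0)
  expect_error(min_distance(NULL, sheet), "empty")
})

test_that("min_distance agrees with the brute-force vertex oracle", {
  set.seed(21)
  for (case in 1:5) {
    blob <- ellipsoid_mesh(center = c(runif(1, 18, 30), runif(1, 10, 30),
                                      runif(1, 10, 30)),
                           semiaxes = runif(3, 2, 5), n_u = 16, n_v = 10)
    sheet <- flat_surface("ID_SC", runif(1, 2, 8))
    sv <- sheet$mesh$vertices
    bv <- blob$vertices
    brute <- sqrt(min(outer(rowSums(bv^2), rowSums(sv^2), "+") - 2 * bv %*% t(sv)))
    edge <- max(sqrt(rowSums((sv[sheet$mesh$faces[, 1], ] -
                              sv[sheet$mesh$faces[, 2], ])^2)))
    d <- min_distance(blob, sheet)
    expect_lte(d, brute + 1e-9)
    expect_gte(d, brute - edge)
  }
})

test_that("depth from skin adds the dermal estimate to the ID/SC distance", {
  expect_equal(depth_from_skin(0.4, 1.5), 1.9)
  expect_equal(depth_from_skin(0, 2.0), 2.0)
  expect_error(depth_from_skin(-1, 1))
})

test_that("ellipsoid projection recovers analytic area and axes", {
  ell <- ellipsoid_mesh(center = c(30, 25, 25), semiaxes = c(3, 10, 5),
                        n_u = 96, n_v = 48)
  pr <- project_and_axes(ell, id_sc = NULL)
  expect_equal(pr$projected_area_cm2, pi * 10 * 5 / 100, tolerance = 0.02)
  expect_equal(pr$principal_x_mm, 20, tolerance = 0.02 * 20)
  expect_equal(pr$principal_y_mm, 10, tolerance = 0.02 * 10)
  expect_equal(pr$z_extent_mm, 6, tolerance = 0.1)
})

test_that("sphere projection is symmetric and rotation leaves axes unchanged", {
  sph <- ellipsoid_mesh(center = c(30, 25, 25), semiaxes = c(6, 6, 6),
                        n_u = 64, n_v = 32)
  pr <- project_and_axes(sph, id_sc = NULL)
  expect_equal(pr$principal_x_mm, pr$principal_y_mm, tolerance = 0.02 * 12)
  # in-plane rotation by 30 degrees
  ell <- ellipsoid_mesh(center = c(0, 0, 0), semiaxes = c(3, 10, 5),
                        n_u = 96, n_v = 48)
  R <- rotation_about_axis("x", 30)
  rot <- surface_mesh(ell$vertices %*% t(R), ell$faces, closed = TRUE)
  pr0 <- project_and_axes(ell, id_sc = NULL)
  pr1 <- project_and_axes(rot, id_sc = NULL)
  expect_equal(pr1$principal_x_mm, pr0$principal_x_mm, tolerance = 0.02 * 20)
  expect_equal(pr1$principal_y_mm, pr0$principal_y_mm, tolerance = 0.02 * 10)
  expect_equal(pr1$projected_area_cm2, pr0$projected_area_cm2, tolerance = 0.03)
})

test_that("thickness map of parallel sheets is the constant gap", {
  up <- flat_surface("ID_SC", 10)
  lo <- flat_surface("SC_IM", 20)
  tm <- thickness_map(up, lo)
  expect_equal(unname(tm$stats[["mean"]]), 10, tolerance = 1e-6)
  expect_lt(max(abs(tm$thickness_mm[tm$valid] - 10)), 1e-6)
  # histogram of a constant map is one bin at 100%
  expect_equal(sum(tm$histogram$percent), 100)
  expect_equal(max(tm$histogram$percent), 100)
})

test_that("tilted upper sheet gives the oblique (cosine) distance", {
  y <- seq(0.5, 39.5, by = 1); z <- seq(1, 39, by = 2)
  theta <- 15 * pi / 180
  up <- flat_surface("ID_SC", NA, y, z,
                     field = outer(tan(theta) * (y - 20), rep(1, length(z))) + 10)
  lo <- flat_surface("SC_IM", 20, y, z)
  tm <- thickness_map(up, lo, window_mm = c(12, 6))
  mid <- tm$thickness_mm[15:25, 8:12]
  expect_equal(mean(mid), 10 * cos(theta), tolerance = 0.02)
  # projection inequality: 3-D minimum never exceeds the vertical gap
  vert <- 20 - up$depth_mm
  expect_true(all(tm$thickness_mm[tm$valid] <= vert[tm$valid] + 1e-9))
})

test_that("thickness maps are non-negative and error on disjoint grids", {
  res <- small_processed()
  for (st in names(res$thickness_maps)) {
    tm <- res$thickness_maps[[st]]
    expect_true(all(tm$thickness_mm[tm$valid] >= 0))
    expect_equal(sum(tm$histogram$percent), 100, tolerance = 1e-9)
  }
  up <- flat_surface("ID_SC", 10)
  lo <- flat_surface("SC_IM", 20)
  lo$valid[] <- FALSE
  expect_error(thickness_map(up, lo), "disjoint")
})

test_that("reference-point percent change is plain arithmetic on thickness", {
  mk <- function(gap) {
    list(id_sc = flat_surface("ID_SC", 20 - gap), sc_im = flat_surface("SC_IM", 20),
         transform = rigid_transform())
  }
  depot <- ellipsoid_mesh(center = c(16, 20, 20), semiaxes = c(2.5, 6, 6))
  sd0 <- list(insertion = mk(10), v10 = mk(14))
  tr <- track_reference_thickness(sd0, depot, "v10")
  expect_equal(tr$stages$thickness_mm[tr$stages$stage == "insertion"], 10,
               tolerance = 0.05)
  expect_equal(tr$stages$pct_change[tr$stages$stage == "v10"], 40,
               tolerance = 1)
  # no growth: zero percent change
  sd1 <- list(insertion = mk(10), v10 = mk(10))
  tr1 <- track_reference_thickness(sd1, depot, "v10")
  expect_equal(tr1$stages$pct_change[tr1$stages$stage == "v10"], 0,
               tolerance = 0.5)
})

test_that("tracked thickness follows the phantom truth and grows monotonically", {
  gen <- small_series()
  res <- small_processed()
  tr <- res$track$stages
  tru <- vapply(gen$truth$stages, function(s) s$apex_thickness_mm, numeric(1))
  err <- tr$thickness_mm - tru[tr$stage]
  expect_lt(sqrt(mean(err^2)), 0.5)
  inj <- tr$thickness_mm[match(c("insertion", "v2", "v5"), tr$stage)]
  expect_true(all(diff(inj) > -0.2))
})

test_that("heatmaps render with a shared fixed scale", {
  res <- small_processed()
  d <- withr::local_tempdir()
  tm <- res$thickness_maps$v5
  p1 <- render_heatmap(tm, file.path(d, "a.png"), range = c(8, 16))
  p2 <- render_heatmap(res$thickness_maps$naive, file.path(d, "b.png"),
                       range = c(8, 16))
  expect_identical(attr(p1, "range"), attr(p2, "range"))
  img <- png::readPNG(file.path(d, "a.png"))
  expect_identical(dim(img)[1:2], c(ncol(tm$thickness_mm), nrow(tm$thickness_mm)))
  # constant map renders a single color
  cm <- thickness_map(flat_surface("ID_SC", 10), flat_surface("SC_IM", 20))
  p3 <- render_heatmap(cm, file.path(d, "c.png"))
  img3 <- png::readPNG(file.path(d, "c.png"))
  expect_equal(nrow(unique(matrix(img3, ncol = 3))), 1L)
  # thickest point sits inside the (dilated) depot footprint
  gen <- small_series()
  mx <- which(tm$thickness_mm == max(tm$thickness_mm[tm$valid]), arr.ind = TRUE)[1, ]
  foot <- apply(res$stages$v5$seg$mask, c(2, 3), any)
  jj <- which(foot, arr.ind = TRUE)
  dist_mm <- min(sqrt(((mx[1] - jj[, 1]) * 0.6)^2 + ((mx[2] - jj[, 2]) * 4)^2))
  expect_lt(dist_mm, 10)
})

test_that("volume, axes and distances are rigid-invariant", {
  gen <- small_series()
  res <- small_processed()
  mesh <- res$stages$v5$seg$mesh
  sheet <- res$stages$v5$id_sc$mesh
  tf <- rigid_transform(rotation_about_axis("x", 25), c(4, -3, 2))
  rmesh <- surface_mesh(rt_apply(tf, mesh$vertices), mesh$faces, closed = TRUE)
  rsheet <- surface_mesh(rt_apply(tf, sheet$vertices), sheet$faces)
  expect_equal(mesh_volume(rmesh), mesh_volume(mesh), tolerance = 1e-9)
  d0 <- min_distance(mesh, sheet)
  d1 <- min_distance(rmesh, rsheet)
  expect_equal(d1, d0, tolerance = 0.01 * max(d0, 1))
  pr0 <- project_and_axes(mesh, id_sc = NULL)
  pr1 <- project_and_axes(rmesh, id_sc = NULL)
  expect_equal(pr1$principal_x_mm, pr0$principal_x_mm,
               tolerance = 0.01 * pr0$principal_x_mm)
  expect_equal(pr1$principal_y_mm, pr0$principal_y_mm,
               tolerance = 0.015 * pr0$principal_y_mm)
})
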