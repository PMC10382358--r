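# Shared fixtures. Phantom series are expensive, so they are generated once
# per test session and cached; every fixture is built in code from a fixed
# seed.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small thigh-like phantom for unit tests: reduced field of view, two
# injection stages, no breathing artifact.
small_spec <- function(seed = 7L, noise_sigma = 3, breathing_shift_mm = 0, ...) {
  phantom_spec(site = "thigh", depot_volumes_mL = c(2, 5),
               stage_pct = c(11.2, 21.3),
               lateral_extent_mm = 72, stack_extent_mm = 64,
               depth_extent_mm = 46, noise_sigma = noise_sigma,
               breathing_shift_mm = breathing_shift_mm, seed = seed, ...)
}

small_series <- function() {
  fixture("small_series", generate_series(small_spec()))
}

small_processed <- function() {
  fixture("small_processed", {
    gen <- small_series()
    process_series(gen$series, run_config(small_spec()))
  })
}

# Full study-condition series (used by the acceptance suite).
study_bundle <- function(site, variant) {
  key <- paste0("study_", site, "_", variant)
  fixture(key, {
    spec <- lvsc_study_spec(site, variant, seed = 11L)
    gen <- generate_series(spec)
    res <- process_series(gen$series, run_config(spec))
    list(spec = spec, truth = gen$truth, series = gen$series, res = res)
  })
}

# Crop a full-grid truth mask to the ROI grid of a processed stage.
crop_truth_to_roi <- function(mask, roi, full) {
  j0 <- round((roi$origin_mm[2] - full$origin_mm[2]) / full$spacing_mm[2])
  k0 <- round((roi$origin_mm[3] - full$origin_mm[3]) / full$spacing_mm[3])
  d <- dim(roi$intensities)
  mask[, j0 + seq_len(d[2]), k0 + seq_len(d[3])]
}

# Crop truth height fields (full grid) to a boundary surface's ROI grid.
crop_field_to_surface <- function(field, bs, truth) {
  j0 <- match(round(bs$y_mm[1], 6), round(truth$y_mm, 6))
  k0 <- match(round(bs$z_mm[1], 6), round(truth$z_mm, 6))
  field[j0 + seq_len(nrow(bs$depth_mm)) - 1L, k0 + seq_len(ncol(bs$depth_mm)) - 1L]
}

# Flat open boundary sheet at a fixed depth over a y/z grid.
flat_surface <- function(kind, depth, y = seq(0.5, 39.5, by = 1),
                         z = seq(1, 39, by = 2), field = NULL) {
  d <- if (is.null(field)) matrix(depth, length(y), length(z)) else field
  boundary_surface(kind, d, matrix(TRUE, length(y), length(z)), y, z)
}

# Minimal fiducial set from a centroid matrix.
make_fiducials <- function(centroids, lower = NULL, radius = 4.5) {
  structure(list(capsules = lapply(seq_len(nrow(centroids)), function(i) {
    list(oil_centroid_mm = centroids[i, ],
         oil_lower_depth_mm = if (is.null(lower)) centroids[i, 1] + radius else lower[i],
         approx_radius_mm = radius)
  })), class = "fiducial_set")
}

# Brute-force Otsu oracle: minimise the weighted within-class variance over
# every split of an integer histogram.
otsu_oracle <- function(values, counts) {
  best <- Inf; best_i <- 1L
  for (i in seq_len(length(values) - 1L)) {
    w1 <- counts[1:i]; w2 <- counts[(i + 1L):length(counts)]
    v1 <- values[1:i]; v2 <- values[(i + 1L):length(values)]
    m1 <- sum(w1 * v1) / sum(w1); m2 <- sum(w2 * v2) / sum(w2)
    wcv <- sum(w1 * (v1 - m1)^2) + sum(w2 * (v2 - m2)^2)
    if (wcv < best) { best <- wcv; best_i <- i }
  }
  (values[best_i] + values[best_i + 1L]) / 2
}
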