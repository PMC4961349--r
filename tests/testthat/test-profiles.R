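test_that("radial rays cross a known shell at its thickness", {
  # concentric spheres r1 = 10, r2 = 14: radial normals hit at 4 mm
  s1 <- phantom_spec(wm_radius_mm = 10, csf_radius_mm = 14,
                     grid_shape = 72L)
  ph <- generate_phantom(s1)
  wm <- mask_to_mesh(ph$wm_mask)
  csf <- mask_to_mesh(ph$csf_mask, invert = TRUE)
  idx <- std_location(wm, n_max = 15)
  for (i in idx[1:5]) {
    v <- wm$vertices[i, ]
    hit <- cast_normal(v, v / sqrt(sum(v^2)), csf, max_ray_mm = 10)
    expect_false(is.null(hit))
    expect_lt(abs(hit$t_mm - (14 - sqrt(sum(v^2)))), 0.5 * 0.5)
  }
  # inward-pointing normal never intersects
  v <- wm$vertices[idx[1], ]
  expect_null(cast_normal(v, -v / sqrt(sum(v^2)), csf, max_ray_mm = 10))
})

test_that("ray casting agrees with brute-force intersection on a half mesh", {
  meshes <- std_meshes()
  wm <- meshes$wm
  csf <- meshes$csf
  # remove the upper hemisphere of the CSF mesh
  ctr_z <- (csf$vertices[csf$faces[, 1], 3] +
            csf$vertices[csf$faces[, 2], 3] +
            csf$vertices[csf$faces[, 3], 3]) / 3
  half <- csf
  half$faces <- csf$faces[ctr_z <= 0, , drop = FALSE]
  set.seed(11)
  idx <- sample(nrow(wm$vertices), 120)
  t_fast <- laminaband:::.cast_rays(wm$vertices[idx, ],
                                    wm$vertex_normals[idx, ],
                                    half$vertices, half$faces, 10)
  t_slow <- vapply(seq_along(idx), function(q) {
    ray_t_brute(wm$vertices[idx[q], ], wm$vertex_normals[idx[q], ],
                half$vertices, half$faces, 10)
  }, numeric(1))
  expect_identical(is.na(t_fast), is.na(t_slow))
  expect_equal(t_fast[!is.na(t_fast)], t_slow[!is.na(t_slow)],
               tolerance = 1e-9)
  # sanity: only downward-pointing normals find the remaining hemisphere
  expect_true(all(wm$vertex_normals[idx[!is.na(t_fast)], 3] < 0.5))
  expect_gt(sum(!is.na(t_fast)), 0)
  expect_gt(sum(is.na(t_fast)), 0)
})

test_that("profile sampling is nearest-neighbour on the exact depth grid", {
  const <- lb_volume(array(5, dim = c(20, 20, 20)), voxel_mm = 1)
  p <- sample_profile(const, c(-5, 0, 0), c(5, 0, 0), 100)
  expect_length(p$intensities, 100)
  expect_true(all(p$intensities == 5))
  expect_equal(p$depths, seq(0, 1, length.out = 100))
  expect_equal(p$length_mm, 10)

  # volume whose value is its voxelised world x-coordinate: staircase oracle
  v0 <- lb_volume(array(0, dim = c(20, 20, 20)), voxel_mm = 1)
  xyz <- voxel_centre_grid(v0)
  vx <- lb_volume(array(xyz[, 1], dim = c(20, 20, 20)), affine = v0$affine)
  p <- sample_profile(vx, c(-6, 0.2, 0.2), c(6, 0.2, 0.2), 100)
  expect_true(all(diff(p$intensities) >= 0))
  steps <- seq(-6, 6, length.out = 100)
  expect_true(all(abs(p$intensities - steps) <= 0.5 + 1e-9))
  # oracle: compute each nearest voxel centre directly
  direct <- vapply(steps, function(x) {
    xyz[which.min(abs(xyz[, 1] - x) + abs(xyz[, 2] - 0.2) +
                    abs(xyz[, 3] - 0.2)), 1]
  }, numeric(1))
  expect_equal(p$intensities, direct)

  expect_error(sample_profile(const, c(-50, 0, 0), c(5, 0, 0), 100),
               "step 1")
})

test_that("every sphere-phantom profile has exactly 100 equal-spaced samples", {
  ph <- std_phantom()
  meshes <- std_meshes()
  filt <- std_location(meshes$wm)
  ps <- extract_location(ph$t1w, meshes$wm, meshes$csf, profile_config(),
                         filt, "loc")
  expect_true(all(lengths(ps$intensities) == 100))
  expect_equal(attr(ps, "depths"), seq(0, 1, length.out = 100))
  expect_true(all(ps$length_mm > 0 & ps$length_mm <= 10))
  expect_lte(nrow(ps), length(filt))
  expect_equal(attr(ps, "n_valid"), nrow(ps))
  expect_equal(attr(ps, "n_candidates"), length(filt))
})

test_that("a fully enclosing CSF surface validates every normal", {
  ph <- std_phantom()
  meshes <- std_meshes()
  set.seed(2)
  filt <- sample(nrow(meshes$wm$vertices), 200)
  ps <- extract_location(ph$t1w, meshes$wm, meshes$csf, profile_config(),
                         filt, "loc")
  expect_equal(attr(ps, "n_valid"), attr(ps, "n_candidates"))
})

test_that("flat-slab profiles all have the slab thickness", {
  spec <- phantom_spec(geometry = "flat_slab",
                       grid_shape = c(32L, 32L, 32L), noise_sd = 0)
  ph <- generate_phantom(spec)
  wm <- mask_to_mesh(ph$wm_mask)
  csf <- mask_to_mesh(ph$csf_mask, invert = TRUE)
  # interior patch, clear of the open sheet edges
  keep <- abs(wm$vertices[, 1]) < 4 & abs(wm$vertices[, 2]) < 4 &
    abs(wm$vertices[, 3] - spec$wm_top_mm) < 0.3
  ps <- extract_location(ph$t1w, wm, csf, profile_config(),
                         which(keep)[1:30], "slab")
  thickness <- spec$csf_top_mm - spec$wm_top_mm
  expect_true(all(abs(ps$length_mm - thickness) < 0.5 * spec$voxel_mm))
})

test_that("noiseless phantom profiles track the analytic laminar profile", {
  ph <- std_phantom()   # noiseless, band at 0.5
  meshes <- std_meshes()
  ps <- extract_location(ph$t1w, meshes$wm, meshes$csf, profile_config(),
                         std_location(meshes$wm), "loc")
  mp <- average_profiles(ps)
  truth <- radial_ground_truth_profile(ph$spec, 100)
  # compare away from the partial-volume contaminated borders
  core <- 15:85
  expect_lt(mean(abs(mp[core] - truth[core])), 2)
})

test_that("insufficient valid profiles raise an informative error", {
  ph <- std_phantom()
  meshes <- std_meshes()
  flipped <- meshes$wm
  flipped$vertex_normals <- -flipped$vertex_normals
  expect_error(
    extract_location(ph$t1w, flipped, meshes$csf,
                     profile_config(min_profiles = 5),
                     std_location(meshes$wm), "loc"),
    "insufficient valid profiles")
  nm <- meshes$wm
  nm$vertex_normals <- NULL
  expect_error(extract_location(ph$t1w, nm, meshes$csf), "normals")
})

test_that("profile CSV round-trips the profile set", {
  ph <- std_phantom()
  meshes <- std_meshes()
  ps <- extract_location(ph$t1w, meshes$wm, meshes$csf, profile_config(),
                         std_location(meshes$wm), "locA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(ps, path)
  back <- read_profiles_csv(path)
  expect_equal(do.call(rbind, back$intensities),
               do.call(rbind, ps$intensities), tolerance = 1e-9)
  expect_equal(back$length_mm, ps$length_mm, tolerance = 1e-9)
  expect_identical(back$location_id, ps$location_id)
})

test_that("farthest-point thinning caps and spreads the selection", {
  meshes <- std_meshes()
  seedv <- meshes$wm$vertices[which.max(meshes$wm$vertices[, 1]), ]
  full <- select_location_vertices(meshes$wm, seedv, 4)
  thinned <- select_location_vertices(meshes$wm, seedv, 4, n_max = 30)
  expect_length(thinned, 30)
  expect_true(all(thinned %in% full))
  # deterministic
  expect_identical(thinned,
                   select_location_vertices(meshes$wm, seedv, 4, n_max = 30))
  # spread: minimal pairwise distance well above adjacent-vertex spacing
  pts <- meshes$wm$vertices[thinned, ]
  dmin <- min(dist(pts))
  expect_gt(dmin, 0.4)
})
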