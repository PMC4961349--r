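# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# standard concentric-sphere phantom (default study conditions)
std_phantom <- function(noise_sd = 0, band_present = TRUE, band_depth = 0.5,
                        bias_field = "none", seed = 7) {
  key <- paste("ph", noise_sd, band_present, band_depth, bias_field, seed,
               sep = "_")
  cached(key, generate_phantom(phantom_spec(
    noise_sd = noise_sd, band_present = band_present,
    band_depth = band_depth, bias_field = bias_field, seed = seed)))
}

# WM/CSF meshes of the standard phantom (masks are noise-independent, so
# one pair serves all standard specs)
std_meshes <- function() {
  cached("meshes", {
    ph <- std_phantom()
    list(wm = mask_to_mesh(ph$wm_mask),
         csf = mask_to_mesh(ph$csf_mask, invert = TRUE))
  })
}

# standard location: 30 spread vertices around the +x pole
std_location <- function(wm_mesh, n_max = 30) {
  seedv <- wm_mesh$vertices[which.max(wm_mesh$vertices[, 1]), ]
  select_location_vertices(wm_mesh, seedv, 4, n_max = n_max)
}

# synthetic profile set: base profile + iid Gaussian noise
noisy_profile_set <- function(base, n = 30, sd = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rep(base, each = n), nrow = n) +
    matrix(stats::rnorm(n * length(base), sd = sd), nrow = n)
  profile_set_from_matrix(m)
}

# Independent pure-R all-faces ray-triangle intersection oracle
# (Moller-Trumbore, vectorised over faces). Returns nearest t or NA.
ray_t_brute <- function(origin, dir, V, F, max_t) {
  A <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - A
  e2 <- V[F[, 3], , drop = FALSE] - A
  p <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * p)
  tv <- cbind(origin[1] - A[, 1], origin[2] - A[, 2], origin[3] - A[, 3])
  u <- rowSums(tv * p) / det
  q <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
             tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
             tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- (dir[1] * q[, 1] + dir[2] * q[, 2] + dir[3] * q[, 3]) / det
  tt <- rowSums(e2 * q) / det
  ok <- abs(det) > 1e-12 & u >= 0 & u <= 1 & v >= 0 & u + v <= 1 &
    tt > 1e-9 & tt <= max_t
  if (any(ok, na.rm = TRUE)) min(tt[ok], na.rm = TRUE) else NA_real_
}
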