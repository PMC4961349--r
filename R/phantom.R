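#' Specify a laminar phantom
#'
#' Defines a synthetic T1-weighted volume with known laminar structure: a
#' white-matter core, a grey-matter ribbon that may carry a hypo-intense
#' (myelin) band modelled as a Gaussian dip in relative cortical depth, and
#' bright CSF outside — the contrast regime of high-resolution T1-w MRI where
#' WM and CSF are both brighter than GM. Two geometries are supported:
#' concentric spheres (curvature, diverging normals) and a flat slab (exact
#' planar oracles).
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_mm isotropic voxel size in mm. Default 0.5 mm, the
#'   resolution at which equi-distance depth is adequate.
#' @param geometry `"concentric_spheres"` or `"flat_slab"`.
#' @param wm_radius_mm,csf_radius_mm sphere case: radius of the WM core and
#'   of the inner CSF boundary; the GM ribbon is the shell between them.
#' @param wm_top_mm,csf_top_mm slab case: world z of the WM/GM and GM/CSF
#'   planes (WM below `wm_top_mm`, CSF above `csf_top_mm`).
#' @param intensity_wm,intensity_gm,intensity_csf plateau intensities in
#'   arbitrary units; must satisfy WM > GM and CSF > GM.
#' @param gm_slope intensity drop across the full cortical depth due to the
#'   intracortical myelin gradient: GM intensity descends linearly from
#'   `intensity_gm + gm_slope/2` at the WM border to
#'   `intensity_gm - gm_slope/2` at the CSF border, as in vivo T1-w
#'   contrast falls from the heavily myelinated deep laminae toward the
#'   sparsely myelinated superficial ones. The band dip is superimposed on
#'   this gradient.
#' @param band_present logical, inject the hypo-intense band?
#' @param band_depth relative depth in (0,1) of the band minimum
#'   (0 = WM border, 1 = CSF border).
#' @param band_width standard deviation of the Gaussian dip, in relative
#'   depth units.
#' @param band_amplitude intensity drop at the dip centre (same units as the
#'   plateaus).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_field `"none"`, `"linear"` or `"polynomial"` multiplicative
#'   receive-field bias, shared between T1-w and PD.
#' @param bias_amplitude peak-to-peak amplitude of the bias relative to its
#'   mean of 1 (0.3 = 30%).
#' @param pv_blur_mm partial-volume blur: Gaussian sigma in mm applied to the
#'   noiseless phantom before bias and noise.
#' @param pd_voxel_mm voxel size of the proton-density volume, generated on
#'   its own (typically coarser) grid spanning the same field of view.
#' @param seed RNG seed making the noise reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_mm = 0.5,
                         geometry = c("concentric_spheres", "flat_slab"),
                         wm_radius_mm = 9,
                         csf_radius_mm = 12,
                         wm_top_mm = -1.5,
                         csf_top_mm = 1.5,
                         intensity_wm = 150,
                         intensity_gm = 100,
                         intensity_csf = 180,
                         gm_slope = 15,
                         band_present = TRUE,
                         band_depth = 0.5,
                         band_width = 0.08,
                         band_amplitude = 10,
                         noise_sd = 0,
                         bias_field = c("none", "linear", "polynomial"),
                         bias_amplitude = 0.3,
                         pv_blur_mm = 0.25,
                         pd_voxel_mm = 1.0,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  bias_field <- match.arg(bias_field)
  spec <- list(grid_shape = as.integer(rep_len(grid_shape, 3)),
               voxel_mm = voxel_mm, geometry = geometry,
               wm_radius_mm = wm_radius_mm, csf_radius_mm = csf_radius_mm,
               wm_top_mm = wm_top_mm, csf_top_mm = csf_top_mm,
               intensity_wm = intensity_wm, intensity_gm = intensity_gm,
               intensity_csf = intensity_csf, gm_slope = gm_slope,
               band_present = isTRUE(band_present), band_depth = band_depth,
               band_width = band_width, band_amplitude = band_amplitude,
               noise_sd = noise_sd, bias_field = bias_field,
               bias_amplitude = bias_amplitude, pv_blur_mm = pv_blur_mm,
               pd_voxel_mm = pd_voxel_mm, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$geometry == "concentric_spheres" &&
      s$csf_radius_mm <= s$wm_radius_mm) {
    stop("csf_radius_mm must exceed wm_radius_mm")
  }
  if (s$geometry == "flat_slab" && s$csf_top_mm <= s$wm_top_mm) {
    stop("csf_top_mm must exceed wm_top_mm")
  }
  stopifnot(s$band_depth > 0, s$band_depth < 1, s$band_width > 0,
            s$band_amplitude >= 0, s$noise_sd >= 0, s$voxel_mm > 0,
            s$intensity_wm > s$intensity_gm,
            s$intensity_csf > s$intensity_gm,
            s$bias_amplitude >= 0, s$pv_blur_mm >= 0)
  invisible(s)
}

# GM intensity at relative depth d (vectorised), before blur/bias/noise.
gm_intensity_at_depth <- function(spec, d) {
  slope <- if (is.null(spec$gm_slope)) 0 else spec$gm_slope
  v <- spec$intensity_gm + slope * (0.5 - d)
  if (spec$band_present) {
    v <- v - spec$band_amplitude *
      exp(-(d - spec$band_depth)^2 / (2 * spec$band_width^2))
  }
  v
}

#' Analytic noiseless laminar profile of a phantom
#'
#' The ground-truth GM intensity at `n_steps` equally spaced relative depths
#' in \[0, 1\]; the oracle for profile-extraction and band-detection tests.
#'
#' @param spec a [phantom_spec()].
#' @param n_steps number of depth samples (>= 2).
#' @return Numeric vector of length `n_steps`.
#' @export
radial_ground_truth_profile <- function(spec, n_steps = 100L) {
  stopifnot(n_steps >= 2)
  d <- seq(0, 1, length.out = n_steps)
  gm_intensity_at_depth(spec, d)
}

# Multiplicative bias field evaluated at world coordinates (n x 3 matrix).
# Mean ~1, peak-to-peak `amp` across the field of view `extent` (mm, per axis
# world bounds as a 3x2 matrix).
bias_field_at <- function(kind, amp, xyz, extent) {
  if (kind == "none" || amp == 0) return(rep(1, nrow(xyz)))
  u <- (xyz[, 1] - extent[1, 1]) / (extent[1, 2] - extent[1, 1])
  if (kind == "linear") {
    return(1 + amp * (u - 0.5))
  }
  # smooth second-order field varying along x and y
  v <- (xyz[, 2] - extent[2, 1]) / (extent[2, 2] - extent[2, 1])
  p <- (u - 0.5)^2 + (v - 0.5)^2   # in [0, 0.5]
  1 + amp * (p / 0.5 - 0.5)
}

#' Generate a synthetic laminar phantom
#'
#' Builds the noiseless anatomy from the spec's geometry, injects the
#' Gaussian hypo-intense band in GM (if requested), applies partial-volume
#' blur, multiplies by the receive-field bias, and adds Gaussian noise. The
#' proton-density volume is flat anatomy (value 1) times the same bias field
#' plus noise, generated on its own grid. Masks are exact pre-noise region
#' indicators. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_output` with elements `t1w`, `pd`,
#'   `wm_mask`, `csf_mask` (all `lb_volume`) and `truth` (ground-truth list).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  fov <- d * spec$voxel_mm
  if (spec$geometry == "concentric_spheres") {
    need <- 2 * (spec$csf_radius_mm + 2 * spec$voxel_mm)
    if (any(fov < need)) {
      stop(sprintf(
        "grid too small: csf_radius_mm=%.3g needs a field of view of %.3g mm",
        spec$csf_radius_mm, need))
    }
  } else {
    if (spec$csf_top_mm + 2 * spec$voxel_mm > fov[3] / 2 ||
        spec$wm_top_mm - 2 * spec$voxel_mm < -fov[3] / 2) {
      stop(sprintf(
        "grid too small: slab bounds [%.3g, %.3g] mm exceed the grid",
        spec$wm_top_mm, spec$csf_top_mm))
    }
  }
  grid <- lb_volume(array(0, dim = d), voxel_mm = spec$voxel_mm)
  xyz <- voxel_centre_grid(grid)

  if (spec$geometry == "concentric_spheres") {
    r <- sqrt(rowSums(xyz^2))
    wm <- r <= spec$wm_radius_mm
    csf <- r > spec$csf_radius_mm
    depth <- (r - spec$wm_radius_mm) /
      (spec$csf_radius_mm - spec$wm_radius_mm)
    thickness <- spec$csf_radius_mm - spec$wm_radius_mm
  } else {
    z <- xyz[, 3]
    wm <- z <= spec$wm_top_mm
    csf <- z > spec$csf_top_mm
    depth <- (z - spec$wm_top_mm) / (spec$csf_top_mm - spec$wm_top_mm)
    thickness <- spec$csf_top_mm - spec$wm_top_mm
  }
  gm <- !wm & !csf
  vol <- numeric(nrow(xyz))
  vol[wm] <- spec$intensity_wm
  vol[csf] <- spec$intensity_csf
  vol[gm] <- gm_intensity_at_depth(spec, depth[gm])
  vol <- array(vol, dim = d)

  if (spec$pv_blur_mm > 0) {
    vol <- blur_voxels(vol, spec$pv_blur_mm / spec$voxel_mm)
  }
  extent <- rbind(range(xyz[, 1]), range(xyz[, 2]), range(xyz[, 3]))
  bias <- bias_field_at(spec$bias_field, spec$bias_amplitude, xyz, extent)
  vol <- vol * array(bias, dim = d)

  # PD grid spans the same field of view at its own resolution
  pd_dim <- pmax(2L, as.integer(round(fov / spec$pd_voxel_mm)))
  pd_grid <- lb_volume(array(0, dim = pd_dim), voxel_mm = spec$pd_voxel_mm)
  pd_xyz <- voxel_centre_grid(pd_grid)
  pd_bias <- bias_field_at(spec$bias_field, spec$bias_amplitude, pd_xyz,
                           extent)
  pd <- array(pd_bias, dim = pd_dim)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    vol <- vol + array(stats::rnorm(length(vol), sd = spec$noise_sd),
                       dim = d)
    pd <- pd + array(stats::rnorm(length(pd),
                                  sd = spec$noise_sd / spec$intensity_gm),
                     dim = pd_dim)
  }

  truth <- list(band_present = spec$band_present,
                band_depth = if (spec$band_present) spec$band_depth else NA,
                band_amplitude = if (spec$band_present)
                  spec$band_amplitude else 0,
                shell_thickness_mm = thickness)
  structure(list(
    t1w = lb_volume(vol, affine = grid$affine),
    pd = lb_volume(pd, affine = pd_grid$affine),
    wm_mask = lb_volume(array(as.numeric(wm), dim = d),
                        affine = grid$affine),
    csf_mask = lb_volume(array(as.numeric(csf), dim = d),
                         affine = grid$affine),
    truth = truth, spec = spec
  ), class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> geometry=%s band=%s grid=%s\n",
              x$spec$geometry,
              if (x$truth$band_present)
                sprintf("depth %.2f amp %.3g", x$truth$band_depth,
                        x$truth$band_amplitude) else "absent",
              paste(dim(x$t1w$data), collapse = "x")))
  invisible(x)
}

#' Write all phantom volumes and ground truth to a directory
#'
#' @param ph a `phantom_output`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$t1w, file.path(dir, "t1w.nii.gz"))
  write_volume(ph$pd, file.path(dir, "pd.nii.gz"))
  write_volume(ph$wm_mask, file.path(dir, "wm_mask.nii.gz"))
  write_volume(ph$csf_mask, file.path(dir, "csf_mask.nii.gz"))
  jsonlite::write_json(ph$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
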