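#' Assemble a pipeline run configuration
#'
#' Bundles the per-stage configurations, the input volumes (or a phantom
#' spec standing in for them) and the analysis locations. Every reference
#' parameter of the analysis (12 mm PD blur FWHM, 0.8 voxel mask smoothing
#' SD, 100 profile steps, spar 0.55, 2000 bootstrap repetitions, 75% null
#' proportion, 95% CI) is a named, defaulted field, so the default run is
#' the reference run.
#'
#' @param phantom a [phantom_spec()], or `NULL` when volumes are supplied.
#' @param t1w,pd,wm_mask,csf_mask `lb_volume`s or NIfTI paths (ignored when
#'   `phantom` is given).
#' @param bias a [bias_corr_config()].
#' @param surface list with `mask_smooth_sd_vox` and `iso_level`.
#' @param profile a [profile_config()].
#' @param band a [band_config()].
#' @param locations list of locations, each a list with `id`, `seed_point`
#'   (world mm), `radius_mm` and optionally `n_max` (profile cap, see
#'   [select_location_vertices()]); `NULL` picks locations automatically on
#'   the WM mesh.
#' @param n_locations number of automatic locations when `locations` is
#'   `NULL`.
#' @param out_dir directory for intermediates and reports, or `NULL` to
#'   keep everything in memory.
#' @param seed top-level seed from which all stage seeds derive.
#' @param verbose print stage progress?
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = NULL, t1w = NULL, pd = NULL,
                       wm_mask = NULL, csf_mask = NULL,
                       bias = bias_corr_config(),
                       surface = list(mask_smooth_sd_vox = 0.8,
                                      iso_level = 0.5),
                       profile = profile_config(),
                       band = band_config(),
                       locations = NULL, n_locations = 1L,
                       out_dir = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(surface$mask_smooth_sd_vox >= 0,
            surface$iso_level > 0, surface$iso_level < 1)
  if (!is.null(locations)) {
    ids <- vapply(locations, `[[`, "", "id")
    if (anyDuplicated(ids)) stop("location ids must be unique")
  }
  structure(list(phantom = phantom, t1w = t1w, pd = pd,
                 wm_mask = wm_mask, csf_mask = csf_mask, bias = bias,
                 surface = surface, profile = profile, band = band,
                 locations = locations,
                 n_locations = as.integer(n_locations),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; nested sections map onto the stage
#' constructors so their invariants are validated on load.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("phantom", "t1w", "pd", "wm_mask", "csf_mask", "bias",
             "surface", "profile", "band", "locations", "n_locations",
             "out_dir", "seed", "verbose")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  for (k in c("t1w", "pd", "wm_mask", "csf_mask", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$bias)) args$bias <- do.call(bias_corr_config, y$bias)
  if (!is.null(y$surface)) {
    args$surface <- utils::modifyList(
      list(mask_smooth_sd_vox = 0.8, iso_level = 0.5), y$surface)
  }
  if (!is.null(y$profile)) args$profile <- do.call(profile_config, y$profile)
  if (!is.null(y$band)) args$band <- do.call(band_config, y$band)
  for (k in c("locations", "n_locations", "seed", "verbose")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

as_volume_input <- function(x, what) {
  if (is.null(x)) stop("missing input volume: ", what)
  if (inherits(x, "lb_volume")) x else read_volume(x)
}

# evenly spread seed directions for automatic phantom locations; each
# location is a patch of radius_mm thinned to n_profiles spread vertices
auto_locations <- function(wm_mesh, n, radius_mm = 4, n_profiles = 30L) {
  centre <- colMeans(wm_mesh$vertices)
  # golden-angle spiral on the unit sphere
  k <- seq_len(n)
  z <- if (n == 1) 0 else (2 * (k - 1) / (n - 1) - 1) * 0.8
  phi <- k * pi * (3 - sqrt(5))
  dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  lapply(k, function(i) {
    # seed at the mesh vertex nearest the ray from the centre
    proj <- sweep(wm_mesh$vertices, 2, centre)
    sc <- proj %*% dirs[i, ]
    v <- wm_mesh$vertices[which.max(sc), ]
    list(id = sprintf("loc%02d", i), seed_point = as.numeric(v),
         radius_mm = radius_mm, n_max = n_profiles)
  })
}

#' Run the full laminar analysis pipeline
#'
#' Chains bias correction, surface extraction, profile extraction and band
#' detection per location, writing all intermediates when `out_dir` is set.
#' The Bonferroni family size defaults to the number of locations analysed.
#' All randomness derives from `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @return A tibble with one row per location (the [glance()] of each
#'   location's `band_result`), with the per-location results attached as
#'   the `results` attribute.
#' @export
run_pipeline <- function(cfg) {
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  stage <- function(what, loc, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s'%s failed: %s", what,
                   if (is.null(loc)) "" else paste0(" (location ", loc, ")"),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(cfg$phantom)) {
    say("generating phantom")
    ph <- stage("phantom", NULL, {
      spec <- cfg$phantom
      spec$seed <- cfg$seed
      generate_phantom(spec)
    })
    t1w <- ph$t1w; pd <- ph$pd
    wm_mask <- ph$wm_mask; csf_mask <- ph$csf_mask
  } else {
    t1w <- as_volume_input(cfg$t1w, "t1w")
    pd <- as_volume_input(cfg$pd, "pd")
    wm_mask <- as_volume_input(cfg$wm_mask, "wm_mask")
    csf_mask <- as_volume_input(cfg$csf_mask, "csf_mask")
    ph <- NULL
  }
  say("bias correction (PD division, FWHM %.3g mm)", cfg$bias$blur_fwhm_mm)
  corrected <- stage("biascorr", NULL, pd_correct(t1w, pd, cfg$bias))
  say("surface extraction (mask SD %.3g vox)",
      cfg$surface$mask_smooth_sd_vox)
  wm_mesh <- stage("surface", NULL,
                   mask_to_mesh(wm_mask, cfg$surface$mask_smooth_sd_vox,
                                cfg$surface$iso_level))
  csf_mesh <- stage("surface", NULL,
                    mask_to_mesh(csf_mask, cfg$surface$mask_smooth_sd_vox,
                                 cfg$surface$iso_level, invert = TRUE))
  locations <- cfg$locations
  if (is.null(locations)) {
    locations <- stage("locations", NULL,
                       auto_locations(wm_mesh, cfg$n_locations))
  }
  band_cfg <- cfg$band
  if (band_cfg$n_tests == 1L && length(locations) > 1L) {
    band_cfg$n_tests <- length(locations)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(ph)) write_phantom(ph, file.path(out_dir, "phantom"))
    write_volume(corrected, file.path(out_dir, "t1w_corrected.nii.gz"))
    write_mesh_ply(wm_mesh, file.path(out_dir, "wm_mesh.ply"))
    write_mesh_ply(csf_mesh, file.path(out_dir, "csf_mesh.ply"))
  }
  results <- lapply(seq_along(locations), function(i) {
    loc <- locations[[i]]
    say("location %s: extracting profiles", loc$id)
    ps <- stage("profiles", loc$id, {
      filt <- select_location_vertices(wm_mesh, loc$seed_point,
                                       loc$radius_mm, loc$n_max)
      extract_location(corrected, wm_mesh, csf_mesh, cfg$profile,
                       location_filter = filt, location_id = loc$id)
    })
    if (!is.null(out_dir)) {
      write_profiles_csv(ps, file.path(out_dir,
                                       paste0("profiles_", loc$id, ".csv")))
    }
    say("location %s: band detection (%d profiles)", loc$id, nrow(ps))
    bc <- band_cfg
    bc$rng_seed <- cfg$seed + i
    stage("detect", loc$id, analyze_location(ps, bc))
  })
  report <- dplyr::bind_rows(lapply(results, glance))
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "band_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "band_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    meta <- list(package_version = as.character(
                   utils::packageVersion("laminaband")),
                 r_version = R.version.string, seed = cfg$seed,
                 n_locations = length(locations),
                 band = unclass(band_cfg), bias = unclass(cfg$bias),
                 surface = cfg$surface, profile = unclass(cfg$profile))
    jsonlite::write_json(meta, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  attr(report, "results") <- results
  report
}
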