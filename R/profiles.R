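#' Profile extraction configuration
#'
#' @param n_steps samples per profile, from the GM/WM border (depth 0) to
#'   the GM/CSF border (depth 1). Default 100.
#' @param max_ray_mm maximum normal growth before a normal is declared
#'   non-intersecting. Default 10 mm, about three times the maximal human
#'   cortical thickness, so rays cannot exit through distant CSF across a
#'   sulcus.
#' @param min_profiles minimum number of valid profiles a location must
#'   yield.
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(n_steps = 100L, max_ray_mm = 10,
                           min_profiles = 1L) {
  stopifnot(n_steps >= 2, max_ray_mm > 0, min_profiles >= 1)
  structure(list(n_steps = as.integer(n_steps), max_ray_mm = max_ray_mm,
                 min_profiles = as.integer(min_profiles)),
            class = "profile_config")
}

#' Cast a surface normal to the CSF mesh
#'
#' Grows a ray from a WM vertex along its outward normal and returns the
#' nearest intersection with the CSF mesh within `max_ray_mm`, or `NULL` if
#' the ray does not intersect (the normal is then invalid and yields no
#' profile).
#'
#' @param wm_vertex world point (mm), the ray origin.
#' @param normal unit direction vector.
#' @param csf_mesh a `triangle_mesh`.
#' @param max_ray_mm maximum ray parameter in mm.
#' @return A list with `point` (world mm) and `t_mm`, or `NULL`.
#' @export
cast_normal <- function(wm_vertex, normal, csf_mesh, max_ray_mm = 10) {
  stopifnot(abs(sqrt(sum(normal^2)) - 1) < 1e-6)
  t <- .cast_rays(matrix(wm_vertex, 1), matrix(normal, 1),
                  csf_mesh$vertices, csf_mesh$faces, max_ray_mm)
  if (is.na(t)) return(NULL)
  list(point = as.numeric(wm_vertex + t * normal), t_mm = as.numeric(t))
}

#' Sample one laminar profile by nearest-neighbour interpolation
#'
#' Intensities are read at `n_steps` points equally spaced along the segment
#' from the WM vertex (depth 0) to the CSF intersection (depth 1), each
#' mapped to the nearest voxel centre (equi-distance depth: relative depth
#' is Euclidean distance from the GM/WM border). Nearest-voxel ties at exact
#' half coordinates break toward the lower index.
#'
#' @param volume an `lb_volume` (typically the bias-corrected T1-w).
#' @param wm_vertex world start point (mm).
#' @param csf_point world end point (mm).
#' @param n_steps number of samples.
#' @return A list with `intensities`, `depths` (the uniform grid 0..1) and
#'   `length_mm`.
#' @export
sample_profile <- function(volume, wm_vertex, csf_point, n_steps = 100L) {
  stopifnot(n_steps >= 2)
  f <- seq(0, 1, length.out = n_steps)
  pts <- cbind(wm_vertex[1] + f * (csf_point[1] - wm_vertex[1]),
               wm_vertex[2] + f * (csf_point[2] - wm_vertex[2]),
               wm_vertex[3] + f * (csf_point[3] - wm_vertex[3]))
  vox <- world_to_voxel(volume, pts)
  d <- dim(volume$data)
  out <- vox[, 1] < -0.5 | vox[, 1] > d[1] - 0.5 |
         vox[, 2] < -0.5 | vox[, 2] > d[2] - 0.5 |
         vox[, 3] < -0.5 | vox[, 3] > d[3] - 0.5
  if (any(out)) {
    stop("profile sample outside volume at step ", which(out)[1])
  }
  idx <- nearest_voxel_index(vox, d)
  list(intensities = volume$data[idx], depths = f,
       length_mm = sqrt(sum((csf_point - wm_vertex)^2)))
}

#' Select WM vertices within a sphere of interest
#'
#' Locations are defined as vertex subsets within `radius_mm` of a seed
#' point in world mm (the scriptable equivalent of manually drawn location
#' boxes). When `n_max` is given, the selection is thinned to at most
#' `n_max` vertices by farthest-point sampling, spreading the profiles
#' across the patch: bundles of adjacent near-parallel normals sample the
#' same voxel columns and their nearest-neighbour staircases average
#' coherently, whereas spread origins decorrelate them.
#'
#' @param mesh a `triangle_mesh`.
#' @param seed_point world point (mm).
#' @param radius_mm selection radius.
#' @param n_max optional cap on the number of vertices (deterministic
#'   farthest-point thinning, starting from the vertex nearest the seed).
#' @return Integer vector of vertex indices.
#' @export
select_location_vertices <- function(mesh, seed_point, radius_mm,
                                     n_max = NULL) {
  d2 <- rowSums(sweep(mesh$vertices, 2, as.numeric(seed_point))^2)
  idx <- which(d2 <= radius_mm^2)
  if (is.null(n_max) || length(idx) <= n_max) return(idx)
  pts <- mesh$vertices[idx, , drop = FALSE]
  chosen <- integer(n_max)
  chosen[1] <- which.min(d2[idx])
  mind <- rowSums(sweep(pts, 2, pts[chosen[1], ])^2)
  for (k in 2:n_max) {
    chosen[k] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[chosen[k], ])^2))
  }
  sort(idx[chosen])
}

#' Extract all valid laminar profiles for one location
#'
#' One candidate ray per WM vertex in `location_filter` (all vertices if
#' `NULL`), grown along the outward vertex normal. Normals that intersect
#' the CSF mesh within `max_ray_mm` are valid and yield profiles; all others
#' are dropped. Rays that pass through the WM surface itself before reaching
#' CSF (deep sulci) are kept but flagged `crossed_wm`.
#'
#' @param volume `lb_volume` to sample (bias-corrected T1-w).
#' @param wm_mesh `triangle_mesh` with outward vertex normals.
#' @param csf_mesh `triangle_mesh` of the GM/CSF boundary.
#' @param cfg a [profile_config()].
#' @param location_filter integer vertex indices, or `NULL` for all.
#' @param location_id label recorded with every profile.
#' @return A tibble of class `profile_set`, one row per valid profile, with
#'   columns `location_id`, `origin_vertex`, `length_mm`, `crossed_wm` and
#'   the list-column `intensities`; attributes `n_candidates`, `n_valid`,
#'   `n_steps` and `depths`.
#' @export
extract_location <- function(volume, wm_mesh, csf_mesh,
                             cfg = profile_config(),
                             location_filter = NULL,
                             location_id = "loc") {
  if (is.null(wm_mesh$vertex_normals)) {
    stop("wm_mesh has no vertex normals; call compute_vertex_normals()")
  }
  idx <- if (is.null(location_filter)) seq_len(nrow(wm_mesh$vertices))
         else as.integer(location_filter)
  origins <- wm_mesh$vertices[idx, , drop = FALSE]
  dirs <- wm_mesh$vertex_normals[idx, , drop = FALSE]
  t_csf <- .cast_rays(origins, dirs, csf_mesh$vertices, csf_mesh$faces,
                      cfg$max_ray_mm)
  valid <- !is.na(t_csf)
  n_candidates <- length(idx)
  n_valid <- sum(valid)
  if (n_valid < cfg$min_profiles) {
    stop("insufficient valid profiles: ", n_valid, " < ", cfg$min_profiles)
  }
  vi <- which(valid)
  # does the ray cross the WM surface itself before reaching CSF?
  t_wm <- .cast_rays(origins[vi, , drop = FALSE], dirs[vi, , drop = FALSE],
                     wm_mesh$vertices, wm_mesh$faces, cfg$max_ray_mm)
  crossed <- !is.na(t_wm) & t_wm < t_csf[vi] - 1e-9
  profs <- purrr::map(seq_along(vi), function(q) {
    i <- vi[q]
    endpt <- origins[i, ] + t_csf[i] * dirs[i, ]
    sample_profile(volume, origins[i, ], endpt, cfg$n_steps)
  })
  out <- tibble::tibble(
    location_id = location_id,
    origin_vertex = idx[vi],
    length_mm = purrr::map_dbl(profs, "length_mm"),
    crossed_wm = crossed,
    intensities = purrr::map(profs, "intensities")
  )
  new_profile_set(out, n_candidates = n_candidates,
                  n_steps = cfg$n_steps)
}

new_profile_set <- function(tbl, n_candidates, n_steps) {
  structure(tbl,
            n_candidates = as.integer(n_candidates),
            n_valid = nrow(tbl),
            n_steps = as.integer(n_steps),
            depths = seq(0, 1, length.out = n_steps),
            class = c("profile_set", class(tibble::tibble())))
}

#' Assemble a profile set from an intensity matrix
#'
#' Builds a `profile_set` directly from a profiles-by-depths matrix, e.g.
#' when profiles come from an external extraction or a simulation.
#'
#' @param m numeric matrix, one row per profile, `n_steps` columns.
#' @param location_id label.
#' @param length_mm per-profile physical lengths (recycled).
#' @return A `profile_set` tibble.
#' @export
profile_set_from_matrix <- function(m, location_id = "loc",
                                    length_mm = NA_real_) {
  m <- as.matrix(m)
  tbl <- tibble::tibble(
    location_id = location_id,
    origin_vertex = seq_len(nrow(m)),
    length_mm = rep_len(length_mm, nrow(m)),
    crossed_wm = FALSE,
    intensities = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  )
  new_profile_set(tbl, n_candidates = nrow(m), n_steps = ncol(m))
}

# profiles-by-depths matrix from a profile_set
profile_matrix <- function(ps) {
  do.call(rbind, ps$intensities)
}

#' Write / read a profile set as CSV
#'
#' One row per profile: `location_id`, `origin_vertex`, `length_mm`,
#' `crossed_wm`, then one intensity column per depth step (`i001`...).
#'
#' @param ps a `profile_set`.
#' @param path output CSV path.
#' @return `path` (write) or a `profile_set` (read).
#' @export
write_profiles_csv <- function(ps, path) {
  m <- profile_matrix(ps)
  colnames(m) <- sprintf("i%03d", seq_len(ncol(m)))
  df <- cbind(data.frame(location_id = ps$location_id,
                         origin_vertex = ps$origin_vertex,
                         length_mm = ps$length_mm,
                         crossed_wm = ps$crossed_wm), as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  icol <- grep("^i[0-9]+$", names(df))
  m <- as.matrix(df[, icol, drop = FALSE])
  tbl <- tibble::tibble(
    location_id = df$location_id,
    origin_vertex = df$origin_vertex,
    length_mm = df$length_mm,
    crossed_wm = as.logical(df$crossed_wm),
    intensities = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  )
  new_profile_set(tbl, n_candidates = nrow(tbl), n_steps = ncol(m))
}
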