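#' Construct a triangle mesh
#'
#' @param vertices n x 3 matrix of world coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_normals optional n x 3 matrix of unit normals.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, vertex_normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_normals = vertex_normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_normals)) "" else ", with normals"))
  invisible(x)
}

#' Smooth a binary mask
#'
#' Gaussian smoothing of a binary segmentation mask with the standard
#' deviation given in voxels (applied per axis in voxel units), the
#' convention used before isosurface extraction of the WM and CSF
#' boundaries.
#'
#' @param mask an `lb_volume` with values in {0, 1}.
#' @param sd_vox Gaussian standard deviation in voxels (default 0.8).
#' @return An `lb_volume` with values in \[0, 1\].
#' @export
smooth_mask <- function(mask, sd_vox = 0.8) {
  stopifnot(sd_vox >= 0)
  vals <- mask$data
  if (!all(vals %in% c(0, 1))) stop("mask is not binary (values in {0,1})")
  lb_volume(blur_voxels(vals, rep(sd_vox, 3)), affine = mask$affine)
}

#' Extract an isosurface mesh from a smoothed mask
#'
#' Marching-tetrahedra surface at `iso_level`, with vertices mapped to world
#' mm through the volume's affine. Optionally keeps only the largest
#' connected component (mask smoothing can create specks).
#'
#' @param smoothed an `lb_volume` whose values straddle `iso_level`.
#' @param iso_level level-set value; 0.5 is the unbiased boundary of a
#'   blurred binary mask.
#' @param largest_component drop all but the largest connected component?
#' @return A `triangle_mesh` (without normals; see
#'   [compute_vertex_normals()]).
#' @export
extract_mesh <- function(smoothed, iso_level = 0.5,
                         largest_component = TRUE) {
  rng <- range(smoothed$data)
  if (rng[1] >= iso_level || rng[2] <= iso_level) {
    stop("empty surface: volume does not straddle iso_level ", iso_level)
  }
  res <- .march_tets(as.numeric(smoothed$data), dim(smoothed$data),
                     iso_level)
  verts <- voxel_to_world(smoothed, res$vertices)
  mesh <- triangle_mesh(verts, res$faces)
  if (largest_component) mesh <- keep_largest_component(mesh)
  mesh
}

# union-find over vertices connected by faces; keep the component with most
# faces
keep_largest_component <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a; parent[find(c)] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  face_root <- roots[f[, 1]]
  keep_root <- as.integer(names(which.max(table(face_root))))
  keep_faces <- f[face_root == keep_root, , drop = FALSE]
  used <- sort(unique(as.vector(keep_faces)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[keep_faces], ncol = 3))
}

# non-normalised face normals (cross products; length = 2 * area) and face
# areas
face_normals_raw <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Compute outward vertex normals
#'
#' Per-vertex normals are area-weighted averages of incident face normals,
#' normalised to unit length, then globally oriented to point away from an
#' interior reference point (e.g. the WM mask centroid), so the orientation
#' does not depend on face winding.
#'
#' @param mesh a `triangle_mesh`.
#' @param reference_inside_point world point (mm) inside the surface.
#' @return The mesh with a `vertex_normals` field.
#' @export
compute_vertex_normals <- function(mesh, reference_inside_point) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  fn <- face_normals_raw(mesh)
  area2 <- sqrt(rowSums(fn^2))
  degen <- area2 < 1e-12
  if (any(degen)) {
    warning(sum(degen), " degenerate (zero-area) faces skipped")
    fn <- fn[!degen, , drop = FALSE]
    faces <- mesh$faces[!degen, , drop = FALSE]
  } else {
    faces <- mesh$faces
  }
  n <- nrow(mesh$vertices)
  # area-weighted accumulation: cross products already carry the area weight
  vn <- matrix(0, n, 3)
  for (cidx in 1:3) {
    idx <- faces[, cidx]
    for (d in 1:3) {
      acc <- rowsum(fn[, d], idx)
      vn[as.integer(rownames(acc)), d] <-
        vn[as.integer(rownames(acc)), d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len
  ref <- matrix(rep(as.numeric(reference_inside_point), each = n), ncol = 3)
  outward <- mesh$vertices - ref
  s <- sign(mean(rowSums(vn * outward)))
  if (s == 0) s <- 1
  mesh$vertex_normals <- vn * s
  mesh
}

#' Check that every edge is shared by exactly two faces
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` if watertight.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Total surface area of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(sqrt(rowSums(face_normals_raw(mesh)^2))) / 2
}

#' Extract a boundary mesh from a binary mask
#'
#' Convenience wrapper: [smooth_mask()] then [extract_mesh()] then
#' [compute_vertex_normals()] with the mask centroid as the interior
#' reference.
#'
#' @param mask binary `lb_volume`.
#' @param sd_vox mask smoothing SD in voxels (default 0.8).
#' @param iso_level isosurface level (default 0.5).
#' @param invert orient normals with the mask's complement as interior
#'   (used for the CSF mask, whose "inside" is the brain, not the CSF).
#' @return A `triangle_mesh` with outward unit normals.
#' @export
mask_to_mesh <- function(mask, sd_vox = 0.8, iso_level = 0.5,
                         invert = FALSE) {
  sm <- smooth_mask(mask, sd_vox)
  mesh <- extract_mesh(sm, iso_level)
  idx <- which(mask$data == (if (invert) 0 else 1))
  d <- dim(mask$data)
  ijk <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  centroid <- colMeans(voxel_to_world(mask, ijk))
  compute_vertex_normals(mesh, centroid)
}
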