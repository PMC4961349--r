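#' Construct a volume
#'
#' A `lb_volume` is the package's 3-D image container: a numeric array plus a
#' 4x4 voxel-to-world affine. Voxel indices are 0-based in the affine
#' convention (world = affine %*% c(i, j, k, 1) for the centre of voxel
#' `data[i+1, j+1, k+1]`), matching the NIfTI convention.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm). If `NULL`, built from
#'   `voxel_mm` and `origin`.
#' @param voxel_mm isotropic voxel size in mm (used when `affine` is `NULL`).
#' @param origin world coordinate (mm) of voxel (0,0,0); default places the
#'   grid centre at the world origin.
#' @return An object of class `lb_volume`.
#' @export
lb_volume <- function(data, affine = NULL, voxel_mm = NULL, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(affine)) {
    if (is.null(voxel_mm)) stop("supply either `affine` or `voxel_mm`")
    if (is.null(origin)) origin <- -voxel_mm * (dim(data) - 1) / 2
    affine <- diag(c(rep(voxel_mm, 3), 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("affine is not invertible")
  }
  structure(list(data = data, affine = affine), class = "lb_volume")
}

#' @export
print.lb_volume <- function(x, ...) {
  sp <- voxel_spacing(x)
  cat(sprintf("<lb_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(sp, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.lb_volume <- function(x) dim(x$data)

#' Voxel spacing of a volume
#'
#' Length in mm of each voxel edge, taken as the column norms of the affine's
#' rotation/scaling block.
#'
#' @param v an `lb_volume`.
#' @return Numeric length-3 vector (mm).
#' @export
voxel_spacing <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param v an `lb_volume`.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(v, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk %*% t(v$affine[1:3, 1:3]), 2, v$affine[1:3, 4], `+`)
}

#' Map world coordinates to 0-based (fractional) voxel indices
#'
#' @param v an `lb_volume`.
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  inv <- solve(v$affine)
  sweep(xyz, 2, v$affine[1:3, 4], `-`) %*% t(inv[1:3, 1:3])
}

#' World coordinates of every voxel centre
#'
#' @param v an `lb_volume`.
#' @return (prod(dim) x 3) matrix, rows in R array order.
#' @export
voxel_centre_grid <- function(v) {
  d <- dim(v$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  voxel_to_world(v, ijk)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `lb_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  aff <- matrix(c(RNifti::xform(img)), 4, 4)
  arr <- array(as.numeric(img), dim = dim(img))
  lb_volume(arr, affine = aff)
}

#' Write a volume as NIfTI
#'
#' @param v an `lb_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data, pixdim = voxel_spacing(v))
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Gaussian blur along one array axis, sd in voxels, edge replication.
blur_axis <- function(arr, sd_vox, axis) {
  if (sd_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sd_vox))
  w <- stats::dnorm(seq(-r, r), sd = sd_vox)
  w <- w / sum(w)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  n <- d[1]
  out <- matrix(0, n, ncol(m))
  for (k in seq(-r, r)) {
    idx <- pmin(pmax(seq_len(n) + k, 1L), n)
    out <- out + w[k + r + 1] * m[idx, , drop = FALSE]
  }
  a <- array(out, dim = d)
  aperm(a, order(perm))
}

# Separable Gaussian blur with per-axis sd given in voxels.
blur_voxels <- function(arr, sd_vox) {
  sd_vox <- rep_len(sd_vox, 3)
  for (ax in 1:3) arr <- blur_axis(arr, sd_vox[ax], ax)
  arr
}

#' Gaussian blur with FWHM in millimetres
#'
#' Applies a separable Gaussian filter with
#' `sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))` per axis, converting sigma to
#' voxels using each axis's spacing. Boundaries are handled by edge
#' replication so that edge voxels are not darkened.
#'
#' @param v an `lb_volume`.
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @return A blurred `lb_volume` on the same grid.
#' @export
gaussian_blur_fwhm <- function(v, fwhm_mm) {
  stopifnot(fwhm_mm > 0)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sd_vox <- sigma_mm / voxel_spacing(v)
  lb_volume(blur_voxels(v$data, sd_vox), affine = v$affine)
}

#' Resample a volume onto another volume's grid
#'
#' Values are interpolated from `src` at the world coordinates of `target`'s
#' voxel centres. Points outside `src`'s support take the nearest edge value
#' (coordinates are clamped to the source grid).
#'
#' @param src source `lb_volume`.
#' @param target `lb_volume` defining the output grid and affine.
#' @param order interpolation order: 0 (nearest neighbour) or 1 (trilinear).
#' @return An `lb_volume` on `target`'s grid.
#' @export
resample_to_grid <- function(src, target, order = 1L) {
  stopifnot(order %in% c(0L, 1L))
  xyz <- voxel_centre_grid(target)
  vox <- world_to_voxel(src, xyz)
  d <- dim(src$data)
  vox[, 1] <- pmin(pmax(vox[, 1], 0), d[1] - 1)
  vox[, 2] <- pmin(pmax(vox[, 2], 0), d[2] - 1)
  vox[, 3] <- pmin(pmax(vox[, 3], 0), d[3] - 1)
  if (order == 0L) {
    idx <- nearest_voxel_index(vox, d)
    vals <- src$data[idx]
  } else {
    f <- floor(vox)
    f[, 1] <- pmin(f[, 1], d[1] - 2); f[, 2] <- pmin(f[, 2], d[2] - 2)
    f[, 3] <- pmin(f[, 3], d[3] - 2)
    f <- pmax(f, 0)
    t1 <- vox - f
    vals <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) t1[, 1] else 1 - t1[, 1]) *
           (if (dy) t1[, 2] else 1 - t1[, 2]) *
           (if (dz) t1[, 3] else 1 - t1[, 3])
      idx <- cbind(f[, 1] + dx, f[, 2] + dy, f[, 3] + dz) + 1
      vals <- vals + w * src$data[idx]
    }
  }
  lb_volume(array(vals, dim = dim(target$data)), affine = target$affine)
}

# Nearest-voxel 1-based index matrix from fractional 0-based coordinates.
# Exact half-coordinates are broken toward the lower index.
nearest_voxel_index <- function(vox, d) {
  idx <- ceiling(vox - 0.5)
  idx[, 1] <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  idx[, 2] <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  idx[, 3] <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  idx + 1
}
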