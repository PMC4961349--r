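#' Write / read a triangle mesh as ASCII PLY
#'
#' Stores vertices (with normals when present) and faces in the standard
#' polygon file format readable by common mesh viewers.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output `.ply` path.
#' @return `path` (write) or a `triangle_mesh` (read).
#' @export
write_mesh_ply <- function(mesh, path) {
  has_n <- !is.null(mesh$vertex_normals)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (has_n) hdr <- c(hdr, "property float nx", "property float ny",
                      "property float nz")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vm <- if (has_n) cbind(mesh$vertices, mesh$vertex_normals)
        else mesh$vertices
  vlines <- apply(vm, 1, function(r) paste(format(r, digits = 9),
                                           collapse = " "))
  flines <- apply(mesh$faces - 1L, 1,
                  function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("malformed PLY (no end_header): ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  has_n <- any(grepl("property float nx", hdr))
  vlines <- lines[end + seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  flines <- lines[end + nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), as.integer))
  mesh <- triangle_mesh(vm[, 1:3, drop = FALSE],
                        fm[, 2:4, drop = FALSE] + 1L)
  if (has_n) mesh$vertex_normals <- vm[, 4:6, drop = FALSE]
  mesh
}

#' Write a mesh as plain vertices/faces text files
#'
#' Writes `<stem>_vertices.txt` (x y z per line) and `<stem>_faces.txt`
#' (1-based i j k per line).
#'
#' @param mesh a `triangle_mesh`.
#' @param stem path stem.
#' @return `stem`, invisibly.
#' @export
write_mesh_txt <- function(mesh, stem) {
  utils::write.table(mesh$vertices, paste0(stem, "_vertices.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mesh$faces, paste0(stem, "_faces.txt"),
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}
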