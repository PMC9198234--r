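#' Write a surface mesh as ASCII STL
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param name Solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "femurfe") {
  v <- mesh$vertices; fc <- mesh$faces
  a <- v[fc[, 2], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  b <- v[fc[, 3], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- paste0(
    "facet normal %.6e %.6e %.6e\n outer loop\n",
    "  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n",
    "  vertex %.6e %.6e %.6e\n endloop\nendfacet")
  lines <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                   v[fc[, 1], 1], v[fc[, 1], 2], v[fc[, 1], 3],
                   v[fc[, 2], 1], v[fc[, 2], 2], v[fc[, 2], 3],
                   v[fc[, 3], 1], v[fc[, 3], 2], v[fc[, 3], 3])
  writeLines(lines, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' @param path Path to an ASCII STL file.
#' @return A [surface_mesh()] (vertices deduplicated exactly).
#' @export
read_stl <- function(path) {
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- xyz[match(uk, key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a tetrahedral mesh with result fields as legacy ASCII VTK
#'
#' Point data: displacement vectors; cell data: von Mises stress, pressure
#' and effective Lagrange strain, when a result is supplied.
#'
#' @param mesh A [tet_mesh()].
#' @param path Output path (`.vtk`).
#' @param result Optional [compute_element_fields()] result.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, result = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nd <- mesh$nodes; el <- mesh$elements
  writeLines(c("# vtk DataFile Version 3.0", "femurfe tetrahedral model",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.9g %.9g %.9g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * 5L), con)
  writeLines(sprintf("4 %d %d %d %d", el[, 1] - 1L, el[, 2] - 1L,
                     el[, 3] - 1L, el[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep("10", nrow(el)), con)
  if (!is.null(result)) {
    U <- result$nodal_displacements
    writeLines(c(sprintf("POINT_DATA %d", nrow(nd)),
                 "VECTORS displacement double"), con)
    writeLines(sprintf("%.9g %.9g %.9g", U[, 1], U[, 2], U[, 3]), con)
    writeLines(c(sprintf("CELL_DATA %d", nrow(el)),
                 "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", result$element_von_mises), con)
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", result$element_pressure), con)
    writeLines(c("SCALARS effective_strain double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", result$element_effective_strain), con)
  }
  invisible(path)
}

#' Write ground truth as NIfTI label volume plus JSON sidecar
#'
#' @param truth A `ground_truth` object.
#' @param spacing Voxel spacing of the mask, mm.
#' @param path_nii,path_json Output paths.
#' @return `path_nii`, invisibly.
#' @export
write_ground_truth <- function(truth, spacing, path_nii, path_json) {
  mask <- binary_mask(truth$bone_mask, spacing = spacing)
  write_nifti_volume(mask, path_nii)
  jsonlite::write_json(
    list(head_center = truth$head_center, head_radius = truth$head_radius,
         neck_axis = truth$neck_axis, junction_point = truth$junction_point,
         junction_normal = truth$junction_normal),
    path_json, auto_unbox = FALSE, digits = NA)
  invisible(path_nii)
}
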