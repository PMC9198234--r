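#' Crop a mask at the head-neck junction and orient it along +Z
#'
#' Removes voxels on the neck (inferior) side of the junction plane, rotates
#' the retained head so the plane normal (inferior to superior) aligns with
#' +Z, and resamples onto a grid at the original spacing by nearest-neighbor
#' lookup. In the output frame the junction plane sits at z = 0 and the first
#' voxel-center layer lies on it, so every retained voxel has z >= 0.
#'
#' @param mask A [binary_mask()].
#' @param junction_point,junction_normal Plane through the head-neck
#'   junction: a point on it (mm, world) and its unit normal pointing into
#'   the head.
#' @return A cropped, re-oriented [binary_mask()] (origin at the plane).
#' @export
crop_and_orient <- function(mask, junction_point, junction_normal) {
  stopifnot(inherits(mask, "binary_mask"))
  h <- mask$spacing
  n <- junction_normal / sqrt(sum(junction_normal^2))
  R <- rotation_between(n, c(0, 0, 1))
  d <- dim(mask$values)
  fg <- which(mask$values)
  if (length(fg) == 0L) {
    abort_femurfe("Cannot crop an empty mask.", "femurfe_empty_mask")
  }
  idx <- arrayInd(fg, d)
  X <- sweep((idx - 1) %*% diag(h), 2, mask$origin, `+`)
  Y <- sweep(X, 2, junction_point, `-`) %*% t(R)
  keep <- Y[, 3] >= -1e-9
  if (!any(keep)) {
    abort_femurfe("Cropping at the junction plane removed every bone voxel.",
                  "femurfe_empty_mask")
  }
  Yk <- Y[keep, , drop = FALSE]
  lo <- apply(Yk, 2, min); hi <- apply(Yk, 2, max)
  new_origin <- c(floor(lo[1] / h[1]) * h[1] - 2 * h[1],
                  floor(lo[2] / h[2]) * h[2] - 2 * h[2],
                  0)
  new_shape <- pmax(2L, as.integer(ceiling((hi - new_origin) / h)) + 3L)
  # resample: target voxel center -> source frame -> nearest voxel
  tx <- axis_coords(new_shape[1], new_origin[1], h[1])
  ty <- axis_coords(new_shape[2], new_origin[2], h[2])
  tz <- axis_coords(new_shape[3], new_origin[3], h[3])
  TXI <- as.matrix(expand.grid(x = tx, y = ty, z = tz))
  SRC <- TXI %*% R   # R^T applied from the right: (R^T y)^T = y^T R
  SRC <- sweep(SRC, 2, junction_point, `+`)
  si <- round(sweep(SRC, 2, mask$origin, `-`) %*% diag(1 / h)) + 1
  ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 & si[, 2] <= d[2] &
    si[, 3] >= 1 & si[, 3] <= d[3] & TXI[, 3] >= -1e-9
  vals <- rep(FALSE, nrow(si))
  lin <- (si[ok, 3] - 1) * d[1] * d[2] + (si[ok, 2] - 1) * d[1] + si[ok, 1]
  vals[ok] <- mask$values[lin]
  out <- array(vals, new_shape)
  if (!any(out)) {
    abort_femurfe("Cropping at the junction plane removed every bone voxel.",
                  "femurfe_empty_mask")
  }
  binary_mask(out, spacing = h, origin = new_origin,
              provenance = c(mask$provenance, list(cropped = TRUE)))
}

#' Tetrahedral solid mesh
#'
#' @param nodes Numeric matrix (N x 3), mm.
#' @param elements Integer matrix (M x 4), 1-based node indices, positively
#'   oriented.
#' @param node_sets List with `inferior_fixed` (node index vector) and
#'   `proximal_load` (boundary face matrix, F x 3 node indices).
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, node_sets = list()) {
  structure(list(nodes = nodes, elements = elements, node_sets = node_sets),
            class = "tet_mesh")
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets, volume %.3f mm^3\n",
              nrow(x$nodes), nrow(x$elements), sum(tet_volumes(x))))
  if (length(x$node_sets)) {
    cat(sprintf("  node sets: %s\n", paste(
      sprintf("%s (%d)", names(x$node_sets),
              vapply(x$node_sets, NROW, 1L)), collapse = ", ")))
  }
  invisible(x)
}

#' Signed volumes of all tetrahedra
#' @param mesh A [tet_mesh()].
#' @return Numeric vector of element volumes (mm^3), positive by convention.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cc <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Convert a voxel mask to a tetrahedral mesh
#'
#' Each foreground voxel is split into 6 tetrahedra sharing the cube's main
#' diagonal, which guarantees face compatibility between neighboring voxels
#' and strictly positive element volumes; total mesh volume equals the voxel
#' volume exactly. Nodes sit on the voxel-corner lattice. Two boundary
#' selections are attached for the standardized load case: `inferior_fixed`
#' (all nodes on the minimal-z layer) and `proximal_load` (boundary faces
#' whose outward normal is within `load_cone_deg` of +Z and whose centroid
#' lies in the top `load_top_fraction` of the mesh z-extent).
#'
#' Only the largest face-connected (6-connected) voxel component is meshed:
#' voxels attached merely by an edge or corner would hinge freely under
#' face-sharing tetrahedra and make the stiffness singular.
#'
#' @param mask A [binary_mask()].
#' @param load_cone_deg Half-angle (degrees) of the +Z normal cone used to
#'   pick load faces.
#' @param load_top_fraction Fraction of the z-extent, from the top, in which
#'   load faces may lie.
#' @return A [tet_mesh()].
#' @export
tetrahedralize <- function(mask, load_cone_deg = 45, load_top_fraction = 0.2) {
  stopifnot(inherits(mask, "binary_mask"))
  vals <- mask$values
  if (!any(vals)) {
    abort_femurfe("Cannot tetrahedralize an empty mask.", "femurfe_empty_mask")
  }
  vals <- largest_component3d(vals, connectivity = 6L)
  d <- dim(vals)
  h <- mask$spacing
  fg <- which(vals)
  idx <- arrayInd(fg, d)                       # voxel (i,j,k), 1-based
  nd1 <- d[1] + 1L; nd12 <- nd1 * (d[2] + 1L)  # corner-lattice dims
  corner_id <- function(ii, jj, kk) (kk - 1) * nd12 + (jj - 1) * nd1 + ii
  # 8 corners in binary offset order (x fastest), matching cube_tets()
  offs <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  corners <- vapply(1:8, function(cc) {
    corner_id(idx[, 1] + offs[cc, 1], idx[, 2] + offs[cc, 2],
              idx[, 3] + offs[cc, 3])
  }, numeric(nrow(idx)))
  if (is.null(dim(corners))) corners <- matrix(corners, nrow = nrow(idx))
  tets <- cube_tets()
  nelem <- nrow(idx) * 6L
  EL <- matrix(0, nelem, 4)
  for (tt in 1:6) {
    EL[seq(tt, nelem, by = 6L), ] <- corners[, tets[tt, ], drop = FALSE]
  }
  used <- sort(unique(as.vector(EL)))
  remap_el <- matrix(match(EL, used), ncol = 4)
  # corner-lattice node (i,j,k) world position: voxel corner below voxel (i,j,k)
  lin0 <- used - 1
  ni <- lin0 %% nd1
  nj <- (lin0 %/% nd1) %% (d[2] + 1L)
  nk <- lin0 %/% nd12
  nodes <- cbind(mask$origin[1] + (ni - 0.5) * h[1],
                 mask$origin[2] + (nj - 0.5) * h[2],
                 mask$origin[3] + (nk - 0.5) * h[3])
  mesh <- tet_mesh(nodes, remap_el)
  vols <- tet_volumes(mesh)
  flip <- vols < 0
  if (any(flip)) {
    tmp <- mesh$elements[flip, 3]
    mesh$elements[flip, 3] <- mesh$elements[flip, 4]
    mesh$elements[flip, 4] <- tmp
  }
  if (any(tet_volumes(mesh) <= 0)) {
    abort_femurfe("Degenerate (non-positive volume) tetrahedron produced.",
                  "femurfe_mesh_error")
  }

  # node sets
  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  tol <- 1e-9 * max(1, abs(zmin))
  inferior_fixed <- which(nodes[, 3] <= zmin + h[3] * 1e-6 + tol)
  bf <- boundary_faces(mesh)
  n_z <- bf$normals[, 3] / sqrt(rowSums(bf$normals^2))
  zcut <- zmax - load_top_fraction * (zmax - zmin)
  sel <- n_z >= cos(load_cone_deg * pi / 180) & bf$centroids[, 3] >= zcut
  mesh$node_sets <- list(inferior_fixed = inferior_fixed,
                         proximal_load = bf$faces[sel, , drop = FALSE])
  mesh
}

# Boundary faces of a tet mesh: triangles appearing in exactly one element,
# oriented outward. Returns faces (node triples), outward normals (not
# normalized, magnitude 2*area) and centroids.
boundary_faces <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  opp <- c(el[, 4], el[, 3], el[, 2], el[, 1])
  srt <- cbind(pmin(faces[, 1], faces[, 2], faces[, 3]),
               pmax(faces[, 1], faces[, 2], faces[, 3]))
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - srt[, 1] - srt[, 2]
  key <- paste(srt[, 1], mid, srt[, 2])
  cnt <- table(key)
  bnd <- which(key %in% names(cnt)[cnt == 1L])
  faces <- faces[bnd, , drop = FALSE]
  opp <- opp[bnd]
  nd <- mesh$nodes
  a <- nd[faces[, 2], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  b <- nd[faces[, 3], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tov <- nd[opp, , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  inward <- rowSums(nrm * tov) > 0
  nrm[inward, ] <- -nrm[inward, , drop = FALSE]
  # flip vertex order too so stored faces are outward-oriented
  if (any(inward)) {
    tmp <- faces[inward, 2]
    faces[inward, 2] <- faces[inward, 3]
    faces[inward, 3] <- tmp
  }
  centroids <- (nd[faces[, 1], , drop = FALSE] + nd[faces[, 2], , drop = FALSE] +
                  nd[faces[, 3], , drop = FALSE]) / 3
  list(faces = faces, normals = nrm, centroids = centroids)
}
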