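#' Triangulated surface mesh
#'
#' @param vertices Numeric matrix (V x 3), mm coordinates.
#' @param faces Integer matrix (F x 3), 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

# The shared 6-tetrahedron decomposition of a unit cube (corners in binary
# offset order c0=(0,0,0) .. c7=(1,1,1)); all tets share the c0-c7 diagonal,
# which makes faces compatible between neighboring cubes. Used both for
# isosurfacing (marching tetrahedra) and solid meshing.
cube_tets <- function() {
  matrix(c(1, 2, 4, 8,
           1, 4, 3, 8,
           1, 3, 7, 8,
           1, 7, 5, 8,
           1, 5, 6, 8,
           1, 6, 2, 8), ncol = 4, byrow = TRUE)
}

# Marching-tetrahedra case table: for each 4-bit inside pattern, a list of
# triangles, each a 3 x 2 matrix of local corner index pairs (edges on which
# the isosurface vertex lies).
mt_case_table <- function() {
  tbl <- vector("list", 16L)
  for (cs in 1:14) {
    S <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
    O <- setdiff(1:4, S)
    if (length(S) == 1L || length(S) == 3L) {
      i <- if (length(S) == 1L) S else O
      oth <- setdiff(1:4, i)
      tbl[[cs + 1L]] <- list(cbind(rep(i, 3), oth))
    } else {
      a <- S[1]; b <- S[2]; cc <- O[1]; dd <- O[2]
      quad <- rbind(c(a, cc), c(a, dd), c(b, dd), c(b, cc))
      tbl[[cs + 1L]] <- list(quad[c(1, 2, 3), , drop = FALSE],
                             quad[c(1, 3, 4), , drop = FALSE])
    }
  }
  tbl
}

#' Extract an isosurface from a binary mask
#'
#' Builds a watertight triangulated isosurface of the voxel indicator field
#' at the 0.5 level, in world (mm) coordinates, by marching tetrahedra on the
#' same 6-tet cube decomposition used for solid meshing. By default the
#' indicator is first smoothed with a small Gaussian (in voxels) so the
#' surface tracks the underlying smooth anatomy rather than the voxel
#' staircase; if smoothing would erase the object entirely (tiny masks), the
#' raw indicator is used instead. The field is zero-padded so surfaces close
#' at the grid boundary.
#'
#' @param mask A [binary_mask()] (or 3D logical array with `spacing`).
#' @param smooth_sigma Gaussian pre-smoothing SD in voxels; 0 disables.
#' @param level Isosurface level in the indicator field.
#' @param spacing,origin Used only when `mask` is a bare array.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mask, smooth_sigma = 1, level = 0.5,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(mask, "binary_mask")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$values
  }
  if (!any(mask)) {
    abort_femurfe("Cannot extract a surface from an empty mask.",
                  "femurfe_empty_mask")
  }
  field <- array(as.numeric(mask), dim(mask))
  if (smooth_sigma > 0) {
    sm <- gaussian_smooth3d(field, smooth_sigma)
    if (max(sm) > level) field <- sm
  }
  d0 <- dim(field)
  d <- d0 + 2L
  f <- array(0, d)
  f[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)] <- field
  # padded grid node (i,j,k) sits at world origin + (i-2)*spacing
  inside <- f > level

  # corner linear-index offsets of a cell at (i,j,k): binary order
  nx <- d[1]; nxy <- d[1] * d[2]
  corner_off <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)
  ci <- seq_len(d[1] - 1L); cj <- seq_len(d[2] - 1L); ck <- seq_len(d[3] - 1L)
  base <- as.vector(outer(outer(ci, (cj - 1L) * nx, `+`), (ck - 1L) * nxy, `+`))
  # active cells: mixed inside/outside corners
  s <- integer(length(base))
  for (cc in 1:8) s <- s + inside[base + corner_off[cc]]
  act <- base[s > 0L & s < 8L]
  if (length(act) == 0L) {
    abort_femurfe("Isosurface is empty at this level.", "femurfe_empty_mask")
  }
  G <- vapply(1:8, function(cc) act + corner_off[cc], numeric(length(act)))
  if (is.null(dim(G))) G <- matrix(G, nrow = length(act))
  FV <- matrix(f[G], nrow = length(act))
  IN <- matrix(inside[G], nrow = length(act))

  tets <- cube_tets()
  case_tbl <- mt_case_table()
  verts_from_edges <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- lo * (nxy * d[3] + 1) + hi
    uk <- unique(key)
    idx <- match(key, uk)
    ulo <- lo[match(uk, key)]; uhi <- hi[match(uk, key)]
    tfrac <- (level - f[ulo]) / (f[uhi] - f[ulo])
    coord <- function(lin) {
      lin0 <- lin - 1
      i <- lin0 %% nx; j <- (lin0 %/% nx) %% d[2]; k <- lin0 %/% nxy
      cbind(origin[1] + (i - 1) * spacing[1],
            origin[2] + (j - 1) * spacing[2],
            origin[3] + (k - 1) * spacing[3])
    }
    P1 <- coord(ulo); P2 <- coord(uhi)
    V <- P1 + tfrac * (P2 - P1)
    list(vertices = V, index = idx)
  }

  # Emit triangles: three edge-vertices per triangle, vectorized per
  # (tet type, case) group.
  A1 <- numeric(0); B1 <- numeric(0)
  A2 <- numeric(0); B2 <- numeric(0)
  A3 <- numeric(0); B3 <- numeric(0)
  for (tt in seq_len(nrow(tets))) {
    loc <- tets[tt, ]
    bits <- IN[, loc[1]] + 2L * IN[, loc[2]] + 4L * IN[, loc[3]] +
      8L * IN[, loc[4]]
    for (cs in 1:14) {
      rows <- which(bits == cs)
      if (length(rows) == 0L) next
      for (tri in case_tbl[[cs + 1L]]) {
        A1 <- c(A1, G[rows, loc[tri[1, 1]]]); B1 <- c(B1, G[rows, loc[tri[1, 2]]])
        A2 <- c(A2, G[rows, loc[tri[2, 1]]]); B2 <- c(B2, G[rows, loc[tri[2, 2]]])
        A3 <- c(A3, G[rows, loc[tri[3, 1]]]); B3 <- c(B3, G[rows, loc[tri[3, 2]]])
      }
    }
  }
  ntri <- length(A1)
  ve <- verts_from_edges(c(A1, A2, A3), c(B1, B2, B3))
  faces <- cbind(ve$index[seq_len(ntri)],
                 ve$index[ntri + seq_len(ntri)],
                 ve$index[2L * ntri + seq_len(ntri)])
  # drop degenerate triangles (repeated vertex index)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  surface_mesh(ve$vertices, faces[keep, , drop = FALSE])
}

#' Total surface area of a mesh
#' @param mesh A [surface_mesh()].
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; fc <- mesh$faces
  a <- v[fc[, 2], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  b <- v[fc[, 3], , drop = FALSE] - v[fc[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Undirected edge list (2-column matrix of vertex indices, lo < hi) with
# multiplicity.
mesh_edge_keys <- function(faces, n_vert) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  lo * (n_vert + 1) + hi
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh A [surface_mesh()].
#' @return Integer; 2 for a topological sphere.
#' @export
euler_characteristic <- function(mesh) {
  keys <- mesh_edge_keys(mesh$faces, nrow(mesh$vertices))
  nrow(mesh$vertices) - length(unique(keys)) + nrow(mesh$faces)
}

#' Is a mesh watertight?
#'
#' A closed 2-manifold has every edge shared by exactly two faces.
#' @param mesh A [surface_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  keys <- mesh_edge_keys(mesh$faces, nrow(mesh$vertices))
  all(table(keys) == 2L)
}
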