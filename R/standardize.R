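#' Standardize a surface mesh
#'
#' Mirrors the data-standardization stage applied to segmented bone surfaces:
#' removes exact duplicate faces and degenerate triangles, keeps only the
#' largest connected component (isolated-piece removal), closes boundary
#' loops by centroid-fan triangulation (hole closure), drops unreferenced
#' vertices, and finally applies shrink-free Taubin smoothing. Topology is
#' stable under repeated application: running the function on an
#' already-clean watertight mesh changes neither the vertex nor the face
#' count.
#'
#' @param mesh A [surface_mesh()].
#' @param taubin_iter Number of Taubin smoothing passes (0 disables).
#' @param lambda,mu Taubin shrink/expand factors.
#' @return A standardized [surface_mesh()].
#' @export
standardize_surface <- function(mesh, taubin_iter = 10L,
                                lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  fc <- mesh$faces
  if (nrow(fc) == 0L) {
    abort_femurfe("Mesh has no faces.", "femurfe_empty_mesh")
  }
  # degenerate faces out
  keep <- fc[, 1] != fc[, 2] & fc[, 2] != fc[, 3] & fc[, 1] != fc[, 3]
  fc <- fc[keep, , drop = FALSE]
  if (nrow(fc) == 0L) {
    abort_femurfe("All faces are degenerate.", "femurfe_empty_mesh")
  }
  # duplicate faces: identical vertex sets regardless of orientation
  sorted <- t(apply(fc, 1, sort))
  fc <- fc[!duplicated(sorted), , drop = FALSE]

  # largest connected component via the vertex-sharing graph
  edges <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(1, 3)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  fc <- fc[comp$membership[fc[, 1]] == big, , drop = FALSE]

  # hole closure: boundary edges are those used once; triangulate each loop
  # by a fan from its centroid
  repeat {
    keys <- mesh_edge_keys(fc, nrow(v))
    tab <- table(keys)
    bkeys <- as.numeric(names(tab)[tab == 1L])
    if (length(bkeys) == 0L) break
    hi <- bkeys %% (nrow(v) + 1); lo <- (bkeys - hi) / (nrow(v) + 1)
    loops <- trace_loops(cbind(lo, hi))
    if (length(loops) == 0L) break
    for (loop in loops) {
      centroid <- colMeans(v[loop, , drop = FALSE])
      v <- rbind(v, centroid)
      cidx <- nrow(v)
      nl <- length(loop)
      newf <- cbind(loop, loop[c(2:nl, 1)], cidx)
      fc <- rbind(fc, newf)
    }
    break
  }

  # drop unreferenced vertices
  used <- sort(unique(as.vector(fc)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  fc <- matrix(remap[fc], ncol = 3)

  if (taubin_iter > 0L) {
    v <- taubin_smooth(v, fc, taubin_iter, lambda, mu)
  }
  surface_mesh(v, fc)
}

# Order boundary edges into closed loops (list of vertex index cycles).
trace_loops <- function(bedges) {
  if (nrow(bedges) == 0L) return(list())
  adj <- list()
  addv <- function(a, b) {
    key <- as.character(a)
    adj[[key]] <<- c(adj[[key]], b)
  }
  for (r in seq_len(nrow(bedges))) {
    addv(bedges[r, 1], bedges[r, 2])
    addv(bedges[r, 2], bedges[r, 1])
  }
  unused <- rep(TRUE, nrow(bedges))
  ekey <- paste(pmin(bedges[, 1], bedges[, 2]),
                pmax(bedges[, 1], bedges[, 2]))
  loops <- list()
  for (r in seq_len(nrow(bedges))) {
    if (!unused[r]) next
    start <- bedges[r, 1]
    loop <- c(start)
    cur <- bedges[r, 2]
    unused[r] <- FALSE
    ok <- TRUE
    while (cur != start) {
      loop <- c(loop, cur)
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA
      for (nb in nbrs) {
        k <- paste(min(cur, nb), max(cur, nb))
        m <- which(ekey == k & unused)
        if (length(m) > 0L) {
          unused[m[1]] <- FALSE
          nxt <- nb
          break
        }
      }
      if (is.na(nxt)) { ok <- FALSE; break }
      cur <- nxt
    }
    if (ok && length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Taubin lambda/mu smoothing with uniform (umbrella) weights.
taubin_smooth <- function(v, fc, iter, lambda, mu) {
  e <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(1, 3)],
             fc[, c(2, 1)], fc[, c(3, 2)], fc[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  A@x <- rep(1, length(A@x))   # collapse duplicate entries to weight 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  step <- function(x, w) {
    lap <- as.matrix(A %*% x) / deg - x
    x + w * lap
  }
  for (it in seq_len(iter)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  v
}
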